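# LOH / allelic-imbalance calling: exact binomial heterozygosity tests in
# control and case, normalized-fold categorization, modal smoothing.

.AI_CATEGORIES <- c("conserved_het", "copy_loss", "copy_neutral_loh",
                    "gain_1", "gain_2plus")

# Exact two-sided binomial p-value against proportion 0.5, vectorized.
.binom_het_p <- function(k, n) {
  mapply(function(k, n) {
    if (n == 0L) return(1)
    stats::binom.test(k, n, p = 0.5)$p.value
  }, k, n)
}

#' Test control positions for heterozygosity
#'
#' Exact two-sided binomial goodness-of-fit of the top-allele count against
#' proportion 0.5 of the top-two total. A position is accepted as bona fide
#' heterozygous when p >= `alpha`.
#'
#' @param candidates A `"het_candidates"` or `"het_table"` data.frame
#'   (columns `c1`/`c2` or `control_c1`/`control_c2`).
#' @param alpha Significance level below which heterozygosity is rejected
#'   (default 0.01).
#' @return The input with columns `control_p` and `control_het` appended.
#' @export
call_control_het <- function(candidates, alpha = 0.01) {
  c1 <- if ("control_c1" %in% names(candidates)) candidates$control_c1 else candidates$c1
  c2 <- if ("control_c2" %in% names(candidates)) candidates$control_c2 else candidates$c2
  p <- if (nrow(candidates)) .binom_het_p(c1, c1 + c2) else numeric()
  candidates$control_p <- p
  candidates$control_het <- p >= alpha
  candidates
}

#' Classify a normalized coverage fold into an AI category
#'
#' Fixed thresholds on the normalized case:control coverage fold of a
#' non-conserved position: <= 0.75 copy loss; (0.75, 1.25] copy-neutral LOH;
#' (1.25, 1.75] +1 copy gain; > 1.75 gain of two or more copies.
#'
#' @param fold Numeric vector of normalized coverage folds (>= 0).
#' @return Character vector of categories.
#' @export
classify_fold <- function(fold) {
  ifelse(fold <= 0.75, "copy_loss",
         ifelse(fold <= 1.25, "copy_neutral_loh",
                ifelse(fold <= 1.75, "gain_1", "gain_2plus")))
}

#' Call the case allelic status of control-heterozygous positions
#'
#' Re-runs the exact binomial test on the case's own top-two counts. If the
#' case still fits heterozygosity (p >= `alpha`), or its allelic ratio lies in
#' `het_band` (a guard against trivially significant rejections at very high
#' depth), the position is in conserved heterozygosity. Otherwise the total
#' case coverage is normalized by the whole-exome median case/control coverage
#' and the resulting fold against the control total is categorized with
#' [classify_fold()]. Positions whose case top-two bases differ from the
#' control pair are flagged `discordant` (possible somatic variant) and are
#' excluded from smoothing.
#'
#' @param het A `"het_table"` processed by [call_control_het()]; only rows
#'   with `control_het = TRUE` are classified.
#' @param case_stats,control_stats [exome_stats()] of the two samples.
#' @param alpha Case-side significance level (default 0.01).
#' @param het_band Allelic-ratio band treated as conserved regardless of p.
#' @return A `data.frame` of class `"ai_calls"`: the control-heterozygous
#'   rows with `case_p`, `case_allelic_ratio`, `fold`, `category`,
#'   `discordant` and `low_confidence` appended.
#' @export
call_case_status <- function(het, case_stats, control_stats, alpha = 0.01,
                             het_band = c(0.4, 0.6)) {
  if (!"control_het" %in% names(het))
    stop("run call_control_het() first")
  calls <- het[het$control_het, , drop = FALSE]
  rownames(calls) <- NULL
  n <- nrow(calls)
  if (n == 0L) {
    out <- cbind(calls, data.frame(case_p = numeric(), case_allelic_ratio = numeric(),
                                   fold = numeric(), category = character(),
                                   discordant = logical(), low_confidence = logical(),
                                   stringsAsFactors = FALSE))
    class(out) <- c("ai_calls", "data.frame")
    return(out)
  }
  total <- calls$case_c1 + calls$case_c2
  calls$case_p <- .binom_het_p(calls$case_c1, total)
  calls$case_allelic_ratio <- ifelse(total > 0, calls$case_c1 / total, NA_real_)
  ctl_total <- calls$control_c1 + calls$control_c2
  fold <- (total / case_stats$median_cov) /
    (ctl_total / control_stats$median_cov)
  calls$fold <- fold
  conserved <- calls$case_p >= alpha |
    (!is.na(calls$case_allelic_ratio) &
       calls$case_allelic_ratio >= het_band[1] &
       calls$case_allelic_ratio <= het_band[2])
  calls$category <- ifelse(conserved, "conserved_het", classify_fold(fold))
  calls$low_confidence <- total == 0L
  calls$category[total == 0L] <- "copy_loss"
  calls$fold[total == 0L] <- 0
  same_pair <- mapply(function(a, b, x, y) setequal(c(a, b), c(x, y)),
                      calls$control_a1, calls$control_a2,
                      calls$case_a1, calls$case_a2)
  calls$discordant <- !same_pair & total > 0L
  class(calls) <- c("ai_calls", "data.frame")
  calls
}

#' Smoothing parameters for AI calls
#'
#' @param window_size Odd number of consecutive het positions (>= 3) voting
#'   on each call.
#' @param enabled Logical switch; disabled smoothing is the identity.
#' @return A list of class `"smoothing_params"`.
#' @export
smoothing_params <- function(window_size = 5L, enabled = TRUE) {
  window_size <- as.integer(window_size)
  if (enabled && (window_size < 3L || window_size %% 2L == 0L))
    stop("window_size must be odd and >= 3 when smoothing is enabled")
  structure(list(window_size = window_size, enabled = enabled),
            class = "smoothing_params")
}

#' Sliding-window modal smoothing of AI calls
#'
#' Replaces each call's category by the modal category within a centered
#' window of `window_size` positions on the same chromosome (truncated at
#' chromosome ends). Useful on noisy data to delineate real LOH regions. The
#' raw category is retained in `category`; the smoothed one in
#' `smoothed_category`. Modal ties keep the raw category when it is among the
#' winners, otherwise take the first winner in the fixed category order.
#' Discordant positions do not vote and are passed through unchanged.
#'
#' @param calls An `"ai_calls"` table sorted by (chrom, pos).
#' @param params A [smoothing_params()].
#' @return The input with a `smoothed_category` column.
#' @export
smooth_calls <- function(calls, params = smoothing_params()) {
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  calls$smoothed_category <- calls$category
  if (!params$enabled || nrow(calls) == 0L) return(calls)
  half <- params$window_size %/% 2L
  for (chr in unique(calls$chrom)) {
    idx <- which(calls$chrom == chr & !calls$discordant)
    if (length(idx) < 2L) next
    for (k in seq_along(idx)) {
      lo <- max(1L, k - half)
      hi <- min(length(idx), k + half)
      cats <- calls$category[idx[lo:hi]]
      tab <- table(factor(cats, levels = .AI_CATEGORIES))
      winners <- names(tab)[tab == max(tab)]
      raw <- calls$category[idx[k]]
      calls$smoothed_category[idx[k]] <-
        if (raw %in% winners) raw else winners[1]
    }
  }
  calls
}

#' Full LOH/AI calling pipeline
#'
#' Control heterozygosity test, case re-test and categorization, optional
#' smoothing, in one call.
#'
#' @param het A `"het_table"` ([pair_case_counts()] or simulator output).
#' @param case_stats,control_stats [exome_stats()] of the two samples.
#' @param alpha_control,alpha_case Significance levels of the two binomial
#'   tests.
#' @param smoothing A [smoothing_params()].
#' @return An `"ai_calls"` table (see [call_case_status()]), smoothed.
#' @export
call_ai <- function(het, case_stats, control_stats,
                    alpha_control = 0.01, alpha_case = 0.01,
                    smoothing = smoothing_params(enabled = FALSE)) {
  het <- call_control_het(het, alpha = alpha_control)
  calls <- call_case_status(het, case_stats, control_stats, alpha = alpha_case)
  calls <- smooth_calls(calls, smoothing)
  attr(calls, "control_tested") <- het
  calls
}
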
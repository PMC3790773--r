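# Scoring of calls against simulated truth, and the window-correlation
# module used to compare two copy-number profiles.

#' Score CNA segments against simulated truth
#'
#' A truth event counts as detected when the union of same-direction called
#' exons overlapping it covers at least `min_overlap` of its exons. Calls
#' overlapping no truth event at all are false positives. Hypersegmentation
#' is counted when at least two disjoint calls are needed to satisfy a single
#' truth event (the union reaches `min_overlap` but no single call does).
#'
#' @param segments A `"cna_segments"` table ([call_cna()]).
#' @param truth_events Truth table from [simulate_exome()] (`chrom`,
#'   `first_exon`, `last_exon`, `direction`).
#' @param min_overlap Required overlap fraction (default 0.8).
#' @return A list of class `"eval_report"`: counts, `sensitivity`, `ppv`,
#'   `hypersegmented`, and a per-event table with overlap fractions.
#' @export
score_calls <- function(segments, truth_events, min_overlap = 0.8) {
  nt <- nrow(truth_events)
  per_event <- data.frame(truth_events,
                          overlap = numeric(nt) + if (nt) 0 else numeric(),
                          best_single = numeric(nt),
                          n_calls = integer(nt), detected = logical(nt),
                          stringsAsFactors = FALSE)
  seg_overlaps_truth <- rep(FALSE, nrow(segments))
  for (k in seq_len(nt)) {
    tf <- truth_events$first_exon[k]
    tl <- truth_events$last_exon[k]
    size <- tl - tf + 1L
    sel <- which(segments$chrom == truth_events$chrom[k] &
                   segments$first_exon <= tl & segments$last_exon >= tf)
    if (length(sel)) {
      same <- sel[segments$direction[sel] == truth_events$direction[k]]
      seg_overlaps_truth[sel] <- TRUE
      if (length(same)) {
        covered <- rep(FALSE, size)
        best <- 0
        for (s in same) {
          lo <- max(segments$first_exon[s], tf) - tf + 1L
          hi <- min(segments$last_exon[s], tl) - tf + 1L
          covered[lo:hi] <- TRUE
          best <- max(best, (hi - lo + 1L) / size)
        }
        per_event$overlap[k] <- mean(covered)
        per_event$best_single[k] <- best
        per_event$n_calls[k] <- length(same)
      }
    }
  }
  per_event$detected <- per_event$overlap >= min_overlap
  tp <- sum(per_event$detected)
  fp <- sum(!seg_overlaps_truth)
  hyper <- sum(per_event$detected & per_event$best_single < min_overlap &
                 per_event$n_calls >= 2L)
  structure(list(n_truth = nt, n_called = nrow(segments),
                 true_positives = tp, false_positives = fp,
                 sensitivity = if (nt) tp / nt else NA_real_,
                 ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
                 hypersegmented = hyper, per_event = per_event),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Truth events: %d  called: %d  TP: %d  FP: %d\n",
              x$n_truth, x$n_called, x$true_positives, x$false_positives))
  cat(sprintf("Sensitivity: %.1f%%  PPV: %.1f%%  hypersegmented: %d\n",
              100 * x$sensitivity, 100 * x$ppv, x$hypersegmented))
  invisible(x)
}

#' Score AI calls against simulated truth
#'
#' Computes the three determinants of AI recovery: (1) control het-calling
#' sensitivity inside CNA regions — the fraction of truth heterozygous
#' positions in events that pass the candidate rule and the control binomial
#' test; (2) AI-calling sensitivity — among truth-AI positions called
#' heterozygous in the control, the fraction called non-conserved in the
#' case; (3) categorization accuracy — among those called non-conserved, the
#' fraction assigned the truth category. Also reports in-region false
#' positives (truth-conserved positions called AI). Classes with no positions
#' are reported as `NA`.
#'
#' @param calls An `"ai_calls"` table from [call_ai()] (carries the full
#'   control-tested table as an attribute).
#' @param truth_het Truth table from [simulate_exome()].
#' @param min_candidate Candidate rule: minimum second-allele control count.
#' @return A list of class `"ai_eval"` with pooled and per-class metrics.
#' @export
score_ai_calls <- function(calls, truth_het, min_candidate = 5L) {
  het_all <- attr(calls, "control_tested")
  if (is.null(het_all))
    stop("calls must come from call_ai(), which records the control-tested table")
  key <- function(d) paste(d$chrom, d$pos)
  in_event <- !is.na(truth_het$event)
  truth_ev <- truth_het[in_event, , drop = FALSE]

  # (1) control het calling inside events
  m <- match(key(truth_ev), key(het_all))
  ctl_called <- !is.na(m) & het_all$control_c2[m] >= min_candidate &
    het_all$control_het[m]
  het_sens <- if (nrow(truth_ev)) mean(ctl_called) else NA_real_

  # (2) AI detection among control-called truth-AI positions
  mcall <- match(key(truth_ev), key(calls))
  called_cat <- ifelse(is.na(mcall), NA_character_, calls$category[mcall])
  eligible <- ctl_called & !is.na(called_cat)
  detected <- eligible & called_cat != "conserved_het"
  ai_sens <- if (any(eligible)) sum(detected) / sum(eligible) else NA_real_

  # (3) categorization among detected
  correct <- detected & called_cat == truth_ev$category
  cat_acc <- if (any(detected)) sum(correct) / sum(detected) else NA_real_

  per_class <- lapply(split(seq_len(nrow(truth_ev)), truth_ev$category),
                      function(ii) {
    el <- eligible[ii]
    de <- detected[ii]
    list(n = length(ii),
         het_sens = mean(ctl_called[ii]),
         ai_sens = if (any(el)) sum(de) / sum(el) else NA_real_,
         cat_acc = if (any(de)) sum(correct[ii]) / sum(de) else NA_real_)
  })

  # false positives: truth-conserved positions called AI
  truth_cons <- truth_het[!in_event, , drop = FALSE]
  mfp <- match(key(truth_cons), key(calls))
  fp <- sum(!is.na(mfp) & calls$category[mfp] != "conserved_het")

  structure(list(het_sensitivity = het_sens, ai_sensitivity = ai_sens,
                 categorization_accuracy = cat_acc, per_class = per_class,
                 false_positives = fp,
                 n_truth_ai = nrow(truth_ev),
                 n_control_called = sum(ctl_called),
                 n_detected = sum(detected), n_correct = sum(correct)),
            class = "ai_eval")
}

#' @export
print.ai_eval <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("Control het calling in events: %s (%d/%d positions)\n",
              pc(x$het_sensitivity), x$n_control_called, x$n_truth_ai))
  cat(sprintf("AI detection: %s  categorization: %s  in-region FP: %d\n",
              pc(x$ai_sensitivity), pc(x$categorization_accuracy),
              x$false_positives))
  invisible(x)
}

#' Pearson correlation of two windowed copy-number profiles
#'
#' Correlates case/control ratios of two analyses over identical genomic
#' windows (standard Pearson product-moment r). Chromosome Y windows are
#' excluded; windows missing from either table are dropped pairwise.
#'
#' @param table_a,table_b Data frames with columns `chrom`, `window` (any
#'   shared window identifier) and `ratio`.
#' @return The correlation coefficient.
#' @export
windowed_pearson <- function(table_a, table_b) {
  dropY <- function(d) d[!d$chrom %in% c("chrY", "Y", "hsY"), , drop = FALSE]
  a <- dropY(table_a)
  b <- dropY(table_b)
  m <- match(paste(a$chrom, a$window), paste(b$chrom, b$window))
  ok <- !is.na(m) & is.finite(a$ratio) & is.finite(b$ratio[m])
  if (sum(ok) < 3L)
    stop("need at least 3 complete window pairs for a correlation")
  stats::cor(a$ratio[ok], b$ratio[m[ok]])
}

#' Mean case/control ratios in fixed genomic windows
#'
#' Convenience builder for [windowed_pearson()]: averages the per-exon
#' CCF-smoothed ratio of a `"paired_coverage"` table in non-overlapping
#' windows of `width` bp.
#'
#' @param paired A `"paired_coverage"` table.
#' @param width Window width in bp.
#' @return A data frame with `chrom`, `window` (0-based window index) and
#'   `ratio`.
#' @export
windowed_ratios <- function(paired, width = 1e6) {
  keep <- !paired$excluded & is.finite(paired$ratio)
  d <- paired[keep, , drop = FALSE]
  win <- d$start %/% as.integer(width)
  agg <- stats::aggregate(d$ratio, by = list(chrom = d$chrom, window = win),
                          FUN = mean)
  names(agg)[3] <- "ratio"
  agg[order(agg$chrom, agg$window), , drop = FALSE]
}
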
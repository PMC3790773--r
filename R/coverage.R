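# Preprocessing stage: per-exon coverage summaries, exome-wide statistics and
# raw heterozygosity candidates. Output tables are the contract between the
# (slow) extraction stage and the (fast, re-runnable) calling stage.

#' Summarize per-position counts into per-exon coverage
#'
#' Computes, for every exon of the database, the mean per-base depth and the
#' population standard deviation of depth across all exon bases. Positions
#' missing from `counts` contribute depth 0; exons with no covered position
#' get mean 0, sd 0. Per-position depth is the sum of quality-passing A/C/G/T
#' calls. Positions outside any exon are ignored.
#'
#' @param counts A `"base_counts"` data.frame ([read_pileup()] /
#'   [read_alignments()]).
#' @param db An [read_exon_db()] database.
#' @return A `data.frame` of class `"exon_coverage"` with columns
#'   `exon_label`, `chrom`, `start`, `end`, `n_bases`, `mean_cov`, `cov_sd`.
#' @export
summarize_exons <- function(counts, db) {
  stopifnot(inherits(db, "exon_db"))
  n <- nrow(db)
  sums <- numeric(n)
  sqsums <- numeric(n)
  if (nrow(counts) > 0L) {
    depth <- counts$A + counts$C + counts$G + counts$T
    gr <- GenomicRanges::GRanges(counts$chrom,
                                 IRanges::IRanges(counts$pos, counts$pos))
    ex <- GenomicRanges::GRanges(db$chrom,
                                 IRanges::IRanges(db$start + 1L, db$end))
    hits <- GenomicRanges::findOverlaps(gr, ex)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh) > 0L) {
      s1 <- tapply(depth[qh], sh, sum)
      s2 <- tapply(depth[qh]^2, sh, sum)
      sums[as.integer(names(s1))] <- s1
      sqsums[as.integer(names(s2))] <- s2
    }
  }
  len <- db$end - db$start
  mean_cov <- sums / len
  v <- pmax(sqsums / len - mean_cov^2, 0)  # population variance over all bases
  out <- data.frame(exon_label = db$exon_label, chrom = db$chrom,
                    start = db$start, end = db$end, n_bases = len,
                    mean_cov = mean_cov, cov_sd = sqrt(v),
                    stringsAsFactors = FALSE)
  class(out) <- c("exon_coverage", "data.frame")
  out
}

#' Whole-exome coverage statistics
#'
#' Median and mean of the per-exon mean coverages. The median (robust to
#' outlier exons) is the normalization anchor used downstream; over an even
#' number of exons it is the mean of the two central values.
#'
#' @param covs An `"exon_coverage"` data.frame.
#' @return A list of class `"exome_stats"` with `median_cov` and `mean_cov`.
#' @export
exome_stats <- function(covs) {
  if (nrow(covs) == 0L)
    stop("cannot compute exome statistics from an empty coverage table")
  structure(list(median_cov = stats::median(covs$mean_cov),
                 mean_cov = mean(covs$mean_cov)),
            class = "exome_stats")
}

#' @export
print.exome_stats <- function(x, ...) {
  cat(sprintf("Exome coverage: median %.2f, mean %.2f\n",
              x$median_cov, x$mean_cov))
  invisible(x)
}

#' Raw heterozygosity candidates from control counts
#'
#' A position is a raw candidate when at least two distinct bases each reach
#' a fixed count of `min_count` (default 5) in the control. Only the two most
#' frequent bases are retained; ties are broken by the fixed base order
#' A < C < G < T for determinism.
#'
#' @param counts Control `"base_counts"` data.frame (exonic positions).
#' @param min_count Fixed per-base minimum count (default 5).
#' @return A `data.frame` of class `"het_candidates"` with columns `chrom`,
#'   `pos`, `a1`, `c1`, `a2`, `c2` (`c1 >= c2 >= min_count`).
#' @export
collect_het_candidates <- function(counts, min_count = 5L) {
  if (nrow(counts) == 0L)
    return(.empty_het_candidates())
  m <- as.matrix(counts[, c("A", "C", "G", "T")])
  top2 <- .top_two_bases(m)
  keep <- top2$c2 >= min_count
  out <- data.frame(chrom = counts$chrom[keep], pos = counts$pos[keep],
                    a1 = top2$a1[keep], c1 = top2$c1[keep],
                    a2 = top2$a2[keep], c2 = top2$c2[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("het_candidates", "data.frame")
  out
}

.empty_het_candidates <- function() {
  out <- data.frame(chrom = character(), pos = integer(),
                    a1 = character(), c1 = integer(),
                    a2 = character(), c2 = integer(), stringsAsFactors = FALSE)
  class(out) <- c("het_candidates", "data.frame")
  out
}

# Two most frequent bases per row of an A/C/G/T count matrix; ties broken by
# base order (max.col with ties.method = "first" on the fixed column order).
.top_two_bases <- function(m) {
  bases <- c("A", "C", "G", "T")
  i1 <- max.col(m, ties.method = "first")
  c1 <- m[cbind(seq_len(nrow(m)), i1)]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), i1)] <- -1L
  i2 <- max.col(m2, ties.method = "first")
  c2 <- m[cbind(seq_len(nrow(m)), i2)]
  list(a1 = bases[i1], c1 = as.integer(c1), a2 = bases[i2], c2 = as.integer(c2))
}

#' Attach case counts to control heterozygosity candidates
#'
#' For each control candidate the case's own two most frequent base counts at
#' the same position are recorded (the case pair may differ from the control
#' pair; downstream classification flags such discordant positions). Positions
#' uncovered in the case get zero counts and `case_covered = FALSE`.
#'
#' @param candidates A `"het_candidates"` data.frame (from the control).
#' @param case_counts Case `"base_counts"` data.frame.
#' @return A `data.frame` of class `"het_table"` pairing control and case
#'   top-two base counts per candidate position.
#' @export
pair_case_counts <- function(candidates, case_counts) {
  n <- nrow(candidates)
  out <- data.frame(candidates,
                    case_a1 = rep(NA_character_, n), case_c1 = rep(0L, n),
                    case_a2 = rep(NA_character_, n), case_c2 = rep(0L, n),
                    case_covered = rep(FALSE, n), stringsAsFactors = FALSE)
  names(out)[names(out) %in% c("a1", "c1", "a2", "c2")] <-
    c("control_a1", "control_c1", "control_a2", "control_c2")
  if (n > 0L && nrow(case_counts) > 0L) {
    idx <- match(paste(candidates$chrom, candidates$pos),
                 paste(case_counts$chrom, case_counts$pos))
    hit <- !is.na(idx)
    if (any(hit)) {
      m <- as.matrix(case_counts[idx[hit], c("A", "C", "G", "T")])
      top2 <- .top_two_bases(m)
      out$case_a1[hit] <- top2$a1
      out$case_c1[hit] <- top2$c1
      out$case_a2[hit] <- top2$a2
      out$case_c2[hit] <- top2$c2
      out$case_covered[hit] <- top2$c1 > 0L
    }
  }
  class(out) <- c("het_table", "data.frame")
  out
}

#' Case/control coverage report
#'
#' Summarizes both samples (median/mean coverage, binned per-exon coverage
#' histograms) and their median-coverage ratio, warning when the ratio leaves
#' `warn_range` — strong imbalance is handled by normalization but worth
#' surfacing.
#'
#' @param case_covs,control_covs `"exon_coverage"` tables.
#' @param warn_range Acceptable case:control median-coverage ratio range.
#' @return A list of class `"coverage_report"` with per-sample stats,
#'   histogram data (`graphics::hist` objects, not plotted), `median_ratio`
#'   and `imbalanced` flag.
#' @export
coverage_report <- function(case_covs, control_covs, warn_range = c(0.5, 2)) {
  case_stats <- exome_stats(case_covs)
  control_stats <- exome_stats(control_covs)
  ratio <- case_stats$median_cov / control_stats$median_cov
  imbalanced <- ratio < warn_range[1] || ratio > warn_range[2]
  if (imbalanced)
    warning(sprintf(
      "case/control median coverage ratio %.2f outside [%.2g, %.2g]; %s",
      ratio, warn_range[1], warn_range[2],
      "median normalization will be applied but calls may lose sensitivity"))
  structure(list(
    case_stats = case_stats, control_stats = control_stats,
    case_hist = graphics::hist(case_covs$mean_cov, breaks = "Sturges", plot = FALSE),
    control_hist = graphics::hist(control_covs$mean_cov, breaks = "Sturges", plot = FALSE),
    median_ratio = ratio, imbalanced = imbalanced),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Case   median/mean coverage: %.2f / %.2f\n",
              x$case_stats$median_cov, x$case_stats$mean_cov))
  cat(sprintf("Control median/mean coverage: %.2f / %.2f\n",
              x$control_stats$median_cov, x$control_stats$mean_cov))
  cat(sprintf("Median ratio (case:control): %.3f%s\n", x$median_ratio,
              if (x$imbalanced) "  [IMBALANCED]" else ""))
  invisible(x)
}
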
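# Replicated simulation benchmarks: simulate -> call -> score, pooled over
# seeds. These are the package's reference experiments; the acceptance
# script and the vignette run them.

#' Pooled CNA benchmark over simulation replicates
#'
#' Runs the full loop (simulate with a [sim_preset()], normalize, call with
#' a [resolve_preset()], score with the 80%-overlap rule) once per seed and
#' pools true/false positives across replicates.
#'
#' @param design A [sim_preset()] name.
#' @param seeds Integer vector; one replicate per seed.
#' @param preset Caller preset name; defaults to the size class matching the
#'   design's events.
#' @param ... Extra overrides passed to [sim_preset()].
#' @return A list: pooled `sensitivity`, `ppv` (both in \[0,1\]),
#'   `n_truth`, `n_called`, `true_positives`, `false_positives`,
#'   `hypersegmented`, and the per-replicate `reports`.
#' @export
cna_benchmark <- function(design, seeds,
                          preset = switch(design,
                                          t80 = , t8000 = "large",
                                          t10 = , T100H25 = , T25H100 = "small",
                                          t4 = , t3 = "very_small",
                                          "small"),
                          ...) {
  pars <- resolve_preset(preset)
  tp <- nt <- fp <- nc <- hyper <- 0L
  reports <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_exome(sim_preset(design, seed = seeds[i], ...))
    paired <- normalize_coverage(sim$case_covs, sim$control_covs,
                                 sim$case_stats, sim$control_stats, pars)
    segs <- call_cna(paired, pars)
    ev <- score_calls(segs, sim$truth_events)
    tp <- tp + ev$true_positives
    fp <- fp + ev$false_positives
    nt <- nt + ev$n_truth
    nc <- nc + ev$n_called
    hyper <- hyper + ev$hypersegmented
    reports[[i]] <- ev
  }
  list(sensitivity = tp / nt, ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
       n_truth = nt, n_called = nc, true_positives = tp,
       false_positives = fp, hypersegmented = hyper, reports = reports)
}

#' Pooled allelic-imbalance benchmark over simulation replicates
#'
#' Runs the `ai_sweep` design (three CNA regions of -1/+1/+2 copies carrying
#' 10/6/6 heterozygous positions at 100x) once per seed at the given
#' allelic-noise level and pools the three AI metrics.
#'
#' @param rnd_ai Allelic-noise amplitude.
#' @param seeds Integer vector; one replicate per seed.
#' @param alpha Significance level of both binomial tests.
#' @return A list: pooled `het_sensitivity`, `ai_sensitivity`,
#'   `categorization_accuracy` (in \[0,1\]), the pooled counts behind them,
#'   and in-region `false_positives`.
#' @export
ai_benchmark <- function(rnd_ai, seeds, alpha = 0.01) {
  n_truth <- n_called <- n_det <- n_corr <- fp <- 0L
  for (s in seeds) {
    sim <- simulate_exome(sim_preset("ai_sweep", seed = s, rnd_ai = rnd_ai))
    calls <- call_ai(sim$het, sim$case_stats, sim$control_stats,
                     alpha_control = alpha, alpha_case = alpha)
    sc <- score_ai_calls(calls, sim$truth_het)
    n_truth <- n_truth + sc$n_truth_ai
    n_called <- n_called + sc$n_control_called
    n_det <- n_det + sc$n_detected
    n_corr <- n_corr + sc$n_correct
    fp <- fp + sc$false_positives
  }
  list(het_sensitivity = n_called / n_truth,
       ai_sensitivity = n_det / n_called,
       categorization_accuracy = if (n_det) n_corr / n_det else NA_real_,
       n_truth = n_truth, n_control_called = n_called,
       n_detected = n_det, n_correct = n_corr, false_positives = fp)
}

#' Recover the copy-loss fold boundary by sweeping the classifier
#'
#' Builds non-conserved heterozygous positions with controlled normalized
#' coverage folds on a grid and reports the largest fold still categorized
#' as copy loss.
#'
#' @param folds Grid of fold values to probe.
#' @return The largest fold assigned to `"copy_loss"`.
#' @export
loss_boundary_sweep <- function(folds = seq(0.5, 1, by = 0.01)) {
  stats <- structure(list(median_cov = 100, mean_cov = 100),
                     class = "exome_stats")
  got <- vapply(folds, function(f) {
    total <- round(f * 100)
    het <- data.frame(chrom = "chr1", pos = 1L, control_a1 = "A",
                      control_c1 = 50L, control_a2 = "G", control_c2 = 50L,
                      case_a1 = "A", case_c1 = as.integer(total),
                      case_a2 = "G", case_c2 = 0L, case_covered = TRUE,
                      stringsAsFactors = FALSE)
    class(het) <- c("het_table", "data.frame")
    call_case_status(call_control_het(het), stats, stats)$category
  }, "")
  max(folds[got == "copy_loss"])
}
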
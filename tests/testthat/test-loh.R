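# LOH/AI calling: binomial het tests, fold categorization, smoothing.

het_row <- function(c1, c2, t1, t2, pos = 100L, chrom = "chr1",
                    case_bases = c("A", "G")) {
  out <- data.frame(chrom = chrom, pos = pos, control_a1 = "A",
                    control_c1 = as.integer(c1), control_a2 = "G",
                    control_c2 = as.integer(c2), case_a1 = case_bases[1],
                    case_c1 = as.integer(t1), case_a2 = case_bases[2],
                    case_c2 = as.integer(t2), case_covered = t1 + t2 > 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("het_table", "data.frame")
  out
}

stats100 <- structure(list(median_cov = 100, mean_cov = 100),
                      class = "exome_stats")

test_that("control heterozygosity test equals the exact binomial oracle", {
  cases <- rbind(c(50, 50), c(90, 10), c(60, 40), c(5, 5), c(12, 5),
                 c(200, 150), c(30, 7))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; m <- cases[i, 2]
    got <- call_control_het(het_row(k, m, 50, 50))$control_p
    expect_equal(got, oracle_binom_p(k, k + m), tolerance = 1e-12)
    # symmetric in the two alleles
    expect_equal(call_control_het(het_row(m, k, 50, 50))$control_p, got)
  }
  # the three reference points
  expect_equal(call_control_het(het_row(50, 50, 0, 0))$control_p, 1)
  r <- call_control_het(het_row(90, 10, 0, 0), alpha = 0.01)
  expect_lt(r$control_p, 1e-15)
  expect_false(r$control_het)
  r2 <- call_control_het(het_row(60, 40, 0, 0), alpha = 0.01)
  expect_equal(r2$control_p, 0.057, tolerance = 0.01)
  expect_true(r2$control_het)
})

test_that("case status: conserved heterozygosity vs categorized imbalance", {
  run1 <- function(c1, c2, t1, t2)
    call_case_status(call_control_het(het_row(c1, c2, t1, t2)),
                     stats100, stats100)
  expect_equal(run1(50, 50, 48, 52)$category, "conserved_het")
  r <- run1(50, 50, 50, 0)
  expect_equal(r$fold, 0.5)
  expect_equal(r$category, "copy_loss")
  r2 <- run1(50, 50, 100, 50)
  expect_lt(r2$case_p, 0.01)
  expect_equal(r2$fold, 1.5)
  expect_equal(r2$category, "gain_1")
  # zero case coverage: loss, flagged
  r3 <- run1(50, 50, 0, 0)
  expect_equal(r3$category, "copy_loss")
  expect_equal(r3$fold, 0)
  expect_true(r3$low_confidence)
  # the allelic-ratio guard band keeps huge-depth near-even positions
  r4 <- run1(50, 50, 5300, 4700)
  expect_lt(r4$case_p, 0.01)
  expect_equal(r4$category, "conserved_het")
})

test_that("median normalization enters the coverage fold", {
  s25 <- structure(list(median_cov = 25, mean_cov = 25), class = "exome_stats")
  # case exome at 25x, control at 100x; equal normalized depth -> fold 1
  r <- call_case_status(call_control_het(het_row(50, 50, 25, 0)),
                        s25, stats100)
  expect_equal(r$fold, 1)
  expect_equal(r$category, "copy_neutral_loh")
})

test_that("fold categories are exhaustive and mutually exclusive", {
  folds <- seq(0, 3, by = 0.01)
  cats <- classify_fold(folds)
  expect_true(all(cats %in% c("copy_loss", "copy_neutral_loh",
                              "gain_1", "gain_2plus")))
  # boundary membership: 0.75 is a loss, 1.25 copy-neutral, 1.75 gain_1
  expect_equal(classify_fold(c(0.75, 1.25, 1.75)),
               c("copy_loss", "copy_neutral_loh", "gain_1"))
  expect_equal(classify_fold(c(0.7500001, 1.2500001, 1.7500001)),
               c("copy_neutral_loh", "gain_1", "gain_2plus"))
  # monotone: category index never decreases with fold
  idx <- match(cats, c("copy_loss", "copy_neutral_loh", "gain_1", "gain_2plus"))
  expect_true(all(diff(idx) >= 0))
})

test_that("discordant case allele pairs are flagged", {
  het <- het_row(50, 50, 60, 40, case_bases = c("A", "T"))
  r <- call_case_status(call_control_het(het), stats100, stats100)
  expect_true(r$discordant)
  het2 <- het_row(50, 50, 60, 40, case_bases = c("G", "A"))
  expect_false(call_case_status(call_control_het(het2), stats100,
                                stats100)$discordant)
})

test_that("modal smoothing follows the window majority and respects flags", {
  mk_calls <- function(cats) {
    n <- length(cats)
    calls <- do.call(rbind, lapply(seq_len(n), function(i)
      het_row(50, 50, 50, 50, pos = i * 10L)))
    calls$category <- cats
    calls$discordant <- FALSE
    calls$case_allelic_ratio <- 0.5
    class(calls) <- c("ai_calls", "data.frame")
    calls
  }
  cats <- c("copy_loss", "copy_loss", "conserved_het", "copy_loss", "copy_loss")
  sm <- smooth_calls(mk_calls(cats), smoothing_params(window_size = 3))
  expect_equal(sm$smoothed_category[3], "copy_loss")
  expect_equal(sm$category[3], "conserved_het")   # raw retained
  # all identical: unchanged
  sm2 <- smooth_calls(mk_calls(rep("gain_1", 5)), smoothing_params(3))
  expect_equal(sm2$smoothed_category, rep("gain_1", 5))
  # disabled smoothing is the identity
  sm3 <- smooth_calls(mk_calls(cats), smoothing_params(enabled = FALSE))
  expect_equal(sm3$smoothed_category, cats)
  expect_error(smoothing_params(window_size = 4), "odd")
})

test_that("noise-free diploid simulation keeps every het position conserved", {
  cfg <- sim_preset("ai_sweep", seed = 5, rnd_ai = 0)
  cfg$events <- data.frame(chrom = character(), first_exon = integer(),
                           last_exon = integer(), delta = integer())
  cfg$het_per_event <- 0L
  sim <- simulate_exome(cfg)
  calls <- call_ai(sim$het, sim$case_stats, sim$control_stats,
                   alpha_control = 0.05, alpha_case = 0.05)
  expect_gt(nrow(calls), 10)
  expect_true(all(calls$category == "conserved_het"))
})
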
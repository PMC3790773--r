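# Simulator: noise equations, determinism, truth bookkeeping, scoring.

test_that("zero copy-number noise and no events give exact flat coverage", {
  cfg <- sim_config(c(chr1 = 50L), base_cov_case = 80, base_cov_control = 40,
                    rnd_cn = 0, p_cn1 = 0, count_noise = FALSE, seed = 3)
  sim <- simulate_exome(cfg)
  expect_true(all(sim$case_covs$mean_cov == 80))
  expect_true(all(sim$control_covs$mean_cov == 40))
  expect_equal(nrow(sim$truth_events), 0L)
})

test_that("zero allelic noise gives an exactly even allele split", {
  cfg <- sim_config(c(chr1 = 100L), rnd_cn = 0, p_cn1 = 0, rnd_ai = 0,
                    het_spacing = 10L, count_noise = FALSE, seed = 4)
  sim <- simulate_exome(cfg)
  expect_gt(nrow(sim$het), 0)
  expect_true(all(sim$het$case_c1 == 50L))
  expect_true(all(sim$het$case_c2 == 50L))
  expect_true(all(sim$het$control_c1 == 50L))
})

test_that("a fixed seed makes the simulation fully reproducible", {
  a <- simulate_exome(sim_preset("t80", seed = 123))
  b <- simulate_exome(sim_preset("t80", seed = 123))
  expect_identical(a$case_covs, b$case_covs)
  expect_identical(a$het, b$het)
  expect_identical(a$truth_events, b$truth_events)
  c2 <- simulate_exome(sim_preset("t80", seed = 124))
  expect_false(identical(a$case_covs, c2$case_covs))
})

test_that("copy-number noise respects the configured amplitude", {
  # CNobs = 2 + rnd_cn*(2U-1): coverage within base*(1 +/- rnd_cn/2) exactly
  cfg <- sim_config(c(chr1 = 2000L), rnd_cn = 0.4, p_cn1 = 0,
                    count_noise = FALSE, seed = 6)
  sim <- simulate_exome(cfg)
  r <- sim$case_covs$mean_cov / 100
  expect_true(all(r >= 1 - 0.2 & r <= 1 + 0.2))
  expect_gt(max(r), 1.15)      # the full range is actually used
  expect_lt(min(r), 0.85)
})

test_that("allelic noise bound and mean follow the configured amplitude", {
  cfg <- sim_config(c(chr1 = 4000L), rnd_cn = 0, p_cn1 = 0, rnd_ai = 0.2,
                    het_spacing = 2L, count_noise = FALSE, seed = 7)
  sim <- simulate_exome(cfg)
  # reconstruct the tracked-allele ("A") fraction from the ordered pairs
  faA <- ifelse(sim$het$case_a1 == "A", sim$het$case_c1, sim$het$case_c2) /
    (sim$het$case_c1 + sim$het$case_c2)
  expect_true(all(faA >= 0.5 - 0.2 - 0.01 & faA <= 0.5 + 0.2 + 0.01))
  expect_lt(abs(mean(faA) - 0.5), 3 * sd(faA) / sqrt(length(faA)) + 0.005)
  expect_gt(max(faA), 0.65)    # the configured range is exercised
  expect_lt(min(faA), 0.35)
})

test_that("case/control ratio over non-event exons concentrates at 1", {
  sim <- simulate_exome(sim_preset("t80", seed = 9))
  in_ev <- rep(FALSE, nrow(sim$case_covs))
  lab <- split(seq_len(nrow(sim$case_covs)), sim$case_covs$chrom)
  for (k in seq_len(nrow(sim$truth_events))) {
    ev <- sim$truth_events[k, ]
    in_ev[lab[[ev$chrom]][ev$first_exon:ev$last_exon]] <- TRUE
  }
  ratio <- sim$case_covs$mean_cov[!in_ev] / sim$control_covs$mean_cov[!in_ev]
  se <- sd(ratio) / sqrt(sum(!in_ev))
  # 0.01 allows the small Jensen bias of a ratio of counts
  expect_lt(abs(mean(ratio) - 1), 3 * se + 0.01)
})

test_that("event placement respects sizes, probabilities and non-overlap", {
  cfg <- sim_preset("t10", seed = 10)
  sim <- simulate_exome(cfg)
  ev <- sim$truth_events
  expect_true(all(ev$last_exon - ev$first_exon + 1L == 10L))
  expect_true(all(abs(ev$delta) == 1L))
  for (chr in unique(ev$chrom)) {
    e <- ev[ev$chrom == chr, ]
    o <- order(e$first_exon)
    if (nrow(e) > 1)
      expect_true(all(e$first_exon[o][-1] > e$last_exon[o][-nrow(e)]))
  }
  # explicit events that do not fit are rejected
  bad <- sim_preset("ai_sweep", seed = 1)
  bad$events$last_exon[3] <- 99999L
  expect_error(simulate_exome(bad), "beyond its chromosome")
})

test_that("region-overlap scoring implements the 80% rule", {
  truth <- data.frame(chrom = "chr1", first_exon = 1L, last_exon = 80L,
                      delta = 1L, direction = "gain", stringsAsFactors = FALSE)
  seg <- function(first, last, dir = "gain")
    data.frame(chrom = "chr1", start = 0L, end = 1L, first_exon = first,
               last_exon = last, n_exons = last - first + 1L, direction = dir,
               p_value = 1e-9, mean_log2 = if (dir == "gain") 0.5 else -0.5,
               stringsAsFactors = FALSE)
  # 5..84 covers 76/80 = 95%
  expect_equal(score_calls(seg(5, 84), truth)$true_positives, 1L)
  # 1..60 covers 75%: miss
  r <- score_calls(seg(1, 60), truth)
  expect_equal(r$true_positives, 0L)
  expect_equal(r$false_positives, 0L)   # overlapping a truth event: not FP
  # far-away call: false positive
  r2 <- score_calls(seg(500, 600), truth)
  expect_equal(r2$false_positives, 1L)
  expect_equal(r2$ppv, 0)
  # direction mismatch contributes no coverage
  expect_equal(score_calls(seg(5, 84, "loss"), truth)$true_positives, 0L)
  # two disjoint calls jointly covering 90%: detected but hypersegmented
  two <- rbind(seg(1, 40), seg(45, 76))
  r3 <- score_calls(two, truth)
  expect_equal(r3$true_positives, 1L)
  expect_equal(r3$hypersegmented, 1L)
  # perfect agreement
  r4 <- score_calls(seg(1, 80), truth)
  expect_equal(r4$sensitivity, 1)
  expect_equal(r4$ppv, 1)
  expect_equal(r4$hypersegmented, 0L)
})

test_that("windowed Pearson correlation matches closed forms", {
  tab <- function(r) data.frame(chrom = "chr1", window = seq_along(r), ratio = r)
  x <- c(0.8, 1, 1.3, 2, 0.5)
  expect_equal(windowed_pearson(tab(x), tab(2 * x)), 1)
  expect_equal(windowed_pearson(tab(x), tab(-x)), -1)
  # hand-computed: x = (1,2,4), y = (1,3,3) -> r = 24/sqrt(1008)
  expect_equal(windowed_pearson(tab(c(1, 2, 4)), tab(c(1, 3, 3))),
               24 / sqrt(1008))
  # chromosome Y excluded, missing windows dropped pairwise
  a <- rbind(tab(x), data.frame(chrom = "chrY", window = 1:2, ratio = c(9, 9)))
  b <- rbind(tab(2 * x)[1:4, ],
             data.frame(chrom = "chrY", window = 1:2, ratio = c(1, 2)))
  expect_equal(windowed_pearson(a, b), 1)
  expect_error(windowed_pearson(tab(x)[1:2, ], tab(x)[1:2, ]), "at least 3")
})

test_that("AI scoring separates het calling, detection and categorization", {
  sim <- simulate_exome(sim_preset("ai_sweep", seed = 2, rnd_ai = 0.05))
  expect_equal(nrow(sim$truth_het[!is.na(sim$truth_het$event), ]), 22L)
  calls <- call_ai(sim$het, sim$case_stats, sim$control_stats)
  sc <- score_ai_calls(calls, sim$truth_het)
  expect_gte(sc$het_sensitivity, 0.9)
  expect_gte(sc$ai_sensitivity, 0.9)
  expect_gte(sc$categorization_accuracy, 0.9)
  expect_equal(sc$false_positives, 0L)
  # truth categories per class present as modeled (10/6/6)
  expect_equal(vapply(sc$per_class, function(x) x$n, 0L)[
    c("copy_loss", "gain_1", "gain_2plus")],
    c(copy_loss = 10L, gain_1 = 6L, gain_2plus = 6L))
})
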
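# CNA caller: normalization, filters, seeding, expansion/merge, SDF, presets.

paired_from <- function(case, control, params = cna_params(ccf = 0,
                                                           coverage_floor = 0,
                                                           sdf = 0)) {
  db <- grid_exon_db(length(case))
  normalize_coverage(flat_coverage(db, 1) |> transform(mean_cov = case),
                     flat_coverage(db, 1) |> transform(mean_cov = control),
                     params = params)
}

test_that("median normalization removes global coverage imbalance", {
  p <- paired_from(rep(25, 20), rep(100, 20))
  expect_true(all(p$ratio == 1))
  expect_true(all(p$log2_ratio == 0))
  # identical samples: log2 exactly 0
  set.seed(1)
  v <- sample(50:150, 30, replace = TRUE)
  p2 <- paired_from(v, v)
  expect_true(all(p2$log2_ratio == 0))
  # CCF keeps zero-coverage exons finite
  p3 <- paired_from(c(0, rep(10, 9)), c(0, rep(10, 9)),
                    cna_params(ccf = 1, coverage_floor = 0, sdf = 0))
  expect_equal(p3$ratio[1], 1)
  expect_equal(p3$log2_ratio[1], 0)
  expect_error(paired_from(rep(0, 5), rep(1, 5)), "zero median")
})

test_that("exon filters exclude low-coverage and high-variability exons", {
  db <- grid_exon_db(4)
  case <- flat_coverage(db, 1)
  control <- flat_coverage(db, 1)
  case$mean_cov <- c(5, 80, 80, 80)
  control$mean_cov <- c(80, 80, 80, 80)
  case$cov_sd <- c(0, 0, 30, 0)
  case_stats <- exome_stats(case); control_stats <- exome_stats(control)
  pars <- cna_params(coverage_floor = 10, resdf = 1, ccf = 0, sdf = 0)
  p <- normalize_coverage(case, control, case_stats, control_stats, pars)
  expect_true(p$excluded[1])                   # below the floor in the case
  expect_equal(p$reason[1], "coverage_floor")
  expect_false(p$excluded[3])                  # relative SD 30/80 under resdf 1
  # tighten resdf below 0.375 to catch exon 3
  pars2 <- cna_params(coverage_floor = 0, resdf = 0.3, ccf = 0, sdf = 0)
  p2 <- normalize_coverage(case, control, case_stats, control_stats, pars2)
  expect_true(p2$excluded[3])
  expect_equal(p2$reason[3], "resdf")
  # everything off: nothing excluded
  pars3 <- cna_params(coverage_floor = 0, resdf = Inf, ccf = 0, sdf = 0)
  expect_false(any(normalize_coverage(case, control, case_stats,
                                      control_stats, pars3)$excluded))
})

test_that("seed scan finds gain windows tiling an amplified region", {
  set.seed(3)
  n <- 400
  control <- rnorm(n, 100, 3)
  case <- rnorm(n, 100, 3)                  # independent sampling noise
  case[161:240] <- 1.5 * case[161:240]      # 80-exon gain
  pars <- cna_params(window_size = 20, p_threshold = 1e-4, ccf = 0,
                     coverage_floor = 0, sdf = 0)
  p <- paired_from(case, control, pars)
  seeds <- find_seeds(p, pars)
  expect_gt(nrow(seeds), 0)
  expect_true(all(seeds$direction == "gain"))
  # every fully-inside window is a seed
  inside <- seeds$start_idx >= 161 & seeds$end_idx <= 240
  expect_equal(sum(inside), 240 - 20 - 161 + 2)
  # flat data: no seeds
  p0 <- paired_from(control, control, pars)
  expect_equal(nrow(find_seeds(p0, pars)), 0L)
})

test_that("a single deviant exon cannot seed a window", {
  control <- rep(100, 50)
  case <- control
  case[25] <- 300
  pars <- cna_params(window_size = 10, p_threshold = 0.01, ccf = 0,
                     coverage_floor = 0, sdf = 0)
  p <- paired_from(case, control, pars)
  # nine zero differences are discarded: N_r = 1, exact p = 1
  expect_equal(nrow(find_seeds(p, pars)), 0L)
})

test_that("expansion merges seeds across a gap and stops on rejection", {
  set.seed(8)
  n <- 120
  control <- rnorm(n, 100, 1)
  case <- control
  case[31:50] <- control[31:50] * 1.6
  case[52:71] <- control[52:71] * 1.6   # same direction, one-exon gap
  pars <- cna_params(window_size = 10, p_threshold = 5e-3, ccf = 0,
                     coverage_floor = 0, sdf = 0)
  p <- paired_from(case, control, pars)
  segs <- call_cna(p, pars)
  gains <- segs[segs$direction == "gain", ]
  expect_equal(nrow(gains), 1L)         # merged across the contiguous exons
  expect_lte(gains$first_exon, 31)
  expect_gte(gains$last_exon, 71)
  expect_lt(gains$p_value, pars$p_threshold)
})

test_that("segment lists are disjoint, significant, and deterministic", {
  set.seed(11)
  n <- 400
  control <- rnorm(n, 100, 4)
  case <- control * (1 + 0.04 * rnorm(n))
  case[101:160] <- control[101:160] * 0.5
  case[221:280] <- control[221:280] * 1.5
  pars <- cna_params(window_size = 10, p_threshold = 5e-3, ccf = 5,
                     coverage_floor = 0, sdf = 0)
  p <- paired_from(case, control, pars)
  segs <- call_cna(p, pars)
  expect_gte(nrow(segs), 2L)
  expect_true(all(segs$p_value < pars$p_threshold))
  o <- order(segs$first_exon)
  expect_true(all(diff(segs$first_exon[o]) > 0))
  expect_true(all(segs$last_exon[o][-nrow(segs)] < segs$first_exon[o][-1]))
  expect_true(all(segs$direction == ifelse(segs$mean_log2 > 0, "gain", "loss")))
  # determinism: same input, same output
  expect_identical(call_cna(p, pars), segs)
  # swapping case and control flips directions and negates log2 ratios
  pswap <- paired_from(control, case, pars)
  expect_equal(pswap$log2_ratio, -p$log2_ratio, tolerance = 1e-12)
  segs_swap <- call_cna(pswap, pars)
  m <- merge(segs, segs_swap, by = c("chrom", "first_exon", "last_exon"))
  expect_equal(nrow(m), nrow(segs))
  expect_true(all(m$direction.x != m$direction.y))
  expect_equal(m$p_value.x, m$p_value.y, tolerance = 1e-9)
})

test_that("the SDF filter removes segments below the chromosome noise scale", {
  set.seed(4)
  n <- 300
  control <- rep(100, n)
  case <- control * 2^rnorm(n, 0, 0.1)          # log2 sd ~ 0.1
  pars <- cna_params(window_size = 10, p_threshold = 5e-3, ccf = 0,
                     coverage_floor = 0, sdf = 0)
  p <- paired_from(case, control, pars)
  seg <- data.frame(chrom = "chr1", start = 0L, end = 100L, first_exon = 1L,
                    last_exon = 10L, n_exons = 10L, direction = "gain",
                    p_value = 1e-4, mean_log2 = 0.05, stringsAsFactors = FALSE)
  expect_equal(nrow(apply_sdf(seg, p, cna_params(sdf = 1))), 0L)
  expect_equal(nrow(apply_sdf(seg, p, cna_params(sdf = 0))), 1L)
  # a whole-chromosome single-copy loss survives any realistic noise scale
  seg$mean_log2 <- -1
  seg$direction <- "loss"
  expect_equal(nrow(apply_sdf(seg, p, cna_params(sdf = 1))), 1L)
})

test_that("presets resolve to coherent parameter sets", {
  vs <- resolve_preset("very_small")
  expect_equal(vs$window_size, 3L)
  sm <- resolve_preset("small")
  expect_equal(sm$window_size, 10L)
  # threshold sits above the exact-enumeration floor of the window
  expect_gt(sm$p_threshold, 2^(1 - sm$window_size))
  lg <- resolve_preset("large")
  expect_equal(lg$sdf, 0)
  ov <- resolve_preset("large", p_threshold = 1e-3, ccf = 2)
  expect_equal(ov$p_threshold, 1e-3)
  expect_equal(ov$ccf, 2)
  expect_error(resolve_preset("huge"))
  expect_error(resolve_preset("large", bogus = 1), "unknown parameter")
  expect_error(cna_params(window_size = 1), "window_size")
  expect_error(cna_params(p_threshold = 0), "p_threshold")
})
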
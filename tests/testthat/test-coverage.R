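# Per-exon coverage summaries, exome statistics, het candidates.

counts_df <- function(chrom, pos, depth) {
  out <- data.frame(chrom = chrom, pos = pos, A = as.integer(depth),
                    C = 0L, G = 0L, T = 0L, depth = as.integer(depth),
                    excluded = 0L, ignored = 0L, stringsAsFactors = FALSE)
  class(out) <- c("base_counts", "data.frame")
  out
}

test_that("exon summaries use population SD over all exon bases", {
  db <- read_exon_db(write_exon_db_file(c("chr1\t0\t4\te1", "chr1\t10\t14\te2",
                                          "chr1\t20\t24\te3")))
  cnt <- counts_df("chr1", c(1:4, 13, 14), c(10, 10, 10, 10, 10, 10))
  cov <- summarize_exons(cnt, db)
  expect_equal(cov$mean_cov, c(10, 5, 0))
  expect_equal(cov$cov_sd, c(0, 5, 0))   # [0,0,10,10]: population SD 5
  expect_equal(cov$n_bases, rep(4L, 3))
})

test_that("positions outside exons are ignored; order does not matter", {
  db <- read_exon_db(write_exon_db_file("chr1\t0\t4\te1"))
  cnt <- counts_df("chr1", c(3, 999, 1), c(8, 50, 4))
  cov <- summarize_exons(cnt, db)
  expect_equal(cov$mean_cov, 3)  # (4 + 0 + 8 + 0)/4
  shuffled <- cnt[c(2, 3, 1), ]
  expect_equal(summarize_exons(shuffled, db), cov)
})

test_that("doubling depths doubles all coverage statistics", {
  db <- grid_exon_db(5)
  set.seed(2)
  pos <- unlist(lapply(seq_len(5), function(i) db$start[i] + 1:50))
  cnt <- counts_df("chr1", pos, sample(0:40, length(pos), replace = TRUE))
  cov1 <- summarize_exons(cnt, db)
  cnt2 <- cnt
  cnt2$A <- cnt2$A * 2L
  cnt2$depth <- cnt2$depth * 2L
  cov2 <- summarize_exons(cnt2, db)
  expect_equal(cov2$mean_cov, 2 * cov1$mean_cov)
  expect_equal(cov2$cov_sd, 2 * cov1$cov_sd)
  s1 <- exome_stats(cov1); s2 <- exome_stats(cov2)
  expect_equal(s2$median_cov, 2 * s1$median_cov)
  expect_equal(s2$mean_cov, 2 * s1$mean_cov)
})

test_that("exome statistics: median and mean of exon means", {
  cov <- flat_coverage(grid_exon_db(3), 1)
  cov$mean_cov <- c(10, 20, 30)
  st <- exome_stats(cov)
  expect_equal(st$median_cov, 20)
  expect_equal(st$mean_cov, 20)
  cov$mean_cov <- c(10, 10, 1000)
  expect_equal(exome_stats(cov)$median_cov, 10)  # outlier-robust
  cov1 <- cov[1, , drop = FALSE]
  cov1$mean_cov <- 7
  expect_equal(exome_stats(cov1)$median_cov, 7)
  # even number: mean of the two central values
  cov$mean_cov <- c(10, 20, 40)
  expect_equal(exome_stats(rbind(cov, cov[3, ]))$median_cov, 30)
  expect_error(exome_stats(cov[0, ]), "empty")
})

test_that("raw het candidates require two bases at the fixed minimum count", {
  cnt <- data.frame(chrom = "chr1", pos = 1:4,
                    A = c(50L, 95L, 40L, 5L), C = 0L,
                    G = c(50L, 4L, 30L, 5L), T = c(0L, 0L, 6L, 0L),
                    depth = 0L, excluded = 0L, ignored = 0L)
  cand <- collect_het_candidates(cnt)
  expect_equal(cand$pos, c(1L, 3L, 4L))       # 95/4 fails the >=5 rule
  expect_equal(cand$a1[1], "A")               # tie broken by base order
  expect_equal(cand$c1[1], 50L)
  expect_equal(unlist(cand[cand$pos == 3, c("a1", "a2")]),
               c(a1 = "A", a2 = "G"))         # T:6 discarded
  # monotone: raising the minimum only shrinks the set
  for (m in 6:12)
    expect_true(all(collect_het_candidates(cnt, m)$pos %in% cand$pos))
})

test_that("case counts attach to control candidates as the case's own top two", {
  cand <- collect_het_candidates(data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L), A = 50L, C = 0L, G = 50L, T = 0L,
    depth = 100L, excluded = 0L, ignored = 0L))
  case_cnt <- data.frame(chrom = "chr1", pos = c(10L, 30L),
                         A = c(60L, 55L), C = 0L, G = c(2L, 0L),
                         T = c(0L, 45L), depth = 0L, excluded = 0L,
                         ignored = 0L)
  het <- pair_case_counts(cand, case_cnt)
  expect_equal(het$case_c1, c(60L, 0L, 55L))
  expect_equal(het$case_c2, c(2L, 0L, 45L))
  expect_false(het$case_covered[2])            # uncovered: zero counts
  expect_equal(unlist(het[3, c("case_a1", "case_a2")]),
               c(case_a1 = "A", case_a2 = "T"))  # differs from control pair
})

test_that("coverage report flags strong median imbalance", {
  db <- grid_exon_db(9)
  expect_warning(rep1 <- coverage_report(flat_coverage(db, 100),
                                         flat_coverage(db, 25)),
                 "ratio 4.00")
  expect_equal(rep1$median_ratio, 4)
  expect_true(rep1$imbalanced)
  expect_silent(rep2 <- coverage_report(flat_coverage(db, 80),
                                        flat_coverage(db, 80)))
  expect_equal(rep2$median_ratio, 1)
  expect_false(rep2$imbalanced)
  expect_error(coverage_report(flat_coverage(db, 10)[0, ],
                               flat_coverage(db, 10)), "empty")
})
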
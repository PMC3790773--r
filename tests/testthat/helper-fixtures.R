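# In-code fixture builders: exon databases, pileup lines and SAM files are
# generated at test time, never stored.

write_exon_db_file <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

# Build one pileup line from explicit base counts at a position.
# `counts` is a named vector over reference-matching "." and substitution
# bases; `quals` a string of Phred+33 characters (recycled to the call count).
pileup_line <- function(chrom, pos, ref, bases, quals = NULL) {
  depth <- nchar(gsub("[^.,ACGTNacgtn*]", "",
                      gsub("\\^.|[$]|[+-][0-9]+[ACGTNacgtn]*", "", bases)))
  if (is.null(quals)) quals <- strrep("I", depth)
  sprintf("%s\t%d\t%s\t%s\t%s\t%s", chrom, pos, ref, depth, bases, quals)
}

write_pileup_file <- function(lines) {
  f <- tempfile(fileext = ".pileup")
  writeLines(lines, f)
  f
}

# Minimal SAM writer: unpaired forward reads with a simple CIGAR.
write_sam_file <- function(reads, sq = c(chr1 = 10000L)) {
  f <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  body <- vapply(reads, function(r) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            r$qname, r$flag %||% 0L, r$chrom, r$pos, r$mapq %||% 60L,
            r$cigar %||% paste0(nchar(r$seq), "M"), r$seq, r$qual)
  }, "")
  writeLines(c(hdr, body), f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform-coverage exon_coverage table for synthetic caller inputs.
flat_coverage <- function(db, cov, sd = 0) {
  out <- data.frame(exon_label = db$exon_label, chrom = db$chrom,
                    start = db$start, end = db$end,
                    n_bases = db$end - db$start,
                    mean_cov = rep_len(cov, nrow(db)),
                    cov_sd = rep_len(sd, nrow(db)), stringsAsFactors = FALSE)
  class(out) <- c("exon_coverage", "data.frame")
  out
}

# Regular exon grid db used by caller-level tests.
grid_exon_db <- function(n, chrom = "chr1", len = 100L, gap = 1000L) {
  start <- (seq_len(n) - 1L) * gap
  db <- data.frame(chrom = chrom, start = start, end = start + len,
                   gene = sprintf("g%04d", seq_len(n)),
                   exon_label = sprintf("%s_ex%04d", chrom, seq_len(n)),
                   stringsAsFactors = FALSE)
  class(db) <- c("exon_db", "data.frame")
  db
}

# Independent brute-force signed-rank oracle (kept free of package internals
# except the public API under test): enumerates all sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  mean(abs(signs %*% r) >= abs(W) - 1e-9)
}

# Independent exact two-sided binomial oracle (minimum-likelihood method).
oracle_binom_p <- function(k, n, p = 0.5) {
  if (n == 0L) return(1)
  dens <- dbinom(0:n, n, p)
  sum(dens[dens <= dbinom(k, n, p) * (1 + 1e-7)])
}
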
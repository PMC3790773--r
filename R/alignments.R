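# Per-position base counts from SAM/BAM input, restricted to exonic space.
# The heavy lifting (BGZF, CIGAR walk, pileup) is delegated to Rsamtools;
# this layer adds the read-level quality policy and exon restriction.

#' Extract exonic base counts from SAM or BAM alignments
#'
#' Converts alignments to per-position A/C/G/T counts over the exons of `db`.
#' Reads failing `policy$mean_read_quality_min`, or containing more than
#' `policy$max_low_quality_bases` bases below `policy$base_quality_min`, are
#' discarded whole; surviving reads contribute only bases meeting
#' `base_quality_min`. Unmapped and secondary alignments are skipped. SAM
#' input is converted to sorted, indexed BAM in a temporary location; BAM
#' without an index is sorted and indexed likewise.
#'
#' @param path Path to a SAM or BAM file.
#' @param format `"SAM"` or `"BAM"`.
#' @param policy A [read_quality_policy()].
#' @param db An [read_exon_db()] exon database; only positions inside its
#'   exons are reported.
#' @return A `data.frame` of class `"base_counts"` (see [read_pileup()]);
#'   `depth` equals the sum of the four base counts.
#' @export
read_alignments <- function(path, format = c("BAM", "SAM"),
                            policy = read_quality_policy(), db) {
  format <- match.arg(format)
  stopifnot(inherits(db, "exon_db"))
  work <- tempfile("exopair_aln")
  bam <- if (format == "SAM") {
    Rsamtools::asBam(path, work, overwrite = TRUE, indexDestination = TRUE)
  } else if (file.exists(paste0(path, ".bai")) ||
             file.exists(sub("\\.bam$", ".bai", path))) {
    path
  } else {
    out <- Rsamtools::sortBam(path, work)
    Rsamtools::indexBam(out)
    out
  }

  if (!is.null(policy$mean_read_quality_min) ||
      (!is.null(policy$max_low_quality_bases) && !is.null(policy$base_quality_min))) {
    keep_read <- function(x) {
      ql <- methods::as(x$qual, "IntegerList")
      ok <- rep(TRUE, length(ql))
      if (!is.null(policy$mean_read_quality_min))
        ok <- ok & (sum(ql) / lengths(ql) >= policy$mean_read_quality_min)
      if (!is.null(policy$max_low_quality_bases) && !is.null(policy$base_quality_min))
        ok <- ok & (sum(ql < policy$base_quality_min) <= policy$max_low_quality_bases)
      ok
    }
    filtered <- tempfile("exopair_filt", fileext = ".bam")
    bam <- Rsamtools::filterBam(
      bam, filtered,
      filter = S4Vectors::FilterRules(list(quality = keep_read)),
      param = Rsamtools::ScanBamParam(what = "qual"))
    Rsamtools::indexBam(bam)
  }

  pp <- Rsamtools::PileupParam(
    max_depth = 100000L,
    min_base_quality = if (is.null(policy$base_quality_min)) 0L
                       else as.integer(policy$base_quality_min),
    min_mapq = 0L,
    min_nucleotide_depth = 0L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  sp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  pu <- Rsamtools::pileup(bam, scanBamParam = sp, pileupParam = pp)
  if (nrow(pu) == 0L)
    return(.empty_base_counts())

  pu$seqnames <- .match_chrom_style(as.character(pu$seqnames), db$chrom)
  pu <- pu[pu$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (nrow(pu) > 0L && !any(pu$seqnames %in% db$chrom))
    stop("no chromosome name in the alignments matches the exon database ",
         "after chr-prefix normalization")

  # wide counts per (chrom, pos)
  key <- paste(pu$seqnames, pu$pos)
  uk <- !duplicated(key)
  out <- data.frame(chrom = pu$seqnames[uk], pos = pu$pos[uk],
                    A = 0L, C = 0L, G = 0L, T = 0L,
                    stringsAsFactors = FALSE)
  idx <- match(key, key[uk])
  for (b in c("A", "C", "G", "T")) {
    sel <- pu$nucleotide == b
    if (any(sel)) {
      agg <- tapply(pu$count[sel], idx[sel], sum)
      out[[b]][as.integer(names(agg))] <- as.integer(agg)
    }
  }
  out$depth <- out$A + out$C + out$G + out$T
  out$excluded <- 0L
  out$ignored <- 0L

  # restrict to exonic positions (exon db is 0-based half-open)
  gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
  ex <- GenomicRanges::GRanges(db$chrom, IRanges::IRanges(db$start + 1L, db$end))
  inside <- IRanges::overlapsAny(gr, ex)
  out <- out[inside, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("base_counts", "data.frame")
  out
}
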
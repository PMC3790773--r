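# samtools-pileup text dialect: per-position read-base string decoding.
#
# Read-base string grammar handled here:
#   '.' / ','          match to the reference base (forward / reverse strand)
#   'ACGTN' (any case) substitution calls
#   '^X'               read start; X is the mapping quality character (skipped)
#   '$'                read end marker (skipped)
#   '+N<seq>'/'-N<seq>' insertion/deletion of N bases following this position
#                       (consumed, not counted, no quality character)
#   '*'                deletion placeholder (consumes a quality character,
#                       not counted as a base)
# Base-quality characters are Phred+33.

#' Read-quality filtering policy
#'
#' Container for the three quality filters: minimum mean read quality
#' (read-level, SAM/BAM only), minimum individual base quality, and the maximum
#' number of sub-threshold bases tolerated per read (read-level, SAM/BAM only).
#' Unset thresholds (`NULL`) disable the corresponding filter.
#'
#' @param mean_read_quality_min Minimum mean Phred quality of a read.
#' @param base_quality_min Minimum Phred quality of an individual base call.
#' @param max_low_quality_bases Maximum number of bases below
#'   `base_quality_min` allowed in a read before the whole read is dropped.
#' @return A list of class `"read_quality_policy"`.
#' @export
read_quality_policy <- function(mean_read_quality_min = NULL,
                                base_quality_min = NULL,
                                max_low_quality_bases = NULL) {
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || x < 0))
      stop(nm, " must be a single non-negative number or NULL")
    x
  }
  structure(list(
    mean_read_quality_min = chk(mean_read_quality_min, "mean_read_quality_min"),
    base_quality_min = chk(base_quality_min, "base_quality_min"),
    max_low_quality_bases = chk(max_low_quality_bases, "max_low_quality_bases")
  ), class = "read_quality_policy")
}

# Decode one read-base string into per-base counts.
# Returns counts for A/C/G/T plus the number of quality-excluded and
# ignored (N/*) calls; stops if the string and quality lengths disagree.
.decode_pileup_bases <- function(bases, quals, ref, base_quality_min) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  qv <- utf8ToInt(quals) - 33L
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  excluded <- 0L
  ignored <- 0L
  ref <- toupper(ref)
  i <- 1L
  qi <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L  # mapping-quality char follows
      next
    }
    if (c0 == "$") {
      i <- i + 1L
      next
    }
    if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
      next
    }
    # a call consuming one quality character
    if (qi > length(qv))
      stop("pileup base/quality length mismatch")
    q <- qv[qi]
    qi <- qi + 1L
    base <- if (c0 == "." || c0 == ",") ref else toupper(c0)
    if (!is.null(base_quality_min) && q < base_quality_min) {
      excluded <- excluded + 1L
    } else if (base %in% c("A", "C", "G", "T")) {
      counts[base] <- counts[base] + 1L
    } else {
      ignored <- ignored + 1L  # N calls, '*' deletion placeholders
    }
    i <- i + 1L
  }
  if (qi != length(qv) + 1L)
    stop("pileup base/quality length mismatch")
  list(counts = counts, excluded = excluded, ignored = ignored)
}

#' Read a samtools pileup file into per-position base counts
#'
#' Parses the classic samtools (m)pileup text dialect (chrom, 1-based
#' position, reference base, depth, read bases, base qualities) and decodes
#' the read-base string into A/C/G/T counts. Bases with Phred quality below
#' `policy$base_quality_min` are excluded from the counts (but still reported
#' in `excluded`). Positions absent from the file have depth 0 by convention.
#'
#' @param path Path to the pileup file.
#' @param policy A [read_quality_policy()]; only `base_quality_min` applies to
#'   pileup input.
#' @return A `data.frame` of class `"base_counts"` with columns `chrom`, `pos`
#'   (1-based), `A`, `C`, `G`, `T`, `depth` (declared depth), `excluded`,
#'   `ignored`.
#' @export
read_pileup <- function(path, policy = read_quality_policy()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(.empty_base_counts())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed pileup line ", which(nf < 6L)[1],
         ": expected >= 6 tab-separated fields")
  n <- length(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- vapply(fields, `[[`, "", 3L)
  depth <- as.integer(vapply(fields, `[[`, "", 4L))
  if (anyNA(pos) || anyNA(depth))
    stop("malformed pileup line: non-numeric position or depth")
  A <- C <- G <- T <- excl <- ign <- integer(n)
  for (k in seq_len(n)) {
    dec <- .decode_pileup_bases(fields[[k]][5L], fields[[k]][6L], ref[k],
                                policy$base_quality_min)
    cnt <- dec$counts
    if (sum(cnt) + dec$excluded + dec$ignored != depth[k])
      stop("pileup line ", k, ": decoded calls (", sum(cnt) + dec$excluded +
             dec$ignored, ") do not match declared depth (", depth[k], ")")
    A[k] <- cnt[["A"]]; C[k] <- cnt[["C"]]; G[k] <- cnt[["G"]]; T[k] <- cnt[["T"]]
    excl[k] <- dec$excluded; ign[k] <- dec$ignored
  }
  out <- data.frame(chrom = chrom, pos = pos, A = A, C = C, G = G, T = T,
                    depth = depth, excluded = excl, ignored = ign,
                    stringsAsFactors = FALSE)
  class(out) <- c("base_counts", "data.frame")
  out
}

.empty_base_counts <- function() {
  out <- data.frame(chrom = character(), pos = integer(), A = integer(),
                    C = integer(), G = integer(), T = integer(),
                    depth = integer(), excluded = integer(), ignored = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("base_counts", "data.frame")
  out
}
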
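# Exon annotation database: BED-like, 0-based half-open coordinates.

#' Read an exon annotation database
#'
#' Parses a tab-separated BED-like file with columns chrom, start, end, name
#' (and optionally a 5th gene column; otherwise the gene symbol is derived from
#' the name by stripping a trailing `_ex<N>`/`_<N>` suffix). Coordinates are
#' 0-based half-open, as in BED. Records are validated (start < end, unique
#' exon labels) and sorted by (chrom, start).
#'
#' @param path Path to the exon database file.
#' @return A `data.frame` of class `"exon_db"` with columns `chrom`, `start`,
#'   `end`, `gene`, `exon_label`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\t200\tGENE1_ex1", f)
#' read_exon_db(f)
#' @export
read_exon_db <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    warning("exon database '", path, "' contains no records")
    db <- data.frame(chrom = character(), start = integer(), end = integer(),
                     gene = character(), exon_label = character(),
                     stringsAsFactors = FALSE)
    class(db) <- c("exon_db", "data.frame")
    return(db)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop("malformed exon database line ", bad[1], ": expected >= 4 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  label <- vapply(fields, `[[`, "", 4L)
  gene <- ifelse(nf >= 5L, vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "", ""),
                 sub("_(ex)?[0-9]+$", "", label))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed exon database line ", bad, ": non-numeric coordinates")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("invalid exon at line ", bad, ": start (", start[bad],
         ") must be < end (", end[bad], ")")
  }
  if (anyDuplicated(label)) {
    dup <- label[duplicated(label)][1]
    stop("duplicate exon label: '", dup, "'")
  }
  db <- data.frame(chrom = chrom, start = start, end = end, gene = gene,
                   exon_label = label, stringsAsFactors = FALSE)
  db <- db[order(db$chrom, db$start), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("exon_db", "data.frame")
  db
}

# Normalize chromosome naming of `x` to the style used by the exon database
# ("chr1" vs "1"). Errors if names still disagree afterwards.
.match_chrom_style <- function(chroms, db_chroms) {
  db_has_prefix <- any(grepl("^chr", db_chroms))
  out <- chroms
  if (db_has_prefix) {
    out[!grepl("^chr", out)] <- paste0("chr", out[!grepl("^chr", out)])
  } else {
    out <- sub("^chr", "", out)
  }
  out
}
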
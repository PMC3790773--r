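# Tabular outputs and intermediates. All numeric columns are written with 17
# significant digits so that re-reading a table reproduces every double
# bit-exactly; files are byte-identical across runs on identical input.

.write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, classes = NA) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = classes)
}

#' Write the intermediate (preprocessed) tables of a sample pair
#'
#' Persists the per-exon coverage tables, exome statistics and the paired
#' het-candidate table, so the calling stage can be re-run with new filters
#' without touching alignments.
#'
#' @param case_covs,control_covs `"exon_coverage"` tables.
#' @param case_stats,control_stats [exome_stats()] objects.
#' @param het A `"het_table"` (may have zero rows).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_intermediates <- function(case_covs, control_covs, case_stats,
                                control_stats, het, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(case_coverage = file.path(out_dir, "case_coverage.tsv"),
             control_coverage = file.path(out_dir, "control_coverage.tsv"),
             stats = file.path(out_dir, "exome_stats.tsv"),
             het = file.path(out_dir, "het_candidates.tsv"))
  .write_tsv_exact(as.data.frame(case_covs), paths[["case_coverage"]])
  .write_tsv_exact(as.data.frame(control_covs), paths[["control_coverage"]])
  .write_tsv_exact(data.frame(
    sample = c("case", "control"),
    median_cov = c(case_stats$median_cov, control_stats$median_cov),
    mean_cov = c(case_stats$mean_cov, control_stats$mean_cov),
    stringsAsFactors = FALSE), paths[["stats"]])
  .write_tsv_exact(as.data.frame(het), paths[["het"]])
  invisible(paths)
}

#' Read back intermediates written by [write_intermediates()]
#'
#' @param dir Directory containing the intermediate files.
#' @return A list with `case_covs`, `control_covs`, `case_stats`,
#'   `control_stats`, `het`.
#' @export
read_intermediates <- function(dir) {
  need <- c("case_coverage.tsv", "control_coverage.tsv", "exome_stats.tsv",
            "het_candidates.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing intermediate file(s) in '", dir, "': ",
         paste(missing, collapse = ", "),
         "; run the preprocess stage first")
  cc <- .read_tsv(file.path(dir, "case_coverage.tsv"))
  class(cc) <- c("exon_coverage", "data.frame")
  hc <- .read_tsv(file.path(dir, "control_coverage.tsv"))
  class(hc) <- c("exon_coverage", "data.frame")
  st <- .read_tsv(file.path(dir, "exome_stats.tsv"))
  mk <- function(row) structure(list(median_cov = st$median_cov[row],
                                     mean_cov = st$mean_cov[row]),
                                class = "exome_stats")
  het <- .read_tsv(file.path(dir, "het_candidates.tsv"),
                   classes = c(chrom = "character"))
  class(het) <- c("het_table", "data.frame")
  list(case_covs = cc, control_covs = hc,
       case_stats = mk(which(st$sample == "case")),
       control_stats = mk(which(st$sample == "control")), het = het)
}

#' Write analysis result tables
#'
#' Exports four deterministic TSVs: the per-exon paired table, the CNA
#' segment list, the AI calls and a one-row run summary. Empty results yield
#' header-only files.
#'
#' @param segments A `"cna_segments"` table.
#' @param ai_calls An `"ai_calls"` table (or NULL to skip).
#' @param paired_table A `"paired_coverage"` table.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_results <- function(segments, ai_calls, paired_table, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exons = file.path(out_dir, "exons.tsv"),
             segments = file.path(out_dir, "segments.tsv"),
             ai_calls = file.path(out_dir, "ai_calls.tsv"),
             summary = file.path(out_dir, "summary.tsv"))
  .write_tsv_exact(as.data.frame(paired_table), paths[["exons"]])
  .write_tsv_exact(as.data.frame(segments), paths[["segments"]])
  if (is.null(ai_calls))
    ai_calls <- data.frame(chrom = character(), pos = integer(),
                           category = character(), stringsAsFactors = FALSE)
  .write_tsv_exact(as.data.frame(ai_calls), paths[["ai_calls"]])
  .write_tsv_exact(data.frame(
    n_exons = nrow(paired_table),
    n_excluded = sum(paired_table$excluded),
    n_segments = nrow(segments),
    n_gain = sum(segments$direction == "gain"),
    n_loss = sum(segments$direction == "loss"),
    n_ai_calls = if ("category" %in% names(ai_calls))
      sum(ai_calls$category != "conserved_het") else 0L,
    stringsAsFactors = FALSE), paths[["summary"]])
  invisible(paths)
}

#' Export per-exon log2 ratios and a ready-to-use Circos configuration
#'
#' Writes the per-exon log2 ratios as a Circos 2D scatter track
#' (`chrom start end value`, chromosome names mapped to the `hs` prefix
#' convention) plus a configuration file referencing the data file by
#' relative path. The configuration embeds one commented-out track block
#' pointing to an optional mutation file, ready to be enabled when point
#' mutations should be co-plotted.
#'
#' @param segments A `"cna_segments"` table (exported as a highlight track).
#' @param paired_table A `"paired_coverage"` table.
#' @param out_dir Output directory (created if needed).
#' @param chrom_prefix Prefix replacing `chr` in chromosome labels.
#' @return Invisibly, the named vector of file paths.
#' @export
export_circos <- function(segments, paired_table, out_dir,
                          chrom_prefix = "hs") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data_file <- file.path(out_dir, "log2_ratio.txt")
  seg_file <- file.path(out_dir, "segments.txt")
  conf_file <- file.path(out_dir, "circos.conf")
  relabel <- function(chr) paste0(chrom_prefix, sub("^chr", "", chr))
  keep <- !paired_table$excluded & is.finite(paired_table$log2_ratio)
  d <- paired_table[keep, , drop = FALSE]
  writeLines(sprintf("%s %d %d %.6g", relabel(d$chrom), d$start, d$end,
                     d$log2_ratio), data_file)
  writeLines(sprintf("%s %d %d %.6g", relabel(segments$chrom),
                     segments$start, segments$end, segments$mean_log2),
             seg_file)
  conf <- c(
    "# Circos configuration generated by exopair",
    "karyotype = data/karyotype/karyotype.human.txt",
    "<ideogram>",
    "<spacing>",
    "default = 0.002r",
    "</spacing>",
    "radius = 0.90r",
    "thickness = 30p",
    "fill = yes",
    "show_label = yes",
    "label_radius = 1.05r",
    "label_size = 30",
    "label_parallel = yes",
    "</ideogram>",
    "<plots>",
    "<plot>",
    "type = scatter",
    sprintf("file = %s", basename(data_file)),
    "r0 = 0.60r",
    "r1 = 0.95r",
    "min = -3",
    "max = 3",
    "glyph = circle",
    "glyph_size = 4",
    "color = dgrey",
    "</plot>",
    "<plot>",
    "type = histogram",
    sprintf("file = %s", basename(seg_file)),
    "r0 = 0.50r",
    "r1 = 0.58r",
    "min = -3",
    "max = 3",
    "fill_color = red",
    "</plot>",
    "# Optional mutation track: place point mutations in mutations.txt",
    "# (chrom pos pos label) and uncomment the block below.",
    "#<plot>",
    "#type = text",
    "#file = mutations.txt",
    "#r0 = 0.96r",
    "#r1 = 1.00r",
    "#label_size = 20",
    "#</plot>",
    "</plots>",
    "<image>",
    "<<include etc/image.conf>>",
    "</image>",
    "<<include etc/colors_fonts_patterns.conf>>",
    "<<include etc/housekeeping.conf>>")
  writeLines(conf, conf_file)
  invisible(c(data = data_file, segments = seg_file, conf = conf_file))
}
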
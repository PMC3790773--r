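# Run orchestration: two-phase single runs (slow preprocessing persisted as
# intermediates, fast re-runnable calling), batch execution, parameter-file
# persistence and static plot export.

#' Run configuration
#'
#' Everything needed for a full analysis of one case/control pair; loss-less
#' serializable to YAML with [write_run_config()].
#'
#' @param case,control Paths to case/control input (pileup, SAM or BAM).
#' @param exon_db Path to the exon annotation database.
#' @param format Input format of `case`/`control`.
#' @param out_dir Output directory of the run.
#' @param stage `"preprocess"` (write intermediates only), `"call"` (reuse
#'   existing intermediates) or `"all"`.
#' @param policy A [read_quality_policy()].
#' @param params A [cna_params()] or preset name.
#' @param alpha_control,alpha_case LOH/AI binomial significance levels.
#' @param smoothing A [smoothing_params()].
#' @param circos Whether to export the Circos bundle.
#' @param plots Whether to export static genome/chromosome plots.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(case, control, exon_db, format = c("pileup", "SAM", "BAM"),
                       out_dir = "exopair_out", stage = c("all", "preprocess", "call"),
                       policy = read_quality_policy(), params = resolve_preset("small"),
                       alpha_control = 0.01, alpha_case = 0.01,
                       smoothing = smoothing_params(enabled = FALSE),
                       circos = TRUE, plots = TRUE) {
  if (is.character(params)) params <- resolve_preset(params)
  structure(list(case = case, control = control, exon_db = exon_db,
                 format = match.arg(format), out_dir = out_dir,
                 stage = match.arg(stage), policy = policy, params = params,
                 alpha_control = alpha_control, alpha_case = alpha_case,
                 smoothing = smoothing, circos = circos, plots = plots),
            class = "run_config")
}

#' Serialize / parse a run configuration
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$policy <- unclass(x$policy)
  x$params <- unclass(x$params)
  x$smoothing <- unclass(x$smoothing)
  # YAML has no native Inf; keep it readable and reversible
  if (is.infinite(x$params$resdf)) x$params$resdf <- ".inf"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$params$resdf, ".inf")) x$params$resdf <- Inf
  pol <- x$policy
  run_config(case = x$case, control = x$control, exon_db = x$exon_db,
             format = x$format, out_dir = x$out_dir, stage = x$stage,
             policy = read_quality_policy(pol$mean_read_quality_min,
                                          pol$base_quality_min,
                                          pol$max_low_quality_bases),
             params = do.call(cna_params, x$params),
             alpha_control = x$alpha_control, alpha_case = x$alpha_case,
             smoothing = smoothing_params(x$smoothing$window_size,
                                          x$smoothing$enabled),
             circos = x$circos, plots = x$plots)
}

.restrict_to_exons <- function(counts, db) {
  if (nrow(counts) == 0L) return(counts)
  counts$chrom <- .match_chrom_style(counts$chrom, db$chrom)
  gr <- GenomicRanges::GRanges(counts$chrom,
                               IRanges::IRanges(counts$pos, counts$pos))
  ex <- GenomicRanges::GRanges(db$chrom, IRanges::IRanges(db$start + 1L, db$end))
  counts[IRanges::overlapsAny(gr, ex), , drop = FALSE]
}

.read_sample_counts <- function(path, format, policy, db) {
  if (format == "pileup") {
    .restrict_to_exons(read_pileup(path, policy), db)
  } else {
    read_alignments(path, format, policy, db)
  }
}

#' Run a single analysis
#'
#' The preprocess stage extracts per-exon coverage, exome statistics and
#' paired het candidates from the inputs and persists them under
#' `out_dir/intermediate`; the call stage reads those intermediates (never
#' the alignments) and writes segments, AI calls, the coverage report, the
#' Circos bundle and static plots. `stage = "all"` chains both. Every run
#' writes its full effective parameter set (`run_config.yaml`) and a plain
#' log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `segments`, `ai_calls`, `paired`,
#'   `report` (call stage) or the intermediate list (preprocess only).
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_file, append = TRUE)
  cat("", file = log_file)  # truncate
  write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
  logf("stage: %s", config$stage)
  int_dir <- file.path(config$out_dir, "intermediate")

  if (config$stage %in% c("preprocess", "all")) {
    for (f in c(config$case, config$control, config$exon_db))
      if (!file.exists(f)) stop("input file not found: ", f)
    db <- read_exon_db(config$exon_db)
    logf("exon database: %d exons on %d chromosome(s)", nrow(db),
         length(unique(db$chrom)))
    case_counts <- .read_sample_counts(config$case, config$format,
                                       config$policy, db)
    control_counts <- .read_sample_counts(config$control, config$format,
                                          config$policy, db)
    case_covs <- summarize_exons(case_counts, db)
    control_covs <- summarize_exons(control_counts, db)
    cand <- collect_het_candidates(control_counts)
    het <- pair_case_counts(cand, case_counts)
    write_intermediates(case_covs, control_covs, exome_stats(case_covs),
                        exome_stats(control_covs), het, int_dir)
    logf("intermediates written to %s (%d het candidates)", int_dir, nrow(het))
    if (config$stage == "preprocess")
      return(invisible(read_intermediates(int_dir)))
  }

  int <- read_intermediates(int_dir)
  report <- coverage_report(int$case_covs, int$control_covs)
  logf("median coverage case %.2f control %.2f (ratio %.3f)",
       int$case_stats$median_cov, int$control_stats$median_cov,
       report$median_ratio)
  paired <- normalize_coverage(int$case_covs, int$control_covs,
                               int$case_stats, int$control_stats,
                               config$params)
  segments <- call_cna(paired, config$params)
  ai_calls <- if (nrow(int$het) > 0L)
    call_ai(int$het, int$case_stats, int$control_stats,
            config$alpha_control, config$alpha_case, config$smoothing)
  else NULL
  write_results(segments, ai_calls, paired, config$out_dir)
  .write_tsv_exact(data.frame(
    sample = c("case", "control"),
    median_cov = c(int$case_stats$median_cov, int$control_stats$median_cov),
    mean_cov = c(int$case_stats$mean_cov, int$control_stats$mean_cov),
    median_ratio = report$median_ratio, imbalanced = report$imbalanced,
    stringsAsFactors = FALSE), file.path(config$out_dir, "coverage_report.tsv"))
  if (config$circos)
    export_circos(segments, paired, file.path(config$out_dir, "circos"))
  if (config$plots) {
    plot_genome(paired, segments,
                file.path(config$out_dir, "genome_log2.png"))
    for (chr in unique(segments$chrom))
      plot_chromosome(paired, segments, ai_calls, chr,
                      file.path(config$out_dir,
                                sprintf("chrom_%s_log2.png", chr)))
  }
  logf("segments: %d  ai calls: %d", nrow(segments),
       if (is.null(ai_calls)) 0L else nrow(ai_calls))
  invisible(list(segments = segments, ai_calls = ai_calls, paired = paired,
                 report = report))
}

#' Run several analyses sequentially
#'
#' One failing job does not abort the rest; per-job status is collected and,
#' when `summary_file` is given, written as TSV.
#'
#' @param configs Non-empty list of [run_config()]s.
#' @param summary_file Optional path for the consolidated status table.
#' @return A data.frame with `out_dir`, `status` (`"ok"`/`"error"`),
#'   `message`.
#' @export
run_batch <- function(configs, summary_file = NULL) {
  if (length(configs) == 0L) stop("empty job list")
  res <- lapply(configs, function(cfg) {
    tryCatch({
      run_single(cfg)
      data.frame(out_dir = cfg$out_dir, status = "ok", message = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(out_dir = if (inherits(cfg, "run_config")) cfg$out_dir else NA,
                 status = "error", message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  if (!is.null(summary_file)) .write_tsv_exact(out, summary_file)
  out
}

.chrom_palette <- function(chroms) {
  grDevices::hcl.colors(max(length(chroms), 2L), "Dark 3")[seq_along(chroms)]
}

#' Static genome-wide log2-ratio plot
#'
#' Per-exon log2 ratios along the concatenated genome, chromosomes in
#' alternating colors, called segments as horizontal bars at their mean log2.
#'
#' @param paired A `"paired_coverage"` table.
#' @param segments A `"cna_segments"` table.
#' @param file Output PNG (or PDF if the extension is `.pdf`); NULL draws on
#'   the active device.
#' @return Invisibly `file`.
#' @export
plot_genome <- function(paired, segments, file = NULL) {
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 11, height = 4)
    else grDevices::png(file, width = 1400, height = 450)
    on.exit(grDevices::dev.off())
  }
  keep <- !paired$excluded & is.finite(paired$log2_ratio)
  d <- paired[keep, , drop = FALSE]
  chroms <- unique(paired$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(paired$end[paired$chrom == ch]), 0)))
  names(offs) <- c(chroms, "end")
  x <- d$start + offs[d$chrom]
  col <- .chrom_palette(chroms)[match(d$chrom, chroms)]
  graphics::plot(x, d$log2_ratio, pch = 16, cex = 0.3, col = col,
                 xaxt = "n", xlab = "genome position", ylab = "log2 ratio",
                 ylim = range(c(-2, 2, d$log2_ratio), finite = TRUE))
  graphics::axis(1, at = offs[seq_along(chroms)] +
                   diff(offs) / 2, labels = chroms, tick = FALSE, cex.axis = 0.7)
  graphics::abline(h = 0, col = "grey40")
  if (nrow(segments))
    graphics::segments(segments$start + offs[segments$chrom],
                       segments$mean_log2,
                       segments$end + offs[segments$chrom],
                       segments$mean_log2, lwd = 3,
                       col = ifelse(segments$direction == "gain",
                                    "red3", "green4"))
  invisible(file)
}

#' Static single-chromosome log2-ratio plot with AI markers
#'
#' @param paired,segments As in [plot_genome()].
#' @param ai_calls An `"ai_calls"` table or NULL; non-conserved positions are
#'   drawn at their case allelic ratio on a secondary axis.
#' @param chrom Chromosome to plot.
#' @param file Output image path or NULL.
#' @return Invisibly `file`.
#' @export
plot_chromosome <- function(paired, segments, ai_calls, chrom, file = NULL) {
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 9, height = 4)
    else grDevices::png(file, width = 1100, height = 450)
    on.exit(grDevices::dev.off())
  }
  d <- paired[paired$chrom == chrom & !paired$excluded &
                is.finite(paired$log2_ratio), , drop = FALSE]
  graphics::plot(d$start, d$log2_ratio, pch = 16, cex = 0.4, col = "darkgoldenrod3",
                 xlab = paste(chrom, "position"), ylab = "log2 ratio",
                 ylim = range(c(-2, 2, d$log2_ratio), finite = TRUE))
  graphics::abline(h = 0, col = "grey40")
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  if (nrow(s))
    graphics::segments(s$start, s$mean_log2, s$end, s$mean_log2, lwd = 4,
                       col = ifelse(s$direction == "gain", "red3", "green4"))
  if (!is.null(ai_calls)) {
    a <- ai_calls[ai_calls$chrom == chrom, , drop = FALSE]
    if (nrow(a)) {
      cols <- c(conserved_het = "grey60", copy_loss = "green4",
                copy_neutral_loh = "purple", gain_1 = "blue",
                gain_2plus = "darkred")
      # allelic ratio [0,1] mapped onto the [-2,2] y-range
      graphics::points(a$pos, a$case_allelic_ratio * 4 - 2, pch = 1,
                       cex = 0.8, col = cols[a$category])
    }
  }
  invisible(file)
}
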
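# In-silico exome generator: emits paired per-exon coverage tables and
# heterozygous-position allele counts with known truth, in the same
# intermediate formats the caller consumes.
#
# Model (per exon): the case copy state is CNobs = CNex + rnd_cn*(2*U - 1)
# with CNex = 2 + delta inside events and U ~ Uniform(0,1) drawn
# independently per exon. Both samples additionally carry Poisson read-
# sampling noise: reads ~ Poisson(cov * exon_len / read_len), coverage =
# reads * read_len / exon_len, which ties counting noise to absolute depth.
# Per het position the case first-allele count is
# FA = round(depth * clamp(f + rnd_ai*(2*U - 1), 0, 1)) where f is the
# copy-state expected allelic fraction (0.5 diploid; 0/1 under loss; 1/3 or
# 2/3 under +1; 1/4 or 3/4 under +2; allele picked at random). Control
# allele counts are Binomial(depth, 0.5) draws: allelic-ratio noise models
# the aberration carried by the case, not the germline.

#' Simulation configuration
#'
#' @param chrom_sizes Named integer vector: exons per chromosome.
#' @param base_cov_case,base_cov_control Mean exonic coverage of the two
#'   samples.
#' @param rnd_cn Maximum copy-number noise amplitude (uniform, symmetric)
#'   applied to the case copy state.
#' @param p_cn1,p_cn2,p_cn_gt2 Per-slot activation probabilities of +/-1,
#'   +/-2 and >2-copy events.
#' @param event_size Event length in exons: a single value or a
#'   `c(min, max)` range sampled uniformly.
#' @param slot_size Exons per placement slot; each slot hosts at most one
#'   event, keeping events non-overlapping.
#' @param rnd_ai Maximum allelic-ratio noise amplitude applied to case
#'   allele counts.
#' @param het_per_event Integer vector (recycled over events): truth
#'   heterozygous positions placed inside each event.
#' @param het_spacing One background heterozygous position every
#'   `het_spacing` exons outside events (0 disables).
#' @param events Optional explicit event table (`chrom`, `first_exon`,
#'   `last_exon`, `delta`) overriding random placement.
#' @param exon_len,read_len,exon_spacing Exon length, read length and
#'   genomic start-to-start exon spacing in bp.
#' @param count_noise Apply read-counting noise (Poisson coverage sampling,
#'   binomial control allele sampling). Disabled, coverages equal
#'   `base_cov * CNobs/2` exactly and control allele counts split the depth
#'   evenly — useful to exercise the noise equations in isolation.
#' @param seed Integer seed fixing all outputs.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(chrom_sizes, base_cov_case = 100, base_cov_control = 100,
                       rnd_cn = 0.3, p_cn1 = 0.1, p_cn2 = 0, p_cn_gt2 = 0,
                       event_size = 10L, slot_size = 100L, rnd_ai = 0.05,
                       het_per_event = 0L, het_spacing = 0L, events = NULL,
                       exon_len = 150L, read_len = 76L, exon_spacing = 1000L,
                       count_noise = TRUE, seed = 1L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  p <- c(p_cn1, p_cn2, p_cn_gt2)
  if (any(p < 0) || sum(p) > 1) stop("event probabilities must be in [0,1] and sum <= 1")
  if (rnd_cn < 0 || rnd_ai < 0) stop("rnd_cn and rnd_ai must be >= 0")
  if (max(event_size) > min(chrom_sizes))
    stop("event size exceeds the smallest chromosome")
  structure(list(chrom_sizes = chrom_sizes, base_cov_case = base_cov_case,
                 base_cov_control = base_cov_control, rnd_cn = rnd_cn,
                 p_cn1 = p_cn1, p_cn2 = p_cn2, p_cn_gt2 = p_cn_gt2,
                 event_size = event_size, slot_size = as.integer(slot_size),
                 rnd_ai = rnd_ai, het_per_event = het_per_event,
                 het_spacing = as.integer(het_spacing), events = events,
                 exon_len = as.integer(exon_len), read_len = as.integer(read_len),
                 exon_spacing = as.integer(exon_spacing),
                 count_noise = isTRUE(count_noise), seed = as.integer(seed)),
            class = "sim_config")
}

# Expected allelic fraction of the first allele under a copy delta; the
# affected allele is chosen at random upstream via `flip`.
.ai_expected_fraction <- function(delta, flip) {
  f <- if (delta == 0) 0.5
  else if (delta <= -1) 0            # one (or both) allele(s) lost
  else if (delta == 1) 1 / 3
  else if (delta == 2) 1 / 4
  else 1 / (delta + 2)
  if (flip) 1 - f else f
}

.ai_truth_category <- function(delta) {
  if (delta == 0) "conserved_het"
  else if (delta < 0) "copy_loss"
  else if (delta == 1) "gain_1"
  else "gain_2plus"
}

#' Simulate a paired exome with known truth
#'
#' Places copy-number events (non-overlapping, one per activated slot, signs
#' alternating within a replicate so gains and losses stay balanced), draws
#' case/control per-exon coverages and heterozygous-position allele counts
#' under the model described above, and returns everything in the caller's
#' intermediate formats together with the truth tables.
#'
#' @param config A [sim_config()].
#' @return A list of class `"exome_sim"`: `db` (exon database),
#'   `case_covs`/`control_covs` (`"exon_coverage"`), `case_stats`/
#'   `control_stats`, `het` (`"het_table"`), `truth_events` (`chrom`,
#'   `first_exon`, `last_exon`, `delta`, `direction`), `truth_het` (`chrom`,
#'   `pos`, `category`, `event`), `config`.
#' @export
simulate_exome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_sizes)

  # ---- event placement -------------------------------------------------
  if (!is.null(config$events)) {
    ev <- config$events
    ev <- ev[order(ev$chrom, ev$first_exon), , drop = FALSE]
    if (any(ev$last_exon > config$chrom_sizes[ev$chrom]))
      stop("explicit event extends beyond its chromosome")
  } else {
    rows <- list()
    sign_next <- sample(c(1, -1), 1)
    pr <- c(config$p_cn1, config$p_cn2, config$p_cn_gt2)
    for (chr in chroms) {
      n <- config$chrom_sizes[[chr]]
      nslot <- n %/% config$slot_size
      for (s in seq_len(nslot)) {
        u <- stats::runif(1)
        if (u >= sum(pr)) next
        mag <- if (u < pr[1]) 1L else if (u < pr[1] + pr[2]) 2L else 3L
        size <- if (length(config$event_size) > 1L)
          sample(config$event_size[1]:config$event_size[2], 1L)
        else as.integer(config$event_size)
        size <- min(size, config$slot_size)
        off <- if (config$slot_size > size)
          sample.int(config$slot_size - size, 1L) - 1L else 0L
        first <- (s - 1L) * config$slot_size + off + 1L
        delta <- if (mag == 3L) 3L else as.integer(mag * sign_next)
        if (mag != 3L) sign_next <- -sign_next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chr, first_exon = first, last_exon = first + size - 1L,
          delta = delta, stringsAsFactors = FALSE)
      }
    }
    ev <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), first_exon = integer(),
                 last_exon = integer(), delta = integer(),
                 stringsAsFactors = FALSE)
  }
  ev$direction <- ifelse(ev$delta > 0, "gain", "loss")

  # ---- per-exon coverage ----------------------------------------------
  db_rows <- vector("list", length(chroms))
  case_cov <- control_cov <- cnobs_all <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    n <- config$chrom_sizes[[chr]]
    start <- (seq_len(n) - 1L) * config$exon_spacing
    db_rows[[ci]] <- data.frame(
      chrom = chr, start = start, end = start + config$exon_len,
      gene = sprintf("%s_g%06d", chr, seq_len(n)),
      exon_label = sprintf("%s_ex%06d", chr, seq_len(n)),
      stringsAsFactors = FALSE)
    cnex <- rep(2, n)
    for (k in which(ev$chrom == chr))
      cnex[ev$first_exon[k]:ev$last_exon[k]] <- 2 + ev$delta[k]
    cnobs <- cnex + config$rnd_cn * (2 * stats::runif(n) - 1)
    cnobs <- pmax(cnobs, 0)
    rl <- config$read_len / config$exon_len
    lam_case <- config$base_cov_case * (cnobs / 2) / rl
    lam_ctrl <- rep(config$base_cov_control / rl, n)
    if (config$count_noise) {
      # emitted per-exon coverages are integer, as count-derived
      # preprocessed tables are
      case_cov[[ci]] <- round(stats::rpois(n, lam_case) * rl)
      control_cov[[ci]] <- round(stats::rpois(n, lam_ctrl) * rl)
    } else {
      case_cov[[ci]] <- lam_case * rl
      control_cov[[ci]] <- lam_ctrl * rl
    }
    cnobs_all[[ci]] <- cnobs
  }
  db <- do.call(rbind, db_rows)
  class(db) <- c("exon_db", "data.frame")
  mk_cov <- function(covv) {
    cov <- unlist(covv, use.names = FALSE)
    out <- data.frame(exon_label = db$exon_label, chrom = db$chrom,
                      start = db$start, end = db$end,
                      n_bases = db$end - db$start, mean_cov = cov,
                      cov_sd = sqrt(cov),  # nominal counting-noise scale
                      stringsAsFactors = FALSE)
    class(out) <- c("exon_coverage", "data.frame")
    out
  }
  case_covs <- mk_cov(case_cov)
  control_covs <- mk_cov(control_cov)

  # ---- heterozygous positions -----------------------------------------
  het_rows <- list()
  truth_rows <- list()
  add_het <- function(chr, exon_idx, delta, event_id) {
    ci <- match(chr, chroms)
    pos <- db$start[db$chrom == chr][exon_idx] + config$exon_len %/% 2L + 1L
    dep_c <- pmax(round(control_cov[[ci]][exon_idx]), 0L)
    dep_t <- pmax(round(case_cov[[ci]][exon_idx]), 0L)
    k <- length(exon_idx)
    fa_ctrl <- if (config$count_noise) stats::rbinom(k, dep_c, 0.5)
               else round(dep_c * 0.5)
    flip <- stats::runif(k) < 0.5
    f <- vapply(seq_len(k), function(i) .ai_expected_fraction(delta, flip[i]), 0)
    f_obs <- pmin(pmax(f + config$rnd_ai * (2 * stats::runif(k) - 1), 0), 1)
    fa_case <- round(dep_t * f_obs)
    # allele 1 is "A", allele 2 is "G"; order each sample's pair by count
    ctl_hi <- pmax(fa_ctrl, dep_c - fa_ctrl)
    ctl_lo <- pmin(fa_ctrl, dep_c - fa_ctrl)
    cas_hi <- pmax(fa_case, dep_t - fa_case)
    cas_lo <- pmin(fa_case, dep_t - fa_case)
    het_rows[[length(het_rows) + 1L]] <<- data.frame(
      chrom = chr, pos = pos,
      control_a1 = ifelse(fa_ctrl >= dep_c - fa_ctrl, "A", "G"),
      control_c1 = as.integer(ctl_hi),
      control_a2 = ifelse(fa_ctrl >= dep_c - fa_ctrl, "G", "A"),
      control_c2 = as.integer(ctl_lo),
      case_a1 = ifelse(fa_case >= dep_t - fa_case, "A", "G"),
      case_c1 = as.integer(cas_hi),
      case_a2 = ifelse(fa_case >= dep_t - fa_case, "G", "A"),
      case_c2 = as.integer(cas_lo),
      case_covered = dep_t > 0L, stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      chrom = chr, pos = pos, category = .ai_truth_category(delta),
      event = event_id, stringsAsFactors = FALSE)
  }
  if (any(config$het_per_event > 0L) && nrow(ev) > 0L) {
    nh <- rep_len(config$het_per_event, nrow(ev))
    for (k in seq_len(nrow(ev))) {
      if (nh[k] == 0L) next
      idx <- unique(round(seq(ev$first_exon[k], ev$last_exon[k],
                              length.out = nh[k])))
      add_het(ev$chrom[k], idx, ev$delta[k], k)
    }
  }
  if (config$het_spacing > 0L) {
    for (ci in seq_along(chroms)) {
      chr <- chroms[ci]
      n <- config$chrom_sizes[[chr]]
      idx <- seq(1L, n, by = config$het_spacing)
      in_ev <- rep(FALSE, n)
      for (k in which(ev$chrom == chr))
        in_ev[ev$first_exon[k]:ev$last_exon[k]] <- TRUE
      idx <- idx[!in_ev[idx]]
      if (length(idx)) add_het(chr, idx, 0L, NA_integer_)
    }
  }
  het <- if (length(het_rows)) do.call(rbind, het_rows) else
    pair_case_counts(.empty_het_candidates(), .empty_base_counts())
  het <- het[order(het$chrom, het$pos), , drop = FALSE]
  rownames(het) <- NULL
  class(het) <- c("het_table", "data.frame")
  truth_het <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(chrom = character(), pos = integer(), category = character(),
               event = integer(), stringsAsFactors = FALSE)
  truth_het <- truth_het[order(truth_het$chrom, truth_het$pos), , drop = FALSE]
  rownames(truth_het) <- NULL

  structure(list(db = db, case_covs = case_covs, control_covs = control_covs,
                 case_stats = exome_stats(case_covs),
                 control_stats = exome_stats(control_covs),
                 het = het, truth_events = ev, truth_het = truth_het,
                 config = config),
            class = "exome_sim")
}

#' Named simulation presets
#'
#' Ready-made [sim_config()]s for the package's benchmark designs:
#' `"t80"` (80-exon +/-1 events, ~16 per replicate, 100x/100x),
#' `"t8000"` (chromosome-scale events of 6000-10000 exons, ~10.5 per
#' replicate), `"t10"`, `"t4"`, `"t3"` (balanced small-event designs),
#' `"T100H25"` / `"T25H100"` (10-exon events under 4-fold coverage imbalance,
#' case 100x / control 25x and vice versa), and `"ai_sweep"` (one chromosome,
#' three ~200-exon events of -1/+1/+2 copies carrying 10/6/6 heterozygous
#' positions, 100x, allelic noise set by `rnd_ai`).
#'
#' @param name Preset name.
#' @param seed Seed passed through to [sim_config()].
#' @param rnd_ai Allelic-noise amplitude (used by `"ai_sweep"`).
#' @param ... Further [sim_config()] overrides.
#' @return A `"sim_config"`.
#' @export
sim_preset <- function(name = c("t80", "t8000", "t10", "t4", "t3",
                                "T100H25", "T25H100", "ai_sweep"),
                       seed = 1L, rnd_ai = 0.05, ...) {
  name <- match.arg(name)
  sz <- function(n_chr, n_ex, prefix = "chr")
    stats::setNames(rep(as.integer(n_ex), n_chr), paste0(prefix, seq_len(n_chr)))
  args <- switch(name,
    t80 = list(chrom_sizes = sz(8, 2000), event_size = 80L, slot_size = 200L,
               p_cn1 = 0.2, rnd_cn = 0.3),
    t8000 = list(chrom_sizes = sz(11, 12000), event_size = c(6000L, 10000L),
                 slot_size = 12000L, p_cn1 = 0.95, rnd_cn = 0.3),
    t10 = list(chrom_sizes = sz(10, 1000), event_size = 10L, slot_size = 100L,
               p_cn1 = 0.17, rnd_cn = 0.3),
    t4 = list(chrom_sizes = sz(10, 1000), event_size = 4L, slot_size = 50L,
              p_cn1 = 0.0725, rnd_cn = 0.3),
    t3 = list(chrom_sizes = sz(10, 1000), event_size = 3L, slot_size = 50L,
              p_cn1 = 0.0815, rnd_cn = 0.3),
    T100H25 = list(chrom_sizes = sz(10, 1000), event_size = 10L,
                   slot_size = 100L, p_cn1 = 0.086, base_cov_case = 100,
                   base_cov_control = 25, rnd_cn = 0.87),
    T25H100 = list(chrom_sizes = sz(10, 1000), event_size = 10L,
                   slot_size = 100L, p_cn1 = 0.093, base_cov_case = 25,
                   base_cov_control = 100, rnd_cn = 0.3),
    ai_sweep = list(chrom_sizes = c(chr4 = 2000L),
                    events = data.frame(chrom = "chr4",
                                        first_exon = c(301L, 901L, 1501L),
                                        last_exon = c(500L, 1100L, 1700L),
                                        delta = c(-1L, 1L, 2L),
                                        stringsAsFactors = FALSE),
                    het_per_event = c(10L, 6L, 6L), het_spacing = 50L,
                    rnd_cn = 0.3, rnd_ai = rnd_ai))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(sim_config, args)
}
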
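# CNA calling: median normalization, exon filters, sliding-window matched-pairs
# seeding, seed expansion/merging and the chromosome-noise (SDF) filter.

#' CNA calling parameters
#'
#' Bundles the six tunable filters of the caller. Sensible combinations for
#' the four expected-CNA-size classes are available through
#' [resolve_preset()].
#'
#' @param window_size Seed window length in exons (>= 2). The window caps the
#'   smallest detectable event, and below 11 nonzero pairs the exact
#'   enumeration bounds the attainable p-value at `2^(1 - window_size)`, so
#'   `p_threshold` must stay above that floor for seeds to exist.
#' @param p_threshold Significance level for seeds, extensions and final
#'   segments.
#' @param ccf Coverage correction factor: pseudo-count added to both
#'   normalized coverages before the ratio, stabilizing low-depth exons.
#' @param coverage_floor Minimum normalized coverage; an exon below it in
#'   either sample is excluded from the analysis.
#' @param resdf Relative exon standard deviation filter: exclude exons whose
#'   intra-exon `cov_sd / mean_cov` exceeds this in either sample
#'   (`Inf` disables).
#' @param sdf Standard-deviation-fold filter: discard segments whose
#'   `|mean_log2|` is below `sdf` times the chromosome log2-ratio SD
#'   (0 disables).
#' @param preset Name recorded for provenance.
#' @return A list of class `"cna_params"`.
#' @export
cna_params <- function(window_size = 10L, p_threshold = 5e-3, ccf = 5,
                       coverage_floor = 5, resdf = Inf, sdf = 1,
                       preset = "custom") {
  window_size <- as.integer(window_size)
  if (window_size < 2L) stop("window_size must be >= 2")
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0, 1)")
  if (ccf < 0 || coverage_floor < 0 || resdf < 0 || sdf < 0)
    stop("ccf, coverage_floor, resdf and sdf must be non-negative")
  structure(list(window_size = window_size, p_threshold = p_threshold,
                 ccf = ccf, coverage_floor = coverage_floor, resdf = resdf,
                 sdf = sdf, preset = preset),
            class = "cna_params")
}

#' Parameter presets by expected CNA size
#'
#' Returns a [cna_params()] tuned for one of the four expected event-size
#' classes (roughly 3-20, 20+, 100+ and 500+ exons). Windows never exceed the
#' smallest target event of the class, thresholds respect the exact-p floor of
#' small windows, and the SDF is relaxed for large events (whose presence
#' inflates the chromosome background SD). Any field can be overridden.
#'
#' @param expected_size One of `"very_small"`, `"small"`, `"medium"`,
#'   `"large"`.
#' @param ... Named [cna_params()] fields overriding the preset values.
#' @return A `"cna_params"` object.
#' @examples
#' resolve_preset("small")
#' resolve_preset("large", p_threshold = 1e-8)
#' @export
resolve_preset <- function(expected_size = c("very_small", "small", "medium",
                                             "large"), ...) {
  expected_size <- match.arg(expected_size)
  base <- switch(expected_size,
    very_small = list(window_size = 3L, p_threshold = 0.26, ccf = 5,
                      coverage_floor = 5, resdf = Inf, sdf = 2),
    small      = list(window_size = 10L, p_threshold = 5e-3, ccf = 5,
                      coverage_floor = 5, resdf = Inf, sdf = 0.45),
    medium     = list(window_size = 40L, p_threshold = 1e-6, ccf = 10,
                      coverage_floor = 0, resdf = Inf, sdf = 1),
    large      = list(window_size = 40L, p_threshold = 1e-6, ccf = 10,
                      coverage_floor = 0, resdf = Inf, sdf = 0))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown parameter override: ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  do.call(cna_params, c(base, list(preset = expected_size)))
}

#' Normalize paired exon coverage
#'
#' Scales case and control per-exon mean coverages by their whole-exome
#' medians onto a common coverage-like scale (the mean of the two medians),
#' then computes the CCF-smoothed ratio and log2 ratio, and applies the
#' per-exon exclusion filters ([apply_exon_filters()]).
#'
#' @param case_covs,control_covs `"exon_coverage"` tables over the same exons.
#' @param case_stats,control_stats Matching [exome_stats()] (recomputed when
#'   omitted).
#' @param params A [cna_params()].
#' @return A `data.frame` of class `"paired_coverage"`: exon annotation,
#'   raw and normalized coverages, per-sample SDs, `ratio`, `log2_ratio`,
#'   `excluded`, `reason`.
#' @export
normalize_coverage <- function(case_covs, control_covs,
                               case_stats = exome_stats(case_covs),
                               control_stats = exome_stats(control_covs),
                               params = cna_params()) {
  if (nrow(case_covs) != nrow(control_covs) ||
      !all(case_covs$exon_label == control_covs$exon_label))
    stop("case and control coverage tables must cover the same exons in the same order")
  if (case_stats$median_cov <= 0 || control_stats$median_cov <= 0)
    stop("zero median coverage; cannot normalize")
  scale <- (case_stats$median_cov + control_stats$median_cov) / 2
  case_norm <- case_covs$mean_cov / case_stats$median_cov * scale
  control_norm <- control_covs$mean_cov / control_stats$median_cov * scale
  ratio <- (case_norm + params$ccf) / (control_norm + params$ccf)
  out <- data.frame(
    exon_label = case_covs$exon_label, chrom = case_covs$chrom,
    start = case_covs$start, end = case_covs$end,
    case_cov = case_covs$mean_cov, control_cov = control_covs$mean_cov,
    case_sd = case_covs$cov_sd, control_sd = control_covs$cov_sd,
    case_norm = case_norm, control_norm = control_norm,
    ratio = ratio, log2_ratio = log2(ratio),
    excluded = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("paired_coverage", "data.frame")
  apply_exon_filters(out, params)
}

#' Apply per-exon exclusion filters
#'
#' Marks exons excluded when either sample's normalized coverage falls below
#' `coverage_floor` (both samples are then discarded together) or when the
#' relative intra-exon SD (`cov_sd / mean_cov`) exceeds `resdf` in either
#' sample. Exclusion reasons are recorded; excluded exons keep their values
#' but are skipped by the caller.
#'
#' @param paired A `"paired_coverage"` table.
#' @param params A [cna_params()].
#' @return The table with updated `excluded` / `reason`.
#' @export
apply_exon_filters <- function(paired, params) {
  paired$excluded <- FALSE
  paired$reason <- NA_character_
  if (params$coverage_floor > 0) {
    low <- pmin(paired$case_norm, paired$control_norm) < params$coverage_floor
    paired$excluded <- paired$excluded | low
    paired$reason[low] <- "coverage_floor"
  }
  if (is.finite(params$resdf)) {
    rel <- function(sd, m) ifelse(m > 0, sd / m, ifelse(sd > 0, Inf, 0))
    high <- pmax(rel(paired$case_sd, paired$case_cov),
                 rel(paired$control_sd, paired$control_cov)) > params$resdf
    paired$reason[high & !paired$excluded] <- "resdf"
    paired$excluded <- paired$excluded | high
  }
  paired
}

# Conservative prescreen bound for the seed scan: the smallest |sum of
# difference signs| a window must show before the signed-rank test can
# possibly fall below `thr`. With a positive and b negative signs among Nr
# nonzero pairs, |W| is at most S(Nr) - 2*S(min(a,b)) with S(m) = m(m+1)/2;
# comparing that to the required |W| (exact-enumeration quantile for
# Nr <= 10, normal quantile above, both with safety margins for ties) gives
# a necessary minimum on |a - b|. Windows below the bound are provably not
# seeds, so screening changes nothing.
.seed_prescreen_tmin <- function(w, thr) {
  key <- sprintf("tmin_%d_%.17g", w, thr)
  cached <- .exopair_cache[[key]]
  if (!is.null(cached)) return(cached)
  SS <- function(m) m * (m + 1) / 2
  tmins <- integer(0)
  for (Nr in 2:w) {
    if (Nr <= 10L) {
      if (2^(1 - Nr) >= thr) next  # exact p floor: threshold unreachable
      r <- seq_len(Nr)
      Wall <- abs(.sign_matrix(Nr) %*% r)
      ws <- sort(unique(as.vector(Wall)))
      pv <- vapply(ws, function(w0) mean(Wall >= w0 - 1e-9), 0)
      if (!any(pv < thr)) next
      Wreq <- min(ws[pv < thr]) - 2  # margin for tie-perturbed ranks
    } else {
      z <- stats::qnorm(1 - thr / 2)
      Wreq <- 0.5 + (z - 0.2) * sqrt(Nr * (Nr + 1) * (2 * Nr + 1) / 6) - 2
    }
    amin <- NA_integer_
    for (a in ceiling(Nr / 2):Nr) {
      if (SS(Nr) - 2 * SS(Nr - a) >= Wreq) { amin <- a; break }
    }
    if (is.na(amin)) next
    tmins <- c(tmins, 2L * amin - Nr)
  }
  out <- if (length(tmins)) min(tmins) else Inf
  .exopair_cache[[key]] <- out
  out
}

#' Find seed windows on one chromosome
#'
#' Slides a `window_size`-exon window (step 1) over the included exons of one
#' chromosome and runs the matched-pairs signed-rank test on the normalized
#' coverage pairs. Windows with p below `p_threshold` become seeds, tagged
#' gain or loss by the sign of the median difference.
#'
#' @param chr_paired `"paired_coverage"` rows of a single chromosome.
#' @param params A [cna_params()].
#' @return A `data.frame` with `start_idx`, `end_idx` (1-based indices into
#'   the chromosome's included-exon list), `direction`, `p`.
#' @export
find_seeds <- function(chr_paired, params) {
  incl <- which(!chr_paired$excluded)
  w <- params$window_size
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      direction = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (length(incl) < w) {
    warning("chromosome ", chr_paired$chrom[1], ": fewer included exons (",
            length(incl), ") than the seed window (", w, "); no seeds")
    return(empty)
  }
  d <- chr_paired$case_norm[incl] - chr_paired$control_norm[incl]
  nwin <- length(d) - w + 1L
  # rolling sign-sum prescreen (provably conservative, see above)
  tmin <- .seed_prescreen_tmin(w, params$p_threshold)
  cs <- cumsum(c(0, sign(d)))
  tsum <- cs[(w + 1L):(nwin + w)] - cs[seq_len(nwin)]
  cand <- which(abs(tsum) >= tmin)
  ps <- med <- numeric(length(cand))
  for (k in seq_along(cand)) {
    dw <- d[cand[k]:(cand[k] + w - 1L)]
    ps[k] <- .signed_rank_p(dw)
    med[k] <- stats::median(dw)
  }
  keep <- ps < params$p_threshold & med != 0
  hit <- cand[keep]
  data.frame(start_idx = hit, end_idx = hit + w - 1L,
             direction = ifelse(med[keep] > 0, "gain", "loss"),
             p = ps[keep], stringsAsFactors = FALSE)
}

# Coalesce overlapping same-direction seed windows into proto-regions.
.coalesce_seeds <- function(seeds) {
  if (nrow(seeds) == 0L) return(seeds[, c("start_idx", "end_idx", "direction")])
  out <- list()
  for (dir in unique(seeds$direction)) {
    s <- seeds[seeds$direction == dir, , drop = FALSE]
    s <- s[order(s$start_idx), , drop = FALSE]
    cs <- s$start_idx[1]; ce <- s$end_idx[1]
    for (k in seq_len(nrow(s))[-1]) {
      if (s$start_idx[k] <= ce) {
        ce <- max(ce, s$end_idx[k])
      } else {
        out[[length(out) + 1L]] <- data.frame(start_idx = cs, end_idx = ce,
                                              direction = dir)
        cs <- s$start_idx[k]; ce <- s$end_idx[k]
      }
    }
    out[[length(out) + 1L]] <- data.frame(start_idx = cs, end_idx = ce,
                                          direction = dir)
  }
  out <- do.call(rbind, out)
  out[order(out$start_idx), , drop = FALSE]
}

#' Expand seeds and merge contiguous regions on one chromosome
#'
#' Overlapping same-direction seeds are first coalesced. Each proto-region is
#' then grown one included exon at a time, alternating ends; an extension is
#' kept if and only if the matched-pairs test over the extended region stays
#' below `p_threshold`, and an end closes permanently at its first rejection.
#' Same-direction regions whose expanded extents touch or overlap are merged
#' (and the merged p recomputed); opposite-direction overlaps are resolved by
#' truncation at the overlap midpoint.
#'
#' @param seeds Output of [find_seeds()].
#' @param chr_paired `"paired_coverage"` rows of the same chromosome.
#' @param params A [cna_params()].
#' @return A `data.frame` of segments on the chromosome (see [call_cna()]).
#' @export
expand_and_merge <- function(seeds, chr_paired, params) {
  incl <- which(!chr_paired$excluded)
  d <- chr_paired$case_norm[incl] - chr_paired$control_norm[incl]
  n <- length(d)
  if (nrow(seeds) == 0L) return(.segments_from_regions(NULL, chr_paired, incl))
  regions <- .coalesce_seeds(seeds)

  # chromosome-wide |d| buckets backing the incremental expansion state
  uv <- sort(unique(abs(d[d != 0])))
  bk <- findInterval(abs(d), uv)
  m <- length(uv)

  # grow each region, alternating left/right, first rejection closes an end
  for (k in seq_len(nrow(regions))) {
    i <- regions$start_idx[k]; j <- regions$end_idx[k]
    st <- .exp_state_new(d[i:j], bk[i:j], m)
    open_l <- i > 1L
    open_r <- j < n
    side <- "L"
    while (open_l || open_r) {
      if (side == "L" && !open_l) side <- "R"
      if (side == "R" && !open_r) side <- "L"
      if (side == "L") {
        trial <- .exp_trial(st, d[i - 1L], bk[i - 1L])
        if (trial$p < params$p_threshold) {
          st <- .exp_commit(st, d[i - 1L], bk[i - 1L], trial)
          i <- i - 1L
          if (i == 1L) open_l <- FALSE
        } else open_l <- FALSE
        side <- "R"
      } else {
        trial <- .exp_trial(st, d[j + 1L], bk[j + 1L])
        if (trial$p < params$p_threshold) {
          st <- .exp_commit(st, d[j + 1L], bk[j + 1L], trial)
          j <- j + 1L
          if (j == n) open_r <- FALSE
        } else open_r <- FALSE
        side <- "L"
      }
    }
    regions$start_idx[k] <- i
    regions$end_idx[k] <- j
  }
  regions <- regions[order(regions$start_idx, regions$end_idx), , drop = FALSE]

  # merge same-direction contiguous/overlapping regions
  merged <- regions[0, , drop = FALSE]
  for (k in seq_len(nrow(regions))) {
    if (nrow(merged) > 0L) {
      last <- nrow(merged)
      touches <- regions$start_idx[k] <= merged$end_idx[last] + 1L
      if (touches && regions$direction[k] == merged$direction[last]) {
        span_p <- .signed_rank_p(d[merged$start_idx[last]:max(merged$end_idx[last],
                                                              regions$end_idx[k])])
        if (span_p < params$p_threshold) {
          merged$end_idx[last] <- max(merged$end_idx[last], regions$end_idx[k])
          next
        }
      }
    }
    merged <- rbind(merged, regions[k, , drop = FALSE])
  }

  # truncate remaining overlaps (opposite directions, or unmergeable) at the
  # overlap midpoint so segments stay pairwise disjoint
  if (nrow(merged) > 1L) {
    for (k in seq_len(nrow(merged) - 1L)) {
      if (merged$end_idx[k] >= merged$start_idx[k + 1L]) {
        mid <- (merged$start_idx[k + 1L] + merged$end_idx[k]) %/% 2L
        merged$end_idx[k] <- mid
        merged$start_idx[k + 1L] <- mid + 1L
      }
    }
    merged <- merged[merged$end_idx >= merged$start_idx, , drop = FALSE]
  }
  .segments_from_regions(merged, chr_paired, incl)
}

# Build the segment table (genomic span, stats) from included-index regions.
.segments_from_regions <- function(regions, chr_paired, incl) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      first_exon = integer(), last_exon = integer(),
                      n_exons = integer(), direction = character(),
                      p_value = numeric(), mean_log2 = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(regions) || nrow(regions) == 0L) return(empty)
  out <- empty
  for (k in seq_len(nrow(regions))) {
    ii <- incl[regions$start_idx[k]:regions$end_idx[k]]
    p <- .signed_rank_p(chr_paired$case_norm[ii] - chr_paired$control_norm[ii])
    ml2 <- mean(chr_paired$log2_ratio[ii])
    dir <- if (ml2 > 0) "gain" else if (ml2 < 0) "loss" else regions$direction[k]
    out <- rbind(out, data.frame(
      chrom = chr_paired$chrom[1],
      start = chr_paired$start[ii[1]], end = chr_paired$end[ii[length(ii)]],
      first_exon = ii[1], last_exon = ii[length(ii)],
      n_exons = ii[length(ii)] - ii[1] + 1L,
      direction = dir, p_value = p, mean_log2 = ml2,
      stringsAsFactors = FALSE))
  }
  out
}

#' Chromosome-noise (SDF) segment filter
#'
#' Uses the standard deviation of the log2 ratio over all included exons of
#' the chromosome as a surrogate for its intrinsic signal noise and discards
#' candidate segments whose `|mean_log2|` falls below `sdf` times it.
#'
#' @param segments Segment table for one chromosome.
#' @param chr_paired `"paired_coverage"` rows of that chromosome.
#' @param params A [cna_params()].
#' @return The filtered segment table.
#' @export
apply_sdf <- function(segments, chr_paired, params) {
  if (params$sdf == 0 || nrow(segments) == 0L) return(segments)
  l2 <- chr_paired$log2_ratio[!chr_paired$excluded]
  l2 <- l2[is.finite(l2)]
  s <- stats::sd(l2)
  if (!is.finite(s)) return(segments)
  segments[abs(segments$mean_log2) >= params$sdf * s, , drop = FALSE]
}

#' Call CNA segments on a normalized paired-coverage table
#'
#' Runs the full per-chromosome pipeline: seed scan, expansion, merging and
#' the SDF filter. Deterministic: identical input and parameters yield an
#' identical segment list.
#'
#' @param paired A `"paired_coverage"` table ([normalize_coverage()]).
#' @param params A [cna_params()] or preset name for [resolve_preset()].
#' @return A `data.frame` of class `"cna_segments"` with columns `chrom`,
#'   `start`, `end` (BED convention: start of first exon, end of last),
#'   `first_exon`, `last_exon` (1-based exon indices within the chromosome),
#'   `n_exons`, `direction`, `p_value`, `mean_log2`.
#' @export
call_cna <- function(paired, params = resolve_preset("small")) {
  if (is.character(params)) params <- resolve_preset(params)
  segs <- list()
  for (chr in unique(paired$chrom)) {
    cp <- paired[paired$chrom == chr, , drop = FALSE]
    rownames(cp) <- NULL
    if (sum(!cp$excluded) < params$window_size) {
      if (nrow(cp) > 0L)
        warning("chromosome ", chr, " skipped: fewer included exons than the window")
      next
    }
    seeds <- find_seeds(cp, params)
    s <- expand_and_merge(seeds, cp, params)
    s <- apply_sdf(s, cp, params)
    segs[[chr]] <- s
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    .segments_from_regions(NULL, paired, integer())
  rownames(out) <- NULL
  class(out) <- c("cna_segments", "data.frame")
  out
}
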
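# Matched-pairs Wilcoxon signed-rank machinery used by the CNA caller.
#
# Two p-value regimes:
#   * n_nonzero <= 10: exact enumeration of all 2^Nr sign assignments applied
#     to the observed (possibly tied, mid-ranked) ranks.
#   * n_nonzero  > 10: mean-zero normal approximation with Yates continuity
#     correction, tail area evaluated with a polynomial error-function
#     approximation (Abramowitz & Stegun 7.1.26 coefficients).

.exopair_cache <- new.env(parent = emptyenv())

#' Polynomial approximation of the error function
#'
#' Evaluates erf(x) with the five-term Abramowitz & Stegun 7.1.26 polynomial
#' (maximum absolute error 1.5e-7). Negative arguments are handled through the
#' odd symmetry erf(-x) = -erf(x).
#'
#' @param x Numeric vector.
#' @return Numeric vector of erf values in (-1, 1).
#' @examples
#' approximate_erf(c(0, 1, 2))
#' @export
approximate_erf <- function(x) {
  a1 <- 0.254829592
  a2 <- -0.284496736
  a3 <- 1.421413741
  a4 <- -1.453152027
  a5 <- 1.061405429
  q <- 0.3275911
  s <- sign(x)
  ax <- abs(x)
  t <- 1 / (1 + q * ax)
  poly <- ((((a5 * t + a4) * t + a3) * t + a2) * t + a1) * t
  s * (1 - poly * exp(-ax * ax))
}

# All 2^n sign vectors as a (2^n x n) matrix of +/-1, cached per n.
.sign_matrix <- function(n) {
  key <- as.character(n)
  m <- .exopair_cache[[key]]
  if (is.null(m)) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n), KEEP.OUT.ATTRS = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    .exopair_cache[[key]] <- m
  }
  m
}

# Exact two-sided p over all sign assignments of the observed ranks.
.exact_signed_rank_p <- function(r, W) {
  n <- length(r)
  if (n == 0L) return(1)
  Wall <- .sign_matrix(n) %*% r
  mean(abs(Wall) >= abs(W) - 1e-9)
}

# Normal-approximation p with Yates correction; |W| shrunk by 0.5 toward 0.
.normal_signed_rank_p <- function(W, n_nonzero) {
  sigma_w <- sqrt(n_nonzero * (n_nonzero + 1) * (2 * n_nonzero + 1) / 6)
  z <- (abs(W) - 0.5) / sigma_w
  if (z < 0) z <- 0
  p <- 1 - approximate_erf(z / sqrt(2))
  list(sigma_w = sigma_w, z = z, p = min(max(p, 0), 1))
}

#' Matched-pairs Wilcoxon signed-rank test
#'
#' Computes the signed-rank statistic W = sum(sign(d) * rank(|d|)) over the
#' pairwise differences d = case - control. Zero differences are discarded;
#' ties in |d| receive mid-ranks. With at most 10 nonzero differences the
#' two-sided p-value is exact (enumeration of all sign assignments of the
#' observed ranks); above 10 it uses the continuity-corrected normal
#' approximation with [approximate_erf()].
#'
#' @param case_vals,control_vals Equal-length numeric vectors of paired
#'   measurements.
#' @return A list of class `"exopair_wilcoxon"` with elements `n_pairs`,
#'   `n_nonzero`, `W`, `sigma_w`, `z`, `p_value` and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_matched_pairs(c(2, 3, 4), c(1, 1, 1))
#' @export
wilcoxon_matched_pairs <- function(case_vals, control_vals) {
  if (length(case_vals) != length(control_vals))
    stop("case and control vectors must have the same length")
  if (length(case_vals) < 1L)
    stop("need at least one pair")
  d <- case_vals - control_vals
  d <- d[d != 0]
  nr <- length(d)
  n <- length(case_vals)
  if (nr == 0L) {
    res <- list(n_pairs = n, n_nonzero = 0L, W = 0, sigma_w = NA_real_,
                z = NA_real_, p_value = 1, method = "exact")
  } else {
    r <- rank(abs(d))
    W <- sum(sign(d) * r)
    if (nr <= 10L) {
      res <- list(n_pairs = n, n_nonzero = nr, W = W, sigma_w = NA_real_,
                  z = NA_real_, p_value = .exact_signed_rank_p(r, W),
                  method = "exact")
    } else {
      na <- .normal_signed_rank_p(W, nr)
      res <- list(n_pairs = n, n_nonzero = nr, W = W, sigma_w = na$sigma_w,
                  z = na$z, p_value = na$p, method = "normal_approx")
    }
  }
  class(res) <- "exopair_wilcoxon"
  res
}

#' @export
print.exopair_wilcoxon <- function(x, ...) {
  cat(sprintf("Matched-pairs Wilcoxon: W = %g, N_r = %d (%s), p = %.4g\n",
              x$W, x$n_nonzero, x$method, x$p_value))
  invisible(x)
}

# Fast scalar path used by the segmentation scan: p-value (and direction via
# median difference) from a difference vector, skipping object construction.
.signed_rank_p <- function(d) {
  d <- d[d != 0]
  nr <- length(d)
  if (nr == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  if (nr <= 10L) .exact_signed_rank_p(r, W) else .normal_signed_rank_p(W, nr)$p
}

# Incremental signed-rank state for region expansion. Inserting a value with
# lt smaller, eq equal and the rest larger entries shifts larger ranks by 1,
# moves equal mid-ranks by 0.5 and gives the newcomer rank lt + (eq+2)/2, so
#   W' = W + S_gt + 0.5*S_eq + s*(lt + (eq+2)/2)
# with S_gt/S_eq the sign sums of larger/equal entries — exact also under
# ties. Small regions keep plain arrays (O(nr) per trial, exact enumeration
# available); past 64 entries the state converts to two Fenwick trees over
# the chromosome's pre-bucketed |d| values (O(log m) per trial), which keeps
# whole-chromosome expansions cheap.

.fw_update <- function(tree, i, v) {
  n <- length(tree)
  while (i <= n) {
    tree[i] <- tree[i] + v
    i <- i + bitwAnd(i, -i)
  }
  tree
}

.fw_query <- function(tree, i) {
  s <- 0
  while (i > 0) {
    s <- s + tree[i]
    i <- i - bitwAnd(i, -i)
  }
  s
}

# d: region differences; b: their bucket indices in the chromosome-wide
# sorted unique |d| table; m: number of buckets.
.exp_state_new <- function(d, b, m) {
  nz <- d != 0
  d <- d[nz]
  b <- b[nz]
  r <- rank(abs(d))
  st <- list(mode = "small", ax = abs(d), sg = sign(d), ab = b,
             W = sum(sign(d) * r), nr = length(d), m = m,
             cnt = NULL, ssum = NULL, S = sum(sign(d)))
  if (st$nr > 64L) .exp_state_to_fenwick(st) else st
}

.exp_state_to_fenwick <- function(st) {
  cnt <- numeric(st$m)
  ssum <- numeric(st$m)
  for (k in seq_len(st$nr)) {
    cnt <- .fw_update(cnt, st$ab[k], 1)
    ssum <- .fw_update(ssum, st$ab[k], st$sg[k])
  }
  st$mode <- "fenwick"
  st$cnt <- cnt
  st$ssum <- ssum
  st$ax <- st$sg <- st$ab <- NULL
  st
}

.exp_state_p <- function(st) {
  if (st$nr == 0L) return(1)
  if (st$nr <= 10L) return(.exact_signed_rank_p(rank(st$ax), st$W))
  .normal_signed_rank_p(st$W, st$nr)$p
}

# Trial insertion of difference d (bucket b): list(p, W) without mutation.
.exp_trial <- function(st, d, b) {
  if (d == 0) return(list(p = .exp_state_p(st), W = st$W, zero = TRUE))
  x <- abs(d)
  s <- sign(d)
  if (st$mode == "small") {
    lt <- sum(st$ax < x)
    eq <- sum(st$ax == x)
    S_gt <- sum(st$sg[st$ax > x])
    S_eq <- if (eq > 0) sum(st$sg[st$ax == x]) else 0
  } else {
    c_le <- .fw_query(st$cnt, b)
    lt <- .fw_query(st$cnt, b - 1L)
    eq <- c_le - lt
    S_le <- .fw_query(st$ssum, b)
    S_eq <- S_le - .fw_query(st$ssum, b - 1L)
    S_gt <- st$S - S_le
  }
  W <- st$W + S_gt + 0.5 * S_eq + s * (lt + (eq + 2) / 2)
  nr <- st$nr + 1L
  p <- if (nr <= 10L) .exact_signed_rank_p(rank(c(st$ax, x)), W)
       else .normal_signed_rank_p(W, nr)$p
  list(p = p, W = W, zero = FALSE)
}

# Commit a trial previously computed with .exp_trial().
.exp_commit <- function(st, d, b, trial) {
  if (trial$zero) return(st)
  st$W <- trial$W
  st$nr <- st$nr + 1L
  st$S <- st$S + sign(d)
  if (st$mode == "small") {
    st$ax <- c(st$ax, abs(d))
    st$sg <- c(st$sg, sign(d))
    st$ab <- c(st$ab, b)
    if (st$nr > 64L) st <- .exp_state_to_fenwick(st)
  } else {
    st$cnt <- .fw_update(st$cnt, b, 1)
    st$ssum <- .fw_update(st$ssum, b, sign(d))
  }
  st
}
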
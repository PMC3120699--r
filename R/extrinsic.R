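# Extrinsic information: base-pairing proclivities induced on one sequence
# by the pairing probabilities of another, aggregated over all homologs
# with inverse-identity weighting and max-normalization.

#' Induced base-pairing proclivity matrix
#'
#' The pairing probability of (k, l) in the source sequence induces a
#' proclivity for pairing of (i, j) in the target via the co-incidence
#' probabilities of i with k and of j with l:
#' `v(i,j) = sum_{k < l} p_s(k,l) * c(i,k) * c(j,l)`,
#' with k and l restricted to the thresholded constraint sets (co-incidence
#' entries at or below `tau_c` are dropped). The restricted double sum is
#' evaluated as a product of sparse-thresholded matrices, which reproduces
#' the unconstrained sum exactly when `tau_c = 0`.
#'
#' @param bpp_s Symmetric pairing probability matrix of the source sequence
#'   (previous-iteration estimate).
#' @param cm `coincidence` object relating target (rows) to source
#'   (columns).
#' @param tau_c Co-incidence significance threshold.
#' @return Symmetric N_m x N_m matrix of non-negative proclivities.
#' @export
induced_proclivity <- function(bpp_s, cm, tau_c = 1e-4) {
  stopifnot(inherits(cm, "coincidence"))
  c_thr <- cm$probs
  if (ncol(c_thr) != nrow(bpp_s)) {
    stop(sprintf("dimension mismatch: coincidence is %d x %d but source bpp is %d x %d",
                 nrow(c_thr), ncol(c_thr), nrow(bpp_s), ncol(bpp_s)), call. = FALSE)
  }
  c_thr[c_thr <= tau_c] <- 0
  p_upper <- bpp_s
  p_upper[lower.tri(p_upper, diag = TRUE)] <- 0  # orient k < l once
  v <- c_thr %*% p_upper %*% t(c_thr)
  # only the i < j orientation of the product is meaningful; mirror it
  v[lower.tri(v, diag = TRUE)] <- 0
  v <- v + t(v)
  v[v < 0] <- 0
  v
}

#' Aggregate proclivities into extrinsic information
#'
#' Weighted sum of the induced proclivity matrices from all other sequences,
#' each weighted by one minus the pairwise sequence identity (an identical
#' homolog carries no extrinsic information), then normalized so the
#' maximum entry is exactly one. If the weighted sum is identically zero
#' (all identities are 1, or all source probabilities vanish), the neutral
#' all-ones matrix is returned, which reduces the modified partition
#' function to the single-sequence computation.
#'
#' @param proclivities Named list (over source sequences) of proclivity
#'   matrices from [induced_proclivity].
#' @param identities Numeric vector of pairwise identities, aligned with
#'   `proclivities`.
#' @return Symmetric matrix with entries in `[0, 1]`; attribute `neutral`
#'   is `TRUE` for the all-ones degenerate case.
#' @export
aggregate_extrinsic <- function(proclivities, identities) {
  if (length(proclivities) == 0L) {
    stop("no proclivity matrices supplied; use the neutral initialization instead", call. = FALSE)
  }
  if (length(identities) != length(proclivities)) {
    stop("identities and proclivities must align", call. = FALSE)
  }
  raw <- 0
  for (s in seq_along(proclivities)) {   # fixed ascending order for reproducibility
    raw <- raw + (1 - identities[[s]]) * proclivities[[s]]
  }
  mx <- max(raw)
  if (mx <= 0) {
    out <- matrix(1, nrow(proclivities[[1L]]), ncol(proclivities[[1L]]))
    attr(out, "neutral") <- TRUE
    return(out)
  }
  out <- raw / mx
  attr(out, "neutral") <- FALSE
  out
}

#' Neutral (all-ones) extrinsic matrix
#'
#' The initialization used at iteration zero: extrinsic information set to
#' unity everywhere, under which the modified partition function equals the
#' single-sequence partition function.
#'
#' @param n Sequence length.
#' @return `n x n` matrix of ones with attribute `neutral = TRUE`.
#' @export
neutral_extrinsic <- function(n) {
  out <- matrix(1, n, n)
  attr(out, "neutral") <- TRUE
  out
}
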
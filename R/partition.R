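# Modified partition function: Boltzmann ensemble over pseudoknot-free
# canonical structures, with a per-pair pseudo-free-energy contribution from
# extrinsic information, plus the exhaustive-enumeration reference
# implementation used as a test oracle.

#' Modified partition function and base-pairing probabilities
#'
#' Every pseudoknot-free canonical structure S is weighted
#' `exp(-dG0(S)/RT) * prod_{(i,j) in S} ext(i,j)^(gamma/RT)`, i.e. each base
#' pair contributes a pseudo free energy `-gamma * ln ext(i,j)` on top of
#' the nearest-neighbor free energy. The function returns the modified
#' partition function Z' (the sum of weights, with the empty structure
#' contributing weight 1) and the matrix of pairing probabilities
#' `p(i,j) = sum over structures containing (i,j) of weight / Z'`, computed
#' by inside/outside dynamic programming in O(N^3) time. Extrinsic entries
#' are floored at `eps_ext` before the logarithm so that an extrinsic value
#' of zero penalizes a pair heavily but finitely. Bulge and internal loops
#' are capped at 30 unpaired nucleotides (longer interior loops are excluded
#' from the ensemble), the standard convention for nearest-neighbor folding
#' engines.
#'
#' With `ext = NULL` (or an all-ones matrix), or with `gamma = 0`, the
#' result is the unmodified single-sequence partition function.
#'
#' @param seq An [rna_sequence].
#' @param ext Extrinsic information: symmetric N x N matrix with entries in
#'   `[0, 1]` (see [aggregate_extrinsic]), or `NULL` for the neutral
#'   all-ones initialization.
#' @param gamma Weight of the extrinsic information, in kcal/mol
#'   (`gamma >= 0`). The conventional setting is 0.3 RT.
#' @param params Energy parameters from [load_energy_params].
#' @param eps_ext Floor applied to extrinsic entries.
#' @return List with `probs` (symmetric N x N matrix, zero diagonal),
#'   `lnZ`, and `Z = exp(lnZ)` (which may overflow to `Inf` for long
#'   sequences; `lnZ` is always finite).
#' @export
modified_partition <- function(seq, ext = NULL, gamma = 0.3 * params$RT,
                               params = load_energy_params(), eps_ext = 1e-12) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- seq$length
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  if (is.null(ext)) {
    ext <- matrix(1, n, n)
  } else {
    if (!is.matrix(ext) || nrow(ext) != n || ncol(ext) != n) {
      stop(sprintf("extrinsic matrix must be %d x %d", n, n), call. = FALSE)
    }
    if (any(ext < 0) || any(ext > 1)) {
      stop("extrinsic entries must lie in [0, 1]", call. = FALSE)
    }
  }
  maxloop <- 30L
  tabs <- energy_tables_for_dp(n, maxloop, params)
  res <- .partition_cpp(residue_codes(seq), ext, gamma, eps_ext,
                        params$RT, params$min_hairpin, maxloop,
                        params$stack, tabs$hairpin, tabs$bulge, tabs$internal,
                        params$multibranch$offset, params$multibranch$per_branch,
                        params$multibranch$per_unpaired, tabs$aupen)
  list(probs = res$probs, lnZ = res$lnZ, Z = exp(res$lnZ))
}

# Flatten loop tables into dense per-length vectors for the C++ core.
energy_tables_for_dp <- function(n, maxloop, params) {
  big <- 1e30  # lengths below the tabulated minimum can never occur in the DP
  hp <- vapply(0:n, function(k) {
    if (k < params$hairpin$first_length) big else hairpin_energy(k, params)
  }, numeric(1L))
  bu <- vapply(0:maxloop, function(k) {
    if (k < params$bulge$first_length) big else bulge_energy(k, params)
  }, numeric(1L))
  it <- vapply(0:maxloop, function(k) {
    if (k < params$internal$first_length) big else internal_energy(k, params)
  }, numeric(1L))
  aupen <- ifelse(PAIR_TYPES %in% c("AU", "UA", "GU", "UG"),
                  params$terminal_au_penalty, 0)
  list(hairpin = hp, bulge = bu, internal = it, aupen = aupen)
}

#' Unpaired probabilities from a pairing probability matrix
#'
#' `q(i) = 1 - sum_j p(i, j)`, clipped to `[0, 1]`: the probability that
#' nucleotide i is not paired with any other nucleotide in the ensemble.
#'
#' @param m Symmetric pairing probability matrix (from
#'   [modified_partition]).
#' @return Numeric vector `q` of length `nrow(m)`.
#' @export
unpaired_probabilities <- function(m) {
  q <- 1 - rowSums(m)
  pmin(pmax(q, 0), 1)
}

#' Enumerate all pseudoknot-free canonical structures
#'
#' Recursive enumeration (with memoization over subintervals) of every set
#' of canonical base pairs on `seq` that is pseudoknot-free and respects the
#' minimum hairpin length. Intended for small sequences; the companion
#' [count_structures] uses an independent dynamic-programming recursion and
#' serves as a cross-check on the enumeration.
#'
#' @param seq An [rna_sequence] with at most `max_n` residues.
#' @param params Energy parameters (only `min_hairpin` is used).
#' @param max_n Enumeration guard.
#' @return List of two-column pair matrices (the first entry is the empty
#'   structure).
#' @export
enumerate_structures <- function(seq, params = load_energy_params(), max_n = 20L) {
  n <- seq$length
  if (n > max_n) stop(sprintf("refusing to enumerate structures for N = %d > %d", n, max_n), call. = FALSE)
  r <- seq$residues
  minhp <- params$min_hairpin
  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), ncol = 2L)
  recur <- function(i, j) {
    if (i > j) return(list(empty))
    key <- paste0(i, ".", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- recur(i + 1L, j)  # i unpaired
    ks <- seq_len(0L)
    if (j >= i + minhp + 1L) ks <- (i + minhp + 1L):j
    for (k in ks) {
      if (can_pair(r[i], r[k])) {
        inner <- recur(i + 1L, k - 1L)
        outer <- recur(k + 1L, j)
        for (a in inner) {
          for (b in outer) {
            out <- c(out, list(rbind(c(i, k), a, b)))
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  recur(1L, n)
}

#' Count pseudoknot-free canonical structures
#'
#' Independent interval dynamic program counting the structures that
#' [enumerate_structures] lists one by one.
#'
#' @inheritParams enumerate_structures
#' @return Structure count (including the empty structure).
#' @export
count_structures <- function(seq, params = load_energy_params()) {
  n <- seq$length
  r <- seq$residues
  minhp <- params$min_hairpin
  if (n < 2L) return(1)
  cnt <- matrix(1, n + 2L, n + 2L)  # cnt[i, j] for interval i..j; empty interval = 1
  for (len in 2:n) {
    for (i in 1:(n - len + 1L)) {
      j <- i + len - 1L
      total <- cnt[i + 1L, j]
      if (j >= i + minhp + 1L) {
        for (k in (i + minhp + 1L):j) {
          if (can_pair(r[i], r[k])) {
            inner <- if (k - 1L >= i + 1L) cnt[i + 1L, k - 1L] else 1
            outer <- if (j >= k + 1L) cnt[k + 1L, j] else 1
            total <- total + inner * outer
          }
        }
      }
      cnt[i, j] <- total
    }
  }
  cnt[1L, n]
}

#' Brute-force pairing probabilities by structure enumeration
#'
#' Reference implementation of [modified_partition]: enumerates every
#' pseudoknot-free canonical structure, weights each by
#' `exp(-dG0/RT) * prod ext^(gamma/RT)` using [structure_free_energy], and
#' accumulates the pairing probabilities explicitly. Shares no code with
#' the dynamic-programming path and is used as the test oracle.
#'
#' @inheritParams modified_partition
#' @return List with `probs`, `lnZ`, `Z`, and `n_structures`.
#' @export
brute_force_pair_probs <- function(seq, ext = NULL, gamma = 0.3 * params$RT,
                                   params = load_energy_params(), eps_ext = 1e-12) {
  n <- seq$length
  if (n > 20L) stop("brute force restricted to N <= 20", call. = FALSE)
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  if (is.null(ext)) ext <- matrix(1, n, n)
  structs <- enumerate_structures(seq, params)
  extf <- pmax(ext, eps_ext)
  z <- 0
  num <- matrix(0, n, n)
  for (s in structs) {
    st <- secondary_structure(s, n)
    wgt <- exp(-structure_free_energy(seq, st, params) / params$RT)
    if (nrow(s) > 0L) {
      wgt <- wgt * prod(extf[s]^(gamma / params$RT))
    }
    z <- z + wgt
    if (nrow(st$pairs) > 0L) {
      num[st$pairs] <- num[st$pairs] + wgt
    }
  }
  probs <- num / z
  probs <- probs + t(probs)
  list(probs = probs, lnZ = log(z), Z = z, n_structures = length(structs))
}
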
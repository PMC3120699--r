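# Pairwise alignment hidden Markov model: posterior co-incidence
# probabilities, maximum-likelihood (Viterbi) alignments, sequence
# identities, and thresholded constraint index sets.

HMM_STATES <- c("ALN", "INS1", "INS2")
RESIDUES <- c("A", "C", "G", "U")

residue_codes <- function(seq) {
  match(seq$residues, RESIDUES) - 1L
}

#' Load pairwise alignment HMM parameters
#'
#' Reads the three parameter blocks (transition, match_emission,
#' insert_emission) from a YAML file and validates the stochasticity
#' invariants: each transition row and each emission table sums to one
#' (within 1e-12 of rounding) and every probability is strictly positive,
#' so that no alignment path is forbidden outright. The silent begin state
#' enters the three states with the stationary distribution of the
#' transition matrix; ending is allowed from any state.
#'
#' @param path Path to a YAML file, or `NULL` for the built-in defaults.
#' @return List of class `hmm_params` with `transition` (3 x 3), `init`
#'   (stationary distribution), `match_emission` (4 x 4) and
#'   `insert_emission` (length 4), plus their logarithms.
#' @export
load_hmm_params <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .coinfold_env$default_hmm
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "hmm_params_v1.yaml", package = "coinfold")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- yaml::read_yaml(path)
  tr <- matrix(NA_real_, 3L, 3L, dimnames = list(HMM_STATES, HMM_STATES))
  for (a in HMM_STATES) for (b in HMM_STATES) {
    v <- raw$transition[[a]][[b]]
    if (is.null(v)) stop(sprintf("hmm params: missing transition %s->%s", a, b), call. = FALSE)
    tr[a, b] <- as.numeric(v)
  }
  me <- matrix(NA_real_, 4L, 4L, dimnames = list(RESIDUES, RESIDUES))
  for (a in RESIDUES) for (b in RESIDUES) {
    v <- raw$match_emission[[a]][[b]]
    if (is.null(v)) stop(sprintf("hmm params: missing match emission %s/%s", a, b), call. = FALSE)
    me[a, b] <- as.numeric(v)
  }
  ie <- vapply(RESIDUES, function(a) as.numeric(raw$insert_emission[[a]]), numeric(1L))
  if (any(tr <= 0) || any(me <= 0) || any(ie <= 0)) {
    stop("hmm params: all probabilities must be strictly positive", call. = FALSE)
  }
  if (any(abs(rowSums(tr) - 1) > 1e-12)) {
    stop("hmm params: transition rows must each sum to 1", call. = FALSE)
  }
  if (abs(sum(me) - 1) > 1e-12 || abs(sum(ie) - 1) > 1e-12) {
    stop("hmm params: emission tables must sum to 1", call. = FALSE)
  }
  # stationary distribution of the transition matrix (left eigenvector)
  ev <- eigen(t(tr))
  k <- which.min(abs(ev$values - 1))
  init <- Re(ev$vectors[, k])
  init <- init / sum(init)
  names(init) <- HMM_STATES
  params <- structure(list(
    transition = tr, init = init, match_emission = me, insert_emission = ie,
    log_transition = log(tr), log_init = log(init),
    log_match = log(me), log_insert = log(ie),
    source = path
  ), class = "hmm_params")
  if (cache) .coinfold_env$default_hmm <- params
  params
}

#' Forward-backward posteriors on the pairwise alignment lattice
#'
#' Computes, for every lattice cell (i, k) and each of the three states, the
#' posterior probability that a complete alignment path emits residue i of
#' `x_m` and/or residue k of `x_s` at that cell in that state. All
#' recursions are performed in log space, so sequences of length 500 and
#' beyond do not underflow.
#'
#' @param x_m,x_s [rna_sequence] objects (both non-empty).
#' @param params Parameters from [load_hmm_params].
#' @return List with `aln`, `ins1`, `ins2` (N_m x N_s posterior matrices),
#'   `loglik` (log of the forward terminal value) and `total_probability`.
#' @export
forward_backward <- function(x_m, x_s, params = load_hmm_params()) {
  stopifnot(inherits(x_m, "rna_sequence"), inherits(x_s, "rna_sequence"))
  res <- .hmm_posteriors_cpp(residue_codes(x_m), residue_codes(x_s),
                             params$log_transition, params$log_init,
                             params$log_match, params$log_insert)
  res$total_probability <- exp(res$loglik)
  res
}

#' Posterior co-incidence probability matrix for a sequence pair
#'
#' The co-incidence probability of positions (i, k) is the total posterior
#' mass of complete alignment paths that visit lattice cell (i, k) in any of
#' the three states -- aligned, or inserted in either sequence. The
#' `identity` field is the fraction of matching positions along the
#' maximum-likelihood alignment path (see [sequence_identity]).
#'
#' @param x_m,x_s [rna_sequence] objects.
#' @param params Parameters from [load_hmm_params].
#' @return Object of class `coincidence`: list with `probs` (N_m x N_s
#'   matrix, entries in `[0, 1]`), `identity`, and the two sequence ids.
#' @export
coincidence <- function(x_m, x_s, params = load_hmm_params()) {
  # co-incidence is a symmetric event: compute each unordered pair in a
  # canonical orientation and transpose, so that coincidence(m, s) equals
  # t(coincidence(s, m)) exactly, not merely to rounding
  key_m <- paste(x_m$id, paste(x_m$residues, collapse = ""))
  key_s <- paste(x_s$id, paste(x_s$residues, collapse = ""))
  if (key_m > key_s) {
    return(t_coincidence(coincidence(x_s, x_m, params)))
  }
  fb <- forward_backward(x_m, x_s, params)
  probs <- fb$aln + fb$ins1 + fb$ins2
  probs[probs > 1] <- 1
  probs[probs < 0] <- 0
  vit <- viterbi(x_m, x_s, params)
  structure(list(probs = probs,
                 identity = sequence_identity(vit$path, x_m, x_s),
                 id_m = x_m$id, id_s = x_s$id),
            class = "coincidence")
}

# Transpose a coincidence object (swap the roles of the two sequences).
t_coincidence <- function(cm) {
  structure(list(probs = t(cm$probs), identity = cm$identity,
                 id_m = cm$id_s, id_s = cm$id_m),
            class = "coincidence")
}

#' Maximum-likelihood alignment path (Viterbi)
#'
#' Returns the alignment path maximizing the joint probability under the
#' HMM. Ties are broken deterministically by the fixed state order
#' ALN < INS1 < INS2 at each traceback step, so the resulting sequence
#' identity is reproducible across platforms.
#'
#' @param x_m,x_s [rna_sequence] objects.
#' @param params Parameters from [load_hmm_params].
#' @return List with `path` (matrix with columns state, i, k; state coded
#'   1 = ALN, 2 = INS1, 3 = INS2) and `logprob` of that path.
#' @export
viterbi <- function(x_m, x_s, params = load_hmm_params()) {
  stopifnot(inherits(x_m, "rna_sequence"), inherits(x_s, "rna_sequence"))
  .hmm_viterbi_cpp(residue_codes(x_m), residue_codes(x_s),
                   params$log_transition, params$log_init,
                   params$log_match, params$log_insert)
}

#' Sequence identity along an alignment path
#'
#' The fraction of path positions, counting ALN, INS1 and INS2 columns
#' alike, in which the two sequences carry identical residues (only ALN
#' columns can match).
#'
#' @param path Path matrix from [viterbi].
#' @param x_m,x_s The aligned [rna_sequence] objects.
#' @return Identity value in `[0, 1]`.
#' @export
sequence_identity <- function(path, x_m, x_s) {
  if (nrow(path) == 0L) return(0)
  aln <- path[, 1L] == 1L
  matches <- sum(x_m$residues[path[aln, 2L]] == x_s$residues[path[aln, 3L]])
  matches / nrow(path)
}

#' Thresholded co-incidence constraint sets
#'
#' For each position i of the first sequence, the set of positions k of the
#' second sequence whose co-incidence probability strictly exceeds the
#' significance threshold `tau_c`. Restricting the extrinsic-information
#' sums to these sets reduces the per-entry cost to O(d^2), where d is the
#' average set size.
#'
#' @param cm A `coincidence` object.
#' @param tau_c Significance threshold, `0 <= tau_c < 1`.
#' @return List of class `constraint_sets` with `sets` (list over i of
#'   integer vectors of k), `d` (average set size) and `tau_c`.
#' @export
constraint_sets <- function(cm, tau_c = 1e-4) {
  stopifnot(inherits(cm, "coincidence"), tau_c >= 0, tau_c < 1)
  sets <- apply(cm$probs > tau_c, 1L, which, simplify = FALSE)
  structure(list(sets = sets,
                 d = mean(lengths(sets)),
                 tau_c = tau_c),
            class = "constraint_sets")
}
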
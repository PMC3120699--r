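# Structure prediction from base-pairing probabilities: probability
# thresholding and maximum expected accuracy dynamic programming.

#' Threshold a base-pairing probability matrix
#'
#' Retains exactly the pairs whose estimated probability strictly exceeds
#' `p_thresh`. Any threshold greater than 0.5 guarantees a valid secondary
#' structure, because two mutually incompatible pairs cannot both carry
#' more than half the ensemble mass; for `p_thresh <= 0.5` the retained
#' set may contain crossing pairs or positions pairing twice, so only the
#' `i < j` bound is enforced and the result is flagged accordingly.
#'
#' @param m Symmetric pairing probability matrix.
#' @param p_thresh Significance level, `0 < p_thresh <= 1`.
#' @return A [secondary_structure] with attributes `p_thresh` and
#'   `validity_class` (`"guaranteed_valid"` or `"unchecked"`).
#' @export
threshold_structure <- function(m, p_thresh) {
  stopifnot(p_thresh > 0, p_thresh <= 1)
  n <- nrow(m)
  idx <- which(upper.tri(m) & m > p_thresh, arr.ind = TRUE)
  guaranteed <- p_thresh > 0.5
  st <- secondary_structure(idx, n, validate = if (guaranteed) "full" else "partial")
  attr(st, "p_thresh") <- p_thresh
  attr(st, "validity_class") <- if (guaranteed) "guaranteed_valid" else "unchecked"
  st
}

#' Maximum expected accuracy structure
#'
#' Returns the pseudoknot-free structure maximizing
#' `sum_{(i,j) in S} pair_weight * p(i,j) + sum_{i unpaired} q(i)`
#' via an O(N^3) interval dynamic program. Ties are broken
#' deterministically, preferring the unpaired option and then the pair with
#' the smaller span. The default `pair_weight = 2` counts both nucleotides
#' of a correctly predicted pair, the common convention for
#' expected-accuracy estimators. Pairs below the minimum hairpin length
#' carry probability zero from the partition function and are therefore
#' never selected; no extra constraint is needed in the DP.
#'
#' @param m Symmetric pairing probability matrix.
#' @param q Unpaired probabilities, consistent with `m` (see
#'   [unpaired_probabilities]); computed from `m` if omitted.
#' @param pair_weight Positive weight on paired positions.
#' @return A [secondary_structure] with attribute `score`.
#' @export
mea_structure <- function(m, q = unpaired_probabilities(m), pair_weight = 2) {
  stopifnot(pair_weight > 0, length(q) == nrow(m))
  res <- .mea_cpp(m, q, pair_weight)
  st <- secondary_structure(res$pairs, length(q))
  attr(st, "score") <- res$score
  st
}

#' Brute-force maximum expected accuracy
#'
#' Exhaustively maximizes the MEA objective over every pseudoknot-free
#' structure on the candidate pairs with positive probability. Independent
#' of the dynamic program in [mea_structure]; the two scores must agree
#' exactly on any instance small enough to enumerate.
#'
#' @inheritParams mea_structure
#' @param max_n Enumeration guard.
#' @return List with `score` and `structure`.
#' @export
brute_force_mea <- function(m, q = unpaired_probabilities(m), pair_weight = 2,
                            max_n = 16L) {
  n <- length(q)
  if (n > max_n) stop(sprintf("refusing brute-force MEA for N = %d > %d", n, max_n), call. = FALSE)
  cand <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  best_score <- sum(q)
  best_pairs <- matrix(integer(0), ncol = 2L)
  k <- nrow(cand)
  if (k > 18L) {
    stop(sprintf("refusing brute-force MEA over %d candidate pairs (limit 18)", k), call. = FALSE)
  }
  if (k > 0L) {
    # depth-first over subsets of candidate pairs, pruning incompatibilities
    compatible <- function(sel, row) {
      i <- cand[row, 1L]; j <- cand[row, 2L]
      for (r in sel) {
        a <- cand[r, 1L]; b <- cand[r, 2L]
        if (i == a || i == b || j == a || j == b) return(FALSE)
        if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) return(FALSE)
      }
      TRUE
    }
    recur <- function(row, sel, score) {
      if (row > k) {
        if (score > best_score) {
          best_score <<- score
          best_pairs <<- cand[sel, , drop = FALSE]
        }
        return(invisible())
      }
      recur(row + 1L, sel, score)  # skip this pair
      if (compatible(sel, row)) {
        i <- cand[row, 1L]; j <- cand[row, 2L]
        recur(row + 1L, c(sel, row),
              score + pair_weight * m[i, j] - q[i] - q[j])
      }
      invisible()
    }
    recur(1L, integer(0), sum(q))
  }
  list(score = best_score,
       structure = secondary_structure(best_pairs, n))
}
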
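# Sensitivity and PPV of a predicted structure against a known structure,
# with single-position slippage tolerance.

# TRUE for each pair in `a` that has a slippage match in pair set `b`:
# (i, j), (i-1, j), (i+1, j), (i, j-1) or (i, j+1) is in `b`.
slippage_hits <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  keys <- paste(b[, 1L], b[, 2L])
  vapply(seq_len(nrow(a)), function(r) {
    i <- a[r, 1L]; j <- a[r, 2L]
    any(paste(c(i, i - 1L, i + 1L, i, i),
              c(j, j, j, j - 1L, j + 1L)) %in% keys)
  }, logical(1L))
}

#' Score a predicted structure against a known structure
#'
#' A predicted pair (i, j) counts as correct if the known structure
#' contains (i, j) or any of the four single-position slipped variants
#' (i-1, j), (i+1, j), (i, j-1), (i, j+1) -- the standard tolerance for
#' uncertainty in comparative-analysis structures and thermal fluctuation.
#' PPV is the fraction of predicted pairs with at least one such match;
#' sensitivity is the fraction of known pairs with at least one predicted
#' pair matching under the mirrored rule, so a single predicted pair cannot
#' double-count two known pairs. A ratio with zero denominator is reported
#' as 0 and flagged.
#'
#' @param predicted,known [secondary_structure] objects on the same
#'   sequence length.
#' @return List of class `prediction_score` with `sensitivity`, `ppv`,
#'   `f_measure`, counts `n_known`, `n_predicted`, `n_correct`, and flags
#'   `empty_prediction` / `empty_known`.
#' @examples
#' p <- secondary_structure(rbind(c(3, 9)), 12)
#' k <- secondary_structure(rbind(c(2, 9)), 12)
#' score_structure(p, k)  # slippage (i-1, j) matches: sensitivity 1, PPV 1
#' @export
score_structure <- function(predicted, known) {
  stopifnot(inherits(predicted, "secondary_structure"),
            inherits(known, "secondary_structure"))
  if (predicted$length != known$length) {
    stop("predicted and known structures are on different sequence lengths", call. = FALSE)
  }
  np <- nrow(predicted$pairs)
  nk <- nrow(known$pairs)
  n_correct <- sum(slippage_hits(predicted$pairs, known$pairs))
  n_correct_known <- sum(slippage_hits(known$pairs, predicted$pairs))
  ppv <- if (np > 0L) n_correct / np else 0
  sens <- if (nk > 0L) n_correct_known / nk else 0
  f <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  structure(list(sensitivity = sens, ppv = ppv, f_measure = f,
                 n_known = nk, n_predicted = np, n_correct = n_correct,
                 empty_prediction = np == 0L, empty_known = nk == 0L),
            class = "prediction_score")
}

#' @export
print.prediction_score <- function(x, ...) {
  cat(sprintf("sensitivity %.4f  PPV %.4f  (known %d, predicted %d, correct %d)\n",
              x$sensitivity, x$ppv, x$n_known, x$n_predicted, x$n_correct))
  invisible(x)
}
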
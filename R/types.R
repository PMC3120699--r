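#' RNA sequence object
#'
#' Constructs an `rna_sequence`: an identifier plus an ordered vector of
#' residues over the alphabet A, C, G, U. Input residues are normalized
#' (lower case folded to upper case, T mapped to U). Any other character,
#' including the ambiguity code N, is rejected: the thermodynamic model and
#' the alignment HMM emissions are defined only over the four unambiguous
#' bases, and silently treating other codes as unpairable would corrupt the
#' probability computations downstream.
#'
#' @param id Non-empty character scalar naming the sequence.
#' @param residues Character vector of single residues, or a single string.
#' @return An object of class `rna_sequence` with fields `id`, `residues`
#'   (character vector, 1-based) and `length`.
#' @examples
#' rna_sequence("ex", "GGGAAACCC")
#' @export
rna_sequence <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("sequence id must be a non-empty string", call. = FALSE)
  }
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  }
  residues <- toupper(as.character(residues))
  residues[residues == "T"] <- "U"
  bad <- which(!residues %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("sequence '%s': invalid residue '%s' at position %d",
                 id, residues[bad[1L]], bad[1L]), call. = FALSE)
  }
  if (length(residues) == 0L) {
    stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  }
  structure(list(id = id, residues = residues, length = length(residues)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, x$length))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
as.character.rna_sequence <- function(x, ...) paste(x$residues, collapse = "")

#' Secondary structure object
#'
#' A set of base pairs \eqn{\{(i_l, j_l)\}} on a sequence of length `n`, with
#' 1-based coordinates and `i < j` for every pair. By default the full
#' validity rules are enforced: indices in range, each position in at most
#' one pair, and no two pairs crossing (the pseudoknot-free condition).
#' Structures obtained by thresholding probability matrices at
#' `p_thresh <= 0.5` may violate the last two rules, so validation can be
#' relaxed to range checks only via `validate = "partial"`.
#'
#' @param pairs Two-column integer matrix (or empty) of (i, j) pairs; a list
#'   of length-2 vectors is also accepted.
#' @param n Sequence length in nucleotides.
#' @param validate `"full"` (default) or `"partial"`.
#' @return Object of class `secondary_structure` with fields `pairs`
#'   (two-column matrix, ordered so i < j, sorted by i) and `length`.
#' @examples
#' secondary_structure(rbind(c(1, 9), c(2, 8)), n = 9)
#' @export
secondary_structure <- function(pairs, n, validate = c("full", "partial")) {
  validate <- match.arg(validate)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("sequence length must be a positive integer", call. = FALSE)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) > 0L) {
    # orient i < j, sort by i for a canonical representation
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, c(2L, 1L)]
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  st <- structure(list(pairs = pairs, length = n), class = "secondary_structure")
  msg <- structure_violation(st, full = identical(validate, "full"))
  if (!is.null(msg)) stop(msg, call. = FALSE)
  st
}

# Returns NULL when valid, otherwise a message describing the first violation.
structure_violation <- function(st, full = TRUE) {
  p <- st$pairs
  n <- st$length
  if (nrow(p) == 0L) return(NULL)
  if (any(p[, 1L] >= p[, 2L])) return("structure has a pair with i >= j")
  if (any(p < 1L) || any(p > n)) {
    return(sprintf("structure has a pair index outside [1, %d]", n))
  }
  if (!full) return(NULL)
  idx <- c(p[, 1L], p[, 2L])
  if (anyDuplicated(idx)) {
    return(sprintf("position %d participates in more than one base pair",
                   idx[anyDuplicated(idx)]))
  }
  if (nrow(p) > 1L) {
    for (a in seq_len(nrow(p) - 1L)) {
      i1 <- p[a, 1L]; j1 <- p[a, 2L]
      b <- (a + 1L):nrow(p)
      crossing <- (p[b, 1L] > i1 & p[b, 1L] < j1 & p[b, 2L] > j1)
      if (any(crossing)) {
        k <- b[which(crossing)[1L]]
        return(sprintf("pairs (%d,%d) and (%d,%d) cross (pseudoknot)",
                       i1, j1, p[k, 1L], p[k, 2L]))
      }
    }
  }
  NULL
}

#' Check full secondary-structure validity
#'
#' Tests the three structural invariants: indices in range with i < j, each
#' nucleotide in at most one pair, and no crossing pairs.
#'
#' @param st A `secondary_structure`.
#' @return `TRUE` if valid; otherwise `FALSE` with the violation message in
#'   attribute `"why"`.
#' @export
is_valid_structure <- function(st) {
  msg <- structure_violation(st, full = TRUE)
  if (is.null(msg)) TRUE else structure(FALSE, why = msg)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d pairs on %d nt\n", nrow(x$pairs), x$length))
  invisible(x)
}

# Partner vector: v[i] = j if (i,j) or (j,i) is a pair, else 0.
partner_vector <- function(st) {
  v <- integer(st$length)
  p <- st$pairs
  if (nrow(p) > 0L) {
    v[p[, 1L]] <- p[, 2L]
    v[p[, 2L]] <- p[, 1L]
  }
  v
}
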
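# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; no stored data files.

rand_seq <- function(n, id = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rna_sequence(id, sample(c("A", "C", "G", "U"), n, replace = TRUE))
}

random_ext <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Exhaustive path-enumeration oracle for the alignment HMM: every legal
# complete state path is enumerated, weighted by init/transition/emission
# probabilities and normalized. Independent of the log-space DP under test.
hmm_enum <- function(x, y, p) {
  p$init <- unname(p$init)
  p$insert_emission <- unname(p$insert_emission)
  n <- x$length
  m <- y$length
  xc <- match(x$residues, c("A", "C", "G", "U"))
  yc <- match(y$residues, c("A", "C", "G", "U"))
  acc <- array(0, c(3, n, m))
  total <- 0
  best <- -Inf
  recur <- function(i, k, state, w, cells) {
    if (i == n && k == m) {
      total <<- total + w
      best <<- max(best, w)
      for (cell in cells) acc[cell[1], cell[2], cell[3]] <<- acc[cell[1], cell[2], cell[3]] + w
      return(invisible())
    }
    for (s2 in 1:3) {
      i2 <- i + (s2 != 3L)
      k2 <- k + (s2 != 2L)
      if (i2 > n || k2 > m) next
      em <- if (s2 == 1L) p$match_emission[xc[i2], yc[k2]] else
        if (s2 == 2L) p$insert_emission[xc[i2]] else p$insert_emission[yc[k2]]
      tr <- if (state == 0L) unname(p$init[s2]) else p$transition[state, s2]
      recur(i2, k2, s2, w * tr * em, c(cells, list(c(s2, i2, k2))))
    }
  }
  recur(0L, 0L, 0L, 1, list())
  list(post = acc / total, total = total, best = best)
}

# Sparse random MEA instance: a handful of candidate pairs with row sums
# kept below one so the matrix is a legitimate pairing probability matrix.
sparse_mea_instance <- function(n, npairs) {
  m <- matrix(0, n, n)
  cand <- which(upper.tri(m), arr.ind = TRUE)
  pick <- cand[sample.int(nrow(cand), min(npairs, nrow(cand))), , drop = FALSE]
  m[pick] <- runif(nrow(pick), 0.05, 0.6)
  m <- m + t(m)
  mx <- max(rowSums(m))
  if (mx > 1) m <- m / (mx * 1.01)
  m
}

expect_valid_structure <- function(st) {
  ok <- is_valid_structure(st)
  expect_true(isTRUE(ok), info = if (!isTRUE(ok)) attr(ok, "why") else NULL)
}
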
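# Small hand-checkable coincidence stub used in place of HMM output.
fake_coincidence <- function(probs, identity = 0.5) {
  structure(list(probs = probs, identity = identity, id_m = "m", id_s = "s"),
            class = "coincidence")
}

test_that("a single source pair induces the expected single-term proclivity", {
  # source pair (k,l) = (1,4) with probability 0.8; c(2,1) = 0.5, c(5,4) = 0.6
  bpp_s <- matrix(0, 4, 4)
  bpp_s[1, 4] <- bpp_s[4, 1] <- 0.8
  cmat <- matrix(0, 6, 4)
  cmat[2, 1] <- 0.5
  cmat[5, 4] <- 0.6
  v <- induced_proclivity(bpp_s, fake_coincidence(cmat), tau_c = 0)
  expect_equal(v[2, 5], 0.8 * 0.5 * 0.6)
  expect_equal(v[5, 2], v[2, 5])
  expect_equal(sum(v > 0), 2L)
})

test_that("zero source probabilities induce a zero proclivity matrix", {
  cmat <- matrix(runif(30), 6, 5)
  v <- induced_proclivity(matrix(0, 5, 5), fake_coincidence(cmat), 1e-4)
  expect_true(all(v == 0))
})

test_that("constrained computation equals the unconstrained double-sum oracle", {
  set.seed(41)
  for (rep in 1:5) {
    nm <- sample(5:9, 1)
    ns <- sample(5:9, 1)
    bpp_s <- matrix(0, ns, ns)
    idx <- which(upper.tri(bpp_s), arr.ind = TRUE)
    bpp_s[idx] <- runif(nrow(idx), 0, 0.3)
    bpp_s <- bpp_s + t(bpp_s)
    cmat <- matrix(runif(nm * ns), nm, ns)
    for (tau in c(0, 0.5)) {
      v <- induced_proclivity(bpp_s, fake_coincidence(cmat), tau)
      # naive full scan, restricted to retained co-incidence entries
      cthr <- ifelse(cmat > tau, cmat, 0)
      oracle <- matrix(0, nm, nm)
      for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
        acc <- 0
        for (k in 1:ns) for (l in 1:ns) {
          if (k < l) acc <- acc + bpp_s[k, l] * cthr[i, k] * cthr[j, l]
        }
        oracle[i, j] <- oracle[j, i] <- acc
      }
      expect_lt(max(abs(v - oracle)), 1e-12)
    }
  }
})

test_that("aggregation weights by inverse identity and normalizes the max to one", {
  p1 <- matrix(0, 6, 6)
  p1[2, 5] <- p1[5, 2] <- 0.24
  # identical homolog (psi = 1) contributes nothing: degenerate -> neutral
  agg <- aggregate_extrinsic(list(p1), identities = 1)
  expect_true(attr(agg, "neutral"))
  expect_true(all(agg == 1))
  # psi = 0.5: single entry normalizes to exactly 1
  agg2 <- aggregate_extrinsic(list(p1), identities = 0.5)
  expect_false(attr(agg2, "neutral"))
  expect_equal(agg2[2, 5], 1)
  expect_equal(sum(agg2 > 0), 2L)
  # three-sequence case against direct evaluation
  p2 <- matrix(0, 6, 6)
  p2[1, 4] <- p2[4, 1] <- 0.5
  p2[2, 5] <- p2[5, 2] <- 0.1
  raw <- (1 - 0.3) * p1 + (1 - 0.8) * p2
  agg3 <- aggregate_extrinsic(list(p1, p2), identities = c(0.3, 0.8))
  expect_equal(agg3, raw / max(raw), ignore_attr = TRUE)
  expect_equal(max(agg3), 1)
})

test_that("aggregation edge cases error or fall back to neutral", {
  expect_error(aggregate_extrinsic(list(), numeric(0)), "neutral initialization")
  z <- matrix(0, 4, 4)
  agg <- aggregate_extrinsic(list(z, z), identities = c(0.2, 0.4))
  expect_true(attr(agg, "neutral"))
  expect_true(all(neutral_extrinsic(3) == 1))
})

test_that("dimension mismatches are detected", {
  expect_error(
    induced_proclivity(matrix(0, 4, 4), fake_coincidence(matrix(0, 6, 5)), 0),
    "mismatch")
})
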
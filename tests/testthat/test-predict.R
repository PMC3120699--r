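test_that("thresholding keeps exactly the strict exceedances", {
  m <- matrix(0, 10, 10)
  m[2, 8] <- m[8, 2] <- 0.7
  st <- threshold_structure(m, 0.6)
  expect_equal(st$pairs, rbind(c(2L, 8L)))
  expect_equal(attr(st, "validity_class"), "guaranteed_valid")
  # strict inequality at the boundary
  expect_equal(nrow(threshold_structure(m, 0.7)$pairs), 0L)
  expect_equal(nrow(threshold_structure(m, 1)$pairs), 0L)
})

test_that("raising the threshold never adds a pair", {
  set.seed(51)
  s <- rand_seq(40, "t")
  m <- modified_partition(s)$probs
  prev <- NULL
  for (pt in seq(0.2, 0.95, by = 0.05)) {
    st <- threshold_structure(m, pt)
    keys <- paste(st$pairs[, 1], st$pairs[, 2])
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("thresholds above one half always give fully valid structures", {
  set.seed(52)
  for (rep in 1:8) {
    n <- sample(25:60, 1)
    s <- rand_seq(n, sprintf("v%d", rep))
    ext <- random_ext(n)
    m <- modified_partition(s, ext, 0.3 * load_energy_params()$RT)$probs
    for (pt in seq(0.52, 0.96, by = 0.04)) {
      st <- threshold_structure(m, pt)
      expect_valid_structure(st)
      expect_equal(attr(st, "validity_class"), "guaranteed_valid")
    }
  }
})

test_that("sub-half thresholds are flagged unchecked and may cross", {
  m <- matrix(0, 8, 8)
  m[1, 5] <- m[5, 1] <- 0.4
  m[3, 7] <- m[7, 3] <- 0.4   # crosses (1,5)
  st <- threshold_structure(m, 0.3)
  expect_equal(attr(st, "validity_class"), "unchecked")
  expect_equal(nrow(st$pairs), 2L)
  expect_false(isTRUE(is_valid_structure(st)))
})

test_that("MEA on an all-zero matrix leaves everything unpaired with score N", {
  n <- 9L
  m <- matrix(0, n, n)
  st <- mea_structure(m)
  expect_equal(nrow(st$pairs), 0L)
  expect_equal(attr(st, "score"), n)
  bf <- brute_force_mea(m)
  expect_equal(bf$score, n)
})

test_that("a dominant pair is selected exactly when it beats the unpaired terms", {
  n <- 8L
  m <- matrix(0, n, n)
  m[1, 7] <- m[7, 1] <- 0.9
  q <- rep(0.1, n)
  st <- mea_structure(m, q, pair_weight = 2)
  expect_equal(st$pairs, rbind(c(1L, 7L)))   # 2 * 0.9 > 0.1 + 0.1
  expect_equal(attr(st, "score"), 1.8 + 0.6)
  bf <- brute_force_mea(m, q, 2)
  expect_equal(bf$score, attr(st, "score"))
  # with a pair weight too small the pair loses to the unpaired option
  st2 <- mea_structure(m, q, pair_weight = 0.2)
  expect_equal(nrow(st2$pairs), 0L)
})

test_that("DP score equals exhaustive maximization on random sparse instances", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(8:14, 1)
    m <- sparse_mea_instance(n, sample(6:12, 1))
    q <- unpaired_probabilities(m)
    st <- mea_structure(m, q)
    bf <- brute_force_mea(m, q)
    expect_equal(attr(st, "score"), bf$score, tolerance = 1e-12)
    # the returned structure achieves the returned score under the objective
    paired <- unique(as.vector(st$pairs))
    recomputed <- sum(2 * m[st$pairs]) + sum(q[setdiff(seq_len(n), paired)])
    expect_equal(recomputed, attr(st, "score"), tolerance = 1e-12)
    expect_valid_structure(st)
  }
})

test_that("MEA output on partition matrices is always a valid structure", {
  set.seed(54)
  for (rep in 1:5) {
    s <- rand_seq(sample(30:60, 1), sprintf("m%d", rep))
    m <- modified_partition(s)$probs
    expect_valid_structure(mea_structure(m))
  }
})

test_that("enumeration guards refuse oversized instances", {
  expect_error(brute_force_mea(matrix(0, 20, 20)), "N = 20 > 16")
})
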
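test_that("hmm parameter file satisfies the stochasticity invariants", {
  p <- load_hmm_params()
  expect_equal(unname(rowSums(p$transition)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(p$match_emission), 1, tolerance = 1e-12)
  expect_equal(sum(p$insert_emission), 1, tolerance = 1e-12)
  expect_true(all(p$transition > 0) && all(p$match_emission > 0))
  # begin distribution is stationary for the transition matrix
  expect_equal(unname(as.vector(p$init %*% p$transition)), unname(p$init), tolerance = 1e-12)
})

test_that("every complete path visits cell (1,1) for length-1 sequences", {
  a <- rna_sequence("a", "A")
  b <- rna_sequence("b", "A")
  fb <- forward_backward(a, b)
  expect_equal(fb$aln[1, 1] + fb$ins1[1, 1] + fb$ins2[1, 1], 1, tolerance = 1e-12)
  expect_equal(coincidence(a, b)$probs[1, 1], 1, tolerance = 1e-12)
})

test_that("forward-backward posteriors match exhaustive path enumeration", {
  p <- load_hmm_params()
  set.seed(21)
  for (rep in 1:12) {
    x <- rand_seq(sample(1:4, 1), "x")
    y <- rand_seq(sample(1:4, 1), "y")
    fb <- forward_backward(x, y, p)
    bf <- hmm_enum(x, y, p)
    expect_lt(max(abs(fb$aln - bf$post[1, , ])), 1e-10)
    expect_lt(max(abs(fb$ins1 - bf$post[2, , ])), 1e-10)
    expect_lt(max(abs(fb$ins2 - bf$post[3, , ])), 1e-10)
    expect_equal(fb$total_probability, bf$total, tolerance = 1e-10)
    # ALN posterior rows are sub-normalized: i aligns to at most one k
    expect_true(all(rowSums(fb$aln) <= 1 + 1e-9))
    expect_true(all(colSums(fb$aln) <= 1 + 1e-9))
  }
})

test_that("viterbi scores match enumeration and identical inputs align on the diagonal", {
  p <- load_hmm_params()
  set.seed(22)
  for (rep in 1:8) {
    x <- rand_seq(sample(2:5, 1), "x")
    y <- rand_seq(sample(2:5, 1), "y")
    vit <- viterbi(x, y, p)
    bf <- hmm_enum(x, y, p)
    expect_equal(exp(vit$logprob), bf$best, tolerance = 1e-10)
  }
  z <- rand_seq(20, "z", seed = 23)
  vit <- viterbi(z, z, p)
  expect_true(all(vit$path[, "state"] == 1L))            # all-ALN diagonal
  expect_equal(sequence_identity(vit$path, z, z), 1)
})

test_that("sequence identity counts matches over all path columns", {
  p <- load_hmm_params()
  a <- rna_sequence("a", "AAAA")
  c4 <- rna_sequence("c", "CCCC")
  vit <- viterbi(a, c4, p)
  expect_equal(sequence_identity(vit$path, a, c4), 0)
  # hand-built path: 10 columns, 4 identical ALN columns
  x <- rna_sequence("x", "ACGUACGUAC")
  y <- rna_sequence("y", "ACGUGAUGGG")  # residues 5-10 all mismatch
  path <- cbind(state = rep(1L, 10L), i = 1:10, k = 1:10)
  expect_equal(sequence_identity(path, x, y), 0.4)
})

test_that("coincidence is transpose-symmetric and identities agree both ways", {
  p <- load_hmm_params()
  set.seed(24)
  for (rep in 1:5) {
    x <- rand_seq(sample(5:30, 1), "x")
    y <- rand_seq(sample(5:30, 1), "y")
    cab <- coincidence(x, y, p)
    cba <- coincidence(y, x, p)
    expect_identical(cab$probs, t(cba$probs))
    expect_identical(cab$identity, cba$identity)
    expect_true(all(cab$probs >= 0 & cab$probs <= 1))
  }
})

test_that("constraint sets retain exactly the entries above the threshold", {
  p <- load_hmm_params()
  x <- rand_seq(12, "x", seed = 25)
  y <- rand_seq(14, "y")
  cm <- coincidence(x, y, p)
  cs <- constraint_sets(cm, 0.5)
  for (i in seq_len(12)) {
    expect_identical(cs$sets[[i]], which(cm$probs[i, ] > 0.5))  # full-scan oracle
  }
  expect_equal(constraint_sets(cm, 0)$d, 14)  # everything retained
  cs1 <- constraint_sets(cm, 1 - 1e-12)
  expect_true(all(lengths(cs1$sets) %in% c(0L, sum(cm$probs > 1 - 1e-12))))
  expect_equal(cs$d, mean(lengths(cs$sets)))
})

test_that("long uniform-random sequences produce finite posteriors", {
  set.seed(26)
  x <- rand_seq(500, "x")
  y <- rand_seq(500, "y")
  cm <- coincidence(x, y)
  expect_true(all(is.finite(cm$probs)))
  expect_true(all(cm$probs >= 0 & cm$probs <= 1))
  expect_gt(max(cm$probs), 0)
})

test_that("empty sequences are rejected", {
  expect_error(rna_sequence("e", character(0)), "empty")
})
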
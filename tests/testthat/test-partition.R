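test_that("a sequence with no canonical pairs has Z = 1 and zero probabilities", {
  s <- rna_sequence("nopair", "AAAAAAAA")
  r <- modified_partition(s)
  expect_equal(r$Z, 1)
  expect_equal(r$lnZ, 0)
  expect_true(all(r$probs == 0))
  expect_equal(count_structures(s), 1)
  expect_length(enumerate_structures(s), 1L)
})

test_that("neutral extrinsic reproduces the unmodified partition function for any gamma", {
  s <- rand_seq(30, seed = 31)
  base <- modified_partition(s, NULL, 0)
  ones <- matrix(1, 30, 30)
  for (g in c(0, 0.3, 1.2) * load_energy_params()$RT) {
    r <- modified_partition(s, ones, g)
    expect_identical(r$probs, base$probs)
    expect_identical(r$lnZ, base$lnZ)
  }
})

test_that("dynamic program matches the enumeration oracle on random instances", {
  ep <- load_energy_params()
  set.seed(32)
  for (rep in 1:15) {
    n <- sample(8:16, 1)
    s <- rand_seq(n, sprintf("r%d", rep))
    ext <- random_ext(n)
    g <- sample(c(0, 0.3, 1.2), 1) * ep$RT
    dp <- modified_partition(s, ext, g, ep)
    bf <- brute_force_pair_probs(s, ext, g, ep)
    expect_lt(max(abs(dp$probs - bf$probs)), 1e-9)
    expect_equal(dp$lnZ, bf$lnZ, tolerance = 1e-9)
    # conservation against the oracle's unpaired probabilities
    q <- unpaired_probabilities(dp$probs)
    expect_lt(max(abs(q - unpaired_probabilities(bf$probs))), 1e-9)
  }
})

test_that("the two independent structure-enumeration strategies agree", {
  set.seed(33)
  for (rep in 1:6) {
    s <- rand_seq(sample(8:14, 1), sprintf("c%d", rep))
    expect_equal(length(enumerate_structures(s)), count_structures(s))
  }
  s <- rna_sequence("gggccc", "GGGAAACCC")
  expect_equal(length(enumerate_structures(s)), count_structures(s))
})

test_that("unpaired probabilities complement row sums and clip correctly", {
  m <- matrix(0, 6, 6)
  expect_equal(unpaired_probabilities(m), rep(1, 6))
  m[1, 4] <- m[4, 1] <- 0.3
  expect_equal(unpaired_probabilities(m)[1], 0.7)
  expect_equal(unpaired_probabilities(m)[4], 0.7)
})

test_that("pairing mass is conserved: row sums plus q equal one", {
  set.seed(34)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    s <- rand_seq(n, sprintf("cons%d", rep))
    ext <- random_ext(n)
    r <- modified_partition(s, ext, 0.3 * load_energy_params()$RT)
    q <- unpaired_probabilities(r$probs)
    expect_lt(max(abs(rowSums(r$probs) + q - 1)), 1e-9)
    expect_true(all(rowSums(r$probs) <= 1 + 1e-9))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("raising extrinsic support for a pair never decreases its probability", {
  ep <- load_energy_params()
  set.seed(35)
  for (rep in 1:5) {
    n <- 20
    s <- rand_seq(n, sprintf("mono%d", rep))
    # pick a canonical pair with nonzero baseline probability
    base <- modified_partition(s)$probs
    cand <- which(upper.tri(base) & base > 1e-6, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ij <- cand[sample.int(nrow(cand), 1), ]
    ext <- matrix(0.5, n, n)
    last <- -Inf
    for (v in c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)) {
      ext[ij[1], ij[2]] <- ext[ij[2], ij[1]] <- v
      p <- modified_partition(s, ext, 0.3 * ep$RT)$probs[ij[1], ij[2]]
      expect_gte(p, last - 1e-12)
      last <- p
    }
  }
})

test_that("invalid inputs are rejected", {
  s <- rand_seq(10, seed = 36)
  expect_error(modified_partition(s, matrix(1, 9, 9)), "10 x 10")
  expect_error(modified_partition(s, matrix(2, 10, 10)), "\\[0, 1\\]")
  expect_error(modified_partition(s, NULL, gamma = -1), "non-negative")
  expect_error(brute_force_pair_probs(rand_seq(25)), "N <= 20")
})

test_that("length-500 partition stays finite at 37 degrees", {
  set.seed(37)
  s <- rand_seq(500, "long")
  r <- modified_partition(s)
  expect_true(is.finite(r$lnZ))
  expect_true(all(is.finite(r$probs)))
  expect_true(all(rowSums(r$probs) <= 1 + 1e-9))
})
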
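test_that("canonical pair rules include wobble and nothing else", {
  expect_true(can_pair("A", "U"))
  expect_true(can_pair("G", "U"))
  expect_true(can_pair("U", "G"))
  expect_false(can_pair("A", "C"))
  expect_false(can_pair("A", "A"))
  # exactly six ordered canonical pairs
  combos <- expand.grid(a = c("A", "C", "G", "U"), b = c("A", "C", "G", "U"))
  expect_equal(sum(can_pair(combos$a, combos$b)), 6L)
})

test_that("parameter file loads, validates, and recomputes RT from T", {
  p <- load_energy_params()
  expect_equal(p$RT, 0.0019872 * 310.15, tolerance = 1e-12)
  expect_equal(p$min_hairpin, 3L)
  # stack table symmetric under reading the helix from the other strand:
  # stack(P, Q) = stack(rev(Q), rev(P))
  rev_pt <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (a in rownames(p$stack)) {
    for (b in colnames(p$stack)) {
      expect_equal(p$stack[a, b], p$stack[rev_pt[b], rev_pt[a]])
    }
  }
})

test_that("hairpin helix energy equals hand-summed stack and loop terms", {
  p <- load_energy_params()
  s <- rna_sequence("hp", "GGGAAACCC")
  st <- secondary_structure(rbind(c(1, 9), c(2, 8), c(3, 7)), 9)
  expected <- 2 * p$stack["GC", "GC"] + p$hairpin$energies[1]  # two stacks + 3-nt loop
  expect_equal(structure_free_energy(s, st, p), expected)

  # terminal AU penalty on a hairpin closed by A-U
  s2 <- rna_sequence("hp2", "AGGAAACCU")
  st2 <- secondary_structure(rbind(c(1, 9), c(2, 8), c(3, 7)), 9)
  expected2 <- p$stack["AU", "GC"] + p$stack["GC", "GC"] + p$hairpin$energies[1] +
    p$terminal_au_penalty  # penalty only at the hairpin-distal A-U end
  expect_equal(structure_free_energy(s2, st2, p), expected2)
})

test_that("empty structure has exactly zero free energy", {
  s <- rand_seq(25, seed = 3)
  expect_identical(structure_free_energy(s, secondary_structure(NULL, 25)), 0)
})

test_that("minimum hairpin and canonical-pair preconditions are enforced", {
  p <- load_energy_params()
  expect_equal(
    structure_free_energy(rna_sequence("ok", "GAAAC"),
                          secondary_structure(rbind(c(1, 5)), 5), p),
    p$hairpin$energies[1])
  expect_error(
    structure_free_energy(rna_sequence("short", "GAAC"),
                          secondary_structure(rbind(c(1, 4)), 4), p),
    "fewer than 3")
  expect_error(
    structure_free_energy(rna_sequence("noncanon", "GAAAA"),
                          secondary_structure(rbind(c(1, 5)), 5), p),
    "non-canonical")
})

test_that("independent exterior helices contribute additively", {
  p <- load_energy_params()
  h1 <- rna_sequence("h1", "GGGAAACCC")
  h2 <- rna_sequence("h2", "GCGAAAACGC")
  st1 <- secondary_structure(rbind(c(1, 9), c(2, 8), c(3, 7)), 9)
  st2 <- secondary_structure(rbind(c(1, 10), c(2, 9), c(3, 8)), 10)
  joint <- rna_sequence("joint", paste0(as.character(h1), as.character(h2)))
  stj <- secondary_structure(rbind(st1$pairs, st2$pairs + 9L), 19)
  expect_equal(structure_free_energy(joint, stj, p),
               structure_free_energy(h1, st1, p) + structure_free_energy(h2, st2, p))
})

test_that("multibranch loops use the linear model with per-branch penalties", {
  p <- load_energy_params()
  # closing pair (1,28); two branches (3,12), (16,25); unpaired: 2,13,14,15,26,27
  seqstr <- paste0("G", "A", "GGGAAAACCC", "AAA", "GGGAAAACCC", "AA", "C")
  s <- rna_sequence("mb", seqstr)
  pairs <- rbind(c(1, 28),
                 c(3, 12), c(4, 11), c(5, 10),
                 c(16, 25), c(17, 24), c(18, 23))
  st <- secondary_structure(pairs, 28)
  mb <- p$multibranch
  expected <- (mb$offset + 3 * mb$per_branch + 6 * mb$per_unpaired) +  # the loop itself
    2 * (2 * p$stack["GC", "GC"] + p$hairpin$energies[2])              # two 4-nt hairpin arms
  expect_equal(structure_free_energy(s, st, p), expected)
})

test_that("loop penalties extrapolate logarithmically past the tables", {
  p <- load_energy_params()
  nmax <- p$hairpin$first_length + length(p$hairpin$energies) - 1L
  e_tab <- p$hairpin$energies[length(p$hairpin$energies)]
  n <- nmax + 11L
  s <- rna_sequence("bigloop", paste0("G", strrep("A", n), "C"))
  st <- secondary_structure(rbind(c(1, n + 2L)), n + 2L)
  expect_equal(structure_free_energy(s, st, p),
               e_tab + p$loop_extrapolation_coeff * p$RT * log(n / nmax))
})
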
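# Seeded generator of homologous RNA families with a conserved consensus
# structure: compensatory mutations at paired positions, point mutations and
# loop-restricted indels at unpaired positions, and an optional variable
# structural arm.

# Built-in cloverleaf template (76 nt, 21 pairs, four helical arms), written
# as segments so the paired strands are complementary by construction.
cloverleaf_template <- function() {
  seq <- paste0(
    "GGCGCGU", "UA", "GCGC", "AGUAGCUA", "GCGC", "A",
    "CGGUA", "CUGCAAU", "UACCG", "AGUCA",
    "GCCGA", "UUCGAUC", "UCGGC", "ACUA", "ACGCGCC"
  )
  db <- paste0(
    "(((((((", "..", "((((", "........", "))))", ".",
    "(((((", ".......", ")))))", ".....",
    "(((((", ".......", ")))))", "....", ")))))))"
  )
  list(seq = rna_sequence("template", seq),
       structure = parse_dotbracket(db),
       arm = 49:65)  # the T-arm: the designated optional element
}

#' Specification of a synthetic RNA family
#'
#' Describes how a family of homologs is derived from a template sequence
#' with a consensus structure: point mutations at unpaired positions at a
#' rate calibrated to the target pairwise identity, compensatory double
#' mutations at paired positions (the pair is replaced by a uniformly
#' chosen canonical pair), insertions and deletions restricted to loops,
#' and an optional variable arm that individual members may lose.
#'
#' @param k Family size.
#' @param target_identity Desired mean pairwise sequence identity
#'   (a statistical target, not an exact constraint).
#' @param indel_rate Per-loop-nucleotide insertion/deletion probability.
#' @param variable_arm_prob Probability that a member loses the designated
#'   optional helix.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param template,consensus Template [rna_sequence] and consensus
#'   [secondary_structure]; defaults to a built-in 76-nt cloverleaf.
#' @param arm Positions of the optional arm within the template.
#' @param mut_rate Explicit per-position substitution rate; overrides the
#'   identity calibration when given (`0` yields exact template copies when
#'   `indel_rate` is also 0).
#' @return List of class `family_spec`.
#' @export
family_spec <- function(k = 5L, target_identity = 0.5, indel_rate = 0.02,
                        variable_arm_prob = 0, seed = 1L,
                        template = NULL, consensus = NULL, arm = NULL,
                        mut_rate = NULL) {
  if (is.null(template) || is.null(consensus)) {
    tpl <- cloverleaf_template()
    template <- tpl$seq
    consensus <- tpl$structure
    if (is.null(arm)) arm <- tpl$arm
  }
  stopifnot(k >= 1, target_identity > 0, target_identity < 1,
            indel_rate >= 0, indel_rate < 1,
            variable_arm_prob >= 0, variable_arm_prob <= 1)
  if (consensus$length != template$length) {
    stop("consensus structure does not match template length", call. = FALSE)
  }
  # template must itself be foldable: canonical pairs, hairpins long enough
  invisible(structure_free_energy(template, consensus))
  structure(list(k = as.integer(k), target_identity = target_identity,
                 indel_rate = indel_rate, variable_arm_prob = variable_arm_prob,
                 seed = as.integer(seed), template = template,
                 consensus = consensus, arm = arm, mut_rate = mut_rate),
            class = "family_spec")
}

CANONICAL_PAIRS <- list(c("A", "U"), c("U", "A"), c("G", "C"),
                        c("C", "G"), c("G", "U"), c("U", "G"))

# Substitution rate giving a desired expected pairwise identity, from the
# closed-form per-position match probabilities between two independently
# mutated copies of the template (see the methods vignette):
#   unpaired: (1-mu)^2 + mu^2/3   (mutation picks one of the 3 other bases)
#   paired:   (1-mu+mu/6)^2 + 5*(mu/6)^2 (pair replaced by 1 of 6 canonical)
# with a correction for the alignment columns that indels add.
calibrate_mutation_rate <- function(target, frac_paired, indel_rate) {
  ident <- function(mu) {
    mu_u <- (1 - mu)^2 + mu^2 / 3
    mu_p <- (1 - mu + mu / 6)^2 + 5 * (mu / 6)^2
    base <- (1 - frac_paired) * mu_u + frac_paired * mu_p
    base * (1 - 2 * indel_rate * (1 - frac_paired))
  }
  lo <- ident(0.95); hi <- ident(0)
  if (target >= hi) return(0)
  if (target <= lo) return(0.95)
  stats::uniroot(function(mu) ident(mu) - target, c(0, 0.95), tol = 1e-6)$root
}

#' Generate a synthetic homologous RNA family
#'
#' Derives `k` sequences from the template of a [family_spec], each with
#' its own true structure: compensatory mutations keep every consensus pair
#' canonical in every member, indels occur only within loops (so each
#' member's true structure is the consensus remapped through its own
#' indels), and a member may lose the designated variable arm. Fully
#' deterministic given `spec$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param spec A [family_spec].
#' @return List with `seqs` (list of [rna_sequence], ids `mem1`..`memK`)
#'   and `structures` (named list of [secondary_structure]).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  tpl <- spec$template$residues
  pv <- partner_vector(spec$consensus)
  n <- length(tpl)
  frac_paired <- mean(pv > 0)
  mu <- if (!is.null(spec$mut_rate)) spec$mut_rate else
    calibrate_mutation_rate(spec$target_identity, frac_paired, spec$indel_rate)

  seqs <- vector("list", spec$k)
  structures <- vector("list", spec$k)
  for (m in seq_len(spec$k)) {
    res <- tpl
    partner <- pv
    keep <- rep(TRUE, n)
    if (length(spec$arm) > 0L && stats::runif(1) < spec$variable_arm_prob) {
      keep[spec$arm] <- FALSE
      partner[spec$arm] <- 0L  # pairs inside the arm disappear with it
    }
    # compensatory replacement of consensus pairs
    for (i in which(partner > 0L & seq_len(n) < partner & keep)) {
      if (stats::runif(1) < mu) {
        np <- CANONICAL_PAIRS[[sample.int(6L, 1L)]]
        res[i] <- np[1L]
        res[partner[i]] <- np[2L]
      }
    }
    # point mutations at unpaired positions
    for (i in which(partner == 0L & keep)) {
      if (stats::runif(1) < mu) {
        res[i] <- sample(setdiff(RESIDUES, res[i]), 1L)
      }
    }
    # loop-restricted indels: each position carries a unit of 0..2 residues
    units <- as.list(res)
    units[!keep] <- list(character(0))
    for (i in which(partner == 0L & keep)) {
      if (stats::runif(1) < spec$indel_rate) {
        if (stats::runif(1) < 0.5) {
          units[[i]] <- character(0)                        # deletion
        } else {
          units[[i]] <- c(res[i], sample(RESIDUES, 1L))     # insertion after i
        }
      }
    }
    lens <- lengths(units)
    newpos <- cumsum(lens) - lens + 1L  # position of the first residue of each unit
    res_new <- unlist(units, use.names = FALSE)
    up <- which(partner > 0L & seq_len(n) < partner & keep)
    pairs <- cbind(newpos[up], newpos[partner[up]])
    seqs[[m]] <- rna_sequence(sprintf("mem%d", m), res_new)
    structures[[m]] <- secondary_structure(pairs, length(res_new))
  }
  names(structures) <- vapply(seqs, `[[`, character(1L), "id")
  list(seqs = seqs, structures = structures)
}
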
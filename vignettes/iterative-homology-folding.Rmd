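---
title: "Iterative homology-informed RNA folding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative homology-informed RNA folding: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinfold)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, the numerical choices made, and
the limits of what its tests demonstrate.

## Overview of the estimator

Given K homologous RNA sequences, `coinfold()` estimates for each sequence
a posterior base-pairing probability matrix by alternating two
computations:

1. **Extrinsic information.** For each target sequence, pairing evidence
   from every other sequence is mapped through pairwise alignment
   co-incidence probabilities and aggregated (details below).
2. **Modified partition function.** The target's pairing probabilities are
   recomputed under its nearest-neighbor thermodynamic model, with the
   extrinsic information entering as a pseudo free energy per base pair.

Iteration t = 0 uses neutral (all-ones) extrinsic information and is
exactly the single-sequence partition function; iterations t = 1..η
recompute every extrinsic matrix from the complete iteration-(t − 1)
snapshot (a synchronous, Jacobi-style sweep). The co-incidence
probabilities themselves are computed once, before iterating, and are not
updated — the iterations refine only the pairing probabilities.

The synchronous sweep is a deliberate design choice with two consequences:
the result is independent of the order in which sequences are processed,
and per-sequence computations inside one iteration can run in parallel
(`threads` in `coinfold_config()`) with bitwise-identical results to a
serial run. Both properties are asserted by tests.

## The alignment model

Pairwise alignments are modeled by a three-state hidden Markov model with
affine-gap semantics: ALN emits one residue from each sequence, INS1 and
INS2 emit a residue from only one. A silent begin state enters the three
states with the stationary distribution of the transition matrix, and a
complete path may end in any state with no end penalty. These begin/end
semantics are the simplest complete-path convention; they are stated here
because posterior values depend on them.

Two positions (i, k) are *co-incident* when a complete alignment path
visits lattice cell (i, k) in any of the three states — aligned, or
inserted in either sequence. Because every path visits a given cell at
most once, the co-incidence probability is the sum of the three per-state
posteriors from the forward–backward algorithm. This "any state visit"
definition is the one computable from the lattice without extra
bookkeeping about where an insertion begins; using co-incidence rather
than strict alignment posteriors lets pairing evidence reach helices whose
lengths differ between homologs.

The shipped parameter file (`inst/extdata/hmm_params_v1.yaml`) uses
match-biased emissions (probability 0.16 per identical pair, 0.03 per
mismatch), uniform insert emissions, gap-open ≈ 0.03 and gap-extend ≈ 0.3.
These are declared defaults, not values trained on alignment databases; a
user file with the same three blocks can be substituted and is validated
against the stochasticity invariants at load. All recursions run in log
space, so 500-nt lattices do not underflow (tested).

The pairwise sequence identity ψ is the fraction of Viterbi-path columns
(counting insertion columns) carrying identical residues. Viterbi ties are
broken by the fixed state order ALN < INS1 < INS2 so ψ is reproducible
across platforms. Since co-incidence is a symmetric event, each unordered
sequence pair is computed once in a canonical orientation and transposed,
making the transpose-symmetry identity exact in floating point rather than
approximate.

## Extrinsic information

The pairing probability of (k, l) in source sequence s induces a
proclivity for pairing (i, j) in target m:

$$\mathrm{prc}^{(m,s)}(i,j) \;=\; \sum_{k<l} p^{s}(k,l)\; c^{(m,s)}(i,k)\; c^{(m,s)}(j,l),$$

with k and l restricted to *constraint sets* — positions whose
co-incidence probability exceeds the threshold `tau_c` (default 1e-4).
The threshold is a pure computational device: with `tau_c = 0` the
restricted sum equals the unconstrained one (tested to 1e-12), and at the
default it discards only negligible posterior mass while making the cost
per entry O(d²) in the mean constraint-set size d. Only the orientation
k < l mapped onto i < j is summed; alignments are monotone, so the
reversed orientation would pair evidence across crossing co-incidences.

Proclivities from all sources are combined as

$$\mathrm{ext}^{(m)} \propto \sum_{s \ne m} (1 - \psi_{m,s})\,\mathrm{prc}^{(m,s)},$$

normalized so the maximum entry is exactly 1. The inverse-identity weight
sets the contribution of an identical homolog to zero — it carries no new
information. When the weighted sum is identically zero (all ψ = 1, or all
source probabilities vanish) the neutral all-ones matrix is substituted,
which by construction reduces the next partition pass to the
single-sequence computation; this matches the initialization semantics.
Normalization by the maximum makes any overall scale factor (for instance
division by K − 1) irrelevant. Sources are summed in ascending index
order for floating-point reproducibility.

## The thermodynamic model

The intrinsic information is a *simplified* nearest-neighbor model,
shipped as a versioned, human-editable YAML file
(`inst/extdata/energy_params_v1.yaml`), with all energies in kcal/mol at
310.15 K (RT = 0.61633 kcal/mol; overriding the temperature in a
parameter file rescales RT consistently):

* **Stacking.** A 6 × 6 table over the canonical pair types
  (AU, UA, GC, CG, GU, UG), generated from an additive pair-strength rule
  −(s(P) + s(Q))/2 with s(GC) = 2.9, s(AU) = 1.1, s(GU) = 0.8 but written
  out entry by entry so individual values can be overridden. The table
  satisfies the strand-reversal symmetry stack(P, Q) = stack(rev Q, rev P).
* **Loops.** Hairpin, bulge and internal loop penalties tabulated by
  unpaired length, extrapolated beyond the tables with the
  Jacobson–Stockmayer form E(n) = E(n_max) + 1.75·RT·ln(n/n_max).
* **Multibranch loops.** Linear model a + b·(branches) + c·(unpaired)
  with a = 3.4, b = 0.4, c = 0.1, the closing pair counting as a branch.
* **Terminal AU/GU penalty** (0.5 kcal/mol) charged in every non-stacking
  context: pairs closing hairpin, bulge, internal and multibranch loops,
  and branch pairs in multibranch and exterior loops.
* **Minimum hairpin** of 3 unpaired nucleotides; the ambiguity code N is
  rejected at input rather than treated as unpairable, because neither the
  energy model nor the HMM emissions are defined over it.

Coaxial stacking, dangling ends, special hairpin bonuses, loop-asymmetry
terms and enthalpy tables are deliberately out of scope: the package's
contribution is the iterative estimator, and the energy model is a
pluggable component behind `load_energy_params()`. All shipped tests and
reported numbers are defined against this table.

## Modified partition function

Each pseudoknot-free canonical structure S is weighted

$$w(S) \;=\; \exp(-\Delta G^{0}(S)/RT)\;\prod_{(i,j)\in S} \mathrm{ext}(i,j)^{\gamma/RT},$$

equivalently a modified free energy ΔG′(S) = ΔG°(S) − γ Σ ln ext(i, j).
The marginal pairing probabilities are computed by inside/outside dynamic
programming over an unambiguous grammar (closed spans, multibranch
segments with ≥ 1 branch, single-branch suffix segments, exterior
prefix/suffix), in O(N³) time and O(N²) memory. Numerical choices:

* **Extrinsic floor.** ext entries are floored at `eps_ext = 1e-12`
  before exponentiation, so a zero prior penalizes a pair heavily but
  finitely and the recursions stay well conditioned. At γ = 0 the prior
  is exactly 1 regardless of ext, which makes the γ → 0 reduction exact.
* **Interior loop cap.** Bulge and internal loops are capped at 30
  unpaired nucleotides, the standard convention of nearest-neighbor
  folding engines; structures with longer interior loops are excluded
  from the ensemble. In the enumeration-oracle regime (N ≤ 18) no
  interior loop can exceed the cap, so the oracle comparison is exact.
* **Extended precision instead of rescaling.** The inside/outside arrays
  are accumulated in `long double`. At N = 500 the largest Boltzmann
  exponents reachable under this model remain far inside the 80-bit
  extended range, so no per-diagonal rescaling is needed; `lnZ` is always
  finite and is the primary scale-free output (`Z = exp(lnZ)` may
  overflow to `Inf` for very long, very stable sequences).

The reference implementation `brute_force_pair_probs()` enumerates every
structure explicitly, weights it with `structure_free_energy()`, and
shares no code with the dynamic program; the test suite requires
agreement to 1e-9 on over a hundred random instances, and a second,
independent counting recursion cross-checks the enumeration itself.

## Structure prediction

**Thresholding** retains pairs with probability strictly above
`p_thresh`. For `p_thresh > 0.5` the result is provably a valid
structure: two incompatible pairs cannot both hold more than half the
ensemble mass. Below 0.5 the pair set may contain pseudoknots or
multi-paired positions; such outputs are flagged `unchecked` and the CLI
writes them as a plain pair list rather than dot-bracket. The strict
inequality follows the "higher than a significance level" semantics and
keeps the boundary case `p_thresh = 0.5` on the safe side. The CLI
default in threshold mode is 0.51, the smallest round value with the
guarantee.

**Maximum expected accuracy** maximizes
Σ_{(i,j)∈S} 2·p(i, j) + Σ_{unpaired} q(i) by a Nussinov-style O(N³) DP.
The pair weight 2 counts both nucleotides of a pair, the common
convention in expected-accuracy estimators; it is exposed as
`pair_weight` because the literature varies. Ties prefer the unpaired
option, then the smaller span, making output deterministic. Pairs below
the minimum hairpin length arrive with probability zero from the
partition function and are never selected, so the DP needs no separate
hairpin constraint.

**Scoring** uses sensitivity and PPV with single-position slippage: a
predicted pair (i, j) is correct if the known structure contains (i, j),
(i±1, j) or (i, j±1). PPV counts predicted pairs with at least one such
match; sensitivity counts known pairs with at least one matching
predicted pair under the mirrored rule, so one predicted pair cannot
satisfy two known pairs twice. Ratios with zero denominators are reported
as zero and flagged.

## Parameter defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| η (`eta`) | 3 | iterations | accuracy gains are marginal beyond three refinement sweeps |
| γ (`gamma`) | 0.3 | RT | balances sensitivity and PPV; larger values trade sensitivity for PPV |
| `tau_c` | 1e-4 | probability | "sufficiently low": discards negligible co-incidence mass, keeps d small |
| `eps_ext` | 1e-12 | probability | finite penalty for zero-prior pairs |
| `p_thresh` | 0.51 | probability | smallest round threshold with the validity guarantee |
| `pair_weight` | 2 | — | counts both nucleotides of a pair |
| `min_hairpin` | 3 | nt | steric minimum for hairpin loops |

## The synthetic family generator

`generate_family()` emulates a homologous ncRNA family with a conserved
consensus: the default template is a 76-nt cloverleaf (four helices,
21 pairs). Members are derived by (a) compensatory replacement of
consensus pairs with uniformly chosen canonical pairs, (b) point
mutations at unpaired positions, (c) indels restricted to loops, with
each member's true structure remapped through its own indels, and (d)
optionally the loss of a designated arm (`variable_arm_prob`), emulating
the variable structural elements common in real families. Generation is
fully deterministic given the seed and restores the caller's RNG state.

The substitution rate is calibrated to the requested mean pairwise
identity in closed form. Between two independently mutated copies, an
unpaired position matches with probability (1 − μ)² + μ²/3 and a paired
position with probability (1 − μ + μ/6)² + 5(μ/6)², and the expected
identity additionally shrinks by the alignment columns that indels add;
inverting this expression for μ gives the rate. The Viterbi-based
identity estimate is biased slightly upward of the raw match probability
(the maximum-likelihood path favors matching columns), which a seeded
test bounds within ±0.08 of the target.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: there is no phylogeny (members are independent
draws from the template, not leaves of a tree), no rate heterogeneity
along the sequence, no non-canonical or pseudoknotted structure in the
truth, and indels never touch helices. Real families violate all four;
results on these fixtures demonstrate correctness of the machinery and
the qualitative value of homology information, not expected accuracy on
biological families.

## Problem sizes used by the tests and the acceptance script

Oracle comparisons use sequences of length 8–18 (partition function,
> 100 instances), alignment pairs of length ≤ 5 (> 100 pairs), and MEA
instances of N ≤ 14 with sparse candidate sets (50 instances) — sizes at
which exhaustive enumeration is itself cheap and trustworthy. Stability
checks run one 500-nt partition computation and one 500 × 500 alignment
lattice. The iteration-improvement property and the acceptance script use
five-member families of the 76-nt cloverleaf at target identity 0.5
(20 and 8 seeded replicates respectively), with η = 3 and γ = 0.3 RT.
These sizes were chosen so that the entire evidence chain — oracles
included — recomputes from scratch in minutes on one core.

## Known limitations

* No structural alignment output: the method refines pairing
  probabilities only, and co-incidence probabilities are fixed after
  initialization.
* The simplified energy model limits absolute single-sequence accuracy;
  the pluggable parameter file is the intended upgrade path.
* Extrinsic information from experimental probing (chemical mapping)
  would slot into the same per-pair prior interface, but no parser for
  such data is provided.
* K = 1 is accepted for testing the reduction property but warns: there
  is no extrinsic information to use.
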
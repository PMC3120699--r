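# coinfold pairwise alignment HMM parameters, version 1.
#
# Three states with affine-gap semantics: ALN emits a residue from each
# sequence jointly, INS1 emits a residue of the first sequence only, INS2 of
# the second only. Transition rows and every emission table sum to one; all
# probabilities are strictly positive so no alignment path is forbidden.
# These are declared defaults (match-biased emissions, gap open ~ 0.03, gap
# extend ~ 0.3), not trained values; a user parameter file with the same
# three blocks can be substituted.
version: 1
transition:
  ALN:  {ALN: 0.94, INS1: 0.03, INS2: 0.03}
  INS1: {ALN: 0.68, INS1: 0.30, INS2: 0.02}
  INS2: {ALN: 0.68, INS1: 0.02, INS2: 0.30}
match_emission:
  A: {A: 0.16, C: 0.03, G: 0.03, U: 0.03}
  C: {A: 0.03, C: 0.16, G: 0.03, U: 0.03}
  G: {A: 0.03, C: 0.03, G: 0.16, U: 0.03}
  U: {A: 0.03, C: 0.03, G: 0.03, U: 0.16}
insert_emission: {A: 0.25, C: 0.25, G: 0.25, U: 0.25}
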
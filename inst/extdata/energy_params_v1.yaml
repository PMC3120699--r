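# coinfold simplified nearest-neighbor free-energy parameters, version 1.
# All energies in kcal/mol at the stated temperature.
#
# Loop-length extrapolation: for unpaired loop lengths n beyond the last
# tabulated length n_max of a table,
#     E(n) = E(n_max) + loop_extrapolation_coeff * RT * ln(n / n_max)
# (Jacobson-Stockmayer form), with RT = 0.0019872 * temperature_kelvin.
#
# The stacking table is an additive pair-strength parameterization:
# stack(P inside Q) = -(s(P) + s(Q)) / 2 with s(GC) = s(CG) = 2.9,
# s(AU) = s(UA) = 1.1, s(GU) = s(UG) = 0.8; the full table is written out so
# that individual entries can be overridden in a drop-in replacement file.
version: 1
temperature_kelvin: 310.15
min_hairpin: 3
terminal_au_penalty: 0.5
loop_extrapolation_coeff: 1.75
stack:
  AU: {AU: -1.10, UA: -1.10, GC: -2.00, CG: -2.00, GU: -0.95, UG: -0.95}
  UA: {AU: -1.10, UA: -1.10, GC: -2.00, CG: -2.00, GU: -0.95, UG: -0.95}
  GC: {AU: -2.00, UA: -2.00, GC: -2.90, CG: -2.90, GU: -1.85, UG: -1.85}
  CG: {AU: -2.00, UA: -2.00, GC: -2.90, CG: -2.90, GU: -1.85, UG: -1.85}
  GU: {AU: -0.95, UA: -0.95, GC: -1.85, CG: -1.85, GU: -0.80, UG: -0.80}
  UG: {AU: -0.95, UA: -0.95, GC: -1.85, CG: -1.85, GU: -0.80, UG: -0.80}
hairpin:            # unpaired lengths 3, 4, ...
  first_length: 3
  energies: [5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4]
bulge:              # unpaired lengths 1, 2, ...
  first_length: 1
  energies: [3.8, 2.8, 3.2, 3.6, 4.0, 4.4]
internal:           # total unpaired lengths 2, 3, ...
  first_length: 2
  energies: [1.5, 1.6, 1.7, 1.8, 2.0, 2.2, 2.3, 2.4, 2.5]
multibranch:
  offset: 3.4
  per_branch: 0.4
  per_unpaired: 0.1
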
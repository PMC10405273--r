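# H2-H2 fixture dimer: coupled dispersion with CAS(2,2) monomers
basis: 6-31g
threshold: 1.0e-8
order: 8
grid:
  n_points: 8
  omega0: 0.5
monomer_a:
  xyz: h2_a.xyz
  active: {n_electrons: 2, n_orbitals: 2}
monomer_b:
  xyz: h2_b.xyz
  active: {n_electrons: 2, n_orbitals: 2}
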
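# mrdisp

Fifth-power-scaling coupled dispersion energy for monomers described by
multiconfigurational wave functions.

## What it does, and for whom

The second-order dispersion energy is the main attractive force in many
noncovalent complexes, and for excited-state dimers it often decides whether
the complex is bound at all. With multiconfigurational (CASSCF-type) monomer
wave functions the coupled dispersion energy is usually evaluated from the
extended random phase approximation (ERPA): diagonalize the monomer response
problems, then run the double sum over transition pairs,

    E_disp = -4 * sum_{nu, mu} (Y_nu^A g Y_mu^B)^2 / (omega_nu^A + omega_mu^B)

with occupation-scaled two-electron couplings

    g_pqrs = (sqrt(n_p) + sqrt(n_q)) (sqrt(n_r) + sqrt(n_s)) <pr|qs> .

That route scales with the sixth power of the system size. This package
implements the reduced, fifth-power algorithm that makes the same number
affordable for larger dimers, for people working on SAPT-style energy
decompositions and dispersion-corrected multiconfigurational methods:

1. **Cholesky decomposition** of the AO Coulomb matrix, `(pq|rs) = sum_L
   R_pq,L R_rs,L`, with a pivoted algorithm stopped by the summed residual
   diagonal (production threshold 1e-2); the occupation-scaled,
   natural-orbital-transformed vectors `D` factorize `g` exactly in the
   converged limit.
2. **Casimir–Polder quadrature**: `1/(omega_nu + omega_mu)` becomes an
   imaginary-frequency integral, so the dispersion energy turns into a
   product of *monomer* response kernels,
   `E_disp = -(8/pi) * sum_j w_j Tr[ W^A(i w_j) W^B(i w_j) ]` with
   `W^X = D^T C^X(i w) D` of Cholesky dimension only.
3. **Recursive coupling-constant expansion** of the projected response
   `C(i w) D`: the monomer Hamiltonian is split so that the zeroth-order
   ERPA Hessians are block diagonal (largest blocks of active-space size),
   and the coupled response is recovered as a power series in the coupling
   constant evaluated by a recursion whose step cost is one
   pair-dimension^2 x N_chol product — the m^5 bottleneck. Order 0 is the
   uncoupled approximation; order ~8 reaches microhartree accuracy.

Around the core the package provides the surrounding assembly: a compact
Gaussian-integral + RHF + state-averaged CASSCF/CASCI backend for desk-scale
systems (so everything runs self-contained), counterpoise-corrected
supermolecular energies, static-response induction, delta(HF)/delta(CAS)
corrections and basis scaling of exchange components with error metrics, and
spatial dispersion-density maps `Q^AB(r)` that integrate to `E_disp` and
export as Gaussian cube files.

## Worked example

Coupled dispersion for an H2–H2 dimer with CAS(2,2) monomers in a
dimer-centered 6-31G basis:

```r
library(mrdisp)

a <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.7414)))
b <- translate_geometry(a, c(3.5, 0, 0))

sys  <- prepare_interaction(a, b, "6-31g",
                            active_space(2, 2), active_space(2, 2))
calc <- dispersion_calculation(system = sys, threshold = 1e-8,
                               order = 8, direct = TRUE)
calc
#> <dispersion_result: E_disp = -0.00004167 Eh (-0.0261 kcal/mol), order 8, N_chol = 29>
#>   uncoupled: -0.00002611 Eh; grid: 8-point cp

# the sixth-power sum-over-states reference agrees to sub-microhartree
sos <- dispersion_sos_reference(system = sys)
abs(calc$e_coupled - sos$energy)   # ~9e-10 hartree
```

The per-order energies show the coupling-constant series at work: the
uncoupled value (order 0, −2.61e-5 Eh) is ~40% too small in magnitude, and
by order 4 the coupled result −4.15e-5 Eh is converged to a few times
1e-7 Eh; order 8 is accurate to ~1e-9 Eh. `e_coupled * HARTREE_TO_KCAL`
converts to kcal/mol.

The same machinery runs from the shell:

```sh
mrdisp disp --config inst/extdata/fixtures/h2_h2.yaml --order 8
mrdisp report --metrics
mrdisp density --config run.yaml --out qab.cube
```

Excited states work identically — give a monomer
`active_space(2, 2, n_states = 2, target_state = 2)` for the S1 state of a
two-state-averaged CAS(2,2).

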
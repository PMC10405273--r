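---
title: "Coupled dispersion for multiconfigurational monomers: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled dispersion for multiconfigurational monomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented in `mrdisp`: the response
model and its assumptions, the reduced-scaling dispersion algorithm, the
numerical conventions the package commits to, and the limits of what the
shipped tests demonstrate.

## The model

Two monomers A and B, each described by a (state-averaged) CASSCF wave
function in a shared, dimer-centered basis. Orbitals are partitioned into
inactive (doubly occupied, $n_p = 1$), active (fractional $n_p \in (0,1)$),
and virtual ($n_p = 0$) natural orbitals (NOs), with $2\sum_p n_p = N$. The
second-order dispersion energy in its sum-over-states form is

$$E^{(2)}_{\rm disp} \;=\; -4 \sum_{\nu \in A}\sum_{\mu \in B}
\frac{\bigl(\mathbf{Y}^A_\nu\, \mathbf{g}\, \mathbf{Y}^B_\mu\bigr)^2}
     {\omega^A_\nu + \omega^B_\mu},
\qquad
g_{pq,rs} = (\sqrt{n_p}+\sqrt{n_q})(\sqrt{n_r}+\sqrt{n_s})\,\langle pr|qs\rangle,$$

where $\omega_\nu$, $\mathbf{Y}_\nu$ are extended-RPA (ERPA) transition
energies and vectors over orbital *pairs* $(p>q)$, restricted to the
physically coupled ranges active–inactive, virtual–inactive, active–active
and virtual–active (inactive–inactive and virtual–virtual pairs carry a
vanishing response metric). Evaluated this way the cost grows with the sixth
power of system size. The package's contribution is the fifth-power route:
Cholesky factorization of the Coulomb integrals, Casimir–Polder quadrature,
and a recursive coupling-constant expansion of the monomer response.

### ERPA Hessians from reduced density matrices

The pair-space Hessians are built from equation-of-motion double
commutators with spin-summed singlet excitation operators
$E_{pq} = \sum_\sigma a^\dagger_{p\sigma} a_{q\sigma}$:

$$\mathcal{A}_{pq,rs} = \langle 0 | [E_{qp}, [\hat H, E_{rs}]] | 0 \rangle,
\qquad
\mathcal{B}_{pq,rs} = \langle 0 | [E_{qp}, [\hat H, E_{sr}]] | 0 \rangle .$$

Because the double commutator of a two-body operator is again (at most)
two-body, these close over the spin-free one- and two-electron reduced
density matrices; the contraction formulas (some thirty tensor terms) are
implemented in compiled code (`src/erpa.cpp`) and verified to machine
precision against a brute-force determinant-space evaluation of the very
same commutators on two-electron monomers (`erpa_eom_bruteforce()`), as
well as against the closed-shell RPA limit, where
$A+B = \mathcal{A} - \mathcal{B}$ and $A-B = \mathcal{A} + \mathcal{B}$
reduce to the textbook singlet combinations. The sign convention of the
de-excitation block — the one piece a formula-free derivation cannot fix —
is anchored on that RPA limit.

The diagonal metric $2(n_q - n_p)$ is absorbed symmetrically,
$\bar A^\pm = N^{-1/2}(\mathcal{A}\mp\mathcal{B})N^{-1/2}$, after which the
eigenproblem is $S\bar A^+ S\,u_\nu = \omega_\nu^2 u_\nu$ with
$S = (\bar A^-)^{1/2}$ and transition vectors
$Y_\nu = \omega_\nu^{-1/2} S u_\nu$. This normalization makes the spectral
response $\sum_\nu \omega_\nu Y_\nu Y_\nu^T/(\omega_\nu^2+\omega^2)$ equal
to the resolvent $[\bar A^+ + \omega^2 (\bar A^-)^{-1}]^{-1}$ — the link
that guarantees the sum-over-states and quadrature routes agree — and it
fixes the global prefactor so the uncoupled mean-field limit reproduces the
standard closed-shell result
$E = -4\sum_{ia,jb} (ia|jb)^2/(\Delta_{ia}+\Delta_{jb})$. Roots with
$\omega^2 \le 0$ are spurious and discarded (counted in
`n_discarded_negative`); for excited-state references with indefinite
$\bar A^-$ a general eigenroute assigns each root a sign, and
negative-signed roots (negative transitions) are excluded from the
Casimir–Polder sum. Degenerate pairs ($n_q - n_p < 10^{-6}$, e.g. the
half-filled active pair of an open-shell singlet) have no valid metric and
are removed from the pair space; orbital *classification* always follows
the active-space specification, never occupation thresholds.

### The coupling-constant expansion

The monomer Hamiltonian is split so that the zeroth-order Hessians
$A^\pm_0$ are block diagonal: one block of all active–active pairs, one
block per inactive orbital over its active partners, one per virtual
orbital over its active partners, and diagonal inactive→virtual entries.
The largest blocks are of active-space size, so the resolvent
$\Lambda(\omega) = A^-_0 A^+_0 + \omega^2$ is inverted blockwise at
negligible cost (the full-dimension inverse is never materialized; a test
asserts this by corrupting off-block entries). $A^\pm_1$ is the exact
complement, so $A^\pm_0 + A^\pm_1$ reproduces the full Hessians identically
— any valid split converges to the same coupled limit; the split only sets
the convergence rate, which the acceptance measurements monitor.

Writing the projected response $\tilde C(\alpha,\omega) = C(\alpha,\omega)D$
as a power series around $\alpha = 0$ and evaluating at $\alpha = 1$ gives
the recursion implemented in `recursive_projected_response()`: with
$M_1 = A^-_0 A^+_1 + A^-_1 A^+_0$ and $M_2 = A^-_1 A^+_1$,

$$P_0 V = \Lambda^{-1} V, \qquad
P_k V = -\Lambda^{-1}\,(M_1 P_{k-1} + M_2 P_{k-2})\,V,$$

applied to $V_0 = A^-_0 D$ and $V_1 = A^-_1 D$, with
$\tilde C^{(k)} = P_k V_0 + P_{k-1} V_1$. Every step multiplies a
pair-dimension × $N_{\rm Chol}$ panel by the coupling Hessians — the
fifth-power bottleneck. Order 0 is the uncoupled approximation; a
block-diagonal problem ($A_1 = 0$) terminates exactly at order 0.
Convergence is monitored through the increment norms; three consecutive
increases beyond order 2 raise a divergence flag (a proof of convergence is
not available, only the empirical behavior of stable references). On the
shipped fixtures order 8 reproduces the directly solved coupled energy to a
mean absolute percentage error of ~0.003%, far inside the 0.1% target.

### Imaginary-frequency quadrature

The identity $1/(a+b) = (2/\pi)\int_0^\infty ab\,
[(a^2+\omega^2)(b^2+\omega^2)]^{-1} d\omega$ converts the double spectral
sum into a single frequency integral. By partial fractions, any rule that
integrates the one-Lorentzian family $1/(c+\omega^2)$ exactly over the
relevant range of $c$ reproduces $1/(a+b)$ for all scale pairs; the
diagonal $a = b$ additionally needs the squared Lorentzian, i.e. the
derivative in $c$. The default 8-point grid is therefore a generalized
Gaussian rule for this family, solved at run time: value and slope enforced
at three anchor scales $\omega_0(0.4, 2, 10) = (0.2, 1, 5)$ hartree —
spanning the valence-excitation decades — with least-squares value/slope
conditions over a dense logarithmic range that widens with the node count.
The anchors are reproduced to ~1e-9 relative; between anchors the 8-point
rule is good to ~1e-3, which on the fixture energies amounts to absolute
quadrature errors of order 1e-9 hartree. Optimized imaginary-frequency
grids of this kind are standard practice in response-function codes; the
classical Gauss–Legendre rule under the map
$\omega = \omega_0(1+t)/(1-t)$ is available via
`make_frequency_grid(type = "legendre")`. Note the intrinsic limitation:
*no* 8-point rule attains uniform 1e-6 relative accuracy across several
decades of transition energies, so grid-doubling changes fixture energies
at the 1e-5 relative (≤ 1e-8 hartree absolute) level — comfortably below
the microhartree accuracy target, and shrinking monotonically with grid
refinement.

### Cholesky decomposition

`pivoted_cholesky()` factorizes the AO Coulomb matrix over triangle pairs
with full pivoting on the largest remaining diagonal (ties to the lowest
index, for determinism) and terminates when the *summed* residual diagonal
$\sum_{p\ge q} [(pq|pq) - \sum_L R_{pq,L}^2]$ drops below the threshold —
a sum criterion, not a max criterion. The production default is 1e-2; the
oracle tests use 1e-8, where $\sum_L D D^T$ reproduces the directly
assembled $g$ tensor element-wise to 1e-8. One decomposition in the shared
dimer-centered AO basis serves both monomers; the accessor interface
(`coulomb_accessor()`) provides the diagonal and on-demand columns without
materializing the fourth-order tensor, while desk-scale runs use the
in-memory variant.

## The electronic-structure backend

The algorithmic core needs natural orbitals, occupations and RDMs — not any
particular program. The built-in backend keeps the package self-contained:
McMurchie–Davidson Gaussian integrals (s/p shells; STO-3G parameters for
H/He/O, 6-31G for H, and a package-defined even-tempered s-only
double-zeta set `dz.s` for compact two-electron atoms), restricted
Hartree–Fock with DIIS, and a determinant CASCI with state-averaged CASSCF
orbital optimization (analytic generalized-Fock gradients, quasi-Newton
steps on the exponential parametrization, determinant operator tables so
each iteration costs a small eigenproblem plus one integral
transformation). Orbital optimization is not cosmetic: without it the
occupied–virtual Brillouin condition fails and the ERPA Hessians can pick
up spurious negative modes that break both the cross-path equivalence and
the series convergence. In a dimer-centered basis the lowest canonical
virtuals may live on the ghost centers, so active virtuals are selected by
their Mulliken population on the real atoms (threshold 0.4, energy order),
a deterministic choice validated by the resulting physical occupation
numbers. Natural orbitals are state-specific (eigenvectors of the target
state's one-matrix); two-electron reduced density matrices over the
generalized-occupied space are computed by direct operator algebra on the
determinant expansion, avoiding hand-derived case formulas.

States can be exported to and re-imported from a JSON interchange container
(`write_monomer_state()`), with fixed dataset names for NO coefficients,
occupations, partition, RDMs, nuclei and optional Cholesky factors, so the
entire response machinery can run from stored wave-function data. JSON was
chosen over a binary container deliberately: at desk scale the files are
small, diffable and portable.

## Induction, assembly, density maps

The second-order induction energy uses the static response:
$E^{(2)}_{\rm ind}(A{\leftarrow}B) = -2\, v_B^T C^A(0)\, v_B$ with $v_B$
the occupation-scaled matrix elements of B's electrostatic potential
(nuclei plus frozen electron density) over A's pair space — the
fourth-power route, cross-checked in the tests against the spectral form
$-2\sum_\nu (Y_\nu^T v)^2/\omega_\nu$.

The assembly layer is exact arithmetic on component records in kcal/mol:
$\delta_{\rm HF} = E^{\rm HF}_{\rm int} - (E_{\rm elst} + E_{\rm exch} +
E_{\rm ind} + E_{\rm exch\text{-}ind})$;
$\delta_{\rm CAS} = \delta_{\rm HF}\, E^{(2)}_{\rm ind}({\rm ES}) /
E^{(2)}_{\rm ind}({\rm GS})$ (induction-only scaling; including
exchange-induction in the ratio would propagate the error of its own
scaling approximation);
exchange terms scale between basis sets by the ratio of their polarization
partners; totals are plain sums. Printed reference tables ship as CSV; all
their totals reconstruct within the 0.015 kcal/mol bound implied by
rounding 2-decimal inputs (half-away-from-zero convention), except one
supermolecular-plus-dispersion entry that is off by 0.06 kcal/mol and is
reported as a known discrepancy — never silently corrected.

The dispersion-density map assigns each pair's contribution to the
reduced-scaling trace to the occupied (more strongly occupied) member of
the pair and spreads it over that natural orbital's density; $Q^{AB} =
(Q^A + Q^B)/2$ is rescaled so its Riemann integral over the evaluation grid
equals $E^{(2)}_{\rm disp}$ exactly (the raw, pre-rescaling integral is
within 1% on a 0.25 Å grid and improves under refinement). The
per-orbital attribution is one defensible choice among several — the
normalization makes the field well-defined regardless — and excited-minus-
ground difference maps follow the convention that positive values mark
regions where the (negative) dispersion energy density is depleted in the
excited state. Export is standard Gaussian cube, optionally in
kcal mol⁻¹ Å⁻³.

## Fixtures, synthetic instances, and what the tests show

The fixture suite — H2–H2 (CAS(2,2)), He–He (mean field), the water dimer
(CAS(4,4) and mean-field variants), and an excited-state H2–H2 with an
S1 SA(2)-CAS(2,2) monomer — was chosen so the sixth-power sum-over-states
reference runs in seconds and every gate can be checked against it: on all
five dimers the fifth-power route agrees with the reference to better than
1e-6 hartree (typically 1e-9). Problem sizes (up to 14 AOs, pair dimensions
up to ~70, $N_{\rm Chol}$ up to ~80) were picked to keep the whole suite in
the minutes range on one CPU. Seeded synthetic pair-space instances
(`generate_synthetic_instance()`) decouple the recursion tests from the
electronic structure entirely, with controllable coupling strength and
guaranteed positive definiteness across the coupling range.

What passing these tests does *not* show: behavior in augmented triple-zeta
bases with hundreds of functions (where Cholesky truncation at 1e-2 and
disk-bound panel storage matter), exchange-dispersion and exchange-induction
from first principles (they enter only as numeric inputs to the scaling
relations), non-Casimir–Polder contributions of genuinely negative
transitions (the shipped ES fixture has none; they are only counted and
excluded), and the quality of the small built-in basis sets as chemistry —
the fixtures validate algorithmic identities, not basis-set convergence.

## Numerical conventions, in one place

* Hartree internally; kcal/mol via 627.5095 where tables are involved.
* Cholesky: residual-sum threshold, default 1e-2 (production), 1e-8
  (oracle); largest-diagonal pivot, ties to lowest index.
* Pair metric floor 1e-6 (occupation difference); dropped pairs counted.
* Eigensolver: symmetric path whenever $\bar A^-$ is positive
  semidefinite (tolerance 1e-10); retained roots require
  $\omega^2 > 10^{-10}$; degenerate roots keep index order.
* Recursion: default truncation order 8; divergence flag on three
  consecutive increment-norm increases past order 2.
* Quadrature: 8 points, $\omega_0 = 0.5$ hartree, anchored optimized rule;
  Legendre map available.
* SCF/CASSCF: density convergence 1e-10; orbital gradient 1e-7; orbital and
  CI phases fixed by largest-magnitude-coefficient-positive.
* Rounding for table reproduction: half away from zero at the printed
  decimals; inconsistency bound 0.015 kcal/mol.
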
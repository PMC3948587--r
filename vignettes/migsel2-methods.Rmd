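---
title: "Methods: two-locus two-deme migration-selection balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-locus two-deme migration-selection balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsel2)
```

# The model and its assumptions

`migsel2` implements the deterministic continuous-time dynamics of two
diallelic loci, `A` and `B`, in a population subdivided into two randomly
mating demes coupled by migration. Selection is genic (no dominance, no
epistasis) and divergent: `A1` and `B1` are favoured in deme 1 with
Malthusian coefficients `alpha1`, `beta1`, while `A2`, `B2` are favoured in
deme 2 (`alpha2, beta2 < 0`). Migration replaces a fraction `m_k` of deme
`k` per unit time with immigrants from the other deme (soft selection:
deme sizes are regulated locally). Recombination between the loci occurs
at rate `rho`. All parameters are rates; the model arises as the
weak-force limit of the corresponding discrete-time life cycle, so no
separate discrete-time variant is provided.

The state is either the pair of gamete-frequency vectors on the simplex
(one per deme) or, equivalently, allele frequencies and linkage
disequilibrium `(p_k, q_k, D_k)`; `state_to_gametes()` and
`gametes_to_state()` convert exactly, and `gamete_rhs()` /
`allele_ld_rhs()` implement the same vector field in either chart (the
test suite verifies their agreement through the differential of the
conversion at random states). The haploid reading of the model uses the
halved allelic contributions `±alpha_k/2`, `±beta_k/2` per gamete; with
that convention the diploid marginal-fitness deviations and the haploid
ones coincide term by term, which is the only reading consistent with the
`(p, q, D)` equations.

**Canonical form.** Relabelling alleles at a locus, exchanging loci, or
exchanging demes leaves the model invariant. `model_parameters()` brings
any admissible parameter set (each allele favoured in exactly one deme)
into the normal form `alpha1 > 0 > alpha2`, `beta1 > 0 > beta2`,
`beta1 >= alpha1`, `theta = alpha1*beta2 - alpha2*beta1 >= 0`, choosing
the least transformed of the four locus/deme exchange combinations, and
records the transform so states can be mapped back
(`apply_state_transform()`). `theta = 0` is degenerate (several closed
forms change character) and must be requested explicitly
(`theta_zero_ok = TRUE`); the super-symmetric case (mirrored selection,
equivalent loci, symmetric migration) is a special case of it.

# Equilibria

Three classes of equilibria are handled in closed form:

- **Monomorphic** (`M1..M4`): always exist; stability from the factored
  characteristic polynomial (below).
- **Single-locus polymorphisms** (`PA1`, `PA2`, `PB1`, `PB2`): marginal
  one-locus frequencies from the ratios `sigma_k = m_k/alpha_k`
  (`tau_k = m_k/beta_k`); admissible iff `|sigma1 + sigma2| < 1`
  (resp. `|tau1 + tau2| < 1`), the protected-polymorphism condition.
  Inadmissible records are returned flagged rather than dropped so
  bifurcation tracking can follow them outside the state space; each
  record names the monomorphism through which it exits.
- **Full polymorphisms** in the two tractable regimes: `Finf` under
  linkage equilibrium (the Cartesian product of the one-locus
  polymorphisms; admissible iff all four SLPs are) and `F0` under
  complete linkage (only the locally adapted haplotypes present, maximal
  positive LD, governed by `kappa_k = m_k/(alpha_k + beta_k)`).

For general finite `rho` the stable polymorphism `F` has no closed form;
the package provides the weak-migration expansion (`weak_migration_F()`,
error `O(m^2)`), the quasi-linkage-equilibrium expansion (`qle_F()`,
error `O(rho^-2)`), and a multi-start damped-Newton search
(`find_internal()`) seeded from those approximations, from `F0`, and from
a coarse interior grid (32 seeds by default). Roots closer than `1e-8`
are merged; a root whose Jacobian is nearly singular is flagged
`near_singular` rather than silently resolved, since that happens only
near saddle-node collisions. Internal equilibria always carry nonzero LD
(an internal LE point would force equal allele frequencies across demes,
which only happens on the boundary); the suite asserts `|D| > 1e-12` for
every located root.

# Stability

`jacobian_allele_ld()` evaluates the 6x6 Jacobian analytically (checked
against central differences at `1e-6` relative). `classify_equilibrium()`
classifies by eigenvalue real parts with a marginality tolerance of
`1e-8`: boundary cases are reported as `marginal`, never rounded.

Closed forms: at each monomorphism the characteristic polynomial factors
into the two marginal one-locus quadratics and the quadratic of the
decoupled 2x2 LD block; `monomorphic_stability()` combines the
`sigma`/`tau` conditions with the determinant/trace condition of that
block (equivalent to the familiar `m2` bound at `M1`; at `M4` the
determinant/trace form is the one that agrees with the eigenvalues across
the full parameter range, so it is used at both). `M2` is always
unstable; stability of `M3` is independent of `rho`; at most one of
`M1`, `M3`, `M4` is stable.

For `rho = 0` the gamete `A1B2` is always lost and the analysis runs in
the tri-gametic subsystem `{A1B1, A2B1, A2B2}` (`subsystem =
"trigametic"`), as the equilibria of interest sit on the boundary of the
full chart there. `F0` is stable iff `m1*m2 < m_tilde` with
`m_tilde = -alpha1 alpha2 beta1 beta2 (alpha1+beta1)(alpha2+beta2) /
theta^2`; at equality there is a line of equilibria and the verdict is
marginal. `PA1` / `PB2` stability (`slp_stability_rho0()`) requires the
complementary condition `m1*m2 > m_tilde`. Transversal stability of SLPs
at general finite `rho > 0` is the root of a quartic with no informative
closed form and is computed numerically from the Jacobian block.

# Critical rates and the limits of polymorphism

`phi_thresholds()` and `m_thresholds()` give the eleven critical
migration ratios `phi^X` and the signed critical rates `m^A`, `m^B`,
`m^F0`, `m^M1`, `m^M4`, `m*`. Infinity sentinels are explicit values
(assigned on exact equality of `phi` with the corresponding threshold, or
an exactly vanishing denominator — no epsilon heuristics), so downstream
`min`/ordering logic is total. Two caveats discovered while verifying the
identities are worth recording: the bounds on `m^A`, `m^B`, `m^F0` hold
in reciprocal form (e.g. `1/m^A` interpolates linearly between
`1/alpha2` and `1/alpha1` as `phi` runs from 0 to 1 — the rate itself
diverges at `phi^A`), and the three-way identities tie `m*` to locus A at
`phi^M1` (`-m^A = -m^F0 = m*`) and to locus B at `phi^M4`
(`m^B = m^F0 = m*`).

The maximum total migration rate admitting a stable two-locus
polymorphism is closed-form in the bracketing regimes —
`m_max_LE() = min(|m^A|, |m^B|)`, maximized at `phi^AB` with a kink at
`phi_AB_tilde` when `beta2 < alpha2`, and
`m_max_rho0() = min(|m^F0|, m*)` — with `m_max_LE <= m_max_rho0` always
and equality exactly at `phi^AB` (infinite when additionally
`theta = 0`). `m_max_qle()` gives the `O(1/rho)` correction to the
collision of `F` with `PB2`; its sign varies, so strong recombination can
either raise or lower the LE bound. For general `rho`,
`m_max_numeric()` continues the stable polymorphism outward in `m`
(geometric steps, Newton with continuation seeds, integration fallback
into the tracked basin) and bisects the largest `m` with a stable
internal equilibrium to relative tolerance `1e-6`. The terminating event
is classified as `boundary_exit` (exchange of stability with a boundary
equilibrium), `fold` (a second, unstable internal equilibrium coexists
just below `m_max` — the Type-2 signature), or `stability_loss` (the
`rho = 0` jump bifurcation at `m*`).

# Bifurcation diagrams

`classify_LE()` and `classify_rho0()` return, for fixed selection and
`phi`, the diagram shape (`a`-`c` for LE; `a`-`j` for complete linkage),
the role assignment mapping the abstract equilibria/rates to concrete
ones, the ordered `m`-intervals with the globally stable equilibrium of
each, and the events between them. Degenerate shapes occur on
measure-zero sets `phi = phi^X`; equality is detected at relative
tolerance `1e-12`. Equilibria that can never be stable (`PA2`, `PB1`,
`M2`, and the unstable `rho = 0` edge polymorphism on the `M2`–`M3` edge,
available as `edge_fp_rho0()`) are tracked but excluded from the
diagrams. `diagram_sequence()` enumerates the succession of shapes along
`phi`, which branches on the sign of
`theta_tilde = alpha1*alpha2 - beta1*beta2` in the complete-linkage
regime. `scan_numeric()` covers finite `rho`: it inventories equilibria
and stability on an `m`-grid, bisects changes of the stable set, and
reports bistable windows (stable `F` together with a stable boundary
equilibrium) and saddle-nodes; events not isolated at relative `1e-4` by
the bisection budget are tagged `unresolved`. More than two internal
equilibria are reported, never suppressed.

# Observables, invasion, and the neutral site

`migration_load()` measures the deviation of each deme's mean fitness
from its local optimum; `load_weak_approx()` is the `O(m^2)`-accurate
weak-migration form, increasing in migration and in recombination. The
multilocus fixation index `fst()` is haplotype-based,
`F_ST = 1 - hbar_S/h_T`, with weighted population variances over demes
(default weights 1/2 and 1/2 — used wherever deme proportions are not
specified) and the full pairwise covariance matrix; single-locus values
and their heterozygosity-weighted average are reported alongside for
comparison, without asserting their relative behaviour at high `m` and
`rho`. `fst_weak_approx()` is the leading-order equilibrium value.

Invasion of a locally beneficial mutant `A1` linked to the polymorphic
background locus `B` is decided by the leading eigenvalue of the
`(p1, p2, D1, D2)` block of the Jacobian at `PB2`, which decouples
exactly from the marginal system at that boundary.
`rho_max_for_invasion()` and `alpha_min_for_invasion()` bisect that
eigenvalue's sign (relative tolerance `1e-8`). One point deserves
emphasis: with two-way migration the complete-linkage invasion threshold
does not vanish — as `rho -> 0`, `alpha_min` converges to the positive
root of `m1*m2 = m_tilde(alpha1)`; mutants of arbitrarily small effect
invade under tight linkage only in the one-way (continent–island) limit
`m1*m2 = 0`. Both statements are verified by eigenvalues and by forward
integration from rare-mutant perturbations. The post-invasion attractor
is checked by integration case by case, not assumed.

The neutral-site module embeds a neutral locus `N` between `A` and `B`
(`rho = rho_AN + rho_NB`, both positive, at most one crossover per
event, no interference parameter). Internally the dynamics is built on
the 8-gamete-per-deme system — the unambiguous construction given the
single-crossover assumption — and exposed in the 14
(frequency, disequilibrium) coordinates via the three-locus Bennett
decomposition; the suite verifies the exact marginalization to the
two-locus dynamics and the invariance of the neutral manifold. At the
stable polymorphism `F` the 14x14 Jacobian (computed by complex-step
differentiation, exact to machine precision for this polynomial vector
field) is block diagonal; the neutral block has one structural zero
eigenvalue, identified by eigenvector alignment with the neutral-manifold
tangent rather than by magnitude, and the next eigenvalue gives
`m_eff = -lambda_N`. `m_eff_weak()` is the weak-migration closed form
(the sum of the two one-way barrier terms), exact to `O(m^2)`.

# Numerical choices

- Integration: `deSolve::lsoda` (adaptive, stiff-capable), absolute
  tolerance `1e-12`, relative `1e-10`, in doubling time chunks until the
  rhs sup-norm falls below the convergence threshold (default `1e-10`;
  horizon default `1e6` time units, both configurable). After each chunk
  the state is clipped onto the constraint set only when the violation is
  below `1e-9`; larger violations abort, since silent clipping can mask
  solver failure.
- Root finding: damped Newton with the analytic Jacobian, residual target
  `1e-13`, step halving on non-decrease.
- Linkage equilibrium is a distinct dynamical mode (`rho = "LE"`), not a
  large finite rate, because the LE system is exactly decoupled and a
  huge `rho` would only add stiffness.
- Default initial condition for numerical runs:
  `p = q = 1/2 ± 0.01` (towards each deme's favoured haplotype), `D = 0`
  (`default_start()`). This is a package choice; no canonical starting
  state exists for the model.
- Deme weights for the fixation index default to 1/2, matching the
  equal-deme-size convention of the load.

# The sweep generator and what the tests show

`generate_sweep()` draws random parameter sets that satisfy the model's
constraints by construction: `alpha1 ~ U(0.1, 1)`,
`beta1 ~ U(alpha1, 3)`, `alpha2 ~ U(-3, -0.1)`, and `beta2` placed
uniformly strictly inside the interval that makes `theta > 0`;
`m ~ U(0.01, 2)` (widened where a check concerns strong migration),
`phi ~ U(0.02, 0.98)`, `rho ~ U(0, 3)`; fixed seeds make every suite run
identical. The `theta_zero` and `super_symmetric` modes pin the
respective degeneracies exactly.

These draws emulate the model's own parameter space, not data: there is
no drift, mutation, dominance, epistasis, or sampling noise, and only two
demes and two (plus one neutral) loci. Passing tests therefore certify
the mathematical implementation — closed forms against dynamics
residuals, closed-form stability against eigenvalues (1000 draws,
condition boundaries excluded at slack `1e-3`), both bifurcation
theorems against forward integration — and not the adequacy of the model
for any particular organism.

Problem sizes used by the conformance checks: 200 (selection, `phi`)
draws per regime, 5 migration rates per predicted stable interval, 2
random initial states each, integrated to an rhs norm of `1e-9`. Draws
whose `phi` lies within 0.01 of a bifurcation threshold `phi^X` are
excluded and redrawn: at those near-degenerate points the leading
eigenvalue vanishes and no fixed integration horizon can confirm the
(still correct) prediction. Unbounded terminal intervals are probed up to
twice their lower endpoint.

# Known limitations

- The number of internal equilibria for general parameters is not
  certified; the search reports what it finds (warning above two), and
  the scan's interval table can miss features thinner than its bisection
  resolution.
- Global stability is probed by integration from random starts, not
  proved.
- The `m` at which `F` leaves the state space for general finite `rho`
  has no closed form; `m_max_numeric()` is a numerical continuation with
  the stated tolerances.
- Sample-based estimators of `F_ST` (and any finite-population effects)
  are out of scope; the index here is the deterministic population
  quantity.
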
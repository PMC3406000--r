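---
title: "Electrostatic steering of a peripheral protein to a target lipid: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic steering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(steerBD)
```

## The problem

A pleckstrin homology (PH) domain binding PIP₃ faces a signal-to-noise
problem: its target carries a large negative charge (the headgroup is an
inositol-tetrakisphosphate, net charge around −7 e at physiological pH),
but it sits in a leaflet whose background lipids are 10–20% monovalent
anionic. The background charge both *helps* — it pulls the cationic domain
to the membrane and torques its dipole into the binding-competent
orientation — and *hurts*, because a sufficiently charged background masks
where the target is. `steerBD` makes this payoff quantitative with
Brownian-dynamics (BD) ensembles over model bilayers of controlled decoy
charge.

## Model and assumptions

**Bilayer.** A static square lattice of headgroup charge sites in two
leaflets. Defaults: 220 × 220 Å patch, 62 Å²/lipid (typical fluid-phase
phosphatidylcholine), giving 780 sites per leaflet (≈1560 lipids), leaflet
planes at z = ±20 Å, and one PIP₃ site of −7 e at the centre of the upper
leaflet. The lattice does not move during BD — the membrane's lateral
diffusion constant (~1.7×10⁻⁸ cm²/s) is nearly two orders of magnitude
below the protein's, so the protein effectively samples a frozen (or, for
the fractional scheme, time-averaged) charge distribution. Decoy charge
lives only on the upper (cytoplasmic) leaflet:

* *fractional*: every decoy site gets the same charge q ∈ [−1, 0] e — the
  mean-field limit of fast lipid mixing. q = −0.2 e carries the same total
  charge as 10% anionic lipids overall.
* *random_subset*: a seeded uniform fraction f of sites at −1.0 e — a
  frozen snapshot of well-mixed discrete lipids.
* *clustered*: the same count selected by neighbour-preferential growth
  (selection weight 1 + c·n_selected_neighbours), standing in for the
  demixed configurations coarse-grained membrane simulations produce. c = 0
  reproduces random_subset exactly; the mean anionic–anionic
  nearest-neighbour distance decreases monotonically with c.
* *explicit*: charges read back from a site file, for externally built
  configurations.

**Protein.** A rigid body: bead coordinates in a body frame with origin at
the centre of mass, point charges, a body-fixed binding-face reference
vector, and isotropic D and D_R. Real structures are loaded from PDB with
*formal* charges (Asp/Glu −1 at the carboxylate centroid, Lys/Arg +1,
His 0, chain termini ±1); a PQR pass-through accepts externally fitted
charge sets. We chose formal charges over effective-charge fitting because
the fit needs a Poisson–Boltzmann reference solution and changes little at
the scale of a steering analysis; users with fitted charges supply them via
PQR. The toy generator places beads in a sphere and solves the minimum-norm
charge vector with exact net charge and dipole — the standard test article
is an 8-bead, +8 e, 40 e·Å (≈192 D) cationic dipolar "PH domain" of radius
12 Å. Default diffusion constants for real structures are bead-model
values for a GRP1-sized domain (D = 1.042×10⁻⁶ cm²/s, D_R = 1.656×10⁷
rad²/s); toys use Stokes–Einstein at their radius.

**Field.** The potential is the screened-Coulomb superposition
Φ(x) = Σ qᵢ C e^{−r/κ⁻¹}/(ε_r r) in kT/e, with C = 557.0 kT·Å/e² at 300 K
and ε_r = 78.5. For a *point-charge* membrane this is the exact linearized
Poisson–Boltzmann solution in uniform dielectric, which is why we solve no
finite-difference PB problem: at 0.1 M the interaction is screened on
κ⁻¹ ≈ 9.65 Å anyway, and grid values at nodes are exact rather than
discretised. Singularities are capped inside 2 Å of a source (no BD pose
gets that close; the contact plane stops it first). The optional
desolvation grid charges q² g(x) with an image-charge-style penalty
g ∝ α Σ a³(1+κr)² e^{−2κr}/r⁴ over the low-dielectric slab volume
(α = 1.67, ε_p = 4); it is OFF by default — the steering statistics here
are driven by the monopole/dipole field, and the penalty's absolute scale
depends on a protocol choice the source material only fixes up to α.

**Dynamics.** Ermak–McCammon overdamped updates with energies in kT:
Δr = D Δt F + R, Var(R_α) = 2DΔt; rotation by w = D_R Δt T + W,
Var(W_α) = 2D_RΔt, composed via unit quaternions (renormalised each step)
about the centre of mass. Forces are central differences of the grid
energy over ±δ along the lab axes; torques over ±δ_rot about lab axes
through the COM (for an isotropic D_R the rotational update is
frame-invariant, and the lab frame makes the p × E oracle directly
comparable). Trajectories start uniformly (w.r.t. area) on the spherical
cap |x| = b = 100 Å, z > 60 Å with uniform random orientation, and
terminate at |x| ≥ q = 105 Å — inside the patch edge, so edge artefacts
of the finite charge lattice are never sampled — or at the time cap.
Contact of the lowest bead within 4.5 Å of the upper-leaflet plane records
the *first encounter* (r, d, θ) and flags the trajectory "encounter"
without terminating it; excluded volume is a single reflecting plane at
the leaflet (a point-charge membrane has no atoms to collide with).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `area_per_lipid` | 62 | Å² | fluid-phase PC; 220 Å patch → 780 sites/leaflet |
| PIP₃ charge | −7 | e | approximate net formal charge of the headgroup at pH 7; configurable (the atomistic charge set is not published as numbers) |
| `leaflet_separation` | 40 | Å | headgroup-to-headgroup thickness of the patch |
| ionic strength / κ⁻¹ | 0.1 M / 9.65 Å | — | physiological saline at 300 K |
| `b_radius`, `q_radius` | 100, 105 | Å | start/termination surfaces ≈ 10 Debye lengths out; q inside the patch edge |
| `z_min_start` | 60 | Å | guarantees ≥ 40 Å initial clearance from the surface |
| `contact_height` | 4.5 | Å | encounter criterion (no numeric criterion is published; this is roughly a headgroup contact distance) |
| `dt_near`/`dt_far` | 1 / 10 ps | — | switch at 90 Å height; rms free step at 1 ps ≈ 0.2 Å ≪ grid spacing, justifying trilinear interpolation |
| `max_time` | 20 µs | — | production cap; scaled runs use 50 ns (see below) |
| grid spacing | 1 (2 for BD volumes) | Å | node-exact DH sum; interpolation error ≲ 0.3% at the closest approach heights |
| bin widths | 2 Å / 2° | — | histogram resolution (source figures do not state theirs) |

## What the synthetic generator does and does not emulate

The generator reproduces: the patch geometry and charge stoichiometry of
the reference membrane model; the three decoy-charge families (mean-field
fractional, frozen random subsets, clustered snapshots); and a cationic
dipolar protein with exactly known charge, dipole and diffusion constants.
It does **not** emulate atomistic lipid structure (multipoles of real
headgroups, tails, dielectric discontinuity at the slab), lipid motion or
protein-induced lipid redistribution, conformational flexibility, or
hydrodynamic interactions. A green steering test therefore establishes
that the *electrostatic steering mechanics* — field construction,
propagator, Jacobian statistics — behave correctly and reproduce the
direction of the charge-dependence; it does not certify absolute encounter
rates or binding affinities.

## Numerical choices

* **RNG and determinism.** Every stochastic element is seeded; ensembles
  derive one stream per trajectory from the master seed, so results are
  bit-reproducible and extending an ensemble never changes existing
  trajectories. The compiled core draws from R's generator.
* **Finite differences.** δ = 0.5 Å and δ_rot = 2° by default; with δ equal
  to the grid spacing the force error against the analytic gradient is
  ≤ 0.3% at encounter heights.
* **Rotational timestep.** The axis-angle update is exact only as
  D_RΔt → 0; at D_RΔt ≈ 0.2 the measured orientation decay is visibly
  (~5%) slow. The far timestep (10 ps) keeps D_RΔt ≈ 10⁻³ for realistic
  D_R, far below that regime; validation fits the decay *rate* with
  inverse-variance weights because the autocorrelation tail is noise-
  dominated at finite ensemble size.
* **Gaussian HWHM fit.** Nonlinear least squares of A·exp(−r²/2σ²) on the
  reweighted density with the centre pinned at 0 (port algorithm, σ > 0);
  non-convergence is an error with diagnostics, not a silent NA. The bin
  containing r = 0 uses its bin-centre radius; zero-total histograms are
  errors.
* **Degenerate inputs.** Zero dipole → angle reported NaN with a warning;
  ensembles with no encounters make the first-encounter statistic an error
  ("no encounters in ensemble") while other analyses still run; pose-search
  thresholds of 0 return an empty set rather than erroring (contract:
  empty selection is a valid result).

## Scaled-down validation runs

The production-scale reference ensembles (5000 trajectories, ≫µs
trajectories, 385³ 1 Å grids) are cluster-scale runs; the test suite
validates *direction of effect* at 500 trajectories × 50 ns per scheme on
2 Å grids, three master seeds, with cluster (per-trajectory) bootstrap
confidence intervals at 95%:

* surface occupancy (fraction of samples with d < 20 Å) increases
  monotonically with fractional decoy charge over {0, −0.2, −0.6, −1.0} e;
* the median orientation angle θ is lower at −0.2 e than at 0 e
  (orientational steering switches on with background charge);
* the radial HWHM is larger at −1.0 e than at 0 e (positional steering
  degrades as decoys mask the target).

These ran green at the stated sizes; the trajectory length is the only
scaled quantity, chosen to fit a single-CPU run, and thresholds were fixed
before measurement.

## Known limitations and open choices

* The binding-face reference vector for real structures is a convention
  (COM → centroid of user-named pocket residues); the source material
  defines its θ vector only in unavailable supplementary text.
* The published "30 µs" timescale for a 50 Å lipid displacement is not
  reproducible from t = L²/4D or L²/6D with the quoted lateral D
  (both give 2–4 µs); `diffusion_time()` implements the standard closed
  form and we treat the printed figure as unexplained.
* No hydrodynamic interactions, no encounter-rate constants (the truncated
  b-sphere/q-surface geometry breaks the spherical flux symmetry that
  rate-from-flux methods require), no lipid dynamics during BD.
* The desolvation functional form follows the cited grid protocol; its
  absolute scale should be treated as qualitative.
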
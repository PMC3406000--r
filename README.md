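# steerBD

Rigid-body Brownian dynamics of protein–membrane **electrostatic steering**.

Peripheral membrane proteins such as pleckstrin homology (PH) domains must
locate a rare, polyvalent target lipid — phosphatidylinositol
(3,4,5)-trisphosphate, PIP₃ — in a cytoplasmic leaflet that also carries
~10–20% monovalent anionic "decoy" lipids. Those decoys cut both ways: they
attract a cationic domain to the surface and orient its binding face, but
they also mask the electrostatic signature of the PIP₃ target. `steerBD`
simulates this encounter problem and quantifies the payoff.

## What it computes

The protein is a rigid body with point charges, an isotropic translational
diffusion constant *D* and rotational diffusion constant *D_R*. It diffuses
over a **static** planar bilayer represented as a square lattice of headgroup
charge sites in two leaflets with a single PIP₃ charge (default −7 e) at the
centre of the upper leaflet. Positions evolve by the Ermak–McCammon
propagator

    Δr = (D Δt / k_BT) F + R,   ⟨R_α R_β⟩ = 2 D Δt δ_αβ

with the analogous axis-angle update for rotation (torque **T**, random
rotation **W** with ⟨W_α W_β⟩ = 2 D_R Δt δ_αβ). Forces and torques are
central finite differences of the interaction free energy

    U = Σ_i q_i Φ(x_i)  (+ Σ_i q_i² g(x_i) with desolvation on)

where Φ is the screened-Coulomb (Debye–Hückel) potential of the bilayer
charges on a regular grid (exact for the point-charge membrane; κ⁻¹ ≈ 10 Å
at 0.1 M, 300 K) and g is an optional Elcock-style electrostatic
desolvation penalty (α = 1.67). Trajectories start uniformly on a truncated
*b*-sphere (|x| = 100 Å, z > 60 Å), terminate at a *q*-surface (105 Å), and
record an encounter when the lowest bead comes within 4.5 Å of the
upper-leaflet plane.

Ensembles are reduced to the steering coordinates

* **r** — in-plane distance from the protein centre of mass to the PIP₃ site,
* **d** — height of the COM above the PIP₃ plane,
* **θ** — angle between the protein's binding-face vector and the downward
  membrane normal (θ = 0 is the binding-competent orientation),

binned with the Jacobian reweightings counts/2πr and counts/sin θ, fitted
with a zero-centred Gaussian whose HWHM = σ√(2 ln 2) measures positional
steering, plus first-encounter distributions, 2D (r, θ) maps, optimal-pose
search for MD hand-off, and residue–phosphorus contact fingerprints.

## Worked example

A scaled-down ensemble (200 trajectories × 50 ns; production runs in the
field use thousands of trajectories of tens of µs) over a 220 Å patch whose
upper leaflet carries −0.2 e per lipid — the charge density equivalent to
~10% anionic lipids overall:

```r
library(steerBD)

bilayer <- assign_charges(build_patch(),
                          charge_scheme("fractional", fractional_charge = -0.2))
grid    <- compute_potential_grid(bilayer, spacing = 2, xy_half = 122,
                                  z_range = c(0, 122))
protein <- make_toy_protein(n_beads = 8, radius = 12, net_charge = 8,
                            dipole_moment = c(0, 0, 40), seed = 3)
params  <- bd_params(n_trajectories = 200, max_time = 5e4,
                     sample_interval = 50, seed = 1)
ens <- run_ensemble(protein, bilayer, grid, params)
print(ens)
#> ensemble_record: 200 trajectories, 35191 samples
#>   terminations: 23 encounter / 176 escape / 1 timeout

hr <- reweight_radial(make_histogram(ens$samples$r, seq(0, 160, 2), "r"))
as.numeric(fit_hwhm(hr))          # 1.85  — r-distribution HWHM in Angstrom
median(ens$samples$theta)         # 72.9  — median orientation angle, degrees
mean(ens$samples$d < 20)          # 0.44  — fraction of time near the surface

head(select_optimal_pose(ens, 10, 20, 30), 3)
#>       traj  time         r        d    theta
#> 34750  198 28500 2.2455679 6.833907 27.10960
#> 16925   98 45650 0.8995153 7.151770 14.51859
#> 16890   98 43900 2.5857727 6.779306 15.03992
```

The HWHM says the protein's radial density is sharply peaked on the PIP₃
site (strong positional steering); 44% of sampled time is spent within
20 Å of the surface (the decoy charge holds the domain near the membrane);
and the pose search returns encounter configurations with small (r, d, θ)
suitable as starting points for atomistic MD. Sweeping the fractional
charge over {0, −0.2, −0.6, −1.0} e shows surface occupancy and
orientational alignment improving with charge while the radial peak
broadens — the decoy/target payoff.

The same pipeline is scriptable from JSON configs:

```sh
Rscript inst/cli/steerbd.R build    config.json
Rscript inst/cli/steerbd.R field    config.json
Rscript inst/cli/steerbd.R simulate config.json bd.n_trajectories=500
Rscript inst/cli/steerbd.R analyze  config.json
```

## Layout

* `R/bilayer.R` — bilayer lattices and charge schemes (fractional,
  random-subset, clustered, explicit)
* `R/protein.R` — rigid-body models from PDB/PQR or toy generators;
  dipoles, mutants, Stokes–Einstein fallback
* `R/grid.R` — Debye–Hückel and desolvation grids, OpenDX I/O,
  interaction energies
* `R/bd.R`, `src/core.cpp` — Ermak–McCammon propagator, trajectory and
  ensemble drivers (compiled core)
* `R/steering.R` — steering statistics and fingerprints
* `R/workflow.R`, `inst/cli/steerbd.R` — JSON-config pipeline with
  manifests
* `vignettes/electrostatic-steering.Rmd` — model, assumptions, parameter
  choices and limitations
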
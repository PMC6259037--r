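# coronadsorb

Trajectory analysis of short polymer chains adsorbing on a protein surface.

When hydrophilic polymers such as poly(ethylene glycol) (PEG) or
poly-sarcosine (PSar) are used to coat therapeutic nanoparticles, their
"stealth" behaviour depends on how weakly and how reversibly they stick to
abundant blood proteins like human serum albumin. Molecular-dynamics studies
of such systems produce trajectories of many short chains (4–7-mers)
diffusing in water around a protein; this package implements the complete
downstream analysis of that kind of trajectory for structural
bioinformaticians and simulators:

* **Shell densities** — the radial distribution function g(r) of polymer
  heavy atoms as a function of the distance to the nearest protein heavy
  atom, shell/bulk polymer heavy-atom fractions, and the distance out to
  which surface enrichment persists.
* **Langmuir isotherm fitting** — with a finite density of equivalent
  polymer-atom binding sites P_s on the surface and the reaction
  A_s + P_s ⇌ A_P, the shell fraction follows
  [A_P] = P_s^max · K_a [A_s] / (1 + K_a [A_s]); the package fits
  (P_s^max, K_a) by weighted nonlinear least squares, with a fixed-P_s^max
  variant for sparse data.
* **Residue-level affinity maps** — polymer/water count ratios in a 0.5 nm
  shell around every amino-acid type, normalized by the bulk ratio, with
  cross-polymer correlations and voxelized 3-D density grids (OpenDX
  export) thresholded at a multiple of the bulk density.
* **Adsorption/desorption kinetics** — a dual-threshold (hysteresis) state
  machine: a free chain adsorbs when more than half of its heavy atoms come
  within 0.5 nm of any protein heavy atom, and desorbs only when every atom
  has left that layer, which suppresses recrossing noise. Completed events
  yield rates, residence times summarized by geometric mean and 68%
  percentile intervals (the natural summary for lognormal-like duration
  distributions), and events-per-unit-time histograms in log-spaced bins.
* **Polymer shape** — end-to-end distance, radius of gyration, and the
  aspect ratio √(λ_max/λ_min) of the unit-mass inertia tensor, overall and
  conditioned on the adsorbed state.
* **Energetics** — ΔG_ads = −RT ln(ρ_ads/ρ_free) from adsorbed/free
  molecule densities, with the shell and bulk volumes estimated by seeded
  Monte-Carlo integration around the (non-spherical) protein.
* **Solvation and aggregation** — cumulative water RDFs around polymer
  atoms, geometric hydrogen-bond counting, chain aggregation clusters, and
  diffusion coefficients from mean-square displacements.

Because studies of this kind rarely deposit their trajectories, the package
ships two first-class synthetic generators that provide ground truth for
every stage: a two-state Markov placement model with exactly known
adsorbed probability and exponential residence times, and an overdamped
Brownian-dynamics bead-spring simulator with a protein surface well,
tunable chain stiffness, and optional chain–chain attraction that
reproduces poly-alanine-like self-aggregation.

## Worked example

Generate a ground-truth dataset (30 tetramer chains around a spherical
protein, per-chain adsorption rate k_on = 0.2 /ns, desorption rate
k_off = 1 /ns), detect adsorption events, and compute shell fractions and
the adsorption free energy:

```r
library(coronadsorb)

params <- markov_params(n_chains = 30, n_frames = 2000, k_on = 0.2,
                        k_off = 1.0, water_density = 0.002,
                        resample = "frame", seed = 42)
gen <- generate_markov_trajectory(params)

ser   <- chain_state_series(gen$traj, gen$system, cutoff = 5)  # 0.5 nm
ev    <- detect_events(ser)
rates <- event_rates(ev, ser)
res   <- lognormal_summary(ev$duration[ev$state == "adsorbed" & !ev$censored])
sf    <- shell_fraction(gen$traj, gen$system)
sv    <- shell_volume(gen$system, cutoff = 5, seed = 1,
                      frame = frame_coords(gen$traj, 1))
dg    <- adsorption_free_energy(ser, sv$shell, sv$bulk)
```

Output (printed by the corresponding `sprintf` calls):

```
mean adsorbed molecules: 4.6 +- 1.7 (truth p*n = 5.0)
adsorption rate: 0.180 /ns   desorption rate: 0.178 /ns
residence time (GM, 68% CI): 0.46 (+0.96 -0.31) ns  [truth 1/k_off = 1.0]
shell polymer fraction [A_P]: 0.302 +- 0.092   bulk [A_s]: 0.217
dG_ads: -0.32 +- 0.05 kcal/mol
```

Reading the numbers: the stationary adsorbed probability of each chain is
k_on/(k_on + k_off) = 1/6, so about 5 of the 30 chains are adsorbed at any
instant, matching the occupancy count. At stationarity adsorption and
desorption fluxes balance (0.180 vs 0.178 events/ns). The geometric mean
residence time (0.46 ns) sits below the arithmetic mean 1/k_off = 1 ns, as
it must for an exponential distribution (GM = e^{-γ}/k_off ≈ 0.56/k_off);
the +0.96/−0.31 asymmetric interval reflects the long right tail. The shell
polymer fraction exceeds the bulk fraction, i.e. surface enrichment, and
correspondingly ΔG_ads < 0.

Every analysis works identically on real data: read a PDB topology with
`load_topology()` (residue-name to role mapping is configurable) and a DCD
or XYZ trajectory with `load_trajectory()`, or drive whole runs from a YAML
config with `run_pipeline()` / the `inst/exec/coronadsorb` script.

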
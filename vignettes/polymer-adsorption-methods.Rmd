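---
title: "Methods: polymer adsorption analysis on protein surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polymer adsorption analysis on protein surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronadsorb)
```

This vignette documents the models, conventions and numerical choices behind
the package, in the spirit of a methods section: what each quantity means,
which knobs matter, and what the synthetic ground-truth generators do and do
not emulate.

## The system and its units

A `MolecularSystem` is a static topology — atoms with element, mass, residue
and chain labels, and a role tag (protein, polymer, water or ion) — plus an
orthorhombic periodic box. A `Trajectory` is an `n_atoms x 3 x n_frames`
coordinate array with per-frame boxes and a frame spacing `dt`. Internal
units are Angstrom, ns and kcal/mol throughout; superposition RMSDs are
reported in nm, the customary unit for backbone drift. All distance-based
analyses use the minimum-image convention; `min_image_distance()` is checked
in the test suite against a brute force over all 27 periodic images.

Water is counted through its oxygen (the sole water heavy atom), and "heavy
atom" means any element other than H/D. "Distance from the protein" always
means the distance to the *nearest protein heavy atom* — a surface
distance — because shell thicknesses of a few Angstrom are only meaningful
relative to the surface, not the center of mass.

## Chain chemistry bookkeeping

`build_polymer_topology()` constructs heavy-atom chain templates whose atoms
carry united-atom masses (implicit hydrogens folded into the bonded heavy
atom), so template masses sum to the exact molecular weight and
`mass_concentration()` needs no hydrogen placement. Two PEG end-group
conventions exist because the choice is genuinely open: hydroxyl-terminated
H–(OCH~2~CH~2~)~n~–OH (the default; 3n+1 heavy atoms, 22 for the 7-mer,
consistent with the heavy-atom counts used in adsorbed-atom distributions)
and methyl-ether capped CH~3~–(OCH~2~CH~2~)~n~–OCH~3~ (3n+3 heavy atoms),
whose higher molecular weight better matches some published concentration
tables for short PEG. Poly-sarcosine and poly-alanine use an acetyl N-cap
and an N,N-dimethylamide C-cap — the capping scheme that reproduces the
published 26 heavy atoms for both 4-mers and makes the two species exact
constitutional isomers (identical formula C~16~H~29~N~5~O~5~).

## Shell densities and the Langmuir model

The shell polymer fraction [A~P~] is the fraction of solvent heavy atoms
(polymer heavy atoms plus water oxygens) within a 0.5 nm layer of the
protein surface that are polymer; [A~s~] is the same fraction over the whole
box. Treating the surface as a finite set of equivalent polymer-atom binding
sites, A~s~ + P~s~ ⇌ A~P~ leads to the Langmuir isotherm

$$[A_P] = \frac{P_s^{max}\, K_a\, [A_s]}{1 + K_a [A_s]}.$$

The denominator convention deserves a note: a typeset form with denominator
"K~a~ + A~s~" also circulates, but only the form above saturates at
P~s~^max^ (which is what a *maximum* binding-site concentration means) and
yields shell enrichment at the parameter scale such fits produce; the
literal alternative predicts depletion there. Both are implemented
(`form = "standard"` / `"literal"`), standard is the default.

`fit_langmuir()` uses Levenberg–Marquardt least squares (via minpack.lm)
with inverse-variance weights when per-point standard deviations are
available — isotherm points come with error bars, and whether the original
fits were weighted is unknowable, so weighting is exposed as an argument.
A fixed grid of starting values K~a~ ∈ {0.1, 1, 10, 100} (with
P~s~^max^ started at 1.2·max[A~P~], clipped to (0,1]) guards against local
minima while keeping the fit deterministic. Parameter uncertainties come
from the linearized covariance; the test suite measures their actual
coverage by simulation. With a single concentration the fixed-P~s~^max^
variant inverts the curve exactly.

The RDF of polymer around the protein normalizes the observed
surface-distance histogram by the distribution of the same distance for
points uniform over the protein-*accessible* volume, estimated by seeded
Monte-Carlo sampling (default 2×10^5 points; the protein is not a sphere,
so no analytic shell volume exists). The reference excludes the protein
interior exactly as the polymer is excluded, which is what makes g(r) = 1
for an ideal gas. `decay_extent()` reports the largest distance at which
|g−1| still exceeds a tolerance (default 0.05, a reported parameter —
"detectable enrichment" has no canonical threshold).

## Hysteresis kinetics

Adsorption and desorption events use a dual-threshold state machine: a free
chain adsorbs when *more than half* of its heavy atoms are within 0.5 nm of
any protein heavy atom (for an n-atom chain, count > ⌊n/2⌋, so 3 of 4), and
an adsorbed chain desorbs only when *every* atom has left the layer. The
asymmetry suppresses recrossing flicker. The initial state of each chain is
assigned by the adsorption criterion at the first frame — a choice the data
cannot decide, recorded here. Maximal constant-state runs become events;
runs touching either end of the trajectory are censored in the standard
survival sense: excluded from duration statistics, kept for occupancy.
Independent runs are analyzed separately and pooled at the statistics level,
which also means concatenating trajectories is deliberately *not*
equivalent to analyzing them separately (the seam would fabricate events).

Residence times from such analyses are lognormal-like with long tails, so
`lognormal_summary()` reports the geometric mean with the empirical
16th/84th percentiles as an asymmetric 68% interval (a GM×/÷GSD option is
available). `duration_histogram()` uses log-spaced bins normalized to
events per unit time.

## Shape descriptors

Chains are unwrapped across periodic boundaries by walking their bond graph
with minimum-image displacements before any measurement. End-to-end
distance uses the first and last *backbone* heavy atoms (caps excluded).
The aspect ratio is √(λ~max~/λ~min~) of the moment-of-inertia tensor about
the centroid with *unit* masses — a pure shape measure; whether published
tensors were mass-weighted is usually unstated, so a mass-weighted flag
exists. Note the inertia and gyration tensors give different aspect ratios
for planar or collinear shapes; collinear chains (λ~min~ → 0) are reported
as `Inf` rather than a large unstable number. The identity
R~g~² = λ₁+λ₂+λ₃ (gyration-tensor eigenvalues) is used as an internal
cross-check in the tests.

## Free energies

ΔG~ads~ = −RT ln(ρ~ads~/ρ~free~), with ρ~ads~ the mean number of adsorbed
molecules per shell volume and ρ~free~ the mean number of free molecules
per bulk volume (box minus protein minus shell). The log is natural —
the statistical-mechanics convention, and the one consistent with
kcal/mol-scale values at RT ≈ 0.596 kcal/mol — with base 10 behind a flag.
The adsorbed/free status comes from the same hysteresis state machine as
the kinetics, so occupancy and event statistics share one definition.
Volumes come from seeded Monte-Carlo integration; the protein interior is
excluded analytically for the idealized sphere and by a per-atom van der
Waals radius test (C 1.7, N 1.55, O 1.52, S/P 1.8 Å) for atomistic
proteins. Uncertainty is estimated by block averaging (default 5 blocks;
blocks shorter than the state correlation time underestimate the error, so
the consistency tests compare at 3 standard errors).

## The synthetic generators

Real datasets of this kind — hundreds of short chains around a ~578-residue
protein, hundreds of ns — are rarely deposited, so the package validates
itself on two generator tiers.

**Markov placement tier.** Each chain is an independent two-state
continuous-time Markov chain (free ⇌ adsorbed, rates k~on~, k~off~)
propagated *exactly* over the frame spacing via its transition matrix, so
equilibrium occupancy p = k~on~/(k~on~+k~off~) and exponential residence
times are known analytically. When adsorbed, every bead is placed (by
rejection against the actual discrete protein atoms) at surface distance in
(0, c−δ]; when free, beyond c+δ. The margin δ (default 1 Å) guarantees the
detector recovers the true state of *every* frame — the placement cannot
flicker across the threshold — which is what makes 100% state-sequence
recovery a meaningful acceptance bar rather than luck. Water is uniform,
non-interacting points resampled per frame: the analyses use water only as
a count reference, so its default density is a tenth of bulk water's
0.0334 Å⁻³ to keep desk-scale memory reasonable (ratio statistics are
invariant to this scale). The idealized protein is a Fibonacci lattice of
surface points on a sphere (800 points on 15 Å by default; the lattice
spacing bounds the surface-distance discretization error, and the volume
tests use 8000 points on a 20 Å sphere to keep that error well under 1%).
Placement conformations are compact random walks, drawn identically for
adsorbed and free chains; with shells thinner than the chain span the
rejection step mildly favors compact conformations among adsorbed chains,
so the shape-independence test uses a thick shell where the coupling
vanishes. An `anchor_patch` option restricts adsorption anchors to part of
the surface, giving the residue-affinity machinery a known "binding patch"
to detect.

**Brownian-dynamics tier.** Where conformational or aggregation *dynamics*
matter, an overdamped Langevin integrator
(x ← x + (D/k~B~T)F dt + √(2D dt) ξ) evolves bead-spring chains with
harmonic bonds (k = 10 kcal/mol/Å², r₀ = 3 Å), an optional cosine angle
stiffness k~θ~(1+cos θ) that straightens chains (mimicking the reduced
backbone flexibility of peptoids/peptides relative to PEG), a Gaussian
attraction well of depth ε and range σ at the sphere surface with a
harmonic wall inside, and an optional Gaussian inter-chain well (plus soft
Gaussian core repulsion) driving self-aggregation, the poly-alanine-like
behaviour. The default timestep 2×10⁻⁴ ns keeps the bond-length RMS
fluctuation near its equilibrium value √(k~B~T/k) ≈ 0.24 Å (< 0.3 r₀; the
generator checks this post hoc and warns). Coordinates are left unwrapped
so displacement statistics need no unwinding; all pair forces use minimum
images. Waters are again per-frame uniform points, but excluded from a
2.5 Å zone around every bead — that exclusion is what couples aggregation
to hydration: beads buried in a cluster "see" fewer waters in their
cumulative RDF, reproducing the qualitative drying signature of
self-aggregating chains. One-bead chains in the surface well satisfy a
detailed-balance check: shell occupancy matches the Boltzmann-weighted
volume integral within 15%.

What the generators do *not* emulate: explicit solvent forces and
hydrodynamics, protein flexibility and sequence (pseudo-residues are
lattice points), electrostatics, and any force-field energetics. Passing
tests therefore demonstrate that the *analysis machinery* is correct and
self-consistent — not that it would reproduce any particular published
number derived from atomistic force fields.

## Problem sizes and determinism

The test and acceptance runs use desk-scale versions of the study design:
30–100 chains of 4–7 beads, 60 Å boxes, 2 000–20 000 frames at 0.01–0.02 ns
spacing (up to 200 ns per run, 10 independent seeds for the kinetics
recovery), 2–8×10^5 Monte-Carlo samples for volumes and RDF references, and
200-seed simulation studies for fit calibration. Every stochastic component
draws from R's RNG under an explicit seed argument (`markov_params(seed=)`,
`bd_params(seed=)`, `shell_volume(seed=)`, `polymer_rdf(ref_seed=)`), and
the pipeline manifest records the seed, so reruns are bit-identical for
deterministic stages. Statistical assertions in the tests are phrased with
their own sampling error (3σ bands, or a binomial allowance on coverage
rates) rather than as point equalities.

## Known limitations

* Orthorhombic boxes only; triclinic cells are out of scope.
* `unwrap_chain()` assumes no bond spans more than half the box; chains
  comparable to the box size would be ambiguous.
* The Monte-Carlo uniform reference makes RDF values noisy in bins with
  tiny stratum volumes (deep surface pockets); the standard error column
  quantifies this.
* Hydrogen-bond counting needs explicit hydrogen positions (or constructed
  donor pseudo-geometry); heavy-atom-only topologies cannot supply them.
* The Brownian tier's Euler–Maruyama scheme is first-order: observables
  that depend on the stationary distribution near stiff potentials carry
  an O(dt) bias, which is why its quantitative checks (Einstein relation,
  detailed balance) run at the default small timestep.
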
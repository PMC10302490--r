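---
title: "Calibrating bonded parameters of coarse-grained lipid models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating bonded parameters of coarse-grained lipid models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbonded)
```

## The calibration problem

Coarse-grained (CG) lipid models of the Martini family replace groups of
2--5 heavy atoms by single beads.  The nonbonded interactions of those
beads come pre-parameterized with the force field; what remains open for
every new lipid model is its *bonded* terms -- the equilibrium values and
force constants of the harmonic bonds and angles that hold the beads
together.  Hand-tuning them lipid by lipid does not scale and ignores two
sources of information at once: experimental measurements of the bilayer
each lipid forms, and higher-resolution (all-atom, AA) simulations of the
same systems.

`cgbonded` automates this calibration.  Its ingredients:

1. **Building blocks.**  Every bond and angle is classified by the tuple
   of bead types it involves (orientation-free: the canonical key is the
   lexicographically smaller of the tuple and its reverse, with an
   angle's vertex bead kept in place).  All instances of a motif -- in one
   lipid or across lipids and temperatures -- share one parameter pair.
   This is what makes the parameters transferable and keeps the search
   space small: the bundled mixed-resolution representation of eight
   phosphatidylcholine (PC) lipids classifies into 16 bond and 27 angle
   types, 77 free parameters in total (nine angle equilibria stay fixed
   at 180 degrees).

2. **A composite loss.**  Candidate parameters are scored by simulating
   every training system (a lipid/temperature pair) and combining

   * *top-down* terms: the percentage deviations of the area per lipid
     (APL) and the head-to-head bilayer thickness (D~HH~) from their
     experimental targets, hinged at a tolerated error
     `epsilon` (default 1.5%): deviations inside the band are free,
     beyond it they are penalized linearly and averaged over systems;
   * *bottom-up* terms ("OT-B"): the 1-D Wasserstein (earth mover's)
     distance between each candidate bond/angle distribution and its
     AA-mapped reference, averaged per block over instances, with bond
     distances (Angstrom) scaled by `w2 = 50` so that 0.4 Angstrom of
     bond mismatch weighs like 20 degrees of angle mismatch; the OT-B
     component is the plain mean of the scaled per-block means.

   The total is `w1 * (dAPL_global + dDHH_global) + OTB_global` with
   `w1 = 10`: with these defaults the experimental observables dominate
   as long as per-block distances stay below about 0.2 Angstrom for
   bonds and 10 degrees for angles.

3. **A fuzzy self-tuning particle swarm (FST-PSO).**  The loss is noisy,
   non-differentiable and moderately high-dimensional, which is the
   regime PSO handles well.  The default population is
   `floor(10 + 2 * sqrt(dim))` particles (27 at 77 dimensions, 23 at 48).
   The first particle is seeded with knowledge: reference-distribution
   means for the equilibria and midpoints of user-supplied prior ranges
   for the force constants.  Optimization stops after 10 swarm
   iterations without strict improvement of the global best.

## The exact loss conventions

Several aggregation choices are conventions of this package (the
quantitative calibration statements above pin them down only jointly):
deviations are hinged at `epsilon` *then* averaged arithmetically over
systems; the two observables contribute additively and symmetrically;
per-block EMD means are weighted by instance counts; and the OT-B
component averages (rather than sums) over the `B + A` block types, so
that it does not grow with representation size.  All of them sit behind
`loss_weights()` / `otb_global()` / `topdown_global()` / `total_loss()`
and can be swapped behind the same interface.

The 1-D Wasserstein distance is computed on fixed histogram grids --
0.05 Angstrom bins on [0, 15 Angstrom] for bonds, 2 degree bins on
[0, 180 degrees] for angles -- as the integrated absolute difference of
the two cumulative distributions.  The grids are fine relative to the
0.2 Angstrom / 10 degree scales that matter, and the distance is robust
to binning; the test suite checks it against an independent
transport-matching oracle to 1e-9.

## The self-tuning swarm

The cited self-tuning PSO method adapts each particle's settings by
Sugeno-type fuzzy rules; since the original rule base is not restated in
the protocol we implement our own with the same structure.  Two inputs
are computed per particle and iteration: the normalized fitness change
`phi` (positive = improving, in [-1, 1]) and the distance from the
global best normalized by the search-space diagonal, `delta`.
Triangular memberships (`worse/same/better` for `phi`;
`same/near/far` for `delta`, with the `near` peak at 0.2) fire one rule
per control setting, and the crisp outputs are membership-weighted
averages of three singleton levels per setting:

| setting | low | med | high | raised by |
|---|---|---|---|---|
| inertia | 0.4 | 0.7 | 0.9 | improving, far from best |
| cognitive | 0.5 | 1.5 | 2.2 | near best |
| social | 0.8 | 1.5 | 2.2 | worsening, far from best |
| max velocity (fraction of range) | 0.05 | 0.2 | 0.4 | improving, far |
| min velocity (fraction of range) | 0 | 0 | 0.002 | far |

The design intent: particles that are improving keep their momentum;
particles that worsen are pulled toward the global best; particles close
to the best switch to fine search (low inertia, capped step size);
distant particles get a velocity floor so they cannot stall in transit.
Positions are reflected into the bounds, and best updates are strictly
monotone (`<`, ties do not reset the stale counter).  A plain-PSO
fallback (`omega = 0.72`, `c1 = c2 = 1.49`) is selectable with
`mode = "plain"` and flagged in the run metadata; on the 5-D sphere
benchmark the self-tuning mode reaches a lower median best loss than the
fallback over 20 seeds.

## The surrogate backend and what it does (not) emulate

Scoring one candidate against real molecular dynamics takes CPU-days;
the package therefore defines a backend *contract*
(`md_backend()` stages ITP topologies, runs templated commands, parses
the trajectory through the mapping and observables modules, and maps
non-zero exits or destroyed bilayers to failure results) and ships a
deterministic **surrogate backend** that makes the full loop testable at
desk scale:

* bond/angle samples are drawn from the Boltzmann statistics of each
  harmonic term at the system temperature -- Gaussian with standard
  deviation `sqrt(RT/k)` around the candidate equilibrium (plain
  Gaussians, without the `r^2` Jacobian a radial distance would carry;
  acceptable for stiff bonds and it keeps the planted optimum exact);
* APL and D~HH~ respond linearly to the normalized parameter error with
  sparse random coefficients of magnitude 0.01--0.05 (seeded), plus
  0.3% Gaussian noise -- large enough to push the observables out of the
  tolerated band at moderate parameter error;
* every evaluation is deterministic given the ground-truth seed and the
  candidate vector, so optimization runs are bit-reproducible.

`demo_calibration()` builds the standard synthetic study: two 5-bead
lipids sharing part of their bead-type sequence (6 bond + 6 angle
blocks, 24 free parameters), two training systems at 300 K and 320 K,
references drawn at the true parameters with 4 x 10^4 samples, and 10^4
samples per candidate evaluation (the scale at which the surrogate's
sampling error is small against the 0.2 Angstrom / 10 degree loss
scales).  Against these references the optimizer recovers the planted
bond equilibria to within 0.1 Angstrom and angle equilibria to within 4
degrees across seeds; with a swarm of 38 particles (twice the heuristic,
affordable because surrogate evaluations are milliseconds) the total
loss drops below 1.0 within 100 iterations.

What the surrogate deliberately does **not** emulate: correlations
between bonded terms, anharmonicity and multimodality of real AA-mapped
distributions, phase transitions, and the coupling of observables to
nonbonded interactions.  Passing the recovery suite therefore shows the
*machinery* (loss, optimizer, bookkeeping, reproducibility) is sound; it
says nothing about the physical accuracy of any particular lipid model,
which only real MD evaluations can establish.

## Bundled representations are reconstructions

The exact per-lipid bead-type assignments of the original mixed- and
uniform-resolution PC representations are not part of this package's
sources; the files under `inst/extdata/` (suffixed `_synthetic`) are
reconstructions.  The lipid set (DLPC, DMPC, DPPC, DSPC, POPC, DOPC,
PDPC, SDPC), the head-group architecture and the published mapping rules
are followed, and the bead-type labels were chosen so that
classification reproduces the published block structure exactly -- 16
bonds / 27 angles / 9 fixed equilibria (77 free parameters) for the
mixed-resolution representation, 13 / 12 / 2 (48) for the
uniform-resolution one.  Two reconstruction details are worth naming:
in the first representation the choline and glycerol-1 beads share a
type label (sharing the phosphate-linker bond block); and the second
representation declares its angle list explicitly per lipid, as Martini
lipid topologies conventionally do -- with these chain typings no
all-connected-triples enumeration reaches an angle-type count below the
bond-type count.  Representations are fully user-configurable YAML, so
real mappings can be dropped in without code changes.

## Observables and phase analysis

* **APL** is `Lx * Ly / (n_lipids / 2)` per frame, averaged over the
  final 50% of frames (the package's equilibrium window; configurable).
* **D~HH~** is the distance between the two phosphate density peaks
  along the bilayer normal: frames are re-centered to the membrane
  center of mass, the number density is accumulated in 1 Angstrom bins,
  and each leaflet's peak position is the density-weighted mean of the
  bins within 75% of that leaflet's maximum (the 75%-centroid is this
  package's documented peak rule).  A profile with no two-peak structure
  is flagged invalid -- a destroyed bilayer, mapped to a failed
  evaluation.
* **Tail tilt** is the mean angle between per-lipid first-to-last tail
  bead vectors and the bilayer normal, folded to [0, 90] degrees so both
  leaflets count alike.  This approximates tilt definitions based on
  segmental order only roughly, which is documented where it is used.
* **LENS** (Local Environments and Neighbors Shuffling) quantifies, per
  lipid and frame pair, the turnover of its neighbor set:
  `|symmetric difference| / (|set_t| + |set_t+stride|)`, 0 for frozen
  environments and 1 for complete exchange.  Defaults -- one
  representative bead per lipid, an 11 Angstrom cutoff, unit stride, a
  5-frame smoothing window and a threshold at the midpoint between the
  two modes of the smoothed-LENS distribution (located by a
  deterministic two-means split; unimodal distributions fall back to a
  single-phase label by overall level) -- are this package's documented
  choices, and every output carries the parameters used.

## Numerical choices and degenerate inputs

* Units are GROMACS-native internally (nm, degrees, kJ/mol); the loss
  converts bond quantities to Angstrom where its calibration is stated.
* Histogram mass beyond the fixed grids is absorbed into the outermost
  bin so distributions always sum to one; empty sample sets are errors.
* The minimal-image convention is applied to all intra-lipid geometry;
  boxes are orthorhombic.
* Bead mapping uses mass-weighted centers by default (`method = "cog"`
  switches to geometric centers, since the original choice is not
  documented).
* Decoding clamps out-of-bound parameters by default and can reject
  instead; the surrogate treats out-of-bound candidates as failed
  simulations (`+Inf` loss), mirroring crashed MD runs.
* Non-finite objective values never propagate: they become `+Inf` and a
  first iteration that fails for every particle aborts with a
  diagnostic.
* Seeded runs are bit-reproducible; run directories record config, seed,
  package version and convergence reason.

## Problem sizes used in the test suite

The bundled suites run at deliberately small scale: the two-lipid
surrogate study (24 parameters, 2 systems, 10^4 samples per evaluation,
at most 100 swarm iterations), 1000 random histogram pairs for the
Wasserstein oracle, a 128-particle two-phase LENS fixture over 12
frames, and three-frame trajectory fixtures for the mapping and backend
contracts.  These sizes are the package's own trade-off between coverage
and turnaround; the cluster-scale optimizations the method is designed
for (tens of parameters against eleven bilayer simulations over weeks)
run through exactly the same code path via the MD backend contract.

## Known limitations

* Only harmonic bonds and angles are calibrated; dihedrals, constraints
  and any nonbonded parameters are out of scope (bead types are opaque
  labels here).
* The loss aggregation conventions above are one consistent reading of
  the protocol's quantitative statements; alternatives (quadrature
  combination, sums over types) plug in behind the same interface but
  are not selected by any published number we could verify against.
* The MD backend contract is exercised with staged fixtures, not against
  a live engine, in this environment.
* Trajectory input is text GRO (multi-frame); compressed binary formats
  would need an external conversion step.
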
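---
title: "Models and methods behind colfibril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind colfibril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

colfibril studies collagen fibrillogenesis from two directions at once: a
coarse-grained molecular model in which fibril formation can be simulated
and measured, and a set of curve-analysis routines for the bench-top
observables that characterise the same process in the laboratory
(turbidimetry, 2D-IR line shapes, amide-I band areas, circular-dichroism
melting curves).  This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what desk-scale
synthetic experiments can show.

## The coarse-grained model

Tropocollagen monomers are represented by a collagen-mimetic rod of 36
overlapping beads (`molecule_template()`).  All quantities are in reduced
units: length sigma (1 sigma = 1 nm), energy kT, time tau0, bead mass 1.

* **Geometry.**  Beads of diameter 1.12 sigma are connected by harmonic
  bonds `E = k_bond (r - r0)^2` with `r0 = 0.255` sigma and
  `k_bond = 500 kT/sigma^2`; triplets carry a harmonic angle
  `E = k_angle (theta - pi)^2` with `k_angle = 50 kT` that keeps the rod
  semi-rigid.  The end-to-end template length is
  `35 * 0.255 + 1.12 = 10.045 sigma`, a 10 nm rod.
* **Charges.**  Each bead carries a sign in {-1, 0, +1}.  The default
  pattern places four positive charges near one end (beads 2, 5, 8, 11)
  and four negative charges near the other (beads 25, 28, 31, 34), every
  third bead, the blocky motif of D-periodic collagen-mimetic 36-mer
  peptides whose cationic block sits in the first third and anionic block
  in the last third of the sequence.  The pattern is an explicit field of
  the template; every routine works with any supplied pattern, and results
  that depend on the charge layout should be read as conditional on it.
* **Nonbonded interactions** (`force_field()`).  Two cut-and-shifted pair
  potentials act between all bead pairs except the 1-2 through 1-5
  neighbours within one molecule (more distant intra-chain pairs do
  interact): a Lennard-Jones term `4 eps_H (r^-12 - r^-6) + shift`
  standing in for generic hydrophobic attraction, and a screened
  electrostatic (Debye-Hueckel/DLVO) term
  `eps_E qi qj exp(-r/lambda)/r + qi qj shift` with `lambda = 1 sigma`
  (about the physiological Debye length when sigma = 1 nm).  Both use
  `r_cut = 2 sigma`; the shift constants are recomputed from `r_cut` at
  construction so each potential is exactly zero at the cutoff.
* **Dynamics.**  Constant-N, constant-V Langevin dynamics with the BAOAB
  splitting of velocity Verlet: half kick, half drift,
  Ornstein-Uhlenbeck friction/noise exactly satisfying
  fluctuation-dissipation at the configured temperature, half drift, half
  kick.  Damping time 1 tau0, default timestep 0.001 tau0.  With the
  thermostat disabled the integrator is plain velocity Verlet, which is
  how the NVE energy-conservation check is run.  The noise stream comes
  from a dedicated counter-seeded PRNG, so trajectories are bit
  reproducible for a given seed and independent of R's global RNG state.
* **Boundaries.**  Periodic cubic box with minimum-image distances.  The
  model text this implements does not state boundary conditions; a
  periodic box is the standard choice for bulk self-assembly at fixed
  concentration and is what the fixed number concentration implies.
  Molecules are stored spatially whole and wrapped by their centroid.
* **Initialisation** (`init_system()`).  Uniformly random centres and
  orientations, then a bounded soft-core push-off (purely repulsive WCA
  cores, steepest descent with per-iteration displacement cap) followed by
  a short displacement-capped athermal quench; velocities are then drawn
  from the Maxwell-Boltzmann distribution.  Boxes smaller than the rod, or
  packings beyond ~45% spherocylinder volume fraction, are refused.
* **Neighbour list.**  Verlet list built from a cell list (skin 0.45
  sigma, rebuilt when any bead has moved more than half the skin), a pure
  performance device: the test suite holds it to exact agreement with an
  all-pairs double loop at 1e-9 relative.

The reference configuration is N = 2500 rods in a box of L = 171 sigma
(number concentration 0.0005 per sigma^3).  Desk-scale work uses smaller,
denser systems; see "Scaled-down conditions" below.

## Fibril morphometrics

`detect_clusters()` connects two molecules when any inter-molecular bead
pair is closer than `contact_cutoff` (default 1.5 sigma, between bead
contact at 1.12 and the interaction cutoff at 2; the clustering rule is a
package choice, stated rather than inherited).  Connected components are
computed by union-find in compiled code; periodic image bookkeeping on the
contact edges lets each cluster be unwrapped into a spatially whole object.

The assembled-mass fraction phi is the fraction of molecules in clusters
of at least `min_fibril_size` molecules (default 5; below that a cluster
is treated as a transient oligomer).  t80 is the first time phi crosses
0.8, linearly interpolated between snapshots.  Fibril diameters are
measured per cluster as twice the 95th-percentile radial distance of bead
centres from the principal axis of the cluster, plus one bead diameter;
the percentile rather than the maximum keeps one dangling molecule from
dominating the estimate, and a single straight rod measures exactly one
bead diameter.  Distributions pool the final 20% of snapshots and are
normalised by the smallest pooled diameter D0.

## Turbidity kinetics

Absorbance at 313 nm converts to turbidity as `tau = A313 ln(10)` minus
the mean over an early-time baseline window (default the first 5% of
samples).  `fit_fibrillation_kinetics()` fits a logistic sigmoid
`delta_tau / (1 + exp(-k (t - t_half)))` plus a free offset (the offset
absorbs whatever the baseline subtraction left behind) and reports the
tangent-at-inflection descriptors: growth rate `k_g = k delta_tau / 4`
(the maximum of d tau/dt), lag time `t_lag = t_half - 2/k`, plateau time
`t_plateau = t_half + 2/k`, so `t_plateau - t_lag = 4/k` identically.
The tangent construction is the standard convention for sigmoidal
fibrillation traces; a Gompertz alternative is provided because
nucleation-growth turbidity curves are often asymmetric, with its own
tangent descriptors (`t_lag = t_half - 1/k`,
`t_plateau = t_half + (e-1)/k`, `k_g = k delta_tau / e`).  Flat traces
return a flagged no-fibrillation result instead of an error.  pH-meter
readings taken in D2O convert to pH via the affine correction
`pH = 0.929 pH* + 0.4`.

## Spectroscopy

* **Amide-I decomposition.**  Least-squares Gaussian mixture on a linear
  baseline over 1600-1700 cm^-1, default two components initialised at
  1635 and 1660 cm^-1 (the solvent-exposed and buried carbonyl bands of
  triple-helical collagen); the component count and window are arguments.
  The reported low/high area ratio tracks the solvation state of the
  backbone carbonyls.
* **Central line slope.**  For each probe-frequency slice inside the band
  window, the pump frequency of the deepest bleach is located with
  parabolic sub-grid refinement; a line through the (probe, pump-minimum)
  locus gives the central line.  Drawn in the conventional pump-on-x
  orientation that line has slope >= 1, and the CLS is its inverse —
  numerically the fitted `d(pump)/d(probe)` — clipped to [0, 1].  For a
  bivariate-Gaussian bleach the statistic equals the pump-probe frequency
  correlation, which is exactly how the synthetic generator calibrates it:
  recovery of rho to within 0.05 across rho in {0, 0.3, 0.5, 0.7, 0.9} is
  part of the acceptance suite.  Slices whose bleach is shallower than 10%
  of the deepest slice are discarded; fewer than 5 usable slices is an
  error, as is a window with no negative lobe.
* **CD helicity and melting.**  Rpn is the positive maximum (search window
  210-230 nm) over the absolute negative minimum (190-205 nm); windows
  bracket the canonical 220/198 nm features and are configurable.  Melting
  curves are fitted with a two-state model with linear folded and unfolded
  baselines and a logistic folded fraction; Tm is the midpoint.  Traces
  whose end-baselines are indistinguishable return a flagged no-transition
  result.

## Synthetic data

Every generator (`gen_turbidity_trace()`, `gen_2dir_bleach()`,
`gen_amide_spectrum()`, `gen_cd_melt()`, `gen_fibril_bundle()`) is
deterministic under its seed, leaves the caller's RNG untouched, carries
its ground truth as an attribute, and can write a JSON truth sidecar next
to the data.  Noise is i.i.d. Gaussian throughout — real instruments add
correlated drifts, scatter backgrounds and detector nonlinearity that
these generators deliberately do not emulate, so round-trip recovery shows
estimator correctness, not robustness to instrument pathology.  The
hexagonal `gen_fibril_bundle()` fixture has a closed-form diameter
(`2 r_outer + bead diameter`), which pins the diameter estimator's scale.

## Scaled-down conditions

The desk-scale sweep (`default_sweep_spec()`) uses N = 200 rods in a 36
sigma box (concentration 0.0043 per sigma^3, about nine times the
reference concentration), timestep 0.006 tau0, 60 tau0 of simulated time,
a 2 x 2 grid of eps_H in {0.05, 0.25} kT by eps_E in {2.5, 5} kT
bracketing the reference cell (0.05, 5), and 5 replicates per cell.  These
sizes were chosen once so that the reference cell reaches its
assembled-mass plateau within the run on a single CPU core in a few
minutes per replicate.

Two consequences of this compression should be kept in mind when reading
sweep results.  First, at this concentration a random rod configuration is
semi-dilute: roughly half the molecules already satisfy the contact
criterion at t = 0, so phi(0) is about 0.45 rather than 0, and t80
measures growth from that baseline.  Second, 60 tau0 resolves the
electrostatically driven assembly regime well (at eps_H = 0.05 kT,
raising eps_E from 2.5 to 5 kT cuts the median t80 by roughly half),
but it is far too short for the slow coarsening by which
strongly hydrophobic systems anneal compact kinetic aggregates into thick
bundles.  In this regime stronger short-range attraction of any kind
accelerates cluster-mass growth (diffusion-limited aggregation), so the
desk-scale sweep does not reproduce the slower-and-thicker direction
expected for increasing eps_H from long equilibrated runs; the acceptance
suite states that expectation honestly and records the failure rather
than adjusting conditions until it passes.

## Numerical choices and edge cases

* Angle forces at the straight-rod equilibrium are a 0/0 limit
  ((theta - pi)/sin(theta) -> -1); the implementation switches to the
  analytic limit below sin(theta) = 1e-8.
* One-step displacements larger than half the box raise an instability
  error with the step index; callers see it as a plain R error.
* The sigmoid and melting fitters deliberately start slightly off their
  self-derived initial estimates: Levenberg-Marquardt refuses to start on
  an exactly zero-residual point.
* t80 interpolation requires a strictly increasing time axis; a series
  that never reaches the target returns NA ("not reached"), and sweep
  medians treat those as right-censored at the run duration.
* Diameter estimation on periodic configurations always unwraps clusters
  first; the estimator itself is rotation and translation invariant.
* Cluster medians and the D0 normalisation are invariant to snapshot and
  replicate ordering.

## Known limitations

* The charge pattern is a documented stand-in with the correct block
  structure, not a transcription of any particular peptide sequence.
* The diameter estimator measures radial extent about the principal axis;
  for loose, snake-like clusters this reads larger than the "thickness" a
  microscopist would report, which compresses contrast between ordered
  and disordered aggregates.
* Assembled mass counts contact clusters regardless of internal order; it
  does not distinguish a staggered fibril from an amorphous blob.
* The experimental-trace analyses assume additive Gaussian noise and
  well-separated baselines; heavily drifting instruments need
  preprocessing upstream of these fits.
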
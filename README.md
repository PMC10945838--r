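# colfibril

Tools for studying collagen fibril self-assembly, in silico and from
bench-top traces.

Collagen monomers (tropocollagen) self-assemble into fibrils whose
formation kinetics and final architecture are set by a competition between
short-range hydrophobic attraction and screened electrostatic interactions
between the charged rod-like molecules. `colfibril` implements both sides
of the problem for people who work on fibrillogenesis:

* **A coarse-grained simulator** of collagen-mimetic charged elastic rods:
  36 beads per molecule joined by harmonic bonds
  (`E = k_bond (r - r0)^2`, `r0 = 0.255` σ, `k_bond = 500` kT/σ²) and
  angles (`E = k_angle (θ - π)^2`, `k_angle = 50` kT), interacting through
  a cut-and-shifted Lennard-Jones potential
  `4ε_H[(σ/r)^12 − (σ/r)^6] + E_shift` (hydrophobic strength ε_H) and a
  cut-and-shifted Debye–Hückel potential
  `ε_E q_i q_j exp(−κr)/r + q_i q_j E_shift` (electrostatic strength ε_E,
  screening length 1/κ = 1 σ = 1 nm), both zero at the cutoff r_c = 2 σ.
  NVT Langevin (BAOAB) dynamics in a periodic cubic box; all reduced units.
* **Fibril morphometrics**: contact-graph cluster detection, the
  assembled-mass fraction φ(t), the time t80 at which φ first reaches 0.8,
  and fibril diameter distributions D/D0 from principal-axis radial
  extents.
* **Turbidity kinetics**: τ = A313·ln 10 with early-time baseline
  subtraction, and logistic/Gompertz sigmoid fits reporting the
  tangent-at-inflection descriptors t_lag = t½ − 2/k,
  t_plateau = t½ + 2/k, k_g = kΔτ/4 and Δτ; plus the D2O pH-meter
  correction pH = 0.929·pH\* + 0.4.
* **Spectroscopy**: Gaussian amide-I band decomposition (1635/1660 cm⁻¹),
  the central line slope (CLS) of 2D-IR bleaches as an inhomogeneity
  statistic in [0, 1], the CD helicity ratio Rpn, and two-state melting
  fits for Tm.
* **Seeded synthetic-data generators** with ground-truth sidecars for every
  stage, so each estimator has a round-trip recovery test.

## Worked example

Simulate a small self-assembling system and measure the Fig.-style
observables:

```r
library(colfibril)

tpl <- molecule_template()            # 36-bead charged rod, 10.045 sigma
ff  <- force_field(eps_H = 0.05, eps_E = 5)
cfg <- sim_config(n_molecules = 100, box_length = 29, timestep = 0.005,
                  n_steps = 8000, seed = 7, snapshot_interval = 400)

tr <- run_simulation(cfg, tpl, ff)
ac <- assembly_curve(tr)              # (time, phi) table
time_to_fraction(ac$time, ac$phi, 0.8)
diameter_distribution(tr)
```

which prints

```
> tr
Coarse-grained trajectory: 100 molecules x 36 beads, 21 snapshots
  t = 0 .. 40 tau0; eps_H = 0.05 kT, eps_E = 5 kT; seed 7
> time_to_fraction(ac$time, ac$phi, 0.8)
[1] 25.84615
> diameter_distribution(tr)
Diameter distribution: 9 fibril measurements, D0 = 11.069 sigma
  D/D0 quartiles: 1.06 / 2.20 / 2.26
```

so this run crossed 80% assembled mass at t80 ≈ 26 τ0, and the pooled
fibril diameters of the final snapshots span about 1–2.3× the smallest
measured fibril, D0 ≈ 11 σ.

Analysing a turbidity trace (here a synthetic one whose true parameters
are known) works the same way on real two-column (time, A313) data:

```r
trace <- gen_turbidity_trace(delta_tau = 0.5, k = 0.02, t_half = 500,
                             noise = 0.05, seed = 1)
tb <- absorbance_to_turbidity(trace$time, trace$A313)
fit_fibrillation_kinetics(tb$time, tb$tau)
```

```
Fibrillation kinetics (logistic sigmoid)
  t_lag = 398.6 s, t_plateau = 599.9 s
  k_g = 0.002464 turbidity/s, delta_tau = 0.4958
  residual RMS = 0.023
```

The true values are t_lag = 400 s, t_plateau = 600 s, k_g = 0.0025 /s,
Δτ = 0.5: the tangent descriptors are recovered to about 1% at 5% noise.

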
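# relkin

Modelling and parameter estimation for the release kinetics of a solute —
typically the chemokine CXCL12 — from cylindrical alginate-based hydrogel
depots, as used in controlled-delivery systems that attract
CXCR4-expressing cells (e.g. glioblastoma) toward an implant.

The package is aimed at pharmaceutics / biomaterials researchers who have
cumulative-release measurements (static supernatant sampling or a
perfusion-bioreactor fraction collector) and want to (i) characterise the
release mechanism, (ii) estimate transport parameters from a mechanistic
diffusion model, and (iii) reduce perfusion data to closed mass balances.
A synthetic-data generator makes the entire pipeline runnable and testable
without any external data.

## The model

**Empirical stage — Korsmeyer–Peppas.** Over the early release window
(first 6 h), the cumulative fraction follows a power law

    M_t / M_inf = a t^n

fitted by ordinary least squares on log(M_t/M_inf) vs log(t). For a
cylinder, `n <= 0.45` indicates Fickian diffusion, `0.45 < n < 0.89`
anomalous transport, `n >= 0.89` erosion-controlled release.

**Mechanistic stage — axial diffusion with an interaction-limited
surface.** Concentration C(z,t) in a gel of height L obeys

    dC/dt = D_eff d2C/dz2,   C(z,0) = C_initial,
    dC/dz|_{z=0} = 0                       (sealed base),
    -D_eff dC/dz|_{z=L} = k (C|_L - C_eq)  (Robin release surface),

where `D_eff` (m²/s) is the effective diffusivity, `k` (m/s) the overall
surface mass-transfer coefficient, and `C_eq` the pseudo-equilibrium
concentration produced by electrostatic solute–alginate interactions —
it caps the long-time release at `100 (1 - C_eq/C_initial)` percent,
below 100%. The PDE is solved by Crank–Nicolson finite differences
(31 nodes, dt = 300 s by default) and released mass is
`M_t = M_inf - pi R^2 * trapz(C)`. An independent eigenfunction-series
solution (`analytic_release_fraction()`) verifies the solver.

**Inverse stage.** `estimate_transport()` recovers `D_eff` and `k`
(optionally `C_eq`) from a measured curve with a seeded real-coded
genetic algorithm (tournament selection, blend crossover, Gaussian
mutation) in log10 space, refined by a Nelder–Mead simplex.
`profile_objective()` diagnoses weakly identified directions — at high
Biot number `k L / D_eff`, release curves carry almost no information
about `k`.

**Perfusion stage.** `fit_pump_calibration()` (flow = mass / density /
time with a polynomial water-density model), `cumulative_release_from_fractions()`,
`dead_time()` (tubing dead-volume detection delay) and `mass_balance()`
(released + compartment percentages ≈ 100%).

## Worked example

Simulate a triplicate static-release experiment for the 0.4 µg/mL
alginate condition (5% measurement noise), then run the full analysis:

```r
library(relkin)
truth <- reference_truth("alginate", "0.4")
cfg <- release_config(truth = truth$params, c_initial = truth$c_initial,
                      noise = noise_model(0.05), n_replicates = 3,
                      ga = ga_config(seed = 42), seed = 7)
report <- run_pipeline(cfg)
report
#> == release pipeline report (relkin 0.1.0 ) ==
#> seed 7; 3 replicates; final release 45.82%
#> Korsmeyer-Peppas: n = 0.445 +/- 0.011 -> fickian
#> recovered d_eff = 9.883e-10 m^2/s (truth 1.04e-09), k = 0.001 m/s (truth 4.13e-05)
#> fit R^2 = 0.9997, sse = 0.4517
```

Reading the output: the release plateaus near 46% (the pseudo-equilibrium
cap), the early-window exponent ~0.45 classifies the mechanism as Fickian
diffusion, and the diffusivity comes back within 5% of the generating
value despite the noise. The surface coefficient lands at its search
bound: at Biot number ~200 the curve is insensitive to `k`, which
`profile_objective()` flags as a weak-identifiability warning — an honest
feature of this inverse problem, not a fitting failure.

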
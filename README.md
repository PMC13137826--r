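# trsaxs

Time-resolved small-angle X-ray scattering (TR-SAXS) analysis for
intrinsically disordered proteins (IDPs) measured in a laminar-flow
microfluidic mixer, with a pool-based ensemble-optimization workflow.

## The problem

An IDP such as monomeric α-synuclein (140 residues) has no single fold: its
solution state is a dynamic ensemble mixing compact conformations
(R<sub>g</sub> ≈ 30 Å) with elongated ones (R<sub>g</sub> ≈ 50–60 Å). When a
ligand — here, a transition-metal ion delivered by the flanking buffer
streams of a cross-shaped microfluidic chip — shifts that balance, SAXS
profiles recorded at positions along the channel become snapshots of the
ensemble at known times after mixing. This package implements the full
analysis chain needed to turn those profiles into population statements:

* **Reduction** — buffer subtraction, inverse-variance frame averaging with
  a median-based outlier guard, common-grid time series.
* **Per-curve descriptors** — Guinier fits of
  I(q) ≈ I(0)·exp(−q²R<sub>g</sub>²/3); a polymer-corrected R<sub>g</sub>
  from the Debye chain form factor P(x) = 2(e<sup>−x</sup> − 1 + x)/x²,
  x = (qR<sub>g</sub>)²; Kratky transforms q²I(q); the mass fractal
  dimension D<sub>m</sub> from log I = log I₀ − D<sub>m</sub> log q over the
  intermediate-q window; the normalized forward-intensity trace
  I(0)/I(0)₀.
* **P(r)** — a regularized indirect Fourier transform (Tikhonov-smoothed,
  nonnegative, endpoint-pinned) giving the pair-distance distribution,
  D<sub>max</sub> scans, and real-space R<sub>g</sub> and I(0).
* **Conformer pools** — self-avoiding Cα random walks (3.8 Å virtual
  bonds, hard-sphere excluded volume) drawn from a mixture of stiffness
  regimes so a single pool spans compact through extended chains.
* **Theoretical scattering** — the Debye formula
  I(q) = Σ<sub>ij</sub> f<sub>i</sub>f<sub>j</sub> sin(qr<sub>ij</sub>)/(qr<sub>ij</sub>),
  exact or histogram-accelerated (per-bin mean distance with a
  second-order curvature correction; relative error ~10⁻⁵).
* **Ensemble optimization** — a genetic algorithm selects a fixed-size
  multiset of pool conformers whose average profile, after fitting a scale
  and constant background, minimizes reduced χ². Elitism, tournament
  selection, uniform multiset crossover, random-reset mutation, an
  NNLS-seeded start and an exact coordinate-descent polish.
* **Downstream statistics** — ensemble-weighted domain distances for the
  NTD/NAC/CTD residue pairs, Ward-linkage clustering of standardized
  (R<sub>g</sub>, R<sub>ee</sub>, fraction) features cut at cophenetic
  distance t = 2.5 with silhouette validation, Kruskal–Wallis and Dunn
  tests with Benjamini–Hochberg correction, and Hedges' g with the
  small-sample factor J = 1 − 3/(4(n₁+n₂) − 9).
* **Microfluidics** — Fick's-law diffusion times t<sub>D</sub> = y²/(2D),
  position-to-time mapping at v = Q/A, and the inlet mass-balance dilution
  plateau.
* **Synthetic data** — a generator that plants two-population ensembles
  with an exponentially relaxing extended fraction f(t), a dilution
  trajectory plateauing at 1/3, and counting-statistics noise, so every
  stage is testable end to end without external data.

## Worked example

```r
library(trsaxs)

# a pool of 2000 self-avoiding 140-mers and their theoretical profiles
pool     <- generate_pool(2000, seed = 7)
profiles <- pool_profiles(pool)

# simulate a fast-compaction scenario and analyze one frame
scn <- make_scenario("fe-like", seed = 21)
sim <- simulate_timeseries(scn, pool, profiles)

guinier_fit(sim$series$profiles[[1]])
#> <guinier_fit> Rg = 35.81 A, I(0) = 1.924e+04, qmax*Rg = 1.07, 6 pts, R2 = 0.9668

fit <- ga_select(sim$series$profiles[[1]], profiles,
                 ga_settings(seed = 101), pool = pool)
fit
#> <ensemble_fit> chi2 = 0.980 (c = 1, b = -2.3), 27 distinct conformers, 370 generations
extended_mass(fit, pool)        # recovered extended fraction at t = 0.18 s
#> [1] 0.4238172
fraction_at(scn, 0.18)          # planted truth
#> [1] 0.4186058

# microfluidic mixing numbers for the default chip geometry
mixing_report()$diffusion_times
#>   species    D_m2s    t_d_s axial_mm
#> 1      Mn 6.88e-10 1.816860 42.39341
#> 2      Fe 6.05e-10 2.066116 48.20937
#> 3      Cu 7.33e-10 1.705321 39.79081
#> 4      Zn 7.15e-10 1.748252 40.79254
```

The Guinier fit of the first frame reads off the apparent (z-average)
radius of gyration of the mixed ensemble; the genetic algorithm then
resolves that average into conformer populations, and `extended_mass`
reports the extended-population fraction those weights imply, which tracks
the planted f(t). The diffusion-time table shows that every metal ion
crosses the 50 µm half-channel in under ~2 s of flow (≈40 mm downstream),
so binding starts immediately at the junction.

A thin command-line wrapper is installed at
`inst/scripts/trsaxs.R` (`simulate`, `run`, `mixing-report`,
`fit-ensemble`) for driving the same functions from a shell.

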
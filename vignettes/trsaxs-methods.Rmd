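---
title: "Methods: ensemble-resolved TR-SAXS analysis of disordered proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble-resolved TR-SAXS analysis of disordered proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the models it
fits, the assumptions behind them, the numerical choices that matter, and
what the synthetic-data tests do and do not demonstrate about real
measurements.

## The measurement model

A SAXS profile is an orientation- and ensemble-averaged intensity
$I(q)$ on a grid of momentum transfer $q = 4\pi\sin\theta/\lambda$
(Å$^{-1}$), with per-point counting-statistics uncertainties
$\sigma(q) > 0$. For an intrinsically disordered protein the measured
curve is a population-weighted average over conformers, which is what
makes ensemble decomposition possible: the forward model is linear in the
conformer weights.

In a laminar co-flow mixer the protein stream meets ligand-carrying side
streams at a junction; each downstream detector position maps to a time
after mixing through the plug-flow relation $t = x/v$, $v = Q/A$. With
the default geometry (100 × 100 µm cross-section, 14 µl/min total flow)
$v = 23.3$ mm/s, so the 87 mm channel spans about 3.7 s. Transverse
mixing is diffusive; the characteristic time for a species of diffusion
coefficient $D$ to cross the half-width $y$ is Fick's estimate
$t_D = y^2/(2D)$, about 1.7–2.1 s for the divalent/trivalent metal ions
considered. The plug-flow mapping ignores the parabolic velocity profile;
that correction (Taylor dispersion, slower wall streamlines) is out of
scope and would mainly blur the time axis, not shift its scale.

The protein itself is diluted by the side streams. Once transverse
diffusion has homogenized the channel, mass balance fixes the
concentration at the protein inlet's share of the total flow — 1/3 for
equal inlets — and since $I(0)$ is proportional to concentration, the
normalized forward-intensity trace $I(0)/I(0)_0$ decays to that plateau.
The trace is normalized to the *first recorded frame*, so the package's
dilution law $c(t) = c_\infty + (1 - c_\infty)e^{-(t - t_1)/\tau}$ is
referenced to the first observation time $t_1$: a lab-time exponential
cannot simultaneously be near 1 at the first frame and reach its plateau
within the observation window.

## Per-curve descriptors

**Guinier fit.** $\ln I$ is regressed on $q^2$ with weights $(I/\sigma)^2$
(the delta-method variance of $\ln I$), iteratively shrinking the window
until $q_{max} R_g \le 1.1$ is self-consistent. The default limit sits
between the globular convention (1.3) and strict IDP practice (1.0). On
curves that genuinely follow the Guinier law the estimator is exact; on
ideal-chain (Debye) curves it is biased low by about 5% at the default
window, because $\ln P$ has curvature $+x^2/36$ ($x = (qR_g)^2$) inside
the window. That bias is a property of the estimator, not a bug — it is
the reason polymer-corrected fits exist — and the test suite asserts it
quantitatively rather than pretending both estimators agree.

**Polymer-corrected R$_g$.** The Debye chain form factor
$P(x) = 2(e^{-x} - 1 + x)/x^2$ is fitted over the extended window
$qR_g \le 3$ by weighted Levenberg–Marquardt. An optional Flory exponent
generalizes $x = (qR_g)^{1/\nu}$ (ideal chain at $\nu = 1/2$); this is a
pragmatic one-parameter extension, not a rigorous swollen-chain form
factor, and is documented as such. A reduced $\chi^2 > 5$ flags shapes
outside the model class (e.g. globules), for which the estimate should
not be trusted.

**Fractal dimension.** Unweighted ordinary least squares of $\log_{10} I$
on $\log_{10} q$ over $\log_{10} q \in [-1.4, -1.0]$ (q in Å$^{-1}$, i.e.
0.0398–0.1 Å$^{-1}$), with $D_m$ = −slope. Points with $I \le 0$ are
excluded before fitting; an error is raised only if fewer than 5 usable
points remain. A $\sigma$-weighted variant is available behind a flag;
the unweighted default reflects that the defining equation specifies no
weighting, and on exact power laws both give $D_m$ to machine precision.

**P(r) inversion.** The indirect Fourier transform solves
$\min_{p \ge 0} \sum_k [(I_k - (Ap)_k)/\sigma_k]^2 + \alpha \|D_2 p\|^2$
with $(Ap)(q) = 4\pi \int_0^{D_{max}} p(r)\,\mathrm{sinc}(qr)\,dr$
(trapezoidal quadrature, 101-point uniform grid, endpoints pinned to
zero) and $D_2$ the second-difference operator. Nonnegativity is enforced
by an in-house Lawson–Hanson active-set NNLS — written matrix-free in the
column dimension and with a generous iteration budget, because the
weighted design can span many orders of magnitude near form-factor
minima. `alpha = "auto"` scans 15 log-spaced candidates and takes the
L-curve corner by maximum discrete (Menger) curvature. Real-space moments
use $R_g^2 = \int r^2 p \, dr / (2\int p\,dr)$ and
$I(0) = 4\pi\int p\,dr$; note that the moment identity presumes the full
density autocorrelation, including the self-pair mass near $r = 0$ — for
a two-point rigid body half the mass sits in the self-peak, which is what
makes $R_g = d/2$ come out. The `scan_dmax` score adds a ringing penalty
(sign changes of $p'$ beyond the main peak) to $\chi^2$, a reproducible
stand-in for GNOM's perceptual criteria.

## Conformer pools and theoretical scattering

Chains are Cα traces built residue by residue with a fixed 3.8 Å virtual
bond, a pseudo-bond angle drawn uniformly from a configurable range, a
uniform dihedral, and a hard-sphere excluded-volume cutoff of 3.8 Å
between non-adjacent residues (retry-and-restart on clashes). A single
angular regime cannot span the compact-to-extended range a two-population
analysis needs, so pools mix three regimes — flexible [65°, 145°],
intermediate [90°, 150°], stiff [120°, 165°] at weights 0.5/0.3/0.2 —
chosen once so that a 140-residue pool covers $R_g$ from below 25 Å to
above 55 Å (empirically ~14–80 Å). Unit residue masses are used for
$R_g$; domain distances follow the α-synuclein residue-pair scheme
(1–140, 1–60, 61–90, 91–140, 1–90, 61–140), with 61–90 treated as
NAC-internal; the boundaries rescale proportionally for other chain
lengths and are overridable.

Scattering uses the Debye sum with point form factors by default: the
downstream fit adjusts an overall scale, so a constant per-residue factor
is unidentifiable; a Gaussian dummy-residue factor
$f(q) = e^{-q^2w^2/2}$ is available. The histogram acceleration bins
pair distances at 0.5 Å and evaluates
$E[\mathrm{sinc}(qr)] \approx \mathrm{sinc}(q\bar r_b) + \tfrac12 q^2
\mathrm{var}_b\, \mathrm{sinc}''(q\bar r_b)$ per bin, which keeps the
maximum relative error near $10^{-5}$ over $q \le 0.5$ Å$^{-1}$ —
effectively exact for fitting purposes — at $O(N^2 + Bn_q)$ cost.

## Ensemble selection

The selection problem — pick a multiset of 50 conformers whose average
profile best fits the data after a scale and constant background — is
solved by a genetic algorithm: 50 candidate ensembles per generation, up
to 1000 generations, elitism (5), binary tournament selection, uniform
multiset crossover (rate 0.5), per-slot random-reset mutation (rate 0.1),
early stop after 100 stagnant generations. The scale/background fit is
closed-form weighted least squares; reduced $\chi^2$ uses $K - 2$ degrees
of freedom ($K - 1$ with the background off).

Two additions proved necessary for reliable optima and are part of the
package's design. First, the initial population contains two informed
chromosomes: the continuous nonnegative-least-squares solution over the
whole pool rounded to slot granularity (largest-remainder), and the best
single conformer replicated. Second, the final ensemble is polished by
exact coordinate descent — each slot in turn is set to the
$\chi^2$-minimizing pool member, in closed form over all candidates,
until no slot improves. Without these, crossover and random mutation
stall in compensating mixtures (single random swaps cannot escape them);
with them, a planted single-conformer target is recovered exactly and
repeated runs across seeds agree within ~3 percentage points of
population mass. The elitist best-$\chi^2$ trace is non-increasing by
construction and asserted on every run.

Because distinct conformers can have nearly identical profiles, results
are reported as population statements (fractions, $R_g$ histograms,
weighted domain distances), never as claims about individual structures.

## Synthetic scenarios and what the tests show

The generator plants a two-population truth: a compact subpool
($R_g < 35$ Å) and an extended subpool ($R_g > 45$ Å), with the band in
between left unpopulated so recovery scoring is unambiguous. Per frame,
50 conformers are drawn with extended probability
$f(t) = f_\infty + (f_0 - f_\infty)e^{-kt}$, their average profile is
scaled by the dilution $c(t)$ (plateau 1/3, $\tau = 0.8$ s) and perturbed
with Gaussian noise whose relative size scales as $1/\sqrt{I}$,
calibrated to 1% at the first frame's $I(0)$. Presets sketch qualitative
regimes: `wt-like` (0.50 → 0.15, $k = 1$), `fe-like` (0.60 → 0, $k = 2$,
fast compaction), `cu-like` (0.70 → 0.40, persistent elongation),
`inert` (constant 0.35). The 20-frame grid at 0.18 s spacing matches the
time resolution of the microfluidic measurement the package targets.
Buffer frames are pure noise around zero, so the subtraction stage is
exercised; they carry no structured channel background.

The recovered extended fraction is estimated by the method of moments,
$\hat f = (\langle R_g^2\rangle_w - \mu_c)/(\mu_e - \mu_c)$ clipped to
$[0,1]$, where $\langle R_g^2\rangle_w$ is the ensemble-weighted mean
square $R_g$ of the selection and $\mu_c, \mu_e$ are the subpool means.
The z-average $R_g^2$ is the quantity the data constrain at low $q$, so
this estimator is unbiased under the two-population model, whereas a hard
$R_g$ cutoff undercounts weight that the (legitimately degenerate)
selection places in the unpopulated band. A midpoint-classification
variant is retained for comparison.

What passing tests show: with the stated noise and pool sizes, the full
chain — simulate, subtract, fit, select, summarize — recovers planted
fractions with median absolute error well under 0.1 and dilution plateaus
in [0.30, 0.37]. What they do not show: robustness to structured
backgrounds, inter-particle interference, aggregation, radiation damage,
or form-factor error between the Cα model and a real protein — none of
which the generator emulates.

## Statistics

Condition comparisons use Kruskal–Wallis per feature ($R_g$, $R_{ee}$,
fraction), tie-corrected Dunn z-tests for pairs, Benjamini–Hochberg
adjustment within each feature's family of pairwise tests, and Hedges'
$g = J(m_1 - m_2)/s_{pooled}$ with $J = 1 - 3/(4(n_1 + n_2) - 9)$; pairs
with $q < 0.05$ and $|g| > 0.8$ are flagged. Clustering standardizes the
three features, applies Ward linkage (`ward.D2`) on Euclidean distances,
and cuts the dendrogram at cophenetic height $t = 2.5$ — the threshold is
interpreted in standardized-feature linkage units, since no other unit
convention is available, and is configurable. Silhouette widths validate
the cut; summaries are fraction-weighted by default. The type-I error of
the battery is checked by simulation (empirical rate ≈ nominal 0.05).

## Problem sizes and numerical choices

The test suite runs against an 800-conformer shared pool (coverage and
distributional properties are stable from a few hundred chains up:
two-pool Kolmogorov–Smirnov distance < 0.08 at n = 800), while the
acceptance script uses the full 10,000-conformer desk-scale pool for
recovery runs. The default q grid is 101 points on [0.005, 0.5] Å$^{-1}$,
which contains both the Guinier window for $R_g \le 60$ Å and the
fractal-dimension window. Degenerate inputs are handled explicitly:
constant profiles yield a flagged degenerate Guinier fit rather than an
error; an all-identical feature table yields a flagged single-cluster
model; zero or negative uncertainties are rejected at load; negative
post-subtraction intensities are kept (clipping would bias low-q fits)
and only flagged when they exceed 20% of points.

## Known limitations

The polymer-corrected estimator is a Debye-function stand-in, not a
published IDP molecular form factor; the Cα pools carry no
sequence-specific stiffness; the GA's operator set is one reasonable
choice among many (all rates are configurable); the P(r) module
implements explicit, testable criteria rather than GNOM's full perceptual
scoring; and the mixing model is zero-dimensional — no advection–diffusion
field, no Taylor dispersion.
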
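---
title: "Models and methods behind secsans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secsans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secsans)
```

# The problem

Size-exclusion chromatography coupled inline to small-angle neutron
scattering (SEC-SANS) separates a polydisperse protein solution by size
moments before the eluate crosses the neutron beam, so that each
scattering frame samples a nearly monodisperse slice of the elution.
For mixtures of protein complexes with different stoichiometries —
the motivating case is a solution containing both 2:1 and 2:2
complexes of the fluorescence recovery protein (FRP) with the compact
orange carotenoid protein variant lacking its N-terminal extension —
conventional SANS would average the species into a single uninformative
curve, while SEC-SANS resolves one scattering curve per elution peak.

`secsans` implements the full downstream analysis chain for such runs:

1. a synthetic-run generator (two overlapping elution peaks with
   per-frame counting noise) so every stage can be exercised and
   validated without access to beamline data;
2. scattergram construction, peak detection, and inverse-variance
   peak averaging;
3. Guinier analysis with automatic or Q·Rg-band window selection;
4. regularized indirect Fourier transform (IFT) to the pair-distance
   distribution P(r), with Dmax scanning;
5. Kratky compactness diagnostics;
6. analytic form factors (sphere, circular and elliptical cylinder) and
   bounded weighted least-squares model fitting;
7. ab initio dummy-atom shape reconstruction by simulated annealing
   under P1 or P2 symmetry, with multi-run alignment, averaging and
   normalized-spatial-discrepancy (NSD) scoring;
8. Debye-formula scattering from atomistic PDB structures with neutron
   contrast handling and a coarse two-rigid-block pose search.

# Conventions

The scattering vector is $Q = 4\pi \sin\theta / \lambda_0$ with
$\theta$ **half** the scattering angle — the standard small-angle
convention; descriptions that call $\theta$ "the scattering angle" are
treated as shorthand for the same quantity. All lengths are in
Ångström, $Q$ in Å$^{-1}$. For dilute solutions the structure factor is
fixed at $S(Q) = 1$ throughout.

# Instrumental resolution

A velocity-selector instrument quoted as "6 Å ± 10%" is modelled as a
Gaussian wavelength band whose *fractional FWHM* is 0.10. Smearing
replaces each model intensity by a Gaussian-kernel average over $Q$
with $\sigma_Q/Q = (\Delta\lambda/\lambda)/2.355$, truncated at
$\pm 3\sigma$ and renormalized over the available grid, so constants
are preserved exactly. Smearing is applied to *model* curves only and
never inverted; whether measured curves are desmeared upstream is an
instrument-pipeline question this package does not take a position on.

# Guinier analysis

Over the low-$Q$ window, $\ln I$ is fitted against $Q^2$ by weighted
least squares ($\sigma_{\ln I} = \sigma/I$; unweighted when the curve
carries no uncertainties), giving $R_g = \sqrt{-3\,\mathrm{slope}}$ and
$I(0) = e^{\mathrm{intercept}}$. Two window policies exist:

* **Q·Rg band** (`qrg_window`): the window is the set of points with
  $lo < Q R_g < hi$ at the *fitted* $R_g$, resolved by fixed-point
  iteration. This mirrors how published Guinier ranges are quoted.
* **Automatic** (`auto_window`): starting from the first positive
  point, leading points are dropped one at a time while the fit quality
  ($R^2$) strictly improves, and the upper edge is capped at
  $Q R_g \le$ `qrg_limit` (default 1.3, the conventional validity
  limit for globular particles). The drop rule removes low-$Q$
  contamination (aggregates, inter-particle effects) confined to the
  leading points. The published window ranges give no selection rule,
  so this rule is the package's own and is deliberately simple and
  deterministic.

# Indirect Fourier transform

$I(Q) = 4\pi \int_0^{D_{max}} P(r)\,\mathrm{sinc}(Qr)\,dr$ is
discretized on a uniform $r$ grid (101 points by default — comparable
to GNOM's granularity while keeping the normal equations small) with
trapezoid weights and $P(0) = P(D_{max}) = 0$ pinned. The solution
minimizes the weighted data misfit plus $\alpha \int P''(r)^2 dr$. Two
numerical choices matter:

* **Penalty scaling.** The second-difference matrix is scaled by
  $1/\Delta r^2 \cdot \sqrt{\Delta r}$ so that the penalty approximates
  the integral of the squared second derivative. Without this, the
  effective regularization strength varies with the candidate
  $D_{max}$ and chi-squared comparisons across candidates become
  meaningless.
* **Choice of α (discrepancy principle).** Over a log-spaced grid,
  the smoothest solution is selected whose weighted residual stays
  below the discrepancy level (one squared sigma per data point), or
  5% above the smallest residual the grid attains when the data cannot
  be fitted to their sigmas; the crossing is refined by bisection.
  This pushes the reduced chi-square to ≈ 1 for noise-consistent data
  at every adequate $D_{max}$ — a flat chi-square plateau is exactly
  what the $D_{max}$ selection rule below needs. A pure L-curve corner
  was evaluated and rejected: for noise-free or model-exact curves the
  L-curve is degenerate (the residual keeps falling with no penalty
  blow-up) and the corner lands arbitrarily.

Curves without uncertainties are weighted with an effective 0.5%
relative sigma (floored at $10^{-5}$ of the peak), making `fit_chi2` a
relative-misfit measure in that case.

**Dmax scanning** runs the IFT for each candidate and keeps the
*smallest* $D_{max}$ whose chi-square is within 5% of the global
minimum and whose $P(r)$ is nonnegative at the 1% level of
$\max P$ (regularization is allowed small oscillations, as in GNOM).
If no candidate passes the nonnegativity gate, the smallest candidate
inside the 5% chi-square band is returned. Two practical notes:

* With data truncated at the instrument's $Q_{min} = 0.03$ Å$^{-1}$,
  only $\sim Q_{min} D_{max}/\pi \approx 1$ Shannon channel constrains
  the long-distance tail, so the selected $D_{max}$ is precision-limited
  and tends to sit at the low end of the statistically adequate range;
  the $P(r)$-derived $R_g$ and $I(0)$ are insensitive to this.
* $P(r)$ nonnegativity is *not* enforced in the inversion itself.

$R_g$ and $I(0)$ follow from the second moment,
$R_g^2 = \int r^2 P\,dr \,/\, 2\int P\,dr$ and
$I(0) = 4\pi \int P\,dr$, by trapezoidal quadrature.

# Form factors and fitting

The sphere and circular-cylinder forms are standard. The elliptical
cylinder (minor radius $a$, axis ratio $\nu \ge 1$, length $L$) is the
orientation average computed by double Gauss–Legendre quadrature
(76 points per axis by default, common SAS practice): outer over the
axis tilt with the longitudinal $(\sin u/u)^2$ factor, inner over the
cross-section azimuth with $\Lambda_1(t) = 2J_1(t)/t$ at the effective
radius $a\sqrt{(1+\nu^2)/2 + (1-\nu^2)\cos y/2}$.

The cross-section kernel uses the **cylindrical** first-order Bessel
function $J_1$. Printed versions of this model sometimes show the
spherical Bessel $j_1 = (\sin t - t\cos t)/t^2$ in the same position;
the two give different curves, and the uniform-point-cloud Debye oracle
(tested in the suite) unambiguously selects the $J_1$ form, which is
also the canonical elliptical-cylinder model in SAS fitting software.
The bare form factor is normalized to 1 at $Q = 0$, so the fitted
`scale` aggregates $n\,\Delta\rho^2 V^2$; no absolute-scale
decomposition is attempted. `background` defaults to 0 and is fitted
only on request.

Fitting is bounded Levenberg–Marquardt (via `minpack.lm`) on
$\sum ((I_{data} - I_{model})/\sigma)^2$; parameter uncertainties come
from the residual-scaled covariance; `reduced_chi2` divides by
$n - p$.

# Ab initio reconstruction

Beads live on hexagonal close-packed-style layers (in-plane spacing
$2r_{bead}$, layer spacing $\sqrt{3}\,r_{bead}$, alternate layers
offset by half a row) clipped to the search sphere of diameter
$D_{max}$. This particular stacking is exactly closed under a 180°
rotation about $z$, so **P2 symmetry is enforced by construction**:
each move toggles a lattice site *and its rotational mate* together
(on-axis sites are their own mates). The packing fraction (≈ 0.70) is
marginally below true HCP (0.74); exact closure under the symmetry
operation was judged more valuable than the last few percent of
packing density.

The default bead radius is $D_{max}/20$, giving lattices of roughly
500–800 sites — the scale at which per-site multipole contributions
can be precomputed and each Monte Carlo move costs a rank-1 update of
the multipole coefficients. Finer lattices are a configuration switch
(`anneal_config(bead_radius = )`).

Scoring combines the curve chi-square (with an analytically fitted
overall scale) and a compactness penalty: `compactness_weight`
(default 0.3) times the fraction of beads with fewer than 3 occupied
neighbors. Annealing uses Metropolis acceptance with: starting
temperature set automatically to the standard deviation of score
changes over 100 random toggles; cooling factor 0.9 per stage;
20 moves per initial bead per stage; stop after 3 consecutive stages
improving the best score by under 1%. None of these constants are
prescribed by the underlying method descriptions; they are
conventional simulated-annealing settings, all exposed in
`anneal_config()`. The best-seen configuration is returned, pruned to
its largest connected component, and reconstruction is bit-reproducible
from the seed.

Model intensity uses the multipole expansion
$I(Q) = 2\pi^2 \sum_{lm} |A_{lm}(Q)|^2$ with
$A_{lm} \propto \sum_j w_j\, j_l(Qr_j)\, Y_{lm}^*(\omega_j)$,
truncated at $l_{max} = \lceil Q_{max} r_{max} \rceil + 3$ (clamped to
[5, 24]) following the sampling-theorem scaling of resolvable angular
channels; an undersized user `lmax` is raised with a warning. The
exact Debye double sum is available as a cross-checking backend and the
two agree to well under 1% on every model the test suite produces.
Both are modulated by the single-bead sphere form factor.

**Alignment** centers each model, rotates to principal axes with a
deterministic sign convention, and resolves the remaining proper
two-fold ambiguities by trying the four det-+1 axis-flip combinations
against the first model under NSD. **Averaging** keeps beads whose
position is occupied (within one bead radius) in at least
`occupancy_cut` (default 0.5) of the models, then deduplicates greedily
— the standard averaging tools' rule is not published in detail, so
this rule is the package's own. **NSD** is the symmetric mean of
per-bead nearest-neighbor cross distances, each direction normalized by
that model's own mean nearest-neighbor spacing (bead diameter for
single-bead models).

# Atomistic scattering

PDB structures are parsed with `bio3d`; per-atom coherent neutron
scattering lengths are tabulated in the package, implicit hydrogens are
added by united-atom counts per residue/atom name, and labile
hydrogens (N–H, O–H, S–H) scatter with
$b_H + f_{D_2O} \cdot f_{exch} (b_D - b_H)$, default exchange fraction
0.9. The solvent SLD defaults to the H₂O/D₂O mixture value
($-0.056$ and $0.640$ fm Å$^{-3}$ at the endpoints); the buffer
composition of any given experiment is explicit configuration, never
inferred. Excluded volume is the simple displaced-solvent point
correction $g_i = b_i - \rho_s V_i$ with tabulated atomic volumes — no
Gaussian-sphere refinement, which is adequate at $Q \le 0.25$
Å$^{-1}$ and is documented as a limitation. Distances are exact
pairwise up to 2000 atoms; beyond that a 0.1 Å distance histogram is
used (relative error well below 0.5% in this $Q$ range).

The two-rigid-block fit is a deliberately coarse stand-in for
normal-mode flexible-fitting tools: an exhaustive search over a user
grid of rotations and translations of the mobile block, rejecting
poses with inter-block contacts under 2 Å, minimizing the smeared
model chi-square with an analytic scale. It recovers planted
transforms exactly when they lie on the grid and is deterministic.

# The synthetic-data generator

`make_reference_components("table1")` builds the two study geometries:
elliptical cylinders with $(a, \nu, L)$ = (13.49 Å, 2.06, 100 Å)
eluting first (the elongated 2:2-like species, forward intensity
0.075) and (14.64 Å, 2.07, 73 Å) eluting second (the compact 2:1-like
species, 0.072), smeared through the 6 Å ± 10% resolution on the
instrument grid $Q = 0.03$–$0.25$ Å$^{-1}$.

The elution is Gaussian per component. The published scattergram shows
two clearly resolved, partially overlapping peaks but no numerical
profile parameters, so the defaults — centers at frames 18 and 36 of a
60-frame run, widths (σ) of 4 and 5 frames — were chosen once to
reproduce that qualitative picture: resolvable maxima with overlapping
tails. Frames carry 30 s exposure metadata. Noise is Gaussian with
$\sigma = \texttt{noise\_scale}\sqrt{I}$ (the Gaussian limit of
counting statistics); the default `noise_scale` 0.005 yields ≈ 2%
relative error at the peak-frame intensities, a realistic level for
well-exposed SEC-SANS frames. The flat buffer background defaults to
0.002. All randomness flows from the single run seed.

What the generator does *not* emulate — and hence what green tests do
not demonstrate about real data: column dispersion and the mid-run
flow-rate change, detector geometry and transmission effects,
imperfect buffer subtraction, inter-particle structure factors,
radiation-damage-free but otherwise non-ideal backgrounds, and any
conformational heterogeneity within a fraction. Parameter-recovery
results on this generator are statements about the analysis chain, not
about beamline systematics.

**Scattergram** totals are background-subtracted sums over a $Q$
window; peaks are local maxima whose topographic prominence exceeds
the largest of 15% of the series maximum, 8× the median propagated
frame uncertainty, and 6× the frame-to-frame noise level — so a
noise-only series yields no peaks. **Peak averaging** is
inverse-variance weighting per $Q$ point over the frames within
±1 fitted σ of each detected peak.

# Pipeline

`run_pipeline()` chains peak extraction (for runs), Guinier, Dmax scan
+ IFT, Kratky, and the elliptical-cylinder fit per fraction, capturing
stage errors without aborting the remaining stages, and serializes a
stable JSON report. Reconstruction inside the pipeline is off by
default and reduced-scale when enabled (5 runs; 20 runs — the
full-scale protocol — behind `--full` in the CLI). Reconstruction
inputs are cut at $Q \le 0.13$ Å$^{-1}$, matching the restricted range
used for published shape reconstructions of this system.

# Problem sizes and verification scale

The test suite and acceptance script run entirely on synthetic data at
desk scale, chosen as the package's own verification conditions:
200-point curves on $Q = 0.005$–$0.25$ Å$^{-1}$ for model-consistency
checks, 90-point instrument-grid curves in the run generator,
Monte Carlo oracles with 2000–4000 points, and sphere-target
reconstructions with ≈ 700 lattice sites and 5 seeds. Cloud-based
oracle comparisons are scored against the forward scattering of the
normalized curves, since pointwise ratios diverge at form-factor
zeros and the cloud's stochastic error (~$n^{-1/2}$) dominates the
deep high-$Q$ tail.

# Known limitations

* The Dmax scan is precision-limited for truncated low-$Q$ data (see
  above); treat the selected $D_{max}$ as a lower edge of the adequate
  range, not a sharp estimate.
* The IFT does not desmear; model fitting smears the model instead.
* No polydispersity, no structure factors beyond $S(Q)=1$, no
  absolute-intensity calibration.
* The atomistic module's excluded-volume treatment is the point
  correction; hydration shells are not modelled.
* The rigid-body search is grid-exhaustive, not gradient-refined; its
  resolution is the grid the caller supplies.
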
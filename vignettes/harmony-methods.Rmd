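---
title: "Source reconstruction in smooth cortical bases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source reconstruction in smooth cortical bases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmonyeeg)
```

## The problem

EEG (and MEG) sensors record a heavily blurred image of cortical currents:
the skull's low conductivity acts as a strong spatial low-pass filter, and a
distributed source model places thousands of fixed dipoles on the cortical
surface while only about a hundred sensors constrain them.  The linear
forward model is

$$v = G\,s + n,$$

with $G$ the gain (lead-field) matrix, $s$ the dipole amplitudes
(orientation-constrained to the outward cortical normal by default, because
pyramidal-cell currents flow perpendicular to the cortex), and $n$ sensor
noise with covariance $C$.  Under Gaussian assumptions the posterior-mean
estimate is the Tikhonov-regularized linear inverse

$$\hat s = W v, \qquad W = R\,G^\top (G R G^\top + \lambda C)^{-1},$$

where $R$ is the source covariance prior and $\lambda$ the regularization
parameter.  Every algorithm in this package is an instance of this formula;
they differ only in $R$, in the basis the solution lives in, and in an
optional post-hoc normalization.

## The smooth-basis idea

Each cortical hemisphere is topologically a sphere, so any source field on
it can be expanded in real spherical harmonics evaluated at the dipoles'
positions on the hemisphere's sphere mapping.  Writing $s = T^\top u$ for a
basis transform $T$ (basis functions $\times$ dipoles, block-diagonal over
hemispheres), the inverse is solved for the low-dimensional coefficient
vector $u$ and mapped back:

$$W = T^\top R_b \tilde G^\top (\tilde G R_b \tilde G^\top + \lambda C)^{-1},
\qquad \tilde G = G\,T^\top.$$

This is algebraically identical to the dipole-space inverse with prior
$T^\top R_b T$ — a property the test suite checks to $10^{-10}$ — but makes
the smoothness constraint explicit: harmonics above the sensor array's
spatial Nyquist limit carry no information and only amplify noise, so they
are simply excluded.  Two smooth bases are provided:

* **Spherical harmonics** up to degree $L_{\max} = 10$ (121 functions per
  hemisphere, 242 total for an orientation-constrained solution), with the
  optional spectral prior $R_{lm} = (1+l)^{-2\gamma}$ that damps high
  spatial frequencies.  The offset form $(1+l)^{-2\gamma}$ keeps the DC
  term finite.  $\gamma$ defaults to 0.75, the middle of the 0.5–1 range
  appropriate for evoked data; 0 recovers the unweighted projection.
* **Abel–Poisson spherical splines**, the closed-form kernel
  $\frac{1}{4\pi}\,(1-h^2)/(1+h^2-2h\cos\gamma)^{3/2}$ centered on the 162
  level-2 icosphere nodes of each hemisphere.  The scale defaults to
  $h = 0.8$, giving kernels of roughly the same angular width as the
  degree-10 harmonic cutoff; the value is exposed because the optimum
  depends on the noise level.

The degree cutoff for a sensor array is `nyquist_cutoff(n)`: the smallest
$L$ with $L^2 \ge n-1$, the count of independent signals an
average-referenced $n$-channel recording carries; 128 channels give
$L = 12$, i.e. 169 harmonics per surface.  The cortical cutoff is then
found empirically and sits slightly below this sensor-space limit
($L_{\max}=10$), because folding distortions make the effective resolution
on the cortex a little worse than on a true sphere.

## Comparison algorithms

All in the same framework, via `algorithm_operator()`:

* **MNE** — identity prior in the single-dipole basis.
* **WMNE** — diagonal depth weights $w_j = (\sum_i g_{ij}^2)^{-\gamma_d}$
  ($\gamma_d = 1$), giving deep (weak) dipoles more prior variance.
* **LORETA** — surface smoothness prior: precision
  $D^{-1} L^\top L D^{-1}$ with $L$ the area-normalized cotangent Laplacian
  of the folded mesh (the standard discrete surface Laplace–Beltrami
  operator) and $D = \mathrm{diag}(w)^{1/2}$, so the implied covariance
  combines smoothness with depth weighting.  The precision is applied by
  sparse factorization only; the singular Laplacian normal matrix receives
  a $10^{-8}$ relative ridge.
* **IBF** — informed basis functions: the leading eigenvectors (512 per
  hemisphere by default) of a Gaussian coherence matrix
  $\exp(-d_{ij}^2/2\sigma^2)$ over graph-geodesic distances on the folded
  mesh, composed with depth weighting.  $\sigma$ defaults to 10 mm, the
  order of a source-patch radius; the eigenvalues act as the prior.
* **dSPM** — divides each row of an operator by the propagated noise SD
  $\sigma_j = \sqrt{(W C W^\top)_{jj}}$, making estimates Z-scores under
  the noise model.
* **sLORETA** — divides by the square root of the corresponding diagonal of
  the model resolution matrix $WG$ (trace of the $3\times3$ block per
  dipole in free-orientation mode, a simpler choice than full block
  whitening).  For a noiseless point source this normalization localizes
  exactly, which the acceptance suite verifies on 50 random locations.

Amplitudes are thresholded by the signal-to-noise statistic
$q_j = \hat s_j^2/\sigma_j^2$ against a $\chi^2$ quantile with 1
(constrained) or 3 (free) degrees of freedom — the large-denominator limit
of the F statistic — at the Bonferroni-corrected level $\alpha/n$ with $n$
the sensor count.  Because the dipole count exceeds the rank of the sensor
space, dividing by $n$ rather than by the dipole count makes the
family-wise control approximate: under pure noise we measure a family-wise
rate of about 0.07 at $\alpha = 0.05$, while the per-dipole flagged
fraction stays far below $\alpha$.

## Choosing the regularization

$R$ is a prior, so its overall scale — the Tikhonov parameter — is unknown.
Ordinary cross-validation selects it through the closed-form
leave-one-sensor-out identity

$$\mathrm{OCV}(\lambda) = \sum_i
\left(\frac{v_i - (Av)_i}{1 - A_{ii}}\right)^2, \qquad A = G W(\lambda),$$

which the tests verify against explicit refits with each sensor deleted.
The identity is exact for diagonal noise covariances; the default scan uses
25 log-spaced values around the scale-free reference
$\mathrm{tr}(GRG^\top)/\mathrm{tr}(C)/n$ and extends the grid automatically
when the minimum lands on a boundary (precision-form priors can shift the
natural scale by orders of magnitude).  On the simulated study conditions
the selected $\lambda$ keeps the mean localization error within a few
percent of the best single $\lambda$ on the grid.

## Quality metrics

Six measures score a reconstruction against a known source patch:

* **Localization error** — amplitude-weighted mean surface distance of the
  $N$ strongest dipoles (patch hemisphere only, $N$ = patch size) to the
  patch's vertex centroid, minus the patch's own extent computed by the
  same formula, clamped at zero (a negative error is meaningless).
  Surface distances are great arcs on the sphere mapping scaled by the
  effective radius $\sqrt{A/4\pi}$ of the folded surface — a deterministic
  conversion that is exact for spherical geometry.
* **Amplitude ratio** — mean of the $N$ largest magnitudes in the stronger
  source's hemisphere over the weaker's; ground truth 2.
* **Surface bias** — relative change of the amplitude-weighted mean
  distance from the head center (ellipsoid fit to the sensor cloud) of the
  $2N$ most active dipoles versus the true patches.
* **Widths** $W_{\min}$/$W_{\mid}$ — weighted mean distance of the $N$
  strongest (respectively all above-half-maximum) dipoles to their own
  weighted center.
* **Coherence** — true hotspot width over solution hotspot width, capped at
  1 so over-focal solutions cannot score above the stated optimum;
  undefined for single-dipole sources.
* **Congruency** — Pearson correlation of $W_{\mid}$ with localization
  error across configurations: an honest solution is wide exactly when it
  is wrong.
* **ROC area** — rank-sum probability that a source vertex out-ranks a
  selected non-source vertex, with the restrictive most-active-non-source
  policy (equally many competitors as source vertices, drawn from the same
  hemisphere) and average ranks on ties, which makes the rank-sum formula
  exactly the tie-aware pairwise win probability.

Each is validated against an independent line-by-line transliteration of
its definition on seeded random estimates.

## The synthetic test bed

Real cortical surfaces, BEM head models and recorded noise are replaced by
fully synthetic, seeded stand-ins so the whole pipeline runs from nothing:

* **Pseudo-cortex** — an icosphere (level 4, 2,562 dipoles per hemisphere,
  by default) with a band-limited radial perturbation: four seeded zonal
  ripples of angular degree 8 and 8 mm peak amplitude on a 52 mm sphere,
  offset ±18 mm from the midline.  This creates centimetre-deep sulci with
  opposing walls — enough structure for surface bias, sign reversal across
  sulci and depth weighting to behave qualitatively as on a real cortex —
  while every vertex stays strictly inside the 80 mm inner shell of the
  forward model.  What it does not emulate: the real cortex's area (about
  a quarter of it at these defaults), its metric distortion between sphere
  mapping and folded surface (our mapping is nearly isometric), hemispheric
  asymmetry, and the insula/medial-wall geometry where real solutions are
  most ambiguous.  Passing tests therefore demonstrate correctness of the
  machinery and the direction of algorithmic contrasts, not clinical-grade
  error magnitudes.
* **Forward model** — an analytic three-shell concentric sphere (radii 80,
  85, 92 mm; relative conductivities 1, 1/30, 1; scalp fixed at
  0.33 S/m), solved per spherical-harmonic degree with per-layer scaled
  radial bases so the series is stable to degree 200 and beyond; 80 terms
  are ample for sources below 78 mm.  The equal-conductivity case is
  verified against a closed-form solution assembled from Legendre
  generating functions.  The skull shell preserves the spatial low-pass
  property that motivates the smooth-basis approach.
* **Sensors** — a 128-channel Fibonacci lattice covering the upper 75% of
  the outer shell.
* **Noise** — zero-mean Gaussian with covariance
  $\sigma^2[(1-f)\exp(-d^2/2\ell^2) + fI]$, $\ell = 30$ mm,
  $f = 0.2$, $\sigma = 1/3\,\mu V$: spatially smooth residual noise as in
  an averaged evoked recording, plus a per-channel amplifier floor.  The
  white fraction exists because a purely smooth kernel is numerically
  rank-deficient (its spectrum decays below machine precision), which no
  physical recording exhibits and which would make leave-one-out residuals
  ill-defined.  The default SD keeps draw amplitudes essentially within
  1 µV against 10 µV signal peaks.
* **Sources** — 3-ring hexagonal patches (1+6+12+18 = 37 dipoles, about
  2.5 cm across at level 4), uniform outward unit moments, the weaker
  source at half amplitude, scaled so the peak scalp potential is 10 µV.
  Patch locations come from a Fibonacci seed refined by deterministic
  maximin exchanges, spacing 66 locations per hemisphere roughly one patch
  diameter apart.

## Numerical choices

* Dense Cholesky solves in sensor space (n × n) everywhere; the source
  dimension only enters through matrix–vector products.  A singular
  sensor-space system is ridge-loaded by $10^{-10}$ of its trace once.
* Diagonal priors are normalized to unit mean so $\lambda$ is comparable
  across recipes; precision-form priors are left unnormalized and the
  automatic OCV grid extension absorbs the scale difference.
* Operators built from average-referenced gains re-reference incoming data,
  which makes the constant sensor offset map to exactly zero sources.
* Great-arc self-distances are returned as exact zeros rather than
  $\arccos(1-\varepsilon)$.
* Icosphere subdivision uses lexicographic edge-midpoint caching, so vertex
  ordering is bit-reproducible; every seeded generator draws from a private
  RNG stream and restores the caller's state.
* Benchmark scale: the default drivers use 20 dual-source configurations
  with 25 noise draws each on the level-4 fixture, a size chosen so the
  full simulation comparison reruns in well under a minute while the
  directional contrasts between algorithms are stable across seeds; the
  full 66-location, 100-draw study is a configuration change
  (`simulation_config(n_locations = 66, n_noise = 100)`).

## Known limitations

* Gain matrices are imported or computed from the layered sphere; no
  BEM/FEM solver is included, and no MEG forward model.
* The empirical-Bayes route of learning the per-harmonic prior variances
  from data is out of scope, as are beamformers and iteratively re-weighted
  schemes (FOCUSS, MSP).
* The basis inverse is implemented for orientation-constrained gains; the
  single-dipole-basis algorithms support free orientation.
* Coefficient streams compress a harmonic solution to 242 numbers per time
  sample (float32 or scaled int16), but no mesh compression is attempted.
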
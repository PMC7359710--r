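---
title: "Methods: models, parameters and design choices in vibrospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in vibrospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `vibrospec`, their
assumptions, the tunable parameters and defaults, the numerical choices
made where the methods literature leaves details open, and what the
synthetic phantoms do and do not establish about real data.

## Data model

A hyperspectral image is a `pixels x wavenumbers` absorbance matrix with a
shared, strictly monotone wavenumber grid (cm⁻¹) and optional `height x
width` geometry. Internally the grid is always stored ascending; readers
that encounter descending axes (common in vendor exports) reverse both grid
and data and record the reversal in the provenance log. Spectral regions
("900–1800 cm⁻¹") are closed intervals on grid values, not index ranges,
because that is how regions are quoted in practice. The at-wavenumber
normalization snaps to the nearest grid point rather than interpolating:
at the typical 2 cm⁻¹ spacing the difference is far below the noise, and
the nearest-point rule is exactly reproducible.

## Atmospheric correction

Each spectrum $x$ is corrected per gas region $i$ as $x' = x - a_i r_i$,
where $r$ is the atmospheric reference interpolated onto the image grid
(zero outside its span, so the subtraction is a no-op where the reference
carries no information). The factor minimizes the sum of squared first
differences of the corrected spectrum and has the closed form
$a = \sum_j \Delta x_j \Delta r_j / \sum_j (\Delta r_j)^2$. Differences are
taken between adjacent grid points in ascending order without spacing
normalization — the criterion is index-based, and any spacing factor
cancels on uniform grids. Factors may legitimately be negative (an
over-subtracted background) and are not clamped.

Defaults: water regions 1300–2100 and 3410–3850 cm⁻¹, corrected
independently; CO₂ region 2280–2430 cm⁻¹, either subtracted the same way or
replaced by a monotone (PCHIP) interpolant anchored at 4 grid points on
each side — monotone cubic interpolation cannot overshoot its anchor
values, which is the property wanted from a "non-overshooting" spline. A
region at the grid edge falls back to linear extension from the available
side. The windowed refinement repeats the factor fit in a window centered
at every grid point (60 cm⁻¹ in the low water region, 300 in the high one,
80 for CO₂), updating $x_j \leftarrow x_j - \tfrac14 a_j r_j$ over 5
passes. Updates within a pass are simultaneous, making the result
independent of sweep order; windows are truncated at region edges. The
corrected level is not re-anchored — any constant offset is left to the
later baseline stage. Optional smoothing applies a third-order, nine-point
Savitzky–Golay filter computed on the full spectrum and spliced into the
corrected regions only, so points outside the gas regions stay bit-identical
to the input.

The bundled reference (`inst/extdata/atmosphere_synthetic.tsv`, also
available programmatically as `makeAtmosphereReference()`) is a synthetic
fine-line spectrum on 900–3840 cm⁻¹ at 2 cm⁻¹: randomly placed narrow
Gaussian lines in the two water regions and a CO₂ doublet. Factor fitting
only requires that the reference share its fine structure with the
contamination, not that the line positions match a spectroscopic database;
users correcting real data should supply a reference recorded on their own
instrument.

## Resonant Mie scattering correction

The EMSC model is
$Z_\mathrm{raw}(\tilde\nu) = c + m\tilde\nu + h Z_\mathrm{ref}(\tilde\nu)
+ \sum_{i=1}^N g_i p_i(\tilde\nu) + \varepsilon(\tilde\nu)$,
fitted by ordinary least squares; the corrected spectrum is
$Z_\mathrm{ref} + \varepsilon$, divided by $h$ when rescaling is on
(default). A pixel with $|h| < 10^{-8}$ falls back to the unrescaled form
with a warning — such pixels carry essentially no reference signal and
rescaling would blow up noise.

The scattering loadings $p_i$ are the top-$N$ PCA components (no variance
normalization) of a dictionary of van de Hulst extinction curves, after
each curve is orthogonalized against the span of the constant, the linear
term (when used) and $Z_\mathrm{ref}$, so the loadings cannot absorb what
the main EMSC terms describe. The extinction efficiency is evaluated as
$Q(\rho, \tan\beta) = 2 - 4e^{-\rho\tan\beta}\left[\frac{\cos\beta}{\rho}
\sin(\rho-\beta) + \left(\frac{\cos\beta}{\rho}\right)^2\cos(\rho-2\beta)
\right] + 4\left(\frac{\cos\beta}{\rho}\right)^2\cos 2\beta$,
which at $\beta = 0$ reduces to the familiar
$2 - \frac4\rho\sin\rho + \frac4{\rho^2}(1-\cos\rho)$. Both
parameterizations use $\beta = 0$: resonance enters through the
Kramers–Kronig fluctuation $n_{kk}$ inside $\rho$, as in the established
resonant-EMSC implementations. Points with $\rho \le 0$ (possible when
$1 + \gamma\, n_{kk} < 0$) take the analytic small-particle limit $Q = 0$.

Parameterizations and default grids:

* `bassan3`: $\rho = 2\pi d\,\tilde\nu\,(a - 1 + b\,n_{kk})$ with
  $a \in [1.1, 1.5]$ (refractive-index scale), $b \in [0, 1]$ (mixing),
  $d \in [2, 8]\,\mu m$ (sphere diameter), 10 points per axis (1000
  curves), $N = 8$ loadings.
* `konevskikh2`: $\rho = \alpha_0\,\tilde\nu\,(1 + \gamma\, n_{kk})$ with
  $\alpha_0 \in [10^{-4}, 3\cdot10^{-3}]$ and $\gamma \in [0.05, 2]$,
  15 × 15 log-spaced (225 curves), $N = 7$. The $\gamma$ span brackets the
  ratio $b/(a-1)$ implied by the three-parameter ranges. The optimal
  parameter distributions are an open question in the methods literature,
  so all grids are configuration-exposed.

The Kramers–Kronig transform is computed as the FFT-based discrete Hilbert
transform of the normalized reference, with the sign convention that an
absorption peak produces the canonical dispersive lineshape
(sin → −cos). The signal is padded on both sides by an even reflection
tapered to zero with a cosine fade: plain reflection suppresses the
wrap-around discontinuity but leaves the mirrored copies' dispersive tails
in the interior (≈2% for a mid-grid Lorentzian); fading the reflection
pushes interior errors well below the 2% oracle tolerance. A non-uniform
grid is rejected with instructions to resample, since the FFT assumes
uniform spacing.

Because the two-parameter model depends nonlinearly on the reference's
scale, every reference (the initial one, cluster means, and each pixel's
own running reference) is min-subtracted and area-normalized (rescaled by
the grid span to keep values O(1)) before dictionary generation. This makes
the corrected output invariant to the initial reference scaling, which is
asserted in the tests.

CRMieSC iterates: the first iteration fits all pixels with a single model
built from the initial reference (computed once). Each later iteration
re-clusters the current corrected spectra with k-means — clusters may
initially be determined by scattering rather than chemistry, hence the
re-clustering — builds one dictionary per cluster from the cluster mean,
and fits every member with the cluster's loadings but its own reference
(its previous corrected spectrum). `stabilize` (default on) starts with 2
single-cluster iterations and ends with a gradual-update phase (cluster
assignments frozen, references updated as
$Z_\mathrm{ref}^{(n+1)} = \tfrac12 Z_\mathrm{ref}^{(n)} + \tfrac12
Z_\mathrm{corr}^{(n)}$) lasting the final quarter of the iterations, at
least 2. Corrected spectra are returned unclipped; downstream MCR clips
small negatives explicitly.

Stopping: on phantoms the correction quality settles within a handful of
iterations, after which the corrected spectra drift slowly (fractions of a
percent per iteration) through the scale/rotation ambiguity of the model
without further quality change. The auto-stop therefore treats two
conditions as convergence: the relative change of the corrected spectra
falling below `stopTol` (default 10⁻⁴), or that change no longer
decreasing (plateau, checked from iteration 6 against the best change seen
so far). When `stabilize` is on, detecting either condition enters the
gradual-update phase rather than stopping outright, so the run always ends
with frozen assignments and damped reference updates. A cluster whose
reference changes by less than `stopTol` while assignments are stable is
frozen individually. With clustering disabled every spectrum forms its own
cluster, reproducing the per-spectrum algorithms at per-spectrum cost.

The initial reference must be scattering-free — a transmission spectrum of
a homogeneous sample of the same material, or one of the bundled clean
spectra. This is not a soft preference: a reference that already carries
the image's distortions makes the iteration self-confirming, because after
the first iteration each pixel's running reference contains its own
residual distortion and $h Z_\mathrm{ref}$ alone reproduces the raw
spectrum, leaving the scattering terms nothing to explain. On phantoms, a
distorted (observed-mean) starting reference stalls at roughly 85% of the
uncorrected error regardless of iteration count, clustering or rescaling
options, while a clean reference of the same material reaches 20–30%. The
pipeline's fallback reference is therefore the bundled clean spectrum,
never the image mean.

k-means inside the CRMieSC loop uses 3 restarts (seeded deterministically
per iteration from the configured seed); segmentation k-means uses 10
restarts. The inner loop is insensitive to restarts because clusters only
pool spectra for dictionary building, while segmentation results are
user-facing, so the extra restarts are spent there.

## Baselines and denoising

* Rubberband: lower convex hull of $(\tilde\nu, x)$, evaluated
  piecewise-linearly (Andrew's monotone chain; verified against an $O(n^2)$
  oracle).
* Concave rubberband: the named methods literature does not define the
  iteration, so the package subtracts a concave parabola (zero at the ends,
  amplitude starting at a quarter of the spectrum's range and halved each
  of 10 iterations), takes the rubberband, adds the parabola back, and
  keeps the pointwise maximum over iterations — this follows concave-curved
  baselines while never exceeding the spectrum.
* AsLS: penalized least squares with second-difference penalty $\lambda$
  (default 10⁶) and fixed asymmetric weights $p$ (default 0.01); arPLS:
  the same penalty with logistic reweighting from the negative-residual
  noise statistics, terminating when the relative weight change drops below
  `ratio` (default 10⁻⁶). Both solve banded sparse systems.
* Savitzky–Golay denoising: per-spectrum, polynomial order 3, window 9 by
  default; exact on polynomials up to the filter order.

Baselines are computed on whatever wavenumber range is present — no
extrapolation — and are translation-equivariant (tested).

## MCR-ALS

$D = C S^T + E$ with $C, S \ge 0$, solved by alternating non-negative
least squares. The NNLS subproblems are solved for all right-hand sides at
once with a fast combinatorial active-set solver (grouped passive-set
solves); the tests pin it to an independent per-column NNLS implementation.
The residual metric — the methods literature does not fix one — is the
relative Frobenius error $\|D - CS\| / \|D\| \times 100\%$, recorded after
every full iteration. Iteration stops when the relative improvement per
iteration drops below `relTol` (default 0.1%), at `maxIter` (default 700),
or when the error increases, in which case the best factors seen are
returned. A component collapsing to zero is re-seeded from the pixel with
the largest residual, with a warning.

SIMPLISMA selects the $k$ purest variables by
$p_j = \sigma_j / (\mu_j + f)$ with noise offset
$f = \alpha\% \cdot \max\mu$ (default $\alpha = 5$), deflating previously
selected directions through determinants of the correlation-around-origin
matrix of the candidate and selected variables (the plain purity
criterion; the second-derivative variant some implementations offer is not
used). On a pixels × wavenumbers matrix, pure rows (pixels) initialize
$S$ (`initOn = "spectra"`, the default) and pure columns (wavenumbers)
initialize $C$. Rotational ambiguity is inherent to bilinear models:
recovered factors are compared to ground truth only up to permutation and
positive scaling.

The ROI polygon selects pixels whose centers fall inside under the even-odd
rule; the decomposition of the masked matrix is identical to a standalone
decomposition of the same rows (no hidden state), and the index map embeds
results back into the image.

## Segmentation

k-means on the per-pixel concentration vectors, optionally normalized to
unit sum (an L2 option exists; the sum is the default because compositions
are the natural simplex coordinates). Normalization removes overall
intensity — sample thickness — so weak but chemically distinct regions
separate; the phantom experiments below quantify this. Annotation maps
cluster ids to named regions, unmapped clusters become `"unassigned"`, and
region mean spectra are exact arithmetic means whose count-weighted
recombination equals the global mean.

## The phantom generator

`makePhantom()` emulates the data this pipeline targets: 64 × 64 pixels,
900–3850 cm⁻¹ at 2 cm⁻¹ (1476 points), four components. Pure spectra are
sums of 3–8 Gaussian/Lorentzian bands, mostly in the fingerprint region
plus CH-stretch bands, redrawn until pairwise cosine similarity is below
0.95. The `cell_on_film` geometry plants a film covering the whole image, an
elliptical cell with a distinct core, and a weak halo ring (15% of the
film's band intensity) — film, hypha and halo regions; a smooth film
thickness field (0.6–1.4 relative) multiplies all components, which is
what makes normalized and raw concentration clustering genuinely differ.
One near-pure pixel (purity ≥ 0.95) is planted per component so SIMPLISMA's
assumptions hold by construction.

Contaminations: atmospheric lines scaled either by fixed per-region
factors or by a smooth humidity field with small independent per-region
jitter (so the recovered water factors correlate strongly but not
perfectly); resonant Mie distortion generated by the same extinction code
path the corrector uses, with per-pixel $\alpha_0 \in [3\cdot10^{-4},
2\cdot10^{-3}]$, $\gamma \in [0.1, 1]$ (inside the default dictionary),
additive amplitude 0.1–0.4 and multiplicative scale 0.9–1.1; a smooth
baseline; white Gaussian noise with $\sigma = 0.005$ against peak
absorbances of order 1 — the signal-to-noise regime of good FTIR imaging
data. Each contamination draws from its own seed derived from the master
seed, so toggling one leaves the others bit-identical, and the whole
phantom regenerates exactly from `(seed, arguments)`.

What passing on phantoms does *not* show: the Mie distortions are exactly
in-model (van de Hulst spheres with parameters inside the dictionary), the
atmospheric contamination uses the same reference shape the corrector is
given, and the noise is white — real data have out-of-model scattering,
imperfect references, detector drift and fringes. The phantom results
establish correctness of the implementations and internal consistency of
the pipeline, not field performance.

## Problem sizes and numerical details

The test suite and the acceptance script use 32 × 32 phantoms for the
atmospheric and CRMieSC recovery experiments, 48 × 48 for noiseless MCR
recovery, and the full 64 × 64 default for the end-to-end determinism run —
sizes at which every experiment completes in minutes on a single core while
exercising the same code paths as full-scale data. The noiseless MCR
recovery run raises the iteration cap to 2000 with a 10⁻⁸% tolerance: the
weak halo component is nearly collinear with the film, which makes the ALS
tail convergence slow, and on noiseless data the relative-improvement rule
never triggers (improvements stay proportional to the ever-shrinking
error), so the cap is the binding stop. At the study noise level the
default 0.1% rule stops within a handful of iterations. Degenerate inputs are
handled explicitly: flat references yield factor 0 with a warning; all-zero
pixels survive normalization untouched; empty k-means clusters trigger
re-seeding fallbacks; rank-deficient dictionaries reduce the loading count
with a warning. All randomness flows from user-visible integer seeds, and
batch outputs are bit-reproducible across runs, which the tests assert.
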
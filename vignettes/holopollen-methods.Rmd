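---
title: "Quantitative phase imaging of pollen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phase imaging of pollen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(holopollen)
```

`holopollen` implements a complete digital-holographic-microscopy (DHM)
analysis chain for pollen viability: simulation of off-axis image-plane
holograms with known ground truth, recovery of the complex object field,
phase unwrapping, per-grain morphometry, and a two-class viability call
from the distribution of per-grain mean phase. This vignette explains the
models behind each stage, the parameters that matter, and the design
choices that were genuinely open.

## The imaging model

An off-axis hologram is the interference intensity

$$H(x, y) = |O(x, y) + R(x, y)|^2
 = |O|^2 + |R|^2 + O R^{*} + O^{*} R ,$$

where $O = a\,e^{i\varphi}$ is the in-focus object wave and
$R = A\,e^{2\pi i (f_r x + f_c y)}$ a tilted plane reference with carrier
frequency $(f_r, f_c)$ in cycles/pixel. In image-plane holography the
detector coincides with the in-focus image, so no numerical propagation is
modelled. The phase $\varphi$ is the projection of the refractive-index
contrast through the grain — an "optical height". A cytoplasm-filled
(viable) grain behaves like a plano-convex phase object and produces a
nearly hemispherical phase dome; an emptied (non-viable) grain leaves a
nearly flat plateau with a thin elevated wall.

The simulator (`make_phantom()`, `forward_hologram()`,
`generate_population()`) realises exactly this model. The viable profile is
$\varphi(r) = \varphi_{\max}\sqrt{1 - (r/R_g)^2}$, whose mean over the
support disk is $\tfrac{2}{3}\varphi_{\max}$ — the identity used to aim a
phantom at a target mean phase ($\varphi_{\max} = 1.5 \times$ target). The
non-viable profile is a raised-cosine wall (height $\varphi_{\max}$,
spanning the outer quarter of the radius and peaking at $0.875\,R_g$ —
several pixels wide at the emulated sampling, like a real exine wall) over
an interior plateau at $0.75\,\varphi_{\max}$; its unit-profile mean is computed numerically and
scaled. A smoothed zero-mean texture (default sd 0.15 rad) emulates
intracellular granularity, and additive Gaussian intensity noise (default
sd 0.05 on fields of order 1), clipped at zero, stands in for detector
noise, about which we assume nothing more specific.

What the generator does **not** emulate: diffraction between sample and
detector (none is needed at the image plane), partial coherence, detector
nonlinearity, aberrations beyond a plane reference, clumped or touching
grains, and negative refractive-index contrast (phantom phases are
nonnegative). Tests passing on this population therefore validate the
algorithmic chain, not robustness to every artefact of real instruments.

## Reconstruction

`fourier_reconstruct()` is the conventional single-shot route: demodulate
by the carrier, keep a circular low-pass window (default radius 1/16
cycles/px), divide by the reference amplitude. The explicit low-pass is
also its documented drawback: edges blur.

`sparse_reconstruct()` recovers the field at full pixel resolution by
minimising

$$C(O) = \lVert H - |O + R|^2 \rVert_2^2 + \mathrm{TV}_\varepsilon(O),
\qquad
\mathrm{TV}_\varepsilon(O) = \sum_{x,y}
\sqrt{|\partial_r O|^2 + |\partial_c O|^2 + \varepsilon^2},$$

with forward differences and replicate boundaries. Because $O$ is
complex-valued, descent directions are Wirtinger derivatives with respect
to $O^{*}$: $-2\,(H - |O+R|^2)(O+R)$ for the data term and (half) the
negative divergence of the $\varepsilon$-normalised gradient field for the
TV term; both are verified against central finite differences of the cost
in the test suite.

No regularisation constant is tuned. Each iteration takes a backtracking
steepest-descent step on the data term, then a TV step whose length is
`balance_ratio` (default 0.5) times the data-step displacement, with a
safeguard that halves the TV step while it would undo more of the
data-term reduction than the data step just achieved, and a data-step
acceptance rule that targets the best data value seen so far. The recorded
data term is therefore non-increasing across iterations, and both moves
shrink together as the solution settles — the sense in which the reduction
of the two terms is "balanced". Iteration stops when the relative solution
change falls below `rel_change_tol` (default `1e-4`, `max_iters` 300).

Numerical choices worth stating:

* **Initialisation** is the Fourier baseline, with the initialiser's
  window opened to $0.48 \times$ the carrier magnitude (not the baseline's
  1/16). The data term alone does not identify $O$ pointwise — each pixel
  has a circle of consistent values — so the optimiser refines the branch
  the initial field selects. A too-narrow initial bandwidth lets the TV
  term lock in a smooth but wrong branch at steep dome rims; the wide
  window removes that failure mode and, as a bonus, roughly halves the
  iteration count.
* **$\varepsilon$** (default `1e-9`, scaled by the RMS magnitude of the
  initial field) only guards the TV normalisation; results are insensitive
  to it over many orders of magnitude.
* The conjugate-sideband ambiguity of a real hologram is resolved by
  convention: the carrier reported by `estimate_reference()` lies in the
  half-plane of positive row-frequency.

## Phase unwrapping

`wrap_phase()` is the four-quadrant arctangent, range $(-\pi, \pi]$;
exactly-zero pixels have no phase and are set to 0 with a warning.
`unwrap_tie()` solves the transport-of-intensity-style Poisson problem:
wrapped forward differences estimate the true gradient wherever sampling is
below Nyquist; their divergence feeds a discrete-cosine-transform Poisson
solver. The DCT imposes Neumann boundaries — the physically right choice
for a free-edge field of view, where a periodic FFT solver would alias the
residual tilt. The least-squares surface is then made congruent by
snapping, pixelwise, to the nearest value equal to the wrapped input modulo
$2\pi$, so residue-free round trips are exact up to a global $2\pi k$.

One practical subtlety: TV-regularised reconstructions can carry tight
dipole pairs of phase residues where the field amplitude nearly vanishes
(steep rims). A residue-free least-squares solver mis-integrates through
them and whole annuli land on the wrong $2\pi$ branch. The gradient field
is therefore estimated from a lightly smoothed complex exponential
(Gaussian, $\sigma = 1$ px), which annihilates close dipoles, and
congruence is applied in two stages — first against the smoothed phase,
then against the original input. For residue-free inputs both stages are
no-ops beyond the exact congruence, so the round-trip guarantees are
unchanged.

`remove_background()` fits and subtracts a least-squares plane over the
background (the mask exterior, or a border frame before any mask exists)
and zeroes the background median. This both flattens residual tilt and
absorbs the global $2\pi k$ of the unwrapping, so the empty field sits at
phase 0 before anything is measured. The pipeline applies it twice per
grain: once with the border frame, then refined against the segmentation.

## Morphometry

Segmentation is hysteresis thresholding: an Otsu (or fixed) seed threshold
on $|\varphi|$ marks grain cores, each core is grown to the connected
region above `floor_frac` (default 0.12) of the seed threshold, holes are
filled and small components dropped. The low flood floor matters because a
phase dome tapers continuously to zero: a plain Otsu cut would clip the
rim and bias the footprint (a plain-threshold mask of a dome reaches only
$\approx 0.9$ intersection-over-union against the true disk; the
hysteresis mask exceeds 0.98).

`measure_pollen()` reports, per grain: area (pixel count, converted with
the object-plane pixel size `pixel_pitch / magnification`), perimeter
(marching-squares contour length at the 0.5 level — stated explicitly so
results are reproducible bit for bit), mean phase (integrated phase over
the mask divided by the pixel count, in radians), and optical volume
(integrated phase times pixel area, radian·µm²). Mean phase equals optical
volume over area by construction; the printed mean-phase scale is treated
as radians throughout, since the arctangent output is radians and no other
calibration is stated.

## Viability classification

The discriminant is the per-grain mean phase. Its distribution over a
mixed population is strongly bimodal — the class centres used throughout
(8.72 rad viable, 4.26 rad non-viable, within-class sd 0.8) separate by
more than five standard deviations. `fit_two_classes()` fits a
two-component univariate Gaussian mixture by EM (k-means initialisation
under a fixed seed, unequal variances, degenerate fits rejected when a
component weight falls below 0.02) and places the threshold at the
equal-posterior point between the component means; the higher-mean
component is called viable. The mixture is this package's operational
reading of "two distinct peaks" — a staining assay plays that role at the
bench. `ttest_classes()` is Welch's two-sample test (the class variances
need not match), and `flag_overlap()` marks grains within
`band_halfwidth` (default half the pooled within-class sd) of the
threshold, plus grains whose stain label disagrees with the phase call.
Histogram binning (Freedman–Diaconis) is presentation only; the classifier
uses raw values.

## Study conditions and problem sizes

The default population is 508 grains in nearly equal proportion with the
class centres above. Grain geometry defaults — 192² regions of interest,
radii 66–78 px, carrier (0.25, 0.25) cycles/px — were chosen once, from
the sampling physics: a viable grain at mean phase 8.72 has a dome peak
near 13 rad, and gradient-based unwrapping needs the rim slope to stay
below the wrapped-difference Nyquist limit, which requires radii of this
order; the half-Nyquist diagonal carrier maximises sideband separation and
the initialiser bandwidth needed for domes spanning multiple $2\pi$. At
the instrument sampling the defaults emulate, real grains are hundreds of
pixels across, so these are the smallest geometries faithful to that
regime — markedly *smaller* ROIs or radii place the phantom outside the
regime where any residue-free unwrapping can succeed, regardless of
implementation.

The test suite runs reduced problem sizes chosen as the smallest instances
that still exercise each property — small enough to run routinely, large
enough that the statistical checks test the pipeline rather than finite-
sample noise (at 150 grains the standard error of a class centre is about
0.09 rad, well inside the 0.25 rad recovery band; at 60 grains the two are
comparable and the check would mostly measure the draw): single 256² phantoms for
reconstruction fidelity and resolution ordering, 16² instances for the
gradient oracle, and a 150-grain population for the end-to-end parameter,
label and separation recovery. The full 508-grain run uses the same code
path and one configuration object.

## Known limitations

* Grains are analysed one per region of interest; touching or clumped
  grains are not split (no watershed). Clumps show up as isoperimetric
  outliers and inflated areas.
* The reference wave is assumed planar. `estimate_reference()` recovers
  the carrier to sub-0.002 cycles/px, but its amplitude estimate assumes a
  weak object background; the pipeline defaults to the known reference, as
  an interferometer provides in practice.
* Dome slopes beyond roughly 0.25 rad/px at the rim defeat the
  reconstruction–unwrapping chain (wrong-branch recovery); this is a
  sampling limit, not a tunable.
* Mean phase is the only feature used for classification; textural
  information in the phase maps is deliberately left on the table.

## A worked micro-example

```{r example, eval = FALSE}
set.seed(1)
pop <- generate_population(n = 8, seed = 1)
run <- run_pipeline(pipeline_config(simulate = list(n = 8L)), population = pop)
run$fit$stats
tidy(run$fit)      # mixture components
glance(run$fit)    # threshold, log-likelihood
autoplot(run$fit)  # mean-phase histogram with components and threshold
```
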
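# holopollen

Quantitative phase imaging pipeline for pollen viability assessment by
off-axis digital holographic microscopy (DHM).

Vital staining — the standard bench assay for pollen viability — is slow,
toxic, and leaves grains unusable. DHM offers a label-free alternative: a
single off-axis hologram encodes the full complex optical field of a grain,
and the recovered phase map (the optical path delay through the grain) acts
as an optical height profile. Cytoplasm-filled viable grains show a nearly
hemispherical phase dome; emptied non-viable grains show a nearly flat
plateau. The mean phase over the grain footprint separates the two classes
cleanly. `holopollen` is for researchers in quantitative phase imaging and
pollen biology who want a tested, fully reproducible implementation of that
analysis chain, including a synthetic-hologram generator with known ground
truth for validation.

## The model and method

A hologram is the interference intensity

    H = |O + R|^2 = |O|^2 + |R|^2 + O R* + O* R,

with `O = a e^{i phi}` the in-focus object wave and `R` a tilted plane
reference carrying frequency `(f_r, f_c)` cycles/pixel. The object field is
recovered two ways:

* **Fourier baseline** — demodulate by the carrier and low-pass around the
  sideband (band-limited; edges blur);
* **TV-regularised sparse optimisation** — minimise
  `||H − |O+R|^2||_2^2 + TV_eps(O)` by adaptive alternating minimisation:
  a backtracking Wirtinger-gradient step on the data term, then a
  total-variation descent step whose length is balanced against the data
  step, so no regularisation weight is ever tuned. This recovers the field
  at full pixel resolution.

The wrapped phase `atan2(Im O, Re O)` is unwrapped by a
transport-of-intensity (Poisson/DCT, Neumann boundary) solver with
congruence correction, flattened against the background, segmented, and
measured per grain: area, perimeter, mean phase (radians) and optical
volume (radian·µm²). A two-component Gaussian mixture on mean phase yields
the viability threshold, per-class statistics, Welch's t-test and flags for
grains in the histogram overlap region.

## Worked example

```r
library(holopollen)

cfg <- pipeline_config(seed = 11, simulate = list(n = 150L))
run <- run_pipeline(cfg)
run
#> <holopollen_run> 150 grains, threshold = 6.642 rad, accuracy vs stain = 100.0%
#>   t = 32.59 (df = 147.4), p = 3e-69; artifacts in /tmp/.../run150
tidy(run$fit)$mu      # fitted component means (nonviable, viable), radians
#> [1] 4.445319 8.760996
```

The run simulates 150 pollen holograms (two classes of mean phase centred
at 8.72 and 4.26 rad, the regime the pipeline is designed around),
reconstructs every grain with the sparse optimiser, unwraps and measures
the phase maps, and classifies by the mean-phase mixture. The recovered
component means sit on the configured class centres; the threshold falls
between the two histogram peaks; accuracy is measured against the
generating (stain) labels; the t-test confirms the class separation. All
artifacts — ground-truth manifest, measurement CSV, class statistics,
JSON report, config echo — land in one run directory.
`autoplot(run$fit)` draws the two-colour mean-phase histogram with the
fitted components and threshold.

Single objects work the same way piecewise:

```r
ph  <- make_phantom("viable", shape = c(256, 256), radius = 40, peak_phase = 8)
R   <- make_reference(c(256, 256), tilt = c(0.125, 0.125))
H   <- forward_hologram(ph, R)
rec <- sparse_reconstruct(H, R)          # field + cost trace (tidy/glance)
phm <- remove_background(unwrap_tie(wrap_phase(rec$field)))
measure_pollen(ph$true_mask, phm)        # area / perimeter / mean phase / volume
```

A thin command-line front end with `simulate`, `reconstruct`, `phase`,
`measure`, `classify` and `run` subcommands is installed at
`inst/cli/holopollen.R`.

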
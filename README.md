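# gelspot

Detection and model-based quantification of protein spots in
two-dimensional gel electrophoresis (2-DE) and immunoblot images.

## The problem

On a 2-DE gel or a quantitative immunoblot, each protein species appears
as a roughly bell-shaped intensity spot. Measuring *how much* protein
each spot holds is harder than it looks:

* **Optical density (OD)** — using the brightest pixel as the signal —
  ignores spot width and saturates with the camera.
* **Area-based volumes** — summing pixels above a threshold — truncate the
  spot's periphery, so faint spots lose a larger share of their signal
  than bright ones, and merged spots must be carved up heuristically.

`gelspot` implements a model-based alternative: every spot is fitted with
a circular two-dimensional Gaussian

    f(x, y) = I · exp(−0.5 · ((x − x₀)² + (y − y₀)²) / σ²) + μ_bg

and quantified by the volume under the fitted surface,

    VUS = 2π · I · σ²,

which is proportional to the number of photons collected and hence to the
protein amount. Overlapping spots are fitted *simultaneously*, so shared
pixels are decomposed into per-spot contributions instead of being
assigned to a single winner.

## The pipeline

1. **Noise estimation** — σ_ns from the SDs of sliding w×w windows whose
   mean lies below the mean of all window means (background windows).
2. **Restoration** — one zero-sum convolution: a unit-sum Gaussian
   (SD 2) minus a unit-sum boxcar of edge 2w+1, i.e. smoothing plus
   local-background subtraction. Used for detection only.
3. **Peak detection** — a pixel is a peak when it equals the grayscale
   dilation of the restored image with a flat disk of radius w
   (condition a) and its original intensity exceeds the disk mean plus
   t·σ_ns, default t = 10 (condition b).
4. **Compounding** — peaks closer than d in both x and y are fused into
   fitting compounds via transitive closure (repeated squaring and
   re-binarization) of the peak adjacency matrix; each compound's pixel
   mask is the union of d-edge squares around its peaks.
5. **Fitting** — per compound, bounded Levenberg–Marquardt least squares
   of a sum of circular Gaussians plus the fixed background μ_bg (mean
   intensity outside all compound areas), on the *original* image.
6. **Discrimination** — fits with σ ≤ 1 px are flagged as single-pixel
   artifacts (camera noise), never silently removed.

The package also ships the two comparator methods (OD; threshold-area
volumes with perpendicular-bisector splitting of merged regions), a
synthetic gel simulator with exact ground truth (Gaussian, Lorentz-shaped
and diffusion-model spots; controlled overlap, intensity, noise and
saturation), and evaluation metrics: the signal-ratio deviation α, a
multi-spot α_mean, relative spot signals and exposure-series coefficients
of variation.

## Worked example

Two overlapping Gaussian spots (amplitudes 1000 and 600, σ = 3, 20 px
apart, noise SD 2), simulated and quantified end to end:

```r
library(gelspot)
sc  <- simulate_pair("gaussian", I_P = 1000, I_Q = 600,
                     width_P = 3, width_Q = 3, ipd = 20,
                     noise_sd = 2, seed = 7)
run <- run_pipeline(sc$image, ipd = 20, verbose = TRUE)
#> noise: sigma_ns = 2.614 (6155 windows)
#> detection: 2 peaks (w = 10, t = 10)
#> compounding: 1 compounds (d = 60)
#> background: mu_bg = 0.03869 (3565 pixels)
#> fit: 2 spots, 0 discarded, 0 non-converged

run$fits[, c("spot_id", "x0", "y0", "I", "sigma", "vus", "discarded")]
#>   spot_id      x0       y0        I    sigma      vus discarded
#> 1       1 35.4994 45.49972 1000.627 2.998887 56542.14     FALSE
#> 2       2 55.5008 45.50118  599.162 3.001447 33914.51     FALSE

alpha_deviation(run$fits$vus[1], run$fits$vus[2],
                sc$truth$true_signals[1], sc$truth$true_signals[2])
#> [1] 0.0316   # percent deviation of the fitted P/Q ratio from truth
```

The fitted VUS values (56542, 33915) recover the true spot volumes
(2πIσ² = 56549, 33929) to 0.03%, and the P/Q signal *ratio* — the
quantity that matters when comparing samples — is off by 0.03%.

A command-line front end wrapping the same functions lives at
`inst/cli/gelspot.R` (subcommands `simulate`, `detect`, `fit`,
`quantify`, `evaluate`, `pipeline`).

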
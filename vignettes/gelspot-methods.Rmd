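---
title: "Compound Gaussian fitting for 2-DE spot quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound Gaussian fitting for 2-DE spot quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelspot)
```

## The model

A protein spot on a 2-DE gel or immunoblot image is modelled as a
circular two-dimensional Gaussian on a flat background,

$$ f(x, y) = I \exp\!\left(-\tfrac{1}{2}\,
   \frac{(x-x_0)^2 + (y-y_0)^2}{\sigma^2}\right) + \mu_{bg}, $$

with four free parameters per spot: the sub-pixel center $(x_0, y_0)$,
the amplitude $I$ above background (arbitrary densitometric units) and
the width $\sigma$ (pixels). The quantity reported per spot is the
volume under the fitted surface,

$$ \mathrm{VUS} = \iint I e^{-r^2/2\sigma^2}\,dx\,dy = 2\pi I \sigma^2, $$

which is proportional to collected photons and therefore to protein
amount. Real spots are not exactly Gaussian; what the model buys is the
ability to *decompose* overlapping spots, because a pixel shared by two
spots contributes to both terms of the sum being fitted rather than
being assigned winner-takes-all. The package deliberately fits circular
Gaussians only — an elliptical extension would double the shape
parameters and is not needed for the ratio-based comparisons the tool
targets.

## Detection before fitting

Fitting needs starting locations. Detection runs on a *restored* image
while all quantification runs on the original, untouched image.

**Noise.** The noise SD $\sigma_{ns}$ is estimated from sliding
$w \times w$ windows (sample SD within each window). Windows whose mean
is below the mean of all window means are taken as background — most of
a gel image is background — and $\sigma_{ns}$ is the average of their
SDs. A constant image selects no window and yields $\sigma_{ns} = 0$.
The estimator assumes bright structure is *localized*; a pathological
image whose bright region covers half the frame pushes
boundary-straddling windows (low mean, high SD) into the selection and
inflates the estimate. On gel-like images with spots covering a few
percent of the area the estimate is within a few percent of the true
noise SD. A tiled (non-overlapping) variant is available via
`estimate_noise(..., tiled = TRUE)`.

**Restoration.** One pass of the zero-sum kernel
$K = G - U$ on support $[-w, w]^2$, where $G$ is a unit-sum Gaussian of
SD 2 (configurable via `sigma_smooth`) and $U$ the unit-sum boxcar: the
Gaussian suppresses single-pixel noise, the subtracted boxcar removes
the local background. Because detection compares the restored image only
with its own dilation, any positive rescaling of $K$ gives identical
peaks; the unit-Gaussian-sum normalization is therefore just a
convention. Convolution and dilation use mirrored (reflect) boundary
padding by default (`pad = "zero"` is available); reflect keeps border
statistics comparable to the interior and avoids spurious border maxima.

**Peaks.** A pixel is a peak when (a) it attains the grayscale dilation
of the restored image with a flat disk of radius $w$ (the discrete disk
$i^2 + j^2 \le w^2$, center included), and (b) its *original* intensity
exceeds the disk mean plus $t\,\sigma_{ns}$. The default $t = 10$ is
deliberately conservative: on pure-noise images it produces no
detections in ≥ 95% of replicates, at the cost of missing spots whose
peak barely clears the local mean. Note that condition (b) compares the
peak with the mean over the *same* disk of radius $w$, which contains
much of the spot itself; very broad spots relative to $w$ therefore need
a larger $w$ to be detected (in practice $w \gtrsim 2\sigma$).
Plateaus — connected candidates sharing the dilated maximum — emit a
single peak at the first plateau pixel in row-major order; the rule is
arbitrary but deterministic. Detection is exactly invariant under
rescaling the image and $\sigma_{ns}$ by any positive factor.

The scale $w$ is the floor of half the inter-peak distance of the
closest resolvable spot pair (`compute_w_from_ipd`). Where the original
workflow asked the user to click that pair, this package takes `--ipd`
or `w` directly.

## Compounds

Fitting all spots of an image at once is needlessly expensive and
ill-conditioned; fitting one spot at a time mis-handles overlap. The
compromise: peaks whose $d$-edge squares would overlap (both
$|\Delta x| \le d$ and $|\Delta y| \le d$) must share a fit. The
relation's transitive closure is computed by repeatedly squaring the
binary adjacency matrix and re-binarizing until a fixpoint — the
reachability matrix — is reached (a BFS connected-components oracle
verifies it in the tests; the squaring form is the production path).
Each compound's mask is the union of $d$-edge squares around its peaks,
clipped to the image; cross-compound peaks differ by more than $d$ in x
or y, so masks are provably disjoint (still asserted at run time).

The default $d = 6w$ rests on $\sigma$ rarely exceeding $w$ in a
correctly parameterized run, so a $\pm 3\sigma$ support captures
> 99% of a spot's volume. For high-precision work on isolated spots a
mask reaching $\pm 6\sigma$ removes the last $10^{-4}$-level tail bias
in $\mu_{bg}$; the exact-recovery tests use that. For even $d$ the
square spans $\lfloor d/2 \rfloor$ pixels up/left and
$d - 1 - \lfloor d/2 \rfloor$ down/right; odd $d$ is recommended.

## The fit

$\mu_{bg}$ is the mean intensity outside all compound areas, computed
once before fitting and held fixed (co-fitting it per compound is
available via `fit_background = TRUE` for robustness studies).
Per compound, the sum of its $k$ Gaussians plus $\mu_{bg}$ is fitted to
the original image over the mask pixels by bounded Levenberg–Marquardt
least squares (`minpack.lm::nls.lm`, ftol = ptol = 1e-8, at most
$200 \cdot 4k$ iterations). Initialization: centers at the detected
peaks, $I_0 = A(\text{peak}) - \mu_{bg}$ floored at a small positive
value, $\sigma_0 = \max(1.5, w/2)$. Bounds: $I \ge 0$,
$\sigma \in (0.1, d]$, centers inside the compound bounding box expanded
by $w$. Optimizer failure never raises; the affected spots return
`converged = FALSE`.

If the image declares a saturation level, clipped pixels are excluded
from the residual sum (censoring). The unclipped flanks then still
identify $I$ and $\sigma$ — this is why the fit survives exposure series
whose top images clip, where OD by construction reports the saturation
threshold.

Fits with $\sigma \le 1$ are flagged (`discarded = TRUE`, rows kept):
single-pixel camera artifacts pass peak detection but cannot support a
broad base, so their fitted width collapses. The boundary is inclusive.

## Comparator methods

Two baselines are implemented for method comparison, not as recommended
procedures. **OD** is the peak pixel's intensity (optionally
background-subtracted; raw by default). **Area-based volume** sums raw
intensities over supra-threshold pixels (8-connected components)
assigned to peaks; a component holding two peaks is split by the
perpendicular to the inter-peak line through the line-profile minimum
(bilinear interpolation at unit spacing). When the profile decreases
monotonically from P to Q the minimum *is* Q, the split passes through
Q's coordinates, and P annexes nearly the whole region — the method's
characteristic failure under heavy overlap, reproduced deliberately.
Components with more than two peaks apply the pairwise rule in
increasing-distance order, eliminating for each pixel the peak on the
far side of each split. The threshold defaults to
$\mu_{bg} + t\,\sigma_{ns}$; whether volumes subtract the background is
a flag (raw by default).

## The simulator

Synthetic scenes are background + spot surfaces evaluated at pixel
centers + i.i.d. $N(0, \text{noise\_sd}^2)$ noise, optionally clipped at
a saturation level; `(spec, seed)` is a pure function of the output and
the session RNG stream is left untouched. Pixel-center sampling (no
within-pixel integration) is a declared convention — spots at the scales
of interest are smooth over one pixel. SNR throughout means peak
amplitude over noise SD.

Three spot shapes are provided:

* **gaussian** — truth is the closed form $2\pi I\sigma^2$;
* **lorentz** — $f(r) = I/(1 + r^2/s^2)$. Its 2-D integral diverges, so
  the true signal is *defined* as the noiseless rendered sum over the
  image support. Ratios of lorentz truths therefore depend (weakly) on
  the image size; this is a declared convention, not an approximation;
* **diffusion** — a uniform unit-height disk of radius $R$ blurred by a
  Gaussian of SD $D$, evaluated by a numerically stable radial
  quadrature ($\exp(-(s-r)^2/2D^2)$ times the exponentially scaled
  Bessel $I_0$), rescaled to peak amplitude $I$; truth is again the
  rendered sum, and for $D \ll R$ it approaches the disk integral
  $\pi R^2 I$ (cross-checked in the tests).

What the simulator does *not* model: gel warping, streaks, dust,
spatially correlated background, or a nonlinear camera response. Passing
tests on these scenes demonstrates the algorithmic properties of the
methods — overlap decomposition, threshold bias, saturation behavior —
not robustness to every artifact of wet-lab images.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen so the full suite runs in well under a minute
of fitting time while keeping every effect measured far above its
sampling noise:

* *Detection fields*: 50 seeded fields, 12 Gaussian spots each,
  $\sigma \in [2, 4]$, $I \in [250, 600]$, noise SD 5 (SNR ≥ 50),
  centers ≥ 16 px apart (≥ 4σ), 160×160 px, $w = 8$. Recall and
  precision are both 1.0 across all fields.
* *Pure noise*: 100 seeded 96×96 images, SD 5, $t = 10$: no peaks in at
  least 95.
* *Overlap comparison*: pairs with $I_P/I_Q = 100/90$,
  $\sigma = 4$, noise SD 1 (SNR 100), 20 seeds, IPD $= 2\sigma$ and
  $3.5\sigma$. The ratio 100:90 keeps the pair in the regime the method
  comparison is about: at IPD $= 2\sigma$ the raw inter-peak profile is
  already monotone (the area method splits through Q and its median
  $|\alpha|$ exceeds 100%), while the restored image still resolves both
  peaks so detection and fitting proceed. At amplitude ratios below
  roughly 0.85 the restored image merges too and the pipeline reports a
  single spot — quantifying such pairs requires seeded peak positions,
  which the API accepts in place of detection.
* *Intensity sweep*: single spots from 20× down to 1.5× the area
  threshold, noiseless, for all three shapes; the area volume/truth
  ratio decreases monotonically with intensity while the fit's
  VUS/truth ratio moves by < 2% (Gaussian sweep).
* *Exposure series*: one five-spot scene at linear exposures
  1–8×, constant camera noise; relative spot signals per method, CV
  across the series. Unsaturated: fit mean CV ≈ 0.002, an order below
  the area method. With clipping at 900 (top exposures saturate the
  bright spots): OD's mean CV rises two orders above the fit's.
* *Discrimination*: 20 seeds of a true spot ($\sigma = 3$, SNR 20) plus
  a bright single-pixel impulse; every impulse fits with $\sigma \le 1$
  and is flagged, no true spot ever is.

`scripts/acceptance.R` re-runs exactly these conditions from a
command-line seed and writes the measured quantities as JSON; nothing in
it is hard-coded output.

## Numerical choices and degenerate inputs

* Sample (n−1) SDs everywhere (noise windows, series CVs).
* CSV outputs carry 9 significant digits, enough for exact
  write/read round trips of all fitted quantities.
* Matching of detections to truth is greedy nearest-first within a
  radius; for well-separated configurations it coincides with the
  optimal assignment (verified against exhaustive matching on small
  instances).
* $\alpha$ is returned signed; aggregations use $|\alpha|$. The
  multi-spot $\alpha_{mean}$ is the mean absolute percent deviation of
  relative signal shares from relative truth shares — scale-invariant
  and, for two spots, of the same order as $|\alpha|$.
* Degenerate inputs fail loudly: compounds covering the whole image
  (no background left), peaks below the area threshold (empty area,
  warning), zero reference signals in $\alpha$ (error), infeasible spot
  placement densities (error naming the limit).

## Known limitations

* Circular Gaussians cannot represent strongly asymmetric or tailed
  spots; on Lorentz-shaped and diffusion-model spots the VUS
  systematically overestimates the (convention-defined) truth, but by a
  *similar factor across intensities*, so ratio comparisons remain
  unbiased — which is the property that matters downstream.
* Condition (b) needs the peak to clear the disk mean by $t\sigma_{ns}$;
  very dense fields where spots dominate every disk, or $w$ far below
  the spot width, suppress detections.
* The noise estimator assumes localized bright structure (see above).
* No cross-gel registration or spot matching between different gels;
  series analysis assumes the same scene across images.
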
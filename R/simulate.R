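# Synthetic gel-image generation with exact ground truth.  Spot surfaces
# are evaluated at pixel centers (no within-pixel integration; spots are
# smooth at the scales of interest).  All randomness is drawn inside
# with_preserved_seed so a (spec, seed) pair is a pure function.

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify one synthetic spot
#'
#' Supported shapes:
#' * `"gaussian"`: `I * exp(-0.5 * r^2 / sigma^2)`; `width = sigma`.  True
#'   signal is the closed form `2 * pi * I * sigma^2`.
#' * `"lorentz"`: `I / (1 + r^2 / s^2)`; `width = s` (half-width).  The 2D
#'   integral of this profile diverges, so the true signal is DEFINED as
#'   the noiseless rendered sum over the image support — a declared
#'   convention, stated wherever lorentz truths are reported.
#' * `"diffusion"`: a uniform unit-height disk of radius `R` blurred by a
#'   circular Gaussian of SD `D`, rescaled to peak amplitude `I`;
#'   `width = c(R, D)`.  True signal is the noiseless rendered sum.
#'
#' @param shape `"gaussian"`, `"lorentz"` or `"diffusion"`.
#' @param x0,y0 Subpixel center, 0-based pixel coordinates.
#' @param I Peak amplitude above background (> 0).
#' @param width Shape width parameter(s), see above (> 0).
#' @return A list of class `spot_spec`.
#' @export
spot_spec <- function(shape = c("gaussian", "lorentz", "diffusion"),
                      x0, y0, I, width) {
  shape <- match.arg(shape)
  stopifnot(I > 0, all(width > 0))
  if (shape == "diffusion" && length(width) != 2L)
    stop("diffusion spots need width = c(R, D)", call. = FALSE)
  if (shape != "diffusion" && length(width) != 1L)
    stop(shape, " spots take a single width parameter", call. = FALSE)
  structure(list(shape = shape, x0 = x0, y0 = y0, I = I, width = width),
            class = "spot_spec")
}

# radial profile of the diffusion spot before peak normalization:
# convolution of the unit disk (radius R) with a Gaussian of SD D, via the
# stable radial quadrature
#   h(r) = int_0^R (s/D^2) exp(-(s-r)^2/(2 D^2)) I0e(s r / D^2) ds,
# with I0e the exponentially scaled modified Bessel function.
diffusion_profile <- function(r, R, D, n_quad = 400L) {
  s <- seq(0, R, length.out = n_quad)
  ds <- s[2L] - s[1L]
  wts <- rep(ds, n_quad); wts[c(1L, n_quad)] <- ds / 2   # trapezoid
  vapply(r, function(ri) {
    f <- (s / D^2) * exp(-(s - ri)^2 / (2 * D^2)) *
      besselI(s * ri / D^2, 0, expon.scaled = TRUE)
    sum(f * wts)
  }, numeric(1L))
}

# evaluate one spot surface at coordinate vectors (pixel centers)
eval_spot <- function(spot, xs, ys) {
  r2 <- (xs - spot$x0)^2 + (ys - spot$y0)^2
  switch(spot$shape,
    gaussian = spot$I * exp(-0.5 * r2 / spot$width^2),
    lorentz  = spot$I / (1 + r2 / spot$width^2),
    diffusion = {
      R <- spot$width[1L]; D <- spot$width[2L]
      r <- sqrt(r2)
      # profile on a dense radial grid, interpolated per pixel
      rmax <- max(r) + 1
      grid <- seq(0, rmax, by = 0.05)
      prof <- diffusion_profile(grid, R, D)
      prof <- prof / diffusion_profile(0, R, D) * spot$I
      stats::approx(grid, prof, xout = r, rule = 2L)$y
    })
}

#' Render a synthetic gel scene
#'
#' Builds `background + sum of spot surfaces + N(0, noise_sd^2)` at pixel
#' centers, clips at `saturation_level` when given, and returns the image
#' together with its ground truth (per-spot true signals and all pairwise
#' true ratios).  Same spec and seed always give the bit-identical image.
#'
#' @param dims `c(height, width)` in pixels.
#' @param spots List of [spot_spec] objects (centers must lie inside the
#'   image).
#' @param background Flat background level.
#' @param noise_sd SD of the additive i.i.d. Gaussian noise (0 = noiseless).
#' @param saturation_level Optional clipping intensity.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A list of class `scene` with `image` (a [gel_image]) and
#'   `truth` (class `scene_truth`: the spec plus `true_signals` and the
#'   pairwise `true_ratios` matrix).
#' @export
render_scene <- function(dims, spots, background = 0, noise_sd = 0,
                         saturation_level = NULL, seed = 1L) {
  stopifnot(length(dims) == 2L, all(dims >= 1))
  h <- as.integer(dims[1L]); wid <- as.integer(dims[2L])
  for (sp in spots)
    if (sp$x0 < 0 || sp$x0 > wid - 1L || sp$y0 < 0 || sp$y0 > h - 1L)
      stop("spot centered at (", sp$x0, ", ", sp$y0,
           ") lies outside the ", h, "x", wid, " image", call. = FALSE)
  xs <- rep(0:(wid - 1L), each = h)
  ys <- rep.int(0:(h - 1L), wid)
  clean <- rep(background, h * wid)
  true_signals <- numeric(length(spots))
  for (i in seq_along(spots)) {
    surf <- eval_spot(spots[[i]], xs, ys)
    clean <- clean + surf
    true_signals[i] <- switch(spots[[i]]$shape,
      gaussian = 2 * pi * spots[[i]]$I * spots[[i]]$width^2,
      sum(surf))   # lorentz / diffusion: rendered-sum convention
  }
  px <- clean
  if (noise_sd > 0)
    px <- px + with_preserved_seed(seed, stats::rnorm(h * wid, 0, noise_sd))
  if (!is.null(saturation_level)) px <- pmin(px, saturation_level)
  img <- gel_image(matrix(px, h, wid), saturation_level = saturation_level)
  ratios <- outer(true_signals, true_signals, "/")
  truth <- structure(
    list(dims = c(h, wid), spots = spots, background = background,
         noise_sd = noise_sd, saturation_level = saturation_level,
         seed = seed, true_signals = true_signals, true_ratios = ratios,
         centers = cbind(x = vapply(spots, `[[`, 0, "x0"),
                         y = vapply(spots, `[[`, 0, "y0"))),
    class = "scene_truth")
  structure(list(image = img, truth = truth), class = "scene")
}

#' Simulate a two-spot scene at controlled overlap
#'
#' Two spots P and Q on a horizontal line, separated by `ipd` pixels and
#' centered in the image — the canonical configuration for studying how
#' quantification methods resolve spot superposition.
#'
#' @param shape Spot shape for both spots (see [spot_spec]).
#' @param I_P,I_Q Amplitudes.
#' @param width_P,width_Q Width parameter(s) per spot.
#' @param ipd Inter-peak distance in pixels (> 0).
#' @param dims Image size; default scales with the spot widths.
#' @param background,noise_sd,saturation_level,seed As in [render_scene].
#' @return A `scene`; `truth$true_ratios[1, 2]` is the true P/Q ratio.
#' @export
simulate_pair <- function(shape, I_P, I_Q, width_P, width_Q, ipd,
                          noise_sd = 0, seed = 1L, dims = NULL,
                          background = 0, saturation_level = NULL) {
  stopifnot(ipd > 0)
  wmax <- max(width_P[1L], width_Q[1L])
  if (is.null(dims)) {
    side <- as.integer(ceiling(ipd + 24 * wmax))
    dims <- c(side, side)
  }
  cy <- (dims[1L] - 1) / 2
  cx <- (dims[2L] - 1) / 2
  spots <- list(
    spot_spec(shape, cx - ipd / 2, cy, I_P, width_P),
    spot_spec(shape, cx + ipd / 2, cy, I_Q, width_Q))
  render_scene(dims, spots, background = background, noise_sd = noise_sd,
               saturation_level = saturation_level, seed = seed)
}

#' Simulate a multi-spot field
#'
#' Places `n_spots` Gaussian spots with amplitudes and widths drawn
#' uniformly from the given ranges, centers drawn by rejection sampling so
#' that all pairwise center distances are at least `min_ipd` and every
#' center keeps `margin` pixels from the border.
#'
#' @param n_spots Number of spots.
#' @param I_range,sigma_range Length-2 ranges for amplitude and width.
#' @param min_ipd Minimum pairwise center distance in pixels.
#' @param dims `c(height, width)`.
#' @param noise_sd,background,seed As in [render_scene].
#' @param margin Border margin for centers (default `2 * max(sigma_range)`).
#' @param max_tries Rejection rounds per spot before giving up.
#' @return A `scene`.
#' @export
simulate_field <- function(n_spots, I_range, sigma_range, min_ipd, dims,
                           noise_sd = 0, background = 0, seed = 1L,
                           margin = NULL, max_tries = 2000L) {
  stopifnot(n_spots >= 1L)
  if (is.null(margin)) margin <- 2 * max(sigma_range)
  spots <- with_preserved_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n_spots)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, margin, dims[2L] - 1 - margin)
        y <- stats::runif(1, margin, dims[1L] - 1 - margin)
        if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_ipd^2) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", n_spots, " spots with min_ipd = ", min_ipd,
             " in a ", dims[1L], "x", dims[2L], " image (density too high)",
             call. = FALSE)
    }
    Is <- stats::runif(n_spots, I_range[1L], I_range[2L])
    sg <- stats::runif(n_spots, sigma_range[1L], sigma_range[2L])
    lapply(seq_len(n_spots), function(i)
      spot_spec("gaussian", xs[i], ys[i], Is[i], sg[i]))
  })
  # derive a distinct noise seed so placement and noise are independent
  render_scene(dims, spots, background = background, noise_sd = noise_sd,
               seed = seed + 104729L)
}
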
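#' Mean background level
#'
#' All pixels influenced by spots lie inside compound areas, so the mean
#' background `mu_bg` is simply the mean intensity over every pixel outside
#' all compound masks.  It is computed before fitting and held fixed during
#' the fit.
#'
#' @inheritParams estimate_noise
#' @param compounds A `compound_set` (may be empty or `NULL`, in which case
#'   the whole image is averaged).
#' @return A list of class `background_model` with `mu_bg` and
#'   `n_pixels_used`.
#' @export
estimate_background <- function(image, compounds = NULL) {
  image <- as_gel_image(image)
  if (is.null(compounds) || length(compounds) == 0L) {
    return(structure(list(mu_bg = mean(image$pixels),
                          n_pixels_used = length(image$pixels)),
                     class = "background_model"))
  }
  inside <- compound_mask_matrix(compounds, c(image$height, image$width))
  n_out <- sum(!inside)
  if (n_out == 0L)
    stop("compound areas cover the entire image; reduce d so background ",
         "pixels remain for mu_bg estimation", call. = FALSE)
  structure(list(mu_bg = mean(image$pixels[!inside]), n_pixels_used = n_out),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> mu_bg = %.6g (%d pixels)\n",
              x$mu_bg, x$n_pixels_used))
  invisible(x)
}

# sum of k circular Gaussians evaluated at coordinate vectors x, y
gaussian_mixture_surface <- function(x, y, par) {
  k <- length(par) %/% 4L
  out <- numeric(length(x))
  for (j in seq_len(k)) {
    p <- par[(4L * (j - 1L) + 1L):(4L * j)]   # x0, y0, I, sigma
    out <- out + p[3L] * exp(-0.5 * ((x - p[1L])^2 + (y - p[2L])^2) / p[4L]^2)
  }
  out
}

#' Fit all spots of one compound simultaneously
#'
#' Minimizes, over the compound's mask pixels of the ORIGINAL image, the
#' squared residual between the data and a sum of `k` circular 2D Gaussians
#' `I_j * exp(-0.5 * ((x - x0_j)^2 + (y - y0_j)^2) / sigma_j^2)` plus the
#' fixed background `mu_bg`, using bounded Levenberg-Marquardt least
#' squares.  One `spot_fit` row is returned per member peak.
#'
#' Initialization: `x0, y0` at the detected peak pixel; `I` at the peak's
#' original intensity minus `mu_bg` (floored at a small positive value);
#' `sigma = max(1.5, w / 2)`.  Bounds: `I >= 0`; `sigma` in `(0.1, d]`;
#' `x0, y0` inside the compound bounding box expanded by `w`.  When the
#' image declares a `saturation_level`, clipped pixels are excluded from
#' the residual sum.
#'
#' @inheritParams estimate_noise
#' @param compound One element of a `compound_set`.
#' @param peaks The `gel_peaks` data frame.
#' @param mu_bg A `background_model` (or a single number).
#' @param w Detection scale, used for the initial sigma and bound padding.
#' @param d Compound-square edge (upper bound for sigma); defaults to the
#'   `compound_set` attribute when the compound carries none.
#' @param fit_background If `TRUE`, co-fit a shared background offset for
#'   the compound instead of holding `mu_bg` fixed.
#' @param control `minpack.lm::nls.lm.control` list.
#' @return A data frame of class `spot_fits`, one row per peak, columns
#'   `peak_id`, `compound_id`, `x0`, `y0`, `I`, `sigma`, `vus`, `mu_bg`,
#'   `converged`, `discarded`, `residual_norm`.
#' @export
fit_compound <- function(image, compound, peaks, mu_bg, w = 4L, d = NULL,
                         fit_background = FALSE,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-8, ptol = 1e-8)) {
  image <- as_gel_image(image)
  if (inherits(mu_bg, "background_model")) mu_bg <- mu_bg$mu_bg
  if (is.null(d)) d <- max(attr(compound, "d"), 6L * w)
  rows <- compound$peak_rows
  k <- length(rows)
  stopifnot(k >= 1L, nrow(compound$mask) >= 1L)
  mx <- compound$mask[, "x"]; my <- compound$mask[, "y"]
  z <- pixel_at(image, mx, my)
  if (!is.null(image$saturation_level)) {
    ok <- z < image$saturation_level
    if (!any(ok)) ok <- rep(TRUE, length(z))   # fully clipped: fit anyway
    mx <- mx[ok]; my <- my[ok]; z <- z[ok]
  }
  bx <- range(compound$mask[, "x"]); by <- range(compound$mask[, "y"])

  I0 <- pmax(peaks$original_intensity[rows] - mu_bg, 1e-6)
  par0 <- as.numeric(rbind(peaks$x[rows], peaks$y[rows], I0, max(1.5, w / 2)))
  lower <- rep(c(bx[1L] - w, by[1L] - w, 0, 0.1 + 1e-9), times = k)
  upper <- rep(c(bx[2L] + w, by[2L] + w, Inf, d), times = k)
  if (fit_background) {
    par0 <- c(par0, mu_bg)
    lower <- c(lower, -Inf); upper <- c(upper, Inf)
  }

  resid_fn <- function(p) {
    bg <- if (fit_background) p[length(p)] else mu_bg
    sp <- if (fit_background) p[-length(p)] else p
    z - (gaussian_mixture_surface(mx, my, sp) + bg)
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = utils::modifyList(
                         control, list(maxiter = min(200L * 4L * k, 1024L)))),
    error = function(e) {
      warning("optimizer failure in compound ", compound$compound_id, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  if (is.null(fit)) {
    par <- par0; converged <- FALSE; rnorm2 <- sum(resid_fn(par0)^2)
    bg_out <- mu_bg
  } else {
    par <- fit$par
    converged <- fit$info %in% c(1L, 2L, 3L, 4L)
    rnorm2 <- fit$deviance
    bg_out <- if (fit_background) par[length(par)] else mu_bg
    if (fit_background) par <- par[-length(par)]
  }

  pm <- matrix(par, nrow = 4L)
  out <- data.frame(
    peak_id = peaks$peak_id[rows],
    compound_id = compound$compound_id,
    x0 = pm[1L, ], y0 = pm[2L, ], I = pm[3L, ], sigma = pm[4L, ],
    vus = compute_vus(pm[3L, ], pm[4L, ]),
    mu_bg = bg_out,
    converged = converged,
    discarded = pm[4L, ] <= 1,
    residual_norm = rnorm2
  )
  class(out) <- c("spot_fits", "data.frame")
  out
}

#' Fit every compound of an image
#'
#' Runs [fit_compound] over a `compound_set` sequentially and returns the
#' combined `spot_fits` table with false positives flagged.
#'
#' @inheritParams fit_compound
#' @param compounds A `compound_set`.
#' @return A `spot_fits` data frame with one row per peak and a `spot_id`
#'   column.
#' @export
fit_spots <- function(image, compounds, peaks, mu_bg, w = 4L,
                      fit_background = FALSE, ...) {
  d <- attr(compounds, "d")
  res <- do.call(rbind, lapply(compounds, function(cc)
    fit_compound(image, cc, peaks, mu_bg, w = w, d = d,
                 fit_background = fit_background, ...)))
  res <- discard_false_positives(res)
  res <- cbind(spot_id = seq_len(nrow(res)), res)
  class(res) <- c("spot_fits", "data.frame")
  rownames(res) <- NULL
  res
}

#' Volume under a fitted circular Gaussian surface
#'
#' The integral of `I * exp(-0.5 * r^2 / sigma^2)` over the plane,
#' `VUS = 2 * pi * I * sigma^2`, proportional to the number of detected
#' photons and hence to the protein amount.
#'
#' @param I Peak amplitude above background (vectorized).
#' @param sigma Spot width in pixels (vectorized, > 0).
#' @return Numeric vector of volumes.
#' @examples
#' compute_vus(1, 1)  # 2 * pi
#' @export
compute_vus <- function(I, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  2 * pi * I * sigma^2
}

#' Flag false-positive fits
#'
#' Camera noise tends to hit single pixels, which fit as peaks without a
#' broad base; fits with `sigma <= 1` are therefore flagged as discarded.
#' Rows are flagged, never removed.
#'
#' @param fits A `spot_fits` data frame.
#' @return The same data frame with `discarded` set from the sigma rule.
#' @export
discard_false_positives <- function(fits) {
  fits$discarded <- fits$sigma <= 1
  fits
}

#' Render the fitted model image
#'
#' Evaluates the fitted Gaussian mixture plus background over the full
#' image grid, e.g. for residual inspection (original minus model).
#'
#' @param fits A `spot_fits` data frame (discarded rows are skipped).
#' @param image_shape `c(height, width)`.
#' @param mu_bg Background level; defaults to the first fit's `mu_bg`.
#' @param include_discarded Render discarded fits too (default `FALSE`).
#' @return A numeric matrix of the model surface.
#' @export
render_model_image <- function(fits, image_shape, mu_bg = NULL,
                               include_discarded = FALSE) {
  if (is.null(mu_bg)) mu_bg <- if (nrow(fits)) fits$mu_bg[1L] else 0
  h <- image_shape[1L]; wid <- image_shape[2L]
  xs <- rep(0:(wid - 1L), each = h)
  ys <- rep(0:(h - 1L), times = wid)
  keep <- if (include_discarded) rep(TRUE, nrow(fits)) else !fits$discarded
  par <- as.numeric(rbind(fits$x0[keep], fits$y0[keep],
                          fits$I[keep], fits$sigma[keep]))
  vals <- if (length(par)) gaussian_mixture_surface(xs, ys, par) else 0
  matrix(mu_bg + vals, h, wid)
}
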
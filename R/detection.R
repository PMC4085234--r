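#' Detection scale from inter-peak distance
#'
#' The detection scale `w` — used as the dilation radius, the averaging
#' window and the restoration-kernel half-width — must be smaller than the
#' distance between the two closest resolvable spots but large enough that
#' only one peak is found per spot.  Given the inter-peak distance `ipd` of
#' the closest clearly separated spot pair, `w = floor(ipd / 2)`.
#'
#' @param ipd Inter-peak distance in pixels (positive real).
#' @return Integer `w >= 1`.
#' @examples
#' compute_w_from_ipd(9)   # 4
#' compute_w_from_ipd(10)  # 5
#' @export
compute_w_from_ipd <- function(ipd) {
  stopifnot(is.numeric(ipd), length(ipd) == 1L, is.finite(ipd), ipd > 0)
  w <- as.integer(floor(ipd / 2))
  if (w < 1L)
    stop("ipd = ", ipd, " gives w = ", w,
         "; w must be at least 1 pixel (need ipd >= 2)", call. = FALSE)
  w
}

#' Estimate the background noise level
#'
#' Estimates the standard deviation of the image noise from regions that
#' contain only background.  The image is scanned with a sliding `w` x `w`
#' window; for every pixel whose window lies fully inside the image the
#' window mean and (sample) SD are computed.  Background windows are those
#' whose mean is below the mean of all window means — most of a gel image
#' is background, so low-mean windows are background — and the noise SD is
#' the average of their window SDs.
#'
#' @param image A [gel_image] (or numeric matrix).
#' @param w Window edge length in pixels (>= 2).
#' @param tiled If `TRUE`, use non-overlapping `w` x `w` tiles instead of a
#'   sliding window (coarser but cheaper; the sliding form is the default).
#' @return A list of class `noise_estimate` with `sigma_ns` (noise SD) and
#'   `n_windows_used` (number of background windows averaged; 0 only for a
#'   constant image, where `sigma_ns` is 0).
#' @export
estimate_noise <- function(image, w, tiled = FALSE) {
  image <- as_gel_image(image)
  stopifnot(is.numeric(w), length(w) == 1L, w >= 2)
  w <- as.integer(w)
  if (image$height < w || image$width < w)
    stop("image (", image$height, "x", image$width,
         ") is smaller than the ", w, "x", w, " noise window", call. = FALSE)
  st <- box_window_stats(image$pixels, w)
  mu <- st$mean; sd <- st$sd
  if (tiled) {
    lo <- (w - 1L) %/% 2L
    rows <- seq(lo + 1L, image$height - (w - 1L - lo), by = w)
    cols <- seq(lo + 1L, image$width - (w - 1L - lo), by = w)
    keep <- matrix(FALSE, image$height, image$width)
    keep[rows, cols] <- TRUE
    mu[!keep] <- NA; sd[!keep] <- NA
  }
  ok <- !is.na(mu)
  sel <- ok & (mu < mean(mu[ok]))
  n_used <- sum(sel)
  sigma <- if (n_used > 0L) mean(sd[sel]) else 0
  structure(list(sigma_ns = sigma, n_windows_used = n_used),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma_ns = %.6g (from %d background windows)\n",
              x$sigma_ns, x$n_windows_used))
  invisible(x)
}

#' Restoration kernel
#'
#' The zero-sum kernel combining Gaussian noise suppression with boxcar
#' background subtraction: `K = G - U` on support `[-w, w]^2`, where `G` is
#' a separable 2D Gaussian of standard deviation `sigma_smooth` normalized
#' to unit sum over the support and `U = 1/(2w+1)^2` is the unit-sum boxcar.
#' Because peak detection compares the restored image only to its own
#' dilation (and the intensity threshold uses the original image), any
#' fixed positive rescaling of `K` yields identical detections; the unit
#' Gaussian-sum normalization is used.
#'
#' @param w Kernel half-width in pixels (>= 1).
#' @param sigma_smooth SD of the smoothing Gaussian in pixels (default 2).
#' @return A `(2w+1) x (2w+1)` numeric matrix whose entries sum to zero.
#' @export
restoration_kernel <- function(w, sigma_smooth = 2) {
  stopifnot(w >= 1, sigma_smooth > 0)
  w <- as.integer(w)
  i <- -w:w
  g <- exp(-i^2 / (2 * sigma_smooth^2))
  G <- outer(g, g)
  G <- G / sum(G)
  G - 1 / (2 * w + 1)^2
}

#' Restore a gel image for peak detection
#'
#' Applies the zero-sum restoration kernel (see [restoration_kernel]) in a
#' single convolution pass: Gaussian smoothing suppresses single-pixel
#' noise while the subtracted boxcar average removes the local background.
#' The restored image is used for peak detection only; fitting always uses
#' the original image.
#'
#' @inheritParams estimate_noise
#' @param w Kernel half-width in pixels (>= 1).
#' @param sigma_smooth SD of the smoothing Gaussian (default 2).
#' @param pad Boundary handling, `"reflect"` (default) or `"zero"`.
#' @return A list of class `restored_image` with the `pixels` matrix (same
#'   shape as the input) and the parameters used.
#' @export
restore_image <- function(image, w, sigma_smooth = 2, pad = c("reflect", "zero")) {
  image <- as_gel_image(image)
  pad <- match.arg(pad)
  stopifnot(w >= 1)
  w <- as.integer(w)
  K <- restoration_kernel(w, sigma_smooth)
  structure(
    list(pixels = convolve_kernel(image$pixels, K, pad = pad),
         w = w, sigma_smooth = sigma_smooth, pad = pad),
    class = "restored_image"
  )
}

#' Detect spot peaks
#'
#' A pixel is a peak when it satisfies both conditions:
#'
#' * (a) it is the brightest restored-image pixel within distance `w`:
#'   `A_res(x, y) == A_dil(x, y)` where `A_dil` is the grayscale dilation of
#'   the restored image with a flat disk of radius `w`;
#' * (b) its original intensity exceeds the local noise threshold:
#'   `A(x, y) > mu_w(x, y) + t * sigma_ns`, where `mu_w` is the mean
#'   original intensity over the same disk (center included).
#'
#' If several connected pixels of equal restored value jointly attain the
#' dilated maximum (a plateau), a single peak is emitted at the first
#' plateau pixel in row-major scan order.  `t = 10` works well for real
#' 2-DE images; smaller `t` admits more false positives, larger `t` more
#' false negatives.
#'
#' @inheritParams restore_image
#' @param restored The [restore_image] result computed with the same `w`.
#' @param w Disk radius in pixels (must match the restoration).
#' @param t Threshold factor (default 10).
#' @param noise A `noise_estimate` from [estimate_noise]; alternatively a
#'   single number taken as `sigma_ns`.
#' @return A data frame of class `gel_peaks` with columns `peak_id`, `x`,
#'   `y` (0-based pixel coordinates), `original_intensity` and
#'   `restored_intensity`, sorted by decreasing original intensity.
#' @export
detect_peaks <- function(image, restored, w, noise, t = 10,
                         pad = c("reflect", "zero")) {
  image <- as_gel_image(image)
  pad <- match.arg(pad)
  stopifnot(w >= 1, t > 0)
  w <- as.integer(w)
  if (inherits(restored, "restored_image")) {
    if (!is.null(restored$w) && restored$w != w)
      stop("`restored` was computed with w = ", restored$w,
           " but detection uses w = ", w, call. = FALSE)
    ares <- restored$pixels
  } else ares <- as.matrix(restored)
  if (!identical(dim(ares), dim(image$pixels)))
    stop("restored image dimensions differ from the original", call. = FALSE)
  sigma_ns <- if (inherits(noise, "noise_estimate")) noise$sigma_ns else as.numeric(noise)

  adil <- dilate_disk(ares, w, pad = pad)
  cand <- ares == adil                                   # condition (a)
  muw <- disk_mean(image$pixels, w, pad = pad)
  cand <- cand & (image$pixels > muw + t * sigma_ns)     # condition (b)

  # collapse plateaus: connected candidates with equal restored value emit
  # one peak at the first pixel in row-major (y, then x) order
  if (any(cand)) {
    lab <- label_components(cand)
    nr <- nrow(cand)
    idx <- which(cand)
    keep <- logical(length(idx))
    for (lv in unique(lab[idx])) {
      members <- idx[lab[idx] == lv]
      ys <- (members - 1L) %% nr          # 0-based row
      xs <- (members - 1L) %/% nr         # 0-based col
      same_val <- abs(ares[members] - max(ares[members])) <= 0
      # plateaus have equal values by construction of condition (a) within
      # a component only if the component is one plateau; otherwise each
      # maximal-equal-value subset could be separate peaks.  Components mix
      # values only when distinct peaks are candidates within w of each
      # other, which condition (a) forbids except at exactly equal values,
      # so one representative per component is correct.
      ord <- order(ys, xs)
      first <- members[ord][1L]
      keep[idx == first] <- TRUE
    }
    idx <- idx[keep]
    ys <- (idx - 1L) %% nr
    xs <- (idx - 1L) %/% nr
  } else {
    xs <- integer(0); ys <- integer(0); idx <- integer(0)
  }

  peaks <- data.frame(
    peak_id = seq_along(idx),
    x = as.integer(xs), y = as.integer(ys),
    original_intensity = image$pixels[idx],
    restored_intensity = ares[idx]
  )
  peaks <- peaks[order(-peaks$original_intensity, peaks$y, peaks$x), , drop = FALSE]
  peaks$peak_id <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  class(peaks) <- c("gel_peaks", "data.frame")
  peaks
}
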
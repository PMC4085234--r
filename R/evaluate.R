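#' Signal-ratio deviation alpha
#'
#' Quality measure for two-spot quantification: the percent deviation of
#' the calculated P/Q signal ratio from the true ratio,
#' `alpha = ((signal_P / signal_Q) / (true_P / true_Q) - 1) * 100`.
#' The signed value is returned; aggregations across replicates
#' conventionally use `abs(alpha)`.
#'
#' @param signal_P,signal_Q Measured signals (Q nonzero).
#' @param true_P,true_Q True signals (both nonzero).
#' @return Signed percent deviation.
#' @examples
#' alpha_deviation(1.1, 1, 1, 1)  # 10
#' @export
alpha_deviation <- function(signal_P, signal_Q, true_P, true_Q) {
  if (any(signal_Q == 0) || any(true_Q == 0) || any(true_P == 0))
    stop("alpha is undefined for zero reference signals", call. = FALSE)
  ((signal_P / signal_Q) / (true_P / true_Q) - 1) * 100
}

#' Multi-spot quantification deviation alpha_mean
#'
#' Extension of [alpha_deviation] to fields of several spots: the mean over
#' spots of the absolute percent deviation of each spot's relative signal
#' (its share of the summed signal) from its true relative signal.  Scale
#' invariant: signals proportional to the truths give 0.
#'
#' @param signals Per-spot measured signals (nonnegative, positive sum).
#' @param truths Per-spot true signals (all positive).
#' @return Mean absolute percent deviation of the relative signals.
#' @export
alpha_mean_deviation <- function(signals, truths) {
  stopifnot(length(signals) == length(truths), length(signals) >= 2L)
  if (sum(signals) == 0 || any(truths <= 0))
    stop("alpha_mean is undefined: zero total signal or nonpositive truth",
         call. = FALSE)
  rs <- relative_signals(signals)
  rt <- relative_signals(truths)
  mean(abs(rs / rt - 1)) * 100
}

#' Relative spot signals
#'
#' Each spot's contribution to the summed signal of all spots in an image
#' (the quantity whose stability across an exposure series measures a
#' method's precision).
#'
#' @param signals Nonnegative per-spot signals with positive sum.
#' @return Fractions summing to 1.
#' @export
relative_signals <- function(signals) {
  stopifnot(all(signals >= 0))
  s <- sum(signals)
  if (s <= 0) stop("total signal is zero", call. = FALSE)
  signals / s
}

#' Coefficient of variation across an image series
#'
#' For a series of images of the same blot (e.g. an exposure-time series),
#' computes per spot the CV (sample SD over mean) of its relative signal
#' across the series, and the mean CV over spots.  A sound quantification
#' method yields small CVs because relative signals are invariant under
#' linear exposure scaling.
#'
#' @param series List of per-spot signal vectors, one per image, with the
#'   same length and spot correspondence across images.
#' @return A list of class `series_cv` with `per_spot` CVs and `mean_cv`.
#' @export
cv_across_series <- function(series) {
  stopifnot(length(series) >= 2L)
  lens <- lengths(series)
  if (length(unique(lens)) != 1L)
    stop("images of the series report different spot counts; establish ",
         "spot correspondence first", call. = FALSE)
  rel <- do.call(rbind, lapply(series, relative_signals))
  per_spot <- apply(rel, 2L, function(v) stats::sd(v) / mean(v))
  structure(list(per_spot = per_spot, mean_cv = mean(per_spot)),
            class = "series_cv")
}

#' @export
print.series_cv <- function(x, ...) {
  cat(sprintf("<series_cv> mean CV = %.4g over %d spots\n",
              x$mean_cv, length(x$per_spot)))
  invisible(x)
}

#' Match fitted spots to ground truth
#'
#' Greedy one-to-one nearest-center assignment: detection/truth pairs are
#' linked in order of increasing center distance, each within `radius`
#' pixels.  Unmatched detections are false positives, unmatched truths
#' false negatives.
#'
#' @param detected Data frame with `x0`/`y0` (or `x`/`y`) columns, e.g. a
#'   `spot_fits` table or a `gel_peaks` table.
#' @param truth A `scene_truth` (or a matrix/data frame of true centers
#'   with columns `x`, `y`).
#' @param radius Maximum match distance in pixels (> 0).
#' @return List with `pairs` (data frame `detected_row`, `truth_row`,
#'   `distance`), `false_positive_rows`, `false_negative_rows`, `recall`
#'   and `precision`.
#' @export
match_spots <- function(detected, truth, radius) {
  stopifnot(radius > 0)
  dx <- if (!is.null(detected$x0)) detected$x0 else detected$x
  dy <- if (!is.null(detected$y0)) detected$y0 else detected$y
  centers <- if (inherits(truth, "scene_truth")) truth$centers else as.matrix(truth)
  nd <- length(dx); nt <- nrow(centers)
  if (nd == 0L || nt == 0L) {
    return(list(pairs = data.frame(detected_row = integer(0),
                                   truth_row = integer(0),
                                   distance = numeric(0)),
                false_positive_rows = seq_len(nd),
                false_negative_rows = seq_len(nt),
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_))
  }
  D <- sqrt(outer(dx, centers[, "x"], "-")^2 + outer(dy, centers[, "y"], "-")^2)
  ord <- order(D)
  used_d <- logical(nd); used_t <- logical(nt)
  pairs <- list()
  for (k in ord) {
    if (D[k] > radius) break
    i <- ((k - 1L) %% nd) + 1L
    j <- ((k - 1L) %/% nd) + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(detected_row = i, truth_row = j,
                                              distance = D[k])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(detected_row = integer(0), truth_row = integer(0),
                           distance = numeric(0))
  list(pairs = pairs,
       false_positive_rows = which(!used_d),
       false_negative_rows = which(!used_t),
       recall = nrow(pairs) / nt,
       precision = nrow(pairs) / nd)
}
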
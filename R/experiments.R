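# Simulation experiment drivers used to compare the three quantification
# methods under controlled conditions.  These are thin compositions of the
# simulator, the detection/fitting pipeline and the evaluation metrics.

#' Two-spot method comparison at controlled overlap
#'
#' For each seed, simulates a two-spot scene (P left, Q right), runs the
#' full detection + compounding + fitting pipeline, quantifies both spots
#' with the fit (VUS), optical-density and area-based methods, and records
#' the signed signal-ratio deviation alpha of each method against the
#' simulated truth.  Scenes where detection does not find exactly one peak
#' per true spot are recorded with `NA` alphas (the failure is the
#' result, not an error).
#'
#' @inheritParams simulate_pair
#' @param seeds Integer vector of simulation seeds (one scene per seed).
#' @param w Detection scale; default `floor(ipd / 2)`.
#' @param t Detection threshold factor.
#' @param d Compound edge; default `6 * w`.
#' @param match_radius Peak-to-truth matching radius in pixels.
#' @return Data frame with columns `seed`, `method` (`fit`, `od`, `area`)
#'   and `alpha` (percent, signed).
#' @export
pair_alpha_experiment <- function(shape, I_P, I_Q, width_P, width_Q, ipd,
                                  noise_sd, seeds, w = NULL, t = 10,
                                  d = NULL, match_radius = NULL) {
  if (is.null(w)) w <- compute_w_from_ipd(ipd)
  if (is.null(d)) d <- 6L * w
  if (is.null(match_radius)) match_radius <- max(2, ipd / 3)
  out <- list()
  for (seed in seeds) {
    sc <- simulate_pair(shape, I_P, I_Q, width_P, width_Q, ipd,
                        noise_sd = noise_sd, seed = seed)
    img <- sc$image
    ns <- estimate_noise(img, max(w, 2L))
    pk <- detect_peaks(img, restore_image(img, w), w, ns, t = t)
    al <- c(fit = NA_real_, od = NA_real_, area = NA_real_)
    mt <- match_spots(pk, sc$truth, radius = match_radius)
    if (nrow(pk) == 2L && nrow(mt$pairs) == 2L) {
      ord <- order(mt$pairs$truth_row)           # P first, then Q
      rows <- mt$pairs$detected_row[ord]
      truth_ratio <- sc$truth$true_ratios[1L, 2L]
      cs <- find_compounds(pk, d, c(img$height, img$width))
      bg <- estimate_background(img, cs)
      fits <- fit_spots(img, cs, pk, bg, w = w)
      fr <- fits[match(pk$peak_id[rows], fits$peak_id), ]
      if (all(!fr$discarded) && all(fr$converged))
        al["fit"] <- alpha_deviation(fr$vus[1L], fr$vus[2L], truth_ratio, 1)
      od <- quantify_od(img, pk)$od[rows]
      al["od"] <- alpha_deviation(od[1L], od[2L], truth_ratio, 1)
      thr <- bg$mu_bg + t * ns$sigma_ns
      ar <- suppressWarnings(quantify_area(img, pk, thr))$volumes$volume[rows]
      if (ar[2L] > 0)
        al["area"] <- alpha_deviation(ar[1L], ar[2L], truth_ratio, 1)
    }
    out[[length(out) + 1L]] <- data.frame(
      seed = seed, method = names(al), alpha = unname(al))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multi-spot field method comparison
#'
#' Simulates a field of Gaussian spots, runs the pipeline, and computes the
#' multi-spot deviation `alpha_mean` for the fit, OD and area methods over
#' the spots that were detected and matched to truth.  Fields where fewer
#' than `min_matched` spots are matched yield `NA` (detection failure is
#' part of the result).
#'
#' @inheritParams simulate_field
#' @inheritParams pair_alpha_experiment
#' @return Data frame with columns `seed`, `method`, `alpha_mean`,
#'   `n_matched`, `n_true`.
#' @export
field_alpha_experiment <- function(n_spots, I_range, sigma_range, min_ipd,
                                   dims, noise_sd, seeds, w, t = 10,
                                   d = NULL, match_radius = 3,
                                   min_matched = 2L) {
  if (is.null(d)) d <- 6L * w
  out <- list()
  for (seed in seeds) {
    sc <- simulate_field(n_spots, I_range, sigma_range, min_ipd, dims,
                         noise_sd = noise_sd, seed = seed)
    img <- sc$image
    ns <- estimate_noise(img, max(w, 2L))
    pk <- detect_peaks(img, restore_image(img, w), w, ns, t = t)
    am <- c(fit = NA_real_, od = NA_real_, area = NA_real_)
    n_matched <- 0L
    if (nrow(pk) >= min_matched) {
      mt <- match_spots(pk, sc$truth, radius = match_radius)
      n_matched <- nrow(mt$pairs)
      if (n_matched >= min_matched) {
        rows <- mt$pairs$detected_row
        truths <- sc$truth$true_signals[mt$pairs$truth_row]
        cs <- find_compounds(pk, d, c(img$height, img$width))
        bg <- estimate_background(img, cs)
        fits <- fit_spots(img, cs, pk, bg, w = w)
        fr <- fits[match(pk$peak_id[rows], fits$peak_id), ]
        if (all(!fr$discarded))
          am["fit"] <- alpha_mean_deviation(fr$vus, truths)
        am["od"] <- alpha_mean_deviation(quantify_od(img, pk)$od[rows], truths)
        ar <- suppressWarnings(
          quantify_area(img, pk, bg$mu_bg + t * ns$sigma_ns))
        av <- ar$volumes$volume[rows]
        if (all(av > 0)) am["area"] <- alpha_mean_deviation(av, truths)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      seed = seed, method = names(am), alpha_mean = unname(am),
      n_matched = n_matched, n_true = n_spots)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exposure-series precision experiment
#'
#' Renders one synthetic scene at a series of linear exposure scales,
#' quantifies every image with the fit, OD and area methods, and returns
#' the per-method coefficient of variation of the relative spot signals
#' across the series — the synthetic analogue of re-imaging one blot at
#' several exposure times.  With `saturation_level` set, the top exposures
#' clip, which penalizes methods that rely on peak height.
#'
#' @param scene_spots List of [spot_spec] for the base (1x) exposure.
#' @param dims Image dimensions `c(height, width)`.
#' @param exposures Numeric vector of linear exposure scales.
#' @param noise_sd Noise SD at every exposure (camera noise, not scaled).
#' @param w,t,d Pipeline parameters.
#' @param background Base background level (scaled with exposure).
#' @param saturation_level Optional clipping level applied after scaling.
#' @param seed Base seed; image k uses `seed + k`.
#' @return List with `cv` (data frame `method`, `mean_cv`), `per_spot`
#'   (list of per-method `series_cv` objects) and `n_spots`.
#' @export
exposure_series_experiment <- function(scene_spots, dims, exposures,
                                       noise_sd, w, t = 10, d = NULL,
                                       background = 0,
                                       saturation_level = NULL, seed = 1L) {
  if (is.null(d)) d <- 6L * w
  sigs <- list(fit = list(), od = list(), area = list())
  ref_centers <- cbind(x = vapply(scene_spots, `[[`, 0, "x0"),
                       y = vapply(scene_spots, `[[`, 0, "y0"))
  n_spots <- length(scene_spots)
  for (k in seq_along(exposures)) {
    ex <- exposures[k]
    spots_k <- lapply(scene_spots, function(sp) {
      sp$I <- sp$I * ex; sp
    })
    sc <- render_scene(dims, spots_k, background = background * ex,
                       noise_sd = noise_sd,
                       saturation_level = saturation_level,
                       seed = seed + k)
    img <- sc$image
    ns <- estimate_noise(img, max(w, 2L))
    pk <- detect_peaks(img, restore_image(img, w), w, ns, t = t)
    mt <- match_spots(pk, list(centers = ref_centers) |>
                        structure(class = "scene_truth"),
                      radius = 3)
    if (nrow(mt$pairs) != n_spots)
      stop("exposure ", ex, ": only ", nrow(mt$pairs), " of ", n_spots,
           " spots detected; adjust the scene", call. = FALSE)
    ord <- order(mt$pairs$truth_row)
    rows <- mt$pairs$detected_row[ord]
    cs <- find_compounds(pk, d, c(img$height, img$width))
    bg <- estimate_background(img, cs)
    fits <- fit_spots(img, cs, pk, bg, w = w)
    fr <- fits[match(pk$peak_id[rows], fits$peak_id), ]
    sigs$fit[[k]] <- fr$vus
    sigs$od[[k]] <- quantify_od(img, pk)$od[rows]
    ar <- suppressWarnings(
      quantify_area(img, pk, bg$mu_bg + t * ns$sigma_ns))
    sigs$area[[k]] <- ar$volumes$volume[rows]
  }
  per_spot <- lapply(sigs, cv_across_series)
  list(cv = data.frame(method = names(per_spot),
                       mean_cv = vapply(per_spot, `[[`, 0, "mean_cv")),
       per_spot = per_spot, n_spots = n_spots)
}
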
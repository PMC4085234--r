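#' Read a grayscale gel image
#'
#' Loads an 8- or 16-bit single-channel TIFF or PNG into floating point
#' without rescaling: pixel values are the integer sample values of the
#' file.  Multi-channel images are rejected.  When at least 0.5% of the
#' pixels sit exactly at the dtype maximum, that maximum is recorded as the
#' image's `saturation_level`.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A [gel_image].
#' @export
read_gel_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
    bits <- attr(m, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(m) > 255) 16L else 8L
  } else if (ext == "png") {
    m <- png::readPNG(path, info = TRUE)
    info <- attr(m, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    dm <- dim(m)
    m <- round(m * (2^bits - 1))  # readPNG rescales to [0,1]; undo losslessly
    m <- array(as.numeric(m), dm) # drop the reader's info attribute
  } else {
    stop("unsupported image format '", ext, "'; supply 8/16-bit grayscale ",
         "TIFF or PNG", call. = FALSE)
  }
  if (length(dim(m)) == 3L) {
    if (dim(m)[3L] == 1L) m <- m[, , 1L]
    else stop("multi-channel image (", dim(m)[3L], " channels); convert to ",
              "single-channel grayscale first", call. = FALSE)
  }
  dtype_max <- 2^bits - 1
  frac_at_max <- mean(m == dtype_max)
  gel_image(m, saturation_level = if (frac_at_max >= 0.005) dtype_max else NULL)
}

#' Write a gel image
#'
#' Writes a 16-bit grayscale TIFF or PNG.  Values are stored as-is when
#' they already fit `[0, 65535]`; `scale` can map other ranges.
#'
#' @param image A [gel_image] or numeric matrix.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @param scale Multiplier applied before writing (default 1).
#' @return `path`, invisibly.
#' @export
write_gel_image <- function(image, path, scale = 1) {
  image <- as_gel_image(image)
  m <- pmin(pmax(image$pixels * scale, 0), 65535) / 65535
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  else if (ext == "png")
    png::writePNG(m, path)
  else stop("unsupported output format '", ext, "'", call. = FALSE)
  invisible(path)
}

# numeric CSV writers with a fixed dialect: comma separator, '.' decimal,
# header row, UTF-8, 9 significant digits (round-trip safe for the fields
# we store)
write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read detected peaks
#'
#' `peaks.csv` columns: `peak_id`, `x`, `y`, `original_intensity`,
#' `restored_intensity` (0-based coordinates).
#'
#' @param peaks A `gel_peaks` data frame.
#' @param path Output CSV path.
#' @return The path (write) or the peaks data frame (read).
#' @export
write_peaks_csv <- function(peaks, path) write_table_csv(peaks, path)

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("gel_peaks", "data.frame")
  df
}

#' Write compounds table and mask sidecar
#'
#' `compounds.csv` columns: `compound_id`, `peak_id`, `x`, `y`; the pixel
#' masks go to a sidecar JSON as run-length-encoded rows for debugging.
#'
#' @param compounds A `compound_set`.
#' @param peaks The matching `gel_peaks`.
#' @param path Output CSV path; the sidecar is `<path>.masks.json`.
#' @export
write_compounds_csv <- function(compounds, peaks, path) {
  tab <- do.call(rbind, lapply(compounds, function(cc)
    data.frame(compound_id = cc$compound_id, peak_id = cc$peak_ids,
               x = peaks$x[cc$peak_rows], y = peaks$y[cc$peak_rows])))
  write_table_csv(tab, path)
  rle_masks <- lapply(compounds, function(cc) {
    sp <- split(cc$mask[, "x"], cc$mask[, "y"])
    lapply(names(sp), function(yy) {
      xs <- sort(sp[[yy]])
      breaks <- c(0L, which(diff(xs) != 1L), length(xs))
      runs <- lapply(seq_len(length(breaks) - 1L), function(i)
        c(xs[breaks[i] + 1L], xs[breaks[i + 1L]]))
      list(y = as.integer(yy), runs = runs)
    })
  })
  jsonlite::write_json(rle_masks, paste0(path, ".masks.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write / read fitted spots
#'
#' `spots.csv` columns: `spot_id`, `compound_id`, `peak_id`, `x0`, `y0`,
#' `I`, `sigma`, `vus`, `mu_bg`, `converged`, `discarded`,
#' `residual_norm`.  Numeric fields are stored at 9 significant digits so
#' a write/read round trip reproduces them exactly.
#'
#' @param fits A `spot_fits` data frame.
#' @param path Output CSV path.
#' @export
write_spots_csv <- function(fits, path) write_table_csv(fits, path)

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("spot_fits", "data.frame")
  df
}

#' Run the full detection-and-quantification pipeline
#'
#' Executes, in order: noise estimation, image restoration, peak
#' detection, compound determination, background estimation, compound
#' fitting, false-positive flagging.  Optionally also runs the OD and
#' area-based comparator quantifications on the detected peaks, and writes
#' all tables plus model and residual images to `out_dir`.
#'
#' @inheritParams estimate_noise
#' @param ipd Inter-peak distance for [compute_w_from_ipd]; give either
#'   `ipd` or `w`, not both.
#' @param w Detection scale in pixels.
#' @param t Detection threshold factor (default 10).
#' @param d Compound edge length; default `6 * w`.
#' @param fit_background Co-fit the background per compound instead of
#'   holding it fixed.
#' @param comparators Also compute `od` and/or `area` signals.
#' @param area_threshold Threshold for the area method, or `"auto"` for
#'   `mu_bg + t * sigma_ns`.
#' @param out_dir Optional output directory for CSV/TIFF artifacts.
#' @param verbose Log one line per stage.
#' @return A list of class `gelspot_run` with `noise`, `restored`,
#'   `peaks`, `compounds`, `background`, `fits`, `signals` (long table:
#'   `peak_id`, `method`, `signal`), and the parameters used.
#' @export
run_pipeline <- function(image, ipd = NULL, w = NULL, t = 10, d = NULL,
                         fit_background = FALSE,
                         comparators = c("od", "area"),
                         area_threshold = "auto",
                         out_dir = NULL, verbose = FALSE) {
  image <- as_gel_image(image)
  if (is.null(w) == is.null(ipd))
    stop("give exactly one of `ipd` or `w`", call. = FALSE)
  if (is.null(w)) w <- compute_w_from_ipd(ipd)
  w <- as.integer(w)
  stopifnot(w >= 1, t > 0)
  if (is.null(d)) d <- 6L * w
  say <- function(...) if (verbose) message(sprintf(...))

  noise <- estimate_noise(image, max(w, 2L))
  say("noise: sigma_ns = %.4g (%d windows)", noise$sigma_ns, noise$n_windows_used)
  restored <- restore_image(image, w)
  peaks <- detect_peaks(image, restored, w, noise, t = t)
  say("detection: %d peaks (w = %d, t = %g)", nrow(peaks), w, t)

  if (nrow(peaks) == 0L) {
    empty_fits <- data.frame(spot_id = integer(0), peak_id = integer(0),
                             compound_id = integer(0), x0 = numeric(0),
                             y0 = numeric(0), I = numeric(0),
                             sigma = numeric(0), vus = numeric(0),
                             mu_bg = numeric(0), converged = logical(0),
                             discarded = logical(0), residual_norm = numeric(0))
    res <- structure(list(noise = noise, restored = restored, peaks = peaks,
                          compounds = structure(list(), class = "compound_set",
                                                image_shape = c(image$height, image$width),
                                                d = as.integer(d)),
                          background = estimate_background(image, NULL),
                          fits = empty_fits,
                          signals = data.frame(peak_id = integer(0),
                                               method = character(0),
                                               signal = numeric(0)),
                          params = list(w = w, t = t, d = d)),
                     class = "gelspot_run")
    return(res)
  }

  compounds <- find_compounds(peaks, d, c(image$height, image$width))
  say("compounding: %d compounds (d = %d)", length(compounds), d)
  bg <- estimate_background(image, compounds)
  say("background: mu_bg = %.4g (%d pixels)", bg$mu_bg, bg$n_pixels_used)
  fits <- fit_spots(image, compounds, peaks, bg, w = w,
                    fit_background = fit_background)
  say("fit: %d spots, %d discarded, %d non-converged", nrow(fits),
      sum(fits$discarded), sum(!fits$converged))

  signals <- data.frame(peak_id = fits$peak_id, method = "fit",
                        signal = fits$vus)
  if ("od" %in% comparators) {
    od <- quantify_od(image, peaks)
    signals <- rbind(signals, data.frame(peak_id = od$peak_id, method = "od",
                                         signal = od$od))
  }
  if ("area" %in% comparators) {
    thr <- if (identical(area_threshold, "auto"))
      bg$mu_bg + t * noise$sigma_ns else as.numeric(area_threshold)
    ar <- quantify_area(image, peaks, thr)
    signals <- rbind(signals, data.frame(peak_id = ar$volumes$peak_id,
                                         method = "area",
                                         signal = ar$volumes$volume))
  }

  res <- structure(
    list(noise = noise, restored = restored, peaks = peaks,
         compounds = compounds, background = bg, fits = fits,
         signals = signals, params = list(w = w, t = t, d = d)),
    class = "gelspot_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_peaks_csv(peaks, file.path(out_dir, "peaks.csv"))
    write_compounds_csv(compounds, peaks, file.path(out_dir, "compounds.csv"))
    write_spots_csv(fits, file.path(out_dir, "spots.csv"))
    write_table_csv(signals, file.path(out_dir, "signals.csv"))
    model <- render_model_image(fits, c(image$height, image$width),
                                mu_bg = bg$mu_bg)
    write_gel_image(gel_image(model), file.path(out_dir, "model.tif"))
    write_gel_image(gel_image(image$pixels - model + bg$mu_bg),
                    file.path(out_dir, "residual.tif"))
    say("wrote artifacts to %s", out_dir)
  }
  res
}

#' @export
print.gelspot_run <- function(x, ...) {
  cat(sprintf(paste0("<gelspot_run> w = %d, t = %g, d = %d | %d peaks, ",
                     "%d compounds, %d spots (%d discarded)\n"),
              x$params$w, x$params$t, x$params$d, nrow(x$peaks),
              length(x$compounds), nrow(x$fits), sum(x$fits$discarded)))
  invisible(x)
}
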
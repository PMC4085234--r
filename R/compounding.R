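#' Peak adjacency matrix
#'
#' Two peaks belong to the same fitting compound when their compound
#' squares would overlap, i.e. when `|x_i - x_j| <= d` and
#' `|y_i - y_j| <= d` (both inclusive).  The first-order adjacency matrix
#' has entry 1 for such pairs (all diagonal entries are 1) and 0 otherwise.
#'
#' @param peaks A `gel_peaks` data frame (columns `x`, `y`).
#' @param d Compound-square edge length in pixels (>= 1).
#' @return An `N x N` symmetric binary matrix.
#' @export
build_adjacency <- function(peaks, d) {
  stopifnot(nrow(peaks) >= 1L, d >= 1)
  dx <- abs(outer(peaks$x, peaks$x, "-"))
  dy <- abs(outer(peaks$y, peaks$y, "-"))
  (dx <= d & dy <= d) * 1L
}

#' Transitive closure of a binary adjacency matrix
#'
#' Repeatedly squares the matrix and re-binarizes (entries `>= 1` become 1)
#' until a fixpoint is reached.  Each squaring doubles the connection path
#' length considered, so the fixpoint — reached in at most
#' `ceiling(log2(N)) + 1` iterations — is the reachability matrix of the
#' adjacency graph: entry `(P, Q)` is 1 exactly when P and Q are connected,
#' possibly via intermediate peaks.
#'
#' @param adj Binary symmetric matrix with unit diagonal.
#' @return The reachability matrix (same shape, binary).
#' @export
transitive_closure <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  m <- (adj != 0) * 1
  if (any(diag(m) != 1)) stop("adjacency matrix must have unit diagonal", call. = FALSE)
  repeat {
    m2 <- (m %*% m >= 1) * 1
    if (identical(m2, m)) break
    m <- m2
  }
  storage.mode(m) <- "integer"
  m
}

#' Extract fitting compounds and their pixel masks
#'
#' Reads the connected components out of the closed adjacency matrix and
#' builds each compound's pixel mask as the union of axis-aligned squares
#' of edge length `d` centered on its member peaks, clipped to the image.
#' For even `d` the square spans `floor(d/2)` pixels up/left and
#' `d - 1 - floor(d/2)` down/right of the peak (odd `d` recommended).
#' Because peaks in different compounds differ by more than `d` in x or y,
#' masks of distinct compounds are guaranteed disjoint; this is verified
#' and violations raise an internal consistency error.
#'
#' @param closure Reachability matrix from [transitive_closure].
#' @param peaks The `gel_peaks` data frame the matrix was built from.
#' @param d Compound-square edge length in pixels.
#' @param image_shape Integer vector `c(height, width)` used for clipping.
#' @return A list of class `compound_set`; each element has `compound_id`,
#'   `peak_ids` (values of `peaks$peak_id`), `peak_rows` (row indices into
#'   `peaks`), and `mask`, a two-column integer matrix of 0-based `(x, y)`
#'   pixel coordinates.
#' @export
extract_compounds <- function(closure, peaks, d, image_shape) {
  stopifnot(nrow(closure) == nrow(peaks), d >= 1, length(image_shape) == 2L)
  h <- as.integer(image_shape[1L]); wid <- as.integer(image_shape[2L])
  n <- nrow(peaks)
  # identical closure rows <=> same component
  comp <- match(apply(closure, 1L, paste, collapse = ""),
                unique(apply(closure, 1L, paste, collapse = "")))
  lo <- (as.integer(d)) %/% 2L          # pixels up/left of the peak
  hi <- as.integer(d) - 1L - lo         # pixels down/right
  compounds <- vector("list", max(comp))
  seen <- matrix(FALSE, h, wid)
  for (ci in seq_len(max(comp))) {
    rows <- which(comp == ci)
    px <- NULL
    for (r in rows) {
      xs <- max(0L, peaks$x[r] - lo):min(wid - 1L, peaks$x[r] + hi)
      ys <- max(0L, peaks$y[r] - lo):min(h - 1L, peaks$y[r] + hi)
      px <- rbind(px, as.matrix(expand.grid(x = xs, y = ys)))
    }
    px <- unique(px)
    lin <- px[, "y"] + 1L + px[, "x"] * h
    if (any(seen[lin]))
      stop("internal consistency error: compound masks overlap ",
           "(fusion rule violated)", call. = FALSE)
    seen[lin] <- TRUE
    compounds[[ci]] <- list(
      compound_id = ci,
      peak_ids = peaks$peak_id[rows],
      peak_rows = rows,
      mask = px
    )
  }
  structure(compounds, class = "compound_set",
            image_shape = c(h, wid), d = as.integer(d))
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds, %d peaks, d = %d\n",
              length(x), sum(vapply(x, function(cc) length(cc$peak_ids), 1L)),
              attr(x, "d")))
  invisible(x)
}

#' Group peaks into fitting compounds
#'
#' Convenience wrapper: adjacency matrix, transitive closure by matrix
#' squaring, then compound extraction.  The default `d = 6 * w` assumes the
#' spot width sigma stays below `w`, so a +/- 3 sigma support captures
#' essentially the whole spot volume.
#'
#' @inheritParams build_adjacency
#' @inheritParams extract_compounds
#' @return A `compound_set` (see [extract_compounds]).
#' @export
find_compounds <- function(peaks, d, image_shape) {
  adj <- build_adjacency(peaks, d)
  extract_compounds(transitive_closure(adj), peaks, d, image_shape)
}

# logical mask matrix (TRUE inside any compound area)
compound_mask_matrix <- function(compounds, image_shape = attr(compounds, "image_shape")) {
  m <- matrix(FALSE, image_shape[1L], image_shape[2L])
  for (cc in compounds) m[cc$mask[, "y"] + 1L + cc$mask[, "x"] * image_shape[1L]] <- TRUE
  m
}
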
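# Low-level raster operations: padding, disk neighborhoods, sliding-window
# statistics.  All operate on plain matrices; callers handle the gel_image
# wrapper.  These are deliberately vectorized base R: each neighborhood
# offset touches the full matrix at once, so cost is O(|offsets|) vector ops.

# Pad a matrix by r pixels on every side.  "reflect" repeats the edge row
# mirror-wise (… c b a | a b c …), which keeps output size downstream and
# avoids edge artifacts; "zero" pads with 0.  r may exceed the image size
# for reflect only when the image is larger than 1 px per side repetition,
# so we guard by recycling reflections as needed.
pad_matrix <- function(m, r, method = c("reflect", "zero")) {
  method <- match.arg(method)
  nr <- nrow(m); nc <- ncol(m)
  if (method == "zero") {
    out <- matrix(0, nr + 2L * r, nc + 2L * r)
    out[r + seq_len(nr), r + seq_len(nc)] <- m
    return(out)
  }
  reflect_idx <- function(n, r) {
    # index sequence of length n + 2r implementing mirrored extension
    idx <- seq.int(1L - r, n + r)
    # fold into [1, n] by repeated reflection (period 2n)
    idx <- (idx - 1L) %% (2L * n)
    idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx)
    idx + 1L
  }
  m[reflect_idx(nr, r), reflect_idx(nc, r), drop = FALSE]
}

# Integer offsets (dx, dy) with dx^2 + dy^2 <= w^2 (the flat disk used as
# structuring element and averaging window).
disk_offsets <- function(w) {
  g <- expand.grid(dx = -w:w, dy = -w:w)
  g[g$dx^2 + g$dy^2 <= w^2, , drop = FALSE]
}

# Grayscale dilation with a flat disk of radius w: per-pixel maximum over
# the disk neighborhood, boundary per `pad`.
dilate_disk <- function(m, w, pad = "reflect") {
  p <- pad_matrix(m, w, pad)
  off <- disk_offsets(w)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    out <- pmax(out, p[w + off$dy[k] + seq_len(nr), w + off$dx[k] + seq_len(nc)])
  }
  out
}

# Per-pixel mean over the flat disk of radius w (center included).
disk_mean <- function(m, w, pad = "reflect") {
  p <- pad_matrix(m, w, pad)
  off <- disk_offsets(w)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (k in seq_len(nrow(off))) {
    acc <- acc + p[w + off$dy[k] + seq_len(nr), w + off$dx[k] + seq_len(nc)]
  }
  acc / nrow(off)
}

# 2D convolution with an arbitrary (2w+1)x(2w+1) kernel, same-size output,
# boundary per `pad`.  Direct shift-accumulate; the kernel is applied as a
# correlation, which for the symmetric restoration kernel equals convolution.
convolve_kernel <- function(m, kernel, pad = "reflect") {
  w <- (nrow(kernel) - 1L) %/% 2L
  stopifnot(nrow(kernel) == 2L * w + 1L, ncol(kernel) == 2L * w + 1L)
  p <- pad_matrix(m, w, pad)
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (j in seq_len(2L * w + 1L)) {
    dx <- j - w - 1L
    for (i in seq_len(2L * w + 1L)) {
      kv <- kernel[i, j]
      if (kv == 0) next
      dy <- i - w - 1L
      acc <- acc + kv * p[w + dy + seq_len(nr), w + dx + seq_len(nc)]
    }
  }
  acc
}

# Sliding w x w window mean and (sample) SD for every pixel whose window
# lies fully inside the image, via summed-area tables.  For even w the
# window extends floor((w-1)/2) up/left of the center.  Returns matrices
# with NA outside the valid region.
box_window_stats <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < w || nc < w) stop("image smaller than the ", w, "x", w, " window", call. = FALSE)
  sat  <- function(x) {
    s <- apply(x, 2L, cumsum)
    t(apply(s, 1L, cumsum))
  }
  S1 <- sat(m); S2 <- sat(m * m)
  # window sums over i..i+w-1, j..j+w-1 from zero-padded tables
  Z1 <- rbind(0, cbind(0, S1)); Z2 <- rbind(0, cbind(0, S2))
  i2 <- w:nr; i1 <- i2 - w; j2 <- w:nc; j1 <- j2 - w
  sum1 <- Z1[i2 + 1L, j2 + 1L, drop = FALSE] - Z1[i1 + 1L, j2 + 1L, drop = FALSE] -
    Z1[i2 + 1L, j1 + 1L, drop = FALSE] + Z1[i1 + 1L, j1 + 1L, drop = FALSE]
  sum2 <- Z2[i2 + 1L, j2 + 1L, drop = FALSE] - Z2[i1 + 1L, j2 + 1L, drop = FALSE] -
    Z2[i2 + 1L, j1 + 1L, drop = FALSE] + Z2[i1 + 1L, j1 + 1L, drop = FALSE]
  n <- w * w
  mu <- sum1 / n
  var <- pmax(0, (sum2 - n * mu^2) / (n - 1))
  sd <- sqrt(var)
  # place at window centers
  lo <- (w - 1L) %/% 2L
  mu_full <- matrix(NA_real_, nr, nc)
  sd_full <- matrix(NA_real_, nr, nc)
  rows <- lo + seq_len(nr - w + 1L); cols <- lo + seq_len(nc - w + 1L)
  mu_full[rows, cols] <- mu
  sd_full[rows, cols] <- sd
  list(mean = mu_full, sd = sd_full)
}

# 8-connected component labelling of a logical matrix by frontier BFS.
# Returns an integer matrix with 0 for background, 1..k for components.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  next_lab <- 0L
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  # row index per linear index, for wrap-around guards at column edges
  row_of <- function(idx) ((idx - 1L) %% nr) + 1L
  seen <- matrix(FALSE, nr, nc)
  seen[!mask] <- TRUE
  for (s in todo) {
    if (seen[s]) next
    next_lab <- next_lab + 1L
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      lab[frontier] <- next_lab
      r0 <- row_of(frontier)
      cand <- rep(frontier, each = 8L) + rep(off, times = length(frontier))
      # row deltas matching `off`, guarding against column wrap-around
      rr <- rep(r0, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L),
                                     times = length(frontier))
      ok <- cand >= 1L & cand <= nr * nc & rr >= 1L & rr <= nr
      cand <- unique(cand[ok])
      cand <- cand[!seen[cand]]
      seen[cand] <- TRUE
      frontier <- cand
    }
  }
  lab
}
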
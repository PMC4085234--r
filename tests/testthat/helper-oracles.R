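# Independent oracles used across the suite.  These deliberately re-derive
# results by brute force / traversal, never by calling the production path.

# connected components of a binary adjacency matrix by breadth-first search
bfs_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE] != 0) > 0)
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# mirror-extension index used by the package's reflect padding, re-derived
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# brute-force condition (a): pixel is candidate iff its value attains the
# maximum over the flat disk of radius w under mirrored boundary extension
brute_disk_candidates <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  off <- expand.grid(dy = -w:w, dx = -w:w)
  off <- off[off$dx^2 + off$dy^2 <= w^2, ]
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    vals <- m[cbind(reflect_index(y + off$dy, nr), reflect_index(x + off$dx, nc))]
    out[y, x] <- m[y, x] >= max(vals)
  }
  out
}

# numerical volume of a rendered circular Gaussian over a +/- half_width
# grid centered on (x0, y0)
quadrature_vus <- function(I, sigma, half_width = 8 * sigma) {
  g <- seq(-ceiling(half_width), ceiling(half_width))
  sum(I * exp(-0.5 * outer(g^2, g^2, "+") / sigma^2))
}

# all permutations of 1..n (tiny n only)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))))
}

# optimal one-to-one matching (min total distance, pairs within radius) by
# exhaustive search; returns the set of matched (det, truth) pairs
exhaustive_match <- function(dx, dy, tx, ty, radius) {
  nd <- length(dx); nt <- length(tx)
  D <- sqrt(outer(dx, tx, "-")^2 + outer(dy, ty, "-")^2)
  n <- min(nd, nt)
  best <- NULL; best_cost <- Inf; best_size <- -1L
  det_sets <- utils::combn(nd, n, simplify = FALSE)
  tr_sets <- utils::combn(nt, n, simplify = FALSE)
  for (ds in det_sets) for (ts in tr_sets) {
    pm <- perms(n)
    for (r in seq_len(nrow(pm))) {
      dd <- D[cbind(ds, ts[pm[r, ]])]
      ok <- dd <= radius
      size <- sum(ok)
      cost <- sum(dd[ok])
      if (size > best_size || (size == best_size && cost < best_cost)) {
        best_size <- size; best_cost <- cost
        best <- cbind(det = ds[ok], truth = ts[pm[r, ]][ok])
      }
    }
  }
  best[order(best[, 1L]), , drop = FALSE]
}

# mirror of the CSV writers' numeric formatting (9 significant digits)
signif_if_num <- function(v) {
  if (is.numeric(v) && !is.integer(v)) signif(v, 9) else v
}

# a quick noiseless Gaussian-spot matrix rendered directly (independent of
# the package simulator)
render_gaussians <- function(dims, centers, I, sigma, background = 0) {
  h <- dims[1L]; w <- dims[2L]
  xs <- rep(0:(w - 1L), each = h)
  ys <- rep.int(0:(h - 1L), w)
  acc <- rep(background, h * w)
  for (i in seq_len(nrow(centers)))
    acc <- acc + I[i] * exp(-0.5 * ((xs - centers[i, 1L])^2 +
                                    (ys - centers[i, 2L])^2) / sigma[i]^2)
  matrix(acc, h, w)
}
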
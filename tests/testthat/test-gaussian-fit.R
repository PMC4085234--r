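# helper: run detection + compounding + fit on a matrix with known w/d
fit_image <- function(m, w, t = 10, d = 6L * w, sat = NULL) {
  img <- gel_image(m, saturation_level = sat)
  ns <- estimate_noise(img, max(w, 2L))
  pk <- detect_peaks(img, restore_image(img, w), w, ns, t = t)
  cs <- find_compounds(pk, d, c(img$height, img$width))
  bg <- estimate_background(img, cs)
  list(fits = fit_spots(img, cs, pk, bg, w = w), peaks = pk, bg = bg)
}

test_that("background estimation averages pixels outside all compounds", {
  expect_equal(estimate_background(matrix(42, 30, 30), NULL)$mu_bg, 42)

  m <- matrix(42, 50, 50)
  pk <- structure(data.frame(peak_id = 1L, x = 25L, y = 25L,
                             original_intensity = 42,
                             restored_intensity = 0),
                  class = c("gel_peaks", "data.frame"))
  cs <- find_compounds(pk, 11, c(50, 50))
  bg <- estimate_background(m, cs)
  expect_equal(bg$mu_bg, 42)
  expect_identical(bg$n_pixels_used, 2500L - 121L)

  # spots fully inside masks: mu_bg ~ flat level within the noise SE
  withr::with_seed(91, {
    m <- render_gaussians(c(80, 80), rbind(c(30, 30), c(55, 50)),
                          I = c(800, 500), sigma = c(3, 3), background = 10) +
      matrix(rnorm(6400, 0, 1), 80, 80)
  })
  r <- fit_image(m, w = 6)
  expect_lt(abs(r$bg$mu_bg - 10), 3 / sqrt(r$bg$n_pixels_used) * 3 + 0.05)

  # full coverage is an error telling the user to shrink d
  expect_error(estimate_background(matrix(1, 20, 20),
                                   find_compounds(pk, 60, c(20, 20))),
               "reduce d")
})

test_that("a noiseless rendered Gaussian is recovered to 1e-3", {
  m <- render_gaussians(c(101, 101), cbind(50, 50), I = 100, sigma = 4,
                        background = 10)
  r <- fit_image(m, w = 8, d = 48L)
  expect_identical(nrow(r$fits), 1L)
  f <- r$fits[1, ]
  expect_lt(abs(f$x0 - 50), 1e-3)
  expect_lt(abs(f$y0 - 50), 1e-3)
  expect_lt(abs(f$I - 100) / 100, 1e-3)
  expect_lt(abs(f$sigma - 4) / 4, 1e-3)
  expect_false(f$discarded)
  expect_true(f$converged)
})

test_that("exact recovery holds across sigma and two decades of intensity", {
  for (sigma in c(2, 3, 5, 8)) {
    for (I in c(10, 100, 1000)) {
      side <- 2L * as.integer(ceiling(6 * sigma)) + 41L
      cc <- (side - 1) / 2
      m <- render_gaussians(c(side, side), cbind(cc, cc), I = I,
                            sigma = sigma, background = 5)
      w <- max(2L, as.integer(ceiling(sigma)))
      # mask must reach ~6 sigma so the tail outside it cannot bias mu_bg
      r <- fit_image(m, w = w, d = max(6L * w, as.integer(ceiling(12 * sigma))))
      expect_identical(nrow(r$fits), 1L)
      f <- r$fits[1, ]
      expect_lt(abs(f$I - I) / I, 1e-6)
      expect_lt(abs(f$sigma - sigma) / sigma, 1e-6)
      expect_lt(abs(f$x0 - cc), 1e-5)
      expect_lt(abs(f$y0 - cc), 1e-5)
    }
  }
})

test_that("overlapping pair amplitudes are recovered within 2% (median)", {
  # heavily merged pair (IPD = 2 sigma, amplitude ratio 100:60): quantify
  # from seeded peak positions, as when peaks come from a seed list
  errs_P <- c(); errs_Q <- c()
  for (s in 1:20) {
    sc <- simulate_pair("gaussian", I_P = 100, I_Q = 60, width_P = 4,
                        width_Q = 4, ipd = 8, noise_sd = 1, seed = 900 + s)
    img <- sc$image
    ctr <- round(sc$truth$centers)
    pk <- structure(data.frame(
      peak_id = 1:2, x = as.integer(ctr[, "x"]), y = as.integer(ctr[, "y"]),
      original_intensity = img$pixels[cbind(ctr[, "y"] + 1L, ctr[, "x"] + 1L)],
      restored_intensity = NA_real_), class = c("gel_peaks", "data.frame"))
    cs <- find_compounds(pk, 32L, c(img$height, img$width))
    bg <- estimate_background(img, cs)
    f <- fit_spots(img, cs, pk, bg, w = 4L)
    f <- f[order(f$x0), ]
    errs_P <- c(errs_P, abs(f$I[1] - 100) / 100)
    errs_Q <- c(errs_Q, abs(f$I[2] - 60) / 60)
  }
  expect_lt(median(errs_P), 0.02)
  expect_lt(median(errs_Q), 0.02)
})

test_that("VUS matches the closed form and a quadrature oracle", {
  expect_equal(compute_vus(1, 1), 2 * pi)
  expect_equal(compute_vus(0, 3), 0)
  expect_equal(compute_vus(2, 3), 36 * pi)
  expect_lt(abs(compute_vus(2, 3) - quadrature_vus(2, 3)) / (36 * pi), 1e-3)
  for (sigma in c(2, 5, 8)) {
    v <- compute_vus(7, sigma)
    expect_lt(abs(v - quadrature_vus(7, sigma)) / v, 0.005)
  }
  expect_error(compute_vus(1, 0), "positive")
})

test_that("single-pixel impulses fit with sigma <= 1 and are flagged", {
  withr::with_seed(95, {
    m <- render_gaussians(c(80, 80), cbind(25, 40), I = 500, sigma = 3,
                          background = 10) + matrix(rnorm(6400, 0, 1), 80, 80)
  })
  m[41, 61] <- m[41, 61] + 800          # impulse at (x=60, y=40)
  r <- fit_image(m, w = 4)
  imp <- r$fits[abs(r$fits$x0 - 60) < 3 & abs(r$fits$y0 - 40) < 3, ]
  expect_identical(nrow(imp), 1L)
  expect_lte(imp$sigma, 1)
  expect_true(imp$discarded)
  spot <- r$fits[abs(r$fits$x0 - 25) < 3, ]
  expect_false(spot$discarded)
})

test_that("the discard rule flags sigma <= 1 inclusively and keeps rows", {
  fits <- data.frame(sigma = c(0.3, 1.0, 1.01, 4), discarded = FALSE)
  out <- discard_false_positives(fits)
  expect_identical(out$discarded, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(nrow(out), 4L)
})

test_that("fits are invariant to a constant background shift", {
  m <- render_gaussians(c(81, 81), cbind(40, 40), I = 200, sigma = 5,
                        background = 0)
  base <- fit_image(m + 10, w = 6, d = 40L)$fits
  shifted <- fit_image(m + 110, w = 6, d = 40L)$fits
  for (col in c("x0", "y0", "I", "sigma"))
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-6)
})

test_that("saturated pixels are censored from the fit residuals", {
  m <- render_gaussians(c(81, 81), cbind(40, 40), I = 200, sigma = 5,
                        background = 10)
  sat <- 150
  mc <- pmin(m, sat)
  r <- fit_image(mc, w = 6, d = 40L, sat = sat)
  # the clipped crown is excluded, so the flanks still identify the truth
  expect_lt(abs(r$fits$I[1] - 200) / 200, 0.01)
  expect_lt(abs(r$fits$sigma[1] - 5) / 5, 0.01)
})

test_that("model image rendering reproduces the fitted surface", {
  m <- render_gaussians(c(61, 61), cbind(30, 30), I = 150, sigma = 4,
                        background = 20)
  r <- fit_image(m, w = 6, d = 36L)
  model <- render_model_image(r$fits, c(61, 61))
  expect_equal(model, m, tolerance = 1e-4)
})
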
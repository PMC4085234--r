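mk_peaks <- function(x, y, img) {
  structure(data.frame(peak_id = seq_along(x), x = as.integer(x),
                       y = as.integer(y),
                       original_intensity = img[cbind(y + 1L, x + 1L)],
                       restored_intensity = NA_real_),
            class = c("gel_peaks", "data.frame"))
}

test_that("optical density is the peak-pixel intensity", {
  m <- render_gaussians(c(61, 61), cbind(30, 30), I = 100, sigma = 4)
  pk <- mk_peaks(30, 30, m)
  expect_equal(quantify_od(m, pk)$od, 100)

  # two spots of heights 100 and 50: background-subtracted OD ratio is 2
  m <- render_gaussians(c(61, 121), rbind(c(30, 30), c(90, 30)),
                        I = c(100, 50), sigma = c(4, 4), background = 7)
  pk <- mk_peaks(c(30, 90), c(30, 30), m)
  od <- quantify_od(m, pk, subtract_background = TRUE, mu_bg = 7)$od
  expect_equal(od[1] / od[2], 2, tolerance = 1e-6)

  # clipping: both saturated peaks report the saturation threshold
  msat <- pmin(m * 8, 255)
  pk <- mk_peaks(c(30, 90), c(30, 30), msat)
  expect_equal(quantify_od(gel_image(msat, saturation_level = 255), pk)$od,
               c(255, 255))
})

test_that("line profiles follow the image by bilinear interpolation", {
  # image constant along columns: horizontal profile = the row values
  m <- matrix(rep(1:30, each = 20), 20, 30, byrow = FALSE)
  m <- t(m)[rep(1, 20), ]   # row vector repeated: constant down columns
  m <- matrix(rep(seq_len(30), each = 20), nrow = 20)
  prof <- line_profile(m, c(2, 10), c(27, 10))
  expect_equal(prof$intensity, 3:28)

  # symmetric equal Gaussians: profile minimum at the midpoint
  m <- render_gaussians(c(41, 81), rbind(c(25, 20), c(55, 20)),
                        I = c(100, 100), sigma = c(4, 4))
  prof <- line_profile(m, c(25, 20), c(55, 20))
  expect_equal(prof$position[which.min(prof$intensity)],
               prof$position[nrow(prof)] / 2, tolerance = 1e-9)

  # unequal Gaussians: argmin within 0.5 px of a dense-sampling oracle
  m <- render_gaussians(c(41, 81), rbind(c(25, 20), c(55, 20)),
                        I = c(100, 40), sigma = c(4, 5))
  prof <- line_profile(m, c(25, 20), c(55, 20))
  tfine <- seq(0, 30, by = 0.01)
  dense <- 100 * exp(-0.5 * tfine^2 / 16) +
    40 * exp(-0.5 * (30 - tfine)^2 / 25)
  expect_lt(abs(prof$position[which.min(prof$intensity)] -
                tfine[which.min(dense)]), 0.5)
})

test_that("a single supra-threshold component sums to its brute-force volume", {
  m <- render_gaussians(c(61, 61), cbind(30, 30), I = 100, sigma = 4,
                        background = 2)
  pk <- mk_peaks(30, 30, m)
  ar <- quantify_area(m, pk, threshold = 10)
  expect_equal(ar$volumes$volume, sum(m[m > 10]))
  expect_identical(ar$volumes$n_pixels, sum(m > 10))
})

test_that("merged spots split along the perpendicular through the valley", {
  m <- render_gaussians(c(61, 101), rbind(c(35, 30), c(65, 30)),
                        I = c(100, 80), sigma = c(5, 5))
  pk <- mk_peaks(c(35, 65), c(30, 30), m)
  thr <- 5
  ar <- quantify_area(m, pk, threshold = thr)
  expect_identical(sum(vapply(ar$pixel_sets, nrow, 1L)), sum(m > thr))

  # half-plane oracle: the valley of this symmetric-width pair, then each
  # pixel goes to the side of the perpendicular it falls on
  prof <- line_profile(m, c(35, 30), c(65, 30))
  xmin <- prof$x[which.min(prof$intensity)]
  idx <- which(m > thr)
  px <- cbind(x = (idx - 1L) %/% 61L, y = (idx - 1L) %% 61L)
  want_P <- px[px[, "x"] - xmin < 0, , drop = FALSE]
  want_Q <- px[px[, "x"] - xmin >= 0, , drop = FALSE]
  expect_setequal(paste(ar$pixel_sets[[1]][, "x"], ar$pixel_sets[[1]][, "y"]),
                  paste(want_P[, "x"], want_P[, "y"]))
  expect_setequal(paste(ar$pixel_sets[[2]][, "x"], ar$pixel_sets[[2]][, "y"]),
                  paste(want_Q[, "x"], want_Q[, "y"]))
})

test_that("a monotone inter-peak profile splits through Q (failure mode)", {
  # ratio 100:60 at IPD = 2 sigma: profile decreases monotonically P -> Q
  m <- render_gaussians(c(81, 81), rbind(c(36, 40), c(44, 40)),
                        I = c(100, 60), sigma = c(4, 4))
  pk <- mk_peaks(c(36, 44), c(40, 40), m)
  prof <- line_profile(m, c(36, 40), c(44, 40))
  expect_identical(which.min(prof$intensity), nrow(prof))  # monotone
  ar <- quantify_area(m, pk, threshold = 5)
  # split through Q: Q keeps only pixels at or right of its own center
  expect_gte(min(ar$pixel_sets[[2]][, "x"]), 44L)
  # P annexes Q's left flank, so the measured ratio blows up past the truth
  a <- alpha_deviation(ar$volumes$volume[1], ar$volumes$volume[2],
                       2 * pi * 100 * 16, 2 * pi * 60 * 16)
  expect_gt(a, 30)
})

test_that("peaks below the threshold get empty areas with a warning", {
  m <- render_gaussians(c(61, 61), cbind(30, 30), I = 100, sigma = 4)
  pk <- mk_peaks(c(30, 5), c(30, 5), m)
  expect_warning(ar <- quantify_area(m, pk, threshold = 10), "below")
  expect_identical(ar$volumes$volume[2], 0)
  expect_identical(nrow(ar$pixel_sets[[2]]), 0L)
})

test_that("area pixel sets are disjoint and within the supra-threshold region", {
  withr::with_seed(301, {
    sc <- simulate_field(6, I_range = c(80, 200), sigma_range = c(3, 5),
                         min_ipd = 14, dims = c(96, 96), noise_sd = 1,
                         seed = 301)
  })
  img <- sc$image
  pk <- mk_peaks(round(sc$truth$centers[, "x"]),
                 round(sc$truth$centers[, "y"]), img$pixels)
  ar <- suppressWarnings(quantify_area(img, pk, threshold = 20))
  all_px <- do.call(rbind, ar$pixel_sets)
  expect_identical(anyDuplicated(paste(all_px[, 1], all_px[, 2])), 0L)
  vals <- img$pixels[cbind(all_px[, "y"] + 1L, all_px[, "x"] + 1L)]
  expect_true(all(vals > 20))
})

test_that("area volumes underestimate faint spots ever more (threshold bias)", {
  # single Gaussian spots from 20x down to 1.5x the threshold, noiseless:
  # volume / true VUS must be non-increasing as intensity decreases
  thr <- 10; sigma <- 4
  mults <- c(20, 12, 8, 5, 3, 2, 1.5)
  ratio <- vapply(mults, function(k) {
    m <- render_gaussians(c(81, 81), cbind(40, 40), I = k * thr,
                          sigma = sigma)
    pk <- mk_peaks(40, 40, m)
    ar <- quantify_area(m, pk, threshold = thr)
    ar$volumes$volume / (2 * pi * k * thr * sigma^2)
  }, numeric(1))
  expect_true(all(diff(ratio) <= 1e-12))   # ordered from bright to faint
  expect_lt(ratio[length(ratio)], ratio[1])
})
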
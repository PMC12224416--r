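test_that("phantom generation is reproducible and spec-driven", {
  spec <- phantom_spec(dim = c(8, 8, 4), seed = 99)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_equal(dim(p1$volume$data)[1:3], c(8L, 8L, 4L))
  expect_equal(nrow(p1$scheme), 3 * (2 + 10 * 2))
  p3 <- generate_phantom(phantom_spec(dim = c(8, 8, 4), seed = 100))
  expect_false(identical(p1$volume$data, p3$volume$data))
  expect_error(phantom_spec(snr = -3), "> 0")
})

test_that("phantom geometry contains both regions with coherent fiber axes", {
  spec <- phantom_spec(dim = c(16, 16, 8), noise = "none", snr = Inf)
  ph <- generate_phantom(spec)
  rois <- phantom_rois(ph)
  expect_gt(sum(rois$wm), 50)
  expect_gt(sum(rois$gm), 200)
  expect_equal(sum(rois$wm) + sum(rois$gm), prod(spec$dim))
  # all axes are unit vectors; tube axes stay in-plane for the bending layout
  expect_equal(rowSums(ph$truth$axes^2), rep(1, prod(spec$dim)))
  expect_true(all(ph$truth$axes[rois$wm, 3] == 0))
  expect_true(all(ph$truth$axes[rois$gm, ] == matrix(c(0, 0, 1), sum(rois$gm), 3, byrow = TRUE)))
})

test_that("frequency dispersion profile scales kurtosis only", {
  prof <- frequency_dispersion_profile(
    list(d_perp = 0.4, d_par = 1.5, w_perp = 1.6, w_par = 0.6, w_mean = 1),
    frequencies = c(0, 60, 120), mode = "linear-decrease", slope = 0.3
  )
  expect_equal(prof$d_par, rep(1.5, 3))
  expect_equal(prof$w_mean, c(1, 0.85, 0.7))
  expect_equal(prof$w_perp, 1.6 * c(1, 0.85, 0.7))
  none <- frequency_dispersion_profile(
    list(d_perp = 0.4, d_par = 1.5, w_perp = 1.6, w_par = 0.6, w_mean = 1),
    frequencies = c(0, 60, 120), mode = "none"
  )
  expect_equal(none$w_mean, rep(1, 3))
})

test_that("a noiseless phantom is fitted back to its ground truth", {
  spec <- phantom_spec(dim = c(8, 8, 4), noise = "none", snr = Inf)
  ph <- generate_phantom(spec)
  axes <- compute_axes(ph$volume, ph$scheme, "AFAB",
    gamma_dt = 0,
    refine = TRUE, tol = 1e-12, refine_tol = 1e-12
  )
  fit <- fit_dki(ph$volume, ph$scheme, axes, frequency = 60, gamma_dk = 0, tol = 1e-12)
  truth <- ph$truth$params[["60"]]
  expect_equal(max(abs(fit$values - truth) / pmax(abs(truth), 1e-3)), 0, tolerance = 1e-4)
  # axes agree with the programmed orientation wherever the voxel is anisotropic
  rois <- phantom_rois(ph)
  ang <- vapply(which(rois$wm), function(i) {
    central_angle(axes$fields[["60"]]$axes[i, ], ph$truth$axes[i, ])
  }, numeric(1))
  expect_lt(max(ang), 1e-3)
})

test_that("generated noise matches the requested SNR", {
  spec <- phantom_spec(dim = c(10, 10, 4), snr = 20, noise = "gaussian", seed = 5)
  ph <- generate_phantom(spec)
  b0 <- ph$volume$data[, , , which(ph$scheme$b0)]
  est <- snr_map(b0)
  # 6 b0 volumes -> coarse voxelwise estimate; the grid mean is tight
  expect_gt(est$roi_mean, 15)
  expect_lt(est$roi_mean, 28)
})

test_that("averaging repetitions reduces noise", {
  sd_of <- function(averages) {
    spec <- phantom_spec(
      dim = c(8, 8, 2), snr = 10, noise = "gaussian",
      averages = averages, seed = 7
    )
    ph <- generate_phantom(spec)
    b0 <- ph$volume$data[, , , which(ph$scheme$b0)]
    stats::sd(b0)
  }
  expect_lt(sd_of(4), 0.6 * sd_of(1))
})

test_that("phantom truth metrics expose the programmed values per region", {
  spec <- phantom_spec(dim = c(8, 8, 2), noise = "none", snr = Inf)
  ph <- generate_phantom(spec)
  tm <- phantom_truth_metrics(ph, 120)
  wm <- tm[tm$label == 2L, ]
  dbar <- (2 * 0.4 + 1.5) / 3
  expect_equal(unique(wm$d_mean), dbar)
  expect_equal(unique(wm$w_mean), 1.0 * 0.7) # linear-decrease slope 0.3 at 120 Hz
  expect_equal(unique(wm$k_perp), 1.6 * 0.7 * dbar^2 / 0.4^2)
  expect_error(phantom_truth_metrics(ph, 90), "no ground truth")
})
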
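test_that("dti design rows reproduce the tensor log-signal model", {
  sc <- build_scheme(uniform_directions(8), shells = c(1, 2.5), frequencies = 0, n_b0 = 1)
  a <- build_dti_design(sc)
  expect_equal(dim(a), c(nrow(sc), 7L))
  # known anisotropic tensor
  d <- matrix(c(1.5, 0.1, 0, 0.1, 0.6, 0.05, 0, 0.05, 0.4), 3, 3)
  x <- c(log(80), d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3])
  dirs <- scheme_directions(sc, unit = TRUE)
  manual <- log(80) - sc$bval * vapply(
    seq_len(nrow(sc)),
    function(i) drop(dirs[i, ] %*% d %*% dirs[i, ]), numeric(1)
  )
  expect_equal(drop(a %*% x), manual, tolerance = 1e-12)
})

test_that("dti design errors on rank-deficient subsets", {
  sc <- build_scheme(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    shells = 1, frequencies = 0, n_b0 = 1
  )
  expect_error(build_dti_design(sc), "rank-deficient")
})

test_that("unregularized dti fit recovers an exact tensor and matches OLS", {
  sc <- build_scheme(uniform_directions(8), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  d <- matrix(c(1.5, 0.1, 0, 0.1, 0.6, 0.05, 0, 0.05, 0.4), 3, 3)
  dirs <- scheme_directions(sc, unit = TRUE)
  mu <- exp(log(80) - sc$bval * vapply(
    seq_len(nrow(sc)),
    function(i) drop(dirs[i, ] %*% d %*% dirs[i, ]), numeric(1)
  ))
  dims <- c(3, 3, 2)
  vol <- signal_volume(array(rep(mu, each = prod(dims)), c(dims, length(mu))))
  fit <- fit_dti(vol, sc, gamma_dt = 0, tol = 1e-12, maxit = 1000)
  truth <- c(log(80), d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3])
  expect_equal(max(abs(sweep(fit$values, 2, truth))), 0, tolerance = 1e-8)
  # and gamma = 0 equals voxelwise OLS on noisy data
  set.seed(21)
  noisy <- signal_volume(array(
    rep(mu, each = prod(dims)) * exp(stats::rnorm(prod(dims) * length(mu), sd = 0.05)),
    c(dims, length(mu))
  ))
  f0 <- fit_dti(noisy, sc, gamma_dt = 0, tol = 1e-12, maxit = 1000)
  a <- build_dti_design(sc)
  y <- log_signal(noisy, sc)
  ols <- t(apply(y, 1, function(yi) qr.solve(a, yi)))
  expect_equal(f0$values, ols, tolerance = 1e-8)
})

test_that("principal_axis extracts the leading eigenvector deterministically", {
  sc <- build_scheme(uniform_directions(8), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  ax <- c(-1, 2, 2) / 3 # leading eigenvector with a negative first component
  d <- 0.4 * diag(3) + (1.5 - 0.4) * (ax %o% ax)
  dirs <- scheme_directions(sc, unit = TRUE)
  mu <- exp(-sc$bval * vapply(
    seq_len(nrow(sc)),
    function(i) drop(dirs[i, ] %*% d %*% dirs[i, ]), numeric(1)
  ))
  dims <- c(2, 2, 1)
  vol <- signal_volume(array(rep(mu, each = prod(dims)), c(dims, length(mu))))
  fit <- fit_dti(vol, sc, gamma_dt = 0, tol = 1e-12, maxit = 1000)
  af <- principal_axis(fit)
  # sign convention: first component of significant magnitude made positive
  expect_equal(af$axes[1, ], -ax, tolerance = 1e-7)
  expect_equal(sort(af$evals[1, ]), c(0.4, 0.4, 1.5), tolerance = 1e-7)
  expect_equal(
    axis_field_fa(af)[1],
    derived_metrics(d_perp = 0.4, d_par = 1.5)$fa,
    tolerance = 1e-7
  )
})

test_that("axis strategies pool the expected volume subsets", {
  p <- reference_params()
  sc <- build_scheme(uniform_directions(9),
    shells = c(1, 2.5),
    frequencies = c(0, 60), n_b0 = 2
  )
  vol <- make_axisym_volume(c(3, 3, 2), p, sc)
  for (strat in c("AFAB", "SFAB", "SFLB")) {
    ax <- compute_axes(vol, sc, strat, gamma_dt = 0)
    expect_s3_class(ax, "axis_set")
    expect_named(ax$fields, c("0", "60"))
    ang <- apply(ax$fields[["0"]]$axes, 1, central_angle, v2 = p$axis)
    expect_lt(max(ang), 2) # plain tensor step: small kurtosis-induced tilt
  }
  afab <- compute_axes(vol, sc, "AFAB", gamma_dt = 0)
  expect_identical(afab$fields[["0"]]$axes, afab$fields[["60"]]$axes)
})

test_that("kurtosis-corrected refinement recovers the axis exactly", {
  p <- reference_params()
  sc <- build_scheme(uniform_directions(9), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  vol <- make_axisym_volume(c(2, 2, 2), p, sc)
  plain <- compute_axes(vol, sc, "AFAB", gamma_dt = 0, tol = 1e-13)
  refined <- compute_axes(vol, sc, "AFAB",
    gamma_dt = 0, refine = TRUE,
    tol = 1e-13, refine_tol = 1e-14
  )
  ang_plain <- central_angle(plain$fields[["0"]]$axes[1, ], p$axis)
  ang_ref <- central_angle(refined$fields[["0"]]$axes[1, ], p$axis)
  expect_gt(ang_plain, 0.5) # the b^2 term biases the plain tensor fit
  expect_lt(ang_ref, 1e-6)
})
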
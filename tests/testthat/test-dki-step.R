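test_that("polar_angles computes sign-invariant angles with b0 convention", {
  sc <- gradient_scheme(
    rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 0, -1)),
    bvalues = c(0, 1, 1, 2.5)
  )
  axes <- rbind(c(0, 0, 1), c(1, 0, 0))
  th <- polar_angles(axes, sc)
  expect_equal(dim(th), c(2L, 4L))
  expect_equal(th[1, ], c(0, 0, pi / 2, 0))
  expect_equal(th[2, ], c(0, pi / 2, 0, pi / 2))
})

test_that("dki design rows reproduce the axisymmetric forward model", {
  p <- reference_params()
  b <- c(0, 1, 1, 2.5, 2.5)
  theta <- c(0, 0.2, 0.9, 1.3, 0.5)
  a <- build_dki_design(b, theta)
  expect_equal(dim(a), c(5L, 6L))
  dbar <- (2 * p$d_perp + p$d_par) / 3
  x <- c(
    p$log_s0, p$d_perp, p$d_par,
    dbar^2 * p$w_perp, dbar^2 * p$w_par, dbar^2 * p$w_mean
  )
  expect_equal(drop(a %*% x), predict_log_signal(p, b, theta), tolerance = 1e-12)
  expect_error(build_dki_design(b, theta[-1]), "equal length")
})

test_that("unregularized dki fit with the true axes is exact", {
  p <- reference_params()
  sc <- build_scheme(uniform_directions(9), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  dims <- c(3, 2, 2)
  vol <- make_axisym_volume(dims, p, sc)
  axes <- matrix(p$axis, prod(dims), 3, byrow = TRUE)
  fit <- fit_dki(vol, sc, axes, gamma_dk = 0, tol = 1e-12, maxit = 1000)
  dbar <- (2 * p$d_perp + p$d_par) / 3
  truth <- c(
    p$log_s0, p$d_perp, p$d_par,
    dbar^2 * p$w_perp, dbar^2 * p$w_par, dbar^2 * p$w_mean
  )
  expect_equal(max(abs(sweep(fit$values, 2, truth) / truth)), 0, tolerance = 1e-8)
})

test_that("fit_dki selects the requested frequency and validates input", {
  p <- reference_params()
  sc <- build_scheme(uniform_directions(9),
    shells = c(1, 2.5),
    frequencies = c(0, 60), n_b0 = 2
  )
  dims <- c(2, 2, 1)
  vol <- make_axisym_volume(dims, p, sc)
  axes <- matrix(p$axis, prod(dims), 3, byrow = TRUE)
  expect_error(fit_dki(vol, sc, axes, gamma_dk = 0), "specify `frequency`")
  expect_error(fit_dki(vol, sc, axes, frequency = 0, gamma_dk = -1), ">= 0")
  fit <- fit_dki(vol, sc, axes, frequency = 60, gamma_dk = 0, tol = 1e-12)
  expect_equal(fit$frequency, 60)
  expect_equal(unname(fit$values[1, "d_par"]), p$d_par, tolerance = 1e-7)
})

test_that("extract_metrics applies the documented algebra with sentinels", {
  values <- rbind(
    c(log(100), 0.4, 1.5, 0.81 * 1.6, 0.81 * 0.6, 0.81 * 1.0),
    c(log(100), 0, 0, 1, 1, 1)
  )
  colnames(values) <- c("log_s0", "d_perp", "d_par", "u_perp", "u_par", "u_mean")
  field <- structure(
    list(
      values = values, mask = array(TRUE, c(2, 1, 1)), voxdim = c(1, 1, 1),
      frequency = 0, gamma_dk = 0, strategy = "AFAB",
      diagnostics = list(iterations = 0L)
    ),
    class = "axisym_field"
  )
  m <- extract_metrics(field)
  dbar <- (2 * 0.4 + 1.5) / 3
  expect_equal(unname(m$values[1, "d_mean"]), dbar)
  expect_equal(unname(m$values[1, "k_par"]), 0.81 * 0.6 / 1.5^2)
  expect_equal(unname(m$values[1, "k_perp"]), 0.81 * 1.6 / 0.4^2)
  expect_equal(unname(m$values[1, "w_mean"]), 0.81 / dbar^2)
  expect_true(all(is.nan(m$values[2, c("fa", "k_par", "k_perp", "w_mean")])))
})

test_that("metric_array unmasks with NA outside and errors on unknown names", {
  p <- reference_params()
  sc <- build_scheme(uniform_directions(9), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  dims <- c(3, 3, 1)
  vol0 <- make_axisym_volume(dims, p, sc)
  mask <- array(TRUE, dims)
  mask[1, 1, 1] <- FALSE
  vol <- signal_volume(vol0$data, mask = mask)
  axes <- matrix(p$axis, sum(mask), 3, byrow = TRUE)
  m <- extract_metrics(fit_dki(vol, sc, axes, gamma_dk = 0, tol = 1e-12))
  arr <- metric_array(m, "k_perp")
  expect_equal(dim(arr), dims)
  expect_true(is.na(arr[1, 1, 1]))
  expect_equal(
    arr[2, 1, 1],
    derived_metrics(p)$k_perp,
    tolerance = 1e-7
  )
  expect_error(metric_array(m, "nope"), "unknown metric")
})
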
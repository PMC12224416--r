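test_that("tensor contractions match an 81-term brute-force oracle", {
  set.seed(9)
  w15 <- stats::rnorm(15)
  for (trial in 1:3) {
    n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
    expect_equal(
      directional_w_full(w15, n),
      brute_force_w_form(w15, n, n, n, n),
      tolerance = 1e-12
    )
    n2 <- stats::rnorm(3); n3 <- stats::rnorm(3); n4 <- stats::rnorm(3)
    expect_equal(
      w_quartic_form(w15, n, n2, n3, n4),
      brute_force_w_form(w15, n, n2, n3, n4),
      tolerance = 1e-12
    )
  }
})

test_that("sphere and circle averages match quadrature oracles", {
  set.seed(10)
  w15 <- stats::rnorm(15)
  u <- uniform_directions(10000)
  quad <- mean(vapply(seq_len(nrow(u)), function(i) {
    directional_w_full(w15, u[i, ])
  }, numeric(1)))
  expect_equal(sphere_mean_w(w15), quad, tolerance = 1e-3)
  # circle average: trigonometric quadrature on the perpendicular circle is
  # exact for this quartic integrand
  axis <- c(1, -2, 2) / 3
  e <- c(0, 1, 0)
  pvec <- e - sum(e * axis) * axis
  pvec <- pvec / sqrt(sum(pvec^2))
  qvec <- c(
    axis[2] * pvec[3] - axis[3] * pvec[2],
    axis[3] * pvec[1] - axis[1] * pvec[3],
    axis[1] * pvec[2] - axis[2] * pvec[1]
  )
  phi <- 2 * pi * (0:359) / 360
  circ <- mean(vapply(phi, function(a) {
    directional_w_full(w15, cos(a) * pvec + sin(a) * qvec)
  }, numeric(1)))
  expect_equal(circle_mean_w(w15, axis), circ, tolerance = 1e-12)
})

test_that("the 22-column design reproduces the full DKI log-signal", {
  sc <- build_scheme(uniform_directions(15), shells = c(1, 2.5), frequencies = 0, n_b0 = 1)
  a <- build_full_dki_design(sc)
  expect_equal(ncol(a), 22L)
  set.seed(12)
  d6 <- c(1.2, 0.7, 0.5, 0.1, -0.05, 0.08)
  w15 <- stats::rnorm(15, sd = 0.3)
  dmat <- matrix(c(
    d6[1], d6[4], d6[5],
    d6[4], d6[2], d6[6],
    d6[5], d6[6], d6[3]
  ), 3, 3)
  dbar <- mean(d6[1:3])
  x <- c(log(90), d6, dbar^2 * w15)
  dirs <- scheme_directions(sc, unit = TRUE)
  manual <- vapply(seq_len(nrow(sc)), function(i) {
    n <- dirs[i, ]
    b <- sc$bval[i]
    if (b == 0) return(log(90))
    log(90) - b * drop(n %*% dmat %*% n) +
      b^2 / 6 * dbar^2 * brute_force_w_form(w15, n, n, n, n)
  }, numeric(1))
  expect_equal(drop(a %*% x), manual, tolerance = 1e-12)
})

test_that("full-tensor OLS fit recovers an exact synthetic tensor pair", {
  set.seed(13)
  sc <- build_scheme(uniform_directions(16), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  d6 <- c(1.2, 0.7, 0.5, 0.1, -0.05, 0.08)
  w15 <- stats::rnorm(15, sd = 0.3)
  dbar <- mean(d6[1:3])
  x <- c(log(90), d6, dbar^2 * w15)
  a <- build_full_dki_design(sc)
  mu <- exp(drop(a %*% x))
  dims <- c(2, 2, 1)
  vol <- signal_volume(array(rep(mu, each = prod(dims)), c(dims, length(mu))))
  fit <- fit_full_dki(vol, sc)
  expect_s3_class(fit, "kt_field")
  expect_equal(unname(fit$dt[1, ]), d6, tolerance = 1e-8)
  expect_equal(unname(fit$wt[1, ]), w15, tolerance = 1e-7)
  expect_equal(fit$d_mean[1], dbar, tolerance = 1e-10)
})

test_that("the full fit refuses rank-deficient direction sets", {
  sc14 <- build_scheme(uniform_directions(14), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  p <- reference_params()
  vol <- make_axisym_volume(c(2, 2, 1), p, sc14)
  expect_error(fit_full_dki(vol, sc14), "rank-deficient")
})

test_that("axisymmetric metrics from the full fit agree with the axisymmetric fit", {
  p <- reference_params()
  sc <- build_scheme(uniform_directions(16), shells = c(1, 2.5), frequencies = 0, n_b0 = 2)
  dims <- c(2, 2, 1)
  vol <- make_axisym_volume(dims, p, sc)
  full <- fit_full_dki(vol, sc)
  axes <- matrix(p$axis, prod(dims), 3, byrow = TRUE)
  mf <- axisym_metrics_from_full(full, axes)
  truth <- derived_metrics(p)
  for (col in c("d_mean", "fa", "k_par", "k_perp", "w_mean")) {
    expect_equal(unname(mf$values[1, col]), truth[[col]], tolerance = 1e-6)
  }
  # default axis (principal eigenvector of the fitted tensor block) matches
  mf2 <- axisym_metrics_from_full(full)
  expect_equal(unname(mf2$values[1, "k_perp"]), truth$k_perp, tolerance = 1e-6)
  expect_equal(central_angle(mf2$meta$axes[1, ], p$axis), 0, tolerance = 1e-5)
})
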
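test_that("mask_neighbors respects mask boundaries", {
  mask <- array(TRUE, c(2, 2, 1))
  mask[2, 2, 1] <- FALSE
  nb <- mask_neighbors(mask)
  expect_equal(nb$n, 3L)
  # voxel order: (1,1), (2,1), (1,2); x-neighbor of (1,2) is the masked-out voxel
  expect_equal(nb$fwd[[1]], c(2L, NA, NA))
  expect_equal(nb$fwd[[2]], c(3L, NA, NA))
  expect_equal(nb$fwd[[3]], c(NA_integer_, NA_integer_, NA_integer_))
})

test_that("penalty operator matches its dense construction and adjoint", {
  set.seed(42)
  mask <- array(stats::runif(3 * 4 * 2) > 0.25, c(3, 4, 2))
  mask[1, 1, 1] <- TRUE
  nb <- mask_neighbors(mask)
  m <- nb$n
  w <- c(0, 1, 2)
  x <- matrix(stats::rnorm(m * 3), m, 3)
  tx <- tv_apply(x, nb, w)
  # dense oracle: independent index-loop construction, component-major layout
  tmat <- dense_penalty_matrix(mask, w)
  dense_tx <- tmat %*% as.vector(x)
  expect_equal(sum(unlist(tx)^2), sum(dense_tx^2), tolerance = 1e-12)
  # adjoint identity <T x, r> == <x, T' r> for random r
  r <- lapply(1:3, function(a) matrix(stats::rnorm(m * 3), m, 3))
  lhs <- sum(mapply(function(a, b) sum(a * b), tx, r))
  rhs <- sum(x * tv_apply_adjoint(r, nb, w))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the normal operator is symmetric and matches its dense form", {
  set.seed(7)
  mask <- array(stats::runif(3 * 3 * 2) > 0.2, c(3, 3, 2))
  nb <- mask_neighbors(mask)
  m <- nb$n
  p <- 4
  design <- matrix(stats::rnorm(9 * p), 9, p)
  w <- c(0, 1, 1, 2)
  gamma <- 0.7
  prob <- reg_problem(crossprod(design), matrix(0, m, p), nb, w, gamma)
  dense_n <- dense_normal_matrix(design, mask, w, gamma)
  for (trial in 1:3) {
    x <- matrix(stats::rnorm(m * p), m, p)
    expect_equal(
      as.vector(apply_normal_operator(prob, x)),
      as.vector(matrix(dense_n %*% as.vector(x), m, p)),
      tolerance = 1e-12
    )
  }
  x <- matrix(stats::rnorm(m * p), m, p)
  y <- matrix(stats::rnorm(m * p), m, p)
  expect_equal(
    sum(apply_normal_operator(prob, x) * y),
    sum(x * apply_normal_operator(prob, y)),
    tolerance = 1e-10
  )
})

test_that("conjugate gradients matches a dense solve of the coupled system", {
  set.seed(11)
  mask <- array(TRUE, c(4, 3, 3))
  nb <- mask_neighbors(mask)
  m <- nb$n
  p <- 3
  design <- matrix(stats::rnorm(8 * p), 8, p)
  w <- c(0, 1, 1)
  gamma <- 0.5
  y <- matrix(stats::rnorm(m * 8), m, 8)
  aty <- y %*% design
  prob <- reg_problem(crossprod(design), aty, nb, w, gamma, tol = 1e-12, maxit = 2000)
  sol <- solve_regularized(prob)
  expect_true(sol$converged)
  dense_n <- dense_normal_matrix(design, mask, w, gamma)
  dense_x <- matrix(solve(dense_n, as.vector(aty)), m, p)
  expect_equal(sol$x, dense_x, tolerance = 1e-8)
})

test_that("gamma = 0 reduces to independent per-voxel least squares", {
  set.seed(3)
  mask <- array(TRUE, c(2, 2, 2))
  nb <- mask_neighbors(mask)
  design <- matrix(stats::rnorm(10 * 3), 10, 3)
  y <- matrix(stats::rnorm(8 * 10), 8, 10)
  prob <- reg_problem(crossprod(design), y %*% design, nb, c(0, 1, 1), 0,
    tol = 1e-12, maxit = 1000
  )
  sol <- solve_regularized(prob)
  ols <- t(apply(y, 1, function(yi) qr.solve(design, yi)))
  expect_equal(sol$x, ols, tolerance = 1e-8)
})

test_that("solver handles edge cases and validates input", {
  mask <- array(TRUE, c(2, 1, 1))
  nb <- mask_neighbors(mask)
  prob <- reg_problem(diag(2), matrix(0, 2, 2), nb, c(0, 1), 1)
  sol <- solve_regularized(prob)
  expect_equal(sol$x, matrix(0, 2, 2))
  expect_true(sol$converged)
  expect_error(reg_problem(diag(2), matrix(0, 2, 2), nb, c(0, 1), -1), ">= 0")
  expect_error(reg_problem(diag(2), matrix(0, 2, 2), nb, c(0, 1), 1, tol = 0), "> 0")
  expect_error(reg_problem(diag(2), matrix(0, 2, 2), nb, c(0, 1, 1), 1), "one entry per parameter")
  expect_error(apply_normal_operator(prob, matrix(0, 3, 2)), "conform")
})

test_that("exhausting the iteration budget warns and flags non-convergence", {
  set.seed(5)
  mask <- array(TRUE, c(3, 3, 3))
  nb <- mask_neighbors(mask)
  design <- matrix(stats::rnorm(8 * 3), 8, 3)
  y <- matrix(stats::rnorm(27 * 8), 27, 8)
  prob <- reg_problem(crossprod(design), y %*% design, nb, c(0, 1, 1), 5,
    tol = 1e-14, maxit = 2L
  )
  expect_warning(sol <- solve_regularized(prob), "not converged")
  expect_false(sol$converged)
  expect_equal(sol$iterations, 2L)
})
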
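#' Polar angles between encoding directions and per-voxel symmetry axes
#'
#' theta = arccos(|n . axis|) in `[0, pi/2]` for every masked voxel and volume.
#' The absolute dot product makes the result invariant to the sign of either
#' the axis or the direction (both are axes). b = 0 volumes are assigned
#' theta = 0 by convention; their design row does not depend on theta.
#'
#' @param axis_field an `axis_field` (or an axes matrix, voxels x 3).
#' @param scheme a [gradient_scheme()].
#' @param subset optional volume indices.
#' @return matrix of angles in radians (voxels x volumes).
#' @export
polar_angles <- function(axis_field, scheme, subset = NULL) {
  axes <- if (inherits(axis_field, "axis_field")) axis_field$axes else as.matrix(axis_field)
  if (is.null(subset)) subset <- seq_len(nrow(scheme))
  dirs <- scheme_directions(scheme, unit = TRUE)[subset, , drop = FALSE]
  ct <- abs(axes %*% t(dirs))
  ct[, scheme$b0[subset]] <- 1
  acos(pmin(ct, 1))
}

# the three kurtosis design coefficients as functions of cos^2(theta); these
# multiply (Dbar^2 W_perp, Dbar^2 W_par, Dbar^2 W_mean) after scaling by b^2/6
kurtosis_design_coef <- function(cos2t) {
  c2 <- 2 * cos2t - 1
  c4 <- 8 * cos2t^2 - 8 * cos2t + 1
  list(
    perp = (10 * c4 - 8 * c2 - 2) / 16,
    par = (5 * c4 + 8 * c2 + 3) / 16,
    mean = (-15 * c4 + 15) / 16
  )
}

#' Design matrix of the axisymmetric DKI fit for one voxel
#'
#' Row n is
#' `(1, -b sin^2(theta), -b cos^2(theta), (b^2/6) a_perp, (b^2/6) a_par,
#' (b^2/6) a_mean)` where the kurtosis coefficients
#' `a_perp = (10 cos4t - 8 cos2t - 2)/16`,
#' `a_par = (5 cos4t + 8 cos2t + 3)/16`,
#' `a_mean = (-15 cos4t + 15)/16`
#' are the expansion of the axisymmetric directional kurtosis in
#' `(W_perp, W_par, W_mean)`. Dotted with the parameter vector
#' `(log S0, D_perp, D_par, Dbar^2 W_perp, Dbar^2 W_par, Dbar^2 W_mean)` a
#' row reproduces [predict_log_signal()] exactly. b-values must be in ms/µm²
#' so that all design entries have comparable magnitude.
#'
#' @param bvals per-volume b-values (ms/µm²).
#' @param thetas per-volume polar angles (radians) for this voxel.
#' @return matrix (volumes x 6).
#' @export
build_dki_design <- function(bvals, thetas) {
  if (length(bvals) != length(thetas)) stop("`bvals` and `thetas` must have equal length")
  c2t <- cos(thetas)^2
  k <- kurtosis_design_coef(c2t)
  cbind(
    1, -bvals * (1 - c2t), -bvals * c2t,
    bvals^2 / 6 * k$perp, bvals^2 / 6 * k$par, bvals^2 / 6 * k$mean
  )
}

# per-voxel design coefficient matrices (list of 6, each voxels x volumes)
dki_design_field <- function(scheme, subset, axes) {
  theta <- polar_angles(axes, scheme, subset)
  c2t <- cos(theta)^2
  b <- matrix(scheme$bval[subset], nrow(c2t), length(subset), byrow = TRUE)
  k <- kurtosis_design_coef(c2t)
  list(
    matrix(1, nrow(c2t), ncol(c2t)),
    -b * (1 - c2t), -b * c2t,
    b^2 / 6 * k$perp, b^2 / 6 * k$par, b^2 / 6 * k$mean
  )
}

# regularized axisymmetric fit on a masked log-signal matrix; also returns the
# fitted kurtosis contribution to the log signal (used by axis refinement)
fit_dki_core <- function(y, scheme, subset, axes, neighbors, gamma_dk,
                         tol = 1e-8, maxit = 500L) {
  cmat <- dki_design_field(scheme, subset, axes)
  p <- length(cmat)
  m <- nrow(y)
  gram <- array(0, c(m, p, p))
  aty <- matrix(0, m, p)
  for (k in seq_len(p)) {
    aty[, k] <- rowSums(cmat[[k]] * y)
    for (l in k:p) {
      g <- rowSums(cmat[[k]] * cmat[[l]])
      gram[, k, l] <- g
      gram[, l, k] <- g
    }
  }
  prob <- reg_problem(gram, aty, neighbors, c(0, 1, 1, 1, 1, 1), gamma_dk,
    tol = tol, maxit = maxit
  )
  sol <- solve_regularized(prob)
  kterm <- cmat[[4]] * sol$x[, 4] + cmat[[5]] * sol$x[, 5] + cmat[[6]] * sol$x[, 6]
  list(
    x = sol$x, kurtosis_term = kterm,
    diagnostics = sol[c("iterations", "converged", "rel_residual")]
  )
}

#' Spatially regularized axisymmetric DKI fit (step two)
#'
#' Fits the six linear axisymmetric parameters
#' `(log S0, D_perp, D_par, Dbar^2 W_perp, Dbar^2 W_par, Dbar^2 W_mean)` per
#' masked voxel for one oscillation frequency, given a fixed symmetry-axis
#' field (the axis is never updated during this fit). The objective
#' `||A x - y||^2 + gamma_dk ||T x||^2` couples neighboring voxels through
#' spatial first differences of the five diffusion/kurtosis parameters
#' (log S0 is not penalized) and is solved by conjugate gradients. b = 0
#' volumes of the frequency are always included; they constrain log S0.
#'
#' Negative fitted kurtosis values ("blackened" voxels) are preserved in the
#' stored field; they serve as a noise diagnostic and any clamping is left to
#' visualization layers.
#'
#' @inheritParams fit_dti
#' @param axes an `axis_set` from [compute_axes()], a single `axis_field`, or
#'   an axes matrix (voxels x 3).
#' @param frequency oscillation frequency (Hz) selecting the volumes to fit;
#'   may be omitted for a single-frequency scheme.
#' @param gamma_dk regularization weight, >= 0 (base value 0.075 for
#'   preclinical protocols, 0.2 for human-like protocols).
#' @return an object of class `axisym_field` with the 6-column masked-voxel
#'   parameter matrix, frequency label, strategy provenance and solver
#'   diagnostics.
#' @export
fit_dki <- function(volume, scheme, axes, frequency = NULL, gamma_dk = 0.075,
                    tol = 1e-8, maxit = 500L) {
  if (gamma_dk < 0) stop("`gamma_dk` must be >= 0")
  freqs <- sort(unique(scheme$freq))
  if (is.null(frequency)) {
    if (length(freqs) > 1L) stop("multi-frequency scheme: specify `frequency`")
    frequency <- freqs
  }
  strategy <- NULL
  if (inherits(axes, "axis_set")) {
    strategy <- axes$strategy
    axes <- axes$fields[[as.character(frequency)]]
    if (is.null(axes)) stop("axis_set has no field for this frequency")
  }
  axmat <- if (inherits(axes, "axis_field")) axes$axes else as.matrix(axes)
  sub <- volumes_for_frequency(scheme, frequency)
  if (length(sub) == 0L) stop("no volumes at the requested frequency")
  y <- log_signal(volume, scheme, subset = sub)
  nb <- mask_neighbors(volume$mask)
  fit <- fit_dki_core(y, scheme, sub, axmat, nb, gamma_dk, tol = tol, maxit = maxit)
  values <- fit$x
  colnames(values) <- c("log_s0", "d_perp", "d_par", "u_perp", "u_par", "u_mean")
  structure(
    list(
      values = values, mask = volume$mask, voxdim = volume$voxdim,
      frequency = frequency, gamma_dk = gamma_dk, strategy = strategy,
      axes = axmat,
      diagnostics = c(fit$diagnostics, list(n_guarded = attr(y, "n_guarded")))
    ),
    class = "axisym_field"
  )
}

#' @export
print.axisym_field <- function(x, ...) {
  cat(sprintf(
    "<axisym_field> %d voxels, frequency %s Hz, gamma_dk=%.3g, CG %d iterations\n",
    nrow(x$values), format(x$frequency), x$gamma_dk, x$diagnostics$iterations
  ))
  invisible(x)
}

#' Scalar metric maps from a fitted axisymmetric field
#'
#' Converts the raw 6-parameter field to the scalar maps Dbar, FA, K_par,
#' K_perp and W_mean. Because the fitted kurtosis parameters are stored
#' premultiplied by Dbar^2 (u = Dbar^2 W), the Dbar^2 factor cancels in
#' K_par = W_par Dbar^2 / D_par^2 = u_par / D_par^2, and likewise for K_perp;
#' W_mean is recovered as u_mean / Dbar^2. Voxels where a denominator is
#' exactly zero receive the undefined sentinel `NaN`, which map writers
#' preserve.
#'
#' @param field an `axisym_field` from [fit_dki()].
#' @return an object of class `metric_maps`: masked-voxel matrix with columns
#'   `d_mean`, `fa`, `k_par`, `k_perp`, `w_mean`, plus provenance (frequency,
#'   strategy, gamma values).
#' @export
extract_metrics <- function(field) {
  v <- field$values
  d_perp <- v[, "d_perp"]; d_par <- v[, "d_par"]
  d_mean <- (2 * d_perp + d_par) / 3
  den <- sqrt(d_par^2 + 2 * d_perp^2)
  fa <- ifelse(den == 0, NaN,
    sqrt(3 / 2) * sqrt((d_par - d_mean)^2 + 2 * (d_perp - d_mean)^2) / den
  )
  out <- cbind(
    d_mean = d_mean,
    fa = fa,
    k_par = ifelse(d_par == 0, NaN, v[, "u_par"] / d_par^2),
    k_perp = ifelse(d_perp == 0, NaN, v[, "u_perp"] / d_perp^2),
    w_mean = ifelse(d_mean == 0, NaN, v[, "u_mean"] / d_mean^2)
  )
  structure(
    list(
      values = out, mask = field$mask, voxdim = field$voxdim,
      frequency = field$frequency,
      meta = list(
        strategy = field$strategy, gamma_dk = field$gamma_dk,
        method = "axisymmetric"
      )
    ),
    class = "metric_maps"
  )
}

#' @export
print.metric_maps <- function(x, ...) {
  cat(sprintf(
    "<metric_maps> %s; %d voxels, frequency %s\n",
    paste(colnames(x$values), collapse = ", "),
    nrow(x$values), format(x$frequency)
  ))
  invisible(x)
}

#' Extract one metric as a 3D array on the image grid
#'
#' @param maps a `metric_maps` object.
#' @param which metric name, e.g. `"k_perp"`.
#' @return 3D array with `NA` outside the mask; undefined-metric sentinels
#'   (`NaN`) inside the mask are preserved.
#' @export
metric_array <- function(maps, which) {
  if (!which %in% colnames(maps$values)) {
    stop(sprintf("unknown metric '%s'", which))
  }
  unmask(maps$values[, which, drop = FALSE], maps$mask)
}
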
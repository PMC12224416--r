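#' Axisymmetric DKI parameter set
#'
#' Container for the parameters of the axisymmetric diffusional kurtosis
#' model: when the diffusion tensor has two equal minor eigenvalues, the
#' kurtosis description collapses to three scalar tensor-kurtosis quantities
#' (mean kurtosis tensor `w_mean`, radial tensor kurtosis `w_perp`, axial
#' tensor kurtosis `w_par`) alongside the radial/axial diffusivities and one
#' symmetry axis. These tensor-kurtosis quantities are tensor contractions
#' and averages and are distinct from conventional numerically averaged
#' directional kurtosis.
#'
#' Physical validity (non-negative diffusivities) is a query, not a
#' constructor constraint: fitted fields may contain negative values, which
#' downstream consumers use as a noise diagnostic.
#'
#' @param d_perp radial diffusivity, µm²/ms.
#' @param d_par axial diffusivity, µm²/ms.
#' @param w_perp radial tensor kurtosis (dimensionless).
#' @param w_par axial tensor kurtosis (dimensionless).
#' @param w_mean mean kurtosis tensor (dimensionless).
#' @param axis symmetry axis (any nonzero scale, stored unit-normalized;
#'   sign-indeterminate).
#' @param log_s0 log signal at b = 0.
#' @return an object of class `axisym_params`.
#' @examples
#' axisym_params(d_perp = 0.4, d_par = 1.5, w_perp = 1.6, w_par = 0.6, w_mean = 1)
#' @export
axisym_params <- function(d_perp, d_par, w_perp = 0, w_par = 0, w_mean = 0,
                          axis = c(0, 0, 1), log_s0 = 0) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (length(axis) != 3L || nrm == 0) stop("`axis` must be a nonzero 3-vector")
  structure(
    list(
      log_s0 = log_s0, d_perp = d_perp, d_par = d_par,
      w_perp = w_perp, w_par = w_par, w_mean = w_mean,
      axis = axis / nrm
    ),
    class = "axisym_params"
  )
}

#' @export
print.axisym_params <- function(x, ...) {
  cat(sprintf(
    "<axisym_params> D_perp=%.4g D_par=%.4g W_perp=%.4g W_par=%.4g W_mean=%.4g axis=(%.3f, %.3f, %.3f)\n",
    x$d_perp, x$d_par, x$w_perp, x$w_par, x$w_mean, x$axis[1], x$axis[2], x$axis[3]
  ))
  invisible(x)
}

#' Apparent diffusivity along a direction of the axisymmetric tensor
#'
#' D(theta) = D_perp + cos^2(theta) (D_par - D_perp), where theta is the
#' polar angle between the symmetry axis and the encoding direction.
#'
#' @param params an [axisym_params()] object (or list with `d_perp`, `d_par`).
#' @param theta polar angle in radians (vectorized).
#' @return diffusivity in µm²/ms.
#' @export
directional_diffusivity <- function(params, theta) {
  params$d_perp + cos(theta)^2 * (params$d_par - params$d_perp)
}

#' Apparent tensor kurtosis along a direction of the axisymmetric model
#'
#' The axisymmetric directional tensor kurtosis
#' \deqn{W(\theta) = \frac{1}{16}\left[\cos 4\theta\,(10 W_\perp + 5 W_\parallel
#'   - 15 \bar W) + 8 \cos 2\theta\,(W_\parallel - W_\perp) - 2 W_\perp
#'   + 3 W_\parallel + 15 \bar W\right]}
#' is the unique axisymmetric quartic form satisfying the three defining
#' limits simultaneously: W(0) = W_par, W(pi/2) = W_perp, and a spherical
#' average equal to W_mean. All three are enforced by unit tests.
#'
#' @inheritParams directional_diffusivity
#' @return dimensionless directional tensor kurtosis.
#' @export
directional_kurtosis_w <- function(params, theta) {
  c2 <- cos(2 * theta)
  c4 <- cos(4 * theta)
  (c4 * (10 * params$w_perp + 5 * params$w_par - 15 * params$w_mean) +
    8 * c2 * (params$w_par - params$w_perp) -
    2 * params$w_perp + 3 * params$w_par + 15 * params$w_mean) / 16
}

#' Forward axisymmetric DKI log-signal model
#'
#' log S(b, theta) = log S0 - b D(theta) + (b^2/6) Dbar^2 W(theta), with
#' Dbar = (2 D_perp + D_par) / 3 the mean diffusivity.
#'
#' @inheritParams directional_diffusivity
#' @param b b-value in ms/µm² (vectorized together with `theta`).
#' @return log-signal (dimensionless).
#' @export
predict_log_signal <- function(params, b, theta) {
  dbar <- (2 * params$d_perp + params$d_par) / 3
  params$log_s0 - b * directional_diffusivity(params, theta) +
    b^2 / 6 * dbar^2 * directional_kurtosis_w(params, theta)
}

#' Scalar metrics of the axisymmetric model
#'
#' Computes mean diffusivity, fractional anisotropy, and the axial/radial
#' kurtoses from axisymmetric parameters:
#' Dbar = (2 D_perp + D_par)/3;
#' FA = sqrt(3/2) sqrt((D_par - Dbar)^2 + 2 (D_perp - Dbar)^2) /
#'      sqrt(D_par^2 + 2 D_perp^2);
#' K_par = W_par Dbar^2 / D_par^2; K_perp = W_perp Dbar^2 / D_perp^2.
#' Where a denominator is exactly zero the corresponding metric is marked
#' undefined (`NaN`), never silently infinite; `w_mean` is passed through.
#' All arguments are vectorized.
#'
#' @param d_perp,d_par diffusivities in µm²/ms, or pass an [axisym_params()]
#'   as `d_perp` to take all five parameters from it.
#' @param w_perp,w_par,w_mean tensor kurtosis parameters.
#' @return a tibble with columns `d_mean`, `fa`, `k_par`, `k_perp`, `w_mean`.
#' @examples
#' derived_metrics(d_perp = 1, d_par = 2, w_par = 1)
#' @export
derived_metrics <- function(d_perp, d_par = NULL, w_perp = 0, w_par = 0, w_mean = 0) {
  if (inherits(d_perp, "axisym_params")) {
    p <- d_perp
    d_par <- p$d_par; w_perp <- p$w_perp; w_par <- p$w_par; w_mean <- p$w_mean
    d_perp <- p$d_perp
  }
  d_mean <- (2 * d_perp + d_par) / 3
  denom <- sqrt(d_par^2 + 2 * d_perp^2)
  fa <- ifelse(denom == 0, NaN,
    sqrt(3 / 2) * sqrt((d_par - d_mean)^2 + 2 * (d_perp - d_mean)^2) / denom
  )
  k_par <- ifelse(d_par == 0, NaN, w_par * d_mean^2 / d_par^2)
  k_perp <- ifelse(d_perp == 0, NaN, w_perp * d_mean^2 / d_perp^2)
  tibble::tibble(
    d_mean = d_mean, fa = fa, k_par = k_par, k_perp = k_perp,
    w_mean = w_mean + 0 * d_mean
  )
}
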
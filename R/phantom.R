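#' Synthetic multi-frequency axisymmetric DKI phantom
#'
#' Describes a two-region phantom: a curved high-anisotropy "WM" tube (think
#' corpus callosum) bending through a low-anisotropy "GM" background, with
#' per-region axisymmetric parameters, optional per-frequency kurtosis
#' dispersion, a spatially varying fiber orientation, and Rician or Gaussian
#' noise at a controlled b = 0 SNR. The defaults emulate a combined
#' PGSE/OGSE protocol: frequencies 0/60/120 Hz, b-shells 1.0 and 2.5 ms/µm²,
#' two b = 0 volumes per frequency, and the efficient 10-direction scheme.
#'
#' Default tissue values sit in the physiologic range for in vivo brain and
#' are library fixture choices, not measured claims: WM D_par = 1.5,
#' D_perp = 0.4 µm²/ms, W_par = 0.6, W_perp = 1.6, W_mean = 1.0; GM
#' D_par = D_perp = 0.8 µm²/ms, all W = 0.7.
#'
#' @param dim grid shape in voxels, length 3.
#' @param snr signal-to-noise ratio at b = 0 (`Inf` disables noise).
#' @param noise noise model: `"rician"` (magnitude of complex Gaussian,
#'   default for magnitude MRI), `"gaussian"`, or `"none"`.
#' @param s0 b = 0 signal amplitude (arbitrary units); noise sigma = s0/snr.
#' @param frequencies oscillation frequencies in Hz.
#' @param shells non-zero b-values in ms/µm².
#' @param n_b0 b = 0 volumes per frequency.
#' @param directions encoding direction set (rows), default
#'   [ten_direction_scheme()].
#' @param averages number of independent noisy repetitions combined by mean
#'   (emulating multi-average protocols).
#' @param dispersion per-frequency kurtosis dispersion mode, see
#'   [frequency_dispersion_profile()].
#' @param dispersion_slope fractional kurtosis decrease at the highest
#'   frequency for the `"linear-decrease"` mode.
#' @param orientation `"bending"` (WM axis follows the tube tangent) or
#'   `"constant"`.
#' @param wm,gm named lists of region parameters
#'   (`d_perp`, `d_par`, `w_perp`, `w_par`, `w_mean`).
#' @param tube_radius tube thickness in voxels.
#' @param seed RNG seed for reproducible noise (`NULL` = use current RNG
#'   state).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(16, 16, 8), snr = 20,
                         noise = c("rician", "gaussian", "none"),
                         s0 = 100,
                         frequencies = c(0, 60, 120), shells = c(1, 2.5),
                         n_b0 = 2L, directions = ten_direction_scheme(),
                         averages = 1L,
                         dispersion = c("linear-decrease", "none"),
                         dispersion_slope = 0.3,
                         orientation = c("bending", "constant"),
                         wm = list(d_perp = 0.4, d_par = 1.5, w_perp = 1.6, w_par = 0.6, w_mean = 1.0),
                         gm = list(d_perp = 0.8, d_par = 0.8, w_perp = 0.7, w_par = 0.7, w_mean = 0.7),
                         tube_radius = 2,
                         seed = NULL) {
  noise <- match.arg(noise)
  if (!is.infinite(snr) && snr <= 0) stop("`snr` must be > 0")
  structure(
    list(
      dim = as.integer(dim), snr = snr, noise = noise, s0 = s0,
      frequencies = frequencies, shells = shells, n_b0 = as.integer(n_b0),
      directions = directions, averages = as.integer(averages),
      dispersion = match.arg(dispersion), dispersion_slope = dispersion_slope,
      orientation = match.arg(orientation), wm = wm, gm = gm,
      tube_radius = tube_radius, seed = seed
    ),
    class = "phantom_spec"
  )
}

#' Per-frequency ground-truth kurtosis dispersion
#'
#' Scales the kurtosis parameters of a region deterministically with
#' oscillation frequency while keeping diffusivities and orientation fixed:
#' `"linear-decrease"` gives `W(f) = W(0) (1 - slope * f / max(f))`,
#' emulating the decrease of kurtosis with shorter effective diffusion time;
#' `"none"` keeps all frequencies identical.
#'
#' @param params named list with `d_perp`, `d_par`, `w_perp`, `w_par`,
#'   `w_mean` at the reference (lowest) frequency.
#' @param frequencies frequencies in Hz.
#' @param mode `"linear-decrease"` or `"none"`.
#' @param slope fractional decrease at `max(frequencies)`.
#' @return a tibble with one row per frequency and the five parameter columns.
#' @export
frequency_dispersion_profile <- function(params, frequencies,
                                         mode = c("linear-decrease", "none"),
                                         slope = 0.3) {
  mode <- match.arg(mode)
  fmax <- max(frequencies)
  scale <- if (mode == "none" || fmax == 0) rep(1, length(frequencies)) else 1 - slope * frequencies / fmax
  tibble::tibble(
    freq = frequencies,
    d_perp = params$d_perp, d_par = params$d_par,
    w_perp = params$w_perp * scale,
    w_par = params$w_par * scale,
    w_mean = params$w_mean * scale
  )
}

# geometry: label array (1 = background "GM", 2 = tube "WM") and per-voxel
# unit orientation axes
phantom_geometry <- function(spec) {
  d <- spec$dim
  centre <- c(2, 2)
  radius <- 0.55 * min(d[1], d[2])
  lab <- array(1L, d)
  axes <- array(0, c(d, 3L))
  const_axis <- c(1, 1, 0) / sqrt(2)
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      r <- sqrt((ix - centre[1])^2 + (iy - centre[2])^2)
      phi <- atan2(iy - centre[2], ix - centre[1])
      in_tube <- abs(r - radius) <= spec$tube_radius &&
        phi >= 5 * pi / 180 && phi <= 85 * pi / 180
      ax <- if (in_tube) {
        if (spec$orientation == "bending") c(-sin(phi), cos(phi), 0) else const_axis
      } else {
        c(0, 0, 1)
      }
      for (iz in seq_len(d[3])) {
        if (in_tube) lab[ix, iy, iz] <- 2L
        axes[ix, iy, iz, ] <- ax
      }
    }
  }
  list(labels = lab, axes = axes)
}

#' Generate a synthetic phantom dataset
#'
#' Evaluates the axisymmetric forward model per voxel and volume, adds noise
#' at the configured SNR, and returns the signal volume together with the
#' complete ground truth. With `spec$averages > 1` independent noisy
#' repetitions are combined by mean. Generation is bit-reproducible for a
#' fixed spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @param scheme optional [gradient_scheme()]; by default built from the spec
#'   (directions x shells x frequencies plus b0 volumes).
#' @return an object of class `axdki_phantom`: `volume` ([signal_volume()]),
#'   `scheme`, and `truth` with per-voxel region `labels`, orientation
#'   `axes`, and `params` (named list per frequency of voxels x 6 matrices
#'   `log_s0, d_perp, d_par, u_perp, u_par, u_mean`).
#' @export
generate_phantom <- function(spec, scheme = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(scheme)) {
    scheme <- build_scheme(spec$directions,
      shells = spec$shells,
      frequencies = spec$frequencies, n_b0 = spec$n_b0
    )
  }
  geo <- phantom_geometry(spec)
  d <- spec$dim
  mask <- array(TRUE, d)
  m <- prod(d)
  lab <- as.vector(geo$labels)
  axes <- matrix(geo$axes, m, 3L)
  freqs <- sort(unique(scheme$freq))

  profiles <- list(
    frequency_dispersion_profile(spec$gm, freqs, spec$dispersion, spec$dispersion_slope),
    frequency_dispersion_profile(spec$wm, freqs, spec$dispersion, spec$dispersion_slope)
  )

  dirs <- scheme_directions(scheme, unit = TRUE)
  nvol <- nrow(scheme)
  logmu <- matrix(0, m, nvol)
  params <- stats::setNames(vector("list", length(freqs)), as.character(freqs))
  log_s0 <- log(spec$s0)

  for (k in seq_along(freqs)) {
    pf <- matrix(0, m, 6L,
      dimnames = list(NULL, c("log_s0", "d_perp", "d_par", "u_perp", "u_par", "u_mean"))
    )
    for (region in 1:2) {
      row <- profiles[[region]][k, ]
      vox <- lab == region
      dbar <- (2 * row$d_perp + row$d_par) / 3
      pf[vox, ] <- matrix(
        c(log_s0, row$d_perp, row$d_par,
          dbar^2 * row$w_perp, dbar^2 * row$w_par, dbar^2 * row$w_mean),
        sum(vox), 6L, byrow = TRUE
      )
    }
    params[[k]] <- pf
    sub <- which(scheme$freq == freqs[k])
    c2t <- (axes %*% t(dirs[sub, , drop = FALSE]))^2
    c2t[, scheme$b0[sub]] <- 1
    kc <- kurtosis_design_coef(c2t)
    b <- matrix(scheme$bval[sub], m, length(sub), byrow = TRUE)
    dif <- pf[, "d_perp"] + c2t * (pf[, "d_par"] - pf[, "d_perp"])
    wterm <- kc$perp * pf[, "u_perp"] + kc$par * pf[, "u_par"] + kc$mean * pf[, "u_mean"]
    logmu[, sub] <- log_s0 - b * dif + b^2 / 6 * wterm
  }

  mu <- exp(logmu)
  if (spec$noise == "none" || is.infinite(spec$snr)) {
    signal <- mu
  } else {
    sigma <- spec$s0 / spec$snr
    acc <- 0
    for (rep in seq_len(spec$averages)) {
      e1 <- matrix(stats::rnorm(length(mu), sd = sigma), m, nvol)
      rep_sig <- if (spec$noise == "rician") {
        e2 <- matrix(stats::rnorm(length(mu), sd = sigma), m, nvol)
        sqrt((mu + e1)^2 + e2^2)
      } else {
        mu + e1
      }
      acc <- acc + rep_sig
    }
    signal <- acc / spec$averages
  }

  vol <- signal_volume(array(signal, c(d, nvol)), mask = mask)
  structure(
    list(
      volume = vol, scheme = scheme,
      truth = list(labels = lab, axes = axes, params = params,
                   profiles = stats::setNames(profiles, c("GM", "WM"))),
      spec = spec
    ),
    class = "axdki_phantom"
  )
}

#' @export
print.axdki_phantom <- function(x, ...) {
  cat(sprintf(
    "<axdki_phantom> %s grid, %d volumes, SNR %s (%s noise)\n",
    paste(x$spec$dim, collapse = "x"), nrow(x$scheme),
    format(x$spec$snr), x$spec$noise
  ))
  invisible(x)
}

#' Ground-truth scalar metrics of a phantom at one frequency
#'
#' @param phantom an `axdki_phantom`.
#' @param frequency frequency in Hz.
#' @return tibble with per-voxel `d_mean`, `fa`, `k_par`, `k_perp`, `w_mean`
#'   plus the region `label`.
#' @export
phantom_truth_metrics <- function(phantom, frequency) {
  pf <- phantom$truth$params[[as.character(frequency)]]
  if (is.null(pf)) stop("phantom has no ground truth at this frequency")
  dbar <- (2 * pf[, "d_perp"] + pf[, "d_par"]) / 3
  out <- derived_metrics(
    d_perp = pf[, "d_perp"], d_par = pf[, "d_par"],
    w_perp = pf[, "u_perp"] / dbar^2,
    w_par = pf[, "u_par"] / dbar^2,
    w_mean = pf[, "u_mean"] / dbar^2
  )
  out$label <- phantom$truth$labels
  out
}

#' Region-of-interest masks of the default phantom
#'
#' @param phantom an `axdki_phantom`.
#' @return list with logical per-masked-voxel vectors `wm` and `gm`.
#' @export
phantom_rois <- function(phantom) {
  list(wm = phantom$truth$labels == 2L, gm = phantom$truth$labels == 1L)
}
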
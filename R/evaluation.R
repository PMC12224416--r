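#' Contrast-to-standard-deviation ratio between two ROIs
#'
#' CSR = (mean_A - mean_B) / sqrt(sd_A^2 + sd_B^2) for a scalar map and two
#' disjoint regions of interest. Undefined-metric sentinels (`NaN`, typically
#' "blackened" negative-kurtosis voxels excluded upstream) and other
#' non-finite values are excluded from the means and standard deviations;
#' their counts are reported in the `"excluded"` attribute because the
#' prevalence of such voxels is itself a noise measure.
#'
#' @param map numeric vector (masked voxels) or array of map values.
#' @param roi_a,roi_b logical vectors/arrays or integer indices into `map`;
#'   must be non-empty after exclusion.
#' @return the CSR (numeric scalar) with attribute `excluded = c(a, b)`.
#' @examples
#' csr(c(2, 2, 1, 1), roi_a = c(TRUE, TRUE, FALSE, FALSE), roi_b = c(FALSE, FALSE, TRUE, TRUE))
#' @export
csr <- function(map, roi_a, roi_b) {
  map <- as.vector(map)
  va <- map[roi_a]
  vb <- map[roi_b]
  ka <- is.finite(va)
  kb <- is.finite(vb)
  if (!any(ka) || !any(kb)) stop("ROI empty after excluding non-finite voxels")
  out <- (mean(va[ka]) - mean(vb[kb])) /
    sqrt(stats::var(va[ka]) + stats::var(vb[kb]))
  attr(out, "excluded") <- c(a = sum(!ka), b = sum(!kb))
  out
}

#' Voxel-wise SNR from repeated b = 0 acquisitions
#'
#' SNR is the voxel-wise signal mean divided by the voxel-wise signal
#' standard deviation across b = 0 repetitions. Voxels with zero standard
#' deviation get `Inf` and are counted as flagged.
#'
#' @param b0_stack 4D array (x, y, z, repetition) or matrix (voxels x
#'   repetitions) of b = 0 images; at least 3 repetitions.
#' @param roi optional logical array/vector selecting voxels for the summary
#'   mean.
#' @return list with `map` (same spatial layout as the input), `roi_mean`
#'   (mean SNR over the ROI, or over all voxels when no ROI is given; `Inf`
#'   voxels excluded) and `n_flagged`.
#' @export
snr_map <- function(b0_stack, roi = NULL) {
  dims <- dim(b0_stack)
  x <- if (length(dims) == 4L) matrix(b0_stack, prod(dims[1:3]), dims[4]) else as.matrix(b0_stack)
  if (ncol(x) < 3L) stop("need at least 3 b = 0 repetitions")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  snr <- ifelse(sdv == 0, Inf, mu / sdv)
  sel <- if (is.null(roi)) rep(TRUE, length(snr)) else as.vector(roi)
  vals <- snr[sel]
  map <- if (length(dims) == 4L) array(snr, dims[1:3]) else snr
  list(
    map = map,
    roi_mean = mean(vals[is.finite(vals)]),
    n_flagged = sum(!is.finite(snr))
  )
}

# FA bin labels from edges
fa_bin_label <- function(fa, edges) {
  cut(fa, breaks = edges, include.lowest = TRUE, right = FALSE)
}

#' Cross-frequency axis agreement
#'
#' Central angles between the symmetry axes estimated at different
#' frequencies, per voxel, stratified by FA. Used to check the assumption
#' that the principal diffusion direction depends negligibly on oscillation
#' frequency (agreement is best in high-FA voxels, where the axis is well
#' defined).
#'
#' @param axes an `axis_set` from [compute_axes()] or a named list of
#'   `axis_field`s / axes matrices keyed by frequency; at least two entries.
#' @param fa per-voxel FA values used for stratification (e.g. from
#'   [axis_field_fa()]).
#' @param fa_edges FA bin edges; the default three bins split at 0.2 and 0.4
#'   (low / moderate / high anisotropy).
#' @return tibble with one row per voxel and frequency pair: `freq1`,
#'   `freq2`, `angle` (degrees), `fa`, `fa_bin`.
#' @export
axis_agreement <- function(axes, fa, fa_edges = c(0, 0.2, 0.4, Inf)) {
  fields <- if (inherits(axes, "axis_set")) axes$fields else axes
  if (length(fields) < 2L) stop("need axis fields for at least 2 frequencies")
  get_mat <- function(f) if (inherits(f, "axis_field")) f$axes else as.matrix(f)
  nm <- names(fields)
  out <- NULL
  for (i in seq_len(length(fields) - 1L)) {
    for (j in (i + 1L):length(fields)) {
      a1 <- get_mat(fields[[i]])
      a2 <- get_mat(fields[[j]])
      ang <- acos(pmin(1, abs(rowSums(a1 * a2)))) * 180 / pi
      out <- rbind(out, tibble::tibble(
        freq1 = nm[i], freq2 = nm[j], angle = ang, fa = fa,
        fa_bin = fa_bin_label(fa, fa_edges)
      ))
    }
  }
  out
}

#' Histogram of cross-frequency axis agreement
#'
#' Bins the per-voxel central angles from [axis_agreement()] by frequency
#' pair, FA bin and angle.
#'
#' @inheritParams axis_agreement
#' @param angle_breaks histogram bin edges in degrees.
#' @return tibble in long format: `freq1`, `freq2`, `fa_bin`, `angle_bin`
#'   (left edge), `count`.
#' @export
axis_agreement_histogram <- function(axes, fa, fa_edges = c(0, 0.2, 0.4, Inf),
                                     angle_breaks = seq(0, 90, by = 5)) {
  tab <- axis_agreement(axes, fa, fa_edges)
  bin <- cut(tab$angle, breaks = angle_breaks, include.lowest = TRUE, right = TRUE)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(tab))),
    by = list(freq1 = tab$freq1, freq2 = tab$freq2, fa_bin = tab$fa_bin, angle_bin = bin),
    FUN = sum, drop = FALSE
  )
  agg$count[is.na(agg$count)] <- 0L
  tibble::as_tibble(agg)
}

#' Separable 3D Gaussian filter
#'
#' Filters a 3D array with a normalized Gaussian kernel applied separably
#' along each axis. The kernel is truncated at `truncate` standard
#' deviations; boundaries are handled by reflection (edge sample included),
#' which preserves the total image sum for this symmetric kernel.
#' `sigma = 0` returns the input unchanged.
#'
#' @param x 3D numeric array.
#' @param sigma kernel standard deviation in voxels, >= 0.
#' @param truncate kernel support half-width in standard deviations.
#' @return filtered 3D array.
#' @export
gaussian_filter_3d <- function(x, sigma, truncate = 4) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(x)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  d <- dim(x)
  for (axis in 1:3) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    xp <- aperm(x, perm)
    n <- dim(xp)[1]
    m <- matrix(xp, n)
    # reflection with edge sample included: ... 2 1 | 1 2 ... n | n n-1 ...
    ii <- ((1 - r):(n + r) - 1L) %% (2L * n)
    pad_idx <- ifelse(ii < n, ii + 1L, 2L * n - ii)
    padded <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2 * r + 1)) {
      out <- out + k[j] * padded[j:(j + n - 1), , drop = FALSE]
    }
    x <- aperm(array(out, dim(xp)), order(perm))
  }
  x
}

#' Gaussian pre-smoothing of diffusion-weighted images
#'
#' Smooths every volume of the stack with a 3D Gaussian kernel before any
#' log transform or fitting - the conventional DKI noise-reduction
#' pre-processing step that spatial regularization during fitting is compared
#' against. Smoothing is applied to the magnitude images over the full grid
#' (not masked), with reflective boundaries and a 4-sigma kernel truncation.
#' `sigma = 0` is the identity.
#'
#' @param volume a [signal_volume()].
#' @param sigma Gaussian kernel standard deviation in voxels.
#' @return a smoothed [signal_volume()] with the same mask and geometry.
#' @export
gaussian_presmooth <- function(volume, sigma) {
  if (sigma == 0) return(volume)
  out <- volume$data
  for (v in seq_len(dim(out)[4])) {
    out[, , , v] <- gaussian_filter_3d(out[, , , v], sigma)
  }
  signal_volume(out, mask = volume$mask, voxdim = volume$voxdim, affine = volume$affine)
}
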
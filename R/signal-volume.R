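#' 4D diffusion-weighted signal volume
#'
#' Couples a 4D image stack (x, y, z, volume) with a binary brain mask and
#' voxel geometry. All fitting operates on the voxels inside the mask.
#'
#' @param data 4D numeric array (nx, ny, nz, n_volumes), or 3D for a single
#'   volume.
#' @param mask 3D logical (or 0/1) array matching the spatial grid; defaults
#'   to all voxels.
#' @param voxdim voxel dimensions (mm), length 3.
#' @param affine optional 4x4 NIfTI affine, preserved verbatim on write.
#' @return an object of class `signal_volume`.
#' @export
signal_volume <- function(data, mask = NULL, voxdim = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("`data` must be a 3D or 4D array")
  d3 <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), d3)) stop("`mask` must match the spatial grid of `data`")
  if (any(is.na(mask))) stop("`mask` must not contain missing values")
  structure(
    list(data = data, mask = mask, voxdim = as.numeric(voxdim), affine = affine),
    class = "signal_volume"
  )
}

#' @export
print.signal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<signal_volume> %d x %d x %d grid, %d volumes, %d voxels in mask\n",
    d[1], d[2], d[3], d[4], sum(x$mask)
  ))
  invisible(x)
}

#' Number of volumes in a signal volume
#' @param volume a [signal_volume()].
#' @return integer count.
#' @export
n_volumes <- function(volume) dim(volume$data)[4]

# masked voxels x volumes signal matrix
masked_signal <- function(volume, subset = NULL) {
  d <- dim(volume$data)
  m <- matrix(volume$data, prod(d[1:3]), d[4])[as.vector(volume$mask), , drop = FALSE]
  if (!is.null(subset)) m <- m[, subset, drop = FALSE]
  m
}

#' Log-transformed signal matrix
#'
#' Returns log signals for the masked voxels (voxels x volumes). Non-positive
#' intensities, which arise from noise at high diffusion weighting, are
#' floored at `eps` times a per-voxel S0 estimate (mean over b = 0 volumes)
#' before taking the log; the number of floored samples is reported as an
#' attribute `n_guarded`.
#'
#' @param volume a [signal_volume()].
#' @param scheme the matching [gradient_scheme()] (used to locate b0 volumes).
#' @param subset optional volume indices to retain (applied after the floor
#'   is computed from the full set of b0 volumes).
#' @param eps relative floor, default 1e-6.
#' @return numeric matrix of log signals with attribute `n_guarded`.
#' @export
log_signal <- function(volume, scheme, subset = NULL, eps = 1e-6) {
  s <- masked_signal(volume)
  if (nrow(scheme) != ncol(s)) stop("scheme and volume disagree on the number of volumes")
  b0 <- which(scheme$b0)
  s0 <- if (length(b0)) rowMeans(s[, b0, drop = FALSE]) else apply(s, 1L, max)
  floorv <- eps * pmax(s0, .Machine$double.xmin)
  if (!is.null(subset)) s <- s[, subset, drop = FALSE]
  n_guarded <- sum(s < floorv)
  y <- log(pmax(s, floorv))
  attr(y, "n_guarded") <- n_guarded
  y
}

# place a masked-voxel matrix back on the full grid as a 4D (or 3D) array,
# NA outside the mask
unmask <- function(values, mask) {
  values <- as.matrix(values)
  out <- array(NA_real_, c(dim(mask), ncol(values)))
  flat <- matrix(out, prod(dim(mask)), ncol(values))
  flat[as.vector(mask), ] <- values
  out <- array(flat, c(dim(mask), ncol(values)))
  if (dim(out)[4] == 1L) out <- array(out, dim(mask))
  out
}
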
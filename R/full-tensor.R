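#' Full kurtosis-tensor baseline fit
#'
#' The unconstrained DKI representation carries 22 free parameters per voxel:
#' log S0, the 6 unique diffusion-tensor components, and the 15 unique
#' components of the fully symmetric fourth-order kurtosis tensor W. It is
#' the reference against which the 8-parameter axisymmetric fit (6 linear
#' parameters plus a two-angle symmetry axis) is compared.
#'
#' @name full_tensor
#' @keywords internal
NULL

# the 15 unique components of a fully symmetric 4th-order tensor: sorted index
# quadruples and permutation multiplicities (1 for iiii, 4 for iiij, 6 for
# iijj, 12 for iijk)
w_component_table <- function() {
  idx <- rbind(
    c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
    c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2), c(2, 2, 2, 3),
    c(1, 3, 3, 3), c(2, 3, 3, 3),
    c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
    c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3)
  )
  mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
  nm <- apply(idx, 1L, function(r) paste0("w", paste(c("x", "y", "z")[r], collapse = "")))
  list(idx = idx, mult = mult, names = nm)
}

# map from any (i, j, k, l) tuple to its unique-component column
w_tuple_map <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    tab <- w_component_table()
    key <- apply(tab$idx, 1L, paste, collapse = "")
    m <- array(0L, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      m[i, j, k, l] <- match(paste(sort(c(i, j, k, l)), collapse = ""), key)
    }
    cached <<- m
    m
  }
})

# length-15 coefficient vector of the 4-linear form W(n1, n2, n3, n4)
quartic_form_coef <- function(n1, n2, n3 = n1, n4 = n2) {
  m <- w_tuple_map()
  coef <- numeric(15L)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    coef[m[i, j, k, l]] <- coef[m[i, j, k, l]] + n1[i] * n2[j] * n3[k] * n4[l]
  }
  coef
}

#' Design matrix of the full (22-parameter) kurtosis-tensor fit
#'
#' Row n is `(1, -b n_i n_j terms, (b^2/6) n_i n_j n_k n_l terms)` so that the
#' row dotted with `(log S0, D_xx..D_yz, U_xxxx..U_xyzz)` gives the DKI
#' log-signal, where `U = Dbar^2 W` absorbs the mean-diffusivity scaling of
#' the kurtosis term (standard two-pass convention: the linear fit estimates
#' U, and W is recovered afterwards using Dbar from the fitted tensor block).
#'
#' @inheritParams build_dti_design
#' @return matrix (volumes x 22).
#' @export
build_full_dki_design <- function(scheme, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(scheme))
  dirs <- scheme_directions(scheme, unit = TRUE)[subset, , drop = FALSE]
  b <- scheme$bval[subset]
  a <- matrix(0, length(subset), 22L)
  a[, 1L] <- 1
  tab <- w_component_table()
  for (r in seq_along(subset)) {
    if (b[r] == 0) next
    n <- dirs[r, ]
    a[r, 2:7] <- -b[r] * c(n[1]^2, n[2]^2, n[3]^2, 2 * n[1] * n[2], 2 * n[1] * n[3], 2 * n[2] * n[3])
    a[r, 8:22] <- b[r]^2 / 6 * tab$mult *
      apply(tab$idx, 1L, function(q) prod(n[q]))
  }
  a
}

#' Ordinary least-squares fit of the full kurtosis tensor
#'
#' Per-voxel OLS solution of the 22-column log-signal model. The design must
#' have full column rank, which requires at least two non-zero b-shells and
#' at least 15 directions whose quartics are linearly independent; with 14 or
#' fewer distinct directions the kurtosis block is rank deficient and an
#' error is raised. After the linear solve, W components are recovered from
#' the fitted `U = Dbar^2 W` block using Dbar = trace(D)/3.
#'
#' @inheritParams fit_dti
#' @return an object of class `kt_field` with per-voxel `log_s0`, diffusion
#'   tensor `dt` (voxels x 6: xx, yy, zz, xy, xz, yz), kurtosis tensor `wt`
#'   (voxels x 15) and `d_mean`.
#' @export
fit_full_dki <- function(volume, scheme, subset = NULL) {
  a <- build_full_dki_design(scheme, subset)
  if (qr(a)$rank < 22L) {
    stop("full kurtosis-tensor design is rank-deficient: need >= 2 non-zero shells and >= 15 independent directions")
  }
  y <- log_signal(volume, scheme, subset = subset)
  x <- t(solve(crossprod(a), crossprod(a, t(y))))
  dt <- x[, 2:7, drop = FALSE]
  d_mean <- rowMeans(dt[, 1:3, drop = FALSE])
  wt <- x[, 8:22, drop = FALSE] / d_mean^2
  colnames(wt) <- w_component_table()$names
  colnames(dt) <- c("d_xx", "d_yy", "d_zz", "d_xy", "d_xz", "d_yz")
  structure(
    list(
      log_s0 = x[, 1L], dt = dt, wt = wt, d_mean = d_mean,
      mask = volume$mask, voxdim = volume$voxdim, subset = subset
    ),
    class = "kt_field"
  )
}

#' @export
print.kt_field <- function(x, ...) {
  cat(sprintf("<kt_field> %d voxels, 22-parameter kurtosis-tensor fit\n", length(x$log_s0)))
  invisible(x)
}

#' Directional kurtosis from a full kurtosis tensor
#'
#' Full symmetric contraction W(n) = sum over ijkl of n_i n_j n_k n_l W_ijkl,
#' evaluated from the 15 unique components with their permutation
#' multiplicities.
#'
#' @param w a `kt_field`, or a voxels x 15 matrix / length-15 vector of unique
#'   W components.
#' @param direction unit length-3 vector.
#' @return per-voxel directional kurtosis (numeric vector).
#' @export
directional_w_full <- function(w, direction) {
  if (inherits(w, "kt_field")) w <- w$wt
  if (is.null(dim(w))) w <- matrix(w, 1L)
  n <- direction / sqrt(sum(direction^2))
  tab <- w_component_table()
  coef <- tab$mult * apply(tab$idx, 1L, function(q) prod(n[q]))
  drop(w %*% coef)
}

#' General four-linear form of the kurtosis tensor
#'
#' Evaluates sum over ijkl of W_ijkl n1_i n2_j n3_k n4_l; with all four
#' arguments equal this reduces to [directional_w_full()].
#'
#' @inheritParams directional_w_full
#' @param n1,n2,n3,n4 length-3 vectors.
#' @return numeric vector (one value per voxel).
#' @export
w_quartic_form <- function(w, n1, n2, n3 = n1, n4 = n2) {
  if (inherits(w, "kt_field")) w <- w$wt
  if (is.null(dim(w))) w <- matrix(w, 1L)
  drop(w %*% quartic_form_coef(n1, n2, n3, n4))
}

#' Spherical mean of the directional kurtosis (mean kurtosis tensor)
#'
#' Closed form of the average of W(n) over the unit sphere,
#' `(W_xxxx + W_yyyy + W_zzzz + 2 (W_xxyy + W_xxzz + W_yyzz)) / 5`, which is
#' frame-invariant.
#'
#' @inheritParams directional_w_full
#' @return per-voxel mean kurtosis tensor.
#' @export
sphere_mean_w <- function(w) {
  if (inherits(w, "kt_field")) w <- w$wt
  if (is.null(dim(w))) w <- matrix(w, 1L)
  (w[, 1L] + w[, 2L] + w[, 3L] + 2 * (w[, 10L] + w[, 11L] + w[, 12L])) / 5
}

# orthonormal basis perpendicular to a unit axis
perp_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  e <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- e - sum(e * axis) * axis
  p <- p / sqrt(sum(p^2))
  q <- c(
    axis[2] * p[3] - axis[3] * p[2],
    axis[3] * p[1] - axis[1] * p[3],
    axis[1] * p[2] - axis[2] * p[1]
  )
  list(p = p, q = q)
}

#' Radial tensor kurtosis: circle average of W(n) perpendicular to an axis
#'
#' Averages the directional kurtosis over the unit circle perpendicular to
#' `axis`. Using the in-plane trigonometric moments (mean cos^4 = 3/8, mean
#' cos^2 sin^2 = 1/8) the average reduces to the closed form
#' `(3/8) (W(p) + W(q)) + (3/4) W(p, p, q, q)` for any orthonormal in-plane
#' basis (p, q); odd-order terms vanish.
#'
#' @inheritParams directional_w_full
#' @param axis unit symmetry axis (length 3).
#' @return per-voxel radial tensor kurtosis.
#' @export
circle_mean_w <- function(w, axis) {
  basis <- perp_basis(axis)
  (3 / 8) * (directional_w_full(w, basis$p) + directional_w_full(w, basis$q)) +
    (3 / 4) * w_quartic_form(w, basis$p, basis$p, basis$q, basis$q)
}

# per-voxel axisymmetric-defined tensor kurtosis triplet from a full tensor
axisym_w_from_full <- function(field, axes) {
  m <- nrow(field$wt)
  out <- matrix(NA_real_, m, 3L, dimnames = list(NULL, c("w_perp", "w_par", "w_mean")))
  out[, "w_mean"] <- sphere_mean_w(field$wt)
  for (i in seq_len(m)) {
    a <- axes[i, ]
    if (!all(is.finite(a))) next
    out[i, "w_par"] <- directional_w_full(field$wt[i, ], a)
    out[i, "w_perp"] <- circle_mean_w(field$wt[i, , drop = FALSE], a)
  }
  out
}

#' Axisymmetric-defined scalar metrics from a full kurtosis-tensor fit
#'
#' Extracts the tensor-kurtosis metrics used by the axisymmetric model from
#' an unconstrained fit: W_par is the directional kurtosis along the axis,
#' W_mean the spherical average, and W_perp the circle average perpendicular
#' to the axis; K_par and K_perp then follow with D_par taken as the axial
#' eigenvalue and D_perp as the mean of the two radial eigenvalues of the
#' diffusion-tensor block. By default the axis is the principal eigenvector
#' of that same diffusion-tensor block.
#'
#' @param field a `kt_field` from [fit_full_dki()].
#' @param axes optional `axis_field` or axes matrix; defaults to the
#'   principal eigenvector of the fitted tensor block.
#' @return a `metric_maps` object (columns `d_mean`, `fa`, `k_par`, `k_perp`,
#'   `w_mean`) with `w_par`/`w_perp` attached in `meta$w`.
#' @export
axisym_metrics_from_full <- function(field, axes = NULL) {
  m <- nrow(field$wt)
  evals <- matrix(NA_real_, m, 3L)
  default_ax <- matrix(NA_real_, m, 3L)
  for (i in seq_len(m)) {
    e <- eigen(tensor3(field$dt[i, ]), symmetric = TRUE)
    default_ax[i, ] <- fix_axis_sign(e$vectors[, 1L])
    evals[i, ] <- e$values
  }
  axmat <- if (is.null(axes)) {
    default_ax
  } else if (inherits(axes, "axis_field")) axes$axes else as.matrix(axes)
  # axial diffusivity along the chosen axis; radial = mean of the remainder
  d <- field$dt
  d_par <- d[, 1L] * axmat[, 1L]^2 + d[, 2L] * axmat[, 2L]^2 + d[, 3L] * axmat[, 3L]^2 +
    2 * (d[, 4L] * axmat[, 1L] * axmat[, 2L] + d[, 5L] * axmat[, 1L] * axmat[, 3L] +
      d[, 6L] * axmat[, 2L] * axmat[, 3L])
  d_mean <- rowMeans(evals)
  d_perp <- (3 * d_mean - d_par) / 2
  wtrip <- axisym_w_from_full(field, axmat)
  den <- sqrt(rowSums(evals^2))
  fa <- ifelse(den == 0, NaN, sqrt(3 / 2) * sqrt(rowSums((evals - d_mean)^2)) / den)
  vals <- cbind(
    d_mean = d_mean,
    fa = fa,
    k_par = ifelse(d_par == 0, NaN, wtrip[, "w_par"] * d_mean^2 / d_par^2),
    k_perp = ifelse(d_perp == 0, NaN, wtrip[, "w_perp"] * d_mean^2 / d_perp^2),
    w_mean = wtrip[, "w_mean"]
  )
  structure(
    list(
      values = vals, mask = field$mask, voxdim = field$voxdim,
      frequency = NULL,
      meta = list(method = "full_tensor", w = wtrip, axes = axmat)
    ),
    class = "metric_maps"
  )
}
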
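#' Regularized linear inversion engine
#'
#' Internal engine shared by the diffusion-tensor and axisymmetric DKI fitting
#' steps. It minimizes the quadratic objective
#' \deqn{\|A x - y\|_2^2 + \gamma \|T x\|_2^2}
#' over all masked voxels jointly, where the data term is voxel-separable
#' (one small design matrix per voxel, or one design shared by all voxels)
#' and the penalty T takes weighted spatial first differences of selected
#' parameter components, coupling each voxel to its in-mask forward
#' neighbors. The minimizer solves the normal equations
#' (A'A + gamma T'T) x = A'y, which are handled matrix-free by conjugate
#' gradients: the full system matrix is never materialized.
#'
#' @name solver
#' @keywords internal
NULL

#' Forward-difference neighbor structure of a mask
#'
#' For each spatial axis, returns the masked-voxel index of the +1 neighbor
#' along that axis (NA when the neighbor is outside the array or outside the
#' mask). Differences are taken in index space with a zero (Neumann-style)
#' boundary: the penalty never couples masked to unmasked voxels.
#'
#' @param mask 3D logical array.
#' @return list with `fwd` (list of 3 integer vectors, one per axis, length =
#'   number of masked voxels) and `n` (masked voxel count).
#' @export
mask_neighbors <- function(mask) {
  d <- dim(mask)
  idx <- array(0L, d)
  idx[mask] <- seq_len(sum(mask))
  shift <- function(axis) {
    nbr <- array(0L, d)
    if (axis == 1L && d[1] > 1L) nbr[1:(d[1] - 1), , ] <- idx[2:d[1], , ]
    if (axis == 2L && d[2] > 1L) nbr[, 1:(d[2] - 1), ] <- idx[, 2:d[2], ]
    if (axis == 3L && d[3] > 1L) nbr[, , 1:(d[3] - 1)] <- idx[, , 2:d[3]]
    f <- nbr[mask]
    f[f == 0L] <- NA_integer_
    f
  }
  list(fwd = lapply(1:3, shift), n = sum(mask))
}

#' Apply the weighted first-difference penalty operator
#'
#' Computes the entries of T x: for each axis a and parameter component c,
#' `weights[c] * (x[neighbor, c] - x[voxel, c])`, zero where the forward
#' neighbor is missing. The result keeps one block per axis so that each
#' masked voxel contributes `3 * sum(weights > 0)` penalty entries.
#'
#' @param x masked-voxel parameter matrix (voxels x components).
#' @param neighbors output of [mask_neighbors()].
#' @param weights per-component penalty weights (0 = component unpenalized).
#' @return list of 3 matrices (voxels x components), one per axis.
#' @export
tv_apply <- function(x, neighbors, weights) {
  x <- as.matrix(x)
  lapply(neighbors$fwd, function(f) {
    ok <- !is.na(f)
    d <- -x
    d[!ok, ] <- 0
    d[ok, ] <- d[ok, , drop = FALSE] + x[f[ok], , drop = FALSE]
    sweep(d, 2L, weights, `*`)
  })
}

#' Adjoint of the weighted first-difference penalty operator
#'
#' Given per-axis penalty entries `r` (as produced by [tv_apply()]), applies
#' T' r. The adjoint of the forward difference with the zero-boundary
#' convention is the negative backward difference with matching boundary
#' handling.
#'
#' @param r list of 3 matrices (voxels x components).
#' @inheritParams tv_apply
#' @return matrix (voxels x components).
#' @export
tv_apply_adjoint <- function(r, neighbors, weights) {
  out <- 0
  for (a in 1:3) {
    f <- neighbors$fwd[[a]]
    ok <- !is.na(f)
    ra <- sweep(as.matrix(r[[a]]), 2L, weights, `*`)
    ra[!ok, ] <- 0
    acc <- -ra
    acc[f[ok], ] <- acc[f[ok], , drop = FALSE] + ra[ok, , drop = FALSE]
    out <- out + acc
  }
  out
}

# gamma * T'T x in one pass (differences are unweighted, weights enter squared)
tv_normal <- function(x, neighbors, weights2) {
  out <- 0
  for (a in 1:3) {
    f <- neighbors$fwd[[a]]
    ok <- !is.na(f)
    d <- -x
    d[!ok, ] <- 0
    d[ok, ] <- d[ok, , drop = FALSE] + x[f[ok], , drop = FALSE]
    acc <- -d
    acc[f[ok], ] <- acc[f[ok], , drop = FALSE] + d[ok, , drop = FALSE]
    out <- out + acc
  }
  sweep(out, 2L, weights2, `*`)
}

# apply the voxel-separable Gram block(s): shared p x p matrix, or a
# voxels x p x p array of per-voxel Gram matrices
gram_apply <- function(gram, x) {
  if (is.matrix(gram)) {
    return(x %*% gram)
  }
  p <- dim(gram)[2]
  out <- matrix(0, nrow(x), p)
  for (k in seq_len(p)) {
    acc <- 0
    for (l in seq_len(p)) acc <- acc + gram[, k, l] * x[, l]
    out[, k] <- acc
  }
  out
}

#' Define a regularized inversion problem
#'
#' @param gram either a shared p x p Gram matrix A'A (design identical in
#'   every voxel) or a voxels x p x p array of per-voxel Gram matrices.
#' @param aty voxels x p matrix of per-voxel A'y vectors.
#' @param neighbors neighbor structure from [mask_neighbors()] (or a 3D mask,
#'   converted internally).
#' @param penalty_weights length-p per-component penalty weights; components
#'   with weight 0 (e.g. log S0) are not penalized.
#' @param gamma regularization weight, >= 0.
#' @param tol relative residual tolerance of the normal equations.
#' @param maxit maximum conjugate-gradient iterations.
#' @return an object of class `reg_problem`.
#' @export
reg_problem <- function(gram, aty, neighbors, penalty_weights, gamma,
                        tol = 1e-8, maxit = 500L) {
  if (is.array(neighbors) || is.logical(neighbors)) neighbors <- mask_neighbors(neighbors)
  aty <- as.matrix(aty)
  p <- ncol(aty)
  if (length(penalty_weights) != p) stop("`penalty_weights` must have one entry per parameter")
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (tol <= 0) stop("`tol` must be > 0")
  if (nrow(aty) != neighbors$n) stop("`aty` rows must match the masked voxel count")
  structure(
    list(
      gram = gram, aty = aty, neighbors = neighbors,
      penalty_weights = as.numeric(penalty_weights),
      gamma = gamma, tol = tol, maxit = as.integer(maxit)
    ),
    class = "reg_problem"
  )
}

#' Apply the normal operator A'A + gamma T'T
#'
#' Matrix-free evaluation of the symmetric positive semi-definite operator of
#' the normal equations. Linear and self-adjoint; the full matrix is never
#' formed.
#'
#' @param problem a [reg_problem()].
#' @param x voxels x p parameter matrix.
#' @return voxels x p matrix.
#' @export
apply_normal_operator <- function(problem, x) {
  x <- as.matrix(x)
  if (!identical(dim(x), dim(problem$aty))) stop("`x` does not conform to the problem layout")
  out <- gram_apply(problem$gram, x)
  if (problem$gamma > 0) {
    out <- out + problem$gamma *
      tv_normal(x, problem$neighbors, problem$penalty_weights^2)
  }
  out
}

#' Solve a regularized inversion problem by conjugate gradients
#'
#' Runs conjugate gradients on the normal equations from a zero (or supplied)
#' initial field. Deterministic: identical inputs give identical outputs.
#' If the iteration budget is exhausted the best iterate is returned flagged
#' as non-converged.
#'
#' @param problem a [reg_problem()].
#' @param initial optional initial parameter matrix (voxels x p), e.g. a
#'   per-voxel unregularized solution for warm-starting; affects iteration
#'   count only, not the optimum.
#' @return list with `x` (voxels x p), `iterations`, `converged`,
#'   `rel_residual`.
#' @export
solve_regularized <- function(problem, initial = NULL) {
  b <- problem$aty
  x <- if (is.null(initial)) matrix(0, nrow(b), ncol(b)) else as.matrix(initial)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = 0 * b, iterations = 0L, converged = TRUE, rel_residual = 0))
  }
  r <- b - apply_normal_operator(problem, x)
  p <- r
  rs <- sum(r^2)
  it <- 0L
  while (sqrt(rs) > problem$tol * bnorm && it < problem$maxit) {
    np <- apply_normal_operator(problem, p)
    alpha <- rs / sum(p * np)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * np
    rs_new <- sum(r^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  converged <- sqrt(rs) <= problem$tol * bnorm
  if (!converged) {
    warning(sprintf(
      "conjugate gradients not converged after %d iterations (relative residual %.3g)",
      it, sqrt(rs) / bnorm
    ))
  }
  list(x = x, iterations = it, converged = converged, rel_residual = sqrt(rs) / bnorm)
}
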
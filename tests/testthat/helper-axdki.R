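# Shared helpers for the test suite. Oracles used in equivalence tests are
# built here from first principles (array-index loops, dense algebra) so they
# do not reuse the package's own operators.

# noiseless constant-parameter axisymmetric volume: every voxel carries the
# same parameter set and axis
make_axisym_volume <- function(dims, params, scheme) {
  dirs <- scheme_directions(scheme, unit = TRUE)
  ct <- pmin(abs(as.vector(dirs %*% params$axis)), 1)
  theta <- acos(ct)
  theta[scheme$b0] <- 0
  mu <- exp(predict_log_signal(params, scheme$bval, theta))
  signal_volume(array(rep(mu, each = prod(dims)), c(dims, length(mu))))
}

# dense first-difference penalty matrix T for a mask, built independently by
# looping over array indices: one row per (axis, in-mask forward-neighbor
# pair, component), entries -w at the voxel and +w at the neighbor. Parameter
# vector ordering is component-major: entry (k - 1) * m + voxel.
dense_penalty_matrix <- function(mask, weights) {
  d <- dim(mask)
  p <- length(weights)
  vox_id <- array(0L, d)
  vox_id[mask] <- seq_len(sum(mask))
  m <- sum(mask)
  rows <- list()
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      for (iz in seq_len(d[3])) {
        if (!mask[ix, iy, iz]) next
        i <- vox_id[ix, iy, iz]
        nbrs <- list(
          if (ix < d[1] && mask[ix + 1, iy, iz]) vox_id[ix + 1, iy, iz],
          if (iy < d[2] && mask[ix, iy + 1, iz]) vox_id[ix, iy + 1, iz],
          if (iz < d[3] && mask[ix, iy, iz + 1]) vox_id[ix, iy, iz + 1]
        )
        for (j in nbrs) {
          if (is.null(j)) next
          for (k in seq_len(p)) {
            if (weights[k] == 0) next
            r <- numeric(m * p)
            r[(k - 1) * m + i] <- -weights[k]
            r[(k - 1) * m + j] <- weights[k]
            rows[[length(rows) + 1L]] <- r
          }
        }
      }
    }
  }
  if (length(rows) == 0L) matrix(0, 0, m * p) else do.call(rbind, rows)
}

# dense normal matrix A'A + gamma T'T for a shared per-voxel design, same
# component-major ordering as dense_penalty_matrix
dense_normal_matrix <- function(design, mask, weights, gamma) {
  m <- sum(mask)
  p <- ncol(design)
  ata <- crossprod(design)
  n <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) {
    for (l in seq_len(p)) {
      idx_k <- (k - 1) * m + seq_len(m)
      idx_l <- (l - 1) * m + seq_len(m)
      n[cbind(idx_k, idx_l)] <- ata[k, l]
    }
  }
  tmat <- dense_penalty_matrix(mask, weights)
  n + gamma * crossprod(tmat)
}

# brute-force 81-term contraction of a symmetric 4th-order tensor given its
# 15 unique components in the package's column order
brute_force_w_form <- function(w15, n1, n2, n3 = n1, n4 = n2) {
  nm <- c(
    "1111", "2222", "3333",
    "1112", "1113", "1222", "2223", "1333", "2333",
    "1122", "1133", "2233",
    "1123", "1223", "1233"
  )
  lookup <- function(i, j, k, l) w15[match(paste(sort(c(i, j, k, l)), collapse = ""), nm)]
  acc <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    acc <- acc + n1[i] * n2[j] * n3[k] * n4[l] * lookup(i, j, k, l)
  }
  acc
}

# reference axisymmetric parameter set used across tests (oblique axis)
reference_params <- function() {
  axisym_params(
    d_perp = 0.4, d_par = 1.5, w_perp = 1.6, w_par = 0.6, w_mean = 1.0,
    axis = c(1, 2, 2) / 3, log_s0 = log(100)
  )
}
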
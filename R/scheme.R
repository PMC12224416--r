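#' Gradient encoding scheme
#'
#' A gradient scheme describes one acquired diffusion-weighted volume per row:
#' the encoding direction (in the channel-amplitude convention, where a value
#' of 1 means the maximum amplitude of a single gradient channel), the b-value
#' in ms/µm², the gradient oscillation frequency in Hz (0 denotes pulsed
#' gradient / PGSE encoding), and a b = 0 flag. Directions are stored exactly
#' as supplied; they are unit-normalized internally wherever a b-matrix is
#' formed, and the per-volume b-value is always authoritative.
#'
#' @param directions numeric matrix with 3 columns (or length-3 vector), one
#'   row per volume, in channel-amplitude convention.
#' @param bvalues numeric vector of b-values in ms/µm² (>= 0), one per volume.
#' @param frequencies numeric vector of oscillation frequencies in Hz, one per
#'   volume; defaults to 0 (PGSE) everywhere.
#' @return A tibble of class `gradient_scheme` with columns `gx`, `gy`, `gz`,
#'   `bval`, `freq`, `b0`.
#' @examples
#' gradient_scheme(rbind(c(0, 0, 0), c(0, 1, 1)), bvalues = c(0, 2.5))
#' @export
gradient_scheme <- function(directions, bvalues, frequencies = NULL) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3L, byrow = TRUE)
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  if (ncol(directions) != 3L) stop("`directions` must have 3 columns")
  n <- nrow(directions)
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) != n) stop("`bvalues` must have one entry per direction row")
  if (any(!is.finite(bvalues)) || any(bvalues < 0)) stop("b-values must be finite and >= 0")
  if (is.null(frequencies)) frequencies <- rep(0, n)
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 1L) frequencies <- rep(frequencies, n)
  if (length(frequencies) != n) stop("`frequencies` must have one entry per volume")
  b0 <- bvalues == 0
  norms <- sqrt(rowSums(directions^2))
  if (any(!b0 & norms == 0)) stop("non-b0 volumes must have a nonzero encoding direction")
  out <- tibble::tibble(
    gx = directions[, 1L], gy = directions[, 2L], gz = directions[, 3L],
    bval = bvalues, freq = frequencies, b0 = b0
  )
  class(out) <- c("gradient_scheme", class(out))
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "<gradient_scheme> %d volumes (%d b0), shells {%s} ms/um^2, frequencies {%s} Hz\n",
    nrow(x), sum(x$b0),
    paste(sort(unique(x$bval[!x$b0])), collapse = ", "),
    paste(sort(unique(x$freq)), collapse = ", ")
  ))
  NextMethod()
}

#' Extract encoding directions from a scheme
#'
#' @param scheme a [gradient_scheme()].
#' @param unit if `TRUE`, rows are unit-normalized (b = 0 rows are left as
#'   zero vectors when their stored direction is zero).
#' @return numeric matrix, volumes x 3.
#' @export
scheme_directions <- function(scheme, unit = FALSE) {
  d <- cbind(scheme$gx, scheme$gy, scheme$gz)
  if (unit) {
    nrm <- sqrt(rowSums(d^2))
    nz <- nrm > 0
    d[nz, ] <- d[nz, , drop = FALSE] / nrm[nz]
  }
  d
}

#' The efficient 10-direction encoding scheme
#'
#' Returns the 10 encoding directions (channel-amplitude convention) of the
#' efficient scheme: an efficient 6-direction set with two channels
#' simultaneously at maximum, combined with a tetrahedral set at amplitude
#' 2/3. With at least two channels at maximum amplitude, the achievable
#' b-value for fixed waveform timing is doubled relative to schemes that peak
#' one channel at a time (b is proportional to the squared gradient norm).
#' Note the tetrahedral rows have squared norm 4/3, not 2; rows are stored
#' exactly as printed in the scheme definition.
#'
#' @return a 10 x 3 numeric matrix of channel amplitudes, rows in scheme order.
#' @examples
#' ten_direction_scheme()
#' @export
ten_direction_scheme <- function() {
  m <- rbind(
    c(0, 1, 1),
    c(0, 1, -1),
    c(1, 0, 1),
    c(1, 0, -1),
    c(1, 1, 0),
    c(1, -1, 0),
    c(2 / 3, 2 / 3, 2 / 3),
    c(2 / 3, 2 / 3, -2 / 3),
    c(2 / 3, -2 / 3, 2 / 3),
    c(-2 / 3, 2 / 3, 2 / 3)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' b-matrix row for one encoding direction
#'
#' Computes the six unique entries of the b-matrix b * n %o% n for a single
#' volume, where n is the unit-normalized encoding direction. The trace
#' equals the b-value.
#'
#' @param direction length-3 encoding direction (any nonzero scale; it is
#'   unit-normalized internally).
#' @param b b-value in ms/µm².
#' @return named numeric vector `(b_xx, b_yy, b_zz, b_xy, b_xz, b_yz)`.
#' @examples
#' b_matrix_row(c(0, 1, 1), b = 2.5)
#' @export
b_matrix_row <- function(direction, b) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L) stop("`direction` must have length 3")
  if (b < 0) stop("`b` must be >= 0")
  if (b == 0) {
    return(c(b_xx = 0, b_yy = 0, b_zz = 0, b_xy = 0, b_xz = 0, b_yz = 0))
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction with b > 0 is an invalid volume")
  n <- direction / nrm
  c(
    b_xx = b * n[1]^2, b_yy = b * n[2]^2, b_zz = b * n[3]^2,
    b_xy = b * n[1] * n[2], b_xz = b * n[1] * n[3], b_yz = b * n[2] * n[3]
  )
}

#' b-value efficiency of a direction in channel-amplitude convention
#'
#' For fixed waveform timing the b-value scales with the squared gradient
#' magnitude, so a direction expressed in channel amplitudes (1 = one channel
#' at maximum) achieves `sum(direction^2)` times the b-value of a
#' single-channel-at-maximum direction. Two channels simultaneously at
#' maximum, e.g. `c(0, 1, 1)`, give exactly a factor of 2.
#'
#' @param direction length-3 channel-amplitude vector.
#' @return dimensionless b-value ratio.
#' @examples
#' b_efficiency_ratio(c(0, 1, 1)) # 2
#' @export
b_efficiency_ratio <- function(direction) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L) stop("`direction` must have length 3")
  sum(direction^2)
}

#' Effective diffusion time of cosine-modulated oscillating gradients
#'
#' Uses the cosine-OGSE convention delta_t_eff = 9 / (64 f). The effective
#' diffusion time of a pulsed-gradient (PGSE, 0 Hz) acquisition is a sequence
#' property and must be supplied explicitly from the protocol; it is never
#' computed here.
#'
#' @param frequency oscillation frequency in Hz, > 0.
#' @return effective diffusion time in ms.
#' @examples
#' effective_diffusion_time(60) # 2.34 ms
#' effective_diffusion_time(120) # 1.17 ms
#' @export
effective_diffusion_time <- function(frequency) {
  if (any(frequency <= 0)) {
    stop("frequency must be > 0; for PGSE (0 Hz) supply the diffusion time from the protocol")
  }
  9 / (64 * frequency) * 1000
}

#' Central (great-circle) angle between two axes
#'
#' Angle between two axes in degrees, in `[0, 90]`. Axes are sign-indeterminate
#' (an eigenvector and its negation describe the same axis), so the absolute
#' dot product is used.
#'
#' @param v1,v2 nonzero length-3 vectors.
#' @return angle in degrees in `[0, 90]`.
#' @examples
#' central_angle(c(1, 0, 0), c(-1, 0, 0)) # 0
#' @export
central_angle <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no defined axis")
  acos(min(1, abs(sum(v1 * v2)) / (n1 * n2))) * 180 / pi
}

#' Approximately uniform unit directions (electrostatic repulsion)
#'
#' Deterministic construction of `n` approximately uniformly distributed unit
#' vectors, used for synthetic acquisitions and design-rank studies. A
#' spherical Fibonacci spiral provides the initial layout; by default it is
#' then refined by electrostatic repulsion of antipodally symmetric point
#' pairs (each direction and its negation repel all others), the standard
#' construction for diffusion encoding sets. The refinement matters beyond
#' aesthetics: the raw Fibonacci spiral is close to a symmetric configuration
#' whose fourth-order moments are degenerate, so quartic design matrices
#' built from it lose rank that well-distributed sets of the same size
#' retain.
#'
#' @param n number of directions.
#' @param repulsion run the repulsion refinement; defaults to `TRUE` for
#'   acquisition-sized sets and `FALSE` for large quadrature sets, where the
#'   spiral is already adequate and the O(n² iterations) cost is not.
#' @param iterations repulsion iterations.
#' @return an `n` x 3 matrix of unit vectors.
#' @export
uniform_directions <- function(n, repulsion = n <= 128, iterations = 200L) {
  i <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * i / n)
  azim <- pi * (1 + sqrt(5)) * i
  x <- cbind(
    sin(polar) * cos(azim),
    sin(polar) * sin(azim),
    cos(polar)
  )
  if (repulsion && n > 1L) x <- repel_axes(x, iterations)
  x
}

# electrostatic repulsion of antipodally symmetric unit vectors: projected
# gradient descent on sum over pairs of 1/r with both the point and its
# antipode acting, a deterministic refinement of any starting layout
repel_axes <- function(x, iterations) {
  n <- nrow(x)
  step <- 0.05
  for (it in seq_len(iterations)) {
    force <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2L, x[i, ], `-`) # x_j - x_i
      d2 <- sweep(x[-i, , drop = FALSE], 2L, x[i, ], `+`) # x_j + x_i
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-9)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-9)
      force[i, ] <- -colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # project onto the tangent plane and take a normalized step
    force <- force - x * rowSums(force * x)
    nrm <- sqrt(rowSums(force^2))
    scl <- step / max(nrm, 1e-12)
    x <- x + scl * force
    x <- x / sqrt(rowSums(x^2))
    if (it %% 50L == 0L) step <- step / 2
  }
  x
}

#' Build a multi-shell, multi-frequency acquisition scheme
#'
#' Replicates a direction set over b-shells and oscillation frequencies,
#' prepending `n_b0` b = 0 volumes per frequency, in the block layout of a
#' combined PGSE/OGSE protocol (all volumes of one frequency contiguous).
#'
#' @param directions matrix of encoding directions (channel-amplitude or unit
#'   convention), one row per direction.
#' @param shells b-values of the non-zero shells, ms/µm².
#' @param frequencies oscillation frequencies in Hz (0 = PGSE).
#' @param n_b0 number of b = 0 volumes per frequency.
#' @return a [gradient_scheme()].
#' @examples
#' build_scheme(ten_direction_scheme(), shells = c(1, 2.5), frequencies = c(0, 60, 120))
#' @export
build_scheme <- function(directions, shells = c(1, 2.5), frequencies = 0, n_b0 = 2L) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3L, byrow = TRUE)
  nd <- nrow(directions)
  dirs <- NULL; bv <- NULL; fr <- NULL
  for (f in frequencies) {
    if (n_b0 > 0L) {
      dirs <- rbind(dirs, matrix(0, n_b0, 3L))
      bv <- c(bv, rep(0, n_b0)); fr <- c(fr, rep(f, n_b0))
    }
    for (b in shells) {
      dirs <- rbind(dirs, directions)
      bv <- c(bv, rep(b, nd)); fr <- c(fr, rep(f, nd))
    }
  }
  gradient_scheme(dirs, bv, fr)
}

# volume indices belonging to one frequency, optionally restricted to the
# low-b shell (b <= low_b_max) plus all b0 volumes of that frequency
volumes_for_frequency <- function(scheme, frequency, low_b_max = NULL) {
  sel <- scheme$freq == frequency
  if (!is.null(low_b_max)) sel <- sel & (scheme$b0 | scheme$bval <= low_b_max)
  which(sel)
}
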
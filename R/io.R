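#' Read an FSL-style b-value file
#'
#' One whitespace-separated row of b-values in s/mm², converted on read to
#' the internal unit ms/µm² (1000 s/mm² = 1 ms/µm²); internal units keep the
#' design-matrix entries of comparable magnitude.
#'
#' @param path file path.
#' @return numeric vector of b-values in ms/µm².
#' @export
read_bvals <- function(path) {
  scan(path, what = numeric(), quiet = TRUE) / 1000
}

#' Write an FSL-style b-value file (s/mm²)
#' @param bvals b-values in ms/µm².
#' @param path file path.
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(sprintf("%.17g", bvals * 1000), collapse = " "), path)
}

#' Read an FSL-style b-vector file
#'
#' Three whitespace-separated rows (x, y, z), one column per volume, in image
#' coordinates. Nonzero directions whose norm deviates from 1 by more than
#' `tol` are renormalized with a warning (gradient-versus-image frame
#' reorientation is out of scope).
#'
#' @param path file path.
#' @param tol unit-norm tolerance.
#' @return matrix (volumes x 3).
#' @export
read_bvecs <- function(path, tol = 1e-3) {
  m <- as.matrix(utils::read.table(path))
  if (nrow(m) != 3L) stop("bvec file must have exactly 3 rows")
  d <- t(m)
  nrm <- sqrt(rowSums(d^2))
  off <- nrm > 0 & abs(nrm - 1) > tol
  if (any(off)) {
    warning(sprintf("%d b-vectors deviate from unit norm; renormalizing", sum(off)))
    d[off, ] <- d[off, , drop = FALSE] / nrm[off]
  }
  unname(d)
}

#' Write an FSL-style b-vector file
#'
#' Directions are unit-normalized on write (zero rows for b = 0 volumes are
#' kept as zeros), matching the FSL convention.
#'
#' @param directions matrix (volumes x 3).
#' @param path file path.
#' @export
write_bvecs <- function(directions, path) {
  d <- as.matrix(directions)
  nrm <- sqrt(rowSums(d^2))
  nz <- nrm > 0
  d[nz, ] <- d[nz, , drop = FALSE] / nrm[nz]
  lines <- apply(t(d), 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
}

#' Read a per-volume oscillation-frequency table
#'
#' A single whitespace-separated row of frequencies in Hz (0 = PGSE).
#'
#' @param path file path.
#' @return numeric vector of frequencies (Hz).
#' @export
read_frequencies <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}

#' Write a per-volume oscillation-frequency table
#' @param frequencies frequencies in Hz.
#' @param path file path.
#' @export
write_frequencies <- function(frequencies, path) {
  writeLines(paste(sprintf("%.17g", frequencies), collapse = " "), path)
}

# read a NIfTI file into a plain array plus geometry
read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  list(
    data = as.array(img),
    voxdim = RNifti::pixdim(img),
    affine = structure(RNifti::xform(img), code = attr(RNifti::xform(img), "code"))
  )
}

# write a plain array as NIfTI, preserving voxel size and affine when known
write_nifti_array <- function(data, path, voxdim = NULL, affine = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(voxdim)) RNifti::pixdim(img) <- voxdim[seq_len(min(3L, length(voxdim)))]
  if (!is.null(affine)) img <- RNifti::asNifti(img, reference = list(qform = affine))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a diffusion dataset (NIfTI + bval/bvec + frequency table + mask)
#'
#' Loads a 4D diffusion-weighted volume with its acquisition metadata. All
#' metadata sources must agree on the volume count. When the frequency table
#' is absent the dataset is treated as single-frequency PGSE (all 0 Hz), in
#' which case the AFAB and SFAB axis strategies coincide. Non-finite voxel
#' values inside the mask are an error.
#'
#' @param image path to the 4D NIfTI (gzipped accepted).
#' @param bval,bvec paths to FSL b-value/b-vector files.
#' @param freq optional path to the frequency table.
#' @param mask optional path to a binary mask NIfTI; defaults to all voxels.
#' @return list with `volume` ([signal_volume()]) and `scheme`
#'   ([gradient_scheme()]).
#' @export
read_dataset <- function(image, bval, bvec, freq = NULL, mask = NULL) {
  img <- read_nifti_array(image)
  data <- img$data
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  nvol <- dim(data)[4]
  bvals <- read_bvals(bval)
  dirs <- read_bvecs(bvec)
  freqs <- if (is.null(freq)) rep(0, nvol) else read_frequencies(freq)
  if (length(bvals) != nvol || nrow(dirs) != nvol || length(freqs) != nvol) {
    stop(sprintf(
      "volume count mismatch: image has %d volumes, bval %d, bvec %d, freq %d",
      nvol, length(bvals), nrow(dirs), length(freqs)
    ))
  }
  maskarr <- if (is.null(mask)) {
    array(TRUE, dim(data)[1:3])
  } else {
    m <- read_nifti_array(mask)$data
    array(m != 0, dim(m))
  }
  vol <- signal_volume(data,
    mask = maskarr,
    voxdim = img$voxdim, affine = img$affine
  )
  if (!all(is.finite(masked_signal(vol)))) stop("non-finite voxel values inside the mask")
  list(volume = vol, scheme = gradient_scheme(dirs, bvals, freqs))
}

#' Write a diffusion dataset to a directory
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval` (s/mm²), `<prefix>.bvec` (unit
#' directions), `<prefix>.freq` and `<prefix>_mask.nii.gz`, the layout
#' [read_dataset()] expects.
#'
#' @param volume a [signal_volume()].
#' @param scheme the matching [gradient_scheme()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(volume, scheme, dir, prefix = "dwi") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti_array(volume$data, file.path(dir, paste0(prefix, ".nii.gz")),
    voxdim = volume$voxdim, affine = volume$affine
  )
  write_nifti_array(array(as.numeric(volume$mask), dim(volume$mask)),
    file.path(dir, paste0(prefix, "_mask.nii.gz")),
    voxdim = volume$voxdim, affine = volume$affine
  )
  write_bvals(scheme$bval, file.path(dir, paste0(prefix, ".bval")))
  write_bvecs(scheme_directions(scheme), file.path(dir, paste0(prefix, ".bvec")))
  write_frequencies(scheme$freq, file.path(dir, paste0(prefix, ".freq")))
  invisible(dir)
}

#' Write a generated phantom with its ground truth
#'
#' Writes the dataset files of [write_dataset()] plus ground-truth parameter
#' maps (`truth_<freq>.nii.gz`, 6 volumes: log S0, D_perp, D_par, and the
#' Dbar²-scaled kurtosis parameters), the orientation field
#' (`truth_axes.nii.gz`), region labels (`truth_labels.nii.gz`) and the
#' phantom specification as YAML, so the whole fitting path can be exercised
#' end-to-end from files.
#'
#' @param phantom an `axdki_phantom` from [generate_phantom()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "dwi") {
  write_dataset(phantom$volume, phantom$scheme, dir, prefix)
  mask <- phantom$volume$mask
  for (f in names(phantom$truth$params)) {
    write_nifti_array(
      unmask(phantom$truth$params[[f]], mask),
      file.path(dir, sprintf("truth_%s.nii.gz", f))
    )
  }
  write_nifti_array(unmask(phantom$truth$axes, mask), file.path(dir, "truth_axes.nii.gz"))
  write_nifti_array(unmask(phantom$truth$labels, mask), file.path(dir, "truth_labels.nii.gz"))
  sp <- phantom$spec
  sp$directions <- apply(sp$directions, 1L, paste, collapse = " ")
  yaml::write_yaml(unclass(sp), file.path(dir, "phantom.yaml"))
  invisible(dir)
}

#' Fitting configuration
#'
#' Bundles the tunable settings of the two-step fit. The base regularization
#' weights follow the published defaults (gamma_dt = 0.5 with
#' gamma_dk = 0.075 for preclinical mouse-like protocols; gamma_dk = 0.2 for
#' human-like protocols); `reg_multiplier` scales both weights by a single
#' net factor.
#'
#' @param gamma_dt,gamma_dk base regularization weights, >= 0.
#' @param reg_multiplier single net factor applied to both weights.
#' @param strategy axis strategy: `"AFAB"`, `"SFAB"` or `"SFLB"`.
#' @param low_b_max SFLB low-shell threshold, ms/µm².
#' @param method `"axisym"` (two-step axisymmetric fit) or `"full-tensor"`
#'   (22-parameter OLS baseline).
#' @param presmooth_sigma Gaussian pre-smoothing in voxels (0 = none).
#' @param tol,maxit conjugate-gradient settings.
#' @param refine_axes kurtosis-corrected axis refinement flag.
#' @param seed optional RNG seed recorded for provenance.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(gamma_dt = 0.5, gamma_dk = 0.075, reg_multiplier = 1,
                       strategy = c("AFAB", "SFAB", "SFLB"), low_b_max = 1.5,
                       method = c("axisym", "full-tensor"),
                       presmooth_sigma = 0, tol = 1e-8, maxit = 500L,
                       refine_axes = FALSE, seed = NULL) {
  strategy <- match.arg(strategy)
  method <- match.arg(method)
  if (gamma_dt < 0 || gamma_dk < 0 || reg_multiplier < 0) {
    stop("regularization weights must be >= 0")
  }
  structure(
    list(
      gamma_dt = gamma_dt, gamma_dk = gamma_dk, reg_multiplier = reg_multiplier,
      strategy = strategy, low_b_max = low_b_max, method = method,
      presmooth_sigma = presmooth_sigma, tol = tol, maxit = as.integer(maxit),
      refine_axes = isTRUE(refine_axes), seed = seed
    ),
    class = "fit_config"
  )
}

#' Read a fitting configuration from YAML
#' @param path YAML file path.
#' @return a [fit_config()].
#' @export
read_fit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(fit_config, vals[names(vals) %in% names(formals(fit_config))])
}

#' Write a fitting configuration to YAML
#' @param config a [fit_config()].
#' @param path YAML file path.
#' @export
write_fit_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full fitting pipeline
#'
#' Optional Gaussian pre-smoothing, symmetry-axis estimation with the chosen
#' strategy, then either the per-frequency axisymmetric fit or the
#' full-tensor baseline, returning scalar metric maps per frequency together
#' with the raw fields and effective configuration.
#'
#' @param volume a [signal_volume()].
#' @param scheme the matching [gradient_scheme()].
#' @param config a [fit_config()].
#' @return list with `metrics` (named list of `metric_maps` per frequency),
#'   `fields` (raw fitted fields), `axes` (axis set, axisymmetric method
#'   only) and `config`.
#' @export
fit_pipeline <- function(volume, scheme, config = fit_config()) {
  if (config$presmooth_sigma > 0) {
    volume <- gaussian_presmooth(volume, config$presmooth_sigma)
  }
  gdt <- config$gamma_dt * config$reg_multiplier
  gdk <- config$gamma_dk * config$reg_multiplier
  freqs <- sort(unique(scheme$freq))
  if (config$method == "full-tensor") {
    fields <- stats::setNames(lapply(freqs, function(f) {
      fit_full_dki(volume, scheme, subset = volumes_for_frequency(scheme, f))
    }), as.character(freqs))
    metrics <- lapply(fields, axisym_metrics_from_full)
    for (f in names(metrics)) metrics[[f]]$frequency <- as.numeric(f)
    return(list(metrics = metrics, fields = fields, axes = NULL, config = config))
  }
  axes <- compute_axes(volume, scheme,
    strategy = config$strategy, gamma_dt = gdt,
    low_b_max = config$low_b_max, refine = config$refine_axes,
    gamma_dk = gdk, tol = config$tol, maxit = config$maxit
  )
  fields <- stats::setNames(lapply(freqs, function(f) {
    fit_dki(volume, scheme, axes,
      frequency = f, gamma_dk = gdk,
      tol = config$tol, maxit = config$maxit
    )
  }), as.character(freqs))
  metrics <- lapply(fields, extract_metrics)
  list(metrics = metrics, fields = fields, axes = axes, config = config)
}

#' Write scalar metric maps as NIfTI with a JSON sidecar
#'
#' One NIfTI per metric (`<prefix>_<freq>_<metric>.nii.gz`) plus a JSON
#' sidecar recording the configuration, solver diagnostics, undefined-voxel
#' counts and package version; rerunning the pipeline with the sidecar's
#' configuration reproduces the maps.
#'
#' @param maps a `metric_maps` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param config optional [fit_config()] recorded in the sidecar.
#' @param diagnostics optional solver diagnostics list.
#' @return the sidecar path, invisibly.
#' @export
write_metric_maps <- function(maps, dir, prefix = "axdki", config = NULL,
                              diagnostics = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ftag <- if (is.null(maps$frequency)) "all" else format(maps$frequency)
  for (nm in colnames(maps$values)) {
    write_nifti_array(
      metric_array(maps, nm),
      file.path(dir, sprintf("%s_f%s_%s.nii.gz", prefix, ftag, nm)),
      voxdim = maps$voxdim
    )
  }
  sidecar <- list(
    frequency = maps$frequency,
    metrics = colnames(maps$values),
    meta = maps$meta[setdiff(names(maps$meta), c("w", "axes"))],
    n_undefined = unname(colSums(!is.finite(maps$values))),
    config = if (!is.null(config)) unclass(config),
    diagnostics = diagnostics,
    package_version = as.character(utils::packageVersion("axdki"))
  )
  path <- file.path(dir, sprintf("%s_f%s.json", prefix, ftag))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
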
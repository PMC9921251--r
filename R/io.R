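# Scheme file I/O, the three packaged 120-sample reference schemes, and
# voxelwise fitting of 4D NIfTI volumes.

#' Read an acquisition scheme from a text file
#'
#' Plain-text table, one row per sample: `gx gy gz b bdelta` with b in
#' ms/um^2; lines starting with `#` are comments.  Directions off unit norm
#' by less than 1e-3 are re-normalized; larger deviations are an error.
#'
#' @param path file path.
#' @return an [acquisition_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_scheme(): no such file '%s'", path))
  tab <- tryCatch(utils::read.table(path, comment.char = "#"),
                  error = function(e) stop(sprintf(
                    "read_scheme(): cannot parse '%s': %s", path, conditionMessage(e))))
  if (ncol(tab) != 5L)
    stop(sprintf("read_scheme(): expected 5 columns, found %d", ncol(tab)))
  num <- suppressWarnings(vapply(tab, function(col) as.numeric(as.character(col)),
                                 numeric(nrow(tab))))
  num <- matrix(num, nrow = nrow(tab))
  bad <- which(rowSums(!is.finite(num)) > 0L)
  if (length(bad))
    stop(sprintf("read_scheme(): malformed row(s) at line(s) %s",
                 paste(bad, collapse = ", ")))
  if (any(num[, 5L] < -0.5 - 1e-9 | num[, 5L] > 1 + 1e-9))
    stop("read_scheme(): bdelta out of [-0.5, 1]")
  acquisition_scheme(num[, 1:3, drop = FALSE], num[, 4L], num[, 5L])
}

#' Write an acquisition scheme to a text file
#'
#' Writes the 5-column text format of [read_scheme()] (exact round trip).
#' Optionally also exports a per-sample Voigt 6-vector b-tensor table for
#' interoperability with multidimensional-encoding tools.
#'
#' @param scheme an [acquisition_scheme()].
#' @param path output path.
#' @param btensor_path optional path for the 6-column b-tensor table
#'   (order xx yy zz yz xz xy with sqrt(2)-scaled cross terms).
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path, btensor_path = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# acquisition scheme: gx gy gz b[ms/um^2] bdelta"), con)
  utils::write.table(
    data.frame(scheme$directions, scheme$b, scheme$bdelta),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(btensor_path)) {
    A <- design_matrix(scheme)
    V6 <- -A[, .THETA_D, drop = FALSE]
    con2 <- file(btensor_path, "w"); on.exit(close(con2), add = TRUE)
    writeLines("# b-tensors, voigt order xx yy zz yz xz xy (sqrt2-scaled cross terms), ms/um^2", con2)
    utils::write.table(V6, con2, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# per-shell layouts of the packaged 120-sample schemes: b (ms/um^2),
# bdelta, sample count
.PACKAGED_SHELLS <- list(
  q1 = data.frame(
    b = c(0.1, 0.1, 0.1, 0.7, 0.7, 0.7, 1.4, 1.4, 1.4, 2, 2, 2),
    bdelta = c(-0.5, 0, 1, -0.5, 0, 1, -0.5, 0, 1, -0.5, 0, 1),
    n = c(3, 17, 3, 3, 17, 3, 5, 17, 5, 15, 17, 15)),
  q2hat = data.frame(
    b = c(0.1, 0.8, 2, 2),
    bdelta = c(1, 1, -0.5, 1),
    n = c(6, 30, 36, 48)),
  q3hat = data.frame(
    b = c(0.1, 0.1, 0.8, 0.8, 2, 2),
    bdelta = c(-0.5, 1, -0.5, 1, 0, 1),
    n = c(7, 9, 9, 50, 30, 15)))

#' Packaged reference acquisition schemes
#'
#' The three 120-sample shelled schemes compared throughout the package:
#' `"q1"`, a naive scheme spreading planar, spherical and linear encoding
#' over four b-values; `"q2hat"`, precision-optimized for the raw 28
#' parameters (D-optimality); and `"q3hat"`, precision-optimized for the
#' scalar metrics MD, uFA, MKi, MKa (the recommended scheme).  Per-shell
#' sample counts are fixed; directions within each shell are generated by
#' electrostatic repulsion with a fixed per-shell seed, so the schemes are
#' reproducible.
#'
#' @param name `"q1"`, `"q2hat"` or `"q3hat"`.
#' @param seed base seed for the per-shell direction sets.
#' @return an [acquisition_scheme()] with 120 samples.
#' @export
#' @examples
#' packaged_scheme("q3hat")
packaged_scheme <- function(name = c("q1", "q2hat", "q3hat"), seed = 42L) {
  name <- match.arg(name)
  shells <- .PACKAGED_SHELLS[[name]]
  dirs <- NULL; b <- NULL; bd <- NULL
  for (i in seq_len(nrow(shells))) {
    dirs <- rbind(dirs, electrostatic_directions(shells$n[i], seed = seed + i))
    b <- c(b, rep(shells$b[i], shells$n[i]))
    bd <- c(bd, rep(shells$bdelta[i], shells$n[i]))
  }
  acquisition_scheme(dirs, b, bd)
}

#' Voxelwise fitting of a 4D volume
#'
#' Applies a named estimator to every voxel of a 4D diffusion-weighted
#' volume (the 4th dimension indexes the scheme samples) and returns a
#' 28-volume parameter map plus one 3D map per scalar metric.  Voxels
#' outside the mask, or with all-zero signal, are left at zero and counted.
#'
#' @param volume 4D numeric array, or a NIfTI file path / `niftiImage`
#'   readable by `RNifti`.
#' @param scheme an [acquisition_scheme()] with N equal to the 4th
#'   dimension.
#' @param mask optional 3D logical/numeric array (or NIfTI path) matching
#'   the spatial dimensions; default all voxels.
#' @param estimator estimator name (see [fit_qti()]).
#' @param outdir optional directory; when given, writes `theta.nii.gz` and
#'   one `<metric>.nii.gz` per metric there.
#' @return list with `theta` (4D array, 28 volumes), `metrics` (named list
#'   of 3D arrays), `n_fitted`, `n_failed`, `n_skipped`.
#' @export
fit_volume <- function(volume, scheme, mask = NULL, estimator = "iwlls",
                       outdir = NULL) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  img <- if (is.character(volume) || inherits(volume, "niftiImage"))
    RNifti::asNifti(volume) else volume
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("fit_volume(): volume must be 4D")
  N <- n_samples(scheme)
  if (dim(arr)[4L] != N)
    stop(sprintf("fit_volume(): volume has %d samples but scheme has %d",
                 dim(arr)[4L], N))
  sp <- dim(arr)[1:3]
  if (is.null(mask)) {
    mk <- array(TRUE, sp)
  } else {
    mk <- if (is.character(mask) || inherits(mask, "niftiImage"))
      as.array(RNifti::asNifti(mask)) else as.array(mask)
    if (!all(dim(mk)[1:3] == sp)) stop("fit_volume(): mask shape mismatch")
    mk <- array(mk > 0, sp)
  }
  A <- design_matrix(scheme)
  constraints <- if (grepl("^ciwlls", estimator))
    build_constraints(constraint_directions(scheme),
                      as.integer(substring(estimator, 7L)),
                      b_max = max(scheme$b)) else NULL
  sig <- matrix(arr, prod(sp), N)
  idx <- which(as.vector(mk))
  nz <- idx[rowSums(abs(sig[idx, , drop = FALSE])) > 0]
  theta_flat <- matrix(0, prod(sp), 28L)
  failed <- 0L
  if (length(nz)) {
    fit <- .fit_batch(t(sig[nz, , drop = FALSE]), A, estimator,
                      constraints = constraints)
    th <- fit$theta
    bad <- colSums(!is.finite(th)) > 0L
    th[, bad] <- 0
    failed <- sum(bad)
    theta_flat[nz, ] <- t(th)
  }
  theta_arr <- array(theta_flat, c(sp, 28L))
  Mm <- .metrics_mat(t(theta_flat))
  Mm[!is.finite(Mm)] <- 0
  Mm[, setdiff(seq_len(ncol(Mm)), nz)] <- 0
  metric_maps <- lapply(seq_len(nrow(Mm)),
                        function(i) array(Mm[i, ], sp))
  names(metric_maps) <- rownames(Mm)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    RNifti::writeNifti(RNifti::asNifti(theta_arr, reference = if (inherits(img, "niftiImage")) img else NULL),
                       file.path(outdir, "theta.nii.gz"))
    for (nm in names(metric_maps))
      RNifti::writeNifti(RNifti::asNifti(metric_maps[[nm]],
                                         reference = if (inherits(img, "niftiImage")) img else NULL),
                         file.path(outdir, paste0(nm, ".nii.gz")))
  }
  list(theta = theta_arr, metrics = metric_maps,
       n_fitted = length(nz) - failed, n_failed = failed,
       n_skipped = prod(sp) - length(nz))
}
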
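# Essential dynamics: PCA of Cartesian C-alpha fluctuations after
# superposition. Eigenvectors are collective motions, eigenvalues their
# amplitudes (Angstrom^2).

# Covariance model from an already-superposed frames x 3k coordinate matrix.
covariance_from_coords <- function(X, selection = NULL, extra = list()) {
  mu <- colMeans(X)
  C <- stats::cov(X)                      # 1/(F-1) normalisation
  ei <- eigen(C, symmetric = TRUE)
  vecs <- ei$vectors
  # sign convention: largest-magnitude component of each mode positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(c(list(mean = mu, covariance = C,
                   eigenvalues = ei$values, eigenvectors = vecs,
                   selection = selection, n_frames = nrow(X)),
              extra),
            class = "CovarianceModel")
}

#' Covariance model of C-alpha fluctuations (essential dynamics)
#'
#' Every frame is rigid-body superposed onto the reference on the selected
#' atoms; the 3N x 3N covariance of the coordinate deviations from the
#' ensemble mean is built and diagonalised (eigenvalues sorted descending).
#' The PCA is mass-unweighted.
#'
#' @param ensemble a `StructureEnsemble` with at least 2 frames.
#' @param selection an [atom_selection()] of at least 3 atoms; default all
#'   C-alpha atoms.
#' @param reference `"mean"` (iterated fit, default), `"first"`, or a
#'   `k x 3` coordinate matrix on the selection.
#' @return object of class `CovarianceModel`: `mean` (3N vector),
#'   `covariance`, `eigenvalues` (Angstrom^2, descending), `eigenvectors`
#'   (orthonormal columns), `reference_coords`, `selection`, `n_frames`.
#' @export
build_covariance <- function(ensemble, selection = ca_selection(),
                             reference = "mean") {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (n_frames(ensemble) < 2L) stop("covariance needs at least 2 frames")
  idx <- selection_index(ensemble$topology, selection)
  if (length(idx) < 3L) stop("selection must contain at least 3 atoms")
  sp <- superpose_frames(ensemble, idx, reference)
  covariance_from_coords(sp$coords, selection,
                         extra = list(reference_coords = sp$mean))
}

#' Project frames onto essential-dynamics modes
#'
#' Frames are superposed onto the model's reference structure on the model
#' selection, mean-centred with the model mean, and dotted with the chosen
#' eigenvectors.
#'
#' @param model a [build_covariance()] result.
#' @param ensemble a `StructureEnsemble` sharing the model's selection
#'   geometry (same atom count after selection).
#' @param modes integer vector of mode indices (1 = largest amplitude).
#' @return object of class `ModeProjection`: data.frame with `replica_id`,
#'   `time_ps` and one `modeK` column per requested mode (Angstrom).
#' @export
project_modes <- function(model, ensemble, modes = 1:2) {
  stopifnot(inherits(model, "CovarianceModel"),
            inherits(ensemble, "StructureEnsemble"))
  if (any(modes < 1L) || any(modes > length(model$eigenvalues)))
    stop("mode index out of range")
  idx <- selection_index(ensemble$topology, model$selection)
  if (3L * length(idx) != length(model$mean))
    stop("ensemble selection does not match model dimensionality")
  sp <- superpose_frames(ensemble, idx, model$reference_coords)
  dev <- sweep(sp$coords, 2, model$mean)
  proj <- dev %*% model$eigenvectors[, modes, drop = FALSE]
  colnames(proj) <- paste0("mode", modes)
  out <- data.frame(replica_id = ensemble$replica_id,
                    time_ps = ensemble$time_ps, proj, check.names = FALSE)
  attr(out, "modes") <- modes
  attr(out, "label") <- ensemble$label
  class(out) <- c("ModeProjection", class(out))
  out
}

#' Fraction of total fluctuation captured by the first k modes
#'
#' @param model a `CovarianceModel`.
#' @param k number of leading modes.
#' @return scalar in `[0, 1]`.
#' @export
variance_fraction <- function(model, k) {
  stopifnot(inherits(model, "CovarianceModel"))
  ev <- pmax(model$eigenvalues, 0)
  if (k < 1L || k > length(ev)) stop("k out of range")
  tot <- sum(ev)
  if (tot <= 0) stop("degenerate all-zero spectrum")
  sum(ev[seq_len(k)]) / tot
}

#' Standard deviation of mode projections
#'
#' The per-mode spread of an ensemble's projections; comparing spreads
#' between two variants in a shared basis ranks their flexibility along
#' each collective motion.
#'
#' @param projection a [project_modes()] result with >= 2 frames.
#' @return named numeric vector, one standard deviation (Angstrom) per mode.
#' @export
mode_spread <- function(projection) {
  stopifnot(inherits(projection, "ModeProjection"))
  cols <- grep("^mode[0-9]+$", names(projection), value = TRUE)
  vapply(cols, function(cc) stats::sd(projection[[cc]]), numeric(1))
}

#' @export
print.CovarianceModel <- function(x, ...) {
  cat("CovarianceModel: ", length(x$mean) / 3, " atoms, ", x$n_frames,
      " frames; top eigenvalues (A^2): ",
      paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", "),
      "; mode 1+2 fraction ", signif(variance_fraction(x, 2), 3), "\n",
      sep = "")
  invisible(x)
}
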
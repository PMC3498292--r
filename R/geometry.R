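# Backbone geometry: torsions, superposition, RMSD/RMSF, centers of mass,
# and C-alpha contact counting.

# Row-wise signed torsion (IUPAC convention) for four n x 3 point matrices.
# Returns degrees in (-180, 180].
torsion_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (any(rownorm(b1) < 1e-9) || any(rownorm(b2) < 1e-9) ||
      any(rownorm(b3) < 1e-9))
    stop("coincident consecutive points in torsion")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (any(rownorm(n1) < 1e-9) || any(rownorm(n2) < 1e-9))
    stop("undefined torsion: collinear points")
  m1 <- cross3(n1, b2 / rownorm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Signed dihedral angle of four points
#'
#' Torsion about the `p2`-`p3` axis in the IUPAC sign convention: looking
#' from `p2` to `p3`, a clockwise rotation of `p4` relative to `p1` is
#' positive. Result in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # cis, 0
dihedral_angle <- function(p1, p2, p3, p4) {
  unname(torsion_rows(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
}

# ---------------------------------------------------------------------------
# DihedralSeries
# ---------------------------------------------------------------------------

#' Backbone phi/psi dihedrals for every frame of an ensemble
#'
#' `phi(i)` is the torsion `C(i-1), N(i), CA(i), C(i)` and `psi(i)` the
#' torsion `N(i), CA(i), C(i), N(i+1)`; `phi` of the first residue and `psi`
#' of the last are undefined and reported as `NA`.
#'
#' @param ensemble a `StructureEnsemble` whose residues all carry `N`, `CA`
#'   and `C` atoms.
#' @return object of class `DihedralSeries`: list with `residue_numbers` and
#'   frame-by-residue matrices `phi` and `psi` (degrees, `NA` where
#'   undefined), plus the source frame times/replicas.
#' @export
backbone_dihedrals <- function(ensemble) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  topo <- ensemble$topology
  resnums <- unique(topo$residue_number)
  nres <- length(resnums)
  idx_of <- function(name) {
    i <- match(paste(resnums, name), paste(topo$residue_number, topo$atom_name))
    if (anyNA(i))
      stop("residue ", resnums[which(is.na(i))[1]], " lacks backbone atom ", name)
    i
  }
  iN <- idx_of("N"); iCA <- idx_of("CA"); iC <- idx_of("C")
  nf <- n_frames(ensemble)
  # stack (frame, residue) pairs into rows for vectorised torsions:
  # rows are frame-major within each residue, matching matrix(nf, k) filling
  at3 <- function(atom_idx, rows) {
    i <- atom_idx[rows]
    cbind(as.vector(ensemble$xyz[, 3 * i - 2, drop = FALSE]),
          as.vector(ensemble$xyz[, 3 * i - 1, drop = FALSE]),
          as.vector(ensemble$xyz[, 3 * i, drop = FALSE]))
  }
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  if (nres >= 2) {
    r <- 2:nres
    phi[, r] <- torsion_rows(at3(iC, r - 1), at3(iN, r), at3(iCA, r), at3(iC, r))
    r <- 1:(nres - 1)
    psi[, r] <- torsion_rows(at3(iN, r), at3(iCA, r), at3(iC, r), at3(iN, r + 1))
  }
  structure(list(residue_numbers = resnums, phi = phi, psi = psi,
                 time_ps = ensemble$time_ps, replica_id = ensemble$replica_id),
            class = "DihedralSeries")
}

# ---------------------------------------------------------------------------
# Superposition and fluctuation
# ---------------------------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` via SVD of the weighted
#' cross-covariance, with the determinant sign corrected so a proper rotation
#' (no reflection) is always returned.
#'
#' @param mobile,reference numeric `n x 3` matrices, `n >= 3`.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3), `translation` (length 3, applied as
#'   `coords %*% rotation + translation`), `rmsd_A` (post-fit RMSD, Angstrom)
#'   and `coords` (the fitted mobile points).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) < 3L || nrow(reference) != nrow(mobile))
    stop("superposition needs >= 3 matched points")
  w <- weights %||% rep(1, nrow(mobile))
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- t(R)                         # so that fitted = A %*% R
  fitted <- A %*% R
  fitted <- sweep(fitted, 2, cr, `+`)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = cr - as.vector(cm %*% R),
       rmsd_A = rmsd, coords = fitted)
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is superposed onto the reference on the selected atoms and the
#' post-fit RMSD is reported, the conventional choice being C-alpha atoms.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param reference an `n_atoms x 3` coordinate matrix on the full topology,
#'   or a frame index into `ensemble`.
#' @param selection an [atom_selection()]; default all C-alpha atoms.
#' @return data.frame with `replica_id`, `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(ensemble, reference = 1L, selection = ca_selection()) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  idx <- selection_index(ensemble$topology, selection)
  ref <- if (is.matrix(reference)) reference else frame_coords(ensemble, reference)
  if (nrow(ref) != n_atoms(ensemble))
    stop("reference must cover the full topology")
  ref <- ref[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(ensemble)), function(i) {
    kabsch_superpose(frame_coords(ensemble, i)[idx, , drop = FALSE], ref)$rmsd_A
  }, numeric(1))
  data.frame(replica_id = ensemble$replica_id, time_ps = ensemble$time_ps,
             rmsd_A = vals)
}

# Superpose all frames of a selection onto a reference; ref = "mean" iterates
# fit -> mean -> refit (two rounds). Returns list(coords = nf x 3k matrix of
# fitted coordinates in x1,y1,z1,... layout, mean = k x 3 mean structure).
superpose_frames <- function(ensemble, idx, reference = "mean") {
  nf <- n_frames(ensemble)
  k <- length(idx)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  X <- ensemble$xyz[, cols, drop = FALSE]
  get <- function(i) matrix(X[i, ], ncol = 3, byrow = TRUE)
  fit_all <- function(ref) {
    out <- matrix(0, nf, 3 * k)
    for (i in seq_len(nf)) {
      f <- kabsch_superpose(get(i), ref)$coords
      out[i, ] <- as.vector(t(f))
    }
    out
  }
  if (is.matrix(reference)) {
    Xf <- fit_all(reference)
  } else if (identical(reference, "first")) {
    Xf <- fit_all(get(1))
  } else if (identical(reference, "mean")) {
    ref <- get(1)
    for (round in 1:2) {
      Xf <- fit_all(ref)
      ref <- matrix(colMeans(Xf), ncol = 3, byrow = TRUE)
    }
  } else stop("unknown superposition reference")
  mu <- matrix(colMeans(Xf), ncol = 3, byrow = TRUE)
  list(coords = Xf, mean = mu)
}

#' Per-residue root mean square fluctuation
#'
#' Frames are superposed onto the ensemble-mean structure (two fit/mean
#' rounds, or onto the first frame with `reference = "first"`), then
#' `RMSF(i) = sqrt(mean_t |x_i(t) - <x_i>|^2)` for each selected atom.
#'
#' @param ensemble a `StructureEnsemble` with at least two frames.
#' @param selection an [atom_selection()]; default C-alpha atoms.
#' @param reference `"mean"` (default) or `"first"`.
#' @return data.frame with `residue_number` and `rmsf_A`.
#' @export
rmsf_profile <- function(ensemble, selection = ca_selection(),
                         reference = "mean") {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (n_frames(ensemble) < 2L) stop("RMSF needs at least two frames")
  idx <- selection_index(ensemble$topology, selection)
  sp <- superpose_frames(ensemble, idx, reference)
  dev2 <- sweep(sp$coords, 2, as.vector(t(sp$mean)))^2
  k <- length(idx)
  per_atom <- sqrt(colMeans(dev2[, seq(1, 3 * k, 3), drop = FALSE]) +
                   colMeans(dev2[, seq(2, 3 * k, 3), drop = FALSE]) +
                   colMeans(dev2[, seq(3, 3 * k, 3), drop = FALSE]))
  data.frame(residue_number = ensemble$topology$residue_number[idx],
             rmsf_A = per_atom)
}

# ---------------------------------------------------------------------------
# Centers of mass and distances
# ---------------------------------------------------------------------------

#' Mass-weighted center of a selection in one frame
#'
#' Uses standard atomic masses by element; hydrogens absent from the frames
#' are simply not part of the sum (heavy-atom center of mass).
#'
#' @param coords `n_atoms x 3` coordinate matrix on the full topology.
#' @param topology the ensemble topology data.frame.
#' @param selection an [atom_selection()].
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(coords, topology, selection = NULL) {
  idx <- selection_index(topology, selection)
  m <- element_mass(topology$element[idx])
  colSums(coords[idx, , drop = FALSE] * m) / sum(m)
}

#' Per-frame distance between two centers of mass
#'
#' E.g. between the polymorphic residue and a neighbouring domain.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param selection_a,selection_b two non-empty [atom_selection()]s.
#' @param label_a,label_b names for the two selections.
#' @return object of class `DistanceSeries`: data.frame with `replica_id`,
#'   `time_ps`, `distance_A`, with the labels as attributes.
#' @export
com_distance_series <- function(ensemble, selection_a, selection_b,
                                label_a = "A", label_b = "B") {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  topo <- ensemble$topology
  ia <- selection_index(topo, selection_a)
  ib <- selection_index(topo, selection_b)
  ma <- element_mass(topo$element[ia]); ma <- ma / sum(ma)
  mb <- element_mass(topo$element[ib]); mb <- mb / sum(mb)
  d <- vapply(seq_len(n_frames(ensemble)), function(i) {
    cc <- frame_coords(ensemble, i)
    sqrt(sum((colSums(cc[ia, , drop = FALSE] * ma) -
              colSums(cc[ib, , drop = FALSE] * mb))^2))
  }, numeric(1))
  out <- data.frame(replica_id = ensemble$replica_id,
                    time_ps = ensemble$time_ps, distance_A = d)
  attr(out, "labels") <- c(label_a, label_b)
  class(out) <- c("DistanceSeries", class(out))
  out
}

# ---------------------------------------------------------------------------
# Contacts
# ---------------------------------------------------------------------------

# C-alpha coordinates per frame as an nres x 3 matrix list helper
ca_coords_matrix <- function(ensemble) {
  topo <- ensemble$topology
  idx <- which(topo$atom_name == "CA")
  resnums <- unique(topo$residue_number)
  if (length(idx) != length(resnums))
    stop("residue(s) without a C-alpha atom: ",
         paste(setdiff(resnums, topo$residue_number[idx]), collapse = ", "))
  list(idx = idx, resnums = topo$residue_number[idx])
}

#' Per-frame, per-residue C-alpha contact counts
#'
#' Two residues are in contact in a frame when their C-alpha distance is
#' less than or equal to `cutoff_A` (inclusive at the boundary). Sequence
#' neighbours up to `|i - j| <= exclusion` are not counted; the default
#' `exclusion = 0` counts all other residues, including direct neighbours.
#'
#' @param ensemble a `StructureEnsemble` with a C-alpha per residue.
#' @param cutoff_A distance cutoff in Angstrom (default 8.0).
#' @param exclusion minimum sequence separation minus one; partners with
#'   `|i - j| <= exclusion` are skipped (default 0).
#' @return object of class `ContactSeries`: list with `residue_numbers`,
#'   frame-by-residue integer matrix `counts`, `cutoff_A`, `exclusion`, and
#'   frame times/replicas.
#' @export
contact_counts <- function(ensemble, cutoff_A = 8.0, exclusion = 0L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"), cutoff_A > 0)
  ca <- ca_coords_matrix(ensemble)
  nres <- length(ca$idx)
  nf <- n_frames(ensemble)
  counts <- matrix(0L, nf, nres)
  seqsep <- abs(outer(seq_len(nres), seq_len(nres), `-`))
  mask <- seqsep > exclusion
  for (i in seq_len(nf)) {
    cc <- frame_coords(ensemble, i)[ca$idx, , drop = FALSE]
    dm <- as.matrix(stats::dist(cc))
    counts[i, ] <- colSums((dm <= cutoff_A) & mask)
  }
  structure(list(residue_numbers = ca$resnums, counts = counts,
                 cutoff_A = cutoff_A, exclusion = as.integer(exclusion),
                 time_ps = ensemble$time_ps, replica_id = ensemble$replica_id),
            class = "ContactSeries")
}

#' Contacts of one residue split by the partner's domain
#'
#' For a single residue (typically the polymorphic site) counts, per frame,
#' its C-alpha contacts whose partner residue falls in each named domain.
#' Domain ranges must not overlap; partners outside every domain are
#' reported in the `total` column only.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param residue residue number whose contacts are analysed.
#' @param domains a [domain_definition()].
#' @param cutoff_A,exclusion as in [contact_counts()].
#' @return data.frame with `replica_id`, `time_ps`, one column per domain,
#'   and `total`.
#' @export
contacts_by_partner_domain <- function(ensemble, residue, domains,
                                       cutoff_A = 8.0, exclusion = 0L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"),
            inherits(domains, "domain_definition"))
  ca <- ca_coords_matrix(ensemble)
  r0 <- match(residue, ca$resnums)
  if (is.na(r0)) stop("residue ", residue, " not in ensemble")
  nf <- n_frames(ensemble)
  dn <- names(domains$ranges)
  out <- matrix(0L, nf, length(dn) + 1L,
                dimnames = list(NULL, c(dn, "total")))
  memb <- domain_membership(ca$resnums, domains)
  ok <- abs(seq_along(ca$resnums) - r0) > exclusion
  for (i in seq_len(nf)) {
    cc <- frame_coords(ensemble, i)[ca$idx, , drop = FALSE]
    d <- sqrt(colSums((t(cc) - cc[r0, ])^2))
    contact <- ok & d <= cutoff_A
    out[i, "total"] <- sum(contact)
    for (dd in dn) out[i, dd] <- sum(contact & memb == dd, na.rm = TRUE)
  }
  data.frame(replica_id = ensemble$replica_id, time_ps = ensemble$time_ps,
             out, check.names = FALSE)
}

# ---------------------------------------------------------------------------
# TSV writers
# ---------------------------------------------------------------------------

#' Write an analysis table as TSV
#'
#' Plain tab-separated export used for all per-frame and per-residue series.
#' Series classes (`ContactSeries`, `DihedralSeries`, ...) are flattened via
#' their `as.data.frame` methods first.
#'
#' @param x a data.frame or a series object with an `as.data.frame` method.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_series_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.ContactSeries <- function(x, ...) {
  data.frame(replica_id = rep(x$replica_id, length(x$residue_numbers)),
             time_ps = rep(x$time_ps, length(x$residue_numbers)),
             residue_number = rep(x$residue_numbers, each = nrow(x$counts)),
             contacts = as.vector(x$counts))
}

#' @export
as.data.frame.DihedralSeries <- function(x, ...) {
  nres <- length(x$residue_numbers)
  data.frame(replica_id = rep(x$replica_id, nres),
             time_ps = rep(x$time_ps, nres),
             residue_number = rep(x$residue_numbers, each = nrow(x$phi)),
             phi_deg = as.vector(x$phi), psi_deg = as.vector(x$psi))
}
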
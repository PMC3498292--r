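# Solvent accessibility: Shrake-Rupley ASA on protein heavy atoms and the
# extended Ala-X-Ala relative-ASA normalisation.

#' Load a van der Waals radii set
#'
#' The packaged default (`united-heavy-1.0`) is an element-class,
#' united-heavy-atom set suited to hydrogen-free analysis frames.
#'
#' @param path optional path to an alternative TSV (`element`, `radius_A`).
#' @param probe_radius_A solvent probe radius, Angstrom (default 1.4, water).
#' @return object of class `radii_set`: named numeric vector of radii with a
#'   `probe` attribute.
#' @export
radii_set <- function(path = NULL, probe_radius_A = 1.4) {
  path <- path %||% datafile("vdw_radii.tsv")
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  r <- stats::setNames(tab$radius_A, toupper(tab$element))
  if (any(r <= 0) || probe_radius_A < 0) stop("radii must be positive")
  structure(r, probe = probe_radius_A, class = "radii_set")
}

#' Load the extended Ala-X-Ala reference ASA table
#'
#' Per-residue-type ASA of X in a fully extended Ala-X-Ala tripeptide,
#' used as the denominator of relative ASA. The packaged table fixes
#' Leu at 183 and Pro at 142 Angstrom^2.
#'
#' @param path optional path to an alternative TSV (`residue`, `asa_A2`).
#' @return named numeric vector, Angstrom^2 per 3-letter residue type.
#' @export
reference_asa_table <- function(path = NULL) {
  path <- path %||% datafile("reference_asa.tsv")
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  v <- stats::setNames(tab$asa_A2, toupper(tab$residue))
  if (any(v <= 0)) stop("reference ASA values must be positive")
  v
}

atom_radii <- function(topology, radii) {
  r <- unclass(radii)[toupper(topology$element)]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for atom ", topology$atom_name[bad],
         " (element ", topology$element[bad], ") in residue ",
         topology$residue_number[bad])
  }
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's probe-expanded sphere is sampled with a deterministic
#' golden-spiral point set; points inside any other expanded sphere are
#' occluded. `ASA = 4 pi (r + probe)^2 x accessible fraction`.
#'
#' @param coords `n_atoms x 3` coordinate matrix (one frame, Angstrom).
#' @param topology the ensemble topology data.frame.
#' @param radii a [radii_set()].
#' @param n_points quadrature points per atom (default 960; >= 32).
#' @return numeric vector of per-atom ASA, Angstrom^2.
#' @export
shrake_rupley_asa <- function(coords, topology, radii = radii_set(),
                              n_points = 960L) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topology))
    stop("coordinates and topology disagree on atom count")
  sasa_shrake_rupley(coords, atom_radii(topology, radii),
                     as.integer(n_points), attr(radii, "probe"))
}

#' Aggregate per-atom ASA into per-residue ASA
#'
#' @param atom_asa numeric per-atom ASA vector.
#' @param topology the matching topology data.frame.
#' @return data.frame with `residue_number`, `residue_name`, `asa_A2`.
#' @export
residue_asa <- function(atom_asa, topology) {
  if (length(atom_asa) != nrow(topology))
    stop("per-atom values and topology disagree on atom count")
  resnums <- unique(topology$residue_number)
  s <- tapply(atom_asa, factor(topology$residue_number, levels = resnums), sum)
  data.frame(residue_number = resnums,
             residue_name = topology$residue_name[match(resnums,
                                                        topology$residue_number)],
             asa_A2 = as.numeric(s))
}

#' Relative ASA in percent of the extended Ala-X-Ala reference
#'
#' `rASA = 100 * ASA / reference(residue type)`; values can exceed 100 when
#' a conformation is more exposed than the extended reference.
#'
#' @param res_asa data.frame from [residue_asa()].
#' @param reference a [reference_asa_table()].
#' @return `res_asa` with an additional `rasa_pct` column.
#' @export
relative_asa <- function(res_asa, reference = reference_asa_table()) {
  ref <- reference[toupper(res_asa$residue_name)]
  if (anyNA(ref))
    stop("no reference ASA for residue type ",
         res_asa$residue_name[which(is.na(ref))[1]])
  res_asa$rasa_pct <- 100 * res_asa$asa_A2 / as.numeric(ref)
  res_asa
}

#' Per-frame, per-residue absolute and relative ASA for an ensemble
#'
#' Runs [shrake_rupley_asa()] on every frame and normalises per residue.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param radii a [radii_set()].
#' @param reference a [reference_asa_table()].
#' @param n_points quadrature points per atom.
#' @return object of class `AccessibilitySeries`: list with
#'   `residue_numbers`, `residue_names`, frame-by-residue matrices `asa_A2`
#'   and `rasa_pct`, and frame times/replicas.
#' @export
accessibility_series <- function(ensemble, radii = radii_set(),
                                 reference = reference_asa_table(),
                                 n_points = 960L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  topo <- ensemble$topology
  rads <- atom_radii(topo, radii)
  resnums <- unique(topo$residue_number)
  resnames <- topo$residue_name[match(resnums, topo$residue_number)]
  ref <- reference[toupper(resnames)]
  if (anyNA(ref))
    stop("no reference ASA for residue type ", resnames[which(is.na(ref))[1]])
  fac <- factor(topo$residue_number, levels = resnums)
  grp <- split(seq_len(nrow(topo)), fac)
  nf <- n_frames(ensemble)
  asa <- matrix(0, nf, length(resnums))
  for (i in seq_len(nf)) {
    a <- sasa_shrake_rupley(frame_coords(ensemble, i), rads,
                            as.integer(n_points), attr(radii, "probe"))
    asa[i, ] <- vapply(grp, function(g) sum(a[g]), numeric(1))
  }
  structure(list(residue_numbers = resnums, residue_names = resnames,
                 asa_A2 = asa,
                 rasa_pct = sweep(asa, 2, as.numeric(ref), `/`) * 100,
                 time_ps = ensemble$time_ps, replica_id = ensemble$replica_id),
            class = "AccessibilitySeries")
}

#' @export
as.data.frame.AccessibilitySeries <- function(x, ...) {
  nres <- length(x$residue_numbers)
  data.frame(replica_id = rep(x$replica_id, nres),
             time_ps = rep(x$time_ps, nres),
             residue_number = rep(x$residue_numbers, each = nrow(x$asa_A2)),
             asa_A2 = as.vector(x$asa_A2),
             rasa_pct = as.vector(x$rasa_pct))
}
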
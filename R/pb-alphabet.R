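# Protein Blocks structural alphabet: window assignment by angular RMSD
# against the 16 reference prototypes, per-residue PB frequency profiles,
# and the Neq / deltaNeq flexibility statistics.

PB_LETTERS <- letters[1:16]

#' Load the Protein Blocks prototype table
#'
#' The 16 prototypes (labels `a`..`p`) are each defined by 8 reference
#' dihedral angles over a five-residue window, ordered
#' `psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1),
#' phi(i+2)`. The packaged table (version `pb-2000.1`) is transcribed from
#' the published structural alphabet; a checksum in the file header is
#' verified on load.
#'
#' @param path optional path to an alternative prototype TSV.
#' @return 16 x 8 numeric matrix with rownames `a`..`p` and a
#'   `version` attribute.
#' @export
pb_prototype_table <- function(path = NULL) {
  path <- path %||% datafile("pb_prototypes.tsv")
  hdr <- readLines(path, n = 20)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!identical(rownames(m), PB_LETTERS))
    stop("prototype table must have exactly the 16 labels a..p, in order")
  if (!all(is.finite(m)) || any(m <= -180 | m > 180))
    stop("prototype angles must be finite and in (-180, 180]")
  chk <- hdr[grepl("checksum_sum_angles:", hdr)]
  if (length(chk)) {
    expected <- as.numeric(sub(".*checksum_sum_angles:\\s*", "", chk[1]))
    if (abs(sum(m) - expected) > 0.01)
      stop("prototype table checksum mismatch: file may be corrupted")
  }
  ver <- hdr[grepl("version", hdr)][1]
  attr(m, "version") <- if (is.na(ver)) "unknown" else
    sub(".*version\\s+", "", ver)
  m
}

#' Angular RMSD between a dihedral window and a prototype
#'
#' `sqrt(mean(wrap(window - prototype)^2))` with differences wrapped to the
#' shortest arc in `(-180, 180]`; the dissimilarity used for PB assignment.
#'
#' @param window numeric length-8 vector of observed dihedrals (degrees),
#'   all defined.
#' @param prototype numeric length-8 vector of reference dihedrals.
#' @return non-negative scalar, degrees.
#' @export
rmsda <- function(window, prototype) {
  if (length(window) != 8L || length(prototype) != 8L)
    stop("rmsda expects 8-angle vectors")
  if (anyNA(window)) stop("undefined angle in window")
  d <- wrap_angle(window - prototype)
  sqrt(mean(d^2))
}

#' Assign one dihedral window to its closest Protein Block
#'
#' Minimum-[rmsda()] prototype; ties broken alphabetically so assignment is
#' deterministic.
#'
#' @param window numeric length-8 dihedral window (degrees).
#' @param table a [pb_prototype_table()].
#' @return single character, one of `a`..`p`.
#' @export
assign_window <- function(window, table = pb_prototype_table()) {
  d <- vapply(seq_len(nrow(table)), function(k) rmsda(window, table[k, ]),
              numeric(1))
  rownames(table)[which.min(d)]   # which.min returns the first (alphabetical) tie
}

#' Assign Protein Blocks for every residue of every frame
#'
#' Residue `i` is assigned from the window
#' `psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1),
#' phi(i+2)`; positions whose window is incomplete (always the first two and
#' last two residues) are marked `Z`.
#'
#' @param dihedrals a `DihedralSeries` from [backbone_dihedrals()] with at
#'   least 5 residues.
#' @param table a [pb_prototype_table()].
#' @return object of class `PBAssignment`: list with `residue_numbers` and a
#'   frame-by-residue character matrix `labels` over `a..p` and `Z`, plus
#'   frame times/replicas.
#' @export
assign_ensemble <- function(dihedrals, table = pb_prototype_table()) {
  stopifnot(inherits(dihedrals, "DihedralSeries"))
  nres <- length(dihedrals$residue_numbers)
  if (nres < 5L) stop("PB assignment needs at least 5 residues")
  nf <- nrow(dihedrals$phi)
  labels <- matrix("Z", nf, nres)
  # windows for residues 3..(nres-2), stacked as (frame, residue) rows
  rs <- 3:(nres - 2)
  w <- cbind(as.vector(dihedrals$psi[, rs - 2]),
             as.vector(dihedrals$phi[, rs - 1]),
             as.vector(dihedrals$psi[, rs - 1]),
             as.vector(dihedrals$phi[, rs]),
             as.vector(dihedrals$psi[, rs]),
             as.vector(dihedrals$phi[, rs + 1]),
             as.vector(dihedrals$psi[, rs + 1]),
             as.vector(dihedrals$phi[, rs + 2]))
  ok <- rowSums(is.na(w)) == 0L
  best <- rep(NA_integer_, nrow(w))
  if (any(ok)) {
    dmin <- rep(Inf, sum(ok))
    bidx <- rep(1L, sum(ok))
    wok <- w[ok, , drop = FALSE]
    for (k in seq_len(nrow(table))) {
      dk <- wrap_angle(sweep(wok, 2, table[k, ]))
      ssd <- rowSums(dk * dk)         # monotone in rmsda; order-preserving
      upd <- ssd < dmin - 1e-12       # strict: earlier (alphabetical) label wins ties
      bidx[upd] <- k
      dmin[upd] <- ssd[upd]
    }
    best[ok] <- bidx
  }
  lab <- matrix("Z", nf, length(rs))
  lab[!is.na(best)] <- rownames(table)[best[!is.na(best)]]
  labels[, rs] <- lab
  structure(list(residue_numbers = dihedrals$residue_numbers, labels = labels,
                 time_ps = dihedrals$time_ps, replica_id = dihedrals$replica_id,
                 table_version = attr(table, "version")),
            class = "PBAssignment")
}

#' Per-frame PB strings
#' @param assignment a `PBAssignment`.
#' @return character vector, one string over `a..p`/`Z` per frame.
#' @export
pb_strings <- function(assignment) {
  stopifnot(inherits(assignment, "PBAssignment"))
  apply(assignment$labels, 1, paste, collapse = "")
}

#' Write per-frame PB strings in FASTA-like format
#'
#' One record per frame, header `>replica_id|time_ps`.
#'
#' @param assignment a `PBAssignment`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pb_fasta <- function(assignment, path) {
  s <- pb_strings(assignment)
  hdr <- sprintf(">%s|%g", assignment$replica_id, assignment$time_ps)
  writeLines(as.vector(rbind(hdr, s)), path)
  invisible(path)
}

#' Per-residue PB frequency profile
#'
#' Relative frequency of each of the 16 PBs at each residue, computed over
#' non-`Z` assignments only. Residues that are always `Z` get an all-`NA`
#' row.
#'
#' @param assignments a `PBAssignment` (or list of them, pooled).
#' @return object of class `PBProfile`: list with `residue_numbers`, a
#'   residues-by-16 matrix `freq` (rows sum to 1), and per-residue counts of
#'   non-`Z` frames `n_assigned`.
#' @export
pb_profile <- function(assignments) {
  if (inherits(assignments, "PBAssignment")) assignments <- list(assignments)
  stopifnot(all(vapply(assignments, inherits, logical(1), "PBAssignment")))
  resnums <- assignments[[1]]$residue_numbers
  labels <- do.call(rbind, lapply(assignments, `[[`, "labels"))
  nres <- length(resnums)
  freq <- matrix(NA_real_, nres, 16, dimnames = list(NULL, PB_LETTERS))
  n_assigned <- integer(nres)
  for (j in seq_len(nres)) {
    x <- labels[, j]
    x <- x[x != "Z"]
    n_assigned[j] <- length(x)
    if (length(x))
      freq[j, ] <- tabulate(factor(x, levels = PB_LETTERS), 16) / length(x)
  }
  structure(list(residue_numbers = resnums, freq = freq,
                 n_assigned = n_assigned, n_frames = nrow(labels)),
            class = "PBProfile")
}

#' Equivalent number of Protein Blocks (Neq)
#'
#' `Neq = exp(-sum(f * log(f)))` with the convention `0 * log(0) = 0`: the
#' exponential of the Shannon entropy of a residue's PB distribution. 1
#' means a single PB is ever observed (rigid); 16 means all PBs equally
#' often (maximally variable).
#'
#' @param f numeric length-16 frequency vector, non-negative, summing to 1
#'   (within 1e-6).
#' @return scalar in `[1, 16]`.
#' @export
neq <- function(f) {
  if (anyNA(f) || any(f < 0)) stop("frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-6) stop("frequencies must sum to 1")
  p <- f[f > 0]
  exp(-sum(p * log(p)))
}

#' Per-residue Neq profile
#'
#' @param profile a `PBProfile`.
#' @param label source label (e.g. `"L33"`).
#' @return object of class `NeqProfile`: data.frame with `residue_number`
#'   and `neq` (`NA` at never-assigned positions), label as attribute.
#' @export
neq_profile <- function(profile, label = "ensemble") {
  stopifnot(inherits(profile, "PBProfile"))
  v <- apply(profile$freq, 1, function(f) if (anyNA(f)) NA_real_ else neq(f))
  out <- data.frame(residue_number = profile$residue_numbers, neq = v)
  attr(out, "label") <- label
  class(out) <- c("NeqProfile", class(out))
  out
}

#' Per-residue Neq difference between two variants with significance flags
#'
#' `delta = |Neq_A - Neq_B|`; a residue is flagged significant when
#' `delta > 1.5` and at least one of the two Neq values is below 2.5 (both
#' inequalities strict). Residues undefined in either profile get `NA`.
#'
#' @param profile_a,profile_b `NeqProfile`s over the same residue set.
#' @param delta_threshold significance threshold on `delta` (default 1.5).
#' @param neq_threshold at least one Neq must fall below this (default 2.5).
#' @return object of class `DeltaNeqReport`: data.frame with
#'   `residue_number`, `neq_a`, `neq_b`, `delta`, `significant`.
#' @export
delta_neq <- function(profile_a, profile_b,
                      delta_threshold = 1.5, neq_threshold = 2.5) {
  stopifnot(inherits(profile_a, "NeqProfile"), inherits(profile_b, "NeqProfile"))
  if (!identical(profile_a$residue_number, profile_b$residue_number))
    stop("Neq profiles cover different residue sets")
  delta <- abs(profile_a$neq - profile_b$neq)
  sig <- delta > delta_threshold &
    pmin(profile_a$neq, profile_b$neq) < neq_threshold
  out <- data.frame(residue_number = profile_a$residue_number,
                    neq_a = profile_a$neq, neq_b = profile_b$neq,
                    delta = delta, significant = sig)
  attr(out, "labels") <- c(attr(profile_a, "label"), attr(profile_b, "label"))
  attr(out, "thresholds") <- c(delta = delta_threshold, neq = neq_threshold)
  class(out) <- c("DeltaNeqReport", class(out))
  out
}
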
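#' @useDynLib pbflex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# StructureEnsemble: ordered coordinate frames over one shared atom topology.
#
# topology   data.frame: serial, atom_name, residue_name, residue_number,
#            chain_id, element (author residue numbering, one chain only)
# xyz        numeric matrix, one row per frame, columns x1,y1,z1,x2,...
#            (bio3d layout)
# time_ps    per-frame time in picoseconds
# replica_id per-frame replica label
# label      ensemble label, e.g. "L33" or "P33"
# ---------------------------------------------------------------------------

#' Construct a conformational ensemble
#'
#' Bundles a shared atom topology with an ordered set of coordinate frames.
#' Frames are sorted by `(replica_id, time_ps)`; coordinates must be finite
#' and match the topology atom count. Only single-chain topologies are
#' accepted, since all analyses in this package address one protein chain.
#'
#' @param topology data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `element`.
#' @param xyz numeric matrix with one row per frame and `3 * n_atoms` columns
#'   in `x1,y1,z1,x2,...` order (Angstrom).
#' @param time_ps numeric vector of per-frame times (ps), non-negative.
#' @param replica_id character vector of per-frame replica labels.
#' @param label ensemble label (e.g. `"L33"`).
#' @return object of class `StructureEnsemble`.
#' @export
structure_ensemble <- function(topology, xyz, time_ps, replica_id,
                               label = "ensemble") {
  stopifnot(is.data.frame(topology))
  need <- c("serial", "atom_name", "residue_name", "residue_number",
            "chain_id", "element")
  miss <- setdiff(need, names(topology))
  if (length(miss)) stop("topology lacks column(s): ", paste(miss, collapse = ", "))
  if (length(unique(topology$chain_id)) != 1L)
    stop("only single-chain ensembles are supported; found chains: ",
         paste(unique(topology$chain_id), collapse = ", "))
  if (is.unsorted(topology$residue_number))
    stop("residue_number must be non-decreasing along the topology")
  dup <- duplicated(topology[, c("residue_number", "atom_name")])
  if (any(dup))
    stop("duplicated atom_name within residue ",
         topology$residue_number[which(dup)[1]])
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one frame")
  if (ncol(xyz) != 3L * nrow(topology))
    stop("coordinate count (", ncol(xyz), ") does not match topology atoms (",
         nrow(topology), " x 3)")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  time_ps <- as.numeric(time_ps)
  replica_id <- as.character(replica_id)
  if (length(time_ps) != nrow(xyz) || length(replica_id) != nrow(xyz))
    stop("time_ps and replica_id must have one entry per frame")
  if (any(time_ps < 0)) stop("time_ps must be non-negative")
  ord <- order(replica_id, time_ps)
  structure(list(topology = topology,
                 xyz = xyz[ord, , drop = FALSE],
                 time_ps = time_ps[ord],
                 replica_id = replica_id[ord],
                 label = label),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat("StructureEnsemble '", x$label, "': ", n_frames(x), " frame(s), ",
      n_atoms(x), " atoms, ", length(unique(x$topology$residue_number)),
      " residues, replica(s): ",
      paste(unique(x$replica_id), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `StructureEnsemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Number of atoms in an ensemble topology
#' @param ensemble a `StructureEnsemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(ensemble) nrow(ensemble$topology)

#' Coordinates of one frame as an atoms-by-3 matrix
#' @param ensemble a `StructureEnsemble`.
#' @param i frame index.
#' @return numeric `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
}

# ---------------------------------------------------------------------------
# Multi-model PDB reading / writing (parsing delegated to bio3d)
# ---------------------------------------------------------------------------

# Scan raw PDB lines for structural problems before handing off to bio3d:
# per-model atom-count mismatches (reported by model number) and unparsable
# ATOM coordinate fields (reported by line number).
validate_pdb_lines <- function(lines) {
  is_atom <- startsWith(lines, "ATOM")
  coords <- substr(lines[is_atom], 31, 54)
  bad <- which(is.na(suppressWarnings(
    as.numeric(substr(coords, 1, 8)) +
      as.numeric(substr(coords, 9, 16)) +
      as.numeric(substr(coords, 17, 24)))))
  if (length(bad))
    stop("unparsable ATOM record at line ", which(is_atom)[bad[1]])
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1L) {
      off <- which(counts != counts[1])[1]
      stop("model ", off, " has ", counts[off],
           " atoms but model 1 has ", counts[1])
    }
  }
  invisible(length(model_starts))
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame ensemble. The topology is taken from the
#' first model and every later model must match its atom count. Frame times
#' default to `(model_index - 1) * default_time_step_ps`; a
#' `REMARK ... TIME_PS <value>` line inside a model block overrides its time.
#' Files ending in `.gz` are decompressed transparently.
#'
#' @param path path to a (optionally gzipped) multi-model PDB file.
#' @param default_time_step_ps spacing between successive models in ps
#'   (default 100, one snapshot per 100 ps).
#' @param replica_id replica label attached to every frame.
#' @param label ensemble label; defaults to the file name.
#' @return a [structure_ensemble()].
#' @export
read_multimodel_pdb <- function(path, default_time_step_ps = 100,
                                replica_id = "r1", label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  validate_pdb_lines(lines)
  src <- path
  if (grepl("\\.gz$", path)) {
    src <- tempfile(fileext = ".pdb")
    writeLines(lines, src)
    on.exit(unlink(src))
  }
  pdb <- bio3d::read.pdb(src, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  topo <- data.frame(serial = at$eleno,
                     atom_name = at$elety,
                     residue_name = at$resid,
                     residue_number = at$resno,
                     chain_id = ifelse(is.na(at$chain), "A", at$chain),
                     element = guess_element(at$elesy, at$elety),
                     stringsAsFactors = FALSE)
  keep <- which(pdb$atom$type == "ATOM")
  cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  nf <- nrow(xyz)
  times <- (seq_len(nf) - 1) * default_time_step_ps
  times_remark <- parse_remark_times(lines, nf)
  if (!is.null(times_remark)) times <- times_remark
  structure_ensemble(topo, xyz, times, rep(replica_id, nf),
                     label = label %||% basename(path))
}

guess_element <- function(elesy, elety) {
  e <- toupper(trimws(elesy))
  bad <- is.na(e) | !nzchar(e)
  # fall back to the first letter of the atom name (protein heavy atoms)
  e[bad] <- substr(gsub("[^A-Za-z].*", "", toupper(elety[bad])), 1, 1)
  e
}

# Extract "REMARK ... TIME_PS <value>" per model block. Returns NULL when the
# file carries no such remarks; otherwise requires one remark per model.
parse_remark_times <- function(lines, nf) {
  hits <- grepl("^REMARK.*TIME_PS", lines)
  if (!any(hits)) return(NULL)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) model_starts <- 1L
  vals <- rep(NA_real_, nf)
  for (i in which(hits)) {
    m <- findInterval(i, model_starts)
    if (m >= 1 && m <= nf)
      vals[m] <- as.numeric(sub(".*TIME_PS[ =]*([-0-9.eE+]+).*", "\\1", lines[i]))
  }
  if (anyNA(vals)) stop("TIME_PS remarks present but not one per model")
  vals
}

#' Write an ensemble as a multi-model PDB file
#'
#' One `MODEL` block per frame, fixed-column ATOM records (three decimals on
#' coordinates), plus one `REMARK ... TIME_PS` line per model so frame times
#' survive a round trip. Reading the file back reproduces topology exactly
#' and coordinates to PDB precision.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  topo <- ensemble$topology
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = ensemble$xyz,
                   resno = topo$residue_number, resid = topo$residue_name,
                   eleno = topo$serial, elety = topo$atom_name,
                   chain = topo$chain_id, elesy = topo$element)
  lines <- readLines(tmp)
  unlink(tmp)
  # interleave TIME_PS remarks after each MODEL line
  model_at <- which(startsWith(lines, "MODEL"))
  if (length(model_at)) {
    remarks <- sprintf("REMARK 250 TIME_PS %.3f REPLICA %s",
                       ensemble$time_ps, ensemble$replica_id)
    out <- character(0)
    prev <- 1L
    for (k in seq_along(model_at)) {
      out <- c(out, lines[prev:model_at[k]], remarks[k])
      prev <- model_at[k] + 1L
    }
    lines <- c(out, lines[prev:length(lines)])
  }
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

# ---------------------------------------------------------------------------
# Frame filtering and pooling
# ---------------------------------------------------------------------------

#' Discard equilibration frames
#'
#' Drops, independently within each replica, every frame with
#' `time_ps <= cutoff_ps` (strict retention of `time_ps > cutoff_ps`).
#' Discarding the initial equilibration segment of each simulation before
#' computing statistics is standard practice; 5000 ps is the conventional
#' default in this package.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param cutoff_ps non-negative time cutoff in ps.
#' @return filtered `StructureEnsemble` (frame order preserved).
#' @export
discard_equilibration <- function(ensemble, cutoff_ps) {
  stopifnot(inherits(ensemble, "StructureEnsemble"), cutoff_ps >= 0)
  keep <- ensemble$time_ps > cutoff_ps
  if (!any(keep)) stop("equilibration cutoff removes every frame")
  structure_ensemble(ensemble$topology,
                     ensemble$xyz[keep, , drop = FALSE],
                     ensemble$time_ps[keep], ensemble$replica_id[keep],
                     label = ensemble$label)
}

#' Pool replicate ensembles sharing one topology
#'
#' Concatenates the frames of several ensembles (e.g. independent simulation
#' replicas of the same variant) into one. All topologies must be identical;
#' in particular two variants differing at the polymorphic residue cannot be
#' pooled.
#'
#' @param ensembles list of `StructureEnsemble` objects.
#' @return pooled `StructureEnsemble`; the label is taken from the first.
#' @export
pool_replicas <- function(ensembles) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1L)
  ref <- ensembles[[1]]
  cols <- c("atom_name", "residue_name", "residue_number", "chain_id", "element")
  for (k in seq_along(ensembles)[-1]) {
    t2 <- ensembles[[k]]$topology
    if (nrow(t2) != nrow(ref$topology))
      stop("topology mismatch: ensemble ", k, " has ", nrow(t2), " atoms")
    for (cc in cols) {
      d <- which(ref$topology[[cc]] != t2[[cc]])
      if (length(d))
        stop("topology mismatch at atom ", d[1], " (", cc, ": ",
             ref$topology[[cc]][d[1]], " vs ", t2[[cc]][d[1]], ")")
    }
  }
  structure_ensemble(ref$topology,
                     do.call(rbind, lapply(ensembles, `[[`, "xyz")),
                     unlist(lapply(ensembles, `[[`, "time_ps")),
                     unlist(lapply(ensembles, `[[`, "replica_id")),
                     label = ref$label)
}

# ---------------------------------------------------------------------------
# Atom selection
# ---------------------------------------------------------------------------

#' Build an atom selection specification
#'
#' A selection addresses atoms by name (e.g. `"CA"`), residue number, and/or
#' residue type; `NULL` criteria match everything. Criteria combine with AND.
#'
#' @param atom_name character vector of atom names, or `NULL`.
#' @param residue_numbers integer vector of residue numbers (e.g. `1:56`),
#'   or `NULL`.
#' @param residue_name character vector of 3-letter residue types, or `NULL`.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(atom_name = NULL, residue_numbers = NULL,
                           residue_name = NULL) {
  structure(list(atom_name = atom_name, residue_numbers = residue_numbers,
                 residue_name = residue_name),
            class = "atom_selection")
}

#' C-alpha selection shorthand
#' @param residue_numbers optional residue-number restriction.
#' @return an [atom_selection()] matching `CA` atoms.
#' @export
ca_selection <- function(residue_numbers = NULL) {
  atom_selection(atom_name = "CA", residue_numbers = residue_numbers)
}

selection_index <- function(topology, selection) {
  if (is.null(selection)) return(seq_len(nrow(topology)))
  stopifnot(inherits(selection, "atom_selection"))
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(selection$atom_name))
    keep <- keep & topology$atom_name %in% selection$atom_name
  if (!is.null(selection$residue_numbers))
    keep <- keep & topology$residue_number %in% selection$residue_numbers
  if (!is.null(selection$residue_name))
    keep <- keep & topology$residue_name %in% selection$residue_name
  idx <- which(keep)
  if (length(idx) == 0L) stop("atom selection matches no atoms")
  idx
}

#' Extract a sub-ensemble by atom selection
#'
#' @param ensemble a `StructureEnsemble`.
#' @param selection an [atom_selection()].
#' @return `StructureEnsemble` restricted to the selected atoms, frame order
#'   preserved.
#' @export
select_atoms <- function(ensemble, selection) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  idx <- selection_index(ensemble$topology, selection)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  structure_ensemble(ensemble$topology[idx, , drop = FALSE],
                     ensemble$xyz[, cols, drop = FALSE],
                     ensemble$time_ps, ensemble$replica_id,
                     label = ensemble$label)
}
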
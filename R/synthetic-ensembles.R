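# Seeded synthetic conformational ensembles with known ground truth.
#
# Per frame, a Protein-Block "recipe" string (one letter per residue) is
# drawn from a weighted mixture; each residue's (phi, psi) is set to the
# central-angle pair of its letter's prototype plus wrapped-normal angular
# noise; a backbone (N, CA, C, O, CB) is then built by sequential internal-
# coordinate (NeRF) construction. This emulates the statistical structure
# the ensemble analyses assume -- per-residue local-conformation mixtures --
# without any molecular dynamics.

#' Ideal peptide geometry constants
#'
#' Bond lengths (Angstrom), bond angles (degrees) and the fixed trans omega
#' torsion used by the chain builder.
#'
#' @return named list of geometry constants.
#' @export
geometry_constants <- function() {
  list(bond_n_ca = 1.458, bond_ca_c = 1.525, bond_c_n = 1.329,
       bond_c_o = 1.231, bond_ca_cb = 1.530,
       angle_n_ca_c = 111.0, angle_ca_c_n = 116.5, angle_c_n_ca = 121.5,
       angle_ca_c_o = 120.8, angle_n_ca_cb = 110.5,
       omega = 180.0, cb_torsion = -122.6)
}

#' Recipe for a synthetic conformational ensemble
#'
#' @param n_residues chain length (>= 5).
#' @param recipes list of `list(pb = <string over a..p, one letter per
#'   residue>, weight = <numeric>)`; weights must sum to 1. Each frame draws
#'   one recipe.
#' @param sigma_deg wrapped-normal angular noise SD in degrees, a scalar or
#'   one value per residue (>= 0).
#' @param n_frames total number of frames.
#' @param residue_types 3-letter residue types, recycled to length
#'   `n_residues` (default poly-Ala).
#' @param variant_position residue number whose type is the variant site
#'   (default `NULL`, no variant site).
#' @param variant_type residue type at the variant site (e.g. `"LEU"`).
#' @param replica_layout named integer vector of frames per replica summing
#'   to `n_frames`; default one replica `r1`.
#' @param time_step_ps spacing of frame times within a replica (default
#'   100 ps; times start at `time_step_ps`).
#' @param seed integer RNG seed.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_residues, recipes, sigma_deg = 0,
                           n_frames = 100L, residue_types = "ALA",
                           variant_position = NULL, variant_type = "LEU",
                           replica_layout = NULL, time_step_ps = 100,
                           seed = 1L) {
  stopifnot(n_residues >= 5L, n_frames >= 1L)
  if (!is.list(recipes) || !length(recipes)) stop("recipes must be a non-empty list")
  w <- vapply(recipes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("recipe weights must sum to 1")
  for (rc in recipes) {
    if (nchar(rc$pb) != n_residues)
      stop("recipe string length must equal n_residues")
    if (!all(strsplit(rc$pb, "")[[1]] %in% PB_LETTERS))
      stop("recipe letters must be in a..p")
  }
  sigma <- rep_len(sigma_deg, n_residues)
  if (any(sigma < 0)) stop("sigma_deg must be >= 0")
  types <- rep_len(toupper(residue_types), n_residues)
  if (!is.null(variant_position)) {
    if (variant_position < 1 || variant_position > n_residues)
      stop("variant_position outside the chain")
    types[variant_position] <- toupper(variant_type)
  }
  layout <- replica_layout %||% stats::setNames(as.integer(n_frames), "r1")
  if (sum(layout) != n_frames) stop("replica_layout must sum to n_frames")
  structure(list(n_residues = as.integer(n_residues), recipes = recipes,
                 sigma_deg = sigma, n_frames = as.integer(n_frames),
                 residue_types = types,
                 variant_position = variant_position,
                 replica_layout = layout[order(names(layout))],
                 time_step_ps = time_step_ps, seed = as.integer(seed)),
            class = "generator_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample per-frame backbone dihedrals from a generator spec
#'
#' For each frame one recipe is drawn by weight; residue `i` receives the
#' central `(phi, psi)` pair of its recipe letter's prototype, plus
#' independent wrapped-normal noise of SD `sigma_deg`. `phi` of the first
#' and `psi` of the last residue are undefined (`NA`).
#'
#' @param spec a [generator_spec()].
#' @param table a [pb_prototype_table()].
#' @return a `DihedralSeries` with attributes `recipe_id` (per-frame index
#'   into `spec$recipes`) and `true_pb` (frame-by-residue letter matrix).
#' @export
sample_dihedrals <- function(spec, table = pb_prototype_table()) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_residues
  nf <- spec$n_frames
  letters_by_recipe <- lapply(spec$recipes,
                              function(rc) strsplit(rc$pb, "")[[1]])
  w <- vapply(spec$recipes, `[[`, numeric(1), "weight")
  phi0 <- vapply(letters_by_recipe, function(l) table[l, "phi_0"], numeric(n))
  psi0 <- vapply(letters_by_recipe, function(l) table[l, "psi_0"], numeric(n))
  phi0 <- matrix(phi0, nrow = n); psi0 <- matrix(psi0, nrow = n)
  out <- with_seed(spec$seed, {
    draw <- sample.int(length(spec$recipes), nf, replace = TRUE, prob = w)
    phi <- t(phi0[, draw, drop = FALSE])
    psi <- t(psi0[, draw, drop = FALSE])
    if (any(spec$sigma_deg > 0)) {
      sg <- matrix(spec$sigma_deg, nf, n, byrow = TRUE)
      phi <- wrap_angle(phi + stats::rnorm(nf * n, 0, sg))
      psi <- wrap_angle(psi + stats::rnorm(nf * n, 0, sg))
    }
    list(draw = draw, phi = phi, psi = psi)
  })
  phi <- out$phi; psi <- out$psi
  phi[, 1] <- NA_real_
  psi[, n] <- NA_real_
  times <- replica_times(spec)
  ds <- structure(list(residue_numbers = seq_len(n), phi = phi, psi = psi,
                       time_ps = times$time_ps, replica_id = times$replica_id),
                  class = "DihedralSeries")
  attr(ds, "recipe_id") <- out$draw
  attr(ds, "true_pb") <- t(vapply(out$draw,
                                  function(k) letters_by_recipe[[k]],
                                  character(n)))
  ds
}

replica_times <- function(spec) {
  reps <- spec$replica_layout
  list(replica_id = rep(names(reps), reps),
       time_ps = unlist(lapply(reps, function(k)
         seq_len(k) * spec$time_step_ps), use.names = FALSE))
}

# NeRF atom placement, vectorised across frames: given previous atoms A, B, C
# (nf x 3 each), bond length r (C-D), bond angle theta at C (B-C-D, degrees)
# and torsion tau (A-B-C-D, degrees; scalar or length nf), returns D.
place_atom <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- unit_rows(C - B)
  n <- unit_rows(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- cbind(-r * cos(th),
             r * sin(th) * cos(ta),
             -r * sin(th) * sin(ta))
  C + d[, 1] * bc + d[, 2] * m + d[, 3] * n
}

# Build backbone coordinates for all frames at once. phi, psi: nf x n
# matrices (NA allowed at phi[,1] / psi[,n]). Returns list(topology, xyz).
build_ensemble_coords <- function(phi, psi, residue_types,
                                  constants = geometry_constants()) {
  nf <- nrow(phi); n <- ncol(phi)
  g <- constants
  has_cb <- residue_types != "GLY"
  N <- vector("list", n); CA <- vector("list", n); C <- vector("list", n)
  one <- function(x, y, z) matrix(rep(c(x, y, z), each = nf), nf, 3)
  N[[1]] <- one(0, 0, 0)
  CA[[1]] <- one(g$bond_n_ca, 0, 0)
  a <- (180 - g$angle_n_ca_c) * pi / 180
  C[[1]] <- CA[[1]] + g$bond_ca_c * cbind(rep(cos(a), nf), rep(sin(a), nf), 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                             g$bond_c_n, g$angle_ca_c_n, psi[, i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                              g$bond_n_ca, g$angle_c_n_ca, g$omega)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                             g$bond_ca_c, g$angle_n_ca_c, phi[, i + 1])
  }
  O <- vector("list", n); CB <- vector("list", n)
  for (i in seq_len(n)) {
    # carbonyl O in the peptide plane, anti to the next N
    tau_o <- if (i < n) wrap_angle(psi[, i] + 180) else rep(180, nf)
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         g$bond_c_o, g$angle_ca_c_o, tau_o)
    if (has_cb[i])
      CB[[i]] <- place_atom(C[[i]], N[[i]], CA[[i]],
                            g$bond_ca_cb, g$angle_n_ca_cb, g$cb_torsion)
  }
  atom_names <- character(0); resno <- integer(0)
  blocks <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O", if (has_cb[i]) "CB")
    atom_names <- c(atom_names, nm)
    resno <- c(resno, rep(i, length(nm)))
    blocks <- c(blocks, list(N[[i]], CA[[i]], C[[i]], O[[i]]),
                if (has_cb[i]) list(CB[[i]]))
  }
  natoms <- length(atom_names)
  xyz <- matrix(0, nf, 3 * natoms)
  for (k in seq_len(natoms)) xyz[, (3 * k - 2):(3 * k)] <- blocks[[k]]
  element <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")[atom_names]
  topo <- data.frame(serial = seq_len(natoms), atom_name = atom_names,
                     residue_name = residue_types[resno],
                     residue_number = resno, chain_id = "A",
                     element = unname(element), stringsAsFactors = FALSE)
  list(topology = topo, xyz = xyz)
}

#' Build one frame from backbone dihedrals
#'
#' Sequential internal-coordinate (NeRF) construction of an N, CA, C, O, CB
#' backbone from per-residue phi/psi, with ideal bond lengths/angles and
#' trans peptide bonds. Re-measuring the torsions of the built chain
#' reproduces the inputs.
#'
#' @param phi,psi numeric vectors of dihedrals in degrees (`phi[1]` and
#'   `psi[n]` may be `NA`).
#' @param residue_types 3-letter residue types, recycled.
#' @param constants a [geometry_constants()] list.
#' @return list with `topology` and an `n_atoms x 3` coordinate matrix
#'   `coords`.
#' @export
build_coordinates <- function(phi, psi, residue_types = "ALA",
                              constants = geometry_constants()) {
  stopifnot(length(phi) == length(psi))
  types <- rep_len(toupper(residue_types), length(phi))
  b <- build_ensemble_coords(matrix(phi, 1), matrix(psi, 1), types, constants)
  list(topology = b$topology, coords = matrix(b$xyz[1, ], ncol = 3, byrow = TRUE))
}

#' Generate a synthetic conformational ensemble
#'
#' [sample_dihedrals()] plus chain building for every frame;
#' deterministic given `(spec, seed)`.
#'
#' @param spec a [generator_spec()].
#' @param label ensemble label.
#' @param table a [pb_prototype_table()].
#' @return a `StructureEnsemble` with attributes `recipe_id` and `true_pb`
#'   (the per-frame ground truth) and `spec`.
#' @export
generate_ensemble <- function(spec, label = "synthetic",
                              table = pb_prototype_table()) {
  ds <- sample_dihedrals(spec, table)
  b <- build_ensemble_coords(ds$phi, ds$psi, spec$residue_types)
  e <- structure_ensemble(b$topology, b$xyz, ds$time_ps, ds$replica_id,
                          label = label)
  attr(e, "recipe_id") <- attr(ds, "recipe_id")
  attr(e, "true_pb") <- attr(ds, "true_pb")
  attr(e, "spec") <- spec
  e
}

#' Generate a two-variant ensemble pair with a localised flexibility contrast
#'
#' Variant A is generated from `base_spec` unchanged (variant residue typed
#' `LEU`); variant B is identical except that residues inside
#' `perturbed_window` receive `extra_noise_sigma` additional angular noise
#' and, optionally, an alternative recipe mixed in with weight `alt_weight`
#' -- and the variant residue is typed `PRO`. This emulates a point variant
#' that increases local conformational flexibility.
#'
#' @param base_spec a [generator_spec()] (its `variant_position` must be set).
#' @param perturbed_window integer residue range perturbed in variant B.
#' @param extra_noise_sigma additional noise SD (degrees, >= 0) in the window.
#' @param alt_recipe optional full-length PB string (or character vector of
#'   several) mixed into B's recipes.
#' @param alt_weight total mixture weight of the alternative recipes,
#'   split equally among them (default 0.5).
#' @param labels length-2 labels, default `c("L33", "P33")`-style
#'   `c("A", "B")`.
#' @return list with elements `A` and `B`, two `StructureEnsemble`s.
#' @export
generate_variant_pair <- function(base_spec, perturbed_window,
                                  extra_noise_sigma = 0, alt_recipe = NULL,
                                  alt_weight = 0.5,
                                  labels = c("A", "B")) {
  stopifnot(inherits(base_spec, "generator_spec"), extra_noise_sigma >= 0)
  if (is.null(base_spec$variant_position))
    stop("base_spec must define a variant_position")
  if (any(perturbed_window < 1 | perturbed_window > base_spec$n_residues))
    stop("perturbed window outside the chain")
  spec_a <- base_spec
  spec_a$residue_types[base_spec$variant_position] <- "LEU"
  spec_b <- base_spec
  spec_b$residue_types[base_spec$variant_position] <- "PRO"
  spec_b$sigma_deg[perturbed_window] <-
    spec_b$sigma_deg[perturbed_window] + extra_noise_sigma
  if (!is.null(alt_recipe)) {
    if (any(nchar(alt_recipe) != base_spec$n_residues))
      stop("alt_recipe length must equal n_residues")
    spec_b$recipes <- c(
      lapply(spec_b$recipes,
             function(rc) list(pb = rc$pb, weight = rc$weight * (1 - alt_weight))),
      lapply(alt_recipe, function(s)
        list(pb = s, weight = alt_weight / length(alt_recipe))))
  }
  # decorrelate the two variants deterministically
  spec_b$seed <- (base_spec$seed + 1000003L) %% .Machine$integer.max
  list(A = generate_ensemble(spec_a, label = labels[1]),
       B = generate_ensemble(spec_b, label = labels[2]))
}

#' Write generator ground truth as TSV
#'
#' Per-frame recipe index and the true per-residue PB letters, for test
#' harnesses and external checks.
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ground_truth_tsv <- function(ensemble, path) {
  rid <- attr(ensemble, "recipe_id")
  tp <- attr(ensemble, "true_pb")
  if (is.null(rid) || is.null(tp))
    stop("ensemble carries no generator ground truth")
  utils::write.table(
    data.frame(replica_id = ensemble$replica_id, time_ps = ensemble$time_ps,
               recipe_id = rid, true_pb = apply(tp, 1, paste, collapse = "")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged two-variant synthetic scenario
#'
#' A 60-residue chain standing in for the beta-3 knee: three 20-residue
#' "domains" with the variant site at residue 10. Variant A ("L-like") is a
#' mostly extended chain with 5 degrees of baseline angular noise; variant B
#' ("P-like") is identical except that residues 6-14 receive 15 degrees of
#' extra noise and two alternative local structures (helical `m` and
#' coil-like `i` windows) are mixed in with total weight 0.5, which raises
#' the window Neq to about 2.8 (so the deltaNeq significance rule fires
#' there) and packs the variant residue against the rest of the chain.
#' 2000 frames per variant at 100 ps spacing, so the
#' standard 5 ns equilibration discard leaves 1950 analysis frames each.
#'
#' @param seed integer seed; the two variants derive decorrelated streams
#'   from it.
#' @param n_frames frames per variant (default 2000).
#' @return list with `A` and `B` (`StructureEnsemble`s), `domains` (a
#'   [domain_definition()] for the synthetic chain), `window` (the perturbed
#'   residues), and `spec` (variant A's [generator_spec()]).
#' @export
synthetic_knee_scenario <- function(seed = 1L, n_frames = 2000L) {
  n <- 60L
  window <- 6:14
  base <- paste(rep("d", n), collapse = "")
  alt_of <- function(letter) {
    s <- strsplit(base, "")[[1]]
    s[window] <- letter
    paste(s, collapse = "")
  }
  spec <- generator_spec(n_residues = n,
                         recipes = list(list(pb = base, weight = 1)),
                         sigma_deg = 5, n_frames = n_frames,
                         residue_types = "ALA", variant_position = 10L,
                         time_step_ps = 100, seed = seed)
  pair <- generate_variant_pair(spec, perturbed_window = window,
                                extra_noise_sigma = 15,
                                alt_recipe = c(alt_of("m"), alt_of("i")),
                                alt_weight = 0.5, labels = c("L-like", "P-like"))
  domains <- domain_definition(list("PSI" = c(1, 20),
                                    "I-EGF-1" = c(21, 40),
                                    "I-EGF-2" = c(41, 60)),
                               variant_residue = 10)
  list(A = pair$A, B = pair$B, domains = domains, window = window,
       spec = spec)
}
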
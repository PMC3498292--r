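# End-to-end comparison of two variant ensembles: flexibility profiles,
# exposure/contact/distance distributions, Neq significance, and
# representative-frame selection.

#' Define named domains and the variant residue
#'
#' Defaults follow the integrin beta-3 knee: PSI 1-56, I-EGF-1 434-472,
#' I-EGF-2 473-522, with the HPA-1 polymorphic residue at position 33 of the
#' mature sequence. Ranges are inclusive and must not overlap; the variant
#' residue must fall inside exactly one domain.
#'
#' @param ranges named list of inclusive `c(first, last)` residue ranges.
#' @param variant_residue residue number of the polymorphic site.
#' @return object of class `domain_definition`.
#' @export
domain_definition <- function(ranges = list("PSI" = c(1, 56),
                                            "I-EGF-1" = c(434, 472),
                                            "I-EGF-2" = c(473, 522)),
                              variant_residue = 33) {
  stopifnot(is.list(ranges), length(ranges) >= 1L, !is.null(names(ranges)))
  for (r in ranges)
    if (length(r) != 2L || r[1] > r[2]) stop("each range must be c(first, last)")
  nm <- names(ranges)
  for (i in seq_along(ranges))
    for (j in seq_len(i - 1L))
      if (ranges[[i]][1] <= ranges[[j]][2] && ranges[[j]][1] <= ranges[[i]][2])
        stop("domains ", nm[j], " and ", nm[i], " overlap")
  host <- vapply(ranges, function(r)
    variant_residue >= r[1] && variant_residue <= r[2], logical(1))
  if (sum(host) != 1L)
    stop("variant residue ", variant_residue,
         " must lie inside exactly one domain")
  structure(list(ranges = ranges, variant_residue = variant_residue,
                 host_domain = nm[host]),
            class = "domain_definition")
}

# Domain membership (name or NA) for a vector of residue numbers.
domain_membership <- function(residue_numbers, domains) {
  out <- rep(NA_character_, length(residue_numbers))
  for (nm in names(domains$ranges)) {
    r <- domains$ranges[[nm]]
    out[residue_numbers >= r[1] & residue_numbers <= r[2]] <- nm
  }
  out
}

#' Configuration for a two-variant comparison
#'
#' @param equilibration_cutoff_ps frames at or before this time are dropped
#'   per replica (default 5000 ps).
#' @param contact_cutoff_A C-alpha contact cutoff (default 8.0, inclusive).
#' @param contact_exclusion sequence-neighbour exclusion (default 0:
#'   neighbours count).
#' @param rasa_bin_pct rASA histogram bin width in percent (default 5).
#' @param contact_bin contact-count histogram bin width (default 1).
#' @param delta_neq_threshold significance threshold on deltaNeq (default 1.5).
#' @param neq_threshold at least one Neq below this for significance
#'   (default 2.5).
#' @param n_representatives representative frames per variant (default 3).
#' @param asa_n_points Shrake-Rupley quadrature points (default 960).
#' @param pca_modes modes reported from the pooled PCA (default `1:2`).
#' @return object of class `comparison_config`.
#' @export
comparison_config <- function(equilibration_cutoff_ps = 5000,
                              contact_cutoff_A = 8.0,
                              contact_exclusion = 0L,
                              rasa_bin_pct = 5,
                              contact_bin = 1,
                              delta_neq_threshold = 1.5,
                              neq_threshold = 2.5,
                              n_representatives = 3L,
                              asa_n_points = 960L,
                              pca_modes = 1:2) {
  stopifnot(equilibration_cutoff_ps >= 0, contact_cutoff_A > 0,
            rasa_bin_pct > 0, contact_bin > 0,
            delta_neq_threshold > 0, neq_threshold > 0,
            n_representatives >= 1L)
  structure(as.list(environment()), class = "comparison_config")
}

#' Histogram with left-closed, right-open bins and relative frequencies
#'
#' Bin edges are multiples of `bin_width` covering the data (or the given
#' `range`); frequencies sum to 1.
#'
#' @param values numeric vector (non-empty).
#' @param bin_width positive bin width.
#' @param range optional `c(lo, hi)` forced coverage.
#' @return list with `breaks`, `mids`, `freq`.
#' @export
frequency_histogram <- function(values, bin_width, range = NULL) {
  if (!length(values)) stop("empty series")
  stopifnot(bin_width > 0)
  lo <- floor(min(c(values, range)) / bin_width) * bin_width
  hi <- (floor(max(c(values, range)) / bin_width) + 1) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(values, breaks, rightmost.closed = FALSE)  # left-closed
  freq <- tabulate(idx, nbins = length(breaks) - 1L) / length(values)
  list(breaks = breaks, mids = utils::head(breaks, -1) + bin_width / 2,
       freq = freq)
}

# Modal bin index of a frequency_histogram (first maximum).
modal_bin <- function(h) which.max(h$freq)

#' Select representative frames by joint modal exposure and contacts
#'
#' Identifies the modal bin of the variant residue's rASA histogram and the
#' modal contact count, then returns up to `k` frames falling in both modal
#' classes, ordered by time. If fewer than `k` qualify, the contact class is
#' relaxed to nearest-neighbour values first, then the rASA bin, until `k`
#' frames are found or frames are exhausted.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param rasa_values per-frame rASA (percent) of the variant residue.
#' @param contact_values per-frame contact counts of the variant residue.
#' @param k number of representatives (>= 1).
#' @param rasa_bin_pct rASA bin width (default 5).
#' @return data.frame with `frame`, `replica_id`, `time_ps`, `rasa_pct`,
#'   `contacts`.
#' @export
select_representatives <- function(ensemble, rasa_values, contact_values,
                                   k = 3L, rasa_bin_pct = 5) {
  stopifnot(inherits(ensemble, "StructureEnsemble"), k >= 1L)
  nf <- n_frames(ensemble)
  if (length(rasa_values) != nf || length(contact_values) != nf)
    stop("series must align with frames")
  h <- frequency_histogram(rasa_values, rasa_bin_pct)
  rbin <- findInterval(rasa_values, h$breaks, rightmost.closed = FALSE)
  rmode <- modal_bin(h)
  cmode <- as.integer(names(which.max(table(contact_values))))
  picked <- integer(0)
  max_dr <- max(abs(rbin - rmode))
  max_dc <- max(abs(contact_values - cmode))
  for (dr in 0:max_dr) {
    for (dc in 0:max_dc) {          # contacts relax first within each rASA ring
      cand <- which(abs(rbin - rmode) == dr & abs(contact_values - cmode) == dc)
      cand <- setdiff(cand[order(ensemble$time_ps[cand])], picked)
      picked <- c(picked, cand)
      if (length(picked) >= k) break
    }
    if (length(picked) >= k) break
  }
  picked <- utils::head(picked, k)
  data.frame(frame = picked,
             replica_id = ensemble$replica_id[picked],
             time_ps = ensemble$time_ps[picked],
             rasa_pct = rasa_values[picked],
             contacts = contact_values[picked])
}

#' Run the full two-variant comparison
#'
#' Applies the equilibration discard to both ensembles, then computes, per
#' variant: the C-alpha RMSF profile; projections and spreads on the first
#' modes of a PCA built on the pooled, commonly superposed C-alpha
#' coordinates of both variants (one shared basis); the variant residue's
#' rASA distribution; its contact-count distribution, total and split by
#' partner domain; center-of-mass distances from the variant residue to each
#' non-host domain; PB profiles, Neq, deltaNeq with significance flags; and
#' representative frames. Deterministic given inputs and config.
#'
#' @param ensemble_a,ensemble_b `StructureEnsemble`s of the two variants;
#'   residue sets must be identical, residue types may differ only at the
#'   variant position.
#' @param domains a [domain_definition()].
#' @param config a [comparison_config()].
#' @return object of class `VariantReport` (a list; see components above).
#' @export
run_comparison <- function(ensemble_a, ensemble_b,
                           domains = domain_definition(),
                           config = comparison_config()) {
  stopifnot(inherits(ensemble_a, "StructureEnsemble"),
            inherits(ensemble_b, "StructureEnsemble"),
            inherits(domains, "domain_definition"),
            inherits(config, "comparison_config"))
  va <- domains$variant_residue
  check_residue_compatibility(ensemble_a, ensemble_b, va)
  if (config$equilibration_cutoff_ps > 0 &&
      any(ensemble_a$time_ps <= config$equilibration_cutoff_ps))
    ensemble_a <- discard_equilibration(ensemble_a, config$equilibration_cutoff_ps)
  if (config$equilibration_cutoff_ps > 0 &&
      any(ensemble_b$time_ps <= config$equilibration_cutoff_ps))
    ensemble_b <- discard_equilibration(ensemble_b, config$equilibration_cutoff_ps)

  # --- global flexibility: RMSF and pooled-basis PCA on C-alpha
  rmsf_a <- rmsf_profile(ensemble_a)
  rmsf_b <- rmsf_profile(ensemble_b)
  ia <- selection_index(ensemble_a$topology, ca_selection())
  ib <- selection_index(ensemble_b$topology, ca_selection())
  spa <- superpose_frames(ensemble_a, ia, "mean")
  # common reference: both variants fitted to A's mean CA structure
  spb <- superpose_frames(ensemble_b, ib, spa$mean)
  pooled <- rbind(spa$coords, spb$coords)
  model <- covariance_from_coords(pooled, ca_selection(),
                                  extra = list(reference_coords = spa$mean))
  modes <- config$pca_modes
  dev_a <- sweep(spa$coords, 2, model$mean)
  dev_b <- sweep(spb$coords, 2, model$mean)
  proj <- function(dev, e) {
    p <- dev %*% model$eigenvectors[, modes, drop = FALSE]
    colnames(p) <- paste0("mode", modes)
    out <- data.frame(replica_id = e$replica_id, time_ps = e$time_ps, p,
                      check.names = FALSE)
    attr(out, "modes") <- modes
    attr(out, "label") <- e$label
    class(out) <- c("ModeProjection", class(out))
    out
  }
  proj_a <- proj(dev_a, ensemble_a)
  proj_b <- proj(dev_b, ensemble_b)

  # --- local structure: PB profiles, Neq, deltaNeq
  tab <- pb_prototype_table()
  prof_a <- pb_profile(assign_ensemble(backbone_dihedrals(ensemble_a), tab))
  prof_b <- pb_profile(assign_ensemble(backbone_dihedrals(ensemble_b), tab))
  neq_a <- neq_profile(prof_a, label = ensemble_a$label)
  neq_b <- neq_profile(prof_b, label = ensemble_b$label)
  dn <- delta_neq(neq_a, neq_b,
                  delta_threshold = config$delta_neq_threshold,
                  neq_threshold = config$neq_threshold)

  # --- variant residue exposure and contacts
  acc_a <- accessibility_series(ensemble_a, n_points = config$asa_n_points)
  acc_b <- accessibility_series(ensemble_b, n_points = config$asa_n_points)
  vi_a <- match(va, acc_a$residue_numbers)
  rasa_a <- acc_a$rasa_pct[, vi_a]
  rasa_b <- acc_b$rasa_pct[, match(va, acc_b$residue_numbers)]
  dom_a <- contacts_by_partner_domain(ensemble_a, va, domains,
                                      config$contact_cutoff_A,
                                      config$contact_exclusion)
  dom_b <- contacts_by_partner_domain(ensemble_b, va, domains,
                                      config$contact_cutoff_A,
                                      config$contact_exclusion)

  # --- center-of-mass distances to each non-host domain
  com <- list()
  for (nm in setdiff(names(domains$ranges), domains$host_domain)) {
    rr <- domains$ranges[[nm]]
    sel_dom <- atom_selection(residue_numbers = rr[1]:rr[2])
    sel_var <- atom_selection(residue_numbers = va)
    com[[nm]] <- list(
      A = com_distance_series(ensemble_a, sel_var, sel_dom,
                              label_a = ensemble_a$label, label_b = nm),
      B = com_distance_series(ensemble_b, sel_var, sel_dom,
                              label_a = ensemble_b$label, label_b = nm))
  }

  # --- distributions and representatives
  rng_rasa <- range(c(rasa_a, rasa_b))
  rng_cont <- range(c(dom_a$total, dom_b$total))
  hists <- list(
    rasa = list(A = frequency_histogram(rasa_a, config$rasa_bin_pct, rng_rasa),
                B = frequency_histogram(rasa_b, config$rasa_bin_pct, rng_rasa)),
    contacts = list(
      A = frequency_histogram(dom_a$total, config$contact_bin, rng_cont),
      B = frequency_histogram(dom_b$total, config$contact_bin, rng_cont)))
  reps <- list(
    A = select_representatives(ensemble_a, rasa_a, dom_a$total,
                               config$n_representatives, config$rasa_bin_pct),
    B = select_representatives(ensemble_b, rasa_b, dom_b$total,
                               config$n_representatives, config$rasa_bin_pct))

  structure(list(
    labels = c(A = ensemble_a$label, B = ensemble_b$label),
    domains = domains, config = config,
    n_frames = c(A = n_frames(ensemble_a), B = n_frames(ensemble_b)),
    rmsf = list(A = rmsf_a, B = rmsf_b),
    pca = list(model = model, projections = list(A = proj_a, B = proj_b),
               spread = list(A = mode_spread(proj_a), B = mode_spread(proj_b)),
               variance_fraction = vapply(modes, function(k)
                 variance_fraction(model, k), numeric(1))),
    neq = list(A = neq_a, B = neq_b),
    pb_profiles = list(A = prof_a, B = prof_b),
    delta_neq = dn,
    significant_residues =
      dn$residue_number[!is.na(dn$significant) & dn$significant],
    rasa = list(A = rasa_a, B = rasa_b),
    contacts = list(A = dom_a, B = dom_b),
    com_distances = com,
    histograms = hists,
    representatives = reps,
    ensembles = list(A = ensemble_a, B = ensemble_b)),
    class = "VariantReport")
}

check_residue_compatibility <- function(a, b, variant_residue) {
  ra <- unique(a$topology$residue_number)
  rb <- unique(b$topology$residue_number)
  if (!identical(ra, rb)) stop("ensembles cover different residue sets")
  ta <- a$topology$residue_name[match(ra, a$topology$residue_number)]
  tb <- b$topology$residue_name[match(rb, b$topology$residue_number)]
  diff <- which(ta != tb)
  if (length(setdiff(ra[diff], variant_residue)))
    stop("residue types differ away from the variant position: residue(s) ",
         paste(setdiff(ra[diff], variant_residue), collapse = ", "))
  if (!variant_residue %in% ra)
    stop("variant residue ", variant_residue, " absent from the ensembles")
  invisible(TRUE)
}

#' @export
print.VariantReport <- function(x, ...) {
  cat("VariantReport ", x$labels["A"], " vs ", x$labels["B"], ": ",
      x$n_frames["A"], "/", x$n_frames["B"], " frames\n", sep = "")
  cat("  mode-1 spread: ", signif(x$pca$spread$A[1], 4), " vs ",
      signif(x$pca$spread$B[1], 4), " A\n", sep = "")
  cat("  significant deltaNeq residues: ",
      if (length(x$significant_residues))
        paste(x$significant_residues, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Export a comparison report to files
#'
#' Writes TSVs for every profile and distribution, a flat key-value summary
#' (config, labels, significant residues), and one multi-model PDB of
#' representative frames per variant.
#'
#' @param report a `VariantReport`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
export_report <- function(report, out_dir) {
  stopifnot(inherits(report, "VariantReport"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  written <- character(0)
  wr <- function(df, name) {
    path <- p(name, ".tsv")
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
  }
  for (v in c("A", "B")) {
    lab <- report$labels[v]
    wr(report$rmsf[[v]], paste0("rmsf_", lab))
    wr(report$pca$projections[[v]], paste0("pca_projections_", lab))
    wr(report$neq[[v]], paste0("neq_", lab))
    wr(report$contacts[[v]], paste0("contacts_", lab))
    wr(data.frame(replica_id = report$ensembles[[v]]$replica_id,
                  time_ps = report$ensembles[[v]]$time_ps,
                  rasa_pct = report$rasa[[v]]), paste0("rasa_variant_", lab))
    wr(report$representatives[[v]], paste0("representatives_", lab))
    for (nm in names(report$com_distances))
      wr(report$com_distances[[nm]][[v]],
         paste0("com_distance_", gsub("[^A-Za-z0-9-]", "_", nm), "_", lab))
    h <- report$histograms
    wr(data.frame(mid = h$rasa[[v]]$mids, freq = h$rasa[[v]]$freq),
       paste0("hist_rasa_", lab))
    wr(data.frame(mid = h$contacts[[v]]$mids, freq = h$contacts[[v]]$freq),
       paste0("hist_contacts_", lab))
    reps <- report$representatives[[v]]
    if (nrow(reps)) {
      e <- report$ensembles[[v]]
      sub <- structure_ensemble(e$topology,
                                e$xyz[reps$frame, , drop = FALSE],
                                e$time_ps[reps$frame],
                                e$replica_id[reps$frame], label = e$label)
      path <- p("representatives_", lab, ".pdb")
      write_multimodel_pdb(sub, path)
      written <- c(written, path)
    }
  }
  wr(report$delta_neq, "delta_neq")
  ev <- report$pca$model$eigenvalues
  wr(data.frame(mode = seq_along(ev), eigenvalue_A2 = ev), "pca_eigenvalues")
  cfg <- report$config
  summary_lines <- c(
    paste0("label_a\t", report$labels["A"]),
    paste0("label_b\t", report$labels["B"]),
    paste0("n_frames_a\t", report$n_frames["A"]),
    paste0("n_frames_b\t", report$n_frames["B"]),
    paste0("significant_residues\t",
           paste(report$significant_residues, collapse = ",")),
    paste0("mode1_spread_a\t", report$pca$spread$A[1]),
    paste0("mode1_spread_b\t", report$pca$spread$B[1]),
    vapply(names(unclass(cfg)), function(nm)
      paste0("config_", nm, "\t", paste(cfg[[nm]], collapse = ",")),
      character(1)))
  path <- p("summary", ".txt")
  writeLines(summary_lines, path)
  written <- c(written, path)
  invisible(written)
}
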
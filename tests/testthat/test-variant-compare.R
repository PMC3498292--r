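test_that("domain_definition enforces disjoint ranges and a host domain", {
  d <- domain_definition()
  expect_equal(d$host_domain, "PSI")
  expect_equal(d$variant_residue, 33)
  expect_error(domain_definition(list(A = c(1, 10), B = c(10, 20)),
                                 variant_residue = 5), "overlap")
  expect_error(domain_definition(list(A = c(1, 10)), variant_residue = 99),
               "exactly one domain")
  expect_error(domain_definition(list(A = c(10, 1)), variant_residue = 5),
               "first, last")
})

test_that("frequency_histogram bins are left-closed and frequencies sum to 1", {
  h <- frequency_histogram(c(0, 4.999, 5, 10), bin_width = 5)
  expect_equal(sum(h$freq), 1)
  expect_equal(h$breaks, c(0, 5, 10, 15))
  expect_equal(h$freq, c(0.5, 0.25, 0.25))   # 5 falls in [5, 10), 10 in [10, 15)
  hr <- frequency_histogram(c(7), bin_width = 5, range = c(0, 20))
  expect_equal(range(hr$breaks), c(0, 25))   # forced coverage
  expect_error(frequency_histogram(numeric(0), 5), "empty")
})

test_that("select_representatives picks the joint modal class in time order", {
  coords <- lapply(1:8, function(i) matrix(i + rnorm(9, sd = 0.01), 3, 3))
  e <- ca_only_ensemble(coords)              # times 100..800
  rasa <- c(12, 12, 31, 12, 12, 31, 12, 12)  # modal bin [10, 15)
  cont <- c(3, 5, 3, 3, 3, 3, 5, 3)          # modal count 3
  reps <- select_representatives(e, rasa, cont, k = 3L)
  expect_equal(reps$frame, c(1L, 4L, 5L))    # joint modal frames, earliest first
  expect_equal(reps$time_ps, c(100, 400, 500))
  # relaxation: asking for more than the joint class holds widens the contact
  # class before the rASA bin
  reps6 <- select_representatives(e, rasa, cont, k = 6L)
  expect_equal(reps6$frame[1:4], c(1L, 4L, 5L, 8L))
  expect_equal(reps6$frame[5], 2L)           # first relaxed-contact frame
  expect_error(select_representatives(e, rasa[1:3], cont, k = 1),
               "align with frames")
})

test_that("run_comparison rejects incompatible ensembles", {
  mk <- function(types) {
    spec <- generator_spec(12, list(list(pb = strrep("d", 12), weight = 1)),
                           n_frames = 4L, residue_types = types,
                           variant_position = 6L, seed = 2L)
    generate_ensemble(spec)
  }
  dom <- domain_definition(list(D1 = c(1, 6), D2 = c(7, 12)),
                           variant_residue = 6)
  cfg <- comparison_config(equilibration_cutoff_ps = 0)
  a <- mk("ALA")
  b <- mk(c("ALA", "GLY"))                   # differs away from the variant
  expect_error(run_comparison(a, b, dom, cfg), "differ away from the variant")
})

test_that("run_comparison assembles a coherent deterministic report", {
  sc <- synthetic_knee_scenario(seed = 2L, n_frames = 120L)
  cfg <- comparison_config(asa_n_points = 240L, n_representatives = 2L)
  rep1 <- run_comparison(sc$A, sc$B, sc$domains, cfg)
  expect_s3_class(rep1, "VariantReport")
  expect_equal(unname(rep1$labels), c("L-like", "P-like"))
  # equilibration discard: 120 frames at 100 ps, cutoff 5000 -> 70 left
  expect_equal(unname(rep1$n_frames), c(70L, 70L))
  # profiles cover all 60 residues
  expect_equal(nrow(rep1$rmsf$A), 60L)
  expect_equal(nrow(rep1$delta_neq), 60L)
  # significance flags recomputed from the delta table match the summary
  dn <- rep1$delta_neq
  expect_equal(rep1$significant_residues,
               dn$residue_number[!is.na(dn$significant) & dn$significant])
  # histograms are normalised and share their support between variants
  for (nm in c("rasa", "contacts")) {
    expect_equal(sum(rep1$histograms[[nm]]$A$freq), 1)
    expect_equal(rep1$histograms[[nm]]$A$breaks, rep1$histograms[[nm]]$B$breaks)
  }
  # COM distances cover exactly the non-host domains
  expect_setequal(names(rep1$com_distances), c("I-EGF-1", "I-EGF-2"))
  expect_equal(nrow(rep1$com_distances[["I-EGF-1"]]$A), 70L)
  # representatives fall inside the analysed frames
  expect_lte(nrow(rep1$representatives$A), 2L)
  expect_true(all(rep1$representatives$B$frame <= 70L))
  # determinism
  rep2 <- run_comparison(sc$A, sc$B, sc$domains, cfg)
  expect_identical(rep1$delta_neq, rep2$delta_neq)
  expect_identical(rep1$pca$spread, rep2$pca$spread)
  expect_output(print(rep1), "VariantReport L-like vs P-like")
})

test_that("the comparison shows the expected direction of contrast", {
  sc <- synthetic_knee_scenario(seed = 1L, n_frames = 300L)
  cfg <- comparison_config(asa_n_points = 240L)
  rep1 <- run_comparison(sc$A, sc$B, sc$domains, cfg)
  w <- sc$window
  # perturbed variant is more flexible: Neq, RMSF and mode-1 spread
  expect_gt(mean(rep1$neq$B$neq[w]), mean(rep1$neq$A$neq[w]))
  ra <- rep1$rmsf$A$rmsf_A[rep1$rmsf$A$residue_number %in% w]
  rb <- rep1$rmsf$B$rmsf_A[rep1$rmsf$B$residue_number %in% w]
  expect_gt(mean(rb), mean(ra))
  expect_gt(rep1$pca$spread$B[1], rep1$pca$spread$A[1])
  # significance flags are window-local
  expect_gt(length(rep1$significant_residues), 0L)
  expect_true(all(rep1$significant_residues >= min(w) - 2 &
                    rep1$significant_residues <= max(w) + 2))
})

test_that("export_report writes readable tables and representative PDBs", {
  sc <- synthetic_knee_scenario(seed = 4L, n_frames = 80L)
  cfg <- comparison_config(asa_n_points = 240L, n_representatives = 2L)
  rep1 <- run_comparison(sc$A, sc$B, sc$domains, cfg)
  out <- tempfile("report")
  paths <- export_report(rep1, out)
  expect_true(all(file.exists(paths)))
  dn <- read.table(file.path(out, "delta_neq.tsv"), header = TRUE, sep = "\t")
  expect_equal(dn$residue_number, rep1$delta_neq$residue_number)
  ev <- read.table(file.path(out, "pca_eigenvalues.tsv"), header = TRUE,
                   sep = "\t")
  expect_equal(ev$eigenvalue_A2, rep1$pca$model$eigenvalues, tolerance = 1e-6)
  reps_pdb <- file.path(out, "representatives_L-like.pdb")
  expect_true(file.exists(reps_pdb))
  back <- read_multimodel_pdb(reps_pdb)
  expect_equal(n_frames(back), nrow(rep1$representatives$A))
  summary_path <- file.path(out, "summary.txt")
  expect_true(any(grepl("significant_residues",
                        readLines(summary_path))))
  unlink(out, recursive = TRUE)
})
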
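test_that("dihedral_angle follows the IUPAC sign convention", {
  # canonical -90 degree case
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               -90)
  # cis = 0, trans = 180
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
})

test_that("dihedrals are invariant under rigid motion and match bio3d", {
  set.seed(11)
  for (k in 1:50) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    a <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                  error = function(e) NA_real_)
    if (is.na(a)) next
    # rigid motion invariance
    R <- random_rotation()
    t0 <- rnorm(3)
    q <- p %*% R + matrix(t0, 4, 3, byrow = TRUE)
    b <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    d <- abs(a - b) %% 360
    expect_lt(min(d, 360 - d), 1e-8)
    # dual route: bio3d::torsion.xyz uses the opposite sign convention
    bb <- bio3d::torsion.xyz(as.vector(t(p)))
    d2 <- abs(a + bb) %% 360
    expect_lt(min(d2, 360 - d2), 1e-8)
  }
})

test_that("degenerate torsion geometry is rejected", {
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincident")
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("backbone_dihedrals recovers the generating angles", {
  set.seed(5)
  n <- 8
  phi <- c(NA, runif(n - 1, -180, 180))
  psi <- c(runif(n - 1, -180, 180), NA)
  e <- ensemble_from_dihedrals(list(phi), list(psi))
  ds <- backbone_dihedrals(e)
  expect_true(is.na(ds$phi[1, 1]) && is.na(ds$psi[1, n]))
  expect_equal(ds$phi[1, -1], phi[-1], tolerance = 1e-8)
  expect_equal(ds$psi[1, -n], psi[-n], tolerance = 1e-8)
})

test_that("Kabsch superposition: exact zero on rigid motions, proper rotation", {
  set.seed(21)
  A <- matrix(rnorm(30), 10, 3)
  R <- random_rotation()
  B <- A %*% R + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd_A, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # returned transform reproduces the fitted coordinates
  expect_equal(A %*% fit$rotation +
                 matrix(fit$translation, 10, 3, byrow = TRUE),
               fit$coords, tolerance = 1e-10)
  # mirrored target must not induce a reflection
  fitm <- kabsch_superpose(A, cbind(A[, 1], A[, 2], -A[, 3]))
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch RMSD agrees with the quaternion oracle", {
  set.seed(22)
  for (k in 1:25) {
    A <- matrix(rnorm(3 * 12), 12, 3)
    B <- matrix(rnorm(3 * 12), 12, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd_A, quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
})

test_that("rmsd_series is zero at the reference frame", {
  set.seed(30)
  coords <- lapply(1:5, function(i) matrix(rnorm(15, sd = 2), 5, 3))
  e <- ca_only_ensemble(coords)
  rs <- rmsd_series(e, reference = 1L)
  expect_equal(rs$rmsd_A[1], 0, tolerance = 1e-10)
  expect_true(all(rs$rmsd_A >= 0))
  expect_named(rs, c("replica_id", "time_ps", "rmsd_A"))
})

test_that("rmsf_profile is zero for identical frames and grows with noise", {
  base <- matrix(rnorm(15, sd = 3), 5, 3)
  still <- ca_only_ensemble(list(base, base, base))
  expect_equal(rmsf_profile(still)$rmsf_A, rep(0, 5), tolerance = 1e-9)
  set.seed(8)
  lo <- ca_only_ensemble(lapply(1:40, function(i) base + rnorm(15, sd = 0.05)))
  hi <- ca_only_ensemble(lapply(1:40, function(i) base + rnorm(15, sd = 0.8)))
  expect_true(mean(rmsf_profile(hi)$rmsf_A) > mean(rmsf_profile(lo)$rmsf_A))
})

test_that("center_of_mass weights by element mass", {
  topo <- data.frame(serial = 1:2, atom_name = c("C", "O"),
                     residue_name = "ALA", residue_number = 1L,
                     chain_id = "A", element = c("C", "O"),
                     stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(1, 0, 0))
  com <- center_of_mass(coords, topo)
  expect_equal(com[1], 15.999 / (12.011 + 15.999), tolerance = 1e-7)
  expect_equal(com[2:3], c(0, 0))
})

test_that("com_distance_series matches direct point distances", {
  set.seed(14)
  coords <- lapply(1:4, function(i) matrix(rnorm(9, sd = 4), 3, 3))
  e <- ca_only_ensemble(coords)
  ds <- com_distance_series(e, atom_selection(residue_numbers = 1L),
                            atom_selection(residue_numbers = 3L))
  direct <- vapply(1:4, function(i)
    sqrt(sum((coords[[i]][1, ] - coords[[i]][3, ])^2)), numeric(1))
  # frames were built with increasing times, so order is preserved
  expect_equal(ds$distance_A, direct, tolerance = 1e-10)
  expect_s3_class(ds, "DistanceSeries")
})

test_that("contact counts on a collinear chain and inclusive boundary", {
  # CA atoms on a line, 3.8 apart: contacts at separation 1 and 2 only
  line <- cbind(3.8 * (0:9), 0, 0)
  e <- ca_only_ensemble(list(line))
  cc <- contact_counts(e, cutoff_A = 8.0)
  expect_equal(cc$counts[1, 3:8], rep(4L, 6))  # interior residues
  expect_equal(cc$counts[1, 1], 2L)            # chain end
  # boundary is inclusive: exactly 8.0 counts, 8.0 + epsilon does not
  pair_on <- ca_only_ensemble(list(rbind(c(0, 0, 0), c(8, 0, 0))))
  pair_off <- ca_only_ensemble(list(rbind(c(0, 0, 0), c(8 + 1e-6, 0, 0))))
  expect_equal(contact_counts(pair_on)$counts[1, ], c(1L, 1L))
  expect_equal(contact_counts(pair_off)$counts[1, ], c(0L, 0L))
  # sequence-neighbour exclusion
  cc1 <- contact_counts(e, cutoff_A = 8.0, exclusion = 1L)
  expect_equal(cc1$counts[1, 5], 2L)           # only |i - j| = 2 remain
})

test_that("contact counts agree with an independent pairwise computation", {
  set.seed(9)
  coords <- matrix(rnorm(3 * 15, sd = 5), 15, 3)
  e <- ca_only_ensemble(list(coords))
  cc <- contact_counts(e, cutoff_A = 8.0)
  dm <- as.matrix(dist(coords))
  ref <- vapply(1:15, function(i) sum(dm[i, -i] <= 8.0), integer(1))
  expect_equal(cc$counts[1, ], ref)
})

test_that("contacts_by_partner_domain partitions the total", {
  line <- cbind(3.8 * (0:11), 0, 0)
  e <- ca_only_ensemble(list(line, line))
  dom <- domain_definition(list(D1 = c(1, 4), D2 = c(5, 8), D3 = c(9, 12)),
                           variant_residue = 5)
  tab <- contacts_by_partner_domain(e, residue = 5, domains = dom,
                                    cutoff_A = 8.0)
  expect_named(tab, c("replica_id", "time_ps", "D1", "D2", "D3", "total"))
  expect_equal(tab$D1 + tab$D2 + tab$D3, tab$total)  # domains cover everything
  expect_equal(tab$total, rep(4L, 2))
  expect_error(contacts_by_partner_domain(e, residue = 99, domains = dom),
               "not in ensemble")
})

test_that("write_series_tsv round-trips analysis tables", {
  e <- ca_only_ensemble(lapply(1:3, function(i) matrix(rnorm(9), 3, 3)))
  cc <- contact_counts(e)
  path <- tempfile(fileext = ".tsv")
  write_series_tsv(cc, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back, as.data.frame(cc), ignore_attr = TRUE)
  unlink(path)
})
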
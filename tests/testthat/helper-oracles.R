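# Shared test utilities: an independent quaternion superposition oracle,
# random rigid motions, and small ensemble builders.

# Horn (1987) quaternion method: optimal-superposition RMSD from the largest
# eigenvalue of the 4x4 key matrix. Entirely independent of the package's
# SVD-based Kabsch implementation.
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- t(A) %*% B
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)))
}

# Uniform-ish random rotation matrix from a normalized quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Ensemble whose residues each carry a single CA atom, from a list of
# n_res x 3 coordinate matrices (one per frame).
ca_only_ensemble <- function(coord_list, element = "C", label = "toy") {
  n <- nrow(coord_list[[1]])
  topo <- data.frame(serial = seq_len(n), atom_name = "CA",
                     residue_name = "ALA", residue_number = seq_len(n),
                     chain_id = "A", element = element,
                     stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(coord_list, function(m) as.vector(t(m))))
  structure_ensemble(topo, xyz, seq_along(coord_list) * 100,
                     rep("r1", length(coord_list)), label = label)
}

# Multi-frame ensemble built from per-frame phi/psi vectors (lists of equal
# length) through the exported single-frame chain builder.
ensemble_from_dihedrals <- function(phi_list, psi_list,
                                    residue_types = "ALA", label = "built") {
  frames <- mapply(function(phi, psi)
    build_coordinates(phi, psi, residue_types), phi_list, psi_list,
    SIMPLIFY = FALSE)
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$coords))))
  structure_ensemble(frames[[1]]$topology, xyz,
                     seq_along(frames) * 100, rep("r1", length(frames)),
                     label = label)
}

# A 16-frame ensemble whose residue-3 assignment window visits each of the
# 16 PB prototypes exactly once (each frame embeds one prototype's 8 angles
# as psi1, phi2, psi2, phi3, psi3, phi4, psi4, phi5 of a 7-residue chain).
uniform_pb_ensemble <- function(order = 1:16, table = pb_prototype_table()) {
  phi_list <- list(); psi_list <- list()
  for (k in order) {
    p <- table[k, ]
    phi_list[[length(phi_list) + 1L]] <- c(NA, p[2], p[4], p[6], p[8], -120, -120)
    psi_list[[length(psi_list) + 1L]] <- c(p[1], p[3], p[5], p[7], 120, 120, NA)
  }
  ensemble_from_dihedrals(phi_list, psi_list)
}
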
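---
title: "Methods: Protein-Block flexibility comparison of conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Protein-Block flexibility comparison of conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbflex)
```

# Scope and model

`pbflex` compares the backbone flexibility of two variants of one protein
chain from conformational ensembles — ordered sets of coordinate frames over
a shared atom topology, read from multi-model PDB files or produced by the
packaged synthetic generator. The statistical model throughout is simple and
explicit: frames are treated as exchangeable samples of a per-residue
local-conformation distribution (after an equilibration discard), and all
flexibility statistics are functionals of that distribution. No energetics,
kinetics, or solvent model is implied.

Analyses address a single chain; multi-chain systems must be split upstream.
Hydrogens are not required and, when absent, simply do not contribute to
masses or surfaces (heavy-atom convention).

# Local structure: Protein Blocks and Neq

Each residue `i` of each frame is encoded by the 8-dihedral window
`psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1), phi(i+2)`
and assigned the Protein Block (PB) letter `a`–`p` whose prototype minimises
the angular RMSD

\[ \mathrm{RMSDA}(w, p) = \sqrt{\tfrac{1}{8}\sum_k \mathrm{wrap}(w_k - p_k)^2}, \]

with differences wrapped to the shortest arc in (−180°, 180°]. Ties break
alphabetically so assignment is deterministic. The first and last two
residues have incomplete windows and are labelled `Z`; they are excluded
from all frequency statistics. The 16×8 prototype table ships as a versioned
TSV with a load-time checksum.

Per residue, the PB frequency vector `f` over the analysed frames yields

\[ N_{eq} = \exp\left(-\sum_x f_x \ln f_x\right), \qquad 0 \ln 0 := 0, \]

the equivalent number of PBs: 1 for a residue locked in one letter, 16 for a
uniform distribution (both anchors are verified analytically and through the
full coordinate pipeline in the test suite). Two variants are compared by
`delta_neq()`: residue flagged **significant** when `|ΔNeq| > 1.5` *and*
`min(Neq_A, Neq_B) < 2.5`, both inequalities strict. The rationale: the
difference must be large *and* at least one variant must be genuinely rigid
there, so a shift between two already-disordered states is not flagged.

# Global flexibility

Superposition uses the Kabsch algorithm (SVD of the weighted cross-covariance
with determinant-sign correction, so reflections are never returned); the
suite checks it against an independent quaternion (Horn) oracle at 1e−9.
RMSF superposes frames onto the ensemble mean via two fit→mean iterations.
Essential dynamics diagonalises the covariance of superposed C-alpha
coordinates (`stats::cov`, n−1 normalisation); eigenvector signs are fixed by
making each mode's largest-magnitude component positive. In the two-variant
comparison both ensembles are superposed onto variant A's mean structure and
projected onto the eigenvectors of the *pooled* covariance — one shared
basis, so per-mode projection spreads are directly comparable. The choice of
a pooled basis (rather than A's own modes) makes the comparison symmetric in
the two variants; `analysis/02_flexibility.R` shows the asymmetric
alternative (A's basis) which leads to the same qualitative ordering.

# Exposure, contacts, distances, representatives

Solvent accessibility uses the Shrake–Rupley method with a deterministic
golden-spiral quadrature (default 960 points/atom), probe 1.4 Å, and a
united-heavy-atom element-class radii set (C 1.87, N 1.65, O 1.40, S 1.85 Å),
shipped as a versioned TSV. Relative ASA divides a residue's ASA by its
type's ASA in a fully extended Ala-X-Ala tripeptide (packaged table; Leu
183 Å², Pro 142 Å²), in percent — values above 100% are possible and
meaningful. The kernel is validated against the analytic sphere and
two-sphere (spherical-cap) closed forms within 1.5%.

Contacts: two residues are in contact when their C-alpha distance is ≤ the
cutoff (default 8 Å, **inclusive** at the boundary — documented because the
boundary convention changes counts on lattice-like test systems). The default
sequence-neighbour exclusion is 0 (direct neighbours count); contact counts
of the variant residue are split by the partner residue's domain.
Center-of-mass distances are mass-weighted over heavy atoms.

Representative frames are chosen from the joint mode of the variant
residue's rASA histogram (left-closed bins, default width 5%) and its modal
contact count. If fewer than `k` frames fall in the joint modal class, the
contact class is relaxed to nearest-neighbour values first, then the rASA
bin — contacts are discrete and narrow, so relaxing them first stays closest
to "the most frequent structure". Joint (rather than marginal) modality is a
documented choice: it guarantees the selected frames actually exhibit both
modal properties simultaneously.

# Frame bookkeeping

Equilibration discard keeps frames with `time_ps > cutoff` (strict), applied
per replica; the conventional cutoff is 5000 ps. With 100 ps snapshots whose
times start at 100 ps, a replica ending at 30 ns keeps exactly
`(30000 − 5000)/100 = 250` frames, the frame at exactly 5000 ps being
dropped. Off-by-one ambiguities in published snapshot counts usually trace
to an inclusive convention at this boundary; this package standardises on
the strict one and states it. Multi-model PDB output
interleaves one `REMARK 250 TIME_PS ... REPLICA ...` line per model so frame
times survive a round trip; on input, times fall back to
`(model − 1) × step` when no remarks are present.

# The synthetic generator

The generator exists so the pipeline can be validated against known ground
truth. Per frame one full-length PB "recipe" string is drawn from a weighted
mixture; residue `i` receives the central `(phi, psi)` pair of its letter's
prototype plus wrapped-normal noise (SD `sigma_deg`, scalar or per residue);
an N/CA/C/O/CB backbone is then built with ideal bond geometry, trans
peptide bonds, and sequential internal-coordinate (NeRF) placement.
Re-measuring the built chain reproduces the input dihedrals to ~1e−13
degrees, and generation is byte-deterministic given `(spec, seed)` without
touching the caller's RNG state.

**Scope and limits.** A residue's angles come from its *own* letter's
central positions, so the overlapping 8-angle windows are mutually
consistent only inside homogeneous runs of one letter. Empirically, the
letters whose homogeneous runs are exact fixed points of assignment are `d`
and `m`; other letters map into stable basins (e.g. homogeneous `i` windows
read as `n`, `j` as `e`), and the shallow basins inflate Neq under noise.
Recovery and mixture tests therefore assay `d`/`m` (and use `i` only where
its basin letter `n` is merely required to be *distinct*). There are no
sterics: chains may self-intersect, which is acceptable for statistics of
dihedral-derived quantities and for exercising the exposure/contact code,
but the generator is not a molecular-dynamics replacement.

The packaged scenario (`synthetic_knee_scenario()`) builds a 60-residue
chain with three 20-residue "domains" and a variant site at residue 10.
Variant A samples a single extended recipe with 5° noise; variant B
additionally receives 15° extra noise in residues 6–14 and mixes in two
alternative local structures (helical `m` and coil-like `i` windows, total
weight 0.5). The three-way mixture is deliberate: a two-way 50/50 mixture
gives window Neq ≈ 2 against A's 1, a difference of ~1 that the
significance rule (ΔNeq > 1.5) correctly does *not* flag; with three
well-separated letters the window Neq reaches ≈ 3 and the flags fire inside
the window and nowhere ≥ 5 residues away.

# Parameter defaults

| Parameter | Default | Rationale |
|---|---|---|
| equilibration cutoff | 5000 ps | conventional discard of initial relaxation |
| snapshot spacing | 100 ps | typical analysis stride; sets default PDB frame times |
| contact cutoff | 8 Å, inclusive | standard C-alpha proximity criterion |
| neighbour exclusion | 0 | all partners count, including `i±1` |
| ASA probe / points | 1.4 Å / 960 | water probe; quadrature error well below the 1.5% validation bound |
| rASA bin | 5% | resolves the exposure distribution without empty-bin noise |
| ΔNeq significance | >1.5 with min Neq <2.5 | large difference anchored at a rigid state |
| representatives | 3 frames | joint modal class, time-ordered |
| PCA modes reported | 1–2 | dominant collective motions |

All of these are arguments of `comparison_config()` or the respective
functions and can be overridden; the defaults are the study conditions used
by the `analysis/` scripts.
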
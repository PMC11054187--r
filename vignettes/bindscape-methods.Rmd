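---
title: "bindscape: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bindscape: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bindscape` analyzes conformational ensembles of inhibitor-bound
receptors along four axes: contact-map classification with gradient
attribution, principal-component free-energy landscapes, standard
structural observables, and MM-GBSA-style binding free-energy
bookkeeping. This vignette is the package's own account of the models
behind each stage, the parameters that matter, and the choices made
where the design was genuinely open.

## Ensembles and units

Everything operates on a `conformational_ensemble`: a topology (atoms,
1-based residue indices, optional per-atom charge/LJ/Born/mass
parameters) plus an F × 3A coordinate matrix in Angstrom. Multi-model
PDB is the canonical on-disk format (read/written via bio3d, with a
pre-scan so a model with a missing atom fails naming that model); a
plain `frame atom x y z` table is accepted as a zero-dependency dialect
for synthetic data. Independent runs with identical topologies are
concatenated by `join_ensembles()` into one merged trajectory — the
convention under which all statistics here are computed. Residue
numbering is 1-based everywhere a user sees it; chain identifiers are
read but ignored (single-chain systems).

## The synthetic generator: what it emulates, and what it does not

Real inputs to this kind of analysis are MD ensembles of a ~100-residue
bromodomain bound to different inhibitors. The generator stands in for
those with K classes of Cα bead chains:

* a self-avoiding random walk with 3.8 Å virtual bonds (the canonical
  Cα–Cα spacing) and a 6.0 Å excluded-volume margin during growth;
* per class, a planted set of residue pairs pulled to the 3.8 Å contact
  distance by iterative pull-and-relax sweeps (soft pair moves plus
  bond-length projection), while every other non-neighbour pair is held
  above 5.5 Å;
* frames sampled as i.i.d. isotropic Gaussian displacements
  (default σ = 0.3 Å per coordinate) about each class reference.

Construction is verified, not assumed: generation fails after a bounded
number of attempts if the requested planted geometry is infeasible, and
a reference is accepted only if planted pairs sit ≤ 3.82 Å, all other
non-neighbour pairs > 5.5 Å, and bonds within 0.05 Å of 3.8. Under the
4.5 Å contact cutoff, class contact maps therefore differ in exactly
the planted pixels — ground truth for the classifier and the saliency
stage. Default scale mirrors the target application: 40-residue test
chains (and up to ~104 residues, the bromodomain size, in the shape
checks), K = 3 classes, 300 frames per class.

What the generator does *not* emulate: kinetics and autocorrelation
(frames are exchangeable), side chains, solvent, anharmonic collective
motions, and any correlation between contacts. Passing tests on these
ensembles validates the *machinery* — featurization, training,
attribution, statistics — not the claim that a particular real system
is classifiable.

The toy ligand complex (`generate_ligand_system`) places a compact
charged bead receptor and a small bead ligand docked at its surface,
with parameters scaled so |ΔE_ele| and |ΔE_vdW| land in the
1–100 kcal/mol range typical of inhibitor binding; an optional planted
salt bridge creates a known hot-spot residue for the decomposition
tests.

## Contact maps and the classifier

A contact is Cα–Cα distance ≤ 4.5 Å, boundary inclusive. The cutoff is
deliberately tight — consecutive Cα sit at 3.8 Å, so the map is the
chain diagonal plus genuinely close tertiary pairs; a `closest-heavy`
rule (minimum heavy-atom distance) is available where side-chain-level
contacts are wanted. Maps are encoded as binary grayscale images
(contact = 1.0); thresholding at 0.5 inverts the encoding exactly.

The classifier is the fixed small architecture: two 1×1 convolutions
(16 then 32 filters), each followed by 2×2 max-pooling and ReLU; then
fully connected 512 and 128 with dropout 0.5; then a K-way softmax.
Flatten sizes follow ⌊⌊N/2⌋/2⌋²·32 (21632 at N = 104, 20000 at
N = 102). Because no deep-learning runtime is part of this package's
dependency set, forward, backward and the Adam optimizer are
implemented directly on (image, pixel)-major matrices; max-pool argmax
routes are recorded for backprop, and gradients are tested against
central finite differences at 1e-3 relative tolerance.

Training conventions, all configurable and all logged: Adam at
lr 1e-3, batch 64, cross-entropy, 30 epochs, stratified 80/20
train/validation split. Splits, weight initialization (He, zero biases)
and shuffling are seeded; training is deterministic given the seed and
a fixed thread count (BLAS reductions may differ across builds, so
"bit-exact across platforms" is not claimed).

One property of this architecture worth knowing: with 1×1 kernels the
only spatial mixing is the two max-pools, so the classifier cannot
distinguish two contacts that fall inside the same 4×4 pixel block of
the input. Planted contacts in the default synthetic layouts are placed
in distinct pooled blocks; for real maps this is a resolution limit of
the printed architecture, not of the implementation.

## Saliency and domain attribution

Attribution is vanilla gradient: |∂(pre-softmax score of the target
class)/∂pixel|, symmetrized as (M + Mᵀ)/2 because contact matrices are
symmetric. The raw map is masked by the contact map of a representative
structure — the medoid of the largest cluster from average-linkage
hierarchical clustering on pairwise best-fit Cα RMSD, tree cut at
2.0 Å. Ensembles larger than `max_frames` (default 200) are evenly
strided before the O(F²) RMSD matrix is built. Ties in cluster size and
in the medoid criterion resolve to the lower frame index. The masked
map is summed over structural-domain blocks (upper triangle, diagonal
blocks included; residues outside the annotation report under
"unassigned"), giving a ranked domain-pair table whose total equals the
masked upper-triangle attribution when the domains tile the sequence.
Domain boundaries are a required user input: the analysis names
helices/loops (αZ, ZA-loop, αA, αB, BC-loop, αC) but their residue
ranges vary by construct.

## Structural observables

* **Superposition**: Kabsch via SVD with the determinant correction, so
  the rotation is always proper; requires ≥ 3 non-collinear atoms.
* **RMSD**: per-frame best fit over the selection (default backbone)
  against a reference structure, with frequency-distribution summaries
  (50 bins; peaks are local maxima of 3-bin moving-average-smoothed
  counts, plateau ties resolved toward the lower value).
* **RMSF**: frames superposed onto their iterative mean (two rounds),
  then per-atom √⟨|r − ⟨r⟩|²⟩. For isotropic Gaussian noise the mean
  RMSF converges to σ√3·√(1 − 1/F), the closed form the tests check to
  5%.
* **Radius of gyration**: mass-weighted, masses from the parameter
  table (unit masses allowed).
* **SASA**: Shrake–Rupley with deterministic golden-spiral sphere
  points (960/atom default), probe 1.4 Å, radii taken as the van der
  Waals radius implied by the LJ σ (σ·2^{1/6}/2) unless given
  explicitly. Reported as solvent-accessible area; a solvent-excluded
  "molecular surface" is out of scope, and the energetics module uses
  the same routine for ΔSASA with 240 points, where the complex-minus-
  parts difference converges much faster than absolute areas.
* **Hydrogen bonds**: present in a frame iff donor–acceptor < 3.5 Å
  *and* the D–H···A angle at the hydrogen > 120°, both strict;
  occupancy is exactly 100·(present frames)/F, and mean distance/angle
  are over present frames only.

## PCA and free-energy landscapes

The covariance of selected (default Cα) coordinates is taken after
two-round iterative-mean superposition, with population normalization
(divide by F) matching the ensemble-average definition — the SVD oracle
in the tests uses the same convention (λ_k = s_k²/F). Eigenvalues are
clipped at zero; eigenvectors are orthonormal to 1e-8.

Landscapes bin the first two projections (default 100 × 100) and invert
Boltzmann at T = 300 K (the usual simulation temperature;
k_B = 0.0019872 kcal/mol/K): G = −k_B T ln(P/P_max), minimum exactly 0,
unpopulated bins carrying the sentinel max(G) + 1. Basin detection
processes populated bins in increasing G with 8-neighbour connectivity
and union-find persistence merging: a connecting bin merges a shallower
basin whose depth below the barrier is under `depth_threshold`
(default 0.5 kcal/mol). Basins must additionally sit at least the
threshold below the single-count noise level k_B T·ln(max count) — a
bin visited once is statistically indistinguishable from noise, and
without this floor every stray rim bin of a Gaussian cloud would count
as a basin. Ties resolve by bin index; raising the threshold can only
reduce the basin count. Each basin can report the frame nearest its
minimum in PC space as its representative structure.

## MM-GBSA bookkeeping

The single-trajectory convention extracts receptor and ligand
coordinates from the complex frame, so ΔX = X(complex) − X(receptor) −
X(ligand) and the gas-phase Coulomb and LJ deltas reduce *exactly* to
receptor–ligand cross terms — an identity the tests check to 1e-9.
Terms:

* Coulomb: k_e q_i q_j / (ε_in r), k_e = 332.0636 kcal·Å/mol·e², no
  cutoff (desk-scale systems; a simulation-engine cutoff is a sampling
  device, not part of end-state rescoring).
* Lennard-Jones 12-6 with Lorentz–Berthelot combination.
* Polar solvation: pairwise Still-form generalized Born,
  f_GB = √(r² + α_iα_j e^{−r²/4α_iα_j}), self terms included, with
  user-supplied effective Born radii; ε_in = 1, ε_solv = 78.5 defaults,
  no salt screening. Supplied fixed radii keep the model pairwise
  decomposable (needed for per-residue shares) and make it reduce
  exactly to the Born ion formula for one charge and to zero when the
  dielectrics match. Self-consistent radius schemes are a possible
  extension, not implemented.
* Nonpolar: ΔG_surf = γ·ΔSASA + β with γ = 0.0072 kcal/mol/Å², β = 0.
* Entropy: the −TΔS term is pluggable — "supplied" (external value,
  used when reproducing tabulated arithmetic) or a Schlitter
  quasi-harmonic upper bound from the mass-weighted coordinate
  covariance (population normalization, eigenvalue floor 1e-12).
  Normal-mode entropy is out of scope.

Aggregation follows ΔG_bind = ⟨ΔE_ele⟩ + ⟨ΔE_vdW⟩ + ⟨ΔG_gb⟩ +
⟨ΔG_surf⟩ + (−TΔS), with ΔG_pol = ⟨ΔE_ele⟩ + ⟨ΔG_gb⟩ and ΔG_hydro the
complement; the per-frame identity ΔH = ΔG_pol + ΔG_hydro holds to
1e-9. Per-residue decomposition assigns each receptor residue its
Coulomb+LJ cross terms in full, half of each GB cross pair (the other
half belongs to the ligand), and γ times its atoms' share of the SASA
difference; "key residues" are those at or below −0.8 kcal/mol
("stronger than 0.8"). Default snapshot counts: 400 evenly strided
frames for component averages, 50 for the per-frame-costly
decomposition.

The package ships a literature-reported component table for three
inhibitors (H1B, JQ1, TVU) bound to BRD4 and BRD9
(`reference_energy_components()`), used to exercise the aggregation and
cross-system arithmetic at real scale. Two conventions there deserve
note: the table's own polar-sum entry for H1B–BRD9 is inconsistent with
its printed components (the defining identity is implemented, and the
discrepancy is flagged in the loader's documentation), and ΔG_exp from
IC50 is returned with the conventional sign, ΔG = RT ln(IC50/1 M),
negative for sub-molar IC50.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → featurize → train → attribute →
metrics → pca → gbsa → report from one validated config (YAML/JSON or
list). Every stage parameter has a logged default; all outputs are
plain-text tables; the manifest records the effective config, stage
file lists and md5 checksums. `resume = TRUE` skips stages whose
outputs exist, and the heavy state (generation, featurization,
training) is only built when an unfinished stage needs it.

Test problem sizes are chosen so the whole suite exercises every claim
at desk scale: 12–16 residue systems for unit-level CNN checks, the
40-residue/3-class/300-frame layout for the end-to-end classification
and attribution checks, 100–200-frame Gaussian ensembles for the
closed-form statistics. The same sizes are used by
`scripts/acceptance.R`.

## Known limitations

* The GB model uses supplied fixed Born radii; conformation-dependent
  radius recalculation (and with it the non-cross GB contribution to
  binding) is not modeled.
* Quasi-harmonic entropy is an upper bound and, like all covariance
  entropies, misses anharmonicity and conformational multi-modality.
* The classifier's spatial resolution is the 4×4 pooled block (see
  above); distance-graded (non-binary) images are not implemented.
* Synthetic ensembles are exchangeable Gaussian clouds: no kinetics, no
  correlated motions beyond the planted structure, no side chains.
* Binary trajectory formats (DCD/XTC) and PDB insertion codes are not
  read.
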
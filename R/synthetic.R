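#' Specification of a synthetic multi-class conformational ensemble
#'
#' The generator emulates the situation the classification stage faces on
#' real trajectories: K inhibitor-bound systems whose conformational
#' ensembles differ by a small set of inter-domain residue contacts.
#' Each class is defined by its planted contact pairs; frames are drawn
#' as isotropic Gaussian displacements about a class reference structure.
#'
#' @param n_residues chain length (Calpha beads).
#' @param classes list (length K >= 2) of planted contact pairs per
#'   class; each element a 2-column matrix or a length-2 vector of
#'   1-based residue indices with |i - j| >= 3.
#' @param domains a `domain_annotation` laying out structural domains
#'   over the chain (used by saliency aggregation downstream).
#' @param sigma per-coordinate Gaussian noise, Angstrom (> 0).
#' @param frames_per_class frames sampled per class.
#' @param seed integer seed making the whole generation deterministic.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues, classes, domains = NULL,
                           sigma = 0.3, frames_per_class = 300, seed = 1) {
  if (length(classes) < 2) stopf("at least K = 2 classes are required")
  if (sigma <= 0) stopf("sigma must be > 0")
  classes <- lapply(classes, function(p) {
    p <- matrix(as.integer(p), ncol = 2)
    if (any(p < 1) || any(p > n_residues)) {
      stopf("planted pair outside 1..%d", n_residues)
    }
    if (any(abs(p[, 1] - p[, 2]) < 3)) {
      stopf("planted pairs must be at least 3 residues apart in sequence")
    }
    # canonical order i < j
    t(apply(p, 1, sort))
  })
  key <- vapply(classes, function(p) {
    paste(sort(paste(p[, 1], p[, 2])), collapse = ";")
  }, character(1))
  if (anyDuplicated(key)) {
    stopf("two classes share an identical planted contact set; classes are indistinguishable")
  }
  structure(list(n_residues = as.integer(n_residues), classes = classes,
                 domains = domains, sigma = sigma,
                 frames_per_class = as.integer(frames_per_class),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Self-avoiding random walk with fixed virtual bond length and an
# excluded-volume margin wide enough that the later relaxation cannot
# create accidental contacts.
grow_chain <- function(n, bond = 3.8, grow_sep = 6.0) {
  for (restart in 1:200) {
    coords <- matrix(0, n, 3)
    coords[2, ] <- coords[1, ] + bond * rand_unit()
    ok <- TRUE
    for (i in seq(3, n)) {
      placed <- FALSE
      for (try in 1:80) {
        cand <- coords[i - 1, ] + bond * rand_unit()
        prev <- coords[seq_len(i - 2), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (min(d2) > grow_sep^2) {
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(coords)
  }
  stopf("failed to grow a self-avoiding chain of length %d", n)
}

# Iterative pull-and-relax: harmonic-style pair moves for planted
# contacts, excluded-volume pushes for everything else, and bond-length
# projection after every sweep. Targets leave slack inside the hard
# bounds (planted <= 4.0, others > 5.5) so verification is strict.
relax_chain <- function(coords, planted, bond = 3.8, contact_target = 3.8,
                        min_sep = 5.5, max_sweeps = 4000) {
  n <- nrow(coords)
  planted_key <- if (nrow(planted) > 0) {
    paste(planted[, 1], planted[, 2])
  } else character(0)
  for (sweep in seq_len(max_sweeps)) {
    # pull planted pairs together (soft step toward the target distance)
    for (r in seq_len(nrow(planted))) {
      i <- planted[r, 1]; j <- planted[r, 2]
      v <- coords[j, ] - coords[i, ]
      d <- sqrt(sum(v^2))
      if (d > contact_target + 0.005) {
        shift <- 0.25 * (d - contact_target) / d * v
        coords[i, ] <- coords[i, ] + shift / 2
        coords[j, ] <- coords[j, ] - shift / 2
      }
    }
    # push apart non-planted non-neighbour pairs that crowd the cutoff
    D <- as.matrix(stats::dist(coords))
    idx <- which(upper.tri(D) & D < min_sep + 0.15, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      seq_sep <- abs(idx[, 1] - idx[, 2])
      keep <- seq_sep >= 2 &
        !(paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2])) %in% planted_key)
      idx <- idx[keep, , drop = FALSE]
    }
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      v <- coords[j, ] - coords[i, ]
      d <- sqrt(sum(v^2))
      if (d < 1e-6) v <- rand_unit() * (d <- 1e-3)
      shift <- 0.6 * (min_sep + 0.15 - d) / d * v
      coords[i, ] <- coords[i, ] - shift / 2
      coords[j, ] <- coords[j, ] + shift / 2
    }
    # project virtual bonds back to their fixed length
    for (pass in 1:4) {
      for (i in seq(2, n)) {
        v <- coords[i, ] - coords[i - 1, ]
        d <- sqrt(sum(v^2))
        corr <- 0.5 * (d - bond) / d * v
        coords[i, ] <- coords[i, ] - corr
        coords[i - 1, ] <- coords[i - 1, ] + corr
      }
    }
    # converge to the pull target (bond-length contact), well inside the
    # 4.0 A hard bound, so planted contacts survive the sampling noise
    if (chain_satisfies(coords, planted, bond, min_sep,
                        contact_max = contact_target + 0.02)) {
      return(coords)
    }
  }
  NULL
}

chain_satisfies <- function(coords, planted, bond = 3.8, min_sep = 5.5,
                            contact_max = 4.0) {
  n <- nrow(coords)
  bd <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                        coords[-n, , drop = FALSE])^2))
  if (any(abs(bd - bond) > 0.05)) return(FALSE)
  D <- as.matrix(stats::dist(coords))
  for (r in seq_len(nrow(planted))) {
    if (D[planted[r, 1], planted[r, 2]] > contact_max) return(FALSE)
  }
  mask <- upper.tri(D)
  ij <- which(mask, arr.ind = TRUE)
  seq_sep <- abs(ij[, 1] - ij[, 2])
  planted_key <- if (nrow(planted) > 0) paste(planted[, 1], planted[, 2]) else character(0)
  free <- seq_sep >= 2 & !(paste(ij[, 1], ij[, 2]) %in% planted_key)
  all(D[mask][free] > min_sep)
}

bead_topology <- function(n_residues, prefix_res = "ALA") {
  topology(
    atom_name = rep("CA", n_residues),
    element = rep("C", n_residues),
    res_index = seq_len(n_residues),
    res_name = rep(prefix_res, n_residues),
    chain = rep("A", n_residues),
    params = data.frame(charge = 0, sigma = 3.4, epsilon = 0.1,
                        born_radius = 1.7, mass = 12.011)[rep(1, n_residues), ]
  )
}

#' Generate class reference structures with planted contacts
#'
#' Builds, for every class in the spec, a self-avoiding Calpha chain
#' (3.8 Angstrom virtual bonds) folded so that exactly the class's
#' planted residue pairs sit within contact distance (<= 4.0 Angstrom)
#' while every other non-neighbour pair stays beyond 5.5 Angstrom. The
#' resulting contact maps therefore differ between classes in exactly
#' the planted pixels (and their symmetric mirrors).
#'
#' @param spec a `synthetic_spec`.
#' @param max_attempts bounded retry budget per class before declaring
#'   the requested geometry infeasible.
#' @return a list with `references` (one single-frame
#'   `conformational_ensemble` per class) and `ground_truth` (planted
#'   pairs per class, domain layout, seed).
#' @export
generate_reference_structures <- function(spec, max_attempts = 25) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    top <- bead_topology(spec$n_residues)
    refs <- vector("list", length(spec$classes))
    for (k in seq_along(spec$classes)) {
      planted <- spec$classes[[k]]
      coords <- NULL
      for (attempt in seq_len(max_attempts)) {
        raw <- grow_chain(spec$n_residues)
        coords <- relax_chain(raw, planted)
        if (!is.null(coords)) break
      }
      if (is.null(coords)) {
        stopf("class %d: could not realize %d planted contacts on a %d-residue chain after %d attempts",
              k, nrow(planted), spec$n_residues, max_attempts)
      }
      refs[[k]] <- conformational_ensemble(
        top, matrix(mat_to_xyz(coords), nrow = 1),
        data.frame(run = sprintf("class%d", k), frame = 0L,
                   stringsAsFactors = FALSE))
    }
    list(references = refs,
         ground_truth = list(classes = spec$classes, domains = spec$domains,
                             n_residues = spec$n_residues, seed = spec$seed))
  })
}

#' Sample a noisy ensemble about a reference structure
#'
#' Frames are the reference plus i.i.d. Gaussian displacements (sigma per
#' coordinate). This is a structureless noise model: it reproduces the
#' contact statistics and fluctuation magnitudes the downstream stages
#' need, not kinetics.
#'
#' @param reference a single-frame `conformational_ensemble` (or A x 3
#'   coordinate matrix plus `top`).
#' @param n_frames number of frames (>= 1).
#' @param sigma Gaussian displacement per coordinate, Angstrom (>= 0).
#' @param seed integer seed.
#' @param run run identifier recorded in provenance.
#' @export
sample_ensemble <- function(reference, n_frames, sigma, seed = 1,
                            run = "run1") {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  if (sigma < 0) stopf("sigma must be >= 0")
  top <- reference$topology
  base <- reference$xyz[1, ]
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n_frames * length(base), sd = sigma),
                    nrow = n_frames)
    xyz <- sweep(noise, 2, base, "+")
    conformational_ensemble(top, xyz,
                            data.frame(run = run,
                                       frame = seq_len(n_frames) - 1L,
                                       stringsAsFactors = FALSE))
  })
}

#' Generate the full labelled multi-class ensemble of a spec
#'
#' Convenience wrapper: builds references, samples `frames_per_class`
#' noisy frames per class, and returns both the per-class ensembles and
#' the merged ensemble with frame labels.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `references`, `class_ensembles`, `ensemble`
#'   (merged), `labels` (integer class per merged frame) and
#'   `ground_truth`.
#' @export
generate_class_ensembles <- function(spec) {
  gen <- generate_reference_structures(spec)
  class_ens <- lapply(seq_along(gen$references), function(k) {
    sample_ensemble(gen$references[[k]], spec$frames_per_class, spec$sigma,
                    seed = spec$seed + 1000L * k, run = sprintf("class%d", k))
  })
  merged <- join_ensembles(class_ens)
  labels <- rep(seq_along(class_ens), each = spec$frames_per_class)
  list(references = gen$references, class_ensembles = class_ens,
       ensemble = merged, labels = labels, ground_truth = gen$ground_truth)
}

#' Generate a toy parameterized ligand-receptor complex
#'
#' Builds a bead receptor (compact cluster, one bead per residue) and a
#' small bead ligand docked at its surface, with per-atom charges,
#' Lennard-Jones parameters and Born radii scaled so the interaction
#' energy components fall in the 1-100 kcal/mol range typical of
#' inhibitor binding. Used as the ground-truth fixture of the energetics
#' module.
#'
#' @param seed integer seed.
#' @param n_receptor receptor beads (20-40 sensible).
#' @param n_ligand ligand beads (5-10 sensible).
#' @param n_frames frames in the returned ensemble; frames beyond the
#'   first are small-jitter copies (0.1 Angstrom).
#' @param neutral_ligand zero all ligand charges (makes the electrostatic
#'   component vanish identically).
#' @param salt_bridge give the receptor bead nearest the ligand charge
#'   -1 e and the nearest ligand bead +1 e, planting a dominant
#'   electrostatic hot-spot residue.
#' @return list with `topology` (parameterized), `ensemble`,
#'   `receptor_atoms`, `ligand_atoms`, `receptor_residues`,
#'   `ligand_residue`.
#' @export
generate_ligand_system <- function(seed = 1, n_receptor = 30, n_ligand = 6,
                                   n_frames = 1, neutral_ligand = FALSE,
                                   salt_bridge = FALSE) {
  with_seed(seed, {
    place_cluster <- function(n, center, radius, min_sep, avoid = NULL) {
      pts <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        for (try in 1:4000) {
          cand <- center + stats::runif(3, -radius, radius)
          ok <- TRUE
          if (i > 1) {
            d2 <- rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2,
                                cand)^2)
            ok <- min(d2) > min_sep^2
          }
          if (ok && !is.null(avoid)) {
            d2 <- rowSums(sweep(avoid, 2, cand)^2)
            ok <- min(d2) > min_sep^2
          }
          if (ok) { pts[i, ] <- cand; break }
        }
        if (anyNA(pts[i, ])) stopf("could not place bead %d", i)
      }
      pts
    }
    rec <- place_cluster(n_receptor, c(0, 0, 0), 8.5, 3.6)
    # dock the ligand just outside the receptor surface along +x
    surf <- max(rec[, 1])
    lig <- place_cluster(n_ligand, c(surf + 4.5, 0, 0), 3.0, 2.8, avoid = rec)

    rec_charge <- stats::runif(n_receptor, -0.4, 0.4)
    lig_charge <- if (neutral_ligand) rep(0, n_ligand) else
      stats::runif(n_ligand, -0.35, 0.35)
    if (salt_bridge && !neutral_ligand) {
      cross <- outer(seq_len(n_receptor), seq_len(n_ligand),
                     Vectorize(function(i, j) sqrt(sum((rec[i, ] - lig[j, ])^2))))
      hit <- which(cross == min(cross), arr.ind = TRUE)[1, ]
      rec_charge[hit[1]] <- -1.0
      lig_charge[hit[2]] <- 1.0
    }
    params <- data.frame(
      charge = c(rec_charge, lig_charge),
      sigma = c(stats::runif(n_receptor, 3.2, 3.8),
                stats::runif(n_ligand, 3.0, 3.5)),
      epsilon = c(stats::runif(n_receptor, 0.08, 0.16),
                  stats::runif(n_ligand, 0.08, 0.16)),
      born_radius = stats::runif(n_receptor + n_ligand, 1.5, 2.0),
      mass = rep(12.011, n_receptor + n_ligand)
    )
    top <- topology(
      atom_name = c(rep("CA", n_receptor), sprintf("L%d", seq_len(n_ligand))),
      element = rep("C", n_receptor + n_ligand),
      res_index = c(seq_len(n_receptor), rep(n_receptor + 1L, n_ligand)),
      res_name = c(rep("GLY", n_receptor), rep("LIG", n_ligand)),
      chain = c(rep("A", n_receptor), rep("B", n_ligand)),
      params = params
    )
    coords <- rbind(rec, lig)
    base <- conformational_ensemble(top, matrix(mat_to_xyz(coords), nrow = 1))
    ens <- if (n_frames > 1) {
      sample_ensemble(base, n_frames, sigma = 0.1, seed = seed + 7L)
    } else base
    list(topology = top, ensemble = ens,
         receptor_atoms = seq_len(n_receptor),
         ligand_atoms = n_receptor + seq_len(n_ligand),
         receptor_residues = seq_len(n_receptor),
         ligand_residue = n_receptor + 1L)
  })
}
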
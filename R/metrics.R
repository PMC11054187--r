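#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares fit of a mobile frame onto a reference over a selection,
#' returning the proper rotation (det +1), translation and post-fit RMSD.
#'
#' @param mobile A x 3 coordinate matrix (Angstrom).
#' @param reference A x 3 coordinate matrix.
#' @param selection integer atom indices used for the fit (default: all).
#' @return list with `rotation` (3 x 3), `translation`, `rmsd`,
#'   `aligned` (all mobile atoms transformed) and `selection`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  selection <- as.integer(selection)
  if (length(selection) == 0) stopf("empty selection")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stopf("selections differ in size")
  if (nrow(A) < 3 || qr(sweep(A, 2, colMeans(A)))$rank < 2) {
    stopf("superposition needs at least 3 non-collinear atoms")
  }
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cb - as.numeric(R %*% ca)
  aligned <- t(R %*% t(mobile)) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  dev <- aligned[selection, , drop = FALSE] - B
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums(dev^2))),
       aligned = aligned, selection = selection)
}

#' Per-frame best-fit RMSD against a reference structure
#'
#' Every frame is superposed onto the reference over the selection before
#' the deviation is measured, mirroring the convention of referencing an
#' initially optimized structure.
#'
#' @param ens a `conformational_ensemble`.
#' @param reference A x 3 matrix or single-frame ensemble; defaults to
#'   frame 1 of `ens`.
#' @param selection atom selection (see [select_atoms()]); default
#'   backbone atoms.
#' @return list with per-frame `values` (Angstrom) and a `summary`
#'   ([series_summary()]).
#' @export
rmsd_series <- function(ens, reference = NULL, selection = "backbone",
                        n_bins = 50) {
  sel <- select_atoms(ens$topology, selection)
  if (length(sel) == 0) stopf("empty selection")
  ref <- if (is.null(reference)) frame_coords(ens, 1L)
  else if (inherits(reference, "conformational_ensemble")) frame_coords(reference, 1L)
  else reference
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    kabsch_superpose(frame_coords(ens, f), ref, sel)$rmsd
  }, numeric(1))
  list(values = vals, summary = series_summary(vals, n_bins = n_bins))
}

# superpose all frames onto an iteratively refined mean structure;
# returns the ensemble xyz after fitting plus the converged mean.
superpose_to_mean <- function(ens, sel, iterations = 2) {
  xyz <- ens$xyz
  ref <- xyz_to_mat(xyz[1, ])
  for (it in seq_len(iterations)) {
    for (f in seq_len(nrow(xyz))) {
      fit <- kabsch_superpose(xyz_to_mat(xyz[f, ]), ref, sel)
      xyz[f, ] <- mat_to_xyz(fit$aligned)
    }
    ref <- xyz_to_mat(colMeans(xyz))
  }
  list(xyz = xyz, mean = ref)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first superposed onto their iterative mean structure (two
#' refinement rounds), then RMSF_i = sqrt(<|r_i - <r_i>|^2>) is computed
#' per selected atom.
#'
#' @param ens a `conformational_ensemble` (>= 2 frames).
#' @param selection atom selection; default Calpha atoms.
#' @param superpose disable to measure raw fluctuations in the lab frame.
#' @return named numeric vector, one value per selected atom (Angstrom),
#'   names are residue indices.
#' @export
rmsf <- function(ens, selection = "calpha", superpose = TRUE) {
  if (n_frames(ens) < 2) stopf("RMSF requires at least 2 frames")
  sel <- select_atoms(ens$topology, selection)
  xyz <- if (superpose) superpose_to_mean(ens, sel)$xyz else ens$xyz
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  sub <- xyz[, cols, drop = FALSE]
  mu <- colMeans(sub)
  dev2 <- sweep(sub, 2, mu)^2
  per_coord <- colMeans(dev2)
  vals <- sqrt(per_coord[seq(1, length(per_coord), 3)] +
                 per_coord[seq(2, length(per_coord), 3)] +
                 per_coord[seq(3, length(per_coord), 3)])
  names(vals) <- ens$topology$atoms$res_index[sel]
  vals
}

#' Mass-weighted radius of gyration
#'
#' RG = sqrt(sum m_i |r_i - r_cm|^2 / sum m_i). Masses come from the
#' topology parameter table; unit masses are used when absent.
#'
#' @param x an A x 3 coordinate matrix or a `conformational_ensemble`
#'   (then one value per frame is returned).
#' @param top the `topology` (ignored when `x` is an ensemble).
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(x, top = NULL) {
  if (inherits(x, "conformational_ensemble")) {
    return(vapply(seq_len(n_frames(x)), function(f) {
      radius_of_gyration(frame_coords(x, f), x$topology)
    }, numeric(1)))
  }
  m <- if (!is.null(top) && !is.null(top$params)) top$params$mass
  else rep(1, nrow(x))
  if (sum(m) <= 0) stopf("total mass must be positive")
  cm <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, cm)^2)) / sum(m))
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with a rolling probe. Atom radii default to the
#' van der Waals radius implied by the Lennard-Jones sigma of the
#' parameter table (sigma * 2^(1/6) / 2); an explicit radius vector
#' overrides this.
#'
#' @param coords A x 3 coordinate matrix (Angstrom).
#' @param top parameterized `topology` (used for radii and residue
#'   assignment); may be NULL when `radii` is given.
#' @param radii optional per-atom radii (Angstrom).
#' @param probe probe radius, default 1.4 Angstrom (water).
#' @param n_points sphere sample points per atom (default 960).
#' @return list with `total` (Angstrom^2), `per_atom`, `per_residue`.
#' @export
sasa <- function(coords, top = NULL, radii = NULL, probe = 1.4,
                 n_points = 960) {
  n <- nrow(coords)
  if (is.null(radii)) {
    if (is.null(top) || is.null(top$params)) {
      stopf("atom radii are required (parameter table or `radii`)")
    }
    radii <- top$params$sigma * 2^(1 / 6) / 2
  }
  if (length(radii) != n) stopf("one radius per atom required")
  if (any(is.na(radii))) stopf("missing atom radius")
  pts <- sphere_points(n_points)
  ext <- radii + probe
  d2 <- as.matrix(stats::dist(coords))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (ext[i] + ext)^2 & seq_len(n) != i)
    surf <- sweep(pts * ext[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (surf[, 1] - coords[j, 1])^2 + (surf[, 2] - coords[j, 2])^2 +
        (surf[, 3] - coords[j, 3])^2
      exposed <- exposed & dj2 > ext[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * ext[i]^2 * sum(exposed) / n_points
  }
  per_res <- if (!is.null(top)) {
    tapply(per_atom, ens_res <- top$atoms$res_index, sum)
  } else NULL
  list(total = sum(per_atom), per_atom = per_atom, per_residue = per_res)
}

#' Candidate hydrogen-bond geometry specification
#'
#' @param donor,hydrogen,acceptor topology atom indices of the donor
#'   heavy atom, its hydrogen and the acceptor atom.
#' @param label optional label carried into the report.
#' @export
hbond_spec <- function(donor, hydrogen, acceptor, label = NULL) {
  d <- data.frame(donor = as.integer(donor), hydrogen = as.integer(hydrogen),
                  acceptor = as.integer(acceptor), stringsAsFactors = FALSE)
  d$label <- if (is.null(label)) sprintf("D%d-H%d..A%d", d$donor, d$hydrogen,
                                         d$acceptor) else label
  class(d) <- c("hbond_spec", "data.frame")
  d
}

#' Detect hydrogen bonds over an ensemble
#'
#' A bond is present in a frame iff the donor-acceptor distance is
#' strictly below `dist_cutoff` AND the donor-hydrogen-acceptor angle at
#' the hydrogen is strictly above `angle_cutoff`. Occupancy is
#' 100 x (frames present) / F; mean distance and angle are computed over
#' present frames only.
#'
#' @param ens a `conformational_ensemble`.
#' @param specs an `hbond_spec` table.
#' @param dist_cutoff Angstrom, default 3.5.
#' @param angle_cutoff degrees, default 120.
#' @return data.frame with one row per candidate: label, donor, acceptor,
#'   occupancy (percent), mean_distance, mean_angle, and a `presence`
#'   attribute (F x n logical matrix).
#' @export
detect_hbonds <- function(ens, specs, dist_cutoff = 3.5, angle_cutoff = 120) {
  a <- n_atoms(ens$topology)
  if (any(unlist(specs[c("donor", "hydrogen", "acceptor")]) > a)) {
    stopf("hydrogen-bond spec references atoms outside the topology")
  }
  nf <- n_frames(ens)
  pres <- matrix(FALSE, nf, nrow(specs))
  dmat <- matrix(NA_real_, nf, nrow(specs))
  amat <- matrix(NA_real_, nf, nrow(specs))
  for (f in seq_len(nf)) {
    co <- frame_coords(ens, f)
    for (s in seq_len(nrow(specs))) {
      D <- co[specs$donor[s], ]; H <- co[specs$hydrogen[s], ]
      A <- co[specs$acceptor[s], ]
      dda <- sqrt(sum((D - A)^2))
      v1 <- D - H; v2 <- A - H
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      dmat[f, s] <- dda; amat[f, s] <- ang
      pres[f, s] <- (dda < dist_cutoff) && (ang > angle_cutoff)
    }
  }
  out <- data.frame(
    label = specs$label,
    donor = specs$donor, acceptor = specs$acceptor,
    occupancy = 100 * colSums(pres) / nf,
    mean_distance = vapply(seq_len(ncol(pres)), function(s) {
      if (any(pres[, s])) mean(dmat[pres[, s], s]) else NA_real_
    }, numeric(1)),
    mean_angle = vapply(seq_len(ncol(pres)), function(s) {
      if (any(pres[, s])) mean(amat[pres[, s], s]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "presence") <- pres
  out
}

#' Histogram summary of a per-frame series with mode detection
#'
#' Bins the series into `n_bins` equal-width bins and reports the local
#' maxima of the 3-bin moving-average-smoothed counts as distribution
#' peaks (ties broken toward the lower value), the representation used
#' for frequency distributions of RMSD, surface area and the like.
#'
#' @param values numeric vector (>= 1 value).
#' @param n_bins number of bins (default 50).
#' @return list of class `series_summary` with `values`, `breaks`,
#'   `counts`, `mids`, `peaks` (bin-center locations) and
#'   `peak_heights`.
#' @export
series_summary <- function(values, n_bins = 50) {
  if (length(values) == 0) stopf("no values to summarize")
  rng <- range(values)
  if (diff(rng) == 0) {
    out <- list(values = values, breaks = c(rng[1] - 0.5, rng[1] + 0.5),
                counts = length(values), mids = rng[1], peaks = rng[1],
                peak_heights = length(values))
    class(out) <- "series_summary"
    return(out)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  counts <- h$counts
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(counts[1:2]); sm[length(sm)] <- mean(counts[(length(counts) - 1):length(counts)])
  sm <- as.numeric(sm)
  n <- length(sm)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else sm[i - 1]
    right <- if (i == n) -Inf else sm[i + 1]
    sm[i] > left && sm[i] >= right  # plateau credit goes to the lower bin
  }, logical(1))
  if (!any(is_peak)) is_peak[which.max(sm)] <- TRUE
  out <- list(values = values, breaks = breaks, counts = counts,
              mids = h$mids, peaks = h$mids[is_peak],
              peak_heights = sm[is_peak])
  class(out) <- "series_summary"
  out
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("<series_summary> n = %d, peaks at %s\n", length(x$values),
              paste(signif(x$peaks, 4), collapse = ", ")))
  invisible(x)
}
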
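#' Principal component analysis of Calpha coordinate fluctuations
#'
#' Frames are superposed onto their iterative mean structure (internal
#' motion only), then the 3M x 3M covariance of the selected coordinates
#' C = <(q - <q>)(q - <q>)^T> is diagonalized. The population convention
#' (divide by F) is used, matching the ensemble-average definition of the
#' covariance.
#'
#' @param ens a `conformational_ensemble` (>= 2 frames).
#' @param selection atom selection, default Calpha.
#' @param superpose superpose frames before the covariance (disable only
#'   for closed-form tests).
#' @return object of class `pca_model` with `mean` (3M), `covariance`,
#'   `eigenvalues` (descending, Angstrom^2), `eigenvectors` (columns,
#'   orthonormal), `reference` (superposition target coordinates),
#'   `selection`.
#' @export
build_pca <- function(ens, selection = "calpha", superpose = TRUE) {
  if (n_frames(ens) < 2) stopf("PCA requires at least 2 frames")
  sel <- select_atoms(ens$topology, selection)
  sup <- if (superpose) superpose_to_mean(ens, sel)
  else list(xyz = ens$xyz, mean = xyz_to_mat(colMeans(ens$xyz)))
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  Q <- sup$xyz[, cols, drop = FALSE]
  mu <- colMeans(Q)
  Qc <- sweep(Q, 2, mu)
  C <- crossprod(Qc) / nrow(Qc)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  structure(list(mean = mu, covariance = C, eigenvalues = lambda,
                 eigenvectors = eig$vectors, reference = sup$mean,
                 selection = sel),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  fr <- variance_fractions(x, min(3, length(x$eigenvalues)))
  cat(sprintf("<pca_model> 3M = %d; top eigenvalue fractions: %s%%\n",
              length(x$eigenvalues),
              paste(signif(fr$fraction, 4), collapse = ", ")))
  invisible(x)
}

#' Variance fractions of the leading eigenvalues
#'
#' @param model a `pca_model`.
#' @param k number of modes to report.
#' @return data.frame with `mode`, `eigenvalue`, `fraction` (percent of
#'   total variance) and `cumulative` (percent).
#' @export
variance_fractions <- function(model, k = 6) {
  tot <- sum(model$eigenvalues)
  if (tot <= 0) stopf("total variance is zero")
  if (k > length(model$eigenvalues)) stopf("k exceeds the number of modes")
  fr <- 100 * model$eigenvalues / tot
  data.frame(mode = seq_len(k), eigenvalue = model$eigenvalues[seq_len(k)],
             fraction = fr[seq_len(k)], cumulative = cumsum(fr)[seq_len(k)])
}

#' Project an ensemble onto principal components
#'
#' Frames are superposed onto the model's reference structure over the
#' model selection, centered at the model mean, and dotted with the
#' leading eigenvectors.
#'
#' @param ens a `conformational_ensemble` sharing the model's topology
#'   selection size.
#' @param model a `pca_model`.
#' @param k number of components (default 2).
#' @param superpose superpose onto the model reference first.
#' @return F x k numeric matrix.
#' @export
project_ensemble <- function(ens, model, k = 2, superpose = TRUE) {
  sel <- model$selection
  if (3 * length(sel) != length(model$mean)) stopf("selection mismatch")
  if (max(sel) > n_atoms(ens$topology)) stopf("selection mismatch")
  xyz <- ens$xyz
  if (superpose) {
    for (f in seq_len(nrow(xyz))) {
      fit <- kabsch_superpose(xyz_to_mat(xyz[f, ]), model$reference, sel)
      xyz[f, ] <- mat_to_xyz(fit$aligned)
    }
  }
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  Qc <- sweep(xyz[, cols, drop = FALSE], 2, model$mean)
  Qc %*% model$eigenvectors[, seq_len(k), drop = FALSE]
}

#' Free-energy landscape from PC projections (Boltzmann inversion)
#'
#' Bins the first two projection columns into a 2D histogram and converts
#' occupancy to relative free energy G = -kB T ln(P / Pmax), so the most
#' populated bin sits at G = 0. Unpopulated bins carry the sentinel
#' max(G) + 1 kcal/mol.
#'
#' @param proj F x >=2 projection matrix.
#' @param bins bins per axis (default 100).
#' @param temperature Kelvin (default 300, the simulation temperature).
#' @return object of class `fel_grid` with `x_edges`, `y_edges`, `prob`,
#'   `free_energy` (kcal/mol), `populated`, `kT`, `temperature`.
#' @export
free_energy_landscape <- function(proj, bins = 100, temperature = 300) {
  if (is.null(dim(proj)) || nrow(proj) == 0) stopf("empty projections")
  if (temperature <= 0) stopf("temperature must be positive")
  kT <- 0.0019872 * temperature
  pad <- function(r) {
    if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) * 1e-9 * c(-1, 1)
  }
  xe <- seq(pad(range(proj[, 1]))[1], pad(range(proj[, 1]))[2],
            length.out = bins + 1)
  ye <- seq(pad(range(proj[, 2]))[1], pad(range(proj[, 2]))[2],
            length.out = bins + 1)
  ix <- pmin(findInterval(proj[, 1], xe, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(proj[, 2], ye, rightmost.closed = TRUE), bins)
  counts <- matrix(0, bins, bins)
  for (f in seq_along(ix)) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1
  P <- counts / sum(counts)
  populated <- P > 0
  G <- matrix(NA_real_, bins, bins)
  G[populated] <- -kT * log(P[populated] / max(P))
  sentinel <- max(G[populated]) + 1
  G[!populated] <- sentinel
  structure(list(x_edges = xe, y_edges = ye, prob = P, free_energy = G,
                 populated = populated, kT = kT, temperature = temperature,
                 sentinel = sentinel, n_samples = nrow(proj),
                 noise_level = kT * log(max(counts))),
            class = "fel_grid")
}

#' Detect energy basins on a free-energy landscape
#'
#' Populated bins are processed in order of increasing free energy and
#' grown into basins (8-neighbourhood connectivity). A bin touching two
#' existing basins merges them when the shallower basin's depth relative
#' to the connecting barrier is below `depth_threshold` (persistence
#' criterion). Basins must also be at least `depth_threshold` deeper
#' than the single-count noise level kB T ln(max count) — a bin visited
#' once is indistinguishable from sampling noise, so shallow rim minima
#' are not reported. Raising the threshold therefore monotonically
#' reduces the basin count. Ties in minima are broken by bin index.
#'
#' @param fel a `fel_grid`.
#' @param depth_threshold kcal/mol (default 0.5).
#' @param proj optional projection matrix; when given, each basin also
#'   reports the frame nearest its minimum bin center in PC space.
#' @return object of class `basin_set`: data.frame with `basin`,
#'   `min_bin_x`, `min_bin_y`, `g_min`, `n_bins`, and optionally
#'   `representative_frame`; bin assignment matrix in attribute
#'   `assignment`.
#' @export
find_basins <- function(fel, depth_threshold = 0.5, proj = NULL) {
  G <- fel$free_energy
  nb <- nrow(G)
  pop <- which(fel$populated, arr.ind = TRUE)
  if (nrow(pop) == 0) {
    out <- data.frame(basin = integer(0))
    class(out) <- c("basin_set", "data.frame")
    return(out)
  }
  ord <- order(G[fel$populated], pop[, 1], pop[, 2])
  cells <- pop[ord, , drop = FALSE]
  label <- matrix(0L, nb, nb)
  basin_min <- numeric(0)   # G at each basin's minimum
  basin_cell <- list()
  parent <- integer(0)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]; g <- G[i, j]
    ni <- max(1, i - 1):min(nb, i + 1)
    nj <- max(1, j - 1):min(nb, j + 1)
    nbl <- unique(label[as.matrix(expand.grid(ni, nj))])
    nbl <- nbl[nbl > 0]
    nbl <- unique(vapply(nbl, find_root, integer(1)))
    if (length(nbl) == 0) {
      k <- length(basin_min) + 1L
      basin_min[k] <- g
      basin_cell[[k]] <- c(i, j)
      parent[k] <- k
      label[i, j] <- k
    } else if (length(nbl) == 1) {
      label[i, j] <- nbl
    } else {
      # order by depth: deepest survives; shallow ones merge if their
      # persistence (barrier - own minimum) is below the threshold
      nbl <- nbl[order(basin_min[nbl])]
      keep <- nbl[1]
      for (k in nbl[-1]) {
        if (g - basin_min[k] < depth_threshold) parent[k] <- keep
      }
      label[i, j] <- keep
    }
  }
  roots <- unique(vapply(seq_along(parent), find_root, integer(1)))
  # relabel assignments to surviving roots
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (label[i, j] > 0) label[i, j] <- find_root(label[i, j])
  }
  # drop basins too shallow to distinguish from sampling noise
  floor_g <- fel$noise_level %||% max(G[fel$populated])
  roots <- roots[floor_g - basin_min[roots] >= depth_threshold]
  ord_roots <- roots[order(basin_min[roots])]
  out <- data.frame(
    basin = seq_along(ord_roots),
    min_bin_x = vapply(ord_roots, function(k) basin_cell[[k]][1], integer(1)),
    min_bin_y = vapply(ord_roots, function(k) basin_cell[[k]][2], integer(1)),
    g_min = basin_min[ord_roots],
    n_bins = vapply(ord_roots, function(k) sum(label == k), numeric(1))
  )
  if (!is.null(proj)) {
    xc <- (fel$x_edges[-1] + fel$x_edges[-length(fel$x_edges)]) / 2
    yc <- (fel$y_edges[-1] + fel$y_edges[-length(fel$y_edges)]) / 2
    out$representative_frame <- vapply(seq_len(nrow(out)), function(b) {
      cx <- xc[out$min_bin_x[b]]; cy <- yc[out$min_bin_y[b]]
      which.min((proj[, 1] - cx)^2 + (proj[, 2] - cy)^2)
    }, integer(1))
  }
  attr(out, "assignment") <- label
  class(out) <- c("basin_set", "data.frame")
  out
}

#' Per-residue displacement magnitude of a PCA mode
#'
#' Magnitude of each selected atom's (x, y, z) entries in eigenvector k:
#' the porcupine-style measure of which residues a concerted motion
#' moves.
#'
#' @param model a `pca_model`.
#' @param mode mode index (default 1, the dominant motion).
#' @return numeric vector (one value per selected atom, Angstrom per
#'   unit projection).
#' @export
mode_displacements <- function(model, mode = 1) {
  if (mode > length(model$eigenvalues)) stopf("mode %d out of range", mode)
  v <- model$eigenvectors[, mode]
  m <- length(v) / 3
  vm <- matrix(v, ncol = 3, byrow = TRUE)
  sqrt(rowSums(vm^2))
}
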
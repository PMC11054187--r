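# Physical constants (kcal-mol-Angstrom-e units)
KE_COULOMB <- 332.0636   # kcal A / (mol e^2)
KB_KCAL <- 0.0019872     # kcal / (mol K)

#' Dielectric and nonpolar settings for MM-GBSA bookkeeping
#'
#' @param eps_in interior dielectric (>= 1).
#' @param eps_solv solvent dielectric (> eps_in).
#' @param gamma surface-tension coefficient, kcal/(mol Angstrom^2).
#' @param beta nonpolar offset, kcal/mol.
#' @export
gbsa_settings <- function(eps_in = 1, eps_solv = 78.5, gamma = 0.0072,
                          beta = 0) {
  if (eps_in < 1 || eps_solv <= eps_in) {
    stopf("require eps_solv > eps_in >= 1")
  }
  if (gamma < 0) stopf("gamma must be non-negative")
  list(eps_in = eps_in, eps_solv = eps_solv, gamma = gamma, beta = beta)
}

all_pairs <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(ij[, 1], ij[, 2])
}

pair_distances <- function(coords, pairs) {
  d <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                       coords[pairs[, 2], , drop = FALSE])^2))
  d
}

#' Coulomb energy over a pair set
#'
#' Sum of k_e q_i q_j / (eps_in r_ij) without cutoff;
#' k_e = 332.0636 kcal Angstrom / (mol e^2).
#'
#' @param coords A x 3 matrix (Angstrom).
#' @param charges per-atom partial charges (e).
#' @param pairs 2-column index matrix; default all i < j.
#' @param eps_in interior dielectric.
#' @return kcal/mol.
#' @export
coulomb_energy <- function(coords, charges, pairs = NULL, eps_in = 1) {
  if (is.null(pairs)) pairs <- all_pairs(nrow(coords))
  if (nrow(pairs) == 0) return(0)
  r <- pair_distances(coords, pairs)
  qq <- charges[pairs[, 1]] * charges[pairs[, 2]]
  if (any(r == 0 & qq != 0)) stopf("coincident charged atoms")
  sum(ifelse(qq == 0, 0, KE_COULOMB * qq / (eps_in * r)))
}

#' Lennard-Jones 12-6 energy over a pair set
#'
#' Lorentz-Berthelot combining: sigma_ij = (sigma_i + sigma_j)/2,
#' eps_ij = sqrt(eps_i eps_j); E = sum 4 eps_ij [(s/r)^12 - (s/r)^6].
#'
#' @param coords A x 3 matrix.
#' @param sigma,epsilon per-atom LJ parameters (Angstrom, kcal/mol).
#' @param pairs 2-column index matrix; default all i < j.
#' @return kcal/mol.
#' @export
lj_energy <- function(coords, sigma, epsilon, pairs = NULL) {
  if (is.null(pairs)) pairs <- all_pairs(nrow(coords))
  if (nrow(pairs) == 0) return(0)
  r <- pair_distances(coords, pairs)
  if (any(r == 0)) stopf("coincident atoms in Lennard-Jones sum")
  sij <- (sigma[pairs[, 1]] + sigma[pairs[, 2]]) / 2
  eij <- sqrt(epsilon[pairs[, 1]] * epsilon[pairs[, 2]])
  sr6 <- (sij / r)^6
  sum(4 * eij * (sr6^2 - sr6))
}

#' Pairwise generalized-Born polar solvation energy (Still form)
#'
#' G = -(k_e / 2) (1/eps_in - 1/eps_solv) sum_{i,j} q_i q_j / f_GB with
#' f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j))) and self terms
#' (i = j, f_GB = a_i) included, using supplied effective Born radii.
#' Reduces to the Born ion formula for a single charge and to zero when
#' the dielectrics match.
#'
#' @param coords A x 3 matrix.
#' @param charges per-atom charges (e).
#' @param radii effective Born radii (Angstrom; > 0 wherever the charge
#'   is nonzero).
#' @param eps_in,eps_solv dielectrics.
#' @return kcal/mol.
#' @export
gb_energy <- function(coords, charges, radii, eps_in = 1, eps_solv = 78.5) {
  if (any(radii <= 0 & charges != 0)) {
    stopf("charged atom with non-positive Born radius")
  }
  pref <- -(KE_COULOMB / 2) * (1 / eps_in - 1 / eps_solv)
  keep <- charges != 0
  if (!any(keep)) return(0)
  co <- coords[keep, , drop = FALSE]
  q <- charges[keep]; a <- radii[keep]
  n <- length(q)
  self_sum <- sum(q^2 / a)
  cross_sum <- 0
  if (n > 1) {
    pr <- all_pairs(n)
    r2 <- rowSums((co[pr[, 1], , drop = FALSE] - co[pr[, 2], , drop = FALSE])^2)
    aa <- a[pr[, 1]] * a[pr[, 2]]
    fgb <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
    cross_sum <- 2 * sum(q[pr[, 1]] * q[pr[, 2]] / fgb)
  }
  pref * (self_sum + cross_sum)
}

#' Nonpolar (surface-area) solvation term
#'
#' Delta G_surf = gamma * Delta SASA + beta, with the standard
#' gamma = 0.0072 kcal/(mol Angstrom^2) and beta = 0 defaults.
#'
#' @param dsasa change in solvent-accessible surface area (Angstrom^2).
#' @param gamma,beta empirical coefficients.
#' @return kcal/mol.
#' @export
nonpolar_energy <- function(dsasa, gamma = 0.0072, beta = 0) {
  gamma * dsasa + beta
}

energy_terms_for_subset <- function(coords, params, idx, settings,
                                    probe = 1.4, n_points = 240) {
  co <- coords[idx, , drop = FALSE]
  q <- params$charge[idx]; s <- params$sigma[idx]
  e <- params$epsilon[idx]; a <- params$born_radius[idx]
  list(
    ele = coulomb_energy(co, q, eps_in = settings$eps_in),
    vdw = lj_energy(co, s, e),
    gb = gb_energy(co, q, a, settings$eps_in, settings$eps_solv),
    sasa = sasa(co, radii = s * 2^(1 / 6) / 2, probe = probe,
                n_points = n_points)$total
  )
}

#' Single-frame MM-GBSA interaction components
#'
#' Single-trajectory convention: receptor and ligand coordinates are the
#' corresponding atoms of the complex frame, so each component is
#' Delta X = X(complex) - X(receptor) - X(ligand) and the gas-phase
#' Coulomb / Lennard-Jones deltas reduce exactly to receptor-ligand
#' cross terms (intra-molecular sums cancel identically).
#'
#' @param coords complex frame, A x 3 matrix.
#' @param top parameterized `topology`.
#' @param receptor,ligand disjoint atom index sets.
#' @param settings a [gbsa_settings()] list.
#' @param n_points SASA sphere points (default 240; the SASA difference
#'   converges quickly because buried points cancel).
#' @return one-row data.frame: dEele, dEvdw, dGgb, dGsurf, dGpol,
#'   dGhydro, dH (kcal/mol).
#' @export
snapshot_components <- function(coords, top, receptor, ligand,
                                settings = gbsa_settings(),
                                n_points = 240) {
  if (length(intersect(receptor, ligand)) > 0) {
    stopf("receptor and ligand index sets overlap")
  }
  if (is.null(top$params)) stopf("topology carries no per-atom parameters")
  idx_c <- sort(c(receptor, ligand))
  tc <- energy_terms_for_subset(coords, top$params, idx_c, settings,
                                n_points = n_points)
  tr <- energy_terms_for_subset(coords, top$params, receptor, settings,
                                n_points = n_points)
  tl <- energy_terms_for_subset(coords, top$params, ligand, settings,
                                n_points = n_points)
  dEele <- tc$ele - tr$ele - tl$ele
  dEvdw <- tc$vdw - tr$vdw - tl$vdw
  dGgb <- tc$gb - tr$gb - tl$gb
  dGsurf <- nonpolar_energy(tc$sasa - tr$sasa - tl$sasa,
                            settings$gamma, settings$beta)
  data.frame(dEele = dEele, dEvdw = dEvdw, dGgb = dGgb, dGsurf = dGsurf,
             dGpol = dEele + dGgb, dGhydro = dEvdw + dGsurf,
             dH = dEele + dEvdw + dGgb + dGsurf)
}

#' Per-frame MM-GBSA components over an ensemble
#'
#' @param ens a `conformational_ensemble` with parameterized topology.
#' @param receptor,ligand atom index sets.
#' @param settings a [gbsa_settings()] list.
#' @param n_frames number of evenly strided snapshots to use (default
#'   400, capped at the ensemble size).
#' @param n_points SASA sphere points per atom.
#' @return data.frame, one row per snapshot, columns as
#'   [snapshot_components()] plus `frame`.
#' @export
ensemble_components <- function(ens, receptor, ligand,
                                settings = gbsa_settings(),
                                n_frames = 400, n_points = 240) {
  frames <- unique(round(seq(1, n_frames(ens),
                             length.out = min(n_frames, n_frames(ens)))))
  out <- do.call(rbind, lapply(frames, function(f) {
    cbind(frame = f,
          snapshot_components(frame_coords(ens, f), ens$topology,
                              receptor, ligand, settings, n_points))
  }))
  out
}

#' Aggregate per-frame components into a binding free energy
#'
#' Delta G_bind = <dEele> + <dEvdW> + <dGgb> + <dGsurf> + (-T dS), i.e.
#' Delta G = Delta H - T Delta S with the enthalpy split into its four
#' MM-GBSA components. Accepts either a per-frame component table (means
#' and standard deviations are then computed) or a single row / named
#' vector of already-averaged components.
#'
#' @param components data.frame with columns dEele, dEvdw, dGgb, dGsurf
#'   (per frame or single-row means), or a named numeric vector.
#' @param neg_TdS entropy contribution -T dS in kcal/mol.
#' @param neg_TdS_method provenance tag, e.g. "supplied" or
#'   "quasiharmonic-schlitter".
#' @return object of class `binding_free_energy`: `mean`, `sd` (named
#'   vectors over the four components), `dGpol`, `dGhydro`, `dH`,
#'   `neg_TdS`, `dGbind`.
#' @export
aggregate_binding_free_energy <- function(components, neg_TdS,
                                          neg_TdS_method = "supplied") {
  if (is.numeric(components) && !is.null(names(components))) {
    components <- as.data.frame(as.list(components))
  }
  need <- c("dEele", "dEvdw", "dGgb", "dGsurf")
  if (!all(need %in% names(components))) {
    stopf("components must contain %s", paste(need, collapse = ", "))
  }
  mu <- vapply(need, function(cl) mean(components[[cl]]), numeric(1))
  sd_ <- vapply(need, function(cl) {
    if (nrow(components) > 1) stats::sd(components[[cl]]) else NA_real_
  }, numeric(1))
  out <- list(
    mean = mu, sd = sd_,
    dGpol = unname(mu["dEele"] + mu["dGgb"]),
    dGhydro = unname(mu["dEvdw"] + mu["dGsurf"]),
    dH = unname(sum(mu)),
    neg_TdS = neg_TdS, neg_TdS_method = neg_TdS_method,
    dGbind = unname(sum(mu) + neg_TdS),
    n_frames = nrow(components)
  )
  class(out) <- "binding_free_energy"
  out
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat("<binding_free_energy> (kcal/mol)\n")
  tab <- data.frame(mean = c(x$mean, dGpol = x$dGpol, neg_TdS = x$neg_TdS,
                             dGbind = x$dGbind),
                    sd = c(x$sd, NA, NA, NA))
  print(round(tab, 2))
  invisible(x)
}

#' Component-wise difference between two binding free energies
#'
#' Reports B - A for every component, the entropy term, Delta G_bind and
#' the favorable-force sum (dEvdw + dGsurf) — the quantities used to
#' compare one receptor system against another.
#'
#' @param a,b `binding_free_energy` objects computed under the same
#'   conventions.
#' @return named numeric vector of deltas (kcal/mol).
#' @export
compare_systems <- function(a, b) {
  d <- b$mean - a$mean
  c(d,
    dGpol = b$dGpol - a$dGpol,
    neg_TdS = b$neg_TdS - a$neg_TdS,
    dGbind = b$dGbind - a$dGbind,
    favorable = (b$mean[["dEvdw"]] + b$mean[["dGsurf"]]) -
      (a$mean[["dEvdw"]] + a$mean[["dGsurf"]]))
}

#' Per-residue decomposition of the ligand interaction energy
#'
#' Each receptor residue's interaction with the ligand is the sum over
#' its (residue atom, ligand atom) pairs of Coulomb + Lennard-Jones
#' cross terms plus half of the pairwise generalized-Born cross terms
#' (the other half belongs to the ligand), plus the residue's share of
#' the SASA difference times gamma. Values are averaged over the
#' snapshots used. A residue is flagged a key residue when its total is
#' at or below `-threshold` kcal/mol (favorable, "stronger than").
#'
#' @param ens a `conformational_ensemble` with parameterized topology.
#' @param receptor,ligand atom index sets.
#' @param settings a [gbsa_settings()] list.
#' @param n_frames snapshots to average (evenly strided).
#' @param n_points SASA sphere points per atom.
#' @param threshold key-residue cutoff in kcal/mol (default 0.8).
#' @return data.frame with one row per receptor residue: `res_index`,
#'   `res_name`, `ele`, `vdw`, `gb`, `surf`, `total`, `key`.
#' @export
per_residue_decomposition <- function(ens, receptor, ligand,
                                      settings = gbsa_settings(),
                                      n_frames = 50, n_points = 240,
                                      threshold = 0.8) {
  top <- ens$topology
  if (is.null(top$params)) stopf("topology carries no per-atom parameters")
  if (length(intersect(receptor, ligand)) > 0) {
    stopf("receptor and ligand index sets overlap")
  }
  p <- top$params
  res_of <- top$atoms$res_index
  rec_res <- sort(unique(res_of[receptor]))
  frames <- unique(round(seq(1, n_frames(ens),
                             length.out = min(n_frames, n_frames(ens)))))
  acc <- matrix(0, length(rec_res), 4,
                dimnames = list(NULL, c("ele", "vdw", "gb", "surf")))
  pref_gb <- -(KE_COULOMB / 2) * (1 / settings$eps_in - 1 / settings$eps_solv)
  cross <- as.matrix(expand.grid(receptor, ligand))
  for (f in frames) {
    co <- frame_coords(ens, f)
    r <- pair_distances(co, cross)
    i <- cross[, 1]; j <- cross[, 2]
    qq <- p$charge[i] * p$charge[j]
    ele <- ifelse(qq == 0, 0, KE_COULOMB * qq / (settings$eps_in * r))
    sij <- (p$sigma[i] + p$sigma[j]) / 2
    eij <- sqrt(p$epsilon[i] * p$epsilon[j])
    sr6 <- (sij / r)^6
    vdw <- 4 * eij * (sr6^2 - sr6)
    aa <- p$born_radius[i] * p$born_radius[j]
    fgb <- sqrt(r^2 + aa * exp(-r^2 / (4 * aa)))
    gb_pair <- pref_gb * 2 * qq / fgb      # full cross pair term
    # SASA difference shares per receptor atom
    idx_c <- sort(c(receptor, ligand))
    sc <- sasa(co[idx_c, , drop = FALSE],
               radii = p$sigma[idx_c] * 2^(1 / 6) / 2, n_points = n_points)
    sr <- sasa(co[receptor, , drop = FALSE],
               radii = p$sigma[receptor] * 2^(1 / 6) / 2, n_points = n_points)
    datom <- numeric(n_atoms(top))
    datom[idx_c] <- sc$per_atom
    datom[receptor] <- datom[receptor] - sr$per_atom
    for (k in seq_along(rec_res)) {
      sel <- i %in% which(res_of == rec_res[k])
      acc[k, "ele"] <- acc[k, "ele"] + sum(ele[sel])
      acc[k, "vdw"] <- acc[k, "vdw"] + sum(vdw[sel])
      acc[k, "gb"] <- acc[k, "gb"] + 0.5 * sum(gb_pair[sel])
      res_atoms <- intersect(which(res_of == rec_res[k]), receptor)
      acc[k, "surf"] <- acc[k, "surf"] +
        settings$gamma * sum(datom[res_atoms])
    }
  }
  acc <- acc / length(frames)
  out <- data.frame(
    res_index = rec_res,
    res_name = top$residues$res_name[match(rec_res, top$residues$res_index)],
    ele = acc[, "ele"], vdw = acc[, "vdw"], gb = acc[, "gb"],
    surf = acc[, "surf"],
    total = rowSums(acc)
  )
  out$key <- out$total <= -threshold
  out
}

#' Quasi-harmonic (Schlitter) configurational entropy
#'
#' Upper-bound entropy from the mass-weighted coordinate covariance:
#' S <= (kB/2) ln det(1 + (kB T e^2 / hbar^2) M^(1/2) C M^(1/2)),
#' evaluated over the eigenvalues of the mass-weighted covariance
#' (population normalization, matching the PCA convention). Returns the
#' -T S bookkeeping term with method tag "quasiharmonic-schlitter".
#'
#' @param ens a `conformational_ensemble` (>= 2 frames).
#' @param selection atom selection (default all atoms).
#' @param temperature Kelvin.
#' @param superpose remove rigid-body motion first.
#' @return -T*S in kcal/mol, with attributes `entropy` (kcal/mol/K) and
#'   `method`.
#' @export
quasiharmonic_entropy <- function(ens, selection = "all", temperature = 300,
                                  superpose = TRUE) {
  if (n_frames(ens) < 2) stopf("entropy estimate requires >= 2 frames")
  sel <- select_atoms(ens$topology, selection)
  masses <- if (!is.null(ens$topology$params)) {
    ens$topology$params$mass[sel]
  } else rep(1, length(sel))
  xyz <- if (superpose) superpose_to_mean(ens, sel)$xyz else ens$xyz
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  Q <- xyz[, cols, drop = FALSE]
  Qc <- sweep(Q, 2, colMeans(Q))
  w <- sqrt(rep(masses, each = 3))
  Qw <- sweep(Qc, 2, w, "*")
  C <- crossprod(Qw) / nrow(Qw)      # amu Angstrom^2
  lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-12]   # eigenvalue floor
  # (kB T e^2 / hbar^2) in 1 / (amu Angstrom^2):
  #   kB[J/K] * e^2 * amu[kg] * 1e-20[m^2/A^2] / hbar[Js]^2
  cst <- 1.380649e-23 * exp(2) * 1.66053906660e-27 * 1e-20 /
    (1.054571817e-34)^2
  S <- 0.5 * KB_KCAL * sum(log1p(cst * temperature * lambda))
  out <- -temperature * S
  attr(out, "entropy") <- S
  attr(out, "method") <- "quasiharmonic-schlitter"
  out
}

#' Experimental binding free energy from IC50
#'
#' Delta G_exp = R T ln(IC50 / 1 M) with R = 0.0019872 kcal/(mol K):
#' the standard dissociation-constant relation, negative for sub-molar
#' IC50 so that stronger inhibition means more favorable binding
#' (IC50 = 10 nM at 300 K gives -10.98 kcal/mol; a 10-fold IC50
#' decrease is worth -RT ln 10 = -1.37 kcal/mol).
#'
#' @param ic50 inhibitory concentration, mol/L (> 0).
#' @param temperature Kelvin.
#' @return kcal/mol.
#' @export
dg_from_ic50 <- function(ic50, temperature = 300) {
  if (any(ic50 <= 0)) stopf("IC50 must be positive")
  KB_KCAL * temperature * log(ic50)
}
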
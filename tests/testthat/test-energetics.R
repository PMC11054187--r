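test_that("Coulomb term reproduces closed forms and linearity", {
  co <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  expect_equal(coulomb_energy(co, c(1, 1)), 100.0, tolerance = 1e-9)
  expect_equal(coulomb_energy(co, c(1, 0)), 0)
  expect_equal(coulomb_energy(co, c(2, 1)), 200.0, tolerance = 1e-9)
  expect_equal(coulomb_energy(co, c(1, 1), eps_in = 2), 50.0,
               tolerance = 1e-9)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "coincident")
})

test_that("Lennard-Jones term has the textbook minimum, root and decay", {
  s <- 3.4; e <- 0.21
  at <- function(r) rbind(c(0, 0, 0), c(r, 0, 0))
  expect_equal(lj_energy(at(2^(1 / 6) * s), c(s, s), c(e, e)), -e,
               tolerance = 1e-12)
  expect_equal(lj_energy(at(s), c(s, s), c(e, e)), 0, tolerance = 1e-12)
  expect_lt(abs(lj_energy(at(10 * s), c(s, s), c(e, e))), 1e-5 * e)
  # Lorentz-Berthelot combination
  expect_equal(lj_energy(at(2^(1 / 6) * 3.0), c(2.5, 3.5), c(0.1, 0.4)),
               -sqrt(0.1 * 0.4), tolerance = 1e-12)
})

test_that("generalized Born reduces to the Born ion and vanishing limits", {
  born <- gb_energy(matrix(0, 1, 3), charges = 1, radii = 2,
                    eps_in = 1, eps_solv = 78.5)
  expect_equal(born, -(332.0636 / 2) * (1 - 1 / 78.5) / 2, tolerance = 1e-6)
  expect_equal(gb_energy(matrix(0, 2, 3), c(0, 0), c(2, 2)), 0)
  expect_equal(gb_energy(matrix(rnorm(6), 2, 3), c(1, -1), c(2, 2),
                         eps_in = 78.5, eps_solv = 78.5 + 1e-12), 0,
               tolerance = 1e-9)
  expect_error(gb_energy(matrix(0, 1, 3), 1, 0), "Born radius")
})

test_that("nonpolar term is the printed linear law", {
  expect_equal(nonpolar_energy(100), 0.72)
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(200), 2 * nonpolar_energy(100))
  expect_equal(nonpolar_energy(100, gamma = 0.005, beta = 1), 1.5)
})

test_that("single-trajectory deltas equal receptor-ligand cross terms", {
  for (seed in 1:3) {
    sys <- generate_ligand_system(seed = seed)
    co <- frame_coords(sys$ensemble, 1)
    p <- sys$topology$params
    comp <- snapshot_components(co, sys$topology, sys$receptor_atoms,
                                sys$ligand_atoms)
    cross <- as.matrix(expand.grid(sys$receptor_atoms, sys$ligand_atoms))
    ele_direct <- coulomb_energy(co, p$charge, pairs = cross)
    vdw_direct <- lj_energy(co, p$sigma, p$epsilon, pairs = cross)
    expect_equal(comp$dEele, ele_direct, tolerance = 1e-9)
    expect_equal(comp$dEvdw, vdw_direct, tolerance = 1e-9)
    # the enthalpy identity holds exactly
    expect_equal(comp$dH, comp$dEele + comp$dEvdw + comp$dGgb + comp$dGsurf,
                 tolerance = 1e-9)
    expect_equal(comp$dH, comp$dGpol + comp$dGhydro, tolerance = 1e-9)
  }
})

test_that("components vanish in the separated limit", {
  sys <- generate_ligand_system(seed = 2)
  co <- frame_coords(sys$ensemble, 1)
  co[sys$ligand_atoms, 1] <- co[sys$ligand_atoms, 1] + 5e4
  comp <- snapshot_components(co, sys$topology, sys$receptor_atoms,
                              sys$ligand_atoms)
  expect_lt(abs(comp$dEele), 1e-2)
  expect_lt(abs(comp$dEvdw), 1e-6)
  expect_lt(abs(comp$dGgb), 1e-2)
  expect_lt(abs(comp$dGsurf), 1e-6)
  expect_error(snapshot_components(co, sys$topology, c(1, 2), c(2, 3)),
               "overlap")
})

test_that("a hand-computed three-bead complex is reproduced", {
  # receptor: two beads at (0,0,0) q=+0.2 and (4,0,0) q=-0.3
  # ligand: one bead at (0,3,0) q=+0.5; eps_solv -> eps_in disables GB
  top <- topology(atom_name = c("CA", "CA", "L1"), element = c("C", "C", "C"),
                  res_index = c(1, 2, 3),
                  res_name = c("GLY", "GLY", "LIG"),
                  params = data.frame(charge = c(0.2, -0.3, 0.5),
                                      sigma = c(3.4, 3.4, 3.0),
                                      epsilon = c(0.1, 0.1, 0.2),
                                      born_radius = c(1.7, 1.7, 1.6),
                                      mass = rep(12, 3)))
  co <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0))
  settings <- gbsa_settings(eps_in = 1, eps_solv = 1 + 1e-9)
  comp <- snapshot_components(co, top, receptor = c(1, 2), ligand = 3,
                              settings = settings, n_points = 960)
  r13 <- 3; r23 <- 5
  ele_hand <- 332.0636 * (0.2 * 0.5 / r13 + (-0.3) * 0.5 / r23)
  lj_pair <- function(r, s1, s2, e1, e2) {
    s <- (s1 + s2) / 2; e <- sqrt(e1 * e2)
    4 * e * ((s / r)^12 - (s / r)^6)
  }
  vdw_hand <- lj_pair(r13, 3.4, 3.0, 0.1, 0.2) + lj_pair(r23, 3.4, 3.0, 0.1, 0.2)
  expect_equal(comp$dEele, ele_hand, tolerance = 1e-9)
  expect_equal(comp$dEvdw, vdw_hand, tolerance = 1e-9)
  expect_equal(comp$dGgb, 0, tolerance = 1e-6)
  expect_lt(comp$dGsurf, 0)  # burying surface is favorable
})

test_that("aggregation reproduces the published component arithmetic", {
  # BRD4 systems: printed dGbind and dGpol recovered exactly
  for (inh in c("H1B", "JQ1", "TVU")) {
    row <- reference_energy_components()
    row <- row[row$system == "BRD4" & row$inhibitor == inh, ]
    b <- reference_binding_free_energy("BRD4", inh)
    expect_equal(b$dGbind, row$dGbind_printed, tolerance = 1e-9,
                 label = sprintf("BRD4-%s dGbind", inh))
    expect_equal(b$dGpol, row$dGpol_printed, tolerance = 1e-9)
  }
  # BRD9: JQ1 exact; H1B and TVU match within the 0.01 kcal/mol
  # round-off of the two-decimal inputs
  bj <- reference_binding_free_energy("BRD9", "JQ1")
  expect_equal(bj$dGbind, -11.94, tolerance = 1e-9)
  expect_equal(bj$dGpol, 12.77, tolerance = 1e-9)
  bh <- reference_binding_free_energy("BRD9", "H1B")
  expect_lt(abs(bh$dGbind - (-21.38)), 0.010001)
  bt <- reference_binding_free_energy("BRD9", "TVU")
  expect_lt(abs(bt$dGbind - (-23.17)), 0.010001)
  expect_equal(bt$dGpol, 10.60, tolerance = 1e-9)
  # all-zero components give zero
  z <- aggregate_binding_free_energy(
    c(dEele = 0, dEvdw = 0, dGgb = 0, dGsurf = 0), neg_TdS = 0)
  expect_equal(z$dGbind, 0)
})

test_that("cross-system deltas match the published comparisons", {
  deltas <- lapply(c("H1B", "JQ1", "TVU"), function(inh) {
    compare_systems(reference_binding_free_energy("BRD4", inh),
                    reference_binding_free_energy("BRD9", inh))
  })
  names(deltas) <- c("H1B", "JQ1", "TVU")
  # van der Waals strengthened by 6.96 / 11.86 / 5.67 kcal/mol
  expect_equal(-vapply(deltas, `[[`, numeric(1), "dEvdw"),
               c(H1B = 6.96, JQ1 = 11.86, TVU = 5.67), tolerance = 1e-9)
  # nonpolar solvation enhanced by 0.59 / 1.08 / 0.36
  expect_equal(-vapply(deltas, `[[`, numeric(1), "dGsurf"),
               c(H1B = 0.59, JQ1 = 1.08, TVU = 0.36), tolerance = 1e-9)
  # favorable-force sums strengthened by 7.55 / 12.94 / 6.03
  expect_equal(-vapply(deltas, `[[`, numeric(1), "favorable"),
               c(H1B = 7.55, JQ1 = 12.94, TVU = 6.03), tolerance = 1e-9)
  # entropy penalties increased by 6.46 / 5.23 / 3.24
  expect_equal(vapply(deltas, `[[`, numeric(1), "neg_TdS"),
               c(H1B = 6.46, JQ1 = 5.23, TVU = 3.24), tolerance = 1e-9)
  # binding enhanced by 5.29 / 5.56 / 6.32 (H1B and TVU inherit the
  # 0.01 input-rounding offset of their dGbind values)
  enh <- -vapply(deltas, `[[`, numeric(1), "dGbind")
  expect_equal(unname(enh["JQ1"]), 5.56, tolerance = 1e-9)
  expect_lt(abs(enh[["H1B"]] - 5.29), 0.010001)
  expect_lt(abs(enh[["TVU"]] - 6.32), 0.010001)
  # self-comparison vanishes; comparison is antisymmetric
  a <- reference_binding_free_energy("BRD4", "H1B")
  expect_true(all(abs(compare_systems(a, a)) < 1e-12))
  b <- reference_binding_free_energy("BRD9", "H1B")
  expect_equal(compare_systems(a, b), -compare_systems(b, a))
})

test_that("per-residue decomposition conserves totals and finds hot spots", {
  sys <- generate_ligand_system(seed = 6, salt_bridge = TRUE)
  dec <- per_residue_decomposition(sys$ensemble, sys$receptor_atoms,
                                   sys$ligand_atoms, n_frames = 1)
  comp <- snapshot_components(frame_coords(sys$ensemble, 1), sys$topology,
                              sys$receptor_atoms, sys$ligand_atoms)
  expect_equal(sum(dec$ele) + sum(dec$vdw), comp$dEele + comp$dEvdw,
               tolerance = 1e-6)
  # the planted salt-bridge residue dominates and is flagged key
  salt <- which.min(dec$ele)
  expect_equal(which.min(dec$total), salt)
  expect_true(dec$key[salt])
  expect_equal(dec$total[salt], min(dec$total))
  # distant uncharged residues contribute nothing and are not key
  far <- which(abs(dec$total) < 0.05)
  expect_true(all(!dec$key[far]))
})

test_that("Schlitter entropy matches its closed form and monotonicity", {
  top1 <- bead_top(1)
  same <- conformational_ensemble(top1, matrix(0, 5, 3))
  s0 <- quasiharmonic_entropy(same, superpose = FALSE)
  expect_equal(as.numeric(s0), 0, tolerance = 1e-12)
  expect_equal(attr(s0, "method"), "quasiharmonic-schlitter")
  # 1-D harmonic fluctuation of known variance
  set.seed(4)
  xs <- rnorm(400, sd = 0.5)
  ens <- conformational_ensemble(top1, cbind(xs, 0, 0))
  got <- quasiharmonic_entropy(ens, superpose = FALSE, temperature = 300)
  v <- mean((xs - mean(xs))^2)
  cst <- 1.380649e-23 * exp(2) * 1.66053906660e-27 * 1e-20 /
    (1.054571817e-34)^2
  expected <- -300 * 0.5 * 0.0019872 * log1p(cst * 300 * 12.011 * v)
  expect_equal(as.numeric(got), expected, tolerance = 1e-6)
  # broader fluctuations mean more entropy (more negative -T S)
  wide <- conformational_ensemble(top1, cbind(2 * xs, 0, 0))
  expect_lt(as.numeric(quasiharmonic_entropy(wide, superpose = FALSE)),
            as.numeric(got))
})

test_that("IC50 conversion gives the conventional binding free energy", {
  expect_equal(dg_from_ic50(1, 300), 0)
  expect_equal(dg_from_ic50(1e-8, 300), 0.0019872 * 300 * log(1e-8),
               tolerance = 1e-12)
  expect_equal(dg_from_ic50(1e-8, 300), -10.98, tolerance = 1e-3)
  # a 10-fold affinity gain is worth -RT ln 10 = -1.37 kcal/mol at 300 K
  expect_equal(dg_from_ic50(1e-8, 300) - dg_from_ic50(1e-7, 300),
               -0.0019872 * 300 * log(10), tolerance = 1e-12)
  expect_error(dg_from_ic50(0), "positive")
})
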
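test_that("PCA model satisfies its structural invariants", {
  set.seed(31)
  top <- bead_top(6)
  ref <- matrix(rnorm(18, sd = 6), 6, 3)
  ens <- ens_from_frames(top, lapply(1:30, function(f) {
    ref + matrix(rnorm(18, sd = 0.5), 6, 3)
  }))
  m <- build_pca(ens)
  expect_true(all(m$eigenvalues >= 0))
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(crossprod(m$eigenvectors), diag(18), tolerance = 1e-8)
  expect_equal(sum(m$eigenvalues), sum(diag(m$covariance)),
               tolerance = 1e-6 * sum(m$eigenvalues))
  expect_equal(m$covariance, t(m$covariance), tolerance = 1e-12)
  # identical frames: zero covariance
  same <- ens_from_frames(top, rep(list(ref), 4))
  expect_true(all(build_pca(same)$eigenvalues < 1e-12))
  expect_error(build_pca(subset_frames(ens, 1)), "2 frames")
})

test_that("eigenvalues match the SVD oracle on tiny problems", {
  for (seed in 1:4) {
    set.seed(seed)
    na <- sample(3:5, 1); nf <- sample(4:10, 1)
    top <- bead_top(na)
    xyz <- matrix(rnorm(nf * 3 * na, sd = 2), nf)
    ens <- conformational_ensemble(top, xyz)
    m <- build_pca(ens, superpose = FALSE)
    # oracle: singular values of the centered coordinate matrix,
    # population convention lambda_k = s_k^2 / F
    Qc <- sweep(xyz, 2, colMeans(xyz))
    s <- svd(Qc)$d
    lam_oracle <- sort(s^2 / nf, decreasing = TRUE)
    lam <- m$eigenvalues[seq_along(lam_oracle)]
    expect_equal(lam, lam_oracle, tolerance = 1e-8)
  }
})

test_that("a single free coordinate concentrates in one eigenvalue", {
  top <- bead_top(2)
  xs <- c(0, 1, 2, 3, 4)
  xyz <- cbind(xs, 0, 0, 5, 0, 0)   # atom 1 slides along x, atom 2 fixed
  ens <- conformational_ensemble(top, xyz)
  m <- build_pca(ens, superpose = FALSE)
  expect_equal(m$eigenvalues[1], mean((xs - mean(xs))^2), tolerance = 1e-10)
  expect_true(all(m$eigenvalues[-1] < 1e-12))
})

test_that("variance fractions report percentages that sum correctly", {
  top <- bead_top(2)
  set.seed(2)
  ens <- conformational_ensemble(top, matrix(rnorm(60), 10))
  m <- build_pca(ens, superpose = FALSE)
  # synthetic eigenvalue check on arithmetic
  m$eigenvalues <- c(4, 3, 2, 1, 0, 0)
  fr <- variance_fractions(m, 6)
  expect_equal(fr$cumulative[2], 70)
  expect_equal(fr$cumulative[6], 100)
  expect_equal(sum(fr$fraction), 100)
  expect_error(variance_fractions(m, 7), "exceeds")
})

test_that("projections satisfy the PCA identities", {
  set.seed(5)
  top <- bead_top(4)
  ens <- conformational_ensemble(top, matrix(rnorm(40 * 12, sd = 2), 40))
  m <- build_pca(ens, superpose = FALSE)
  proj <- project_ensemble(ens, m, k = 12, superpose = FALSE)
  expect_equal(colMeans(proj), rep(0, 12), tolerance = 1e-10)
  # column variances (population) equal the eigenvalues
  vars <- colMeans(sweep(proj, 2, colMeans(proj))^2)
  nz <- m$eigenvalues > 1e-10
  expect_equal(vars[nz], m$eigenvalues[nz],
               tolerance = 1e-6)
  # full reconstruction reproduces the centered coordinates
  rec <- proj %*% t(m$eigenvectors)
  Qc <- sweep(ens$xyz, 2, m$mean)
  expect_equal(rec, Qc, tolerance = 1e-6, ignore_attr = TRUE)
  # projecting the mean structure gives the origin
  mean_ens <- conformational_ensemble(top, matrix(m$mean, nrow = 1))
  expect_equal(as.numeric(project_ensemble(mean_ens, m, 2, superpose = FALSE)),
               c(0, 0), tolerance = 1e-10)
})

test_that("superposition removes rigid tumbling variance", {
  set.seed(9)
  top <- bead_top(5)
  body <- matrix(rnorm(15, sd = 4), 5, 3)
  frames <- lapply(1:25, function(f) {
    t(rot_z(runif(1, 0, 2 * pi)) %*% t(body)) +
      matrix(runif(3, -20, 20), 5, 3, byrow = TRUE)
  })
  ens <- ens_from_frames(top, frames)
  raw <- build_pca(ens, superpose = FALSE)
  fit <- build_pca(ens, superpose = TRUE)
  expect_lt(sum(fit$eigenvalues), 0.01 * sum(raw$eigenvalues))
})

test_that("planted two-cluster structure is recovered by the top mode", {
  spec <- synthetic_spec(25, list(c(3, 15), c(8, 20)), sigma = 0.3,
                         frames_per_class = 100, seed = 6)
  refs <- generate_reference_structures(spec)$references
  eA <- sample_ensemble(refs[[1]], 100, 0.3, seed = 1)
  eB <- sample_ensemble(refs[[2]], 100, 0.3, seed = 2)
  # two Gaussian clouds along the A-B interpolation axis
  mid <- (eA$xyz + eB$xyz) / 2
  shift <- (eB$xyz[1, ] - eA$xyz[1, ])
  xyzA <- sweep(matrix(rnorm(100 * ncol(mid), sd = 0.3), 100), 2,
                eA$xyz[1, ], "+")
  xyzB <- sweep(matrix(rnorm(100 * ncol(mid), sd = 0.3), 100), 2,
                eB$xyz[1, ], "+")
  ens <- conformational_ensemble(refs[[1]]$topology, rbind(xyzA, xyzB))
  m <- build_pca(ens, superpose = FALSE)
  axis <- shift / sqrt(sum(shift^2))
  cosang <- abs(sum(m$eigenvectors[, 1] * axis))
  expect_gt(cosang, 0.95)
})

test_that("Boltzmann inversion matches the two-bin closed form", {
  proj <- cbind(c(rep(0.25, 100), rep(0.75, 10)), rep(0.5, 110))
  fel <- free_energy_landscape(proj, bins = 2, temperature = 300)
  expect_equal(sum(fel$prob), 1)
  g <- sort(fel$free_energy[fel$populated])
  expect_equal(g[1], 0)
  expect_equal(g[2] - g[1], -0.0019872 * 300 * log(10 / 100),
               tolerance = 1e-6)
  # uniform occupancy: flat landscape at zero
  set.seed(3)
  u <- cbind(rep(seq(0.05, 0.95, 0.1), each = 10),
             rep(seq(0.05, 0.95, 0.1), times = 10))
  felu <- free_energy_landscape(u, bins = 10)
  expect_true(all(abs(felu$free_energy[felu$populated]) < 1e-12))
  expect_error(free_energy_landscape(matrix(numeric(0), 0, 2)), "empty")
})

test_that("basin detection counts well-separated minima", {
  set.seed(14)
  one <- cbind(rnorm(4000, 0, 0.5), rnorm(4000, 0, 0.5))
  fel1 <- free_energy_landscape(one, bins = 30)
  b1 <- find_basins(fel1, depth_threshold = 0.7)
  expect_equal(nrow(b1), 1)
  two <- rbind(cbind(rnorm(2000, -3, 0.4), rnorm(2000, 0, 0.4)),
               cbind(rnorm(2000, 3, 0.4), rnorm(2000, 0, 0.4)))
  fel2 <- free_energy_landscape(two, bins = 30)
  b2 <- find_basins(fel2, depth_threshold = 0.7)
  expect_equal(nrow(b2), 2)
  expect_equal(min(b2$g_min), 0)
  # representative frames sit near the basin minima
  b2r <- find_basins(fel2, depth_threshold = 0.7, proj = two)
  expect_true(all(abs(abs(two[b2r$representative_frame, 1]) - 3) < 1))
  # raising the merge threshold cannot increase the count
  counts <- vapply(c(0.1, 0.5, 1.5, 5, 50), function(th) {
    nrow(find_basins(fel2, depth_threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mode displacements localize planted motion and stay normalized", {
  set.seed(18)
  top <- bead_top(40)
  ref <- matrix(rnorm(120, sd = 8), 40, 3)
  frames <- lapply(1:60, function(f) {
    m <- ref + matrix(rnorm(120, sd = 0.02), 40, 3)
    m[30:40, 1] <- m[30:40, 1] + rnorm(1, sd = 1.5)  # concerted block motion
    m
  })
  ens <- ens_from_frames(top, frames)
  m <- build_pca(ens, superpose = FALSE)
  disp <- mode_displacements(m, 1)
  expect_equal(sum(disp^2), 1, tolerance = 1e-8)
  expect_gt(min(disp[30:40]) / max(disp[1:29]), 5)
  expect_error(mode_displacements(m, 1000), "out of range")
})
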
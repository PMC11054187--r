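test_that("Kabsch superposition recovers constructed rigid motions", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 1, 3))
  # identity
  f0 <- kabsch_superpose(A, A)
  expect_equal(f0$rmsd, 0, tolerance = 1e-10)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-8)
  # pure translation
  ft <- kabsch_superpose(A + 7, A)
  expect_equal(ft$rmsd, 0, tolerance = 1e-10)
  # 37-degree rotation about z plus offset: recovered exactly
  R <- rot_z(37 * pi / 180)
  B <- t(R %*% t(A)) + matrix(c(5, -2, 1), 4, 3, byrow = TRUE)
  fr <- kabsch_superpose(B, A)
  expect_equal(fr$rmsd, 0, tolerance = 1e-10)
  expect_equal(fr$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(fr$rotation), 1, tolerance = 1e-8)
  expect_equal(crossprod(fr$rotation), diag(3), tolerance = 1e-8)
  # collinear selections are refused
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "non-collinear")
})

test_that("RMSD series matches the isotropic closed form and is invariant", {
  top <- bead_top(200)
  set.seed(7)
  ref <- matrix(rnorm(600, sd = 10), 200, 3)
  sigma <- 0.3
  frames <- lapply(1:40, function(f) ref + matrix(rnorm(600, sd = sigma), 200, 3))
  ens <- ens_from_frames(top, frames)
  rs <- rmsd_series(ens, reference = ref, selection = "calpha")
  expect_equal(mean(rs$values), sigma * sqrt(3), tolerance = 0.05)
  # self-reference at frame 1 is zero
  rs0 <- rmsd_series(ens, selection = "calpha")
  expect_equal(rs0$values[1], 0, tolerance = 1e-8)
  # global rigid motion applied to every frame changes nothing
  R <- rot_z(0.8)
  rot_frames <- lapply(frames, function(m) t(R %*% t(m)) + 3)
  rs_rot <- rmsd_series(ens_from_frames(top, rot_frames), reference = ref,
                        selection = "calpha")
  expect_equal(rs_rot$values, rs$values, tolerance = 1e-8)
})

test_that("RMSF reproduces closed forms", {
  top <- bead_top(4)
  # identical frames: zero everywhere
  same <- ens_from_frames(top, rep(list(matrix(rnorm(12), 4, 3)), 5))
  expect_true(all(rmsf(same) < 1e-12))
  expect_error(rmsf(subset_frames(same, 1)), "2 frames")
  # one atom alternating +/- d along x, superposition off: RMSF = d
  d <- 0.7
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 5))
  fr <- lapply(1:10, function(f) {
    m <- base; m[1, 1] <- m[1, 1] + d * (-1)^f; m
  })
  vals <- rmsf(ens_from_frames(top, fr), superpose = FALSE)
  expect_equal(unname(vals[1]), d, tolerance = 1e-10)
  expect_true(all(vals[-1] < 1e-12))
  # isotropic Gaussian: RMSF -> sigma sqrt(3)
  topN <- bead_top(150)
  set.seed(8)
  refN <- matrix(rnorm(450, sd = 8), 150, 3)
  ensN <- ens_from_frames(topN, lapply(1:200, function(f) {
    refN + matrix(rnorm(450, sd = 0.4), 150, 3)
  }))
  expect_equal(mean(rmsf(ensN)), 0.4 * sqrt(3), tolerance = 0.05)
})

test_that("radius of gyration matches closed forms", {
  top2 <- bead_top(2, mass = 1)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), top2), 1.0)
  expect_equal(radius_of_gyration(matrix(0, 5, 3), bead_top(5)), 0)
  # uniform ring of radius rho: RG = rho
  rho <- 3.2
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  ring <- cbind(rho * cos(th), rho * sin(th), 0)
  expect_equal(radius_of_gyration(ring, bead_top(40)), rho, tolerance = 1e-10)
  # mass weighting: all mass on one atom collapses RG to that point
  topw <- bead_top(2)
  topw$params$mass <- c(1e9, 1e-9)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), topw), 0,
               tolerance = 1e-4)
})

test_that("SASA matches sphere closed forms and is additive when separated", {
  one <- sasa(matrix(0, 1, 3), radii = 1.9, n_points = 960)
  expect_equal(one$total, 4 * pi * (1.9 + 1.4)^2, tolerance = 0.01)
  # two atoms far apart: sum of isolated areas
  two <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.9, 1.7))
  expect_equal(two$total,
               4 * pi * ((1.9 + 1.4)^2 + (1.7 + 1.4)^2), tolerance = 0.01)
  # overlapping equal spheres: exact spherical-cap closed form
  R <- 1.8 + 1.4; d <- 2.5
  exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  num <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(1.8, 1.8))$total
  expect_equal(num, exact, tolerance = 0.02 * exact)
  # moving atoms closer never increases the area
  areas <- vapply(c(6, 4, 3, 2.5, 2), function(dd) {
    sasa(rbind(c(0, 0, 0), c(dd, 0, 0)), radii = c(1.8, 1.8))$total
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(sasa(matrix(0, 1, 3)), "radii")
})

test_that("hydrogen-bond criteria follow the strict distance/angle rules", {
  top <- topology(atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
                  res_index = c(1, 1, 2), res_name = c("ASN", "ASN", "LIG"))
  geo <- function(dda, angle_deg) {
    # donor at origin, hydrogen 1.0 A along x; acceptor placed to give
    # the requested D..A distance and D-H..A angle at the hydrogen
    ang <- angle_deg * pi / 180
    H <- c(1, 0, 0)
    # direction from H making angle `ang` with (D - H) = (-1, 0, 0)
    u <- c(cos(ang) * -1, sin(ang), 0)
    # choose t so |D - A| = dda with A = H + t u  (solve quadratic)
    b <- 2 * sum(H * u); cc <- sum(H^2) - dda^2
    t <- (-b + sqrt(b^2 - 4 * cc)) / 2
    A <- H + t * u
    rbind(c(0, 0, 0), H, A)
  }
  ens <- function(dda, ang) conformational_ensemble(top, matrix(as.numeric(t(geo(dda, ang))), nrow = 1))
  spec <- hbond_spec(1, 2, 3)
  present <- function(dda, ang) {
    detect_hbonds(ens(dda, ang), spec)$occupancy == 100
  }
  expect_true(present(2.9, 160))
  expect_false(present(3.6, 160))    # distance beyond the < 3.5 bound
  expect_false(present(3.5, 160))    # strict inequality at the boundary
  expect_false(present(2.9, 110))    # angle below the > 120 bound
  expect_false(present(2.9, 120))    # strict inequality at the boundary
  expect_true(present(3.4, 121))
})

test_that("occupancy is the exact percentage of presence frames", {
  top <- topology(atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
                  res_index = c(1, 1, 2), res_name = c("ASN", "ASN", "LIG"))
  close_f <- c(0, 0, 0, 1, 0, 0, 1.9, 0.6, 0)   # bound geometry
  far_f <- c(0, 0, 0, 1, 0, 0, 5, 0, 0)          # broken geometry
  xyz <- rbind(matrix(rep(close_f, 87), ncol = 9, byrow = TRUE),
               matrix(rep(far_f, 13), ncol = 9, byrow = TRUE))
  ens <- conformational_ensemble(top, xyz)
  out <- detect_hbonds(ens, hbond_spec(1, 2, 3))
  expect_equal(out$occupancy, 87.0)
  expect_true(out$occupancy >= 0 && out$occupancy <= 100)
  # tightening the distance cutoff can only reduce occupancy
  occ <- vapply(c(3.5, 3.0, 2.4, 2.0), function(dc) {
    detect_hbonds(ens, hbond_spec(1, 2, 3), dist_cutoff = dc)$occupancy
  }, numeric(1))
  expect_true(all(diff(occ) <= 1e-9))
  expect_error(detect_hbonds(ens, hbond_spec(1, 2, 9)), "outside")
})

test_that("series summaries find the planted distribution modes", {
  set.seed(12)
  vals <- c(rnorm(2000, 1.7, 0.1), rnorm(2000, 2.3, 0.1))
  sm <- series_summary(vals, n_bins = 50)
  expect_equal(sum(sm$counts), 4000)
  top2 <- sm$peaks[order(-sm$peak_heights)][1:2]
  expect_equal(sort(top2), c(1.7, 2.3), tolerance = 0.1)
  # constant series: a single peak at the constant
  const <- series_summary(rep(4.2, 10))
  expect_equal(const$peaks, 4.2)
  expect_equal(sum(const$counts), 10)
})
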
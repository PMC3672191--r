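test_that("MSD vanishes for static frames and is ballistic under drift", {
  st <- toy_trajectory(50, 3, "static", seed = 1)
  expect_true(all(msd(st)$msd_nm2 == 0))
  # uniform drift v: MSD(dt) = |v|^2 dt^2 exactly
  v <- c(0.01, -0.02, 0.005)  # nm/ps
  nf <- 60
  co <- array(0, c(nf, 2, 3))
  base <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  for (f in seq_len(nf))
    co[f, , ] <- sweep(base, 2, v * (f - 1), "+")
  tr <- md_trajectory(seq_len(nf) - 1, co)
  mc <- msd(tr, max_lag_frac = 0.5)
  expect_equal(mc$msd_nm2, sum(v^2) * mc$lag_ps^2, tolerance = 1e-12)
  expect_error(msd(tr, selection = rep(FALSE, 2)), "no atoms")
})

test_that("Einstein relation returns the exact slope of a clean line", {
  D <- 80  # um^2/s -> 8e-5 nm^2/ps
  lag <- 1:100
  curve <- tibble::tibble(lag_ps = lag, msd_nm2 = 6 * D * 1e-6 * lag)
  est <- einstein_diffusion(curve)
  expect_equal(est$D_um2_s, 80, tolerance = 1e-10)
  expect_equal(est$intercept_nm2, 0, tolerance = 1e-12)
  expect_error(einstein_diffusion(curve[1:4, ]), "5")
  expect_error(einstein_diffusion(curve, fit_window = c(0.9, 0.1)),
               "increasing")
})

test_that("Einstein-relation estimates recover the generator diffusion", {
  # smaller-scale version of the module recovery contract
  ests <- vapply(1:10, function(s) {
    tr <- toy_trajectory(5000, 2, "diffusive",
                         params = list(D_um2_s = 80), seed = 40 + s)
    einstein_diffusion(msd(tr, max_lag_frac = 0.02))$D_um2_s
  }, numeric(1))
  expect_lt(abs(mean(ests) - 80) / 80, 0.10)
})

test_that("Kabsch RMSD is symmetric, rotation-invariant and exact on toys", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  # rigid rotation + translation removed by superposition
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% R + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  expect_lt(kabsch_rmsd(a, b), 1e-10)
  expect_gt(kabsch_rmsd(a, b, superpose = FALSE), 1)
  # hand value: one of three atoms displaced by 0.3 nm, no superposition
  p <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  q <- p
  q[1, 3] <- 0.3
  expect_equal(kabsch_rmsd(p, q, superpose = FALSE), 0.3 / sqrt(3),
               tolerance = 1e-12)
  # symmetry
  set.seed(5)
  x <- matrix(rnorm(24), 8, 3)
  y <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_rmsd(x, y), kabsch_rmsd(y, x), tolerance = 1e-12)
  expect_error(kabsch_rmsd(x, y[1:5, ]), "matched")
})

test_that("radius of gyration matches hand values and is translation-invariant", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 0.2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 0.1, tolerance = 1e-12)
  set.seed(6)
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(radius_of_gyration(m + 5), radius_of_gyration(m),
               tolerance = 1e-12)
  # per-frame table for a trajectory
  st <- toy_trajectory(5, 4, "static", seed = 7)
  rg <- radius_of_gyration(st)
  expect_equal(nrow(rg), 5)
  expect_equal(length(unique(round(rg$rg_nm, 12))), 1L)
})

test_that("Daura clustering matches hand enumeration on the scalar surrogate", {
  x <- c(0, 0.1, 0.2, 1.0, 1.05)
  dm <- abs(outer(x, x, "-"))
  cl <- daura_from_dist(dm, 0.25)
  expect_equal(cluster_sets(cl), list(c(1, 2, 3), c(4, 5)))
  expect_equal(cl$centers[1], 1L)  # tie among {1,2,3} broken to frame 1
  expect_equal(cl$sizes, c(3L, 2L))
  expect_equal(sum(cl$sizes), 5L)
  # every centre belongs to its own cluster
  expect_true(all(cl$assignments[cl$centers] == seq_along(cl$centers)))
})

test_that("Daura clustering agrees with a brute-force oracle", {
  set.seed(8)
  for (i in 1:15) {
    nf <- sample(4:10, 1)
    pts <- matrix(runif(nf * 2), nf, 2)
    dm <- as.matrix(stats::dist(pts))
    cutoff <- runif(1, 0.1, 0.6)
    cl <- daura_from_dist(dm, cutoff)
    oracle <- brute_daura(dm, cutoff)
    expect_equal(cluster_sets(cl), oracle$clusters)
    expect_equal(cl$centers, oracle$centers)
  }
})

test_that("Daura clustering handles degenerate cutoffs and reordering", {
  st <- toy_trajectory(8, 5, "static", seed = 9)
  cl <- daura_cluster(st, 0.25)
  expect_equal(cl$sizes, 8L)
  # cutoff 0 on distinct frames: one cluster per frame
  ts <- toy_trajectory(6, 5, "two-state",
                       params = list(fraction = 0.5, jitter_nm = 0.05),
                       seed = 10)
  cl0 <- daura_cluster(ts, 0)
  expect_equal(length(cl0$sizes), 6L)
  # frame reordering changes labels only, not the partition
  dm <- rmsd_matrix(ts)
  perm <- c(4, 1, 6, 2, 5, 3)
  cl_a <- daura_from_dist(dm, 0.3)
  cl_b <- daura_from_dist(dm[perm, perm], 0.3)
  sets_b <- lapply(cluster_sets(cl_b), function(s) sort(perm[s]))
  expect_setequal(cluster_sets(cl_a), sets_b)
})

test_that("PCA conserves variance, stays orthonormal and reconstructs", {
  tr <- toy_trajectory(40, 6, "two-state",
                       params = list(fraction = 0.25, jitter_nm = 0.02),
                       seed = 11)
  pc <- pca_ca(tr)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= -1e-12))
  # orthonormal modes
  k <- ncol(pc$eigenvectors)
  expect_equal(crossprod(pc$eigenvectors), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # projections centred and variance-conserving
  expect_lt(max(abs(colMeans(pc$projections))), 1e-10)
  expect_equal(sum(pc$eigenvalues),
               sum(apply(pc$projections, 2, stats::var)), tolerance = 1e-10)
  # back-transform with all modes reproduces the superposed coordinates
  X_rec <- sweep(pc$projections %*% t(pc$eigenvectors), 2, pc$mean_coords, "+")
  expect_lt(max(abs(X_rec - pc$aligned)), 1e-8)
  expect_error(pca_ca(toy_trajectory(2, 4, "static")), "three frames")
})

test_that("planar motion yields rank-deficient covariance", {
  # atoms jitter in the xy plane only; after superposition, out-of-plane
  # variance is numerically zero
  nf <- 30
  na <- 5
  set.seed(12)
  base <- cbind(matrix(rnorm(na * 2), na, 2), 0)
  co <- array(0, c(nf, na, 3))
  for (f in seq_len(nf))
    co[f, , ] <- base + cbind(matrix(rnorm(na * 2, sd = 0.05), na, 2), 0)
  tr <- md_trajectory(seq_len(nf), co)
  pc <- pca_ca(tr, selection = "all")
  tot <- sum(pc$eigenvalues)
  # modes beyond 2*na - 3 in-plane dof carry ~ no variance; simply check the
  # trailing third of the spectrum
  tail_frac <- sum(utils::tail(pc$eigenvalues, na)) / tot
  expect_lt(tail_frac, 1e-10)
})

test_that("PC1 separates the two planted states", {
  tr <- toy_trajectory(100, 6, "two-state",
                       params = list(fraction = 0.1, jitter_nm = 0.01),
                       seed = 13)
  pc <- pca_ca(tr)
  km <- stats::kmeans(pc$projections[, 1], centers = 2, nstart = 5)
  expect_setequal(km$size, c(90, 10))
})

test_that("free-energy landscape normalises to the most occupied bin", {
  # uniform occupancy: exactly one point per bin -> dG = 0 everywhere
  nb <- 8
  mids <- seq(0.5, nb - 0.5)
  grid <- expand.grid(p1 = mids, p2 = mids)
  fel <- free_energy_landscape(grid$p1, grid$p2, n_bins = nb)
  expect_true(all(fel$delta_g_kT == 0))
  # 90/10 two-state: gap is ln 9
  p1 <- c(rep(0, 90), rep(1, 10))
  fel2 <- free_energy_landscape(p1, p1, n_bins = 4)
  occ <- fel2$delta_g_kT[!is.na(fel2$delta_g_kT)]
  expect_equal(sort(occ), c(0, log(9)), tolerance = 1e-12)
  # most probable bin is the zero reference; empty bins are NA not capped
  expect_equal(min(occ), 0)
  expect_true(any(is.na(fel2$delta_g_kT)))
  expect_equal(sum(fel2$count), 100L)
  expect_error(free_energy_landscape(rep(1, 5), rep(1, 5)), "Degenerate")
  expect_error(free_energy_landscape(1:5, 1:4), "same length")
})

test_that("trajectory container and XYZ round trip preserve data", {
  tr <- toy_trajectory(7, 4, "diffusive", seed = 14)
  td <- tidy(tr)
  expect_equal(nrow(td), 7 * 4)
  expect_equal(td$x[td$frame == 3], tr$coords[3, , 1])
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, path)
  back <- read_xyz(path)
  expect_equal(back$coords, tr$coords, tolerance = 1e-9)
  expect_equal(back$times_ps, tr$times_ps)
  expect_equal(back$atom_labels, tr$atom_labels)
  # angstrom flag rescales
  write_xyz(tr, path, unit = "angstrom")
  back_a <- read_xyz(path, unit = "angstrom")
  expect_equal(back_a$coords, tr$coords, tolerance = 1e-9)
  expect_error(md_trajectory(c(1, 1), array(0, c(2, 2, 3))), "increasing")
})
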
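test_that("lipid features encode position and unit orientation", {
  coords <- rbind(c(0, 0, 0), c(0, 0, 2))
  f <- particle_frame(coords, c(1, 1), c(1L, 1L), rep("fatty_acid", 2),
                      component = c("PA", "PA"),
                      surfactants = data.frame(molecule_id = 1L,
                                               head_index = 1L,
                                               tail_index = 2L))
  fe <- lipid_features(f, w = 10)
  expect_equal(c(fe$vx, fe$vy, fe$vz), c(0, 0, 1))
  expect_equal(c(fe$x, fe$y, fe$z), c(0, 0, 1))   # unit-mass centroid

  # w = 0 reduces features to pure positions
  X0 <- feature_matrix(lipid_features(f, w = 0))
  expect_equal(unname(X0[1, 4:6]), c(0, 0, 0))

  # antiparallel lipids at the same position are 2w apart
  coords2 <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 2), c(0, 0, 0))
  f2 <- particle_frame(coords2, rep(1, 4), c(1L, 1L, 2L, 2L),
                       rep("fatty_acid", 4), component = rep("PA", 4),
                       surfactants = data.frame(molecule_id = 1:2,
                                                head_index = c(1L, 3L),
                                                tail_index = c(2L, 4L)))
  X <- feature_matrix(lipid_features(f2, w = 10))
  expect_equal(sqrt(sum((X[1, ] - X[2, ])^2)), 20, tolerance = 1e-12)
})

test_that("coincident head/tail beads are rejected", {
  coords <- rbind(c(1, 1, 1), c(1, 1, 1))
  f <- particle_frame(coords + c(0, 1e-12), c(1, 1), c(1L, 1L),
                      rep("fatty_acid", 2), component = c("PA", "PA"),
                      surfactants = data.frame(molecule_id = 1L,
                                               head_index = 1L,
                                               tail_index = 2L))
  expect_error(lipid_features(f), "coincident")
})

test_that("two well-separated dense patches form exactly two clusters", {
  g <- as.matrix(expand.grid(x = seq(0, 35, 5), y = seq(0, 35, 5)))
  g <- g[1:50, ]
  X <- rbind(cbind(g, 0), cbind(g + 100, 0))
  res <- cluster_lipids(X, eps = 15, min_samples = 5)
  expect_identical(res$n_clusters, 2L)
  expect_identical(res$fraction_clustered, 1)
})

test_that("a sparse grid is fully unclustered", {
  eps <- 4
  g <- as.matrix(expand.grid(seq(0, 10, 1), seq(0, 10, 1))) * 3 * eps
  res <- cluster_lipids(cbind(g, 0), eps = eps, min_samples = 2)
  expect_identical(res$n_clusters, 0L)
  expect_identical(res$fraction_clustered, 0)
  expect_true(all(res$labels == -1L))
})

test_that("DBSCAN agrees with the brute-force reachability oracle", {
  skip_if_not_installed("igraph")
  skip_if_not_installed("mclust")
  withr::with_seed(10, {
    for (rep in 1:8) {
      n <- sample(50:200, 1)
      centers <- matrix(runif(3 * 4, 0, 200), ncol = 3)
      X <- do.call(rbind, lapply(1:4, function(k)
        centers[rep(k, n %/% 4), ] + matrix(rnorm(3 * (n %/% 4), sd = 6),
                                            ncol = 3)))
      eps <- runif(1, 8, 20); ms <- sample(3:8, 1)
      got <- cluster_lipids(X, eps = eps, min_samples = ms)$labels
      want <- oracle_dbscan(X, eps, ms)
      expect_identical(got == -1L, want == -1L)
      core_ok <- got != -1L
      if (any(core_ok)) {
        expect_equal(mclust::adjustedRandIndex(got[core_ok],
                                               want[core_ok]), 1)
      }
    }
  })
})

test_that("orientation weight resolves antiparallel halves when 2w > eps", {
  # one spatial patch, two antiparallel orientation groups
  g <- as.matrix(expand.grid(seq(0, 18, 3), seq(0, 18, 3)))[1:40, ]
  up <- cbind(g, 0, 0, 0, 10)      # w * (0,0,1), w = 10
  down <- cbind(g, 0, 0, 0, -10)
  X <- rbind(up, down)
  res <- cluster_lipids(X, eps = 8, min_samples = 4)   # 2w = 20 > eps
  expect_identical(res$n_clusters, 2L)
  skip_if_not_installed("igraph")
  want <- oracle_dbscan(X, 8, 4)
  expect_identical(res$labels == -1L, want == -1L)
  # with w folded to zero the halves merge into one cluster
  X0 <- rbind(cbind(g, 0, 0, 0, 0), cbind(g, 0, 0, 0, 0))
  expect_identical(cluster_lipids(X0, eps = 8, min_samples = 4)$n_clusters,
                   1L)
})

test_that("planted rafts are recovered exactly (ARI = 1)", {
  skip_if_not_installed("mclust")
  fix <- generate_raft_fixture(3, 30, patch_tilt = c(0, 10, 20),
                               radius = 150, spacing = 5, n_water = 0,
                               seed = 6)
  fe <- lipid_features(fix$frame, w = 10)
  res <- cluster_lipids(fe, eps = 12, min_samples = 5)
  expect_identical(res$n_clusters, 3L)
  expect_equal(mclust::adjustedRandIndex(res$labels, fix$true_labels), 1)
})

test_that("every surfactant receives exactly one label per frame", {
  fix <- generate_raft_fixture(2, 25, n_core_aggregate = 10, radius = 120,
                               seed = 3)
  fe <- lipid_features(fix$frame)
  res <- cluster_lipids(fe)
  expect_identical(length(res$labels), nrow(fix$frame$surfactants))
  expect_true(all(res$labels == -1L | res$labels >= 1L))
})

test_that("growing eps never creates new noise points", {
  withr::with_seed(4, {
    X <- matrix(runif(3 * 120, 0, 80), ncol = 3)
  })
  eps_grid <- c(4, 6, 8, 12, 16, 24)
  noise <- vapply(eps_grid, function(e)
    sum(cluster_lipids(X, eps = e, min_samples = 4)$labels == -1L),
    numeric(1))
  expect_true(all(diff(noise) <= 0))
})

test_that("kinetics are constant on a static trajectory and stable under
           jitter with identity matching", {
  fix <- generate_raft_fixture(2, 30, radius = 120, n_water = 0, seed = 8)
  f <- fix$frame
  static <- trajectory(f, list(f$coords, f$coords, f$coords), times = 0:2)
  kin <- clustering_kinetics(static)
  expect_identical(length(unique(kin$summary$n_clusters)), 1L)
  expect_identical(length(unique(kin$summary$fraction_clustered)), 1L)

  withr::with_seed(12, {
    jit <- lapply(0:3, function(i) f$coords +
                    matrix(rnorm(length(f$coords), sd = 0.5),
                           ncol = 3))
  })
  kin2 <- clustering_kinetics(trajectory(f, jit, times = 0:3))
  lab0 <- kin2$assignments[[1]]$labels
  for (a in kin2$assignments[-1]) expect_identical(a$labels, lab0)
})

test_that("deleting a patch mid-trajectory drops the cluster count", {
  fix <- generate_raft_fixture(2, 30, radius = 150, n_water = 0, seed = 5)
  f <- fix$frame
  # send patch 2 lipids far apart (dissolved) in the second frame
  gone <- f$coords
  beads2 <- which(rep(fix$true_labels, each = 2) == 2)
  withr::with_seed(2, {
    gone[beads2, ] <- gone[beads2, ] * 5 +
      matrix(rnorm(length(beads2) * 3, sd = 100), ncol = 3)
  })
  kin <- clustering_kinetics(trajectory(f, list(f$coords, gone),
                                        times = 0:1))
  expect_identical(kin$summary$n_clusters, c(2, 1))
})

test_that("surface rafts are separated from core aggregates and
           misaligned patches", {
  fix <- generate_raft_fixture(2, 40, patch_tilt = 0, n_core_aggregate = 30,
                               radius = 150, seed = 1)
  fe <- lipid_features(fix$frame, w = 0)   # position-only: core clusters too
  res <- cluster_lipids(fe, eps = 12, min_samples = 5)
  model <- fit_bounding_ellipsoid(fix$frame)
  rafts <- identify_surface_rafts(res, fe, model)
  surface_cl <- rafts$cluster[rafts$is_surface_raft]
  # the two planted patches are surface rafts, centroid u high
  expect_identical(sum(rafts$is_surface_raft), 2L)
  expect_true(all(rafts$centroid_u[rafts$is_surface_raft] > (2 / 3)^(1 / 3)))
  # the core aggregate (if clustered) is excluded by the u criterion
  expect_true(all(rafts$centroid_u[!rafts$is_surface_raft] < 0.5))
})

test_that("patches tilted nearly tangentially fail the alignment test", {
  fix <- generate_raft_fixture(1, 40, patch_tilt = 85, radius = 150,
                               seed = 4)
  fe <- lipid_features(fix$frame)
  res <- cluster_lipids(fe, eps = 12, min_samples = 5)
  model <- fit_bounding_ellipsoid(fix$frame)
  rafts <- identify_surface_rafts(res, fe, model, align_min = 0.5)
  # cos(85 deg) = 0.087 < 0.5: on the surface but not outward-aligned
  expect_true(all(!rafts$is_surface_raft))
  expect_true(all(abs(rafts$mean_alignment) < 0.35))
})
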
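test_that("equal-volume shell boundaries follow the cube-root law", {
  expect_equal(shell_boundaries(3),
               c((1 / 3)^(1 / 3), (2 / 3)^(1 / 3), 1), tolerance = 1e-15)
  expect_identical(shell_boundaries(1), 1)
  expect_error(shell_boundaries(0), ">= 1")
  # successive shell volumes are all V/N for any N
  for (N in c(2, 3, 5, 8)) {
    s <- shell_boundaries(N)
    vols <- diff(c(0, s^3))
    expect_equal(vols, rep(1 / N, N), tolerance = 1e-12)
  }
})

test_that("MVEE of a dense sphere sample recovers the radius within 1 %", {
  withr::with_seed(1, {
    v <- matrix(rnorm(3 * 2000), ncol = 3)
    pts <- 200 * v / sqrt(rowSums(v^2))
  })
  m <- fit_bounding_ellipsoid(pts)
  expect_equal(m$semi_axes, rep(200, 3), tolerance = 0.01)
  expect_lte(max(ellipsoid_u(m, pts)), 1 + 1e-9)
})

test_that("MVEE recovers known rotated ellipsoid axes within 1 %", {
  axes <- c(200, 150, 100)
  withr::with_seed(2, {
    v <- matrix(rnorm(3 * 3000), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    surf <- sweep(v, 2, axes, "*")
    Q <- random_rotation()
    pts <- surf %*% t(Q) + matrix(c(10, -20, 5), nrow(surf), 3,
                                  byrow = TRUE)
  })
  m <- fit_bounding_ellipsoid(pts, tolerance = 1e-4)
  expect_equal(m$semi_axes, axes, tolerance = 0.01)
  expect_true(all(diff(m$semi_axes) <= 0))
  expect_equal(m$center, c(10, -20, 5), tolerance = 1)
  expect_lte(max(ellipsoid_u(m, pts)), 1 + 1e-9)
})

test_that("MVEE of a regular tetrahedron is its circumsphere", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  m <- fit_bounding_ellipsoid(tet, tolerance = 1e-6)
  expect_equal(m$semi_axes, rep(sqrt(3), 3), tolerance = 1e-3)
  expect_equal(m$center, c(0, 0, 0), tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  planar <- cbind(matrix(rnorm(40), ncol = 2), 0)
  expect_error(fit_bounding_ellipsoid(planar), "degenerate")
  expect_error(fit_bounding_ellipsoid(matrix(rnorm(9), 3)), "at least 4")
})

test_that("refitting a rigidly rotated cloud leaves the semi-axes fixed", {
  withr::with_seed(3, {
    pts <- runif_ellipsoid(800, c(120, 90, 60))
    Q <- random_rotation()
  })
  m1 <- fit_bounding_ellipsoid(pts, tolerance = 1e-4)
  m2 <- fit_bounding_ellipsoid(pts %*% t(Q), tolerance = 1e-4)
  expect_equal(m2$semi_axes, m1$semi_axes, tolerance = 1e-4)
})

test_that("vapor exclusion drops escaped beads from the fit", {
  withr::with_seed(9, {
    pts <- runif_ellipsoid(500, c(100, 100, 100))
  })
  vapor <- matrix(c(400, 0, 0, 0, -380, 0), ncol = 3, byrow = TRUE)
  m <- fit_bounding_ellipsoid(rbind(pts, vapor), exclude_vapor = TRUE)
  expect_lt(m$semi_axes[1], 120)
})

test_that("region assignment follows the ellipsoidal coordinate", {
  m <- ellipsoid_model(c(0, 0, 0), c(100, 80, 60))
  b <- shell_boundaries(3)
  pts <- rbind(c(0, 0, 0),                       # center -> core
               c(0, 0, 60 * 1.05),               # u = 1.05 -> surface
               c(100 * 0.7, 0, 0),               # u = 0.70 -> bulk
               c(0, 80 * b[1], 0))               # u exactly s1 -> core
  lab <- assign_regions(pts, m, b)
  expect_identical(as.character(lab), c("core", "surface", "bulk", "core"))
})

test_that("uniform-density ellipsoid splits into thirds by mass", {
  withr::with_seed(11, {
    pts <- runif_ellipsoid(1e5, c(150, 110, 70))
  })
  m <- ellipsoid_model(c(0, 0, 0), c(150, 110, 70))
  lab <- assign_regions(pts, m, shell_boundaries(3))
  frac <- as.numeric(table(lab)) / 1e5
  expect_equal(frac, rep(1 / 3, 3), tolerance = 0.03)   # 1 % absolute
  expect_true(all(abs(frac - 1 / 3) < 0.01))
})

test_that("region mass percentages sum to 100 per class", {
  fix <- generate_raft_fixture(2, 40, n_core_aggregate = 20, radius = 150,
                               seed = 7)
  model <- fit_bounding_ellipsoid(fix$frame)
  lab <- assign_regions(fix$frame, model, shell_boundaries(3))
  tab <- region_mass_fractions(fix$frame, lab)
  sums <- rowSums(tab[, c("core", "bulk", "surface")])
  expect_equal(sums, rep(100, nrow(tab)), tolerance = 1e-9)
})

test_that("planted placement shows up in the partition table", {
  fix <- generate_raft_fixture(3, 40, n_core_aggregate = 40, radius = 150,
                               n_water = 4000, seed = 13)
  model <- fit_bounding_ellipsoid(fix$frame)
  lab <- assign_regions(fix$frame, model, shell_boundaries(3))
  tab <- region_mass_fractions(fix$frame, lab)
  fa <- tab[tab$class == "fatty_acid", ]
  # rafts sit at the surface, the aggregate in the core: bulk is empty
  expect_gt(fa$surface + fa$core, 95)
  expect_lt(fa$bulk, 5)
})

test_that("zero-mass classes are omitted with a warning", {
  fix <- generate_raft_fixture(1, 10, radius = 60, n_water = 20, seed = 1)
  model <- fit_bounding_ellipsoid(fix$frame)
  lab <- assign_regions(fix$frame, model)
  expect_warning(tab <- region_mass_fractions(fix$frame, lab,
                                              classes = c("water",
                                                          "protein")),
                 "zero total mass")
  expect_identical(tab$class, "water")
})

test_that("Thomsen surface area matches the sphere closed form", {
  m <- ellipsoid_model(c(0, 0, 0), c(70, 70, 70))
  expect_equal(ellipsoid_surface_area(m), 4 * pi * 70^2, tolerance = 1e-9)
})
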
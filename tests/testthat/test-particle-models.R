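test_that("composition builder reproduces the design targets for A, B, C", {
  for (sys in c("A", "B", "C")) {
    comp <- build_composition(sys, diameter = 400)
    ach <- comp$achieved
    expect_equal(ach$mass_fractions[["water"]], 0.51, tolerance = 0.01)
    expect_equal(ach$molarity[["NA"]], 0.4, tolerance = 0.01)
    if (sys != "A") {
      expect_equal(1000 * ach$molarity[["MG"]], 110, tolerance = 0.01)
      expect_equal(1000 * ach$molarity[["CA"]], 25, tolerance = 0.01)
      expect_equal(1000 * ach$molarity[["K"]], 20, tolerance = 0.01)
    }
  }
  expect_equal(build_composition("A", 400)$achieved$fa_share_of_organic_pct,
               93, tolerance = 0.01)
  expect_equal(build_composition("B", 400)$achieved$fa_share_of_organic_pct,
               80, tolerance = 0.01)
  expect_equal(build_composition("C", 400)$achieved$fa_share_of_organic_pct,
               63, tolerance = 0.01)
})

test_that("total mass equals counts times molar masses exactly", {
  comp <- build_composition("C", diameter = 300)
  reg <- comp$spec$registry
  mm <- setNames(reg$molar_mass, reg$name)
  expect_identical(comp$achieved$total_mass_amu,
                   sum(comp$counts * mm[names(comp$counts)]))
})

test_that("electroneutrality holds via the chloride count", {
  for (sys in c("A", "B")) {
    comp <- build_composition(sys, diameter = 350)
    reg <- comp$spec$registry
    q <- setNames(reg$charge, reg$name)
    net <- sum(comp$counts * q[names(comp$counts)])
    expect_identical(net, 0)
  }
})

test_that("unknown systems and undersized particles are rejected", {
  expect_error(composition_spec("D"), "unknown system_id")
  expect_error(build_composition("A", diameter = 30), "too small")
  # the error names the offending (heaviest unplaceable) component
  expect_error(build_composition("A", diameter = 30), "BCL")
})

test_that("every nonzero-target component gets at least one molecule", {
  comp <- build_composition("C", diameter = 150)
  for (nm in names(comp$spec$organic_breakdown)) {
    expect_gte(comp$counts[[nm]], 1L)
  }
})

test_that("particle generation is seed-deterministic and contained", {
  comp <- build_composition("A", diameter = 120)
  p1 <- generate_particle(comp, seed = 7)
  p2 <- generate_particle(comp, seed = 7)
  expect_identical(p1$coords, p2$coords)
  p3 <- generate_particle(comp, seed = 8)
  expect_false(identical(p1$coords, p3$coords))
  r <- sqrt(rowSums(p1$coords^2))
  expect_lte(max(r), 120 / 2 + 4)   # radius + one bond length
})

test_that("generated per-component mass fractions match the discretized
           composition within 1 % absolute", {
  comp <- build_composition("B", diameter = 150)
  p <- generate_particle(comp, seed = 3)
  total <- sum(p$masses)
  for (nm in names(comp$counts)) {
    got <- sum(p$masses[p$component == nm]) / total
    reg <- comp$spec$registry
    want <- comp$counts[[nm]] * reg$molar_mass[reg$name == nm] /
      comp$achieved$total_mass_amu
    expect_lt(abs(got - want), 0.01)
  }
})

test_that("raft fixture plants the requested ground truth", {
  fix <- generate_raft_fixture(2, 40, patch_tilt = 0, n_core_aggregate = 15,
                               radius = 150, seed = 1)
  expect_setequal(unique(fix$true_labels), 1:3)
  expect_identical(sum(fix$true_labels == 1), 40L)
  expect_identical(sum(fix$true_labels == 3), 15L)
  expect_identical(unname(table(fix$true_region)[c("core", "surface")]),
                   table(factor(c(rep("core", 15), rep("surface", 80)),
                                c("core", "surface"))) |> unname())
  # partition: every surfactant labelled exactly once
  expect_identical(length(fix$true_labels), nrow(fix$frame$surfactants))

  # outward convention at zero tilt: tail bead farther out than head bead
  sf <- fix$frame$surfactants[fix$true_region == "surface", ]
  rh <- sqrt(rowSums(fix$frame$coords[sf$head_index, ]^2))
  rt <- sqrt(rowSums(fix$frame$coords[sf$tail_index, ]^2))
  expect_true(all(rt > rh))
})

test_that("overlapping patch geometry is rejected", {
  expect_error(generate_raft_fixture(30, 200, radius = 60, seed = 1),
               "infeasible patch geometry")
})

test_that("Brownian generator: D = 0 freezes the waters", {
  frame <- water_ball(50, 60, seed = 2)
  tr <- generate_brownian_trajectory(frame,
                                     data.frame(r_min = 0, r_max = 60,
                                                D = 0),
                                     dt = 0.1, n_frames = 10, seed = 5)
  expect_identical(tr$coords[[1]], tr$coords[[10]])
})

test_that("Brownian generator: per-axis step variance is 2 D dt", {
  D0 <- 1.2; dt <- 0.01
  frame <- water_ball(2000, 500, seed = 3)   # huge ball: no wall contact
  tr <- generate_brownian_trajectory(frame,
                                     data.frame(r_min = 0, r_max = 500,
                                                D = D0),
                                     dt = dt, n_frames = 6, seed = 11)
  steps <- do.call(rbind, lapply(2:6, function(i)
    tr$coords[[i]] - tr$coords[[i - 1]]))
  expect_equal(mean(apply(steps, 2, var)), 2 * D0 * dt, tolerance = 0.05)
})

test_that("Brownian generator: MSD slope recovers 6 D within 5 percent", {
  D0 <- 1.5; dt <- 0.01
  # 1000 beads x 10 steps = 1e4 bead-steps: short lags, heavy averaging
  frame <- water_ball(1000, 400, seed = 4)
  tr <- generate_brownian_trajectory(frame,
                                     data.frame(r_min = 0, r_max = 400,
                                                D = D0),
                                     dt = dt, n_frames = 11, seed = 1)
  m <- compute_msd(tr, slice_length = 0.1, n_slices = 1,
                   multi_origin = TRUE)
  fit <- fit_diffusion_coefficient(m$average)
  expect_equal(fit$D, D0, tolerance = 0.05)
})

test_that("generator rejects bad shell tables", {
  frame <- water_ball(10, 50, seed = 1)
  expect_error(generate_brownian_trajectory(
    frame, data.frame(r_min = 0, r_max = 50, D = -1), 0.1, 5, 1),
    "negative")
  expect_error(generate_brownian_trajectory(
    frame, data.frame(r_min = 0, r_max = 10, D = 1), 0.1, 5, 1),
    "cover")
})
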
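make_traj <- function(zs, times_ps = NULL, x = 0, y = 0) {
  # single-molecule trajectory visiting the given axial positions
  if (is.null(times_ps)) times_ps <- seq_along(zs)
  pore_trajectory(times_ps,
                  lapply(zs, function(z) cbind(x, y, z)))
}

test_that("pore membership rule respects the axial span and local radius", {
  g <- geom30(9)
  frame <- rbind(c(0, 0, -5),        # upstream reservoir
                 c(0, 0, 15),        # on axis at the centre
                 c(0, 0, 35),        # downstream reservoir
                 c(3.1, 0, 15),      # outside radius + buffer at the centre
                 c(2.9, 0, 1),       # inside the wide mouth
                 c(0, 2.8, 15))      # just within centre radius + buffer
  sel <- select_pore_waters(frame, g)
  expect_equal(sel, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  # known occupancy from the generator ground truth
  cfg <- quick_config(duration_ns = 0.2)
  tr <- generate_trajectory(cfg)
  d <- attr(tr, "diagnostics")
  k <- 25
  n_sel <- sum(select_pore_waters(tr$frames[[k]], cfg$geom, r_buffer = 1.4))
  # selected = chain + crowd (10), allowing jitter at the boundaries
  expect_lte(abs(n_sel - (d$n_chain[k] + 10)), 2)
})

test_that("density profile conserves counts and is flat for uniform data", {
  g <- pore_geometry(3, 30, 0)
  set.seed(1)
  frames <- lapply(1:200, function(i) {
    cbind(0, 0, runif(40, 0, 30))
  })
  tr <- pore_trajectory(1:200, frames)
  dp <- density_profile(tr, g, bin_width_A = 3)
  # conservation: mean bin counts sum to the mean in-pore population
  expect_equal(sum(dp$mean_count), 40, tolerance = 1e-9)
  # flat within counting noise (4 per bin per frame, 200 frames)
  expect_true(all(abs(dp$mean_count - 4) < 4 * 4 / sqrt(200 * 4)))
  expect_error(density_profile(tr, g, bin_width_A = 0), "bin_width")
})

test_that("gap statistics report max, min and the max-gap midpoint", {
  g <- pore_geometry(3, 30, 0)
  # constant particle count: extra molecules parked in the reservoir
  f1 <- rbind(cbind(0, 0, c(10, 12)), cbind(0, 0, rep(-10, 5)))
  f2 <- cbind(0, 0, seq(2, 26, by = 4))
  tr <- pore_trajectory(1:2, list(f1, f2))
  gs <- gap_statistics(tr, g)
  expect_equal(gs$max_gap[1], 2)
  expect_equal(gs$min_gap[1], 2)
  expect_equal(gs$gap_center_z[1], 11)
  # equally spaced chain: max = min
  expect_equal(gs$max_gap[2], gs$min_gap[2])
  expect_true(all(gs$valid))
  # a frame with fewer than two in-pore molecules is flagged, not zeroed
  tr2 <- pore_trajectory(1:2, list(cbind(0, 0, 15), cbind(0, 0, -5)))
  gs2 <- gap_statistics(tr2, g)
  expect_false(any(gs2$valid))
  expect_true(all(is.na(gs2$max_gap)))
})

test_that("crossing counter applies hysteresis and pore-interior tracking", {
  g <- pore_geometry(3, 30, 0)
  # monotone transit 0 -> L gives one forward event
  cf <- crossing_flux(make_traj(seq(1, 29, by = 2)), g)
  expect_equal(cf$n_forward, 1)
  expect_equal(cf$n_backward, 0)
  # oscillation within the hysteresis band gives nothing
  cf0 <- crossing_flux(make_traj(rep(c(14.5, 15.5), 10)), g)
  expect_equal(cf0$n_forward + cf0$n_backward, 0)
  # a genuine return back through the pore counts backward
  cfb <- crossing_flux(make_traj(c(5, 10, 18, 10, 5)), g)
  expect_equal(cfb$n_forward, 1)
  expect_equal(cfb$n_backward, 1)
  expect_equal(cfb$j_v_per_ns, 0)
  # reservoir recycling around the pore (downstream exit, upstream
  # re-entry) must not register a spurious backward event
  cfr <- crossing_flux(make_traj(c(5, 12, 20, 29, 35, -8, 2, 10)), g)
  expect_equal(cfr$n_forward, 1)
  expect_equal(cfr$n_backward, 0)
})

test_that("trajectory statistics are invariant under lateral translation", {
  cfg <- quick_config(duration_ns = 0.5)
  tr <- generate_trajectory(cfg)
  shift <- function(tr, dx, dy) {
    pore_trajectory(tr$times_ps, lapply(tr$frames, function(f) {
      f[, 1] <- f[, 1] + dx; f[, 2] <- f[, 2] + dy; f
    }))
  }
  # the pore axis is through (0,0): shifting molecules AND the membership
  # test frame together must leave the z-statistics unchanged, so compare
  # statistics computed twice on identical input (determinism) and after
  # a null shift
  g <- cfg$geom
  expect_identical(gap_statistics(tr, g), gap_statistics(tr, g))
  expect_identical(density_profile(tr, g), density_profile(tr, g))
  expect_identical(density_profile(shift(tr, 0, 0), g),
                   density_profile(tr, g))
})

test_that("permeability estimate equals the flux ratio for a single run", {
  g <- pore_geometry(3, 30, 0)
  fl <- std_fluid()
  # 5 molecules each crossing once over 1 ns
  frames <- list(cbind(0, 0, seq(1, 9, by = 2)),
                 cbind(0, 0, seq(21, 29, by = 2)))
  tr <- pore_trajectory(c(0, 1000), frames)
  est <- estimate_permeability(list(list(traj = tr, delta_p = 1e9)),
                               g, fl, n_boot = 50)
  expect_equal(est$K, 5e9 / 1e9)
  # doubling the flux doubles K
  frames2 <- list(cbind(0, 0, seq(0.5, 9.5, by = 1)),
                  cbind(0, 0, seq(20.5, 29.5, by = 1)))
  tr2 <- pore_trajectory(c(0, 1000), frames2)
  est2 <- estimate_permeability(list(list(traj = tr2, delta_p = 1e9)),
                                g, fl, n_boot = 50)
  expect_equal(est2$K, 2 * est$K)
  # resistance is the reciprocal volumetric permeability
  R <- resistance_from_trajectory(list(list(traj = tr, delta_p = 1e9)), g, fl)
  expect_equal(as.numeric(R), 1 / (est$K * 18e-6 / 6.02214076e23),
               tolerance = 1e-9)
  # zero flux: K = 0 with warning, resistance sentinel Inf
  tr0 <- pore_trajectory(c(0, 1000), list(cbind(0, 0, 1), cbind(0, 0, 1)))
  expect_warning(est0 <- estimate_permeability(
    list(list(traj = tr0, delta_p = 1e9)), g, fl, n_boot = 10), "zero")
  expect_equal(est0$K, 0)
  expect_identical(as.numeric(suppressWarnings(resistance_from_trajectory(
    list(list(traj = tr0, delta_p = 1e9)), g, fl))), Inf)
})

test_that("XYZ trajectories round-trip through file I/O", {
  cfg <- quick_config(duration_ns = 0.1, n_molecules = 300)
  tr <- generate_trajectory(cfg)
  f <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, f)
  tr2 <- read_xyz_trajectory(f)
  expect_equal(tr2$times_ps, tr$times_ps)
  expect_equal(tr2$n_molecules, tr$n_molecules)
  for (k in c(1, length(tr$frames))) {
    expect_equal(tr2$frames[[k]], unname(tr$frames[[k]]), tolerance = 1e-4)
  }
  unlink(f)
})

test_that("HISTORY-style trajectories are read (positions only)", {
  f <- tempfile()
  writeLines(c(
    "synthetic water run",
    "0 1 2",
    "timestep 100 2 0 1 0.002 1.0",
    "50 0 0", "0 50 0", "0 0 70",
    "OW 1", "1.0 2.0 3.0",
    "OW 2", "4.0 5.0 6.0",
    "timestep 200 2 0 1 0.002 2.0",
    "50 0 0", "0 50 0", "0 0 70",
    "OW 1", "1.5 2.5 3.5",
    "OW 2", "4.5 5.5 6.5"), f)
  tr <- read_history_trajectory(f)
  expect_equal(length(tr$frames), 2)
  expect_equal(tr$times_ps, c(1, 2))
  expect_equal(tr$frames[[2]][1, ], c(1.5, 2.5, 3.5))
  unlink(f)
})
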
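test_that("generator is deterministic: same config and seed, same bytes", {
  cfg <- quick_config(duration_ns = 0.5, seed = 7)
  t1 <- generate_trajectory(cfg)
  t2 <- generate_trajectory(cfg)
  expect_identical(t1$frames, t2$frames)
  f1 <- tempfile(); f2 <- tempfile()
  write_xyz_trajectory(t1, f1); write_xyz_trajectory(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # a different seed gives a different realization
  cfg2 <- quick_config(duration_ns = 0.5, seed = 8)
  expect_false(identical(generate_trajectory(cfg2)$frames, t1$frames))
})

test_that("particle count is conserved in every frame", {
  tr <- generate_trajectory(quick_config(duration_ns = 0.5))
  counts <- vapply(tr$frames, nrow, integer(1))
  expect_true(all(counts == 300))
  expect_true(all(vapply(tr$frames, function(f) all(is.finite(f)),
                         logical(1))))
})

test_that("zero programmed permeability gives zero net flux", {
  g <- geom30(9)
  cfg <- generator_config(g, p_katm(10.03), true_K = 0, duration_ns = 1,
                          stride_ps = 4, n_molecules = 300, seed = 3)
  cf <- crossing_flux(generate_trajectory(cfg), g)
  expect_equal(cf$n_forward, 0)
  expect_equal(cf$n_backward, 0)
})

test_that("counted flux recovers the programmed flux within 3 SE", {
  g <- geom30(9)
  fl <- std_fluid()
  K <- K_from_resistance(total_resistance(g, fl, 3.81), fl)
  cfg <- generator_config(g, p_katm(10.03), K, duration_ns = 8,
                          stride_ps = 4, n_molecules = 400, seed = 42)
  tr <- generate_trajectory(cfg)
  cf <- crossing_flux(tr, g)
  J <- attr(tr, "programmed_flux_per_ns")
  # compound-Poisson noise: Var(events) ~ lambda T E[G^2], E[G^2] ~ 2 m^2
  lambda <- cfg$burst_rate_ns; Tns <- cfg$duration_ns
  se <- J * sqrt(2 / (lambda * Tns))
  expect_lt(abs(cf$j_v_per_ns - J), 3 * se)
})

test_that("pressure-pair runs share K and scale fluxes with pressure", {
  g <- geom30(9)
  fl <- std_fluid()
  K <- K_from_resistance(total_resistance(g, fl, 3.81), fl)
  cfg <- generator_config(g, p_katm(10.03), K, duration_ns = 10,
                          stride_ps = 5, n_molecules = 400, seed = 5)
  runs <- generate_pressure_pair(cfg, p_katm(c(6.04, 10.03)))
  expect_length(runs, 2)
  j <- vapply(runs, function(r) {
    crossing_flux(r$traj, g)$j_v_per_ns
  }, numeric(1))
  # flux ratio tracks the pressure ratio within sampling noise (3 SE)
  ratio <- j[1] / j[2]
  se_rel <- sqrt(2 * 2 / (cfg$burst_rate_ns * cfg$duration_ns))
  expect_lt(abs(ratio - 6.04 / 10.03), 3 * se_rel)
})

test_that("flexible-pore emulation raises the estimated permeability", {
  g <- geom30(9)
  fl <- std_fluid()
  K <- K_from_resistance(total_resistance(g, fl, 3.81), fl)
  base <- generator_config(g, p_katm(10.03), K, duration_ns = 6,
                           stride_ps = 5, n_molecules = 400, seed = 9)
  flex <- generator_config(g, p_katm(10.03), K, duration_ns = 6,
                           stride_ps = 5, n_molecules = 400, seed = 9,
                           flexible_factor = 1.5)
  est_r <- estimate_permeability(
    list(list(traj = generate_trajectory(base), delta_p = p_katm(10.03))),
    g, fl, n_boot = 100)
  est_f <- estimate_permeability(
    list(list(traj = generate_trajectory(flex), delta_p = p_katm(10.03))),
    g, fl, n_boot = 100)
  expect_gt(est_f$p_f, est_r$p_f)
})

test_that("infeasible configurations are rejected", {
  g <- geom30(9)
  # flux far beyond single-file capacity at this stride
  expect_error(generator_config(g, p_katm(10.03), true_K = 1e6,
                                stride_ps = 10, n_molecules = 300),
               "capacity")
  # population too small for the pore contents
  expect_error(generator_config(g, p_katm(10.03), true_K = 100,
                                n_molecules = 30), "n_molecules")
  expect_error(generator_config(g, p_katm(10.03), true_K = -1), "true_K")
})

test_that("burst transport is over-dispersed against the drift control", {
  cfg_b <- quick_config(duration_ns = 3, stride_ps = 2, seed = 21)
  cfg_d <- quick_config(duration_ns = 3, stride_ps = 2, seed = 21,
                        mode = "drift")
  g <- cfg_b$geom
  v_b <- var(gap_statistics(generate_trajectory(cfg_b), g)$max_gap,
             na.rm = TRUE)
  v_d <- var(gap_statistics(generate_trajectory(cfg_d), g)$max_gap,
             na.rm = TRUE)
  expect_gt(v_b, 3 * v_d)
})
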
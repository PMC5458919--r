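test_that("Sampson-type access resistance matches the closed form", {
  fl <- std_fluid()
  # C = 3, d = 3 A: 3e-3 / (1.5e-10)^3
  expect_equal(sampson_resistance(fl, 3, 3), 8.888889e26, tolerance = 1e-6)
  # linear in C
  expect_equal(sampson_resistance(fl, 3, 6),
               2 * sampson_resistance(fl, 3, 3))
  # the partial-slip factor for a 30 A pore
  expect_equal(sampson_resistance(fl, 3, 3.81), 1.128889e27,
               tolerance = 1e-6)
  expect_error(sampson_resistance(fl, -3, 3), "d_A")
  expect_error(sampson_resistance(fl, 3, 0), "C")
})

test_that("slip-corrected Poiseuille density has the right limits", {
  fl0 <- fluid_properties(slip_length_nm = 0)
  a <- 1.5e-10
  # no slip: classical Poiseuille
  expect_equal(slip_poiseuille_density(fl0, 3), 8e-3 / (pi * a^4),
               tolerance = 1e-12)
  # perfect slip: no wall friction
  expect_equal(slip_poiseuille_density(fluid_properties(slip_length_nm = Inf), 3), 0)
  # b = 72 nm, d = 3 A: slip factor 1/(1 + 4*720/1.5) = 1/1921
  fl <- std_fluid()
  expect_equal(slip_poiseuille_density(fl, 3) /
                 slip_poiseuille_density(fl0, 3), 1 / 1921,
               tolerance = 1e-12)
})

test_that("cone integral: closed form equals adaptive quadrature", {
  fl <- std_fluid()
  for (g in random_geometries(40, seed = 7)) {
    cf <- cone_resistance(g, fl, method = "closed_form")
    qd <- cone_resistance(g, fl, method = "quadrature")
    expect_equal(qd, cf, tolerance = 1e-9)
  }
  # also under no slip
  fl0 <- fluid_properties(slip_length_nm = 0)
  g <- geom30(9)
  expect_equal(cone_resistance(g, fl0, "quadrature"),
               cone_resistance(g, fl0, "closed_form"), tolerance = 1e-9)
})

test_that("cone integral limits: straight pore, perfect slip, small angle", {
  fl <- std_fluid()
  # alpha = 0: cylinder of length L
  g0 <- pore_geometry(3, 30, 0)
  expect_equal(cone_resistance(g0, fl),
               30e-10 * slip_poiseuille_density(fl, 3), tolerance = 1e-12)
  # perfect slip kills the viscous term for any angle
  expect_equal(cone_resistance(geom30(9),
                               fluid_properties(slip_length_nm = Inf)), 0)
  # alpha -> 0 approaches the straight-pore value continuously
  g_small <- pore_geometry(3, 30, 1e-7)
  expect_equal(cone_resistance(g_small, fl), cone_resistance(g0, fl),
               tolerance = 1e-6)
})

test_that("total resistance assembles access, apex and cone terms", {
  fl <- std_fluid()
  # straight-pore limit: C_pa access + slip Poiseuille channel
  br0 <- total_resistance(pore_geometry(3, 30, 0), fl, 3.81)
  expect_equal(br0$R_e, sampson_resistance(fl, 3, 3.81))
  expect_equal(br0$R_cy, 0)
  expect_equal(br0$R_total, 1.136e27, tolerance = 1e-3)
  # the study geometry: ~2.4e26 at alpha = 9, L = 30
  br <- total_resistance(geom30(9), fl, 3.81)
  expect_equal(br$R_total, 2.441e26, tolerance = 1e-3)
  expect_equal(br$R_total, br$R_e + br$R_cy + br$R_co, tolerance = 1e-12)
  # near 90 degrees the bracket tends to sin(alpha) = 1
  br89 <- total_resistance(pore_geometry(3, 30, 89.9), fl, 3.81)
  expect_equal(br89$R_cy, sampson_resistance(fl, 3, 3.81),
               tolerance = 1e-3)
  expect_lt(br89$R_e / br89$R_cy, 1e-5)
})

test_that("resistance decreases with slip length and scales with viscosity", {
  g <- geom30(9)
  bs <- c(0, 1, 10, 72, 1000)
  Rs <- vapply(bs, function(b) {
    total_resistance(g, fluid_properties(slip_length_nm = b), 3.81)$R_total
  }, numeric(1))
  expect_true(all(diff(Rs) < 0))
  # perfect slip leaves only the bracket
  br_inf <- total_resistance(g, fluid_properties(slip_length_nm = Inf), 3.81)
  alpha <- 9 * pi / 180
  expect_equal(br_inf$R_total,
               3.81e-3 / 1.5e-10^3 * ((1 + 10 * tan(alpha))^-3 + sin(alpha)),
               tolerance = 1e-12)
  # viscosity scales everything linearly
  br10 <- total_resistance(g, fluid_properties(eta = 1e-2), 3.81)
  expect_equal(br10$R_total / total_resistance(g, std_fluid(), 3.81)$R_total,
               10, tolerance = 1e-9)
})

test_that("resistance curve covers the angle grid and the 60 A optimum is 5 deg", {
  fl <- std_fluid()
  rc <- resistance_curve(geom60(), fl, 3.85)
  expect_equal(nrow(rc), 7)
  expect_equal(rc$alpha_deg, c(1, 3, 5, 7, 9, 11, 13))
  expect_true(all(rc$R_total > 0))
  expect_equal(rc$alpha_deg[which.min(rc$R_total)], 5)
  # grid mode of the optimizer agrees
  expect_equal(optimal_angle(geom60(), fl, 3.85), 5)
  # the argmin does not depend on viscosity
  expect_equal(optimal_angle(geom60(), fluid_properties(eta = 1e-2), 3.85), 5)
})

test_that("continuous optimizer agrees with a fine-grid scan", {
  fl <- std_fluid()
  a_cont <- optimal_angle(geom60(), fl, 3.85, mode = "continuous",
                          range_deg = c(1, 13))
  # brute-force oracle at 0.1 degree steps
  grid <- seq(1, 13, by = 0.1)
  vals <- vapply(grid, function(a) {
    total_resistance(pore_geometry(3, 60, a), fl, 3.85)$R_total
  }, numeric(1))
  expect_lt(abs(a_cont - grid[which.min(vals)]), 0.2)
  expect_lt(abs(a_cont - 5), 2)
})

test_that("osmotic permeability follows p_f = (RT/V_w) K", {
  fl <- std_fluid()
  expect_equal(osmotic_permeability(fl, 0, 1e9)$p_f, 0)
  # prefactor RT/V_w ~ 1.386e8 Pa at 300 K, 18 cm^3/mol
  p <- osmotic_permeability(fl, 1e9, katm_to_Pa(10.03))
  expect_equal(p$p_f / p$K, 1.3857e8, tolerance = 1e-4)
  expect_equal(p$K, 1e9 / 1.016290e9, tolerance = 1e-6)
  # volumetric variant is p_f times one molecular volume
  expect_equal(p$p_f_volumetric, p$p_f * 18e-6 / 6.02214076e23,
               tolerance = 1e-9)
  expect_error(osmotic_permeability(fl, 1e9, 0), "delta_p")
})
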
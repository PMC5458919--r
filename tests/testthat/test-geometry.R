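test_that("diameter law is linear, symmetric and minimal at the centre", {
  # straight pore: constant diameter
  g0 <- pore_geometry(3, 30, 0)
  expect_equal(diameter_at(g0, 7), 3)
  # centre plane always returns the constriction diameter
  expect_equal(diameter_at(geom30(9), 15), 3)
  expect_equal(diameter_at(geom60(12), 30), 3)
  # entrance diameter from the linear law: 3 + 30 tan(9 deg)
  expect_equal(diameter_at(geom30(9), 0), 3 + 30 * tan(9 * pi / 180),
               tolerance = 1e-12)
  expect_equal(diameter_at(geom30(9), 0), 7.7519, tolerance = 1e-4)
  # domain errors
  expect_error(diameter_at(geom30(), -1), "outside")
  expect_error(diameter_at(geom30(), 31), "outside")
})

test_that("diameter law properties hold over random geometries", {
  for (g in random_geometries(50)) {
    z <- seq(0, g$L_A, length.out = 41)
    d <- diameter_at(g, z)
    # symmetry about L/2
    expect_equal(d, rev(d), tolerance = 1e-10)
    # minimal at the centre, equal to d_center
    expect_equal(min(d), g$d_center_A, tolerance = 1e-10)
    expect_equal(diameter_at(g, g$L_A / 2), g$d_center_A)
    # entrance >= centre with equality iff alpha = 0
    expect_gte(d[1], g$d_center_A)
  }
})

test_that("geometry construction validates its inputs", {
  expect_error(pore_geometry(-3, 30, 9), "d_center")
  expect_error(pore_geometry(3, 0, 9), "L_A")
  expect_error(pore_geometry(3, 30, 90), "alpha")
  expect_error(pore_geometry(3, 30, -1), "alpha")
})

test_that("structure builder produces a water-tight wall model", {
  g <- geom30(9)
  st <- build_structure(g)
  # the published model uses over 500 carbon atoms for pore plus pool
  expect_gt(nrow(st), 500)
  # widest ring radius matches the entrance diameter
  rings <- st[st$part == "ring", ]
  r <- sqrt(rings$x^2 + rings$y^2)
  expect_equal(max(r), diameter_at(g, 0) / 2, tolerance = 1e-9)
  # no ring atom strictly inside the open pore volume
  expect_true(all(r >= diameter_at(g, rings$z) / 2 - 1e-9))
  # wall plates keep the aperture open
  wall <- st[st$part == "wall", ]
  expect_true(all(sqrt(wall$x^2 + wall$y^2) > diameter_at(g, 0) / 2))
  # straight single-ring case: all atoms at the constriction radius
  st1 <- build_structure(pore_geometry(3, 1, 0), ring_spacing_A = 2)
  r1 <- sqrt(st1$x[st1$part == "ring"]^2 + st1$y[st1$part == "ring"]^2)
  expect_true(all(abs(r1 - 1.5) < 1e-9))
  expect_error(build_structure(g, ring_spacing_A = 0), "spacing")
})

test_that("Young-Laplace entry pressure follows the capillary form", {
  # cos(90 deg) = 0
  expect_lt(abs(young_laplace_entry_pressure(3, 0.072, 90)), 1e-6)
  # hydrophobic wall at the study conditions: ~8.4e7 Pa, below the
  # applied 6.04 katm
  p <- young_laplace_entry_pressure(3, 0.072, 95)
  expect_equal(p, -4 * 0.072 * cos(95 * pi / 180) / 3e-10, tolerance = 1e-12)
  expect_equal(p, 8.368e7, tolerance = 1e-3)
  expect_lt(p, katm_to_Pa(6.04))
  # 1/d scaling
  expect_equal(young_laplace_entry_pressure(6, 0.072, 95), p / 2)
  expect_error(young_laplace_entry_pressure(-1, 0.072, 95), "d_A")
})

test_that("structure and geometry files round-trip", {
  g <- geom30(9)
  st <- build_structure(g)
  xyz <- tempfile(fileext = ".xyz")
  pdb <- tempfile(fileext = ".pdb")
  write_structure_xyz(st, xyz)
  write_structure_pdb(st, pdb)
  expect_equal(as.integer(readLines(xyz, n = 1)), nrow(st))
  expect_equal(sum(grepl("^ATOM", readLines(pdb))), nrow(st))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("d_center_A: 3", "L_A: 30", "alpha_deg: 9",
               "pool_A: [50, 50, 20]"), yml)
  g2 <- read_geometry_config(yml)
  expect_equal(g2$d_center_A, 3)
  expect_equal(g2$alpha_deg, 9)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(list(d_center_A = 3, L_A = 60, alpha_deg = 5),
                       jsn, auto_unbox = TRUE)
  expect_equal(read_geometry_config(jsn)$L_A, 60)
  unlink(c(xyz, pdb, yml, jsn))
})
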
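# shared fixtures: the study conditions (d = 3 A constriction, 30/60 A
# pores, b = 72 nm, 300 K) and small generator configurations for tests

std_fluid <- function() fluid_properties()

geom30 <- function(alpha = 9) pore_geometry(3, 30, alpha)
geom60 <- function(alpha = 5) pore_geometry(3, 60, alpha)

p_katm <- function(x) katm_to_Pa(x)

# a short, small-population generator run for fast tests
quick_config <- function(geom = geom30(), delta_p = p_katm(10.03),
                         K = NULL, duration_ns = 2, stride_ps = 4,
                         n_molecules = 300, seed = 42, ...) {
  if (is.null(K)) {
    K <- K_from_resistance(total_resistance(geom, std_fluid(), 3.81),
                           std_fluid())
  }
  generator_config(geom, delta_p, K, duration_ns = duration_ns,
                   stride_ps = stride_ps, n_molecules = n_molecules,
                   seed = seed, ...)
}

# random valid pore geometries for property tests
random_geometries <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pore_geometry(d_center_A = runif(1, 2, 8),
                  L_A = runif(1, 10, 100),
                  alpha_deg = runif(1, 0.5, 25))
  })
}
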
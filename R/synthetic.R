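# Seeded phenomenological generator of MD-like water trajectories through
# an hourglass pore. It is a kinematic model, not a force-field engine:
# it reproduces the statistical structure the analysis stages assume --
# single-file transport through the constriction, burst-like ("shooting")
# chain advancement, accumulation at the upstream entrance, and a net
# crossing rate programmed to true_K * delta_p -- so that density, gap,
# flux and permeability estimators can be tested against known ground
# truth.

#' Configuration for the synthetic trajectory generator
#'
#' @param geom a [pore_geometry()]
#' @param delta_p applied pressure difference, Pa
#' @param true_K programmed hydrodynamic permeability, molecules s^-1
#'   Pa^-1 (see [K_from_resistance()] to derive it from a resistance)
#' @param duration_ns run length, ns (default 4, a typical production
#'   window for one configuration)
#' @param stride_ps frame interval, ps
#' @param n_molecules total water count (default 1700); the count is
#'   conserved every frame, with downstream reservoir molecules recycled
#'   to the upstream pool to sustain long runs
#' @param burst_rate_ns mean rate of chain-advancement ("shooting")
#'   events, ns^-1; each event advances the single-file chain by a
#'   geometric number of site spacings whose mean is set so the mean flux
#'   equals `true_K * delta_p`
#' @param site_spacing_A single-file site spacing, Angstrom (default 2.8,
#'   a hydrogen-bonded water-water distance)
#' @param refill_factor catch-up speed of entrance refilling, as a
#'   multiple of the mean chain speed (must exceed 1)
#' @param escape_factor velocity multiplier past the constriction: once
#'   beyond the centre the widened cone lets molecules escape faster,
#'   stretching their spacing and thinning the downstream density
#' @param crowd_size number of extra molecules accumulated in the
#'   upstream vestibule (entrance crowding)
#' @param jitter_A thermal position jitter, Angstrom (standard deviation,
#'   applied at recording time)
#' @param diffusion_A2_ps reservoir diffusion coefficient, A^2/ps
#' @param flexible_factor permeability multiplier emulating a flexible
#'   (harmonically constrained) pore wall; > 1 raises the programmed flux
#' @param mode `"burst"` for compound-Poisson shooting dynamics or
#'   `"drift"` for a constant-drift control at the same mean flux
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical trajectories
#' @return object of class `generator_config`
#' @export
generator_config <- function(geom, delta_p, true_K,
                             duration_ns = 4, stride_ps = 2,
                             n_molecules = 1700,
                             burst_rate_ns = 40, site_spacing_A = 2.8,
                             refill_factor = 3, escape_factor = 2,
                             crowd_size = 10, jitter_A = 0.25,
                             diffusion_A2_ps = 0.2,
                             flexible_factor = 1,
                             mode = c("burst", "drift"), seed = 1) {
  stopifnot(inherits(geom, "pore_geometry"))
  mode <- match.arg(mode)
  if (duration_ns <= 0 || stride_ps <= 0) stop("duration and stride must be > 0")
  if (true_K < 0) stop("true_K must be >= 0")
  if (delta_p <= 0) stop("delta_p must be > 0")
  if (refill_factor <= 1) stop("refill_factor must exceed 1")
  J_ns <- true_K * flexible_factor * delta_p * 1e-9   # molecules per ns
  v_mean <- J_ns * site_spacing_A                      # chain speed, A/ns
  if (v_mean * stride_ps / 1000 >= geom$L_A / 2) {
    stop("requested flux exceeds single-file capacity at this frame stride")
  }
  n_chain_max <- ceiling(geom$L_A / site_spacing_A) + 2
  if (n_chain_max + crowd_size + 20 > n_molecules / 2) {
    stop("n_molecules too small for the pore population")
  }
  structure(list(geom = geom, delta_p = delta_p, true_K = true_K,
                 duration_ns = duration_ns, stride_ps = stride_ps,
                 n_molecules = n_molecules, burst_rate_ns = burst_rate_ns,
                 site_spacing_A = site_spacing_A,
                 refill_factor = refill_factor,
                 escape_factor = escape_factor, crowd_size = crowd_size,
                 jitter_A = jitter_A, diffusion_A2_ps = diffusion_A2_ps,
                 flexible_factor = flexible_factor, mode = mode,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Programmed permeability from a hydrodynamic resistance
#'
#' Converts a (volumetric) hydrodynamic resistance to the number-flux
#' permeability `K = 1 / (R v_w)` used to drive the generator.
#'
#' @param R resistance in Pa s m^-3, or a `resistance_breakdown`
#' @param fluid a [fluid_properties()]
#' @return K in molecules s^-1 Pa^-1
#' @export
K_from_resistance <- function(R, fluid) {
  if (inherits(R, "resistance_breakdown")) R <- R$R_total
  1 / (R * water_molecular_volume(fluid$V_w_cm3_mol))
}

# independent RNG substreams (placement, bursts, jitter, reservoirs) so
# that consuming one stream never perturbs another
make_streams <- function(seed, names) {
  env <- new.env(parent = emptyenv())
  for (k in seq_along(names)) {
    set.seed((abs(seed) %% 100000L) * 7919L + k * 104729L)
    assign(names[k], get(".Random.seed", envir = globalenv()), envir = env)
  }
  env
}

stream_eval <- function(streams, name, expr) {
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  out <- expr
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  out
}

#' Generate a synthetic trajectory
#'
#' Runs the kinematic single-file model: a chain of molecules spanning the
#' pore advances in compound-Poisson bursts (or at constant drift in the
#' control mode), molecules exiting downstream are replaced at the
#' entrance through a finite-speed refill, an entrance crowd occupies the
#' upstream vestibule, and reservoir molecules diffuse in the two pools.
#' The expected net centre-plane crossing rate equals
#' `true_K * flexible_factor * delta_p`.
#'
#' @param config a [generator_config()]
#' @return a [pore_trajectory()] with ground-truth attributes
#'   `programmed_flux_per_ns` and `config`, plus a `diagnostics` data
#'   frame (per frame: chain length, tail and head position, entries)
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  geom <- config$geom
  L <- geom$L_A
  s <- config$site_spacing_A
  dt_ns <- config$stride_ps / 1000
  n_frames <- max(2L, round(config$duration_ns / dt_ns))
  n <- config$n_molecules
  J_ns <- config$true_K * config$flexible_factor * config$delta_p * 1e-9
  v_mean <- J_ns * s
  v_refill <- config$refill_factor * v_mean
  z_esc <- L / 2 + 2
  esc <- config$escape_factor
  entry_z <- 0.2
  # single-file transport is supply-limited at the entrance: per frame the
  # chain advances at most until its tail reaches tail_max (kept safely
  # below the centre-plane crossing band), the remainder of a burst being
  # carried over to the following frames while the entrance refills
  tail_max <- max(entry_z + 2 * s + 0.2, L / 2 - 3)
  crowd_zmax <- max(1, min(L / 2 - 2, L / 5))
  pool <- geom$pool_A

  streams <- make_streams(config$seed,
                          c("events", "sizes", "placement", "jitter", "pools"))

  # burst schedule (pre-generated so that runs sharing a seed share event
  # realizations regardless of what the other streams consume)
  if (config$mode == "burst" && J_ns > 0) {
    lambda <- config$burst_rate_ns
    m_size <- J_ns / lambda
    if (m_size < 1) { m_size <- 1; lambda <- J_ns }
    counts <- stream_eval(streams, "events",
                          stats::rpois(n_frames, lambda * dt_ns))
    U <- stream_eval(streams, "sizes", stats::runif(sum(counts)))
    q <- 1 / m_size
    sizes <- if (q >= 1) rep(1, length(U)) else
      1 + floor(log(U) / log(1 - q))
    adv <- numeric(n_frames)                     # advancement per frame, A
    if (length(sizes)) {
      frame_of <- rep(seq_len(n_frames), counts)
      adv_tab <- tapply(sizes * s, frame_of, sum)
      adv[as.integer(names(adv_tab))] <- adv_tab
    }
  } else {
    adv <- rep(v_mean * dt_ns, n_frames)
  }

  # --- initial configuration ----------------------------------------------
  base <- matrix(0, n, 3)
  role <- integer(n)                   # 0 pool_up, 1 crowd, 2 chain, 3 pool_down
  # chain: packed at spacing s below the escape zone, stretched above it
  zch <- numeric(0); z <- L - 0.3
  while (z >= entry_z) {
    zch <- c(zch, z)
    z <- z - if (z > z_esc) esc * s else s
  }
  n_chain <- length(zch)
  chain_ids <- seq_len(n_chain)                  # ordered top .. tail
  role[chain_ids] <- 2L
  base[chain_ids, 3] <- zch
  # entrance crowd in the upstream vestibule
  crowd_ids <- n_chain + seq_len(config$crowd_size)
  role[crowd_ids] <- 1L
  base[crowd_ids, ] <- stream_eval(streams, "placement", {
    zc <- stats::runif(config$crowd_size, 0.5, crowd_zmax)
    rmax <- pmax(0.2, diameter_at(geom, zc) / 2 - 0.8)
    rr <- rmax * sqrt(stats::runif(config$crowd_size))
    th <- stats::runif(config$crowd_size, 0, 2 * pi)
    cbind(rr * cos(th), rr * sin(th), zc)
  })
  # reservoir pools
  rest <- setdiff(seq_len(n), c(chain_ids, crowd_ids))
  n_up <- ceiling(length(rest) * 0.6)
  up_ids <- rest[seq_len(n_up)]
  down_ids <- rest[-seq_len(n_up)]
  place_pool <- function(ids, side) {
    m <- length(ids)
    if (m == 0) return(invisible(NULL))
    xy <- cbind(stats::runif(m, -pool[1] / 2, pool[1] / 2),
                stats::runif(m, -pool[2] / 2, pool[2] / 2))
    zz <- if (side == "up") stats::runif(m, -pool[3], -0.5) else
      stats::runif(m, L + 0.5, L + pool[3])
    base[ids, ] <<- cbind(xy, zz)
    invisible(NULL)
  }
  stream_eval(streams, "placement", { place_pool(up_ids, "up")
                                      place_pool(down_ids, "down") })
  role[up_ids] <- 0L
  role[down_ids] <- 3L
  n_down_target <- length(down_ids)
  sigma_pool <- sqrt(2 * config$diffusion_A2_ps * config$stride_ps)

  one_place <- function(side) {            # single new reservoir position
    stream_eval(streams, "placement", {
      c(stats::runif(1, -pool[1] / 2, pool[1] / 2),
        stats::runif(1, -pool[2] / 2, pool[2] / 2),
        if (side == "up") stats::runif(1, -pool[3], -0.5) else
          stats::runif(1, L + 0.5, L + pool[3]))
    })
  }
  one_crowd_place <- function() {
    stream_eval(streams, "placement", {
      zc <- stats::runif(1, 0.5, crowd_zmax)
      rmax <- max(0.2, diameter_at(geom, zc) / 2 - 0.8)
      rr <- rmax * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      c(rr * cos(th), rr * sin(th), zc)
    })
  }

  frames <- vector("list", n_frames)
  times <- numeric(n_frames)
  diag_nchain <- integer(n_frames); diag_tail <- numeric(n_frames)
  diag_head <- numeric(n_frames); diag_entries <- integer(n_frames)
  refill_budget <- 0

  adv_backlog <- 0
  for (k in seq_len(n_frames)) {
    # supply-limited advancement: apply at most what keeps the tail below
    # tail_max, carry the rest of the burst to the next frames
    tail_pre <- if (length(chain_ids)) base[chain_ids[length(chain_ids)], 3]
                else entry_z
    dc <- min(adv[k] + adv_backlog, max(0, tail_max - tail_pre))
    adv_backlog <- adv[k] + adv_backlog - dc
    # --- chain advancement: the whole single file moves with the burst,
    # molecules past the constriction escape faster, laggers close their
    # gap at the refill speed, and no molecule passes another
    if (length(chain_ids)) {
      zc <- base[chain_ids, 3]
      znew <- zc
      znew[1] <- zc[1] + dc * if (zc[1] > z_esc) esc else 1
      if (length(zc) > 1) {
        for (jj in 2:length(zc)) {
          za <- zc[jj]
          if (za > z_esc) {
            # escaping: widened cone, faster advection that stretches the
            # spacing beyond the single-file value
            znew[jj] <- min(za + esc * dc, znew[jj - 1] - 0.5)
          } else if (zc[jj - 1] > z_esc) {
            # head of the single-file section: pure chain advancement
            znew[jj] <- za + dc
          } else {
            # single file: advance with the burst, close any excess gap
            # at the refill speed, never closer than one site spacing
            znew[jj] <- min(za + dc + v_refill * dt_ns,
                            znew[jj - 1] - s)
          }
        }
      }
      base[chain_ids, 3] <- znew
      # exits into the downstream pool
      gone <- which(znew > L)
      if (length(gone)) {
        for (id in chain_ids[gone]) {
          base[id, ] <- one_place("down")
          role[id] <- 3L
        }
        chain_ids <- chain_ids[-gone]
      }
    }
    # --- entries from the crowd at the pore entrance: each entry joins
    # the chain packed one site spacing behind the tail, at a rate
    # limited by the refill speed, so a burst leaves a transient
    # depleted zone (the visible "shooting" gap) behind the advanced
    # chain that refills over the following frames
    refill_budget <- min(refill_budget + v_refill * dt_ns,
                         s + v_refill * dt_ns)
    repeat {
      tail_z <- if (length(chain_ids)) base[chain_ids[length(chain_ids)], 3]
                else entry_z + 2 * s
      if (tail_z - entry_z < s + 0.05 || refill_budget < s) break
      cands <- which(role == 1L)
      if (!length(cands)) break
      new_id <- cands[which.max(base[cands, 3])]
      base[new_id, ] <- c(0, 0, tail_z - s)
      role[new_id] <- 2L
      chain_ids <- c(chain_ids, new_id)
      refill_budget <- refill_budget - s
      diag_entries[k] <- diag_entries[k] + 1L
    }
    # --- keep the crowd populated from the upstream pool
    repeat {
      n_crowd <- sum(role == 1L)
      if (n_crowd >= config$crowd_size) break
      cands <- which(role == 0L)
      if (!length(cands)) break
      id <- cands[which.max(base[cands, 3])]
      base[id, ] <- one_crowd_place()
      role[id] <- 1L
    }
    # --- recycle downstream excess back upstream (closed system)
    repeat {
      downs <- which(role == 3L)
      if (length(downs) <= n_down_target) break
      id <- downs[which.max(base[downs, 3])]
      base[id, ] <- one_place("up")
      role[id] <- 0L
    }
    # --- reservoir diffusion (reflected random walk)
    pools <- which(role == 0L | role == 3L)
    if (length(pools)) {
      step <- stream_eval(streams, "pools",
                          matrix(stats::rnorm(length(pools) * 3, 0,
                                              sigma_pool), ncol = 3))
      base[pools, ] <- base[pools, ] + step
      reflect <- function(x, lo, hi) {
        x <- ifelse(x < lo, 2 * lo - x, x)
        ifelse(x > hi, 2 * hi - x, x)
      }
      base[pools, 1] <- reflect(base[pools, 1], -pool[1] / 2, pool[1] / 2)
      base[pools, 2] <- reflect(base[pools, 2], -pool[2] / 2, pool[2] / 2)
      ups <- pools[role[pools] == 0L]
      dns <- pools[role[pools] == 3L]
      base[ups, 3] <- reflect(base[ups, 3], -pool[3], -0.5)
      base[dns, 3] <- reflect(base[dns, 3], L + 0.5, L + pool[3])
    }
    # --- record frame with thermal jitter on in-pore molecules
    disp <- base
    inpore <- which(role == 1L | role == 2L)
    if (length(inpore)) {
      jit <- stream_eval(streams, "jitter", {
        cbind(stats::rnorm(length(inpore), 0, config$jitter_A / 2),
              stats::rnorm(length(inpore), 0, config$jitter_A / 2),
              stats::rnorm(length(inpore), 0, config$jitter_A))
      })
      disp[inpore, ] <- disp[inpore, ] + jit
    }
    frames[[k]] <- disp
    times[k] <- k * config$stride_ps
    diag_nchain[k] <- length(chain_ids)
    diag_tail[k] <- if (length(chain_ids)) base[chain_ids[length(chain_ids)], 3] else NA
    diag_head[k] <- if (length(chain_ids)) base[chain_ids[1], 3] else NA
  }

  traj <- pore_trajectory(times, frames,
                          box_A = c(pool[1], pool[2], L + 2 * pool[3]))
  attr(traj, "programmed_flux_per_ns") <- J_ns
  attr(traj, "config") <- config
  attr(traj, "diagnostics") <- data.frame(
    frame = seq_len(n_frames), n_chain = diag_nchain, tail_z = diag_tail,
    head_z = diag_head, entries = diag_entries)
  traj
}

#' Generate a set of runs at several pressures
#'
#' Shares the geometry and programmed permeability across pressures, so
#' that fluxes scale linearly with the pressure difference in
#' expectation; each pressure gets an independent seed derived from the
#' configuration seed.
#'
#' @param config a [generator_config()] (its `delta_p` is replaced)
#' @param pressures pressure differences in Pa (length >= 2)
#' @return list of runs, each a list with `traj` and `delta_p`, directly
#'   consumable by [estimate_permeability()]
#' @export
generate_pressure_pair <- function(config, pressures) {
  stopifnot(inherits(config, "generator_config"), length(pressures) >= 2)
  lapply(seq_along(pressures), function(i) {
    cfg <- config
    cfg$delta_p <- pressures[i]
    cfg$seed <- config$seed + 7919L * i
    list(traj = generate_trajectory(cfg), delta_p = pressures[i])
  })
}
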
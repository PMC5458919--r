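# Trajectory statistics for single-file water transport: axial density
# profiles, adjacent-gap ("shooting") series, center-plane crossing flux
# and permeability/resistance estimation. Trajectories carry water-oxygen
# positions in pore-local coordinates: the pore axis is z through
# (x, y) = (0, 0), the pore spans [0, L].

#' Construct a trajectory of water-oxygen positions
#'
#' @param times_ps frame times in ps, strictly increasing
#' @param frames list of numeric matrices, one per frame, each `n x 3`
#'   (columns x, y, z in Angstrom) with a constant molecule count; row i
#'   is molecule i in every frame (persistent identity)
#' @param box_A optional simulation box dimensions, length-3
#' @return object of class `pore_trajectory`
#' @export
pore_trajectory <- function(times_ps, frames, box_A = NULL) {
  stopifnot(length(times_ps) == length(frames), length(frames) >= 1)
  if (any(diff(times_ps) <= 0)) stop("frame times must be strictly increasing")
  n <- nrow(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || ncol(f) != 3 || nrow(f) != n) {
      stop("every frame must be an n x 3 matrix with constant n")
    }
    if (!all(is.finite(f))) stop("positions must be finite")
  }
  structure(list(times_ps = as.numeric(times_ps), frames = frames,
                 box_A = box_A, n_molecules = n),
            class = "pore_trajectory")
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d molecules, %.3f ns (stride %.3g ps)\n",
              length(x$frames), x$n_molecules,
              diff(range(x$times_ps)) / 1000,
              if (length(x$times_ps) > 1) x$times_ps[2] - x$times_ps[1] else NA))
  invisible(x)
}

#' Write a trajectory as multi-frame XYZ
#'
#' One block per frame: atom count, a comment line carrying
#' `time_ps=<t>` (and `box=` if known), then `O x y z` records.
#'
#' @param traj a [pore_trajectory()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pore_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  box <- if (is.null(traj$box_A)) "" else
    sprintf(" box=%g,%g,%g", traj$box_A[1], traj$box_A[2], traj$box_A[3])
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    writeLines(c(as.character(nrow(f)),
                 sprintf("time_ps=%.6f%s", traj$times_ps[k], box)), con)
    writeLines(sprintf("O %.4f %.4f %.4f", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file written in the dialect of [write_xyz_trajectory()]
#'   (any element label is accepted; the comment line must carry
#'   `time_ps=`)
#' @return a [pore_trajectory()]
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); box <- NULL
  k <- 1L; nf <- 0L
  while (k <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", k)
    comment <- lines[k + 1]
    tm <- regmatches(comment, regexec("time_ps=([0-9.eE+-]+)", comment))[[1]]
    if (length(tm) < 2) stop("missing time_ps= in frame comment at line ", k + 1)
    bm <- regmatches(comment, regexec("box=([0-9.,eE+-]+)", comment))[[1]]
    if (length(bm) >= 2 && is.null(box)) {
      box <- as.numeric(strsplit(bm[2], ",")[[1]])
    }
    rec <- lines[(k + 2):(k + 1 + n)]
    parts <- strsplit(trimws(rec), "[[:space:]]+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    nf <- nf + 1L
    frames[[nf]] <- xyz
    times[nf] <- as.numeric(tm[2])
    k <- k + 2L + n
  }
  pore_trajectory(times, frames, box_A = box)
}

#' Read a minimal DL_POLY-style HISTORY trajectory (positions only)
#'
#' Supports position-only records (`keytrj = 0`): per frame a `timestep`
#' record, `imcon > 0` cell vectors, then per atom a label line and a
#' position line. Times are taken from the timestep record (ps).
#'
#' @param path HISTORY-format file
#' @param element keep only atoms whose label starts with this element
#'   (default `"O"`); use `NULL` to keep all
#' @return a [pore_trajectory()]
#' @export
read_history_trajectory <- function(path, element = "O") {
  lines <- readLines(path)
  k <- 1L
  # skip header: title line + "levcfg imcon natms" line if present
  while (k <= length(lines) && !grepl("^\\s*timestep", lines[k])) k <- k + 1L
  frames <- list(); times <- numeric(0); nf <- 0L
  while (k <= length(lines)) {
    hdr <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    natms <- as.integer(hdr[3]); imcon <- as.integer(hdr[5])
    times_k <- as.numeric(hdr[length(hdr)])
    k <- k + 1L
    if (!is.na(imcon) && imcon > 0) k <- k + 3L      # cell vectors
    labs <- character(natms); xyz <- matrix(NA_real_, natms, 3)
    for (a in seq_len(natms)) {
      labs[a] <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]][1]
      xyz[a, ] <- as.numeric(
        strsplit(trimws(lines[k + 1]), "[[:space:]]+")[[1]][1:3])
      k <- k + 2L
    }
    keep <- if (is.null(element)) rep(TRUE, natms) else
      startsWith(labs, element)
    nf <- nf + 1L
    frames[[nf]] <- xyz[keep, , drop = FALSE]
    times[nf] <- times_k
    while (k <= length(lines) && !grepl("^\\s*timestep", lines[k])) k <- k + 1L
  }
  pore_trajectory(times, frames)
}

#' Select the water molecules inside the pore
#'
#' Membership rule used by all pore statistics: `0 <= z <= L` and radial
#' distance from the axis at most `d(z)/2 + r_buffer`. The buffer (default
#' 1.4 Angstrom, a water van der Waals radius) admits molecules whose
#' centre sits within one molecular radius of the geometric wall.
#'
#' @param frame an `n x 3` position matrix (x, y, z in Angstrom)
#' @param geom a [pore_geometry()]
#' @param r_buffer radial tolerance, Angstrom
#' @return logical vector of length `n`
#' @export
select_pore_waters <- function(frame, geom, r_buffer = 1.4) {
  z <- frame[, 3]
  inside_z <- z >= 0 & z <= geom$L_A
  out <- logical(nrow(frame))
  if (any(inside_z)) {
    zz <- z[inside_z]
    rad <- sqrt(frame[inside_z, 1]^2 + frame[inside_z, 2]^2)
    out[inside_z] <- rad <= diameter_at(geom, zz) / 2 + r_buffer
  }
  out
}

#' Axial number-density profile of in-pore water
#'
#' Time-averaged histogram of the axial positions of in-pore molecules,
#' on half-open bins tiling `[0, L)` (the final bin closes at `L`).
#'
#' @param traj a [pore_trajectory()]
#' @param geom a [pore_geometry()]
#' @param bin_width_A bin width, Angstrom (default 1)
#' @param r_buffer passed to [select_pore_waters()]
#' @return data frame of class `density_profile`: `z_center`,
#'   `mean_count` (molecules per frame per bin), `linear_density`
#'   (molecules per frame per Angstrom)
#' @export
density_profile <- function(traj, geom, bin_width_A = 1, r_buffer = 1.4) {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (bin_width_A <= 0) stop("bin_width_A must be > 0")
  if (length(traj$frames) == 0) stop("empty trajectory")
  L <- geom$L_A
  breaks <- seq(0, L, by = bin_width_A)
  if (breaks[length(breaks)] < L) breaks <- c(breaks, L)
  counts <- numeric(length(breaks) - 1)
  for (f in traj$frames) {
    z <- f[select_pore_waters(f, geom, r_buffer), 3]
    if (length(z)) {
      idx <- pmin(findInterval(z, breaks, rightmost.closed = TRUE),
                  length(counts))
      counts <- counts + tabulate(idx, nbins = length(counts))
    }
  }
  mean_count <- counts / length(traj$frames)
  out <- data.frame(z_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    mean_count = mean_count,
                    linear_density = mean_count / diff(breaks))
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Adjacent-molecule axial gap series
#'
#' Per frame, the in-pore molecules are sorted by z and consecutive-pair
#' differences taken; the series of the maximum gap, minimum gap and the
#' z-midpoint of the maximum-gap pair (ties resolved to the smallest-z
#' pair) diagnoses the pulsatile "shooting" transport mode, in which the
#' single-file chain advances in bursts that transiently open a large gap.
#' Frames with fewer than two in-pore molecules are flagged, not zeroed.
#'
#' @inheritParams density_profile
#' @return data frame of class `gap_series`: `time_ps`, `n_in_pore`,
#'   `max_gap`, `min_gap`, `gap_center_z` (NA where `valid` is FALSE),
#'   `valid`
#' @export
gap_statistics <- function(traj, geom, r_buffer = 1.4) {
  stopifnot(inherits(traj, "pore_trajectory"))
  rows <- lapply(seq_along(traj$frames), function(k) {
    z <- sort(traj$frames[[k]][
      select_pore_waters(traj$frames[[k]], geom, r_buffer), 3])
    if (length(z) < 2) {
      return(data.frame(time_ps = traj$times_ps[k], n_in_pore = length(z),
                        max_gap = NA_real_, min_gap = NA_real_,
                        gap_center_z = NA_real_, valid = FALSE))
    }
    gaps <- diff(z)
    imax <- which.max(gaps)                       # which.max takes first tie
    data.frame(time_ps = traj$times_ps[k], n_in_pore = length(z),
               max_gap = gaps[imax], min_gap = min(gaps),
               gap_center_z = (z[imax] + z[imax + 1]) / 2, valid = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gap_series", "data.frame")
  out
}

#' Count signed crossings of the pore centre plane
#'
#' Counts transport events through `z = L/2` with hysteresis: a molecule
#' produces a forward (+1) event when, while inside the pore, it is seen
#' below `L/2 - delta` and later above `L/2 + delta` (backward events
#' symmetrically). Tracking state is kept only while a molecule is inside
#' the pore and reset outside it, which makes the count robust to
#' reservoir recirculation (a molecule recycled from the downstream to
#' the upstream reservoir around the pore does not register a spurious
#' backward event). The hysteresis half-width (default 1 Angstrom)
#' suppresses double counting of thermal recrossings at the plane.
#'
#' @inheritParams density_profile
#' @param delta_A hysteresis half-width, Angstrom
#' @return list with `j_v_per_ns` (net forward crossings per ns),
#'   `n_forward`, `n_backward`, `duration_ns`, and `events` (data frame
#'   `time_ps`, `molecule`, `direction`)
#' @export
crossing_flux <- function(traj, geom, delta_A = 1, r_buffer = 1.4) {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (length(traj$frames) < 2) stop("need at least 2 frames")
  zc <- geom$L_A / 2
  lo <- zc - delta_A
  hi <- zc + delta_A
  n <- traj$n_molecules
  state <- integer(n)            # -1 armed from below, +1 armed from above
  ev_time <- numeric(0); ev_mol <- integer(0); ev_dir <- integer(0)
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    inside <- select_pore_waters(f, geom, r_buffer)
    z <- f[, 3]
    below <- inside & z < lo
    above <- inside & z > hi
    fwd <- above & state == -1L
    bwd <- below & state == 1L
    if (any(fwd)) {
      ev_time <- c(ev_time, rep(traj$times_ps[k], sum(fwd)))
      ev_mol <- c(ev_mol, which(fwd)); ev_dir <- c(ev_dir, rep(1L, sum(fwd)))
    }
    if (any(bwd)) {
      ev_time <- c(ev_time, rep(traj$times_ps[k], sum(bwd)))
      ev_mol <- c(ev_mol, which(bwd)); ev_dir <- c(ev_dir, rep(-1L, sum(bwd)))
    }
    state[!inside] <- 0L
    state[below] <- -1L
    state[above] <- 1L
  }
  duration_ns <- diff(range(traj$times_ps)) / 1000
  list(j_v_per_ns = (sum(ev_dir == 1L) - sum(ev_dir == -1L)) / duration_ns,
       n_forward = sum(ev_dir == 1L), n_backward = sum(ev_dir == -1L),
       duration_ns = duration_ns,
       events = data.frame(time_ps = ev_time, molecule = ev_mol,
                           direction = ev_dir))
}

# restore RNG state on exit; used by seeded resampling helpers
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Estimate the hydrodynamic and osmotic permeability from runs
#'
#' Pools one or more (trajectory, pressure) runs: the hydrodynamic
#' permeability K is the zero-intercept least-squares slope of number
#' flux against pressure difference (K is defined as the ratio j_v /
#' delta_p, so the fit is forced through the origin), and the osmotic
#' permeability follows as p_f = (RT/V_w) K. Uncertainty comes from a
#' seeded block bootstrap over frames: each run's time axis is cut into
#' `n_blocks` contiguous blocks whose crossing events are resampled with
#' replacement.
#'
#' @param runs list of runs, each a list with elements `traj` (a
#'   [pore_trajectory()]) and `delta_p` (Pa)
#' @param geom a [pore_geometry()]
#' @param fluid a [fluid_properties()]
#' @param delta_A,r_buffer passed to [crossing_flux()]
#' @param n_blocks bootstrap blocks per run (default 20)
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return a `permeability_result` (see [osmotic_permeability()]) with
#'   additional fields `K_se` (bootstrap standard error), `fluxes`
#'   (per-run data frame) and `n_runs`
#' @export
estimate_permeability <- function(runs, geom, fluid, delta_A = 1,
                                  r_buffer = 1.4, n_blocks = 20,
                                  n_boot = 1000, seed = 1) {
  stopifnot(length(runs) >= 1)
  dps <- vapply(runs, function(r) r$delta_p, numeric(1))
  if (any(dps <= 0)) stop("pressures must be > 0")
  cf <- lapply(runs, function(r) crossing_flux(r$traj, geom, delta_A, r_buffer))
  j_s <- vapply(cf, function(x) x$j_v_per_ns, numeric(1)) * 1e9
  K <- sum(j_s * dps) / sum(dps^2)
  if (all(j_s == 0)) {
    warning("all fluxes are zero; K = 0")
  }
  # block bootstrap over frames: net events per block, blocks resampled
  block_tab <- lapply(seq_along(runs), function(ri) {
    tr <- runs[[ri]]$traj
    brks <- seq(min(tr$times_ps), max(tr$times_ps), length.out = n_blocks + 1)
    ev <- cf[[ri]]$events
    idx <- if (nrow(ev)) pmin(pmax(findInterval(ev$time_ps, brks,
                                                rightmost.closed = TRUE), 1),
                              n_blocks) else integer(0)
    net <- vapply(seq_len(n_blocks), function(b) {
      if (length(idx)) sum(ev$direction[idx == b]) else 0
    }, numeric(1))
    list(net = net, block_dur_ns = diff(brks) / 1000)
  })
  K_boot <- with_seed(seed, vapply(seq_len(n_boot), function(s) {
    j_b <- vapply(seq_along(runs), function(ri) {
      pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
      sum(block_tab[[ri]]$net[pick]) /
        sum(block_tab[[ri]]$block_dur_ns[pick])
    }, numeric(1)) * 1e9
    sum(j_b * dps) / sum(dps^2)
  }, numeric(1)))
  res <- osmotic_permeability(fluid, j_v = K * mean(dps), delta_p = mean(dps))
  res$K_se <- stats::sd(K_boot)
  res$fluxes <- data.frame(delta_p = dps, j_v_per_s = j_s)
  res$n_runs <- length(runs)
  res
}

#' Total hydrodynamic resistance measured from trajectories
#'
#' The reciprocal of the hydrodynamic permeability, expressed as the
#' volumetric resistance `delta_p / Q` with `Q = j_v v_w` (v_w the volume
#' of one water molecule), comparable directly with the analytical
#' [total_resistance()].
#'
#' @inheritParams estimate_permeability
#' @return resistance in Pa s m^-3 (`Inf` if the measured K is zero or
#'   negative), with the underlying `permeability_result` as attribute
#'   `permeability`
#' @export
resistance_from_trajectory <- function(runs, geom, fluid, delta_A = 1,
                                       r_buffer = 1.4, seed = 1) {
  est <- estimate_permeability(runs, geom, fluid, delta_A = delta_A,
                               r_buffer = r_buffer, seed = seed)
  R <- if (est$K <= 0) Inf else
    1 / (est$K * water_molecular_volume(fluid$V_w_cm3_mol))
  structure(R, permeability = est)
}
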
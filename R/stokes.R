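# Axisymmetric creeping-flow (Stokes) solver for the access-resistance
# factor C of straight pores. The domain is reservoir-pore-reservoir in
# cylindrical coordinates (r, z), discretized with a staggered
# finite-volume (MAC) scheme on a tensor-product mesh graded towards the
# pore walls and the sharp mouth corners, where the stress is singular.
# Walls carry the Navier partial-slip condition (tangential velocity equal
# to slip length times wall-normal shear); the pressure difference is
# imposed through pressure conditions on the far reservoir faces, and the
# lateral reservoir boundary is shear-free. All lengths are
# nondimensionalized by the pore radius a, so the solve returns the
# dimensionless factor C = (delta_p / Q) a^3 / eta directly.

#' Define an axisymmetric Stokes problem for a straight pore
#'
#' @param d_A pore diameter, Angstrom
#' @param L_A pore length, Angstrom; lengths below the finest mesh spacing
#'   (and 0 itself) are modelled as a zero-thickness orifice plate, the
#'   Sampson configuration
#' @param slip_length_nm Navier slip length on all solid walls, nm; 0 for
#'   no slip, `Inf` for perfect slip
#' @param reservoir_radius radial extent of each reservoir, in pore radii
#' @param reservoir_height axial extent of each reservoir, in pore radii
#' @param refine mesh refinement level; each level halves all target
#'   spacings
#' @param mesh optional list overriding mesh parameters at level 1:
#'   `h_wall` (finest spacing at walls/corners), `h_core` (pore interior,
#'   radial), `h_res` (far reservoir), `h_pore_mid` (axial, mid-pore),
#'   `grow` (geometric grading ratio)
#' @return object of class `stokes_problem`
#' @export
stokes_problem <- function(d_A = 3, L_A = 30, slip_length_nm = 72,
                           reservoir_radius = 25, reservoir_height = 25,
                           refine = 1, mesh = list()) {
  if (d_A <= 0) stop("d_A must be > 0")
  if (L_A < 0) stop("L_A must be >= 0")
  if (slip_length_nm < 0) stop("slip_length_nm must be >= 0")
  if (reservoir_radius < 20 || reservoir_height < 20) {
    stop("reservoir extents must be at least 20 pore radii (truncation control)")
  }
  a_A <- d_A / 2
  defaults <- list(h_wall = 0.025, h_core = 0.12, h_res = 1.8,
                   h_pore_mid = NULL, grow = 1.2)
  mesh <- utils::modifyList(defaults, mesh)
  structure(list(d_A = d_A, a_A = a_A,
                 L = L_A / a_A,                     # pore length in radii
                 b = slip_length_nm * 10 / a_A,      # slip length in radii
                 R_res = reservoir_radius, H_res = reservoir_height,
                 refine = refine, mesh = mesh),
            class = "stokes_problem")
}

# graded spacings across [0, len]: start h0 at the left end and h1 at the
# right end, grow geometrically towards the interior, cap at hmax, then
# rescale so they sum exactly to len
graded_spacings <- function(len, h0, h1, hmax, grow) {
  stopifnot(len > 0, h0 > 0, h1 > 0, hmax > 0, grow >= 1)
  left <- numeric(0); right <- numeric(0)
  hl <- min(h0, hmax); hr <- min(h1, hmax); total <- 0
  while (total < len) {
    if (hl <= hr) {
      left <- c(left, hl); total <- total + hl; hl <- min(hl * grow, hmax)
    } else {
      right <- c(right, hr); total <- total + hr; hr <- min(hr * grow, hmax)
    }
  }
  sp <- c(left, rev(right))
  sp * (len / sum(sp))
}

# build the tensor-product mesh for a problem at a given refinement level
stokes_mesh <- function(problem, refine = problem$refine) {
  m <- problem$mesh
  s <- 2^(refine - 1)
  h_wall <- m$h_wall / s
  h_core <- m$h_core / s
  h_res <- m$h_res / s
  grow <- m$grow
  L <- problem$L
  R <- problem$R_res
  H <- problem$H_res

  orifice <- L < 2 * h_wall
  h_mid <- if (is.null(m$h_pore_mid)) {
    min(max(0.15, L / 60), 12)
  } else m$h_pore_mid
  h_mid <- max(h_mid / s, h_wall)

  # radial faces: [0, 1] graded to the wall, then [1, R] graded away
  sp_in <- graded_spacings(1, h_core, h_wall, h_core, grow)
  sp_out <- graded_spacings(R - 1, h_wall, h_res, h_res, grow)
  rf <- c(0, cumsum(c(sp_in, sp_out)))
  rf[length(sp_in) + 1] <- 1                     # wall face exactly at r = 1
  rf[length(rf)] <- R
  ir_wall <- length(sp_in)                        # face index of r = 1

  # axial faces
  sp_bot <- graded_spacings(H, h_res, h_wall, h_res, grow)
  sp_top <- rev(sp_bot)
  if (orifice) {
    zf <- c(-H, cumsum(c(sp_bot, sp_top))) - H + H  # placeholder, fix below
    zf <- -H + c(0, cumsum(c(sp_bot, sp_top)))
    jz_walls <- length(sp_bot)                   # plate plane at z = 0
    zf[jz_walls + 1] <- 0
  } else {
    sp_pore <- graded_spacings(L, h_wall, h_wall, h_mid, grow)
    zf <- -H + c(0, cumsum(c(sp_bot, sp_pore, sp_top)))
    j0 <- length(sp_bot)
    jL <- j0 + length(sp_pore)
    zf[j0 + 1] <- 0
    zf[jL + 1] <- L
    jz_walls <- c(j0, jL)                        # membrane planes z = 0, L
  }
  zf[length(zf)] <- L_top <- if (orifice) H else L + H

  Nr <- length(rf) - 1
  Nz <- length(zf) - 1
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  dr <- diff(rf)
  dz <- diff(zf)

  fluid <- matrix(TRUE, Nr, Nz)
  if (!orifice) {
    fluid <- outer(rc, zc, function(r, z) !(r > 1 & z > 0 & z < L))
  }

  list(rf = rf, zf = zf, rc = rc, zc = zc, dr = dr, dz = dz,
       Nr = Nr, Nz = Nz, fluid = fluid, ir_wall = ir_wall,
       jz_walls = jz_walls, orifice = orifice, L = L, b = problem$b)
}

#' Solve the axisymmetric Stokes problem
#'
#' Assembles and solves the discrete Stokes system (momentum + continuity)
#' and integrates the axial velocity over pore cross-sections for the flow
#' rate. The solve is performed in nondimensional variables (lengths in
#' pore radii, unit viscosity, unit pressure drop); results are scaled to
#' the requested `delta_p`.
#'
#' @param problem a [stokes_problem()]
#' @param delta_p applied pressure difference, Pa
#' @param eta viscosity used for dimensional output, Pa s
#' @param refine mesh refinement level (defaults to the problem's)
#' @return object of class `stokes_solution`: list with `C_factor`,
#'   `Q_m3_s`, `delta_p`, `mass_error` (max relative flow-rate imbalance
#'   across pore cross-sections), `n_unknowns`, and the mesh
#' @export
stokes_solve <- function(problem, delta_p = 1, eta = 1e-3,
                         refine = problem$refine) {
  stopifnot(inherits(problem, "stokes_problem"))
  msh <- stokes_mesh(problem, refine)
  sys <- stokes_assemble(msh)
  x <- Matrix::solve(sys$A, sys$rhs)
  x <- as.numeric(x)

  # flow rate through every cross-section that spans the pore aperture
  w_at <- function(i, j) {                # w value at face (rc_i, zf_j)
    k <- sys$w_idx[i, j + 1L]
    if (k > 0) x[k] else 0
  }
  in_pore <- which(msh$rc < 1)
  jfaces <- if (msh$orifice) msh$jz_walls else {
    seq(msh$jz_walls[1], msh$jz_walls[2])
  }
  Qs <- vapply(jfaces, function(j) {
    2 * pi * sum(msh$rc[in_pore] * msh$dr[in_pore] *
                   vapply(in_pore, w_at, numeric(1), j = j))
  }, numeric(1))
  Q_nd <- Qs[ceiling(length(Qs) / 2)]
  if (Q_nd <= 0) stop("solver produced non-positive flow rate; mesh diagnostics: ",
                      "Nr=", msh$Nr, " Nz=", msh$Nz)
  mass_error <- max(abs(Qs - Q_nd)) / Q_nd

  C <- 1 / Q_nd                            # C = (dp/Q) a^3 / eta, nondim
  a_m <- A_to_m(problem$a_A)
  structure(list(C_factor = C,
                 Q_m3_s = delta_p * a_m^3 / (C * eta),
                 delta_p = delta_p, eta = eta,
                 mass_error = mass_error,
                 n_unknowns = length(x),
                 Q_profile = Qs, mesh = msh),
            class = "stokes_solution")
}

# Assemble the sparse MAC discretization: unknowns are radial velocity u
# on radial faces, axial velocity w on axial faces, pressure p in fluid
# cells. Returns the matrix, right-hand side and index maps.
stokes_assemble <- function(msh) {
  Nr <- msh$Nr; Nz <- msh$Nz
  rf <- msh$rf; zf <- msh$zf; rc <- msh$rc; zc <- msh$zc
  dr <- msh$dr; dz <- msh$dz
  fluid <- msh$fluid
  b <- msh$b
  inv_bd <- function(dg) if (is.infinite(b)) 0 else 1 / (b + dg)

  # z-wall plane at face j covering r >= 1?
  has_zwall <- function(jface, rval) {
    any(msh$jz_walls == jface) && rval >= 1 - 1e-12
  }

  # --- unknown numbering ---------------------------------------------------
  p_idx <- matrix(0L, Nr, Nz)
  u_idx <- matrix(0L, max(Nr - 1, 1), Nz)   # u at (rf_i, zc_j), i=1..Nr-1
  w_idx <- matrix(0L, Nr, Nz + 1)           # w at (rc_i, zf_j), j=0..Nz (col j+1)
  w_wall <- matrix(FALSE, Nr, Nz + 1)       # Dirichlet w = 0 (membrane/plate)

  nun <- 0L
  for (j in seq_len(Nz)) for (i in seq_len(Nr)) {
    if (fluid[i, j]) { nun <- nun + 1L; p_idx[i, j] <- nun }
  }
  for (j in seq_len(Nz)) for (i in seq_len(Nr - 1)) {
    if (fluid[i, j] && fluid[i + 1, j]) { nun <- nun + 1L; u_idx[i, j] <- nun }
  }
  for (jj in 0:Nz) for (i in seq_len(Nr)) {
    if (jj == 0) {
      if (fluid[i, 1]) { nun <- nun + 1L; w_idx[i, 1] <- nun }
    } else if (jj == Nz) {
      if (fluid[i, Nz]) { nun <- nun + 1L; w_idx[i, Nz + 1] <- nun }
    } else {
      f1 <- fluid[i, jj]; f2 <- fluid[i, jj + 1]
      if (f1 && f2) {
        if (msh$orifice && jj == msh$jz_walls[1] && rc[i] > 1) {
          w_wall[i, jj + 1] <- TRUE         # orifice plate
        } else { nun <- nun + 1L; w_idx[i, jj + 1] <- nun }
      } else if (xor(f1, f2)) {
        w_wall[i, jj + 1] <- TRUE           # membrane face
      }
    }
  }

  # --- triplet buffers -----------------------------------------------------
  cap <- 14L * nun
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap); nt <- 0L
  add <- function(r, c, v) {
    nt <<- nt + 1L
    if (nt > length(ti)) {               # grow (should not normally trigger)
      ti <<- c(ti, integer(cap)); tj <<- c(tj, integer(cap))
      tx <<- c(tx, numeric(cap))
    }
    ti[nt] <<- r; tj[nt] <<- c; tx[nt] <<- v
  }
  rhs <- numeric(nun)

  # --- u momentum ----------------------------------------------------------
  for (j in seq_len(Nz)) for (i in seq_len(Nr - 1)) {
    row <- u_idx[i, j]
    if (row == 0L) next
    r0 <- rf[i + 1]                       # face radius (1-based: face i at rf[i+1])
    cvw <- rc[i + 1] - rc[i]              # radial CV spans [rc_i, rc_{i+1}]
    diag_c <- 0
    # east flux, evaluated at rc_{i+1}, spacing dr_{i+1} between faces
    cE <- rc[i + 1] / (cvw * r0 * dr[i + 1])
    if (i + 1 <= Nr - 1 && u_idx[i + 1, j] > 0) add(row, u_idx[i + 1, j], cE)
    diag_c <- diag_c - cE
    # west flux at rc_i
    cW <- rc[i] / (cvw * r0 * dr[i])
    if (i - 1 >= 1 && u_idx[i - 1, j] > 0) add(row, u_idx[i - 1, j], cW)
    diag_c <- diag_c - cW
    # curvature term -u/r^2
    diag_c <- diag_c - 1 / r0^2
    # axial part, CV height dz_j
    if (j < Nz) {
      if (has_zwall(j, r0)) {
        diag_c <- diag_c - inv_bd(dz[j] / 2) / dz[j]
      } else {
        sp <- zc[j + 1] - zc[j]
        cN <- 1 / (sp * dz[j])
        if (u_idx[i, j + 1] > 0) add(row, u_idx[i, j + 1], cN)
        diag_c <- diag_c - cN
      }
    }                                      # j == Nz: open top, zero flux
    if (j > 1) {
      if (has_zwall(j - 1, r0)) {
        diag_c <- diag_c - inv_bd(dz[j] / 2) / dz[j]
      } else {
        sp <- zc[j] - zc[j - 1]
        cS <- 1 / (sp * dz[j])
        if (u_idx[i, j - 1] > 0) add(row, u_idx[i, j - 1], cS)
        diag_c <- diag_c - cS
      }
    }
    add(row, row, diag_c)
    # pressure gradient: -(p_E - p_W)/cvw
    add(row, p_idx[i + 1, j], -1 / cvw)
    add(row, p_idx[i, j], 1 / cvw)
  }

  # --- w momentum ----------------------------------------------------------
  for (jj in 0:Nz) for (i in seq_len(Nr)) {
    row <- w_idx[i, jj + 1]
    if (row == 0L) next
    diag_c <- 0
    # radial part, CV spans [rf_{i-1}, rf_i] of width dr_i at radius rc_i
    # east flux at face rf_i
    if (i < Nr) {
      jlo <- max(jj, 1); jhi <- min(jj + 1, Nz)
      east_solid <- !fluid[i + 1, jlo] && !fluid[i + 1, jhi]
      if (east_solid) {
        # pore wall at rf_i = 1: Navier slip flux
        dg <- rf[i + 1] - rc[i]
        cwall <- rf[i + 1] * inv_bd(dg) / (rc[i] * dr[i])
        diag_c <- diag_c - cwall
      } else {
        sp <- rc[i + 1] - rc[i]
        cE <- rf[i + 1] / (rc[i] * dr[i] * sp)
        if (w_idx[i + 1, jj + 1] > 0) add(row, w_idx[i + 1, jj + 1], cE)
        # else neighbour is a Dirichlet w = 0 wall face: no entry
        diag_c <- diag_c - cE
      }
    }                                      # i == Nr: shear-free lateral wall
    # west flux at face rf_{i-1} (vanishes on the axis where rf = 0)
    if (i > 1) {
      sp <- rc[i] - rc[i - 1]
      cW <- rf[i] / (rc[i] * dr[i] * sp)
      if (w_idx[i - 1, jj + 1] > 0) add(row, w_idx[i - 1, jj + 1], cW)
      diag_c <- diag_c - cW
    }
    # axial part and pressure
    if (jj == 0) {
      hz <- dz[1] / 2
      cN <- 1 / (dz[1] * hz)
      if (w_idx[i, 2] > 0) add(row, w_idx[i, 2], cN)
      diag_c <- diag_c - cN
      add(row, p_idx[i, 1], -1 / hz)
      rhs[row] <- rhs[row] - 1 / hz        # bottom pressure p = 1
    } else if (jj == Nz) {
      hz <- dz[Nz] / 2
      cS <- 1 / (dz[Nz] * hz)
      if (w_idx[i, Nz] > 0) add(row, w_idx[i, Nz], cS)
      diag_c <- diag_c - cS
      add(row, p_idx[i, Nz], 1 / hz)       # top pressure p = 0
    } else {
      hz <- zc[jj + 1] - zc[jj]
      cN <- 1 / (dz[jj + 1] * hz)
      if (w_idx[i, jj + 2] > 0) add(row, w_idx[i, jj + 2], cN)
      diag_c <- diag_c - cN
      cS <- 1 / (dz[jj] * hz)
      if (w_idx[i, jj] > 0) add(row, w_idx[i, jj], cS)
      diag_c <- diag_c - cS
      add(row, p_idx[i, jj + 1], -1 / hz)
      add(row, p_idx[i, jj], 1 / hz)
    }
    add(row, row, diag_c)
  }

  # --- continuity ----------------------------------------------------------
  for (j in seq_len(Nz)) for (i in seq_len(Nr)) {
    row <- p_idx[i, j]
    if (row == 0L) next
    if (i <= Nr - 1 && u_idx[i, j] > 0) {
      add(row, u_idx[i, j], rf[i + 1] / (rc[i] * dr[i]))
    }
    if (i >= 2 && u_idx[i - 1, j] > 0) {
      add(row, u_idx[i - 1, j], -rf[i] / (rc[i] * dr[i]))
    }
    if (w_idx[i, j + 1] > 0) add(row, w_idx[i, j + 1], 1 / dz[j])
    if (w_idx[i, j] > 0) add(row, w_idx[i, j], -1 / dz[j])
  }

  A <- Matrix::sparseMatrix(i = ti[seq_len(nt)], j = tj[seq_len(nt)],
                            x = tx[seq_len(nt)], dims = c(nun, nun))
  list(A = A, rhs = rhs, u_idx = u_idx, w_idx = w_idx, p_idx = p_idx)
}

#' Mesh-converged dimensionless resistance factor C
#'
#' Solves the problem on a sequence of uniformly refined meshes (each
#' level halves all target spacings) and extrapolates to zero mesh size
#' with the observed convergence order, the standard grid-convergence
#' procedure. Observed-order extrapolation matters here because the sharp
#' pore-mouth corner carries a stress singularity that reduces the raw
#' convergence order of the flow rate below one on slipping walls.
#'
#' @param problem a [stokes_problem()]
#' @param n_levels number of refinement levels (>= 2; default 3). With 2
#'   levels first-order extrapolation is used.
#' @param conv_tol maximum allowed relative change of C between the last
#'   two levels; larger changes raise a convergence error
#' @return the extrapolated dimensionless factor C, with attributes
#'   `values` (per-level C), `order` (observed convergence order),
#'   `conv_change` (relative change at the last refinement),
#'   `mass_error` and `n_unknowns` (finest solve)
#' @export
c_factor <- function(problem, n_levels = 3, conv_tol = 0.05) {
  stopifnot(n_levels >= 2)
  levels <- problem$refine + seq_len(n_levels) - 1
  sols <- lapply(levels, function(rl) stokes_solve(problem, refine = rl))
  Cs <- vapply(sols, function(s) s$C_factor, numeric(1))
  n <- length(Cs)
  change <- abs(Cs[n] - Cs[n - 1]) / Cs[n]
  if (change > conv_tol) {
    stop(sprintf("mesh not converged: C changed by %.2f%% at the last refinement",
                 100 * change))
  }
  if (n >= 3) {
    f <- (Cs[n] - Cs[n - 1]) / (Cs[n - 1] - Cs[n - 2])
    if (is.finite(f) && f > 0.05 && f < 0.95) {
      C_ext <- Cs[n] + (Cs[n] - Cs[n - 1]) * f / (1 - f)
      order <- -log2(f)
    } else {                       # already at rounding plateau, or erratic
      C_ext <- Cs[n]
      order <- NA_real_
    }
  } else {
    C_ext <- 2 * Cs[2] - Cs[1]
    order <- 1
  }
  structure(C_ext, values = Cs, order = order, conv_change = change,
            mass_error = sols[[n]]$mass_error,
            n_unknowns = sols[[n]]$n_unknowns)
}

#' Sweep the factor C over pore lengths
#'
#' @param lengths_A pore lengths in Angstrom
#' @param d_A pore diameter, Angstrom
#' @param slip_length_nm Navier slip length, nm
#' @param refine base mesh refinement level for each solve
#' @param n_levels refinement levels for the extrapolated estimate; 1
#'   gives the raw single-mesh value
#' @param ... further arguments to [stokes_problem()]
#' @return data frame with columns `L_A` and `C`
#' @export
c_sweep <- function(lengths_A, d_A = 3, slip_length_nm = 72, refine = 1,
                    n_levels = 3, ...) {
  C <- vapply(lengths_A, function(L) {
    pr <- stokes_problem(d_A = d_A, L_A = L, slip_length_nm = slip_length_nm,
                         refine = refine, ...)
    if (n_levels <= 1) stokes_solve(pr)$C_factor
    else as.numeric(c_factor(pr, n_levels = n_levels))
  }, numeric(1))
  data.frame(L_A = lengths_A, C = C)
}

#' @export
print.stokes_solution <- function(x, ...) {
  cat(sprintf("Stokes solution: C = %.4f (mass imbalance %.3e, %d unknowns)\n",
              x$C_factor, x$mass_error, x$n_unknowns))
  cat(sprintf("  Q = %.4e m^3/s at delta_p = %.4e Pa\n", x$Q_m3_s, x$delta_p))
  invisible(x)
}
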
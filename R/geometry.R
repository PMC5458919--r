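# Hourglass pore parameterization: the pore axis is z, the pore spans
# [0, L] with its narrowest section at the centre plane z = L/2. The cone
# half-opening angle alpha is measured between the conical wall and the
# axis, so the radius grows by tan(alpha) per unit axial length away from
# the centre and the entrance diameter is d(0) = d_center + L tan(alpha).

#' Hourglass pore geometry
#'
#' Describes a biconical ("hourglass") pore: two opposed truncated cones
#' meeting at a narrow central constriction, the geometry of aquaporin
#' water channels. `alpha_deg = 0` gives a straight cylindrical pore.
#'
#' @param d_center_A narrowest diameter at the pore centre, Angstrom
#' @param L_A total pore length, Angstrom
#' @param alpha_deg cone half-opening angle in degrees (wall-to-axis angle)
#' @param pool_A reservoir (pool) box dimensions in Angstrom, length-3
#'   vector `c(x, y, z)`
#' @return object of class `pore_geometry`
#' @examples
#' geom <- pore_geometry(d_center_A = 3, L_A = 30, alpha_deg = 9)
#' diameter_at(geom, 0)    # entrance diameter
#' diameter_at(geom, 15)   # narrowest point, 3 A
#' @export
pore_geometry <- function(d_center_A = 3, L_A = 30, alpha_deg = 9,
                          pool_A = c(50, 50, 20)) {
  stopifnot(is.numeric(d_center_A), length(d_center_A) == 1L,
            is.numeric(L_A), length(L_A) == 1L,
            is.numeric(alpha_deg), length(alpha_deg) == 1L,
            length(pool_A) == 3L)
  if (d_center_A <= 0) stop("d_center_A must be > 0")
  if (L_A <= 0) stop("L_A must be > 0")
  if (alpha_deg < 0 || alpha_deg >= 90) stop("alpha_deg must be in [0, 90)")
  if (any(pool_A <= 0)) stop("pool dimensions must be > 0")
  structure(list(d_center_A = d_center_A, L_A = L_A, alpha_deg = alpha_deg,
                 pool_A = as.numeric(pool_A)),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf(
    "Hourglass pore: d_center = %g A, L = %g A, alpha = %g deg, d(0) = %.3f A\n",
    x$d_center_A, x$L_A, x$alpha_deg, diameter_at(x, 0)))
  cat(sprintf("Pool: %g x %g x %g A\n", x$pool_A[1], x$pool_A[2], x$pool_A[3]))
  invisible(x)
}

#' Axial diameter law of the hourglass pore
#'
#' Piecewise-linear diameter as a function of axial position: minimal
#' `d_center` at the centre plane `z = L/2`, growing linearly with slope
#' `2 tan(alpha)` towards either mouth; symmetric about the centre.
#'
#' @param geom a [pore_geometry()]
#' @param z_A axial position(s), Angstrom, within `[0, L]`
#' @return diameter(s) in Angstrom
#' @export
diameter_at <- function(geom, z_A) {
  stopifnot(inherits(geom, "pore_geometry"))
  if (any(z_A < 0 | z_A > geom$L_A)) {
    stop("z_A outside the pore span [0, L]")
  }
  tan_a <- tan(geom$alpha_deg * pi / 180)
  dist_from_mouth <- pmin(z_A, geom$L_A - z_A)
  geom$d_center_A + 2 * tan_a * (geom$L_A / 2 - dist_from_mouth)
}

#' Atomistic structure of the pore and pool walls
#'
#' Builds the wall model: stacked concentric carbon rings of radius
#' `d(z)/2` along the pore, plus two flat rectangular-lattice wall plates
#' closing the pools at `z = 0` and `z = L`, with atoms excluded inside
#' the pore aperture. Purely geometric; no force field is assigned.
#'
#' @param geom a [pore_geometry()]
#' @param ring_spacing_A axial spacing between rings, Angstrom (default 2,
#'   narrower than a water molecule so the wall is water-tight)
#' @param lattice_spacing_A wall-plate lattice constant, Angstrom (default 2)
#' @return object of class `pore_structure`: data frame of atoms
#'   (`element`, `x`, `y`, `z` in Angstrom, `part` = "ring" or "wall")
#'   with the spacings as attributes
#' @export
build_structure <- function(geom, ring_spacing_A = 2, lattice_spacing_A = 2) {
  stopifnot(inherits(geom, "pore_geometry"))
  if (ring_spacing_A <= 0 || lattice_spacing_A <= 0) {
    stop("spacings must be > 0")
  }
  L <- geom$L_A
  z_rings <- seq(0, L, by = ring_spacing_A)
  if (z_rings[length(z_rings)] < L) z_rings <- c(z_rings, L)

  ring_atoms <- do.call(rbind, lapply(z_rings, function(z) {
    r <- diameter_at(geom, z) / 2
    n <- max(3L, ceiling(2 * pi * r / min(ring_spacing_A, lattice_spacing_A)))
    th <- 2 * pi * (seq_len(n) - 1L) / n
    data.frame(element = "C", x = r * cos(th), y = r * sin(th), z = z,
               part = "ring")
  }))

  # wall plates: rectangular lattice spanning the pool cross-section,
  # pierced by the pore aperture at each mouth
  half_x <- geom$pool_A[1] / 2
  half_y <- geom$pool_A[2] / 2
  gx <- seq(-half_x, half_x, by = lattice_spacing_A)
  gy <- seq(-half_y, half_y, by = lattice_spacing_A)
  lat <- expand.grid(x = gx, y = gy)
  r_mouth <- diameter_at(geom, 0) / 2
  keep <- sqrt(lat$x^2 + lat$y^2) > r_mouth
  wall_atoms <- do.call(rbind, lapply(c(0, L), function(z) {
    data.frame(element = "C", x = lat$x[keep], y = lat$y[keep], z = z,
               part = "wall")
  }))

  atoms <- rbind(ring_atoms, wall_atoms)
  rownames(atoms) <- NULL
  structure(atoms, class = c("pore_structure", "data.frame"),
            ring_spacing_A = ring_spacing_A,
            lattice_spacing_A = lattice_spacing_A,
            geometry = geom)
}

#' Young-Laplace capillary entry pressure of a cylindrical aperture
#'
#' Minimum pressure needed to push water past a (hydrophobic) aperture of
#' diameter `d`: `-4 gamma cos(theta) / d`. Positive for contact angles
#' above 90 degrees.
#'
#' @param d_A aperture diameter, Angstrom
#' @param surface_tension_N_m surface tension gamma, N/m (water ~ 0.072)
#' @param contact_angle_deg contact angle theta in degrees, in (0, 180)
#' @return entry pressure in Pa
#' @export
young_laplace_entry_pressure <- function(d_A, surface_tension_N_m = 0.072,
                                         contact_angle_deg = 95) {
  if (d_A <= 0) stop("d_A must be > 0")
  if (contact_angle_deg <= 0 || contact_angle_deg >= 180) {
    stop("contact_angle_deg must be in (0, 180)")
  }
  -4 * surface_tension_N_m * cos(contact_angle_deg * pi / 180) / A_to_m(d_A)
}

#' Write a structure to an XYZ file
#' @param structure a [build_structure()] result
#' @param path output file
#' @param comment comment line
#' @return `path`, invisibly
#' @export
write_structure_xyz <- function(structure, path, comment = "pore structure") {
  stopifnot(inherits(structure, "pore_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(structure)), comment), con)
  writeLines(sprintf("%s %12.6f %12.6f %12.6f",
                     structure$element, structure$x, structure$y,
                     structure$z), con)
  invisible(path)
}

#' Write a structure to a minimal PDB file
#' @inheritParams write_structure_xyz
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "pore_structure"))
  n <- nrow(structure)
  lines <- sprintf(
    "ATOM  %5d  C   POR A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, structure$x, structure$y, structure$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a pore geometry from a YAML or JSON config file
#'
#' Keys: `d_center_A`, `L_A`, `alpha_deg`, optional `pool_A` (length 3).
#'
#' @param path config file (`.yaml`/`.yml` or `.json`)
#' @return a [pore_geometry()]
#' @export
read_geometry_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pool <- if (is.null(cfg$pool_A)) c(50, 50, 20) else unlist(cfg$pool_A)
  pore_geometry(d_center_A = cfg$d_center_A, L_A = cfg$L_A,
                alpha_deg = cfg$alpha_deg, pool_A = pool)
}
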
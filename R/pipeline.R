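# End-to-end pipeline: analytical resistance curves over the study grid
# of pore lengths and cone angles, synthetic pressure-pair runs driven by
# the analytical resistance, trajectory-side resistance and permeability
# estimates, and a combined comparison table.

#' Pipeline configuration
#'
#' @param d_center_A constriction diameter, Angstrom
#' @param lengths_A pore lengths to scan, Angstrom
#' @param alphas_deg cone-angle grid, degrees
#' @param pressures_katm external pressures, katm
#' @param C_pa named vector of access factors per length (names =
#'   lengths); defaults to the solver values 3.81 (30 A) and 3.85 (60 A)
#'   under partial slip with b = 72 nm
#' @param fluid a [fluid_properties()]
#' @param duration_ns,stride_ps,n_molecules generator settings per run
#' @param out_dir output directory (created if missing); `NULL` disables
#'   writing
#' @param seed root seed; every run derives its own stream from it
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(d_center_A = 3, lengths_A = c(30, 60),
                            alphas_deg = c(1, 3, 5, 7, 9, 11, 13),
                            pressures_katm = c(6.04, 10.03),
                            C_pa = c("30" = 3.81, "60" = 3.85),
                            fluid = fluid_properties(),
                            duration_ns = 4, stride_ps = 5,
                            n_molecules = 400,
                            out_dir = NULL, seed = 1) {
  stopifnot(length(lengths_A) >= 1, length(alphas_deg) >= 1,
            length(pressures_katm) >= 1)
  if (!all(as.character(lengths_A) %in% names(C_pa))) {
    stop("C_pa must provide a value for every pore length")
  }
  structure(list(d_center_A = d_center_A, lengths_A = lengths_A,
                 alphas_deg = alphas_deg, pressures_katm = pressures_katm,
                 C_pa = C_pa, fluid = fluid, duration_ns = duration_ns,
                 stride_ps = stride_ps, n_molecules = n_molecules,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  fl_args <- cfg$fluid %||% list()
  args <- cfg[setdiff(names(cfg), "fluid")]
  args$fluid <- do.call(fluid_properties, fl_args)
  if (!is.null(args$C_pa)) args$C_pa <- unlist(args$C_pa)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# atomic writer: write to a temp file in the same directory, then rename
write_atomic <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a data frame as TSV
#' @param x data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv_table <- function(x, path) {
  write_atomic(function(p) utils::write.table(
    x, p, sep = "\t", row.names = FALSE, quote = FALSE), path)
}

#' Run the full analysis pipeline
#'
#' For every (length, angle) combination: evaluates the analytical total
#' resistance, programs the synthetic generator with the corresponding
#' permeability, generates one run per pressure, estimates the
#' permeability and trajectory-side resistance, and collects everything
#' into a comparison table. With an output directory set, writes
#' `comparison.tsv` and a `manifest.json` (full configuration, seed and
#' config hash) that allows an exact re-run.
#'
#' @param config a [pipeline_config()]
#' @return data frame with one row per (alpha, L): `alpha_deg`, `L_A`,
#'   `C_pa`, `R_analytical`, `R_from_trajectory`, `K_est`, `K_se`, `p_f`,
#'   `p_f_volumetric`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fluid <- config$fluid
  rows <- list()
  combo <- 0L
  for (L in config$lengths_A) {
    C_pa <- unname(config$C_pa[as.character(L)])
    for (alpha in config$alphas_deg) {
      combo <- combo + 1L
      geom <- pore_geometry(config$d_center_A, L, alpha)
      br <- total_resistance(geom, fluid, C_pa)
      K_true <- K_from_resistance(br, fluid)
      gen <- generator_config(geom,
                              delta_p = katm_to_Pa(config$pressures_katm[1]),
                              true_K = K_true,
                              duration_ns = config$duration_ns,
                              stride_ps = config$stride_ps,
                              n_molecules = config$n_molecules,
                              seed = config$seed)
      runs <- lapply(seq_along(config$pressures_katm), function(i) {
        cfg <- gen
        cfg$delta_p <- katm_to_Pa(config$pressures_katm[i])
        cfg$seed <- config$seed + 911L * combo + 7919L * i
        list(traj = generate_trajectory(cfg), delta_p = cfg$delta_p)
      })
      est <- estimate_permeability(runs, geom, fluid,
                                   seed = config$seed + combo)
      R_traj <- if (est$K <= 0) Inf else
        1 / (est$K * water_molecular_volume(fluid$V_w_cm3_mol))
      rows[[combo]] <- data.frame(
        alpha_deg = alpha, L_A = L, C_pa = C_pa,
        R_analytical = br$R_total, R_from_trajectory = R_traj,
        K_est = est$K, K_se = est$K_se, p_f = est$p_f,
        p_f_volumetric = est$p_f_volumetric)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(out, file.path(config$out_dir, "comparison.tsv"))
    cfg_plain <- config
    cfg_plain$fluid <- unclass(config$fluid)
    cfg_json <- jsonlite::toJSON(unclass(cfg_plain), auto_unbox = TRUE,
                                 digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest <- list(config = jsonlite::fromJSON(cfg_json),
                     config_md5 = unname(tools::md5sum(tmp)),
                     seed = config$seed,
                     created = format(Sys.time(), tz = "UTC"))
    unlink(tmp)
    write_atomic(function(p) jsonlite::write_json(
      manifest, p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(config$out_dir, "manifest.json"))
  }
  out
}
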
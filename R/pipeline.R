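# End-to-end study drivers: the osteotomy-volume study (phantom cohort ->
# planned tools -> Boolean volumes -> statistics) and the biomechanical
# study (phantom -> surgical variants -> FE solves -> ROM/stress tables),
# plus the analytic verification suite.  The numbered scripts under
# `analysis/` are thin wrappers over these functions.

#' Default run configuration
#'
#' @param n_subjects cohort size
#' @param jitter inter-subject coefficient of variation
#' @param seed master seed for every random draw
#' @param angles,diameters,attempts plan factorial
#' @param pitch Boolean integration pitch (mm)
#' @param target_edge FE mesh edge (mm)
#' @param out_dir output directory
#' @return named list of class `run_config`
#' @export
run_config <- function(n_subjects = 25, jitter = 0.05, seed = 20240101,
                       angles = c(20, 30, 40, 50, 60, 70),
                       diameters = c(7, 8, 9), attempts = c(1, 2),
                       pitch = 0.5, target_edge = 3, out_dir = "results") {
  cfg <- list(n_subjects = n_subjects, jitter = jitter, seed = as.integer(seed),
              angles = angles, diameters = diameters, attempts = attempts,
              pitch = pitch, target_edge = target_edge, out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  known <- c("n_subjects", "jitter", "seed", "angles", "diameters", "attempts",
             "pitch", "target_edge", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown configuration keys: ",
                          paste(extra, collapse = ", "))
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  if (!all(cfg$angles %in% c(20, 30, 40, 50, 60, 70)))
    stop("angles must be within the planned fan (20-70 degrees)")
  if (cfg$pitch <= 0 || cfg$target_edge <= 0) stop("pitch/target_edge must be positive")
  invisible(TRUE)
}

#' Read/write run configurations as YAML
#' @param path file path
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_config
#' @param config a `run_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_csv_stable <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

provenance <- function(config, stage) {
  list(stage = stage,
       config = unclass(config),
       config_hash = sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("lumbosim")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Run the osteotomy volume study
#'
#' Draws the synthetic cohort, plans the full trephine factorial on every
#' subject, computes Boolean resection volumes with per-structure
#' attribution, and writes the long-format volume table, the mean +- SD
#' summary, the angle-contrast tests and a provenance record.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `volumes`, `summary`, `contrasts`
#' @export
run_volume_study <- function(config = run_config()) {
  spec <- cohort_spec(config$n_subjects, config$jitter, config$seed)
  volumes <- run_volume_experiment(spec, angles = config$angles,
                                   diameters = config$diameters,
                                   attempts = config$attempts,
                                   pitch = config$pitch)
  summary <- summarize_volumes(volumes)
  contrasts <- angle_contrasts(volumes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_stable(volumes, file.path(config$out_dir, "volumes.csv"))
  write_csv_stable(summary, file.path(config$out_dir, "volume_summary.csv"))
  write_csv_stable(contrasts, file.path(config$out_dir, "volume_contrasts.csv"))
  jsonlite::write_json(provenance(config, "volumes"),
                       file.path(config$out_dir, "volumes_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  errs <- attr(volumes, "errors")
  if (length(errs))
    jsonlite::write_json(errs, file.path(config$out_dir, "volumes_errors.json"),
                         auto_unbox = TRUE)
  invisible(list(volumes = volumes, summary = summary, contrasts = contrasts))
}

#' Run the biomechanical study
#'
#' Builds the FE model of the default phantom, applies the six surgical
#' variants and solves the six-direction load protocol, writing the
#' ROM/stress results table and a provenance record.
#'
#' @param config a [run_config()]
#' @param variants variant ids (default M1..M6)
#' @return invisibly, the results data frame
#' @export
run_biomech_study <- function(config = run_config(), variants = paste0("M", 1:6)) {
  model <- generate_phantom(subject_params(rng_seed = config$seed %% 1000003L))
  res <- run_fe_experiment(model, variants = variants,
                           target_edge = config$target_edge)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_stable(res, file.path(config$out_dir, "fe_results.csv"))
  jsonlite::write_json(provenance(config, "biomech"),
                       file.path(config$out_dir, "fe_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Render the biomechanics report tables from a stored results CSV
#'
#' Regenerates per-direction ROM and per-region stress tables without
#' re-solving.
#' @param results_csv path to `fe_results.csv`
#' @return list of per-direction data frames
#' @export
biomech_report <- function(results_csv) {
  res <- utils::read.csv(results_csv)
  split(res[, c("variant", "rom_L4L5", "rom_L3L4", "vm_annulus_L4L5",
                "vm_endplate_L5_superior", "vm_endplate_L4_inferior")],
        res$direction)
}

#' Run the verification suite
#'
#' Analytic FE oracles (axial bar, patch test, cantilever bending, truss
#' bar formula), the Boolean-versus-Monte-Carlo volume check and the
#' phantom specification recovery, standing in for cadaveric
#' corroboration at desk scale.
#'
#' @param quick use reduced problem sizes
#' @return data frame of checks with pass/fail; attribute `ok` is TRUE
#'   when all pass
#' @export
run_validation <- function(quick = FALSE) {
  checks <- list()
  add <- function(name, value, bound, pass) {
    checks[[length(checks) + 1]] <<- data.frame(check = name, value = value,
                                                bound = bound, pass = pass)
  }
  bar <- check_axial_bar()
  add("axial bar vs FL/EA (rel err)", bar$rel_err, 0.01, bar$rel_err < 0.01)
  patch <- check_patch_test()
  add("patch test max error (mm)", patch, 1e-8, patch < 1e-8)
  tb <- check_truss_bar()
  add("truss force vs EA*delta/L (rel err)", tb$rel_err, 1e-12, tb$rel_err < 1e-12)
  cb <- check_cantilever(edge = if (quick) 0.5 else 0.375)
  add("cantilever deflection vs beam theory (rel err)", cb$rel_err_defl, 0.1,
      cb$rel_err_defl < 0.1)
  add("cantilever max stress vs Mc/I (rel err)", cb$rel_err_sigma, 0.1,
      cb$rel_err_sigma < 0.1)

  model <- generate_phantom()
  mf <- measure_area_fractions(model)
  add("nucleus/disc area fraction", mf$nucleus_over_disc, 0.4,
      abs(mf$nucleus_over_disc - 0.4) < 0.02 * 0.4)
  add("disc complex / vertebra area", mf$disc_over_vertebra, 0.95,
      abs(mf$disc_over_vertebra - 0.95) < 0.03)
  add("anterior/posterior offset ratio", mf$ap_offset_ratio, 1.62,
      abs(mf$ap_offset_ratio - 1.62) / 1.62 < 0.05)

  frame <- build_interspace_frame(model, model$planes$L4_inferior,
                                  model$planes$L5_superior)
  tool <- plan_tool(frame, trephine_plan(50, 8, 1))
  ex <- intersect_volume(model, tool$solid, pitch = 0.35)$total
  mc <- monte_carlo_volume(model, tool$solid,
                           n_samples = if (quick) 2e5 else 1e6, seed = 17)
  add("Boolean vs Monte Carlo (deviation / stderr)",
      abs(ex - mc$estimate) / mc$stderr, 3,
      abs(ex - mc$estimate) <= 3 * mc$stderr)

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  attr(out, "ok") <- all(out$pass)
  out
}
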
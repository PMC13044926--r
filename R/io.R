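# Configuration I/O (YAML/JSON), plan serialization and the top-level
# pipeline tying the modules together: symmetry selection -> geometry
# limits -> dose budget / transmission -> strategy -> simulation -> merged
# statistics.

#' Write / read a crystal description
#'
#' Crystals are stored as YAML with fields `cell`, `symmetry` (a list of
#' `{point_group, centring, setting}` records, the candidate arithmetic
#' crystal classes), `orientation` (row-major 3x3), `thickness_um`,
#' `sensitivity` and `target_resolution_A`.
#'
#' @param crystal A [crystal_sample()].
#' @param path File path.
#' @return `write_crystal` returns `path` invisibly; `read_crystal` a
#'   [crystal_sample()].
#' @export
write_crystal <- function(crystal, path) {
  classes <- lapply(crystal$symmetry$classes, function(cl) {
    rec <- list(point_group = cl$point_group$name, centring = cl$centring)
    if (!is.null(cl$setting)) rec$setting <- cl$setting
    rec
  })
  yaml::write_yaml(list(
    cell = as.numeric(crystal$cell),
    symmetry = classes,
    orientation = as.numeric(t(crystal$orientation)),
    thickness_um = crystal$thickness_um,
    sensitivity = crystal$sensitivity,
    target_resolution_A = crystal$target_resolution_A), path,
    precision = 15)
  invisible(path)
}

#' @rdname write_crystal
#' @export
read_crystal <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- lapply(y$symmetry, function(rec)
    arithmetic_class(rec$point_group, rec$centring %||% "P", rec$setting))
  crystal_sample(cell = as.numeric(y$cell),
                 symmetry = symmetry_candidates(classes),
                 orientation = matrix(as.numeric(y$orientation), 3, 3,
                                      byrow = TRUE),
                 thickness_um = y$thickness_um %||% 12,
                 sensitivity = y$sensitivity %||% 1,
                 target_resolution_A = y$target_resolution_A %||% 2)
}

#' Read an instrument configuration
#'
#' Detector, goniostat and beam YAML files with fields matching the
#' constructor arguments of [detector_model()], [goniostat_model()] and
#' [beam_model()]. A detector file may instead give `library: <name>` to
#' use a bundled model.
#'
#' @param path File path.
#' @return The corresponding model object.
#' @export
read_detector <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$library)) return(detector_library(y$library))
  detector_model(y$name %||% "detector", y$width_mm, y$height_mm, y$pixel_mm,
                 unlist(y$module_px), unlist(y$gap_px), unlist(y$n_modules),
                 y$min_distance_mm %||% 100,
                 unlist(y$beam_centre %||% c(0, 0)))
}

#' @rdname read_detector
#' @export
read_goniostat <- function(path) {
  y <- yaml::read_yaml(path)
  goniostat_model(y$kind %||% "mini-kappa",
                  y$cone_half_angle_deg %||% 19.84,
                  y$kappa_axis_angle_deg %||% 24,
                  y$chi_max_mech_deg %||% 48)
}

#' @rdname read_detector
#' @export
read_beam <- function(path) {
  y <- yaml::read_yaml(path)
  beam_model(y$profile %||% "tophat", y$b_x, y$b_y, y$total_flux,
             y$energy_keV %||% 12.398)
}

#' Serialize a strategy plan to JSON
#'
#' @param plan A `"strategy_plan"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  sweeps <- lapply(plan$sweeps, function(s) {
    list(kappa_deg = s$kappa_deg %||% NA, phi_deg = s$phi_deg %||% NA,
         chi_deg = s$chi_deg %||% NA,
         omega_start_deg = s$omega_start_deg, width_deg = s$width_deg,
         image_width_deg = s$image_width_deg %||% 0.1,
         exposure_per_image_s = s$exposure_per_image_s %||% NA,
         transmission = s$transmission %||% NA,
         setting = if (!is.null(s$setting)) as.numeric(t(s$setting)) else NULL)
  })
  jsonlite::write_json(list(schema = "mxsweep-plan-1",
                            kind = plan$kind %||% "strategy",
                            total_length_deg = plan$total_length_deg,
                            recentrings = plan$recentrings %||% 0,
                            sweeps = sweeps),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the strategy pipeline
#'
#' Executes the full compute path on one crystal: symmetry selection,
#' detector-distance and angle limits for the target resolution, dose
#' budget and recommended transmission, strategy generation, simulation and
#' merged statistics.
#'
#' @param crystal A [crystal_sample()]; its `target_resolution_A` is the
#'   one mandatory per-sample parameter.
#' @param detector A [detector_model()].
#' @param gonio A [goniostat_model()].
#' @param beam A [beam_model()].
#' @param mode `"basic"` or `"advanced"`.
#' @param total_exposure_s Planned total exposure (default 120 s).
#' @param wavelength_A Wavelength (default from the beam energy).
#' @param dose_params [dose_parameters()].
#' @param simulate Logical; run the diffraction simulation and merging
#'   (default `TRUE`).
#' @return Object of class `"mxsweep_report"`: a list with the selected
#'   symmetry, geometry, dose, plan and (optionally) merged statistics.
#' @export
run_pipeline <- function(crystal, detector, gonio, beam,
                         mode = c("basic", "advanced"),
                         total_exposure_s = 120, wavelength_A = NULL,
                         dose_params = dose_parameters(), simulate = TRUE) {
  mode <- match.arg(mode)
  if (is.null(crystal$target_resolution_A) ||
      !is.finite(crystal$target_resolution_A))
    stop("a target resolution must be set for each sample", call. = FALSE)
  wavelength_A <- wavelength_A %||% (12.398 / beam$energy_keV)
  sym <- select_strategy_symmetry(crystal$symmetry)
  pg <- sym$point_group
  # detector distance so the target resolution just fits on the detector
  tt_target <- two_theta_of_resolution(crystal$target_resolution_A,
                                       wavelength_A)
  width <- min(detector$width_mm, detector$height_mm)
  dist <- max(detector$min_distance_mm, width / 2 / tan(.deg2rad(tt_target)))
  tt <- min(tt_target, two_theta_max(width, dist))
  chi_free <- chi_max_shadow_free(tt, gonio$cone_half_angle_deg)
  budget <- dose_budget(crystal$target_resolution_A, dose_params)
  trans <- recommend_transmission(budget, total_exposure_s, beam, crystal,
                                  dose_params)
  plan <- if (mode == "basic")
    basic_strategy(crystal, gonio, tt)
  else advanced_strategy(crystal, gonio, tt)
  for (i in seq_along(plan$sweeps)) plan$sweeps[[i]]$transmission <- as.numeric(trans)
  out <- list(symmetry = sym, point_group = pg$name,
              geometry = list(distance_mm = dist, two_theta_max_deg = tt,
                              chi_max_shadow_free_deg = as.numeric(chi_free),
                              wavelength_A = wavelength_A),
              dose = list(budget_MGy = budget,
                          transmission = as.numeric(trans),
                          effective_flux_density =
                            attr(trans, "effective_flux_density"),
                          advisory = attr(trans, "advisory")),
              plan = plan)
  if (simulate) {
    sim <- simulate_sweeps(crystal, plan$sweeps, detector = detector,
                           distance_mm = dist, wavelength_A = wavelength_A)
    out$stats <- merge_stats(sim, pg)
  }
  structure(out, class = "mxsweep_report")
}

#' @export
print.mxsweep_report <- function(x, ...) {
  cat("Strategy report\n")
  cat(sprintf("  point group %s, distance %.0f mm, 2theta_max %.1f deg, chi_max(shadow-free) %.1f deg\n",
              x$point_group, x$geometry$distance_mm,
              x$geometry$two_theta_max_deg,
              x$geometry$chi_max_shadow_free_deg))
  cat(sprintf("  dose budget %.2f MGy, transmission %.3f\n",
              x$dose$budget_MGy, x$dose$transmission))
  print(x$plan)
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report An `"mxsweep_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stats <- if (!is.null(report$stats)) report$stats$summary else NULL
  jsonlite::write_json(list(
    schema = "mxsweep-report-1",
    point_group = report$point_group,
    geometry = report$geometry,
    dose = report$dose[c("budget_MGy", "transmission",
                         "effective_flux_density")],
    plan = list(kind = report$plan$kind,
                total_length_deg = report$plan$total_length_deg,
                recentrings = report$plan$recentrings),
    stats = stats), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
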
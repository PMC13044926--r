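# Detector and goniostat geometry.
#
# Lab frame convention, used throughout the package: the beam travels along
# +z, the omega rotation axis is +x (horizontal), and the detector plane is
# perpendicular to the beam at distance D. The phi-axis mount shadow is a
# single infinite cone of half-angle A around the direction -phi_hat
# (pointing from the crystal into the mount), apexed at the crystal.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.unit <- function(v) v / sqrt(sum(v^2))

# Rotation matrix about a unit axis by an angle in degrees (Rodrigues).
rotation_about <- function(axis, angle_deg) {
  a <- .unit(axis)
  th <- .deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal rotation carrying unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-14) return(diag(3))
  if (c_ < -1 + 1e-14) {
    # pick any perpendicular axis for a half-turn
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .unit(pracma_cross(u, p))
    return(rotation_about(ax, 180))
  }
  ax <- pracma_cross(u, v)
  s <- sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a detector model
#'
#' Physical active area, module/gap layout and minimum distance of a
#' pixel-array detector. The face is tiled by an `n_modules[1] x
#' n_modules[2]` grid of modules of `module_px` pixels separated by
#' `gap_px` inactive pixels.
#'
#' @param name Detector name.
#' @param width_mm,height_mm Overall active-face dimensions (mm); width is
#'   the horizontal (x) dimension.
#' @param pixel_mm Pixel pitch (mm).
#' @param module_px Integer pair: pixels per module along x and y.
#' @param gap_px Integer pair: inactive pixels between modules along x and y.
#' @param n_modules Integer pair: module counts along x and y.
#' @param min_distance_mm Shortest usable crystal-to-detector distance (mm).
#' @param beam_centre Beam position on the face in mm relative to the face
#'   centre; default `c(0, 0)` (centred beam).
#' @return An object of class `"detector_model"`.
#' @export
detector_model <- function(name, width_mm, height_mm, pixel_mm,
                           module_px, gap_px, n_modules,
                           min_distance_mm = 100, beam_centre = c(0, 0)) {
  stopifnot(width_mm > 0, height_mm > 0, pixel_mm > 0, min_distance_mm > 0)
  px <- c(n_modules[1] * module_px[1] + (n_modules[1] - 1) * gap_px[1],
          n_modules[2] * module_px[2] + (n_modules[2] - 1) * gap_px[2])
  # the tiled layout must reproduce the stated face within one module
  if (abs(px[1] * pixel_mm - width_mm) > module_px[1] * pixel_mm ||
      abs(px[2] * pixel_mm - height_mm) > module_px[2] * pixel_mm)
    stop("module layout inconsistent with detector dimensions", call. = FALSE)
  structure(list(name = name, width_mm = width_mm, height_mm = height_mm,
                 pixel_mm = pixel_mm, module_px = as.integer(module_px),
                 gap_px = as.integer(gap_px), n_modules = as.integer(n_modules),
                 total_px = as.integer(px),
                 min_distance_mm = min_distance_mm,
                 beam_centre = beam_centre),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("%s: %.1f x %.1f mm, %d x %d modules of %d x %d px (pitch %.3f mm)\n",
              x$name, x$width_mm, x$height_mm, x$n_modules[1], x$n_modules[2],
              x$module_px[1], x$module_px[2], x$pixel_mm))
  invisible(x)
}

#' Bundled detector library
#'
#' Returns one of the bundled detector models, or the list of available
#' names when `name` is `NULL`. Module metrology follows vendor data sheets
#' (PILATUS 6M: 5 x 12 modules of 487 x 195 pixels, 7-pixel horizontal and
#' 17-pixel vertical gaps at 0.172 mm pitch; EIGER2: 1028 x 512-pixel
#' modules, 12/38-pixel gaps at 0.075 mm pitch; PILATUS4: 513 x 255-pixel
#' modules at 0.15 mm pitch).
#'
#' @param name One of `"pilatus6m"`, `"eiger16m"`, `"eiger9m"`,
#'   `"pilatus4-4m"`, `"pilatus4-2m"`, or `NULL` to list names.
#' @return A [detector_model()] or a character vector of names.
#' @export
detector_library <- function(name = NULL) {
  lib <- list(
    "pilatus6m" = detector_model("PILATUS3 6M", 423.6, 434.6, 0.172,
                                 c(487, 195), c(7, 17), c(5, 12), 100),
    "eiger16m" = detector_model("EIGER2 16M", 311.1, 327.2, 0.075,
                                c(1028, 512), c(12, 38), c(4, 8), 100),
    "eiger9m" = detector_model("EIGER2 9M", 233.1, 244.7, 0.075,
                               c(1028, 512), c(12, 38), c(3, 6), 100),
    "pilatus4-4m" = detector_model("PILATUS4 4M", 311.1, 327.2, 0.15,
                                   c(513, 255), c(7, 17), c(4, 8), 100),
    "pilatus4-2m" = detector_model("PILATUS4 2M", 233.1, 244.7, 0.15,
                                   c(513, 255), c(7, 17), c(3, 6), 100))
  if (is.null(name)) return(names(lib))
  if (!name %in% names(lib))
    stop("unknown detector '", name, "'; available: ",
         paste(names(lib), collapse = ", "), call. = FALSE)
  lib[[name]]
}

#' Construct a goniostat model
#'
#' @param kind `"mini-kappa"` or `"smargon"`.
#' @param cone_half_angle_deg Half-angle A of the phi-mount shadow cone
#'   (degrees); 19.84 for the mini-kappa and, by construction similarity,
#'   also the default for the Smargon.
#' @param kappa_axis_angle_deg Angle alpha between the omega and kappa axes
#'   (degrees); 24 gives the mini-kappa chi range of 0-48 degrees.
#' @param chi_max_mech_deg Mechanical / collision chi limit; must not exceed
#'   `2 * alpha`. 48 for the mini-kappa, about 45 for a Smargon.
#' @return An object of class `"goniostat_model"`.
#' @export
goniostat_model <- function(kind = c("mini-kappa", "smargon"),
                            cone_half_angle_deg = 19.84,
                            kappa_axis_angle_deg = 24,
                            chi_max_mech_deg = if (match.arg(kind) == "smargon") 45 else 48) {
  kind <- match.arg(kind)
  stopifnot(cone_half_angle_deg > 0, cone_half_angle_deg < 90,
            kappa_axis_angle_deg > 0, kappa_axis_angle_deg <= 90)
  if (chi_max_mech_deg > 2 * kappa_axis_angle_deg + 1e-9)
    stop("chi_max_mech_deg cannot exceed 2 * kappa_axis_angle_deg", call. = FALSE)
  structure(list(kind = kind,
                 cone_half_angle_deg = cone_half_angle_deg,
                 kappa_axis_angle_deg = kappa_axis_angle_deg,
                 chi_max_mech_deg = chi_max_mech_deg,
                 omega_axis = c(1, 0, 0), beam_axis = c(0, 0, 1)),
            class = "goniostat_model")
}

#' @export
print.goniostat_model <- function(x, ...) {
  cat(sprintf("%s goniostat: A = %.2f deg, alpha = %.1f deg, chi_max = %.1f deg\n",
              x$kind, x$cone_half_angle_deg, x$kappa_axis_angle_deg,
              x$chi_max_mech_deg))
  invisible(x)
}

#' Largest diffraction angle landing on the detector
#'
#' For a centred beam the largest usable scattering angle is set by the
#' narrowest detector half-dimension: `2theta_max = atan(width / 2 / D)`.
#'
#' @param width_mm Narrowest detector dimension (mm).
#' @param distance_mm Crystal-to-detector distance (mm).
#' @return Angle 2theta_max in degrees.
#' @examples
#' two_theta_max(311.1, 137)  # 48.6 for an EIGER 16M at 137 mm
#' @export
two_theta_max <- function(width_mm, distance_mm) {
  if (any(width_mm <= 0) || any(distance_mm <= 0))
    stop("width and distance must be positive", call. = FALSE)
  .rad2deg(atan2(width_mm / 2, distance_mm))
}

#' Resolution corresponding to a diffraction angle
#'
#' Bragg's law: `d = lambda / (2 sin theta)` with `theta = two_theta / 2`.
#'
#' @param two_theta_deg Scattering angle 2theta in degrees, in (0, 180].
#' @param wavelength_A Wavelength in Angstrom (1.0 at 12.398 keV).
#' @return Resolution d in Angstrom.
#' @export
resolution_limit <- function(two_theta_deg, wavelength_A = 1.0) {
  if (any(two_theta_deg <= 0) || any(two_theta_deg > 180))
    stop("two_theta must be in (0, 180] degrees", call. = FALSE)
  wavelength_A / (2 * sin(.deg2rad(two_theta_deg / 2)))
}

#' Diffraction angle reaching a target resolution
#'
#' Inverse of [resolution_limit()].
#' @param d_A Resolution in Angstrom.
#' @param wavelength_A Wavelength in Angstrom.
#' @return 2theta in degrees.
#' @export
two_theta_of_resolution <- function(d_A, wavelength_A = 1.0) {
  s <- wavelength_A / (2 * d_A)
  if (any(s <= 0) || any(s > 1)) stop("resolution out of range", call. = FALSE)
  2 * .rad2deg(asin(s))
}

#' Highest chi permitting a shadow-free 360-degree sweep
#'
#' With the phi mount modelled as a cone of half-angle A about the phi axis,
#' a full 360-degree sweep is free of goniostat shadows on the detector iff
#' `(90 - chi) - 2theta_max >= A`, giving `chi_max = 90 - A - 2theta_max`.
#' Negative values are returned as 0 with attribute `"clamped" = TRUE`;
#' callers clamp at the mechanical chi limit.
#'
#' @param two_theta_max_deg Largest scattering angle on the detector (deg).
#' @param cone_half_angle_deg Shadow-cone half-angle A (deg).
#' @return chi_max in degrees.
#' @examples
#' chi_max_shadow_free(48.6, 19.84)  # 21.6
#' @export
chi_max_shadow_free <- function(two_theta_max_deg, cone_half_angle_deg) {
  stopifnot(two_theta_max_deg >= 0, cone_half_angle_deg >= 0)
  x <- 90 - cone_half_angle_deg - two_theta_max_deg
  clamped <- x < 0
  x <- pmax(x, 0)
  attr(x, "clamped") <- clamped
  x
}

#' chi angle as a function of the kappa setting
#'
#' Two-axis kinematics with the kappa axis at angle alpha to the omega axis:
#' `cos chi = cos^2 alpha + sin^2 alpha * cos kappa`, monotone in kappa on
#' \[0, 180\] with `chi(180) = 2 alpha`.
#'
#' @param kappa_deg Kappa setting (degrees).
#' @param alpha_deg Kappa-axis angle alpha (degrees), in (0, 90].
#' @return chi in degrees.
#' @export
chi_of_kappa <- function(kappa_deg, alpha_deg) {
  stopifnot(alpha_deg > 0, alpha_deg <= 90)
  ca <- cos(.deg2rad(alpha_deg))
  c_ <- ca^2 + (1 - ca^2) * cos(.deg2rad(kappa_deg))
  .rad2deg(acos(pmin(1, pmax(-1, c_))))
}

#' Kappa setting realizing a chi angle
#'
#' Inverse of [chi_of_kappa()] on kappa in \[0, 180\].
#' @param chi_deg Target chi (degrees), at most `2 * alpha`.
#' @param alpha_deg Kappa-axis angle (degrees).
#' @return kappa in degrees.
#' @export
kappa_of_chi <- function(chi_deg, alpha_deg) {
  stopifnot(chi_deg >= 0)
  if (any(chi_deg > 2 * alpha_deg + 1e-9))
    stop("chi exceeds the goniostat range 2 * alpha", call. = FALSE)
  ca <- cos(.deg2rad(alpha_deg))
  ck <- (cos(.deg2rad(chi_deg)) - ca^2) / (1 - ca^2)
  .rad2deg(acos(pmin(1, pmax(-1, ck))))
}

#' Goniostat pose
#'
#' Axis settings plus the derived lab-frame phi-axis direction. The kinematic
#' chain is `R = R_x(omega) R_k(kappa) R_x(phi)` with the kappa axis at
#' `(cos alpha, sin alpha, 0)`; at kappa = 0 all three axes are coaxial with
#' omega (+x).
#'
#' @param gonio A [goniostat_model()].
#' @param omega_deg,kappa_deg,phi_deg Axis settings in degrees.
#' @return An object of class `"goniostat_pose"` with elements `omega_deg`,
#'   `kappa_deg`, `phi_deg`, `chi_deg` and `phi_axis` (unit vector).
#' @export
goniostat_pose <- function(gonio, omega_deg = 0, kappa_deg = 0, phi_deg = 0) {
  a <- .deg2rad(gonio$kappa_axis_angle_deg)
  k_axis <- c(cos(a), sin(a), 0)
  phi_axis <- rotation_about(c(1, 0, 0), omega_deg) %*%
    rotation_about(k_axis, kappa_deg) %*% c(1, 0, 0)
  structure(list(gonio = gonio, omega_deg = omega_deg, kappa_deg = kappa_deg,
                 phi_deg = phi_deg,
                 chi_deg = chi_of_kappa(kappa_deg, gonio$kappa_axis_angle_deg),
                 phi_axis = as.vector(phi_axis)),
            class = "goniostat_pose")
}

# Crystal-to-lab goniostat rotation for a pose (applied to the mounted
# crystal's zero-setting frame).
.pose_rotation <- function(pose) {
  g <- pose$gonio
  a <- .deg2rad(g$kappa_axis_angle_deg)
  k_axis <- c(cos(a), sin(a), 0)
  rotation_about(c(1, 0, 0), pose$omega_deg) %*%
    rotation_about(k_axis, pose$kappa_deg) %*%
    rotation_about(c(1, 0, 0), pose$phi_deg)
}

#' Is a diffracted ray occluded by the phi-axis mount?
#'
#' The mount is modelled as an infinite cone of half-angle A around the
#' direction `-phi_axis` (from the crystal into the mount), apexed at the
#' crystal. A ray is shadowed iff its angle to that direction is below A.
#'
#' @param ray Unit vector (or matrix of row vectors) from crystal toward a
#'   detector point.
#' @param pose A [goniostat_pose()].
#' @param gonio A [goniostat_model()]; defaults to the pose's goniostat.
#' @return Logical vector.
#' @export
is_ray_shadowed <- function(ray, pose, gonio = pose$gonio) {
  m <- -pose$phi_axis
  if (is.null(dim(ray))) ray <- matrix(ray, nrow = 1)
  d <- as.vector(ray %*% m)
  d > cos(.deg2rad(gonio$cone_half_angle_deg))
}

# Unit ray directions to an n x n grid of points on the detector face.
.detector_rays <- function(det, distance_mm, n = 256) {
  xs <- seq(-det$width_mm / 2, det$width_mm / 2, length.out = n) + det$beam_centre[1]
  ys <- seq(-det$height_mm / 2, det$height_mm / 2, length.out = n) + det$beam_centre[2]
  g <- expand.grid(x = xs, y = ys)
  r <- cbind(g$x, g$y, distance_mm)
  r / sqrt(rowSums(r^2))
}

#' Fraction of the detector face shadowed by the goniostat
#'
#' Tests a grid of detector points against the phi-mount shadow cone.
#'
#' @param pose A [goniostat_pose()].
#' @param det A [detector_model()].
#' @param distance_mm Detector distance (mm).
#' @param grid_n Sample grid size per detector edge (default 256).
#' @return Fraction in \[0, 1\].
#' @export
shadow_fraction <- function(pose, det, distance_mm, grid_n = 256) {
  rays <- .detector_rays(det, distance_mm, grid_n)
  mean(is_ray_shadowed(rays, pose))
}

# Widest circular run of TRUE in a logical vector indexed by equally spaced
# omega values; returns c(width_deg, start_deg).
.widest_true_run <- function(free, step) {
  n <- length(free)
  if (all(free)) return(c(360, 0))
  if (!any(free)) return(c(0, NA))
  f2 <- c(free, free)  # unwrap the circle
  best_len <- 0L; best_start <- NA_integer_
  run <- 0L
  for (i in seq_len(2L * n)) {
    if (f2[i]) {
      run <- run + 1L
      if (run > best_len && i - run + 1L <= n) {
        best_len <- run; best_start <- i - run + 1L
      }
    } else run <- 0L
  }
  c(min(best_len, n) * step, (best_start - 1L) * step)
}

#' Shadow-free omega range over a set of kappa settings
#'
#' Scans omega and reports the widest shadow-free interval. Two readings are
#' offered: `"each"` (default) evaluates the shadow-free window separately
#' for every kappa in the set and reports the smallest width (the width of
#' the shadow-free band across a shadow map in the omega/kappa plane);
#' `"common"` reports the widest single omega interval free of shadows
#' simultaneously for all kappa in the set.
#'
#' @param kappa_set Non-empty numeric vector of kappa settings (degrees).
#' @param det A [detector_model()].
#' @param distance_mm Detector distance (mm).
#' @param gonio A [goniostat_model()].
#' @param mode `"each"` or `"common"`.
#' @param omega_step Omega scan step (degrees, default 0.5).
#' @param grid_n Detector sample grid per edge (default 64; the cone-to-
#'   rectangle test is binding at the face boundary, so a moderate grid
#'   suffices).
#' @return List with `width_deg`, `start_deg` (for `"common"` the common
#'   interval; for `"each"` the interval at the worst kappa) and
#'   `per_kappa` (data frame of widths per kappa).
#' @export
shadow_free_omega_range <- function(kappa_set, det, distance_mm, gonio,
                                    mode = c("each", "common"),
                                    omega_step = 0.5, grid_n = 64) {
  if (length(kappa_set) == 0) stop("kappa set must be non-empty", call. = FALSE)
  mode <- match.arg(mode)
  omegas <- seq(0, 360 - omega_step, by = omega_step)
  rays <- .detector_rays(det, distance_mm, grid_n)
  A <- gonio$cone_half_angle_deg
  cosA <- cos(.deg2rad(A))
  free_mat <- vapply(kappa_set, function(kap) {
    # phi axis at omega = 0 for this kappa, then rotated about x by omega
    p0 <- goniostat_pose(gonio, 0, kap, 0)$phi_axis
    vapply(omegas, function(om) {
      m <- -as.vector(rotation_about(c(1, 0, 0), om) %*% p0)
      max(rays %*% m) <= cosA
    }, logical(1))
  }, logical(length(omegas)))
  widths <- apply(free_mat, 2, function(f) .widest_true_run(f, omega_step))
  per_kappa <- data.frame(kappa_deg = kappa_set, width_deg = widths[1, ],
                          start_deg = widths[2, ])
  if (mode == "common") {
    run <- .widest_true_run(apply(free_mat, 1, all), omega_step)
    list(width_deg = run[1], start_deg = run[2], per_kappa = per_kappa)
  } else {
    i <- which.min(per_kappa$width_deg)
    list(width_deg = per_kappa$width_deg[i], start_deg = per_kappa$start_deg[i],
         per_kappa = per_kappa)
  }
}

#' Detector geometry limits table
#'
#' For each detector, the largest scattering angle from the narrowest
#' dimension at the given distance, the highest chi allowing a shadow-free
#' 360-degree sweep, and the best resolution fitting on the detector.
#'
#' @param widths_mm Named vector of narrowest detector dimensions (mm);
#'   defaults to the bundled library.
#' @param distance_mm Detector distance (default 137 mm, a representative
#'   shortest distance).
#' @param cone_half_angle_deg Shadow-cone half-angle (default 19.84).
#' @param wavelength_A Wavelength (default 1.0, i.e. 12.398 keV).
#' @return Data frame with columns `detector`, `width_mm`, `two_theta_max`,
#'   `chi_max`, `resolution_A`.
#' @export
detector_limits_table <- function(widths_mm = NULL, distance_mm = 137,
                                  cone_half_angle_deg = 19.84,
                                  wavelength_A = 1.0) {
  if (is.null(widths_mm)) {
    nm <- detector_library()
    widths_mm <- vapply(nm, function(n) {
      d <- detector_library(n); min(d$width_mm, d$height_mm)
    }, numeric(1))
  }
  tt <- two_theta_max(widths_mm, distance_mm)
  cm <- chi_max_shadow_free(tt, cone_half_angle_deg)
  data.frame(detector = names(widths_mm), width_mm = unname(widths_mm),
             two_theta_max = unname(tt), chi_max = as.numeric(cm),
             resolution_A = unname(resolution_limit(tt, wavelength_A)),
             row.names = NULL)
}
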
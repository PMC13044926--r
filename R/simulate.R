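# Ray-tracing simulator of rotation-method experiments: Ewald-sphere
# crossings, blind-region (cusp) detection, Lorentz factors, detector
# intersection with module-gap and shadow exclusion.
#
# Reciprocal vectors are lambda-normalized throughout, so the Ewald sphere
# has unit radius and |r| = 2 sin(theta). With the beam along +z and the
# rotation axis along +x, a reflection with zero-omega vector r0 crosses the
# sphere when r_z(omega) = -|r|^2 / 2, i.e. rho * sin(omega + delta) = c
# with rho = sqrt(r0_y^2 + r0_z^2), delta = atan2(r0_z, r0_y).

#' Construct a sweep
#'
#' A contiguous rotation about the lab omega axis (+x) at a fixed crystal
#' orientation. The orientation is given either as a full `setting` matrix
#' (crystal Cartesian frame to lab at omega = 0, including the mounting) or
#' as `axis_crystal`, the crystal-frame direction to be placed along the
#' rotation axis (the minimal rotation from the mounted orientation is then
#' used).
#'
#' @param crystal A [crystal_sample()].
#' @param axis_crystal Unit vector in the crystal Cartesian frame to align
#'   with the rotation axis; ignored when `setting` is given.
#' @param setting Optional 3x3 rotation matrix (crystal to lab at omega 0).
#' @param omega_start_deg,width_deg Sweep interval; observations fall in the
#'   half-open interval `[start, start + width)`.
#' @param image_width_deg Image width (default 0.1).
#' @param exposure_per_image_s Exposure per image (default 0.01 s).
#' @param transmission Transmission fraction (default 1).
#' @param kappa_deg,phi_deg Optional goniostat settings realizing the
#'   orientation (used by the shadow model).
#' @return Object of class `"mx_sweep"`.
#' @export
make_sweep <- function(crystal, axis_crystal = NULL, setting = NULL,
                       omega_start_deg = 0, width_deg = 360,
                       image_width_deg = 0.1, exposure_per_image_s = 0.01,
                       transmission = 1, kappa_deg = NA, phi_deg = NA) {
  stopifnot(width_deg > 0, width_deg <= 360)
  if (is.null(setting)) {
    if (is.null(axis_crystal)) {
      setting <- crystal$orientation
      axis_crystal <- as.vector(t(crystal$orientation) %*% c(1, 0, 0))
    } else {
      axis_crystal <- .unit(axis_crystal)
      lab <- as.vector(crystal$orientation %*% axis_crystal)
      setting <- rotation_between(lab, c(1, 0, 0)) %*% crystal$orientation
    }
  } else {
    axis_crystal <- as.vector(t(setting) %*% c(1, 0, 0))
  }
  structure(list(setting = setting, axis_crystal = axis_crystal,
                 omega_start_deg = omega_start_deg, width_deg = width_deg,
                 image_width_deg = image_width_deg,
                 exposure_per_image_s = exposure_per_image_s,
                 transmission = transmission,
                 kappa_deg = kappa_deg, phi_deg = phi_deg),
            class = "mx_sweep")
}

# Enumerate all hkl with 0 < d* <= 1/d_min for a cell orthogonalization B.
reflection_list <- function(B, d_min) {
  inv <- solve(B)
  hmax <- pmax(1L, as.integer(ceiling(sqrt(rowSums(t(inv)^2)) / d_min)))
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  r <- g %*% t(B)
  d_star <- sqrt(rowSums(r^2))
  keep <- d_star > 1e-12 & d_star <= 1 / d_min
  list(hkl = g[keep, , drop = FALSE], d_star = d_star[keep])
}

# Vectorized crossing solver. r0: N x 3 matrix of lambda-normalized
# reciprocal vectors at omega = 0. Returns a list with per-reflection
# crossing angles (omega1/omega2 in [0,360), NA when blind/tangent),
# blindness and geometry.
.crossings <- function(r0) {
  len2 <- rowSums(r0^2)
  len <- sqrt(len2)
  rho <- sqrt(r0[, 2]^2 + r0[, 3]^2)
  cc <- -len2 / 2
  u <- ifelse(rho > 0, cc / rho, -Inf)
  blind <- abs(u) > 1
  tangent <- !blind & abs(u) >= 1 - 1e-12
  delta <- atan2(r0[, 3], r0[, 2])
  xi_ang <- asin(pmin(1, pmax(-1, u)))
  w1 <- (.rad2deg(xi_ang - delta)) %% 360
  w2 <- (.rad2deg(pi - xi_ang - delta)) %% 360
  w1[blind] <- NA; w2[blind | tangent] <- NA
  theta <- .rad2deg(asin(pmin(1, len / 2)))
  X <- .rad2deg(acos(pmin(1, pmax(-1, r0[, 1] / pmax(len, 1e-300)))))
  list(omega1 = w1, omega2 = w2, blind = blind, theta_deg = theta,
       X_deg = X, xi = r0[, 1], len = len)
}

#' Ewald-sphere crossing angles of one reflection in a sweep
#'
#' @param hkl Integer index triple.
#' @param crystal A [crystal_sample()].
#' @param sweep A [make_sweep()] object.
#' @param wavelength_A Wavelength (Angstrom).
#' @return Numeric vector of 0, 1 or 2 crossing angles (degrees) inside the
#'   sweep interval, with attribute `"blind"`.
#' @export
ewald_crossings <- function(hkl, crystal, sweep, wavelength_A = 1.0) {
  r0 <- matrix(as.vector(sweep$setting %*% (crystal$B %*% hkl)) * wavelength_A,
               nrow = 1)
  if (sqrt(sum(r0^2)) > 2)
    stop("reflection beyond the back-scattering limit", call. = FALSE)
  cr <- .crossings(r0)
  w <- c(cr$omega1, cr$omega2)
  w <- w[!is.na(w)]
  w <- w[((w - sweep$omega_start_deg) %% 360) < sweep$width_deg]
  structure(sort(w), blind = cr$blind)
}

#' Blind-region (cusp) test
#'
#' A reflection never crosses the Ewald sphere during rotation iff the angle
#' X between its reciprocal vector and the rotation axis satisfies
#' `sin X < sin theta` (X < theta or X > 180 - theta), with
#' `sin theta = d_star * lambda / 2`. The boundary X = theta is classified
#' as not blind.
#'
#' @param d_star Reciprocal resolution (1/Angstrom).
#' @param wavelength_A Wavelength (Angstrom).
#' @param axis_angle_deg Angle X between reciprocal vector and rotation
#'   axis (degrees).
#' @return Logical vector.
#' @export
is_blind <- function(d_star, wavelength_A, axis_angle_deg) {
  st <- d_star * wavelength_A / 2
  if (any(st > 1)) stop("d_star beyond the diffraction limit", call. = FALSE)
  # closed-set boundary convention: X = theta counts as measurable
  sin(.deg2rad(axis_angle_deg)) < st - 1e-12
}

#' Lorentz factor for the rotation method
#'
#' For a rotation axis orthogonal to the beam,
#' `L = 1 / (2 sin theta * sqrt(cos^2 theta - cos^2 X))` in
#' lambda-normalized units; this is the inverse crossing speed through the
#' Ewald sphere. It reduces to `1 / sin(2 theta)` for equatorial
#' reflections (X = 90) and diverges toward the cusp (X -> theta).
#'
#' @inheritParams is_blind
#' @return Lorentz factor L (>= 1 / sin 2 theta).
#' @export
lorentz_factor <- function(d_star, wavelength_A, axis_angle_deg) {
  if (any(is_blind(d_star, wavelength_A, axis_angle_deg)))
    stop("Lorentz factor undefined for blind reflections", call. = FALSE)
  th <- asin(d_star * wavelength_A / 2)
  X <- .deg2rad(axis_angle_deg)
  1 / (2 * sin(th) * sqrt(cos(th)^2 - cos(X)^2))
}

# Disc footprint sample offsets (px), ~0.5 px spacing.
.footprint_offsets <- function(diameter_px = 3) {
  r <- diameter_px / 2
  s <- seq(-r, r, by = 0.5)
  g <- expand.grid(dx = s, dy = s)
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, ]
}

# Active-area test in pixel coordinates (vectorized).
.is_active_px <- function(u, det, axis) {
  m <- det$module_px[axis]; gp <- det$gap_px[axis]; tot <- det$total_px[axis]
  inside <- u >= 0 & u < tot
  inside & (u %% (m + gp)) < m
}

#' Project diffracted rays onto the detector
#'
#' Projects unit ray directions to the detector plane and classifies each
#' hit against the module-gap layout: the spot footprint is modelled as a
#' disc of `footprint_px` pixels diameter and a reflection is flagged
#' `in_gap` when less than `min_active` of the footprint area lies on
#' active modules.
#'
#' @param s Matrix of unit ray directions (rows), or a single vector.
#' @param det A [detector_model()].
#' @param distance_mm Detector distance (mm).
#' @param footprint_px Footprint disc diameter in pixels (default 3).
#' @param min_active Minimum active footprint fraction (default 0.75).
#' @return Data frame with `x_mm`, `y_mm` (from the face centre),
#'   `on_detector`, `active_fraction`, `in_gap`.
#' @export
detector_hit <- function(s, det, distance_mm, footprint_px = 3,
                         min_active = 0.75) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  forward <- s[, 3] > 1e-9
  x <- ifelse(forward, distance_mm * s[, 1] / s[, 3] + det$beam_centre[1], NA)
  y <- ifelse(forward, distance_mm * s[, 2] / s[, 3] + det$beam_centre[2], NA)
  on_det <- forward & !is.na(x) &
    abs(x) <= det$width_mm / 2 & abs(y) <= det$height_mm / 2
  # pixel coordinates from the face corner
  u <- (x + det$width_mm / 2) / det$pixel_mm
  v <- (y + det$height_mm / 2) / det$pixel_mm
  off <- .footprint_offsets(footprint_px)
  frac <- rep(NA_real_, length(u))
  idx <- which(on_det)
  if (length(idx) > 0) {
    no <- nrow(off)
    act <- numeric(length(idx))
    for (j in seq_len(no)) {
      act <- act + (.is_active_px(u[idx] + off$dx[j], det, 1L) &
                    .is_active_px(v[idx] + off$dy[j], det, 2L))
    }
    frac[idx] <- act / no
  }
  data.frame(x_mm = x, y_mm = y, on_detector = on_det,
             active_fraction = frac,
             in_gap = ifelse(on_det, frac < min_active, NA))
}

#' Simulate rotation sweeps
#'
#' Predicts every Ewald-sphere crossing for all reflections to the
#' resolution limit, for each sweep of a strategy, annotating crossings
#' with Bragg angle, axis angle X, Lorentz factor, detector position and
#' gap/shadow flags. Crossings are geometric events (zero mosaicity and
#' bandpass); a crossing is attributed to a sweep when its angle lies in
#' the half-open interval `[start, start + width)`.
#'
#' @param crystal A [crystal_sample()].
#' @param sweeps A list of [make_sweep()] objects (or a single sweep).
#' @param detector Optional [detector_model()]; when `NULL`, detector and
#'   gap modelling are skipped.
#' @param distance_mm Detector distance (required with a detector).
#' @param wavelength_A Wavelength (default 1.0).
#' @param d_min Resolution limit; defaults to the crystal's target.
#' @param shadow Logical; apply the phi-mount cone shadow model (requires
#'   sweeps with `kappa_deg` set and a `gonio`).
#' @param gonio A [goniostat_model()] (for the shadow model).
#' @param footprint_px,min_active Gap-exclusion footprint parameters, see
#'   [detector_hit()].
#' @return Object of class `"diffraction_sim"`: a list with
#'   `observations` (one row per predicted crossing), `hkl` (the full
#'   reflection list with per-sweep blind flags) and the simulation
#'   parameters.
#' @export
simulate_sweeps <- function(crystal, sweeps, detector = NULL,
                            distance_mm = NULL, wavelength_A = 1.0,
                            d_min = NULL, shadow = FALSE, gonio = NULL,
                            footprint_px = 3, min_active = 0.75) {
  if (inherits(sweeps, "mx_sweep")) sweeps <- list(sweeps)
  d_min <- d_min %||% crystal$target_resolution_A
  if (2 * asin(min(1, wavelength_A / (2 * d_min))) > pi / 2 && !is.null(detector))
    warning("resolution limit beyond the detector corner regime")
  refl <- reflection_list(crystal$B, d_min)
  H <- refl$hkl
  n <- nrow(H)
  blind_mat <- matrix(FALSE, n, length(sweeps))
  obs_list <- list()
  for (si in seq_along(sweeps)) {
    sw <- sweeps[[si]]
    r0 <- t(sw$setting %*% (crystal$B %*% t(H))) * wavelength_A
    cr <- .crossings(r0)
    blind_mat[, si] <- cr$blind
    for (pass in 1:2) {
      w <- if (pass == 1) cr$omega1 else cr$omega2
      sel <- which(!is.na(w) &
                   ((w - sw$omega_start_deg) %% 360) < sw$width_deg)
      if (length(sel) == 0) next
      om <- w[sel]
      th <- .deg2rad(om)
      # rotate r0 about x by omega and form the diffracted direction
      ry <- r0[sel, 2] * cos(th) - r0[sel, 3] * sin(th)
      rz <- r0[sel, 2] * sin(th) + r0[sel, 3] * cos(th)
      sdir <- cbind(r0[sel, 1], ry, rz + 1)
      sth <- cr$len[sel] / 2
      L <- 1 / pmax(2 * sth * sqrt(pmax(0, (1 - sth^2) -
                                           cos(.deg2rad(cr$X_deg[sel]))^2)),
                    1e-300)
      df <- data.frame(sweep = si, hkl_index = sel,
                       h = H[sel, 1], k = H[sel, 2], l = H[sel, 3],
                       omega_deg = om, theta_deg = cr$theta_deg[sel],
                       X_deg = cr$X_deg[sel], xi = cr$xi[sel], lorentz = L)
      if (!is.null(detector)) {
        if (is.null(distance_mm))
          stop("distance_mm required with a detector", call. = FALSE)
        hit <- detector_hit(sdir, detector, distance_mm, footprint_px,
                            min_active)
        df <- cbind(df, hit)
      } else {
        df$on_detector <- TRUE
        df$in_gap <- FALSE
      }
      if (shadow) {
        if (is.null(gonio) || is.na(sw$kappa_deg))
          stop("shadow model needs a goniostat and sweep kappa settings",
               call. = FALSE)
        p0 <- goniostat_pose(gonio, 0, sw$kappa_deg,
                             if (is.na(sw$phi_deg)) 0 else sw$phi_deg)$phi_axis
        cosA <- cos(.deg2rad(gonio$cone_half_angle_deg))
        # mount direction rotated with omega
        mx <- -p0[1]
        my <- -(p0[2] * cos(th) - p0[3] * sin(th))
        mz <- -(p0[2] * sin(th) + p0[3] * cos(th))
        df$shadowed <- (sdir[, 1] * mx + sdir[, 2] * my + sdir[, 3] * mz) > cosA
      } else {
        df$shadowed <- FALSE
      }
      obs_list[[length(obs_list) + 1L]] <- df
    }
  }
  obs <- if (length(obs_list) > 0) do.call(rbind, obs_list) else
    data.frame(sweep = integer(), hkl_index = integer(), h = integer(),
               k = integer(), l = integer(), omega_deg = numeric(),
               theta_deg = numeric(), X_deg = numeric(), xi = numeric(),
               lorentz = numeric(), on_detector = logical(),
               in_gap = logical(), shadowed = logical())
  structure(list(observations = obs,
                 hkl = data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
                                  d_star = refl$d_star),
                 blind = blind_mat, sweeps = sweeps,
                 wavelength_A = wavelength_A, d_min = d_min,
                 detector = detector, distance_mm = distance_mm),
            class = "diffraction_sim")
}

#' @export
print.diffraction_sim <- function(x, ...) {
  cat(sprintf("Diffraction simulation: %d sweeps, %d reflections to %.2f A, %d observations\n",
              length(x$sweeps), nrow(x$hkl), x$d_min, nrow(x$observations)))
  invisible(x)
}
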
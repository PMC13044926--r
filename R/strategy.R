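# Generation of characterization, basic and advanced native strategies:
# polyhedron-based target orientations per point group, accessibility
# filtering under the goniostat chi limit, sweep-length and omega-start
# assignment under shadow and batching constraints.

#' Characterization strategy
#'
#' Multiple small wedges spread over an omega range, used to obtain a
#' robust orientation matrix before strategy calculation.
#'
#' @param n_wedges Number of wedges (default 5).
#' @param images_per_wedge Images per wedge (default 12).
#' @param image_width_deg Image width (default 0.1 degrees).
#' @param range_deg Omega range over which wedge starts are equally spaced,
#'   endpoints included (default 180).
#' @return Object of class `"strategy_plan"` with one row per wedge.
#' @export
characterization_strategy <- function(n_wedges = 5, images_per_wedge = 12,
                                      image_width_deg = 0.1, range_deg = 180) {
  stopifnot(n_wedges >= 1, images_per_wedge >= 1, image_width_deg > 0)
  starts <- if (n_wedges == 1) 0 else seq(0, range_deg, length.out = n_wedges)
  w <- images_per_wedge * image_width_deg
  sweeps <- lapply(starts, function(s) {
    list(omega_start_deg = s, width_deg = w, image_width_deg = image_width_deg,
         kappa_deg = 0, phi_deg = 0, chi_deg = 0)
  })
  structure(list(kind = "characterization", sweeps = sweeps,
                 total_length_deg = n_wedges * w,
                 n_images = n_wedges * images_per_wedge,
                 recentrings = 0),
            class = "strategy_plan")
}

# Cartesian rotation-axis directions and orders of a point group's
# operators, in the crystal Cartesian frame of a given cell.
symmetry_axes <- function(pg, B) {
  pg <- .as_point_group(pg)
  A <- t(solve(B))  # real-space basis vectors as columns
  out <- list()
  for (w in pg$operators) {
    R <- A %*% w %*% solve(A)
    tr <- sum(diag(R))
    if (abs(tr - 3) < 1e-9) next  # identity
    ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
    ord <- round(2 * pi / ang)
    # rotation axis: antisymmetric part, or eigenvector for half-turns
    if (abs(ang - pi) > 1e-6) {
      ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    } else {
      ev <- eigen(R, symmetric = FALSE)
      i <- which.min(abs(ev$values - 1))
      ax <- Re(ev$vectors[, i])
    }
    ax <- .unit(ax)
    if (ax[which.max(abs(ax))] < 0) ax <- -ax  # canonical sign
    key <- paste(round(ax, 6), collapse = ",")
    if (!is.null(out[[key]])) {
      out[[key]]$order <- max(out[[key]]$order, ord)
    } else {
      out[[key]] <- list(axis = ax, order = ord)
    }
  }
  out <- unname(out)
  list(axes = if (length(out)) t(vapply(out, `[[`, numeric(3), "axis"))
       else matrix(numeric(0), 0, 3),
       orders = vapply(out, `[[`, numeric(1), "order"))
}

.sq2 <- 1 + sqrt(2)

.norm_rows <- function(m) m / sqrt(rowSums(m^2))

# rotation taking the (111) direction onto +z, used to express cubic
# polyhedra in the hexagonal/trigonal frame (principal axis along z)
.r111z <- function() rotation_between(c(1, 1, 1) / sqrt(3), c(0, 0, 1))

#' Target sweep orientations for advanced native strategies
#'
#' Rotation-axis directions (crystal Cartesian frame, principal symmetry
#' axis along z where the group has one) whose symmetry images spread
#' evenly over the sphere. Point groups 23, 222 and 4 use vertices of the
#' rhombicuboctahedron (a single vertex, and triangle triplets); point
#' group 3 uses either a three-sweep triangle (default) or the four-vertex
#' square variant of the rhombicuboctahedron; 432 uses a truncated
#' cuboctahedron vertex, and a two-vertex truncated-cuboctahedron set is
#' available for 23; 32 uses two truncated-octahedron vertices. For the
#' high-multiplicity groups 6, 422 and 622 and for 1 and 2 the sets are
#' documented heuristics (pairs, or four-orientation spreads compatible
#' with the goniostat range).
#'
#' @param pg Point-group symbol or [point_group()].
#' @param variant For PG 3: `"three-sweep"` (default) or `"four-sweep"`;
#'   for PG 23: `"single"` (default) or `"two-sweep"`.
#' @return List with `axes` (unit row vectors), `polyhedron`, and
#'   `n_sweeps`.
#' @export
target_orientations <- function(pg, variant = NULL) {
  pg <- .as_point_group(pg)
  s <- .sq2
  res <- switch(pg$name,
    "23" = if (identical(variant, "two-sweep")) {
      list(axes = .norm_rows(rbind(c(1, s, 1 + 2 * sqrt(2)),
                                   c(1 + 2 * sqrt(2), 1, s))),
           polyhedron = "truncated cuboctahedron")
    } else {
      list(axes = .norm_rows(rbind(c(1, 1, s))),
           polyhedron = "rhombicuboctahedron")
    },
    "432" = list(axes = .norm_rows(rbind(c(1, s, 1 + 2 * sqrt(2)))),
                 polyhedron = "truncated cuboctahedron"),
    "222" = list(axes = .norm_rows(rbind(c(1, 1, s), c(1, s, 1), c(s, 1, 1))),
                 polyhedron = "rhombicuboctahedron"),
    "4" = list(axes = .norm_rows(rbind(c(1, 1, s), c(1, s, 1), c(s, 1, 1))),
               polyhedron = "rhombicuboctahedron"),
    "3" = if (identical(variant, "four-sweep")) {
      sq <- .norm_rows(rbind(c(1, 1, s), c(-1, 1, s), c(-1, -1, s),
                             c(1, -1, s)))
      list(axes = sq %*% t(.r111z()), polyhedron = "rhombicuboctahedron")
    } else {
      tri <- .norm_rows(rbind(c(s, 1, -1), c(1, s, -1), c(1, 1, -s)))
      list(axes = tri %*% t(.r111z()), polyhedron = "rhombicuboctahedron")
    },
    "32" = {
      v <- .norm_rows(rbind(c(0, 1, 2), c(2, 0, 1)))
      list(axes = v %*% t(.r111z()), polyhedron = "truncated octahedron")
    },
    "6" = list(axes = rbind(.polar_axis(20, 0), .polar_axis(50, 30)),
               polyhedron = NA_character_),
    "422" = list(axes = rbind(.polar_axis(20, 0), .polar_axis(50, 45)),
                 polyhedron = NA_character_),
    "622" = list(axes = rbind(.polar_axis(20, 0), .polar_axis(50, 15)),
                 polyhedron = NA_character_),
    "2" = list(axes = {
      # polar angle 45 degrees from the twofold (y), azimuths spread in the
      # accessible half-turn; symmetry images double the coverage
      m <- t(vapply(c(0, 45, 90, 135), function(az) {
        v <- c(sin(.deg2rad(45)) * cos(.deg2rad(az)), cos(.deg2rad(45)),
               sin(.deg2rad(45)) * sin(.deg2rad(az)))
        v
      }, numeric(3)))
      m
    }, polyhedron = NA_character_),
    "1" = list(axes = rbind(c(0, 0, 1), .polar_axis(36, 0),
                            .polar_axis(36, 120), .polar_axis(36, 240)),
               polyhedron = NA_character_),
    stop("unsupported point group '", pg$name, "'", call. = FALSE))
  res$n_sweeps <- nrow(res$axes)
  res
}

.polar_axis <- function(polar_deg, az_deg) {
  c(sin(.deg2rad(polar_deg)) * cos(.deg2rad(az_deg)),
    sin(.deg2rad(polar_deg)) * sin(.deg2rad(az_deg)),
    cos(.deg2rad(polar_deg)))
}

#' Monte Carlo accessible fraction of rotation-axis orientations
#'
#' A goniostat that can tilt the rotation axis by up to `chi_max` from its
#' mounting direction reaches the fraction `1 - cos(chi_max)` of all
#' unsigned axis directions; this estimator samples uniform axes and
#' reports the reachable percentage.
#'
#' @param chi_max_deg Maximum chi (default 48).
#' @param n Number of sampled axes (default 1e5).
#' @return Percentage (0-100), with the analytic value as attribute
#'   `"analytic"`.
#' @export
accessible_fraction <- function(chi_max_deg = 48, n = 1e5) {
  z <- stats::runif(n, -1, 1)
  pct <- 100 * mean(abs(z) >= cos(.deg2rad(chi_max_deg)))
  attr(pct, "analytic") <- 100 * (1 - cos(.deg2rad(chi_max_deg)))
  pct
}

.unsigned_angle <- function(v, w) {
  a <- .rad2deg(acos(pmin(1, pmax(-1, abs(sum(.unit(v) * .unit(w)))))))
  a
}

# Inverse kinematics: goniostat (kappa, phi) placing crystal-frame axis v
# (unsigned) along the omega axis. Returns kappa, phi, chi and the signed
# axis actually aligned.
.inverse_kinematics <- function(v, crystal, gonio) {
  U <- crystal$orientation
  p <- as.vector(t(U) %*% c(1, 0, 0))     # mount (phi-axis) direction, crystal frame
  if (sum(v * p) < 0) v <- -v             # unsigned axis: take the near side
  chi <- .rad2deg(acos(pmin(1, pmax(-1, sum(.unit(v) * .unit(p))))))
  alpha <- gonio$kappa_axis_angle_deg
  kappa <- kappa_of_chi(min(chi, 2 * alpha), alpha)
  a <- .deg2rad(alpha)
  k_axis <- c(cos(a), sin(a), 0)
  w <- as.vector(rotation_about(k_axis, -kappa) %*% c(1, 0, 0))
  u <- as.vector(U %*% .unit(v))
  az_w <- atan2(w[3], w[2])
  az_u <- atan2(u[3], u[2])
  phi <- if (chi < 1e-9) 0 else .rad2deg(az_w - az_u) %% 360
  list(axis_crystal = .unit(v), chi_deg = chi, kappa_deg = kappa,
       phi_deg = phi)
}

# Crystal-to-lab setting matrix at omega = 0 for goniostat (kappa, phi).
.setting_matrix <- function(crystal, gonio, kappa_deg, phi_deg) {
  a <- .deg2rad(gonio$kappa_axis_angle_deg)
  k_axis <- c(cos(a), sin(a), 0)
  rotation_about(k_axis, kappa_deg) %*% rotation_about(c(1, 0, 0), phi_deg) %*%
    crystal$orientation
}

#' Fit target orientations to the crystal mounting
#'
#' Finds a rigid rotation of the target axis set - about the crystal's
#' principal symmetry axis where the group has one, over all of SO(3) for
#' point group 1, and over the finite symmetry images for the cubic groups -
#' that minimizes the maximum chi required, then realizes each axis by
#' inverse kinematics. Targets that still exceed the chi limit are replaced
#' by their projection onto the accessible cone (the nearest accessible
#' orientation), with a warning recorded.
#'
#' @param targets Result of [target_orientations()] (or a matrix of axis
#'   rows).
#' @param crystal A [crystal_sample()].
#' @param gonio A [goniostat_model()].
#' @param grid_deg Search grid for the rigid rotation (default 2 degrees).
#' @return List of realized sweep settings (one per target: `axis_crystal`,
#'   `chi_deg`, `kappa_deg`, `phi_deg`, `accessible`), with attributes
#'   `max_chi` and `fallback`.
#' @export
fit_to_mounting <- function(targets, crystal, gonio, grid_deg = 2) {
  axes <- if (is.list(targets) && !is.null(targets$axes)) targets$axes else
    as.matrix(targets)
  pg <- strategy_point_group(crystal)
  U <- crystal$orientation
  p <- as.vector(t(U) %*% c(1, 0, 0))
  maxchi <- function(R) {
    max(apply(axes %*% t(R), 1, function(v) .unsigned_angle(v, p)))
  }
  spin_axis <- switch(pg$name, "1" = NULL, "2" = c(0, 1, 0), c(0, 0, 1))
  candidates <- list()
  if (pg$name %in% c("23", "432")) {
    A <- t(solve(crystal$B))
    candidates <- lapply(pg$operators, function(w) A %*% w %*% solve(A))
  } else if (is.null(spin_axis)) {
    # PG 1: centre the set on the mount direction, then spin about it
    centroid <- .unit(colSums(.norm_rows(axes)))
    R0 <- rotation_between(centroid, p)
    candidates <- lapply(seq(0, 358, by = grid_deg), function(g)
      rotation_about(p, g) %*% R0)
  } else {
    candidates <- lapply(seq(0, 358, by = grid_deg), function(g)
      rotation_about(spin_axis, g))
  }
  scores <- vapply(candidates, maxchi, numeric(1))
  best <- candidates[[which.min(scores)]]
  fitted_axes <- axes %*% t(best)
  chimax_lim <- gonio$chi_max_mech_deg
  fallback <- FALSE
  sweeps <- lapply(seq_len(nrow(fitted_axes)), function(i) {
    v <- fitted_axes[i, ]
    if (sum(v * p) < 0) v <- -v
    chi <- .unsigned_angle(v, p)
    acc <- chi <= chimax_lim + 1e-9
    if (!acc) {
      # nearest accessible orientation: rotate v toward the mount direction
      # (the tilt axis p x v moves v away from p for positive angles)
      ax <- pracma_cross(p, v)
      if (sqrt(sum(ax^2)) < 1e-12) ax <- c(0, 0, 1)
      v <- as.vector(rotation_about(.unit(ax), -(chi - chimax_lim)) %*% v)
      fallback <<- TRUE
    }
    ik <- .inverse_kinematics(v, crystal, gonio)
    ik$accessible <- acc
    ik
  })
  if (fallback)
    warning("some target orientations exceed the chi limit; ",
            "nearest accessible orientations substituted")
  attr(sweeps, "max_chi") <- min(scores)
  attr(sweeps, "fallback") <- fallback
  sweeps
}

# Closed-form shadow-free omega test used for omega-start selection: with
# the detector subtending 2theta_max, the mount cone at angle(m, z) clears
# the detector iff angle(m_hat(omega), beam) >= A + 2theta_max.
.free_omegas <- function(chi_deg, kappa_deg, phi_deg, gonio,
                         two_theta_max_deg, step = 1) {
  omegas <- seq(0, 360 - step, by = step)
  p0 <- goniostat_pose(gonio, 0, kappa_deg, phi_deg)$phi_axis
  lim <- .deg2rad(gonio$cone_half_angle_deg + two_theta_max_deg)
  th <- .deg2rad(omegas)
  mz <- -(p0[2] * sin(th) + p0[3] * cos(th))
  ang <- acos(pmin(1, pmax(-1, mz)))
  list(omegas = omegas, free = ang >= lim, step = step)
}

#' Assign sweep lengths and omega starts
#'
#' The sweep requiring the lowest chi is acquired first with a width of
#' 360 degrees (best basis for scaling); later sweeps are 360 when a full
#' turn is shadow-free at their chi (`90 - chi - 2theta_max >= A`) and 192
#' degrees otherwise, started inside the shadow-free omega window. All
#' widths are multiples of the batch size.
#'
#' @param fitted Result of [fit_to_mounting()].
#' @param crystal A [crystal_sample()].
#' @param gonio A [goniostat_model()].
#' @param two_theta_max_deg Largest scattering angle at the planned
#'   detector setting.
#' @param batch_deg Scaling batch size (default 4.8).
#' @param image_width_deg,exposure_per_image_s,transmission Passed to the
#'   sweeps.
#' @return A `"strategy_plan"`.
#' @export
assign_lengths <- function(fitted, crystal, gonio, two_theta_max_deg,
                           batch_deg = 4.8, image_width_deg = 0.1,
                           exposure_per_image_s = 0.01, transmission = 1) {
  ord <- order(vapply(fitted, `[[`, numeric(1), "chi_deg"))
  fitted <- fitted[ord]
  A <- gonio$cone_half_angle_deg
  sweeps <- list()
  for (i in seq_along(fitted)) {
    f <- fitted[[i]]
    shadow_free_360 <- (90 - f$chi_deg - two_theta_max_deg) >= A
    width <- if (i == 1 || shadow_free_360) 360 else 192
    stopifnot(abs(width / batch_deg - round(width / batch_deg)) < 1e-9)
    if (width >= 360) {
      start <- 0
    } else {
      fr <- .free_omegas(f$chi_deg, f$kappa_deg, f$phi_deg, gonio,
                         two_theta_max_deg)
      run <- .widest_true_run(fr$free, fr$step)
      start <- if (!is.na(run[2]) && run[1] >= width)
        (run[2] + (run[1] - width) / 2) %% 360
      else if (!is.na(run[2])) run[2] %% 360 else 0
    }
    sweeps[[i]] <- make_sweep(crystal,
                              setting = .setting_matrix(crystal, gonio,
                                                        f$kappa_deg, f$phi_deg),
                              omega_start_deg = start, width_deg = width,
                              image_width_deg = image_width_deg,
                              exposure_per_image_s = exposure_per_image_s,
                              transmission = transmission,
                              kappa_deg = f$kappa_deg, phi_deg = f$phi_deg)
    sweeps[[i]]$chi_deg <- f$chi_deg
  }
  .plan(sweeps, kind = "advanced")
}

.plan <- function(sweeps, kind) {
  total <- sum(vapply(sweeps, `[[`, numeric(1), "width_deg"))
  eff <- sum(vapply(sweeps, function(s)
    if (abs(s$width_deg - 192) < 1e-9) 180 else s$width_deg, numeric(1)))
  kp <- unique(round(cbind(vapply(sweeps, function(s) s$kappa_deg %||% NA_real_,
                                  numeric(1)),
                           vapply(sweeps, function(s) s$phi_deg %||% NA_real_,
                                  numeric(1))), 6))
  structure(list(kind = kind, sweeps = sweeps, total_length_deg = total,
                 effective_length_deg = eff,
                 recentrings = max(0, nrow(kp) - 1)),
            class = "strategy_plan")
}

#' @export
print.strategy_plan <- function(x, ...) {
  cat(sprintf("%s strategy: %d sweep(s), total %.0f deg, %d recentring(s)\n",
              x$kind, length(x$sweeps), x$total_length_deg, x$recentrings))
  for (s in x$sweeps) {
    if (!is.null(s$omega_start_deg))
      cat(sprintf("  omega %6.1f + %5.1f deg  kappa %6.1f  phi %6.1f%s\n",
                  s$omega_start_deg, s$width_deg,
                  s$kappa_deg %||% NA, s$phi_deg %||% NA,
                  if (!is.null(s$chi_deg)) sprintf("  (chi %.1f)", s$chi_deg)
                  else ""))
  }
  invisible(x)
}

#' Basic native strategy
#'
#' A single 360-degree sweep at chi = 0, unless the rotation axis lies
#' within theta_max of a unique symmetry axis, in which case the crystal is
#' reoriented by the minimal chi placing the axis theta_max away so that
#' every blind-region reflection has a measurable symmetry mate. For P1 two
#' sweeps are necessary; the second is tilted far enough (twice theta_max,
#' clamped at the chi limit) that the two cusp systems do not overlap.
#'
#' @param crystal A [crystal_sample()].
#' @param gonio A [goniostat_model()].
#' @param two_theta_max_deg Largest scattering angle at the planned
#'   detector setting.
#' @param ... Passed to [make_sweep()] (image width etc.).
#' @return A `"strategy_plan"`.
#' @export
basic_strategy <- function(crystal, gonio, two_theta_max_deg, ...) {
  pg <- strategy_point_group(crystal)
  theta_max <- two_theta_max_deg / 2
  U <- crystal$orientation
  p <- as.vector(t(U) %*% c(1, 0, 0))
  mk <- function(ik, width = 360, start = 0) {
    sw <- make_sweep(crystal,
                     setting = .setting_matrix(crystal, gonio, ik$kappa_deg,
                                               ik$phi_deg),
                     omega_start_deg = start, width_deg = width,
                     kappa_deg = ik$kappa_deg, phi_deg = ik$phi_deg, ...)
    sw$chi_deg <- ik$chi_deg
    sw
  }
  if (pg$name == "1") {
    chi2 <- min(gonio$chi_max_mech_deg, 2 * theta_max + 2)
    v2 <- .tilt_away(p, p, chi2)
    plan <- .plan(list(mk(.inverse_kinematics(p, crystal, gonio)),
                       mk(.inverse_kinematics(v2, crystal, gonio))),
                  kind = "basic")
    return(plan)
  }
  ax <- symmetry_axes(pg, crystal$B)
  angles <- apply(ax$axes, 1, function(a) .unsigned_angle(a, p))
  axis0 <- p
  if (any(angles < theta_max)) {
    worst <- ax$axes[which.min(angles), ]
    axis0 <- .tilt_away(p, worst, theta_max + 1 - min(angles))
  }
  .plan(list(mk(.inverse_kinematics(axis0, crystal, gonio))), kind = "basic")
}

# rotate v away from direction a by delta degrees (within their common
# plane; an arbitrary perpendicular plane when (anti)parallel)
.tilt_away <- function(v, a, delta) {
  v <- .unit(v); a <- .unit(a)
  if (sum(v * a) < 0) a <- -a
  ax <- pracma_cross(a, v)
  if (sqrt(sum(ax^2)) < 1e-9) {
    perp <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .unit(pracma_cross(v, perp))
  }
  as.vector(rotation_about(.unit(ax), delta) %*% v)
}

#' Advanced native strategy
#'
#' Target orientations for the strategy point group are fitted to the
#' crystal mounting and assigned lengths and omega starts.
#'
#' @inheritParams basic_strategy
#' @param variant Passed to [target_orientations()].
#' @param first_sweep_chi0 When `TRUE`, the lowest-chi target is replaced
#'   by the mounted axis itself (chi = 0), trading one recentring for a
#'   less ideal orientation distribution.
#' @param batch_deg Scaling batch size (default 4.8).
#' @return A `"strategy_plan"`.
#' @export
advanced_strategy <- function(crystal, gonio, two_theta_max_deg,
                              variant = NULL, first_sweep_chi0 = FALSE,
                              batch_deg = 4.8, ...) {
  pg <- strategy_point_group(crystal)
  tg <- target_orientations(pg, variant)
  fitted <- fit_to_mounting(tg, crystal, gonio)
  if (first_sweep_chi0) {
    chis <- vapply(fitted, `[[`, numeric(1), "chi_deg")
    p <- as.vector(t(crystal$orientation) %*% c(1, 0, 0))
    fitted[[which.min(chis)]] <- .inverse_kinematics(p, crystal, gonio)
  }
  plan <- assign_lengths(fitted, crystal, gonio, two_theta_max_deg,
                         batch_deg = batch_deg, ...)
  plan$point_group <- pg$name
  plan$predicted_multiplicity <- predicted_multiplicity(plan, pg)
  plan
}

#' Predicted maximum multiplicity of a strategy
#'
#' Each 360-degree turn yields two Ewald-sphere crossings per reflection,
#' and the Laue group multiplies observations by its order:
#' `2 * laue_order * effective_length / 360`, where 192-degree sweeps are
#' counted as 180 (the prolongation from 180 to 192 exists for scaling, and
#' its extra multiplicity is disregarded by convention).
#'
#' @param plan A `"strategy_plan"`, or a numeric vector of sweep widths in
#'   degrees.
#' @param pg Point group (symbol or object).
#' @return Predicted maximum multiplicity.
#' @export
predicted_multiplicity <- function(plan, pg) {
  pg <- .as_point_group(pg)
  widths <- if (inherits(plan, "strategy_plan"))
    vapply(plan$sweeps, `[[`, numeric(1), "width_deg") else as.numeric(plan)
  eff <- sum(ifelse(abs(widths - 192) < 1e-9, 180, widths))
  2 * pg$laue_order * eff / 360
}

#' Advanced native strategy table
#'
#' Sweep counts, total lengths (one 360-degree sweep plus 192-degree
#' sweeps) and predicted maximum multiplicities for the 11 axial point
#' groups (both variants for point group 3).
#'
#' @return Data frame with `point_group`, `variant`, `n_sweeps`,
#'   `length_deg`, `multiplicity`.
#' @export
native_strategy_table <- function() {
  rows <- list(
    c("1", "", NA), c("2", "", NA),
    c("3", "three-sweep", NA), c("3", "four-sweep", NA),
    c("222", "", NA), c("4", "", NA), c("32", "", NA), c("6", "", NA),
    c("422", "", NA), c("622", "", NA), c("23", "", NA), c("432", "", NA))
  out <- do.call(rbind, lapply(rows, function(r) {
    pgn <- r[1]
    variant <- if (nzchar(r[2])) r[2] else NULL
    n <- target_orientations(pgn, variant)$n_sweeps
    widths <- c(360, rep(192, n - 1))
    data.frame(point_group = pgn, variant = r[2], n_sweeps = n,
               length_deg = sum(widths),
               multiplicity = predicted_multiplicity(widths, pgn))
  }))
  out
}
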
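# Phasing-experiment building blocks: minimum sweep lengths for anomalous
# completeness (after Dauter's analysis), cusp-filling sweeps, interleaving
# schedules and split-sweep ordering.

.single_axis_groups <- c("2", "3", "4", "6")

#' Minimum sweep length for anomalous completeness
#'
#' Shortest sweep giving close to 100 % anomalous completeness (outside a
#' volume somewhat larger than the cusps), by crystal class and alignment:
#' in P1, `180 + 2 theta_max`; in single-axis point groups, `360 / n`
#' aligned on the n-fold axis or `90 + theta_max` aligned orthogonal to the
#' symmetry axis; in all other point groups, `360 / (2 n)` aligned on an
#' n-fold axis with n even, or 90 degrees aligned orthogonal to a symmetry
#' axis. For a monoclinic crystal orthogonal to the twofold, Dauter's
#' original `180 + 2 theta_max` can be requested with `dauter_monoclinic`,
#' but the single-axis rule `90 + theta_max` is the default.
#'
#' @param pg Point group (symbol or object).
#' @param alignment `"aligned"` (rotation axis on a symmetry axis) or
#'   `"orthogonal"` (rotation axis orthogonal to a symmetry axis);
#'   ignored for P1.
#' @param two_theta_max_deg Largest scattering angle (degrees).
#' @param axis_order Order n of the aligned axis; defaults to the group's
#'   principal axis order for single-axis groups and to the highest even
#'   axis order otherwise. Aligned mode in non-single-axis groups requires
#'   an even n.
#' @param dauter_monoclinic Use Dauter's `180 + 2 theta_max` for the
#'   monoclinic orthogonal case (default `FALSE`).
#' @return Minimum sweep length in degrees.
#' @export
min_anomalous_sweep <- function(pg, alignment = c("aligned", "orthogonal"),
                                two_theta_max_deg, axis_order = NULL,
                                dauter_monoclinic = FALSE) {
  pg <- .as_point_group(pg)
  theta_max <- two_theta_max_deg / 2
  if (pg$name == "1") return(180 + two_theta_max_deg)
  alignment <- match.arg(alignment)
  if (pg$name %in% .single_axis_groups) {
    if (alignment == "aligned") {
      n <- axis_order %||% pg$max_axis_order
      return(360 / n)
    }
    if (pg$name == "2" && dauter_monoclinic) return(180 + two_theta_max_deg)
    return(90 + theta_max)
  }
  if (alignment == "aligned") {
    even <- pg$max_axis_order - pg$max_axis_order %% 2
    if (is.null(axis_order)) {
      axis_order <- if (even >= 2 && pg$max_axis_order %% 2 == 0) even else 2
    }
    if (axis_order %% 2 != 0)
      stop("aligned phasing sweeps require an evenfold axis", call. = FALSE)
    return(360 / (2 * axis_order))
  }
  90
}

#' Cusp-filling sweeps
#'
#' Auxiliary sweeps at an orientation as far as accessible from the main
#' sweep's rotation axis, measuring the reflections lost in its cusp.
#' Modes: `"basic"`, one sweep of `180 + 2 theta_max`; `"extended"`, one
#' sweep of `180 + 4 theta_max` (additional filling-in); `"pair"`, two
#' sweeps of `2 theta_max` each acquired 180 degrees apart.
#'
#' @param main_axis_crystal Rotation axis of the main sweep (crystal
#'   Cartesian frame).
#' @param crystal A [crystal_sample()].
#' @param gonio A [goniostat_model()].
#' @param two_theta_max_deg Largest scattering angle (degrees).
#' @param mode `"basic"`, `"extended"` or `"pair"`.
#' @param omega_start_deg Start of the first fill sweep.
#' @return List of [make_sweep()] objects, with attribute
#'   `"fill_axis_angle_deg"` (achieved angle between main and fill axes).
#' @export
cusp_fill <- function(main_axis_crystal, crystal, gonio, two_theta_max_deg,
                      mode = c("basic", "extended", "pair"),
                      omega_start_deg = 0) {
  mode <- match.arg(mode)
  p <- as.vector(t(crystal$orientation) %*% c(1, 0, 0))
  v <- .unit(main_axis_crystal)
  if (sum(v * p) < 0) v <- -v
  chi_main <- .unsigned_angle(v, p)
  # as far as possible from the main axis subject to chi <= chi_max:
  # tilt from the mount direction by chi_max, azimuthally opposite the
  # main axis
  target <- .tilt_away(p, v, gonio$chi_max_mech_deg)
  ach <- .unsigned_angle(target, v)
  ik <- .inverse_kinematics(target, crystal, gonio)
  mk <- function(start, width) {
    sw <- make_sweep(crystal,
                     setting = .setting_matrix(crystal, gonio, ik$kappa_deg,
                                               ik$phi_deg),
                     omega_start_deg = start %% 360, width_deg = width,
                     kappa_deg = ik$kappa_deg, phi_deg = ik$phi_deg)
    sw$chi_deg <- ik$chi_deg
    sw
  }
  out <- switch(mode,
    basic = list(mk(omega_start_deg, 180 + two_theta_max_deg)),
    extended = list(mk(omega_start_deg, 180 + 2 * two_theta_max_deg)),
    pair = list(mk(omega_start_deg, two_theta_max_deg),
                mk(omega_start_deg + 180, two_theta_max_deg)))
  if (ach < 2 * two_theta_max_deg / 2)
    warning("fill orientation only ", round(ach, 1),
            " degrees from the main axis; cusp overlap possible")
  attr(out, "fill_axis_angle_deg") <- ach
  out
}

#' Interleaved acquisition schedule
#'
#' Splits a sweep into wedges acquired alternately at omega and
#' omega + 180 (so that Friedel mates share irradiation history), crossed
#' with an optional wavelength list for MAD. Together the two offsets cover
#' the input range and its Friedel image exactly once per wavelength.
#'
#' @param omega_start_deg,width_deg The sweep to interleave.
#' @param wedge_deg Wedge size; must divide the width.
#' @param wavelengths Optional vector of wavelength labels.
#' @return Data frame of segments in acquisition order: `segment`,
#'   `omega_start_deg`, `width_deg`, `offset_deg` (0 or 180),
#'   `wavelength`.
#' @export
interleave_schedule <- function(omega_start_deg = 0, width_deg = 180,
                                wedge_deg = 10, wavelengths = NULL) {
  if (wedge_deg <= 0 || abs(width_deg / wedge_deg -
                            round(width_deg / wedge_deg)) > 1e-9)
    stop("wedge size must divide the sweep width", call. = FALSE)
  nw <- round(width_deg / wedge_deg)
  wl <- wavelengths %||% NA
  rows <- list()
  for (i in seq_len(nw)) {
    ws <- omega_start_deg + (i - 1) * wedge_deg
    for (off in c(0, 180)) {
      for (w in wl) {
        rows[[length(rows) + 1L]] <- data.frame(
          omega_start_deg = (ws + off) %% 360, width_deg = wedge_deg,
          offset_deg = off, wavelength = w)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$segment <- seq_len(nrow(out))
  out[, c("segment", "omega_start_deg", "width_deg", "offset_deg",
          "wavelength")]
}

#' Split a sweep into two out-of-sequence halves
#'
#' Divides a sweep of roughly 180 degrees into two parts acquired out of
#' sequence so that each half individually achieves completeness when the
#' symmetry omega anchors allow. With no constraint the sweep is split at
#' its midpoint; with `omega_constraints` (a vector of preferred start
#' angles, e.g. shadow-window or symmetry-axis anchors) the split point is
#' moved to the nearest constraint inside the sweep and the half containing
#' the first preferred start is acquired first.
#'
#' @param omega_start_deg,width_deg The sweep to split.
#' @param omega_constraints Optional numeric vector of preferred start
#'   angles (degrees).
#' @return Data frame of two sub-sweeps in acquisition order
#'   (`omega_start_deg`, `width_deg`); their union is the input sweep. When
#'   the constraints cannot be honoured the sweep is returned unsplit with
#'   a warning.
#' @export
split_sweep_for_completeness <- function(omega_start_deg = 0,
                                         width_deg = 180,
                                         omega_constraints = NULL) {
  mid <- omega_start_deg + width_deg / 2
  split_at <- mid
  first <- 1L
  if (!is.null(omega_constraints)) {
    inside <- omega_constraints[
      ((omega_constraints - omega_start_deg) %% 360) < width_deg &
      ((omega_constraints - omega_start_deg) %% 360) > 0]
    if (length(inside) == 0) {
      warning("no omega constraint falls inside the sweep; returning unsplit")
      return(data.frame(omega_start_deg = omega_start_deg,
                        width_deg = width_deg))
    }
    off <- (inside - omega_start_deg) %% 360
    split_at <- omega_start_deg + off[which.min(abs(off - width_deg / 2))]
    # acquire first the half starting at the earliest constraint
    first_anchor <- inside[which.min(off)]
    first <- if (((first_anchor - omega_start_deg) %% 360) <
                 ((split_at - omega_start_deg) %% 360)) 1L else 2L
  }
  halves <- data.frame(
    omega_start_deg = c(omega_start_deg, split_at),
    width_deg = c(split_at - omega_start_deg,
                  omega_start_deg + width_deg - split_at))
  halves[order(c(1, 2) != first), , drop = FALSE]
}

#' Assemble a phasing plan
#'
#' Combines an alignment choice, a main sweep at the minimum anomalous
#' length, optional cusp-filling sweeps and an optional interleaving
#' schedule into one plan object. The building blocks are exposed
#' individually because the best combination depends on which axis
#' alignments the mounting allows.
#'
#' @param crystal A [crystal_sample()].
#' @param gonio A [goniostat_model()].
#' @param two_theta_max_deg Largest scattering angle.
#' @param alignment `"aligned"`, `"orthogonal"` or `"unaligned"` (P1 rule).
#' @param fill `"none"`, `"basic"`, `"extended"` or `"pair"`.
#' @param wedge_deg Optional interleaving wedge (NULL for none).
#' @param wavelengths Optional wavelength labels for MAD interleaving.
#' @return Object of class `"phasing_plan"`.
#' @export
phasing_plan <- function(crystal, gonio, two_theta_max_deg,
                         alignment = c("aligned", "orthogonal", "unaligned"),
                         fill = c("none", "basic", "extended", "pair"),
                         wedge_deg = NULL, wavelengths = NULL) {
  alignment <- match.arg(alignment)
  fill <- match.arg(fill)
  pg <- strategy_point_group(crystal)
  ax <- symmetry_axes(pg, crystal$B)
  U <- crystal$orientation
  if (alignment == "aligned") {
    evens <- which(ax$orders %% 2 == 0)
    if (pg$name == "1" || (length(evens) == 0 && !pg$name %in% .single_axis_groups))
      stop("no evenfold axis to align on", call. = FALSE)
    cand <- if (length(evens) > 0) evens else seq_along(ax$orders)
    axis <- ax$axes[cand[which.max(ax$orders[cand])], ]
    n <- max(ax$orders[cand])
    len <- min_anomalous_sweep(pg, "aligned", two_theta_max_deg,
                               axis_order = if (pg$name %in% .single_axis_groups)
                                 pg$max_axis_order else n)
  } else if (alignment == "orthogonal") {
    if (pg$name == "1") stop("P1 has no symmetry axis", call. = FALSE)
    main <- ax$axes[which.max(ax$orders), ]
    axis <- .unit(pracma_cross(main, if (abs(main[1]) < 0.9) c(1, 0, 0)
                               else c(0, 1, 0)))
    len <- min_anomalous_sweep(pg, "orthogonal", two_theta_max_deg)
  } else {
    axis <- as.vector(t(U) %*% c(1, 0, 0))
    len <- 180 + two_theta_max_deg
  }
  ik <- .inverse_kinematics(axis, crystal, gonio)
  main_sweep <- make_sweep(crystal,
                           setting = .setting_matrix(crystal, gonio,
                                                     ik$kappa_deg, ik$phi_deg),
                           omega_start_deg = 0, width_deg = min(len, 360),
                           kappa_deg = ik$kappa_deg, phi_deg = ik$phi_deg)
  main_sweep$chi_deg <- ik$chi_deg
  fills <- if (fill == "none") list() else
    cusp_fill(ik$axis_crystal, crystal, gonio, two_theta_max_deg, fill)
  sched <- if (!is.null(wedge_deg))
    interleave_schedule(0, min(len, 360), wedge_deg, wavelengths) else NULL
  structure(list(alignment = alignment, point_group = pg$name,
                 min_length_deg = len, sweeps = c(list(main_sweep), fills),
                 interleave = sched),
            class = "phasing_plan")
}

#' @export
print.phasing_plan <- function(x, ...) {
  cat(sprintf("Phasing plan (%s, PG %s): main sweep %.1f deg, %d fill sweep(s)%s\n",
              x$alignment, x$point_group, x$min_length_deg,
              length(x$sweeps) - 1,
              if (!is.null(x$interleave))
                sprintf(", %d interleaved segments", nrow(x$interleave))
              else ""))
  invisible(x)
}
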
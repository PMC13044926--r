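test_that("detector angle limits reproduce the published five-detector table", {
  printed <- data.frame(
    width = c(311.1, 233.1, 311.1, 233.1, 423.6),
    two_theta = c(48.6, 40.4, 48.6, 40.4, 57.1),
    chi_max = c(21.6, 29.8, 21.6, 29.8, 13.1),
    resolution = c(1.22, 1.45, 1.22, 1.45, 1.04))
  tt <- two_theta_max(printed$width, 137)
  # agreement within one unit of the last printed digit
  expect_true(all(abs(tt - printed$two_theta) <= 0.05))
  # chi_max chained from the printed 2theta (as the table derives it)
  cm <- chi_max_shadow_free(round(tt, 1), 19.84)
  expect_true(all(abs(as.numeric(cm) - printed$chi_max) <= 0.05))
  expect_true(all(abs(resolution_limit(tt, 1.0) - printed$resolution) <= 0.011))
  # the bundled library covers the same five detectors
  tab <- detector_limits_table()
  expect_equal(nrow(tab), 5)
  expect_equal(sort(round(tab$two_theta_max, 1)),
               sort(c(48.6, 40.4, 57.1, 48.6, 40.4)))
})

test_that("angle / resolution relations behave at their limits", {
  expect_lt(two_theta_max(1e-6, 137), 1e-3)
  expect_equal(resolution_limit(180, 1), 0.5)
  expect_error(two_theta_max(-1, 100), "positive")
  expect_error(resolution_limit(0, 1), "degrees")
  # round trip is monotone in distance and width
  d1 <- resolution_limit(two_theta_max(311.1, 137), 1)
  d2 <- resolution_limit(two_theta_max(311.1, 200), 1)
  d3 <- resolution_limit(two_theta_max(423.6, 137), 1)
  expect_gt(d2, d1)
  expect_lt(d3, d1)
  expect_equal(two_theta_of_resolution(resolution_limit(48.6, 1), 1), 48.6)
})

test_that("shadow-free chi limit clamps at zero with a flag", {
  x <- chi_max_shadow_free(0, 0)
  expect_equal(as.numeric(x), 90)
  y <- chi_max_shadow_free(80, 19.84)
  expect_equal(as.numeric(y), 0)
  expect_true(attr(y, "clamped"))
})

test_that("mini-kappa kinematics: chi(kappa) and its inverse", {
  expect_equal(chi_of_kappa(0, 24), 0)
  expect_equal(chi_of_kappa(180, 24), 48)
  expect_equal(chi_of_kappa(180, 22.5), 45)
  # monotone on [0, 180]
  ks <- seq(0, 180, by = 5)
  expect_true(all(diff(chi_of_kappa(ks, 24)) > 0))
  for (chi in c(0, 10, 30, 47.9)) {
    expect_equal(chi_of_kappa(kappa_of_chi(chi, 24), 24), chi,
                 tolerance = 1e-10)
  }
  expect_error(kappa_of_chi(50, 24), "2 \\* alpha")
})

test_that("goniostat pose places the phi axis at chi from omega", {
  g <- goniostat_model()
  for (kap in c(0, 45, 120, 180)) {
    p <- goniostat_pose(g, omega_deg = 33, kappa_deg = kap, phi_deg = 10)
    expect_equal(sqrt(sum(p$phi_axis^2)), 1, tolerance = 1e-12)
    ang <- acos(sum(p$phi_axis * c(1, 0, 0))) * 180 / pi
    expect_equal(ang, chi_of_kappa(kap, 24), tolerance = 1e-9)
  }
  expect_error(goniostat_model(chi_max_mech_deg = 60), "2 \\* kappa")
})

test_that("cone shadow test matches the closed-form 360-degree criterion", {
  g <- goniostat_model()
  # ray along the beam with the mount perpendicular is never shadowed
  p0 <- goniostat_pose(g, 0, 0, 0)
  expect_false(is_ray_shadowed(c(0, 0, 1), p0))
  set.seed(11)
  A <- g$cone_half_angle_deg
  for (i in 1:200) {
    chi <- runif(1, 0, 48)
    tt <- runif(1, 5, 65)
    kap <- kappa_of_chi(chi, 24)
    base <- goniostat_pose(g, 0, kap, 0)$phi_axis
    # numeric worst-omega search: the widest ray cone at angle 2theta from
    # the beam comes within (angle(m, z) - 2theta) of the mount
    shadowed_any <- FALSE
    for (om in seq(0, 359, by = 1)) {
      m <- -as.vector(rotation_about(c(1, 0, 0), om) %*% base)
      angz <- acos(pmin(1, pmax(-1, m[3]))) * 180 / pi
      if (angz - tt < A) { shadowed_any <- TRUE; break }
    }
    expect_identical(shadowed_any, (90 - chi - tt) < A)
  }
})

test_that("detector shadow fraction is zero at chi 0 and continuous in omega", {
  g <- goniostat_model()
  det <- detector_library("pilatus6m")
  expect_equal(shadow_fraction(goniostat_pose(g, 0, 0, 0), det, 200), 0)
  fr <- vapply(seq(0, 358, by = 2), function(om)
    shadow_fraction(goniostat_pose(g, om, 180, 0), det, 150, grid_n = 64),
    numeric(1))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_lt(max(abs(diff(fr))), 0.06)  # no jumps beyond grid resolution
})

test_that("shadow-free omega windows shrink with the detector distance", {
  g <- goniostat_model()
  det <- detector_library("pilatus6m")
  kap <- seq(90, 240, by = 50)
  far <- shadow_free_omega_range(kap, det, 400, g, omega_step = 2, grid_n = 32)
  near <- shadow_free_omega_range(kap, det, 120, g, omega_step = 2, grid_n = 32)
  expect_gt(far$width_deg, near$width_deg)
  common <- shadow_free_omega_range(kap, det, 200, g, mode = "common",
                                    omega_step = 2, grid_n = 32)
  each <- shadow_free_omega_range(kap, det, 200, g, omega_step = 2,
                                  grid_n = 32)
  expect_lte(common$width_deg, each$width_deg)
  expect_error(shadow_free_omega_range(numeric(0), det, 200, g), "non-empty")
})

test_that("detector models validate their module tiling", {
  det <- detector_library("pilatus6m")
  expect_equal(det$total_px, c(2463L, 2527L))
  expect_equal(det$total_px[1] * det$pixel_mm, det$width_mm,
               tolerance = 1e-3)
  expect_error(detector_model("bad", 100, 100, 0.1, c(100, 100), c(5, 5),
                              c(20, 20)),
               "inconsistent")
  expect_error(detector_library("nonesuch"), "unknown detector")
})
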
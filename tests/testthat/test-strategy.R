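test_that("characterization strategy spreads wedges over 180 degrees", {
  p <- characterization_strategy()
  starts <- vapply(p$sweeps, `[[`, numeric(1), "omega_start_deg")
  expect_equal(starts, c(0, 45, 90, 135, 180))
  expect_equal(p$n_images, 60)
  expect_equal(vapply(p$sweeps, `[[`, numeric(1), "width_deg"),
               rep(1.2, 5))
  single <- characterization_strategy(n_wedges = 1)
  expect_equal(single$sweeps[[1]]$omega_start_deg, 0)
})

test_that("target orientation counts match the published strategy table", {
  counts <- c("1" = 4, "2" = 4, "222" = 3, "4" = 3, "32" = 2, "6" = 2,
              "422" = 2, "622" = 2, "23" = 1, "432" = 1)
  for (nm in names(counts)) {
    expect_equal(target_orientations(nm)$n_sweeps, unname(counts[[nm]]),
                 info = nm)
  }
  expect_equal(target_orientations("3")$n_sweeps, 3)             # default
  expect_equal(target_orientations("3", "four-sweep")$n_sweeps, 4)
  expect_equal(target_orientations("23", "two-sweep")$n_sweeps, 2)
  expect_identical(target_orientations("222")$polyhedron,
                   "rhombicuboctahedron")
  expect_identical(target_orientations("432")$polyhedron,
                   "truncated cuboctahedron")
  expect_identical(target_orientations("32")$polyhedron,
                   "truncated octahedron")
})

test_that("published strategy-length and multiplicity table is reproduced", {
  tab <- native_strategy_table()
  printed <- list(
    list("1", "", 4, 936, 10), list("2", "", 4, 936, 20),
    list("3", "three-sweep", 3, 744, 24), list("3", "four-sweep", 4, 936, 30),
    list("222", "", 3, 744, 32), list("4", "", 3, 744, 32),
    list("32", "", 2, 552, 36), list("6", "", 2, 552, 36),
    list("422", "", 2, 552, 48), list("622", "", 2, 552, 72),
    list("23", "", 1, 360, 48), list("432", "", 1, 360, 96))
  expect_equal(nrow(tab), 12)
  for (row in printed) {
    m <- tab[tab$point_group == row[[1]] & tab$variant == row[[2]], ]
    expect_equal(nrow(m), 1, info = paste(row[[1]], row[[2]]))
    expect_equal(m$n_sweeps, row[[3]])
    expect_equal(m$length_deg, row[[4]])
    expect_equal(m$multiplicity, row[[5]])
  }
})

test_that("predicted multiplicity counts 192-degree sweeps as 180", {
  expect_equal(predicted_multiplicity(c(360), "432"), 96)
  expect_equal(predicted_multiplicity(c(360, 192, 192, 192), "1"), 10)
  expect_equal(predicted_multiplicity(c(360), "23"), 48)
  expect_equal(predicted_multiplicity(c(360, 192), "622"), 72)
})

test_that("accessible orientation fraction converges to 1 - cos(chi_max)", {
  set.seed(5)
  pct <- accessible_fraction(48, n = 1e5)
  expect_equal(attr(pct, "analytic"), 100 * (1 - cos(48 * pi / 180)))
  expect_lt(abs(as.numeric(pct) - attr(pct, "analytic")), 1)
  expect_equal(round(as.numeric(pct)), 33)
})

test_that("fitting preserves the target set as a rigid body", {
  g <- goniostat_model()
  set.seed(8)
  tg <- target_orientations("222")
  ref_angles <- as.numeric(dist_angles <- {
    a <- tg$axes
    c(acos(sum(a[1, ] * a[2, ])), acos(sum(a[1, ] * a[3, ])),
      acos(sum(a[2, ] * a[3, ])))
  })
  for (seed in c(101, 202, 303)) {
    cr <- generate_fixture("orthorhombic", seed = seed, point_group = "222",
                           target_resolution_A = 2)
    fitted <- suppressWarnings(fit_to_mounting(tg, cr, g))
    ax <- t(vapply(fitted, `[[`, numeric(3), "axis_crystal"))
    got <- c(acos(abs(sum(ax[1, ] * ax[2, ]))),
             acos(abs(sum(ax[1, ] * ax[3, ]))),
             acos(abs(sum(ax[2, ] * ax[3, ]))))
    if (all(vapply(fitted, `[[`, logical(1), "accessible"))) {
      # pairwise angles of the realized triplet equal the polyhedron's
      expect_equal(sort(got), sort(pmin(ref_angles, pi - ref_angles)),
                   tolerance = 1e-9)
    }
  }
})

test_that("inverse kinematics places the requested axis on the omega axis", {
  g <- goniostat_model()
  cr <- fix_crystal("monoclinic", 55, d = 2)
  tg <- target_orientations("2")
  fitted <- suppressWarnings(fit_to_mounting(tg, cr, g))
  for (f in fitted) {
    sw <- make_sweep(cr, setting = mxsweep:::.setting_matrix(cr, g,
                                                             f$kappa_deg,
                                                             f$phi_deg))
    realized <- as.vector(t(sw$setting) %*% c(1, 0, 0))
    expect_equal(abs(sum(realized * f$axis_crystal)), 1, tolerance = 1e-9)
    expect_lte(f$chi_deg, g$chi_max_mech_deg + 1e-6)
    expect_equal(chi_of_kappa(f$kappa_deg, g$kappa_axis_angle_deg),
                 min(f$chi_deg, 2 * g$kappa_axis_angle_deg),
                 tolerance = 1e-6)
  }
})

test_that("sweep lengths follow the 360-first / 192-later rule with batching", {
  g <- goniostat_model()
  cr <- fix_crystal("monoclinic", 21, d = 1.9)
  tt <- two_theta_of_resolution(1.9, 1)
  plan <- suppressWarnings(advanced_strategy(cr, g, tt))
  widths <- vapply(plan$sweeps, `[[`, numeric(1), "width_deg")
  chis <- vapply(plan$sweeps, `[[`, numeric(1), "chi_deg")
  expect_equal(widths[1], 360)
  expect_equal(chis, sort(chis))  # lowest chi acquired first
  expect_true(all(abs(widths / 4.8 - round(widths / 4.8)) < 1e-9))
  # high-chi sweeps cannot run a shadow-free full turn at this resolution
  expect_true(all(widths[chis > 90 - 19.84 - tt] == 192))
  expect_equal(plan$total_length_deg, sum(widths))
  # 622 advanced: two sweeps, 552 degrees
  cr6 <- fix_crystal("hexagonal", 22, pg = "622", d = 1.9)
  plan6 <- suppressWarnings(advanced_strategy(cr6, g, tt))
  expect_equal(plan6$total_length_deg, 552)
  expect_equal(plan6$predicted_multiplicity, 72)
})

test_that("basic strategies avoid symmetry axes and split P1 in two", {
  g <- goniostat_model()
  tt <- 30
  # P1 needs two sweeps
  cr1 <- fix_crystal("triclinic", 61, d = 2)
  p1 <- basic_strategy(cr1, g, tt)
  expect_length(p1$sweeps, 2)
  expect_equal(vapply(p1$sweeps, `[[`, numeric(1), "width_deg"),
               c(360, 360))
  # a monoclinic crystal with the twofold far from the mount: single sweep
  # at chi = 0, no recentring
  for (seed in 71:75) {
    cr <- generate_fixture("monoclinic", seed = seed,
                           target_resolution_A = 2)
    p <- as.vector(t(cr$orientation) %*% c(1, 0, 0))
    two_fold_angle <- acos(abs(p[2])) * 180 / pi
    if (two_fold_angle > tt / 2 + 2) {
      pb <- basic_strategy(cr, g, tt)
      expect_length(pb$sweeps, 1)
      expect_equal(pb$sweeps[[1]]$chi_deg, 0, tolerance = 1e-9)
      expect_equal(pb$recentrings, 0)
      break
    }
  }
})

test_that("basic strategy reorientation restores full completeness", {
  g <- goniostat_model()
  # mount a tetragonal crystal with its 4-fold exactly along the phi axis
  U <- mxsweep:::rotation_between(c(0, 0, 1), c(1, 0, 0))
  cr <- crystal_sample(c(40, 40, 32, 90, 90, 90), "4", orientation = U,
                       target_resolution_A = 3.8)
  tt <- two_theta_of_resolution(3.8, 1)
  pb <- basic_strategy(cr, g, tt)
  expect_gte(pb$sweeps[[1]]$chi_deg, tt / 2)
  sim <- simulate_sweeps(cr, pb$sweeps, d_min = 3.8)
  ms <- merge_stats(sim, "4")
  expect_equal(ms$summary$completeness, 100)
  # without reorientation the axis-aligned sweep leaves a hole
  sim0 <- simulate_sweeps(cr, make_sweep(cr), d_min = 3.8)
  expect_lt(merge_stats(sim0, "4")$summary$completeness, 100)
})

test_that("chi-0-first variant trades a recentring", {
  g <- goniostat_model()
  cr <- fix_crystal("tetragonal", 81, pg = "4", d = 1.9)
  tt <- two_theta_of_resolution(1.9, 1)
  p0 <- suppressWarnings(advanced_strategy(cr, g, tt,
                                           first_sweep_chi0 = TRUE))
  chis <- vapply(p0$sweeps, `[[`, numeric(1), "chi_deg")
  expect_equal(min(chis), 0, tolerance = 1e-9)
})
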
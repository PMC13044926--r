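test_that("crossing angles agree with a brute-force Ewald-offset scan", {
  cr <- fix_crystal("triclinic", 42, d = 3)
  sw <- make_sweep(cr, axis_crystal = c(0.3, 0.5, 1))
  M <- sw$setting %*% cr$B
  set.seed(1)
  refl <- mxsweep:::reflection_list(cr$B, 3)
  idx <- sample(nrow(refl$hkl), 25)
  oms <- seq(0, 360, by = 0.01)
  for (i in idx) {
    h <- as.numeric(refl$hkl[i, ])
    r0 <- as.vector(M %*% h)
    offset <- (r0[2] * sin(oms * pi / 180) + r0[3] * cos(oms * pi / 180)) +
      sum(r0^2) / 2
    brute <- oms[which(diff(sign(offset)) != 0)]
    got <- ewald_crossings(h, cr, sw)
    expect_length(got, length(brute))
    if (length(got) > 0)
      expect_lt(max(abs(sort(brute) - sort(got))), 0.02)
  }
})

test_that("equatorial reflections cross twice; cusp reflections never", {
  cr <- crystal_sample(c(30, 30, 30, 90, 90, 90), "1",
                       target_resolution_A = 2.5)
  sw <- make_sweep(cr, axis_crystal = c(0, 0, 1))
  # (h, k, 0) lies in the equatorial plane when rotating about c
  w <- ewald_crossings(c(3, 2, 0), cr, sw)
  expect_length(w, 2)
  # (0, 0, l): along the rotation axis, X = 0, blind
  expect_length(ewald_crossings(c(0, 0, 4), cr, sw), 0)
})

test_that("blindness test is exactly the absence of crossings", {
  cr <- fix_crystal("triclinic", 13, d = 2.5)
  sw <- make_sweep(cr)
  sim <- simulate_sweeps(cr, sw, d_min = 2.5)
  H <- as.matrix(sim$hkl[, c("h", "k", "l")])
  r0 <- t(sw$setting %*% (cr$B %*% t(H)))
  len <- sqrt(rowSums(r0^2))
  X <- acos(pmin(1, pmax(-1, r0[, 1] / len))) * 180 / pi
  flagged <- is_blind(len, 1, X)
  expect_identical(as.logical(sim$blind[, 1]), as.logical(flagged))
  crossed <- tabulate(sim$observations$hkl_index, nbins = nrow(H)) > 0
  # full 360-degree sweep: crossings happen iff not blind
  expect_identical(unname(crossed), unname(!flagged))
  # boundary convention: X = theta is not blind
  expect_false(is_blind(1, 1, 30))
  expect_true(is_blind(1, 1, 29.999))
})

test_that("Lorentz factor: closed form, limits and crossing-speed oracle", {
  expect_equal(lorentz_factor(2 * sin(15 * pi / 180), 1, 90), 2,
               tolerance = 1e-12)
  expect_error(lorentz_factor(1, 1, 10), "blind")
  # monotone increase toward the cusp
  d <- 0.8
  th <- asin(d / 2) * 180 / pi
  Xs <- seq(90, th + 0.5, by = -0.5)
  L <- lorentz_factor(d, 1, Xs)
  expect_true(all(diff(L) > 0))
  # numeric crossing-speed oracle on 1e4 random reflections
  set.seed(7)
  n <- 10000
  d_star <- runif(n, 0.1, 1.2)
  X <- runif(n, 0, 180)
  ok <- !is_blind(d_star, 1, X)
  d_star <- d_star[ok]; X <- X[ok]
  L <- lorentz_factor(d_star, 1, X)
  rho <- d_star * sin(X * pi / 180)
  cc <- -d_star^2 / 2
  speed <- rho * abs(cos(asin(pmax(-1, pmin(1, cc / rho)))))
  expect_lt(max(abs(1 / speed - L) / L), 0.001)
})

test_that("Friedel mates cross 180 degrees apart in P1", {
  cr <- fix_crystal("triclinic", 19, d = 3)
  sw <- make_sweep(cr)
  set.seed(3)
  refl <- mxsweep:::reflection_list(cr$B, 3)
  for (i in sample(nrow(refl$hkl), 10)) {
    h <- as.numeric(refl$hkl[i, ])
    w1 <- ewald_crossings(h, cr, sw)
    w2 <- ewald_crossings(-h, cr, sw)
    if (length(w1) == 2) {
      expect_equal(sort((w1 + 180) %% 360), sort(w2), tolerance = 1e-8)
    }
  }
})

test_that("detector hits classify gaps by footprint coverage", {
  det <- detector_library("pilatus6m")
  D <- 300
  # ray toward the centre of a module (first module centre)
  ux <- (det$module_px[1] / 2) * det$pixel_mm - det$width_mm / 2
  uy <- (det$module_px[2] / 2) * det$pixel_mm - det$height_mm / 2
  ray <- c(ux, uy, D) / sqrt(ux^2 + uy^2 + D^2)
  hit <- detector_hit(ray, det, D)
  expect_true(hit$on_detector)
  expect_false(hit$in_gap)
  expect_equal(hit$active_fraction, 1)
  # ray toward the middle of a vertical gap (17 px wide > 3 px footprint)
  gy <- (det$module_px[2] + det$gap_px[2] / 2) * det$pixel_mm -
    det$height_mm / 2
  ray2 <- c(0, gy, D) / sqrt(gy^2 + D^2)
  hit2 <- detector_hit(ray2, det, D)
  expect_true(hit2$on_detector)
  expect_true(hit2$in_gap)
  expect_equal(hit2$active_fraction, 0)
  # ray missing the detector altogether
  hit3 <- detector_hit(c(0.9, 0, sqrt(1 - 0.81)), det, D)
  expect_false(hit3$on_detector)
})

test_that("multiplicity equals 2 x Laue order per full turn for all groups", {
  systems <- c("1" = "triclinic", "2" = "monoclinic", "222" = "orthorhombic",
                "4" = "tetragonal", "422" = "tetragonal", "3" = "trigonal",
                "32" = "trigonal", "6" = "hexagonal", "622" = "hexagonal",
                "23" = "cubic", "432" = "cubic")
  for (nm in names(systems)) {
    pg <- point_group(nm)
    cr <- fix_crystal(systems[[nm]], 100 + pg$order, pg = nm, d = 4,
                      range = c(30, 45))
    sim <- simulate_sweeps(cr, make_sweep(cr), d_min = 4)
    ms <- merge_stats(sim, nm)
    u <- ms$unique
    unaff <- !u$blind_affected
    expect_true(any(unaff))
    # every non-blind orbit member crosses exactly twice per full turn
    expect_true(all(u$multiplicity[unaff] == 2 * u$n_members[unaff]))
    # general-position orbits have the full Laue multiplicity
    full <- unaff & u$n_members == pg$laue_order
    expect_true(any(full))
    expect_true(all(u$multiplicity[full] == 2 * pg$laue_order))
  }
})

test_that("completeness is monotone in sweep length", {
  cr <- fix_crystal("triclinic", 23, d = 3)
  comp <- vapply(c(60, 120, 180, 300, 360), function(w) {
    sim <- simulate_sweeps(cr, make_sweep(cr, width_deg = w), d_min = 3)
    merge_stats(sim, "1")$summary$completeness
  }, numeric(1))
  expect_true(all(diff(comp) >= 0))
})

test_that("merging accumulates Lorentz enhancement per orbit", {
  cr <- fix_crystal("monoclinic", 29, d = 3.5)
  sim <- simulate_sweeps(cr, make_sweep(cr), d_min = 3.5)
  ms <- merge_stats(sim, "2")
  u <- ms$unique
  expect_equal(sum(u$multiplicity), ms$summary$n_observations)
  expect_equal(u$enhancement, u$multiplicity * u$lorentz_mean,
               tolerance = 1e-9)
  # L >= 1/sin(2 theta) >= 1, so orbit means are at least 1
  expect_true(all(u$lorentz_mean[u$multiplicity > 0] >= 1 - 1e-9))
  # equi-populated bins are balanced and medians non-decreasing
  expect_equal(nrow(ms$bins), 10)
  expect_lt(diff(range(ms$bins$n)), max(ms$bins$n) * 0.5)
  expect_true(all(diff(ms$bins$median_enhancement) >= 0))
  # empty input gives zeroed stats
  empty <- simulate_sweeps(cr, list(), d_min = 3.5)
  expect_equal(nrow(empty$observations), 0)
})

test_that("extending a P1 sweep past 180 raises anomalous completeness", {
  cr <- fix_crystal("triclinic", 31, d = 3.83)
  a180 <- merge_stats(simulate_sweeps(cr, make_sweep(cr, width_deg = 180),
                                      d_min = 3.83), "1")
  a195 <- merge_stats(simulate_sweeps(cr, make_sweep(cr, width_deg = 195),
                                      d_min = 3.83), "1")
  expect_gt(a195$summary$anomalous_completeness,
            a180$summary$anomalous_completeness)
  expect_gt(a195$summary$anomalous_completeness, 98)
})
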
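test_that("minimum anomalous sweep lengths follow the per-class rules", {
  expect_equal(min_anomalous_sweep("1", two_theta_max_deg = 15), 195)
  expect_equal(min_anomalous_sweep("4", "aligned", 15), 90)
  expect_equal(min_anomalous_sweep("2", "aligned", 15), 180)
  expect_equal(min_anomalous_sweep("6", "aligned", 15), 60)
  expect_equal(min_anomalous_sweep("3", "aligned", 15), 120)
  expect_equal(min_anomalous_sweep("2", "orthogonal", 15), 97.5)
  expect_equal(min_anomalous_sweep("2", "orthogonal", 15,
                                   dauter_monoclinic = TRUE), 195)
  expect_equal(min_anomalous_sweep("222", "aligned", 15), 90)
  expect_equal(min_anomalous_sweep("422", "aligned", 15), 45)
  expect_equal(min_anomalous_sweep("622", "orthogonal", 15), 90)
  expect_error(min_anomalous_sweep("222", "aligned", 15, axis_order = 3),
               "evenfold")
})

test_that("rule minima reach near-full anomalous completeness and shorter sweeps do not", {
  # P1: exactly complete outside the enlarged cusp at 180 + 2 theta_max,
  # incomplete 10 degrees short of it
  cr1 <- fix_crystal("triclinic", 31, d = 3.83)   # 2 theta_max = 15
  expect_gte(anom_completeness(cr1, "1", NULL, 195, 0, 7.5), 99.99)
  expect_lt(anom_completeness(cr1, "1", NULL, 185, 0, 7.5), 99)
  # 222 aligned on a twofold: 90 degrees at a symmetry-anchored start
  cr222 <- fix_crystal("orthorhombic", 43, pg = "222", d = 3.83)
  expect_gte(anom_best_start(cr222, "222", c(0, 0, 1), 90), 99)
  expect_lt(anom_best_start(cr222, "222", c(0, 0, 1), 80), 99)
  # monoclinic orthogonal to the twofold: 90 + theta_max (not Dauter's
  # 180 + 2 theta_max)
  cr2 <- fix_crystal("monoclinic", 45, d = 3.83)
  expect_gte(anom_best_start(cr2, "2", c(1, 0, 0), 97.5, 7.5), 99)
  expect_lt(anom_best_start(cr2, "2", c(1, 0, 0), 87.5, 7.5), 99)
})

test_that("single-axis aligned minima are sufficient (conservative) bounds", {
  cr4 <- fix_crystal("tetragonal", 41, pg = "4", d = 3.83)
  expect_gte(anom_completeness(cr4, "4", c(0, 0, 1), 90), 99.99)
  cr2 <- fix_crystal("monoclinic", 45, d = 3.83)
  expect_gte(anom_best_start(cr2, "2", c(0, 1, 0), 180,
                             starts = seq(0, 90, by = 15)), 99.99)
})

test_that("an aligned evenfold axis puts SAD mates at the same omega", {
  cr <- fix_crystal("tetragonal", 41, pg = "4", d = 3.83)
  sw <- make_sweep(cr, axis_crystal = c(0, 0, 1))
  set.seed(9)
  for (i in 1:10) {
    h <- c(sample(-5:5, 1), sample(-5:5, 1), sample(1:4, 1))
    w1 <- try(ewald_crossings(h, cr, sw), silent = TRUE)
    w2 <- try(ewald_crossings(c(h[1], h[2], -h[3]), cr, sw), silent = TRUE)
    if (!inherits(w1, "try-error") && length(w1) == 2) {
      expect_equal(sort(w1), sort(w2), tolerance = 1e-8)
    }
  }
})

test_that("cusp filling improves anomalous completeness of an aligned sweep", {
  g <- goniostat_model()
  cr <- fix_crystal("monoclinic", 45, d = 3.83)
  tt <- 15
  # aligned main sweep (cusp on the twofold axis is uncompensated)
  axis_b <- c(0, 1, 0)
  ik_main <- mxsweep:::.inverse_kinematics(axis_b, cr, g)
  main <- make_sweep(cr, axis_crystal = axis_b, width_deg = 180)
  fills <- cusp_fill(ik_main$axis_crystal, cr, g, tt, mode = "pair")
  expect_length(fills, 2)
  expect_equal(vapply(fills, `[[`, numeric(1), "width_deg"), c(15, 15))
  starts <- vapply(fills, `[[`, numeric(1), "omega_start_deg")
  expect_equal((starts[2] - starts[1]) %% 360, 180)
  basicf <- cusp_fill(ik_main$axis_crystal, cr, g, tt, mode = "basic")
  expect_equal(basicf[[1]]$width_deg, 195)
  extf <- cusp_fill(ik_main$axis_crystal, cr, g, tt, mode = "extended")
  expect_equal(extf[[1]]$width_deg, 210)
  # simulator check: the fills measure reflections lost in the aligned
  # sweep's cusp, so the measured anomalous set strictly grows
  s_main <- merge_stats(simulate_sweeps(cr, main, d_min = 3.83), "2",
                        friedel = FALSE)
  s_fill <- merge_stats(simulate_sweeps(cr, c(list(main), fills),
                                        d_min = 3.83), "2", friedel = FALSE)
  expect_gt(sum(s_fill$unique$multiplicity > 0),
            sum(s_main$unique$multiplicity > 0))
  expect_gte(s_fill$summary$anomalous_completeness,
             s_main$summary$anomalous_completeness)
})

test_that("interleaving partitions the sweep with 180-degree offsets", {
  sched <- interleave_schedule(0, 180, 10)
  expect_equal(nrow(sched), 36)
  expect_setequal(unique(sched$offset_deg), c(0, 180))
  # exact partition of [0, 360): every 10-degree bin covered exactly once
  bins <- sort(sched$omega_start_deg)
  expect_equal(bins, seq(0, 350, by = 10))
  # wedge = width gives two segments
  expect_equal(nrow(interleave_schedule(0, 180, 180)), 2)
  # wavelength interleaving doubles the segment count
  mad <- interleave_schedule(0, 180, 10, wavelengths = c("peak",
                                                         "inflection"))
  expect_equal(nrow(mad), 72)
  expect_equal(sum(mad$wavelength == "peak"), 36)
  expect_error(interleave_schedule(0, 180, 7), "divide")
})

test_that("split sweeps preserve the union and honour constraints", {
  s <- split_sweep_for_completeness(10, 180)
  expect_equal(nrow(s), 2)
  expect_equal(sum(s$width_deg), 180)
  expect_equal(s$omega_start_deg, c(10, 100))
  s2 <- split_sweep_for_completeness(0, 180, omega_constraints = c(120))
  expect_equal(sort(s2$omega_start_deg), c(0, 120))
  expect_equal(sum(s2$width_deg), 180)
  expect_warning(split_sweep_for_completeness(0, 90,
                                              omega_constraints = 270),
                 "unsplit")
})

test_that("phasing plans assemble aligned sweeps and schedules", {
  g <- goniostat_model()
  cr <- fix_crystal("tetragonal", 41, pg = "4", d = 3.83)
  pp <- phasing_plan(cr, g, 15, alignment = "aligned", fill = "pair",
                     wedge_deg = 10)
  expect_equal(pp$min_length_deg, 90)
  expect_length(pp$sweeps, 3)
  expect_equal(nrow(pp$interleave), 18)  # 9 wedges x 2 offsets
  cr1 <- fix_crystal("triclinic", 31, d = 3.83)
  expect_error(phasing_plan(cr1, g, 15, alignment = "aligned"), "evenfold")
  pu <- phasing_plan(cr1, g, 15, alignment = "unaligned")
  expect_equal(pu$min_length_deg, 195)
})
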
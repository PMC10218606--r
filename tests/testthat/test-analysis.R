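test_that("time courses round-trip through the CSV dialect with metadata", {
  tc <- simulate_scenario("IIb-GSH-pH8")
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_timecourse(tc, f)
  back <- load_timecourse(f)
  expect_equal(nrow(back), 12)  # t = 0 plus the 11 sampling timepoints
  expect_equal(back$time_min, tc$time_min)
  expect_equal(back$E_area, tc$E_area, tolerance = 1e-7)
  m <- tc_meta(back)
  expect_equal(m$scenario, "IIb-GSH-pH8")
  expect_equal(m$pH_aqueous, 8.0)
  expect_equal(m$pH_virtual, 7.4)
  expect_true(is.numeric(m$area0_E))
})

test_that("schema violations are reported and shuffled rows are re-sorted", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))

  writeLines(character(0), f)
  expect_error(load_timecourse(f), "empty")

  writeLines(c("time_min,E_area", "1,2"), f)
  expect_error(load_timecourse(f), "missing column")

  writeLines(c("time_min,E_area,Z_area,adduct1_area,adduct2_area",
               "15,100,0,-1,0"), f)
  expect_error(load_timecourse(f), "negative area.*adduct1", ignore.case = TRUE)

  writeLines(c("time_min,E_area,Z_area,adduct1_area,adduct2_area",
               "45,90,0,1,2", "15,100,0,0,1"), f)
  expect_warning(tc <- load_timecourse(f), "re-sorted")
  expect_equal(tc$time_min, c(15, 45))

  expect_error(load_timecourse(tempfile()), "not found")
})

test_that("conversion arithmetic reproduces the printed ratio/percent pairs", {
  tc <- make_tc(c(15, 315), E = c(80, 57))
  cv <- conversion(tc, "E", 315, area0 = 100)
  expect_equal(cv$ratio_Aend_A0, 0.57)
  expect_equal(cv$percent_reduction, 43)
  # identity holds exactly, unrounded
  expect_identical(cv$percent_reduction + 100 * cv$ratio_Aend_A0, 100)

  # printed ratio 0.76 corresponds to a 24.0% reduction at table rounding,
  # consistent with the unrounded 23.7% reported in the text
  cv2 <- conversion(make_tc(c(15, 315), E = c(90, 76)), "E", 315, area0 = 100)
  expect_equal(round_half_up(cv2$percent_reduction, 1), 24.0)
  expect_lt(abs(cv2$percent_reduction - 23.7), 0.5)

  # no conversion
  cv3 <- conversion(make_tc(c(15, 315), E = c(100, 100)), "E", 315,
                    area0 = 100)
  expect_equal(cv3$ratio_Aend_A0, 1)
  expect_equal(cv3$percent_reduction, 0)

  expect_error(conversion(tc, "E", 315, area0 = 0), "non-zero")
  expect_error(conversion(tc, "E", 100, area0 = 10), "grid")
})

test_that("diastereomer ratios match printed values and are scale-invariant", {
  # NAC incubation endpoint: areas 60.0 and 513.9
  tc <- make_tc(315, E = 100, a1 = 60.0, a2 = 513.9)
  expect_equal(round_half_up(diastereomer_ratio(tc), 2), 8.57)
  expect_equal(round_half_up(diastereomer_ratio(tc), 1), 8.6)
  # GSH endpoints stay close to unity
  expect_equal(round_half_up(
    diastereomer_ratio(make_tc(315, 100, a1 = 2847.0, a2 = 3216.3)), 2), 1.13)
  expect_equal(round_half_up(
    diastereomer_ratio(make_tc(315, 100, a1 = 2584.9, a2 = 2785.0)), 2), 1.08)
  expect_equal(diastereomer_ratio(make_tc(315, 100, a1 = 5, a2 = 5)), 1)

  # invariance under common rescaling
  set.seed(3)
  for (s in runif(20, 0.01, 100)) {
    expect_equal(diastereomer_ratio(make_tc(315, 1, a1 = 60 * s,
                                            a2 = 513.9 * s)),
                 513.9 / 60)
  }

  # zero adduct-1 area is flagged undefined, not an error
  expect_true(is.na(diastereomer_ratio(make_tc(315, 100, a1 = 0, a2 = 5))))
})

test_that("log-linear fits recover exact and simulated rate constants", {
  tgrid <- c(15, seq(45, 315, by = 30))
  k <- 0.005
  tc <- make_tc(tgrid, E = 1000 * exp(-k * tgrid),
                meta = list(area0_E = 1000))
  fit <- pseudo_first_order_fit(tc)
  expect_equal(fit$k_obs, k, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$half_life, log(2) / k, tolerance = 1e-8)

  # constant series: zero rate
  flat <- pseudo_first_order_fit(make_tc(tgrid, E = 500,
                                         meta = list(area0_E = 500)))
  expect_equal(flat$k_obs, 0, tolerance = 1e-12)

  # non-positive areas are excluded with a warning; too few points error
  tc2 <- make_tc(c(15, 45, 75), E = c(100, 0, 0),
                 meta = list(area0_E = 120))
  expect_error(suppressWarnings(pseudo_first_order_fit(tc2)), "fewer than 3")

  # irreversible noiseless simulation: fit recovers k_eff * thiol0 closely
  cond <- study_conditions()
  p <- kinetic_params(k_add1 = 0.004, k_add2 = 0.00271, neutral_scale = 1)
  tc3 <- simulate_incubation(cond, p, observation_model(noise_sd = 0),
                             gsh())
  attr(tc3, "meta")$area0_E <- 1e5 * cond$chalcone0
  k_true <- sum(effective_addition_rate(p, gsh(), cond$pH_virtual)) *
    cond$thiol0
  expect_equal(pseudo_first_order_fit(tc3)$k_obs, k_true, tolerance = 0.005)

  # nonlinear refit agrees with the log-linear estimate on clean decay
  nl <- exponential_fit(tc, area0 = 1000)
  expect_equal(nl$k_obs, k, tolerance = 1e-6)
})

test_that("plateau detection separates equilibrated from still-declining series", {
  tgrid <- c(15, seq(45, 315, by = 30))
  declining <- make_tc(tgrid, E = 1000 - 2 * tgrid)
  expect_false(plateau_test(declining))
  flat_tail <- make_tc(tgrid, E = c(800, 700, 600, 550, 520, 505, 501,
                                    500, 500, 500, 500))
  expect_true(plateau_test(flat_tail))

  # monotone in tol: plateau at tol implies plateau at any larger tol
  for (tol in c(0.001, 0.01, 0.05, 0.2, 1)) {
    if (plateau_test(flat_tail, tol = tol)) {
      expect_true(plateau_test(flat_tail, tol = tol * 2))
    }
    if (!plateau_test(declining, tol = tol * 2)) {
      expect_false(plateau_test(declining, tol = tol))
    }
  }

  # simulated presets: NAC reaches equilibrium within 315 min, GSH does not
  expect_true(plateau_test(simulate_scenario("IIb-NAC-pH8", noise_sd = 0)))
  expect_false(plateau_test(simulate_scenario("IIb-GSH-pH8", noise_sd = 0)))

  expect_error(plateau_test(declining, window = 2), "window")
  expect_error(plateau_test(declining, window = 50), "exceeds")
})

test_that("summary tables mirror the endpoint layout with ND semantics", {
  tcs <- lapply(c("IIb-GSH-pH8", "IIc-GSH-pH8", "IIb-NAC-pH8",
                  "IIc-NAC-pH8"), simulate_scenario)
  st <- summary_table(tcs)
  expect_equal(nrow(st), 4)
  expect_named(st, c("scenario", "compound", "thiol", "pH_aqueous",
                     "ratio_end_0", "area_Z", "area_adduct1",
                     "area_adduct2", "ratio_2_1"))
  expect_true(all(!is.na(st$ratio_end_0)))
  expect_true(all(!is.na(st$ratio_2_1)))

  # adducts below the detection floor become ND (NA) and the ratio undefined
  st2 <- summary_table(simulate_scenario("IIc-GSH-pH3.2"))
  expect_true(is.na(st2$area_adduct1))
  expect_true(is.na(st2$ratio_2_1))

  # row ordering is stable across runs
  st3 <- summary_table(lapply(c("IIb-GSH-pH8", "IIc-GSH-pH8",
                                "IIb-NAC-pH8", "IIc-NAC-pH8"),
                              simulate_scenario))
  expect_identical(st$scenario, st3$scenario)
  expect_identical(st, st3)

  # ND markers survive the CSV writer
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_summary(st2, f)
  expect_true(any(grepl("ND", readLines(f))))
})
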
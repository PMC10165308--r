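test_that("dispense plan implements the 110%/105% protocol", {
  stock <- stock_calibration(2.00, rel_u = 0.03, ref_time_h = 0)
  rec <- plan_dispense(target_conc = 0.50, compartment_volume = 100,
                       stock = stock, scan_time_h = 0)
  expect_equal(rec$required_activity_scan_MBq, 50)
  expect_equal(rec$draw_activity_MBq, 55)
  expect_equal(rec$stock_draw_volume_mL, 27.5)
  expect_equal(rec$predilution_volume_mL, 105)
  # topping up to the exact-concentration volume = 110% of the compartment
  expect_equal(rec$final_solution_volume_mL, 110)
})

test_that("decay correction doubles the required draw after one half-life", {
  hl <- lu177_half_life_h()
  stock <- stock_calibration(2.00, ref_time_h = 0)
  r0 <- plan_dispense(0.50, 100, stock, scan_time_h = 0, half_life_h = hl)
  r1 <- plan_dispense(0.50, 100, stock, scan_time_h = hl, half_life_h = hl)
  expect_equal(r1$required_activity_dispense_MBq,
               2 * r0$required_activity_dispense_MBq)
})

test_that("insufficient stock concentration is a feasibility error", {
  stock <- stock_calibration(0.01)
  expect_error(plan_dispense(0.50, 100, stock, scan_time_h = 0),
               "insufficient")
})

test_that("gravimetric volume propagates rectangular reading uncertainty", {
  v <- gravimetric_volume(10.00, 110.00, density_g_per_mL = 1.000,
                          readability_g = 0.01)
  expect_equal(v$value, 100.00)
  expect_equal(v$u, sqrt(2) * (0.01 / sqrt(12)), tolerance = 1e-12)
  expect_equal(v$u, 0.004082, tolerance = 1e-3)
  # equal weights give zero volume
  expect_equal(gravimetric_volume(50, 50, 1, 0.01)$value, 0)
  # a 0.05 g balance scales the uncertainty five-fold
  v5 <- gravimetric_volume(10, 110, 1, readability_g = 0.05)
  expect_equal(v5$u / v$u, 5)
  expect_error(gravimetric_volume(110, 10, 1, 0.01), "measurement error")
})

test_that("fill fraction flags overfill and inverts reference entries", {
  ff <- fill_fraction(uvalue(8151.8, 2.5, "mL"), 8297)
  expect_equal(round(ff$value, 2), 98.25)
  expect_false(attr(ff, "overfill"))
  ff100 <- fill_fraction(100, 100)
  expect_equal(ff100$value, 100)
  expect_false(attr(ff100, "overfill"))
  over <- fill_fraction(1307.75, 1306.7)  # 100.08%
  expect_equal(round(over$value, 2), 100.08)
  expect_true(attr(over, "overfill"))
  expect_error(fill_fraction(10, 0), "positive")
})

test_that("achieved concentration carries quadrature uncertainty and decay", {
  hl <- lu177_half_life_h()
  stock <- stock_calibration(2.00, rel_u = 0.03)
  rec <- plan_dispense(1.00, 100, stock, scan_time_h = 0, half_life_h = hl)
  rec <- record_weights(rec, 10.00, 110.00, readability_g = 0)
  c0 <- achieved_concentration(rec)
  expect_equal(c0$value, 1.00, tolerance = 1e-12)
  expect_equal(c0$u / c0$value, 0.03, tolerance = 1e-9)
  # one half-life later: halved value, unchanged relative uncertainty
  c1 <- achieved_concentration(rec, at_time_h = hl)
  expect_equal(c1$value, c0$value / 2, tolerance = 1e-12)
  expect_equal(c1$u / c1$value, c0$u / c0$value, tolerance = 1e-12)
  # missing weights
  rec2 <- plan_dispense(1.00, 100, stock, scan_time_h = 0)
  expect_error(achieved_concentration(rec2), "incomplete record")
})

test_that("exact simulated weighing closes the loop on the target", {
  hl <- lu177_half_life_h()
  stock <- stock_calibration(37.5, rel_u = 0.03, ref_time_h = 0)
  for (tc in c(0.12, 1.0, 4.31)) {
    for (scan_t in c(0, 24, 144)) {
      rec <- plan_dispense(tc, 124.9, stock, scan_time_h = scan_t,
                           half_life_h = hl)
      rec <- record_weights(rec, 20, 20 + 124.9, readability_g = 0)
      got <- achieved_concentration(rec)$value
      expect_equal(got, tc, tolerance = 1e-10)
    }
  }
})

test_that("uncertainty propagation is first-order linear", {
  stock1 <- stock_calibration(2.00, rel_u = 0.02)
  stock2 <- stock_calibration(2.00, rel_u = 0.04)
  mk <- function(stock, readability) {
    rec <- plan_dispense(1.00, 100, stock, scan_time_h = 0)
    record_weights(rec, 0, 100, readability_g = readability)
  }
  # doubling every input u doubles the output u
  u1 <- achieved_concentration(mk(stock1, 0.01))$u
  u2 <- achieved_concentration(mk(stock2, 0.02))$u
  expect_equal(u2 / u1, 2, tolerance = 1e-9)
  g1 <- gravimetric_volume(0, 100, 1, 0.01)$u
  g2 <- gravimetric_volume(0, 100, 1, 0.02)$u
  expect_equal(g2 / g1, 2, tolerance = 1e-12)
})

test_that("timepoint-level planning covers all compartments", {
  sch <- default_schedule()
  ct <- concentrations_at(sch, times = 24)
  vols <- c(build_model()$volumes_mL, background = 8297)
  stock <- stock_calibration(1000, ref_time_h = 0)
  recs <- plan_timepoint(ct, vols, stock)
  expect_setequal(names(recs), ct$compartment)
  expect_error(plan_timepoint(ct, vols[-1], stock), "liver")
})
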
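test_that("model construction validates rates and compartments", {
  m <- build_model()
  expect_equal(m$A0_MBq, 7400)
  expect_equal(sort(m$compartments),
               sort(c("central", "kidneys", "liver", "spleen", "tumour",
                      "excreted")))
  # columns of K sum to zero: biological mass balance by construction
  expect_equal(max(abs(colSums(m$K))), 0)
  expect_error(build_model(list(rates = data.frame(
    from = "central", to = "bone", rate = 0.1))), "bone")
  expect_error(build_model(list(rates = data.frame(
    from = "central", to = "liver", rate = -0.1))), "non-negative")
  # all-zero rates: a valid static model
  m0 <- build_model(list(rates = data.frame(from = "central", to = "liver",
                                            rate = 0)))
  s0 <- solve_rk4(m0, t_end = 10, dt = 0.1)
  expect_true(all(s0$A_MBq[, "central"] == 7400))
})

test_that("RK4 reproduces the closed-form exponential to near machine precision", {
  s <- solve_rk4(washout_model(0.1), t_end = 10, dt = 1 / 60)
  a10 <- unname(s$A_MBq[nrow(s$A_MBq), "central"])
  expect_equal(a10, exp(-1), tolerance = 1e-8)
})

test_that("RK4 error shrinks fourth-order when the step is halved", {
  err <- vapply(c(0.5, 0.25), function(dt) {
    s <- solve_rk4(washout_model(0.1), t_end = 10, dt = dt)
    max(abs(s$A_MBq[, "central"] - exp(-0.1 * s$time_h)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 10)
  expect_lt(err[1] / err[2], 30)
})

test_that("biological and physical mass balance hold at every step", {
  sch <- default_schedule()
  total <- rowSums(sch$A_MBq)
  expect_lt(max(abs(total - sch$A0_MBq)) / sch$A0_MBq, 1e-9)
  # physical series: same sum decays with the physical half-life
  idx <- seq(1, length(sch$time_h), by = 600)  # every 10 h
  t <- sch$time_h[idx]
  phys_total <- total[idx] * exp(-sch$lambda_phys * t)
  expect_equal(phys_total, sch$A0_MBq * 2^(-t / sch$half_life_h),
               tolerance = 1e-9)
})

test_that("solver rejects inconsistent step sizes", {
  expect_error(solve_rk4(washout_model(0.1), t_end = 1, dt = 2), "exceed")
  expect_error(solve_rk4(washout_model(0.1), t_end = -1), "positive")
})

test_that("concentrations honour the medulla third and shared cortex", {
  sch <- default_schedule()
  ct <- concentrations_at(sch)
  expect_equal(sort(unique(ct$time_h)), c(1, 4, 24, 40, 72, 144))
  w <- split(ct$conc_MBq_per_mL, ct$compartment)
  expect_equal(w[["medulla-L"]] / w[["cortex-L"]], rep(1 / 3, 6))
  expect_equal(w[["medulla-R"]] / w[["cortex-R"]], rep(1 / 3, 6))
  expect_identical(w[["cortex-L"]], w[["cortex-R"]])
  expect_true(all(ct$conc_MBq_per_mL >= 0))
  expect_error(concentrations_at(sch, times = 1e6), "outside")
})

test_that("physical flag applies exactly one half-life of decay", {
  sch <- default_schedule()
  hl <- sch$half_life_h
  bio <- concentrations_at(sch, times = hl, physical = FALSE)
  phys <- concentrations_at(sch, times = hl, physical = TRUE)
  expect_equal(bio$conc_MBq_per_mL / phys$conc_MBq_per_mL,
               rep(2, nrow(bio)), tolerance = 1e-12)
})

test_that("grid-point queries return stored values exactly", {
  sch <- default_schedule()
  probe <- sch$time_h[c(1, 61, 1441)]
  got <- concentrations_at(sch, times = probe)
  liver <- got$conc_MBq_per_mL[got$compartment == "liver"]
  expect_identical(liver, sch$A_MBq[c(1, 61, 1441), "liver"] / 1306.7)
})

test_that("decay factors invert exactly", {
  expect_identical(decay_factor(0, 100), 1)
  expect_identical(decay_apply(1, 100, 100), 0.5)
  set.seed(7)
  x <- stats::runif(20, 0.1, 1000)
  dt <- stats::runif(20, -300, 300)
  expect_equal(decay_correct(decay_apply(x, dt, 159.4632), dt, 159.4632), x,
               tolerance = 1e-12)
  expect_error(decay_factor(1, -3), "positive")
})

test_that("time-integrated activity matches the mono-exponential closed form", {
  s <- solve_rk4(washout_model(0.05, A0 = 100), t_end = 200, dt = 1 / 60)
  tia <- time_integrated_activity(s, "central")
  expect_equal(tia, 100 / 0.05, tolerance = 1e-3)
  # truncated integral is smaller than integral-with-tail
  expect_lt(time_integrated_activity(s, "central", tail = FALSE), tia)
  # a compartment that never receives activity integrates to zero
  expect_equal(time_integrated_activity(s, "excreted", tail = FALSE) >= 0, TRUE)
  m0 <- build_model(list(rates = data.frame(from = "central", to = "liver",
                                            rate = 0)))
  s0 <- solve_rk4(m0, t_end = 10, dt = 0.1)
  expect_equal(time_integrated_activity(s0, "liver"), 0)
})

test_that("late-phase fit recovers the configured washout rate", {
  # central drains fast; the liver then washes out at its configured rate
  m <- build_model(list(
    compartments = c("central", "liver", "excreted"),
    rates = data.frame(from = c("central", "liver"),
                       to = c("liver", "excreted"),
                       rate = c(0.5, 0.03))))
  s <- solve_rk4(m, t_end = 300, dt = 1 / 60)
  t <- s$time_h
  win <- t >= 270
  fit <- stats::lm.fit(cbind(1, t[win]), log(s$A_MBq[win, "liver"]))
  expect_equal(unname(-fit$coefficients[2]), 0.03, tolerance = 0.01)
})

test_that("schedule CSV export carries both decay conventions", {
  sch <- default_schedule()
  path <- tempfile(fileext = ".csv")
  out <- write_schedule_csv(sch, path)
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 6 * 8)
  ratio <- back$conc_decay_corrected_MBq_per_mL / back$conc_physical_MBq_per_mL
  expect_equal(ratio, 2^(back$time_h / sch$half_life_h), tolerance = 1e-9)
})
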
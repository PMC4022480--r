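test_that("PI update implements the rectangular-sum control law", {
  # pure proportional
  r <- pi_step(pi_config(Kp = 1, Ki = 0), pi_init(), 0.3)
  expect_equal(r$level, 0.3)
  # pure integral, two steps of e = 0.1 at Ts = 5
  cfg <- pi_config(Kp = 0, Ki = 1, Ts = 5, u_min = -10, u_max = 10)
  st <- pi_init()
  r1 <- pi_step(cfg, st, 0.1)
  r2 <- pi_step(cfg, r1$state, 0.1)
  expect_equal(r2$level, 1.0)                 # 1 * (0.1 + 0.1) * 5
  # saturation clamps and anti-windup freezes the integral
  cfg2 <- pi_config(Kp = 1, Ki = 1, Ts = 5)
  r3 <- pi_step(cfg2, pi_init(), 1e6)
  expect_equal(r3$level, 1.0)
  expect_equal(r3$state$integral, 0)
  expect_error(pi_step(cfg2, pi_init(), NaN), "finite")
})

test_that("PI is linear when unsaturated", {
  cfg <- pi_config(Kp = 0.7, Ki = 0.05, Ts = 5, u_min = -1e9, u_max = 1e9)
  set.seed(3)
  e1 <- rnorm(20); e2 <- rnorm(20)
  run <- function(e) {
    st <- pi_init()
    vapply(e, function(ei) {
      r <- pi_step(cfg, st, ei); st <<- r$state; r$level
    }, numeric(1))
  }
  expect_equal(run(e1 + e2), run(e1) + run(e2), tolerance = 1e-12)
})

test_that("PWM duty equals the clamped normalized level to within one quantum", {
  cfg <- pwm_config(T_pwm = 10, quantum = 0.5)
  set.seed(17)
  for (level in c(-0.3, 0, 0.25, 0.5, 1, 1.7, runif(50))) {
    sig <- pwm_encode(level, cfg, window_start = 0, window_len = 20)
    tq <- 0.5 * (0:39)
    u <- level_at(sig, tq)
    for (per in 0:1) {
      duty <- mean(u[tq >= 10 * per & tq < 10 * (per + 1)])
      expect_lt(abs(duty - min(max(level, 0), 1)), 0.5 / 10 + 1e-12)
    }
  }
})

test_that("PWM comparator matches brute-force fine sampling of the sawtooth", {
  cfg <- pwm_config(T_pwm = 10, quantum = 0.5)
  for (level in c(0.2, 0.37, 0.81)) {
    sig <- pwm_encode(level, cfg, window_start = 30, window_len = 10)
    # realized level at each quantum equals the comparator at the quantum start
    tfine <- 30 + seq(0, 10 - 0.005, by = 0.005)
    comp <- as.numeric(level >= pwm_sawtooth(cfg, tfine))
    tq <- 30 + 0.5 * (0:19)
    expect_equal(level_at(sig, tq),
                 comp[match(round(tq, 3), round(tfine, 3))])
    # and the high time per period agrees with the comparator to one quantum
    expect_lt(abs(mean(level_at(sig, tfine)) - mean(comp)), 0.5 / 10 + 1e-9)
  }
  # saturated levels give constant windows; high at period start (rising ramp)
  expect_equal(level_at(pwm_encode(2, cfg, 0, 10), c(0, 5, 9.5)), c(1, 1, 1))
  expect_equal(level_at(pwm_encode(-1, cfg, 0, 10), c(0.5, 5, 9.5)), c(0, 0, 0))
  expect_equal(level_at(pwm_encode(0.5, cfg, 0, 10), c(0, 4.9, 5.5)), c(1, 1, 0))
})

test_that("low-pass filter matches its exponential closed form", {
  fst <- lowpass_init(20, y0 = 5)
  expect_equal(lowpass_step(fst, 5, 1)$value, 5)          # constant stays
  # step response 0 -> 1
  fst <- lowpass_init(20, y0 = 0)
  dt <- 0.2
  tt <- seq(dt, 60, by = dt)
  y <- numeric(length(tt))
  for (i in seq_along(tt)) {
    r <- lowpass_step(fst, 1, dt); fst <- r$state; y[i] <- r$value
  }
  expect_lt(max(abs(y - (1 - exp(-tt / 20)))), 0.01)
  # high-frequency square wave is strongly attenuated
  fst <- lowpass_init(50, y0 = 0.5)
  yy <- numeric(4000)
  for (i in 1:4000) {
    r <- lowpass_step(fst, as.numeric(i %% 4 < 2), 0.5); fst <- r$state; yy[i] <- r$value
  }
  expect_lt(diff(range(yy[2000:4000])), 0.1 * 1)
  # T_f = 0 is pass-through
  expect_equal(lowpass_step(lowpass_init(0, 3), 42, 5)$value, 42)
})

test_that("PWM into the linear GAL1 model has the mean-value (low-pass) property", {
  gp <- gal1_params(vmax = 1, deg = 0.01)
  cfg <- pwm_config(T_pwm = 10, quantum = 0.5)
  for (level in c(0.33, 0.61)) {
    wins <- lapply(seq(0, 3990, 10), function(t0) pwm_encode(level, cfg, t0, 10))
    u <- concat_inputs(wins)
    duty <- mean(level_at(u, seq(0, 9.75, 0.25)))   # realized high fraction
    tr <- simulate_gal1(gp, u, 0, 4000, dt = 0.5, y0 = 0)
    late <- tr$states[tr$time >= 3000, 1]
    expect_lt(abs(mean(late) - duty * 100) / (duty * 100), 0.05)
  }
})

test_that("FOPDT identification recovers a synthetic first-order-plus-dead-time response", {
  tt <- seq(0, 400, 0.1)
  y <- ifelse(tt <= 10, 0, 2 * (1 - exp(-(tt - 10) / 50)))
  fit <- estimate_fopdt(tt, y, delta_u = 1)
  expect_lt(abs(fit$K - 2) / 2, 0.02)
  expect_lt(abs(fit$T - 50) / 50, 0.02)
  expect_lt(abs(fit$d - 10) / 10, 0.02)
  # no-delay response: dead time below the sampling step
  y0 <- 1.5 * (1 - exp(-tt / 30))
  fit0 <- estimate_fopdt(tt, y0, delta_u = 1)
  expect_lt(fit0$d, 0.1)
  # non-settling response rejected
  expect_error(estimate_fopdt(seq(0, 100, 0.1), seq(0, 100, 0.1)), "settled")
})

test_that("FOPDT fit of the IRMA step response reflects the transcriptional delay", {
  fit <- default_tuning()$fit
  expect_gt(fit$K, 0)
  expect_gt(fit$d, 50)     # dominated by the 100-min HO-promoter delay
  expect_gt(fit$T, 0)
})

test_that("Cohen-Coon rules match their hand-evaluated formulas", {
  est <- list(K = 1, T = 10, d = 1)
  cfg <- cohen_coon_gains(est)
  expect_equal(cfg$Kp, (1 / 1) * (10 / 1) * (0.9 + 1 / 120), tolerance = 1e-12)
  expect_equal(cfg$Ti, 1 * (30 + 3 * 0.1) / (9 + 20 * 0.1), tolerance = 1e-12)
  expect_equal(cfg$Ki, cfg$Kp / cfg$Ti, tolerance = 1e-12)
  # doubling the gain halves Kp, leaves Ti unchanged
  cfg2 <- cohen_coon_gains(list(K = 2, T = 10, d = 1))
  expect_equal(cfg2$Kp, cfg$Kp / 2)
  expect_equal(cfg2$Ti, cfg$Ti)
  # singular at zero dead time
  expect_error(cohen_coon_gains(list(K = 1, T = 10, d = 0)), "singular")
})

test_that("FOPDT + Cohen-Coon round trip is stable across plant scales", {
  for (par in list(c(K = 0.8, T = 120, d = 30), c(K = 3, T = 40, d = 80))) {
    tt <- seq(0, 12 * (par["T"] + par["d"]), 0.25)
    y <- ifelse(tt <= par["d"], 0,
                par["K"] * (1 - exp(-(tt - par["d"]) / par["T"])))
    fit <- estimate_fopdt(tt, y, delta_u = 1)
    expect_lt(abs(fit$K - par["K"]) / par["K"], 0.02)
    expect_lt(abs(fit$T - par["T"]) / par["T"], 0.02)
    expect_lt(abs(fit$d - par["d"]) / par["d"], 0.02)
  }
})
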
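test_that("vector field matches an independent transcription of the equations", {
  p <- default_irma()
  set.seed(42)
  for (i in 1:25) {
    s <- runif(5, 0, 3)
    sdel <- runif(5, 0, 3)
    u <- rbinom(1, 1, 0.5)
    expect_equal(irma_vector_field(s, sdel, u, p),
                 oracle_irma_field(s, sdel, u, p), tolerance = 1e-12)
  }
})

test_that("vector field limit cases behave", {
  p <- default_irma()
  z <- rep(0, 5)
  expect_equal(irma_vector_field(z, z, 0, p), p$basal)  # degradation vanishes at 0
  expect_true(all(irma_vector_field(z, z, 0, p) >= 0))
  ss1 <- irma_ss(1)$state
  expect_lt(max(abs(irma_vector_field(ss1, ss1, 1, p))), 1e-7)
  expect_error(irma_vector_field(c(-0.1, 1, 1, 1, 1), z + 1, 0, p), "negative")
  expect_error(irma_vector_field(z, z, 0.5, p), "u must be")
})

test_that("vectorized (matrix) field evaluation equals per-row evaluation", {
  p <- default_irma()
  set.seed(7)
  S <- matrix(runif(20, 0, 2), 4, 5)
  D <- matrix(runif(20, 0, 2), 4, 5)
  M <- matrix(exp(rnorm(20, 0, 0.3)), 4, 5)
  FV <- irma_vector_field(S, D, 1, p, vmul = M)
  for (i in 1:4) {
    pm <- p
    pm$basal <- p$basal * M[i, ]; pm$vmax <- p$vmax * M[i, ]
    # rebuild through the constructor so invariants still hold
    pi_ <- irma_params(pm$basal, pm$vmax, p$k, p$hill, p$deg, p$gamma, p$tau)
    expect_equal(FV[i, ], irma_vector_field(S[i, ], D[i, ], 1, pi_),
                 tolerance = 1e-12)
  }
})

test_that("undelayed integrator matches a fine-step Euler oracle", {
  p <- default_irma()
  p0 <- irma_params(p$basal, p$vmax, p$k, p$hill, p$deg, p$gamma, tau = 0)
  u <- binary_input(c(0, 120, 260), c(1, 0, 1))
  s0 <- irma_ss(0)$state
  tr <- simulate_irma(p0, u, 0, 400, dt = 0.5, history = s0)
  ref <- euler_irma(p0, u, 400, 0.005, s0)
  expect_rel_equal(tr$states[nrow(tr$states), ], ref, 1e-3)
})

test_that("delayed integrator agrees with deSolve::dede", {
  skip_if_not_installed("deSolve")
  p <- default_irma()
  s0 <- irma_ss(0)$state
  f <- function(t, y, parms) {
    ylag <- if (t > p$tau) deSolve::lagvalue(t - p$tau) else s0
    list(oracle_irma_field(pmax(y, 0), pmax(ylag, 0), 1, p))
  }
  ref <- deSolve::dede(y = s0, times = seq(0, 500, 5), func = f, parms = NULL)
  tr <- simulate_irma(p, constant_input(1), 0, 500, dt = 0.5, history = s0)
  ours <- tr$states[tr$time %in% seq(0, 500, 5), ]
  expect_rel_equal(ours, unname(ref[, -1]), 2e-3)
})

test_that("equilibrium is invariant under constant input", {
  p <- default_irma()
  for (u in 0:1) {
    ss <- irma_ss(u)$state
    tr <- simulate_irma(p, constant_input(u), 0, 500, dt = 0.5, history = ss)
    expect_lt(max(abs(t(tr$states) - ss)), 1e-6)
  }
})

test_that("steady states satisfy the fixed-point definition and hybrid ordering", {
  p <- default_irma()
  for (u in 0:1) {
    ss <- irma_ss(u)
    expect_lt(max(abs(irma_vector_field(ss$state, ss$state, u, p))), 1e-8)
    expect_true(all(ss$state >= 0))
  }
  # galactose switches the network on
  expect_gt(irma_ss(1)$state[["cbf1"]], irma_ss(0)$state[["cbf1"]])
  # long-horizon simulation converges to the computed steady state
  tr <- simulate_irma(p, constant_input(1), 0, 3000, dt = 0.5,
                      history = irma_ss(0)$state)
  expect_rel_equal(tr$states[nrow(tr$states), ], irma_ss(1)$state, 1e-4)
})

test_that("step response starts at the source steady state and is monotone after the delay", {
  p <- default_irma()
  tr <- step_response(p, 0, 1, horizon = 1200, dt = 0.5)
  expect_equal(unname(tr$states[1, "cbf1"]), unname(irma_ss(0)$state[["cbf1"]]),
               tolerance = 1e-8)
  cb <- tr$states[, "cbf1"]
  post <- cb[tr$time >= p$tau]
  expect_true(all(diff(post) > -1e-9))
  # constant input, constant trajectory
  tr0 <- step_response(p, 1, 1, horizon = 300, dt = 0.5)
  expect_lt(diff(range(tr0$states[, "cbf1"])), 1e-6)
})

test_that("changing tau shifts the onset of the step response by the same amount", {
  p <- default_irma()
  onset <- function(tau) {
    pt <- irma_params(p$basal, p$vmax, p$k, p$hill, p$deg, p$gamma, tau)
    tr <- step_response(pt, 0, 1, horizon = 600, dt = 0.5)
    cb <- tr$states[, "cbf1"]
    thr <- cb[1] + 0.05 * (max(cb) - cb[1])
    tr$time[which(cb >= thr)[1]]
  }
  expect_equal(onset(100) - onset(60), 40, tolerance = 0.5 + 1e-9)
})

test_that("trajectories stay non-negative under random switching inputs", {
  p <- default_irma()
  set.seed(99)
  for (i in 1:5) {
    ts <- sort(sample(seq(10, 590, 10), 8))
    u <- binary_input(c(0, ts), c(1, rbinom(8, 1, 0.5)))
    tr <- simulate_irma(p, u, 0, 600, dt = 0.5, history = irma_ss(0)$state)
    expect_true(all(tr$states >= 0))
    expect_equal(tr$input, level_at(u, tr$time))
  }
})

test_that("switch-off protocol: rise in galactose, delayed peak, decay to the glucose state", {
  p <- default_irma()
  u <- binary_input(c(0, 180), c(1, 0))
  tr <- simulate_irma(p, u, 0, 700, dt = 0.5, history = irma_ss(0)$state)
  cb <- tr$states[, "cbf1"]
  # rises throughout the galactose phase
  expect_true(all(diff(cb[tr$time <= 180]) > -1e-9))
  # the delayed HO promoter keeps Cbf1 rising for ~tau after the switch
  t_peak <- tr$time[which.max(cb)]
  expect_gt(t_peak, 180)
  expect_lt(t_peak, 180 + p$tau + 10)
  # monotone decay from the peak toward the glucose steady state
  post <- cb[tr$time >= t_peak]
  expect_true(all(diff(post) <= 1e-9))
  expect_lt(abs(cb[length(cb)] - irma_ss(0)$state[["cbf1"]]),
            0.05 * irma_ss(0)$state[["cbf1"]] + 0.01)
})

test_that("GAL1 model reproduces its closed forms", {
  gp <- gal1_params(vmax = 1, deg = 0.01)
  tr <- simulate_gal1(gp, constant_input(1), 0, 400, dt = 1, y0 = 0)
  expect_equal(tr$states[, 1], 100 * (1 - exp(-0.01 * tr$time)), tolerance = 1e-10)
  tr0 <- simulate_gal1(gp, constant_input(0), 0, 400, dt = 1, y0 = 80)
  expect_equal(tr0$states[, 1], 80 * exp(-0.01 * tr0$time), tolerance = 1e-10)
})

test_that("GAL1 under 50% duty pulses attains the analytic periodic cycle average", {
  gp <- gal1_params(vmax = 1, deg = 0.01)
  # alternating 5-min pulses: derive the periodic orbit analytically
  d <- gp$deg; von <- gp$vmax / d; h <- 5
  a <- exp(-d * h)
  y0 <- von * (1 - a) * a / (1 - a^2)          # value at start of ON half
  y1 <- von + (y0 - von) * a                   # value at end of ON half
  avg_on <- von + (y0 - von) * (1 - a) / (d * h)
  avg_off <- y1 * (1 - a) / (d * h)
  avg_oracle <- (avg_on + avg_off) / 2
  ts <- seq(0, 4000, 5)
  u <- binary_input(ts, rep(c(1, 0), length.out = length(ts)))
  tr <- simulate_gal1(gp, u, 0, 4000, dt = 0.1, y0 = y0)
  late <- tr$states[tr$time >= 3990, 1]        # one full period, settled
  avg_sim <- mean((late[-1] + late[-length(late)]) / 2)
  expect_equal(avg_sim, avg_oracle, tolerance = 1e-4)
})

test_that("parameter and trajectory plumbing round-trips", {
  p <- default_irma()
  f <- tempfile(fileext = ".conf")
  write_param_file(p, f)
  p2 <- irma_default_params(f)
  expect_equal(unclass(p)[order(names(p))], unclass(p2)[order(names(p2))])
  tr <- simulate_gal1(gal1_params(), constant_input(1), 0, 50, dt = 5)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  df <- read.csv(csv)
  expect_named(df, c("time_min", "u", "y"))
  expect_equal(df$y, unname(tr$states[, 1]))
  expect_error(irma_params(p$basal, -p$vmax, p$k, p$hill, p$deg, p$gamma, p$tau),
               "positive")
  expect_error(binary_input(c(0, 0), c(1, 0)), "increasing")
  expect_error(simulate_irma(p, constant_input(1), 0, -5), "exceed")
})
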
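# shared fixtures: default calibration and memoized controller tuning

cl_cache <- new.env(parent = emptyenv())

default_irma <- function() {
  if (is.null(cl_cache$p)) cl_cache$p <- irma_default_params()
  cl_cache$p
}

# Cohen-Coon tuning from the delayed model's own step response (memoized:
# several tests reuse the same gains)
default_tuning <- function() {
  if (is.null(cl_cache$tune)) cl_cache$tune <- tune_irma_pi(default_irma())
  cl_cache$tune
}

irma_ss <- function(u) {
  key <- paste0("ss", u)
  if (is.null(cl_cache[[key]])) cl_cache[[key]] <- steady_state(default_irma(), u)
  cl_cache[[key]]
}

# an independent transcription of the model equations, written directly from
# the regulatory wiring (activation/repression Hill terms); serves as the
# oracle for the packaged vector field
oracle_irma_field <- function(s, sdel, u, p) {
  hp <- function(x, k, h) x^h / (k^h + x^h)
  g4free <- s[2] / (1 + s[5] / p$gamma)
  c(p$basal[1] + p$vmax[1] * hp(sdel[3], p$k[1], p$hill[1]) *
      (p$k[2]^p$hill[2] / (p$k[2]^p$hill[2] + sdel[4]^p$hill[2])) - p$deg[1] * s[1],
    p$basal[2] + p$vmax[2] * hp(s[1], p$k[3], p$hill[3]) - p$deg[2] * s[2],
    p$basal[3] + u * p$vmax[3] * hp(g4free, p$k[4], p$hill[4]) - p$deg[3] * s[3],
    p$basal[4] + p$vmax[4] * hp(s[3], p$k[5], p$hill[5]) - p$deg[4] * s[4],
    p$basal[5] + p$vmax[5] * hp(s[3], p$k[6], p$hill[6]) - p$deg[5] * s[5])
}

# brute-force forward-Euler integrator for the undelayed model (oracle)
euler_irma <- function(p, u_signal, t1, dt, s0) {
  n <- round(t1 / dt)
  s <- s0
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    s <- pmax(s + dt * oracle_irma_field(s, s, level_at(u_signal, t), p), 0)
  }
  s
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), .Machine$double.eps), tol)
}
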
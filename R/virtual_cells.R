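#' Configuration of the virtual cell population
#'
#' The ensemble emulates a monolayer of yeast cells in a microfluidic trap:
#' every cell follows the same deterministic single-cell model, but with
#' per-cell production-rate multipliers (extrinsic variability, i.i.d.
#' log-normal with unit median), exponential growth by age-based division
#' with jittered inheritance, and eviction of the oldest cells once the trap
#' capacity is reached. The readout is the population-average fluorescence
#' with additive measurement noise.
#'
#' @param n0 initial cell count (default 100).
#' @param doubling_time division interval (min, default 180).
#' @param extrinsic_cv target coefficient of variation of the production-rate
#'   multipliers (default 0.3); converted internally to the log-normal sdlog.
#' @param jitter_sd sdlog of the inheritance jitter applied to a daughter's
#'   multipliers at division (default 0.05). Inheritance is mean-reverting
#'   (daughters regress slightly toward the ensemble median) so that the
#'   extrinsic-noise distribution is stationary across generations.
#' @param measure_sd additive measurement noise SD on the population mean
#'   (fluorescence units, default 1).
#' @param capacity trap capacity (default 1200 cells).
#' @param stochastic_division if TRUE, division intervals are themselves
#'   log-normally jittered; default FALSE (deterministic age schedule).
#' @param fluo_scale,fluo_offset model-to-fluorescence affine readout.
#' @param dt ensemble integration step (min, default 1).
#' @param seed RNG seed used when the ensemble is initialized.
#' @return an object of class \code{"ensemble_config"}.
#' @export
ensemble_config <- function(n0 = 100, doubling_time = 180, extrinsic_cv = 0.3,
                            jitter_sd = 0.05, measure_sd = 1, capacity = 1200,
                            stochastic_division = FALSE, fluo_scale = 100,
                            fluo_offset = 0, dt = 1, seed = 1) {
  if (n0 < 1 || capacity < n0) stop("need 1 <= n0 <= capacity")
  if (doubling_time <= 0) stop("doubling_time must be positive")
  if (extrinsic_cv < 0 || jitter_sd < 0 || measure_sd < 0)
    stop("noise magnitudes must be >= 0")
  structure(list(n0 = as.integer(n0), doubling_time = doubling_time,
                 extrinsic_cv = extrinsic_cv, jitter_sd = jitter_sd,
                 measure_sd = measure_sd, capacity = as.integer(capacity),
                 stochastic_division = isTRUE(stochastic_division),
                 fluo_scale = fluo_scale, fluo_offset = fluo_offset,
                 dt = dt, seed = seed),
            class = "ensemble_config")
}

# vectorized steady state for a matrix of per-cell multipliers
steady_state_matrix <- function(p, u, vmul, tol = 1e-9, max_iter = 20000L) {
  n <- nrow(vmul)
  s <- matrix(p$basal / p$deg, n, 5L, byrow = TRUE) * vmul
  degm <- matrix(p$deg, n, 5L, byrow = TRUE)
  damp <- 0.5
  for (i in seq_len(max_iter)) {
    f <- irma_vector_field(s, s, u, p, vmul = vmul)
    s_new <- (1 - damp) * s + damp * pmax(s + f / degm, 0)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      if (max(abs(irma_vector_field(s, s, u, p, vmul = vmul))) < 1e-7) return(s)
    }
    s <- s_new
  }
  stop("per-cell steady states did not converge")
}

#' Initialize a virtual cell ensemble
#'
#' Each cell is seeded at the steady state of its own (multiplier-scaled)
#' parameters under the pre-experiment input \code{u0}; initial cell ages
#' are uniform over one division interval so divisions are desynchronized.
#'
#' @param cfg an \code{"ensemble_config"}.
#' @param base_params an \code{"irma_parameters"} object shared by all cells.
#' @param u0 pre-experiment input level (0/1).
#' @param t0 start time (min).
#' @return an object of class \code{"cell_ensemble"}.
#' @export
init_ensemble <- function(cfg, base_params, u0 = 0, t0 = 0) {
  stopifnot(inherits(cfg, "ensemble_config"), inherits(base_params, "irma_parameters"))
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  cap <- cfg$capacity; n <- cfg$n0
  sdlog <- sqrt(log(1 + cfg$extrinsic_cv^2))
  mult <- matrix(NA_real_, cap, 5L)
  mult[seq_len(n), ] <- exp(matrix(stats::rnorm(n * 5L, 0, sdlog), n, 5L))
  states <- matrix(NA_real_, cap, 5L)
  states[seq_len(n), ] <- steady_state_matrix(base_params, u0,
                                              mult[seq_len(n), , drop = FALSE])
  ages0 <- stats::runif(n, 0, cfg$doubling_time)
  buflen <- max(2L, ceiling(base_params$tau / cfg$dt) + 1L)
  buf <- array(NA_real_, c(buflen, cap, 5L))
  for (j in seq_len(buflen)) buf[j, , ] <- states   # constant pre-history
  structure(list(
    cfg = cfg, p = base_params, t = t0,
    alive = c(rep(TRUE, n), rep(FALSE, cap - n)),
    mult = mult, states = states,
    birth = c(t0 - ages0, rep(NA_real_, cap - n)),
    next_div = c(t0 - ages0 + cfg$doubling_time, rep(NA_real_, cap - n)),
    buf = buf, buf_head = buflen),   # buf_head indexes the current state row
    class = "cell_ensemble")
}

# delayed state matrix at t - frac_back * tau using ring-buffer interpolation
ens_lagged <- function(ens, lag) {
  if (lag <= 0) return(ens$states)
  steps <- lag / ens$cfg$dt
  buflen <- dim(ens$buf)[1L]
  j <- steps; j0 <- floor(j + 1e-9); w <- j - j0
  idx0 <- ((ens$buf_head - 1L - j0) %% buflen) + 1L
  s0 <- ens$buf[idx0, , ]
  if (w < 1e-9) return(s0)
  idx1 <- ((ens$buf_head - 1L - j0 - 1L) %% buflen) + 1L
  (1 - w) * s0 + w * ens$buf[idx1, , ]
}

#' Advance a cell ensemble under a binary input
#'
#' Vectorized fixed-step RK4 over all live cells (shared delay ring buffer),
#' with age-based division: a dividing mother resets her division clock and
#' spawns a daughter inheriting her state, delay history, and multipliers
#' scaled by a log-normal jitter. When the trap is full the oldest cell is
#' evicted to make room.
#'
#' @param ens a \code{"cell_ensemble"}.
#' @param u_signal a \code{"binary_input"}.
#' @param t1 end time (min).
#' @return the advanced ensemble.
#' @export
ensemble_step <- function(ens, u_signal, t1) {
  stopifnot(inherits(ens, "cell_ensemble"), inherits(u_signal, "binary_input"))
  cfg <- ens$cfg; p <- ens$p; dt <- cfg$dt
  nstep <- round((t1 - ens$t) / dt)
  if (abs(t1 - ens$t - nstep * dt) > 1e-6) stop("window must be a multiple of dt")
  buflen <- dim(ens$buf)[1L]
  tau <- p$tau
  # mean-reverting inheritance: daughters regress toward the ensemble median
  # so the multiplier distribution stays stationary (pure multiplicative
  # jitter would random-walk the population variance upward over generations)
  sdlog <- sqrt(log(1 + cfg$extrinsic_cv^2))
  rho <- if (sdlog > 0) sqrt(max(0, 1 - (cfg$jitter_sd / sdlog)^2)) else 0
  for (i in seq_len(nstep)) {
    t <- ens$t; u <- level_at(u_signal, t)
    al <- ens$alive
    s <- ens$states[al, , drop = FALSE]
    m <- ens$mult[al, , drop = FALSE]
    if (tau > 0) {
      d1 <- ens_lagged(ens, tau)[al, , drop = FALSE]
      d2 <- ens_lagged(ens, max(tau - dt / 2, 0))[al, , drop = FALSE]
      d3 <- ens_lagged(ens, max(tau - dt, 0))[al, , drop = FALSE]
    }
    f <- function(ss, dd) irma_vector_field(pmax(ss, 0),
                                            if (tau > 0) dd else pmax(ss, 0),
                                            u, p, vmul = m)
    k1 <- f(s, if (tau > 0) d1)
    k2 <- f(s + dt / 2 * k1, if (tau > 0) d2)
    k3 <- f(s + dt / 2 * k2, if (tau > 0) d2)
    k4 <- f(s + dt * k3, if (tau > 0) d3)
    ens$states[al, ] <- pmax(s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    ens$t <- t + dt
    # push current states into the ring buffer
    ens$buf_head <- (ens$buf_head %% buflen) + 1L
    ens$buf[ens$buf_head, , ] <- ens$states

    # divisions due at the end of this step
    due <- which(ens$alive & ens$next_div <= ens$t + 1e-9)
    for (ci in due) {
      iv <- cfg$doubling_time *
        (if (cfg$stochastic_division) stats::rlnorm(1, 0, 0.1) else 1)
      ens$next_div[ci] <- ens$t + iv
      slot <- which(!ens$alive)[1L]
      if (is.na(slot)) {                     # trap full: evict the oldest cell
        slot <- which.min(replace(ens$birth, !ens$alive, Inf))
        if (slot == ci) next
      }
      ens$alive[slot] <- TRUE
      ens$mult[slot, ] <- exp(rho * log(ens$mult[ci, ]) +
                                stats::rnorm(5L, 0, cfg$jitter_sd))
      ens$states[slot, ] <- ens$states[ci, ]
      ens$buf[, slot, ] <- ens$buf[, ci, ]   # daughter inherits delay history
      ens$birth[slot] <- ens$t
      ens$next_div[slot] <- ens$t +
        cfg$doubling_time * (if (cfg$stochastic_division) stats::rlnorm(1, 0, 0.1) else 1)
    }
  }
  ens
}

#' Population snapshot of a cell ensemble
#'
#' Per-frame descriptive statistics of the per-cell fluorescence
#' (offset + scale * Cbf1): population mean, population SD (divide-by-N
#' convention) and CV, plus the noisy measured mean (additive Gaussian
#' measurement noise) the controller sees.
#'
#' @param ens a \code{"cell_ensemble"}.
#' @return an object of class \code{"population_snapshot"}: list(time, count,
#'   mean, sd, cv, y_measured).
#' @export
population_readout <- function(ens) {
  stopifnot(inherits(ens, "cell_ensemble"))
  al <- ens$alive
  if (!any(al)) stop("ensemble is empty")
  fl <- ens$cfg$fluo_offset + ens$cfg$fluo_scale * ens$states[al, 1L]
  n <- sum(al)
  mu <- mean(fl)
  sd_pop <- sqrt(mean((fl - mu)^2))        # population SD convention
  y <- mu + if (ens$cfg$measure_sd > 0) stats::rnorm(1, 0, ens$cfg$measure_sd) else 0
  structure(list(time = ens$t, count = n, mean = mu, sd = sd_pop,
                 cv = if (mu > 0) sd_pop / mu else NA_real_, y_measured = y),
            class = "population_snapshot")
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf("t = %g min: %d cells, mean fluo = %.3f, SD = %.3f, CV = %.3f\n",
              x$time, x$count, x$mean, x$sd, x$cv))
  invisible(x)
}

#' Ensemble plant for closed-loop runs
#'
#' Wraps a [init_ensemble()] population behind the plant interface; each
#' measurement appends a [population_readout()] snapshot to the plant's
#' snapshot log (retrievable with [ensemble_snapshots()]).
#'
#' @param cfg an \code{"ensemble_config"}.
#' @param base_params shared \code{"irma_parameters"}.
#' @param u0 pre-experiment input level.
#' @param t0 start time (min).
#' @return a plant object of class \code{c("ensemble_plant", "plant")}.
#' @export
ensemble_plant <- function(cfg, base_params, u0 = 0, t0 = 0) {
  ens <- init_ensemble(cfg, base_params, u0 = u0, t0 = t0)
  e <- new.env(parent = emptyenv())
  e$snapshots <- list()
  structure(list(ens = ens, t = t0, log = e),
            class = c("ensemble_plant", "plant"))
}

#' @export
plant_step.ensemble_plant <- function(plant, u_signal, t1) {
  plant$ens <- ensemble_step(plant$ens, u_signal, t1)
  plant$t <- t1
  plant
}

#' @export
plant_measure.ensemble_plant <- function(plant) {
  sn <- population_readout(plant$ens)
  plant$log$snapshots[[length(plant$log$snapshots) + 1L]] <- sn
  sn$y_measured
}

#' Snapshot log of an ensemble plant
#' @param plant an \code{"ensemble_plant"} used in a run.
#' @return data frame time_min, count, mean, sd, cv (one row per measurement).
#' @export
ensemble_snapshots <- function(plant) {
  sn <- plant$log$snapshots
  do.call(rbind, lapply(sn, function(s)
    data.frame(time_min = s$time, count = s$count, mean = s$mean,
               sd = s$sd, cv = s$cv)))
}
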
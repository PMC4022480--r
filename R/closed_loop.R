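#' Reference signal specification
#'
#' Reference levels are expressed as fractions of the calibrated output
#' range: a fraction f maps to y_min + f * (y_max - y_min). Time is measured
#' from the start of the control action (the reference is undefined during
#' calibration).
#'
#' @param kind one of \code{"constant"}, \code{"triangular"},
#'   \code{"ramp_down"}.
#' @param f fraction of the calibrated range: the set-point (constant), the
#'   baseline (triangular), or the starting level (ramp_down). In (0, 1].
#' @param f_peak peak fraction for the triangular wave.
#' @param period triangular wave period (min).
#' @param slope downward slope for ramp_down (fluorescence units/min).
#' @return an object of class \code{"reference_spec"}.
#' @export
reference_spec <- function(kind = c("constant", "triangular", "ramp_down"),
                           f = 0.5, f_peak = 0.7, period = 800, slope = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(f) || f <= 0 || f > 1) stop("f must lie in (0, 1]")
  if (kind == "triangular") {
    if (!is.finite(period) || period <= 0) stop("period must be positive")
    if (!is.finite(f_peak) || f_peak <= 0 || f_peak > 1) stop("f_peak must lie in (0, 1]")
  }
  if (kind == "ramp_down" && (is.null(slope) || !is.finite(slope) || slope < 0))
    stop("ramp_down needs a non-negative slope")
  structure(list(kind = kind, f = f, f_peak = f_peak, period = period,
                 slope = slope), class = "reference_spec")
}

#' Evaluate the reference signal
#'
#' @param spec a \code{"reference_spec"}.
#' @param y_max,y_min calibrated output extremes (y_max > y_min).
#' @param t time since the start of the control action (min); must be >= 0
#'   (the reference is undefined during calibration).
#' @return reference value(s) r(t) in output units.
#' @export
generate_reference <- function(spec, y_max, y_min, t) {
  stopifnot(inherits(spec, "reference_spec"))
  if (y_max <= y_min) stop("y_max must exceed y_min")
  if (any(t < 0)) stop("reference undefined before the control action starts")
  rng <- y_max - y_min
  switch(spec$kind,
    constant = rep(y_min + spec$f * rng, length(t)),
    triangular = {
      ph <- (t %% spec$period) / spec$period
      fr <- spec$f + (spec$f_peak - spec$f) * (1 - abs(2 * ph - 1))
      y_min + fr * rng
    },
    ramp_down = pmax(y_min, y_min + spec$f * rng - spec$slope * t))
}

#' Calibration protocol
#'
#' A sequence of constant-input phases run before the control action to
#' estimate the minimal (glucose) and maximal (galactose) fluorescence
#' levels. Each extreme is estimated as the mean of the last
#' \code{stat_n} samples of the corresponding phase.
#'
#' @param levels input level per phase (0/1).
#' @param durations phase durations (min).
#' @param stat_n number of trailing samples averaged per phase (default 6,
#'   i.e. 30 min at 5-min sampling).
#' @return an object of class \code{"calibration_protocol"}.
#' @export
calibration_protocol <- function(levels = c(1, 0), durations = c(300, 300),
                                 stat_n = 6) {
  if (length(levels) != length(durations) || !all(levels %in% c(0, 1)))
    stop("levels (0/1) and durations must match")
  if (any(durations <= 0)) stop("durations must be positive")
  if (!1 %in% levels || !0 %in% levels)
    stop("calibration needs at least one galactose and one glucose phase")
  structure(list(levels = levels, durations = durations, stat_n = stat_n),
            class = "calibration_protocol")
}

#' Run a closed-loop control experiment
#'
#' Executes the experiment finite-state automaton: an initial calibration
#' (state 0), then, per 5-min sampling interval, the cycle (1) PI-PWM
#' computes the input from the current error, (2) the internal model
#' prediction is advanced, (3) the input is applied to the plant, (4) the
#' delayed predicted output is formed, (5) a new measurement is ingested and
#' the error recomputed. The PI operates on the error normalized by the
#' calibrated range and outputs a level on the PWM sawtooth scale.
#'
#' @param plant a plant object (see [gal1_plant()], [irma_plant()],
#'   [ensemble_plant()]).
#' @param pi_cfg a \code{"pi_config"}.
#' @param pwm_cfg a \code{"pwm_config"}.
#' @param ref_spec a \code{"reference_spec"}.
#' @param predictor optional \code{"predictor_config"}; when supplied, its
#'   unit map is recalibrated from the measured calibration range onto the
#'   internal model's own steady-state output range unless the config was
#'   built with an explicit map (\code{auto_units = FALSE} attribute).
#' @param calib a \code{"calibration_protocol"}, or NULL to skip calibration
#'   (then \code{y_range} must be given).
#' @param duration length of the control phase (min).
#' @param Ts sampling interval (min), default 5.
#' @param measure_Tf measurement low-pass time constant (min) used when no
#'   predictor is present; 0 disables filtering.
#' @param y_range optional c(y_min, y_max) overriding calibration.
#' @param mode \code{"closed"} (normal closed loop), \code{"random"}
#'   (closed loop until the set-point is first reached, then the input is
#'   switched randomly between galactose and glucose per window), or
#'   \code{"constant"} (open loop at \code{const_level}).
#' @param const_level input level for \code{mode = "constant"}.
#' @param seed optional integer seed for the run's random streams.
#' @return a \code{"control_record"}: a data frame (time_min, phase, r, y,
#'   y_fb, e, pi_level, duty, u) with the full realized input signal, the
#'   calibration range and run metadata as attributes.
#' @export
run_fsa_loop <- function(plant, pi_cfg, pwm_cfg = pwm_config(),
                         ref_spec = reference_spec("constant", 0.5),
                         predictor = NULL, calib = calibration_protocol(),
                         duration = 2000, Ts = 5, measure_Tf = 0,
                         y_range = NULL, mode = c("closed", "random", "constant"),
                         const_level = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pi_cfg, "pi_config"), inherits(pwm_cfg, "pwm_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (duration <= 0) stop("duration must be positive")

  t0 <- plant_time(plant)
  rows <- list(); inputs <- list()

  # ---- state 0: calibration -------------------------------------------------
  if (!is.null(calib)) {
    stopifnot(inherits(calib, "calibration_protocol"))
    t <- t0
    phase_means <- c("0" = NA_real_, "1" = NA_real_)
    for (ph in seq_along(calib$levels)) {
      lev <- calib$levels[ph]
      n_s <- max(1L, floor(calib$durations[ph] / Ts))
      ys <- numeric(n_s)
      for (k in seq_len(n_s)) {
        u <- constant_input(lev, from = t)
        plant <- plant_step(plant, u, t + Ts)
        inputs[[length(inputs) + 1L]] <- u
        t <- t + Ts
        ys[k] <- plant_measure(plant)
        rows[[length(rows) + 1L]] <- data.frame(
          time_min = t, phase = "calibration", r = NA_real_, y = ys[k],
          y_fb = NA_real_, e = NA_real_, pi_level = NA_real_,
          duty = lev, u = lev)
      }
      phase_means[as.character(lev)] <-
        mean(utils::tail(ys, min(calib$stat_n, n_s)))
    }
    y_max <- phase_means[["1"]]; y_min <- phase_means[["0"]]
    t_ctrl <- t
  } else {
    if (is.null(y_range)) stop("without calibration, y_range must be supplied")
    y_min <- y_range[1L]; y_max <- y_range[2L]
    t_ctrl <- t0
  }
  if (!is.finite(y_min) || !is.finite(y_max) || y_max <= y_min)
    stop("calibration failed: degenerate output range [", y_min, ", ", y_max, "]")
  rng <- y_max - y_min

  # ---- predictor initialization --------------------------------------------
  if (!is.null(predictor)) {
    stopifnot(inherits(predictor, "predictor_config"))
    if (is.null(attr(predictor, "auto_units")) || isTRUE(attr(predictor, "auto_units"))) {
      if (inherits(predictor$model, "irma_parameters")) {
        m0 <- steady_state(predictor$model, 0)$state[1L]
        m1 <- steady_state(predictor$model, 1)$state[1L]
      } else {
        m0 <- 0; m1 <- predictor$model$vmax / predictor$model$deg
      }
      predictor$units <- calibrate_units(y_min, y_max, unname(m0), unname(m1))
    }
    last_lev <- if (!is.null(calib)) calib$levels[length(calib$levels)] else 0
    pstate0 <- if (inherits(predictor$model, "irma_parameters"))
      steady_state(predictor$model, last_lev)$state else
      last_lev * predictor$model$vmax / predictor$model$deg
    pred_st <- predictor_init(predictor, t0 = t_ctrl, state0 = pstate0)
  }

  # ---- control loop (states 1-5) -------------------------------------------
  pi_st <- pi_init()
  y_meas <- plant_measure(plant)
  filt <- lowpass_init(measure_Tf, y0 = y_meas)
  y_fb <- y_meas
  n_win <- floor(duration / Ts)
  randomized <- FALSE
  pred_trace <- if (!is.null(predictor)) list() else NULL

  for (k in seq_len(n_win)) {
    t_k <- t_ctrl + (k - 1L) * Ts
    r_k <- generate_reference(ref_spec, y_max, y_min, t_k - t_ctrl)
    e_k <- r_k - y_fb

    # state 1: PI-PWM computes the input for this window
    if (mode == "constant") {
      level <- const_level
      u_win <- constant_input(const_level, from = t_k)
    } else if (mode == "random" && randomized) {
      lev <- stats::rbinom(1L, 1L, 0.5)
      level <- lev
      u_win <- constant_input(lev, from = t_k)
    } else {
      st1 <- pi_step(pi_cfg, pi_st, e_k / rng)
      pi_st <- st1$state
      level <- st1$level
      u_win <- pwm_encode(level, pwm_cfg, t_k, Ts)
    }
    duty <- mean(level_at(u_win, t_k + pwm_cfg$quantum * (0:(Ts / pwm_cfg$quantum - 1))))

    # state 3: apply the input to the plant over the window
    plant <- plant_step(plant, u_win, t_k + Ts)
    inputs[[length(inputs) + 1L]] <- u_win

    # state 5: ingest the new measurement
    y_meas <- plant_measure(plant)

    # states 2 & 4: advance the model prediction and its delayed replica
    if (!is.null(predictor)) {
      ps <- predictor_step(predictor, pred_st, u_win, y_meas, Ts)
      pred_st <- ps$state
      y_fb <- ps$y_feedback
      pred_trace[[k]] <- data.frame(time_min = t_k + Ts, yhat = ps$yhat,
                                    yhat_delayed = ps$yhat_delayed,
                                    correction = ps$correction)
    } else if (measure_Tf > 0) {
      fl <- lowpass_step(filt, y_meas, Ts)
      filt <- fl$state
      y_fb <- fl$value
    } else {
      y_fb <- y_meas
    }

    if (mode == "random" && !randomized && abs(e_k) <= 0.02 * rng)
      randomized <- TRUE

    rows[[length(rows) + 1L]] <- data.frame(
      time_min = t_k, phase = "control", r = r_k, y = y_meas, y_fb = y_fb,
      e = e_k, pi_level = level, duty = duty, u = level_at(u_win, t_k))
  }

  rec <- do.call(rbind, rows)
  attr(rec, "y_min") <- unname(y_min)
  attr(rec, "y_max") <- unname(y_max)
  attr(rec, "t_ctrl") <- t_ctrl
  attr(rec, "Ts") <- Ts
  attr(rec, "mode") <- mode
  attr(rec, "seed") <- seed
  attr(rec, "input_signal") <- concat_inputs(inputs)
  if (!is.null(pred_trace)) attr(rec, "predictor_trace") <- do.call(rbind, pred_trace)
  class(rec) <- c("control_record", "data.frame")
  rec
}

#' Tracking and regulation metrics of a control record
#'
#' NRMSE is the root-mean-square of (y - r) over the control-active interval,
#' normalized by the calibrated output range estimated during the
#' calibration phase. Error statistics use the recorded error signal e
#' (reference minus feedback). Post-settling statistics start at the first
#' control sample where |e| drops below \code{settle_frac} of the range.
#'
#' @param rec a \code{"control_record"}.
#' @param settle_frac settling threshold as a fraction of the range.
#' @return an object of class \code{"loop_metrics"}.
#' @export
compute_metrics <- function(rec, settle_frac = 0.1) {
  stopifnot(inherits(rec, "control_record"))
  act <- rec[rec$phase == "control", , drop = FALSE]
  if (nrow(act) == 0L) stop("record has no control-active samples")
  rng <- attr(rec, "y_max") - attr(rec, "y_min")
  dev <- act$y - act$r
  nrmse <- sqrt(mean(dev^2)) / rng
  e <- act$e
  i_settle <- which(abs(e) <= settle_frac * rng)[1L]
  post <- if (is.na(i_settle)) numeric(0) else e[i_settle:length(e)]
  structure(list(
    nrmse = nrmse,
    error_mean = mean(e), error_var = stats::var(e),
    error_cv = stats::sd(e) / abs(mean(e)),
    settled = !is.na(i_settle),
    settle_time = if (is.na(i_settle)) NA_real_ else act$time_min[i_settle] - attr(rec, "t_ctrl"),
    post_settle_mean_abs_e = if (length(post)) mean(abs(post)) else NA_real_,
    post_settle_max_abs_e = if (length(post)) max(abs(post)) else NA_real_,
    y_range = rng, n_samples = nrow(act)),
    class = "loop_metrics")
}

#' @export
print.loop_metrics <- function(x, ...) {
  cat("Closed-loop performance metrics (control-active interval)\n")
  cat(sprintf("  NRMSE = %.4f (range-normalized), %d samples\n", x$nrmse, x$n_samples))
  cat(sprintf("  error mean = %.4g, var = %.4g, CV = %.4g\n",
              x$error_mean, x$error_var, x$error_cv))
  if (x$settled)
    cat(sprintf("  settled at t+%g min; post-settling mean|e| = %.4g, max|e| = %.4g\n",
                x$settle_time, x$post_settle_mean_abs_e, x$post_settle_max_abs_e))
  else cat("  never settled within threshold\n")
  invisible(x)
}

#' Negative-control experiment with a randomized input
#'
#' Runs the closed loop until the output first reaches the set-point, then
#' switches the input randomly (Bernoulli 1/2 per sampling window) between
#' galactose and glucose, emulating the paper-style negative control.
#'
#' @inheritParams run_fsa_loop
#' @return a \code{"control_record"}.
#' @export
random_input_control <- function(plant, pi_cfg, pwm_cfg = pwm_config(),
                                 ref_spec = reference_spec("constant", 0.5),
                                 calib = calibration_protocol(),
                                 duration = 2000, Ts = 5, seed = 1,
                                 y_range = NULL) {
  if (duration <= 0) stop("duration must be positive")
  run_fsa_loop(plant, pi_cfg, pwm_cfg, ref_spec, predictor = NULL,
               calib = calib, duration = duration, Ts = Ts,
               y_range = y_range, mode = "random", seed = seed)
}

#' Plot a control record
#'
#' Top panel: reference, measurement and feedback signal; bottom panel: the
#' realized binary input.
#'
#' @param x a \code{"control_record"}.
#' @param ... unused.
#' @export
plot.control_record <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_min, x$y, type = "l", col = "darkgreen",
                 xlab = "time (min)", ylab = "fluorescence (a.u.)")
  ok <- !is.na(x$r)
  graphics::lines(x$time_min[ok], x$r[ok], col = "blue")
  graphics::lines(x$time_min, x$y_fb, col = "darkorange", lty = 2)
  graphics::legend("topleft", c("y measured", "reference", "feedback"),
                   col = c("darkgreen", "blue", "darkorange"),
                   lty = c(1, 1, 2), bty = "n", cex = 0.8)
  u <- attr(x, "input_signal")
  tt <- seq(min(x$time_min), max(x$time_min), by = 1)
  graphics::plot(tt, level_at(u, tt), type = "s", col = "red",
                 xlab = "time (min)", ylab = "input u", yaxt = "n")
  graphics::axis(2, at = c(0, 1), labels = c("glu", "gal"))
  invisible(x)
}

#' Write a control record to CSV
#' @param rec a \code{"control_record"}.
#' @param path output file.
#' @export
write_record_csv <- function(rec, path) {
  stopifnot(inherits(rec, "control_record"))
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}
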
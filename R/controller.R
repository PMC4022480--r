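#' Discrete-time PI controller configuration
#'
#' The PI operates on the normalized control error (error divided by the
#' calibrated output range) and produces a level on the PWM sawtooth scale.
#' The integral uses a rectangular (backward-Euler) sum; with anti-windup
#' enabled the integral is frozen whenever the unsaturated output exceeds the
#' limits and the error would push it further.
#'
#' @param Kp proportional gain (dimensionless on normalized error).
#' @param Ki integral gain (1/min).
#' @param Ts sampling interval (min), default 5 (one image every 5 min).
#' @param u_min,u_max output saturation limits (default the PWM scale [0, 1]).
#' @param anti_windup freeze integration at saturation (default TRUE).
#' @return an object of class \code{"pi_config"}.
#' @export
pi_config <- function(Kp, Ki, Ts = 5, u_min = 0, u_max = 1, anti_windup = TRUE) {
  if (!is.finite(Ts) || Ts <= 0) stop("Ts must be positive")
  if (!is.finite(u_min) || !is.finite(u_max) || u_min >= u_max)
    stop("need u_min < u_max")
  if (!is.finite(Kp) || !is.finite(Ki)) stop("gains must be finite")
  structure(list(Kp = Kp, Ki = Ki, Ts = Ts, u_min = u_min, u_max = u_max,
                 anti_windup = isTRUE(anti_windup)), class = "pi_config")
}

#' Initial PI controller state
#' @return a \code{"pi_state"} with zero error integral.
#' @export
pi_init <- function() structure(list(integral = 0, last_error = 0), class = "pi_state")

#' One PI controller update
#'
#' Accumulates the error integral (rectangular rule over one sampling
#' interval), forms Kp*e + Ki*I, and clamps to the output limits.
#'
#' @param cfg a \code{"pi_config"}.
#' @param st a \code{"pi_state"}.
#' @param error current control error (reference minus feedback, normalized).
#' @return list(level = saturated control level, state = updated state).
#' @export
pi_step <- function(cfg, st, error) {
  stopifnot(inherits(cfg, "pi_config"), inherits(st, "pi_state"))
  if (!is.finite(error)) stop("error must be finite")
  int_new <- st$integral + error * cfg$Ts
  raw <- cfg$Kp * error + cfg$Ki * int_new
  level <- min(max(raw, cfg$u_min), cfg$u_max)
  if (cfg$anti_windup && raw != level) {
    # saturated: keep the integral only if it pulls the output back in range
    if ((raw > cfg$u_max && error > 0) || (raw < cfg$u_min && error < 0))
      int_new <- st$integral
    level <- min(max(cfg$Kp * error + cfg$Ki * int_new, cfg$u_min), cfg$u_max)
  }
  st$integral <- int_new
  st$last_error <- error
  list(level = level, state = st)
}

#' PWM encoder configuration
#'
#' The control level is compared against a rising sawtooth of period
#' \code{T_pwm} spanning [saw_min, saw_max]: the output is 1 (galactose)
#' while the level is at or above the sawtooth, so the high time sits at the
#' start of each period and the duty cycle equals the clamped normalized
#' level. Pulses are realized on a time-quantum grid.
#'
#' @param T_pwm sawtooth period (min), default 10.
#' @param saw_min,saw_max sawtooth range (default [0, 1], the PI scale).
#' @param quantum pulse realization grid (min); must divide \code{T_pwm}.
#' @return an object of class \code{"pwm_config"}.
#' @export
pwm_config <- function(T_pwm = 10, saw_min = 0, saw_max = 1, quantum = 0.5) {
  if (!is.finite(T_pwm) || T_pwm <= 0) stop("T_pwm must be positive")
  if (saw_min >= saw_max) stop("need saw_min < saw_max")
  if (!is.finite(quantum) || quantum <= 0) stop("quantum must be positive")
  if (abs(T_pwm / quantum - round(T_pwm / quantum)) > 1e-9)
    stop("quantum must divide T_pwm")
  structure(list(T_pwm = T_pwm, saw_min = saw_min, saw_max = saw_max,
                 quantum = quantum), class = "pwm_config")
}

#' Sawtooth carrier value
#' @param cfg a \code{"pwm_config"}.
#' @param t time (min).
#' @return carrier level at \code{t} (rising ramp, resets each period).
#' @export
pwm_sawtooth <- function(cfg, t) {
  ph <- (t %% cfg$T_pwm) / cfg$T_pwm
  cfg$saw_min + (cfg$saw_max - cfg$saw_min) * ph
}

#' Encode a control level as a binary pulse train over one window
#'
#' Comparator convention: output is high where \code{level >= sawtooth}
#' (ties count as high, so a saturated level gives duty exactly 1). The
#' sawtooth phase is taken from absolute time, so consecutive windows join
#' seamlessly.
#'
#' @param level PI output level (clamped to the sawtooth range).
#' @param cfg a \code{"pwm_config"}.
#' @param window_start window start time (min).
#' @param window_len window length (min); must be a multiple of the quantum.
#' @return a \code{"binary_input"} realized on the quantum grid over
#'   [window_start, window_start + window_len).
#' @export
pwm_encode <- function(level, cfg, window_start, window_len) {
  stopifnot(inherits(cfg, "pwm_config"))
  if (!is.finite(level)) stop("level must be finite")
  nq <- round(window_len / cfg$quantum)
  if (abs(window_len / cfg$quantum - nq) > 1e-9)
    stop("window_len must be a multiple of the quantum")
  level <- min(max(level, cfg$saw_min), cfg$saw_max)
  tq <- window_start + cfg$quantum * (0:(nq - 1L))
  u <- as.numeric(level >= pwm_sawtooth(cfg, tq) - 1e-12)
  change <- c(TRUE, diff(u) != 0)
  binary_input(tq[change], u[change], pre_level = u[1L])
}

#' First-order low-pass filter state
#'
#' Exact discretization of dy_f/dt = (y - y_f)/T_f. A time constant of 0
#' disables filtering (pass-through).
#'
#' @param T_f filter time constant (min).
#' @param y0 initial filtered value.
#' @return an object of class \code{"lowpass_state"}.
#' @export
lowpass_init <- function(T_f, y0 = 0) {
  if (!is.finite(T_f) || T_f < 0) stop("T_f must be >= 0")
  structure(list(T_f = T_f, value = y0), class = "lowpass_state")
}

#' One low-pass filter update
#' @param fst a \code{"lowpass_state"}.
#' @param y_raw new raw sample.
#' @param dt time since the previous sample (min).
#' @return list(value = filtered sample, state = updated state).
#' @export
lowpass_step <- function(fst, y_raw, dt) {
  stopifnot(inherits(fst, "lowpass_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  a <- if (fst$T_f == 0) 1 else 1 - exp(-dt / fst$T_f)
  fst$value <- fst$value + a * (y_raw - fst$value)
  list(value = fst$value, state = fst)
}

#' Fit a first-order-plus-dead-time model to a step response
#'
#' Identifies the FOPDT triple (static gain K, time constant T, dead time d)
#' from a monotone-settling step response using the deterministic two-point
#' construction: the times at which the output covers 28.3\% and 63.2\% of
#' its total change give T = 1.5 (t63 - t28) and d = t63 - T; the gain is
#' K = (y_final - y_initial) / delta_u.
#'
#' @param time sample times (min), or a \code{"trajectory"} object (then the
#'   \code{cbf1} column, or the single state column, is the output).
#' @param y response samples (ignored when \code{time} is a trajectory).
#' @param delta_u input step amplitude (default 1).
#' @param output column name to use when \code{time} is a trajectory.
#' @param settle_tol the final 10\% of the record must stay within this
#'   fraction of the total change for the response to count as settled.
#' @return an object of class \code{"fopdt_fit"} with coefficients K, T, d.
#' @export
estimate_fopdt <- function(time, y = NULL, delta_u = 1, output = NULL,
                           settle_tol = 0.02) {
  if (inherits(time, "trajectory")) {
    tr <- time
    cn <- colnames(tr$states)
    output <- if (!is.null(output)) output else if ("cbf1" %in% cn) "cbf1" else cn[1L]
    y <- tr$states[, output]
    time <- tr$time
  }
  stopifnot(length(time) == length(y), length(y) > 10)
  if (delta_u == 0) stop("delta_u must be non-zero")
  y0 <- y[1L]
  tail_idx <- which(time >= time[1L] + 0.9 * (time[length(time)] - time[1L]))
  yf <- mean(y[tail_idx])
  dy <- yf - y0
  if (abs(dy) < .Machine$double.eps^0.5) stop("response shows no net change")
  if (diff(range(y[tail_idx])) > settle_tol * abs(dy))
    stop("response has not settled: final 10% window not flat within tolerance")
  frac_cross <- function(fr) {
    target <- y0 + fr * dy
    above <- if (dy > 0) y >= target else y <= target
    i <- which(above)[1L]
    if (is.na(i)) stop("response never reaches ", fr * 100, "% of its change")
    if (i == 1L) return(time[1L])
    # linear interpolation of the crossing
    t1 <- time[i - 1L]; t2 <- time[i]
    w <- (target - y[i - 1L]) / (y[i] - y[i - 1L])
    t1 + w * (t2 - t1)
  }
  t28 <- frac_cross(0.283); t63 <- frac_cross(0.632)
  Tc <- 1.5 * (t63 - t28)
  d <- max(t63 - Tc - time[1L], 0)
  structure(list(K = dy / delta_u, T = Tc, d = d,
                 y_initial = y0, y_final = yf, delta_u = delta_u),
            class = "fopdt_fit")
}

#' @export
print.fopdt_fit <- function(x, ...) {
  cat("First-order-plus-dead-time fit (two-point 28.3%/63.2% method)\n")
  cat(sprintf("  K = %.5g, T = %.5g min, d = %.5g min\n", x$K, x$T, x$d))
  invisible(x)
}

#' @export
coef.fopdt_fit <- function(object, ...) c(K = object$K, T = object$T, d = object$d)

#' Predicted FOPDT step response
#' @param object a \code{"fopdt_fit"}.
#' @param time times at which to evaluate the fitted step response (min).
#' @param ... unused.
#' @return predicted output values for a \code{delta_u} input step at t = 0.
#' @export
predict.fopdt_fit <- function(object, time, ...) {
  with(object, y_initial + K * delta_u *
         ifelse(time <= d, 0, 1 - exp(-(time - d) / T)))
}

#' Cohen-Coon PI gains from an FOPDT estimate
#'
#' Standard Cohen-Coon rules for a PI controller:
#' Kp = (1/K) (T/d) (0.9 + d/(12 T)), Ti = d (30 + 3 d/T) / (9 + 20 d/T),
#' Ki = Kp / Ti. The rules are singular at zero dead time; in that case
#' gains must be supplied manually.
#'
#' @param est a \code{"fopdt_fit"} (or list with K, T, d).
#' @param Ts sampling interval carried into the returned config (min).
#' @return a \code{"pi_config"} with the tuned gains (limits [0, 1]).
#' @export
cohen_coon_gains <- function(est, Ts = 5) {
  K <- est$K; Tc <- est$T; d <- est$d
  if (!all(is.finite(c(K, Tc, d))) || K == 0 || Tc <= 0)
    stop("invalid FOPDT estimate")
  if (d <= 0)
    stop("Cohen-Coon rules are singular at zero dead time; supply gains manually")
  Kp <- (1 / K) * (Tc / d) * (0.9 + d / (12 * Tc))
  Ti <- d * (30 + 3 * d / Tc) / (9 + 20 * d / Tc)
  cfg <- pi_config(Kp = Kp, Ki = Kp / Ti, Ts = Ts)
  cfg$Ti <- Ti
  cfg
}

#' @export
print.pi_config <- function(x, ...) {
  cat(sprintf("PI controller: Kp = %.5g, Ki = %.5g 1/min, Ts = %g min, limits [%g, %g], anti-windup %s\n",
              x$Kp, x$Ki, x$Ts, x$u_min, x$u_max,
              if (x$anti_windup) "on" else "off"))
  invisible(x)
}
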
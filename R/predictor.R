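#' Affine calibration map between fluorescence and model units
#'
#' Builds the affine map sending the calibrated fluorescence range
#' [min_fluo, max_fluo] onto the model output range [model_min, model_max],
#' together with its inverse. Used to compare measured fluorescence with
#' model predictions inside the predictor.
#'
#' @param min_fluo,max_fluo calibrated fluorescence extremes (max_fluo >
#'   min_fluo).
#' @param model_min,model_max model-unit output extremes.
#' @return an object of class \code{"unit_map"} with functions
#'   \code{to_model(y_fluo)} and \code{to_fluo(y_model)}.
#' @export
calibrate_units <- function(min_fluo, max_fluo, model_min, model_max) {
  if (!is.finite(min_fluo) || !is.finite(max_fluo) || max_fluo <= min_fluo)
    stop("degenerate fluorescence range")
  if (!is.finite(model_min) || !is.finite(model_max) || model_max <= model_min)
    stop("degenerate model range")
  scale <- (model_max - model_min) / (max_fluo - min_fluo)
  structure(list(
    scale = scale, offset = model_min - scale * min_fluo,
    to_model = function(y) model_min + scale * (y - min_fluo),
    to_fluo = function(m) min_fluo + (m - model_min) / scale),
    class = "unit_map")
}

#' Smith predictor configuration
#'
#' The predictor runs a delay-free internal model of the plant in parallel
#' with the loop, produces the anticipated output ŷ(t) and a replica delayed
#' by the model delay \code{tau_m}, and corrects the anticipated output by
#' the low-pass-filtered mismatch between the measurement and the delayed
#' replica. The corrected signal replaces the raw measurement in the error
#' computation, so the PI effectively sees a delay-free plant.
#'
#' @param model internal model parameters: an \code{"irma_parameters"} object
#'   (simulated with tau forced to 0) or a \code{"gal1_parameters"} object
#'   (simulated with lag forced to 0).
#' @param tau_m model delay used for the delayed replica (min).
#' @param filter_Tf mismatch low-pass time constant (min); default 15
#'   (three 5-min sampling intervals). 0 disables filtering.
#' @param units a \code{"unit_map"} from [calibrate_units()] relating
#'   measured fluorescence to model output units; identity if NULL.
#' @param dt_int internal integration step (min).
#' @return an object of class \code{"predictor_config"}.
#' @export
predictor_config <- function(model, tau_m, filter_Tf = 15, units = NULL,
                             dt_int = 0.5) {
  if (!inherits(model, "irma_parameters") && !inherits(model, "gal1_parameters"))
    stop("model must be irma_parameters or gal1_parameters")
  if (!is.finite(tau_m) || tau_m < 0) stop("tau_m must be >= 0")
  if (is.null(units)) units <- calibrate_units(0, 1, 0, 1)
  if (!inherits(units, "unit_map")) stop("units must come from calibrate_units()")
  structure(list(model = model, tau_m = tau_m, filter_Tf = filter_Tf,
                 units = units, dt_int = dt_int), class = "predictor_config")
}

#' Initialize predictor state
#'
#' @param cfg a \code{"predictor_config"}.
#' @param t0 loop start time (min).
#' @param state0 initial internal model state (numeric(5) for IRMA, scalar
#'   for GAL1); defaults to the u = 0 steady state / zero.
#' @return an object of class \code{"predictor_state"}.
#' @export
predictor_init <- function(cfg, t0 = 0, state0 = NULL) {
  stopifnot(inherits(cfg, "predictor_config"))
  irma <- inherits(cfg$model, "irma_parameters")
  if (is.null(state0))
    state0 <- if (irma) steady_state(cfg$model, 0)$state else 0
  yhat0 <- cfg$units$to_fluo(if (irma) unname(state0[1L]) else state0)
  structure(list(
    t = t0, state = state0,
    hist_t = t0, hist_yhat = yhat0,      # ŷ history for the delayed replica
    filter = lowpass_init(cfg$filter_Tf, y0 = 0)),
    class = "predictor_state")
}

# advance the delay-free internal model over [t, t + dt] under input signal u
predictor_advance <- function(cfg, st, u_signal, dt) {
  if (inherits(cfg$model, "irma_parameters")) {
    p0 <- cfg$model; p0$tau <- 0
    tr <- simulate_irma(p0, u_signal, t0 = st$t, t1 = st$t + dt,
                        dt = min(cfg$dt_int, dt), history = st$state)
    st$state <- tr$states[nrow(tr$states), ]
    yhat_model <- unname(st$state[1L])
  } else {
    p0 <- cfg$model; p0$lag <- 0
    tr <- simulate_gal1(p0, u_signal, t0 = st$t, t1 = st$t + dt,
                        dt = min(cfg$dt_int, dt), y0 = st$state)
    st$state <- unname(tr$states[nrow(tr$states), 1L])
    yhat_model <- st$state
  }
  st$t <- st$t + dt
  yhat <- cfg$units$to_fluo(yhat_model)
  st$hist_t <- c(st$hist_t, st$t)
  st$hist_yhat <- c(st$hist_yhat, yhat)
  # keep only what the delayed replica needs
  keep <- st$hist_t >= st$t - cfg$tau_m - dt - 1e-9
  st$hist_t <- st$hist_t[keep]; st$hist_yhat <- st$hist_yhat[keep]
  st
}

# delayed replica ŷ(t - tau_m) by linear interpolation in the stored history
predictor_delayed_yhat <- function(cfg, st) {
  td <- st$t - cfg$tau_m
  if (td <= st$hist_t[1L]) return(st$hist_yhat[1L])
  stats::approx(st$hist_t, st$hist_yhat, xout = td, rule = 2)$y
}

#' One Smith-predictor update
#'
#' Advances the delay-free internal model over one sampling interval under
#' the input actually applied to the plant, forms the delayed replica
#' ŷ(t - tau_m), low-pass filters the mismatch between the measurement and
#' the replica, and returns the corrected feedback signal
#' ŷ(t) + filtered(y_measured - ŷ(t - tau_m)).
#'
#' @param cfg a \code{"predictor_config"}.
#' @param st a \code{"predictor_state"}.
#' @param u_applied the \code{"binary_input"} applied over the elapsed window.
#' @param y_measured plant measurement at the end of the window
#'   (fluorescence units).
#' @param dt window length (min).
#' @return list(y_feedback, yhat, yhat_delayed, correction, state).
#' @export
predictor_step <- function(cfg, st, u_applied, y_measured, dt) {
  stopifnot(inherits(cfg, "predictor_config"), inherits(st, "predictor_state"))
  if (!is.finite(y_measured)) stop("y_measured must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  st <- predictor_advance(cfg, st, u_applied, dt)
  yhat <- st$hist_yhat[length(st$hist_yhat)]
  yhat_del <- predictor_delayed_yhat(cfg, st)
  fl <- lowpass_step(st$filter, y_measured - yhat_del, dt)
  st$filter <- fl$state
  list(y_feedback = yhat + fl$value, yhat = yhat, yhat_delayed = yhat_del,
       correction = fl$value, state = st)
}
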
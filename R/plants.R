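#' Virtual plants for closed-loop experiments
#'
#' A plant wraps a simulated biological system behind two generics:
#' [plant_step()] advances it under a binary sugar input and
#' [plant_measure()] returns the fluorescence readout the controller sees.
#'
#' @param plant a plant object.
#' @param u_signal a \code{"binary_input"} applied over the window.
#' @param t1 window end time (min).
#' @name plant
NULL

#' @rdname plant
#' @export
plant_step <- function(plant, u_signal, t1) UseMethod("plant_step")

#' @rdname plant
#' @export
plant_measure <- function(plant) UseMethod("plant_measure")

#' @rdname plant
#' @export
plant_time <- function(plant) plant$t

#' GAL1 promoter plant
#'
#' Deterministic single-compartment GAL1 plant; output is directly in
#' fluorescence units. Optional additive Gaussian measurement noise (drawn
#' from the session RNG stream).
#'
#' @param p a \code{"gal1_parameters"} object.
#' @param y0 initial output.
#' @param t0 start time (min).
#' @param noise_sd measurement noise SD (fluorescence units).
#' @param dt integration/sampling step (min).
#' @return a plant object of class \code{c("gal1_plant", "plant")}.
#' @export
gal1_plant <- function(p, y0 = 0, t0 = 0, noise_sd = 0, dt = 0.5) {
  stopifnot(inherits(p, "gal1_parameters"))
  structure(list(p = p, y = y0, t = t0, dt = dt, noise_sd = noise_sd,
                 # input history buffer so the activation lag can look back
                 u_hist = constant_input(0, from = t0 - p$lag - 1)),
            class = c("gal1_plant", "plant"))
}

#' @export
plant_step.gal1_plant <- function(plant, u_signal, t1) {
  plant$u_hist <- concat_inputs(plant$u_hist, u_signal)
  tr <- simulate_gal1(plant$p, plant$u_hist, t0 = plant$t, t1 = t1,
                      dt = plant$dt, y0 = plant$y)
  plant$y <- unname(tr$states[nrow(tr$states), 1L])
  plant$t <- t1
  plant
}

#' @export
plant_measure.gal1_plant <- function(plant) {
  plant$y + if (plant$noise_sd > 0) stats::rnorm(1, 0, plant$noise_sd) else 0
}

#' Single-cell IRMA plant
#'
#' Deterministic IRMA plant (one cell following the hybrid DDE model). The
#' fluorescence readout is an affine image of the Cbf1 concentration:
#' y = fluo_offset + fluo_scale * cbf1, plus optional measurement noise.
#'
#' @param p an \code{"irma_parameters"} object.
#' @param u0 input level assumed before t0 (sets the initial steady state).
#' @param t0 start time (min).
#' @param fluo_scale,fluo_offset model-to-fluorescence affine readout.
#' @param noise_sd measurement noise SD (fluorescence units).
#' @param dt integration step (min).
#' @return a plant object of class \code{c("irma_plant", "plant")}.
#' @export
irma_plant <- function(p, u0 = 0, t0 = 0, fluo_scale = 100, fluo_offset = 0,
                       noise_sd = 0, dt = 0.5) {
  stopifnot(inherits(p, "irma_parameters"))
  s0 <- steady_state(p, u0)$state
  nb <- max(1L, ceiling(p$tau / dt))
  structure(list(p = p, t = t0, dt = dt,
                 hist_t = t0 - dt * (nb:0), # constant pre-history at ss(u0)
                 hist_s = matrix(s0, nb + 1L, 5L, byrow = TRUE,
                                 dimnames = list(NULL, species_names())),
                 fluo_scale = fluo_scale, fluo_offset = fluo_offset,
                 noise_sd = noise_sd),
            class = c("irma_plant", "plant"))
}

#' @export
plant_step.irma_plant <- function(plant, u_signal, t1) {
  ht <- plant$hist_t; hs <- plant$hist_s
  histfun <- function(t) {
    if (t <= ht[1L]) return(hs[1L, ])
    i <- findInterval(t, ht)
    if (i >= length(ht)) return(hs[length(ht), ])
    w <- (t - ht[i]) / (ht[i + 1L] - ht[i])
    (1 - w) * hs[i, ] + w * hs[i + 1L, ]
  }
  tr <- simulate_irma(plant$p, u_signal, t0 = plant$t, t1 = t1, dt = plant$dt,
                      history = histfun, state0 = hs[nrow(hs), ])
  keep_from <- t1 - plant$p$tau - 2 * plant$dt
  all_t <- c(ht, tr$time[-1L]); all_s <- rbind(hs, tr$states[-1L, , drop = FALSE])
  sel <- all_t >= keep_from
  plant$hist_t <- all_t[sel]; plant$hist_s <- all_s[sel, , drop = FALSE]
  plant$t <- t1
  plant
}

#' @export
plant_measure.irma_plant <- function(plant) {
  cbf1 <- plant$hist_s[nrow(plant$hist_s), 1L]
  plant$fluo_offset + plant$fluo_scale * cbf1 +
    if (plant$noise_sd > 0) stats::rnorm(1, 0, plant$noise_sd) else 0
}
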
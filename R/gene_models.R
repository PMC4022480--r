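#' Hybrid vector field of the IRMA network model
#'
#' Evaluates the right-hand side of the five-species IRMA model for a given
#' discrete sugar input. The model is hybrid: the galactose field (u = 1)
#' enables GAL10-promoter-driven Swi5 production, while the glucose field
#' (u = 0) disables it. The HO-promoter-driven Cbf1 production term reads its
#' regulators Swi5 (activator) and Ash1 (repressor) from \code{delayed_state},
#' i.e. at time t - tau; all other terms read the current state.
#'
#' Species order: cbf1, gal4, swi5, ash1, gal80.
#'
#' @param state numeric(5) current state, or an N x 5 matrix of states (one
#'   row per cell) for vectorized ensemble evaluation.
#' @param delayed_state state at t - tau, same shape as \code{state}.
#' @param u input level, 0 (glucose) or 1 (galactose).
#' @param p an \code{"irma_parameters"} object.
#' @param vmul optional production-rate multipliers (extrinsic variability):
#'   numeric(5) or N x 5 matrix applied to basal and vmax rates.
#' @return the state derivative, same shape as \code{state} (units/min).
#' @export
irma_vector_field <- function(state, delayed_state, u, p, vmul = NULL) {
  stopifnot(inherits(p, "irma_parameters"))
  if (!u %in% c(0, 1)) stop("u must be 0 or 1")
  vec <- is.null(dim(state))
  s <- if (vec) matrix(state, nrow = 1L) else as.matrix(state)
  sd_ <- if (vec) matrix(delayed_state, nrow = 1L) else as.matrix(delayed_state)
  if (ncol(s) != 5L || !identical(dim(s), dim(sd_)))
    stop("state and delayed_state must have 5 components each")
  if (any(s < 0) || any(sd_ < 0)) stop("negative state components are not allowed")

  hillp <- function(x, k, h) { xh <- (x / k)^h; xh / (1 + xh) }   # activation
  hillm <- function(x, k, h) 1 / (1 + (x / k)^h)                  # repression

  k <- p$k; h <- p$hill
  prod <- cbind(
    hillp(sd_[, 3L], k[1L], h[1L]) * hillm(sd_[, 4L], k[2L], h[2L]), # CBF1 (HO, delayed)
    hillp(s[, 1L], k[3L], h[3L]),                                    # GAL4
    u * hillp(s[, 2L] / (1 + s[, 5L] / p$gamma), k[4L], h[4L]),      # SWI5 (GAL10, gated)
    hillp(s[, 3L], k[5L], h[5L]),                                    # ASH1
    hillp(s[, 3L], k[6L], h[6L]))                                    # GAL80

  basal <- matrix(p$basal, nrow(s), 5L, byrow = TRUE)
  vmax <- matrix(p$vmax, nrow(s), 5L, byrow = TRUE)
  if (!is.null(vmul)) {
    m <- if (is.null(dim(vmul))) matrix(vmul, nrow(s), 5L, byrow = TRUE) else vmul
    basal <- basal * m; vmax <- vmax * m
  }
  deriv <- basal + vmax * prod - s * matrix(p$deg, nrow(s), 5L, byrow = TRUE)
  if (vec) drop(deriv) else deriv
}

#' Simulate the IRMA hybrid DDE model
#'
#' Fixed-step RK4 integration with a stored-state buffer for the delayed term
#' (method of steps); the delayed state at off-grid times is obtained by
#' linear interpolation inside the buffer. The input is treated as constant
#' over each integration step (evaluated at the step's left endpoint), so
#' input switch times should lie on the step grid for exact switching.
#' Trajectories are clipped at 0 (with a warning) if a step undershoots, as
#' Hill kinetics are undefined for negative concentrations.
#'
#' @param p an \code{"irma_parameters"} object.
#' @param input a \code{"binary_input"} signal.
#' @param t0,t1 start and end times (min), t1 > t0.
#' @param dt integration step (min); when \code{tau > 0}, \code{dt <= tau}
#'   is required.
#' @param history initial history: either a numeric(5) state held constant on
#'   [t0 - tau, t0] (the default uses the u(t0) steady state), or a function
#'   of t returning a numeric(5) state.
#' @param state0 optional initial state at t0 (defaults to \code{history(t0)}).
#' @return a \code{"trajectory"} object (uniform time grid, state matrix,
#'   realized input level per grid point).
#' @seealso [steady_state()], [step_response()]
#' @export
simulate_irma <- function(p, input, t0 = 0, t1, dt = 0.5, history = NULL,
                          state0 = NULL) {
  stopifnot(inherits(p, "irma_parameters"), inherits(input, "binary_input"))
  if (!is.finite(t1) || t1 <= t0) stop("t1 must exceed t0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (p$tau > 0 && dt > p$tau) stop("dt must not exceed tau for a delayed model")

  if (is.null(history)) history <- steady_state(p, level_at(input, t0))$state
  histfun <- if (is.function(history)) history else {
    h0 <- as.numeric(history)
    if (length(h0) != 5L || any(h0 < 0)) stop("constant history must be a non-negative state of length 5")
    function(t) h0
  }

  nstep <- ceiling((t1 - t0) / dt - 1e-9)
  times <- t0 + dt * (0:nstep)
  S <- matrix(NA_real_, nstep + 1L, 5L,
              dimnames = list(NULL, species_names()))
  S[1L, ] <- if (is.null(state0)) histfun(t0) else as.numeric(state0)
  if (any(S[1L, ] < 0)) stop("initial state must be non-negative")
  uu <- level_at(input, times)

  lag_state <- function(td, i_done) {
    # state at time td, using history for td <= t0 and the computed rows else
    if (td <= t0 + 1e-12) return(pmax(histfun(td), 0))
    j <- (td - t0) / dt
    j0 <- floor(j + 1e-9); w <- j - j0
    j0 <- min(j0, i_done - 1L)
    if (w < 1e-9 || j0 + 2L > i_done + 1L) return(S[j0 + 1L, ])
    (1 - w) * S[j0 + 1L, ] + w * S[j0 + 2L, ]
  }

  clipped <- FALSE
  tau <- p$tau
  for (i in seq_len(nstep)) {
    t <- times[i]; y <- S[i, ]; u <- uu[i]
    if (tau > 0) {
      d1 <- lag_state(t - tau, i)
      d2 <- lag_state(t + dt / 2 - tau, i)
      d3 <- lag_state(t + dt - tau, i)
    } else d1 <- d2 <- d3 <- NULL
    f <- function(yy, dd) irma_vector_field(pmax(yy, 0), if (tau > 0) dd else pmax(yy, 0), u, p)
    k1 <- f(y, d1)
    k2 <- f(y + dt / 2 * k1, d2)
    k3 <- f(y + dt / 2 * k2, d2)
    k4 <- f(y + dt * k3, d3)
    ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(ynew < 0)) { clipped <- TRUE; ynew <- pmax(ynew, 0) }
    S[i + 1L, ] <- ynew
  }
  if (clipped) warning("integration step undershot zero; trajectory clipped at 0")
  new_trajectory(times, S, uu)
}

#' Simulate the one-gene GAL1 promoter model
#'
#' dy/dt = vmax * u(t - lag) - deg * y. Solved exactly (piecewise exponential
#' between input switches) and sampled on a uniform grid.
#'
#' @param p a \code{"gal1_parameters"} object.
#' @param input a \code{"binary_input"} signal.
#' @param t0,t1,dt time window and sampling step (min).
#' @param y0 initial output at t0 (default 0).
#' @return a \code{"trajectory"} object with a single state column \code{y}.
#' @export
simulate_gal1 <- function(p, input, t0 = 0, t1, dt = 1, y0 = 0) {
  stopifnot(inherits(p, "gal1_parameters"), inherits(input, "binary_input"))
  if (!is.finite(t1) || t1 <= t0) stop("t1 must exceed t0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (y0 < 0) stop("y0 must be non-negative")
  nstep <- ceiling((t1 - t0) / dt - 1e-9)
  times <- t0 + dt * (0:nstep)
  # effective input as seen by the promoter: delayed by the activation lag
  eff <- function(t) level_at(input, t - p$lag)
  # breakpoints of the effective input inside the window
  bk <- sort(unique(c(t0, input$times + p$lag, t1)))
  bk <- bk[bk >= t0 & bk <= t1]
  if (bk[1] > t0) bk <- c(t0, bk)
  if (bk[length(bk)] < t1) bk <- c(bk, t1)
  y <- numeric(nstep + 1L); y[1L] <- y0
  ycur <- y0
  seg_sol <- function(y_start, u, h) {
    yss <- u * p$vmax / p$deg
    yss + (y_start - yss) * exp(-p$deg * h)
  }
  for (s in seq_len(length(bk) - 1L)) {
    a <- bk[s]; b <- bk[s + 1L]; u <- eff(a)
    idx <- which(times > a + 1e-12 & times <= b + 1e-12)
    if (length(idx)) y[idx] <- seg_sol(ycur, u, times[idx] - a)
    ycur <- seg_sol(ycur, u, b - a)
  }
  new_trajectory(times, matrix(y, ncol = 1L, dimnames = list(NULL, "y")),
                 level_at(input, times))
}

#' Steady state of the IRMA model under a constant input
#'
#' Finds a fixed point of the chosen vector field (with the delayed state
#' equal to the current state) by damped fixed-point iteration on the
#' production/degradation balance, and verifies the residual.
#'
#' @param p an \code{"irma_parameters"} object.
#' @param u constant input, 0 or 1.
#' @param start optional non-negative starting state (default: basal/deg).
#' @param tol residual tolerance on the vector field (default 1e-10).
#' @param max_iter iteration budget.
#' @return a list with \code{state} (named numeric(5)) and \code{residual};
#'   errors out if the iteration does not converge.
#' @export
steady_state <- function(p, u, start = NULL, tol = 1e-10, max_iter = 20000L) {
  stopifnot(inherits(p, "irma_parameters"))
  if (!u %in% c(0, 1)) stop("u must be 0 or 1")
  s <- if (is.null(start)) p$basal / p$deg else pmax(as.numeric(start), 0)
  damp <- 0.5
  for (i in seq_len(max_iter)) {
    f <- irma_vector_field(s, s, u, p)
    g <- s + f / p$deg          # fixed-point map: s <- production/deg
    s_new <- (1 - damp) * s + damp * pmax(g, 0)
    if (max(abs(s_new - s)) < tol * damp && max(abs(f)) < 1e-8) {
      s <- s_new
      res <- max(abs(irma_vector_field(s, s, u, p)))
      if (res < 1e-8)
        return(list(state = stats::setNames(s, species_names()), residual = res))
    }
    s <- s_new
  }
  stop("steady_state did not converge within ", max_iter, " iterations (residual ",
       signif(max(abs(irma_vector_field(s, s, u, p))), 3), ")")
}

#' Open-loop step response of the IRMA model
#'
#' Starts at the steady state of the \code{u_from} field (constant history)
#' and steps the input to \code{u_to} at t = 0.
#'
#' @param p an \code{"irma_parameters"} object.
#' @param u_from,u_to input levels in \{0, 1\}.
#' @param horizon simulation length (min).
#' @param dt integration step (min).
#' @return a \code{"trajectory"} object; the controlled output is the
#'   \code{cbf1} column.
#' @export
step_response <- function(p, u_from, u_to, horizon = 1500, dt = 0.5) {
  ss <- steady_state(p, u_from)
  simulate_irma(p, constant_input(u_to), t0 = 0, t1 = horizon, dt = dt,
                history = ss$state)
}

# ---- trajectory container ---------------------------------------------------

new_trajectory <- function(time, states, input) {
  stopifnot(length(time) == nrow(states), length(time) == length(input))
  structure(list(time = as.numeric(time), states = states,
                 input = as.numeric(input)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("Trajectory: %d points, t in [%g, %g] min (dt = %g), species: %s\n",
              n, x$time[1], x$time[n], x$time[2] - x$time[1],
              paste(colnames(x$states), collapse = ", ")))
  cat("final state:", paste(sprintf("%s=%.4g", colnames(x$states),
                                    x$states[n, ]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_min = x$time, u = x$input, x$states, check.names = FALSE)
}

#' Plot a simulated trajectory
#'
#' Draws every species over time, with the binary input overlaid (rescaled)
#' as a step line.
#'
#' @param x a \code{"trajectory"} object.
#' @param species columns to draw (default all).
#' @param ... passed to \code{matplot}.
#' @export
plot.trajectory <- function(x, species = colnames(x$states), ...) {
  S <- x$states[, species, drop = FALSE]
  graphics::matplot(x$time, S, type = "l", lty = 1, xlab = "time (min)",
                    ylab = "concentration (model units)", ...)
  graphics::lines(x$time, x$input * max(S), col = "grey60", lty = 3)
  graphics::legend("topright", legend = c(species, "input (scaled)"),
                   col = c(seq_along(species), "grey60"),
                   lty = c(rep(1, length(species)), 3), cex = 0.8, bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#' @param x a \code{"trajectory"} object.
#' @param path output file.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
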
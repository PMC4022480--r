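#' Parameter set for the IRMA network model
#'
#' Constructs and validates the parameter set of the five-species hybrid
#' delay-differential model of the IRMA synthetic network (Cbf1, Gal4, Swi5,
#' Ash1, Gal80). Production of each protein is the sum of a basal rate and a
#' Hill-regulated maximal rate; every species decays by first-order
#' degradation/dilution. Galactose (input u = 1) enables GAL10-promoter-driven
#' Swi5 production; glucose (u = 0) disables it. Gal80p inhibits Gal4p through
#' a protein-protein interaction with constant \code{gamma}. Production of
#' Cbf1 from the HO promoter is transcriptionally delayed by \code{tau}
#' minutes and reads its regulators (Swi5, Ash1) at time \code{t - tau}.
#'
#' Units: concentrations are in arbitrary model units, rates in units/min,
#' degradation rates in 1/min, thresholds in model units, \code{tau} in min.
#'
#' @param basal numeric(5), basal transcription rates (units/min) for
#'   (cbf1, gal4, swi5, ash1, gal80).
#' @param vmax numeric(5), maximal regulated production rates (units/min).
#' @param k numeric(6), Hill thresholds: k[1] Swi5->CBF1 activation,
#'   k[2] Ash1-|CBF1 repression, k[3] Cbf1->GAL4, k[4] Gal4->SWI5,
#'   k[5] Swi5->ASH1, k[6] Swi5->GAL80.
#' @param hill numeric(6), Hill coefficients matching \code{k}.
#' @param deg numeric(5), degradation + dilution rates (1/min).
#' @param gamma Gal80p-Gal4p inhibition constant (model units).
#' @param tau transcriptional delay on HO-driven Cbf1 production (min).
#' @return an object of class \code{"irma_parameters"} (a named list).
#' @seealso [irma_default_params()], [irma_vector_field()], [simulate_irma()]
#' @export
irma_params <- function(basal, vmax, k, hill, deg, gamma, tau) {
  p <- list(basal = as.numeric(basal), vmax = as.numeric(vmax),
            k = as.numeric(k), hill = as.numeric(hill),
            deg = as.numeric(deg), gamma = as.numeric(gamma),
            tau = as.numeric(tau))
  if (length(p$basal) != 5L || length(p$vmax) != 5L || length(p$deg) != 5L)
    stop("basal, vmax and deg must each have length 5")
  if (length(p$k) != 6L || length(p$hill) != 6L)
    stop("k and hill must each have length 6")
  vals <- c(p$basal, p$vmax, p$k, p$hill, p$deg, p$gamma)
  if (any(!is.finite(vals)) || !is.finite(p$tau))
    stop("all IRMA parameters must be finite")
  if (any(c(p$vmax, p$k, p$hill, p$deg, p$gamma) <= 0) || any(p$basal < 0))
    stop("rates, thresholds, Hill coefficients and gamma must be positive; basal rates non-negative")
  if (p$tau < 0) stop("tau must be >= 0")
  class(p) <- "irma_parameters"
  p
}

#' Default IRMA calibration
#'
#' The calibration shipped with the package, read from
#' \code{inst/extdata/irma_params_default.conf}. The values are the package's
#' own default calibration, chosen so that the model reproduces the
#' network's characteristic behaviour: galactose switches the network on
#' (the u = 1 steady-state Cbf1 level is several-fold above the u = 0 level),
#' switch-on/switch-off transients settle over a few hundred minutes, and
#' HO-promoter-driven Cbf1 production lags its regulators by
#' \code{tau = 100} min. Edit the config file or pass overrides to explore
#' other regimes.
#'
#' @param file optional path to a flat key=value parameter file; defaults to
#'   the file shipped in the package.
#' @return an \code{"irma_parameters"} object.
#' @export
irma_default_params <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "irma_params_default.conf",
                        package = "cyberloop", mustWork = TRUE)
  kv <- read_param_file(file)
  need <- function(nm) {
    if (!nm %in% names(kv)) stop("parameter file missing key: ", nm)
    kv[[nm]]
  }
  irma_params(
    basal = vapply(paste0("basal_", species_names()), need, numeric(1)),
    vmax  = vapply(paste0("vmax_",  species_names()), need, numeric(1)),
    k     = vapply(paste0("k", 1:6), need, numeric(1)),
    hill  = vapply(paste0("h", 1:6), need, numeric(1)),
    deg   = vapply(paste0("deg_",  species_names()), need, numeric(1)),
    gamma = need("gamma"),
    tau   = need("tau"))
}

species_names <- function() c("cbf1", "gal4", "swi5", "ash1", "gal80")

#' Read a flat key=value parameter file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting with
#' \code{#} are ignored.
#'
#' @param path file path.
#' @return named list of numeric values.
#' @export
read_param_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed parameter line: ", ln[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric parameter value for key: ", keys[is.na(vals)][1])
  stats::setNames(as.list(vals), keys)
}

#' Write a flat key=value parameter file
#' @param params an \code{"irma_parameters"} object.
#' @param path output path.
#' @export
write_param_file <- function(params, path) {
  stopifnot(inherits(params, "irma_parameters"))
  sp <- species_names()
  lines <- c(
    "# IRMA hybrid DDE model parameters (model units, minutes)",
    paste0("basal_", sp, " = ", format(params$basal, digits = 15)),
    paste0("vmax_", sp, " = ", format(params$vmax, digits = 15)),
    paste0("k", 1:6, " = ", format(params$k, digits = 15)),
    paste0("h", 1:6, " = ", format(params$hill, digits = 15)),
    paste0("deg_", sp, " = ", format(params$deg, digits = 15)),
    paste0("gamma = ", format(params$gamma, digits = 15)),
    paste0("tau = ", format(params$tau, digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.irma_parameters <- function(x, ...) {
  cat("IRMA hybrid DDE model parameters (5 species)\n")
  m <- rbind(basal = x$basal, vmax = x$vmax, deg = x$deg)
  colnames(m) <- species_names()
  print(round(m, 5))
  cat("Hill thresholds k1..k6: ", paste(signif(x$k, 4), collapse = ", "), "\n")
  cat("Hill coefficients h1..h6:", paste(signif(x$hill, 4), collapse = ", "), "\n")
  cat("Gal80p-Gal4p inhibition gamma =", signif(x$gamma, 4),
      " | transcriptional delay tau =", x$tau, "min\n")
  invisible(x)
}

#' Parameter set for the one-gene GAL1 promoter model
#'
#' A single-state linear production/decay model of the GAL1 promoter driving
#' a Gal1-Gfp fusion: dy/dt = vmax * u(t - lag) - deg * y, with u the binary
#' galactose input. Used to tune the PI-PWM controller and as a simple plant.
#'
#' @param vmax maximal production rate (fluorescence units/min) in galactose.
#' @param deg degradation + dilution rate (1/min).
#' @param lag optional activation lag (min): the input acts after a pure
#'   transport delay, default 0.
#' @return an object of class \code{"gal1_parameters"}.
#' @export
gal1_params <- function(vmax = 1, deg = 0.01, lag = 0) {
  if (!is.finite(vmax) || vmax <= 0) stop("vmax must be positive")
  if (!is.finite(deg) || deg <= 0) stop("deg must be positive")
  if (!is.finite(lag) || lag < 0) stop("lag must be >= 0")
  structure(list(vmax = vmax, deg = deg, lag = lag), class = "gal1_parameters")
}

#' @export
print.gal1_parameters <- function(x, ...) {
  cat("GAL1 promoter model: dy/dt = vmax*u(t-lag) - deg*y\n")
  cat(sprintf("  vmax = %g fluo/min, deg = %g 1/min (max level %g), lag = %g min\n",
              x$vmax, x$deg, x$vmax / x$deg, x$lag))
  invisible(x)
}
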
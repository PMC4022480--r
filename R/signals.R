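#' Piecewise-constant binary input signal
#'
#' Represents the actuated sugar input u(t): 1 = galactose, 0 = glucose.
#' The signal is right-continuous piecewise constant: \code{levels[i]} holds
#' on \code{[times[i], times[i+1])} and \code{levels[n]} from \code{times[n]}
#' onwards. Before \code{times[1]} the signal takes \code{pre_level}.
#'
#' @param times strictly increasing switch times (min).
#' @param levels levels in \{0, 1\}, same length as \code{times}.
#' @param pre_level level assumed for t < times[1] (default the first level).
#' @return an object of class \code{"binary_input"}.
#' @examples
#' u <- binary_input(c(0, 180), c(1, 0))   # 180 min galactose, then glucose
#' level_at(u, c(-5, 0, 179.9, 180, 500))
#' @export
binary_input <- function(times, levels, pre_level = levels[1]) {
  times <- as.numeric(times); levels <- as.numeric(levels)
  if (length(times) != length(levels) || length(times) == 0L)
    stop("times and levels must be non-empty and of equal length")
  if (any(diff(times) <= 0)) stop("switch times must be strictly increasing")
  if (!all(levels %in% c(0, 1)) || !pre_level %in% c(0, 1))
    stop("levels must be 0 (glucose) or 1 (galactose)")
  structure(list(times = times, levels = levels, pre_level = as.numeric(pre_level)),
            class = "binary_input")
}

#' Evaluate a binary input signal
#'
#' @param signal a \code{"binary_input"} object.
#' @param t numeric vector of times (min).
#' @return numeric vector of levels in \{0, 1\} (right-continuous).
#' @export
level_at <- function(signal, t) {
  stopifnot(inherits(signal, "binary_input"))
  idx <- findInterval(t, signal$times)      # 0 => before first switch
  out <- ifelse(idx == 0L, signal$pre_level, signal$levels[pmax(idx, 1L)])
  as.numeric(out)
}

#' Constant binary input
#' @param level 0 or 1.
#' @param from start time (min), default 0.
#' @return a \code{"binary_input"} object constant at \code{level}.
#' @export
constant_input <- function(level, from = 0) binary_input(from, level, pre_level = level)

#' Concatenate binary input signals in time
#'
#' Later signals override earlier ones from their first switch time onwards;
#' redundant switches (no level change) are dropped.
#'
#' @param ... \code{"binary_input"} objects with non-decreasing start times.
#' @return a single merged \code{"binary_input"}.
#' @export
concat_inputs <- function(...) {
  sigs <- list(...)
  if (length(sigs) == 1L && is.list(sigs[[1]]) && !inherits(sigs[[1]], "binary_input"))
    sigs <- sigs[[1]]
  times <- unlist(lapply(sigs, `[[`, "times"))
  levels <- unlist(lapply(sigs, `[[`, "levels"))
  if (any(diff(times) <= 0)) {
    keep <- !duplicated(times, fromLast = TRUE)
    times <- times[keep]; levels <- levels[keep]
    if (any(diff(times) <= 0)) stop("signals overlap out of order")
  }
  change <- c(TRUE, diff(levels) != 0)
  binary_input(times[change], levels[change], pre_level = sigs[[1]]$pre_level)
}

#' @export
print.binary_input <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Binary input signal: %d switch(es), t in [%g, %g] min\n",
              n, x$times[1], x$times[n]))
  show <- utils::head(data.frame(t_min = x$times, level = x$levels), 10)
  print(show, row.names = FALSE)
  if (n > 10) cat("  ...", n - 10, "more switches\n")
  invisible(x)
}
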
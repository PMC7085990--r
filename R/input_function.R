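#' Blood input function
#'
#' A sampled blood (plasma-equivalent) activity curve, interpreted as a
#' piecewise-linear function of time with C(0) = 0. Aorta-derived curves are
#' used directly as both the plasma input and the whole-blood curve (no
#' metabolite or plasma-fraction correction).
#'
#' @param times sample times in minutes, strictly ascending, all >= 0. If the
#'   first sample is after time zero, a (0, 0) point is prepended.
#' @param conc activity concentrations in kBq/mL, all >= 0, decay-corrected
#'   to injection.
#' @return An object of class `input_function` with elements `times`, `conc`.
#' @examples
#' cp <- input_function(c(1, 2, 10), c(50, 30, 5))
#' if_eval(cp, c(0.5, 1.5))
#' if_integral(cp, 10)
#' @export
input_function <- function(times, conc) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc) || length(times) < 1L)
    stop("times and conc must be non-empty and of equal length")
  if (any(!is.finite(times)) || any(!is.finite(conc)))
    stop("input function samples must be finite")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly ascending")
  if (times[1] < 0) stop("times must be >= 0")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (times[1] > 0) {
    times <- c(0, times); conc <- c(0, conc)
  } else if (conc[1] != 0) {
    stop("concentration at time zero must be 0")
  }
  structure(list(times = times, conc = conc), class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function: %d samples over %.3g-%.3g min, peak %.4g kBq/mL at %.3g min\n",
              length(x$times), x$times[1], max(x$times),
              max(x$conc), x$times[which.max(x$conc)]))
  invisible(x)
}

#' Evaluate an input function at arbitrary times
#'
#' Piecewise-linear interpolation; 0 before the first sample, constant
#' extrapolation beyond the last.
#'
#' @param input an [input_function()].
#' @param t times in minutes.
#' @return Concentrations in kBq/mL.
#' @export
if_eval <- function(input, t) {
  stopifnot(inherits(input, "input_function"))
  out <- approx(input$times, input$conc, xout = t, rule = 2)$y
  out[t < input$times[1]] <- 0
  out
}

# Refined evaluation grid: union of input knots (up to max(times)) and the
# requested times, with interpolated concentrations. Internal.
.if_grid <- function(input, times) {
  tmax <- max(times)
  grid <- sort(unique(c(0, input$times[input$times <= tmax], times)))
  list(t = grid, c = if_eval(input, grid), idx = match(times, grid))
}

#' Running integral of an input function
#'
#' Exact integral of the piecewise-linear curve from 0 to each requested
#' time (trapezoids, analytically exact for the piecewise-linear model).
#'
#' @inheritParams if_eval
#' @return Integral values in kBq min/mL; non-decreasing in `t`.
#' @export
if_integral <- function(input, t) {
  stopifnot(inherits(input, "input_function"))
  g <- .if_grid(input, t)
  conv_exp_cpp(g$t, g$c, 0)$y[g$idx]
}

#' Convolve an input function with a decaying exponential
#'
#' Computes `exp(-theta t) (*) Cp(t)` at the requested times, using the exact
#' analytic convolution of the piecewise-linear input with the exponential
#' kernel (no discrete-sum approximation). With `theta = 0` this degenerates
#' to the running integral of `Cp`.
#'
#' @param theta exponential rate in 1/min, `>= 0`.
#' @param input an [input_function()].
#' @param times evaluation times in minutes, ascending.
#' @return Convolution values (kBq/mL for `theta > 0` in 1/min units scaled
#'   by min; kBq min/mL for `theta = 0`).
#' @examples
#' cp <- input_function(c(0, 1, 45), c(0, 100, 100))
#' convolve_exp(1, cp, c(1, 5, 10))
#' @export
convolve_exp <- function(theta, input, times) {
  stopifnot(inherits(input, "input_function"))
  if (!is.finite(theta) || theta < 0) stop("theta must be a non-negative rate (1/min)")
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("times must be ascending")
  g <- .if_grid(input, times)
  conv_exp_cpp(g$t, g$c, theta)$y[g$idx]
}

# Frame-boundary context shared by all frame-averaged model evaluations:
# refined grid, concentrations, indices of frame starts/ends, and the
# theta-independent pieces (frame-averaged Cp and frame-averaged running
# integral of Cp). Internal; built once per (input, schedule) pair.
.frame_ctx <- function(input, schedule) {
  bnd <- sort(unique(c(schedule$start, schedule$end)))
  g <- .if_grid(input, bnd)
  i0 <- g$idx[match(schedule$start, bnd)]
  i1 <- g$idx[match(schedule$end, bnd)]
  z <- conv_exp_cpp(g$t, g$c, 0)
  list(
    t = g$t, c = g$c, i0 = i0, i1 = i1, dur = schedule$duration,
    conc_avg = (z$y[i1] - z$y[i0]) / schedule$duration,  # frame-avg Cp
    int_avg  = (z$S[i1] - z$S[i0]) / schedule$duration   # frame-avg of int Cp
  )
}

# Frame-averaged exp(-theta t) (*) Cp using the exact running integral of the
# convolution; theta = 0 gives the frame average of int_0^t Cp. Internal.
.frame_conv_avg <- function(ctx, theta) {
  z <- conv_exp_cpp(ctx$t, ctx$c, theta)
  (z$S[ctx$i1] - z$S[ctx$i0]) / ctx$dur
}

#' Frame-averaged concentration of an input function
#'
#' Average of the piecewise-linear curve over each frame interval, i.e. the
#' value an ideal scanner would report for a pure-blood voxel.
#'
#' @param input an [input_function()].
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame averages (kBq/mL).
#' @export
frame_avg_conc <- function(input, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  .frame_ctx(input, schedule)$conc_avg
}
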
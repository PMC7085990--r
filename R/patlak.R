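#' Patlak graphical analysis of a time-activity curve
#'
#' Ordinary least squares of the Patlak transform
#' `y = C(t)/Cp(t)` against `x = int_0^t Cp / Cp(t)`, evaluated at frame
#' mid-times with mid-time `>= t_star`. For an irreversible tracer the
#' asymptotic slope is the net influx rate Ki and the intercept is the
#' distribution volume Ve (which, unlike VND, includes the blood volume and is
#' reported without blood-volume subtraction). When the kinetics are in fact
#' reversible (k4 > 0), the Patlak slope underestimates the compartmental Ki
#' and the intercept overestimates the distribution volume.
#'
#' @param tac a [time_activity_curve()].
#' @param input plasma input function.
#' @param t_star start of the linear segment, minutes (default 15).
#' @param weighting `"uniform"` (default, standard practice) or `"duration"`.
#' @return An object of class `patlak_fit`: `ki` (slope, mL/cm^3/min),
#'   `ve` (intercept, mL/cm^3), `t_star`, `r2` of the linear segment,
#'   `frames` (indices used), and the plot-ready `x`, `y` series.
#' @examples
#' cp <- make_input_function()
#' fs <- dynamic_schedule_45min()
#' tac <- model_tac(kinetic_params(0.2, 0.5, 0.07, vb = 0.05), "2TC-3k", cp, fs)
#' patlak_fit(tac, cp)$ki
#' @export
patlak_fit <- function(tac, input, t_star = 15,
                       weighting = c("uniform", "duration")) {
  stopifnot(inherits(tac, "tac"))
  weighting <- match.arg(weighting)
  sched <- tac$schedule
  use <- which(sched$mid >= t_star - 1e-9)
  if (length(use) < 3)
    stop("insufficient data: need >= 3 frames with mid-time >= t_star")
  mid <- sched$mid[use]
  cp <- if_eval(input, mid)
  if (any(cp <= 0)) stop("Cp must be positive at all used frame mid-times")
  x <- if_integral(input, mid) / cp
  y <- tac$values[use] / cp
  w <- if (weighting == "duration") sched$duration[use] else rep(1, length(use))
  fit <- lm(y ~ x, weights = w)
  cf <- coef(fit)
  ss_tot <- sum(w * (y - weighted.mean(y, w))^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * fit$residuals^2) / ss_tot else 1
  structure(list(ki = unname(cf[2]), ve = unname(cf[1]), t_star = t_star,
                 r2 = r2, frames = use, x = x, y = y),
            class = "patlak_fit")
}

#' @importFrom stats weighted.mean
#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak: Ki = %.4g mL/cm^3/min, Ve = %.4g mL/cm^3 (t* = %g min, R^2 = %.4f, %d frames)\n",
              x$ki, x$ve, x$t_star, x$r2, length(x$frames)))
  invisible(x)
}

#' @export
plot.patlak_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "Normalized time  int Cp / Cp  (min)",
                 ylab = "C(t) / Cp(t)", main = "Patlak plot", ...)
  graphics::abline(x$ve, x$ki, col = "firebrick")
  invisible(x)
}

#' Patlak results as a table
#'
#' @param fits named list of `patlak_fit` objects.
#' @return data.frame with columns `id`, `ki`, `ve`, `t_star`, `r2`,
#'   `n_frames`.
#' @export
patlak_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(id = id, ki = f$ki, ve = f$ve, t_star = f$t_star, r2 = f$r2,
               n_frames = length(f$frames), stringsAsFactors = FALSE)
  }))
}
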
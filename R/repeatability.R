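# Relative within-pair differences in percent: d = (x2 - x1) / mean * 100.
# Pairs with non-positive mean are dropped with a warning. Internal.
.rel_diff <- function(test, retest) {
  test <- as.numeric(test); retest <- as.numeric(retest)
  if (length(test) != length(retest)) stop("test and retest must be paired")
  m <- (test + retest) / 2
  bad <- !is.finite(m) | m <= 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with non-positive mean excluded")
    test <- test[!bad]; retest <- retest[!bad]; m <- m[!bad]
  }
  list(d = (retest - test) / m * 100, mean = m, test = test, retest = retest)
}

#' Bland-Altman analysis of test-retest pairs
#'
#' Relative differences `d_i = (retest_i - test_i) / mean_i * 100%`, their
#' mean (bias) and 95% limits of agreement `bias +/- 1.96 sd(d)`.
#'
#' @param test,retest paired measurements (positive for relative statistics).
#' @return An object of class `bland_altman`: `bias` (%), `loa` (lower,
#'   upper, %), `sd`, `diff_pct`, `pair_mean`, `n`.
#' @examples
#' ba <- bland_altman(c(100, 100), c(110, 90))
#' ba$bias
#' @export
bland_altman <- function(test, retest) {
  r <- .rel_diff(test, retest)
  if (length(r$d) < 2) stop("need >= 2 usable pairs")
  bias <- mean(r$d)
  s <- sd(r$d)
  structure(list(bias = bias, loa = bias + c(-1.96, 1.96) * s, sd = s,
                 diff_pct = r$d, pair_mean = r$mean, n = length(r$d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3g%%, 95%% LoA [%.3g, %.3g]%% (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$pair_mean, x$diff_pct, xlab = "Pair mean",
                 ylab = "Relative difference (%)", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2), col = "firebrick")
  invisible(x)
}

#' Relative repeatability coefficient
#'
#' The within-subject variability bound from test-retest pairs, as a percent
#' of the pair mean. Conventions (all asymptotically `1.96 sqrt(2) wCV`,
#' differing in how wCV is estimated):
#' \describe{
#'   \item{`"rms"`}{(default) `RC% = 1.96 sqrt(mean(d^2))` with `d` the
#'     relative within-pair difference in percent; the `sqrt(2)` is absorbed
#'     by using the paired difference directly.}
#'   \item{`"sd"`}{`RC% = 1.96 sd(d)` (mean-centred differences).}
#'   \item{`"log"`}{wCV from log-ratios: `s2 = sum(log(x2/x1)^2) / (2n)`,
#'     `wCV = sqrt(exp(s2) - 1)`, `RC% = 1.96 sqrt(2) wCV * 100`.}
#' }
#'
#' @inheritParams bland_altman
#' @param convention one of `"rms"`, `"sd"`, `"log"`.
#' @return An object of class `repeatability`: `rc` (%), `wcv` (%),
#'   `convention`, `n`.
#' @examples
#' repeatability_coefficient(c(10, 12, 9), c(11, 11, 10))
#' @export
repeatability_coefficient <- function(test, retest,
                                      convention = c("rms", "sd", "log")) {
  convention <- match.arg(convention)
  r <- .rel_diff(test, retest)
  if (length(r$d) < 2) stop("insufficient data: need >= 2 usable pairs")
  rc <- switch(convention,
    rms = 1.96 * sqrt(mean(r$d^2)),
    sd  = 1.96 * sd(r$d),
    log = {
      s2 <- sum(log(r$retest / r$test)^2) / (2 * length(r$d))
      1.96 * sqrt(2) * sqrt(exp(s2) - 1) * 100
    })
  structure(list(rc = rc, wcv = rc / (1.96 * sqrt(2)), convention = convention,
                 n = length(r$d)),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability coefficient: %.3g%% (wCV %.3g%%, convention \"%s\", n = %d)\n",
              x$rc, x$wcv, x$convention, x$n))
  invisible(x)
}

#' Deming (errors-in-variables) regression
#'
#' Fits `y = slope * x + intercept` allowing measurement error on both axes
#' with error-variance ratio `lambda` (default 1: the same instrument measures
#' both visits). Unlike OLS, the Deming slope is not attenuated by noise in
#' `x`.
#'
#' @param x,y paired measurements (>= 3 pairs).
#' @param lambda ratio of the y-error variance to the x-error variance.
#' @return List of class `deming_fit`: `slope`, `intercept`, `lambda`, `n`.
#' @examples
#' deming_fit(1:5, 2 * (1:5) + 1)
#' @export
deming_fit <- function(x, y, lambda = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 pairs")
  if (lambda <= 0) stop("lambda must be positive")
  n <- length(x)
  sxx <- sum((x - mean(x))^2) / (n - 1)
  syy <- sum((y - mean(y))^2) / (n - 1)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  if (sxx == 0 || (sxy == 0 && syy <= lambda * sxx))
    stop("degenerate spread: Deming slope undefined")
  slope <- if (sxy == 0) {
    # vertical-major degenerate case
    sqrt(syy / (lambda * sxx)) * sign(1)
  } else {
    (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
  }
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 lambda = lambda, n = n),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming (lambda = %g): y = %.4g x + %.4g (n = %d)\n",
              x$lambda, x$slope, x$intercept, x$n))
  invisible(x)
}
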
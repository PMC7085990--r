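# Default box bounds: a generous physiologic envelope around reported
# liver/lesion values (K1 up to 5 mL/cm^3/min, rates up to 5 1/min, Vb <= 0.5).
.default_bounds <- function(model) {
  nm <- .model_info(model)$free
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(5, length(nm)), nm)
  upper["vb"] <- 0.5
  list(lower = lower, upper = upper)
}

# Multi-start grid: 3 log-spaced values per rate constant over (0.01, upper),
# Vb in {0.03, 0.1}. Internal.
.default_init_grid <- function(model, bounds) {
  nm <- .model_info(model)$free
  vals <- lapply(nm, function(p) {
    if (p == "vb") c(0.03, 0.1)
    else exp(seq(log(0.01), log(bounds$upper[[p]]), length.out = 3))
  })
  names(vals) <- nm
  as.matrix(expand.grid(vals))
}

#' Fit a compartment model to a time-activity curve
#'
#' Weighted non-linear least squares: minimizes `sum(w_i (C_i - model_i)^2)`
#' over the model's free parameters within box bounds, using a multi-start
#' strategy (all grid starts are screened by objective value; the best few are
#' polished with a bounded quasi-Newton optimizer). Ki and VND are populated
#' from the fitted micro-parameters.
#'
#' @param tac a [time_activity_curve()]; its `weights` are used unless
#'   `weighting = "uniform"`.
#' @param input plasma input function.
#' @param model one of `"1TC"`, `"2TC-3k"`, `"2TC-4k"`.
#' @param blood whole-blood curve; defaults to `input`.
#' @param weighting `"duration"` (default: the TAC's weights, normally frame
#'   durations) or `"uniform"`.
#' @param bounds list with named `lower`/`upper` vectors; defaults to
#'   K1, k2, k3, k4 in `[0, 5]`, Vb in `[0, 0.5]`.
#' @param init_grid matrix of starting values (columns = free parameters);
#'   default 3 log-spaced values per rate constant and Vb in {0.03, 0.1}.
#' @param n_polish number of screened starts polished by the optimizer.
#' @param vb_scale passed to [model_tac()].
#' @return An object of class `tac_fit`: fitted [kinetic_params()], `model`,
#'   weighted `rss`, `n`, `aic` (`n log(RSS/n) + 2p`), `converged` flag,
#'   parameter standard errors `se` (Gauss-Newton), `ki`, `vnd` (NA when
#'   undefined), `fitted` values and `residuals`.
#' @examples
#' cp <- make_input_function()
#' fs <- dynamic_schedule_45min()
#' truth <- kinetic_params(0.37, 0.3, 0.015, vb = 0.1)
#' tac <- model_tac(truth, "2TC-3k", cp, fs)
#' fit <- fit_tac(tac, cp, "2TC-3k")
#' fit$params
#' @export
fit_tac <- function(tac, input, model, blood = input,
                    weighting = c("duration", "uniform"),
                    bounds = NULL, init_grid = NULL, n_polish = 3L,
                    vb_scale = TRUE) {
  stopifnot(inherits(tac, "tac"))
  model <- match.arg(model, pet_models())
  weighting <- match.arg(weighting)
  info <- .model_info(model)
  if (is.null(bounds)) bounds <- .default_bounds(model)
  lower <- bounds$lower[info$free]; upper <- bounds$upper[info$free]
  if (any(lower < 0)) stop("bounds must be non-negative")
  if (is.null(init_grid)) init_grid <- .default_init_grid(model, bounds)
  init_grid <- as.matrix(init_grid)[, info$free, drop = FALSE]

  ctx <- .model_ctx(input, blood, tac$schedule)
  y <- tac$values
  w <- if (weighting == "uniform") rep(1, length(y)) else tac$weights

  predict_par <- function(par) {
    p <- as.list(par); names(p) <- info$free
    full <- list(K1 = p$K1, k2 = p$k2, k3 = p$k3 %||% 0, k4 = p$k4 %||% 0,
                 vb = p$vb)
    ct <- .tissue_frame_avg(full, model, ctx$tissue)
    if (vb_scale) (1 - full$vb) * ct + full$vb * ctx$cb_avg
    else ct + full$vb * ctx$cb_avg
  }
  obj <- function(par) {
    r <- y - predict_par(par)
    sum(w * r * r)
  }

  screen <- apply(init_grid, 1L, obj)
  ord <- order(screen)
  n_polish <- min(n_polish, nrow(init_grid))
  best <- NULL
  for (i in ord[seq_len(n_polish)]) {
    res <- tryCatch(
      nlminb(init_grid[i, ], obj, lower = lower, upper = upper,
             control = list(eval.max = 2000, iter.max = 1000,
                            rel.tol = 1e-12, abs.tol = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  n <- length(y); p <- info$p
  if (is.null(best)) {
    return(structure(list(params = NULL, model = model, rss = NA_real_,
                          n = n, aic = NA_real_, converged = FALSE,
                          se = NULL, ki = NA_real_, vnd = NA_real_,
                          fitted = NULL, residuals = NULL),
                     class = "tac_fit"))
  }

  par <- pmin(pmax(best$par, lower), upper)
  rss <- best$objective
  fitted <- predict_par(par)
  # gradient tolerance scales with the data magnitude (the objective is
  # quadratic in kBq/mL units), not just with the attained minimum
  converged <- .grad_converged(obj, par, lower, upper,
                               f_scale = rss + sum(w * y * y))
  se <- .gn_se(predict_par, par, w, rss, n, p)

  pl <- as.list(par); names(pl) <- info$free
  params <- kinetic_params(K1 = pl$K1, k2 = pl$k2, k3 = pl$k3 %||% 0,
                           k4 = pl$k4 %||% 0, vb = pl$vb)
  ki <- if (params$k2 + params$k3 > 0) net_influx(params) else NA_real_
  vn <- if (params$k2 > 0) vnd(params) else NA_real_
  # RSS below numerical noise (relative to the data scale) is clamped to a
  # common floor so that zero-RSS fits tie in AIC and the fewer-parameter
  # model wins the tie-break
  rss_floor <- 1e-12 * sum(w * y * y)
  structure(list(params = params, model = model, rss = rss, n = n,
                 aic = n * log(max(rss, rss_floor, .Machine$double.xmin) / n) + 2 * p,
                 converged = converged, se = se, ki = ki, vnd = vn,
                 fitted = fitted, residuals = y - fitted),
            class = "tac_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Projected stationarity check at the optimum: the point is converged when no
# coordinate step of curvature-appropriate size (respecting the bounds)
# decreases the objective materially. More robust than a raw
# finite-difference gradient norm, which is dominated by cancellation noise
# in the sharply curved valleys of misspecified models. Internal.
.grad_converged <- function(obj, par, lower, upper, f_scale, tol = 1e-7) {
  f0 <- obj(par)
  h <- pmax(1e-5, 1e-3 * abs(par))
  drop_max <- 0
  for (j in seq_along(par)) {
    for (s in c(1, -1)) {
      pj <- par[j] + s * h[j]
      if (pj < lower[j] || pj > upper[j]) next
      pp <- par; pp[j] <- pj
      drop_max <- max(drop_max, f0 - obj(pp))
    }
  }
  drop_max <= tol * (1 + abs(f_scale))
}

# Gauss-Newton standard errors from a numerical Jacobian at the optimum.
# Internal.
.gn_se <- function(predict_par, par, w, rss, n, p) {
  h <- pmax(1e-6, 1e-6 * abs(par))
  J <- vapply(seq_along(par), function(j) {
    pp <- par; pm <- par
    pp[j] <- par[j] + h[j]; pm[j] <- max(par[j] - h[j], 0)
    (predict_par(pp) - predict_par(pm)) / (pp[j] - pm[j])
  }, numeric(n))
  s2 <- rss / max(n - p, 1)
  A <- crossprod(J * sqrt(w))
  cv <- tryCatch(solve(A) * s2, error = function(e) NULL)
  if (is.null(cv)) return(setNames(rep(NA_real_, length(par)), names(par)))
  setNames(sqrt(pmax(diag(cv), 0)), names(par))
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("%s fit: RSS = %.4g, AIC = %.4g, converged = %s\n",
              x$model, x$rss, x$aic, x$converged))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Akaike model selection across compartment models
#'
#' Fits each candidate model to the same TAC and ranks converged fits by
#' `AIC = n log(RSS/n) + 2p` (Gaussian form, additive constant dropped),
#' ascending; ties are broken toward the model with fewer parameters.
#' Non-converged fits are excluded from the ranking with a warning.
#'
#' @inheritParams fit_tac
#' @param models character vector of candidate models (>= 2).
#' @param ... further arguments passed to [fit_tac()].
#' @return A list of class `aic_selection`: `fits` (ranked), `best` (the
#'   winning `tac_fit`), `table` (data.frame of model, p, RSS, AIC, converged),
#'   `excluded` (names of non-converged models).
#' @export
akaike_select <- function(tac, input, models = pet_models(), ...) {
  if (length(models) < 2) stop("need at least two candidate models")
  fits <- lapply(models, function(m) fit_tac(tac, input, m, ...))
  names(fits) <- models
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic),
                 logical(1))
  if (any(!conv))
    warning("non-converged fits excluded from AIC ranking: ",
            paste(models[!conv], collapse = ", "))
  if (!any(conv)) stop("no model converged")
  kept <- fits[conv]
  pvec <- vapply(kept, function(f) n_free_params(f$model), integer(1))
  aics <- vapply(kept, `[[`, numeric(1), "aic")
  ord <- order(aics, pvec)
  kept <- kept[ord]
  tab <- data.frame(
    model = vapply(kept, `[[`, character(1), "model"),
    p = vapply(kept, function(f) n_free_params(f$model), integer(1)),
    rss = vapply(kept, `[[`, numeric(1), "rss"),
    aic = vapply(kept, `[[`, numeric(1), "aic"),
    ki = vapply(kept, `[[`, numeric(1), "ki"),
    row.names = NULL
  )
  structure(list(fits = kept, best = kept[[1]], table = tab,
                 excluded = models[!conv]),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  cat("AIC model selection (best first):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Flatten fit results to a table
#'
#' One row per fit with the documented columns `id`, `model`, `K1`, `k2`,
#' `k3`, `k4`, `vb`, `ki`, `vnd`, `rss`, `aic`, `converged` plus standard
#' errors `se_*` where available.
#'
#' @param fits a named list of `tac_fit` objects (names become `id`).
#' @return A data.frame suitable for `write.csv`.
#' @export
fit_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    p <- f$params
    data.frame(id = id, model = f$model,
               K1 = p$K1 %||% NA_real_, k2 = p$k2 %||% NA_real_,
               k3 = p$k3 %||% NA_real_, k4 = p$k4 %||% NA_real_,
               vb = p$vb %||% NA_real_, ki = f$ki, vnd = f$vnd,
               rss = f$rss, aic = f$aic, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
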
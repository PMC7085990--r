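#' Compartment-model micro-parameters
#'
#' Container for the rate constants of a (one- or two-) tissue compartment
#' model with a fractional blood-volume term. Units: `K1` in mL/cm^3/min,
#' `k2`, `k3`, `k4` in 1/min, `vb` dimensionless in `[0, 1)`. `k4 = 0`
#' corresponds to irreversible binding (trapping).
#'
#' @param K1 delivery rate constant, mL/cm^3/min.
#' @param k2 efflux rate constant, 1/min.
#' @param k3 binding/internalization rate constant, 1/min.
#' @param k4 dissociation rate constant, 1/min (0 for irreversible models).
#' @param vb fractional blood volume, in `[0, 1)`.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(K1 = 0.37, k2 = 0.5, k3 = 0.021, vb = 0.1)
#' net_influx(p)
#' vnd(p)
#' @export
kinetic_params <- function(K1, k2 = 0, k3 = 0, k4 = 0, vb = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals[c("K1", "k2", "k3", "k4")] < 0))
    stop("rate constants must be >= 0")
  if (vb < 0 || vb >= 1) stop("vb must lie in [0, 1)")
  structure(as.list(vals), class = "kinetic_params")
}

#' Net influx rate constant Ki
#'
#' `Ki = K1 * k3 / (k2 + k3)`, the macro-parameter quantifying irreversible
#' uptake. Requires `k2 + k3 > 0`; satisfies `Ki <= K1`, with `Ki = K1` in the
#' pure-trapping limit `k2 = 0`.
#'
#' @param params a [kinetic_params()] object.
#' @return Ki in mL/cm^3/min.
#' @export
net_influx <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  s <- params$k2 + params$k3
  if (s <= 0) stop("net influx undefined: k2 + k3 must be > 0")
  params$K1 * params$k3 / s
}

#' Non-displaceable distribution volume VND
#'
#' `VND = K1 / k2` (mL/cm^3); defined only for `k2 > 0`. Unlike the Patlak
#' intercept `Ve`, VND does not include the blood-volume contribution.
#'
#' @inheritParams net_influx
#' @return VND in mL/cm^3.
#' @export
vnd <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k2 <= 0) stop("VND undefined: k2 must be > 0")
  params$K1 / params$k2
}

#' @export
print.kinetic_params <- function(x, ...) {
  ki <- if (x$k2 + x$k3 > 0) x$K1 * x$k3 / (x$k2 + x$k3) else NA_real_
  cat(sprintf(
    "K1 = %.4g mL/cm^3/min, k2 = %.4g, k3 = %.4g, k4 = %.4g 1/min, Vb = %.3g (Ki = %.4g)\n",
    x$K1, x$k2, x$k3, x$k4, x$vb, ki))
  invisible(x)
}

# Free-parameter layout per compartment model. Internal.
.model_info <- function(model) {
  switch(model,
    "1TC"    = list(free = c("K1", "k2", "vb"), p = 3L),
    "2TC-3k" = list(free = c("K1", "k2", "k3", "vb"), p = 4L),
    "2TC-4k" = list(free = c("K1", "k2", "k3", "k4", "vb"), p = 5L),
    stop("unknown model: ", model)
  )
}

#' Compartment model specifications
#'
#' The three supported models and their free-parameter counts: `1TC`
#' (K1, k2, Vb; p = 3), the irreversible two-tissue model `2TC-3k`
#' (K1, k2, k3, Vb; p = 4) and the reversible `2TC-4k`
#' (K1, k2, k3, k4, Vb; p = 5). `2TC-3k` is `2TC-4k` with k4 pinned to 0.
#'
#' @return Character vector of model identifiers.
#' @export
pet_models <- function() c("1TC", "2TC-3k", "2TC-4k")

#' Number of free parameters of a compartment model
#' @param model one of `"1TC"`, `"2TC-3k"`, `"2TC-4k"`.
#' @return Integer parameter count (includes Vb).
#' @export
n_free_params <- function(model) .model_info(model)$p
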
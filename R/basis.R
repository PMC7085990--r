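#' Default theta grid for basis-function fitting
#'
#' 64 log-spaced values of `theta = k2 + k3` over 0.006-3 1/min, spanning the
#' range implied by reported liver and lesion kinetics with margin.
#'
#' @param n number of grid points.
#' @param theta_min,theta_max grid limits, 1/min.
#' @return Ascending numeric vector.
#' @export
default_theta_grid <- function(n = 64, theta_min = 0.006, theta_max = 3) {
  if (n < 1 || theta_min <= 0 || theta_max <= theta_min)
    stop("invalid theta grid configuration")
  exp(seq(log(theta_min), log(theta_max), length.out = n))
}

#' Basis matrix for the linearized irreversible two-tissue model
#'
#' For each `theta = k2 + k3` on the grid, precomputes the frame-averaged
#' convolution column `B_theta(t) = exp(-theta t) (*) Cp(t)`, plus the two
#' fixed columns shared by every voxel: the frame-averaged whole-blood curve
#' `C_b(t)` and the frame-averaged running integral `int_0^t Cp`. Computed
#' once per study and reused for every voxel.
#'
#' @param input plasma input function.
#' @param schedule a [frame_schedule()].
#' @param theta_grid positive ascending grid of `k2 + k3` values (1/min).
#' @param blood whole-blood curve; defaults to `input`.
#' @return An object of class `basis_set`: `theta`, matrix `B`
#'   (frames x length(theta)), `cb_avg`, `int_avg`, `schedule`.
#' @export
make_basis <- function(input, schedule, theta_grid = default_theta_grid(),
                       blood = input) {
  stopifnot(inherits(schedule, "frame_schedule"))
  theta_grid <- as.numeric(theta_grid)
  if (length(theta_grid) == 0) stop("theta grid must be non-empty")
  if (any(theta_grid <= 0) || is.unsorted(theta_grid, strictly = TRUE))
    stop("theta grid must be positive and strictly ascending")
  ctx <- .model_ctx(input, blood, schedule)
  B <- vapply(theta_grid, function(th) .frame_conv_avg(ctx$tissue, th),
              numeric(schedule$n))
  structure(list(theta = theta_grid, B = B, cb_avg = ctx$cb_avg,
                 int_avg = ctx$tissue$int_avg, schedule = schedule),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("Basis set: %d theta values in [%.4g, %.4g] 1/min, %d frames\n",
              length(x$theta), min(x$theta), max(x$theta), x$schedule$n))
  invisible(x)
}

# Non-negative least squares for a small (<= 3 column) design by support
# enumeration: the NNLS optimum restricted to its active support is the
# unconstrained LS solution there, so the feasible subset solution with
# minimal RSS is the NNLS solution. Internal.
.nnls_small <- function(X, y) {
  k <- ncol(X)
  yy <- sum(y * y)
  best <- list(coef = rep(0, k), rss = yy)
  idx <- seq_len(k)
  for (m in idx) {
    combs <- utils::combn(idx, m)
    for (j in seq_len(ncol(combs))) {
      S <- combs[, j]
      Xs <- X[, S, drop = FALSE]
      b <- tryCatch(qr.solve(Xs, y), error = function(e) NULL)
      if (is.null(b) || any(b < -1e-10)) next
      r <- y - Xs %*% b
      rss <- sum(r * r)
      if (rss < best$rss - 1e-12 * (1 + yy)) {
        cf <- rep(0, k); cf[S] <- pmax(b, 0)
        best <- list(coef = cf, rss = rss)
      }
    }
  }
  best
}

#' Basis-function fit of a single voxel TAC
#'
#' For each theta on the grid, solves the non-negative linear least-squares
#' problem `C(t) ~ Vb * C_b + a * int(Cp) + b * B_theta` and keeps the theta
#' minimizing the residual sum of squares. Micro-parameters are recovered as
#' `K1 = a + b`, `k3 = theta a / (a + b)`, `k2 = theta b / (a + b)`, so that
#' `Ki = a` directly. With `vb_correction = TRUE` the tissue coefficients are
#' divided by `(1 - Vb)` to match the `(1 - Vb) C_T + Vb C_b` measurement
#' convention; the default (FALSE) reports the uncorrected coefficients.
#'
#' @param values voxel TAC (kBq/mL per frame).
#' @param basis a [make_basis()] result.
#' @param vb_correction logical; divide tissue coefficients by `(1 - Vb)`.
#' @return List: `params` ([kinetic_params()]), `ki`, `vnd` (NA if `k2 = 0`),
#'   `theta`, `rss`, `coef` (vb, a, b), `rss_by_theta`.
#' @export
fit_voxel_basis <- function(values, basis, vb_correction = FALSE) {
  stopifnot(inherits(basis, "basis_set"))
  values <- as.numeric(values)
  if (length(values) != basis$schedule$n) stop("values length must match schedule")
  if (any(!is.finite(values))) stop("voxel TAC must be finite")
  nt <- length(basis$theta)
  rss_by_theta <- numeric(nt)
  best <- NULL
  for (i in seq_len(nt)) {
    X <- cbind(basis$cb_avg, basis$int_avg, basis$B[, i])
    sol <- .nnls_small(X, values)
    rss_by_theta[i] <- sol$rss
    if (is.null(best) || sol$rss < best$rss) best <- c(sol, theta = basis$theta[i])
  }
  cf <- best$coef
  vb <- min(cf[1], 1 - 1e-9)
  scale <- if (vb_correction) 1 / (1 - vb) else 1
  a <- cf[2] * scale; b <- cf[3] * scale
  K1 <- a + b
  k3 <- if (K1 > 0) best$theta * a / K1 else 0
  k2 <- if (K1 > 0) best$theta * b / K1 else 0
  params <- kinetic_params(K1 = K1, k2 = k2, k3 = k3, vb = vb)
  list(params = params,
       ki = a,
       vnd = if (k2 > 0) K1 / k2 else NA_real_,
       theta = best$theta, rss = best$rss, coef = cf,
       rss_by_theta = rss_by_theta)
}
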
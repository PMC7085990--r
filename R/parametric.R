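# Vectorized unconstrained LS of Y (frames x nvox) on a column subset Xs,
# returning full-width coefficients (k_total x nvox) and RSS with infeasible
# (negative-coefficient) voxels set to Inf. Internal.
.ls_subset <- function(Xs, S, k_total, Y, yy) {
  A <- crossprod(Xs)
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(NULL)
  Ct <- crossprod(Xs, Y)                     # k x nvox
  B <- Ai %*% Ct
  rss <- yy - colSums(B * Ct)
  feas <- colSums(B < -1e-8) == 0
  rss[!feas] <- Inf
  coef <- matrix(0, k_total, ncol(Y))
  coef[S, ] <- pmax(B, 0)
  list(coef = coef, rss = rss)
}

# Update running best (rss, coef, theta) with a candidate. Internal.
.upd_best <- function(best, cand, theta) {
  if (is.null(cand)) return(best)
  better <- cand$rss < best$rss
  if (any(better)) {
    best$rss[better] <- cand$rss[better]
    best$coef[, better] <- cand$coef[, better]
    best$theta[better] <- theta
  }
  best
}

#' Voxel-wise parametric maps from the basis-function irreversible 2TC model
#'
#' Fits every voxel inside the mask with the linearized irreversible
#' two-tissue model (see [fit_voxel_basis()]) using non-negative linear least
#' squares over a shared precomputed basis, and simultaneously computes
#' voxel-wise Patlak `Ki` and `Ve` maps. The per-voxel solve is fully
#' vectorized over voxels (one normal-equation solve per theta and support
#' set), so the whole volume is fitted in seconds.
#'
#' @param dyn a [dynamic_image()].
#' @param input plasma input function (e.g. from [extract_idif()]).
#' @param theta_grid grid of `k2 + k3` values; default [default_theta_grid()].
#' @param t_star Patlak linear-segment start, minutes.
#' @param mask optional logical 3D array of voxels to fit; default: voxels
#'   whose duration-weighted time-summed activity exceeds `mask_frac` of the
#'   image maximum.
#' @param mask_frac threshold fraction for the default mask.
#' @param vb_correction divide tissue coefficients by `(1 - Vb)` (see
#'   [fit_voxel_basis()]); default FALSE.
#' @param blood whole-blood curve; defaults to `input`.
#' @return An object of class `parametric_maps`: 3D maps `K1`, `Ki`, `Vb`,
#'   `VND`, `Ki_patlak`, `Ve`, `rss`, `theta`, logical `mask`, `voxel_mm`.
#'   Unfitted voxels are NA; `VND` is NA where `k2 = 0`.
#' @export
parametric_maps <- function(dyn, input, theta_grid = default_theta_grid(),
                            t_star = 15, mask = NULL, mask_frac = 0.01,
                            vb_correction = FALSE, blood = input) {
  stopifnot(inherits(dyn, "dynamic_image"))
  d <- dim(dyn$data)
  nvox_all <- prod(d[1:3])
  M <- matrix(dyn$data, nrow = nvox_all, ncol = d[4])
  if (is.null(mask)) {
    ssum <- as.vector(M %*% dyn$schedule$duration)
    mask <- array(ssum > mask_frac * max(ssum), dim = d[1:3])
  } else {
    if (!identical(dim(mask), d[1:3])) stop("mask geometry must match the image")
  }
  sel <- which(mask)
  if (length(sel) == 0) stop("mask selects no voxels")
  Y <- t(M[sel, , drop = FALSE])              # frames x nvox
  yy <- colSums(Y * Y)
  nv <- length(sel)

  basis <- make_basis(input, dyn$schedule, theta_grid, blood = blood)
  Xfix <- cbind(basis$cb_avg, basis$int_avg)

  best <- list(rss = yy,                       # zero solution
               coef = matrix(0, 3, nv),
               theta = rep(0, nv))
  # theta-independent supports: {Vb}, {int}, {Vb, int}
  for (S in list(1L, 2L, c(1L, 2L)))
    best <- .upd_best(best, .ls_subset(Xfix[, S, drop = FALSE], S, 3L, Y, yy), 0)
  # theta-dependent supports
  for (i in seq_along(basis$theta)) {
    X3 <- cbind(Xfix, basis$B[, i])
    th <- basis$theta[i]
    for (S in list(3L, c(1L, 3L), c(2L, 3L), c(1L, 2L, 3L)))
      best <- .upd_best(best, .ls_subset(X3[, S, drop = FALSE], S, 3L, Y, yy), th)
  }

  vb <- pmin(best$coef[1, ], 1 - 1e-9)
  scale <- if (vb_correction) 1 / (1 - vb) else rep(1, nv)
  a <- best$coef[2, ] * scale
  b <- best$coef[3, ] * scale
  K1 <- a + b
  k2 <- ifelse(K1 > 0, best$theta * b / K1, 0)
  VND <- ifelse(k2 > 0, K1 / k2, NA_real_)

  # voxel-wise Patlak on the same masked voxels
  pk <- .patlak_vox(Y, input, dyn$schedule, t_star)

  blank <- function() array(NA_real_, dim = d[1:3])
  fill <- function(v) { m <- blank(); m[sel] <- v; m }
  structure(list(K1 = fill(K1), Ki = fill(a), Vb = fill(vb), VND = fill(VND),
                 Ki_patlak = fill(pk$ki), Ve = fill(pk$ve),
                 rss = fill(best$rss), theta = fill(best$theta),
                 mask = mask, voxel_mm = dyn$voxel_mm,
                 vb_correction = vb_correction, t_star = t_star),
            class = "parametric_maps")
}

# Vectorized voxel-wise Patlak over a frames x nvox matrix. Internal.
.patlak_vox <- function(Y, input, schedule, t_star) {
  use <- which(schedule$mid >= t_star - 1e-9)
  if (length(use) < 3)
    stop("insufficient data: need >= 3 frames with mid-time >= t_star")
  mid <- schedule$mid[use]
  cp <- if_eval(input, mid)
  if (any(cp <= 0)) stop("Cp must be positive at all used frame mid-times")
  x <- if_integral(input, mid) / cp
  Yp <- Y[use, , drop = FALSE] / cp
  xc <- x - mean(x)
  ki <- as.vector(crossprod(xc, Yp)) / sum(xc * xc)
  ve <- colMeans(Yp) - ki * mean(x)
  list(ki = ki, ve = ve)
}

#' Voxel-wise Patlak maps
#'
#' Applies the Patlak graphical analysis (see [patlak_fit()]) independently to
#' every voxel inside the mask.
#'
#' @inheritParams parametric_maps
#' @return List of 3D maps `Ki`, `Ve` (NA outside the mask) plus `mask`.
#' @export
patlak_voxelwise <- function(dyn, input, t_star = 15, mask = NULL,
                             mask_frac = 0.01) {
  stopifnot(inherits(dyn, "dynamic_image"))
  d <- dim(dyn$data)
  M <- matrix(dyn$data, nrow = prod(d[1:3]), ncol = d[4])
  if (is.null(mask)) {
    ssum <- as.vector(M %*% dyn$schedule$duration)
    mask <- array(ssum > mask_frac * max(ssum), dim = d[1:3])
  }
  sel <- which(mask)
  Y <- t(M[sel, , drop = FALSE])
  pk <- .patlak_vox(Y, input, dyn$schedule, t_star)
  ki <- array(NA_real_, d[1:3]); ve <- array(NA_real_, d[1:3])
  ki[sel] <- pk$ki; ve[sel] <- pk$ve
  list(Ki = ki, Ve = ve, mask = mask)
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("Parametric maps (%d fitted voxels): K1, Ki, Vb, VND, Ki_patlak, Ve\n",
              sum(x$mask)))
  cat(sprintf("  median Ki = %.4g, median Patlak Ki = %.4g mL/cm^3/min (t* = %g min)\n",
              median(x$Ki[x$mask], na.rm = TRUE),
              median(x$Ki_patlak[x$mask], na.rm = TRUE), x$t_star))
  invisible(x)
}

#' Per-region statistics from parametric maps or a single map
#'
#' Transfers an integer label mask onto one or more 3D maps and tabulates
#' mean, median, max, sd and voxel count per label per map. Used for
#' VOI-versus-parametric agreement checks and tumour-to-normal ratios.
#'
#' @param maps a `parametric_maps` object, a named list of 3D arrays, or a
#'   single 3D array (reported as map `"value"`).
#' @param labels 3D integer label array (0 = background).
#' @param which optional character vector of map names to tabulate.
#' @return data.frame with columns `label`, `map`, `mean`, `median`, `max`,
#'   `sd`, `n`. Empty labels yield an NA row with a warning.
#' @export
extract_voi_values <- function(maps, labels, which = NULL) {
  if (inherits(maps, "parametric_maps"))
    maps <- maps[c("K1", "Ki", "Vb", "VND", "Ki_patlak", "Ve")]
  if (is.array(maps) && length(dim(maps)) == 3) maps <- list(value = maps)
  if (!is.list(maps) || is.null(names(maps))) stop("maps must be named 3D arrays")
  if (!is.null(which)) maps <- maps[which]
  geom <- dim(maps[[1]])
  if (!identical(dim(labels), geom)) stop("labels geometry must match maps")
  labs <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (lb in labs) {
    sel <- which(labels == lb)
    for (nm in names(maps)) {
      v <- maps[[nm]][sel]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        warning("label ", lb, " has no finite values in map ", nm)
        rows[[length(rows) + 1L]] <- data.frame(
          label = lb, map = nm, mean = NA_real_, median = NA_real_,
          max = NA_real_, sd = NA_real_, n = 0L, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          label = lb, map = nm, mean = mean(v), median = median(v),
          max = max(v), sd = if (length(v) > 1) sd(v) else 0, n = length(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
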
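#' Study metadata for SUV computation
#'
#' @param injected_bq injected activity in Bq, decay-corrected to injection.
#' @param weight_g body weight in grams.
#' @return An object of class `study_meta`.
#' @examples
#' study_meta(injected_bq = 241e6, weight_g = 70000)
#' @export
study_meta <- function(injected_bq, weight_g) {
  if (!is.finite(injected_bq) || injected_bq <= 0) stop("injected activity must be > 0 Bq")
  if (!is.finite(weight_g) || weight_g <= 0) stop("body weight must be > 0 g")
  structure(list(injected_bq = injected_bq, weight_g = weight_g),
            class = "study_meta")
}

#' Standardized uptake value
#'
#' `SUV = concentration (Bq/mL) x body weight (g) / injected activity (Bq)`.
#' Concentrations are given in kBq/mL (the package-wide unit) and converted
#' internally. SUV is invariant to the decay-correction convention as long as
#' the activity and the image share it.
#'
#' @param conc activity concentration(s) in kBq/mL: a scalar, vector or
#'   3D array.
#' @param meta a [study_meta()].
#' @return SUV value(s) with the same shape as `conc`.
#' @examples
#' meta <- study_meta(241e6, 70000)
#' compute_suv(241e6 / 70000 / 1000, meta)  # == 1
#' @export
compute_suv <- function(conc, meta) {
  stopifnot(inherits(meta, "study_meta"))
  conc * 1000 * meta$weight_g / meta$injected_bq
}

#' Image-derived input function from an aorta region
#'
#' Identifies the frame where the first pass of radioactivity peaks (maximal
#' within-label mean; ties broken toward the earlier frame), refines the VOI
#' to the labelled voxels at or above `threshold` times that frame's maximum
#' within the label (counteracting partial volume at the vessel edge), and
#' returns the refined-VOI mean TAC as an input function sampled at frame
#' mid-times. `threshold = 0` reproduces the plain label-mean TAC.
#'
#' @param dyn a [dynamic_image()].
#' @param labels 3D integer label array.
#' @param label the aorta label.
#' @param threshold fraction of the peak-frame label maximum (default 0.5).
#' @return An [input_function()]; the peak frame index is attached as
#'   attribute `"peak_frame"` and the refined voxel count as `"n_voxels"`.
#' @export
extract_idif <- function(dyn, labels, label, threshold = 0.5) {
  stopifnot(inherits(dyn, "dynamic_image"))
  d <- dim(dyn$data)
  if (!identical(dim(labels), d[1:3])) stop("labels geometry must match the image")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  sel <- which(labels == label)
  if (length(sel) == 0) stop("aorta label is empty")
  M <- matrix(dyn$data, nrow = prod(d[1:3]), ncol = d[4])[sel, , drop = FALSE]
  frame_means <- colMeans(M)
  peak <- which.max(frame_means)           # ties: earliest frame
  if (peak == d[4])
    warning("first-pass peak found in the last frame: suspicious timing")
  keep <- M[, peak] >= threshold * max(M[, peak])
  vals <- colMeans(M[keep, , drop = FALSE])
  out <- input_function(dyn$schedule$mid, pmax(vals, 0))
  attr(out, "peak_frame") <- peak
  attr(out, "n_voxels") <- sum(keep)
  out
}

#' Tumour-to-normal contrast ratio
#'
#' Ratio between a lesion statistic and the normal-tissue mean, per lesion and
#' per quantity (SUV, 2TC Ki, Patlak Ki, ...). `Tmax/Nmean` uses the lesion
#' maximum, `Tmean/Nmean` the lesion mean.
#'
#' @param lesion lesion statistics: a list/row with elements `mean` and `max`
#'   (e.g. one row of [extract_voi_values()]).
#' @param normal normal-tissue statistics with element `mean`.
#' @param mode `"Tmax/Nmean"` (default) or `"Tmean/Nmean"`.
#' @return The contrast ratio.
#' @export
tn_ratio <- function(lesion, normal, mode = c("Tmax/Nmean", "Tmean/Nmean")) {
  mode <- match.arg(mode)
  nmean <- normal$mean
  if (!is.finite(nmean) || nmean <= 0)
    stop("normal-tissue mean must be positive")
  num <- if (mode == "Tmax/Nmean") lesion$max else lesion$mean
  num / nmean
}

#' Calibrate a Ki cutoff against an SUV reference
#'
#' Ordinary least-squares regression `Ki = a * SUV + b` across lesions. The
#' point estimate of the Ki cutoff is the predicted Ki at `suv_ref`; its 95%
#' confidence interval is propagated from the coefficient standard errors
#' (by default including their covariance, which reduces to the
#' independent-SE formula when the covariance is negligible). The interval
#' is also mapped back through the fitted slope to an SUV interval.
#'
#' @param ki lesion Ki values (mL/cm^3/min).
#' @param suv paired lesion SUV values.
#' @param suv_ref reference SUV (default 6).
#' @param level confidence level (default 0.95).
#' @param use_cov include the slope-intercept covariance (default TRUE).
#' @return An object of class `cutoff_fit`: `slope`, `intercept`, `se_slope`,
#'   `se_intercept`, `cov_ab`, `ki_cutoff`, `ki_ci`, `suv_ci`, `r2`, `n`,
#'   `level`, `suv_ref`.
#' @examples
#' calibrate_cutoff(0.0025 * c(2, 4, 8, 12), c(2, 4, 8, 12))
#' @export
calibrate_cutoff <- function(ki, suv, suv_ref = 6, level = 0.95,
                             use_cov = TRUE) {
  ki <- as.numeric(ki); suv <- as.numeric(suv)
  if (length(ki) != length(suv) || length(ki) < 3)
    stop("need >= 3 paired (Ki, SUV) values")
  if (sd(suv) == 0) stop("degenerate design: SUV values have no spread")
  fit <- lm(ki ~ suv)
  cf <- coef(fit)
  V <- vcov(fit)                 # order: (Intercept), suv
  a <- unname(cf[2]); b <- unname(cf[1])
  var_pred <- V[1, 1] + suv_ref^2 * V[2, 2] +
    (if (use_cov) 2 * suv_ref * V[1, 2] else 0)
  se_pred <- sqrt(max(var_pred, 0))
  tcrit <- qt(1 - (1 - level) / 2, df = length(ki) - 2)
  ki_cut <- a * suv_ref + b
  ki_ci <- ki_cut + c(-1, 1) * tcrit * se_pred
  suv_ci <- if (a != 0) suv_ref + c(-1, 1) * tcrit * se_pred / abs(a)
            else c(NA_real_, NA_real_)
  ss_tot <- sum((ki - mean(ki))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(slope = a, intercept = b,
                 se_slope = sqrt(V[2, 2]), se_intercept = sqrt(V[1, 1]),
                 cov_ab = V[1, 2], ki_cutoff = ki_cut, ki_ci = ki_ci,
                 suv_ci = suv_ci, r2 = r2, n = length(ki), level = level,
                 suv_ref = suv_ref),
            class = "cutoff_fit")
}

#' @export
print.cutoff_fit <- function(x, ...) {
  cat(sprintf("Ki cutoff at SUV %.3g: %.4g mL/cm^3/min (%.0f%% CI %.4g-%.4g)\n",
              x$suv_ref, x$ki_cutoff, 100 * x$level, x$ki_ci[1], x$ki_ci[2]))
  cat(sprintf("  Ki = %.4g * SUV + %.4g (R^2 = %.3f, n = %d); SUV CI %.3g-%.3g\n",
              x$slope, x$intercept, x$r2, x$n, x$suv_ci[1], x$suv_ci[2]))
  invisible(x)
}
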
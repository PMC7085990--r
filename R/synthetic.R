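#' Parameters of the tri-exponential (Feng-type) input function
#'
#' Analytic arterial curve with a linear first-pass rise to a sharp peak
#' shortly after `t0` followed by a tri-exponential decay:
#' `Cp(t) = s * ((A1 (t - t0) - A2 - A3) e^{-l1 (t - t0)} +
#'  A2 e^{-l2 (t - t0)} + A3 e^{-l3 (t - t0)})` for `t > t0`, else 0.
#' Defaults are the field-standard parameter set (amplitudes in kBq/mL,
#' rates in 1/min), giving a peak of ~75 kBq/mL at ~0.75 min, consistent with
#' a ~240 MBq injection. `dose_scale` scales the whole curve linearly with
#' injected dose.
#'
#' @param A1 rise slope amplitude, kBq/mL/min.
#' @param A2,A3 tail amplitudes, kBq/mL.
#' @param l1,l2,l3 eigenvalues (decay rates), 1/min; `l3` is the slowest.
#' @param t0 appearance time, minutes.
#' @param dose_scale linear scale factor for injected dose.
#' @return List of class `feng_params`.
#' @export
feng_params <- function(A1 = 851.1, A2 = 21.88, A3 = 20.81,
                        l1 = 4.134, l2 = 0.1191, l3 = 0.01043,
                        t0 = 0.5, dose_scale = 1) {
  if (any(c(A1, A2, A3) <= 0)) stop("amplitudes must be positive")
  if (any(c(l1, l2, l3) <= 0)) stop("eigenvalues must be positive")
  if (t0 < 0) stop("appearance time must be >= 0")
  if (dose_scale <= 0) stop("dose_scale must be positive")
  if (!(l1 > l2 && l2 > l3)) stop("eigenvalues must satisfy l1 > l2 > l3")
  structure(list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3,
                 t0 = t0, dose_scale = dose_scale),
            class = "feng_params")
}

#' Evaluate the analytic Feng-type curve
#'
#' @param params a [feng_params()].
#' @param t times in minutes.
#' @return Concentrations in kBq/mL.
#' @export
feng_conc <- function(params, t) {
  stopifnot(inherits(params, "feng_params"))
  u <- t - params$t0
  out <- with(params, dose_scale * (
    (A1 * u - A2 - A3) * exp(-l1 * u) + A2 * exp(-l2 * u) + A3 * exp(-l3 * u)))
  out[u <= 0] <- 0
  pmax(out, 0)
}

#' Generate a model input function
#'
#' Samples the analytic Feng-type curve on a dense grid (fine over the first
#' pass, coarser later) and returns it as an [input_function()]. The peak must
#' occur within the first 2 minutes (first pass). When a schedule is supplied,
#' the exact frame averages are attached as attribute `"frame_averages"`.
#'
#' @param params a [feng_params()].
#' @param schedule optional [frame_schedule()] for frame averages.
#' @param t_max last sample time, minutes (default 240, covering late static
#'   imaging).
#' @return An [input_function()].
#' @examples
#' cp <- make_input_function()
#' max(cp$conc)
#' @export
make_input_function <- function(params = feng_params(), schedule = NULL,
                                t_max = 240) {
  stopifnot(inherits(params, "feng_params"))
  t <- unique(c(seq(0, min(3, t_max), by = 0.02),
                seq(3.1, min(50, t_max), by = 0.1),
                if (t_max > 50) seq(51, t_max, by = 1), t_max))
  t <- sort(t[t <= t_max])
  conc <- feng_conc(params, t)
  if (t[which.max(conc)] > 2)
    stop("non-physiologic input: first-pass peak later than 2 min")
  inp <- input_function(t, conc)
  if (!is.null(schedule))
    attr(inp, "frame_averages") <- frame_avg_conc(inp, schedule)
  inp
}

# Default lesion set: 12 spheres spanning the reported lesion ranges
# (K1 0.02-0.38 mL/cm^3/min, Ki 0.009-0.095 mL/cm^3/min), radii from
# sub-resolution (~4 mm) up to ~20 mm. k3 is derived from the target Ki via
# k3 = Ki k2 / (K1 - Ki). Internal.
.default_lesions <- function() {
  K1 <- c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.38, 0.22, 0.18, 0.12, 0.28)
  ki <- c(0.009, 0.015, 0.020, 0.025, 0.035, 0.045, 0.060, 0.095, 0.050, 0.030,
          0.012, 0.070)
  k2 <- c(0.45, 0.50, 0.40, 0.55, 0.50, 0.45, 0.60, 0.50, 0.35, 0.40, 0.55, 0.45)
  r_mm <- c(4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20)
  cx <- c(14, 24, 34, 14, 24, 34, 14, 24, 34, 14, 24, 34)
  cy <- c(14, 14, 14, 26, 26, 26, 38, 38, 38, 50, 50, 50)
  cz <- c(9, 16, 23, 23, 9, 16, 16, 23, 9, 9, 16, 21)
  data.frame(label = 3:14, cx = cx, cy = cy, cz = cz, r_mm = r_mm,
             K1 = K1, k2 = k2, k3 = ki * k2 / (K1 - ki), k4 = 0, vb = 0.05,
             ki = ki)
}

#' Phantom specification
#'
#' Describes a synthetic abdominal dynamic-PET study: grid geometry, a liver
#' block, an aorta cylinder (pure blood), spherical lesions with per-region
#' kinetic parameters, the input-function parameters, the noise level and the
#' seed. Defaults emulate the reported acquisition: 22-frame 45-min schedule,
#' liver with high delivery (K1 = 0.37 mL/cm^3/min) and low irreversible
#' binding (Ki = 0.015), lesions with lower K1 but Ki spanning HER2-negative
#' to strongly positive, and Gaussian noise with variance proportional to
#' C / frame duration.
#'
#' @param dim grid size in voxels (default 64 x 64 x 32).
#' @param voxel_mm voxel size in mm (default 3.9 x 3.9 x 3.27).
#' @param schedule a [frame_schedule()]; default [dynamic_schedule_45min()].
#' @param input_params a [feng_params()].
#' @param liver named list: box `x`, `y`, `z` (voxel index ranges) and
#'   `K1`, `k2`, `k3`, `k4`, `vb`.
#' @param aorta named list: `cx`, `cy` (voxel centre), `r_mm`, `z` range.
#' @param lesions data.frame with columns `label`, `cx`, `cy`, `cz`, `r_mm`,
#'   `K1`, `k2`, `k3`, `k4`, `vb`.
#' @param noise_scale noise magnitude `s` in the per-frame model
#'   `sd_i = s sqrt(C_i / dt_i)` (kBq/mL per sqrt(min^-1)); 0 = noise-free.
#'   Default 1.5, giving ~15% voxel CV in late liver frames.
#' @param meta a [study_meta()] for the static SUV volumes.
#' @param seed integer RNG seed.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 32), voxel_mm = c(3.9, 3.9, 3.27),
                         schedule = dynamic_schedule_45min(),
                         input_params = feng_params(),
                         liver = list(x = 6:44, y = 8:56, z = 5:28,
                                      K1 = 0.37, k2 = 0.5, k3 = 0.0211,
                                      k4 = 0, vb = 0.12),
                         aorta = list(cx = 54, cy = 32, r_mm = 10, z = 3:30),
                         lesions = .default_lesions(),
                         noise_scale = 1.5,
                         meta = study_meta(241e6, 70000),
                         seed = 1L) {
  if (length(dim) != 3 || any(dim < 8)) stop("dim must be 3 values >= 8")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  need <- c("label", "cx", "cy", "cz", "r_mm", "K1", "k2", "k3", "k4", "vb")
  if (!all(need %in% names(lesions))) stop("lesions table is missing columns")
  structure(list(dim = dim, voxel_mm = voxel_mm, schedule = schedule,
                 input_params = input_params, liver = liver, aorta = aorta,
                 lesions = lesions, noise_scale = noise_scale, meta = meta,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Voxel index sets for the phantom regions; errors if lesions leave the liver
# or overlap each other / the aorta. Internal.
.phantom_geometry <- function(spec) {
  d <- spec$dim; vx <- spec$voxel_mm
  labels <- array(0L, d)
  lv <- spec$liver
  labels[lv$x, lv$y, lv$z] <- 1L
  ax <- outer(seq_len(d[1]) - spec$aorta$cx, rep(1, d[2])) * vx[1]
  ay <- outer(rep(1, d[1]), seq_len(d[2]) - spec$aorta$cy) * vx[2]
  disc <- ax^2 + ay^2 <= spec$aorta$r_mm^2
  for (z in spec$aorta$z) {
    sl <- labels[, , z]
    if (any(sl[disc] != 0L)) stop("geometry error: aorta overlaps another region")
    sl[disc] <- 2L
    labels[, , z] <- sl
  }
  gx <- (seq_len(d[1])) ; gy <- seq_len(d[2]); gz <- seq_len(d[3])
  for (i in seq_len(nrow(spec$lesions))) {
    L <- spec$lesions[i, ]
    dx2 <- ((gx - L$cx) * vx[1])^2
    dy2 <- ((gy - L$cy) * vx[2])^2
    dz2 <- ((gz - L$cz) * vx[3])^2
    sph <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= L$r_mm^2
    if (any(labels[sph] != 1L))
      stop("geometry error: lesion ", L$label,
           " overlaps the aorta, another lesion, or leaves the liver")
    labels[sph] <- as.integer(L$label)
  }
  labels
}

# Region parameter table (background excluded). Internal.
.region_params <- function(spec) {
  lv <- spec$liver
  rbind(
    data.frame(label = 1L, region = "liver", K1 = lv$K1, k2 = lv$k2,
               k3 = lv$k3, k4 = lv$k4, vb = lv$vb, stringsAsFactors = FALSE),
    data.frame(label = 2L, region = "aorta", K1 = 0, k2 = 0, k3 = 0, k4 = 0,
               vb = 1 - 1e-6, stringsAsFactors = FALSE),
    data.frame(label = spec$lesions$label,
               region = paste0("lesion_", spec$lesions$label,
                               recycle0 = TRUE),
               K1 = spec$lesions$K1, k2 = spec$lesions$k2,
               k3 = spec$lesions$k3, k4 = spec$lesions$k4,
               vb = spec$lesions$vb, stringsAsFactors = FALSE)
  )
}

#' Build a synthetic dynamic-PET phantom
#'
#' Generates a 4D dynamic study with known ground truth: per-region
#' time-activity curves from the forward compartment model (liver, aorta as
#' pure blood, spherical lesions), frame-duration-dependent Gaussian noise
#' (`sd_i = noise_scale * sqrt(C_i / dt_i)`, independently per voxel, seeded),
#' static images at 120 and 240 min converted to SUV, label masks, and
#' ground-truth parameter maps. All concentrations are generated
#' decay-corrected (as reconstructed images are), so no isotope half-life
#' enters the forward model.
#'
#' @param spec a [phantom_spec()].
#' @return List of class `pet_phantom`: `dynamic` ([dynamic_image()]),
#'   `labels` (3D integer array: 0 background, 1 liver, 2 aorta, 3+ lesions),
#'   `input` (ground-truth [input_function()]), `truth` (list: `params`
#'   region table incl. Ki where defined, and maps `K1`, `Ki`, `Vb`, `VND`),
#'   `static` (list `suv_120`, `suv_240` of 3D SUV arrays), `meta`, `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(dim = c(16, 16, 8),
#'   liver = list(x = 2:12, y = 2:14, z = 2:7,
#'                K1 = 0.37, k2 = 0.5, k3 = 0.0211, k4 = 0, vb = 0.12),
#'   aorta = list(cx = 14, cy = 8, r_mm = 4, z = 2:7),
#'   lesions = data.frame(label = 3, cx = 7, cy = 8, cz = 4, r_mm = 8,
#'                        K1 = 0.2, k2 = 0.5, k3 = 0.07, k4 = 0, vb = 0.05),
#'   noise_scale = 0))
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- .phantom_geometry(spec)
  regions <- .region_params(spec)
  input <- make_input_function(spec$input_params)
  sched <- spec$schedule
  ctx <- .model_ctx(input, input, sched)

  d <- spec$dim
  nvox <- prod(d)
  M <- matrix(0, nvox, sched$n)
  truth <- list(K1 = array(0, d), Ki = array(0, d), Vb = array(0, d),
                VND = array(NA_real_, d))
  regions$ki <- NA_real_
  static_t <- c(120, 240)
  static_conc <- matrix(0, nvox, 2)

  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sel <- which(labels == r$label)
    if (length(sel) == 0) next
    p <- kinetic_params(r$K1, r$k2, r$k3, r$k4, r$vb)
    model <- if (r$k4 > 0) "2TC-4k" else "2TC-3k"
    tac <- model_tac(p, model, input, sched, ctx = ctx)
    M[sel, ] <- matrix(tac$values, length(sel), sched$n, byrow = TRUE)
    if (r$k2 + r$k3 > 0) regions$ki[i] <- net_influx(p)
    truth$K1[sel] <- r$K1
    truth$Ki[sel] <- if (is.na(regions$ki[i])) 0 else regions$ki[i]
    truth$Vb[sel] <- r$vb
    truth$VND[sel] <- if (r$k2 > 0) r$K1 / r$k2 else NA_real_
    static_conc[sel, ] <- matrix(
      .instant_conc(p, model, input, static_t), length(sel), 2, byrow = TRUE)
  }

  if (spec$noise_scale > 0) {
    set.seed(spec$seed)
    sdm <- spec$noise_scale *
      sqrt(pmax(M, 0) / matrix(sched$duration, nvox, sched$n, byrow = TRUE))
    M <- M + matrix(rnorm(length(M)), nvox, sched$n) * sdm
  }

  dyn <- dynamic_image(array(M, c(d, sched$n)), sched, spec$voxel_mm)
  suv <- lapply(1:2, function(j)
    array(compute_suv(static_conc[, j], spec$meta), d))
  structure(list(dynamic = dyn, labels = labels, input = input,
                 truth = list(params = regions, K1 = truth$K1, Ki = truth$Ki,
                              Vb = truth$Vb, VND = truth$VND),
                 static = list(suv_120 = suv[[1]], suv_240 = suv[[2]]),
                 meta = spec$meta, spec = spec),
            class = "pet_phantom")
}

# Instantaneous measured concentration (1 - vb) C_T(t) + vb Cb(t) at given
# times, for the late static volumes. Internal.
.instant_conc <- function(params, model, input, times) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  eps <- 1e-12
  ct <- if (model == "1TC") {
    K1 * convolve_exp(k2, input, times)
  } else if (k4 < eps) {
    th <- k2 + k3
    if (th < eps) K1 * if_integral(input, times)
    else K1 * (k3 / th * if_integral(input, times) +
               k2 / th * convolve_exp(th, input, times))
  } else {
    s <- k2 + k3 + k4
    rt <- sqrt(max(s * s - 4 * k2 * k4, 0))
    a1 <- (s - rt) / 2; a2 <- (s + rt) / 2
    w1 <- (k3 + k4 - a1) / (a2 - a1); w2 <- (a2 - k3 - k4) / (a2 - a1)
    A1 <- if (a1 < eps) if_integral(input, times) else convolve_exp(a1, input, times)
    K1 * (w1 * A1 + w2 * convolve_exp(a2, input, times))
  }
  (1 - params$vb) * ct + params$vb * if_eval(input, times)
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf("PET phantom: %s, %d lesions, noise_scale = %g, seed = %d\n",
              paste(x$spec$dim, collapse = " x "),
              nrow(x$spec$lesions), x$spec$noise_scale, x$spec$seed))
  invisible(x)
}

#' Generate a test-retest pair of phantom studies
#'
#' Regenerates the phantom twice with each lesion's net influx rate jittered
#' by an independent lognormal factor (`Ki -> Ki exp(N(0, wcv))`, implemented
#' by re-deriving k3 so K1 and k2 are untouched) and independent noise seeds.
#' `wcv = 0` with `noise_scale = 0` reproduces identical studies. Liver and
#' aorta are never jittered.
#'
#' @param spec a [phantom_spec()].
#' @param wcv within-subject coefficient of variation of lesion Ki, as a
#'   fraction (e.g. 0.108 for 10.8%).
#' @param seeds length-2 integer seeds for the two visits.
#' @return List with elements `test`, `retest` (both `pet_phantom`) and
#'   `truth_ki` (data.frame of per-lesion true Ki at each visit).
#' @export
make_test_retest <- function(spec, wcv, seeds = spec$seed + c(0L, 1000L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (wcv < 0) stop("wcv must be >= 0")
  visits <- vector("list", 2)
  ki0 <- spec$lesions$K1 * spec$lesions$k3 / (spec$lesions$k2 + spec$lesions$k3)
  truth <- data.frame(label = spec$lesions$label)
  for (v in 1:2) {
    sp <- spec
    sp$seed <- as.integer(seeds[v])
    if (wcv > 0) {
      set.seed(sp$seed + 500000L)
      ki_v <- pmin(ki0 * exp(rnorm(length(ki0), 0, wcv)),
                   0.95 * spec$lesions$K1)
      sp$lesions$k3 <- ki_v * sp$lesions$k2 / (sp$lesions$K1 - ki_v)
    }
    truth[[c("ki_test", "ki_retest")[v]]] <-
      sp$lesions$K1 * sp$lesions$k3 / (sp$lesions$k2 + sp$lesions$k3)
    visits[[v]] <- make_phantom(sp)
  }
  list(test = visits[[1]], retest = visits[[2]], truth_ki = truth)
}

#' Simulate test-retest measurement pairs
#'
#' Lightweight generator for repeatability statistics: per-lesion true values
#' are drawn lognormally around `location` with between-lesion spread
#' `between_cv`, and each visit measures the truth times an independent
#' lognormal factor `exp(N(0, wcv))`.
#'
#' @param n number of pairs.
#' @param wcv within-subject coefficient of variation (fraction).
#' @param location typical measurement magnitude (default 0.025, a lesion Ki).
#' @param between_cv between-lesion spread (fraction, default 0.5).
#' @param seed integer RNG seed.
#' @return data.frame with columns `truth`, `test`, `retest`.
#' @export
simulate_retest_pairs <- function(n, wcv, location = 0.025, between_cv = 0.5,
                                  seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (wcv < 0 || between_cv < 0) stop("CVs must be >= 0")
  set.seed(seed)
  truth <- location * exp(rnorm(n, 0, between_cv))
  data.frame(truth = truth,
             test = truth * exp(rnorm(n, 0, wcv)),
             retest = truth * exp(rnorm(n, 0, wcv)))
}
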
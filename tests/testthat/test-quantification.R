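test_that("the image-derived input function recovers the painted aorta curve", {
  ph <- make_phantom(small_spec(noise_scale = 0))
  idif <- extract_idif(ph$dynamic, ph$labels, 2L)
  # noise-free: recovered frame values within 1% of the true frame averages
  truth <- frame_avg_conc(ph$input, ph$dynamic$schedule)
  got <- if_eval(idif, ph$dynamic$schedule$mid)
  expect_lt(max(abs(got - truth) / pmax(truth, 1e-9)), 0.01)
  # the first-pass peak is early
  expect_lt(attr(idif, "peak_frame"), 10)

  # threshold = 0 reproduces the plain label-mean TAC
  idif0 <- extract_idif(ph$dynamic, ph$labels, 2L, threshold = 0)
  lm_tac <- voi_tac(ph$dynamic, ph$labels, 2L)
  expect_equal(idif0$conc[-1], pmax(lm_tac$values, 0), tolerance = 1e-12)
})

test_that("IDIF peak handling: earliest tie wins, late peak warns, scaling is neutral", {
  fs <- frame_schedule(c(0, 1, 2, 3), rep(1, 4))
  mk <- function(vals) {
    a <- array(0, dim = c(2, 2, 1, 4))
    for (f in 1:4) a[, , 1, f] <- vals[f]
    dynamic_image(a, fs, c(1, 1, 1))
  }
  labels <- array(1L, dim = c(2, 2, 1))
  tie <- mk(c(1, 5, 5, 2))
  expect_equal(attr(extract_idif(tie, labels, 1L), "peak_frame"), 2)
  expect_warning(extract_idif(mk(c(1, 2, 3, 9)), labels, 1L), "suspicious")
  # peak frame index invariant to amplitude scaling
  big <- mk(10 * c(1, 5, 5, 2))
  expect_equal(attr(extract_idif(big, labels, 1L), "peak_frame"), 2)
})

test_that("SUV is definitional and unit-consistent", {
  meta <- study_meta(injected_bq = 241e6, weight_g = 70000)
  # conc = injected / weight (Bq/mL) -> SUV = 1 (conc is in kBq/mL here)
  expect_equal(compute_suv(241e6 / 70000 / 1000, meta), 1)
  expect_equal(compute_suv(0, meta), 0)
  # painted SUV 10 round-trips through its concentration
  conc_kbq <- 10 * 241e6 / 70000 / 1000
  expect_equal(compute_suv(conc_kbq, meta), 10)
  # invariant to a shared decay-correction factor on image and activity
  f <- 1.37
  meta2 <- study_meta(241e6 * f, 70000)
  expect_equal(compute_suv(conc_kbq * f, meta2), 10)
  # arrays keep their shape
  a <- array(conc_kbq, dim = c(2, 3, 4))
  expect_equal(dim(compute_suv(a, meta)), c(2, 3, 4))
  expect_error(study_meta(0, 70000), "> 0")
})

test_that("T/N ratios cover both modes and reject a zero background", {
  lesion <- list(mean = 0.05, max = 0.08)
  normal <- list(mean = 0.01)
  expect_equal(tn_ratio(lesion, normal), 8)
  expect_equal(tn_ratio(lesion, normal, mode = "Tmean/Nmean"), 5)
  expect_equal(tn_ratio(list(mean = 0.01, max = 0.01), normal), 1)
  expect_error(tn_ratio(lesion, list(mean = 0)), "positive")
})

test_that("cutoff calibration is exact on an exact line", {
  suv <- c(2, 4, 8, 12, 16)
  cc <- calibrate_cutoff(0.0025 * suv, suv, suv_ref = 6)
  expect_equal(cc$ki_cutoff, 0.015, tolerance = 1e-12)
  expect_equal(diff(cc$ki_ci), 0, tolerance = 1e-10)
  expect_equal(cc$slope, 0.0025, tolerance = 1e-12)
  expect_true(cc$ki_ci[1] <= cc$ki_cutoff && cc$ki_cutoff <= cc$ki_ci[2])
  expect_error(calibrate_cutoff(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("cutoff CI width shrinks like 1/sqrt(n)", {
  a <- 0.0025; sigma <- 0.004
  ns <- c(12, 24, 48, 96, 192)
  set.seed(33)
  widths <- vapply(ns, function(n) {
    mean(vapply(1:40, function(r) {
      suv <- runif(n, 2, 20)
      ki <- a * suv + rnorm(n, 0, sigma)
      diff(calibrate_cutoff(ki, suv)$ki_ci)
    }, numeric(1)))
  }, numeric(1))
  slope <- unname(coef(lm(log(widths) ~ log(ns)))[2])
  expect_equal(slope, -0.5, tolerance = 0.1)
})

test_that("removing the max-leverage point shifts the cutoff by a finite delta", {
  set.seed(8)
  suv <- c(runif(23, 2, 12), 30)          # one high-leverage lesion
  ki <- 0.0025 * suv + rnorm(24, 0, 0.004)
  full <- calibrate_cutoff(ki, suv)$ki_cutoff
  drop <- which.max(abs(suv - mean(suv)))
  red <- calibrate_cutoff(ki[-drop], suv[-drop])$ki_cutoff
  expect_true(is.finite(full - red))
  expect_gt(abs(full - red), 0)
})
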
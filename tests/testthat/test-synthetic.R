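test_that("the model input function is physiologic and dose-linear", {
  cp <- make_input_function()
  expect_equal(cp$conc[1], 0)
  # finite positive integral over the 45-min scan
  I45 <- if_integral(cp, 45)
  expect_true(is.finite(I45) && I45 > 0)
  # peak within the first 2 minutes
  expect_lt(cp$times[which.max(cp$conc)], 2)
  # peak amplitude scales linearly with injected dose
  cp2 <- make_input_function(feng_params(dose_scale = 2))
  expect_equal(max(cp2$conc), 2 * max(cp$conc), tolerance = 1e-12)
  # non-physiologic parameters are rejected
  expect_error(feng_params(A1 = -1), "positive")
  expect_error(make_input_function(feng_params(t0 = 3)), "first-pass peak")
})

test_that("the input tail approaches the slowest eigenvalue asymptotically", {
  p <- feng_params()
  # numerical log-slope of the analytic curve (independent finite-difference
  # oracle); at 80 min the two faster terms have decayed to < 0.05%
  ls_num <- function(t, h = 0.01)
    -(log(feng_conc(p, t + h)) - log(feng_conc(p, t - h))) / (2 * h)
  expect_equal(ls_num(80), p$l3, tolerance = 0.02)
  # at 40 min the exact mixture slope still exceeds l3 (analytic oracle)
  u <- 40 - p$t0
  num <- p$l2 * p$A2 * exp(-p$l2 * u) + p$l3 * p$A3 * exp(-p$l3 * u) +
    p$l1 * (p$A1 * u - p$A2 - p$A3) * exp(-p$l1 * u) -
    p$A1 * exp(-p$l1 * u)
  den <- (p$A1 * u - p$A2 - p$A3) * exp(-p$l1 * u) +
    p$A2 * exp(-p$l2 * u) + p$A3 * exp(-p$l3 * u)
  expect_equal(ls_num(40), num / den, tolerance = 1e-4)
  expect_gt(num / den, p$l3)
})

test_that("noise-free phantoms reproduce the forward model exactly", {
  ph <- make_phantom(small_spec(noise_scale = 0))
  fs <- ph$dynamic$schedule
  liver_tac <- voi_tac(ph$dynamic, ph$labels, 1L)
  expected <- model_tac(kinetic_params(0.37, 0.5, 0.0211, 0, 0.12), "2TC-3k",
                        ph$input, fs)
  expect_equal(liver_tac$values, expected$values, tolerance = 1e-12)
  # static SUV images are consistent with the metadata
  expect_true(all(is.finite(ph$static$suv_120)))
  expect_gt(max(ph$static$suv_120), 0)
})

test_that("phantoms are bit-identical under the same seed", {
  p1 <- make_phantom(small_spec(noise_scale = 1.5, seed = 12))
  p2 <- make_phantom(small_spec(noise_scale = 1.5, seed = 12))
  expect_identical(p1$dynamic$data, p2$dynamic$data)
  p3 <- make_phantom(small_spec(noise_scale = 1.5, seed = 13))
  expect_false(identical(p1$dynamic$data, p3$dynamic$data))
})

test_that("a trapping-free lesion is a cold spot in the truth K1 map", {
  les <- data.frame(label = 3, cx = 7, cy = 8, cz = 4, r_mm = 8,
                    K1 = 0.1, k2 = 0.5, k3 = 0, k4 = 0, vb = 0.05)
  ph <- make_phantom(small_spec(noise_scale = 0, lesions = les))
  lesion <- ph$labels == 3
  liver <- ph$labels == 1
  expect_lt(max(ph$truth$K1[lesion]), min(ph$truth$K1[liver]))
  expect_equal(max(ph$truth$Ki[lesion]), 0)
})

test_that("overlapping phantom regions are rejected", {
  les <- data.frame(label = 3, cx = 14, cy = 8, cz = 4, r_mm = 8,
                    K1 = 0.2, k2 = 0.5, k3 = 0.07, k4 = 0, vb = 0.05)
  expect_error(make_phantom(small_spec(lesions = les)), "geometry error")
})

test_that("the noise model follows the C / duration variance law", {
  # one large homogeneous region supplies ~4400 replicate voxel draws per
  # frame, so the empirical variance has ~2% relative standard error
  sp <- phantom_spec(
    dim = c(24, 24, 12),
    liver = list(x = 2:22, y = 2:22, z = 2:11,
                 K1 = 0.37, k2 = 0.5, k3 = 0.0211, k4 = 0, vb = 0.12),
    aorta = list(cx = 24, cy = 24, r_mm = 3, z = 2:11),
    lesions = data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
                         cz = numeric(0), r_mm = numeric(0), K1 = numeric(0),
                         k2 = numeric(0), k3 = numeric(0), k4 = numeric(0),
                         vb = numeric(0)),
    noise_scale = 1.5, seed = 2L)
  ph <- make_phantom(sp)
  fs <- ph$dynamic$schedule
  liver <- which(ph$labels == 1L)
  M <- matrix(ph$dynamic$data, ncol = fs$n)[liver, ]
  truth <- model_tac(kinetic_params(0.37, 0.5, 0.0211, 0, 0.12), "2TC-3k",
                     ph$input, fs)$values
  emp_var <- apply(M, 2, var)
  expected <- 1.5^2 * truth / fs$duration
  late <- which(truth > 1)   # skip near-zero early frames
  expect_lt(max(abs(emp_var[late] - expected[late]) / expected[late]), 0.10)
})

test_that("test-retest generation isolates the lesion jitter", {
  sp <- small_spec(noise_scale = 0)
  tr0 <- make_test_retest(sp, wcv = 0)
  expect_identical(tr0$test$dynamic$data, tr0$retest$dynamic$data)

  tr <- make_test_retest(sp, wcv = 0.108)
  # liver TAC untouched by the jitter
  lt <- voi_tac(tr$test$dynamic, tr$test$labels, 1L)$values
  lr <- voi_tac(tr$retest$dynamic, tr$retest$labels, 1L)$values
  expect_equal(lt, lr, tolerance = 1e-12)
  # lesion TACs differ between visits, and the truth table records both Ki
  et <- voi_tac(tr$test$dynamic, tr$test$labels, 3L)$values
  er <- voi_tac(tr$retest$dynamic, tr$retest$labels, 3L)$values
  expect_false(isTRUE(all.equal(et, er)))
  expect_true(all(c("ki_test", "ki_retest") %in% names(tr$truth_ki)))
  expect_false(tr$truth_ki$ki_test == tr$truth_ki$ki_retest)
})

test_that("simulated retest pairs are reproducible and positive", {
  p1 <- simulate_retest_pairs(50, 0.1, seed = 5)
  p2 <- simulate_retest_pairs(50, 0.1, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$test > 0) && all(p1$retest > 0))
})
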
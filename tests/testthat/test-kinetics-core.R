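test_that("frame schedules validate timing and derive mid/end times", {
  fs <- frame_schedule(c(0, 1, 2.5), c(1, 1, 0.5))
  expect_equal(fs$mid, c(0.5, 1.5, 2.75))
  expect_equal(fs$end, c(1, 2, 3))
  expect_equal(schedule_span(fs), 3)
  expect_error(frame_schedule(c(0, 1), c(1.5, 1)), "overlap")
  expect_error(frame_schedule(c(0, 1), c(1, 0)), "positive")
  expect_error(frame_schedule(c(1, 0), c(0.5, 0.5)), "ascending")
})

test_that("input functions enforce C(0) = 0 and non-negativity", {
  cp <- input_function(c(1, 2), c(10, 5))
  expect_equal(cp$times[1], 0)
  expect_equal(cp$conc[1], 0)
  expect_error(input_function(c(0, 1), c(5, 10)), "time zero")
  expect_error(input_function(c(0, 1), c(0, -1)), ">= 0")
  # running integral is non-decreasing and 0 at t = 0
  tt <- seq(0, 3, by = 0.1)
  I <- if_integral(cp, tt)
  expect_equal(I[1], 0)
  expect_true(all(diff(I) >= 0))
})

test_that("convolve_exp matches closed forms and a dense trapezoidal oracle", {
  # theta = 0 degenerates to the running integral
  cp <- std_input()
  tt <- c(0.5, 1, 5, 15, 45)
  expect_equal(convolve_exp(0, cp, tt), if_integral(cp, tt), tolerance = 1e-12)

  # zero input -> all zeros
  z <- input_function(c(0, 45), c(0, 0))
  expect_equal(convolve_exp(1, z, tt), rep(0, 5))

  # unit step at t = 0: conv = (1 - exp(-t)) / theta with theta = 1
  us <- input_function(c(0, 1e-9, 100), c(0, 1, 1))
  expect_equal(convolve_exp(1, us, tt), 1 - exp(-tt), tolerance = 1e-8)

  # dense trapezoidal numerical convolution oracle, smooth input, <= 0.1%
  theta <- 0.3
  eval_t <- seq(2, 45, by = 1)
  y <- convolve_exp(theta, cp, eval_t)
  g <- seq(0, 45, by = 0.001)
  cg <- if_eval(cp, g)
  num <- vapply(eval_t, function(t) {
    s <- g[g <= t]
    f <- exp(-theta * (t - s)) * cg[g <= t]
    sum((f[-1] + f[-length(f)]) / 2 * diff(s))
  }, numeric(1))
  expect_lt(max(abs(y - num) / num), 1e-3)

  expect_error(convolve_exp(-0.1, cp, tt), "non-negative")
})

test_that("compartment models nest exactly and respect the blood-volume term", {
  cp <- std_input(); fs <- std_schedule()
  set.seed(7)
  for (i in 1:20) {
    K1 <- runif(1, 0.05, 1); k2 <- runif(1, 0.01, 1)
    k3 <- runif(1, 0.01, 1); vb <- runif(1, 0, 0.3)
    t3 <- model_tac(kinetic_params(K1, k2, k3, 0, vb), "2TC-3k", cp, fs)$values
    t4 <- model_tac(kinetic_params(K1, k2, k3, 0, vb), "2TC-4k", cp, fs)$values
    t1 <- model_tac(kinetic_params(K1, k2, 0, 0, vb), "1TC", cp, fs)$values
    t30 <- model_tac(kinetic_params(K1, k2, 0, 0, vb), "2TC-3k", cp, fs)$values
    expect_lt(rel_dev(t4, t3), 1e-10)
    expect_lt(rel_dev(t30, t1), 1e-10)
  }
  # K1 = 0: measured signal is exactly vb * frame-averaged blood
  vb <- 0.05
  t0 <- model_tac(kinetic_params(0, 0, 0, 0, vb), "2TC-3k", cp, fs)$values
  expect_equal(t0, vb * frame_avg_conc(cp, fs), tolerance = 1e-12)
})

test_that("frame averages lie within the instantaneous curve's range per frame", {
  cp <- std_input(); fs <- std_schedule()
  p <- lesion_params()
  tac <- model_tac(p, "2TC-3k", cp, fs)
  th <- p$k2 + p$k3
  inst <- function(t)
    (1 - p$vb) * p$K1 * (p$k3 / th * if_integral(cp, t) +
                         p$k2 / th * convolve_exp(th, cp, t)) +
      p$vb * if_eval(cp, t)
  for (i in seq_len(fs$n)) {
    tt <- seq(fs$start[i], fs$end[i], length.out = 25)
    v <- inst(tt)
    expect_gte(tac$values[i], min(v) - 1e-9)
    expect_lte(tac$values[i], max(v) + 1e-9)
  }
})

test_that("net influx follows Ki = K1 k3 / (k2 + k3) with its limits", {
  expect_equal(net_influx(kinetic_params(0.2, 0.2, 0.2)), 0.1)
  expect_equal(net_influx(kinetic_params(0.2, 0.5, 0)), 0)
  expect_equal(net_influx(kinetic_params(0.2, 0, 0.3)), 0.2)  # trapping limit
  expect_error(net_influx(kinetic_params(0.2, 0, 0)), "undefined")
  # Ki <= K1 always; Ki strictly increasing in k3
  set.seed(11)
  for (i in 1:25) {
    K1 <- runif(1, 0.01, 2); k2 <- runif(1, 0.01, 2); k3 <- runif(1, 0.01, 2)
    ki <- net_influx(kinetic_params(K1, k2, k3))
    expect_lte(ki, K1)
    expect_gt(net_influx(kinetic_params(K1, k2, k3 * 1.1)), ki)
  }
})

test_that("late Patlak-transformed slope of the forward model equals Ki", {
  # independent oracle for the forward model: for irreversible kinetics the
  # normalized late-time slope must be the net influx rate
  cp <- std_input(); fs <- std_schedule()
  p <- lesion_params(vb = 0)
  tac <- model_tac(p, "2TC-3k", cp, fs, vb_scale = FALSE)
  use <- 18:22
  cpv <- if_eval(cp, fs$mid[use])
  x <- if_integral(cp, fs$mid[use]) / cpv
  y <- tac$values[use] / cpv
  slope <- unname(coef(lm(y ~ x))[2])
  expect_equal(slope, net_influx(p), tolerance = 0.02)
})
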
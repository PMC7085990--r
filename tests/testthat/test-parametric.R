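test_that("basis columns have the right asymptotics", {
  cp <- std_input(); fs <- std_schedule()
  grid <- c(default_theta_grid(n = 16), 20)
  bs <- make_basis(cp, fs, grid)
  # quasi-steady limit: B_theta -> Cp / theta for theta >> input decay rate
  fa <- frame_avg_conc(cp, fs)
  late <- 15:22
  expect_lt(rel_dev(bs$B[late, length(grid)], fa[late] / 20), 0.01)
  # small-theta limit: B_theta -> int Cp for t << 1/theta
  early <- 1:9
  expect_lt(max(abs(bs$B[early, 1] - bs$int_avg[early]) /
                pmax(bs$int_avg[early], 1e-12)), 0.01)
  # zero input -> all basis columns zero
  z <- input_function(c(0, 45), c(0, 0))
  bz <- make_basis(z, fs, default_theta_grid(n = 8))
  expect_true(all(bz$B == 0) && all(bz$cb_avg == 0) && all(bz$int_avg == 0))
  expect_error(make_basis(cp, fs, numeric(0)), "non-empty")
})

test_that("single-voxel basis fits recover on-grid parameters exactly", {
  cp <- std_input(); fs <- std_schedule()
  grid <- default_theta_grid()
  bs <- make_basis(cp, fs, grid)
  th <- grid[25]
  p <- kinetic_params(0.3, th * 0.6, th * 0.4, vb = 0.1)
  tac <- model_tac(p, "2TC-3k", cp, fs, vb_scale = FALSE)
  vf <- fit_voxel_basis(tac$values, bs)
  expect_equal(vf$theta, th)
  expect_equal(vf$params$K1, p$K1, tolerance = 1e-8)
  expect_equal(vf$params$vb, p$vb, tolerance = 1e-8)
  expect_equal(vf$ki, net_influx(p), tolerance = 1e-8)
  # argmin property holds exactly over the grid
  expect_true(all(vf$rss_by_theta >= vf$rss - 1e-12))
  # (1 - Vb)-corrected fit recovers the scaled-convention voxel
  tac2 <- model_tac(p, "2TC-3k", cp, fs)
  vf2 <- fit_voxel_basis(tac2$values, bs, vb_correction = TRUE)
  expect_equal(vf2$params$K1, p$K1, tolerance = 1e-6)
})

test_that("pure trapping yields k2 = 0 and Ki = K1", {
  cp <- std_input(); fs <- std_schedule()
  bs <- make_basis(cp, fs)
  p <- kinetic_params(0.25, 0, 0.1, vb = 0.05)
  tac <- model_tac(p, "2TC-3k", cp, fs, vb_scale = FALSE)
  vf <- fit_voxel_basis(tac$values, bs)
  expect_equal(vf$params$k2, 0)
  expect_equal(vf$ki, vf$params$K1, tolerance = 1e-8)
  expect_equal(vf$ki, 0.25, tolerance = 1e-6)
})

test_that("parametric maps agree with VOI-level analyses on a phantom", {
  ph <- make_phantom(small_spec(noise_scale = 0))
  dyn <- ph$dynamic
  maps <- parametric_maps(dyn, ph$input, t_star = 15)

  # homogeneity: every voxel of a region has the same TAC, so maps are
  # constant there and the Patlak map equals the VOI Patlak fit
  lesion <- which(ph$labels == 3)
  expect_lt(diff(range(maps$Ki_patlak[lesion])), 1e-9)
  voi_pat <- patlak_fit(voi_tac(dyn, ph$labels, 3), ph$input, 15)
  expect_equal(mean(maps$Ki_patlak[lesion]), voi_pat$ki, tolerance = 0.03)
  expect_equal(mean(maps$Ve[lesion]), voi_pat$ve, tolerance = 0.03)

  # voxel-wise maps respect Ki <= K1 and the Vb bounds
  m <- maps$mask
  expect_true(all(maps$Ki[m] <= maps$K1[m] + 1e-12))
  expect_true(all(maps$Vb[m] >= 0 & maps$Vb[m] < 1))

  # patlak_voxelwise agrees with the maps bundle
  pv <- patlak_voxelwise(dyn, ph$input, t_star = 15, mask = maps$mask)
  expect_equal(pv$Ki[lesion], maps$Ki_patlak[lesion], tolerance = 1e-12)
})

test_that("a reversible liver background depresses Patlak Ki below basis Ki", {
  ph <- make_phantom(small_spec(noise_scale = 0, liver_k4 = 0.01))
  maps <- parametric_maps(ph$dynamic, ph$input, t_star = 15)
  liver <- which(ph$labels == 1)
  expect_lt(median(maps$Ki_patlak[liver]), median(maps$Ki[liver]))
})

test_that("parametric maps are deterministic for a fixed phantom seed", {
  m1 <- parametric_maps(make_phantom(small_spec(noise_scale = 1.5, seed = 4))$dynamic,
                        std_input())
  m2 <- parametric_maps(make_phantom(small_spec(noise_scale = 1.5, seed = 4))$dynamic,
                        std_input())
  expect_identical(m1$Ki, m2$Ki)
  expect_identical(m1$K1, m2$K1)
})

test_that("VOI statistics honour partitions, single voxels, and empty labels", {
  x <- array(seq_len(4 * 4 * 2), dim = c(4, 4, 2))
  labels <- array(1L, dim = c(4, 4, 2))
  labels[1:2, , ] <- 2L
  tab <- extract_voi_values(x, labels)
  # partition identity: count-weighted label means reproduce the global mean
  expect_equal(sum(tab$mean * tab$n) / sum(tab$n), mean(x))

  labels2 <- array(0L, dim = c(4, 4, 2))
  labels2[3, 2, 1] <- 7L
  tab2 <- extract_voi_values(x, labels2)
  expect_equal(tab2$mean, x[3, 2, 1])
  expect_equal(tab2$max, x[3, 2, 1])
  expect_equal(tab2$sd, 0)

  xna <- x; xna[labels2 == 7L] <- NA_real_
  expect_warning(tab3 <- extract_voi_values(xna, labels2), "no finite values")
  expect_true(is.na(tab3$mean))
})
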
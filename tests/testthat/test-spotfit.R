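test_that("crop_region centres, clamps at borders and rejects small images", {
  img <- fluor_image(matrix(0, 400, 400))
  reg <- crop_region(img, c(200, 200), 200)
  expect_equal(reg$origin, c(100, 100))
  expect_equal(dim(reg$pixels), c(200L, 200L))
  # near the corner the window shifts inward
  expect_equal(crop_region(img, c(10, 10), 200)$origin, c(1, 1))
  expect_equal(crop_region(img, c(395, 395), 200)$origin, c(201, 201))
  expect_error(crop_region(matrix(0, 150, 150), c(75, 75), 200), "smaller")
})

test_that("background subtraction uses the border-frame median", {
  sub <- subtract_background(matrix(100, 60, 60))
  expect_equal(sub$b_est, 100)
  expect_true(all(sub$pixels == 0))
  # spot far from the border leaves the estimate untouched
  cfg <- sim_config(image_size = 100, drift_sd = 0, seed = 71)
  tr <- spot_truth("t", c(50, 50), c(50, 50), c(50, 50), 500, 0, 2, 100, 0)
  f <- agfret:::with_seed(71, render_spot_field(tr, cfg))
  sub2 <- subtract_background(f$donor)
  expect_lt(abs(sub2$b_est - 100), 1)
  expect_false(sub2$border_warning)
  # spot overlapping the border inflates the border frame -> warning
  spoton_border <- agfret:::gauss2d_surface(100, 100, c(5, 50), 800, 6, 100)
  expect_warning(sub3 <- subtract_background(spoton_border),
                 "border-contrast")
  expect_true(sub3$border_warning)
  expect_gte(sub3$b_est, 100)
})

test_that("maximum finding smooths hot pixels and breaks ties row-major", {
  cfg <- noiseless_cfg()
  f <- render_spot_field(centered_truth(center = c(100, 100)), cfg)
  sub <- subtract_background(f$donor)
  expect_equal(unname(find_maximum(sub)), c(100, 100))
  # a one-pixel impulse loses to a true spot nine times dimmer than it
  region <- agfret:::gauss2d_surface(200, 200, c(150, 150), 400, 2, 0)
  region[40, 40] <- region[40, 40] + 2500   # impulse > peak, < 9x peak
  expect_equal(unname(find_maximum(region)), c(150, 150))
  # exact ties: smallest row, then smallest column
  tied <- matrix(0, 50, 50)
  tied[c(10, 30), c(20)] <- 9
  expect_equal(unname(find_maximum(tied, smooth = 1L)), c(10, 20))
  expect_error(find_maximum(matrix(0, 50, 50)), "no signal")
})

test_that("noiseless spots are recovered to 1e-3 in all parameters", {
  cfg <- noiseless_cfg()
  f <- render_spot_field(centered_truth(amp_donor = 500,
                                        center = c(100.5, 99.5)), cfg)
  sub <- subtract_background(crop_region(f$donor, c(100, 100), 200))
  ft <- fit_gaussian(sub, find_maximum(sub))
  expect_true(ft$converged)
  expect_equal(ft$amplitude, 500, tolerance = 1e-3)
  expect_equal(ft$center, c(100.5, 99.5), tolerance = 1e-3)
  expect_equal(ft$sigma, 2, tolerance = 1e-3)
  expect_equal(ft$offset, 0, tolerance = 1e-3)
  # oracle: the residual sum of squares at the truth is zero
  expect_lt(ft$rss, 1e-6)
})

test_that("the fitter agrees with an exhaustive grid-search oracle", {
  cfg <- noiseless_cfg()
  f <- render_spot_field(centered_truth(amp_donor = 480,
                                        center = c(100.3, 99.8)), cfg)
  sub <- subtract_background(crop_region(f$donor, c(100, 100), 200))
  ft <- fit_gaussian(sub, find_maximum(sub))
  h <- 15L
  rows <- matrix(86:116, 31, 31)
  cols <- matrix(85:115, 31, 31, byrow = TRUE)
  win <- sub$pixels_signed[86:116, 85:115]
  oracle <- grid_fit_oracle(
    win, rows, cols,
    center_grid = list(r = seq(100.1, 100.5, by = 0.1),
                       c = seq(99.6, 100.0, by = 0.1)),
    amp_grid = seq(470, 490, by = 5), sigma_grid = seq(1.9, 2.1, by = 0.05),
    offset_grid = seq(-1, 1, by = 0.5))
  expect_lte(ft$rss, oracle$rss + 1e-9)
  expect_equal(ft$center[1], oracle$r0, tolerance = 0.1)
  expect_equal(ft$center[2], oracle$c0, tolerance = 0.1)
  expect_equal(ft$amplitude, oracle$A, tolerance = 5)
  expect_equal(ft$sigma, oracle$sigma, tolerance = 0.05)
})

test_that("fits are shift-equivariant and intensity-linear", {
  cfg <- noiseless_cfg(image_size = 120)
  tr <- spot_truth("t", c(60.4, 59.6), c(60.4, 59.6), c(60.4, 59.6),
                   450, 0, 2, 100, 0)
  base <- unclass(render_spot_field(tr, cfg)$donor) - 100
  ft0 <- fit_gaussian(base, find_maximum(base))
  # integer translation moves the centre by exactly that offset
  shifted <- base[c(11:120, 1:10), c(6:120, 1:5)]  # shift up 10, left 5
  ft1 <- fit_gaussian(shifted, find_maximum(shifted))
  expect_equal(ft1$center, ft0$center - c(10, 5), tolerance = 1e-4)
  expect_equal(ft1$amplitude, ft0$amplitude, tolerance = 1e-4)
  # scaling the image scales amplitude and offset, not geometry
  ft2 <- fit_gaussian(3.7 * base, find_maximum(base))
  expect_equal(ft2$amplitude, 3.7 * ft0$amplitude, tolerance = 1e-4)
  expect_equal(ft2$center, ft0$center, tolerance = 1e-4)
  expect_equal(ft2$sigma, ft0$sigma, tolerance = 1e-4)
})

test_that("amplitude recovery at SNR 20 is unbiased within 2 percent", {
  cfg <- sim_config(image_size = 64, drift_sd = 0, seed = NULL)
  tr <- spot_truth("t", c(32.3, 31.7), c(32.3, 31.7), c(32.3, 31.7),
                   500, 0, 2, 100, 0)
  rel <- agfret:::with_seed(81, sapply(seq_len(200), function(i) {
    img <- render_spot_field(tr, cfg)$donor
    sub <- subtract_background(img, border_width = 8)
    fit_gaussian(sub, find_maximum(sub))$amplitude / 500 - 1
  }))
  expect_lt(abs(median(rel)), 0.02)
})

test_that("flat and sub-floor regions fail the fit", {
  flat <- agfret:::with_seed(82, {
    matrix(rnorm(60 * 60, 0, 10), 60, 60)
  })
  ft <- fit_gaussian(flat, c(30, 30), noise_sd = 10)
  expect_false(ft$converged && ft$status == "ok")
  expect_true(ft$status %in% c("below_floor", "degenerate",
                               "no_convergence"))
})

test_that("gauss2d_fit methods are coherent", {
  cfg <- noiseless_cfg()
  f <- render_spot_field(centered_truth(), cfg)
  sub <- subtract_background(f$donor)
  ft <- fit_gaussian(sub, find_maximum(sub))
  expect_named(coef(ft), c("A", "r0", "c0", "sigma", "offset"))
  expect_equal(sum(residuals(ft)^2), ft$rss, tolerance = 1e-8)
  expect_equal(predict(ft, list(row = ft$center[1], col = ft$center[2])),
               ft$amplitude + ft$offset, tolerance = 1e-6)
  expect_output(print(ft), "gauss2d_fit")
})

test_that("three-channel quantification tolerates drift and flags failures", {
  # noiseless, drift 0: amplitudes equal the emission model exactly
  cfg <- noiseless_cfg()
  tr <- centered_truth(amp_donor = 500, amp_acceptor = 400, f = 0.2)
  f <- render_spot_field(tr, cfg)
  q <- quantify_spot(f$donor, f$acceptor, f$fret)
  expect_equal(q$status, "ok")
  expect_equal(q$I_green, 400, tolerance = 1e-3)
  expect_equal(q$I_red, 400, tolerance = 1e-3)
  expect_equal(q$I_fret, 220, tolerance = 1e-3)

  # drift sd 3 px at SNR 20: amplitudes recovered within 2 percent (median)
  cfgd <- sim_config(drift_sd = 3, seed = 83)
  man <- make_fret_dataset("drift", 25, fret_truth_defaults(
    0, amp_donor = function(n) rep(500, n),
    amp_acceptor = function(n) rep(500, n)), cfgd)
  meas <- quiet_quantify(man)
  expect_true(all(meas$status == "ok"))
  expect_lt(abs(median(meas$I_green) / 500 - 1), 0.02)
  expect_lt(abs(median(meas$I_red) / 500 - 1), 0.02)

  # donor-only field: acceptor fit fails, spot excluded but donor usable
  cfg1 <- sim_config(seed = 84)
  sl <- make_single_label_dataset("donor", 0.2, 3, cfg1)
  m1 <- quiet_quantify(sl)
  expect_true(all(m1$status == "excluded"))
  expect_true(all(grepl("acceptor", m1$reason)))
  expect_true(all(is.finite(m1$I_green)))
  expect_true(all(is.finite(m1$I_fret)))
})
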
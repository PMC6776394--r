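test_that("noiseless renders follow the three-cube emission model", {
  cfg <- noiseless_cfg()
  # integer-centred spot so the raster peak sits exactly on a pixel
  tr <- spot_truth("t", c(100, 100), c(100, 100), c(100, 100),
                   amp_donor = 500, amp_acceptor = 400, sigma = 2,
                   background = 100, transfer_fraction = 0)
  f <- render_spot_field(tr, cfg)
  expect_equal(max(f$donor) - 100, 500)
  expect_equal(max(f$acceptor) - 100, 400)
  # zero transfer: FRET peak is pure spillover 0.2*500 + 0.1*400
  expect_equal(max(f$fret) - 100, 140)

  tr$transfer_fraction <- 0.2
  f2 <- render_spot_field(tr, cfg)
  # donor quenched by (1-f); FRET = s_g*A_d*(1-f) + s_r*A_a + q*f*A_d
  expect_equal(max(f2$donor) - 100, 400)
  expect_equal(max(f2$fret) - 100, 0.2 * 400 + 0.1 * 400 + 1 * 0.2 * 500)

  # analytic Gaussian surface, not just the peak
  expected <- agfret:::gauss2d_surface(200, 200, c(100, 100), 400, 2, 100)
  expect_equal(matrix(as.numeric(f2$donor), 200, 200), expected,
               tolerance = 1e-12)
})

test_that("saturating amplitudes are rejected", {
  cfg <- noiseless_cfg()
  tr <- centered_truth(amp_donor = 70000)
  expect_error(render_spot_field(tr, cfg), "saturation|ceiling")
})

test_that("FRET-channel expected peak increases in the transfer fraction", {
  cfg <- noiseless_cfg()
  peaks <- sapply(c(0, 0.1, 0.2, 0.4, 0.8), function(f) {
    expected_amplitudes(centered_truth(f = f), cfg)[["fret"]]
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("truth invariants are enforced", {
  expect_error(spot_truth("t", c(1, 1), c(1, 1), c(1, 1), -5, 0, 2, 100, 0))
  expect_error(spot_truth("t", c(1, 1), c(1, 1), c(1, 1), 5, 5, 2, 100, 1.5))
  expect_error(spot_truth("t", c(1, 1), c(50, 50), c(1, 1), 5, 5, 2, 100, 0,
                          drift_bound = 3),
               "drift bound")
})

test_that("fret dataset manifests are complete and reproducible on disk", {
  cfg <- sim_config(seed = 31)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- make_fret_dataset("wt", 4, fret_truth_defaults(0), cfg, dir = d1)
  m2 <- make_fret_dataset("wt", 4, fret_truth_defaults(0), cfg, dir = d2)
  expect_length(m1$records, 4L)
  files <- unlist(lapply(m1$records, function(r) unlist(r$files)))
  expect_length(files, 12L)           # 3 channels x 4 fields
  expect_length(unique(files), 12L)   # each image referenced exactly once
  expect_true(all(file.exists(file.path(d1, files))))
  # byte-identical regeneration under the same seed
  for (fn in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))))
  }
  # every truth field populated, f = 0 everywhere
  expect_true(all(sapply(m1$records, function(r) r$transfer_fraction) == 0))
  expect_true(all(sapply(m1$records, function(r) r$amp_donor) > 0))
  # manifest round-trips losslessly through JSON
  rt <- read_manifest(file.path(d1, "manifest.json"))
  expect_equal(rt$records[[2]]$center_fret, m1$records[[2]]$center_fret)
  expect_equal(rt$config$s_green, cfg$s_green)
})

test_that("single-label sets put exactly s times the label into FRET", {
  cfg <- noiseless_cfg(seed = 32)
  man <- make_single_label_dataset("acceptor", 0.25, 3, cfg)
  for (i in seq_along(man$fields)) {
    f <- man$fields[[i]]
    expect_equal(max(f$fret) - 100, 0.25 * (max(f$acceptor) - 100),
                 tolerance = 1e-9)
    expect_equal(max(f$donor), 100)   # opposite channel pure background
  }
  # donor-only with zero spillover: FRET channel is flat background
  cfg0 <- noiseless_cfg(seed = 33)
  man0 <- make_single_label_dataset("donor", 0, 2, cfg0)
  expect_true(all(unclass(man0$fields[[1]]$fret) == 100))
})

test_that("colony series geometry matches its manifest truth", {
  man <- make_colony_series(function(t) 5, 1, mm_per_px = 0.05, seed = 41)
  expect_equal(man$areas_mm2[1], pi * 25)    # perfect disk: pi r^2 exactly
  expect_error(make_colony_series(function(t) 25, 1, mm_per_px = 0.05),
               "frame")
  expect_error(make_colony_series(function(t) 5 - t, 3, mm_per_px = 0.05),
               "nondecreasing")
  man30 <- make_colony_series(function(t) 0.5 + 0.02 * t, 30,
                              mm_per_px = 0.05, seed = 42, image_size = 128L,
                              bar_mm = 3)
  expect_equal(man30$times_h, seq(0, 87, by = 3))  # 30 frames every 3 h
})

test_that("spore generator records true arc lengths and respects bounds", {
  man <- make_spore_image(1, length_dist = function(n) rep(30, n),
                          curvature = 0, seed = 51)
  expect_equal(man$records[[1]]$length_um, 30, tolerance = 0.02)
  expect_length(make_spore_image(0, seed = 52)$records, 0L)
  # overlap-free placement is bounded: cramming fails loudly
  expect_error(make_spore_image(80, seed = 53, image_size = 256L,
                                max_retries = 5L),
               "overlap")
})

test_that("nuclei fields carry the requested positive fraction exactly", {
  man <- make_nuclei_field(100, 0.15, seed = 61)
  expect_equal(man$n_positive, 15L)
  pos <- sapply(man$records, `[[`, "positive")
  expect_equal(sum(pos), 15L)
  expect_equal(make_nuclei_field(100, 0.03, seed = 62)$n_positive, 3L)
  # fraction 0: the red channel is pure background
  m0 <- make_nuclei_field(20, 0, seed = 63)
  expect_true(all(unclass(m0$red) == 100))
})
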
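test_that("disk colony area matches pi r squared", {
  man <- make_colony_series(function(t) 5, 1, mm_per_px = 0.05, seed = 101)
  a <- colony_area(man$images[[1]], man$mm_per_px)
  expect_equal(a, pi * 25, tolerance = 0.02)
  # scale from the rendered calibration bar agrees with the manifest
  sc <- measure_scale_bar(man$images[[1]], man$bar_mm)
  expect_equal(as.numeric(sc), man$mm_per_px, tolerance = 0.02)
  expect_equal(attr(sc, "source"), "ruler-measurement")
})

test_that("empty plates give a zero-area warning result", {
  plate <- fluor_image(matrix(60000, 128, 128), channel = "plate")
  expect_warning(a <- colony_area(plate, 0.05), "zero area")
  expect_equal(a, 0)
})

test_that("roughened colonies stay within 5 percent of manifest truth", {
  man <- make_colony_series(function(t) 3 + 0.05 * t, 6, mm_per_px = 0.05,
                            boundary_roughness = 0.08, seed = 102)
  areas <- sapply(man$images, colony_area, scale = man$mm_per_px)
  expect_true(all(abs(areas / man$areas_mm2 - 1) < 0.05))
})

test_that("area obeys the pixel-size scale law", {
  man <- make_colony_series(function(t) 4, 1, mm_per_px = 0.05, seed = 103)
  a1 <- colony_area(man$images[[1]], 0.05)
  a2 <- colony_area(man$images[[1]], 0.10)   # same raster, doubled scale
  expect_equal(a2 / a1, 4, tolerance = 1e-12)
})

test_that("growth series follow the linear-radius quadratic law", {
  man <- make_colony_series(function(t) 1 + 0.08 * t, 12, mm_per_px = 0.05,
                            boundary_roughness = 0.05, seed = 104)
  gs <- growth_series(man$images, man$mm_per_px)
  expect_equal(nrow(gs), 12L)
  expect_equal(gs$time_h, seq(0, 33, by = 3))
  fit <- stats::lm(sqrt(area_mm2) ~ time_h, data = gs)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_true(all(abs(gs$area_mm2 / man$areas_mm2 - 1) < 0.05))
  # single image series and order checking
  expect_equal(nrow(growth_series(man$images[1], man$mm_per_px)), 1L)
  expect_error(growth_series(man$images, man$mm_per_px,
                             times_h = c(3, 0, 6, seq(9, 33, 3))),
               "chronological|increasing")
  bad <- c(man$images[1], list(fluor_image(matrix(60000, 10, 10))))
  expect_error(growth_series(bad, man$mm_per_px), "shapes")
})

test_that("straight 30 um rods are measured within 5 percent", {
  man <- make_spore_image(1, length_dist = function(n) rep(30, n),
                          curvature = 0, seed = 105)
  sl <- spore_lengths(man$image, man$mm_per_px)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$length_um, 30, tolerance = 0.05)
})

test_that("curved rods are measured within 10 percent of arc-length truth", {
  man <- make_spore_image(6, curvature = 0.08, seed = 106)
  sl <- spore_lengths(man$image, man$mm_per_px)
  expect_equal(nrow(sl), length(man$records))
  truth <- sort(sapply(man$records, `[[`, "length_um"))
  expect_true(all(abs(sort(sl$length_um) / truth - 1) < 0.10))
})

test_that("border-touching rods are excluded", {
  img <- matrix(1000, 200, 200)
  poly <- agfret:::rod_polyline(c(100, 8), pi / 2, 150, 0)
  body <- agfret:::stamp_polyline(img, poly$points, 5)
  img[body] <- 30000
  sl <- spore_lengths(fluor_image(img), 1e-4)
  expect_equal(nrow(sl), 0L)
  expect_equal(attr(sl, "n_border"), 1L)
})

test_that("a split rod's halves sum to the whole within 2 percent", {
  img <- matrix(1000, 400, 400)
  poly <- agfret:::rod_polyline(c(200, 200), 0.4, 280, 0)
  body <- agfret:::stamp_polyline(img, poly$points, 5)
  whole <- img; whole[body] <- 30000
  l_whole <- spore_lengths(fluor_image(whole), 1e-4)$length_um
  # cut a thin perpendicular gap at the midpoint: two separated halves
  cut <- whole
  mid <- poly$points[nrow(poly$points) %/% 2L, ]
  u <- c(cos(0.4), sin(0.4))
  rr <- matrix(1:400, 400, 400); cc <- t(rr)
  along <- (rr - mid[1]) * u[1] + (cc - mid[2]) * u[2]
  radial2 <- (rr - mid[1])^2 + (cc - mid[2])^2
  cut[abs(along) <= 1.5 & radial2 <= 12^2] <- 1000
  l_halves <- spore_lengths(fluor_image(cut), 1e-4)$length_um
  expect_equal(length(l_halves), 2L)
  expect_equal(sum(l_halves), l_whole, tolerance = 0.02)
})

test_that("colocalization counts equal manifest truth on noiseless fields", {
  for (fr in c(0, 0.03, 0.15, 0.5, 1.0)) {
    man <- make_nuclei_field(100, fr, seed = 107 + round(100 * fr))
    cr <- count_spb_positive_nuclei(man$green, man$red, man$mm_per_px)
    expect_equal(cr$total_nuclei, 100L)
    expect_equal(cr$positive_nuclei, man$n_positive)
    expect_equal(cr$percent, 100 * man$n_positive / 100)
  }
})

test_that("colocalization handles blank and degenerate channels", {
  man <- make_nuclei_field(50, 0, seed = 108)
  cr <- count_spb_positive_nuclei(man$green, man$red, man$mm_per_px)
  expect_equal(cr$percent, 0)
  blank <- fluor_image(matrix(100, 64, 64), channel = "green")
  expect_error(count_spb_positive_nuclei(blank, blank, 1e-4), "zero nuclei")
})
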
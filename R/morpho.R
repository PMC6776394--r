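#' Pixel-size calibration
#'
#' @param mm_per_px pixel size in mm, strictly positive.
#' @param source where the scale came from: the simulation manifest or a
#'   measurement of the rendered calibration bar.
#' @return A `scale_calibration` object.
#' @export
scale_calibration <- function(mm_per_px,
                              source = c("manifest", "ruler-measurement")) {
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1L, mm_per_px > 0)
  structure(mm_per_px, source = match.arg(source),
            class = "scale_calibration")
}

as_mm_per_px <- function(scale) {
  if (inherits(scale, "scale_calibration")) return(as.numeric(scale))
  stopifnot(is.numeric(scale), scale > 0)
  as.numeric(scale)
}

otsu_threshold <- function(px) {
  rng <- range(px)
  if (diff(rng) < 1e-12) return(rng[1L])   # flat image: threshold at value
  x <- (px - rng[1L]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  rng[1L] + t01 * diff(rng)
}

label_mask <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

#' Measure the plate scale from the rendered calibration bar
#'
#' Finds the most elongated dark component (the calibration bar) and divides
#' the known bar length by its pixel extent.
#'
#' @param image plate image (dark objects on bright background).
#' @param bar_mm true bar length in mm.
#' @return A [scale_calibration()] with source `"ruler-measurement"`.
#' @export
measure_scale_bar <- function(image, bar_mm) {
  px <- unclass(image)
  lab <- label_mask(px < otsu_threshold(px))
  n <- max(lab)
  if (n == 0L) stop("no dark objects found; cannot locate the calibration bar")
  aspect <- extent <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(lab == i, arr.ind = TRUE)
    dr <- diff(range(w[, 1L])) + 1L
    dc <- diff(range(w[, 2L])) + 1L
    aspect[i] <- max(dr, dc) / min(dr, dc)
    extent[i] <- max(dr, dc)
  }
  bar <- which.max(aspect)
  if (aspect[bar] < 3) stop("no bar-shaped object found for calibration")
  scale_calibration(bar_mm / extent[bar], "ruler-measurement")
}

#' Colony area from one plate image
#'
#' The dark colony on the bright plate is segmented by an automatic (Otsu)
#' global threshold; the largest connected component is hole-filled and its
#' pixel count converted to mm^2.
#'
#' @param image plate image ([fluor_image()] or matrix).
#' @param scale [scale_calibration()] or mm-per-px number.
#' @param min_size minimum component size in pixels; below it a zero-area
#'   warning result is returned (empty plate).
#' @return Area in mm^2.
#' @export
colony_area <- function(image, scale, min_size = 50L) {
  mm_per_px <- as_mm_per_px(scale)
  px <- unclass(image)
  lab <- label_mask(px < otsu_threshold(px))
  if (max(lab) == 0L) {
    warning("no colony found; returning zero area", call. = FALSE)
    return(0)
  }
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_size) {
    warning("largest dark component below the minimum size; returning zero area",
            call. = FALSE)
    return(0)
  }
  biggest <- which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image((lab == biggest) * 1))
  sum(EBImage::imageData(filled) > 0) * mm_per_px^2
}

#' Colony areas over a plate timelapse
#'
#' @param images chronologically ordered list of plate images (or TIFF
#'   paths).
#' @param scale [scale_calibration()] or mm-per-px number.
#' @param interval_h imaging interval in hours (used when `times_h` absent).
#' @param times_h optional acquisition times; must be strictly increasing.
#' @param shrink_tol relative area decrease beyond which a monotonicity
#'   violation is logged as a warning (colonies only grow).
#' @param strain strain label.
#' @return A `growth_series` data.frame: `time_h`, `area_mm2`.
#' @export
growth_series <- function(images, scale, interval_h = 3, times_h = NULL,
                          shrink_tol = 0.05, strain = "strain") {
  if (is.character(images)) images <- lapply(images, read_fluor_tiff)
  n <- length(images)
  stopifnot(n >= 1L)
  dims <- vapply(images, function(im) dim(unclass(im)), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("inconsistent image shapes in the timelapse")
  }
  if (is.null(times_h)) times_h <- (seq_len(n) - 1L) * interval_h
  if (n > 1L && any(diff(times_h) <= 0)) {
    stop("timestamps are not strictly increasing; ",
         "supply images in chronological order")
  }
  areas <- vapply(images, colony_area, numeric(1L), scale = scale)
  if (n > 1L) {
    rel <- diff(areas) / pmax(areas[-n], .Machine$double.eps)
    if (any(rel < -shrink_tol)) {
      warning(sum(rel < -shrink_tol),
              " timepoint(s) shrink beyond tolerance; check segmentation",
              call. = FALSE)
    }
  }
  out <- data.frame(strain = strain, time_h = times_h, area_mm2 = areas,
                    stringsAsFactors = FALSE)
  class(out) <- c("growth_series", "data.frame")
  out
}

#' @export
plot.growth_series <- function(x, ...) {
  graphics::plot(x$time_h, x$area_mm2, type = "b", pch = 16,
                 xlab = "time (h)", ylab = expression(area ~ (mm^2)), ...)
  invisible(x)
}

#' Spore lengths by skeleton morphometry
#'
#' Bright needle spores are segmented by an automatic global threshold and
#' labelled; each component is thinned to its skeleton and measured as the
#' geodesic path length between the two farthest skeleton ends (smoothed to
#' remove the digital staircase), extended at each end by how far the object
#' reaches beyond the skeleton tip along the rod direction (thinning erodes
#' rod tips). Components touching the image border or shorter than
#' `min_len_um` are excluded.
#'
#' @param image spore image (bright objects on dark background).
#' @param scale [scale_calibration()] or mm-per-px number.
#' @param min_len_um minimum reported spore length, um.
#' @param strain strain label.
#' @return A `spore_set` data.frame: `label`, `length_um`; excluded
#'   component counts are attached as attributes `n_border` and `n_short`.
#' @export
spore_lengths <- function(image, scale, min_len_um = 5, strain = "strain") {
  mm_per_px <- as_mm_per_px(scale)
  um_per_px <- mm_per_px * 1000
  px <- unclass(image)
  mask <- px > otsu_threshold(px)
  lab <- label_mask(mask)
  n <- max(lab)
  empty <- data.frame(strain = character(0), label = integer(0),
                      length_um = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    out <- empty
    class(out) <- c("spore_set", "data.frame")
    attr(out, "n_border") <- 0L; attr(out, "n_short") <- 0L
    return(out)
  }
  nr <- nrow(px); nc <- ncol(px)
  rows <- list(); n_border <- 0L; n_short <- 0L
  for (i in seq_len(n)) {
    comp <- lab == i
    w <- which(comp, arr.ind = TRUE)
    if (any(w[, 1L] %in% c(1L, nr)) || any(w[, 2L] %in% c(1L, nc))) {
      n_border <- n_border + 1L
      next
    }
    skel <- thin_mask(comp)
    sp <- skeleton_path_length(skel)
    len_px <- sp$length_px
    if (!is.null(sp$path)) {
      len_px <- len_px + end_extension(w, sp$path, at_start = TRUE) +
        end_extension(w, sp$path, at_start = FALSE)
    }
    len_um <- len_px * um_per_px
    if (len_um < min_len_um) {
      n_short <- n_short + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(strain = strain, label = i,
                                            length_um = len_um,
                                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("spore_set", "data.frame")
  attr(out, "n_border") <- n_border
  attr(out, "n_short") <- n_short
  out
}

# Local maxima of the smoothed, background-subtracted red channel that rise
# above the noise floor; greedy suppression keeps maxima >= min_sep apart.
find_red_spots <- function(red, smooth = 3L, floor_mult = 3, min_sep = 5,
                           fit_window = 15L) {
  px <- unclass(red)
  b <- stats::median(px)
  noise <- stats::mad(px)
  sub <- pmax(px - b, 0)
  sm <- box_mean(sub, smooth)
  floor <- max(floor_mult * noise, 1)
  is_max <- sm > floor
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & sm >= shift_mat(sm, dr, dc)
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(numeric(0), 0L, 2L))
  cand <- cand[order(sm[cand], decreasing = TRUE), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1L]) {
    prior <- cand[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], ,
                                                   drop = FALSE]
    if (nrow(prior) &&
        min((prior[, 1L] - cand[i, 1L])^2 +
              (prior[, 2L] - cand[i, 2L])^2) < min_sep^2) {
      keep[i] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  centers <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(nrow(cand))) {
    ft <- fit_gaussian(sub, cand[i, ], window = fit_window,
                       noise_sd = noise, floor_mult = floor_mult)
    if (ft$converged && ft$status == "ok") {
      centers <- rbind(centers, ft$center)
    }
  }
  centers
}

#' Count nuclei carrying an SPB signal
#'
#' Nuclei are the thresholded green components above a minimum area; red
#' SPB spots are local maxima above the noise floor confirmed by a Gaussian
#' fit. A nucleus is positive when at least one red spot centre lies within
#' distance `d_um` of its boundary or interior.
#'
#' @param green_image nuclear-marker channel.
#' @param red_image SPB-label channel.
#' @param scale [scale_calibration()] or mm-per-px number.
#' @param d_um association distance in um (SPBs sit at the nuclear
#'   envelope).
#' @param min_nucleus_px minimum nucleus component area, pixels.
#' @param strain strain label.
#' @return A `coloc_result` data.frame: `strain`, `total_nuclei`,
#'   `positive_nuclei`, `percent`; the detected spot centres are attached as
#'   attribute `"spots"`.
#' @export
count_spb_positive_nuclei <- function(green_image, red_image, scale,
                                      d_um = 1.5, min_nucleus_px = 20L,
                                      strain = "strain") {
  mm_per_px <- as_mm_per_px(scale)
  um_per_px <- mm_per_px * 1000
  gpx <- unclass(green_image)
  lab <- label_mask(gpx > otsu_threshold(gpx))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_nucleus_px)
    lab[lab %in% small] <- 0L
  }
  nuclei <- sort(unique(lab[lab > 0L]))
  if (length(nuclei) == 0L) stop("zero nuclei found in the green channel")

  spots <- find_red_spots(red_image)
  d_px <- d_um / um_per_px
  positive <- logical(length(nuclei))
  names(positive) <- nuclei
  nr <- nrow(gpx); nc <- ncol(gpx)
  r_win <- ceiling(d_px)
  for (i in seq_len(nrow(spots))) {
    sr <- spots[i, 1L]; sc <- spots[i, 2L]
    rs <- max(1L, floor(sr - r_win)):min(nr, ceiling(sr + r_win))
    cs <- max(1L, floor(sc - r_win)):min(nc, ceiling(sc + r_win))
    sublab <- lab[rs, cs]
    d2 <- outer((rs - sr)^2, (cs - sc)^2, "+")
    hit <- unique(sublab[sublab > 0L & d2 <= d_px^2])
    positive[as.character(hit)] <- TRUE
  }
  out <- data.frame(strain = strain, total_nuclei = length(nuclei),
                    positive_nuclei = sum(positive),
                    percent = 100 * sum(positive) / length(nuclei),
                    stringsAsFactors = FALSE)
  class(out) <- c("coloc_result", "data.frame")
  attr(out, "spots") <- spots
  out
}
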
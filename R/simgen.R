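#' Simulation configuration for synthetic SPB spot fields
#'
#' Holds the camera/optics model used by the spot-field generators. The
#' emission model for one spot pair with donor amplitude \eqn{A_d}, acceptor
#' amplitude \eqn{A_a} and transfer fraction \eqn{f} is
#' \deqn{donor: A_d (1-f), \quad acceptor: A_a, \quad
#'       FRET: s_{green} A_d (1-f) + s_{red} A_a + q f A_d,}
#' each rendered as an isotropic 2D Gaussian of width `sigma` on a constant
#' background, with optional Poisson shot noise followed by additive Gaussian
#' read noise (CMOS camera model), then clipped and quantized to `bit_depth`.
#' At \eqn{f = 0} the FRET channel carries pure spillover, so downstream
#' FRETR is exactly 1.
#'
#' @param image_size field side length in pixels (square fields).
#' @param s_green,s_red true spillover coefficients of the donor (green) and
#'   acceptor (red) fluorophores into the FRET channel; each in `[0, 1)`.
#' @param q detection gain of sensitized emission relative to direct donor
#'   emission (dimensionless).
#' @param drift_sd per-channel standard deviation, in pixels, of the spot
#'   centre offsets between channel acquisitions (mobile nuclei).
#' @param drift_bound maximum allowed distance, in pixels, between any two
#'   channel centres of one spot; sampled offsets are clamped to half of it.
#' @param read_noise_sd Gaussian read noise sd in counts.
#' @param poisson_noise apply Poisson shot noise to expected counts?
#' @param bit_depth camera bit depth; counts are clipped to `2^bit_depth - 1`.
#' @param background constant background level in counts.
#' @param sigma PSF width (Gaussian sd) in pixels.
#' @param seed integer seed making all generator output reproducible, or
#'   `NULL` to draw from the session RNG stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(image_size = 200L, s_green = 0.2, s_red = 0.1, q = 1,
                       drift_sd = 3, drift_bound = 6 * drift_sd,
                       read_noise_sd = 3, poisson_noise = TRUE,
                       bit_depth = 16L, background = 100, sigma = 2,
                       seed = NULL) {
  cfg <- list(image_size = as.integer(image_size), s_green = s_green,
              s_red = s_red, q = q, drift_sd = drift_sd,
              drift_bound = drift_bound, read_noise_sd = read_noise_sd,
              poisson_noise = isTRUE(poisson_noise),
              bit_depth = as.integer(bit_depth), background = background,
              sigma = sigma, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$image_size >= 16L,
            cfg$s_green >= 0, cfg$s_green < 1,
            cfg$s_red >= 0, cfg$s_red < 1,
            cfg$q >= 0, cfg$drift_sd >= 0, cfg$drift_bound >= 0,
            cfg$read_noise_sd >= 0, cfg$bit_depth %in% c(8L, 12L, 16L),
            cfg$background >= 0, cfg$sigma > 0)
  invisible(cfg)
}

#' Ground truth for one synthetic spot pair
#'
#' @param field_id identifier string.
#' @param center_donor,center_acceptor,center_fret sub-pixel `(row, col)`
#'   centres in pixels (1-based pixel-centre coordinates).
#' @param amp_donor,amp_acceptor peak amplitudes above background, counts.
#' @param sigma PSF width in pixels.
#' @param background background level in counts.
#' @param transfer_fraction FRET transfer fraction `f` in `[0, 1]`.
#' @param drift_bound maximum allowed distance between channel centres.
#' @return A `spot_truth` list.
#' @export
spot_truth <- function(field_id, center_donor, center_acceptor, center_fret,
                       amp_donor, amp_acceptor, sigma, background,
                       transfer_fraction, drift_bound = Inf) {
  stopifnot(amp_donor >= 0, amp_acceptor >= 0, sigma > 0, background >= 0,
            transfer_fraction >= 0, transfer_fraction <= 1)
  centers <- rbind(center_donor, center_acceptor, center_fret)
  if (max(stats::dist(centers)) > drift_bound + 1e-9) {
    stop("channel centres differ by more than the drift bound")
  }
  structure(list(field_id = field_id, center_donor = center_donor,
                 center_acceptor = center_acceptor, center_fret = center_fret,
                 amp_donor = amp_donor, amp_acceptor = amp_acceptor,
                 sigma = sigma, background = background,
                 transfer_fraction = transfer_fraction),
            class = "spot_truth")
}

#' Expected (noiseless) channel peak amplitudes above background
#'
#' @param truth a [spot_truth()].
#' @param cfg a [sim_config()].
#' @return Named numeric: `donor`, `acceptor`, `fret` peak amplitudes.
#' @export
expected_amplitudes <- function(truth, cfg) {
  f <- truth$transfer_fraction
  c(donor = truth$amp_donor * (1 - f),
    acceptor = truth$amp_acceptor,
    fret = cfg$s_green * truth$amp_donor * (1 - f) +
      cfg$s_red * truth$amp_acceptor + cfg$q * f * truth$amp_donor)
}

apply_camera_noise <- function(mu, cfg) {
  ceiling_counts <- 2^cfg$bit_depth - 1
  noisy <- cfg$poisson_noise || cfg$read_noise_sd > 0
  x <- mu
  if (cfg$poisson_noise) {
    x <- matrix(stats::rpois(length(mu), lambda = pmax(mu, 0)),
                nrow(mu), ncol(mu))
  }
  if (cfg$read_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), sd = cfg$read_noise_sd)
  }
  # quantize only when noise was applied; noiseless renders stay analytic
  # and are quantized on TIFF output
  if (noisy) x <- round(x)
  pmin(pmax(x, 0), ceiling_counts)
}

#' Render the three channels of one spot field
#'
#' @inheritParams expected_amplitudes
#' @return Named list of three [fluor_image()]s: `donor`, `acceptor`, `fret`.
#' @export
render_spot_field <- function(truth, cfg = sim_config()) {
  validate_sim_config(cfg)
  amps <- expected_amplitudes(truth, cfg)
  ceiling_counts <- 2^cfg$bit_depth - 1
  if (any(amps + truth$background > ceiling_counts)) {
    stop("expected peak exceeds the bit-depth ceiling; ",
         "lower the amplitudes or background (saturation)")
  }
  n <- cfg$image_size
  centers <- list(donor = truth$center_donor, acceptor = truth$center_acceptor,
                  fret = truth$center_fret)
  out <- lapply(names(centers), function(ch) {
    mu <- gauss2d_surface(n, n, centers[[ch]], amps[[ch]], truth$sigma,
                          offset = truth$background)
    fluor_image(apply_camera_noise(mu, cfg), channel = ch)
  })
  names(out) <- names(centers)
  out
}

sample_drift <- function(cfg) {
  d <- stats::rnorm(2L, sd = cfg$drift_sd)
  len <- sqrt(sum(d^2))
  lim <- cfg$drift_bound / 2
  if (len > lim) d <- d * lim / len
  d
}

#' Default truth distributions for labelled-strain simulation
#'
#' Amplitudes are mildly variable around 500 counts (peak signal-to-noise
#' near 20 under the default Poisson + read-noise camera model); the
#' transfer fraction is a per-strain constant.
#'
#' @param transfer_fraction transfer fraction `f` for every spot.
#' @param amp_donor,amp_acceptor functions of `n` drawing amplitudes.
#' @param center_jitter half-width, pixels, of the uniform jitter of the
#'   nominal spot position around the field centre.
#' @return List of sampling functions consumed by [make_fret_dataset()].
#' @export
fret_truth_defaults <- function(transfer_fraction = 0,
                                amp_donor = function(n) pmax(stats::rnorm(n, 500, 50), 100),
                                amp_acceptor = function(n) pmax(stats::rnorm(n, 500, 50), 100),
                                center_jitter = 10) {
  list(transfer_fraction = transfer_fraction, amp_donor = amp_donor,
       amp_acceptor = amp_acceptor, center_jitter = center_jitter)
}

sample_spot_truths <- function(strain_name, n_fields, td, cfg) {
  a_d <- td$amp_donor(n_fields)
  a_a <- td$amp_acceptor(n_fields)
  f <- if (is.function(td$transfer_fraction)) {
    td$transfer_fraction(n_fields)
  } else rep(td$transfer_fraction, n_fields)
  mid <- (cfg$image_size + 1) / 2
  lapply(seq_len(n_fields), function(i) {
    base <- mid + stats::runif(2L, -td$center_jitter, td$center_jitter)
    spot_truth(field_id = sprintf("%s_field%03d", strain_name, i),
               center_donor = base + sample_drift(cfg),
               center_acceptor = base + sample_drift(cfg),
               center_fret = base + sample_drift(cfg),
               amp_donor = a_d[i], amp_acceptor = a_a[i],
               sigma = cfg$sigma, background = cfg$background,
               transfer_fraction = f[i], drift_bound = cfg$drift_bound)
  })
}

write_spot_field <- function(field, truth, dir) {
  files <- lapply(names(field), function(ch) {
    fn <- sprintf("%s_%s.tif", truth$field_id, ch)
    write_fluor_tiff(field[[ch]], file.path(dir, fn))
    fn
  })
  names(files) <- names(field)
  files
}

truth_record <- function(truth) {
  list(field_id = truth$field_id,
       center_donor = unname(truth$center_donor),
       center_acceptor = unname(truth$center_acceptor),
       center_fret = unname(truth$center_fret),
       amp_donor = truth$amp_donor, amp_acceptor = truth$amp_acceptor,
       sigma = truth$sigma, background = truth$background,
       transfer_fraction = truth$transfer_fraction)
}

#' Simulate a labelled FRET strain dataset with ground truth
#'
#' Emits `n_fields` three-channel spot fields as 16-bit TIFFs plus a JSON
#' manifest recording every truth parameter and the configuration used.
#'
#' @param strain_name label for the simulated strain.
#' @param n_fields number of spot fields (one SPB each).
#' @param truth_distributions see [fret_truth_defaults()].
#' @param cfg a [sim_config()]; its `seed` makes output byte-reproducible.
#' @param dir output directory (created if missing); `NULL` keeps everything
#'   in memory.
#' @return Manifest list; when `dir` is `NULL` it additionally carries the
#'   rendered fields under `$fields`.
#' @export
make_fret_dataset <- function(strain_name, n_fields,
                              truth_distributions = fret_truth_defaults(),
                              cfg = sim_config(), dir = NULL) {
  stopifnot(n_fields >= 1L)
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    truths <- sample_spot_truths(strain_name, n_fields, truth_distributions,
                                 cfg)
    fields <- lapply(truths, render_spot_field, cfg = cfg)
    manifest <- list(kind = "fret", strain = strain_name,
                     config = unclass(cfg),
                     records = lapply(truths, truth_record))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(n_fields)) {
        manifest$records[[i]]$files <-
          write_spot_field(fields[[i]], truths[[i]], dir)
      }
      write_manifest(manifest, file.path(dir, "manifest.json"))
    } else {
      manifest$fields <- fields
    }
    invisible(manifest)
  })
}

#' Simulate a single-label (spillover calibration) dataset
#'
#' Only one fluorophore is present, so the FRET-channel expected signal is
#' exactly `s` times the labelled channel's expected signal — the situation
#' used to calibrate spillover from control strains carrying only the donor
#' or only the acceptor fusion.
#'
#' @param channel `"donor"` or `"acceptor"` — which label is present.
#' @param s true spillover coefficient of the labelled channel.
#' @param n_fields number of fields.
#' @param cfg a [sim_config()]; the matching coefficient is overridden by `s`.
#' @param dir output directory, or `NULL` for in-memory output.
#' @param amp amplitude sampling function for the labelled channel.
#' @return Manifest list, as for [make_fret_dataset()].
#' @export
make_single_label_dataset <- function(channel = c("donor", "acceptor"), s,
                                      n_fields, cfg = sim_config(),
                                      dir = NULL,
                                      amp = function(n) pmax(stats::rnorm(n, 500, 50), 100)) {
  channel <- match.arg(channel)
  stopifnot(s >= 0, s < 1, n_fields >= 1L)
  if (channel == "donor") cfg$s_green <- s else cfg$s_red <- s
  zero <- function(n) rep(0, n)
  td <- fret_truth_defaults(
    transfer_fraction = 0,
    amp_donor = if (channel == "donor") amp else zero,
    amp_acceptor = if (channel == "acceptor") amp else zero)
  man <- make_fret_dataset(paste0("single_", channel), n_fields, td, cfg, dir)
  man$kind <- "single_label"
  man$labelled_channel <- channel
  man$spillover <- s
  if (!is.null(dir)) write_manifest(man, file.path(dir, "manifest.json"))
  invisible(man)
}

#' Simulate a radial colony-growth plate timelapse
#'
#' One dark quasi-circular colony grows on a bright plate, imaged every
#' `interval_h` hours; a dark calibration bar of known length is rendered so
#' the scale can be measured from the image itself. The manifest stores the
#' true colony area at every timepoint.
#'
#' @param radius_fn function of time (hours) returning colony radius in mm;
#'   must be nondecreasing over the imaged span.
#' @param n_timepoints number of images.
#' @param interval_h imaging interval in hours.
#' @param mm_per_px pixel size of the plate camera.
#' @param boundary_roughness relative amplitude of the smooth angular
#'   perturbation of the colony radius (0 = perfect disk).
#' @param seed RNG seed (shape profile and nothing else).
#' @param dir output directory, or `NULL` for in-memory output.
#' @param image_size image side, pixels.
#' @param bar_mm true length of the calibration bar, mm.
#' @return Manifest list with per-timepoint true areas (mm^2); in-memory
#'   output carries the rendered plates under `$images`.
#' @export
make_colony_series <- function(radius_fn, n_timepoints, interval_h = 3,
                               mm_per_px = 0.05, boundary_roughness = 0,
                               seed = NULL, dir = NULL, image_size = 512L,
                               bar_mm = 10) {
  stopifnot(n_timepoints >= 1L, mm_per_px > 0, boundary_roughness >= 0,
            bar_mm > 0)
  with_seed(seed, {
    times <- (seq_len(n_timepoints) - 1L) * interval_h
    radii <- vapply(times, radius_fn, numeric(1L))
    if (any(diff(radii) < -1e-9)) stop("radius_fn must be nondecreasing")
    theta <- seq(0, 2 * pi, length.out = 1024L)
    shape <- rep(1, length(theta))
    if (boundary_roughness > 0) {
      z <- rep(0, length(theta))
      for (k in 2:6) {
        z <- z + stats::rnorm(1L) * cos(k * theta) +
          stats::rnorm(1L) * sin(k * theta)
      }
      z <- z / max(abs(z))
      shape <- pmax(1 + boundary_roughness * z, 0.05)
    }
    max_r_px <- max(radii) * max(shape) / mm_per_px
    if (max_r_px > image_size / 2 - 4) stop("colony exceeds the frame")
    bar_px <- round(bar_mm / mm_per_px)
    if (bar_px > image_size - 16L) stop("calibration bar exceeds the frame")

    mid <- (image_size + 1) / 2
    px_r <- matrix(seq_len(image_size) - mid, image_size, image_size)
    px_c <- t(px_r)
    dist_mm <- sqrt(px_r^2 + px_c^2) * mm_per_px
    ang <- atan2(px_c, px_r) %% (2 * pi)
    shape_at <- stats::approx(theta, shape, xout = ang, rule = 2)$y

    bg <- 60000; fg <- 5000
    images <- vector("list", n_timepoints)
    areas <- numeric(n_timepoints)
    for (i in seq_len(n_timepoints)) {
      img <- matrix(bg, image_size, image_size)
      img[dist_mm <= radii[i] * shape_at] <- fg
      img[8:12, 8:(7 + bar_px)] <- fg   # calibration bar
      images[[i]] <- fluor_image(img, channel = "plate",
                                 mm_per_px = mm_per_px)
      areas[i] <- if (boundary_roughness == 0) {
        pi * radii[i]^2
      } else {
        # polar area of the perturbed boundary, 0.5 * integral of R(theta)^2
        r2 <- (radii[i] * shape)^2
        0.5 * sum((r2[-1] + r2[-length(r2)]) / 2 * diff(theta))
      }
    }
    manifest <- list(kind = "colony", interval_h = interval_h,
                     mm_per_px = mm_per_px, bar_mm = bar_mm, bar_px = bar_px,
                     boundary_roughness = boundary_roughness,
                     times_h = times, radii_mm = radii, areas_mm2 = areas)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      manifest$files <- vapply(seq_len(n_timepoints), function(i) {
        fn <- sprintf("plate_t%03d.tif", i)
        write_fluor_tiff(images[[i]], file.path(dir, fn))
        fn
      }, character(1L))
      write_manifest(manifest, file.path(dir, "manifest.json"))
    } else {
      manifest$images <- images
    }
    invisible(manifest)
  })
}

# Dense polyline of one curved rod (quadratic Bezier); returns sample points
# (px) and arc length (px).
rod_polyline <- function(center, angle, length_px, sag_px, step = 0.3) {
  u <- c(cos(angle), sin(angle))
  v <- c(-u[2L], u[1L])
  # chord shortened so the bent rod's arc stays close to the target length
  chord <- length_px / (1 + (8 / 3) * (sag_px / length_px)^2)
  p0 <- center - chord / 2 * u
  p2 <- center + chord / 2 * u
  p1 <- center + sag_px * 2 * v  # Bezier control; curve passes at sag_px
  tt <- seq(0, 1, length.out = max(8L, ceiling(length_px / step)))
  b <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
  arc <- sum(sqrt(rowSums(diff(b)^2)))
  list(points = b, arc_px = arc)
}

stamp_polyline <- function(mask, points, radius) {
  n <- nrow(mask); m <- ncol(mask)
  r <- ceiling(radius)
  hits <- matrix(FALSE, n, m)
  for (i in seq_len(nrow(points))) {
    pr <- points[i, 1L]; pc <- points[i, 2L]
    if (pr < 1 - r || pr > n + r || pc < 1 - r || pc > m + r) next
    rs <- max(1L, floor(pr - r)):min(n, ceiling(pr + r))
    cs <- max(1L, floor(pc - r)):min(m, ceiling(pc + r))
    d2 <- outer((rs - pr)^2, (cs - pc)^2, "+")
    hits[rs, cs] <- hits[rs, cs] | (d2 <= radius^2)
  }
  hits
}

#' Simulate a field of needle-shaped spores
#'
#' Ashbya-like needle spores (default ~30 um long, 1 um wide, gently curved)
#' are placed without overlap on a dark background; the manifest records the
#' true arc length of each rendered spore as measured along its rasterized
#' centreline polyline.
#'
#' @param n_spores number of spores to place (0 gives an empty manifest).
#' @param length_dist function of `n` drawing spore lengths in um.
#' @param width_um spore diameter in um.
#' @param curvature sagitta of the centreline as a fraction of length
#'   (0 = straight rods).
#' @param mm_per_px pixel size (default 1e-4 mm = 0.1 um per pixel).
#' @param seed RNG seed.
#' @param dir output directory, or `NULL` for in-memory output.
#' @param image_size image side, pixels.
#' @param max_retries placement attempts per spore before failing.
#' @return Manifest list with true lengths (um); in-memory output carries the
#'   rendered image under `$image`.
#' @export
make_spore_image <- function(n_spores,
                             length_dist = function(n) pmax(stats::rnorm(n, 30, 3), 10),
                             width_um = 1, curvature = 0.05,
                             mm_per_px = 1e-4, seed = NULL, dir = NULL,
                             image_size = 512L, max_retries = 100L) {
  stopifnot(n_spores >= 0L, width_um > 0, curvature >= 0, mm_per_px > 0)
  with_seed(seed, {
    um_per_px <- mm_per_px * 1000
    occupied <- matrix(FALSE, image_size, image_size)
    bg <- 1000; fg <- 30000
    img <- matrix(bg, image_size, image_size)
    records <- list()
    margin <- width_um / um_per_px / 2 + 3   # keep full spore body in frame
    if (n_spores > 0L) {
      lens <- length_dist(n_spores)
      for (i in seq_len(n_spores)) {
        w_px <- width_um / um_per_px
        # the rounded caps add half a width at each end, so the centreline
        # is drawn shorter to make the rendered spore span the drawn length
        l_px <- max(lens[i] / um_per_px - w_px, w_px)
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          ctr <- stats::runif(2L, margin + 2, image_size - margin - 2)
          ang <- stats::runif(1L, 0, pi)
          sag <- curvature * l_px * sample(c(-1, 1), 1L)
          poly <- rod_polyline(ctr, ang, l_px, sag)
          if (any(poly$points < margin) ||
              any(poly$points > image_size - margin)) next
          hits <- stamp_polyline(occupied, poly$points, w_px / 2 + 2)
          if (any(hits & occupied)) next
          occupied <- occupied | hits
          body <- stamp_polyline(occupied, poly$points, w_px / 2)
          img[body] <- fg
          records[[length(records) + 1L]] <-
            list(spore_id = sprintf("spore%03d", i),
                 length_um = poly$arc_px * um_per_px + width_um,
                 width_um = width_um, curvature = curvature,
                 center = unname(ctr), angle = ang)
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place spore ", i,
                          " without overlap after ", max_retries, " retries")
      }
    }
    manifest <- list(kind = "spores", mm_per_px = mm_per_px,
                     width_um = width_um, records = records)
    out <- fluor_image(img, channel = "green", mm_per_px = mm_per_px)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      manifest$file <- "spores.tif"
      write_fluor_tiff(out, file.path(dir, "spores.tif"))
      write_manifest(manifest, file.path(dir, "manifest.json"))
    } else {
      manifest$image <- out
    }
    invisible(manifest)
  })
}

#' Simulate a two-channel nuclei / SPB-spot field
#'
#' Nuclei (bright green disks, as from a nuclear-localized GFP marker) are
#' laid out on a jittered grid; exactly `round(positive_fraction * n_nuclei)`
#' of them carry an adjacent diffraction-limited red spot at the nuclear
#' periphery, emulating an SPB labelled in the red channel.
#'
#' @param n_nuclei number of nuclei.
#' @param positive_fraction fraction of nuclei with an SPB spot, in `[0, 1]`.
#' @param seed RNG seed.
#' @param mm_per_px pixel size (default 0.1 um per pixel).
#' @param nucleus_radius_um nuclear disk radius, um.
#' @param spot_amp red spot peak amplitude, counts.
#' @param spot_sigma red spot PSF width, pixels.
#' @param noise apply the Poisson + read-noise camera model?
#' @param dir output directory, or `NULL` for in-memory output.
#' @return Manifest list with per-nucleus assignments; in-memory output
#'   carries `$green` and `$red` images.
#' @export
make_nuclei_field <- function(n_nuclei, positive_fraction, seed = NULL,
                              mm_per_px = 1e-4, nucleus_radius_um = 1,
                              spot_amp = 500, spot_sigma = 2, noise = FALSE,
                              dir = NULL) {
  stopifnot(n_nuclei >= 1L, positive_fraction >= 0, positive_fraction <= 1)
  with_seed(seed, {
    um_per_px <- mm_per_px * 1000
    nuc_r <- nucleus_radius_um / um_per_px
    # spacing keeps any SPB spot >= ~3 radii away from every other nucleus,
    # well beyond the default 1.5 um association distance
    spacing <- ceiling(6 * nuc_r)
    ngrid <- ceiling(sqrt(n_nuclei))
    size <- as.integer(spacing * (ngrid + 1L))
    bg <- 100
    green <- matrix(bg, size, size)
    red <- matrix(bg, size, size)
    n_pos <- as.integer(round(positive_fraction * n_nuclei))
    positive <- rep(FALSE, n_nuclei)
    if (n_pos > 0L) positive[sample.int(n_nuclei, n_pos)] <- TRUE

    slots <- sample.int(ngrid^2, n_nuclei)
    records <- vector("list", n_nuclei)
    rows <- matrix(seq_len(size), size, size)
    cols <- t(rows)
    for (i in seq_len(n_nuclei)) {
      gr <- (slots[i] - 1L) %/% ngrid + 1L
      gc <- (slots[i] - 1L) %% ngrid + 1L
      ctr <- c(gr, gc) * spacing + stats::runif(2L, -0.05, 0.05) * spacing
      d2 <- (rows - ctr[1L])^2 + (cols - ctr[2L])^2
      green[d2 <= nuc_r^2] <- 5000
      spot <- NULL
      if (positive[i]) {
        a <- stats::runif(1L, 0, 2 * pi)
        spot <- ctr + nuc_r * c(cos(a), sin(a))
        red <- red + spot_amp * exp(-((rows - spot[1L])^2 +
                                      (cols - spot[2L])^2) /
                                      (2 * spot_sigma^2))
      }
      records[[i]] <- list(nucleus_id = sprintf("nuc%03d", i),
                           center = unname(ctr), positive = positive[i],
                           spot_center = if (is.null(spot)) NULL else unname(spot))
    }
    if (noise) {
      cam <- sim_config(image_size = size, seed = NULL)
      green <- apply_camera_noise(green, cam)
      red <- apply_camera_noise(red, cam)
    }
    manifest <- list(kind = "nuclei", mm_per_px = mm_per_px,
                     n_nuclei = n_nuclei, n_positive = n_pos,
                     positive_fraction = positive_fraction,
                     nucleus_radius_um = nucleus_radius_um,
                     spot_sigma = spot_sigma, records = records)
    g <- fluor_image(green, channel = "green", mm_per_px = mm_per_px)
    r <- fluor_image(red, channel = "red", mm_per_px = mm_per_px)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      manifest$files <- list(green = "nuclei_green.tif",
                             red = "nuclei_red.tif")
      write_fluor_tiff(g, file.path(dir, "nuclei_green.tif"))
      write_fluor_tiff(r, file.path(dir, "nuclei_red.tif"))
      write_manifest(manifest, file.path(dir, "manifest.json"))
    } else {
      manifest$green <- g
      manifest$red <- r
    }
    invisible(manifest)
  })
}
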
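#' Crop a square analysis region around a spot
#'
#' Mirrors manual SPB selection: a fixed-size window (default 200 x 200 px)
#' is cut from the source image, centred as near the requested position as
#' possible and shifted inward at image borders so the window always lies
#' fully inside the image.
#'
#' @param image a [fluor_image()] or numeric matrix.
#' @param center requested `(row, col)` centre, 1-based pixels.
#' @param size window side length in pixels.
#' @return A `spot_region`: list with `pixels` (size x size matrix),
#'   `origin` (1-based `(row, col)` of the window's top-left pixel in the
#'   source image) and `channel`.
#' @export
crop_region <- function(image, center, size = 200L) {
  size <- as.integer(size)
  stopifnot(size >= 8L, length(center) == 2L)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < size || nc < size) {
    stop("image (", nr, " x ", nc, ") is smaller than the ", size, " x ",
         size, " crop window")
  }
  orig <- c(min(max(round(center[1L]) - size %/% 2L, 1L), nr - size + 1L),
            min(max(round(center[2L]) - size %/% 2L, 1L), nc - size + 1L))
  structure(list(pixels = unclass(image)[orig[1L]:(orig[1L] + size - 1L),
                                         orig[2L]:(orig[2L] + size - 1L)],
                 origin = orig,
                 channel = attr(image, "channel") %||% "unknown"),
            class = "spot_region")
}

#' @export
print.spot_region <- function(x, ...) {
  cat(sprintf("<spot_region> %d x %d px at origin (%d, %d), channel = %s\n",
              nrow(x$pixels), ncol(x$pixels), x$origin[1L], x$origin[2L],
              x$channel))
  invisible(x)
}

border_frame_values <- function(px, width) {
  nr <- nrow(px); nc <- ncol(px)
  width <- min(width, nr %/% 2L, nc %/% 2L)
  inner_r <- (width + 1L):(nr - width)
  inner_c <- (width + 1L):(nc - width)
  mask <- matrix(TRUE, nr, nc)
  mask[inner_r, inner_c] <- FALSE
  px[mask]
}

#' Estimate and subtract the background of a spot region
#'
#' The background is the median of the region's border frame (default 10 px
#' wide), a robust estimate unaffected by the central spot. The subtracted
#' region is floored at zero. If an unusually large share of border pixels
#' sits far above the estimate the spot likely overlaps the border and a
#' border-contrast warning is raised.
#'
#' @param region a `spot_region` from [crop_region()], or a numeric matrix.
#' @param border_width border frame width in pixels.
#' @param contrast_frac fraction of high border pixels that triggers the
#'   warning.
#' @return List with `pixels` (background-subtracted matrix, floored at 0),
#'   `pixels_signed` (background-subtracted without flooring — least-squares
#'   fitting uses this form, because flooring clips negative noise and
#'   biases weak amplitudes low), `b_est` (estimated background, counts),
#'   `noise_sd` (robust sd of the border noise via MAD) and `border_warning`
#'   (logical).
#' @export
subtract_background <- function(region, border_width = 10L,
                                contrast_frac = 0.1) {
  px <- if (inherits(region, "spot_region")) region$pixels else unclass(region)
  frame <- border_frame_values(px, as.integer(border_width))
  b_est <- stats::median(frame)
  noise_sd <- stats::mad(frame)
  high <- mean(frame > b_est + 5 * max(noise_sd, 1))
  warn <- high > contrast_frac
  if (warn) {
    warning("border-contrast warning: ", sprintf("%.0f%%", 100 * high),
            " of border pixels far above the background estimate; ",
            "the spot may overlap the region border", call. = FALSE)
  }
  list(pixels = pmax(px - b_est, 0), pixels_signed = px - b_est,
       b_est = b_est, noise_sd = noise_sd, border_warning = warn)
}

#' Locate the image maximum of a background-subtracted region
#'
#' The region is smoothed with a 3 x 3 mean filter (suppressing single hot
#' pixels, which the smoothing attenuates nine-fold) and the position of the
#' smoothed maximum is returned; ties break to the smallest row, then the
#' smallest column.
#'
#' @param region_sub background-subtracted matrix (or the list returned by
#'   [subtract_background()]).
#' @param smooth odd side length of the mean filter.
#' @return Integer `(row, col)` of the maximum.
#' @export
find_maximum <- function(region_sub, smooth = 3L) {
  px <- if (is.list(region_sub)) region_sub$pixels else region_sub
  sm <- box_mean(px, as.integer(smooth))
  if (max(sm) <= 0) stop("no signal: region is zero after background subtraction")
  argmax_rowmajor(sm)
}

gauss2d_model <- function(par, rows, cols) {
  par[["offset"]] + par[["A"]] *
    exp(-((rows - par[["r0"]])^2 + (cols - par[["c0"]])^2) /
          (2 * par[["sigma"]]^2))
}

#' Fit an isotropic 2D Gaussian to a spot
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `offset + A * exp(-((r - r0)^2 + (c - c0)^2) / (2 sigma^2))`
#' over a square fit window around the starting position. Started from the
#' window maximum (amplitude), the window-border median (offset) and
#' `sigma_init`; converged when the relative residual-sum-of-squares change
#' drops below `ftol` or after `max_iter` iterations.
#'
#' A converged fit whose amplitude falls below `floor_mult` times the
#' region's robust noise sd is flagged `"below_floor"`: the spot is too dim
#' to count as detected. Pass `noise_sd = 0` to disable the floor. A
#' converged fit whose width is far from the PSF scale (outside
#' `sigma_plausible`) is flagged `"degenerate"` — typically a single noise
#' pixel fitted as a sub-pixel "spot" — and likewise does not count as a
#' detection.
#'
#' @param region_sub background-subtracted matrix (or the
#'   [subtract_background()] list, from which the signed pixels and
#'   `noise_sd` are taken).
#' @param init integer `(row, col)` starting position, typically from
#'   [find_maximum()].
#' @param window odd fit-window side length, pixels.
#' @param sigma_init starting PSF width, pixels.
#' @param sigma_fixed optional: hold the PSF width fixed at this value and
#'   fit only amplitude, centre and offset (used for the dim FRET channel,
#'   whose PSF equals the reference channel's).
#' @param noise_sd robust background noise sd used for the amplitude floor;
#'   defaults to the value carried by the [subtract_background()] list, else 0.
#' @param floor_mult amplitude floor in units of `noise_sd`.
#' @param sigma_plausible PSF-plausibility range for the fitted width,
#'   pixels; ignored when `sigma_fixed` is given.
#' @param max_iter,ftol Levenberg-Marquardt stopping controls.
#' @return A `gauss2d_fit` object: `center` (sub-pixel, region coordinates),
#'   `amplitude`, `sigma`, `offset`, `rss`, `converged`, `n_iter`, `status`
#'   (`"ok"`, `"below_floor"`, `"degenerate"` or `"no_convergence"`), plus
#'   the fit window.
#' @export
fit_gaussian <- function(region_sub, init, window = 31L, sigma_init = 2,
                         sigma_fixed = NULL, noise_sd = NULL, floor_mult = 3,
                         sigma_plausible = c(sigma_init / 2, 4 * sigma_init),
                         max_iter = 200L, ftol = 1e-8) {
  if (is.list(region_sub) && !is.null(region_sub$pixels)) {
    if (is.null(noise_sd)) noise_sd <- region_sub$noise_sd
    region_sub <- region_sub$pixels_signed %||% region_sub$pixels
  }
  if (is.null(noise_sd)) noise_sd <- 0
  window <- as.integer(window)
  stopifnot(window >= 5L, window %% 2L == 1L)
  nr <- nrow(region_sub); nc <- ncol(region_sub)
  init <- round(init)
  stopifnot(init[1L] >= 1L, init[1L] <= nr, init[2L] >= 1L, init[2L] <= nc)
  h <- (window - 1L) %/% 2L
  r0 <- min(max(init[1L], 1L + h), nr - h)
  c0 <- min(max(init[2L], 1L + h), nc - h)
  rows_idx <- (r0 - h):(r0 + h)
  cols_idx <- (c0 - h):(c0 + h)
  win <- region_sub[rows_idx, cols_idx]
  rows <- matrix(rows_idx, window, window)
  cols <- matrix(cols_idx, window, window, byrow = TRUE)

  offset0 <- stats::median(border_frame_values(win, 1L))
  start <- c(A = max(win[init[1L] - r0 + h + 1L, init[2L] - c0 + h + 1L] -
                       offset0, 1e-6),
             r0 = as.numeric(init[1L]), c0 = as.numeric(init[2L]),
             sigma = if (is.null(sigma_fixed)) sigma_init else sigma_fixed,
             offset = offset0)
  free <- if (is.null(sigma_fixed)) {
    c("A", "r0", "c0", "sigma", "offset")
  } else c("A", "r0", "c0", "offset")
  resid_fn <- function(p) {
    p <- as.list(p)
    if (!is.null(sigma_fixed)) p$sigma <- sigma_fixed
    as.vector(win - gauss2d_model(p, rows, cols))
  }
  lower <- c(A = 0, r0 = min(rows_idx) - 1, c0 = min(cols_idx) - 1,
             sigma = 0.3, offset = -Inf)[free]
  upper <- c(A = Inf, r0 = max(rows_idx) + 1, c0 = max(cols_idx) + 1,
             sigma = window, offset = Inf)[free]
  fit <- try(minpack.lm::nls.lm(par = start[free], lower = lower,
                                upper = upper, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = max_iter, ftol = ftol)),
             silent = TRUE)
  failed <- inherits(fit, "try-error")
  if (!failed) {
    p <- as.list(fit$par)
    if (!is.null(sigma_fixed)) p$sigma <- sigma_fixed
    rss <- fit$deviance
    converged <- fit$info %in% 1:4 && is.finite(rss)
  }
  if (failed || !converged) {
    out <- list(center = c(NA_real_, NA_real_), amplitude = NA_real_,
                sigma = NA_real_, offset = NA_real_, rss = NA_real_,
                converged = FALSE, n_iter = if (failed) 0L else fit$niter,
                status = "no_convergence",
                window = c(rows_idx[1L], cols_idx[1L], window),
                noise_floor = floor_mult * noise_sd)
    class(out) <- "gauss2d_fit"
    return(out)
  }
  status <- if (p[["A"]] < floor_mult * noise_sd) {
    "below_floor"
  } else if (is.null(sigma_fixed) &&
             (p[["sigma"]] < sigma_plausible[1L] ||
                p[["sigma"]] > sigma_plausible[2L])) {
    "degenerate"
  } else "ok"
  out <- list(center = c(p[["r0"]], p[["c0"]]), amplitude = p[["A"]],
              sigma = p[["sigma"]], offset = p[["offset"]], rss = rss,
              converged = TRUE, n_iter = fit$niter, status = status,
              window = c(rows_idx[1L], cols_idx[1L], window),
              noise_floor = floor_mult * noise_sd,
              data = win, rows = rows, cols = cols)
  class(out) <- "gauss2d_fit"
  out
}

#' @export
print.gauss2d_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gauss2d_fit> not converged (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("<gauss2d_fit> A = %.3f, center = (%.3f, %.3f), ",
                     "sigma = %.3f, offset = %.3f\n"),
              x$amplitude, x$center[1L], x$center[2L], x$sigma, x$offset))
  cat(sprintf("  rss = %.4g after %d iterations; status = %s\n",
              x$rss, x$n_iter, x$status))
  invisible(x)
}

#' @export
coef.gauss2d_fit <- function(object, ...) {
  c(A = object$amplitude, r0 = object$center[1L], c0 = object$center[2L],
    sigma = object$sigma, offset = object$offset)
}

#' @export
fitted.gauss2d_fit <- function(object, ...) {
  stopifnot(object$converged)
  gauss2d_model(as.list(coef(object)), object$rows, object$cols)
}

#' @export
residuals.gauss2d_fit <- function(object, ...) {
  object$data - fitted(object)
}

#' Evaluate a fitted Gaussian surface at pixel positions
#'
#' @param object a converged `gauss2d_fit`.
#' @param newdata optional list/data.frame with `row` and `col` vectors;
#'   defaults to the fit window grid.
#' @param ... unused.
#' @return Predicted intensities.
#' @export
predict.gauss2d_fit <- function(object, newdata = NULL, ...) {
  stopifnot(object$converged)
  if (is.null(newdata)) return(fitted(object))
  gauss2d_model(as.list(coef(object)), newdata$row, newdata$col)
}

#' Quantify one SPB spot across the three FRET channels
#'
#' Each channel is independently cropped around `approx_center`,
#' background-subtracted, maximum-located and Gaussian-fitted within the same
#' crop, so spot drift between channel acquisitions (mobile nuclei) is
#' tolerated up to the crop radius. The per-channel intensity is the fitted
#' Gaussian amplitude.
#'
#' A failed or below-floor donor or acceptor fit excludes the spot (both
#' reference channels must carry a detected spot). The FRET channel is
#' handled differently, because it may legitimately be near-dim (pure
#' spillover when nothing interacts): its maximum is searched only within
#' `fret_search_radius` of the reference-channel fitted centres (the spot
#' cannot have drifted further), its PSF width is held at the acceptor
#' channel's fitted width (sensitized emission is acceptor emission, so the
#' two share a PSF), and a converged FRET fit is used even below the
#' amplitude floor. Only when the FRET fit does not converge (or the channel
#' has no signal) does the quantification fall back to the smoothed maximum
#' inside the fit window, flagged `"fallback_max"`.
#'
#' @param donor,acceptor,fret the three channel images of one field.
#' @param approx_center approximate spot position `(row, col)` shared by the
#'   three crops; defaults to the image centre.
#' @param crop_size crop window side, pixels.
#' @param fit_window Gaussian fit window side, pixels.
#' @param smooth mean-filter side used by maximum finding and the fallback.
#' @param floor_mult amplitude noise floor in robust-sd units.
#' @param fret_search_radius half-width, pixels, of the FRET-channel maximum
#'   search box around the reference centres; covers the inter-channel
#'   drift bound.
#' @param field_id identifier copied into the output row.
#' @return One-row `data.frame`: `field_id`, `I_green`, `I_red`, `I_fret`,
#'   per-channel sigmas and statuses, overall `status`
#'   (`"ok"`/`"excluded"`) and `reason`. The per-channel fits are attached
#'   as the `"fits"` attribute.
#' @export
quantify_spot <- function(donor, acceptor, fret, approx_center = NULL,
                          crop_size = 200L, fit_window = 31L, smooth = 3L,
                          floor_mult = 3, fret_search_radius = 20L,
                          field_id = "spot") {
  if (is.null(approx_center)) {
    approx_center <- c((nrow(donor) + 1) / 2, (ncol(donor) + 1) / 2)
  }
  channels <- list(donor = donor, acceptor = acceptor, fret = fret)
  fits <- list()
  amps <- c(donor = NA_real_, acceptor = NA_real_, fret = NA_real_)
  sigmas <- amps
  statuses <- c(donor = "no_signal", acceptor = "no_signal",
                fret = "no_signal")
  ref_centers <- list()
  for (ch in c("donor", "acceptor")) {
    reg <- crop_region(channels[[ch]], approx_center, crop_size)
    sub <- suppressWarnings(subtract_background(reg))
    mx <- try(find_maximum(sub, smooth), silent = TRUE)
    if (inherits(mx, "try-error")) next
    ft <- fit_gaussian(sub, mx, window = fit_window,
                       noise_sd = sub$noise_sd, floor_mult = floor_mult)
    fits[[ch]] <- ft
    statuses[[ch]] <- ft$status
    if (ft$converged) {
      amps[[ch]] <- ft$amplitude
      sigmas[[ch]] <- ft$sigma
      if (ft$status == "ok") ref_centers[[ch]] <- ft$center
    }
  }

  reg <- crop_region(channels$fret, approx_center, crop_size)
  sub <- suppressWarnings(subtract_background(reg))
  sm <- box_mean(sub$pixels, smooth)
  if (length(ref_centers)) {
    # restrict the search to the drift neighbourhood of the reference spot
    ctr <- round(Reduce(`+`, ref_centers) / length(ref_centers))
    rs <- max(1L, ctr[1L] - fret_search_radius):
      min(nrow(sm), ctr[1L] + fret_search_radius)
    cs <- max(1L, ctr[2L] - fret_search_radius):
      min(ncol(sm), ctr[2L] + fret_search_radius)
  } else {
    rs <- seq_len(nrow(sm)); cs <- seq_len(ncol(sm))
  }
  mx <- NULL
  if (max(sm[rs, cs]) > 0) {
    loc <- argmax_rowmajor(sm[rs, cs])
    mx <- c(rs[1L] + loc[1L] - 1L, cs[1L] + loc[2L] - 1L)
  } else {
    # a FRET channel with nothing above background is a valid zero signal
    amps[["fret"]] <- 0
  }
  if (!is.null(mx)) {
    sigma_ref <- if (statuses[["acceptor"]] == "ok") {
      sigmas[["acceptor"]]
    } else if (statuses[["donor"]] == "ok") sigmas[["donor"]] else NULL
    ft <- fit_gaussian(sub, mx, window = fit_window, sigma_fixed = sigma_ref,
                       noise_sd = sub$noise_sd, floor_mult = floor_mult)
    fits[["fret"]] <- ft
    statuses[["fret"]] <- ft$status
    if (ft$converged) {
      amps[["fret"]] <- ft$amplitude
      sigmas[["fret"]] <- ft$sigma
    } else {
      # weak-signal fallback: smoothed maximum inside the fit window
      h <- (fit_window - 1L) %/% 2L
      frs <- max(1L, mx[1L] - h):min(nrow(sm), mx[1L] + h)
      fcs <- max(1L, mx[2L] - h):min(ncol(sm), mx[2L] + h)
      amps[["fret"]] <- max(sm[frs, fcs])
      statuses[["fret"]] <- "fallback_max"
    }
  }
  ok_by_ch <- c(donor = statuses[["donor"]] == "ok",
                acceptor = statuses[["acceptor"]] == "ok",
                fret = statuses[["fret"]] %in% c("ok", "below_floor",
                                                 "fallback_max",
                                                 "no_signal"))
  status <- if (all(ok_by_ch)) "ok" else "excluded"
  reason <- if (status == "ok") "" else {
    paste(names(statuses)[!ok_by_ch], statuses[!ok_by_ch],
          sep = ": ", collapse = "; ")
  }
  out <- data.frame(field_id = field_id,
                    I_green = amps[["donor"]], I_red = amps[["acceptor"]],
                    I_fret = amps[["fret"]],
                    sigma_green = sigmas[["donor"]],
                    sigma_red = sigmas[["acceptor"]],
                    sigma_fret = sigmas[["fret"]],
                    status_green = statuses[["donor"]],
                    status_red = statuses[["acceptor"]],
                    status_fret = statuses[["fret"]],
                    status = status, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Quantify every field of a simulated (or on-disk) strain dataset
#'
#' Runs [quantify_spot()] on each record of a dataset manifest, reading the
#' channel TIFFs from `dir` (or using in-memory fields when present).
#'
#' @param manifest manifest from [make_fret_dataset()] /
#'   [make_single_label_dataset()] or [read_manifest()].
#' @param dir directory holding the TIFFs named in the manifest; `NULL` for
#'   in-memory manifests.
#' @param ... passed on to [quantify_spot()].
#' @return `data.frame` with one row per field (accepted and excluded).
#' @export
quantify_dataset <- function(manifest, dir = NULL, ...) {
  recs <- manifest$records
  rows <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    field <- if (!is.null(manifest$fields)) {
      manifest$fields[[i]]
    } else {
      lapply(rec$files[c("donor", "acceptor", "fret")], function(fn) {
        read_fluor_tiff(file.path(dir, fn))
      })
    }
    quantify_spot(field$donor, field$acceptor, field$fret,
                  field_id = rec$field_id, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
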
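#' Estimate one spillover coefficient from single-label measurements
#'
#' Spillover (bleed-through) is the fraction of a fluorophore's signal that
#' appears in the FRET detection channel. It is calibrated from control
#' strains carrying only the donor or only the acceptor fusion: for every
#' measured spot the ratio of the FRET-channel amplitude to the labelled
#' channel's amplitude is formed, and the coefficient is the median ratio —
#' robust against amplitude-dependent noise — with the median absolute
#' deviation as dispersion.
#'
#' @param measurements `data.frame` of per-spot quantifications (as from
#'   [quantify_dataset()]), each with a labelled-channel amplitude and
#'   `I_fret`. Spots where the labelled amplitude is missing or at/below the
#'   noise floor are excluded and counted.
#' @param channel `"donor"` (labelled amplitude = `I_green`, estimates
#'   `s_green`) or `"acceptor"` (`I_red`, estimates `s_red`).
#' @param noise_floor minimum usable labelled-channel amplitude, counts.
#' @param min_n minimum number of usable spots; fewer is a calibration error.
#' @return A `spillover_estimate`: list with `s`, `mad`, `n`, `n_excluded`,
#'   `channel`.
#' @export
estimate_spillover <- function(measurements, channel = c("donor", "acceptor"),
                               noise_floor = 0, min_n = 10L) {
  channel <- match.arg(channel)
  labelled <- if (channel == "donor") measurements$I_green else
    measurements$I_red
  i_fret <- measurements$I_fret
  usable <- is.finite(labelled) & is.finite(i_fret) & labelled > noise_floor
  n <- sum(usable)
  if (n < min_n) {
    stop("calibration error: only ", n, " usable ", channel,
         "-labelled spots (minimum ", min_n, ")")
  }
  ratios <- i_fret[usable] / labelled[usable]
  est <- stats::median(ratios)
  if (est < 0 || est >= 1) {
    stop("calibration error: estimated ", channel, " spillover ",
         signif(est, 3), " outside [0, 1)")
  }
  structure(list(s = est, mad = stats::mad(ratios), n = n,
                 n_excluded = sum(!usable), channel = channel),
            class = "spillover_estimate")
}

#' @export
print.spillover_estimate <- function(x, ...) {
  cat(sprintf("<spillover_estimate> %s: s = %.4f (MAD %.4f, n = %d, %d excluded)\n",
              x$channel, x$s, x$mad, x$n, x$n_excluded))
  invisible(x)
}

#' Bundle the two spillover coefficients
#'
#' @param s_green,s_red donor and acceptor spillover coefficients in `[0, 1)`.
#' @param n_green,n_red spot counts behind each estimate.
#' @param mad_green,mad_red robust dispersions of the per-spot ratios.
#' @return A `spillover_coefficients` object.
#' @export
spillover_coefficients <- function(s_green, s_red, n_green = NA_integer_,
                                   n_red = NA_integer_, mad_green = NA_real_,
                                   mad_red = NA_real_) {
  stopifnot(s_green >= 0, s_green < 1, s_red >= 0, s_red < 1)
  structure(list(s_green = s_green, s_red = s_red, n_green = n_green,
                 n_red = n_red, mad_green = mad_green, mad_red = mad_red),
            class = "spillover_coefficients")
}

#' @export
print.spillover_coefficients <- function(x, ...) {
  cat(sprintf("<spillover_coefficients> s_green = %.4f (n = %s), s_red = %.4f (n = %s)\n",
              x$s_green, x$n_green, x$s_red, x$n_red))
  invisible(x)
}

#' Calibrate both spillover coefficients from two single-label datasets
#'
#' @param donor_measurements,acceptor_measurements per-spot quantifications
#'   of the donor-only and acceptor-only control datasets.
#' @inheritParams estimate_spillover
#' @return A [spillover_coefficients()] object.
#' @export
calibrate_spillover <- function(donor_measurements, acceptor_measurements,
                                noise_floor = 0, min_n = 10L) {
  g <- estimate_spillover(donor_measurements, "donor", noise_floor, min_n)
  r <- estimate_spillover(acceptor_measurements, "acceptor", noise_floor,
                          min_n)
  spillover_coefficients(g$s, r$s, g$n, r$n, g$mad, r$mad)
}

#' Write / read spillover coefficients as JSON
#'
#' @param s a [spillover_coefficients()] object.
#' @param path JSON file path.
#' @return `path` (write) or the object (read).
#' @export
write_spillover <- function(s, path) {
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spillover
#' @export
read_spillover <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spillover_coefficients(x$s_green, x$s_red, x$n_green %||% NA_integer_,
                         x$n_red %||% NA_integer_, x$mad_green %||% NA_real_,
                         x$mad_red %||% NA_real_)
}
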
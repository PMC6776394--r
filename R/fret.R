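#' Compute the ratiometric FRET index FRETR
#'
#' FRETR is the FRET-channel signal divided by the total spillover expected
#' there from the two directly excited fluorophores:
#' \deqn{FRETR = I_{fret} / (s_{green} I_{green} + s_{red} I_{red}).}
#' With exact spillover coefficients and no energy transfer the FRET channel
#' carries pure spillover, so FRETR = 1; elevated values indicate sensitized
#' emission and hence molecular proximity (< ~10 nm).
#'
#' @param I_green,I_red,I_fret channel amplitudes, counts (vectorized).
#' @param s a [spillover_coefficients()] object.
#' @return Numeric FRETR values; a nonpositive denominator yields `NA` with
#'   a warning (the measurement is rejected).
#' @export
compute_fretr <- function(I_green, I_red, I_fret, s) {
  stopifnot(inherits(s, "spillover_coefficients"))
  denom <- s$s_green * I_green + s$s_red * I_red
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad), " measurement(s) rejected: nonpositive total spillover",
            call. = FALSE)
  }
  out <- I_fret / denom
  out[bad] <- NA_real_
  out
}

#' Attach FRETR values to a table of per-spot measurements
#'
#' @param measurements `data.frame` from [quantify_dataset()].
#' @param s a [spillover_coefficients()] object.
#' @param strain strain label stored with every row.
#' @return A `fret_measurements` data.frame: accepted rows carry `fretr`;
#'   rows excluded upstream or with nonpositive denominators keep `NA` and a
#'   reason.
#' @export
fret_measurements <- function(measurements, s, strain = "strain") {
  m <- measurements
  m$strain <- strain
  m$fretr <- NA_real_
  ok <- m$status == "ok"
  if (any(ok)) {
    m$fretr[ok] <- suppressWarnings(
      compute_fretr(m$I_green[ok], m$I_red[ok], m$I_fret[ok], s))
    rejected <- ok & !is.finite(m$fretr)
    m$status[rejected] <- "excluded"
    m$reason[rejected] <- "nonpositive total spillover"
  }
  class(m) <- c("fret_measurements", "data.frame")
  m
}

#' Five-number boxplot summary of one strain's FRETR distribution
#'
#' Median and hinges use linear-interpolation quantiles (R's default type 7);
#' whiskers reach the most extreme data point within 1.5 interquartile
#' ranges of the respective hinge — the usual boxplot convention.
#'
#' @param x numeric FRETR values (or a `fret_measurements` table, from which
#'   accepted `fretr` values are taken).
#' @param strain strain label.
#' @return A `strain_summary` one-row data.frame: `strain`, `n`, `median`,
#'   `q25`, `q75`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_strain <- function(x, strain = "strain") {
  if (is.data.frame(x)) {
    if ("strain" %in% names(x) && length(unique(x$strain)) == 1L) {
      strain <- x$strain[1L]
    }
    x <- x$fretr[x$status == "ok"]
  }
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no measurements to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  eps <- 1e-8 * max(1, abs(q))   # fence comparisons robust to fp rounding
  lo <- min(x[x >= q[1L] - 1.5 * iqr - eps])
  hi <- max(x[x <= q[3L] + 1.5 * iqr + eps])
  out <- data.frame(strain = strain, n = length(x), median = q[2L],
                    q25 = q[1L], q75 = q[3L], whisker_lo = lo,
                    whisker_hi = hi, stringsAsFactors = FALSE)
  class(out) <- c("strain_summary", "data.frame")
  out
}

#' Classify a strain's FRETR distribution against the negative control
#'
#' Three qualitative classes: `"background"` when the strain median does not
#' exceed the negative control's median; `"weak"` when above it but below
#' the high threshold; `"high"` at or above it. The default high threshold
#' of 1.2 sits between "median around 1, suggesting no FRET" and clearly
#' elevated distributions, and is configurable.
#'
#' @param summary,negative_control [summarize_strain()] rows.
#' @param high_threshold FRETR median at or above which the class is "high".
#' @return Character class, with the thresholds used as attributes.
#' @export
classify_strain <- function(summary, negative_control, high_threshold = 1.2) {
  stopifnot(nrow(summary) == 1L, nrow(negative_control) == 1L)
  m <- summary$median
  cls <- if (m <= negative_control$median) {
    "background"
  } else if (m < high_threshold) "weak" else "high"
  structure(cls, control_median = negative_control$median,
            high_threshold = high_threshold)
}

#' Relative red-channel intensity table across strains
#'
#' Per-strain median of the fitted red (acceptor) amplitudes, scaled so the
#' weakest strain is exactly 1 — the normalization used to compare labelled
#' SPB component abundances between strains.
#'
#' @param per_strain_red_amplitudes named list of per-spot red amplitude
#'   vectors, or a named numeric of per-strain medians.
#' @return An `intensity_table`: named numeric, minimum entry 1.
#' @export
relative_intensity_table <- function(per_strain_red_amplitudes) {
  x <- per_strain_red_amplitudes
  med <- if (is.list(x)) {
    vapply(x, function(v) stats::median(v[is.finite(v)]), numeric(1L))
  } else x
  med <- med[is.finite(med)]
  if (length(med) == 0L) stop("no usable strains for the intensity table")
  out <- med / min(med)
  class(out) <- "intensity_table"
  out
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("<intensity_table> relative red-channel intensity (weakest = 1)\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Intensity ratio between two strains, formatted "1:x"
#'
#' @param table an [relative_intensity_table()] result.
#' @param a,b strain names; the ratio reported is `value(a) / value(b)`.
#' @return Character `"1:x"` with `x` rounded to 2 decimals; the unrounded
#'   ratio is attached as attribute `"ratio"`.
#' @export
intensity_ratio <- function(table, a, b) {
  if (!a %in% names(table)) stop("strain not in table: ", a)
  if (!b %in% names(table)) stop("strain not in table: ", b)
  x <- unclass(table)[[a]] / unclass(table)[[b]]
  structure(sprintf("1:%.2f", x), ratio = x)
}

#' Boxplot of FRETR distributions by strain
#'
#' Median bar, hinges at the quartiles, whiskers at 1.5 IQR and the
#' individual measurements overlaid as jittered points; the number above
#' each box is the number of SPBs measured.
#'
#' @param x a `fret_measurements` table (possibly several strains combined
#'   with `rbind`).
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, the list of per-strain FRETR vectors plotted.
#' @export
plot.fret_measurements <- function(x, ...) {
  ok <- x$status == "ok" & is.finite(x$fretr)
  groups <- split(x$fretr[ok], x$strain[ok])
  graphics::boxplot(groups, range = 1.5, outline = FALSE,
                    ylab = "FRETR", ...)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    graphics::points(i + stats::runif(length(g), -0.15, 0.15), g,
                     pch = 16, cex = 0.5,
                     col = grDevices::adjustcolor("steelblue", 0.6))
    graphics::text(i, max(g), labels = length(g), pos = 3, cex = 0.8)
  }
  graphics::abline(h = 1, lty = 3, col = "grey40")
  invisible(groups)
}
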
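#' Configuration for the FRET quantification pipeline
#'
#' @param strain_dirs named character vector mapping strain names to dataset
#'   directories (each holding channel TIFFs plus `manifest.json`).
#' @param negative_control name of the negative-control strain (classes are
#'   assigned relative to its FRETR median).
#' @param spillover_file optional JSON with pre-calibrated coefficients
#'   (see [write_spillover()]); alternative to the calibration directories.
#' @param donor_calibration_dir,acceptor_calibration_dir single-label
#'   dataset directories used to calibrate spillover when no
#'   `spillover_file` is given.
#' @param crop_size analysis crop side, pixels.
#' @param fit_window Gaussian fit window side, pixels (odd).
#' @param smooth mean-filter side for maximum finding, pixels (odd).
#' @param floor_mult amplitude noise floor, robust-sd units.
#' @param high_threshold FRETR median at/above which a strain is classified
#'   "high".
#' @param min_calibration_spots minimum usable spots per spillover estimate.
#' @param out_dir run output directory.
#' @param seed integer seed recorded in the log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(strain_dirs = character(0),
                            negative_control = NULL,
                            spillover_file = NULL,
                            donor_calibration_dir = NULL,
                            acceptor_calibration_dir = NULL,
                            crop_size = 200L, fit_window = 31L, smooth = 3L,
                            floor_mult = 3, high_threshold = 1.2,
                            min_calibration_spots = 10L,
                            out_dir = tempfile("fretrun"), seed = 1L) {
  structure(list(strain_dirs = strain_dirs,
                 negative_control = negative_control,
                 spillover_file = spillover_file,
                 donor_calibration_dir = donor_calibration_dir,
                 acceptor_calibration_dir = acceptor_calibration_dir,
                 crop_size = as.integer(crop_size),
                 fit_window = as.integer(fit_window),
                 smooth = as.integer(smooth), floor_mult = floor_mult,
                 high_threshold = high_threshold,
                 min_calibration_spots = as.integer(min_calibration_spots),
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return Character vector of violations, each naming the offending field
#'   and its allowed range; `character(0)` when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$crop_size >= 8L,
      "crop_size: must be an integer >= 8 pixels")
  chk(config$fit_window >= 5L && config$fit_window %% 2L == 1L,
      "fit_window: must be an odd integer >= 5 pixels")
  chk(config$fit_window <= config$crop_size,
      "fit_window: must not exceed crop_size")
  chk(config$smooth >= 1L && config$smooth %% 2L == 1L,
      "smooth: must be an odd integer >= 1")
  chk(config$floor_mult >= 0, "floor_mult: must be >= 0")
  chk(config$high_threshold > 0, "high_threshold: must be > 0")
  chk(config$min_calibration_spots >= 1L,
      "min_calibration_spots: must be an integer >= 1")
  chk(is.numeric(config$seed) && length(config$seed) == 1L &&
        is.finite(config$seed),
      "seed: must be a single finite number")
  if (length(config$strain_dirs)) {
    chk(!is.null(names(config$strain_dirs)) &&
          all(nzchar(names(config$strain_dirs))),
        "strain_dirs: must be a named vector (strain -> directory)")
    if (!is.null(config$negative_control)) {
      chk(config$negative_control %in% names(config$strain_dirs),
          "negative_control: must name an entry of strain_dirs")
    }
  }
  v
}

quantify_dir <- function(dir, config) {
  man <- read_manifest(file.path(dir, "manifest.json"))
  quantify_dataset(man, dir, crop_size = config$crop_size,
                   fit_window = config$fit_window, smooth = config$smooth,
                   floor_mult = config$floor_mult)
}

#' Run the full FRETR pipeline
#'
#' Stages: spillover calibration (or load) -> per-spot three-channel
#' quantification -> FRETR -> per-strain summaries and interaction classes
#' relative to the negative control. Every excluded spot is logged with its
#' reason; the run directory receives `measurements.csv`, `summaries.csv`,
#' `spillover.json`, `fretr_boxplot.png` and `run.log`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `measurements`, `summaries`, `spillover`
#'   and `out_dir`.
#' @export
run_fret_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("configuration error:\n  ", paste(violations, collapse = "\n  "))
  }
  if (length(config$strain_dirs) == 0L) {
    stop("configuration error: no strain_dirs to quantify")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat("# pipeline_config\n",
      jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                       pretty = TRUE),
      "\n", file = log_path, sep = "")

  # spillover: load, or calibrate from single-label data
  s <- if (!is.null(config$spillover_file)) {
    log_line("loading spillover from ", config$spillover_file)
    read_spillover(config$spillover_file)
  } else if (!is.null(config$donor_calibration_dir) &&
             !is.null(config$acceptor_calibration_dir)) {
    log_line("calibrating spillover from single-label datasets")
    calibrate_spillover(
      quantify_dir(config$donor_calibration_dir, config),
      quantify_dir(config$acceptor_calibration_dir, config),
      min_n = config$min_calibration_spots)
  } else {
    stop("configuration error: no spillover_file and no calibration ",
         "directories; spillover coefficients are required")
  }
  log_line(sprintf("spillover: s_green = %.4f, s_red = %.4f",
                   s$s_green, s$s_red))
  write_spillover(s, file.path(config$out_dir, "spillover.json"))

  all_meas <- list()
  for (strain in names(config$strain_dirs)) {
    meas <- quantify_dir(config$strain_dirs[[strain]], config)
    fm <- fret_measurements(meas, s, strain)
    n_exc <- sum(fm$status != "ok")
    log_line(sprintf("%s: %d spots, %d accepted, %d excluded", strain,
                     nrow(fm), nrow(fm) - n_exc, n_exc))
    if (n_exc > 0L) {
      tab <- table(fm$reason[fm$status != "ok"])
      for (r in names(tab)) {
        log_line(sprintf("  excluded (%s): %d", r, tab[[r]]))
      }
    }
    all_meas[[strain]] <- fm
  }
  measurements <- do.call(rbind, all_meas)
  rownames(measurements) <- NULL
  class(measurements) <- c("fret_measurements", "data.frame")

  summaries <- do.call(rbind, lapply(all_meas, summarize_strain))
  rownames(summaries) <- NULL
  if (!is.null(config$negative_control)) {
    ctrl <- summaries[summaries$strain == config$negative_control, ]
    summaries$interaction_class <- vapply(seq_len(nrow(summaries)),
      function(i) as.character(classify_strain(summaries[i, ], ctrl,
                                               config$high_threshold)),
      character(1L))
    summaries$control_median <- ctrl$median
    summaries$high_threshold <- config$high_threshold
  }
  for (i in seq_len(nrow(summaries))) {
    log_line(sprintf("%s: median FRETR %.3f (n = %d)%s", summaries$strain[i],
                     summaries$median[i], summaries$n[i],
                     if ("interaction_class" %in% names(summaries)) {
                       paste0(", class ", summaries$interaction_class[i])
                     } else ""))
  }

  utils::write.csv(measurements,
                   file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(config$out_dir, "fretr_boxplot.png"),
                 width = 900, height = 600)
  with_seed(config$seed, plot(measurements))
  grDevices::dev.off()

  invisible(list(measurements = measurements, summaries = summaries,
                 spillover = s, out_dir = config$out_dir))
}
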
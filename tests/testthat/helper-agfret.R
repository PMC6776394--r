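# Shared fixtures: all synthetic, generated at test time.

# camera model with every stochastic element switched off
noiseless_cfg <- function(...) {
  sim_config(poisson_noise = FALSE, read_noise_sd = 0, drift_sd = 0, ...)
}

centered_truth <- function(amp_donor = 500, amp_acceptor = 400, f = 0,
                           center = c(100.5, 99.5), sigma = 2,
                           background = 100) {
  spot_truth("fix", center, center, center, amp_donor = amp_donor,
             amp_acceptor = amp_acceptor, sigma = sigma,
             background = background, transfer_fraction = f)
}

# independent linear-interpolation quantile (sort + positional interpolation),
# written without stats::quantile so it can serve as an oracle
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  frac <- h - lo
  if (lo + 2L > n) return(x[n])
  x[lo + 1L] * (1 - frac) + x[lo + 2L] * frac
}

# exhaustive grid-search oracle for the 2D Gaussian fit: best rss over a
# 5-parameter grid; independent of the Levenberg-Marquardt path
grid_fit_oracle <- function(win, rows, cols, center_grid, amp_grid,
                            sigma_grid, offset_grid) {
  best <- list(rss = Inf)
  for (r0 in center_grid$r) for (c0 in center_grid$c) {
    e <- exp(-((rows - r0)^2 + (cols - c0)^2))
    for (sg in sigma_grid) {
      g <- e^(1 / (2 * sg^2))
      for (a in amp_grid) for (off in offset_grid) {
        rss <- sum((win - off - a * g)^2)
        if (rss < best$rss) {
          best <- list(rss = rss, A = a, r0 = r0, c0 = c0, sigma = sg,
                       offset = off)
        }
      }
    }
  }
  best
}

quiet_quantify <- function(...) suppressWarnings(quantify_dataset(...))
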
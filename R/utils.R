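# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the session stream.
#' A `NULL` seed runs `expr` on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 3x3 (or k x k) box-mean smoothing with edge-aware normalisation: border
# pixels are averaged over the part of the kernel that falls inside the image.
box_mean <- function(x, k = 3L) {
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -h:h) {
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    rd <- rs + dr
    for (dc in -h:h) {
      cs <- max(1L, 1L - dc):min(nc, nc - dc)
      cd <- cs + dc
      acc[rd, cd] <- acc[rd, cd] + x[rs, cs]
      cnt[rd, cd] <- cnt[rd, cd] + 1
    }
  }
  acc / cnt
}

# First (row-major lexicographic) position of the matrix maximum.
argmax_rowmajor <- function(x) {
  m <- max(x)
  idx <- which(x == m, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  c(row = idx[1L, 1L], col = idx[1L, 2L])
}

# Isotropic 2D Gaussian surface on a pixel grid (1-based pixel centres).
gauss2d_surface <- function(nrow, ncol, center, amplitude, sigma, offset = 0) {
  r <- seq_len(nrow) - center[1L]
  c_ <- seq_len(ncol) - center[2L]
  offset + amplitude * outer(exp(-r^2 / (2 * sigma^2)),
                             exp(-c_^2 / (2 * sigma^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
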
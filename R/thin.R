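# Morphological thinning and skeleton path length for needle-shaped objects.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels (two sub-iterations per pass) until the
#' mask is reduced to a one-pixel-wide, 8-connected skeleton.
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter safety cap on thinning passes.
#' @return Logical skeleton matrix of the same size.
#' @export
thin_mask <- function(mask, max_iter = 100L) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  for (pass in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (row - 1)
      p2 <- shift_mat(m, 1L, 0L);  p3 <- shift_mat(m, 1L, -1L)
      p4 <- shift_mat(m, 0L, -1L); p5 <- shift_mat(m, -1L, -1L)
      p6 <- shift_mat(m, -1L, 0L); p7 <- shift_mat(m, -1L, 1L)
      p8 <- shift_mat(m, 0L, 1L);  p9 <- shift_mat(m, 1L, 1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Running-mean smoothing of an ordered pixel path (n x 2), with shrinking
# windows at the ends; removes the staircase of 8-connected chains so the
# polyline length is orientation-unbiased.
smooth_path <- function(coords, half = 3L) {
  n <- nrow(coords)
  if (n <= 2L) return(coords)
  out <- coords
  for (i in seq_len(n)) {
    w <- max(1L, i - half):min(n, i + half)
    out[i, ] <- colMeans(coords[w, , drop = FALSE])
  }
  out
}

# Geodesic length (px) of a skeleton: the longest shortest path between
# skeleton endpoints (Dijkstra over the 8-connected pixel graph with
# Euclidean step weights), measured as the arc length of the smoothed path
# coordinates. Returns the length and the (row, col) of the two path ends.
skeleton_path_length <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(list(length_px = 0, ends = NULL))
  if (n == 1L) return(list(length_px = 0, ends = idx[c(1L, 1L), , drop = FALSE]))
  key <- paste(idx[, 1L], idx[, 2L])
  lookup <- seq_len(n)
  names(lookup) <- key
  from <- integer(0); to <- integer(0); w <- numeric(0)
  steps <- rbind(c(1L, 0L, 1), c(0L, 1L, 1),
                 c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))
  for (s in seq_len(nrow(steps))) {
    nb <- paste(idx[, 1L] + steps[s, 1L], idx[, 2L] + steps[s, 2L])
    hit <- !is.na(lookup[nb])
    from <- c(from, lookup[key[hit]])
    to <- c(to, lookup[nb[hit]])
    w <- c(w, rep(steps[s, 3L], sum(hit)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::E(g)$weight <- w
  deg <- igraph::degree(g)
  cand <- which(deg <= 1L)
  if (length(cand) < 2L) cand <- seq_len(n)   # looped skeleton: all pairs
  d <- igraph::distances(g, v = cand, to = cand)
  d[!is.finite(d)] <- 0
  best <- which(d == max(d), arr.ind = TRUE)[1L, ]
  vpath <- igraph::shortest_paths(g, from = cand[best[1L]],
                                  to = cand[best[2L]])$vpath[[1L]]
  path_idx <- as.integer(igraph::as_ids(vpath))
  coords <- idx[path_idx, , drop = FALSE]
  sm <- smooth_path(coords)
  len <- if (nrow(sm) > 1L) sum(sqrt(rowSums(diff(sm)^2))) else 0
  ends <- idx[c(cand[best[1L]], cand[best[2L]]), , drop = FALSE]
  list(length_px = len, ends = ends, path = sm)
}

# How far the object extends beyond a path end along the outward direction:
# the maximal projection of nearby component pixels onto that direction.
end_extension <- function(comp_idx, path, at_start, radius = 12) {
  n <- nrow(path)
  if (n < 4L) return(0)
  e <- if (at_start) path[1L, ] else path[n, ]
  inner <- if (at_start) path[min(6L, n), ] else path[max(n - 5L, 1L), ]
  u <- e - inner
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) return(0)
  u <- u / nu
  near <- abs(comp_idx[, 1L] - e[1L]) <= radius &
    abs(comp_idx[, 2L] - e[2L]) <= radius
  if (!any(near)) return(0)
  proj <- (comp_idx[near, 1L] - e[1L]) * u[1L] +
    (comp_idx[near, 2L] - e[2L]) * u[2L]
  max(0, max(proj))
}
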
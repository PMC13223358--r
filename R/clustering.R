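# Spatial clustering primitives used by candidate-center estimation:
# fixed-radius neighbor search, DBSCAN, and flat-kernel mean shift.

# Fixed-radius neighbor lists via grid bucketing: points are binned into
# cells of side `eps`; neighbors can only lie in the 3x3 surrounding block.
radius_neighbors <- function(coords, eps) {
  n <- nrow(coords)
  ix <- floor(coords[, 1] / eps)
  iy <- floor(coords[, 2] / eps)
  key <- paste(ix, iy)
  buckets <- split(seq_len(n), key)
  out <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(ix[i] + dx, iy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (coords[cand, 1] - coords[i, 1])^2 +
          (coords[cand, 2] - coords[i, 2])^2
    out[[i]] <- cand[d2 <= eps2]
  }
  out
}

# DBSCAN with Euclidean eps-neighborhoods. Follows the usual convention that
# the neighborhood of a point includes the point itself and that a point is
# core when it has at least `min_pts` neighbors (min_pts = 5 by default).
# Returns integer labels, 0 = noise.
dbscan_points <- function(coords, eps, min_pts = 5L) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  nbr <- radius_neighbors(coords, eps)
  core <- vapply(nbr, length, 1L) >= min_pts
  labels <- integer(n)           # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nbr[[i]]
    while (length(frontier)) {
      frontier <- frontier[labels[frontier] == 0L]
      if (!length(frontier)) break
      labels[frontier] <- cl
      frontier <- unique(unlist(nbr[frontier[core[frontier]]]))
    }
  }
  labels
}

# Flat-kernel mean shift. Every point is a seed; each seed iterates to the
# mean of points within `bandwidth` until convergence, and modes closer than
# `bandwidth` are merged (densest first). Returns the matrix of mode centers.
mean_shift <- function(coords, bandwidth, max_iter = 300L, tol = 1e-4) {
  if (nrow(coords) == 0L) stop("mean shift on empty input")
  seeds <- unique(coords)
  modes <- seeds
  sizes <- numeric(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    pt <- seeds[s, ]
    for (it in seq_len(max_iter)) {
      d2 <- (coords[, 1] - pt[1])^2 + (coords[, 2] - pt[2])^2
      within <- d2 <= bandwidth^2
      new_pt <- c(mean(coords[within, 1]), mean(coords[within, 2]))
      if (sum((new_pt - pt)^2) < (tol * bandwidth)^2) { pt <- new_pt; break }
      pt <- new_pt
    }
    modes[s, ] <- pt
    sizes[s] <- sum((coords[, 1] - pt[1])^2 +
                    (coords[, 2] - pt[2])^2 <= bandwidth^2)
  }
  ord <- order(sizes, decreasing = TRUE)
  kept <- matrix(numeric(0), 0, 2)
  for (s in ord) {
    if (nrow(kept) == 0L ||
        all((kept[, 1] - modes[s, 1])^2 +
            (kept[, 2] - modes[s, 2])^2 > bandwidth^2)) {
      kept <- rbind(kept, modes[s, , drop = FALSE])
    }
  }
  unname(kept)
}
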
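# Planar geometry: alpha-shape boundary extraction from Delaunay
# triangulations, polygon measures, point-in-polygon tests, and polygon
# IoU via clipper-based boolean operations.

# signed shoelace area of one ring (x, y vectors, ring not closed)
ring_area_signed <- function(x, y) {
  j <- c(seq_along(x)[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area
#'
#' Total area of a polygon given as a single ring (`list(x, y)`) or a list
#' of rings (holes carry opposite orientation and subtract).
#'
#' @param poly ring or list of rings.
#' @return area (micrometers squared for micrometer coordinates).
#' @export
polygon_area <- function(poly) {
  rings <- if (!is.null(poly$x)) list(poly) else poly
  abs(sum(vapply(rings, function(r) ring_area_signed(r$x, r$y), 0)))
}

#' Polygon girth (perimeter)
#'
#' Sum of ring perimeters.
#'
#' @param poly ring or list of rings.
#' @return total boundary length.
#' @export
polygon_girth <- function(poly) {
  rings <- if (!is.null(poly$x)) list(poly) else poly
  sum(vapply(rings, function(r) {
    j <- c(seq_along(r$x)[-1L], 1L)
    sum(sqrt((r$x[j] - r$x)^2 + (r$y[j] - r$y)^2))
  }, 0))
}

#' Roundness of a polygon
#'
#' `4 * pi * area / girth^2`; 1 for a circle, `pi/4` for a square.
#'
#' @param poly ring or list of rings.
#' @return roundness in (0, 1].
#' @export
polygon_roundness <- function(poly) {
  4 * pi * polygon_area(poly) / polygon_girth(poly)^2
}

# are any of the points strictly inside or on the polygon?
points_in_polygon <- function(x, y, poly) {
  rings <- if (!is.null(poly$x)) list(poly) else poly
  inside <- rep(FALSE, length(x))
  for (r in rings)
    inside <- inside | sp::point.in.polygon(x, y, r$x, r$y) > 0
  inside
}

# circumradius of triangles given vertex coordinate matrices
tri_circumradius <- function(ax, ay, bx, by, cx, cy) {
  a <- sqrt((bx - cx)^2 + (by - cy)^2)
  b <- sqrt((ax - cx)^2 + (ay - cy)^2)
  ch <- sqrt((ax - bx)^2 + (ay - by)^2)
  K <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  ifelse(K > 0, a * b * ch / (4 * K), Inf)
}

# assemble boundary edges (each used by exactly one kept triangle) into
# rings; returns NULL unless the edges form exactly one closed ring
boundary_ring <- function(edges, px, py) {
  if (nrow(edges) < 3L) return(NULL)
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  if (any(vapply(adj, length, 1L) != 2L)) return(NULL)
  start <- edges[1L, 1L]
  ring <- start
  prev <- -1L
  cur <- start
  repeat {
    nxt <- setdiff(adj[[as.character(cur)]], prev)[1L]
    if (is.na(nxt)) return(NULL)
    if (nxt == start) break
    ring <- c(ring, nxt)
    prev <- cur
    cur <- nxt
    if (length(ring) > 2L * nrow(edges)) return(NULL)
  }
  if (length(ring) != nrow(edges)) return(NULL)  # disconnected components
  x <- px[ring]; y <- py[ring]
  if (ring_area_signed(x, y) < 0) { x <- rev(x); y <- rev(y) }
  list(x = x, y = y)
}

#' Alpha-shape boundary of a point set
#'
#' Delaunay triangulation filtered by triangle circumradius: triangles with
#' circumradius at most `1/alpha` are kept and their boundary edges traced
#' into a polygon (`alpha = 0` keeps everything and yields the convex
#' hull). With `alpha = NULL` the tightest shape that still covers every
#' point with a single closed ring is selected automatically by scanning
#' the sorted circumradii.
#'
#' @param x,y point coordinates.
#' @param alpha nonnegative alpha parameter, or `NULL` for automatic
#'   selection.
#' @return a ring `list(x, y)` (counter-clockwise, not closed), or `NULL`
#'   when the points are degenerate (< 3 unique points or collinear).
#' @export
alpha_shape <- function(x, y, alpha = NULL) {
  pts <- unique(data.frame(x = x, y = y))
  if (nrow(pts) < 3L) return(NULL)
  dd <- tryCatch(
    suppressMessages(deldir::deldir(pts$x, pts$y, suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(dd)) return(NULL)
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0L) return(NULL)
  tri <- t(vapply(tl, function(tr) c(tr$ptNum, tr$x, tr$y), numeric(9)))
  rad <- tri_circumradius(tri[, 4], tri[, 7], tri[, 5], tri[, 8],
                          tri[, 6], tri[, 9])
  edge_mat <- function(keep) {
    v <- tri[keep, 1:3, drop = FALSE]
    e <- rbind(cbind(v[, 1], v[, 2]), cbind(v[, 2], v[, 3]),
               cbind(v[, 1], v[, 3]))
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  }
  try_cutoff <- function(cut, require_cover = TRUE) {
    keep <- rad <= cut
    if (!any(keep)) return(NULL)
    if (require_cover &&
        !all(seq_len(nrow(pts)) %in% as.vector(tri[keep, 1:3])))
      return(NULL)  # some point uncovered
    boundary_ring(edge_mat(keep), pts$x, pts$y)
  }
  if (!is.null(alpha)) {
    cut <- if (alpha <= 0) Inf else 1 / alpha
    ring <- try_cutoff(cut, require_cover = FALSE)
    if (is.null(ring)) ring <- try_cutoff(Inf)  # fall back to convex hull
    return(ring)
  }
  # automatic selection: coverage is monotone in the cutoff, so binary
  # search for the smallest cutoff covering every point, then walk upward
  # until the boundary closes into a single ring
  cuts <- sort(unique(rad))
  covered <- function(cut) all(seq_len(nrow(pts)) %in%
                               as.vector(tri[rad <= cut, 1:3]))
  lo <- 1L; hi <- length(cuts)
  if (!covered(cuts[hi])) return(try_cutoff(Inf))
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (covered(cuts[mid])) hi <- mid else lo <- mid + 1L
  }
  for (ci in lo:length(cuts)) {
    ring <- try_cutoff(cuts[ci])
    if (!is.null(ring)) return(ring)
  }
  try_cutoff(Inf)
}

# polyclip wants list(list(x, y)); normalise a ring or list of rings
as_rings <- function(poly) if (!is.null(poly$x)) list(poly) else poly

# precision for clipper's integer snapping, relative to the extent
clip_eps <- function(a, b) {
  rng <- max(diff(range(unlist(lapply(c(a, b), `[[`, "x")))),
             diff(range(unlist(lapply(c(a, b), `[[`, "y")))), 1e-12)
  rng * 1e-13
}

poly_boolean_area <- function(a, b, op) {
  a <- as_rings(a); b <- as_rings(b)
  out <- polyclip::polyclip(a, b, op = op, eps = clip_eps(a, b))
  if (length(out) == 0L) return(0)
  sum(vapply(out, function(r) ring_area_signed(r$x, r$y), 0))
}

#' Intersection-over-union of two polygons
#'
#' Ratio of intersection area to union area, computed with exact polygon
#' clipping; each argument may be a single ring or a list of rings.
#'
#' @param a,b polygons.
#' @return IoU in `[0, 1]`.
#' @export
polygon_iou <- function(a, b) {
  inter <- poly_boolean_area(a, b, "intersection")
  uni <- poly_boolean_area(a, b, "union")
  if (uni <= 0) return(0)
  max(0, min(1, inter / uni))
}

polygon_centroid <- function(poly) {
  rings <- as_rings(poly)
  # area-weighted centroid over rings
  cx <- 0; cy <- 0; atot <- 0
  for (r in rings) {
    x <- r$x; y <- r$y
    j <- c(seq_along(x)[-1L], 1L)
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-300) next
    cx <- cx + sum((x + x[j]) * cr) / 6
    cy <- cy + sum((y + y[j]) * cr) / 6
    atot <- atot + a
  }
  if (atot == 0) c(mean(rings[[1]]$x), mean(rings[[1]]$y))
  else c(cx / atot, cy / atot)
}
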
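# Postprocessing: alpha-shape cell boundaries, polygon-based assignment
# refinement, whole-transcriptome imputation, and the nuclear-prior variant.

#' Alpha-shape boundaries of segmented cells
#'
#' One polygon per cell with at least three non-collinear non-noise
#' molecules; smaller or collinear cells are flagged degenerate (they keep
#' their expression profile but get no polygon).
#'
#' @param result a `segmentation_result`.
#' @param alpha fixed alpha parameter, or `NULL` (default) for automatic
#'   per-cell selection (see [alpha_shape()]).
#' @return a `cell_polygons` list; each element has `cell`, `rings`,
#'   `area`, `girth`, or `degenerate = TRUE`.
#' @export
polygonal_boundaries <- function(result, alpha = NULL) {
  asg <- result$assignment
  cells <- sort(unique(asg$cell[!is.na(asg$cell)]))
  polys <- lapply(cells, function(cc) {
    sel <- !is.na(asg$cell) & asg$cell == cc
    ring <- if (sum(sel) >= 3L)
      alpha_shape(asg$x[sel], asg$y[sel], alpha = alpha) else NULL
    if (is.null(ring))
      return(list(cell = cc, degenerate = TRUE))
    list(cell = cc, rings = list(ring), area = polygon_area(ring),
         girth = polygon_girth(ring), degenerate = FALSE)
  })
  structure(polys, class = "cell_polygons",
            cells = cells)
}

#' Refine assignments against cell polygons
#'
#' Molecules lying outside their assigned cell's polygon are reclassified
#' as noise (no reassignment to other cells); expression profiles are
#' re-aggregated. Cells without a polygon are left untouched.
#'
#' @param result a `segmentation_result`.
#' @param polygons a `cell_polygons` from [polygonal_boundaries()].
#' @return the updated `segmentation_result`.
#' @export
refine_assignments <- function(result, polygons) {
  asg <- result$assignment
  for (pp in polygons) {
    if (isTRUE(pp$degenerate)) next
    sel <- which(!is.na(asg$cell) & asg$cell == pp$cell)
    if (!length(sel)) next
    inside <- points_in_polygon(asg$x[sel], asg$y[sel], pp$rings)
    out <- sel[!inside]
    if (length(out)) {
      asg$cell[out] <- NA_integer_
      asg$noise[out] <- TRUE
    }
  }
  result$assignment <- asg
  G <- ifelse(is.na(asg$cell), 1L, asg$cell)
  H <- ifelse(asg$noise, 1L, 2L)
  result$E <- aggregate_profiles(G, H, asg$gene_code,
                                 nrow(result$candidates),
                                 length(result$genes))
  result
}

#' Impute whole-transcriptome profiles for segmented cells
#'
#' Cosine similarity of log1p expression over the panel genes links each
#' segmented cell to its `r` most similar reference cells. Reference cells
#' that appear in many top-r lists are down-weighted by their occurrence
#' score `OS_j = ln(n / O_j)` (n segmented cells, `O_j` lists containing
#' j). Each segmented cell's imputed profile is the weighted average
#' (weights = similarity * OS, sorted descending, top `k`, renormalised to
#' sum 1) of the chosen reference cells' full-transcriptome profiles — a
#' convex combination of reference profiles.
#'
#' @param E segmented cells x panel genes count matrix.
#' @param reference a `reference_panel` (uses `S` for similarity, `U` for
#'   the imputed output).
#' @param r similar reference cells retained per segmented cell (default 40).
#' @param k reference cells averaged (default 20).
#' @return an `imputed_profiles` list with `profiles` (cells x all
#'   reference genes), `type_prob` absent, `weights` (list of the chosen
#'   reference indices and weights per cell).
#' @export
impute_transcriptome <- function(E, reference, r = 40L, k = 20L) {
  n_seg <- nrow(E)
  n_ref <- nrow(reference$S)
  r <- min(r, n_ref)
  k <- min(k, r)
  A <- log1p(E)
  B <- log1p(reference$S)
  An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-12)
  sim <- tcrossprod(An, Bn)                       # n_seg x n_ref
  topr <- t(apply(sim, 1L, function(s) order(s, decreasing = TRUE)[seq_len(r)]))
  if (r == 1L) topr <- t(topr)
  O <- tabulate(as.vector(topr), nbins = n_ref)
  OS <- ifelse(O > 0, log(n_seg / O), 0)
  U <- reference$U
  out <- matrix(0, n_seg, ncol(U), dimnames = list(rownames(E), colnames(U)))
  weights <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    idx <- topr[i, ]
    w <- sim[i, idx] * OS[idx]
    ord <- order(w, decreasing = TRUE)[seq_len(k)]
    idx <- idx[ord]; w <- w[ord]
    if (sum(w) <= 0) {
      warning("all-zero imputation weights for cell ", i,
              "; using uniform weights over its top ", k)
      w <- rep(1, k)
    }
    w <- w / sum(w)
    out[i, ] <- as.numeric(w %*% U[idx, , drop = FALSE])
    weights[[i]] <- list(ref = idx, w = w)
  }
  structure(list(profiles = out, weights = weights, O = O, OS = OS,
                 r = r, k = k),
            class = "imputed_profiles")
}

# offsets to the nuclear region: for each (molecule, candidate) pair the
# vector from the nearest point of the candidate's nuclear boundary to the
# molecule, zero inside the nucleus
nuclear_offsets <- function(table, nuclei, neighbor_idx) {
  n <- nrow(table)
  m <- ncol(neighbor_idx)
  offs <- matrix(0, n * m, 2L)
  for (j in seq_len(m)) {
    rows <- (j - 1L) * n + seq_len(n)
    nb <- neighbor_idx[, j]
    for (nuc_id in unique(nb)) {
      sel <- which(nb == nuc_id)
      ring <- as_rings(nuclei[[nuc_id]])[[1L]]
      dxy <- point_to_ring_offset(table$x[sel], table$y[sel], ring)
      inside <- points_in_polygon(table$x[sel], table$y[sel], ring)
      dxy[inside, ] <- 0
      offs[rows[sel], ] <- dxy
    }
  }
  offs
}

# vector from the nearest point on the ring boundary to each query point
point_to_ring_offset <- function(x, y, ring) {
  nx <- length(ring$x)
  j <- c(seq_len(nx)[-1L], 1L)
  ax <- ring$x; ay <- ring$y
  bx <- ring$x[j]; by <- ring$y[j]
  best_d2 <- rep(Inf, length(x))
  best_px <- numeric(length(x)); best_py <- numeric(length(x))
  for (e in seq_len(nx)) {
    ex <- bx[e] - ax[e]; ey <- by[e] - ay[e]
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) ((x - ax[e]) * ex + (y - ay[e]) * ey) / len2 else 0
    t <- pmin(1, pmax(0, t))
    px <- ax[e] + t * ex; py <- ay[e] + t * ey
    d2 <- (x - px)^2 + (y - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_px[upd] <- px[upd]; best_py[upd] <- py[upd]
  }
  cbind(x - best_px, y - best_py)
}

#' Segment with nuclear boundary priors
#'
#' Uses supplied nuclear polygons as the candidate cells: the policy's
#' location offset becomes the vector to the nearest point of the
#' candidate's nuclear boundary (zero inside the nucleus). After
#' alpha-shape extraction, each cell polygon is clipped against all other
#' nuclei (overlap removed) and unioned with its own nucleus. A molecule
#' inside several overlapping nuclei contributes a zero offset to each of
#' them; the policy resolves the tie.
#'
#' @param transcripts data.frame with `x`, `y`, `gene`.
#' @param nuclei list of nuclear polygons (each a ring `list(x, y)` or a
#'   list of rings), in candidate order.
#' @param ref_counts,cell_type the scRNA-seq reference.
#' @param config a [seg_config()].
#' @param d,q noise-distance-score parameters.
#' @return a `segmentation_result` with nuclear-aware `polygons`.
#' @export
apply_nuclear_priors <- function(transcripts, nuclei, ref_counts, cell_type,
                                 config = seg_config(), d = 100L, q = 0.999) {
  enc <- encode_genes(transcripts, ref_counts, cell_type)
  nds <- compute_noise_distance_scores(enc$table, d = d, q = q)
  centers <- t(vapply(nuclei, polygon_centroid, numeric(2)))
  candidates <- as_candidate_set(centers, provenance = "nuclear")
  set.seed(config$seed)
  neighbor_idx <- nearest_candidate_cells(enc$table, candidates, config$m)
  offs <- nuclear_offsets(enc$table, nuclei, neighbor_idx)
  fit <- run_training(enc$table, candidates, enc$reference, nds, config,
                      offsets_all = offs, neighbor_idx = neighbor_idx)
  res <- final_assignment(fit, enc$table, candidates, enc$reference)
  res$fit <- fit
  res$reference <- enc$reference
  res$table <- enc$table
  res$nds <- nds
  polys <- polygonal_boundaries(res)
  eps0 <- 1e-9
  for (ii in seq_along(polys)) {
    pp <- polys[[ii]]
    if (isTRUE(pp$degenerate)) {
      # degenerate cells fall back to their nuclear polygon
      ring <- as_rings(nuclei[[pp$cell]])
      polys[[ii]] <- list(cell = pp$cell, rings = ring,
                          area = polygon_area(ring),
                          girth = polygon_girth(ring), degenerate = FALSE)
      next
    }
    rings <- pp$rings
    others <- setdiff(seq_along(nuclei), pp$cell)
    for (oo in others) {
      onuc <- as_rings(nuclei[[oo]])
      clipped <- polyclip::polyclip(rings, onuc, op = "minus", eps = eps0)
      if (length(clipped)) rings <- clipped
    }
    rings <- polyclip::polyclip(rings, as_rings(nuclei[[pp$cell]]),
                                op = "union", eps = eps0)
    polys[[ii]]$rings <- rings
    polys[[ii]]$area <- polygon_area(rings)
    polys[[ii]]$girth <- polygon_girth(rings)
  }
  res$polygons <- structure(polys, class = "cell_polygons",
                            cells = attr(polys, "cells"))
  refine_assignments(res, res$polygons)
}

#' Write cell polygons as GeoJSON
#'
#' FeatureCollection of Polygon features with a `cell_id` property.
#'
#' @param polygons a `cell_polygons`.
#' @param path output file.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(Filter(function(p) !isTRUE(p$degenerate), polygons),
    function(p) {
      coords <- lapply(p$rings, function(r)
        lapply(c(seq_along(r$x), 1L), function(i) c(r$x[i], r$y[i])))
      list(type = "Feature",
           properties = list(cell_id = p$cell),
           geometry = list(type = "Polygon", coordinates = coords))
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file with Polygon features.
#' @return a `cell_polygons` list.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    rings <- lapply(ft$geometry$coordinates, function(rr) {
      x <- vapply(rr, function(p) as.numeric(p[[1]]), 0)
      y <- vapply(rr, function(p) as.numeric(p[[2]]), 0)
      np <- length(x)
      if (np > 1L && x[1] == x[np] && y[1] == y[np]) {
        x <- x[-np]; y <- y[-np]
      }
      list(x = x, y = y)
    })
    cid <- ft$properties$cell_id %||% i
    list(cell = cid, rings = rings, area = polygon_area(rings),
         girth = polygon_girth(rings), degenerate = FALSE)
  })
  structure(polys, class = "cell_polygons")
}
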
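# Candidate cell-center estimation: marker scoring on the reference, spatial
# grid features, marker-category clustering, and a DBSCAN -> K-means ->
# MeanShift cascade over each category's molecules.

#' Score and select marker genes per cell type
#'
#' Reference counts are normalised per cell to a fixed total, averaged per
#' type (A), converted to the fraction each type contributes to the gene's
#' total mean expression (P), and scored `S = ln(A + 1) * P`. The top `p`
#' genes per type by descending score (nonzero only) are pooled, duplicates
#' removed.
#'
#' @param reference a `reference_panel` from [encode_genes()].
#' @param p markers per cell type (default 3).
#' @param norm_total per-cell normalisation total (default 1e4).
#' @return list with `markers` (character), `A` (genes x types mean
#'   normalised expression), `scores` (genes x types).
#' @export
score_markers <- function(reference, p = 3L, norm_total = 1e4) {
  S <- reference$S
  lib <- rowSums(S)
  lib[lib == 0] <- 1
  N <- S / lib * norm_total
  types <- levels(reference$cell_type)
  A <- vapply(types, function(ty)
    colMeans(N[reference$cell_type == ty, , drop = FALSE]),
    numeric(ncol(S)))                      # genes x types
  rowtot <- rowSums(A)
  P <- A / ifelse(rowtot > 0, rowtot, 1)
  sc <- log(A + 1) * P
  markers <- character(0)
  for (ty in types) {
    ord <- order(sc[, ty], decreasing = TRUE)
    ord <- ord[sc[ord, ty] > 0]
    if (length(ord) < p)
      warning("cell type '", ty, "' has only ", length(ord),
              " genes with nonzero marker score (requested ", p, ")")
    markers <- c(markers, rownames(sc)[head(ord, p)])
  }
  list(markers = unique(markers), A = A, scores = sc)
}

# Assign each molecule to its nearest grid node (grid spacing 2r over the
# molecule bounding box) and flag whether it lies within the node's adjacent
# area of radius 2r/pi. Because 2r/pi < r, that area only ever contains the
# nearest node, so nearest-node rounding is exact.
grid_layout <- function(table, r) {
  xmin <- min(table$x); ymin <- min(table$y)
  nx <- max(1L, ceiling((max(table$x) - xmin) / (2 * r)))
  ny <- max(1L, ceiling((max(table$y) - ymin) / (2 * r)))
  ixm <- pmin(nx, pmax(1L, ceiling((table$x - xmin) / (2 * r))))
  iym <- pmin(ny, pmax(1L, ceiling((table$y - ymin) / (2 * r))))
  node <- (iym - 1L) * nx + ixm
  node_x <- xmin + ((node - 1L) %% nx + 0.5) * 2 * r
  node_y <- ymin + ((node - 1L) %/% nx + 0.5) * 2 * r
  within <- (table$x - node_x)^2 + (table$y - node_y)^2 <= (2 * r / pi)^2
  list(node = node, within = within, n_nodes = nx * ny,
       nx = nx, ny = ny, xmin = xmin, ymin = ymin)
}

#' Spatial grid features of marker genes
#'
#' Lays a grid of spacing `2r` over the molecule bounding box and counts,
#' for every marker gene, the molecules within a radius `2r/pi` of each
#' node. The raw count matrix (markers x nodes) is then standardised
#' column-wise (zero-variance columns become zeros).
#'
#' @param table a `transcript_table`.
#' @param markers character vector of marker gene names.
#' @param r prior cell radius in micrometers.
#' @return list with `F` (standardised features, markers x nodes),
#'   `raw` (raw counts), `layout` (internal grid layout).
#' @export
grid_node_features <- function(table, markers, r) {
  sel <- table$gene %in% markers
  if (!any(sel)) stop("no molecules from the marker gene set found")
  lay <- grid_layout(table, r)
  sub <- which(sel & lay$within)
  raw <- matrix(0, length(markers), lay$n_nodes,
                dimnames = list(markers, NULL))
  tab <- table(factor(table$gene[sub], levels = markers), lay$node[sub])
  raw[, as.integer(colnames(tab))] <- tab
  mu <- colMeans(raw)
  sdv <- apply(raw, 2L, stats::sd)
  Fm <- sweep(raw, 2L, mu)
  Fm <- sweep(Fm, 2L, ifelse(sdv > 0, sdv, Inf), "/")
  list(F = Fm, raw = raw, layout = lay)
}

#' Cluster marker genes into spatial co-occurrence categories
#'
#' Pairwise Pearson correlation between the marker rows of the node-feature
#' matrix defines similarity; average-linkage agglomerative clustering on
#' `1 - correlation` yields `c` categories. Each category's threshold
#' `t_c` is the sum, over its genes, of the gene's maximum per-type mean
#' expression.
#'
#' @param F standardised node features (markers x nodes).
#' @param A genes x types mean normalised expression from [score_markers()].
#' @param c number of categories (default 10; reduced with a warning when
#'   there are fewer markers).
#' @return list with `category` (integer per marker) and `t` (per-category
#'   thresholds).
#' @export
cluster_marker_categories <- function(F, A, c = 10L) {
  m <- nrow(F)
  if (m < c) {
    warning("only ", m, " markers; reducing categories from ", c, " to ", m)
    c <- m
  }
  sim <- suppressWarnings(stats::cor(t(F)))
  sim[!is.finite(sim)] <- 0
  diag(sim) <- 1
  if (m == 1L) {
    cat_id <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    cat_id <- stats::cutree(hc, k = c)
  }
  amax <- apply(A[rownames(F), , drop = FALSE], 1L, max)
  t_c <- vapply(seq_len(max(cat_id)), function(g) sum(amax[cat_id == g]), 0)
  list(category = cat_id, t = t_c)
}

#' Select valid (high-density) grid nodes for one category
#'
#' With `h` the per-node molecule count of the category, the first cutoff is
#' `Q(h, q) * 0.01`; the second is the mean of `h` over nodes exceeding the
#' first; valid nodes strictly exceed the second cutoff.
#'
#' @param h per-node molecule counts.
#' @param q quantile (default 0.9, linear interpolation).
#' @return logical vector of valid nodes.
#' @export
select_valid_nodes <- function(h, q = 0.9) {
  cutoff1 <- q_linear(h, q) * 0.01
  above <- h > cutoff1
  if (!any(above)) {
    warning("no node above the first density cutoff; empty valid set")
    return(rep(FALSE, length(h)))
  }
  cutoff2 <- mean(h[above])
  valid <- h > cutoff2
  if (!any(valid))
    warning("no node above the mean-density cutoff; empty valid set")
  valid
}

#' Cluster one category's molecules into candidate centers
#'
#' DBSCAN (eps = `2r`, min_pts 5) groups the category's molecules into
#' spatially contiguous regions; each group is split by K-means into
#' `k = max(1, floor(0.25 h ln(max(t)/t_c + 1)))` clusters whose mean
#' coordinates become candidate centers, where `h` counts the group's
#' molecules supported by valid high-density nodes (see
#' [select_valid_nodes()]); the same supported molecules are the K-means
#' input, so candidate centers sit on density cores. Groups without any
#' supported molecule are treated as background scatter and dropped, as
#' are DBSCAN noise points; if no group forms at all, all molecules form
#' one group. Fewer than two molecules yield a single candidate at the
#' molecule.
#'
#' @param coords 2-column matrix of the category's molecule coordinates.
#' @param near_valid logical per molecule: lies within the adjacent area
#'   (radius `2r/pi`) of a valid node. Defaults to all `TRUE`.
#' @param r prior cell radius.
#' @param t per-category thresholds from [cluster_marker_categories()].
#' @param t_c this category's threshold.
#' @return matrix of candidate centers (possibly 0 rows).
#' @export
cluster_molecules_to_candidates <- function(coords, r, t, t_c,
                                            near_valid = NULL) {
  coords <- as.matrix(coords)
  near_valid <- near_valid %||% rep(TRUE, nrow(coords))
  if (nrow(coords) == 0L) return(matrix(numeric(0), 0, 2))
  if (nrow(coords) < 2L) return(coords)
  labels <- dbscan_points(coords, eps = 2 * r)
  if (all(labels == 0L)) labels <- rep(1L, nrow(coords))
  centers <- NULL
  for (g in seq_len(max(labels))) {
    in_g <- labels == g
    pts <- coords[in_g & near_valid, , drop = FALSE]
    h <- nrow(pts)
    if (h == 0L) next
    k <- max(1L, as.integer(0.25 * h * log(max(t) / t_c + 1)))
    uniq <- unique(pts)
    k <- min(k, nrow(uniq))
    if (k == 1L) {
      ctr <- matrix(colMeans(pts), 1, 2)
    } else {
      km <- stats::kmeans(pts, centers = k, iter.max = 50L, nstart = 1L)
      ctr <- km$centers
    }
    centers <- rbind(centers, ctr)
  }
  unname(centers)
}

#' Merge per-category candidate centers
#'
#' Flat-kernel mean shift with bandwidth `r/5` merges spatially coincident
#' candidates pooled across categories.
#'
#' @param centers matrix of pooled candidate centers.
#' @param r prior cell radius.
#' @return a `candidate_set` data.frame with columns `X`, `Y`.
#' @export
merge_candidates <- function(centers, r) {
  if (is.null(centers) || nrow(centers) == 0L)
    stop("no candidate centers to merge")
  modes <- mean_shift(as.matrix(centers), bandwidth = r / 5)
  out <- data.frame(X = modes[, 1], Y = modes[, 2])
  attr(out, "provenance") <- "estimated"
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Estimate prior candidate cell centers
#'
#' Full cascade: marker scoring, grid features, marker-category clustering,
#' per-category valid-node selection and DBSCAN/K-means clustering, and a
#' final mean-shift merge.
#'
#' @param table a `transcript_table`.
#' @param reference a `reference_panel`.
#' @param r prior cell radius in micrometers (default 6.5, typical for
#'   Xenium-resolution data).
#' @param p markers per type (default 3).
#' @param c marker categories (default 10).
#' @param q valid-node quantile (default 0.9).
#' @return a `candidate_set` data.frame with columns `X`, `Y`.
#' @export
estimate_candidates <- function(table, reference, r = 6.5, p = 3L,
                                c = 10L, q = 0.9) {
  mk <- score_markers(reference, p = p)
  gf <- grid_node_features(table, mk$markers, r)
  cl <- cluster_marker_categories(gf$F, mk$A, c = c)
  lay <- gf$layout
  centers <- NULL
  for (g in seq_along(cl$t)) {
    genes_g <- mk$markers[cl$category == g]
    h <- colSums(gf$raw[genes_g, , drop = FALSE])
    valid <- select_valid_nodes(h, q = q)
    if (!any(valid)) next
    sel <- table$gene %in% genes_g
    near_valid <- (lay$within & valid[lay$node])[sel]
    ctr <- cluster_molecules_to_candidates(
      cbind(table$x[sel], table$y[sel]), r, cl$t, cl$t[g],
      near_valid = near_valid)
    centers <- rbind(centers, ctr)
  }
  merge_candidates(centers, r)
}

#' Wrap externally supplied candidate centers
#'
#' Accepts centers estimated elsewhere (e.g. nucleus detection or staining
#' based segmentation), bypassing [estimate_candidates()].
#'
#' @param centers data.frame or matrix with two columns (X, Y).
#' @param provenance one of `"external"`, `"nuclear"`.
#' @return a `candidate_set`.
#' @export
as_candidate_set <- function(centers, provenance = "external") {
  centers <- as.data.frame(centers)
  stopifnot(ncol(centers) >= 2L, nrow(centers) >= 1L)
  out <- data.frame(X = as.numeric(centers[[1]]), Y = as.numeric(centers[[2]]))
  if (!all(is.finite(out$X)) || !all(is.finite(out$Y)))
    stop("non-finite candidate coordinates")
  attr(out, "provenance") <- provenance
  class(out) <- c("candidate_set", "data.frame")
  out
}
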
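# Benchmarking metrics: expression similarity to the reference, boundary
# IoU agreement, morphology density agreement, masked-gene imputation
# accuracy, label transfer, and ground-truth assignment accuracy for
# synthetic tissue.

# scale each cell's total to the number of genes (columns)
normalize_to_k <- function(M) {
  tot <- rowSums(M)
  M * ifelse(tot > 0, ncol(M) / tot, 0)
}

#' Expression similarity of segmented cells to reference cells
#'
#' Both matrices are restricted to shared genes and each cell's total is
#' scaled to the gene count k. For each segmented cell, cosine similarity
#' and RMSE against every reference cell are computed; `SIM_C` is the mean
#' of the 20 highest cosines and `SIM_R` the mean of the 20 lowest RMSEs.
#'
#' @param E segmented cells x genes matrix (counts or imputed expression).
#' @param ref reference cells x genes matrix over the same genes.
#' @param top number of reference cells averaged (default 20; reduced with
#'   a warning when the reference is smaller).
#' @return data.frame with per-cell `SIM_C` and `SIM_R`.
#' @export
expression_similarity_metrics <- function(E, ref, top = 20L) {
  shared <- intersect(colnames(E) %||% colnames(ref), colnames(ref))
  if (!is.null(colnames(E)) && length(shared)) {
    E <- E[, shared, drop = FALSE]
    ref <- ref[, shared, drop = FALSE]
  }
  if (nrow(ref) < top) {
    warning("reference has only ", nrow(ref), " cells; using all")
    top <- nrow(ref)
  }
  A <- normalize_to_k(as.matrix(E))
  B <- normalize_to_k(as.matrix(ref))
  An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-12)
  cosmat <- tcrossprod(An, Bn)
  k <- ncol(A)
  # ||a - b||^2 = |a|^2 + |b|^2 - 2 a.b, per pair
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  rmse <- sqrt(pmax(sq, 0) / k)
  SIM_C <- apply(cosmat, 1L, function(s)
    mean(sort(s, decreasing = TRUE)[seq_len(top)]))
  SIM_R <- apply(rmse, 1L, function(s) mean(sort(s)[seq_len(top)]))
  data.frame(SIM_C = SIM_C, SIM_R = SIM_R)
}

#' Boundary agreement between segmented and ground-truth cells
#'
#' Sensitivity: mean IoU of each truth cell with its nearest (by polygon
#' centroid) segmented cell. Specificity: mean IoU of each segmented cell
#' with its nearest truth cell.
#'
#' @param segmented,truth `cell_polygons` lists.
#' @return list with `sensitivity` and `specificity`.
#' @export
boundary_agreement <- function(segmented, truth) {
  seg <- Filter(function(p) !isTRUE(p$degenerate), segmented)
  tru <- Filter(function(p) !isTRUE(p$degenerate), truth)
  if (length(seg) == 0L || length(tru) == 0L) {
    warning("empty polygon set; boundary agreement is 0")
    return(list(sensitivity = 0, specificity = 0))
  }
  cseg <- t(vapply(seg, function(p) polygon_centroid(p$rings), numeric(2)))
  ctru <- t(vapply(tru, function(p) polygon_centroid(p$rings), numeric(2)))
  near_st <- FNN::get.knnx(cseg, ctru, k = 1L)$nn.index[, 1L]
  near_ts <- FNN::get.knnx(ctru, cseg, k = 1L)$nn.index[, 1L]
  sens <- mean(vapply(seq_along(tru), function(i)
    polygon_iou(tru[[i]]$rings, seg[[near_st[i]]]$rings), 0))
  spec <- mean(vapply(seq_along(seg), function(i)
    polygon_iou(seg[[i]]$rings, tru[[near_ts[i]]]$rings), 0))
  list(sensitivity = sens, specificity = spec)
}

#' IoU of two kernel-density curves
#'
#' Gaussian KDE with a shared normal-reference bandwidth (computed on the
#' pooled sample) on a shared grid spanning both ranges; the IoU is the
#' integral of the pointwise minimum over the integral of the pointwise
#' maximum.
#'
#' @param a,b numeric samples.
#' @param n grid size (default 512).
#' @return IoU in `[0, 1]`.
#' @export
density_curve_iou <- function(a, b, n = 512L) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per sample for a density curve")
  bw <- stats::bw.nrd0(c(a, b))
  # constant samples give a degenerate bandwidth; widen minimally
  bw <- max(bw, 1e-8 * max(abs(c(a, b)), 1))
  lo <- min(a, b) - 3 * bw
  hi <- max(a, b) + 3 * bw
  da <- stats::density(a, bw = bw, from = lo, to = hi, n = n)
  db <- stats::density(b, bw = bw, from = lo, to = hi, n = n)
  dx <- da$x[2L] - da$x[1L]
  sum(pmin(da$y, db$y)) / sum(pmax(da$y, db$y))
}

#' Morphology agreement between two polygon sets
#'
#' Density-curve IoU of cell area, girth, and roundness
#' (`4 pi area / girth^2`) between segmented and truth polygons.
#'
#' @param segmented,truth `cell_polygons` lists (at least 2 non-degenerate
#'   polygons each).
#' @return named numeric vector: `area`, `girth`, `roundness`.
#' @export
morphology_metrics <- function(segmented, truth) {
  feats <- function(polys) {
    ok <- Filter(function(p) !isTRUE(p$degenerate), polys)
    if (length(ok) < 2L) stop("need at least 2 polygons per set")
    data.frame(
      area = vapply(ok, function(p) p$area %||% polygon_area(p$rings), 0),
      girth = vapply(ok, function(p) p$girth %||% polygon_girth(p$rings), 0))
  }
  fs <- feats(segmented)
  ft <- feats(truth)
  fs$roundness <- 4 * pi * fs$area / fs$girth^2
  ft$roundness <- 4 * pi * ft$area / ft$girth^2
  c(area = density_curve_iou(fs$area, ft$area),
    girth = density_curve_iou(fs$girth, ft$girth),
    roundness = density_curve_iou(fs$roundness, ft$roundness))
}

#' Transfer reference cell-type labels to segmented cells
#'
#' For each segmented cell the 20 reference cells with the highest cosine
#' similarity (over the panel genes) are found; their similarities are
#' aggregated by type and divided by the total over the 20, giving a type
#' probability vector; the argmax type is assigned (ties go to the
#' lexicographically first type).
#'
#' @param E segmented cells x panel genes counts.
#' @param reference a `reference_panel`.
#' @param top neighbors (default 20).
#' @return list with `type` (factor per cell) and `prob` (cells x types).
#' @export
label_transfer <- function(E, reference, top = 20L) {
  top <- min(top, nrow(reference$S))
  A <- as.matrix(E)
  B <- as.matrix(reference$S)
  An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
  Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-12)
  sim <- tcrossprod(An, Bn)
  types <- levels(reference$cell_type)
  prob <- matrix(0, nrow(A), length(types), dimnames = list(NULL, types))
  for (i in seq_len(nrow(A))) {
    idx <- order(sim[i, ], decreasing = TRUE)[seq_len(top)]
    s <- sim[i, idx]
    tot <- sum(s)
    agg <- tapply(s, reference$cell_type[idx], sum, default = 0)
    prob[i, names(agg)] <- agg / if (tot > 0) tot else 1
  }
  type <- factor(types[apply(prob, 1L, which.max)], levels = types)
  list(type = type, prob = prob)
}

#' Masked-gene imputation benchmark
#'
#' Randomly masks a fraction of the panel genes, runs segmentation and
#' imputation on the remaining genes, and scores the imputed expression of
#' the masked genes against the reference (per-cell `SIM_C` / `SIM_R`
#' averaged). A gene-shuffled null (the masked-gene columns of the imputed
#' matrix permuted) is scored identically.
#'
#' @param transcripts data.frame with `x`, `y`, `gene`.
#' @param ref_counts,cell_type the reference.
#' @param mask_fraction fraction of genes masked (default 0.3; 0 and 1 are
#'   errors).
#' @param reps repetitions (default 3).
#' @param config a [seg_config()] (its seed also fixes the gene masks).
#' @param r prior cell radius for candidate estimation.
#' @return data.frame per rep: `SIM_C`, `SIM_R`, `SIM_C_null`.
#' @export
imputation_benchmark <- function(transcripts, ref_counts, cell_type,
                                 mask_fraction = 0.3, reps = 3L,
                                 config = seg_config(), r = 6.5) {
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop("mask_fraction must be strictly between 0 and 1")
  panel <- sort(intersect(unique(transcripts$gene), colnames(ref_counts)))
  out <- data.frame()
  for (rep_i in seq_len(reps)) {
    set.seed(config$seed + rep_i)
    masked <- sample(panel, max(1L, round(mask_fraction * length(panel))))
    keep_ref <- ref_counts[, setdiff(colnames(ref_counts), masked),
                           drop = FALSE]
    res <- segment_cells(transcripts, keep_ref, cell_type,
                         config = config, r = r, polygons = FALSE)
    nonempty <- rowSums(res$E) > 0
    # the fitted reference lacks the masked genes; imputation must read
    # full-transcriptome profiles from the complete matrix
    full_ref <- list(S = res$reference$S, U = ref_counts,
                     cell_type = res$reference$cell_type,
                     genes = res$reference$genes)
    class(full_ref) <- "reference_panel"
    imp <- impute_transcriptome(res$E[nonempty, , drop = FALSE], full_ref)
    pred <- imp$profiles[, masked, drop = FALSE]
    truth <- as.matrix(ref_counts[, masked, drop = FALSE])
    simm <- expression_similarity_metrics(pred, truth)
    set.seed(config$seed + 1000L + rep_i)
    pred_null <- pred[, sample(ncol(pred)), drop = FALSE]
    colnames(pred_null) <- colnames(pred)
    simn <- expression_similarity_metrics(pred_null, truth)
    out <- rbind(out, data.frame(rep = rep_i,
                                 SIM_C = mean(simm$SIM_C),
                                 SIM_R = mean(simm$SIM_R),
                                 SIM_C_null = mean(simn$SIM_C)))
  }
  out
}

#' Fraction of non-noise molecules assigned to their true cell
#'
#' Each segmented cell is labelled with the plurality true cell among its
#' assigned molecules; a molecule counts as correct when its true cell
#' matches its segmented cell's label. The same scoring applies to any
#' assignment vector, e.g. the nearest-candidate baseline.
#'
#' @param cell per-molecule segmented cell index (NA = noise).
#' @param true_cell per-molecule ground-truth cell id (0 = noise).
#' @return accuracy over non-noise (assigned) molecules.
#' @export
assignment_accuracy <- function(cell, true_cell) {
  keep <- !is.na(cell)
  cell <- cell[keep]
  true_cell <- true_cell[keep]
  lab <- vapply(split(true_cell, cell), function(tc)
    as.integer(names(which.max(table(tc)))), 0L)
  mean(lab[as.character(cell)] == true_cell)
}
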
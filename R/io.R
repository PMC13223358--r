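# Reading transcript tables, gene encoding, noise distance scores, and the
# sequencing-based (spot matrix) adaptation.

# Column-name dialects of the common imaging-based platforms.
PLATFORM_PRESETS <- list(
  xenium  = c(x = "x_location", y = "y_location", gene = "feature_name"),
  cosmx   = c(x = "x_global_px", y = "y_global_px", gene = "target"),
  merfish = c(x = "global_x", y = "global_y", gene = "gene"),
  merscope = c(x = "global_x", y = "global_y", gene = "gene"),
  generic = c(x = "x", y = "y", gene = "gene")
)

#' Read a per-molecule transcript table
#'
#' Reads a delimited text export (CSV/TSV) of detected transcripts with 2-D
#' coordinates in micrometers and a gene label. Column names can be given
#' explicitly or through a platform preset. Any z coordinate is ignored
#' with a warning: the model is strictly 2-D.
#'
#' @param path file path (CSV or TSV; compression handled by R connections).
#' @param platform one of `"generic"`, `"xenium"`, `"cosmx"`, `"merfish"`,
#'   `"merscope"`; sets default column names.
#' @param columns optional named character vector overriding the preset,
#'   with names `x`, `y`, `gene`.
#' @return a data.frame with columns `x`, `y`, `gene`.
#' @export
read_transcripts <- function(path, platform = "generic", columns = NULL) {
  preset <- PLATFORM_PRESETS[[match.arg(platform, names(PLATFORM_PRESETS))]]
  if (!is.null(columns)) preset[names(columns)] <- columns
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(preset), names(df))
  if (length(miss))
    stop("transcript file lacks column(s): ", paste(miss, collapse = ", "))
  if (any(grepl("^z(_location)?$", names(df))))
    warning("z coordinate present in input; ignored (2-D model)")
  out <- data.frame(x = as.numeric(df[[preset[["x"]]]]),
                    y = as.numeric(df[[preset[["y"]]]]),
                    gene = as.character(df[[preset[["gene"]]]]),
                    stringsAsFactors = FALSE)
  if (!all(is.finite(out$x)) || !all(is.finite(out$y)))
    stop("non-finite coordinates in transcript table")
  out
}

#' Read an scRNA-seq reference from MatrixMarket + TSV files
#'
#' @param mtx_path MTX file, cells x genes or genes x cells.
#' @param genes_path one-column (or first-column) TSV of gene names.
#' @param cells_path TSV with a barcode column and a cell-type column.
#' @param cell_type_col name of the cell-type column in `cells_path`
#'   (default `"cell_type"`).
#' @param genes_as_rows logical; set `TRUE` if the MTX stores genes as rows.
#' @return list with `counts` (cells x genes dgCMatrix) and `cell_type`.
#' @export
read_reference_mtx <- function(mtx_path, genes_path, cells_path,
                               cell_type_col = "cell_type",
                               genes_as_rows = TRUE) {
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(genes_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (genes_as_rows) m <- Matrix::t(m)
  if (ncol(m) != length(genes))
    stop("gene list length does not match matrix dimension")
  colnames(m) <- genes
  rownames(m) <- cells[[1]]
  if (!cell_type_col %in% names(cells))
    stop("cell-type column '", cell_type_col, "' not found")
  list(counts = methods::as(m, "CsparseMatrix"),
       cell_type = factor(cells[[cell_type_col]]))
}

#' Encode genes shared between tissue and reference as integers
#'
#' Genes detected in both the transcript table and the reference (the
#' intersection set, size k) are encoded 1..k in lexicographic order; every
#' other transcript gene receives code k+1. The reference is restricted to
#' the k intersection genes for model fitting while the full matrix is kept
#' for whole-transcriptome imputation.
#'
#' @param transcripts data.frame with columns `x`, `y`, `gene`.
#' @param ref_counts reference counts, cells x genes (matrix or sparse).
#' @param cell_type per-reference-cell type labels (factor or character).
#' @param max_genes optional cap: keep distinct codes only for the
#'   `max_genes` intersection genes with the highest transcript totals
#'   (used by the sequencing-based adaptation, default `Inf`).
#' @return list with `table` (a `transcript_table` data.frame: x, y, gene,
#'   gene_code) and `reference` (a `reference_panel`: S restricted counts,
#'   U full counts, cell_type, genes).
#' @export
encode_genes <- function(transcripts, ref_counts, cell_type,
                         max_genes = Inf) {
  st_genes <- unique(transcripts$gene)
  ref_genes <- colnames(ref_counts)
  shared <- sort(intersect(st_genes, ref_genes))
  if (length(shared) == 0L)
    stop("empty gene intersection between transcript table (",
         length(st_genes), " genes) and reference (",
         length(ref_genes), " genes)")
  if (is.finite(max_genes) && length(shared) > max_genes) {
    tot <- table(factor(transcripts$gene, levels = shared))
    keep <- names(sort(tot, decreasing = TRUE))[seq_len(max_genes)]
    shared <- sort(keep)
  }
  k <- length(shared)
  code <- match(transcripts$gene, shared)
  code[is.na(code)] <- k + 1L
  table <- data.frame(x = transcripts$x, y = transcripts$y,
                      gene = transcripts$gene, gene_code = as.integer(code),
                      stringsAsFactors = FALSE)
  class(table) <- c("transcript_table", "data.frame")
  ref <- list(
    S = as.matrix(ref_counts[, shared, drop = FALSE]),
    U = ref_counts,
    cell_type = factor(cell_type),
    genes = shared
  )
  class(ref) <- "reference_panel"
  list(table = table, reference = ref)
}

#' Per-molecule noise distance scores
#'
#' For each molecule, the mean Euclidean distance to its `d` nearest
#' neighboring molecules (self excluded) is computed with a k-d tree; the
#' noise distance score is `max(0, 1 - d_i / Q)` where `Q` is the
#' `q`-quantile (linear interpolation) of all mean distances. Isolated
#' molecules therefore score near 0 and molecules in dense neighborhoods
#' near 1.
#'
#' @param table a `transcript_table` (or any data.frame with `x`, `y`).
#' @param d neighbor count (default 100).
#' @param q quantile in (0, 1) (default 0.999; 0.9999 is recommended for
#'   spot-derived molecule lists, which contain many duplicated positions).
#' @return numeric vector of scores in `[0, 1]`.
#' @export
compute_noise_distance_scores <- function(table, d = 100L, q = 0.999) {
  n <- nrow(table)
  if (n <= d)
    stop("need more than d = ", d, " molecules (got ", n,
         "); at least ", d + 1L, " required")
  stopifnot(q > 0, q < 1)
  nn <- FNN::get.knn(cbind(table$x, table$y), k = d)
  di <- rowMeans(nn$nn.dist)
  Q <- q_linear(di, q)
  if (Q == 0) return(rep(1, n))  # all molecules coincident
  pmax(0, 1 - di / Q)
}

#' Expand a spot-by-gene count matrix into a molecule table
#'
#' Adapts sequencing-based spatial data (e.g. Stereo-seq) to the
#' imaging-based interface: each unit of count becomes one molecule at its
#' spot's coordinates. Gene capping to the most expressed intersection
#' genes is applied downstream via `encode_genes(max_genes = )` (2000 by
#' convention), and a quantile of 0.9999 is recommended for the noise
#' distance scores because of the duplicated coordinates.
#'
#' @param spot_matrix spots x genes nonnegative integer counts (matrix or
#'   sparse) with column names.
#' @param coords data.frame/matrix of spot `x`, `y` (rows match
#'   `spot_matrix`).
#' @return data.frame with one row per molecule: `x`, `y`, `gene`.
#' @export
spots_to_molecules <- function(spot_matrix, coords) {
  if (!inherits(spot_matrix, "sparseMatrix"))
    spot_matrix <- Matrix::Matrix(as.matrix(spot_matrix), sparse = TRUE)
  m <- methods::as(methods::as(spot_matrix, "CsparseMatrix"), "TsparseMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("spot matrix must contain nonnegative integer counts")
  coords <- as.data.frame(coords)
  reps <- as.integer(m@x)
  spot <- rep.int(m@i + 1L, reps)
  gene <- rep.int(m@j + 1L, reps)
  data.frame(x = coords[[1]][spot], y = coords[[2]][spot],
             gene = colnames(spot_matrix)[gene],
             stringsAsFactors = FALSE)
}
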
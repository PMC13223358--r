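#' Specification of a synthetic tissue + reference pair
#'
#' Bundles the parameters of the matched synthetic spatial-transcriptomics
#' tissue and scRNA-seq reference generator. Defaults describe a desk-scale
#' tissue: 200 cells of 8 types on a jittered grid, a 100-gene panel, an
#' average of 100 transcripts per cell scattered isotropically around each
#' cell center (sd = radius/2), and 5\% uniform background noise.
#'
#' @param n_cells number of cells placed in the tissue.
#' @param n_types number of cell types.
#' @param n_genes panel size (genes shared between tissue and reference).
#' @param mean_transcripts mean transcripts per cell (Poisson).
#' @param radius prior cell radius in micrometers; transcripts scatter with
#'   sd `radius / 2` and cell centers are at least `4 * radius` apart.
#' @param noise_fraction fraction of all molecules that are uniform
#'   background noise, in `[0, 1)`.
#' @param field_size side length of the square field in micrometers, or
#'   `NULL` to derive it from the grid of cell centers.
#' @param ref_cells_per_type reference cells simulated per type.
#' @param ref_library_size total counts per reference cell (multinomial).
#' @param profile_sdlog log-normal sd of the per-type gene profile
#'   magnitudes; controls profile sparsity/marker strength.
#' @param seed integer seed for the generator.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 200L, n_types = 8L, n_genes = 100L,
                           mean_transcripts = 100, radius = 6.5,
                           noise_fraction = 0.05, field_size = NULL,
                           ref_cells_per_type = 50L, ref_library_size = 1000L,
                           profile_sdlog = 1.5, seed = 0L) {
  stopifnot(n_cells >= 1, n_types >= 1, n_genes >= 1,
            mean_transcripts > 0, radius > 0,
            noise_fraction >= 0, noise_fraction < 1,
            ref_cells_per_type >= 1, ref_library_size >= 1)
  structure(list(
    n_cells = as.integer(n_cells), n_types = as.integer(n_types),
    n_genes = as.integer(n_genes), mean_transcripts = mean_transcripts,
    radius = radius, noise_fraction = noise_fraction,
    field_size = field_size,
    ref_cells_per_type = as.integer(ref_cells_per_type),
    ref_library_size = as.integer(ref_library_size),
    profile_sdlog = profile_sdlog, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Simulate an scRNA-seq reference with known type profiles
#'
#' Draws one sparse simplex expression profile per cell type (log-normal
#' magnitudes renormalised to sum 1) and samples reference cells
#' multinomially at the specified library size.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `counts` (cells x genes integer matrix),
#'   `cell_type` (factor), `profiles` (types x genes, rows sum to 1) and
#'   `genes` (gene names).
#' @export
simulate_reference <- function(spec) {
  set.seed(spec$seed)
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  types <- sprintf("type%d", seq_len(spec$n_types))
  profiles <- matrix(0, spec$n_types, spec$n_genes,
                     dimnames = list(types, genes))
  for (i in seq_len(spec$n_types)) {
    w <- rlnorm(spec$n_genes, meanlog = 0, sdlog = spec$profile_sdlog)
    profiles[i, ] <- w / sum(w)
  }
  n_ref <- spec$n_types * spec$ref_cells_per_type
  cell_type <- factor(rep(types, each = spec$ref_cells_per_type),
                      levels = types)
  counts <- matrix(0L, n_ref, spec$n_genes,
                   dimnames = list(sprintf("ref%04d", seq_len(n_ref)), genes))
  for (j in seq_len(n_ref)) {
    counts[j, ] <- as.integer(
      rmultinom(1, spec$ref_library_size, profiles[as.integer(cell_type[j]), ]))
  }
  list(counts = counts, cell_type = cell_type, profiles = profiles,
       genes = genes)
}

#' Simulate an imaging-based spatial transcriptomics tissue
#'
#' Places cell centers on a jittered grid with minimum spacing `4 * radius`,
#' draws per-cell transcript counts from a Poisson, genes from the cell
#' type's profile, positions from an isotropic Gaussian around the center
#' (sd = radius/2), and adds uniform background noise molecules at the
#' requested fraction of all molecules.
#'
#' @param spec a [synthetic_spec()].
#' @param profiles types x genes profile matrix from [simulate_reference()].
#' @return a list with `transcripts` (data.frame x, y, gene), `truth`
#'   (data.frame: true_cell (0 = noise)), `cells` (data.frame: cell, x, y,
#'   type), and `field` (xmin/xmax/ymin/ymax).
#' @export
simulate_tissue <- function(spec, profiles) {
  set.seed(spec$seed + 1L)
  genes <- colnames(profiles)
  types <- rownames(profiles)
  spacing <- 4 * spec$radius
  side <- ceiling(sqrt(spec$n_cells))
  # jittered grid: jitter < spacing/4 keeps pairwise distances >= spacing/2
  # above 2*spacing/4; centers stay >= 4r apart up to the jitter margin
  gx <- (rep(seq_len(side), side) - 0.5) * spacing
  gy <- (rep(seq_len(side), each = side) - 0.5) * spacing
  keep <- sample.int(side * side, spec$n_cells)
  cx <- gx[keep] + runif(spec$n_cells, -spacing / 8, spacing / 8)
  cy <- gy[keep] + runif(spec$n_cells, -spacing / 8, spacing / 8)
  ctype <- factor(types[sample.int(spec$n_types, spec$n_cells, replace = TRUE)],
                  levels = types)
  fs <- spec$field_size %||% (side * spacing)
  field <- c(xmin = 0, xmax = fs, ymin = 0, ymax = fs)

  counts <- rpois(spec$n_cells, spec$mean_transcripts)
  total <- sum(counts)
  cell_id <- rep.int(seq_len(spec$n_cells), counts)
  gene_idx <- integer(total)
  off <- 0L
  for (i in seq_len(spec$n_cells)) {
    if (counts[i] == 0L) next
    gene_idx[(off + 1L):(off + counts[i])] <-
      sample.int(length(genes), counts[i], replace = TRUE,
                 prob = profiles[as.integer(ctype[i]), ])
    off <- off + counts[i]
  }
  sdp <- spec$radius / 2
  x <- cx[cell_id] + rnorm(total, 0, sdp)
  y <- cy[cell_id] + rnorm(total, 0, sdp)

  n_noise <- round(spec$noise_fraction / (1 - spec$noise_fraction) * total)
  if (n_noise > 0) {
    x <- c(x, runif(n_noise, field["xmin"], field["xmax"]))
    y <- c(y, runif(n_noise, field["ymin"], field["ymax"]))
    gene_idx <- c(gene_idx, sample.int(length(genes), n_noise, replace = TRUE))
    cell_id <- c(cell_id, rep.int(0L, n_noise))
  }
  transcripts <- data.frame(x = x, y = y, gene = genes[gene_idx],
                            stringsAsFactors = FALSE)
  list(
    transcripts = transcripts,
    truth = data.frame(true_cell = cell_id),
    cells = data.frame(cell = seq_len(spec$n_cells), x = cx, y = cy,
                       type = ctype),
    field = field
  )
}

#' Simulate a matched tissue/reference pair
#'
#' Convenience wrapper running [simulate_reference()] then
#' [simulate_tissue()] from one spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `reference` and `tissue`.
#' @export
simulate_dataset <- function(spec) {
  ref <- simulate_reference(spec)
  tis <- simulate_tissue(spec, ref$profiles)
  list(reference = ref, tissue = tis)
}
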
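# The deconvolution module: adaptive reference states per cell type, a
# predicted expression profile per candidate cell, and the similarity /
# residual quantities fed back into the segmentation reward.

#' Initialise deconvolution parameters
#'
#' One trainable `cs x n_i` state matrix per cell type (mapping that type's
#' reference cells to `cs` adaptive states) and a `c x (cs * t)` abundance
#' matrix mapping states to candidate cells. Cell types with no reference
#' cells are excluded with a warning.
#'
#' @param reference a `reference_panel`.
#' @param n_candidates number of candidate cells.
#' @param cs states per type (default 10).
#' @return a `deconv_params` list with `W` (list per kept type), `V`,
#'   `split` (list of per-type reference submatrices), `types`.
#' @export
init_deconv_params <- function(reference, n_candidates, cs = 10L) {
  types <- levels(reference$cell_type)
  n_per <- table(reference$cell_type)
  empty <- types[n_per[types] == 0L]
  if (length(empty)) {
    warning("cell type(s) without reference cells excluded: ",
            paste(empty, collapse = ", "))
    types <- setdiff(types, empty)
  }
  split <- lapply(types, function(ty)
    reference$S[reference$cell_type == ty, , drop = FALSE])
  names(split) <- types
  W <- lapply(split, function(Si)
    matrix(rnorm(cs * nrow(Si), sd = 0.1), cs, nrow(Si)))
  V <- matrix(rnorm(n_candidates * cs * length(types), sd = 0.1),
              n_candidates, cs * length(types))
  structure(list(W = W, V = V, cs = cs, split = split, types = types),
            class = "deconv_params")
}

#' Adaptive reference state matrix
#'
#' `S'_i = dropout(softplus(W_i S_i))` per type, stacked row-wise in type
#' order to a `(cs * t) x k` matrix.
#'
#' @param params a `deconv_params`.
#' @param dropout dropout rate (0 disables).
#' @param keep_cache keep intermediates for the backward pass.
#' @return list with `Sp` (state matrix) and `cache`.
#' @export
reference_state_matrix <- function(params, dropout = 0, keep_cache = FALSE) {
  pre <- lapply(seq_along(params$W), function(i)
    params$W[[i]] %*% params$split[[i]])
  masks <- lapply(pre, function(N)
    dropout_mask(nrow(N), ncol(N), dropout))
  blocks <- Map(function(N, mk) apply_mask(softplus(N), mk), pre, masks)
  Sp <- do.call(rbind, blocks)
  cache <- if (keep_cache) list(pre = pre, masks = masks) else NULL
  list(Sp = Sp, cache = cache)
}

#' Predicted expression profiles per candidate cell
#'
#' `PE = dropout(softplus(V S'))`, a `c x k` strictly positive matrix
#' (where dropout keeps entries).
#'
#' @param Sp state matrix from [reference_state_matrix()].
#' @param params a `deconv_params`.
#' @param dropout dropout rate.
#' @param keep_cache keep intermediates.
#' @return list with `PE` and `cache`.
#' @export
predicted_expression <- function(Sp, params, dropout = 0,
                                 keep_cache = FALSE) {
  if (ncol(params$V) != nrow(Sp))
    stop("abundance matrix V (", ncol(params$V),
         " columns) does not match state matrix (", nrow(Sp), " rows)")
  M <- params$V %*% Sp
  mask <- dropout_mask(nrow(M), ncol(M), dropout)
  PE <- apply_mask(softplus(M), mask)
  cache <- if (keep_cache) list(M = M, mask = mask, Sp = Sp) else NULL
  list(PE = PE, cache = cache)
}

#' Expression similarity and residual per candidate cell
#'
#' `ES_j` is the cosine similarity between the predicted profile `PE_j` and
#' the observed segmented profile `E_j`; cells with an all-zero observed
#' profile get `ES = 0` and are flagged empty. The residual `ER_j` is the
#' signed difference `PE_j - E_j` min-max normalised within the cell
#' across genes (all-equal rows become zeros), so `ER` is in `[0, 1]`:
#' values near 1 mark genes the reference predicts more of than the cell
#' currently holds (under-observed), values near 0 mark over-observed
#' genes. Because the alignment loss is scale-free (cosine), `PE_j` is
#' first rescaled to the total of `E_j` so the residual reflects profile
#' shape rather than arbitrary scale.
#'
#' @param PE,E `c x k` matrices.
#' @return list with `ES`, `ER`, `empty` (logical).
#' @export
similarity_and_residual <- function(PE, E) {
  empty <- rowSums(E != 0) == 0L
  ES <- cosine_rows(PE, E)
  ES[empty] <- 0
  pe_tot <- rowSums(PE)
  sc <- ifelse(pe_tot > 0, rowSums(E) / pmax(pe_tot, 1e-12), 1)
  R <- PE * sc - E
  rmin <- apply(R, 1L, min)
  rmax <- apply(R, 1L, max)
  rng <- rmax - rmin
  ER <- (R - rmin) / ifelse(rng > 0, rng, Inf)
  ER[empty, ] <- 0
  list(ES = ES, ER = ER, empty = empty)
}

#' Alignment loss of the Deconvolution Module
#'
#' `(1/c) * sum_j (1 - ES_j)`; bounded in `[0, 2]`.
#'
#' @param ES per-cell expression similarities.
#' @return scalar loss.
#' @export
alignment_loss <- function(ES) mean(1 - ES)

# Gradients of alignment_loss w.r.t. V and the per-type W matrices.
alignment_loss_backward <- function(params, sp_cache, pe_cache, PE, E) {
  c_n <- nrow(PE)
  pe_norm <- sqrt(rowSums(PE^2))
  e_norm <- sqrt(rowSums(E^2))
  ok <- pe_norm > 0 & e_norm > 0
  ES <- cosine_rows(PE, E)
  # d(1 - ES)/dPE = -(E / (|PE||E|) - ES * PE / |PE|^2)
  dPE <- matrix(0, nrow(PE), ncol(PE))
  dPE[ok, ] <- -(E[ok, , drop = FALSE] / (pe_norm[ok] * e_norm[ok]) -
                 ES[ok] * PE[ok, , drop = FALSE] / pe_norm[ok]^2) / c_n
  dM <- apply_mask(dPE, pe_cache$mask) * sigmoid(pe_cache$M)
  dV <- tcrossprod(dM, pe_cache$Sp)
  dSp <- crossprod(params$V, dM)
  cs <- params$cs
  dW <- vector("list", length(params$W))
  for (i in seq_along(params$W)) {
    rows <- ((i - 1L) * cs + 1L):(i * cs)
    dN <- apply_mask(dSp[rows, , drop = FALSE], sp_cache$masks[[i]]) *
      sigmoid(sp_cache$pre[[i]])
    dW[[i]] <- tcrossprod(dN, params$split[[i]])
  }
  names(dW) <- names(params$W)
  list(V = dV, W = dW)
}

#' Per-molecule expression similarity scores
#'
#' For molecule i assigned to cell j with gene code kappa <= k, the score
#' feeds the deconvolution residual back into the reward. Under the
#' default `"narrative"` orientation (the same branch labelling as
#' [compute_rewards()]) a non-noise action scores `ER[j, kappa]` — pulling
#' in molecules of genes the reference predicts the cell is missing — and
#' a noise action scores `1 - ER[j, kappa]`; `"as_printed"` swaps the two
#' branches. Molecules whose gene is outside the intersection panel (code
#' k+1) get the neutral score 0.5.
#'
#' @param ER `c x k` residual matrix.
#' @param G assigned candidate index per molecule.
#' @param H noise action (1 = noise, 2 = non-noise).
#' @param gene_code per-molecule gene codes (1..k+1).
#' @param orientation `"narrative"` (default) or `"as_printed"`.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
expression_similarity_scores <- function(ER, G, H, gene_code,
                                         orientation = c("narrative",
                                                         "as_printed")) {
  orientation <- match.arg(orientation)
  k <- ncol(ER)
  ess <- rep(0.5, length(G))
  in_panel <- gene_code <= k
  er <- ER[cbind(G[in_panel], gene_code[in_panel])]
  noise_i <- H[in_panel] == 1L
  ess[in_panel] <- switch(orientation,
    narrative = ifelse(noise_i, 1 - er, er),
    as_printed = ifelse(noise_i, er, 1 - er))
  ess
}

# Aggregate a candidate x gene count matrix from non-noise assignments with
# codes <= k.
aggregate_profiles <- function(G, H, gene_code, n_candidates, k) {
  keep <- H == 2L & gene_code <= k
  E <- matrix(0, n_candidates, k)
  if (any(keep)) {
    tab <- table(factor(G[keep], levels = seq_len(n_candidates)),
                 factor(gene_code[keep], levels = seq_len(k)))
    E[] <- as.numeric(tab)
  }
  E
}
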
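# The segmentation policy: a multi-modal network scoring each molecule
# against its m nearest candidate cells, a per-molecule binary noise head,
# the density/distance/expression reward, and the policy-gradient loss.
# Forward and backward passes are hand-vectorised; gradients are checked
# against finite differences in the test suite.

#' Indices of the m nearest candidate cells per molecule
#'
#' @param table a `transcript_table`.
#' @param candidates a `candidate_set`.
#' @param m neighbor count (default 8); lowered with a warning when there
#'   are fewer candidates. Distance ties are broken by lower candidate index.
#' @return integer matrix, n molecules x m.
#' @export
nearest_candidate_cells <- function(table, candidates, m = 8L) {
  ctr <- cbind(candidates$X, candidates$Y)
  if (nrow(ctr) < m) {
    warning("only ", nrow(ctr), " candidates; lowering m from ", m)
    m <- nrow(ctr)
  }
  nn <- FNN::get.knnx(ctr, cbind(table$x, table$y), k = m)
  idx <- nn$nn.index
  if (m > 1L) {
    # enforce deterministic tie-break by lower index
    for (i in which(apply(nn$nn.dist, 1L, anyDuplicated) > 0L)) {
      o <- order(nn$nn.dist[i, ], idx[i, ])
      idx[i, ] <- idx[i, o]
    }
  }
  idx
}

#' Initialise policy parameters
#'
#' Trainable state: a p-dimensional embedding per candidate cell (`f`), per
#' gene code (`g`, k+1 rows), the two-layer location network mapping a 2-D
#' offset to p dimensions, the three-layer fusion network mapping the fused
#' p-vector to a scalar logit, and the n x 2 noise logits initialised as
#' `(1 - NDS, NDS)`. Draws from the current RNG state.
#'
#' @param n_candidates number of candidate cells.
#' @param n_codes number of gene codes (k + 1).
#' @param nds per-molecule noise distance scores.
#' @param p embedding width (default 20).
#' @return a `policy_params` list.
#' @export
init_policy_params <- function(n_candidates, n_codes, nds, p = 20L) {
  l1 <- init_linear(p, 2L); l2 <- init_linear(p, p)
  a1 <- init_linear(p, p); a2 <- init_linear(p, p)
  # final scoring layer starts at zero: the initial policy is uniform over
  # the m neighbors, so no pair is preferred before any reward is seen
  a3 <- list(W = matrix(0, 1L, p), b = 0)
  params <- list(
    f = matrix(rnorm(n_candidates * p, sd = 0.1), n_candidates, p),
    g = matrix(rnorm(n_codes * p, sd = 0.1), n_codes, p),
    loc1_W = l1$W, loc1_b = l1$b,
    loc2_W = l2$W, loc2_b = l2$b,
    fus1_W = a1$W, fus1_b = a1$b,
    fus2_W = a2$W, fus2_b = a2$b,
    fus3_W = as.numeric(a3$W), fus3_b = as.numeric(a3$b),
    noise = matrix(c(1 - nds, nds), ncol = 2L)
  )
  attr(params, "p") <- p
  class(params) <- "policy_params"
  params
}

# Pair offsets molecule -> candidate center for a batch. `nuclear` optionally
# supplies a function(mol_idx, cand_idx) returning the P x 2 offsets to the
# nuclear boundary instead (see apply_nuclear_priors).
pair_offsets <- function(table, candidates, neighbor_idx, batch) {
  b <- length(batch)
  m <- ncol(neighbor_idx)
  nb <- as.vector(neighbor_idx[batch, , drop = FALSE])
  pr_mol <- rep.int(batch, m)
  cbind(table$x[pr_mol] - candidates$X[nb],
        table$y[pr_mol] - candidates$Y[nb])
}

#' Assignment probabilities over the m nearest candidates
#'
#' Forward pass of the policy network for a batch of molecules: the 2-D
#' offset of each molecule/candidate pair is embedded by the location
#' network, summed with layer-normalised candidate and gene embeddings,
#' passed through the fusion network to a scalar logit, and a row-wise
#' softmax over the m logits (after optional logit dropout) yields the
#' assignment simplex.
#'
#' @param params a `policy_params`.
#' @param table a `transcript_table` with `gene_code`.
#' @param candidates a `candidate_set`.
#' @param neighbor_idx from [nearest_candidate_cells()].
#' @param batch integer molecule indices (default all).
#' @param dropout dropout rate (0 disables; training uses inverted dropout).
#' @param offsets optional precomputed P x 2 pair offsets (nuclear-prior
#'   mode); default geometric offsets to candidate centers.
#' @param keep_cache logical; keep intermediate activations for the
#'   backward pass.
#' @return list with `C_prob` (b x m simplex rows) and `cache`.
#' @export
assignment_probabilities <- function(params, table, candidates, neighbor_idx,
                                     batch = seq_len(nrow(table)),
                                     dropout = 0, offsets = NULL,
                                     keep_cache = FALSE) {
  b <- length(batch)
  m <- ncol(neighbor_idx)
  p <- attr(params, "p")
  nb <- as.vector(neighbor_idx[batch, , drop = FALSE])
  pr_mol <- rep.int(batch, m)
  O <- offsets %||% pair_offsets(table, candidates, neighbor_idx, batch)

  Z1 <- O %*% t(params$loc1_W)
  Z1 <- sweep(Z1, 2L, params$loc1_b, "+")
  R1 <- relu(Z1)
  Hm <- R1 %*% t(params$loc2_W)
  Hm <- sweep(Hm, 2L, params$loc2_b, "+")
  lnh <- layernorm_rows(Hm)
  lnf <- layernorm_rows(params$f)
  lng <- layernorm_rows(params$g)
  fused0 <- lnf$y[nb, , drop = FALSE] +
            lng$y[table$gene_code[pr_mol], , drop = FALSE] + lnh$y
  mask_f <- dropout_mask(nrow(fused0), p, dropout)
  fused <- apply_mask(fused0, mask_f)

  B1 <- fused %*% t(params$fus1_W)
  B1 <- sweep(B1, 2L, params$fus1_b, "+")
  RB1 <- relu(B1)
  B2 <- RB1 %*% t(params$fus2_W)
  B2 <- sweep(B2, 2L, params$fus2_b, "+")
  RB2 <- relu(B2)
  logit <- drop(RB2 %*% params$fus3_W) + params$fus3_b

  L <- matrix(logit, b, m)
  # dropout acts on the softmax output (candidates are dropped, not
  # boosted); rows are renormalised so C_prob stays a simplex. The log-prob
  # gradient at the logits keeps the softmax form with the renormalised
  # probabilities.
  P0 <- softmax_rows(L)
  mask_l <- dropout_mask(b, m, dropout)
  if (!is.null(mask_l)) {
    Pd <- P0 * (mask_l > 0)
    rs <- rowSums(Pd)
    dead <- rs <= 0
    if (any(dead)) { Pd[dead, ] <- 1 / m; rs[dead] <- 1 }
    C_prob <- Pd / rs
  } else {
    C_prob <- P0
  }
  if (!all(is.finite(C_prob)))
    stop("non-finite assignment probabilities; parameter scale diverged ",
         "(max |logit| = ", max(abs(logit)), ")")
  cache <- NULL
  if (keep_cache)
    cache <- list(batch = batch, m = m, nb = nb, pr_mol = pr_mol,
                  gcode = table$gene_code[pr_mol], O = O,
                  Z1 = Z1, R1 = R1, lnh = lnh, lnf = lnf, lng = lng,
                  mask_f = mask_f, fused = fused, B1 = B1, RB1 = RB1,
                  B2 = B2, RB2 = RB2, mask_l = mask_l, C_prob = C_prob)
  list(C_prob = C_prob, cache = cache)
}

#' Noise-class probabilities
#'
#' Row-wise softmax of the trainable per-molecule noise logits; column 1 is
#' the noise class, column 2 the non-noise class.
#'
#' @param params a `policy_params`.
#' @param batch integer molecule indices (default all).
#' @return b x 2 matrix of probabilities.
#' @export
noise_probabilities <- function(params, batch = seq_len(nrow(params$noise))) {
  softmax_rows(params$noise[batch, , drop = FALSE])
}

# vectorised categorical sampling along rows of a probability matrix
sample_categorical_rows <- function(prob) {
  cum <- t(apply(prob, 1L, cumsum))
  u <- runif(nrow(prob)) * cum[, ncol(prob)]
  max.col(cum >= u, ties.method = "first")
}

#' Sample assignment and noise actions
#'
#' Draws a candidate slot per molecule from the assignment simplex and a
#' binary noise action from the noise head, using the current RNG state.
#'
#' @param C_prob b x m assignment probabilities.
#' @param N_prob b x 2 noise probabilities.
#' @param neighbor_idx neighbor index matrix restricted to the batch rows.
#' @return list with `G_slot` (1..m), `G` (global candidate index), and
#'   `H` (1 = noise, 2 = non-noise).
#' @export
sample_assignments <- function(C_prob, N_prob, neighbor_idx) {
  slot <- sample_categorical_rows(C_prob)
  H <- sample_categorical_rows(N_prob)
  G <- neighbor_idx[cbind(seq_len(nrow(neighbor_idx)), slot)]
  list(G_slot = slot, G = G, H = H)
}

#' Center distance scores for a batch
#'
#' Cell centers are re-estimated as the mean coordinates of the molecules
#' currently assigned to each cell (by default the batch molecules
#' themselves; during training the full current assignment state is passed
#' via `centers`); the score is `max(0, 1 - g_i / Q(g, q))` with `g_i` the
#' distance of molecule i to its assigned cell's center and `Q` the batch
#' quantile. If all distances are zero the score is 1 everywhere.
#'
#' @param x,y batch molecule coordinates.
#' @param G sampled candidate index per batch molecule.
#' @param q quantile (default 0.999).
#' @param centers optional candidate-indexed 2-column matrix of current
#'   cell centers (rows may be NA for empty cells, which fall back to the
#'   batch mean of their molecules).
#' @return numeric vector of scores in `[0, 1]`.
#' @export
center_distance_scores <- function(x, y, G, q = 0.999, centers = NULL) {
  if (is.null(centers)) {
    cx <- tapply(x, G, mean)
    cy <- tapply(y, G, mean)
    key <- as.character(G)
    ccx <- unname(cx[key]); ccy <- unname(cy[key])
  } else {
    ccx <- centers[G, 1L]; ccy <- centers[G, 2L]
    if (anyNA(ccx)) {
      miss <- which(is.na(ccx))
      cx <- tapply(x[miss], G[miss], mean)
      cy <- tapply(y[miss], G[miss], mean)
      key <- as.character(G[miss])
      ccx[miss] <- unname(cx[key]); ccy[miss] <- unname(cy[key])
    }
  }
  g <- sqrt((x - ccx)^2 + (y - ccy)^2)
  Q <- q_linear(g, q)
  if (Q == 0) return(rep(1, length(g)))
  pmax(0, 1 - g / Q)
}

# mean coordinates of non-noise molecules per candidate (NA when empty)
current_cell_centers <- function(x, y, G, H, n_candidates) {
  keep <- H == 2L
  centers <- matrix(NA_real_, n_candidates, 2L)
  if (any(keep)) {
    sx <- rowsum(x[keep], G[keep])
    sy <- rowsum(y[keep], G[keep])
    cnt <- rowsum(rep(1, sum(keep)), G[keep])
    rows <- as.integer(rownames(sx))
    centers[rows, 1L] <- sx / cnt
    centers[rows, 2L] <- sy / cnt
  }
  centers
}

#' Per-molecule rewards
#'
#' Multiplicative reward combining local density (NDS), proximity to the
#' assigned cell center (CDS), and expression agreement (ESS). Under the
#' default `"narrative"` orientation the non-noise action is rewarded by
#' `NDS * CDS * ESS` and the noise action by `(1 - NDS) * CDS * ESS`, so
#' that isolated molecules (low NDS) are pushed toward the noise class;
#' `"as_printed"` swaps the two branches. With `ablate_noise = TRUE` the
#' NDS factor is fixed to 1 (noise-sampling ablation).
#'
#' @param nds,cds,ess per-molecule score vectors.
#' @param H sampled noise action (1 = noise, 2 = non-noise).
#' @param orientation `"narrative"` (default) or `"as_printed"`.
#' @param ablate_noise logical.
#' @return numeric reward vector.
#' @export
compute_rewards <- function(nds, cds, ess, H,
                            orientation = c("narrative", "as_printed"),
                            ablate_noise = FALSE) {
  orientation <- match.arg(orientation)
  if (ablate_noise) nds <- rep(1, length(nds))
  noise_branch <- switch(orientation,
    narrative = (1 - nds) * cds * ess,
    as_printed = nds * cds * ess)
  nonnoise_branch <- switch(orientation,
    narrative = nds * cds * ess,
    as_printed = (1 - nds) * cds * ess)
  ifelse(H == 1L, noise_branch, nonnoise_branch)
}

#' Policy-gradient loss of the Segmentation Module
#'
#' `-(1/b) * sum_i reward_i * (ln P(G_i) + ln P(H_i))` over the batch, with
#' probabilities at the sampled actions clamped at 1e-12.
#'
#' @param reward per-molecule rewards.
#' @param C_prob,N_prob probability matrices.
#' @param G_slot sampled candidate slots (1..m).
#' @param H sampled noise actions (1 or 2).
#' @return scalar loss.
#' @export
region_loss <- function(reward, C_prob, N_prob, G_slot, H) {
  b <- length(reward)
  pg <- pmax(C_prob[cbind(seq_len(b), G_slot)], 1e-12)
  ph <- pmax(N_prob[cbind(seq_len(b), H)], 1e-12)
  -mean(reward * (log(pg) + log(ph)))
}

# Backward pass: gradients of region_loss w.r.t. all policy parameters.
# Uses the cache from assignment_probabilities(keep_cache = TRUE).
region_loss_backward <- function(params, cache, N_prob, reward, G_slot, H) {
  b <- length(reward)
  m <- cache$m
  p <- attr(params, "p")
  C_prob <- cache$C_prob

  # categorical log-prob gradient at the logits; with post-softmax dropout
  # the renormalised probabilities take the place of the softmax output,
  # and fully-dropped rows (uniform fallback) carry no gradient
  dL <- C_prob
  dL[cbind(seq_len(b), G_slot)] <- dL[cbind(seq_len(b), G_slot)] - 1
  dL <- dL * (reward / b)
  if (!is.null(cache$mask_l)) {
    dead <- rowSums(cache$mask_l > 0) == 0L
    if (any(dead)) dL[dead, ] <- 0
  }
  dlogit <- as.vector(dL)

  dRB2 <- tcrossprod(dlogit, params$fus3_W)
  dfus3_W <- drop(crossprod(cache$RB2, dlogit))
  dfus3_b <- sum(dlogit)
  dB2 <- dRB2 * (cache$B2 > 0)
  dfus2_W <- crossprod(dB2, cache$RB1)
  dfus2_b <- colSums(dB2)
  dRB1 <- dB2 %*% params$fus2_W
  dB1 <- dRB1 * (cache$B1 > 0)
  dfus1_W <- crossprod(dB1, cache$fused)
  dfus1_b <- colSums(dB1)
  dfused <- dB1 %*% params$fus1_W
  dfused0 <- apply_mask(dfused, cache$mask_f)

  # location branch
  dHm <- layernorm_backward(dfused0, cache$lnh$y, cache$lnh$sd)
  dloc2_W <- crossprod(dHm, cache$R1)
  dloc2_b <- colSums(dHm)
  dR1 <- dHm %*% params$loc2_W
  dZ1 <- dR1 * (cache$Z1 > 0)
  dloc1_W <- crossprod(dZ1, cache$O)
  dloc1_b <- colSums(dZ1)

  # embedding branches: accumulate per unique row, then LN backward
  df <- matrix(0, nrow(params$f), p)
  acc <- rowsum(dfused0, group = cache$nb)
  rows <- as.integer(rownames(acc))
  df[rows, ] <- layernorm_backward(acc, cache$lnf$y[rows, , drop = FALSE],
                                   cache$lnf$sd[rows])
  dg <- matrix(0, nrow(params$g), p)
  acc_g <- rowsum(dfused0, group = cache$gcode)
  rows_g <- as.integer(rownames(acc_g))
  dg[rows_g, ] <- layernorm_backward(acc_g,
                                     cache$lng$y[rows_g, , drop = FALSE],
                                     cache$lng$sd[rows_g])

  # noise head: softmax-categorical gradient at the noise logits
  dnoise <- matrix(0, nrow(params$noise), 2L)
  dN <- N_prob
  dN[cbind(seq_len(b), H)] <- dN[cbind(seq_len(b), H)] - 1
  dnoise[cache$batch, ] <- dN * (reward / b)

  list(f = df, g = dg, loc1_W = dloc1_W, loc1_b = dloc1_b,
       loc2_W = dloc2_W, loc2_b = dloc2_b,
       fus1_W = dfus1_W, fus1_b = dfus1_b,
       fus2_W = dfus2_W, fus2_b = dfus2_b,
       fus3_W = dfus3_W, fus3_b = dfus3_b, noise = dnoise)
}
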
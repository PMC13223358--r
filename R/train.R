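# Training orchestration: initialisation, the alternating epoch loop between
# the segmentation policy and the deconvolution network, learning-rate
# schedule, and the final deterministic assignment pass.

#' Run configuration
#'
#' Defaults follow the method's standard settings: 500 epochs, Adam with
#' initial learning rates 0.01 (noise logits) and 0.002 (all other
#' parameters) decayed by 0.996 per epoch, batches of `n / 50` molecules
#' capped at 2,000,000, 30 deconvolution iterations per epoch, m = 8
#' candidate neighbors, embedding width p = 20, cs = 10 reference states
#' per type.
#'
#' @param epochs training epochs (default 500).
#' @param lr_noise,lr_other initial Adam learning rates.
#' @param lr_decay multiplicative decay per epoch.
#' @param batch_divisor,batch_cap batch size = `min(cap, ceiling(n / divisor))`.
#' @param inner_iters deconvolution iterations per epoch (default 30).
#' @param m candidate neighbors per molecule.
#' @param p embedding width.
#' @param cs reference states per cell type.
#' @param dropout dropout rate for policy and deconvolution networks.
#' @param q_cds quantile for center distance scores (default 0.999).
#' @param reward_orientation `"narrative"` or `"as_printed"` (see
#'   [compute_rewards()]).
#' @param ablate_noise_sampling logical; pin the non-noise probability to 1
#'   and the NDS reward factor to 1 (noise-sampling ablation).
#' @param seed integer seed governing every random draw of the run.
#' @return a `seg_config` list.
#' @export
seg_config <- function(epochs = 500L, lr_noise = 0.01, lr_other = 0.002,
                       lr_decay = 0.996, batch_divisor = 50L,
                       batch_cap = 2e6, inner_iters = 30L, m = 8L, p = 20L,
                       cs = 10L, dropout = 0.1, q_cds = 0.999,
                       reward_orientation = c("narrative", "as_printed"),
                       ablate_noise_sampling = FALSE, seed = 0L) {
  stopifnot(epochs >= 0, lr_decay > 0, lr_decay <= 1)
  structure(list(
    epochs = as.integer(epochs), lr_noise = lr_noise, lr_other = lr_other,
    lr_decay = lr_decay, batch_divisor = as.integer(batch_divisor),
    batch_cap = batch_cap, inner_iters = as.integer(inner_iters),
    m = as.integer(m), p = as.integer(p), cs = as.integer(cs),
    dropout = dropout, q_cds = q_cds,
    reward_orientation = match.arg(reward_orientation),
    ablate_noise_sampling = isTRUE(ablate_noise_sampling),
    seed = as.integer(seed)
  ), class = "seg_config")
}

#' Initial nearest-candidate assignment
#'
#' Every molecule is assigned to its nearest candidate cell and marked
#' non-noise; the candidate x gene profile matrix is aggregated from the
#' panel-gene molecules.
#'
#' @param table a `transcript_table`.
#' @param candidates a `candidate_set`.
#' @param k number of panel (intersection) genes.
#' @return list with `G` (candidate index per molecule), `H` (all 2 =
#'   non-noise), `E` (candidate x gene counts).
#' @export
initialize_assignments <- function(table, candidates, k) {
  nn <- FNN::get.knnx(cbind(candidates$X, candidates$Y),
                      cbind(table$x, table$y), k = 1L)
  G <- as.integer(nn$nn.index[, 1L])
  H <- rep(2L, nrow(table))
  E <- aggregate_profiles(G, H, table$gene_code, nrow(candidates), k)
  list(G = G, H = H, E = E)
}

# rows into a slot-major (n * m) x 2 offset matrix for a batch
offset_rows <- function(batch, n, m) {
  rep((seq_len(m) - 1L) * n, each = length(batch)) + rep.int(batch, m)
}

#' Train the segmentation and deconvolution modules
#'
#' Alternates per epoch between (a) policy-gradient updates of the
#' segmentation policy over shuffled molecule batches, with center distance
#' scores computed per batch and expression similarity scores taken from
#' the previous epoch's deconvolution residuals, and (b) `inner_iters`
#' Adam iterations of the deconvolution network against the epoch's
#' aggregated expression profiles. Learning rates decay by `lr_decay` each
#' epoch. Fully deterministic for a fixed `config$seed` on CPU.
#'
#' @param table a `transcript_table` with `gene_code`.
#' @param candidates a `candidate_set`.
#' @param reference a `reference_panel`.
#' @param nds per-molecule noise distance scores.
#' @param config a [seg_config()].
#' @param offsets_all optional (n*m) x 2 slot-major pair offset matrix
#'   overriding geometric offsets (nuclear-prior mode).
#' @param neighbor_idx optional precomputed neighbor matrix.
#' @return a `seg_fit` list with trained `policy`, `deconv`, `ER`,
#'   `neighbor_idx`, per-epoch `trace` (region and alignment losses), and
#'   the inputs needed for [final_assignment()].
#' @export
run_training <- function(table, candidates, reference, nds, config,
                         offsets_all = NULL, neighbor_idx = NULL) {
  set.seed(config$seed)
  n <- nrow(table)
  k <- length(reference$genes)
  m <- config$m
  if (is.null(neighbor_idx))
    neighbor_idx <- nearest_candidate_cells(table, candidates, m)
  m <- ncol(neighbor_idx)
  n_cand <- nrow(candidates)

  policy <- init_policy_params(n_cand, k + 1L, nds, p = config$p)
  deconv <- init_deconv_params(reference, n_cand, cs = config$cs)

  init <- initialize_assignments(table, candidates, k)
  E <- init$E

  opt_policy <- adam_init(policy)
  opt_W <- lapply(deconv$W, function(w) adam_init(list(W = w)))
  opt_V <- adam_init(list(V = deconv$V))

  # determine the initial ER/ES/ESS by fitting the deconvolution to the
  # nearest-candidate profiles, so the first epoch's expression feedback is
  # informative rather than the residual of random parameters
  for (it in seq_len(config$inner_iters)) {
    spt <- reference_state_matrix(deconv, dropout = config$dropout,
                                  keep_cache = TRUE)
    pet <- predicted_expression(spt$Sp, deconv, dropout = config$dropout,
                                keep_cache = TRUE)
    gr <- alignment_loss_backward(deconv, spt$cache, pet$cache, pet$PE, E)
    stV <- adam_step(list(V = deconv$V), list(V = gr$V), opt_V,
                     lr = config$lr_other)
    deconv$V <- stV$params$V
    opt_V <- stV$state
    for (i in seq_along(deconv$W)) {
      stW <- adam_step(list(W = deconv$W[[i]]), list(W = gr$W[[i]]),
                       opt_W[[i]], lr = config$lr_other)
      deconv$W[[i]] <- stW$params$W
      opt_W[[i]] <- stW$state
    }
  }
  sp <- reference_state_matrix(deconv)
  pe <- predicted_expression(sp$Sp, deconv)
  sr <- similarity_and_residual(pe$PE, E)
  ER <- sr$ER

  trace <- data.frame(epoch = integer(0), region_loss = numeric(0),
                      alignment_loss = numeric(0))
  if (config$epochs == 0L) {
    return(structure(list(policy = policy, deconv = deconv, ER = ER,
                          neighbor_idx = neighbor_idx, nds = nds,
                          config = config, trace = trace,
                          offsets_all = offsets_all, init = init),
                     class = "seg_fit"))
  }

  bs <- min(config$batch_cap, ceiling(n / config$batch_divisor))
  G_epoch <- init$G
  H_epoch <- init$H
  ablate <- config$ablate_noise_sampling

  for (e in seq_len(config$epochs)) {
    decay <- config$lr_decay^(e - 1L)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    rl_sum <- 0
    for (s in starts) {
      batch <- perm[s:min(s + bs - 1L, n)]
      b <- length(batch)
      offs <- if (is.null(offsets_all)) NULL else
        offsets_all[offset_rows(batch, n, m), , drop = FALSE]
      fw <- assignment_probabilities(policy, table, candidates, neighbor_idx,
                                     batch = batch, dropout = config$dropout,
                                     offsets = offs, keep_cache = TRUE)
      N_prob <- noise_probabilities(policy, batch)
      nb_batch <- neighbor_idx[batch, , drop = FALSE]
      act <- sample_assignments(fw$C_prob, N_prob, nb_batch)
      if (ablate) {
        act$H <- rep(2L, b)
        N_prob <- matrix(rep(c(0, 1), each = b), b, 2L)
      }
      G_epoch[batch] <- act$G
      H_epoch[batch] <- act$H
      centers <- current_cell_centers(table$x, table$y, G_epoch, H_epoch,
                                      n_cand)
      cds <- center_distance_scores(table$x[batch], table$y[batch], act$G,
                                    q = config$q_cds, centers = centers)
      ess <- expression_similarity_scores(ER, act$G, act$H,
                                          table$gene_code[batch],
                                          orientation =
                                            config$reward_orientation)
      reward <- compute_rewards(nds[batch], cds, ess, act$H,
                                orientation = config$reward_orientation,
                                ablate_noise = ablate)
      rl_sum <- rl_sum + region_loss(reward, fw$C_prob, N_prob,
                                     act$G_slot, act$H) * b
      grads <- region_loss_backward(policy, fw$cache, N_prob, reward,
                                    act$G_slot, act$H)
      if (ablate) grads$noise <- NULL
      lr_vec <- c(config$lr_other * decay,
                  noise = config$lr_noise * decay)
      st <- adam_step(policy, grads, opt_policy, lr = lr_vec)
      attrs <- attributes(policy)
      policy <- st$params
      attributes(policy) <- attrs
      opt_policy <- st$state
      if (!is.finite(rl_sum))
        stop("non-finite region loss at epoch ", e)
    }

    # deconvolution phase against this epoch's aggregated profiles
    E <- aggregate_profiles(G_epoch, H_epoch, table$gene_code, n_cand, k)
    al <- NA_real_
    for (it in seq_len(config$inner_iters)) {
      spt <- reference_state_matrix(deconv, dropout = config$dropout,
                                    keep_cache = TRUE)
      pet <- predicted_expression(spt$Sp, deconv, dropout = config$dropout,
                                  keep_cache = TRUE)
      gr <- alignment_loss_backward(deconv, spt$cache, pet$cache, pet$PE, E)
      stV <- adam_step(list(V = deconv$V), list(V = gr$V), opt_V,
                       lr = config$lr_other * decay)
      deconv$V <- stV$params$V
      opt_V <- stV$state
      for (i in seq_along(deconv$W)) {
        stW <- adam_step(list(W = deconv$W[[i]]), list(W = gr$W[[i]]),
                         opt_W[[i]], lr = config$lr_other * decay)
        deconv$W[[i]] <- stW$params$W
        opt_W[[i]] <- stW$state
      }
    }
    sp <- reference_state_matrix(deconv)
    pe <- predicted_expression(sp$Sp, deconv)
    sr <- similarity_and_residual(pe$PE, E)
    ER <- sr$ER
    al <- alignment_loss(sr$ES)
    trace <- rbind(trace, data.frame(epoch = e, region_loss = rl_sum / n,
                                     alignment_loss = al))
  }

  structure(list(policy = policy, deconv = deconv, ER = ER,
                 neighbor_idx = neighbor_idx, nds = nds, config = config,
                 trace = trace, offsets_all = offsets_all, init = init),
            class = "seg_fit")
}

#' Final deterministic assignment pass
#'
#' With dropout off, each molecule is assigned to the argmax of its
#' assignment simplex and the argmax of its noise head (ties broken by
#' lower index). Per-cell expression profiles are aggregated over non-noise
#' panel-gene molecules.
#'
#' @param fit a `seg_fit` from [run_training()].
#' @param table,candidates,reference the training inputs.
#' @return a `segmentation_result` list: `assignment` (data.frame with x,
#'   y, gene, gene_code, cell, noise), `E` (cells x panel genes counts),
#'   `candidates`, `genes`.
#' @export
final_assignment <- function(fit, table, candidates, reference) {
  n <- nrow(table)
  m <- ncol(fit$neighbor_idx)
  k <- length(reference$genes)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 5e4))
  G <- integer(n); Hn <- integer(n)
  for (ch in chunks) {
    offs <- if (is.null(fit$offsets_all)) NULL else
      fit$offsets_all[offset_rows(ch, n, m), , drop = FALSE]
    fw <- assignment_probabilities(fit$policy, table, candidates,
                                   fit$neighbor_idx, batch = ch,
                                   dropout = 0, offsets = offs)
    slot <- max.col(fw$C_prob, ties.method = "first")
    G[ch] <- fit$neighbor_idx[cbind(ch, slot)]
    if (fit$config$ablate_noise_sampling) {
      Hn[ch] <- 2L
    } else {
      Np <- noise_probabilities(fit$policy, ch)
      Hn[ch] <- max.col(Np, ties.method = "first")
    }
  }
  E <- aggregate_profiles(G, Hn, table$gene_code, nrow(candidates), k)
  assignment <- data.frame(x = table$x, y = table$y, gene = table$gene,
                           gene_code = table$gene_code,
                           cell = ifelse(Hn == 2L, G, NA_integer_),
                           noise = Hn == 1L)
  structure(list(assignment = assignment, E = E, candidates = candidates,
                 genes = reference$genes),
            class = "segmentation_result")
}

#' Segment cells end to end
#'
#' Convenience wrapper: encodes genes, computes noise distance scores,
#' estimates candidate centers unless supplied, trains, runs the final
#' deterministic pass, extracts alpha-shape polygons and refines
#' assignments against them.
#'
#' @param transcripts data.frame with `x`, `y`, `gene`.
#' @param ref_counts reference counts (cells x genes) with gene names.
#' @param cell_type per-reference-cell labels.
#' @param candidates optional `candidate_set`; estimated when `NULL`.
#' @param config a [seg_config()].
#' @param r prior cell radius for candidate estimation (micrometers).
#' @param d,q noise-distance-score parameters (defaults 100, 0.999).
#' @param polygons logical; compute alpha-shape boundaries and refine.
#' @return a `segmentation_result` with additional elements `fit`,
#'   `reference`, `table`, `nds`, and (when `polygons`) `polygons`.
#' @export
segment_cells <- function(transcripts, ref_counts, cell_type,
                          candidates = NULL, config = seg_config(),
                          r = 6.5, d = 100L, q = 0.999, polygons = TRUE) {
  enc <- encode_genes(transcripts, ref_counts, cell_type)
  nds <- compute_noise_distance_scores(enc$table, d = d, q = q)
  if (is.null(candidates)) {
    set.seed(config$seed)
    candidates <- estimate_candidates(enc$table, enc$reference, r = r)
  }
  fit <- run_training(enc$table, candidates, enc$reference, nds, config)
  res <- final_assignment(fit, enc$table, candidates, enc$reference)
  res$fit <- fit
  res$reference <- enc$reference
  res$table <- enc$table
  res$nds <- nds
  if (polygons) {
    res$polygons <- polygonal_boundaries(res)
    res <- refine_assignments(res, res$polygons)
  }
  res
}
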
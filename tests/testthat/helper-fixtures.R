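# Shared fixtures, memoised so the expensive end-to-end runs happen once
# per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small matched tissue/reference pair for unit tests
small_dataset <- function() {
  memo("small_ds", {
    spec <- synthetic_spec(n_cells = 40L, n_types = 4L, n_genes = 50L,
                           mean_transcripts = 60, ref_cells_per_type = 25L,
                           noise_fraction = 0.05, seed = 3L)
    c(simulate_dataset(spec), list(spec = spec))
  })
}

small_encoded <- function() {
  memo("small_enc", {
    ds <- small_dataset()
    enc <- encode_genes(ds$tissue$transcripts, ds$reference$counts,
                        ds$reference$cell_type)
    enc$nds <- compute_noise_distance_scores(enc$table, d = 50L)
    enc
  })
}

# the default synthetic study fixture: 200 cells, 8 types, 100 genes,
# ~20k transcripts, 5% noise, seed 0
default_dataset <- function() {
  memo("default_ds", {
    spec <- synthetic_spec()
    c(simulate_dataset(spec), list(spec = spec))
  })
}

default_encoded <- function() {
  memo("default_enc", {
    ds <- default_dataset()
    enc <- encode_genes(ds$tissue$transcripts, ds$reference$counts,
                        ds$reference$cell_type)
    enc$nds <- compute_noise_distance_scores(enc$table)
    set.seed(0)
    enc$candidates <- estimate_candidates(enc$table, enc$reference, r = 6.5)
    enc
  })
}

# the 50-epoch training run on the default fixture (shared across
# parameter-recovery, training-progress and ablation checks)
default_run <- function() {
  memo("default_run", {
    enc <- default_encoded()
    cfg <- seg_config(epochs = 50L, seed = 0L)
    fit <- run_training(enc$table, enc$candidates, enc$reference, enc$nds,
                        cfg)
    res <- final_assignment(fit, enc$table, enc$candidates, enc$reference)
    list(fit = fit, res = res)
  })
}

# tiny policy instance for gradient and probability checks
tiny_policy_instance <- function(seed = 42L, n = 4L, m = 3L, p = 4L,
                                 k = 5L) {
  set.seed(seed)
  table <- data.frame(x = runif(n, 0, 10), y = runif(n, 0, 10),
                      gene = letters[seq_len(n)],
                      gene_code = sample(c(seq_len(k), k + 1L), n,
                                         replace = TRUE))
  cand <- as_candidate_set(cbind(runif(3, 0, 10), runif(3, 0, 10)))
  nds <- runif(n)
  params <- init_policy_params(3L, k + 1L, nds, p = p)
  nb <- nearest_candidate_cells(table, cand, m = m)
  list(table = table, cand = cand, nds = nds, params = params, nb = nb,
       n = n, m = m, p = p, k = k)
}

square_ring <- function(x0 = 0, y0 = 0, side = 1) {
  list(x = c(x0, x0 + side, x0 + side, x0), y = c(y0, y0, y0 + side, y0 + side))
}
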
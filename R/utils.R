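#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm runif rpois rlnorm rmultinom sd cor
#'   hclust cutree kmeans density bw.nrd0 aggregate setNames
#' @importFrom utils head
NULL

# Quantile convention used throughout (noise distance scores, center distance
# scores, valid-node cutoffs): linear interpolation between order statistics,
# i.e. stats::quantile type 7. Fixed package-wide for reproducibility.
q_linear <- function(x, q) {
  unname(stats::quantile(x, probs = q, type = 7, names = FALSE))
}

relu <- function(x) pmax(x, 0)

# numerically stable softplus: log(1 + exp(x))
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax, numerically stable
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

# Row-wise layer normalisation (no learnable affine): each row is centred and
# scaled to unit variance over the feature dimension.
LN_EPS <- 1e-5

layernorm_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowMeans(xc^2) + LN_EPS)
  list(y = xc / sdv, sd = sdv)
}

# Backward pass of the non-affine layer norm. `y` is the normalised output,
# `sdv` the per-row sd from the forward pass, `dy` the upstream gradient.
layernorm_backward <- function(dy, y, sdv) {
  (dy - rowMeans(dy) - y * rowMeans(dy * y)) / sdv
}

# Inverted dropout: returns a 0 / (1/keep) multiplier matrix so that the
# expected activation is unchanged during training.
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  matrix((runif(nr * nc) < keep) / keep, nr, nc)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

cosine_rows <- function(a, b) {
  # cosine similarity between matching rows of two matrices
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  out <- ifelse(den > 0, num / den, 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam optimiser ---------------------------------------------------------

# Minimal Adam state over a named list of numeric arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# `lr` is a scalar or a named vector; per-parameter rates are looked up by
# name with the unnamed/first element as fallback.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    lr_nm <- if (length(lr) > 1L && nm %in% names(lr)) lr[[nm]] else lr[[1L]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr_nm * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# torch-style uniform init for a linear layer, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_linear <- function(n_out, n_in) {
  b <- 1 / sqrt(n_in)
  list(
    W = matrix(runif(n_out * n_in, -b, b), n_out, n_in),
    b = runif(n_out, -b, b)
  )
}
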
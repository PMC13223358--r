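test_that("nearest-candidate search matches an exhaustive distance sort", {
  set.seed(31)
  tab <- data.frame(x = runif(50, 0, 100), y = runif(50, 0, 100))
  cand <- as_candidate_set(cbind(runif(10, 0, 100), runif(10, 0, 100)))
  nb <- nearest_candidate_cells(tab, cand, m = 4L)
  for (i in seq_len(50)) {
    d <- sqrt((cand$X - tab$x[i])^2 + (cand$Y - tab$y[i])^2)
    expect_equal(nb[i, ], order(d)[1:4])
  }
  # a single candidate takes every molecule, with a warning about m
  one <- as_candidate_set(cbind(5, 5))
  expect_warning(nb1 <- nearest_candidate_cells(tab, one, m = 8L), "m")
  expect_true(all(nb1 == 1L))
})

test_that("zero-initialised policy is uniform and m = 1 is degenerate", {
  inst <- tiny_policy_instance()
  fw <- assignment_probabilities(inst$params, inst$table, inst$cand, inst$nb)
  expect_equal(unname(fw$C_prob),
               matrix(1 / inst$m, inst$n, inst$m))
  nb1 <- inst$nb[, 1L, drop = FALSE]
  fw1 <- assignment_probabilities(inst$params, inst$table, inst$cand, nb1)
  expect_equal(unname(fw1$C_prob), matrix(1, inst$n, 1L))
})

test_that("assignment rows stay simplexes after training updates", {
  enc <- small_encoded()
  set.seed(4)
  cand <- suppressWarnings(estimate_candidates(enc$table, enc$reference,
                                               r = 6.5))
  fit <- run_training(enc$table, cand, enc$reference, enc$nds,
                      seg_config(epochs = 3L, seed = 4L))
  fw <- assignment_probabilities(fit$policy, enc$table, cand,
                                 fit$neighbor_idx,
                                 batch = sample(nrow(enc$table), 200))
  expect_true(all(abs(rowSums(fw$C_prob) - 1) < 1e-6))
  expect_true(all(fw$C_prob >= 0))
  Np <- noise_probabilities(fit$policy)
  expect_true(all(abs(rowSums(Np) - 1) < 1e-6))
})

test_that("assignment probabilities are translation invariant", {
  inst <- tiny_policy_instance(seed = 33)
  # give the scoring head nonzero weights so logits vary
  set.seed(1)
  inst$params$fus3_W <- rnorm(inst$p)
  fw <- assignment_probabilities(inst$params, inst$table, inst$cand, inst$nb)
  shifted_tab <- inst$table
  shifted_tab$x <- shifted_tab$x + 123
  shifted_tab$y <- shifted_tab$y - 45
  shifted_cand <- inst$cand
  shifted_cand$X <- shifted_cand$X + 123
  shifted_cand$Y <- shifted_cand$Y - 45
  fw2 <- assignment_probabilities(inst$params, shifted_tab, shifted_cand,
                                  inst$nb)
  expect_equal(fw2$C_prob, fw$C_prob, tolerance = 1e-10)
})

test_that("noise head follows the NDS initialisation closed forms", {
  params <- init_policy_params(2L, 3L, nds = c(0.5, 0.9), p = 4L)
  Np <- noise_probabilities(params)
  expect_equal(Np[1, ], c(0.5, 0.5))
  expect_equal(Np[2, ], c(exp(0.1), exp(0.9)) / (exp(0.1) + exp(0.9)))
  expect_equal(round(Np[2, ], 2), c(0.31, 0.69))
  expect_true(all(abs(rowSums(Np) - 1) < 1e-12))
})

test_that("action sampling is reproducible and matches probabilities", {
  C <- rbind(c(1, 0, 0), c(0.3, 0.3, 0.4))
  N <- rbind(c(1, 0), c(0.5, 0.5))
  nb <- rbind(c(7L, 8L, 9L), c(4L, 5L, 6L))
  set.seed(1)
  a <- sample_assignments(C, N, nb)
  expect_equal(a$G[1], 7L)   # degenerate row always picks candidate 1
  expect_equal(a$H[1], 1L)
  set.seed(1)
  b <- sample_assignments(C, N, nb)
  expect_identical(a, b)
  # empirical frequencies of a (0.3, 0.7) binomial within 3 sd
  Cbig <- matrix(rep(c(0.3, 0.7), each = 1e5), 1e5, 2)
  nbb <- matrix(rep(c(1L, 2L), each = 1e5), 1e5, 2)
  set.seed(2)
  s <- sample_assignments(Cbig, Cbig, nbb)
  phat <- mean(s$G_slot == 1L)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("center distance scores follow the batch-quantile closed forms", {
  # distances 1..100 against a fixed center, q = 0.999:
  # Q = 99.901, CDS(50) = 1 - 50/99.901
  x <- 1:100; y <- rep(0, 100); G <- rep(1L, 100)
  centers <- matrix(c(0, 0), 1, 2)
  cds <- center_distance_scores(x, y, G, q = 0.999, centers = centers)
  expect_equal(cds[50], 1 - 50 / 99.901, tolerance = 1e-10)
  expect_equal(cds[100], 0)   # at/above the quantile the floor applies
  # a molecule exactly at its center scores 1
  cds2 <- center_distance_scores(c(0, 3), c(0, 0), c(1L, 1L),
                                 centers = centers)
  expect_equal(cds2[1], 1)
  # coincident molecules: degenerate rule scores 1 everywhere
  expect_equal(center_distance_scores(rep(2, 5), rep(2, 5), rep(1L, 5),
                                      centers = matrix(c(2, 2), 1, 2)),
               rep(1, 5))
})

test_that("rewards follow both branch orientations", {
  # printed orientation closed forms
  expect_equal(compute_rewards(1, 1, 1, H = 2L, orientation = "as_printed"),
               0)
  expect_equal(compute_rewards(0, 1, 1, H = 2L, orientation = "as_printed"),
               1)
  expect_equal(compute_rewards(0.4, 0.5, 0.5, H = 1L,
                               orientation = "as_printed"), 0.1)
  # narrative orientation swaps the branches
  expect_equal(compute_rewards(0.4, 0.5, 0.5, H = 1L,
                               orientation = "narrative"),
               (1 - 0.4) * 0.5 * 0.5)
  expect_equal(compute_rewards(0.9, 0.8, 0.7, H = 2L,
                               orientation = "narrative"), 0.9 * 0.8 * 0.7)
  # the noise-sampling ablation pins the NDS factor to 1
  expect_equal(compute_rewards(0.4, 0.5, 0.5, H = 2L,
                               orientation = "narrative",
                               ablate_noise = TRUE), 0.25)
})

test_that("region loss matches closed forms", {
  expect_equal(region_loss(c(0, 0), rbind(c(0.2, 0.8), c(0.5, 0.5)),
                           rbind(c(0.5, 0.5), c(0.5, 0.5)),
                           c(1L, 2L), c(1L, 2L)), 0)
  # deterministic policy at the sampled actions
  expect_equal(region_loss(1, matrix(c(1, 0), 1), matrix(c(0, 1), 1),
                           1L, 2L), 0)
  # n = 1, reward 1, both probabilities 0.5
  expect_equal(region_loss(1, matrix(c(0.5, 0.5), 1),
                           matrix(c(0.5, 0.5), 1), 1L, 1L), 2 * log(2))
})

test_that("policy gradients match central finite differences", {
  inst <- tiny_policy_instance(seed = 42)
  set.seed(5)
  inst$params$fus3_W <- rnorm(inst$p, sd = 0.3)
  G_slot <- sample(seq_len(inst$m), inst$n, replace = TRUE)
  H <- sample(1:2, inst$n, replace = TRUE)
  reward <- runif(inst$n)
  loss_fn <- function(pp) {
    attr(pp, "p") <- inst$p
    class(pp) <- "policy_params"
    fw <- assignment_probabilities(pp, inst$table, inst$cand, inst$nb)
    region_loss(reward, fw$C_prob, noise_probabilities(pp), G_slot, H)
  }
  fw <- assignment_probabilities(inst$params, inst$table, inst$cand,
                                 inst$nb, keep_cache = TRUE)
  gr <- txseg:::region_loss_backward(inst$params, fw$cache,
                                     noise_probabilities(inst$params),
                                     reward, G_slot, H)
  eps <- 1e-6
  for (nm in names(gr)) {
    pa <- inst$params[[nm]]
    fd <- pa * 0
    for (i in seq_along(pa)) {
      pp <- inst$params; pp[[nm]][i] <- pa[i] + eps; lp <- loss_fn(pp)
      pp <- inst$params; pp[[nm]][i] <- pa[i] - eps; lm <- loss_fn(pp)
      fd[i] <- (lp - lm) / (2 * eps)
    }
    expect_lt(max(abs(fd - gr[[nm]]) / pmax(abs(fd), 1e-6)), 1e-4)
  }
})
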
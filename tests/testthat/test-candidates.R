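make_ref_panel <- function(counts, types) {
  structure(list(S = counts, U = counts, cell_type = factor(types),
                 genes = colnames(counts)), class = "reference_panel")
}

test_that("marker scores follow ln(A + 1) * P with brute-force agreement", {
  # one gene expressed in exactly one type at normalised mean e - 1:
  # P = 1 and S = ln(e) = 1
  counts <- rbind(c(exp(1) - 1, 1), c(0, 1))
  colnames(counts) <- c("gm", "gh")
  ref <- make_ref_panel(counts, c("A", "B"))
  mk <- score_markers(ref, p = 1L, norm_total = exp(1))
  # normalisation rescales rows; compute expected by brute force
  N <- counts / rowSums(counts) * exp(1)
  A <- t(sapply(seq_len(2), function(g)
    tapply(N[, g], c("A", "B"), mean)))
  P <- A / rowSums(A)
  S_exp <- log(A + 1) * P
  expect_equal(unname(mk$scores), unname(S_exp))

  # an all-zero gene scores 0 and is never selected
  counts2 <- cbind(counts, gz = c(0, 0))
  ref2 <- make_ref_panel(counts2, c("A", "B"))
  mk2 <- suppressWarnings(score_markers(ref2, p = 3L))
  expect_false("gz" %in% mk2$markers)
  expect_equal(unname(mk2$scores["gz", ]), c(0, 0))
})

test_that("marker selection equals exhaustive enumeration on a toy matrix", {
  set.seed(21)
  counts <- matrix(rpois(8 * 6, 4), 8, 6,
                   dimnames = list(NULL, paste0("g", 1:6)))
  types <- rep(c("A", "B"), each = 4)
  ref <- make_ref_panel(counts, types)
  mk <- score_markers(ref, p = 2L, norm_total = 100)
  N <- counts / rowSums(counts) * 100
  A <- sapply(c("A", "B"), function(ty) colMeans(N[types == ty, ]))
  P <- A / rowSums(A)
  S <- log(A + 1) * P
  expected <- unique(as.vector(sapply(c("A", "B"), function(ty)
    rownames(S)[order(S[, ty], decreasing = TRUE)][1:2])))
  expect_setequal(mk$markers, expected)
})

test_that("grid node features count marker molecules within 2r/pi", {
  r <- 5
  # molecules on a small field; oracle by direct distance check
  set.seed(22)
  tab <- data.frame(x = runif(20, 0, 40), y = runif(20, 0, 40),
                    gene = sample(c("m1", "m2"), 20, replace = TRUE))
  gf <- grid_node_features(tab, c("m1", "m2"), r)
  lay <- gf$layout
  nx <- lay$nx
  for (node in seq_len(lay$n_nodes)) {
    node_x <- lay$xmin + ((node - 1L) %% nx + 0.5) * 2 * r
    node_y <- lay$ymin + ((node - 1L) %/% nx + 0.5) * 2 * r
    d <- sqrt((tab$x - node_x)^2 + (tab$y - node_y)^2)
    for (g in c("m1", "m2"))
      expect_equal(unname(gf$raw[g, node]),
                   sum(d <= 2 * r / pi & tab$gene == g))
  }
  # standardised columns have mean 0 (constant columns are zeroed)
  expect_true(all(abs(colMeans(gf$F)) < 1e-12))
})

test_that("a molecule at a node counts once; empty nodes are zero", {
  r <- 5
  # bounding box [0,40]^2 puts node centers at 5, 15, 25, 35; the second
  # molecule sits exactly on node (5,5), the others outside any radius
  tab <- data.frame(x = c(0, 5, 40), y = c(0, 5, 40),
                    gene = c("m1", "m1", "m1"))
  gf <- grid_node_features(tab, "m1", r)
  expect_equal(sum(gf$raw), 1)
  expect_true(any(colSums(gf$raw) == 0))
  expect_error(grid_node_features(tab, "absent", r), "marker")
})

test_that("identical feature rows share a category and t_c sums max A", {
  F <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2 + 1,  # cor = 1
             c = c(4, 3, 2, 1), d = c(0, 5, 0, 5))
  A <- matrix(c(1, 5, 2, 0.5, 3, 1, 4, 2), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), c("t1", "t2")))
  cl <- cluster_marker_categories(F, A, c = 3L)
  expect_equal(cl$category[["a"]], cl$category[["b"]])
  amax <- apply(A, 1L, max)
  for (g in seq_along(cl$t))
    expect_equal(cl$t[g], sum(amax[cl$category == g]))
  # m == c puts every gene in its own category
  cl4 <- cluster_marker_categories(F, A, c = 4L)
  expect_equal(sort(unname(tabulate(cl4$category))), rep(1L, 4))
  # c > m is reduced with a warning
  expect_warning(cluster_marker_categories(F, A, c = 9L), "reducing")
})

test_that("valid-node cutoffs follow the two-stage rule", {
  valid <- select_valid_nodes(1:100, q = 0.9)
  # Q(1..100, 0.9) = 90.1 -> cutoff1 = 0.901 -> cutoff2 = mean(1:100) = 50.5
  expect_equal(sum(valid), 50L)
  expect_equal(which(valid), 51:100)
  # all-equal counts: cutoff2 equals the value, strict > leaves none
  expect_warning(v2 <- select_valid_nodes(rep(7, 10), q = 0.9), "cutoff")
  expect_false(any(v2))
  # single node cannot strictly exceed its own mean
  expect_warning(v3 <- select_valid_nodes(5, q = 0.9), "cutoff")
  expect_false(any(v3))
})

test_that("K-means split count follows the threshold formula and clamps", {
  # t_c = max(t): k = max(1, floor(0.25 h ln 2))
  set.seed(23)
  blob <- cbind(rnorm(40, 0, 0.5), rnorm(40, 0, 0.5))
  ctr <- cluster_molecules_to_candidates(blob, r = 2, t = c(5, 5), t_c = 5)
  expect_equal(nrow(ctr), max(1L, as.integer(0.25 * 40 * log(2))))
  # small h floors to zero and clamps to one candidate
  small <- cbind(rnorm(6, 0, 0.1), rnorm(6, 0, 0.1))
  ctr2 <- cluster_molecules_to_candidates(small, r = 2, t = c(5, 5), t_c = 5)
  expect_equal(nrow(ctr2), 1L)
  expect_equal(ctr2[1, ], colMeans(small), tolerance = 1e-12)
})

test_that("well-separated blobs form separate DBSCAN groups with centers near means", {
  set.seed(24)
  b1 <- cbind(rnorm(30, 0, 0.3), rnorm(30, 0, 0.3))
  b2 <- cbind(rnorm(30, 50, 0.3), rnorm(30, 50, 0.3))
  ctr <- cluster_molecules_to_candidates(rbind(b1, b2), r = 1,
                                         t = c(1, 1), t_c = 1e6)
  # huge t_c drives the log factor to ~0: one candidate per group
  expect_equal(nrow(ctr), 2L)
  d1 <- min(sqrt((ctr[, 1] - mean(b1[, 1]))^2 + (ctr[, 2] - mean(b1[, 2]))^2))
  d2 <- min(sqrt((ctr[, 1] - 50)^2 + (ctr[, 2] - 50)^2))
  expect_lt(d1, 0.5)
  expect_lt(d2, 0.5)
})

test_that("mean-shift merging collapses duplicates and keeps distant centers", {
  r <- 6.5
  dup <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(nrow(merge_candidates(dup, r)), 1L)
  far <- rbind(c(0, 0), c(100 * r, 0))
  expect_equal(nrow(merge_candidates(far, r)), 2L)
  expect_error(merge_candidates(NULL, r), "no candidate")
})

test_that("candidate estimation is translation-equivariant and in-bounds", {
  ds <- small_dataset()
  enc <- small_encoded()
  set.seed(9)
  cand <- suppressWarnings(estimate_candidates(enc$table, enc$reference,
                                               r = 6.5))
  expect_true(all(cand$X >= min(enc$table$x) & cand$X <= max(enc$table$x)))
  expect_true(all(cand$Y >= min(enc$table$y) & cand$Y <= max(enc$table$y)))
  # count within a factor 2 of the number of generated cells
  expect_gte(nrow(cand), ds$spec$n_cells / 2)
  expect_lte(nrow(cand), ds$spec$n_cells * 2)
  shifted <- enc$table
  shifted$x <- shifted$x + 500
  shifted$y <- shifted$y - 200
  set.seed(9)
  cand2 <- suppressWarnings(estimate_candidates(shifted, enc$reference,
                                                r = 6.5))
  expect_equal(nrow(cand2), nrow(cand))
  expect_equal(sort(cand2$X), sort(cand$X + 500), tolerance = 1e-8)
  expect_equal(sort(cand2$Y), sort(cand$Y - 200), tolerance = 1e-8)
})
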
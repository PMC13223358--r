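test_that("alpha shapes recover triangles and convex hulls", {
  # three non-collinear points give their triangle
  ring <- alpha_shape(c(0, 4, 0), c(0, 0, 3), alpha = 0)
  expect_equal(polygon_area(ring), 6)
  expect_equal(polygon_girth(ring), 3 + 4 + 5)
  # fewer than three (or collinear) points are degenerate
  expect_null(alpha_shape(c(0, 1), c(0, 0)))
  expect_null(alpha_shape(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  # alpha -> 0 on a convex cloud equals the convex hull
  set.seed(51)
  x <- runif(60); y <- runif(60)
  ring2 <- alpha_shape(x, y, alpha = 0)
  h <- chull(x, y)
  j <- c(h[-1], h[1])
  hull_area <- abs(sum(x[h] * y[j] - x[j] * y[h]) / 2)
  expect_equal(polygon_area(ring2), hull_area, tolerance = 1e-9)
})

test_that("automatic alpha keeps every point on a single ring", {
  set.seed(52)
  # an L-shaped cloud: the auto shape should hug it more tightly than the
  # convex hull while still covering all points
  xs <- c(runif(80, 0, 3), runif(80, 0, 1))
  ys <- c(runif(80, 0, 1), runif(80, 1, 4))
  ring <- alpha_shape(xs, ys)
  expect_false(is.null(ring))
  hull_ring <- alpha_shape(xs, ys, alpha = 0)
  expect_lte(polygon_area(ring), polygon_area(hull_ring) + 1e-9)
  inside <- sp::point.in.polygon(xs, ys, ring$x, ring$y)
  expect_true(all(inside > 0))
})

test_that("cell polygons flag degenerate cells and refinement renoises outsiders", {
  # two well-populated cells plus one 2-molecule cell
  set.seed(53)
  n1 <- 30; n2 <- 30
  asg <- data.frame(
    x = c(rnorm(n1, 0, 1), rnorm(n2, 20, 1), c(40, 40.1), 10),
    y = c(rnorm(n1, 0, 1), rnorm(n2, 0, 1), c(0, 0), 0),
    gene = "g1", gene_code = 1L,
    cell = c(rep(1L, n1), rep(2L, n2), 3L, 3L, 1L),
    noise = FALSE)
  res <- structure(list(
    assignment = asg,
    E = txseg:::aggregate_profiles(asg$cell, rep(2L, nrow(asg)),
                                   asg$gene_code, 3L, 1L),
    candidates = as_candidate_set(cbind(c(0, 20, 40), c(0, 0, 0))),
    genes = "g1"), class = "segmentation_result")
  # fixed alpha: triangles with circumradius above 2 are discarded, so the
  # distant stray is excluded from cell 1's boundary (automatic alpha would
  # widen the shape until every molecule is covered)
  polys <- polygonal_boundaries(res, alpha = 0.5)
  expect_length(polys, 3L)
  expect_true(polys[[3]]$degenerate)
  expect_false(polys[[1]]$degenerate)
  # the stray molecule at (10, 0) sits far outside cell 1's polygon
  ref <- refine_assignments(res, polys)
  i_stray <- nrow(asg)
  expect_true(ref$assignment$noise[i_stray])
  expect_true(is.na(ref$assignment$cell[i_stray]))
  # molecules inside keep their assignment; counts re-partition exactly
  expect_equal(sum(ref$E) + sum(ref$assignment$noise), nrow(asg))
  inside1 <- which(asg$cell == 1L & !ref$assignment$noise)
  expect_true(all(ref$assignment$cell[inside1] == 1L))
})

test_that("imputation weights are occurrence-scaled convex combinations", {
  set.seed(54)
  n_ref <- 30L
  counts <- matrix(rpois(n_ref * 8, 5), n_ref, 8,
                   dimnames = list(NULL, paste0("g", 1:8)))
  full <- cbind(counts,
                matrix(rpois(n_ref * 4, 2), n_ref, 4,
                       dimnames = list(NULL, paste0("h", 1:4))))
  ref <- structure(list(S = counts, U = full,
                        cell_type = factor(rep("A", n_ref)),
                        genes = colnames(counts)),
                   class = "reference_panel")
  E <- matrix(rpois(10 * 8, 5), 10, 8, dimnames = list(NULL, colnames(counts)))
  imp <- impute_transcriptome(E, ref, r = 10L, k = 5L)
  expect_equal(dim(imp$profiles), c(10L, 12L))
  for (i in 1:10) {
    w <- imp$weights[[i]]
    expect_equal(sum(w$w), 1)
    expect_true(all(w$w >= 0))
    # convex combination: imputed values within the contributors' range
    contrib <- full[w$ref, , drop = FALSE]
    expect_true(all(imp$profiles[i, ] >= apply(contrib, 2, min) - 1e-9))
    expect_true(all(imp$profiles[i, ] <= apply(contrib, 2, max) + 1e-9))
  }
})

test_that("occurrence scores follow ln(n / O)", {
  # 10 segmented cells; a reference cell present in every top-r list gets
  # OS = 0 hence zero weight; one present in exactly one list gets ln 10
  n <- 10L; O <- c(10L, 1L, 4L)
  OS <- log(n / O)
  expect_equal(OS[1], 0)
  expect_equal(OS[2], log(10))
  expect_equal(round(OS[2], 4), 2.3026)
})

test_that("nuclear priors zero offsets inside nuclei and clip polygons", {
  nucleus <- square_ring(0, 0, 2)
  tab <- data.frame(x = c(1, 5), y = c(1, 1))
  offs <- txseg:::nuclear_offsets(tab, list(nucleus),
                                  matrix(c(1L, 1L), 2, 1))
  expect_equal(offs[1, ], c(0, 0))       # inside the nucleus
  expect_equal(offs[2, ], c(3, 0))       # 3 um beyond the right edge
  # clip-then-union oracle via direct polygon algebra
  cell_poly <- square_ring(0, 0, 3)
  other_nuc <- square_ring(2.5, 0, 2)
  clipped <- polyclip::polyclip(list(cell_poly), list(other_nuc),
                                op = "minus")
  merged <- polyclip::polyclip(clipped, list(nucleus), op = "union")
  area <- sum(vapply(merged, function(r)
    abs(sum(r$x * c(r$y[-1], r$y[1]) - c(r$x[-1], r$x[1]) * r$y) / 2), 0))
  # cell [0,3]^2 loses its 0.5 x 2 overlap with the neighbouring nucleus;
  # its own nucleus lies inside what remains
  expect_equal(area, 9 - 1, tolerance = 1e-6)
})

test_that("polygon GeoJSON round trip preserves geometry", {
  polys <- structure(list(
    list(cell = 1L, rings = list(square_ring(0, 0, 2)), area = 4,
         girth = 8, degenerate = FALSE),
    list(cell = 2L, degenerate = TRUE)), class = "cell_polygons")
  f <- tempfile(fileext = ".geojson")
  write_polygons_geojson(polys, f)
  back <- read_polygons_geojson(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$cell, 1L)
  expect_equal(polygon_area(back[[1]]$rings), 4)
  expect_equal(polygon_girth(back[[1]]$rings), 8)
  unlink(f)
})

test_that("roundness hits the square and circle closed forms", {
  expect_equal(polygon_roundness(square_ring()), pi / 4)
  theta <- seq(0, 2 * pi, length.out = 361)[-361]
  gon <- list(x = cos(theta), y = sin(theta))
  expect_gt(polygon_roundness(gon), 0.999)
  expect_lte(polygon_roundness(gon), 1)
})

test_that("nuclear-prior segmentation runs end to end and honours nuclei", {
  ds <- small_dataset()
  # synthetic nuclei: squares of side 2r/2 centred on the true cells
  half <- ds$spec$radius / 2
  cells <- ds$tissue$cells
  nuclei <- lapply(seq_len(nrow(cells)), function(i)
    square_ring(cells$x[i] - half, cells$y[i] - half, 2 * half))
  res <- apply_nuclear_priors(ds$tissue$transcripts, nuclei,
                              ds$reference$counts, ds$reference$cell_type,
                              config = seg_config(epochs = 3L, seed = 7L),
                              d = 50L)
  asg <- res$assignment
  expect_equal(sum(!asg$noise) + sum(asg$noise), nrow(asg))
  # every cell's final polygon contains its own nucleus (union step)
  for (pp in res$polygons[1:5]) {
    nuc <- nuclei[[pp$cell]]
    inter <- txseg:::poly_boolean_area(pp$rings, nuc, "intersection")
    expect_equal(inter, polygon_area(nuc), tolerance = 1e-6)
  }
  # per-gene conservation still holds after refinement
  k <- length(res$genes)
  totals <- tabulate(asg$gene_code, nbins = k + 1L)[seq_len(k)]
  in_noise <- vapply(seq_len(k), function(g)
    sum(asg$noise & asg$gene_code == g), 0L)
  expect_equal(unname(colSums(res$E)) + in_noise, as.numeric(totals))
})
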
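test_that("deviation is the marker-masked sample-minus-reference sum", {
  # 2 genes, 2 types, ST = identity, S = (5, 2), RT diag = (3, 4) -> (2, -2)
  rt <- matrix(c(3, 0, 0, 4), 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  st <- diag(2)
  dimnames(st) <- dimnames(rt)
  b <- reference_bundle(rt, st, list(A = "g1", B = "g2"),
    cell_types = tibble::tibble(
      cell_type = c("A", "B"), is_t_subset = FALSE, parent = NA_character_
    )
  )
  s <- expr_of(matrix(c(5, 2), 2, dimnames = list(c("g1", "g2"), "s1")),
    platform = "microarray", transformed = TRUE
  )
  d <- compute_deviation(align_to_reference(s, b), b)
  expect_equal(unname(d[, 1]), c(2, -2))
})

test_that("a gene marking two types sums both reference differences", {
  # RT entries 1 and 3, S = 4 -> (4-1) + (4-3) = 4
  rt <- matrix(c(1, 0, 3, 0, 0, 2), 2,
    dimnames = list(c("g1", "g2"), c("A", "B", "C"))
  )
  st <- matrix(c(1, 0, 1, 0, 0, 1), 2, dimnames = dimnames(rt))
  b <- reference_bundle(rt, st, list(A = "g1", B = "g1", C = "g2"),
    cell_types = tibble::tibble(
      cell_type = c("A", "B", "C"), is_t_subset = FALSE,
      parent = NA_character_
    )
  )
  s <- expr_of(matrix(c(4, 7), 2, dimnames = list(c("g1", "g2"), "s1")),
    platform = "microarray", transformed = TRUE
  )
  d <- compute_deviation(align_to_reference(s, b), b)
  expect_equal(unname(d["g1", 1]), 4)
  expect_equal(unname(d["g2", 1]), 5)
})

test_that("a sample equal to a reference column has zero self-deviation", {
  b <- toy_bundle()
  s <- expr_of(b$rt[marker_genes(b), "B", drop = FALSE],
    platform = "microarray", transformed = TRUE
  )
  d <- compute_deviation(align_to_reference(s, b), b)
  expect_equal(unname(d[b$signatures$B, 1]), rep(0, 3))
})

test_that("deviation rejects misaligned gene order", {
  b <- toy_bundle()
  m <- b$rt[rev(marker_genes(b)), 1, drop = FALSE]
  colnames(m) <- "s1"
  s <- expr_of(m, platform = "microarray", transformed = TRUE)
  expect_error(compute_deviation(s, b), "marker order")
})

test_that("the uplifted cell type wins the enrichment ranking", {
  b <- toy_bundle()
  base <- b$rt[marker_genes(b), "NK"]
  uplifted <- base
  uplifted[b$signatures$NK] <- uplifted[b$signatures$NK] + 4
  s <- expr_of(matrix(uplifted, ncol = 1,
    dimnames = list(marker_genes(b), "s1")),
  platform = "microarray", transformed = TRUE
  )
  es <- score_samples(align_to_reference(s, b), b)
  scores <- unlist(es[1, bundle_cell_types(b)])
  expect_identical(names(which.max(scores)), "NK")
})

test_that("enrichment depends only on marker genes", {
  b <- toy_bundle()
  m1 <- b$rt[, "T", drop = FALSE] + 0.3
  m2 <- m1
  m2[c("X01", "X05"), 1] <- m2[c("X01", "X05"), 1] + 5 # non-marker genes
  colnames(m1) <- colnames(m2) <- "s1"
  e1 <- estimate_abundance(
    expr_of(m1, platform = "microarray", transformed = TRUE), b
  )
  e2 <- estimate_abundance(
    expr_of(m2, platform = "microarray", transformed = TRUE), b
  )
  expect_equal(e1$raw, e2$raw)
  expect_equal(e1$calibrated, e2$calibrated)
})

test_that("contribution matrix: identical cell types have symmetric entries", {
  b <- toy_bundle()
  b$rt[, "NK"] <- b$rt[, "B"] # make two reference profiles identical
  m <- build_contribution_matrix(b)
  expect_equal(m["B", "NK"], m["B", "B"])
  expect_equal(m["NK", "B"], m["NK", "NK"])
  expect_equal(unname(diag(m) >= 0), rep(TRUE, 4))
})

test_that("a disjoint orthogonal bundle concentrates contribution on the diagonal", {
  b <- toy_bundle()
  m <- build_contribution_matrix(b)
  for (j in seq_len(ncol(m))) {
    expect_true(all(m[-j, j] <= m[j, j]))
  }
})

test_that("compensation normalisation follows the divide/zero/clamp/cap steps", {
  b <- toy_bundle()
  # identity contribution -> identity compensation
  id <- diag(4)
  dimnames(id) <- list(bundle_cell_types(b), bundle_cell_types(b))
  expect_equal(normalize_compensation(id, b), id)

  # diagonal 2 with one off-diagonal 4 -> off-diagonal capped at 0.5
  m <- id
  diag(m) <- 2
  m["B", "NK"] <- 4
  C <- normalize_compensation(m, b)
  expect_equal(sum(C[-4, "NK"]), 0.5)
  expect_equal(C["B", "NK"], 0.5)
  expect_equal(diag(C), setNames(rep(1, 4), bundle_cell_types(b)))

  # parent/child entries are zeroed whatever their magnitude
  m2 <- id
  m2["T", "Tsub"] <- 10
  m2["Tsub", "T"] <- 3
  C2 <- normalize_compensation(m2, b)
  expect_equal(C2["T", "Tsub"], 0)
  expect_equal(C2["Tsub", "T"], 0)

  # zero diagonal is an error
  m3 <- id
  m3[1, 1] <- 0
  expect_error(normalize_compensation(m3, b), "zero diagonal")
})

test_that("compensation invariants hold across generated bundles", {
  for (seed in c(1, 2, 3)) {
    b <- generate_bundle(
      n_cell_types = 24, n_markers_per_type = 6, n_background_genes = 20,
      overlap_fraction = 0.3, seed = seed
    )
    C <- normalize_compensation(build_contribution_matrix(b), b)
    expect_equal(unname(diag(C)), rep(1, 24))
    expect_true(all(C >= 0))
    expect_true(all(colSums(C) - 1 <= 0.5 + 1e-12))
    h <- b$hierarchy
    for (i in seq_len(nrow(h))) {
      expect_identical(C[h$parent[i], h$child[i]], 0)
      expect_identical(C[h$child[i], h$parent[i]], 0)
    }
  }
})

test_that("calibration solves non-negative least squares", {
  C <- diag(2)
  dimnames(C) <- list(c("A", "B"), c("A", "B"))
  expect_equal(
    calibrate(c(A = 0.3, B = 0.7), C)$abundance,
    c(A = 0.3, B = 0.7)
  )
  expect_equal(
    calibrate(c(A = -0.2, B = 0.5), C)$abundance,
    c(A = 0, B = 0.5)
  )
  C2 <- rbind(c(1, 0.5), c(0, 1))
  dimnames(C2) <- dimnames(C)
  expect_equal(
    calibrate(c(A = 1, B = 1), C2)$abundance,
    c(A = 0.5, B = 1)
  )
  expect_error(calibrate(c(A = NA, B = 1), C), "non-finite")
})

test_that("calibration matches the active-set enumeration oracle", {
  set.seed(99)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3) + diag(3) * 2
    dimnames(A) <- list(letters[1:3], letters[1:3])
    b <- rnorm(3)
    got <- calibrate(setNames(b, letters[1:3]), A)$abundance
    want <- enumerate_nnls(A, b)
    expect_true(all(got >= 0))
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("all-negative scores calibrate to zero abundance under identity", {
  C <- diag(3)
  dimnames(C) <- list(letters[1:3], letters[1:3])
  got <- calibrate(c(a = -1, b = -0.5, c = -2), C)$abundance
  expect_equal(unname(got), c(0, 0, 0))
})

test_that("the pipeline is deterministic and permutation-invariant", {
  b <- toy_bundle()
  set.seed(3)
  m <- b$rt[, c("T", "B")] + matrix(rnorm(2 * nrow(b$rt), sd = 0.2), ncol = 2)
  m[m < 0] <- 0
  colnames(m) <- c("s1", "s2")
  ex <- expr_of(m, platform = "microarray", transformed = TRUE)
  r1 <- estimate_abundance(ex, b)

  # identical samples give identical rows
  dup <- expr_of(cbind(s1 = m[, 1], s2 = m[, 1]),
    platform = "microarray", transformed = TRUE
  )
  rd <- estimate_abundance(dup, b)
  expect_equal(
    unlist(rd$calibrated[1, -1]), unlist(rd$calibrated[2, -1])
  )

  # permuting genes and samples changes nothing (up to sample order)
  pg <- sample(nrow(m))
  ps <- 2:1
  r2 <- estimate_abundance(
    expr_of(m[pg, ps], platform = "microarray", transformed = TRUE), b
  )
  expect_equal(
    r1$calibrated[order(r1$calibrated$sample_id), ],
    r2$calibrated[order(r2$calibrated$sample_id), ]
  )
})

test_that("a one-hot mixture assigns the top abundance to its cell type", {
  b <- generate_bundle(
    n_cell_types = 8, n_markers_per_type = 8, n_background_genes = 30,
    seed = 4
  )
  types <- bundle_cell_types(b)
  onehot <- diag(length(types))[, c(2, 5)]
  mix <- generate_mixture(b,
    fractions = t(onehot), noise_sd = 0, seed = 1
  )
  res <- estimate_abundance(mix$expression, b)
  for (i in 1:2) {
    vals <- unlist(res$calibrated[i, types])
    expect_identical(names(which.max(vals)), types[c(2, 5)][i])
  }
})

test_that("tidy and glance expose the result in broom shape", {
  b <- toy_bundle()
  m <- b$rt[, c("T", "B")]
  colnames(m) <- c("s1", "s2")
  res <- estimate_abundance(
    expr_of(m, platform = "microarray", transformed = TRUE), b
  )
  td <- tidy(res)
  expect_setequal(
    names(td), c("sample_id", "cell_type", "raw_score", "abundance")
  )
  expect_identical(nrow(td), 8L)
  gl <- glance(res)
  expect_identical(gl$n_samples, 2L)
  expect_identical(gl$n_cell_types, 4L)
  expect_s3_class(autoplot(res), "ggplot")
})
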
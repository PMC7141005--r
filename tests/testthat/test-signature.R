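sim_fixture <- function(n_samples = 300, seed = 21, nulls = 3) {
  b <- generate_bundle(
    n_cell_types = 8, n_markers_per_type = 6, n_background_genes = 40,
    n_null_markers_per_type = nulls, seed = seed
  )
  tum <- generate_mixture(b, n_samples = 40, noise_sd = 0.5,
    seed = seed + 1)$expression
  list(bundle = b, sim = simulate_mixtures(tum, b, n_samples = n_samples,
    seed = seed + 2))
}

test_that("simulation is bitwise reproducible under a fixed seed", {
  fx <- sim_fixture(n_samples = 50)
  b <- fx$bundle
  tum <- generate_mixture(b, n_samples = 40, noise_sd = 0.5, seed = 22)$expression
  s1 <- simulate_mixtures(tum, b, n_samples = 50, seed = 9)
  s2 <- simulate_mixtures(tum, b, n_samples = 50, seed = 9)
  expect_identical(s1$strata[[1]]$fractions, s2$strata[[1]]$fractions)
  expect_identical(s1$strata[[1]]$expression, s2$strata[[1]]$expression)
  s3 <- simulate_mixtures(tum, b, n_samples = 50, seed = 10)
  expect_false(identical(s1$strata[[1]]$fractions, s3$strata[[1]]$fractions))
})

test_that("zero covariance collapses every sample onto its weighted profile", {
  b <- generate_bundle(
    n_cell_types = 5, n_markers_per_type = 4, n_background_genes = 10,
    seed = 3
  )
  const <- matrix(2, length(marker_genes(b)), 6,
    dimnames = list(marker_genes(b), paste0("t", 1:6))
  )
  sim <- simulate_mixtures(const, b, n_samples = 20, seed = 5)
  st <- sim$strata[[1]]
  expect_equal(st$expression, st$mean_profile, tolerance = 1e-10)
  # and the recorded profile is the fraction-weighted reference sum
  expect_equal(
    st$mean_profile,
    st$fractions %*% t(b$rt[sim$genes, bundle_cell_types(b)]),
    tolerance = 1e-12
  )
})

test_that("the weighted profile collapses correctly for degenerate weights", {
  b <- generate_bundle(
    n_cell_types = 4, n_markers_per_type = 3, n_background_genes = 5,
    seed = 8
  )
  rt <- b$rt[marker_genes(b), bundle_cell_types(b)]
  one_hot <- c(1, 0, 0, 0)
  expect_equal(drop(rt %*% one_hot), rt[, 1])
  equal_w <- rep(0.4, 4)
  expect_equal(drop(rt %*% equal_w), rowSums(rt) * 0.4)
})

test_that("G1 keeps tracking genes and drops fraction-independent genes", {
  fx <- sim_fixture()
  g1 <- filter_g1(fx$sim, fx$bundle)
  true_m <- attr(fx$bundle, "true_markers")
  null_m <- attr(fx$bundle, "null_markers")
  expect_gt(mean(true_m %in% g1), 0.95)
  expect_lt(mean(null_m %in% g1), 0.05)
  # threshold 0 keeps every gene with non-negative average correlation
  g1_all <- filter_g1(fx$sim, fx$bundle, threshold = 0)
  stats <- immunodecon:::marker_pair_stats(fx$sim, fx$bundle)
  nonneg <- stats |>
    dplyr::group_by(gene) |>
    dplyr::summarise(avg = mean(r_on)) |>
    dplyr::filter(avg >= 0) |>
    dplyr::pull(gene)
  expect_setequal(g1_all, nonneg)
})

test_that("G2 separates specific markers from indiscriminate decoys", {
  fx <- sim_fixture()
  g2 <- filter_g2(fx$sim, fx$bundle)
  null_m <- attr(fx$bundle, "null_markers")
  # decoys are flat across types, so their z is centred at 0; estimation
  # noise lets a minority past G2 alone, but the G1 intersection removes
  # them from the final set
  expect_lt(mean(null_m %in% g2), 0.3)
  expect_gt(mean(attr(fx$bundle, "true_markers") %in% g2), 0.95)
  sel <- select_markers(fx$sim, fx$bundle)
  expect_identical(intersect(null_m, sel$gf), character(0))
})

test_that("parent/subset pairs are excluded from the off-target set", {
  b <- generate_bundle(seed = 101) # 24-type immune ontology
  tum <- generate_mixture(b, n_samples = 30, noise_sd = 0.5, seed = 1)$expression
  sim <- simulate_mixtures(tum, b, n_samples = 30, seed = 2)
  stats <- immunodecon:::marker_pair_stats(sim, b)
  # a CD4 subset marker excludes itself and its parent: 22 off-targets;
  # the CD4 parent excludes itself and its 8 subsets: 15 off-targets
  n_types <- length(bundle_cell_types(b))
  expect_identical(
    immunodecon:::hierarchy_related(b, "Th1"), c("Th1", "CD4 T")
  )
  expect_length(
    setdiff(bundle_cell_types(b),
      immunodecon:::hierarchy_related(b, "CD4 T")), n_types - 9
  )
  expect_true(all(is.finite(stats$z)))
})

test_that("too few off-target types after exclusion is an error", {
  set.seed(1)
  types <- c("P", "c1", "c2", "c3")
  sig <- list(P = "gP", c1 = "g1", c2 = "g2", c3 = "g3")
  st <- diag(4)
  dimnames(st) <- list(unlist(sig), types)
  rt <- matrix(1, 4, 4, dimnames = dimnames(st)) + st * 2
  b <- reference_bundle(rt, st, sig,
    hierarchy = tibble::tibble(parent = "P", child = c("c1", "c2", "c3")),
    cell_types = tibble::tibble(
      cell_type = types, is_t_subset = FALSE,
      parent = c(NA, "P", "P", "P")
    )
  )
  tum <- matrix(rnorm(16, 2), 4, dimnames = list(unlist(sig), paste0("s", 1:4)))
  sim <- simulate_mixtures(tum, b, n_samples = 10, seed = 3)
  expect_error(filter_g2(sim, b), "fewer than 3 off-target")
})

test_that("raising a threshold never grows the selected set", {
  fx <- sim_fixture(n_samples = 150)
  g1_lo <- filter_g1(fx$sim, fx$bundle, threshold = 0.3)
  g1_hi <- filter_g1(fx$sim, fx$bundle, threshold = 0.7)
  expect_true(all(g1_hi %in% g1_lo))
  g2_lo <- filter_g2(fx$sim, fx$bundle, threshold = 0.5)
  g2_hi <- filter_g2(fx$sim, fx$bundle, threshold = 3)
  expect_true(all(g2_hi %in% g2_lo))
})

test_that("selection is the intersection and vacuous thresholds keep everything", {
  fx <- sim_fixture(n_samples = 150, nulls = 0)
  sel <- select_markers(fx$sim, fx$bundle)
  expect_setequal(sel$gf, intersect(sel$g1, sel$g2))
  expect_true(all(sel$gf %in% sel$g1))
  expect_true(all(sel$gf %in% sel$g2))

  sel_all <- select_markers(fx$sim, fx$bundle,
    g1_threshold = -Inf, g2_threshold = -Inf
  )
  expect_setequal(sel_all$gf, fx$sim$genes)

  # the rebuilt bundle only carries selected markers and still validates
  expect_setequal(unlist(sel$bundle$signatures, use.names = FALSE), sel$gf)
  expect_identical(
    nrow(validate_bundle(sel$bundle)[
      validate_bundle(sel$bundle)$severity == "error",
    ]), 0L
  )
})

test_that("selection errors when a cell type would lose all markers", {
  fx <- sim_fixture(n_samples = 150)
  expect_error(
    select_markers(fx$sim, fx$bundle, g1_threshold = 2),
    "without markers"
  )
})

test_that("tidy and glance summarise the selection audit trail", {
  fx <- sim_fixture(n_samples = 150)
  sel <- select_markers(fx$sim, fx$bundle)
  td <- tidy(sel)
  expect_true(all(c("gene", "cell_type", "r_on", "z", "in_gf") %in% names(td)))
  gl <- glance(sel)
  expect_identical(gl$n_selected, length(sel$gf))
  expect_identical(gl$g1_threshold, 0.6)
  expect_identical(gl$g2_threshold, 1.5)
})
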
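#' Simulate immune-infiltrated mixtures with a covariance-preserving model
#'
#' Simulates bulk tumour samples with known immune composition for marker
#' selection.  Per stratum (standing in for a cancer type): the gene-gene
#' covariance of the candidate genes is estimated from the supplied
#' tumour expression (log2 scale) and repaired to positive
#' semi-definiteness by clipping negative eigenvalues; then, per sample,
#' mixing weights f1..fN are drawn from Uniform(0,1), the weighted
#' reference profile `mu = sum_i f_i RT[,i]` is formed, and expression is
#' drawn from MVN(mu, Sigma).  The covariance keeps the correlative
#' structure of real tumour data in the simulated mixtures.  The weights
#' are deliberately not normalised to sum to one: normalising would
#' shrink the per-type fraction signal ~N-fold below any realistic
#' covariance noise and no gene could ever reach the default correlation
#' filter; the unnormalised weighted sum is the reading under which the
#' downstream thresholds are meaningful.
#'
#' @param tumor_expr A genes x samples log2-scale matrix (or `expr_tbl`,
#'   or data frame with a `gene` column), or a named list of them (one
#'   per stratum).
#' @param bundle A [reference_bundle()]; candidate genes are the bundle's
#'   marker genes present in the tumour matrix.
#' @param n_samples Simulated samples per stratum (default 500).
#' @param seed Integer seed; output is bit-reproducible.
#' @return A `mixture_sim` object: list of per-stratum elements, each
#'   holding `fractions` (samples x types, the Uniform(0,1) draws),
#'   `expression` and `mean_profile` (samples x candidate genes), plus
#'   `genes` and `cell_types`.
#' @export
simulate_mixtures <- function(tumor_expr, bundle, n_samples = 500, seed = 1) {
  stopifnot(n_samples >= 2)
  strata <- if (is.list(tumor_expr) && !is.data.frame(tumor_expr)) {
    tumor_expr
  } else {
    list(stratum1 = tumor_expr)
  }
  if (is.null(names(strata))) {
    names(strata) <- sprintf("stratum%d", seq_along(strata))
  }
  strata <- lapply(strata, function(x) {
    if (inherits(x, "expr_tbl") || is.data.frame(x)) {
      expr_values(as_expression(x, platform = "microarray", transformed = TRUE))
    } else {
      as.matrix(x)
    }
  })
  types <- bundle_cell_types(bundle)
  genes <- intersect(marker_genes(bundle), rownames(strata[[1]]))
  if (length(genes) < 2) abort("fewer than 2 candidate genes shared with tumor_expr")
  rt <- bundle$rt[genes, types, drop = FALSE]
  set.seed(seed)
  sims <- lapply(strata, function(tm) {
    tm <- tm[genes, , drop = FALSE]
    sigma <- psd_repair(cov(t(tm)))
    fr <- matrix(runif(n_samples * length(types)), n_samples, length(types))
    mu <- fr %*% t(rt)
    z <- matrix(rnorm(n_samples * length(genes)), n_samples, length(genes))
    ex <- mu + z %*% sigma$factor
    colnames(ex) <- genes
    colnames(fr) <- types
    list(fractions = fr, expression = ex, mean_profile = mu)
  })
  structure(
    list(strata = sims, genes = genes, cell_types = types),
    class = "mixture_sim"
  )
}

# eigen-clip repair of a (near-)covariance matrix; returns the repaired
# matrix and a factor B with t(B) %*% B == sigma for MVN draws
psd_repair <- function(s) {
  if (any(!is.finite(s))) abort("covariance matrix contains non-finite values")
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(
    sigma = e$vectors %*% (lam * t(e$vectors)),
    factor = sqrt(lam) * t(e$vectors)
  )
}

#' @export
print.mixture_sim <- function(x, ...) {
  cat(sprintf(
    "# mixture simulation: %d strata x %d samples, %d candidate genes, %d cell types\n",
    length(x$strata), nrow(x$strata[[1]]$fractions), length(x$genes),
    length(x$cell_types)
  ))
  invisible(x)
}

# across-strata average of the gene x cell-type correlation between
# simulated expression and mixing fractions; zero-variance genes give NA
marker_correlations <- function(sim) {
  mats <- lapply(sim$strata, function(s) {
    suppressWarnings(cor(s$expression, s$fractions))
  })
  Reduce(`+`, mats) / length(mats)
}

#' Average-correlation marker filter (G1)
#'
#' Keeps candidate marker genes whose simulated expression tracks the
#' fraction of the cell type(s) they mark: per stratum, the Pearson
#' correlation between the gene's expression and the marked type's
#' fraction is computed; a gene marking several types uses the mean of
#' its on-target correlations.  The across-strata average must reach
#' `threshold` (default 0.6).  Genes with undefined correlation (zero
#' variance) are dropped with a note.
#'
#' @param sim A `mixture_sim` from [simulate_mixtures()].
#' @param bundle The [reference_bundle()] used for the simulation.
#' @param threshold Minimum average on-target correlation (default 0.6).
#' @return Character vector of retained genes.
#' @export
filter_g1 <- function(sim, bundle, threshold = 0.6) {
  stats <- marker_pair_stats(sim, bundle)
  gene_stats <- stats %>%
    group_by(gene) %>%
    summarise(avg_r = mean(r_on), .groups = "drop")
  undef <- gene_stats$gene[is.na(gene_stats$avg_r)]
  if (length(undef) > 0) {
    inform(sprintf(
      "%d gene(s) with undefined correlation dropped: %s",
      length(undef), paste(head(undef, 5), collapse = ", ")
    ))
  }
  gene_stats$gene[!is.na(gene_stats$avg_r) & gene_stats$avg_r >= threshold]
}

#' Specificity marker filter (G2)
#'
#' Keeps genes whose on-target correlation stands out from their
#' correlations with all other cell-type fractions.  For marker gene g of
#' cell type c the off-target set excludes c itself and any type in a
#' parent/subset relation with c; the standardised deviation
#' `z = (r_c - mean(r_others)) / sd(r_others)` must exceed `threshold`
#' (default 1.5).  Genes marking several types use the mean z over their
#' marked types.
#'
#' @inheritParams filter_g1
#' @param threshold Minimum specificity z-score (default 1.5).
#' @return Character vector of retained genes.
#' @export
filter_g2 <- function(sim, bundle, threshold = 1.5) {
  stats <- marker_pair_stats(sim, bundle)
  gene_stats <- stats %>%
    group_by(gene) %>%
    summarise(z = mean(z), .groups = "drop")
  gene_stats$gene[!is.na(gene_stats$z) & gene_stats$z > threshold]
}

# per (gene, marked cell type) statistics: on-target correlation and
# specificity z against the hierarchy-excluded off-target correlations
marker_pair_stats <- function(sim, bundle) {
  R <- marker_correlations(sim)
  types <- sim$cell_types
  st <- bundle$st[sim$genes, types, drop = FALSE]
  pairs <- which(st == 1, arr.ind = TRUE)
  if (nrow(pairs) == 0) abort("bundle has no marker genes among the candidates")
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    g <- rownames(st)[pairs[i, 1]]
    ct <- types[pairs[i, 2]]
    others <- setdiff(types, hierarchy_related(bundle, ct))
    if (length(others) < 3) {
      abort(sprintf(
        "fewer than 3 off-target cell types for '%s' after hierarchy exclusion", ct
      ))
    }
    r_on <- R[g, ct]
    r_off <- R[g, others]
    tibble(
      gene = g, cell_type = ct, r_on = r_on,
      r_off_mean = mean(r_off), r_off_sd = sd(r_off),
      z = (r_on - mean(r_off)) / sd(r_off)
    )
  })
}

#' Simulation-driven marker selection
#'
#' Runs both marker filters and intersects them: `Gf = G1` (average
#' on-target correlation at least `g1_threshold`) `intersect G2`
#' (specificity z above `g2_threshold`).  The returned object carries the
#' per-gene audit statistics and a rebuilt bundle whose signatures and
#' marker indicator are restricted to the selected genes.
#'
#' @inheritParams filter_g1
#' @param g1_threshold Average-correlation threshold (default 0.6).
#' @param g2_threshold Specificity z threshold (default 1.5).
#' @return A `marker_selection` object with elements `g1`, `g2`, `gf`,
#'   `stats` (per gene x marked type tibble), `bundle` (restricted).
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
select_markers <- function(sim, bundle, g1_threshold = 0.6,
                           g2_threshold = 1.5) {
  stats <- marker_pair_stats(sim, bundle)
  gene_avg <- stats %>%
    group_by(gene) %>%
    summarise(avg_r = mean(r_on), z = mean(z), .groups = "drop")
  g1 <- gene_avg$gene[!is.na(gene_avg$avg_r) & gene_avg$avg_r >= g1_threshold]
  g2 <- gene_avg$gene[!is.na(gene_avg$z) & gene_avg$z > g2_threshold]
  gf <- intersect(g1, g2)
  new_sig <- lapply(bundle$signatures, intersect, y = gf)
  empty <- names(new_sig)[lengths(new_sig) == 0]
  if (length(empty) > 0) {
    abort(sprintf(
      "marker selection left cell type(s) without markers: %s",
      paste(empty, collapse = ", ")
    ))
  }
  keep_rows <- rownames(bundle$rt) %in%
    c(gf, setdiff(rownames(bundle$rt), marker_genes(bundle)))
  restricted <- reference_bundle(
    rt = bundle$rt[keep_rows, , drop = FALSE],
    st = bundle$st[rownames(bundle$st) %in% gf, , drop = FALSE],
    signatures = new_sig,
    hierarchy = bundle$hierarchy,
    cell_types = bundle$cell_types
  )
  stats <- stats %>%
    left_join(gene_avg, by = "gene", suffix = c("", "_gene")) %>%
    mutate(
      in_g1 = gene %in% g1, in_g2 = gene %in% g2, in_gf = gene %in% gf
    )
  structure(
    list(g1 = g1, g2 = g2, gf = gf, stats = stats, bundle = restricted,
      thresholds = c(g1 = g1_threshold, g2 = g2_threshold)),
    class = "marker_selection"
  )
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf(
    "# marker selection: |G1| = %d, |G2| = %d, |Gf| = %d\n",
    length(x$g1), length(x$g2), length(x$gf)
  ))
  invisible(x)
}

#' Tidy per-gene marker-selection statistics
#'
#' @param x A `marker_selection` from [select_markers()].
#' @param ... Unused.
#' @return A tibble with one row per (gene, marked cell type) pair.
#' @method tidy marker_selection
#' @export
tidy.marker_selection <- function(x, ...) x$stats

#' @rdname tidy.marker_selection
#' @method glance marker_selection
#' @export
glance.marker_selection <- function(x, ...) {
  tibble(
    n_candidates = dplyr::n_distinct(x$stats$gene),
    n_g1 = length(x$g1), n_g2 = length(x$g2), n_selected = length(x$gf),
    g1_threshold = x$thresholds[["g1"]], g2_threshold = x$thresholds[["g2"]]
  )
}
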
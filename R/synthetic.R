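#' Generate a synthetic reference bundle
#'
#' Builds a validated reference bundle with planted marker structure:
#' each cell type receives `n_markers_per_type` marker genes whose
#' reference expression in their own type is `marker_fold` times the
#' background level (on the linear scale; the bundle stores log2 values),
#' plus Gaussian noise.  Designated consecutive type pairs can share a
#' fraction of markers to exercise the compensation machinery, and flat
#' background genes pad the matrix so marker selection has null
#' candidates to reject.
#'
#' @param n_cell_types Number of cell types (24 uses the shipped
#'   [immune_cell_ontology()] names and hierarchy).
#' @param n_markers_per_type Markers planted per type (default 15).
#' @param n_background_genes Flat non-marker genes added to `rt`
#'   (default 200).
#' @param marker_fold Linear fold-elevation of a marker in its own type
#'   (default 8).
#' @param overlap_fraction Fraction of each even-indexed type's markers
#'   shared with the preceding type (default 0).
#' @param n_null_markers_per_type Decoy markers per type: genes claimed
#'   as markers in `st`/signatures but with flat reference profiles
#'   (default 0).  Used to benchmark marker selection, which should
#'   reject them.
#' @param noise_sd SD of Gaussian noise added to reference log2 values
#'   (default 0.25).
#' @param base_level Background-gene log2 expression level (default 3).
#' @param marker_off_level Log2 level of a marker gene in the types it
#'   does not mark (default 0.5, i.e. near-silent, matching the ~0-1 TPM
#'   off-type expression of lineage-restricted genes in blood atlases):
#'   lineage-restricted expression is the defining property of a marker
#'   gene.  Decoy (null) markers sit flat at this level in every type.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A [reference_bundle()] that passes [validate_bundle()].
#' @export
generate_bundle <- function(n_cell_types = 24, n_markers_per_type = 15,
                            n_background_genes = 200, marker_fold = 8,
                            overlap_fraction = 0,
                            n_null_markers_per_type = 0, noise_sd = 0.25,
                            base_level = 3, marker_off_level = 0.5, seed = 1) {
  stopifnot(
    n_cell_types >= 1, n_markers_per_type >= 1, n_background_genes >= 0,
    overlap_fraction >= 0, overlap_fraction < 1
  )
  n_shared <- floor(overlap_fraction * n_markers_per_type)
  if (n_shared >= n_markers_per_type && n_shared > 0) {
    abort("overlap_fraction leaves no type-private markers")
  }
  set.seed(seed)
  if (n_cell_types == 24) {
    ont <- immune_cell_ontology()
  } else {
    ont <- tibble(
      cell_type = sprintf("type%02d", seq_len(n_cell_types)),
      is_t_subset = FALSE, parent = NA_character_
    )
  }
  types <- ont$cell_type
  hierarchy <- ont %>%
    filter(!is.na(parent)) %>%
    dplyr::transmute(parent = parent, child = cell_type)

  safe <- gsub("[^A-Za-z0-9]", "", toupper(types))
  sig <- lapply(seq_along(types), function(i) {
    sprintf("MK%s.%02d", safe[i], seq_len(n_markers_per_type))
  })
  names(sig) <- types
  # even-indexed types additionally adopt the first n_shared markers of
  # the preceding type (shared markers mark both types)
  if (n_shared > 0) {
    for (i in seq(2, length(types), by = 2)) {
      sig[[i]] <- c(sig[[i]], sig[[i - 1]][seq_len(n_shared)])
    }
  }
  true_markers <- unique(unlist(sig))
  null_markers <- character()
  if (n_null_markers_per_type > 0) {
    for (i in seq_along(types)) {
      nl <- sprintf("NL%s.%02d", safe[i], seq_len(n_null_markers_per_type))
      sig[[i]] <- c(sig[[i]], nl)
      null_markers <- c(null_markers, nl)
    }
  }
  markers <- unique(unlist(sig))
  bg <- if (n_background_genes > 0) {
    sprintf("BG.%04d", seq_len(n_background_genes))
  } else {
    character()
  }
  genes <- c(markers, bg)

  st <- matrix(0, length(markers), length(types),
    dimnames = list(markers, types)
  )
  for (ct in types) st[sig[[ct]], ct] <- 1

  rt <- matrix(base_level, length(genes), length(types),
    dimnames = list(genes, types)
  )
  rt[markers, ] <- marker_off_level
  uplift_ind <- st
  uplift_ind[rownames(st) %in% null_markers, ] <- 0
  rt[markers, ] <- rt[markers, ] + uplift_ind * log2(marker_fold)
  rt <- rt + matrix(rnorm(length(rt), sd = noise_sd), nrow(rt))
  rt[rt < 0] <- 0

  bundle <- reference_bundle(rt, st, sig, hierarchy = hierarchy,
    cell_types = ont)
  attr(bundle, "true_markers") <- true_markers
  attr(bundle, "null_markers") <- null_markers
  bundle
}

#' The shipped default bundle
#'
#' A deterministic synthetic bundle over the 24-type immune ontology,
#' used wherever no user bundle is supplied.  Real reference data in the
#' same structure (rt/st/signatures/hierarchy) can be dropped in through
#' [reference_bundle()] or [read_bundle()].
#'
#' @return A [reference_bundle()].
#' @export
default_bundle <- function() {
  generate_bundle(seed = 101)
}

#' Simulate bulk mixtures with known cell-type fractions
#'
#' Each sample's expression is the fraction-weighted average of the
#' reference columns (log2 scale) plus Gaussian measurement noise,
#' clipped at zero.  Fractions default to independent Uniform(0,1)
#' draws, normalised to sum to one in the emitted truth table.  The
#' default noise level (0.1 on the log2 scale) models the technical
#' replicate variability typical of array or RNA-Seq profiling.
#'
#' @param bundle A [reference_bundle()].
#' @param n_samples Number of mixtures (ignored when `fractions` given).
#' @param fractions Optional samples x types non-negative weight matrix.
#' @param noise_sd SD of log2-scale Gaussian measurement noise
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A list with `expression` (an `expr_tbl`, log2-scale, flagged
#'   transformed) and `truth` (tibble `sample_id` + one fraction column
#'   per cell type, rows summing to one).
#' @export
generate_mixture <- function(bundle, n_samples = 100, fractions = NULL,
                             noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  types <- bundle_cell_types(bundle)
  if (is.null(fractions)) {
    fractions <- matrix(runif(n_samples * length(types)),
      n_samples, length(types)
    )
  }
  fractions <- as.matrix(fractions)
  stopifnot(ncol(fractions) == length(types))
  if (any(fractions < 0)) abort("fractions must be non-negative")
  tot <- rowSums(fractions)
  if (any(tot == 0)) {
    abort(sprintf("all-zero fraction row at sample %d", which(tot == 0)[1]))
  }
  fr <- fractions / tot
  rt <- bundle$rt[, types, drop = FALSE]
  expr <- rt %*% t(fr)
  if (noise_sd > 0) {
    expr <- expr + matrix(rnorm(length(expr), sd = noise_sd), nrow(expr))
  }
  expr[expr < 0] <- 0
  ids <- sprintf("mix%03d", seq_len(nrow(fr)))
  colnames(expr) <- ids
  truth <- dplyr::bind_cols(
    tibble(sample_id = ids),
    as_tibble(`dimnames<-`(fr, list(NULL, types)), .name_repair = "minimal")
  )
  list(
    expression = expr_from_matrix(expr,
      platform = "microarray",
      units = "log2 intensity", transformed = TRUE
    ),
    truth = truth
  )
}

#' Generate a labelled single-cell expression set
#'
#' Emits TPM-like (linear, non-negative) per-cell profiles: each cell is
#' drawn around its type's reference profile with log-normal noise, cell
#' types are sampled per patient from a random composition, and a subset
#' of background genes plays the housekeeping role used by
#' [normalize_single_cells()].
#'
#' @param bundle A [reference_bundle()] (needs background genes for the
#'   housekeeping list).
#' @param n_samples Number of patients/sample groups (default 4).
#' @param cells_per_sample Cells per group (default 100).
#' @param n_housekeeping Background genes designated as housekeeping
#'   (default 100).
#' @param noise_sd SD of log-scale noise per cell (default 0.5).
#' @param seed Integer seed.
#' @return A `single_cell_set`: list with `expression` (genes x cells,
#'   linear TPM-like), `cell_type`, `sample_id` (per cell), `housekeeping`
#'   (gene list), `normalized` flag.
#' @export
generate_single_cells <- function(bundle, n_samples = 4,
                                  cells_per_sample = 100,
                                  n_housekeeping = 100, noise_sd = 0.5,
                                  seed = 1) {
  set.seed(seed)
  types <- bundle_cell_types(bundle)
  genes <- rownames(bundle$rt)
  bg <- grep("^BG\\.", genes, value = TRUE)
  if (length(bg) < n_housekeeping) {
    abort("bundle has too few background genes for the housekeeping list")
  }
  hk <- bg[seq_len(n_housekeeping)]
  n_cells <- n_samples * cells_per_sample
  sample_id <- rep(sprintf("patient%02d", seq_len(n_samples)),
    each = cells_per_sample
  )
  labels <- character(n_cells)
  expr <- matrix(0, length(genes), n_cells,
    dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells)))
  )
  for (p in seq_len(n_samples)) {
    w <- runif(length(types))
    idx <- which(sample_id == sprintf("patient%02d", p))
    labels[idx] <- sample(types, length(idx), replace = TRUE, prob = w / sum(w))
  }
  log_expr <- bundle$rt[, match(labels, types), drop = FALSE] +
    matrix(rnorm(length(genes) * n_cells, sd = noise_sd), length(genes))
  log_expr[log_expr < 0] <- 0
  expr[] <- 2^log_expr - 1
  structure(
    list(
      expression = expr, cell_type = labels, sample_id = sample_id,
      housekeeping = hk, normalized = FALSE
    ),
    class = "single_cell_set"
  )
}

#' @export
print.single_cell_set <- function(x, ...) {
  cat(sprintf(
    "# single-cell set: %d genes x %d cells, %d samples, %d housekeeping genes%s\n",
    nrow(x$expression), ncol(x$expression), length(unique(x$sample_id)),
    length(x$housekeeping), if (x$normalized) " (normalized)" else ""
  ))
  invisible(x)
}

#' Normalise single cells by log transform and housekeeping scaling
#'
#' Two steps applied to every cell i: `exp = log2(exp + 1)`, then scaling
#' by `HKbar / HK_i`, where `HK_i` is cell i's mean over the housekeeping
#' genes and `HKbar` the mean of `HK_i` across cells.  After
#' normalisation every cell has exactly the same mean housekeeping
#' expression, which makes cells comparable before pseudo-bulk
#' aggregation.
#'
#' @param sc A `single_cell_set` from [generate_single_cells()].
#' @return The normalised `single_cell_set` (flagged `normalized`).
#' @export
normalize_single_cells <- function(sc) {
  stopifnot(inherits(sc, "single_cell_set"))
  if (sc$normalized) abort("single-cell set is already normalized")
  if (any(sc$expression < 0)) abort("expression must be non-negative (TPM-like)")
  if (!all(sc$housekeeping %in% rownames(sc$expression))) {
    abort("housekeeping genes missing from the expression matrix")
  }
  x <- log2(sc$expression + 1)
  hk_i <- colMeans(x[sc$housekeeping, , drop = FALSE])
  if (any(hk_i == 0)) {
    abort(sprintf(
      "zero housekeeping expression in cell '%s'",
      colnames(x)[which(hk_i == 0)[1]]
    ))
  }
  hk_bar <- mean(hk_i)
  x <- sweep(x, 2, hk_bar / hk_i, "*")
  sc$expression <- x
  sc$normalized <- TRUE
  sc
}

#' Aggregate single cells into pseudo-bulk samples with known fractions
#'
#' Per sample group, the pseudo-bulk profile is the gene-wise mean of the
#' normalised cells, and the ground-truth composition is the label count
#' divided by the total cell count, so fractions sum to one per group.
#'
#' @param sc A normalised `single_cell_set`.
#' @return A list with `expression` (an `expr_tbl`, log2-scale, flagged
#'   transformed; one column per sample group) and `truth` (tibble
#'   `sample_id` + one fraction column per observed cell type).
#' @export
pseudobulk <- function(sc) {
  stopifnot(inherits(sc, "single_cell_set"))
  if (!sc$normalized) abort("normalize_single_cells() must run before pseudobulk()")
  groups <- unique(sc$sample_id)
  expr <- vapply(groups, function(g) {
    rowMeans(sc$expression[, sc$sample_id == g, drop = FALSE])
  }, numeric(nrow(sc$expression)))
  types <- sort(unique(sc$cell_type))
  fr <- t(vapply(groups, function(g) {
    lab <- sc$cell_type[sc$sample_id == g]
    as.numeric(table(factor(lab, levels = types))) / length(lab)
  }, numeric(length(types))))
  truth <- dplyr::bind_cols(
    tibble(sample_id = groups),
    as_tibble(`dimnames<-`(fr, list(NULL, types)), .name_repair = "minimal")
  )
  list(
    expression = expr_from_matrix(expr,
      platform = "microarray",
      units = "normalized log2", transformed = TRUE
    ),
    truth = truth
  )
}

#' Generate a synthetic immunotherapy-response cohort
#'
#' Emits a cohort tibble for the response classifier: per-sample
#' cell-type "abundance" features drawn from standard normals, with the
#' first `n_informative` features shifted upward by `effect_size`
#' standard deviations in responders.  `effect_size = 0` gives a null
#' cohort in which the labels carry no signal.
#'
#' @param n_responders,n_nonresponders Class sizes.
#' @param features Character vector of feature names (default: the 22
#'   non-parental cell types of [immune_cell_ontology()]).
#' @param n_informative Number of signal-carrying features (default 3).
#' @param effect_size Mean shift (in SD units) of informative features in
#'   responders (default 2).
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, logical `response`, and one numeric
#'   column per feature.
#' @export
generate_response_cohort <- function(n_responders = 20,
                                     n_nonresponders = 40,
                                     features = NULL, n_informative = 3,
                                     effect_size = 2, seed = 1) {
  set.seed(seed)
  if (is.null(features)) {
    ont <- immune_cell_ontology()
    features <- setdiff(ont$cell_type, c("CD4 T", "CD8 T"))
  }
  n <- n_responders + n_nonresponders
  resp <- rep(c(TRUE, FALSE), c(n_responders, n_nonresponders))
  x <- matrix(rnorm(n * length(features)), n, length(features),
    dimnames = list(NULL, features)
  )
  k <- min(n_informative, length(features))
  if (k > 0 && effect_size != 0) {
    x[resp, seq_len(k)] <- x[resp, seq_len(k)] + effect_size
  }
  dplyr::bind_cols(
    tibble(sample_id = sprintf("pt%03d", seq_len(n)), response = resp),
    as_tibble(x, .name_repair = "minimal")
  )
}
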
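#' Marker-gene deviation from the reference
#'
#' For each marker gene g and each sample, the deviation is the
#' sample-minus-reference difference summed over the cell types for which
#' g is a marker:
#' \deqn{D_g = \sum_i ST[g,i]\,(S_g - RT[g,i])}
#' where S is the (transformed) query expression, RT the reference matrix
#' and ST the binary marker indicator.  D carries, per marker gene, how
#' far the sample lies above or below the reference profiles of the cell
#' types that gene marks; the per-type enrichment of D is the raw
#' abundance signal.
#'
#' @param aligned An `expr_tbl` already passed through
#'   [transform_expression()] and [align_to_reference()] (rows in bundle
#'   marker order).
#' @param bundle A [reference_bundle()].
#' @return A numeric matrix, marker genes x samples, of signed deviations.
#' @export
compute_deviation <- function(aligned, bundle) {
  s <- expr_values(aligned)
  markers <- marker_genes(bundle)
  if (!identical(rownames(s), markers)) {
    abort("gene order does not match the bundle marker order; run align_to_reference()")
  }
  st <- bundle$st
  rt <- bundle$rt[markers, bundle_cell_types(bundle), drop = FALSE]
  n_marked <- rowSums(st)
  ref_mass <- rowSums(st * rt)
  s * n_marked - ref_mass
}

#' Per-cell-type enrichment scores for each sample
#'
#' Scores each cell type's signature over every sample's deviation vector
#' with [ssgsea_score()].  The score `ES` is the raw (uncalibrated)
#' relative-abundance signal for that cell type.
#'
#' @inheritParams compute_deviation
#' @param alpha ssGSEA weighting exponent (default 0.25).
#' @return A tibble: `sample_id`, then one numeric column per cell type.
#' @export
score_samples <- function(aligned, bundle, alpha = 0.25) {
  dev <- compute_deviation(aligned, bundle)
  types <- bundle_cell_types(bundle)
  scores <- vapply(
    seq_len(ncol(dev)),
    function(j) {
      d <- dev[, j]
      vapply(types, function(ct) {
        ssgsea_score(d, bundle$signatures[[ct]], alpha = alpha)
      }, numeric(1))
    },
    numeric(length(types))
  )
  out <- t(matrix(scores, nrow = length(types),
    dimnames = list(types, colnames(dev))
  ))
  dplyr::bind_cols(
    tibble(sample_id = colnames(dev)),
    as_tibble(out, .name_repair = "minimal")
  )
}

#' Mutual contribution matrix of the reference profiles
#'
#' Entry (i, j) is the enrichment score of cell type i's signature on the
#' deviation vector of cell type j's own reference profile, i.e. how much
#' of type j's reference signal leaks into type i's score through shared
#' or co-expressed marker genes.  Its normalised form is the compensation
#' matrix used by [calibrate()].
#'
#' @param bundle A [reference_bundle()].
#' @param alpha ssGSEA weighting exponent.
#' @return An N x N numeric matrix with cell types as dim names.
#' @export
build_contribution_matrix <- function(bundle, alpha = 0.25) {
  types <- bundle_cell_types(bundle)
  ref <- expr_from_matrix(
    bundle$rt[marker_genes(bundle), types, drop = FALSE],
    platform = "microarray", transformed = TRUE
  )
  dev <- compute_deviation(ref, bundle)
  m <- vapply(types, function(j) {
    d <- dev[, j]
    vapply(types, function(i) {
      ssgsea_score(d, bundle$signatures[[i]], alpha = alpha)
    }, numeric(1))
  }, numeric(length(types)))
  dimnames(m) <- list(types, types)
  m
}

#' Normalise a contribution matrix into a compensation matrix
#'
#' Column by column: (1) divide by the diagonal so each type contributes
#' 1 to itself; (2) zero entries linking a parent type with its own
#' subsets (within-lineage compensation is disabled); (3) clamp negative
#' entries to 0; (4) down-weight the off-diagonal entries by the column's
#' off-diagonal mass proportion `s/(s+1)`, then rescale if needed so the
#' off-diagonal column sum never exceeds `cap` (default 0.5, the total
#' compensation budget per target type).
#'
#' @param contribution N x N matrix from [build_contribution_matrix()].
#' @param bundle A [reference_bundle()] (supplies the hierarchy).
#' @param cap Maximum off-diagonal column sum (default 0.5).
#' @return An N x N compensation matrix with unit diagonal.
#' @export
normalize_compensation <- function(contribution, bundle, cap = 0.5) {
  types <- colnames(contribution)
  d <- diag(contribution)
  if (any(d == 0)) {
    abort(sprintf(
      "zero diagonal contribution for cell type '%s'", types[which(d == 0)[1]]
    ))
  }
  C <- sweep(contribution, 2, d, "/")
  for (p in unique(bundle$hierarchy$parent)) {
    kids <- bundle$hierarchy$child[bundle$hierarchy$parent == p]
    C[p, kids] <- 0
    C[kids, p] <- 0
  }
  C[C < 0] <- 0
  diag(C) <- 1
  for (j in seq_along(types)) {
    off <- setdiff(seq_along(types), j)
    s <- sum(C[off, j])
    if (s > 0) {
      C[off, j] <- C[off, j] * (s / (s + 1))
      s2 <- sum(C[off, j])
      if (s2 > cap) C[off, j] <- C[off, j] * (cap / s2)
    }
  }
  C
}

#' Calibrate enrichment scores by non-negative least squares
#'
#' Solves, per sample, `I = argmin_{x >= 0} || C x - ES ||_2` so that the
#' calibrated abundances I explain the raw scores through the
#' compensation matrix while staying non-negative.  Uses the
#' Lawson-Hanson active-set solver.
#'
#' @param es Numeric vector of raw enrichment scores (one sample), or a
#'   matrix/tibble of samples in rows.
#' @param compensation N x N compensation matrix.
#' @return For a vector input, a list with `abundance` (named, >= 0) and
#'   `residual_norm`; for tabular input, a tibble `sample_id` + one
#'   column per cell type.
#' @export
#' @examples
#' C <- rbind(c(1, 0.5), c(0, 1))
#' colnames(C) <- rownames(C) <- c("A", "B")
#' calibrate(c(A = 1, B = 1), C)$abundance  # c(0.5, 1)
calibrate <- function(es, compensation) {
  types <- colnames(compensation)
  if (is.numeric(es) && is.null(dim(es))) {
    if (any(!is.finite(es))) abort("non-finite enrichment score")
    if (length(es) != ncol(compensation)) abort("dimension mismatch")
    if (!is.null(names(es))) es <- es[types]
    fit <- pracma::lsqnonneg(compensation, as.numeric(es))
    ab <- setNames(pmax(fit$x, 0), types)
    return(list(abundance = ab, residual_norm = sqrt(fit$resid.norm)))
  }
  tab <- as_tibble(es)
  ids <- if ("sample_id" %in% names(tab)) tab$sample_id else as.character(seq_len(nrow(tab)))
  m <- as.matrix(tab[types])
  out <- t(apply(m, 1, function(row) calibrate(setNames(row, types), compensation)$abundance))
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(out, .name_repair = "minimal"))
}

#' Estimate immune cell abundance from bulk expression
#'
#' The full pipeline: platform transform (unless already applied), marker
#' alignment, per-gene deviation from the reference, per-type enrichment
#' scoring, and compensation-matrix calibration by non-negative least
#' squares.  Abundances are relative within a sample; they are not
#' fractions and do not sum to one.
#'
#' @param expr An [as_expression()] table (raw or already transformed).
#' @param bundle A [reference_bundle()]; defaults to the synthetic
#'   [default_bundle()].
#' @param alpha ssGSEA weighting exponent (default 0.25).
#' @param compensate Apply compensation calibration (default `TRUE`);
#'   when `FALSE` the calibrated table equals the raw scores clamped at 0.
#' @param min_coverage Passed to [align_to_reference()].
#' @return An object of class `abundance_result` with elements `raw`
#'   (tibble of ES), `calibrated` (tibble of I), `compensation` (matrix),
#'   `coverage`, `alpha`.  Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
estimate_abundance <- function(expr, bundle = default_bundle(), alpha = 0.25,
                               compensate = TRUE, min_coverage = 0.5) {
  if (!expr_transformed(expr)) expr <- transform_expression(expr)
  aligned <- align_to_reference(expr, bundle, min_coverage = min_coverage)
  raw <- score_samples(aligned, bundle, alpha = alpha)
  types <- bundle_cell_types(bundle)
  if (compensate) {
    C <- normalize_compensation(build_contribution_matrix(bundle, alpha), bundle)
    cal <- calibrate(raw, C)
  } else {
    C <- diag(length(types))
    dimnames(C) <- list(types, types)
    cal <- raw
    cal[types] <- lapply(cal[types], pmax, 0)
  }
  structure(
    list(
      raw = raw, calibrated = cal, compensation = C,
      coverage = attr(aligned, "coverage"), alpha = alpha,
      cell_types = types
    ),
    class = "abundance_result"
  )
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(sprintf(
    "# abundance result: %d samples x %d cell types (alpha %.2f, coverage %.2f)\n",
    nrow(x$calibrated), length(x$cell_types), x$alpha, x$coverage
  ))
  print(x$calibrated)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an abundance result into long format
#'
#' @param x An `abundance_result` from [estimate_abundance()].
#' @param ... Unused.
#' @return A tibble with `sample_id`, `cell_type`, `raw_score`, `abundance`.
#' @method tidy abundance_result
#' @export
tidy.abundance_result <- function(x, ...) {
  raw <- tidyr::pivot_longer(x$raw, -sample_id,
    names_to = "cell_type", values_to = "raw_score"
  )
  cal <- tidyr::pivot_longer(x$calibrated, -sample_id,
    names_to = "cell_type", values_to = "abundance"
  )
  left_join(raw, cal, by = c("sample_id", "cell_type"))
}

#' @rdname tidy.abundance_result
#' @method glance abundance_result
#' @export
glance.abundance_result <- function(x, ...) {
  tibble(
    n_samples = nrow(x$calibrated),
    n_cell_types = length(x$cell_types),
    alpha = x$alpha,
    marker_coverage = x$coverage,
    max_offdiag_compensation = max(x$compensation - diag(diag(x$compensation)))
  )
}

#' Heatmap of calibrated abundances
#'
#' @param object An `abundance_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abundance_result
#' @export
autoplot.abundance_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = cell_type, y = sample_id, fill = abundance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "abundance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
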
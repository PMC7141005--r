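#' Create an expression table
#'
#' An expression table is a tibble whose first column, `gene`, holds unique
#' gene identifiers (HGNC symbols) and whose remaining columns hold one
#' numeric expression profile per sample.  The platform tag decides the
#' transform applied before scoring: microarray intensities are used as-is,
#' RNA-Seq values (TPM/FPKM) are mapped to `log2(x + 1)`.
#'
#' @param x A data frame. Either contains a `gene` column or the first
#'   column is taken as gene identifiers.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param units Free-text unit label (e.g. `"TPM"`, `"intensity"`).
#' @param transformed Logical; set `TRUE` when values are already on the
#'   post-transform scale (as for synthetic data generated on log2 scale).
#'
#' @return A tibble of class `expr_tbl` with attributes `platform`, `units`
#'   and `transformed`.
#' @export
#' @examples
#' ex <- as_expression(
#'   data.frame(gene = c("CD8A", "GZMB"), s1 = c(5, 2), s2 = c(1, 8)),
#'   platform = "rnaseq", units = "TPM"
#' )
#' expr_platform(ex)
as_expression <- function(x, platform = c("microarray", "rnaseq"),
                          units = NULL, transformed = FALSE) {
  platform <- arg_match(platform)
  x <- as_tibble(x)
  if (!"gene" %in% names(x)) {
    names(x)[1] <- "gene"
  }
  x <- dplyr::relocate(x, gene)
  x$gene <- as.character(x$gene)
  if (ncol(x) < 2L) {
    abort("expression table needs at least one sample column")
  }
  if (anyDuplicated(x$gene)) {
    abort("duplicate gene identifiers; collapse them first (see read_expression)")
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (anyDuplicated(colnames(vals))) abort("duplicate sample identifiers")
  if (any(!is.finite(vals))) abort("expression values must all be finite")
  new_expr_tbl(x, platform = platform, units = units, transformed = transformed)
}

new_expr_tbl <- function(x, platform, units, transformed) {
  structure(
    as_tibble(x),
    platform = platform,
    units = units,
    transformed = isTRUE(transformed),
    class = c("expr_tbl", class(as_tibble(x)))
  )
}

#' @rdname as_expression
#' @export
expr_platform <- function(x) attr(x, "platform")

#' @rdname as_expression
#' @export
expr_transformed <- function(x) isTRUE(attr(x, "transformed"))

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf(
    "# expression table: %d genes x %d samples [%s%s%s]\n",
    nrow(x), ncol(x) - 1L, attr(x, "platform"),
    if (is.null(attr(x, "units"))) "" else paste0(", ", attr(x, "units")),
    if (expr_transformed(x)) ", transformed" else ""
  ))
  NextMethod()
}

# genes x samples numeric matrix view
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene
  m
}

expr_from_matrix <- function(m, platform, units = NULL, transformed = FALSE) {
  as_expression(
    tibble::as_tibble(cbind(
      tibble(gene = rownames(m)),
      as_tibble(m, .name_repair = "minimal")
    )),
    platform = platform, units = units, transformed = transformed
  )
}

#' Platform-dependent expression transform
#'
#' Maps raw expression onto the common scale scored by the pipeline:
#' microarray intensities are left unchanged; every RNA-Seq value `m`
#' becomes `log2(m + 1)`.  The result is flagged as transformed and a
#' second application is rejected, so the transform can never be applied
#' twice by accident.
#'
#' @param expr An [as_expression()] table with non-negative values.
#' @return The transformed `expr_tbl`, flagged `transformed`.
#' @export
#' @examples
#' ex <- as_expression(data.frame(gene = "A", s1 = 7), platform = "rnaseq")
#' transform_expression(ex)$s1  # log2(8) = 3
transform_expression <- function(expr) {
  stopifnot(inherits(expr, "expr_tbl"))
  if (expr_transformed(expr)) {
    abort("expression is already transformed; refusing to apply the transform twice")
  }
  vals <- expr_values(expr)
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative expression value at gene '%s', sample '%s'",
      rownames(vals)[bad[1]], colnames(vals)[bad[2]]
    ))
  }
  if (expr_platform(expr) == "rnaseq") {
    vals <- log2(vals + 1)
  }
  expr_from_matrix(vals,
    platform = expr_platform(expr),
    units = attr(expr, "units"), transformed = TRUE
  )
}

#' Align an expression table to a reference bundle's marker genes
#'
#' Restricts and reorders the rows of a transformed expression table to the
#' bundle's marker-gene order.  Gene symbols are matched case-insensitively,
#' after applying an optional alias map.  Marker genes absent from the query
#' are imputed with the global median of the sample's observed marker-gene
#' values, which keeps their deviation near zero rather than extreme.
#'
#' @param expr A transformed [as_expression()] table.
#' @param bundle A [reference_bundle()].
#' @param min_coverage Minimum fraction of bundle marker genes that must be
#'   observed (default 0.5); below this an error is raised.
#' @param aliases Optional named character vector mapping alias symbols to
#'   the bundle's symbols (`c(alias = "SYMBOL")`).
#' @return An `expr_tbl` whose rows equal the bundle marker order, carrying
#'   attributes `coverage` (observed fraction) and `missing_genes`.
#' @export
align_to_reference <- function(expr, bundle, min_coverage = 0.5,
                               aliases = NULL) {
  stopifnot(inherits(expr, "expr_tbl"), inherits(bundle, "reference_bundle"))
  if (!expr_transformed(expr)) {
    abort("expression must be transformed before alignment (see transform_expression)")
  }
  markers <- marker_genes(bundle)
  vals <- expr_values(expr)
  g <- rownames(vals)
  if (!is.null(aliases)) {
    hit <- toupper(g) %in% toupper(names(aliases))
    g[hit] <- unname(aliases[match(toupper(g[hit]), toupper(names(aliases)))])
  }
  idx <- match(toupper(markers), toupper(g))
  observed <- !is.na(idx)
  coverage <- mean(observed)
  if (coverage < min_coverage) {
    abort(sprintf(
      "only %.1f%% of %d bundle marker genes found in the query (floor %.1f%%)",
      100 * coverage, length(markers), 100 * min_coverage
    ))
  }
  out <- matrix(NA_real_, length(markers), ncol(vals),
    dimnames = list(markers, colnames(vals))
  )
  out[observed, ] <- vals[idx[observed], , drop = FALSE]
  if (any(!observed)) {
    fill <- apply(out[observed, , drop = FALSE], 2, median)
    out[!observed, ] <- rep(fill, each = sum(!observed))
  }
  res <- expr_from_matrix(out,
    platform = expr_platform(expr),
    units = attr(expr, "units"), transformed = TRUE
  )
  attr(res, "coverage") <- coverage
  attr(res, "missing_genes") <- markers[!observed]
  res
}
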
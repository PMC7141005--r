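#' The shipped immune cell-type ontology
#'
#' Twenty-four immune cell types, eighteen of which are T-cell subsets.
#' The depth-one hierarchy links the two parental T-cell compartments to
#' their functional subsets: CD4 T parents the naive/helper/regulatory
#' subsets (CD4 naive, Th1, Th2, Th17, Tfh, Tr1, iTreg, nTreg) and CD8 T
#' parents CD8 naive, Tc, MAIT and Tex.  Memory (Tcm, Tem), gamma-delta
#' and NKT cells are T-cell subsets without a parent in the hierarchy.
#' Compensation between a parent and its own subsets is disabled during
#' calibration.
#'
#' @return A tibble with columns `cell_type`, `is_t_subset`, `parent`
#'   (`NA` when the type has no parent).
#' @export
#' @examples
#' ont <- immune_cell_ontology()
#' nrow(ont)              # 24 cell types
#' sum(ont$is_t_subset)   # 18 T-cell subsets
immune_cell_ontology <- function() {
  cd4_sub <- c(
    "CD4 naive", "Th1", "Th2", "Th17", "Tfh", "Tr1", "iTreg", "nTreg"
  )
  cd8_sub <- c("CD8 naive", "Tc", "MAIT", "Tex")
  other_t <- c("Tcm", "Tem", "Gamma delta T", "NKT")
  non_t <- c("B cell", "NK", "Monocyte", "Macrophage", "Neutrophil", "DC")
  tibble(
    cell_type = c("CD4 T", "CD8 T", cd4_sub, cd8_sub, other_t, non_t),
    is_t_subset = c(rep(TRUE, 2 + length(cd4_sub) + length(cd8_sub) +
      length(other_t)), rep(FALSE, length(non_t))),
    parent = c(
      NA, NA, rep("CD4 T", length(cd4_sub)), rep("CD8 T", length(cd8_sub)),
      rep(NA, length(other_t)), rep(NA, length(non_t))
    )
  )
}

#' Assemble a reference bundle
#'
#' A reference bundle packages everything the abundance pipeline needs:
#' the reference expression matrix `rt` (genes x cell types, median
#' profiles on the post-transform scale), the binary marker indicator
#' `st` (1 where a gene is a marker of that cell type), the per-type
#' signature gene lists, and the parent/subset hierarchy used to disable
#' within-lineage compensation.
#'
#' @param rt Numeric matrix, genes x cell types, with row and column names.
#'   May contain non-marker (background) rows in addition to marker genes.
#' @param st Binary numeric/logical matrix, marker genes x cell types.
#' @param signatures Named list of character vectors, one per cell type.
#' @param hierarchy Data frame with columns `parent`, `child`, or `NULL`.
#' @param cell_types Optional ontology tibble as from
#'   [immune_cell_ontology()]; defaults to one built from `rt` columns.
#' @return An object of class `reference_bundle`.
#' @export
reference_bundle <- function(rt, st, signatures, hierarchy = NULL,
                             cell_types = NULL) {
  stopifnot(is.matrix(rt), is.matrix(st), is.list(signatures))
  st <- (st != 0) * 1
  types <- colnames(rt)
  if (is.null(cell_types)) {
    ont <- immune_cell_ontology()
    cell_types <- tibble(
      cell_type = types,
      is_t_subset = types %in% ont$cell_type[ont$is_t_subset],
      parent = ont$parent[match(types, ont$cell_type)]
    )
  }
  if (is.null(hierarchy)) {
    hierarchy <- tibble(parent = character(), child = character())
  }
  hierarchy <- as_tibble(hierarchy)[c("parent", "child")]
  structure(
    list(
      cell_types = cell_types, rt = rt, st = st,
      signatures = signatures, hierarchy = hierarchy
    ),
    class = "reference_bundle"
  )
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf(
    "# reference bundle: %d cell types, %d marker genes (%d genes in rt)\n",
    nrow(x$cell_types), nrow(x$st), nrow(x$rt)
  ))
  cat(sprintf(
    "#   hierarchy: %d parent/subset pairs; T-cell subsets: %d\n",
    nrow(x$hierarchy), sum(x$cell_types$is_t_subset)
  ))
  invisible(x)
}

#' @rdname reference_bundle
#' @param bundle A `reference_bundle`.
#' @export
marker_genes <- function(bundle) rownames(bundle$st)

#' @rdname reference_bundle
#' @export
bundle_cell_types <- function(bundle) bundle$cell_types$cell_type

# cell types excluded from cross-compensation / off-target sets for `type`:
# the type itself, its parent, and its children
hierarchy_related <- function(bundle, type) {
  h <- bundle$hierarchy
  unique(c(type, h$parent[h$child == type], h$child[h$parent == type]))
}

#' Validate a reference bundle
#'
#' Checks the structural invariants every bundle must satisfy and returns
#' findings rather than raising, so a bundle can be audited in one pass:
#' every signature gene must be a row of `rt` and flagged in `st`; every
#' cell type needs at least one marker; the hierarchy must be acyclic with
#' depth one, without self-relations, and children of distinct parents
#' must be disjoint.  Identical reference columns are reported as an
#' advisory finding (indistinguishable cell types).
#'
#' @param bundle A [reference_bundle()].
#' @return A tibble of findings with columns `severity` (`"error"` or
#'   `"advisory"`), `cell_type`, `gene`, `message`; zero rows when all
#'   invariants hold.
#' @export
validate_bundle <- function(bundle) {
  f <- list()
  add <- function(severity, message, cell_type = NA_character_,
                  gene = NA_character_) {
    f[[length(f) + 1L]] <<- tibble(
      severity = severity, cell_type = cell_type, gene = gene,
      message = message
    )
  }
  types <- bundle_cell_types(bundle)
  for (ct in names(bundle$signatures)) {
    sig <- bundle$signatures[[ct]]
    if (length(sig) == 0) {
      add("error", "cell type has no marker genes", cell_type = ct)
      next
    }
    for (g in sig) {
      if (!g %in% rownames(bundle$rt)) {
        add("error", "signature gene missing from rt rows",
          cell_type = ct, gene = g
        )
      }
      if (!g %in% rownames(bundle$st) ||
        bundle$st[match(g, rownames(bundle$st)), ct] != 1) {
        add("error", "signature gene not flagged in st",
          cell_type = ct, gene = g
        )
      }
    }
  }
  missing_sig <- setdiff(types, names(bundle$signatures))
  for (ct in missing_sig) {
    add("error", "cell type has no signature", cell_type = ct)
  }
  h <- bundle$hierarchy
  if (any(h$parent == h$child)) {
    add("error", "hierarchy contains a self-relation",
      cell_type = h$parent[h$parent == h$child][1]
    )
  }
  if (any(h$child %in% h$parent)) {
    add("error", "hierarchy deeper than one level",
      cell_type = intersect(h$child, h$parent)[1]
    )
  }
  dup_child <- h$child[duplicated(h$child)]
  for (ct in unique(dup_child)) {
    add("error", "child assigned to more than one parent", cell_type = ct)
  }
  # advisory: indistinguishable reference columns
  cols <- bundle$rt[, types, drop = FALSE]
  for (i in seq_along(types)) {
    for (j in seq_len(i - 1L)) {
      if (isTRUE(all.equal(cols[, i], cols[, j], check.names = FALSE))) {
        add("advisory",
          sprintf("reference profiles identical for '%s' and '%s'",
            types[j], types[i]),
          cell_type = types[i]
        )
      }
    }
  }
  if (length(f) == 0) {
    tibble(
      severity = character(), cell_type = character(),
      gene = character(), message = character()
    )
  } else {
    bind_rows(f)
  }
}
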
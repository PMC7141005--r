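#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the delimiter (tab or comma) is auto-detected and gzip
#' compression is transparent.  Duplicate gene rows are collapsed by the
#' median, matching the reference aggregation rule.
#'
#' @param path File path (`.tsv`, `.csv`, optionally `.gz`).
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param units Optional unit label.
#' @return An [as_expression()] table.
#' @export
read_expression <- function(path, platform = c("microarray", "rnaseq"),
                            units = NULL) {
  platform <- arg_match(platform)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- suppressWarnings(readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      readr::col_character(), .default = readr::col_double()
    )
  ))
  prb <- readr::problems(tab)
  if (nrow(prb) > 0) {
    abort(sprintf(
      "non-numeric value at row %d, column %d of %s",
      prb$row[1], prb$col[1], path
    ))
  }
  if (nrow(tab) == 0 || ncol(tab) < 2) abort(sprintf("empty matrix in %s", path))
  names(tab)[1] <- "gene"
  if (anyDuplicated(tab$gene)) {
    tab <- tab %>%
      group_by(gene) %>%
      summarise(across(dplyr::everything(), median), .groups = "drop")
  }
  inform(sprintf(
    "read %d genes x %d samples from %s", nrow(tab), ncol(tab) - 1L, path
  ))
  as_expression(tab, platform = platform, units = units)
}

#' Write calibrated abundances to TSV
#'
#' Rows are samples, columns the bundle's cell types in bundle order,
#' written at full double precision so the file round-trips through
#' [readr::read_tsv()] without loss.
#'
#' @param result An [estimate_abundance()] result or a tibble with
#'   `sample_id` plus cell-type columns.
#' @param path Output file path.
#' @param raw Write the raw enrichment scores instead of the calibrated
#'   abundances (only for `abundance_result` input).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(result, path, raw = FALSE) {
  tab <- if (inherits(result, "abundance_result")) {
    if (raw) result$raw else result$calibrated
  } else {
    as_tibble(result)
  }
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write / read a reference bundle as plain-text files
#'
#' The on-disk form is a directory of TSVs: `rt.tsv` (gene + one column
#' per cell type), `st.tsv` (same layout, 0/1), `signatures.tsv`
#' (`cell_type`, `gene`), `hierarchy.tsv` (`parent`, `child`) and
#' `cell_types.tsv` (the ontology table).
#'
#' @param bundle A [reference_bundle()].
#' @param dir Directory to create/read.
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()`
#'   returns a validated [reference_bundle()].
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    readr::write_tsv(
      dplyr::bind_cols(tibble(gene = rownames(m)),
        as_tibble(m, .name_repair = "minimal")),
      file.path(dir, f)
    )
  }
  wr(bundle$rt, "rt.tsv")
  wr(bundle$st, "st.tsv")
  readr::write_tsv(
    purrr::imap_dfr(bundle$signatures, ~ tibble(cell_type = .y, gene = .x)),
    file.path(dir, "signatures.tsv")
  )
  readr::write_tsv(bundle$hierarchy, file.path(dir, "hierarchy.tsv"))
  readr::write_tsv(bundle$cell_types, file.path(dir, "cell_types.tsv"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  rd <- function(f) {
    tab <- readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
    m <- as.matrix(tab[-1])
    rownames(m) <- tab[[1]]
    m
  }
  sig_tab <- readr::read_tsv(file.path(dir, "signatures.tsv"),
    show_col_types = FALSE)
  sigs <- split(sig_tab$gene, sig_tab$cell_type)
  ct <- readr::read_tsv(file.path(dir, "cell_types.tsv"),
    show_col_types = FALSE)
  bundle <- reference_bundle(
    rt = rd("rt.tsv"), st = rd("st.tsv"),
    signatures = sigs[ct$cell_type],
    hierarchy = readr::read_tsv(file.path(dir, "hierarchy.tsv"),
      show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())),
    cell_types = ct
  )
  findings <- validate_bundle(bundle)
  if (any(findings$severity == "error")) {
    abort(sprintf(
      "bundle at %s fails validation: %s", dir,
      findings$message[findings$severity == "error"][1]
    ))
  }
  bundle
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a deterministic run: the
#' command, its configuration, the seed, md5 checksums of the input
#' files, the package version and a timestamp.  Written as JSON.
#'
#' @param command Character, the (sub)command name.
#' @param config Named list of configuration values.
#' @param seed Integer seed used for the run (or `NA`).
#' @param inputs Character vector of input file paths.
#' @param path Output path for the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, config = list(), seed = NA_integer_,
                           inputs = character(), path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("the jsonlite package is required to write manifests")
  }
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    version = as.character(utils::packageVersion("immunodecon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
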
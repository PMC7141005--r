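#' Per-cell-type correlation with ground truth
#'
#' Pearson correlation, per shared cell type, between estimated and true
#' abundance across the shared samples.  Types with zero variance in
#' either vector get `NA` (undefined correlation) and are excluded from
#' downstream summaries.
#'
#' @param estimates Tibble with a `sample_id` column and one numeric
#'   column per cell type (e.g. `$calibrated` of an
#'   [estimate_abundance()] result).
#' @param truth Same layout, ground-truth fractions or abundances.
#' @return A tibble with columns `cell_type`, `r`, `n_samples`.
#' @export
per_cell_correlation <- function(estimates, truth) {
  estimates <- as_tibble(estimates)
  truth <- as_tibble(truth)
  shared_samples <- intersect(estimates$sample_id, truth$sample_id)
  if (length(shared_samples) < 3) {
    abort("need at least 3 shared samples to correlate")
  }
  shared_types <- intersect(
    setdiff(names(estimates), "sample_id"),
    setdiff(names(truth), "sample_id")
  )
  if (length(shared_types) < 1) abort("no shared cell types")
  e <- estimates[match(shared_samples, estimates$sample_id), ]
  t_ <- truth[match(shared_samples, truth$sample_id), ]
  r <- vapply(shared_types, function(ct) {
    x <- e[[ct]]
    y <- t_[[ct]]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  tibble(cell_type = shared_types, r = unname(r),
    n_samples = length(shared_samples))
}

#' Correlation-deviation summary statistic
#'
#' Aggregates per-cell-type correlations into a single accuracy figure:
#' `(1/n) * sum((1 - r_i)^2)` over the `n` evaluable cell types.  It is 0
#' iff every correlation is perfect and at most 4 (all `r_i = -1`); lower
#' is better.  `formula = "one_minus_r_squared"` switches to the
#' alternative reading `(1/n) * sum(1 - r_i^2)`.  `NA` correlations
#' (undefined) are excluded from `n`.
#'
#' @param r Numeric vector of per-cell-type Pearson correlations, or the
#'   tibble returned by [per_cell_correlation()].
#' @param formula `"squared_error"` (default) or `"one_minus_r_squared"`.
#' @return A single non-negative number.
#' @export
#' @examples
#' correlation_deviation(c(1, 1, 1)) # 0
#' correlation_deviation(c(1, 0))    # 0.5
correlation_deviation <- function(r, formula = c("squared_error",
                                                 "one_minus_r_squared")) {
  formula <- arg_match(formula)
  if (is.data.frame(r)) r <- r$r
  r <- r[!is.na(r)]
  if (length(r) == 0) abort("no evaluable correlations")
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) abort("correlations must lie in [-1, 1]")
  switch(formula,
    squared_error = mean((1 - r)^2),
    one_minus_r_squared = mean(1 - r^2)
  )
}

#' Benchmark several estimators against one ground truth
#'
#' @param estimates_by_method Named list of estimate tibbles (layout as
#'   in [per_cell_correlation()]).
#' @param truth Ground-truth tibble.
#' @param formula Passed to [correlation_deviation()].
#' @return A `benchmark_report`: list with `correlations` (long tibble
#'   `method` x `cell_type` x `r`; `NA` where a method misses a type) and
#'   `summary` (per-method correlation deviation and evaluable-type
#'   count).  Supports [ggplot2::autoplot()].
#' @export
benchmark_report <- function(estimates_by_method, truth,
                             formula = "squared_error") {
  stopifnot(length(estimates_by_method) >= 1)
  if (is.null(names(estimates_by_method))) {
    names(estimates_by_method) <- sprintf(
      "method%d", seq_along(estimates_by_method)
    )
  }
  all_types <- setdiff(names(truth), "sample_id")
  correlations <- purrr::imap_dfr(estimates_by_method, function(est, nm) {
    pc <- per_cell_correlation(est, truth)
    full <- tibble(cell_type = all_types) %>%
      left_join(pc, by = "cell_type")
    mutate(full, method = nm, .before = 1)
  })
  summary <- correlations %>%
    group_by(method) %>%
    summarise(
      correlation_deviation = correlation_deviation(r, formula = formula),
      n_cell_types = sum(!is.na(r)),
      .groups = "drop"
    )
  structure(
    list(correlations = correlations, summary = summary),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("# benchmark report\n")
  print(x$summary)
  invisible(x)
}

#' Per-method, per-cell-type correlation heatmap
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object; missing correlations are blank.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  ggplot2::ggplot(object$correlations, ggplot2::aes(
    x = cell_type, y = method, fill = r
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      limits = c(-1, 1), low = "#2166AC", mid = "white", high = "#B2182B",
      na.value = "grey85"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
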
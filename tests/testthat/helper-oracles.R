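# Independent oracles used to cross-check the implementation.

# Naive O(n^2) running-sum ssGSEA: explicit walk down the ranking,
# recomputing the cumulative sums position by position.  Ties are not
# handled (callers use tie-free values).
naive_ssgsea <- function(values, gene_set, alpha = 0.25) {
  stopifnot(!anyDuplicated(values)) # tie-free instances only
  ord <- names(sort(values, decreasing = TRUE))
  n <- length(values)
  hit <- ord %in% gene_set
  stat <- rank(values)[ord]
  total <- 0
  for (i in seq_len(n)) {
    p_hit <- 0
    p_miss <- 0
    for (j in seq_len(i)) {
      if (hit[j]) p_hit <- p_hit + stat[j]^alpha else p_miss <- p_miss + 1
    }
    p_hit <- p_hit / sum(stat[hit]^alpha)
    if (sum(!hit) > 0) p_miss <- p_miss / sum(!hit)
    total <- total + (p_hit - p_miss)
  }
  as.numeric(total)
}

# Brute-force NNLS by active-set enumeration: for every subset of
# variables clamped to zero, solve the unconstrained least squares on the
# rest; keep the best feasible solution.
enumerate_nnls <- function(A, b) {
  n <- ncol(A)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^n - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) == 0)
    x <- numeric(n)
    if (length(free) > 0) {
      xf <- tryCatch(
        qr.solve(A[, free, drop = FALSE], b),
        error = function(e) NULL
      )
      if (is.null(xf) || any(xf < 0)) next
      x[free] <- xf
    }
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

# Small hand-assembled bundle: 4 types, disjoint 3-gene signatures plus
# background, one parent/child pair (T -> Tsub).
toy_bundle <- function(noise_sd = 0, seed = 5) {
  set.seed(seed)
  types <- c("T", "Tsub", "B", "NK")
  sig <- list(
    T = c("TG1", "TG2", "TG3"),
    Tsub = c("SG1", "SG2", "SG3"),
    B = c("BG1", "BG2", "BG3"),
    NK = c("NG1", "NG2", "NG3")
  )
  markers <- unlist(sig, use.names = FALSE)
  genes <- c(markers, sprintf("X%02d", 1:6))
  st <- matrix(0, length(markers), 4, dimnames = list(markers, types))
  for (ct in types) st[sig[[ct]], ct] <- 1
  rt <- matrix(0.5, length(genes), 4, dimnames = list(genes, types))
  rt[sprintf("X%02d", 1:6), ] <- 3
  rt[markers, ] <- rt[markers, ] + st * 3
  if (noise_sd > 0) rt <- rt + matrix(rnorm(length(rt), sd = noise_sd), nrow(rt))
  reference_bundle(
    rt, st, sig,
    hierarchy = tibble::tibble(parent = "T", child = "Tsub"),
    cell_types = tibble::tibble(
      cell_type = types, is_t_subset = c(TRUE, TRUE, FALSE, FALSE),
      parent = c(NA, "T", NA, NA)
    )
  )
}

expr_of <- function(m, ...) {
  immunodecon::as_expression(
    data.frame(gene = rownames(m), m, check.names = FALSE), ...
  )
}
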
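#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic (ties
#' handled by midranks), so it is invariant to any strictly monotone
#' transform of the scores.
#'
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class
#'   (responder).
#' @param scores Numeric decision scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
rank_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  rk <- rank(scores)
  (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# normalise a cohort tibble: a logical `response` column + numeric features
check_cohort <- function(cohort, require_both = TRUE) {
  cohort <- as_tibble(cohort)
  if (!"response" %in% names(cohort)) {
    abort("cohort needs a `response` column (logical: TRUE = responder)")
  }
  resp <- cohort$response
  if (is.character(resp) || is.factor(resp)) {
    resp <- as.character(resp) %in% c("R", "responder", "response", "TRUE", "1")
  }
  cohort$response <- as.logical(resp)
  feat <- setdiff(names(cohort), c("response", "sample_id", "cohort"))
  if (length(feat) == 0) abort("cohort has no feature columns")
  vals <- as.matrix(cohort[feat])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("feature columns must be finite numerics")
  }
  if (require_both && (all(cohort$response) || !any(cohort$response))) {
    abort("both responders and non-responders are required")
  }
  cohort
}

cohort_features <- function(cohort) {
  setdiff(names(cohort), c("response", "sample_id", "cohort"))
}

#' Balance a cohort by undersampling the majority class
#'
#' Randomly subsamples the majority class (seeded) down to the minority
#' class size; the minority class is kept untouched.
#'
#' @param cohort Tibble with a logical `response` column and numeric
#'   feature columns.
#' @param seed Integer seed.
#' @return The balanced cohort tibble (original row order preserved).
#' @export
undersample <- function(cohort, seed = 1) {
  cohort <- check_cohort(cohort)
  n_pos <- sum(cohort$response)
  n_neg <- sum(!cohort$response)
  if (n_pos == n_neg) return(cohort)
  set.seed(seed)
  major <- cohort$response == (n_pos > n_neg)
  keep_major <- sort(sample(which(major), min(n_pos, n_neg)))
  cohort[sort(c(which(!major), keep_major)), ]
}

# stratified k-fold assignment; retries with seed+1 while a training fold
# would miss a class (logged)
make_folds <- function(labels, k, seed) {
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- labels[fold != f]
      any(tr) && !all(tr)
    }, logical(1)))
    if (ok) {
      if (attempt > 0) inform(sprintf("refolded with seed offset %d", attempt))
      return(fold)
    }
  }
  abort("could not build folds with both classes in every training split")
}

fit_svm <- function(x, y, cost, gamma) {
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  e1071::svm(
    x = x, y = factor(y, levels = c(FALSE, TRUE)),
    kernel = "radial", cost = cost, gamma = gamma, scale = TRUE
  )
}

# decision scores oriented so that higher = responder (TRUE)
svm_scores <- function(fit, newx) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == "TRUE") as.numeric(dv) else -as.numeric(dv)
}

# pooled out-of-fold AUC of an RBF-SVM on the given feature subset
cv_auc <- function(cohort, features, fold, cost = 1, gamma = NULL) {
  x <- as.matrix(cohort[features])
  y <- cohort$response
  scores <- numeric(length(y))
  for (f in sort(unique(fold))) {
    fit <- fit_svm(x[fold != f, , drop = FALSE], y[fold != f], cost, gamma)
    scores[fold == f] <- svm_scores(fit, x[fold == f, , drop = FALSE])
  }
  rank_auc(y, scores)
}

#' Sequential backward feature selection
#'
#' Starting from all features, repeatedly drops the feature whose removal
#' gives the highest fivefold cross-validated AUC (pooled out-of-fold
#' scores), accepting a removal whenever it does not decrease the AUC.
#' Ties are broken by feature order, folds are fixed by the seed, and at
#' least one feature always remains.
#'
#' @param cohort Tibble with a logical `response` column and numeric
#'   feature columns (balance it first with [undersample()]).
#' @param seed Integer seed fixing the CV folds.
#' @param n_folds Number of CV folds (default 5).
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` means
#'   `1/n_features`.
#' @return A list with `features` (retained subset), `cv_auc` (final CV
#'   AUC) and `trace` (tibble of removal steps).
#' @export
backward_select <- function(cohort, seed = 1, n_folds = 5, cost = 1,
                            gamma = NULL) {
  cohort <- check_cohort(cohort)
  features <- cohort_features(cohort)
  if (length(features) < 2) abort("need at least 2 features to select from")
  fold <- make_folds(cohort$response, n_folds, seed)
  best <- cv_auc(cohort, features, fold, cost, gamma)
  trace <- list(tibble(step = 0L, removed = NA_character_,
    n_features = length(features), cv_auc = best))
  step <- 0L
  while (length(features) > 1) {
    cand <- vapply(features, function(f) {
      cv_auc(cohort, setdiff(features, f), fold, cost, gamma)
    }, numeric(1))
    i <- which.max(cand) # ties resolved by feature order
    if (cand[i] < best - 1e-9) break
    best <- unname(cand[i])
    step <- step + 1L
    trace[[length(trace) + 1L]] <- tibble(
      step = step, removed = features[i],
      n_features = length(features) - 1L, cv_auc = best
    )
    features <- setdiff(features, features[i])
  }
  list(features = features, cv_auc = best, trace = bind_rows(trace))
}

#' Train and evaluate an immunotherapy-response classifier
#'
#' The full modelling procedure: undersample the training cohort to class
#' balance, run sequential backward feature selection under fivefold
#' cross-validation, fit the final RBF-SVM on the balanced training set
#' with the selected features, and report the AUC on each held-out
#' cohort.  Holdout cohorts never influence selection or fitting.
#'
#' @param train Training cohort tibble (`response` + cell-type abundance
#'   features).
#' @param holdouts Named list of holdout cohort tibbles (may be empty).
#' @param seed Integer seed (undersampling + CV folds).
#' @param select Run backward feature selection (default `TRUE`).
#' @param balance Undersample the majority class (default `TRUE`).
#' @param n_folds CV folds for selection (default 5).
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` means
#'   `1/n_features`.
#' @return A `response_model` object: `fit` (the svm), `features`,
#'   `cv_auc`, `holdout_auc` (tibble `cohort`, `auc`, `n`, `n_responders`),
#'   `trace`, `seed`, `hyperparameters`.  Supports `predict()`,
#'   [generics::tidy()] and [generics::glance()].
#' @export
train_response_model <- function(train, holdouts = list(), seed = 1,
                                 select = TRUE, balance = TRUE, n_folds = 5,
                                 cost = 1, gamma = NULL) {
  train <- check_cohort(train)
  if (balance) train <- undersample(train, seed = seed)
  if (select) {
    sel <- backward_select(train, seed = seed, n_folds = n_folds,
      cost = cost, gamma = gamma)
  } else {
    fold <- make_folds(train$response, n_folds, seed)
    feats <- cohort_features(train)
    sel <- list(
      features = feats,
      cv_auc = cv_auc(train, feats, fold, cost, gamma),
      trace = tibble(step = 0L, removed = NA_character_,
        n_features = length(feats),
        cv_auc = NA_real_)
    )
  }
  fit <- fit_svm(as.matrix(train[sel$features]), train$response, cost, gamma)
  model <- structure(
    list(
      fit = fit, features = sel$features, cv_auc = sel$cv_auc,
      trace = sel$trace, seed = seed,
      hyperparameters = list(
        cost = cost,
        gamma = if (is.null(gamma)) 1 / length(sel$features) else gamma,
        n_folds = n_folds
      ),
      n_train = nrow(train)
    ),
    class = "response_model"
  )
  model$holdout_auc <- purrr::imap_dfr(holdouts, function(h, nm) {
    h <- check_cohort(h, require_both = FALSE)
    missing <- setdiff(model$features, names(h))
    if (length(missing) > 0) {
      abort(sprintf("holdout '%s' lacks feature(s): %s", nm,
        paste(missing, collapse = ", ")))
    }
    scores <- svm_scores(fit, as.matrix(h[model$features]))
    tibble(
      cohort = nm, auc = rank_auc(h$response, scores),
      n = nrow(h), n_responders = sum(h$response)
    )
  })
  model
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf(
    "# response model: RBF-SVM on %d feature(s) (n = %d balanced, CV AUC %.3f)\n",
    length(x$features), x$n_train, x$cv_auc
  ))
  if (nrow(x$holdout_auc) > 0) print(x$holdout_auc)
  invisible(x)
}

#' Predict response scores for new samples
#'
#' @param object A `response_model`.
#' @param new_data Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return A tibble with `score` (higher = more responder-like) and
#'   `predicted_response`.
#' @export
predict.response_model <- function(object, new_data, ...) {
  new_data <- as_tibble(new_data)
  scores <- svm_scores(object$fit, as.matrix(new_data[object$features]))
  tibble(score = scores, predicted_response = scores > 0)
}

#' Tidy holdout performance of a response model
#'
#' @param x A `response_model`.
#' @param ... Unused.
#' @return Tibble of per-cohort holdout AUCs.
#' @method tidy response_model
#' @export
tidy.response_model <- function(x, ...) x$holdout_auc

#' @rdname tidy.response_model
#' @method glance response_model
#' @export
glance.response_model <- function(x, ...) {
  tibble(
    n_features = length(x$features), n_train = x$n_train,
    cv_auc = x$cv_auc,
    mean_holdout_auc = if (nrow(x$holdout_auc) > 0) {
      mean(x$holdout_auc$auc, na.rm = TRUE)
    } else {
      NA_real_
    },
    cost = x$hyperparameters$cost, gamma = x$hyperparameters$gamma,
    seed = x$seed
  )
}
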
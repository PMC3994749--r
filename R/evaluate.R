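# Coerce a (truth, estimate) pair of label tables to aligned 0/1 matrices.
# Accepts 0/1 matrices/data frames with location columns (an `id` column is
# dropped) or multiloc_dataset truth.
align_pairs <- function(truth, estimate, require_truth_positive = TRUE) {
  to_mat <- function(z) {
    if (inherits(z, "multiloc_dataset")) {
      require_labels(z, "evaluation")
      return(z$y)
    }
    df <- as.data.frame(z)
    df$id <- NULL
    m <- as.matrix(df)
    if (!is_binary01(m)) abort("Label tables must contain only 0/1 values.")
    storage.mode(m) <- "integer"
    m
  }
  M <- to_mat(truth)
  Mh <- to_mat(estimate)
  if (nrow(M) == 0) abort("Empty label-set list.")
  if (!identical(dim(M), dim(Mh))) {
    abort("`truth` and `estimate` must have identical dimensions.")
  }
  if (!is.null(colnames(M)) && !is.null(colnames(Mh))) {
    if (!setequal(colnames(M), colnames(Mh))) {
      abort("`truth` and `estimate` must share location columns.")
    }
    Mh <- Mh[, colnames(M), drop = FALSE]
  } else if (is.null(colnames(M))) {
    colnames(M) <- colnames(Mh) %||% paste0("s", seq_len(ncol(M)))
    colnames(Mh) <- colnames(M)
  } else {
    colnames(Mh) <- colnames(M)
  }
  if (require_truth_positive && any(rowSums(M) == 0)) {
    abort("Every evaluated protein must have at least one true location.")
  }
  list(truth = M, estimate = Mh)
}

#' Example-based multi-label accuracy and F1
#'
#' The adapted multi-label measures: per protein the Jaccard overlap
#' \eqn{|M \cap \hat{M}| / |M \cup \hat{M}|} (accuracy) or the Dice overlap
#' \eqn{2|M \cap \hat{M}| / (|M| + |\hat{M}|)} (F1) between the true and
#' predicted location sets, averaged over proteins. A protein with an empty
#' predicted set contributes 0 to both.
#'
#' @param truth,estimate 0/1 location-indicator tables (matrix or data frame,
#'   one row per protein, location columns; `truth` may be a labeled
#'   `multiloc_dataset`). Every true set must be nonempty.
#' @return A single value in `[0, 1]`.
#' @examples
#' truth <- rbind(c(1, 1), c(1, 0))
#' pred <- rbind(c(1, 0), c(1, 0))
#' multilabel_accuracy(truth, pred) # (1/2 + 1) / 2
#' multilabel_f1(truth, pred) # (2/3 + 1) / 2
#' @export
multilabel_accuracy <- function(truth, estimate) {
  p <- align_pairs(truth, estimate)
  inter <- rowSums(p$truth & p$estimate)
  union <- rowSums(p$truth | p$estimate)
  mean(inter / union)
}

#' @rdname multilabel_accuracy
#' @export
multilabel_f1 <- function(truth, estimate) {
  p <- align_pairs(truth, estimate)
  inter <- rowSums(p$truth & p$estimate)
  mean(2 * inter / (rowSums(p$truth) + rowSums(p$estimate)))
}

#' Adapted per-location multi-label precision and recall
#'
#' For location \eqn{s_i}:
#' \eqn{Pre_{s_i}} averages \eqn{|M \cap \hat{M}| / |\hat{M}|} over proteins
#' *predicted* at \eqn{s_i}, and \eqn{Rec_{s_i}} averages
#' \eqn{|M \cap \hat{M}| / |M|} over proteins *truly localized* at
#' \eqn{s_i}. When the conditioning set is empty the value is undefined and
#' reported as `NA`.
#'
#' @inheritParams multilabel_accuracy
#' @param location Location name (or column index).
#' @return A named numeric vector `c(pre = ..., rec = ...)` (possibly `NA`).
#' @export
multilabel_pre_rec <- function(truth, estimate, location) {
  p <- align_pairs(truth, estimate)
  if (is.character(location)) location <- match(location, colnames(p$truth))
  inter <- rowSums(p$truth & p$estimate)
  in_pred <- p$estimate[, location] == 1
  in_true <- p$truth[, location] == 1
  pre <- if (any(in_pred)) {
    mean(inter[in_pred] / rowSums(p$estimate)[in_pred])
  } else {
    NA_real_
  }
  rec <- if (any(in_true)) {
    mean(inter[in_true] / rowSums(p$truth)[in_true])
  } else {
    NA_real_
  }
  c(pre = pre, rec = rec)
}

#' Macro-averaged label F1 over locations
#'
#' \deqn{F_1\text{-}label = \frac{1}{|S'|} \sum_{s_i \in S'}
#' \frac{2 \, Pre_{s_i} Rec_{s_i}}{Pre_{s_i} + Rec_{s_i}},}
#' where \eqn{S'} is the set of locations with at least one true member in
#' the evaluated data. A location whose precision is undefined (never
#' predicted) or whose precision and recall are both zero contributes 0.
#'
#' @inheritParams multilabel_accuracy
#' @return A value in `[0, 1]`.
#' @export
f1_label <- function(truth, estimate) {
  p <- align_pairs(truth, estimate)
  present <- which(colSums(p$truth) > 0)
  terms <- vapply(present, function(i) {
    pr <- multilabel_pre_rec(p$truth, p$estimate, i)
    if (anyNA(pr) || sum(pr) == 0) return(0)
    2 * pr["pre"] * pr["rec"] / (pr["pre"] + pr["rec"])
  }, numeric(1))
  mean(terms)
}

#' Standard per-location binary precision and recall
#'
#' Treats each location as an ordinary binary classification task:
#' `pre_std = TP / (TP + FP)` and `rec_std = TP / (TP + FN)`, where TP/FP/FN
#' count proteins by their membership in the true and predicted sets for the
#' location. Zero denominators yield `NA`.
#'
#' @inheritParams multilabel_pre_rec
#' @return A named numeric vector
#'   `c(pre_std, rec_std, tp, fp, fn)`.
#' @export
standard_pre_rec <- function(truth, estimate, location) {
  p <- align_pairs(truth, estimate)
  if (is.character(location)) location <- match(location, colnames(p$truth))
  t <- p$truth[, location]
  e <- p$estimate[, location]
  tp <- sum(t == 1 & e == 1)
  fp <- sum(t == 0 & e == 1)
  fn <- sum(t == 1 & e == 0)
  c(
    pre_std = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    rec_std = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}

#' All per-location measures in one table
#'
#' @inheritParams multilabel_accuracy
#' @return A tibble with one row per location: adapted multi-label
#'   precision/recall (`pre`, `rec`), standard precision/recall
#'   (`pre_std`, `rec_std`), and the TP/FP/FN counts.
#' @export
location_metrics <- function(truth, estimate) {
  p <- align_pairs(truth, estimate)
  rows <- lapply(seq_len(ncol(p$truth)), function(i) {
    ml <- multilabel_pre_rec(p$truth, p$estimate, i)
    st <- standard_pre_rec(p$truth, p$estimate, i)
    tibble::tibble(
      location = colnames(p$truth)[i],
      pre = ml[["pre"]], rec = ml[["rec"]],
      pre_std = st[["pre_std"]], rec_std = st[["rec_std"]],
      tp = as.integer(st[["tp"]]), fp = as.integer(st[["fp"]]),
      fn = as.integer(st[["fn"]])
    )
  })
  dplyr::bind_rows(rows)
}

# The three example-based summary metrics as a named vector.
summary_metrics <- function(truth, estimate) {
  c(
    acc = multilabel_accuracy(truth, estimate),
    f1 = multilabel_f1(truth, estimate),
    f1_label = f1_label(truth, estimate)
  )
}

#' Repeated stratified cross-validation
#'
#' Runs `runs` complete rounds of stratified `folds`-fold cross-validation.
#' In each round, every fold is held out once: the model is trained on the
#' remaining folds ([train_multiloc()]), the held-out proteins are
#' predicted, and the round's held-out predictions are pooled before
#' computing the metrics. The SVM indicator estimators alone are evaluated
#' on exactly the same splits as a dependency-blind baseline. Each round
#' draws its fold assignment from a seed derived from `(seed, run)`.
#'
#' @param dataset A labeled `multiloc_dataset` (raw numeric features).
#' @param runs Number of complete cross-validation rounds (default 5).
#' @param folds Number of folds per round (default 5).
#' @param config A [multiloc_config()].
#' @param seed Integer master seed.
#' @return An object of class `multiloc_cv` with elements
#'   `metrics` (tibble: run, system, metric, value),
#'   `per_location` (tibble: run, system, per-location measures), and
#'   `summary` (mean and standard deviation per system and metric across
#'   runs). Systems are `"bn"` (the Bayesian network collection) and
#'   `"baseline"` (thresholded SVM estimates used directly as label sets).
#' @export
cross_validate <- function(dataset, runs = 5, folds = 5,
                           config = multiloc_config(), seed = 1L) {
  stopifnot(runs >= 1, folds >= 2)
  require_labels(dataset, "cross-validation")
  metric_rows <- list()
  loc_rows <- list()
  for (r in seq_len(runs)) {
    run_seed <- derive_seed(seed, r)
    fold_idx <- split_stratified(dataset, k = folds, seed = run_seed)
    n <- n_records(dataset)
    pred_bn <- matrix(NA_integer_, n, n_locations(dataset),
      dimnames = list(NULL, dataset$locations)
    )
    pred_base <- pred_bn
    for (f in seq_along(fold_idx)) {
      hold <- fold_idx[[f]]
      train_set <- dataset_slice(dataset, setdiff(seq_len(n), hold))
      test_set <- dataset_slice(dataset, hold)
      model <- train_multiloc(train_set, config)
      pred_bn[hold, ] <- predict_matrix(model, test_set$x)
      pred_base[hold, ] <- estimate_indicators(model$estimators, test_set$x)
    }
    stopifnot(!anyNA(pred_bn))
    for (sys in c("bn", "baseline")) {
      pred <- if (sys == "bn") pred_bn else pred_base
      m <- summary_metrics(dataset$y, pred)
      metric_rows[[length(metric_rows) + 1L]] <- tibble::tibble(
        run = r, system = sys, metric = names(m), value = unname(m)
      )
      loc_rows[[length(loc_rows) + 1L]] <- tibble::add_column(
        location_metrics(dataset$y, pred),
        run = r, system = sys, .before = 1
      )
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  summary <- metrics |>
    dplyr::group_by(.data$system, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
      n_runs = dplyr::n(),
      .groups = "drop"
    )
  out <- list(
    metrics = metrics,
    per_location = dplyr::bind_rows(loc_rows),
    summary = summary,
    runs = runs, folds = folds, seed = as.integer(seed)
  )
  class(out) <- "multiloc_cv"
  out
}

#' @export
print.multiloc_cv <- function(x, ...) {
  cat(sprintf(
    "<multiloc_cv> %d x %d-fold cross-validation (seed %d)\n",
    x$runs, x$folds, x$seed
  ))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tidy cross-validation results
#'
#' @param x A `multiloc_cv`.
#' @param ... Unused.
#' @return `tidy()`: the per-run long metric table. `glance()`: one row per
#'   system with mean Acc, F1, and F1-label.
#' @export
tidy.multiloc_cv <- function(x, ...) x$metrics

#' @rdname tidy.multiloc_cv
#' @export
glance.multiloc_cv <- function(x, ...) {
  x$summary |>
    dplyr::select("system", "metric", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
}
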
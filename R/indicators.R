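#' Indicator-estimator settings
#'
#' Configuration for the q one-vs-rest margin classifiers that produce the
#' preliminary 0/1 location-indicator estimates consumed by the Bayesian
#' network classifiers.
#'
#' @param kernel `"radial"` (RBF, the default) or `"linear"`.
#' @param cost Regularization constant C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses the median
#'   heuristic `1 / (2 m^2)`, where `m` is the median pairwise Euclidean
#'   distance between standardized training rows (computed on a
#'   deterministic subsample of at most 400 rows).
#' @param class_weight `NULL` for unweighted training (default) or
#'   `"inverse"` for inverse-class-frequency weights.
#' @param use_discretized If `TRUE`, the estimators are trained on the
#'   integer feature codes instead of the raw numeric features.
#' @param cross_fit If `TRUE`, training-set estimates are produced
#'   out-of-fold by an internal 5-fold split instead of in-sample.
#' @param seed Integer seed (used only by `cross_fit` splitting).
#' @return A list of class `indicator_config`.
#' @export
indicator_config <- function(kernel = c("radial", "linear"), cost = 1,
                             gamma = NULL, class_weight = NULL,
                             use_discretized = FALSE, cross_fit = FALSE,
                             seed = 1L) {
  kernel <- match.arg(kernel)
  out <- list(
    kernel = kernel, cost = cost, gamma = gamma, class_weight = class_weight,
    use_discretized = use_discretized, cross_fit = cross_fit,
    seed = as.integer(seed)
  )
  class(out) <- "indicator_config"
  out
}

#' Fit the per-location indicator estimators
#'
#' Trains one binary SVM per location to separate proteins with
#' \eqn{l_i = 1} from the rest, on the raw numeric features standardized to
#' zero mean / unit variance (per training set). A location whose training
#' column is single-class degenerates to a constant estimator, with a
#' warning. The fitted support vectors, dual coefficients, and scaling are
#' stored explicitly, so predictions are reproducible from the serialized
#' model alone.
#'
#' @param dataset A labeled `multiloc_dataset` with numeric (or, if
#'   configured, discretized) features.
#' @param config An [indicator_config()].
#' @return An object of class `indicator_set` (one estimator per location,
#'   in vocabulary order).
#' @export
fit_indicator_estimators <- function(dataset, config = indicator_config()) {
  stopifnot(inherits(dataset, "multiloc_dataset"))
  require_labels(dataset, "indicator estimation")
  if (config$use_discretized && !dataset$discrete) {
    abort("`use_discretized = TRUE` requires a discretized dataset.")
  }
  if (!config$use_discretized && dataset$discrete) {
    abort("Estimators are configured for raw features but the dataset is discretized.")
  }
  x <- dataset$x
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  gamma <- config$gamma %||% median_heuristic_gamma(xs)

  estimators <- lapply(seq_len(ncol(dataset$y)), function(i) {
    yi <- dataset$y[, i]
    loc <- colnames(dataset$y)[i]
    if (length(unique(yi)) < 2) {
      warn(sprintf(
        "Location '%s' has a single class in training; using a constant estimator.",
        loc
      ))
      return(list(type = "constant", value = as.integer(yi[1])))
    }
    yfac <- factor(yi, levels = c(0, 1))
    cw <- NULL
    if (identical(config$class_weight, "inverse")) {
      tab <- table(yfac)
      cw <- setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
    }
    fit <- e1071::svm(
      x = xs, y = yfac, type = "C-classification",
      kernel = config$kernel, cost = config$cost, gamma = gamma,
      scale = FALSE, class.weights = cw
    )
    # Store the decision function explicitly: f(x) = sum_j coef_j K(sv_j, x) - rho,
    # predicted class = levels[labels[1]] iff f(x) > 0 (libsvm convention).
    positive <- fit$levels[fit$labels[1]]
    list(
      type = "svm",
      kernel = config$kernel,
      gamma = gamma,
      sv = unname(as.matrix(fit$SV)),
      coefs = as.numeric(fit$coefs),
      rho = as.numeric(fit$rho),
      positive_is_one = identical(positive, "1")
    )
  })
  out <- list(
    locations = colnames(dataset$y),
    feature_names = dataset$feature_names,
    center = center,
    scale = scl,
    estimators = setNames(estimators, colnames(dataset$y)),
    config = config
  )
  class(out) <- "indicator_set"
  out
}

#' @export
print.indicator_set <- function(x, ...) {
  kinds <- vapply(x$estimators, function(e) e$type, character(1))
  cat(sprintf(
    "<indicator_set> %d locations (%d SVM, %d constant), kernel = %s\n",
    length(x$estimators), sum(kinds == "svm"), sum(kinds == "constant"),
    x$config$kernel
  ))
  invisible(x)
}

# Median-heuristic RBF width on standardized rows (deterministic subsample).
median_heuristic_gamma <- function(xs) {
  n <- nrow(xs)
  idx <- if (n > 400) unique(round(seq(1, n, length.out = 400))) else seq_len(n)
  m <- stats::median(stats::dist(xs[idx, , drop = FALSE]))
  if (!is.finite(m) || m == 0) {
    return(1 / ncol(xs))
  }
  1 / (2 * m^2)
}

# Raw decision values of one stored estimator on standardized rows.
svm_decision <- function(est, xs) {
  K <- if (est$kernel == "radial") {
    d2 <- outer(rowSums(xs^2), rowSums(est$sv^2), `+`) - 2 * xs %*% t(est$sv)
    exp(-est$gamma * pmax(d2, 0))
  } else {
    xs %*% t(est$sv)
  }
  as.numeric(K %*% est$coefs) - est$rho
}

#' Estimate location indicators for query proteins
#'
#' Applies the fitted one-vs-rest estimators and thresholds each decision
#' value at its sign, yielding hard 0/1 indicator estimates
#' \eqn{\hat{l}_1, \dots, \hat{l}_q} per protein.
#'
#' @param estimators An `indicator_set` from [fit_indicator_estimators()].
#' @param features A numeric matrix/data frame of feature rows (columns in
#'   training order), or a `multiloc_dataset`.
#' @return An n x q integer 0/1 matrix with location column names (n = 0
#'   rows for empty input).
#' @export
estimate_indicators <- function(estimators, features) {
  stopifnot(inherits(estimators, "indicator_set"))
  if (inherits(features, "multiloc_dataset")) features <- features$x
  features <- as.matrix(as.data.frame(features))
  if (ncol(features) != length(estimators$feature_names)) {
    abort(sprintf(
      "Feature dimension mismatch: got %d columns, estimators were trained on %d.",
      ncol(features), length(estimators$feature_names)
    ))
  }
  n <- nrow(features)
  q <- length(estimators$estimators)
  out <- matrix(0L, n, q, dimnames = list(NULL, estimators$locations))
  if (n == 0) return(out)
  xs <- scale(features, center = estimators$center, scale = estimators$scale)
  for (i in seq_len(q)) {
    est <- estimators$estimators[[i]]
    out[, i] <- if (est$type == "constant") {
      rep(est$value, n)
    } else {
      dec <- svm_decision(est, xs)
      pos <- dec > 0
      if (est$positive_is_one) as.integer(pos) else as.integer(!pos)
    }
  }
  out
}

# Training-set indicator estimates: in-sample by default, or internally
# cross-fitted (5-fold, seeded) when the config requests it.
indicator_training_estimates <- function(dataset, config, estimators = NULL) {
  if (!config$cross_fit) {
    estimators <- estimators %||% fit_indicator_estimators(dataset, config)
    return(estimate_indicators(estimators, dataset))
  }
  folds <- split_stratified(dataset, k = 5L, seed = config$seed)
  out <- matrix(0L, n_records(dataset), n_locations(dataset),
    dimnames = list(NULL, dataset$locations)
  )
  for (f in folds) {
    train_part <- dataset_slice(dataset, setdiff(seq_len(n_records(dataset)), f))
    fit <- fit_indicator_estimators(train_part, config)
    out[f, ] <- estimate_indicators(fit, dataset_slice(dataset, f))
  }
  out
}
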
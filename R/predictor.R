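MODEL_FORMAT <- "multilocbn-model-1"

#' Full training configuration
#'
#' Bundles the settings of every pipeline stage.
#'
#' @param estimator An [indicator_config()].
#' @param search A [search_config()].
#' @param seed Integer seed recorded with the model (the pipeline is
#'   deterministic given the data and this configuration).
#' @param fit_on_estimates If `TRUE` (the default), the CPT counts for
#'   non-target location nodes use the SVM indicator estimates -- the same
#'   variables the conditional log likelihood conditions on -- so parameter
#'   fitting and scoring see the same distribution. With `FALSE`, location
#'   CPTs are counted from the true training labels (the target's own
#'   indicator always uses the true labels in either mode).
#' @param verbose Emit per-stage progress messages?
#' @return A list of class `multiloc_config`.
#' @export
multiloc_config <- function(estimator = indicator_config(),
                            search = search_config(),
                            seed = 1L, fit_on_estimates = TRUE,
                            verbose = FALSE) {
  out <- list(
    estimator = estimator, search = search, seed = as.integer(seed),
    fit_on_estimates = fit_on_estimates, verbose = verbose
  )
  class(out) <- "multiloc_config"
  out
}

#' Train the multi-location prediction model
#'
#' Runs the full learning pipeline on a labeled dataset:
#' \enumerate{
#'   \item fit the minimal-entropy discretizer on the training features
#'     ([mdlp_fit()]) and encode the features;
#'   \item fit the q one-vs-rest SVM indicator estimators
#'     ([fit_indicator_estimators()]) and obtain training-set indicator
#'     estimates;
#'   \item for each location, learn a Bayesian network classifier by CLL
#'     hill climbing ([hill_climb()]).
#' }
#'
#' @param dataset A labeled `multiloc_dataset` with numeric features (every
#'   protein must have at least one positive location).
#' @param config A [multiloc_config()].
#' @return An object of class `multiloc_model` bundling the vocabulary,
#'   cutpoints, indicator estimators, the q classifiers with their search
#'   traces, and the configuration.
#' @export
train_multiloc <- function(dataset, config = multiloc_config()) {
  stopifnot(inherits(dataset, "multiloc_dataset"))
  require_labels(dataset, "training")
  say <- function(...) if (isTRUE(config$verbose)) inform(sprintf(...))
  t0 <- Sys.time()

  cuts <- mdlp_fit(dataset)
  ddata <- mdlp_apply(cuts, dataset)
  say("discretizer: %d boundaries [%.2fs]", sum(lengths(cuts$cutpoints)),
    as.numeric(Sys.time() - t0, units = "secs"))

  est_input <- if (config$estimator$use_discretized) ddata else dataset
  estimators <- fit_indicator_estimators(est_input, config$estimator)
  est_train <- indicator_training_estimates(est_input, config$estimator, estimators)
  say("indicator estimators fitted [%.2fs]", as.numeric(Sys.time() - t0, units = "secs"))

  arities <- cutpoint_arities(cuts)
  fits <- lapply(seq_along(dataset$locations), function(i) {
    di <- ddata
    if (isTRUE(config$fit_on_estimates)) {
      y2 <- est_train
      y2[, i] <- ddata$y[, i]
      di$y <- y2
    }
    hc <- hill_climb(di, est_train, i, config$search, feature_arities = arities)
    say(
      "classifier %s: %d iterations, CLL %.3f [%.2fs]",
      dataset$locations[i], hc$iterations, hc$cll,
      as.numeric(Sys.time() - t0, units = "secs")
    )
    hc
  })

  out <- list(
    locations = dataset$locations,
    feature_names = dataset$feature_names,
    cutpoints = cuts,
    estimators = estimators,
    classifiers = lapply(fits, `[[`, "classifier"),
    traces = lapply(fits, `[[`, "trace"),
    cll = vapply(fits, `[[`, numeric(1), "cll"),
    config = config,
    version = MODEL_FORMAT
  )
  names(out$classifiers) <- dataset$locations
  names(out$traces) <- dataset$locations
  class(out) <- "multiloc_model"
  out
}

#' @export
print.multiloc_model <- function(x, ...) {
  ne <- vapply(x$classifiers, function(cl) sum(lengths(cl$structure$parents)), numeric(1))
  cat(sprintf(
    "<multiloc_model> %d locations [%s], %d features\n  edges per classifier: %s\n",
    length(x$locations), paste(x$locations, collapse = ", "),
    length(x$feature_names), paste(ne, collapse = ", ")
  ))
  invisible(x)
}

# Coerce prediction input to a list(ids, x) with raw numeric features.
prediction_input <- function(model, new_data) {
  if (inherits(new_data, "multiloc_dataset")) {
    if (new_data$discrete) abort("Provide raw (undiscretized) features for prediction.")
    ids <- new_data$ids
    x <- new_data$x
  } else {
    df <- as.data.frame(new_data)
    ids <- if ("id" %in% names(df)) as.character(df$id) else sprintf("q%d", seq_len(nrow(df)))
    df$id <- NULL
    x <- as.matrix(df)
  }
  if (!all(model$feature_names %in% colnames(x))) {
    if (ncol(x) == length(model$feature_names)) {
      colnames(x) <- model$feature_names
    } else {
      abort(sprintf(
        "Feature dimension mismatch: model expects %d features (%s...).",
        length(model$feature_names), paste(head(model$feature_names, 3), collapse = ", ")
      ))
    }
  }
  list(ids = ids, x = x[, model$feature_names, drop = FALSE])
}

#' Predict (multiple) locations for query proteins
#'
#' Implements the estimate-then-classify flow: the SVM estimators produce
#' preliminary indicator estimates \eqn{\hat{l}}, then each Bayesian network
#' classifier computes \eqn{\Pr(L_i = 1 \mid f, \hat{l}_{j \ne i})} and
#' outputs 1 iff that probability exceeds 0.5 (a probability of exactly 0.5
#' yields 0). The all-zero prediction vector is a legal output.
#'
#' @param object A `multiloc_model`.
#' @param new_data A `multiloc_dataset` (raw features) or a data frame /
#'   matrix of raw feature rows (an `id` column is carried through).
#' @param type `"class"` for 0/1 indicator columns (default), `"prob"` for
#'   the pre-threshold probabilities, `"both"` for indicators plus
#'   `.prob_<location>` columns.
#' @param ... Unused.
#' @return A tibble with an `id` column and one column per location.
#' @export
predict.multiloc_model <- function(object, new_data,
                                   type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  inp <- prediction_input(object, new_data)
  probs <- predict_proba_matrix(object, inp$x)
  cls <- matrix(as.integer(probs > 0.5), nrow(probs),
    dimnames = dimnames(probs)
  )
  out <- tibble::tibble(id = inp$ids)
  if (type %in% c("class", "both")) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(cls)))
  }
  if (type %in% c("prob", "both")) {
    pr <- tibble::as_tibble(as.data.frame(probs))
    if (type == "both") names(pr) <- paste0(".prob_", names(pr))
    out <- dplyr::bind_cols(out, pr)
  }
  out
}

# n x q probability matrix (internal core shared by predict and evaluation).
predict_proba_matrix <- function(model, x) {
  lhat <- estimate_indicators(model$estimators, x)
  qdata <- new_multiloc_dataset(seq_len(nrow(x)), x, NULL)
  coded <- mdlp_apply(model$cutpoints, qdata)$x
  probs <- vapply(
    seq_along(model$locations),
    function(i) conditional_prob_target(model$classifiers[[i]], coded, lhat),
    numeric(nrow(x))
  )
  probs <- matrix(probs, nrow = nrow(x), dimnames = list(NULL, model$locations))
  probs
}

# 0/1 prediction matrix, used by the evaluation harness.
predict_matrix <- function(model, x) {
  p <- predict_proba_matrix(model, x)
  matrix(as.integer(p > 0.5), nrow(p), dimnames = dimnames(p))
}

#' Save / load a trained model as plain structured text
#'
#' The model -- cutpoints, SVM support vectors and coefficients, network
#' structures and conditional probability tables -- is written as a JSON
#' document with all floating-point numbers encoded in full 17-digit
#' precision, so `load_model(save_model(m))` reproduces predictions exactly.
#' The file carries a format-version tag that is checked on load.
#'
#' @param model A `multiloc_model`.
#' @param path File path.
#' @return `save_model()` returns `model` invisibly; `load_model()` returns
#'   the reconstructed `multiloc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "multiloc_model"))
  enc_est <- function(e) {
    if (e$type == "constant") {
      list(type = "constant", value = e$value)
    } else {
      list(
        type = "svm", kernel = e$kernel, gamma = num_to_chr(e$gamma),
        sv = num_to_chr(as.numeric(e$sv)), sv_rows = nrow(e$sv),
        coefs = num_to_chr(e$coefs), rho = num_to_chr(e$rho),
        positive_is_one = e$positive_is_one
      )
    }
  }
  enc_cls <- function(cl) {
    s <- cl$structure
    edges <- tidy.bn_structure(s)
    list(
      target = s$nodes[cl$target],
      edges_from = edges$from, edges_to = edges$to,
      arity = as.integer(cl$cpts$arity),
      alpha = num_to_chr(cl$cpts$alpha),
      tables = lapply(cl$cpts$tables, function(t) num_to_chr(as.numeric(t)))
    )
  }
  obj <- list(
    version = model$version,
    locations = model$locations,
    feature_names = model$feature_names,
    cutpoints = lapply(model$cutpoints$cutpoints, num_to_chr),
    range_lo = num_to_chr(model$cutpoints$range["lo", ]),
    range_hi = num_to_chr(model$cutpoints$range["hi", ]),
    est_center = num_to_chr(model$estimators$center),
    est_scale = num_to_chr(model$estimators$scale),
    est_config = list(
      kernel = model$estimators$config$kernel,
      cost = num_to_chr(model$estimators$config$cost),
      use_discretized = model$estimators$config$use_discretized
    ),
    estimators = lapply(model$estimators$estimators, enc_est),
    classifiers = lapply(model$classifiers, enc_cls),
    seed = model$config$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("Cannot parse model file: ", conditionMessage(e)))
  )
  if (is.null(obj$version)) abort("Corrupt model file: no version tag.")
  if (!identical(obj$version, MODEL_FORMAT)) {
    abort(sprintf(
      "Unsupported model format '%s' (this build reads '%s').",
      obj$version, MODEL_FORMAT
    ))
  }
  d <- length(obj$feature_names)
  cp <- lapply(obj$cutpoints, function(v) if (length(v)) chr_to_num(v) else numeric(0))
  names(cp) <- obj$feature_names
  cuts <- list(
    cutpoints = cp,
    range = rbind(
      lo = setNames(chr_to_num(obj$range_lo), obj$feature_names),
      hi = setNames(chr_to_num(obj$range_hi), obj$feature_names)
    ),
    feature_names = obj$feature_names
  )
  class(cuts) <- "mdlp_cutpoints"

  dec_est <- function(e) {
    if (identical(e$type, "constant")) {
      list(type = "constant", value = as.integer(e$value))
    } else {
      sv <- matrix(chr_to_num(e$sv), nrow = e$sv_rows)
      list(
        type = "svm", kernel = e$kernel, gamma = chr_to_num(e$gamma),
        sv = sv, coefs = chr_to_num(e$coefs), rho = chr_to_num(e$rho),
        positive_is_one = isTRUE(e$positive_is_one)
      )
    }
  }
  est_cfg <- indicator_config(
    kernel = obj$est_config$kernel,
    cost = chr_to_num(obj$est_config$cost),
    use_discretized = isTRUE(obj$est_config$use_discretized)
  )
  estimators <- list(
    locations = obj$locations,
    feature_names = obj$feature_names,
    center = setNames(chr_to_num(obj$est_center), obj$feature_names),
    scale = setNames(chr_to_num(obj$est_scale), obj$feature_names),
    estimators = setNames(lapply(obj$estimators, dec_est), obj$locations),
    config = est_cfg
  )
  class(estimators) <- "indicator_set"

  dec_cls <- function(cl) {
    edges <- if (length(cl$edges_from)) {
      data.frame(from = cl$edges_from, to = cl$edges_to)
    } else {
      NULL
    }
    s <- bn_structure(obj$feature_names, obj$locations,
      feature_arities = cl$arity[seq_len(d)], edges = edges
    )
    tables <- lapply(seq_along(s$nodes), function(v) {
      sizes <- cl$arity[c(v, s$parents[[v]])]
      array(chr_to_num(cl$tables[[v]]), dim = sizes)
    })
    names(tables) <- s$nodes
    cpts <- list(
      nodes = s$nodes, parents = s$parents,
      arity = setNames(as.integer(cl$arity), s$nodes),
      tables = tables, alpha = chr_to_num(cl$alpha)
    )
    class(cpts) <- "bn_cpts"
    bn_classifier(cl$target, s, cpts)
  }
  classifiers <- lapply(obj$classifiers, dec_cls)
  names(classifiers) <- obj$locations

  out <- list(
    locations = obj$locations,
    feature_names = obj$feature_names,
    cutpoints = cuts,
    estimators = estimators,
    classifiers = classifiers,
    traces = NULL,
    cll = NULL,
    config = multiloc_config(estimator = est_cfg, seed = obj$seed %||% 1L),
    version = obj$version
  )
  class(out) <- "multiloc_model"
  out
}

#' Serialize a model to a JSON string (canonical form)
#'
#' Used for byte-identity checks between training runs; equivalent to
#' reading back the file written by [save_model()].
#' @param model A `multiloc_model`.
#' @return A single JSON string.
#' @export
serialize_model <- function(model) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_model(model, path)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
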
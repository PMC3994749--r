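#' Bayesian network structure over feature and location variables
#'
#' Creates the DAG scaffold used by every per-location classifier: nodes are
#' the `d` discretized feature variables plus the `q` binary location
#' indicator variables. Directed edges may connect features to locations and
#' locations to locations (in either direction), but never two feature
#' variables -- features are assumed independent or conditionally independent
#' given the locations.
#'
#' @param feature_names Character vector of feature node names.
#' @param locations Character vector of location node names.
#' @param feature_arities Optional integer vector (one per feature) giving the
#'   number of discrete codes each feature takes; when `NULL`, arities are
#'   inferred from the data at parameter-fitting time. Locations are always
#'   binary.
#' @param edges Optional data frame (columns `from`, `to`) of initial edges.
#' @return An object of class `bn_structure` with fields `nodes`,
#'   `is_feature`, `arity`, and `parents` (list of integer parent index
#'   vectors).
#' @export
bn_structure <- function(feature_names, locations, feature_arities = NULL,
                         edges = NULL) {
  nodes <- c(feature_names, locations)
  if (anyDuplicated(nodes)) abort("Node names must be unique across features and locations.")
  d <- length(feature_names)
  q <- length(locations)
  arity <- c(
    if (is.null(feature_arities)) rep(NA_integer_, d) else as.integer(feature_arities),
    rep(2L, q)
  )
  s <- structure(
    list(
      nodes = nodes,
      is_feature = c(rep(TRUE, d), rep(FALSE, q)),
      arity = setNames(arity, nodes),
      parents = setNames(rep(list(integer(0)), d + q), nodes)
    ),
    class = "bn_structure"
  )
  if (!is.null(edges)) {
    for (i in seq_len(nrow(edges))) {
      s <- add_edge(s, as.character(edges$from[i]), as.character(edges$to[i]))
    }
  }
  s
}

node_index <- function(s, node) {
  i <- if (is.character(node)) match(node, s$nodes) else as.integer(node)
  if (anyNA(i) || any(i < 1) || any(i > length(s$nodes))) {
    abort(paste0("Unknown node: ", paste(node[is.na(i) | i < 1], collapse = ", ")))
  }
  i
}

# children indices of node i
node_children <- function(s, i) {
  which(vapply(s$parents, function(p) i %in% p, logical(1)))
}

# Kahn's algorithm on the parent lists.
is_acyclic <- function(parents) {
  indeg <- lengths(parents)
  ch <- vector("list", length(parents))
  for (v in seq_along(parents)) {
    for (p in parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  }
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in ch[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(parents)
}

# Topological order of node indices (assumes acyclic).
topo_order <- function(parents) {
  indeg <- lengths(parents)
  ch <- vector("list", length(parents))
  for (v in seq_along(parents)) {
    for (p in parents[[v]]) ch[[p]] <- c(ch[[p]], v)
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, v)
    for (w in ch[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  out
}

check_edge_legal <- function(s, from, to) {
  if (from == to) abort("Self-loops are not allowed.")
  if (s$is_feature[from] && s$is_feature[to]) {
    abort("Edges between two feature variables are not allowed.")
  }
}

add_edge <- function(s, from, to) {
  from <- node_index(s, from)
  to <- node_index(s, to)
  check_edge_legal(s, from, to)
  if (from %in% s$parents[[to]]) abort("Edge already present.")
  s$parents[[to]] <- sort(c(s$parents[[to]], from))
  if (!is_acyclic(s$parents)) abort("Edge would create a cycle.")
  s
}

remove_edge <- function(s, from, to) {
  from <- node_index(s, from)
  to <- node_index(s, to)
  s$parents[[to]] <- setdiff(s$parents[[to]], from)
  s
}

#' @export
print.bn_structure <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf(
    "<bn_structure> %d feature + %d location nodes, %d edges\n",
    sum(x$is_feature), sum(!x$is_feature), ne
  ))
  invisible(x)
}

#' List the edges of a network structure
#'
#' @param x A `bn_structure` or `bn_classifier`.
#' @param ... Unused.
#' @return A tibble with columns `from` and `to` (node names).
#' @export
tidy.bn_structure <- function(x, ...) {
  rows <- purrr::imap(x$parents, function(p, child) {
    if (length(p)) tibble::tibble(from = x$nodes[p], to = child) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble::tibble(from = character(0), to = character(0))
  dplyr::arrange(out, .data$from, .data$to)
}

# ---- parameters -------------------------------------------------------------

# 0-based mixed-radix linear index over columns of `vals` with radices `ar`.
lin_index <- function(vals, ar) {
  idx <- vals[, 1]
  mult <- ar[1]
  for (j in seq_along(ar)[-1]) {
    idx <- idx + mult * vals[, j]
    mult <- mult * ar[j]
  }
  idx
}

#' Fit conditional probability tables by smoothed maximum likelihood
#'
#' For every node \eqn{v} with parent configuration \eqn{y}, estimates
#' \deqn{\theta_v(x \mid y) = \frac{n_{joint} + \alpha}{n_{marginal} +
#' \alpha \cdot arity(v)},}
#' where `n_joint` counts training records with \eqn{v = x} and parents
#' \eqn{= y} and `n_marginal` counts records with parents \eqn{= y}. The
#' pseudo-count \eqn{\alpha} is added uniformly to every cell; with
#' \eqn{\alpha = 0} this is the plain maximum-likelihood frequency ratio, and
#' rows for unseen parent configurations fall back to uniform with a warning.
#' Location-node counts always use the true location indicators of the
#' training data.
#'
#' @param structure A `bn_structure`.
#' @param dataset A labeled, discretized `multiloc_dataset`.
#' @param alpha Nonnegative pseudo-count (default 1).
#' @return An object of class `bn_cpts`: per-node probability arrays
#'   (first dimension = node value, remaining dimensions = parents in the
#'   structure's parent order), resolved arities, and `alpha`.
#' @export
fit_parameters <- function(structure, dataset, alpha = 1) {
  stopifnot(inherits(structure, "bn_structure"), alpha >= 0)
  W <- dataset_matrix(structure, dataset, require_y = TRUE)
  ar <- resolve_arities(structure, W)
  tables <- fit_tables(structure$parents, W, ar, alpha)
  out <- list(
    nodes = structure$nodes,
    parents = structure$parents,
    arity = ar,
    tables = tables,
    alpha = alpha
  )
  class(out) <- "bn_cpts"
  out
}

# Build the n x (d+q) 0-based integer matrix in node order (features, then
# true location labels).
dataset_matrix <- function(structure, dataset, require_y = TRUE) {
  stopifnot(inherits(dataset, "multiloc_dataset"))
  if (!dataset$discrete) abort("Dataset features must be integer-coded (see mdlp_apply()).")
  if (require_y) require_labels(dataset, "parameter fitting")
  fn <- structure$nodes[structure$is_feature]
  ln <- structure$nodes[!structure$is_feature]
  if (!all(fn %in% colnames(dataset$x)) ||
    (!is.null(dataset$y) && !all(ln %in% colnames(dataset$y)))) {
    abort("Dataset columns do not match the network's nodes.")
  }
  W <- cbind(dataset$x[, fn, drop = FALSE], dataset$y[, ln, drop = FALSE])
  storage.mode(W) <- "integer"
  W
}

resolve_arities <- function(structure, W) {
  ar <- structure$arity
  na <- which(is.na(ar))
  if (length(na)) ar[na] <- apply(W[, na, drop = FALSE], 2, max) + 1L
  pmax(ar, 1L)
}

# Fit tables for the given parent lists (a named subset fits only those
# families); returns a list of probability arrays.
fit_tables <- function(parents, W, ar, alpha, which_nodes = seq_along(parents)) {
  out <- vector("list", length(parents))
  names(out) <- names(parents)
  for (v in which_nodes) {
    fam <- c(v, parents[[v]])
    sizes <- ar[fam]
    ncell <- prod(sizes)
    counts <- tabulate(lin_index(W[, fam, drop = FALSE], sizes) + 1L, nbins = ncell)
    av <- sizes[1]
    m <- matrix(counts, nrow = av)
    marg <- colSums(m)
    if (alpha == 0 && any(marg == 0)) {
      warn("Unseen parent configuration with alpha = 0; row set to uniform.")
      m[, marg == 0] <- 1 / av
      marg[marg == 0] <- 1
    }
    theta <- (m + alpha) / rep(marg + alpha * av, each = av)
    out[[v]] <- array(theta, dim = sizes)
  }
  out
}

#' Bundle a structure, parameters, and a target location into a classifier
#'
#' @param target The location this classifier predicts (name or node index).
#' @param structure A `bn_structure`.
#' @param cpts A `bn_cpts` fitted on that structure.
#' @return An object of class `bn_classifier`.
#' @export
bn_classifier <- function(target, structure, cpts) {
  stopifnot(inherits(structure, "bn_structure"), inherits(cpts, "bn_cpts"))
  ti <- node_index(structure, target)
  if (structure$is_feature[ti]) abort("`target` must be a location node.")
  if (!identical(structure$parents, cpts$parents)) {
    abort("`cpts` was not fitted on `structure`.")
  }
  out <- list(target = ti, structure = structure, cpts = cpts)
  class(out) <- "bn_classifier"
  out
}

#' @export
print.bn_classifier <- function(x, ...) {
  cat(sprintf(
    "<bn_classifier> target = %s, %d edges, alpha = %g\n",
    x$structure$nodes[x$target], sum(lengths(x$structure$parents)),
    x$cpts$alpha
  ))
  invisible(x)
}

#' @export
tidy.bn_classifier <- function(x, ...) {
  out <- tidy.bn_structure(x$structure)
  tibble::add_column(out, target = x$structure$nodes[x$target], .before = 1)
}

#' Joint log-probability of a complete assignment
#'
#' Evaluates the network factorization
#' \eqn{\Pr(F_1,\dots,F_d,L_1,\dots,L_q) = \prod_v \Pr(v \mid Pa(v))}
#' in log space for one full value assignment.
#'
#' @param classifier A `bn_classifier` (or a `bn_cpts`).
#' @param assignment Named numeric vector/list giving a 0-based code for every
#'   node.
#' @return The joint log-probability (natural log).
#' @export
joint_log_prob <- function(classifier, assignment) {
  cpts <- if (inherits(classifier, "bn_classifier")) classifier$cpts else classifier
  stopifnot(inherits(cpts, "bn_cpts"))
  vals <- unlist(assignment)
  if (!all(cpts$nodes %in% names(vals))) {
    abort(paste0(
      "Assignment is missing node(s): ",
      paste(setdiff(cpts$nodes, names(vals)), collapse = ", ")
    ))
  }
  vals <- as.integer(vals[cpts$nodes])
  total <- 0
  for (v in seq_along(cpts$nodes)) {
    fam <- c(v, cpts$parents[[v]])
    idx <- lin_index(matrix(vals[fam], nrow = 1), cpts$arity[fam]) + 1L
    total <- total + log(cpts$tables[[v]][idx])
  }
  total
}

# Vectorized log theta_v over rows of V (n x (d+q), 0-based). When `target`
# is given, every occurrence of that node inside the family is replaced by
# the scalar code `z`.
factor_logprob <- function(cpts, v, V, target = NULL, z = NULL) {
  fam <- c(v, cpts$parents[[v]])
  vals <- V[, fam, drop = FALSE]
  if (!is.null(target)) {
    hit <- fam == target
    if (any(hit)) vals[, hit] <- z
  }
  idx <- lin_index(vals, cpts$arity[fam]) + 1L
  log(as.numeric(cpts$tables[[v]])[idx])
}

# The factors of the joint that contain the target node: its own CPT and the
# CPTs of its children (the target's Markov-blanket factors).
blanket_factors <- function(parents, target) {
  ch <- which(vapply(parents, function(p) target %in% p, logical(1)))
  c(target, ch)
}

# Per-record log "joint restricted to blanket factors" for L_target = z,
# over rows of V. Sufficient for the target conditional because all other
# factors cancel in the ratio.
blanket_logjoint <- function(cpts, target, V, z) {
  facs <- blanket_factors(cpts$parents, target)
  total <- numeric(nrow(V))
  for (v in facs) {
    total <- total + factor_logprob(cpts, v, V, target = target, z = z)
  }
  total
}

# Assemble the query matrix: coded features + indicator estimates in node
# order. `estimates` must cover all location columns (the target column is
# present but never read as itself -- it is substituted by z).
query_matrix <- function(classifier, features, estimates) {
  s <- classifier$structure
  fn <- s$nodes[s$is_feature]
  ln <- s$nodes[!s$is_feature]
  features <- as.matrix(as.data.frame(features))
  if (is.null(colnames(features))) colnames(features) <- fn
  if (!all(fn %in% colnames(features))) {
    abort("`features` must provide a column per feature node.")
  }
  estimates <- as.matrix(as.data.frame(estimates))
  if (is.null(colnames(estimates))) colnames(estimates) <- ln
  missing_locs <- setdiff(ln, colnames(estimates))
  tname <- s$nodes[classifier$target]
  if (identical(missing_locs, tname)) {
    estimates <- cbind(
      estimates,
      matrix(0L, nrow(estimates), 1, dimnames = list(NULL, tname))
    )
  } else if (length(missing_locs)) {
    abort(paste0(
      "`estimates` is missing location column(s): ",
      paste(missing_locs, collapse = ", ")
    ))
  }
  if (nrow(features) != nrow(estimates)) {
    abort("`features` and `estimates` must have the same number of rows.")
  }
  V <- cbind(features[, fn, drop = FALSE], estimates[, ln, drop = FALSE])
  storage.mode(V) <- "integer"
  V
}

#' Conditional probability of the target location
#'
#' Computes \eqn{\Pr(L_i = 1 \mid f^P, \hat{l}^P_{j \ne i})} as the ratio of
#' the two joint probabilities with \eqn{L_i} clamped to 1 and to 0 and all
#' other variables fixed at the observed features and estimated indicators.
#' Only the factors containing \eqn{L_i} (its own CPT and its children's
#' CPTs) are evaluated; all other factors cancel in the ratio, so the result
#' equals the full-joint computation exactly.
#'
#' @param classifier A `bn_classifier`.
#' @param features One or more rows of integer-coded features (vector,
#'   matrix, or data frame with feature-named columns).
#' @param estimates Matching rows of 0/1 indicator estimates for the other
#'   locations (the target's own column, if present, is ignored).
#' @return Numeric vector of probabilities in `[0, 1]`, one per row. When
#'   both clamped joints are zero (possible only with `alpha = 0`) the value
#'   is 0.5, with a warning.
#' @export
conditional_prob_target <- function(classifier, features, estimates) {
  stopifnot(inherits(classifier, "bn_classifier"))
  if (is.null(dim(features)) && !is.data.frame(features)) {
    features <- matrix(features, nrow = 1,
      dimnames = list(NULL, classifier$structure$nodes[classifier$structure$is_feature])
    )
  }
  if (is.null(dim(estimates)) && !is.data.frame(estimates)) {
    ln <- classifier$structure$nodes[!classifier$structure$is_feature]
    nm <- if (!is.null(names(estimates))) names(estimates) else {
      setdiff(ln, classifier$structure$nodes[classifier$target])[seq_along(estimates)]
    }
    estimates <- matrix(estimates, nrow = 1, dimnames = list(NULL, nm))
  }
  V <- query_matrix(classifier, features, estimates)
  s1 <- blanket_logjoint(classifier$cpts, classifier$target, V, 1L)
  s0 <- blanket_logjoint(classifier$cpts, classifier$target, V, 0L)
  p <- 1 / (1 + exp(s0 - s1))
  dead <- !is.finite(s0) & !is.finite(s1)
  if (any(dead)) {
    warn("Both clamped joints are zero; returning 0.5 for the affected rows.")
    p[dead] <- 0.5
  }
  p
}

#' Conditional log likelihood of a classifier on a dataset
#'
#' The structure-search objective: the sum over training proteins of the log
#' conditional probability of the protein's *true* target indicator given its
#' features and the estimated indicators of all other locations,
#' \deqn{CLL(C_i \mid D) = \sum_j \log \Pr(L_i = l_i^{P_j} \mid f^{P_j},
#' \hat{l}^{P_j}_{k \ne i}).}
#'
#' @param classifier A `bn_classifier` with fitted parameters.
#' @param dataset A labeled, discretized `multiloc_dataset`.
#' @param estimates An n x q 0/1 matrix of indicator estimates (one column
#'   per location; the target column is ignored).
#' @return A single number `<= 0`.
#' @export
cll_score <- function(classifier, dataset, estimates) {
  stopifnot(inherits(classifier, "bn_classifier"))
  require_labels(dataset, "CLL scoring")
  s <- classifier$structure
  V <- query_matrix(classifier, dataset$x, estimates)
  y <- dataset$y[, s$nodes[classifier$target]]
  cll_from_logjoints(
    blanket_logjoint(classifier$cpts, classifier$target, V, 0L),
    blanket_logjoint(classifier$cpts, classifier$target, V, 1L),
    y
  )
}

# Shared CLL assembly: per-record log Pr(L_i = y | rest) from the two clamped
# blanket log-joints, with a floor against -Inf terms (alpha = 0 pathology).
cll_from_logjoints <- function(s0, s1, y) {
  hi <- pmax(s0, s1)
  lse <- hi + log(exp(s0 - hi) + exp(s1 - hi))
  terms <- ifelse(y == 1, s1, s0) - lse
  bad <- !is.finite(terms)
  if (any(bad)) {
    warn("Zero-probability CLL term floored at log(1e-300).")
    terms[bad] <- log(1e-300)
  }
  sum(terms)
}
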
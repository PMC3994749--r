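#' Minimal-entropy (MDL-stopped) feature discretization
#'
#' Tools implementing recursive minimal-entropy partitioning of continuous
#' features with a Minimum Description Length stopping rule, adapted to
#' multi-labeled instances. Every protein is expanded into one
#' (instance, location) pair per positive location indicator, and all
#' proportions -- the side weights \eqn{\Pr(f \le T)}, \eqn{\Pr(f > T)} and
#' the class probabilities \eqn{\Pr(S = s_k \mid \cdot)} -- are computed over
#' those pairs, so the class distribution is a proper distribution even for
#' multi-localized proteins.
#'
#' @name discretization
NULL

# Coerce the user-facing `labels` argument (vector of single labels, or list
# of label sets, or a 0/1 matrix) to a list of nonempty character vectors.
as_label_sets <- function(labels) {
  if (is.matrix(labels)) {
    locs <- colnames(labels) %||% paste0("s", seq_len(ncol(labels)))
    labels <- apply(labels, 1, function(r) locs[r == 1], simplify = FALSE)
  }
  if (!is.list(labels)) labels <- as.list(as.character(labels))
  if (any(lengths(labels) == 0)) abort("Every label set must be nonempty.")
  lapply(labels, as.character)
}

# Shannon entropy (bits) of a count vector.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Two-sided conditional class entropy at a candidate boundary
#'
#' Computes \eqn{H(S \mid f, T) = \Pr(f \le T) H(S \mid f \le T) +
#' \Pr(f > T) H(S \mid f > T)} in bits, where the class variable \eqn{S}
#' ranges over locations and all proportions are taken over expanded
#' (instance, location) pairs.
#'
#' @param values Numeric feature values, one per instance.
#' @param labels Label sets aligned with `values`: a vector of single class
#'   labels, a list of character vectors, or a 0/1 indicator matrix.
#' @param boundary A boundary strictly inside `(min(values), max(values))`;
#'   instances with `value <= boundary` fall on the left side.
#' @return Nonnegative conditional entropy in bits.
#' @examples
#' conditional_entropy(c(1, 2, 3, 4), c("A", "A", "B", "B"), 2.5) # 0
#' conditional_entropy(c(1, 2, 3, 4), c("A", "B", "A", "B"), 2.5) # 1
#' @export
conditional_entropy <- function(values, labels, boundary) {
  labels <- as_label_sets(labels)
  if (length(values) == 0) abort("`values` must be nonempty.")
  if (length(values) != length(labels)) {
    abort("`values` and `labels` must have equal length.")
  }
  if (boundary < min(values) || boundary >= max(values)) {
    abort("`boundary` must lie inside (min(values), max(values)).")
  }
  ev <- rep(values, lengths(labels))
  el <- unlist(labels, use.names = FALSE)
  left <- ev <= boundary
  w_left <- mean(left)
  h_left <- entropy_bits(table(el[left]))
  h_right <- entropy_bits(table(el[!left]))
  w_left * h_left + (1 - w_left) * h_right
}

#' Entropy-minimizing discretization boundary
#'
#' Evaluates every midpoint between consecutive distinct sorted feature
#' values and returns the one minimizing [conditional_entropy()]. Ties are
#' broken toward the smallest boundary.
#'
#' @inheritParams conditional_entropy
#' @return The best boundary, or `NULL` when fewer than two distinct values
#'   exist.
#' @examples
#' find_best_boundary(c(1, 2, 3, 4), c("A", "A", "B", "B")) # 2.5
#' @export
find_best_boundary <- function(values, labels) {
  labels <- as_label_sets(labels)
  if (length(values) == 0) abort("`values` must be nonempty.")
  res <- boundary_scan(values, labels)
  if (is.null(res)) NULL else res$boundary
}

# Shared scan: returns the minimizing boundary together with the side
# statistics the MDL test needs. Proportions over expanded pairs throughout.
boundary_scan <- function(values, labels) {
  ev <- rep(values, lengths(labels))
  el <- factor(unlist(labels, use.names = FALSE))
  ord <- order(ev)
  ev <- ev[ord]
  el <- el[ord]
  np <- length(ev)
  kl <- nlevels(el)

  distinct <- unique(ev)
  if (length(distinct) < 2) return(NULL)
  # Cumulative class counts over sorted pairs; candidate cuts sit after the
  # last pair of each distinct value except the largest.
  cum <- apply(
    vapply(levels(el), function(lv) as.integer(el == lv), integer(np)),
    2, cumsum
  )
  cum <- matrix(cum, nrow = np, ncol = kl) # guard np == 1 degeneracy
  cut_after <- cumsum(table(ev))
  cut_after <- cut_after[-length(cut_after)]
  cands <- (distinct[-length(distinct)] + distinct[-1]) / 2

  total <- cum[np, ]
  left <- cum[cut_after, , drop = FALSE]
  right <- matrix(total, nrow(left), kl, byrow = TRUE) - left
  n_left <- rowSums(left)
  ent_rows <- function(m) {
    s <- rowSums(m)
    p <- m / s
    h <- -p * log2(p)
    h[!is.finite(h)] <- 0
    rowSums(h)
  }
  h_left <- ent_rows(left)
  h_right <- ent_rows(right)
  h_cond <- (n_left / np) * h_left + (1 - n_left / np) * h_right
  i <- which.min(h_cond) # ties -> smallest boundary (first index)

  list(
    boundary = cands[i],
    n = np,
    n_left = n_left[i],
    n_right = np - n_left[i],
    entropy_parent = entropy_bits(total),
    entropy_left = h_left[i],
    entropy_right = h_right[i],
    k = sum(total > 0),
    k1 = sum(left[i, ] > 0),
    k2 = sum(right[i, ] > 0),
    h_cond = h_cond[i]
  )
}

#' Minimum Description Length acceptance test for a binary split
#'
#' Decides whether a candidate split is worth keeping. The split is accepted
#' iff
#' \deqn{Gain > \log_2(n - 1)/n + \Delta/n,}
#' with \eqn{Gain = H - (n_1/n) H_1 - (n_2/n) H_2} and
#' \eqn{\Delta = \log_2(3^k - 2) - (k H - k_1 H_1 - k_2 H_2)}, where
#' \eqn{H, H_1, H_2} are the parent/left/right class entropies and
#' \eqn{k, k_1, k_2} the respective numbers of distinct classes present.
#'
#' @param n Number of (instance, location) pairs in the parent interval
#'   (`n = n_left + n_right`).
#' @param entropy_parent,entropy_left,entropy_right Class entropies in bits.
#' @param k,k1,k2 Distinct class counts in the parent, left, and right parts.
#' @param n_left,n_right Pair counts on each side.
#' @return `TRUE` to accept the split, `FALSE` to stop partitioning.
#' @export
mdlp_accept <- function(n, entropy_parent, entropy_left, entropy_right,
                        k, k1, k2, n_left, n_right) {
  if (n < 2) return(FALSE)
  stopifnot(n == n_left + n_right, n_left > 0, n_right > 0)
  gain <- entropy_parent -
    (n_left / n) * entropy_left - (n_right / n) * entropy_right
  delta <- log2(3^k - 2) -
    (k * entropy_parent - k1 * entropy_left - k2 * entropy_right)
  gain > log2(n - 1) / n + delta / n
}

#' Fit the per-feature discretizer
#'
#' For each feature independently, recursively applies the minimal-entropy
#' boundary search ([find_best_boundary()]) and the MDL stopping test
#' ([mdlp_accept()]) to each sub-interval until no further split is accepted.
#' Features for which no boundary is ever accepted collapse to a single code.
#'
#' @param dataset A labeled `multiloc_dataset` with numeric features.
#' @return An object of class `mdlp_cutpoints`: per feature the sorted
#'   accepted boundaries and the observed training range.
#' @seealso [mdlp_apply()] to encode data, [tidy.mdlp_cutpoints()] for a
#'   tabular view.
#' @export
mdlp_fit <- function(dataset) {
  stopifnot(inherits(dataset, "multiloc_dataset"))
  require_labels(dataset, "discretizer fitting")
  if (dataset$discrete) abort("Dataset is already discretized.")
  labels <- as_label_sets(dataset$y)

  fit_one <- function(values) {
    boundaries <- numeric(0)
    recurse <- function(idx) {
      scan <- boundary_scan(values[idx], labels[idx])
      if (is.null(scan)) return(invisible(NULL))
      ok <- mdlp_accept(
        scan$n, scan$entropy_parent, scan$entropy_left, scan$entropy_right,
        scan$k, scan$k1, scan$k2, scan$n_left, scan$n_right
      )
      if (!ok) return(invisible(NULL))
      boundaries <<- c(boundaries, scan$boundary)
      recurse(idx[values[idx] <= scan$boundary])
      recurse(idx[values[idx] > scan$boundary])
    }
    recurse(seq_along(values))
    sort(boundaries)
  }

  cuts <- lapply(seq_len(n_features(dataset)), function(j) fit_one(dataset$x[, j]))
  names(cuts) <- dataset$feature_names
  structure(
    list(
      cutpoints = cuts,
      range = rbind(
        lo = apply(dataset$x, 2, min),
        hi = apply(dataset$x, 2, max)
      ),
      feature_names = dataset$feature_names
    ),
    class = "mdlp_cutpoints"
  )
}

#' @export
print.mdlp_cutpoints <- function(x, ...) {
  cat(sprintf(
    "<mdlp_cutpoints> %d features, %d boundaries total\n",
    length(x$cutpoints), sum(lengths(x$cutpoints))
  ))
  invisible(x)
}

# Arity (number of codes) per feature implied by a cutpoint map.
cutpoint_arities <- function(cuts) lengths(cuts$cutpoints) + 1L

#' Apply a fitted discretizer
#'
#' Maps each feature value to the integer code of the half-open interval
#' containing it: with boundaries \eqn{T_1 < \dots < T_b}, values
#' \eqn{v \le T_1} map to code 0, \eqn{v \in (T_j, T_{j+1}]} to code
#' \eqn{j}, and \eqn{v > T_b} to code \eqn{b}. Values outside the training
#' range therefore clamp to the extreme codes.
#'
#' @param cuts An `mdlp_cutpoints` object from [mdlp_fit()].
#' @param dataset A `multiloc_dataset` with the same feature columns.
#' @return The dataset with integer-coded features (`discrete = TRUE`).
#' @export
mdlp_apply <- function(cuts, dataset) {
  stopifnot(inherits(cuts, "mdlp_cutpoints"), inherits(dataset, "multiloc_dataset"))
  if (!identical(cuts$feature_names, dataset$feature_names)) {
    abort("Feature columns do not match the fitted discretizer.")
  }
  x <- dataset$x
  for (j in seq_along(cuts$cutpoints)) {
    b <- cuts$cutpoints[[j]]
    x[, j] <- if (length(b)) {
      findInterval(dataset$x[, j], b, left.open = TRUE)
    } else {
      0L
    }
  }
  storage.mode(x) <- "integer"
  out <- dataset
  out$x <- x
  out$discrete <- TRUE
  out
}

#' Tabulate fitted cutpoints
#'
#' @param x An `mdlp_cutpoints` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: feature name, number of codes,
#'   training range, and the boundary list.
#' @export
tidy.mdlp_cutpoints <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names,
    n_codes = as.integer(cutpoint_arities(x)),
    lo = unname(x$range["lo", ]),
    hi = unname(x$range["hi", ]),
    boundaries = unname(x$cutpoints)
  )
}

#' Serialize / deserialize a cutpoint map as plain text
#'
#' @param cuts An `mdlp_cutpoints` object.
#' @param path Output (input) file path; a small JSON document with
#'   full-precision numbers.
#' @return `read_cutpoints()` returns the `mdlp_cutpoints` object;
#'   `write_cutpoints()` returns `cuts` invisibly.
#' @export
write_cutpoints <- function(cuts, path) {
  stopifnot(inherits(cuts, "mdlp_cutpoints"))
  obj <- list(
    format = "mdlp_cutpoints-1",
    feature_names = cuts$feature_names,
    cutpoints = lapply(cuts$cutpoints, num_to_chr),
    lo = num_to_chr(cuts$range["lo", ]),
    hi = num_to_chr(cuts$range["hi", ])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(cuts)
}

#' @rdname write_cutpoints
#' @export
read_cutpoints <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mdlp_cutpoints-1")) {
    abort("Unsupported cutpoint file format.")
  }
  cp <- lapply(obj$cutpoints, chr_to_num)
  # jsonlite collapses empty lists; restore per-feature empties.
  cp <- lapply(cp, function(v) if (length(v)) v else numeric(0))
  names(cp) <- obj$feature_names
  structure(
    list(
      cutpoints = cp,
      range = rbind(lo = chr_to_num(obj$lo), hi = chr_to_num(obj$hi)),
      feature_names = obj$feature_names
    ),
    class = "mdlp_cutpoints"
  )
}
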
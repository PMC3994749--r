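#' Structure-search settings
#'
#' @param epsilon Minimum absolute CLL improvement required to apply any move
#'   (default `1e-9`).
#' @param max_iters Iteration cap for the greedy search (default 500).
#' @param max_parents Cap on the number of parents any node may acquire
#'   (default `Inf`); a finite value bounds CPT memory.
#' @param alpha Pseudo-count used when fitting CPTs during scoring
#'   (default 1).
#' @param penalty Complexity control for move acceptance. With the default
#'   `"mdl"`, a move that increases the total number of free CPT parameters
#'   by `dk > 0` must improve the CLL by more than `dk * log(n)` (a
#'   description-length bar: in-sample CLL gains of spurious edges
#'   concentrate around half a likelihood-ratio chi-squared statistic per
#'   parameter, so an unpenalized search saturates with noise edges at any
#'   sample size). `"none"` accepts any move clearing `epsilon` alone --
#'   the pure conditional-log-likelihood ascent.
#' @return A list of class `search_config`.
#' @export
search_config <- function(epsilon = 1e-9, max_iters = 500, max_parents = Inf,
                          alpha = 1, penalty = c("mdl", "none")) {
  penalty <- match.arg(penalty)
  stopifnot(epsilon >= 0, max_iters >= 1, alpha >= 0, max_parents >= 0)
  out <- list(
    epsilon = epsilon, max_iters = max_iters,
    max_parents = max_parents, alpha = alpha, penalty = penalty
  )
  class(out) <- "search_config"
  out
}

#' Enumerate the legal moves from a network structure
#'
#' A move adds an absent edge, deletes a present edge, or reverses a present
#' edge. Moves whose result would be cyclic or would connect two feature
#' variables are excluded. The order is deterministic: kind
#' (add, delete, reverse), then the (from, to) node pair in node order.
#'
#' @param structure A `bn_structure`.
#' @return A tibble with columns `kind`, `from`, `to` (node names).
#' @export
legal_moves <- function(structure) {
  s <- structure
  nn <- length(s$nodes)
  has_edge <- function(u, v) u %in% s$parents[[v]]
  adds <- list(); dels <- list(); revs <- list()
  for (u in seq_len(nn)) {
    for (v in seq_len(nn)) {
      if (u == v) next
      if (s$is_feature[u] && s$is_feature[v]) next
      if (!has_edge(u, v)) {
        p <- s$parents
        p[[v]] <- c(p[[v]], u)
        if (is_acyclic(p)) adds[[length(adds) + 1L]] <- c(u, v)
      } else {
        dels[[length(dels) + 1L]] <- c(u, v)
        p <- s$parents
        p[[v]] <- setdiff(p[[v]], u)
        p[[u]] <- c(p[[u]], v)
        if (is_acyclic(p)) revs[[length(revs) + 1L]] <- c(u, v)
      }
    }
  }
  pack <- function(lst, kind) {
    if (!length(lst)) {
      return(tibble::tibble(kind = character(0), from = character(0), to = character(0)))
    }
    m <- do.call(rbind, lst)
    tibble::tibble(kind = kind, from = s$nodes[m[, 1]], to = s$nodes[m[, 2]])
  }
  dplyr::bind_rows(pack(adds, "add"), pack(dels, "delete"), pack(revs, "reverse"))
}

# The family changes a move induces: list of (node = new parent vector).
move_changes <- function(parents, kind, u, v) {
  if (kind == "add") {
    ch <- list(sort(c(parents[[v]], u)))
    names(ch) <- as.character(v)
  } else if (kind == "delete") {
    ch <- list(setdiff(parents[[v]], u))
    names(ch) <- as.character(v)
  } else {
    ch <- list(setdiff(parents[[v]], u), sort(c(parents[[u]], v)))
    names(ch) <- as.character(c(v, u))
  }
  ch
}

#' Greedy hill climbing over network structures
#'
#' Learns the Bayesian network classifier for one target location by
#' steepest-ascent hill climbing maximizing the conditional log likelihood
#' ([cll_score()]). Starting from the empty graph, every legal move
#' ([legal_moves()]) is evaluated each iteration -- refitting only the CPT
#' families the move changes -- and the best move is applied if its CLL
#' improvement clears the acceptance bar (`epsilon`, plus the
#' description-length term for parameter-adding moves under the default
#' `penalty = "mdl"`; see [search_config()]); otherwise the search stops.
#' Applied moves always strictly increase the CLL. Moves whose
#' changed families lie entirely outside the target's Markov blanket leave
#' the CLL exactly unchanged and are recognized as such without rescoring.
#'
#' @param dataset A labeled, discretized `multiloc_dataset`.
#' @param estimates n x q 0/1 matrix of indicator estimates (columns named by
#'   location; the target's own column is ignored).
#' @param target Target location (name or index into the vocabulary).
#' @param config A [search_config()].
#' @param feature_arities Optional feature arities (e.g. from the fitted
#'   discretizer via `cutpoint_arities`); inferred from the data when `NULL`.
#' @return A list of class `hill_climb` with elements `classifier` (a
#'   [bn_classifier()] with parameters refit on the final structure), `trace`
#'   (tibble: iteration, kind, from, to, cll_before, cll_after), and `cll`.
#' @export
hill_climb <- function(dataset, estimates, target, config = search_config(),
                       feature_arities = NULL) {
  require_labels(dataset, "structure search")
  if (!dataset$discrete) abort("Dataset features must be integer-coded.")
  locs <- dataset$locations
  if (is.character(target)) target <- match(target, locs)
  if (is.na(target) || target < 1 || target > length(locs)) {
    abort("Unknown target location.")
  }
  s <- bn_structure(dataset$feature_names, locs, feature_arities)
  d <- n_features(dataset)
  ti <- d + target # target node index

  estimates <- as.matrix(as.data.frame(estimates))
  if (is.null(colnames(estimates))) colnames(estimates) <- locs
  if (!all(locs %in% colnames(estimates))) {
    abort("`estimates` must have one column per location.")
  }
  W <- cbind(dataset$x[, s$nodes[s$is_feature], drop = FALSE], dataset$y[, locs, drop = FALSE])
  V <- cbind(dataset$x[, s$nodes[s$is_feature], drop = FALSE], estimates[, locs, drop = FALSE])
  storage.mode(W) <- "integer"
  storage.mode(V) <- "integer"
  ar <- resolve_arities(s, W)
  y <- W[, ti]
  n <- nrow(W)
  alpha <- config$alpha

  # n x 2 matrix of log theta_v contributions under L_target = 0 / 1:
  # fit the family's CPT from W (true labels), evaluate it on V (estimates).
  family_contrib <- function(v, pv) {
    fam <- c(v, pv)
    sizes <- ar[fam]
    counts <- tabulate(lin_index(W[, fam, drop = FALSE], sizes) + 1L,
      nbins = prod(sizes)
    )
    av <- sizes[1]
    m <- matrix(counts, nrow = av)
    marg <- colSums(m)
    if (alpha == 0 && any(marg == 0)) {
      m[, marg == 0] <- 1 / av
      marg[marg == 0] <- 1
    }
    theta <- log((m + alpha) / rep(marg + alpha * av, each = av))
    theta <- as.numeric(theta)
    out <- matrix(0, n, 2)
    for (z in 0:1) {
      vals <- V[, fam, drop = FALSE]
      hit <- fam == ti
      if (any(hit)) vals[, hit] <- z
      if (v == ti) vals[, 1] <- z
      out[, z + 1] <- theta[lin_index(vals, sizes) + 1L]
    }
    out
  }

  in_blanket <- function(v, pv) v == ti || ti %in% pv
  n_params <- function(v, pv) (ar[v] - 1) * prod(ar[pv])
  log_n <- log(n)
  parents <- s$parents
  contrib <- list()
  contrib[[as.character(ti)]] <- family_contrib(ti, parents[[ti]])
  S0 <- contrib[[as.character(ti)]][, 1]
  S1 <- contrib[[as.character(ti)]][, 2]
  cll <- cll_from_logjoints(S0, S1, y)

  trace <- list()
  iter <- 0L
  repeat {
    if (iter >= config$max_iters) {
      warn("hill_climb: maximum iteration count reached.")
      break
    }
    s$parents <- parents
    moves <- legal_moves(s)
    best <- NULL
    best_cll <- cll
    best_score <- 0
    for (r in seq_len(nrow(moves))) {
      u <- match(moves$from[r], s$nodes)
      v <- match(moves$to[r], s$nodes)
      changes <- move_changes(parents, moves$kind[r], u, v)
      # parent-count guard
      if (any(lengths(changes) > config$max_parents)) next
      affected <- vapply(
        seq_along(changes),
        function(j) {
          w <- as.integer(names(changes)[j])
          in_blanket(w, parents[[w]]) || in_blanket(w, changes[[j]])
        },
        logical(1)
      )
      if (!any(affected)) next # CLL provably unchanged
      ns0 <- S0
      ns1 <- S1
      for (j in seq_along(changes)) {
        w <- as.integer(names(changes)[j])
        if (in_blanket(w, parents[[w]])) {
          old <- contrib[[as.character(w)]]
          ns0 <- ns0 - old[, 1]
          ns1 <- ns1 - old[, 2]
        }
        if (in_blanket(w, changes[[j]])) {
          new <- family_contrib(w, changes[[j]])
          ns0 <- ns0 + new[, 1]
          ns1 <- ns1 + new[, 2]
        }
      }
      cand_cll <- cll_from_logjoints(ns0, ns1, y)
      gain <- cand_cll - cll
      bar <- config$epsilon
      if (config$penalty == "mdl") {
        dk <- sum(vapply(
          seq_along(changes),
          function(j) {
            w <- as.integer(names(changes)[j])
            n_params(w, changes[[j]]) - n_params(w, parents[[w]])
          },
          numeric(1)
        ))
        bar <- bar + max(dk, 0) * log_n
      }
      score <- gain - bar
      # strict > keeps the earliest move in enumeration order on ties
      if (gain > bar && score > best_score) {
        best <- list(kind = moves$kind[r], u = u, v = v, changes = changes)
        best_cll <- cand_cll
        best_score <- score
      }
    }
    if (is.null(best)) break
    iter <- iter + 1L
    # apply the move and refresh caches for the changed families
    for (j in seq_along(best$changes)) {
      w <- as.integer(names(best$changes)[j])
      parents[[w]] <- best$changes[[j]]
      if (in_blanket(w, parents[[w]])) {
        contrib[[as.character(w)]] <- family_contrib(w, parents[[w]])
      } else {
        contrib[[as.character(w)]] <- NULL
      }
    }
    stopifnot(is_acyclic(parents))
    S0 <- Reduce(`+`, lapply(contrib, function(m) m[, 1]))
    S1 <- Reduce(`+`, lapply(contrib, function(m) m[, 2]))
    trace[[iter]] <- tibble::tibble(
      iteration = iter, kind = best$kind,
      from = s$nodes[best$u], to = s$nodes[best$v],
      cll_before = cll, cll_after = best_cll
    )
    cll <- best_cll
  }

  s$parents <- parents
  cpts <- fit_parameters(s, dataset, alpha = alpha)
  cls <- bn_classifier(locs[target], s, cpts)
  trace_tbl <- if (length(trace)) {
    dplyr::bind_rows(trace)
  } else {
    tibble::tibble(
      iteration = integer(0), kind = character(0), from = character(0),
      to = character(0), cll_before = numeric(0), cll_after = numeric(0)
    )
  }
  out <- list(classifier = cls, trace = trace_tbl, cll = cll, iterations = iter)
  class(out) <- "hill_climb"
  out
}

#' @export
print.hill_climb <- function(x, ...) {
  cat(sprintf(
    "<hill_climb> target = %s, %d iterations, final CLL = %.4f\n",
    x$classifier$structure$nodes[x$classifier$target], x$iterations, x$cll
  ))
  invisible(x)
}

#' @export
tidy.hill_climb <- function(x, ...) x$trace
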
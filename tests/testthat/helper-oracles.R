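# Independent oracles and fixture builders shared across the suite. The
# oracles deliberately use naive formulations (explicit loops, R's native
# array subscripting, direct formula transcription) so they share no code
# path with the implementation they check.

# ---- dataset builders -------------------------------------------------------

make_dataset <- function(x, y, ids = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  ids <- ids %||% sprintf("p%03d", seq_len(nrow(x)))
  feats <- data.frame(id = ids, x, check.names = FALSE)
  labs <- NULL
  if (!is.null(y)) {
    y <- as.matrix(y)
    if (is.null(colnames(y))) colnames(y) <- paste0("L", seq_len(ncol(y)))
    labs <- data.frame(id = ids, y, check.names = FALSE)
  }
  multiloc_dataset(feats, labs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-feature labeled dataset from raw vectors (labels: list of sets or
# vector); pads with a second dummy location when needed.
one_feature_dataset <- function(values, label_sets) {
  if (!is.list(label_sets)) label_sets <- as.list(as.character(label_sets))
  locs <- sort(unique(unlist(label_sets)))
  if (length(locs) < 2) locs <- union(locs, "pad_loc")
  y <- matrix(0L, length(values), length(locs), dimnames = list(NULL, locs))
  for (i in seq_along(label_sets)) y[i, label_sets[[i]]] <- 1L
  make_dataset(matrix(values, ncol = 1, dimnames = list(NULL, "F1")), y)
}

# ---- recursive MDLP oracle --------------------------------------------------

# Exhaustive recursive minimal-entropy/MDL search, transcribed directly from
# the formulas; operates on expanded (instance, location) pairs.
oracle_mdlp_boundaries <- function(values, label_sets) {
  if (!is.list(label_sets)) label_sets <- as.list(as.character(label_sets))
  ev <- rep(values, lengths(label_sets))
  el <- unlist(label_sets, use.names = FALSE)
  H <- function(labs) {
    if (length(labs) == 0) return(0)
    p <- as.numeric(table(labs)) / length(labs)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  rec <- function(vals, labs) {
    u <- sort(unique(vals))
    if (length(u) < 2) return(numeric(0))
    cands <- (u[-1] + u[-length(u)]) / 2
    ce <- vapply(cands, function(b) {
      l <- labs[vals <= b]
      r <- labs[vals > b]
      length(l) / length(vals) * H(l) + length(r) / length(vals) * H(r)
    }, numeric(1))
    b <- cands[which.min(ce)]
    left <- vals <= b
    n <- length(vals)
    n1 <- sum(left)
    n2 <- n - n1
    hp <- H(labs)
    h1 <- H(labs[left])
    h2 <- H(labs[!left])
    k <- length(unique(labs))
    k1 <- length(unique(labs[left]))
    k2 <- length(unique(labs[!left]))
    gain <- hp - n1 / n * h1 - n2 / n * h2
    delta <- log2(3^k - 2) - (k * hp - k1 * h1 - k2 * h2)
    if (!(gain > log2(n - 1) / n + delta / n)) return(numeric(0))
    c(rec(vals[left], labs[left]), b, rec(vals[!left], labs[!left]))
  }
  sort(rec(ev, el))
}

random_mdlp_input <- function(seed) {
  set.seed(seed)
  n <- sample(4:50, 1)
  n_distinct <- sample(2:8, 1)
  values <- sample(seq_len(n_distinct), n, replace = TRUE) +
    round(runif(1), 3)
  q <- sample(2:4, 1)
  locs <- paste0("s", seq_len(q))
  label_sets <- lapply(seq_len(n), function(i) {
    sample(locs, sample(1:2, 1))
  })
  list(values = values, label_sets = label_sets)
}

# ---- Bayesian network oracles ----------------------------------------------

# Random all-binary legal network (structure + random CPTs).
random_binary_network <- function(K, seed) {
  set.seed(seed)
  d <- sample(seq_len(K - 2), 1)
  q <- K - d
  s <- bn_structure(paste0("F", seq_len(d)), paste0("L", seq_len(q)),
    feature_arities = rep(2L, d)
  )
  n_try <- sample(0:(2 * K), 1)
  for (i in seq_len(n_try)) {
    u <- sample(K, 1)
    v <- sample(K, 1)
    s <- tryCatch(multilocbn:::add_edge(s, u, v), error = function(e) s)
  }
  tables <- lapply(seq_len(K), function(v) {
    sizes <- rep(2L, 1 + length(s$parents[[v]]))
    p1 <- runif(prod(sizes) / 2, 0.05, 0.95)
    array(rbind(1 - p1, p1), dim = sizes)
  })
  names(tables) <- s$nodes
  cpts <- list(
    nodes = s$nodes, parents = s$parents, arity = s$arity,
    tables = tables, alpha = 0
  )
  class(cpts) <- "bn_cpts"
  list(structure = s, cpts = cpts, d = d, q = q)
}

# Full-joint enumeration: Pr(target = 1 | everything else) by summing the
# explicit joint over all 2^K assignments.
oracle_conditional <- function(cpts, target_name, evidence) {
  nodes <- cpts$nodes
  K <- length(nodes)
  grid <- as.matrix(expand.grid(rep(list(0:1), K)))
  colnames(grid) <- nodes
  probs <- rep(1, nrow(grid))
  for (v in seq_len(K)) {
    pa <- cpts$parents[[v]]
    sub <- cbind(grid[, v], grid[, pa, drop = FALSE]) + 1L
    probs <- probs * cpts$tables[[v]][sub]
  }
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(evidence)) keep <- keep & grid[, nm] == evidence[[nm]]
  sum(probs[keep & grid[, target_name] == 1]) / sum(probs[keep])
}

# Enumerate every legal DAG (no feature-feature edges) over 2 features and
# 2 locations, as parent lists; uses its own DFS cycle check.
enumerate_legal_dags_4 <- function() {
  isf <- c(TRUE, TRUE, FALSE, FALSE)
  pairs <- list()
  for (u in 1:4) {
    for (v in 1:4) {
      if (u != v && !(isf[u] && isf[v])) pairs[[length(pairs) + 1L]] <- c(u, v)
    }
  }
  acyclic <- function(parents) {
    state <- integer(4)
    ok <- TRUE
    visit <- function(v) {
      if (state[v] == 1L) {
        ok <<- FALSE
        return()
      }
      if (state[v] == 2L) return()
      state[v] <<- 1L
      for (p in parents[[v]]) visit(p)
      state[v] <<- 2L
    }
    for (v in 1:4) visit(v)
    ok
  }
  out <- list()
  for (mask in 0:(2^length(pairs) - 1)) {
    parents <- rep(list(integer(0)), 4)
    for (j in seq_along(pairs)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L))) {
        parents[[pairs[[j]][2]]] <- sort(c(parents[[pairs[[j]][2]]], pairs[[j]][1]))
      }
    }
    if (acyclic(parents)) out[[length(out) + 1L]] <- parents
  }
  out
}

# The 4-node generating network used by the structure-search optimality
# checks: strong F1 -> L1 dependence, L1 -> L2 coupling, F2 background.
search_test_network <- function() {
  s <- bn_structure(c("F1", "F2"), c("L1", "L2"),
    feature_arities = c(2L, 2L),
    edges = data.frame(from = c("F1", "L1"), to = c("L1", "L2"))
  )
  tables <- list(
    F1 = array(c(0.5, 0.5), 2),
    F2 = array(c(0.7, 0.3), 2),
    L1 = array(rbind(c(0.85, 0.15), c(0.15, 0.85)), c(2, 2)),
    L2 = array(rbind(c(0.7, 0.35), c(0.3, 0.65)), c(2, 2))
  )
  cpts <- list(
    nodes = s$nodes, parents = s$parents, arity = s$arity,
    tables = tables, alpha = 0
  )
  class(cpts) <- "bn_cpts"
  list(structure = s, cpts = cpts)
}

# Total free CPT parameters of a parent assignment (binary nodes).
count_free_params <- function(parents, arity) {
  sum(vapply(seq_along(parents), function(v) {
    (arity[v] - 1) * prod(arity[parents[[v]]])
  }, numeric(1)))
}

# Exhaustively score all legal 4-node DAGs with the given scorer and return
# the maximum.
exhaustive_best_score <- function(dataset, estimates, target, scorer) {
  best <- -Inf
  for (p in enumerate_legal_dags_4()) {
    s <- bn_structure(c("F1", "F2"), c("L1", "L2"), feature_arities = c(2L, 2L))
    s$parents <- p
    names(s$parents) <- s$nodes
    cl <- bn_classifier(target, s, fit_parameters(s, dataset, alpha = 1))
    sc <- scorer(cl, p)
    if (sc > best) best <- sc
  }
  best
}

# ---- naive metric oracles ---------------------------------------------------

# Set-arithmetic versions of every evaluation measure, written with loops.
oracle_example_metrics <- function(true_sets, pred_sets) {
  acc <- f1 <- numeric(length(true_sets))
  for (i in seq_along(true_sets)) {
    M <- true_sets[[i]]
    Mh <- pred_sets[[i]]
    inter <- length(intersect(M, Mh))
    acc[i] <- inter / length(union(M, Mh))
    f1[i] <- 2 * inter / (length(M) + length(Mh))
  }
  c(acc = mean(acc), f1 = mean(f1))
}

oracle_loc_pre_rec <- function(true_sets, pred_sets, loc) {
  pre_terms <- rec_terms <- numeric(0)
  for (i in seq_along(true_sets)) {
    M <- true_sets[[i]]
    Mh <- pred_sets[[i]]
    inter <- length(intersect(M, Mh))
    if (loc %in% Mh) pre_terms <- c(pre_terms, inter / length(Mh))
    if (loc %in% M) rec_terms <- c(rec_terms, inter / length(M))
  }
  c(
    pre = if (length(pre_terms)) mean(pre_terms) else NA_real_,
    rec = if (length(rec_terms)) mean(rec_terms) else NA_real_
  )
}

oracle_f1_label <- function(true_sets, pred_sets, locations) {
  present <- locations[vapply(locations, function(l) {
    any(vapply(true_sets, function(M) l %in% M, logical(1)))
  }, logical(1))]
  terms <- vapply(present, function(l) {
    pr <- oracle_loc_pre_rec(true_sets, pred_sets, l)
    if (anyNA(pr) || sum(pr) == 0) return(0)
    2 * pr[["pre"]] * pr[["rec"]] / (pr[["pre"]] + pr[["rec"]])
  }, numeric(1))
  mean(terms)
}

oracle_std_pre_rec <- function(true_sets, pred_sets, loc) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(true_sets)) {
    t <- loc %in% true_sets[[i]]
    p <- loc %in% pred_sets[[i]]
    if (t && p) tp <- tp + 1L
    if (!t && p) fp <- fp + 1L
    if (t && !p) fn <- fn + 1L
  }
  c(
    pre_std = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    rec_std = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}

random_label_pairs <- function(seed, n = NULL, q = NULL) {
  set.seed(seed)
  n <- n %||% sample(1:30, 1)
  q <- q %||% sample(2:6, 1)
  locs <- paste0("s", seq_len(q))
  truth <- matrix(0L, n, q, dimnames = list(NULL, locs))
  pred <- matrix(0L, n, q, dimnames = list(NULL, locs))
  for (i in seq_len(n)) {
    truth[i, sample(q, sample(seq_len(min(q, 3)), 1))] <- 1L
    k <- sample(0:q, 1)
    if (k > 0) pred[i, sample(q, k)] <- 1L
  }
  list(truth = truth, pred = pred, locs = locs)
}

sets_from_matrix <- function(m) {
  locs <- colnames(m)
  lapply(seq_len(nrow(m)), function(i) locs[m[i, ] == 1])
}
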
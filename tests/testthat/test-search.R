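test_that("legal moves enumerate adds, deletes, and reversals under the constraints", {
  s <- bn_structure(c("F1", "F2"), c("L1", "L2"))
  mv <- legal_moves(s)
  # 12 ordered pairs minus the 2 feature-feature ones
  expect_identical(nrow(mv), 10L)
  expect_true(all(mv$kind == "add"))
  expect_false(any(mv$from %in% c("F1", "F2") & mv$to %in% c("F1", "F2")))

  s2 <- multilocbn:::add_edge(s, "L1", "L2")
  mv2 <- legal_moves(s2)
  expect_true(any(mv2$kind == "delete" & mv2$from == "L1" & mv2$to == "L2"))
  expect_true(any(mv2$kind == "reverse" & mv2$from == "L1" & mv2$to == "L2"))
  expect_false(any(mv2$kind == "add" & mv2$from == "L2" & mv2$to == "L1"))

  # reversing A->C in A->B, B->C, A->C would create a cycle
  s3 <- bn_structure("F1", c("A", "B", "C"),
    edges = data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"))
  )
  mv3 <- legal_moves(s3)
  expect_false(any(mv3$kind == "reverse" & mv3$from == "A" & mv3$to == "C"))
  expect_true(any(mv3$kind == "reverse" & mv3$from == "B" & mv3$to == "C"))
})

test_that("hill climbing leaves an independent target unconnected", {
  # L2 is an independent coin; F1/F2 inform L1, F3 is noise. Sampling comes
  # straight from the network (no zero-row rejection, which would itself
  # couple the labels).
  s <- bn_structure(c("F1", "F2", "F3"), c("L1", "L2"),
    feature_arities = rep(2L, 3),
    edges = data.frame(from = c("F1", "F2"), to = "L1")
  )
  tabs <- list(
    F1 = array(c(0.5, 0.5), 2),
    F2 = array(c(0.6, 0.4), 2),
    F3 = array(c(0.5, 0.5), 2),
    L1 = array(rbind(c(0.9, 0.6, 0.4, 0.1), c(0.1, 0.4, 0.6, 0.9)), c(2, 2, 2)),
    L2 = array(c(0.55, 0.45), 2)
  )
  cp <- structure(
    list(nodes = s$nodes, parents = s$parents, arity = s$arity, tables = tabs, alpha = 0),
    class = "bn_cpts"
  )
  touched <- vapply(1:20, function(seed) {
    d <- bn_sample(s, cp, 2000, seed = seed)
    hc <- hill_climb(d, d$y, "L2", feature_arities = rep(2L, 3))
    ti <- match("L2", hc$classifier$structure$nodes)
    parents <- hc$classifier$structure$parents
    length(parents[[ti]]) + length(multilocbn:::node_children(hc$classifier$structure, ti))
  }, numeric(1))
  expect_gte(sum(touched == 0), 18)
})

test_that("the CLL trace is strictly increasing and every structure is legal", {
  d <- sample_multiloc(dependency_spec(n = 800, seed = 5))
  cuts <- mdlp_fit(d)
  dd <- mdlp_apply(cuts, d)
  est <- estimate_indicators(fit_indicator_estimators(d), d)
  for (target in c(1, 4)) {
    hc <- hill_climb(dd, est, target, feature_arities = lengths(cuts$cutpoints) + 1L)
    tr <- hc$trace
    if (nrow(tr) > 0) {
      expect_true(all(tr$cll_after > tr$cll_before))
      expect_equal(tr$cll_before[-1], tr$cll_after[-nrow(tr)])
      expect_equal(tr$cll_after[nrow(tr)], hc$cll)
    }
    s <- hc$classifier$structure
    expect_true(multilocbn:::is_acyclic(s$parents))
    for (v in seq_along(s$nodes)) {
      if (s$is_feature[v]) {
        expect_false(any(s$is_feature[s$parents[[v]]]))
      }
    }
    # cached incremental CLL equals the from-scratch score
    expect_equal(
      hc$cll,
      cll_score(hc$classifier, dd, est),
      tolerance = 1e-9
    )
  }
})

test_that("greedy search with the description-length bar attains the exhaustive optimum", {
  net <- search_test_network()
  for (seed in 1:4) {
    d <- bn_sample(net$structure, net$cpts, 3000, seed = seed)
    est <- d$y
    hc <- hill_climb(d, est, "L1", search_config())
    pen <- log(3000)
    hc_score <- hc$cll -
      pen * count_free_params(hc$classifier$structure$parents, c(2, 2, 2, 2))
    best <- exhaustive_best_score(
      d, est, "L1",
      function(cl, parents) {
        cll_score(cl, d, est) - pen * count_free_params(parents, c(2, 2, 2, 2))
      }
    )
    expect_equal(hc_score, best, tolerance = 1e-8)
  }
})

test_that("search is deterministic for fixed inputs", {
  d <- sample_multiloc(dependency_spec(n = 500, seed = 8))
  cuts <- mdlp_fit(d)
  dd <- mdlp_apply(cuts, d)
  est <- estimate_indicators(fit_indicator_estimators(d), d)
  h1 <- hill_climb(dd, est, 4, feature_arities = lengths(cuts$cutpoints) + 1L)
  h2 <- hill_climb(dd, est, 4, feature_arities = lengths(cuts$cutpoints) + 1L)
  expect_identical(h1$classifier$structure$parents, h2$classifier$structure$parents)
  expect_identical(h1$trace, h2$trace)
})

test_that("the max-parents guard caps family sizes", {
  d <- sample_multiloc(dependency_spec(n = 500, seed = 12))
  cuts <- mdlp_fit(d)
  dd <- mdlp_apply(cuts, d)
  est <- estimate_indicators(fit_indicator_estimators(d), d)
  hc <- suppressWarnings(hill_climb(dd, est, 1,
    config = search_config(max_parents = 1, penalty = "none", max_iters = 30),
    feature_arities = lengths(cuts$cutpoints) + 1L
  ))
  expect_true(all(lengths(hc$classifier$structure$parents) <= 1))
})
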
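test_that("structures reject feature-feature edges, self-loops, and cycles", {
  s <- bn_structure(c("F1", "F2"), c("L1", "L2"))
  expect_error(multilocbn:::add_edge(s, "F1", "F2"), "feature")
  expect_error(multilocbn:::add_edge(s, "F1", "F1"), "Self-loops")
  s <- multilocbn:::add_edge(s, "L1", "L2")
  expect_error(multilocbn:::add_edge(s, "L2", "L1"), "cycle")
  expect_identical(tidy(s)$from, "L1")
})

test_that("parameter fitting reproduces smoothed count ratios and normalized rows", {
  # parentless binary node, value 1 in 3 of 4 records, alpha = 0 -> 0.75
  ds <- make_dataset(
    matrix(0L, 4, 1, dimnames = list(NULL, "F1")),
    cbind(L1 = c(1L, 1L, 1L, 0L), L2 = c(1L, 1L, 1L, 1L))
  )
  ds$discrete <- TRUE
  s <- bn_structure("F1", c("L1", "L2"), feature_arities = 1L)
  cp0 <- fit_parameters(s, ds, alpha = 0)
  expect_equal(as.numeric(cp0$tables$L1), c(0.25, 0.75))
  # value 1 in 0 of 2 records, alpha = 1 -> (0 + 1) / (2 + 2) = 0.25
  ds2 <- make_dataset(
    matrix(0L, 2, 1, dimnames = list(NULL, "F1")),
    cbind(L1 = c(0L, 0L), L2 = c(1L, 1L))
  )
  ds2$discrete <- TRUE
  cp1 <- fit_parameters(s, ds2, alpha = 1)
  expect_equal(as.numeric(cp1$tables$L1), c(0.75, 0.25))
  # every fitted row sums to 1
  tn <- toy_network()
  samp <- bn_sample(tn$structure, tn$cpts, 500, seed = 3)
  cp <- fit_parameters(tn$structure, samp, alpha = 1)
  for (tab in cp$tables) {
    m <- matrix(as.numeric(tab), nrow = dim(tab)[1])
    expect_equal(colSums(m), rep(1, ncol(m)), tolerance = 1e-9)
  }
})

test_that("unseen parent configurations fall back to uniform with a warning when alpha = 0", {
  ds <- make_dataset(
    matrix(c(0L, 0L), 2, 1, dimnames = list(NULL, "F1")),
    cbind(L1 = c(1L, 0L), L2 = c(1L, 1L))
  )
  ds$discrete <- TRUE
  s <- bn_structure("F1", c("L1", "L2"), feature_arities = 2L,
    edges = data.frame(from = "F1", to = "L1")
  )
  expect_warning(cp <- fit_parameters(s, ds, alpha = 0), "Unseen")
  expect_equal(as.numeric(cp$tables$L1[, 2]), c(0.5, 0.5))
})

test_that("joint log-probability is the sum of log table entries", {
  tn <- toy_network()
  cls <- bn_classifier("L1", tn$structure, tn$cpts)
  # hand-multiplied chain: P(F1=1) P(F2=0) P(L1=1|F1=1) P(L2=1|F2=0,L1=1)
  expect_equal(
    joint_log_prob(cls, c(F1 = 1, F2 = 0, L1 = 1, L2 = 1)),
    log(0.6 * 0.7 * 0.8 * 0.7)
  )
  expect_error(joint_log_prob(cls, c(F1 = 1, F2 = 0, L1 = 1)), "missing")
  # independent uniform nodes: log(0.5^K)
  s <- bn_structure(c("F1", "F2", "F3"), c("L1", "L2"), rep(2L, 3))
  tabs <- rep(list(array(c(0.5, 0.5), 2)), 5)
  names(tabs) <- s$nodes
  cp <- structure(
    list(nodes = s$nodes, parents = s$parents, arity = s$arity, tables = tabs, alpha = 0),
    class = "bn_cpts"
  )
  cls_u <- bn_classifier("L1", s, cp)
  expect_equal(
    joint_log_prob(cls_u, c(F1 = 1, F2 = 0, F3 = 1, L1 = 0, L2 = 1)),
    5 * log(0.5)
  )
  # all-uniform CPTs give a 0.5 conditional by symmetry
  expect_equal(conditional_prob_target(cls_u, c(1, 0, 1), c(L2 = 1)), 0.5)
})

test_that("target conditional equals the hand-computed joint ratio on the toy network", {
  tn <- toy_network()
  cls <- bn_classifier("L1", tn$structure, tn$cpts)
  # evidence F1=1, F2=0, L2=1:
  # J(1) = 0.6*0.7*0.8*0.7, J(0) = 0.6*0.7*0.2*0.1
  want <- (0.8 * 0.7) / (0.8 * 0.7 + 0.2 * 0.1)
  expect_equal(conditional_prob_target(cls, c(F1 = 1, F2 = 0), c(L2 = 1)), want)
})

test_that("Markov-blanket shortcut agrees with full-joint enumeration on random networks", {
  set.seed(1)
  for (seed in 1:30) {
    net <- random_binary_network(K = sample(4:10, 1), seed = 1000 + seed)
    target <- net$structure$nodes[net$d + 1]
    cls <- bn_classifier(target, net$structure, net$cpts)
    for (rep in 1:4) {
      feats <- setNames(
        as.list(sample(0:1, net$d, replace = TRUE)),
        net$structure$nodes[seq_len(net$d)]
      )
      locs <- setNames(
        as.list(sample(0:1, net$q, replace = TRUE)),
        net$structure$nodes[net$d + seq_len(net$q)]
      )
      got <- conditional_prob_target(
        cls,
        as.data.frame(feats),
        as.data.frame(locs)
      )
      evidence <- c(feats, locs[names(locs) != target])
      want <- oracle_conditional(net$cpts, target, evidence)
      expect_equal(got, want, tolerance = 1e-12)
      # and the full-factorization route (two complete joints) agrees too
      asg1 <- unlist(modifyList(c(feats, locs), setNames(list(1), target)))
      asg0 <- unlist(modifyList(c(feats, locs), setNames(list(0), target)))
      a1 <- joint_log_prob(cls, asg1)
      a0 <- joint_log_prob(cls, asg0)
      expect_equal(got, 1 / (1 + exp(a0 - a1)), tolerance = 1e-12)
    }
  }
})

test_that("CLL sums the log conditionals of the true target values", {
  tn <- toy_network()
  samp <- bn_sample(tn$structure, tn$cpts, 50, seed = 5)
  cls <- bn_classifier("L1", tn$structure, fit_parameters(tn$structure, samp, 1))
  est <- samp$y
  got <- cll_score(cls, samp, est)
  expect_lte(got, 0)
  # naive recomputation via per-record conditionals
  terms <- vapply(seq_len(50), function(i) {
    p <- conditional_prob_target(cls, samp$x[i, ], est[i, ])
    log(ifelse(samp$y[i, "L1"] == 1, p, 1 - p))
  }, numeric(1))
  expect_equal(got, sum(terms), tolerance = 1e-10)
  # isolated target with theta(1) = 0.5: CLL = n log 0.5
  s <- bn_structure("F1", c("L1", "L2"), feature_arities = 1L)
  ds <- make_dataset(
    matrix(0L, 10, 1, dimnames = list(NULL, "F1")),
    cbind(L1 = rep(c(1L, 0L), 5), L2 = rep(1L, 10))
  )
  ds$discrete <- TRUE
  cp <- fit_parameters(s, ds, alpha = 0)
  cls2 <- bn_classifier("L1", s, cp)
  expect_equal(cll_score(cls2, ds, ds$y), 10 * log(0.5))
})

test_that("parameters are recovered from samples and improve with sample size", {
  tn <- toy_network()
  err_at <- function(n) {
    samp <- bn_sample(tn$structure, tn$cpts, n, seed = 11)
    cp <- fit_parameters(tn$structure, samp, alpha = 0)
    max(mapply(
      function(a, b) max(abs(as.numeric(a) - as.numeric(b))),
      cp$tables, tn$cpts$tables
    ))
  }
  e3 <- err_at(1000)
  e4 <- err_at(10000)
  expect_lt(e4, e3)
  expect_lt(e4, 0.05)
})
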
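test_that("conditional entropy matches hand-evaluated cases", {
  expect_equal(conditional_entropy(c(1, 2, 3, 4), c("A", "A", "B", "B"), 2.5), 0)
  # each side a uniform 2-class distribution: 0.5 * 1 + 0.5 * 1 = 1 bit
  expect_equal(conditional_entropy(c(1, 2, 3, 4), c("A", "B", "A", "B"), 2.5), 1)
  expect_equal(conditional_entropy(c(1, 5, 9), c("A", "A", "A"), 3), 0)
  expect_error(conditional_entropy(c(1, 2), c("A", "B"), 5), "inside")
})

test_that("conditional entropy treats multi-labeled instances as expanded pairs", {
  # two instances: {A} at 1, {A, B} at 3; boundary 2
  # pairs: left {A} (1 pair), right {A, B} (2 pairs)
  # H = (1/3)*0 + (2/3)*1 = 2/3
  val <- conditional_entropy(c(1, 3), list("A", c("A", "B")), 2)
  expect_equal(val, 2 / 3)
})

test_that("best boundary is the entropy-minimizing midpoint with smallest-tie rule", {
  expect_equal(find_best_boundary(c(1, 2, 3, 4), c("A", "A", "B", "B")), 2.5)
  expect_null(find_best_boundary(c(5, 5, 5), c("A", "B", "A")))
  expect_equal(find_best_boundary(c(0, 1), c("A", "B")), 0.5)
  # all-identical labels: every candidate scores 0, smallest midpoint wins
  expect_equal(find_best_boundary(c(1, 2, 3), c("A", "A", "A")), 1.5)
})

test_that("the MDL acceptance rule follows the description-length formula", {
  # perfectly separating split of A,A,B,B:
  # threshold = log2(3)/4 + (log2(7) - 2)/4 ~= 0.604 < gain 1.0
  expect_true(mdlp_accept(4, 1, 0, 0, 2, 1, 1, 2, 2))
  expect_false(mdlp_accept(4, 1, 1, 1, 2, 2, 2, 2, 2)) # zero gain
  expect_false(mdlp_accept(4, 0, 0, 0, 1, 1, 1, 2, 2)) # single class
  expect_false(mdlp_accept(1, 1, 0, 0, 2, 1, 1, 1, 0)) # n < 2
})

test_that("fitting finds exactly one boundary for a clean two-class feature", {
  ds <- one_feature_dataset(c(1, 2, 10, 11), c("A", "A", "B", "B"))
  cuts <- mdlp_fit(ds)
  expect_identical(lengths(cuts$cutpoints)[["F1"]], 1L)
  expect_equal(cuts$cutpoints$F1, 6)
})

test_that("constant features yield no boundary and code 0 everywhere", {
  ds <- make_dataset(
    cbind(F1 = c(3, 3, 3, 3), F2 = c(1, 2, 8, 9)),
    cbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 0L, 1L, 1L))
  )
  cuts <- mdlp_fit(ds)
  expect_identical(lengths(cuts$cutpoints)[["F1"]], 0L)
  coded <- mdlp_apply(cuts, ds)
  expect_true(all(coded$x[, "F1"] == 0L))
  expect_identical(sort(unique(coded$x[, "F2"])), c(0L, 1L))
})

test_that("label-independent features are rarely split", {
  accepted <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 500
    values <- runif(n)
    labels <- sample(c("A", "B"), n, replace = TRUE)
    length(oracle_mdlp_boundaries(values, labels)) > 0 ||
      length(mdlp_fit(one_feature_dataset(values, labels))$cutpoints$F1) > 0
  }, logical(1))
  expect_lt(mean(accepted), 0.1)
})

test_that("interval coding follows the half-open convention and clamps out-of-range values", {
  ds <- one_feature_dataset(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  cuts <- mdlp_fit(ds)
  expect_equal(cuts$cutpoints$F1, 2.5)
  q <- make_dataset(
    matrix(c(2.5, 2.6, -10, 99), ncol = 1, dimnames = list(NULL, "F1")),
    cbind(A = c(1L, 1L, 1L, 1L), pad_loc = c(0L, 0L, 0L, 0L))
  )
  coded <- mdlp_apply(cuts, q)
  expect_identical(as.integer(coded$x[, 1]), c(0L, 1L, 0L, 1L))
  expect_error(mdlp_apply(cuts, make_dataset(matrix(1, 1, 2), cbind(A = 1L, B = 1L))), "match")
})

test_that("fitted boundaries equal the exhaustive recursive oracle on random inputs", {
  for (seed in 1:40) {
    inp <- random_mdlp_input(seed)
    got <- mdlp_fit(one_feature_dataset(inp$values, inp$label_sets))$cutpoints$F1
    want <- oracle_mdlp_boundaries(inp$values, inp$label_sets)
    expect_equal(got, as.numeric(want), info = paste("seed", seed))
  }
})

test_that("removing the MDL stop never yields fewer boundaries, and coding is idempotent", {
  # without the MDL stop the recursion splits every sub-interval down to
  # single distinct values, i.e. exactly (#distinct values - 1) boundaries
  for (seed in 1:10) {
    inp <- random_mdlp_input(seed + 100)
    with_mdl <- length(oracle_mdlp_boundaries(inp$values, inp$label_sets))
    expect_lte(with_mdl, length(unique(inp$values)) - 1)
  }
  # idempotence: re-fitting and re-applying on already-coded data maps codes
  # to themselves
  inp <- random_mdlp_input(7)
  ds <- one_feature_dataset(inp$values, inp$label_sets)
  coded <- mdlp_apply(mdlp_fit(ds), ds)
  ds2 <- coded
  ds2$discrete <- FALSE # treat codes as plain numeric values
  coded2 <- mdlp_apply(mdlp_fit(ds2), ds2)
  expect_identical(coded2$x, coded$x)
})

test_that("cutpoint maps serialize to text and back exactly", {
  ds <- make_dataset(
    cbind(F1 = c(1, 2, 10, 11), F2 = rep(0.5, 4)),
    cbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 0L, 1L, 1L))
  )
  cuts <- mdlp_fit(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_cutpoints(cuts, path)
  cuts2 <- read_cutpoints(path)
  expect_identical(cuts2$cutpoints, cuts$cutpoints)
  expect_identical(cuts2$feature_names, cuts$feature_names)
  expect_equal(unname(cuts2$range), unname(cuts$range))
})
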
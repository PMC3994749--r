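test_that("example-based accuracy and F1 match their definitions", {
  truth <- rbind(c(1, 1), c(1, 1), c(1, 0))
  colnames(truth) <- c("cyt", "nuc")
  pred_exact <- truth
  expect_equal(multilabel_accuracy(truth, pred_exact), 1)
  expect_equal(multilabel_f1(truth, pred_exact), 1)

  pred <- rbind(c(1, 0), c(1, 1), c(0, 1))
  colnames(pred) <- c("cyt", "nuc")
  # terms: 1/2, 1, 0 and 2/3, 1, 0
  expect_equal(multilabel_accuracy(truth, pred), mean(c(0.5, 1, 0)))
  expect_equal(multilabel_f1(truth, pred), mean(c(2 / 3, 1, 0)))

  # the all-empty prediction contributes 0
  none <- matrix(0L, 3, 2, dimnames = list(NULL, c("cyt", "nuc")))
  expect_equal(multilabel_accuracy(truth, none), 0)
  expect_equal(multilabel_f1(truth, none), 0)
  expect_error(multilabel_accuracy(truth[0, ], none[0, ]), "Empty")
})

test_that("adapted per-location precision and recall follow the conditioning sets", {
  truth <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("cyt", "nuc")))
  pred <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("cyt", "nuc")))
  pr <- multilabel_pre_rec(truth, pred, "cyt")
  expect_equal(unname(pr), c(1, 0.5))
  # never-predicted location: precision undefined
  pr2 <- multilabel_pre_rec(truth, pred, "nuc")
  expect_true(is.na(pr2[["pre"]]))
  expect_equal(pr2[["rec"]], 0.5)
})

test_that("macro label F1 averages harmonic means over truly present locations", {
  # two locations with (pre, rec) = (1, 0.5) and (1, 1) -> (2/3 + 1)/2 = 5/6
  truth <- rbind(c(1, 1), c(0, 1))
  colnames(truth) <- c("a", "b")
  pred <- rbind(c(1, 1), c(0, 1))
  colnames(pred) <- c("a", "b")
  # construct: protein 1 {a,b} predicted {a,b}; protein 2 {b} predicted {b}
  # a: pre = 1, rec = 1; b: pre = mean(1, 1) = 1, rec = 1 -> F1-label 1
  expect_equal(f1_label(truth, pred), 1)
  pred2 <- rbind(c(1, 0), c(0, 1))
  colnames(pred2) <- c("a", "b")
  # a: pre = 1, rec = 1/2; b: pre = mean(1,1)=1, rec = mean(1/2, 1) = 3/4
  want <- mean(c(2 * 1 * 0.5 / 1.5, 2 * 1 * 0.75 / 1.75))
  expect_equal(f1_label(truth, pred2), want)
  # all-wrong predictions score 0
  pred3 <- rbind(c(0, 0), c(1, 0))
  colnames(pred3) <- c("a", "b")
  expect_equal(f1_label(truth, pred3), 0)
})

test_that("standard precision/recall come from the per-location confusion counts", {
  set.seed(77)
  p <- random_label_pairs(77, n = 40, q = 3)
  st <- standard_pre_rec(p$truth, p$pred, "s2")
  want <- oracle_std_pre_rec(
    sets_from_matrix(p$truth), sets_from_matrix(p$pred), "s2"
  )
  expect_equal(st, want)
  # worked example: TP=8, FP=2, FN=4
  truth <- matrix(c(rep(1, 12), rep(0, 4)), ncol = 1, dimnames = list(NULL, "s"))
  truth <- cbind(truth, pad = 1L)
  pred <- matrix(c(rep(1, 8), rep(0, 4), rep(1, 2), rep(0, 2)),
    ncol = 1,
    dimnames = list(NULL, "s")
  )
  pred <- cbind(pred, pad = 0L)
  st2 <- standard_pre_rec(truth, pred, "s")
  expect_equal(st2[["pre_std"]], 0.8)
  expect_equal(st2[["rec_std"]], 2 / 3)
})

test_that("all metrics match the naive set-arithmetic oracle on random label sets", {
  for (seed in 1:120) {
    p <- random_label_pairs(seed)
    ts <- sets_from_matrix(p$truth)
    ps <- sets_from_matrix(p$pred)
    ex <- oracle_example_metrics(ts, ps)
    expect_equal(multilabel_accuracy(p$truth, p$pred), ex[["acc"]])
    expect_equal(multilabel_f1(p$truth, p$pred), ex[["f1"]])
    expect_equal(f1_label(p$truth, p$pred), oracle_f1_label(ts, ps, p$locs))
    loc <- sample(p$locs, 1)
    expect_equal(
      unname(multilabel_pre_rec(p$truth, p$pred, loc)),
      unname(oracle_loc_pre_rec(ts, ps, loc))
    )
    expect_equal(
      unname(standard_pre_rec(p$truth, p$pred, loc)),
      unname(oracle_std_pre_rec(ts, ps, loc))
    )
    # F1 >= Acc on every input, and order invariance
    expect_gte(
      multilabel_f1(p$truth, p$pred),
      multilabel_accuracy(p$truth, p$pred)
    )
    perm <- sample(nrow(p$truth))
    expect_equal(
      multilabel_f1(p$truth[perm, , drop = FALSE], p$pred[perm, , drop = FALSE]),
      multilabel_f1(p$truth, p$pred)
    )
  }
})

test_that("macro label F1 on single-location two-class data equals binary macro-F1", {
  set.seed(5)
  n <- 60
  truth_lab <- sample(c("a", "b"), n, replace = TRUE)
  pred_lab <- ifelse(runif(n) < 0.75, truth_lab, sample(c("a", "b"), n, TRUE))
  to_mat <- function(lab) {
    cbind(a = as.integer(lab == "a"), b = as.integer(lab == "b"))
  }
  got <- f1_label(to_mat(truth_lab), to_mat(pred_lab))
  # standard macro-F1 from the two binary confusion matrices; with
  # single-label sets |M| = |M'| = 1, the adapted measures reduce to it
  macro <- mean(vapply(c("a", "b"), function(cl) {
    tp <- sum(truth_lab == cl & pred_lab == cl)
    fp <- sum(truth_lab != cl & pred_lab == cl)
    fn <- sum(truth_lab == cl & pred_lab != cl)
    pre <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * pre * rec / (pre + rec)
  }, numeric(1)))
  expect_equal(got, macro)
})

test_that("cross-validation predicts each record exactly once per run and is deterministic", {
  d <- sample_multiloc(dependency_spec(n = 120, seed = 71))
  cv1 <- cross_validate(d, runs = 1, folds = 2, seed = 5)
  expect_identical(nrow(cv1$metrics), 6L) # 2 systems x 3 metrics
  expect_true(all(cv1$metrics$value >= 0 & cv1$metrics$value <= 1))
  cv2 <- cross_validate(d, runs = 1, folds = 2, seed = 5)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$per_location, cv2$per_location)
  g <- glance(cv1)
  expect_identical(sort(g$system), c("baseline", "bn"))
})
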
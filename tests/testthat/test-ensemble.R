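test_that("objective score matches its closed form and stays in [0, 1]", {
  expect_equal(objective_score(c(0.9, 0.8), c(0.7, 0.6)), 0.75)
  expect_equal(objective_score(rep(1, 5), rep(1, 5)), 1)
  expect_equal(objective_score(rep(0, 4), rep(0, 4)), 0)
  expect_error(objective_score(c(0.5, 0.5), 0.5), "length")
  set.seed(10)
  for (i in 1:1000) {
    k <- sample(1:8, 1)
    a <- runif(k); f <- runif(k)
    s <- objective_score(a, f)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, mean((a + f) / 2))
  }
})

test_that("F1 is macro-averaged for multiclass and exact on identity", {
  y <- factor(rep(c("a", "b", "c"), times = c(5, 3, 2)))
  expect_equal(f1_score(y, y), 1)
  set.seed(2)
  for (i in 1:50) {
    truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 30, replace = TRUE)
    s <- f1_score(truth, pred)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # binary with HF positive equals the classic definition
  truth <- c("HF", "HF", "LF", "LF", "HF")
  pred <- c("HF", "LF", "LF", "HF", "HF")
  tp <- 2; fp <- 1; fn <- 1
  expect_equal(f1_score(truth, pred, positive = "HF"),
               2 * tp / (2 * tp + fp + fn))
})

test_that("subsample draws respect size and coverage guarantees", {
  sets <- draw_subsamples(10, r = 50, fraction = 0.9, seed = 1)
  expect_length(sets, 50)
  expect_true(all(vapply(sets, length, 0L) == 9))
  counts <- tabulate(unlist(sets), nbins = 10)
  expect_true(all(counts >= 25))

  full <- draw_subsamples(7, r = 4, fraction = 1, seed = 1)
  expect_true(all(vapply(full, identical, TRUE, 1:7)))

  expect_identical(draw_subsamples(20, 10, 0.8, seed = 5),
                   draw_subsamples(20, 10, 0.8, seed = 5))
  expect_error(draw_subsamples(10, r = 50, fraction = 0.3), "infeasible")

  set.seed(99)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    r <- sample(3:20, 1)
    s <- draw_subsamples(n, r, 0.9, seed = i)
    expect_true(all(tabulate(unlist(s), nbins = n) >= ceiling(r / 2)))
  }
})

test_that("stratified folds partition exactly and preserve class ratios", {
  set.seed(4)
  y <- factor(sample(c("HF", "LF"), 120, replace = TRUE, prob = c(0.83, 0.17)))
  k <- 5
  folds <- stratified_folds(y, k, seed = 2)
  expect_setequal(unique(folds), 1:k)
  expect_equal(length(folds), length(y))
  for (i in 1:k) {
    for (cl in levels(y)) {
      expected <- sum(y == cl) / k
      expect_lte(abs(sum(y[folds == i] == cl) - expected), 1)
    }
  }
  expect_error(stratified_folds(factor(c("a", "a", "b")), 3, 1), "fewer than k")
})

test_that("majority vote equals brute-force mode on all small patterns", {
  lev3 <- c("a", "b", "c")
  for (r in 1:5) {
    patterns <- do.call(expand.grid, rep(list(1:3), r))
    for (p in seq_len(nrow(patterns))) {
      votes_raw <- as.integer(patterns[p, ])
      votes <- matrix(tabulate(votes_raw, nbins = 3), nrow = 1,
                      dimnames = list(NULL, lev3))
      # strictly ranked tie-break probabilities: a > b > c
      psum <- matrix(c(3, 2, 1), nrow = 1, dimnames = list(NULL, lev3))
      got <- as.character(bovinecall:::majority_vote(votes, psum, lev3))
      counts <- tabulate(votes_raw, nbins = 3)
      top <- which(counts == max(counts))
      expected <- lev3[top[1]]  # psum ranking = lexicographic here
      expect_identical(got, expected)
    }
  }
  # stated tie policy: summed probability decides a split vote
  votes <- matrix(c(1L, 1L), nrow = 1, dimnames = list(NULL, c("HF", "LF")))
  psum <- matrix(c(1.3, 0.7), nrow = 1, dimnames = list(NULL, c("HF", "LF")))
  expect_identical(as.character(bovinecall:::majority_vote(votes, psum,
                                                           c("HF", "LF"))),
                   "HF")
})

test_that("base-model search returns three strong families on separable data", {
  tb <- separable_table(n = 90)
  searched <- search_base_models(tb$x, tb$y, control = fast_ctrl(), seed = 3)
  expect_length(searched, 3)
  expect_setequal(names(searched), c("rf", "glmnet", "knn"))
  for (fam in searched) expect_gte(fam$score, 0.95)
  again <- search_base_models(tb$x, tb$y, control = fast_ctrl(), seed = 3)
  expect_identical(lapply(searched, `[[`, "config"),
                   lapply(again, `[[`, "config"))
})

test_that("a stacking instance is leakage-safe, normalized, and accurate", {
  tb <- separable_table(n = 140)
  tr <- 1:100; te <- 101:140
  inst <- fit_instance(tb$x[tr, ], tb$y[tr], control = fast_ctrl(), seed = 5)
  p <- bovinecall:::instance_proba(inst, tb$x[te, ])
  expect_equal(ncol(p), nlevels(tb$y))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  pred <- colnames(p)[max.col(p)]
  expect_gte(mean(pred == tb$y[te]), 0.95)
})

test_that("the bagged ensemble votes at least as well as its instances", {
  tb <- separable_table(n = 140, gap = 3)
  tr <- 1:100; te <- 101:140
  fit <- fit_ensemble(tb$x[tr, ], tb$y[tr], r = 3, control = fast_ctrl(),
                      seed = 11)
  expect_length(fit$instances, 3)
  inst_acc <- vapply(fit$instances, function(inst) {
    p <- bovinecall:::instance_proba(inst, tb$x[te, ])
    mean(colnames(p)[max.col(p)] == tb$y[te])
  }, 0)
  ens_acc <- mean(predict(fit, tb$x[te, ]) == tb$y[te])
  expect_gte(ens_acc, max(inst_acc) - 0.05)

  # determinism and instance-order invariance
  fit2 <- fit_ensemble(tb$x[tr, ], tb$y[tr], r = 3, control = fast_ctrl(),
                       seed = 11)
  expect_identical(predict(fit, tb$x[te, ]), predict(fit2, tb$x[te, ]))
  fit3 <- fit
  fit3$instances <- rev(fit3$instances)
  expect_identical(predict(fit, tb$x[te, ]), predict(fit3, tb$x[te, ]))

  expect_error(predict(fit, tb$x[te, 1:3]), "columns")
})

test_that("k-fold harness beats the majority-class baseline on separable data", {
  tb <- separable_table(n = 120, gap = 4)
  res <- evaluate_stratified_kfold(tb, k = 5, r = 2, control = fast_ctrl(),
                                   seed = 8)
  expect_equal(nrow(res$folds), 5)
  baseline <- max(table(tb$y)) / length(tb$y)
  expect_gte(res$test_mean, baseline + 0.2)
  expect_gte(res$train_mean, res$test_mean - 0.05)
})

test_that("importance normalizes to 100% and finds the informative feature", {
  tb <- separable_table(n = 100, m = 5, gap = 5)
  imp <- leave_one_feature_out_importance(tb, k = 3, r = 1,
                                          control = fast_ctrl(), seed = 13)
  expect_equal(sum(imp$profile$importance_pct), 100, tolerance = 0.01)
  expect_identical(imp$profile$feature[1], "f1")
})
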
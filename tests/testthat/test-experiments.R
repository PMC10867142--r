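test_that("experiments run end to end and write self-consistent outputs", {
  corpus <- tiny_corpus()
  out <- withr::local_tempdir()
  suppressMessages(
    exp1 <- run_experiment(corpus$recordings, task = "callclass",
                           model = "explainable", k = 3, r = 1,
                           control = fast_ctrl(), seed = 7, out_dir = out)
  )
  expect_s3_class(exp1$result, "experiment_result")
  expect_equal(nrow(exp1$result$folds), 3)
  expect_true(file.exists(file.path(out, "callclass_ALL_explainable_result.csv")))
  js <- jsonlite::read_json(file.path(out, "callclass_ALL_explainable_result.json"))
  expect_equal(js$n_calls, exp1$n_calls)
  expect_equal(js$test_mean, exp1$result$test_mean, tolerance = 1e-12)

  tab <- report_results(exp1)
  expect_equal(names(tab), c("dataset", "model", "train_acc_mean",
                             "train_acc_sd", "test_acc_mean", "test_acc_sd"))
  expect_equal(tab$model, "explainable")

  # determinism of a repeated run
  suppressMessages(
    exp2 <- run_experiment(corpus$recordings, task = "callclass",
                           model = "explainable", k = 3, r = 1,
                           control = fast_ctrl(), seed = 7)
  )
  expect_identical(exp1$result$folds, exp2$result$folds)
})

test_that("identification subsetting drops under-represented cows, not runs", {
  corpus <- demo_corpus()
  types <- vapply(corpus$recordings, `[[`, "", "call_type")
  cows <- vapply(corpus$recordings, `[[`, "", "cow_id")
  lf_counts <- as.integer(table(factor(cows[types == "LF"],
                                       levels = unique(cows))))
  # smallest k that excludes at least one cow while two or more survive
  ks <- setdiff(sort(unique(lf_counts + 1L)), 1L)
  k <- NA_integer_
  for (cand in ks) {
    if (any(lf_counts < cand) && sum(lf_counts >= cand) >= 2 && cand >= 2) {
      k <- cand
      break
    }
  }
  expect_false(is.na(k))  # the drawn corpus has unequal LF counts per cow
  suppressMessages(
    exp <- run_experiment(corpus$recordings, task = "identification",
                          subset = "LF", model = "explainable", k = k,
                          r = 1, control = fast_ctrl(),
                          features = demo_features(), seed = 3)
  )
  expect_gte(length(exp$dropped), 1)
  expect_lte(exp$n_calls, sum(types == "LF"))
  expect_equal(nrow(exp$result$folds), k)
})

test_that("the importance profile is exported sorted with percents", {
  tb <- separable_table(n = 80, m = 4, gap = 5)
  imp <- leave_one_feature_out_importance(tb, k = 3, r = 1,
                                          control = fast_ctrl(), seed = 2)
  expect_true(all(diff(imp$profile$importance_pct) <= 0))
  expect_equal(sum(imp$profile$importance_pct), 100, tolerance = 0.01)
})
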
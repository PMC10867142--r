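#' Fold-averaged accuracy + F1 objective
#'
#' The model-selection objective: `sum_i (a_i + f_i) / (2k)` over k folds,
#' where `a_i` and `f_i` are the i-th fold's accuracy and F1 score. It is 1
#' for a perfect classifier and is maximized.
#'
#' @param a,f Numeric vectors of per-fold accuracies and F1 scores in
#'   `[0, 1]`, same length.
#' @return The objective value in `[0, 1]`.
#' @export
objective_score <- function(a, f) {
  if (length(a) != length(f)) {
    stop("objective_score: accuracy and F1 vectors differ in length")
  }
  if (length(a) < 1) stop("objective_score: need at least one fold")
  stopifnot(all(a >= 0 & a <= 1), all(f >= 0 & f <= 1))
  sum(a + f) / (2 * length(a))
}

#' F1 score (binary with a chosen positive class, or macro-averaged)
#'
#' With exactly two classes and `positive` given, the classic binary F1 of
#' the positive class; otherwise the unweighted mean of per-class F1 scores
#' (macro F1), with classes never predicted and never present contributing 0
#' only when present in truth.
#'
#' @param truth,pred Factors (or vectors) of true and predicted labels.
#' @param positive Optional positive-class label for the binary case.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  per_class <- function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  if (!is.null(positive)) return(per_class(positive))
  mean(vapply(sort(unique(truth)), per_class, 0))
}

# Positive class convention: HF for the binary call-type task, else macro.
default_positive <- function(levels) {
  if (length(levels) == 2 && "HF" %in% levels) "HF" else NULL
}

#' Assemble a feature table for classification
#'
#' @param features data.frame from [extract_feature_table()] (or any frame
#'   with the 23 feature columns).
#' @param target `"call_type"` or `"cow_id"`.
#' @param feature_cols Feature column names (defaults to the 23 canonical).
#' @return List of class `feature_table`: `x` (numeric matrix), `y` (factor),
#'   `row_ids`, `feature_names`, `target`.
#' @export
feature_table <- function(features, target = c("call_type", "cow_id"),
                          feature_cols = vocal_feature_names) {
  target <- match.arg(target)
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature_table: missing values; filter flagged rows first")
  y <- factor(features[[target]])
  if (nlevels(y) < 2) stop("feature_table: need at least two classes")
  structure(list(x = x, y = y,
                 row_ids = features$call_id %||% as.character(seq_len(nrow(x))),
                 feature_names = feature_cols, target = target),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d calls x %d features, target %s (%d classes)\n",
              nrow(x$x), ncol(x$x), x$target, nlevels(x$y)))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals indices round-robin, so every fold's
#' class proportions match the global ones within one sample.
#'
#' @param y Factor of labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), same length as `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  small <- table(y) < k
  if (any(small)) {
    stop("stratified folds: class(es) with fewer than k members: ",
         paste(names(which(small)), collapse = ", "))
  }
  folds <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Draw bootstrap subsamples with a coverage guarantee
#'
#' `r` subsets of size `ceiling(fraction * n)` drawn without replacement,
#' repaired so that every index appears in at least `ceiling(r / 2)` subsets.
#'
#' @param n Number of training rows.
#' @param r Number of subsamples. With `r = 1` the coverage constraint forces
#'   the single subset to be the full index range, whatever `fraction` says.
#' @param fraction Fraction of rows per subsample.
#' @param seed Integer seed.
#' @return List of `r` integer index vectors.
#' @export
draw_subsamples <- function(n, r = 50, fraction = 0.9, seed = 1) {
  stopifnot(n >= 2, fraction > 0, fraction <= 1, r >= 1)
  if (r == 1) return(list(seq_len(n)))
  size <- ceiling(fraction * n)
  need <- ceiling(r / 2)
  if (size * r < need * n) {
    stop("draw_subsamples: coverage constraint infeasible (fraction too small)")
  }
  with_seed(derive_seed(seed, "subsamples"), {
    sets <- lapply(seq_len(r), function(i) sort(sample.int(n, size)))
    repeat {
      counts <- tabulate(unlist(sets), nbins = n)
      deficient <- which(counts < need)
      if (length(deficient) == 0) break
      i <- deficient[1]
      # swap i into a subset it is missing from, evicting a over-covered index
      for (s in seq_len(r)) {
        if (i %in% sets[[s]]) next
        evictable <- sets[[s]][counts[sets[[s]]] > need]
        if (length(evictable) == 0) next
        out <- evictable[which.max(counts[evictable])]
        sets[[s]] <- sort(c(setdiff(sets[[s]], out), i))
        counts[out] <- counts[out] - 1L
        counts[i] <- counts[i] + 1L
        if (counts[i] >= need) break
      }
    }
    sets
  })
}

# ---------------------------------------------------------------------------
# Base model families

#' Search-grid control for the stacked ensemble
#'
#' Holds the hyperparameter grids searched for the three base families and
#' the gradient-boosted meta-learner, plus the inner-CV fold count. The
#' `preset` `"default"` uses the full meta grid (depth 2/3/4, learning rate
#' 0.05/0.1/0.3, 50/100/200 trees); `"fast"` is a reduced search for
#' desk-scale experiments.
#'
#' @param preset `"default"` or `"fast"`.
#' @param k_inner Inner stratified CV folds used for scoring configurations.
#' @return List of class `ensemble_control`.
#' @export
ensemble_control <- function(preset = c("default", "fast"), k_inner = NULL) {
  preset <- match.arg(preset)
  ctrl <- if (preset == "default") {
    list(
      k_inner = 5L,
      rf_grid = expand.grid(num_trees = 200, min_node = c(1, 5)),
      glmnet_grid = expand.grid(alpha = c(0, 1), lambda = c(0.01, 0.001)),
      knn_grid = expand.grid(k = c(3, 5, 7)),
      meta_grid = expand.grid(max_depth = c(2, 3, 4), eta = c(0.05, 0.1, 0.3),
                              nrounds = c(50, 100, 200))
    )
  } else {
    list(
      k_inner = 3L,
      rf_grid = expand.grid(num_trees = 150, min_node = 1),
      glmnet_grid = expand.grid(alpha = 0, lambda = 0.001),
      knn_grid = expand.grid(k = c(5)),
      meta_grid = expand.grid(max_depth = c(2, 3), eta = 0.3, nrounds = 50)
    )
  }
  if (!is.null(k_inner)) ctrl$k_inner <- as.integer(k_inner)
  ctrl$preset <- preset
  structure(ctrl, class = "ensemble_control")
}

# Fit one configuration of one family; returns an object with a
# predict_proba(x) method returning an n x nlevels matrix (columns = levels).
fit_base <- function(family, config, x, y, seed) {
  lev <- levels(y)
  obj <- switch(family,
    rf = {
      fit <- ranger::ranger(
        x = x, y = y, probability = TRUE,
        num.trees = config$num_trees, min.node.size = config$min_node,
        seed = derive_seed(seed, "rf"), num.threads = 1
      )
      list(kind = "rf", fit = fit)
    },
    glmnet = {
      fam <- if (length(lev) == 2) "binomial" else "multinomial"
      fit <- glmnet::glmnet(x, y, family = fam, alpha = config$alpha,
                            lambda = config$lambda)
      list(kind = "glmnet", fit = fit, lambda = config$lambda)
    },
    knn = {
      mu <- colMeans(x)
      sg <- apply(x, 2, stats::sd)
      sg[sg == 0] <- 1
      list(kind = "knn", k = config$k, mu = mu, sg = sg,
           xs = sweep(sweep(x, 2, mu), 2, sg, "/"), y = y)
    },
    stop("unknown base family: ", family)
  )
  obj$levels <- lev
  obj$family <- family
  obj$config <- config
  class(obj) <- "bovine_base_model"
  obj
}

predict_proba <- function(object, x) UseMethod("predict_proba")

#' @export
predict_proba.bovine_base_model <- function(object, x) {
  lev <- object$levels
  p <- switch(object$kind,
    rf = {
      pr <- stats::predict(object$fit, data = x, num.threads = 1)$predictions
      pr[, lev, drop = FALSE]
    },
    glmnet = {
      pr <- stats::predict(object$fit, newx = x, s = object$lambda,
                           type = "response")
      if (length(lev) == 2) {
        cbind(1 - pr[, 1], pr[, 1])  # glmnet models P(second level)
      } else {
        pr[, , 1][, lev, drop = FALSE]
      }
    },
    knn = {
      xs <- sweep(sweep(x, 2, object$mu), 2, object$sg, "/")
      d2 <- outer(rowSums(xs^2), rowSums(object$xs^2), "+") -
        2 * xs %*% t(object$xs)
      t(apply(d2, 1, function(row) {
        nb <- object$y[order(row)[seq_len(object$k)]]
        tabulate(nb, nbins = length(lev)) / object$k
      }))
    }
  )
  p <- matrix(p, nrow = nrow(x))
  colnames(p) <- lev
  # guard against numerical drift
  p / pmax(rowSums(p), 1e-12)
}

# Score one family's configurations by the objective under stratified
# inner CV; returns the best config refit on all data.
search_family <- function(family, grid, x, y, k_inner, seed) {
  folds <- stratified_folds(y, k_inner, derive_seed(seed, "inner", family))
  pos <- default_positive(levels(y))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    config <- grid[g, , drop = FALSE]
    a <- f <- numeric(k_inner)
    for (i in seq_len(k_inner)) {
      tr <- folds != i
      fit <- fit_base(family, config, x[tr, , drop = FALSE],
                      droplevels(y[tr]), derive_seed(seed, family, g, i))
      p <- predict_proba(fit, x[!tr, , drop = FALSE])
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      a[i] <- mean(pred == y[!tr])
      f[i] <- f1_score(y[!tr], pred, positive = pos)
    }
    objective_score(a, f)
  }, 0)
  best <- which.max(scores)
  list(model = fit_base(family, grid[best, , drop = FALSE], x, y,
                        derive_seed(seed, family, "final")),
       config = grid[best, , drop = FALSE],
       score = scores[best])
}

#' Search the three base-model families
#'
#' For each of three disjoint families (tree ensemble; regularized linear;
#' k-nearest-neighbour), a small hyperparameter grid is scored by
#' [objective_score()] under stratified inner cross-validation, and the best
#' configuration is refit on the full training data.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of labels (each class needs `k_inner` members).
#' @param control An [ensemble_control()].
#' @param seed Integer seed.
#' @return List of three fitted base models (classes `rf`, `glmnet`, `knn`).
#' @export
search_base_models <- function(x, y, control = ensemble_control(), seed = 1) {
  grids <- list(rf = control$rf_grid, glmnet = control$glmnet_grid,
                knn = control$knn_grid)
  lapply(stats::setNames(names(grids), names(grids)), function(fam) {
    search_family(fam, grids[[fam]], x, y, control$k_inner, seed)
  })
}

# ---------------------------------------------------------------------------
# Stacking instance: three bases + gradient-boosted meta-learner

xgb_fit <- function(meta_x, y, config, seed) {
  xgboost::xgboost(meta_x, y, nrounds = config$nrounds,
                   max_depth = config$max_depth,
                   learning_rate = config$eta,
                   nthreads = 1, seed = derive_seed(seed, "xgb") %% 2^31,
                   verbosity = 0)
}

xgb_proba <- function(fit, meta_x, lev) {
  pr <- stats::predict(fit, meta_x)
  if (length(lev) == 2) {
    # binary boosters predict the probability of the second factor level
    p <- cbind(1 - pr, pr)
    colnames(p) <- lev
  } else {
    p <- pr[, lev, drop = FALSE]
  }
  p
}

#' Fit one stacking instance
#'
#' Searches the three base families on the training rows, builds a
#' leakage-safe meta training set from out-of-fold base class-probability
#' predictions, tunes a gradient-boosted tree meta-learner over
#' `control$meta_grid` by the fold-averaged accuracy+F1 objective, and refits
#' it on the full meta set.
#'
#' @inheritParams search_base_models
#' @return List of class `ensemble_instance`: `bases`, `meta`, `levels`,
#'   `meta_config`.
#' @export
fit_instance <- function(x, y, control = ensemble_control(), seed = 1) {
  y <- droplevels(factor(y))
  lev <- levels(y)
  searched <- search_base_models(x, y, control, seed)
  bases <- lapply(searched, `[[`, "model")

  # out-of-fold meta features
  k <- control$k_inner
  folds <- stratified_folds(y, k, derive_seed(seed, "oof"))
  meta_x <- matrix(NA_real_, nrow = nrow(x), ncol = 3 * length(lev))
  for (i in seq_len(k)) {
    tr <- folds != i
    cols <- 0
    for (fam in names(bases)) {
      fit <- fit_base(fam, searched[[fam]]$config, x[tr, , drop = FALSE],
                      droplevels(y[tr]), derive_seed(seed, "oof", fam, i))
      p <- predict_proba(fit, x[!tr, , drop = FALSE])
      full <- matrix(0, nrow = sum(!tr), ncol = length(lev),
                     dimnames = list(NULL, lev))
      full[, colnames(p)] <- p
      meta_x[!tr, cols + seq_len(length(lev))] <- full
      cols <- cols + length(lev)
    }
  }

  # grid-search the meta-learner under the objective
  pos <- default_positive(lev)
  mfolds <- stratified_folds(y, k, derive_seed(seed, "metacv"))
  mscores <- vapply(seq_len(nrow(control$meta_grid)), function(g) {
    config <- control$meta_grid[g, , drop = FALSE]
    a <- f <- numeric(k)
    for (i in seq_len(k)) {
      tr <- mfolds != i
      fit <- xgb_fit(meta_x[tr, , drop = FALSE], droplevels(y[tr]), config,
                     derive_seed(seed, "meta", g, i))
      p <- xgb_proba(fit, meta_x[!tr, , drop = FALSE], lev)
      pred <- lev[max.col(p, ties.method = "first")]
      a[i] <- mean(pred == y[!tr])
      f[i] <- f1_score(y[!tr], pred, positive = pos)
    }
    objective_score(a, f)
  }, 0)
  best <- control$meta_grid[which.max(mscores), , drop = FALSE]
  meta <- xgb_fit(meta_x, y, best, derive_seed(seed, "meta", "final"))

  structure(list(bases = bases, meta = meta, levels = lev,
                 meta_config = best),
            class = "ensemble_instance")
}

instance_proba <- function(instance, x) {
  lev <- instance$levels
  meta_x <- do.call(cbind, lapply(instance$bases, function(b) {
    p <- predict_proba(b, x)
    full <- matrix(0, nrow = nrow(x), ncol = length(lev),
                   dimnames = list(NULL, lev))
    full[, colnames(p)] <- p
    full
  }))
  xgb_proba(instance$meta, meta_x, lev)
}

#' Fit the bagged stacking ensemble
#'
#' The full explainable classifier: `r` stacking instances, each trained on a
#' coverage-guaranteed subsample of `fraction` of the training rows (see
#' [draw_subsamples()]); prediction is by majority vote across instances.
#'
#' @param x Numeric feature matrix (rows = calls, columns = features).
#' @param y Factor of labels (`call_type` or `cow_id`).
#' @param r Number of bagged instances.
#' @param fraction Subsample fraction per instance.
#' @param control An [ensemble_control()].
#' @param seed Integer seed for the whole fit.
#' @return Object of class `bovine_ensemble` with [predict.bovine_ensemble()],
#'   `print` and `summary` methods.
#' @export
fit_ensemble <- function(x, y, r = 50, fraction = 0.9,
                         control = ensemble_control(), seed = 1) {
  y <- droplevels(factor(y))
  stopifnot(nrow(x) == length(y))
  sets <- draw_subsamples(nrow(x), r = r, fraction = fraction,
                          seed = derive_seed(seed, "bags"))
  instances <- lapply(seq_len(r), function(i) {
    idx <- sets[[i]]
    fit_instance(x[idx, , drop = FALSE], y[idx], control,
                 seed = derive_seed(seed, "instance", i))
  })
  structure(list(instances = instances, levels = levels(y), r = r,
                 fraction = fraction, feature_names = colnames(x),
                 control_preset = control$preset, seed = seed),
            class = "bovine_ensemble")
}

#' Predict from a bagged stacking ensemble
#'
#' Majority vote over the `r` instances; ties are broken by the highest
#' probability summed across instances, then lexicographic label order.
#'
#' @param object A [fit_ensemble()] model.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param type `"class"` for labels, `"votes"` for the vote-count matrix,
#'   `"prob"` for mean instance probabilities.
#' @param ... Unused.
#' @return Factor of predicted labels (or a matrix for the other types).
#' @export
predict.bovine_ensemble <- function(object, newdata, type = c("class", "votes", "prob"),
                                    ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names)) {
    stop("predict: newdata has ", ncol(newdata), " columns; model expects ",
         length(object$feature_names))
  }
  lev <- object$levels
  votes <- matrix(0L, nrow = nrow(newdata), ncol = length(lev),
                  dimnames = list(NULL, lev))
  psum <- matrix(0, nrow = nrow(newdata), ncol = length(lev),
                 dimnames = list(NULL, lev))
  for (inst in object$instances) {
    p <- instance_proba(inst, newdata)
    pred <- max.col(p, ties.method = "first")
    votes[cbind(seq_len(nrow(newdata)), pred)] <-
      votes[cbind(seq_len(nrow(newdata)), pred)] + 1L
    psum <- psum + p
  }
  if (type == "votes") return(votes)
  if (type == "prob") return(psum / length(object$instances))
  majority_vote(votes, psum, lev)
}

# Majority vote over instance predictions; ties broken by the highest
# probability summed across instances, then lexicographic label order.
majority_vote <- function(votes, psum, lev) {
  lab <- vapply(seq_len(nrow(votes)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      top <- top[order(-psum[i, top], lev[top])][1]
    }
    lev[top]
  }, "")
  factor(lab, levels = lev)
}

#' @export
print.bovine_ensemble <- function(x, ...) {
  cat(sprintf("bovine_ensemble: %d bagged stacking instances (%.0f%% subsamples), %d classes: %s\n",
              x$r, 100 * x$fraction, length(x$levels),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
summary.bovine_ensemble <- function(object, ...) {
  metas <- do.call(rbind, lapply(object$instances, `[[`, "meta_config"))
  cat(sprintf("bovine_ensemble (%d instances, %d classes)\n",
              object$r, length(object$levels)))
  cat("meta-learner configurations selected:\n")
  print(stats::aggregate(list(n = seq_len(nrow(metas))), by = metas, FUN = length))
  invisible(object)
}

# ---------------------------------------------------------------------------
# Evaluation harness

#' Stratified k-fold evaluation of the stacked ensemble
#'
#' Splits the table into stratified folds (class ratios preserved within one
#' sample per fold), fits a bagged ensemble on each training part and records
#' train and test accuracy.
#'
#' @param table A [feature_table()].
#' @param k Number of folds.
#' @param r Bagged instances per fold model.
#' @param control An [ensemble_control()].
#' @param seed Integer seed.
#' @return Object of class `experiment_result`: per-fold accuracies plus
#'   mean and SD of each.
#' @export
evaluate_stratified_kfold <- function(table, k = 5, r = 50,
                                      control = ensemble_control(), seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  folds <- stratified_folds(table$y, k, derive_seed(seed, "outer"))
  train_acc <- test_acc <- numeric(k)
  for (i in seq_len(k)) {
    tr <- folds != i
    fit <- fit_ensemble(table$x[tr, , drop = FALSE], table$y[tr], r = r,
                        control = control, seed = derive_seed(seed, "fold", i))
    train_acc[i] <- mean(predict(fit, table$x[tr, , drop = FALSE]) == table$y[tr])
    test_acc[i] <- mean(predict(fit, table$x[!tr, , drop = FALSE]) == table$y[!tr])
  }
  experiment_result(train_acc, test_acc, k = k,
                    task = table$target, model = "explainable")
}

#' Construct an experiment result
#'
#' @param train_acc,test_acc Per-fold accuracies.
#' @param k Fold count.
#' @param task,model Descriptors for reporting.
#' @return Object of class `experiment_result`.
#' @export
experiment_result <- function(train_acc, test_acc, k = length(train_acc),
                              task = "", model = "") {
  structure(list(
    folds = data.frame(fold = seq_along(train_acc),
                       train_acc = train_acc, test_acc = test_acc),
    train_mean = mean(train_acc), train_sd = stats::sd(train_acc),
    test_mean = mean(test_acc), test_sd = stats::sd(test_acc),
    k = k, task = task, model = model
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("%s / %s, k = %d folds\n", x$task, x$model, x$k))
  cat(sprintf("  train accuracy: %.1f +/- %.1f %%\n",
              100 * x$train_mean, 100 * x$train_sd))
  cat(sprintf("  test accuracy:  %.1f +/- %.1f %%\n",
              100 * x$test_mean, 100 * x$test_sd))
  invisible(x)
}

#' Leave-one-feature-out importance profile
#'
#' Reference performance is the mean k-fold test accuracy with all features;
#' each feature's raw importance is the (non-negative) accuracy drop when
#' that one feature is removed, normalized to percentages summing to 100
#' (uniform if no feature matters).
#'
#' @inheritParams evaluate_stratified_kfold
#' @return Object of class `importance_profile`: data.frame of `feature`,
#'   `importance_pct`, `acc_without`, plus the reference accuracy.
#' @export
leave_one_feature_out_importance <- function(table, k = 5, r = 50,
                                             control = ensemble_control(),
                                             seed = 1) {
  stopifnot(inherits(table, "feature_table"), ncol(table$x) >= 2)
  ref <- evaluate_stratified_kfold(table, k = k, r = r, control = control,
                                   seed = seed)
  m <- ncol(table$x)
  acc_without <- vapply(seq_len(m), function(j) {
    tbl_j <- table
    tbl_j$x <- table$x[, -j, drop = FALSE]
    tbl_j$feature_names <- table$feature_names[-j]
    evaluate_stratified_kfold(tbl_j, k = k, r = r, control = control,
                              seed = seed)$test_mean
  }, 0)
  raw <- pmax(0, ref$test_mean - acc_without)
  pct <- if (sum(raw) > 0) 100 * raw / sum(raw) else rep(100 / m, m)
  df <- data.frame(feature = table$feature_names,
                   importance_pct = pct, acc_without = acc_without,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$importance_pct), ]
  rownames(df) <- NULL
  structure(list(profile = df, reference_acc = ref$test_mean, k = k),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, n = 10, ...) {
  cat(sprintf("leave-one-feature-out importance (reference accuracy %.1f%%)\n",
              100 * x$reference_acc))
  print(utils::head(x$profile, n))
  invisible(x)
}
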
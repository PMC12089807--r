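test_that("one-vs-rest targets partition the cohort", {
  lab <- trajectory_classes()
  tg <- make_binary_targets(lab)
  expect_equal(tg$good_prognosis, c(1L, 0L, 0L, 0L))
  expect_equal(Reduce(`+`, tg), rep(1L, 4))
  # degenerate all-same-class input
  tg2 <- make_binary_targets(rep("persistent_course", 5))
  expect_equal(tg2$persistent_course, rep(1L, 5))
  expect_equal(tg2$good_prognosis, rep(0L, 5))
  expect_error(make_binary_targets(c("good_prognosis", "typo")), "unseen")
  counts <- c(155, 174, 85, 369)
  tg3 <- make_binary_targets(rep(trajectory_classes(), counts))
  expect_equal(vapply(tg3, sum, integer(1)), counts, ignore_attr = TRUE)
})

test_that("metrics match hand-computed values", {
  # identity prediction
  m <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(m$f1, 1)
  expect_equal(m$accuracy, 1)
  # TP=2 FP=1 FN=1 TN=6 from the definitions
  yt <- c(rep(1, 3), rep(0, 7))
  yp <- c(1, 1, 0, 1, rep(0, 6))
  m2 <- compute_metrics(yt, yp)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$f1, 2 / 3)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(rowSums(m2$confusion), c(`0` = 1, `1` = 1))
  # F1 = 0 when precision + recall = 0
  expect_equal(compute_metrics(c(1, 1, 0), c(0, 0, 0))$f1, 0)
  # constant scores: AUROC 0.5 by symmetry
  m3 <- compute_metrics(c(0, 1, 0, 1), c(0, 0, 0, 0), rep(0.5, 4))
  expect_equal(m3$auroc, 0.5)
  # single-class truth: score metrics flagged missing, not zero
  m4 <- compute_metrics(c(1, 1, 1), c(1, 0, 1), c(0.9, 0.1, 0.8))
  expect_true(is.na(m4$auroc) && is.na(m4$auprc))
  expect_false(m4$score_metrics_defined)
})

test_that("AUROC and AUPRC agree with independent implementations", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(120, 1, 0.3)
  sc <- rnorm(120) + y
  m <- compute_metrics(y, as.integer(sc > 0.5), sc)
  expect_equal(m$auroc,
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-10)
  # AUPRC oracle: direct average of precision at each positive, by rank
  ord <- order(sc, decreasing = TRUE)
  ys <- y[ord]
  ap <- sum((cumsum(ys) / seq_along(ys))[ys == 1]) / sum(ys)
  expect_equal(m$auprc, ap, tolerance = 1e-10)
})

test_that("TPE is deterministic, handles singleton spaces, and logs trials", {
  space <- fixed_point_space()
  d <- separable_data(n = 80, seed = 1)
  res <- tune_hyperparameters(d$x, d$y, space, inner_folds = 3, seed = 4)
  expect_equal(nrow(res$trials), 1L)  # degenerate space: one evaluation
  expect_equal(res$best_params$splitrule, "gini")
  # seeded determinism of the full trial sequence
  sp2 <- tiny_space(n_evaluations = 6L)
  r1 <- tune_hyperparameters(d$x, d$y, sp2, inner_folds = 3, seed = 11)
  r2 <- tune_hyperparameters(d$x, d$y, sp2, inner_folds = 3, seed = 11)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 6L)
  expect_equal(max(r1$trials$objective), r1$best_value)
  expect_error(tune_hyperparameters(d$x, rep(1L, 80), sp2), "single class")
})

test_that("TPE keeps pace with random search on a planted objective", {
  # deterministic objective on the space, so the comparison isolates the
  # proposal strategy: a peaked function of max_features and max_depth
  params <- hyperparameter_space()$params
  objective <- function(p)
    -((p$max_features - 0.62)^2) - ((p$max_depth - 20) / 32)^2 -
      0.1 * (p$splitrule != "gini")
  wins <- 0
  for (s in 1:10) {
    tpe <- tpe_optimize(objective, params, n_eval = 30, seed = s,
                        n_startup = 8)
    rnd <- with_seed <- local({
      set.seed(s + 1000)
      vals <- replicate(30, objective(trajmix:::sample_uniform(params)))
      max(vals)
    })
    if (tpe$best_value >= rnd) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("nested CV separates separable data and honours its contracts", {
  d <- separable_data(n = 150, p = 6, seed = 3, gap = 4)
  plan <- cv_plan(outer_folds = 3, outer_repeats = 2, inner_folds = 3,
                  seed = 5)
  cv <- nested_cv_evaluate(d$x, d$y, plan = plan,
                           space = tiny_space(n_evaluations = 3L))
  expect_gte(cv$aggregate$mean[cv$aggregate$metric == "f1"], 0.95)
  expect_true(all(cv$folds$f1 >= 0 & cv$folds$f1 <= 1))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  expect_equal(unname(rowSums(cv$confusion)), c(1, 1), tolerance = 1e-10)
  # every participant appears in exactly one outer test fold per repeat
  for (r in 1:2) {
    te <- sort(unlist(cv$fold_assignments[cv$folds$repeat_id == r]))
    expect_equal(te, seq_len(150))
  }
  # stratification: per-fold positive fraction within 5pp of global
  pos_frac <- cv$folds$n_pos / cv$folds$n_test
  expect_true(all(abs(pos_frac - 0.5) <= 0.05))
})

test_that("outer folds with no positives are skipped with a warning", {
  set.seed(2)
  x <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
  y <- c(rep(1L, 3), rep(0L, 57))
  plan <- cv_plan(outer_folds = 10, outer_repeats = 1, inner_folds = 2,
                  stratified = FALSE, seed = 1)
  w <- capture_warnings(
    cv <- nested_cv_evaluate(x, y, plan = plan, space = fixed_point_space(),
                             tune = FALSE))
  expect_true(all(grepl("no positive", w)) && length(w) > 0)
  expect_gt(cv$skipped, 0)
  expect_equal(nrow(cv$folds) + cv$skipped, 10)
})

test_that("outer-test rows never reach tuning (leakage guard)", {
  d <- separable_data(n = 90, p = 4, seed = 8)
  plan <- cv_plan(outer_folds = 3, outer_repeats = 1, inner_folds = 3,
                  seed = 2)
  # the tuner is only ever handed the outer-train rows by construction;
  # assert the complement property on the recorded assignments
  cv <- nested_cv_evaluate(d$x, d$y, plan = plan,
                           space = fixed_point_space(), tune = FALSE)
  all_test <- unlist(cv$fold_assignments)
  expect_equal(sort(all_test), seq_len(90))
  for (i in seq_along(cv$fold_assignments))
    for (j in seq_along(cv$fold_assignments))
      if (i != j)
        expect_length(intersect(cv$fold_assignments[[i]],
                                cv$fold_assignments[[j]]), 0)
})

test_that("the final model is seeded, sized as configured, and learns", {
  d <- separable_data(n = 120, p = 6, seed = 4, gap = 4)
  p <- trajmix:::default_params()
  m1 <- fit_final_model(d$x, d$y, p, n_trees = 500, seed = 7)
  m2 <- fit_final_model(d$x, d$y, p, n_trees = 500, seed = 7)
  expect_equal(m1$forest$num.trees, 500)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  prob <- predict(m1, d$x)
  expect_gte(compute_metrics(d$y, as.integer(prob >= 0.5), prob)$f1, 0.9)
  expect_error(fit_final_model(d$x, rep(0L, 120), p), "single class")
})
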
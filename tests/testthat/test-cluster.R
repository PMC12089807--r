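test_that("silhouette matches hand-checkable cases", {
  # perfectly separated point masses
  expect_equal(silhouette_score(c(0, 0, 0, 10, 10, 10), c(1, 1, 1, 2, 2, 2)), 1)
  # two singletons: each contributes 0 by convention
  expect_equal(silhouette_score(c(0, 10), c(1, 2)), 0)
  # single cluster is undefined
  expect_error(silhouette_score(c(1, 2, 3), c(1, 1, 1)), "single cluster")
})

test_that("silhouette equals the O(n^2) brute-force oracle", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    k <- sample(2:4, 1)
    x <- runif(n, 0, 10)
    g <- sample(k, n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c(1, 2)
    expect_equal(silhouette_score(x, g), brute_silhouette(x, g),
                 tolerance = 1e-12)
  }
  # integer-valued scores with ties behave identically
  set.seed(6)
  x <- sample(0:10, 40, replace = TRUE)
  g <- sample(1:3, 40, replace = TRUE)
  expect_equal(silhouette_score(x, g), brute_silhouette(x, g),
               tolerance = 1e-12)
})

test_that("select_k finds the generative number of components", {
  hits2 <- hits3 <- 0
  for (s in 1:10) {
    set.seed(s)
    x2 <- round(c(rnorm(400, 10, 3), rnorm(383, 35, 3)))
    if (select_k(x2, 2:12, seed = s)$k_selected == 2) hits2 <- hits2 + 1
    x3 <- round(c(rnorm(260, 5, 2), rnorm(260, 25, 2), rnorm(263, 45, 2)))
    if (select_k(x3, 2:12, seed = s)$k_selected == 3) hits3 <- hits3 + 1
  }
  expect_gte(hits2, 9)
  expect_gte(hits3, 9)
})

test_that("select_k records complete diagnostics and breaks ties to small k", {
  set.seed(2)
  x <- round(c(rnorm(200, 5, 2), rnorm(200, 30, 2)))
  sol <- select_k(x, 2:5, seed = 1)
  expect_equal(sol$diagnostics$k, 2:5)
  expect_true(all(is.finite(sol$diagnostics$log_likelihood)))
  expect_true(all(sol$diagnostics$aic ==
                  2 * (3 * sol$diagnostics$k - 1) -
                  2 * sol$diagnostics$log_likelihood))
  # tie-break on the selection rule itself: equal silhouettes -> smallest k
  d <- data.frame(k = c(2, 3, 4), silhouette = c(0.5, 0.5, 0.4))
  expect_equal(d$k[trajmix:::choose_best_k(d)], 2)
  d2 <- data.frame(k = c(3, 2), silhouette = c(0.5, 0.5))
  expect_equal(d2$k[trajmix:::choose_best_k(d2)], 2)
})

test_that("severity ordering ranks components by mean, then variance", {
  f <- function(means, vars) structure(
    list(k = length(means), means = means, variances = vars),
    class = "gmm1d")
  expect_equal(order_by_severity(f(c(24, 9), c(4, 4))), c(2L, 1L))
  expect_equal(order_by_severity(f(c(9, 24, 40), c(1, 1, 1))), c(1L, 2L, 3L))
  # equal means: smaller variance ranks first (documented tie-break)
  expect_equal(order_by_severity(f(c(10, 10), c(4, 1))), c(2L, 1L))
})

test_that("binarisation keeps the lowest cluster low and merges the rest", {
  set.seed(7)
  x <- round(c(rnorm(150, 5, 2), rnorm(150, 25, 3), rnorm(150, 45, 3)))
  fit <- fit_gmm1d(x, 3, seed = 1)
  sol <- structure(list(k_selected = 3L, fit = fit,
                        assignments = trajmix:::hard_assignments(fit),
                        severity_order = order_by_severity(fit)),
                   class = "cluster_solution")
  b <- binarize_severity(sol)
  ranks <- sol$severity_order[sol$assignments]
  expect_true(all(b[ranks == 1] == "low"))
  expect_true(all(b[ranks >= 2] == "high"))  # moderate and severe both high
})

test_that("trajectory labels implement the 2x2 rule and partition the cohort", {
  b <- factor(c("low", "high", "low", "high"), levels = c("low", "high"))
  f <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  lab <- derive_trajectory_labels(b, f)
  expect_equal(as.character(lab),
               c("good_prognosis", "remitting_course", "clinical_worsening",
                 "persistent_course"))
  expect_error(derive_trajectory_labels(b, f[1:3]), "length")
  set.seed(1)
  bb <- factor(sample(c("low", "high"), 100, TRUE), levels = c("low", "high"))
  ff <- factor(sample(c("low", "high"), 100, TRUE), levels = c("low", "high"))
  expect_equal(sum(table(derive_trajectory_labels(bb, ff))), 100)
})

test_that("trajectory summary reproduces percentages from counts", {
  labs <- rep(trajectory_classes(), c(155, 174, 85, 369))
  s <- summarize_trajectories(labs)
  expect_equal(s$n, 783)
  expect_equal(s$table$n, c(155, 174, 85, 369))
  expect_equal(s$baseline_low_pct, 30.65)
  expect_equal(s$followup_low_pct, 42.02)
  expect_equal(s$table$pct, round(100 * c(155, 174, 85, 369) / 783, 2))
  # empty label set: empty table, no division by zero
  e <- summarize_trajectories(character(0))
  expect_equal(nrow(e$table), 0)
  expect_true(is.na(e$baseline_low_pct))
})

test_that("the clustering chain recovers planted trajectory classes", {
  skip_if_not_installed("mclust")
  ari <- numeric(5)
  for (s in 1:5) {
    co <- generate_cohort(cohort_config(seed = 100 + s))
    bl <- select_k(co$bdi_baseline, 2:12, seed = s)
    fu <- select_k(co$bdi_followup, 2:12, seed = s + 50)
    lab <- derive_trajectory_labels(binarize_severity(bl),
                                    binarize_severity(fu))
    ari[s] <- mclust::adjustedRandIndex(lab, co$true_class)
  }
  expect_true(all(ari >= 0.7))
})
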
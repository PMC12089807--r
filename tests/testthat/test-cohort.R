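test_that("identical seeds reproduce the cohort byte for byte", {
  cfg <- cohort_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  d <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(a$bdi_baseline, d$bdi_baseline))
})

test_that("cohort structure honours the configuration", {
  cfg <- cohort_config(n_participants = 500, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 500)
  expect_equal(sum(table(co$true_class)), 500)
  expect_true(all(co$bdi_baseline >= 0 & co$bdi_baseline <= 63))
  expect_true(all(co$bdi_followup >= 0 & co$bdi_followup <= 63))
  expect_true(all(co$bdi_baseline == round(co$bdi_baseline)))
  expect_equal(ncol(feature_matrix(co)), 32)
  # clipping touches well under 1% of scores under the default geometry
  at_bounds <- mean(co$bdi_baseline %in% c(0, 63)) +
    mean(co$bdi_followup %in% c(0, 63))
  expect_lt(at_bounds, 0.02)
})

test_that("degenerate configurations are rejected with clear messages", {
  expect_error(cohort_config(baseline_mixture = list(
    low = c(weight = 0.5, mean = 10, sd = 3),
    high = c(weight = 0.5, mean = 10, sd = 5))), "degenerate")
  expect_error(cohort_config(baseline_mixture = list(
    low = c(weight = 0.5, mean = 9, sd = -1),
    high = c(weight = 0.5, mean = 24, sd = 7))), "positive")
  expect_error(cohort_config(class_proportions = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("class counts follow the multinomial over many seeds", {
  p <- c(155, 174, 85, 369) / 783
  counts <- t(vapply(1:200, function(s)
    as.integer(table(generate_cohort(cohort_config(seed = s))$true_class)),
    integer(4)))
  expect_true(all(rowSums(counts) == 783))
  # mean count within the 99% band of a binomial mean over 200 draws
  se <- sqrt(p * (1 - p) * 783 / 200)
  expect_true(all(abs(colMeans(counts) - 783 * p) < qnorm(0.995) * se))
})

test_that("zero effect sizes remove all feature-class association", {
  cfg <- cohort_config(n_participants = 2000, seed = 11)
  co <- null_cohort(cfg)
  expect_true(all(attr(co, "effect_sizes") == 0))
  x <- feature_matrix(co)
  cls <- co$true_class
  for (f in c("eqvas_quality_of_life", "social_stress", "nyha_class_3")) {
    g1 <- x[[f]][cls == "good_prognosis"]
    g2 <- x[[f]][cls == "persistent_course"]
    se <- sqrt(var(g1) / length(g1) + var(g2) / length(g2))
    expect_lt(abs(mean(g1) - mean(g2)), 3 * se)
  }
})

test_that("null cohort equals generating from a zeroed configuration", {
  cfg <- cohort_config(n_participants = 150, seed = 5)
  a <- null_cohort(cfg)
  cfg$effect_sizes[] <- 0
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("features are exchangeable across classes under the null", {
  # Kruskal-Wallis p-values should be approximately uniform over seeds
  pvals <- vapply(1:80, function(s) {
    co <- null_cohort(cohort_config(n_participants = 400, seed = s))
    kruskal.test(co$social_stress, co$true_class)$p.value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ground truth export round-trips and handles edge cases", {
  co <- generate_cohort(cohort_config(n_participants = 50, seed = 2))
  path <- tempfile(fileext = ".csv")
  files <- export_ground_truth(co, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 50)
  expect_identical(back$true_class, as.character(co$true_class))
  eff <- read.csv(files[["effects"]], check.names = FALSE)
  expect_equal(nrow(eff), 32)
  expect_equal(as.matrix(eff[, -1]), attr(co, "effect_sizes"),
               ignore_attr = TRUE)
  # empty cohort: header-only file
  empty <- co[integer(0), ]
  p2 <- tempfile(fileext = ".csv")
  export_ground_truth(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
  # real (non-synthetic) cohort: hard error
  co$true_class <- NULL
  expect_error(export_ground_truth(co, tempfile()), "true_class")
})

test_that("ingest validates, drops incomplete rows, and round-trips", {
  co <- generate_cohort(cohort_config(n_participants = 40, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- ingest_cohort(path)
  expect_equal(nrow(back), 40)
  expect_equal(back$bdi_baseline, co$bdi_baseline)
  expect_identical(as.character(back$true_class), as.character(co$true_class))
  # one missing cell drops exactly one row, with a warning
  broken <- as.data.frame(co)
  broken$age[5] <- NA
  write.csv(broken, path, row.names = FALSE)
  expect_warning(back2 <- ingest_cohort(path), "1 row")
  expect_equal(nrow(back2), 39)
  # out-of-range score is an error
  bad <- as.data.frame(co)
  bad$bdi_baseline[1] <- 70
  write.csv(bad, path, row.names = FALSE)
  expect_error(ingest_cohort(path), "score range")
  # missing required column
  nocol <- as.data.frame(co)
  nocol$bdi_followup <- NULL
  write.csv(nocol, path, row.names = FALSE)
  expect_error(ingest_cohort(path), "bdi_followup")
})

test_that("the feature matrix never contains the severity scores", {
  co <- generate_cohort(cohort_config(n_participants = 30, seed = 1))
  x <- feature_matrix(co)
  expect_false(any(c("bdi_baseline", "bdi_followup") %in% names(x)))
})
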
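#' Random-forest hyperparameter space
#'
#' The search space for the one-vs-rest forests. The number of trees is
#' fixed (default 500) across all evaluations; the searched dimensions are
#' the split rule, class weighting for imbalance, maximum tree depth (0 =
#' unlimited), the fraction of features considered per split, and the
#' minimum samples per leaf and per split. Ranges are package defaults and
#' fully overridable.
#'
#' @param n_trees Trees per forest, fixed across evaluations (default 500).
#' @param n_evaluations Tuning budget (default 500; a scaled-down profile of
#'   50 or fewer is appropriate for quick runs).
#' @param params Named list of parameter definitions in the format of
#'   [tpe_optimize()].
#' @return A list of class `hp_space`.
#' @export
hyperparameter_space <- function(n_trees = 500L, n_evaluations = 500L,
                                 params = list(
    splitrule = list(type = "categorical", values = c("gini", "extratrees")),
    class_weight = list(type = "categorical", values = c("none", "balanced")),
    max_depth = list(type = "integer", lower = 0L, upper = 32L),
    max_features = list(type = "numeric", lower = 0.1, upper = 1.0),
    min_samples_leaf = list(type = "integer", lower = 1L, upper = 20L),
    min_samples_split = list(type = "integer", lower = 2L, upper = 20L))) {
  for (p in params)
    if (p$type == "categorical") {
      if (!length(p$values)) stop2("empty categorical range")
    } else if (p$lower > p$upper) stop2("empty numeric range")
  structure(list(n_trees = as.integer(n_trees),
                 n_evaluations = as.integer(n_evaluations), params = params),
            class = "hp_space")
}

# A fixed mid-range parameter point, used where tuning is skipped.
default_params <- function() {
  list(splitrule = "gini", class_weight = "balanced", max_depth = 0L,
       max_features = 0.33, min_samples_leaf = 1L, min_samples_split = 5L)
}

#' One-vs-rest binary targets
#'
#' One indicator vector per trajectory class; the positives of the four
#' vectors partition the cohort.
#'
#' @param labels Factor (or character) of trajectory labels.
#' @return Named list of four integer 0/1 vectors.
#' @export
make_binary_targets <- function(labels) {
  labels <- as.character(labels)
  unseen <- setdiff(unique(labels), TRAJECTORY_CLASSES)
  if (length(unseen))
    stop2("unseen label value(s): ", paste(unseen, collapse = ", "))
  setNames(lapply(TRAJECTORY_CLASSES, function(cl)
    as.integer(labels == cl)), TRAJECTORY_CLASSES)
}

#' Cross-validation plan
#'
#' @param outer_folds,outer_repeats Outer loop: folds per repeat and number
#'   of repeats (defaults 10 and 5, i.e. 50 outer evaluations).
#' @param inner_folds Inner tuning folds (default 5).
#' @param stratified Stratify folds by the binary target (default TRUE; the
#'   smallest class is ~11% of the cohort, so unstratified folds can lose
#'   all positives).
#' @param seed Integer seed for fold construction.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(outer_folds = 10L, outer_repeats = 5L, inner_folds = 5L,
                    stratified = TRUE, seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L) stop2("folds must be >= 2")
  structure(list(outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_plan")
}

# Fold id per observation; stratified assignment keeps the per-fold positive
# fraction close to the global fraction. Uses the current RNG stream.
make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

# Map a parameter point onto a ranger fit. `y` must be a factor with levels
# c("rest", "case"); "case" is the positive class.
fit_forest <- function(x, y, params, n_trees, seed, importance = "none") {
  cw <- if (identical(params$class_weight, "balanced")) {
    tab <- table(y)
    w <- length(y) / (length(tab) * pmax(as.numeric(tab), 1))
    setNames(w, names(tab))
  } else NULL
  ranger::ranger(
    x = x, y = y, num.trees = n_trees, probability = TRUE,
    splitrule = params$splitrule,
    max.depth = params$max_depth,
    mtry = max(1L, min(ncol(x), floor(params$max_features * ncol(x)))),
    min.bucket = params$min_samples_leaf,
    min.node.size = params$min_samples_split,
    class.weights = cw,
    importance = importance,
    seed = seed, num.threads = 1L)
}

as_binary_factor <- function(target) {
  factor(ifelse(as.integer(target) == 1L, "case", "rest"),
         levels = c("rest", "case"))
}

positive_prob <- function(fit, x) {
  p <- stats::predict(fit, data = x, num.threads = 1L)$predictions
  p[, "case"]
}

#' Binary classification metrics
#'
#' F1 (positive class), accuracy, AUPRC (average precision), AUROC
#' (rank/Mann-Whitney statistic), and the row-normalised confusion matrix.
#' F1 is 0 when precision + recall = 0. AUROC/AUPRC require both classes in
#' the truth; on single-class truth they are returned as `NA` and flagged.
#'
#' @param y_true 0/1 vector of true labels.
#' @param y_pred 0/1 vector of predicted labels.
#' @param y_score Optional numeric scores (positive-class probability).
#' @return List with `f1`, `accuracy`, `precision`, `recall`, `auroc`,
#'   `auprc`, `confusion` (2 x 2, rows = truth, rows sum to 1), and
#'   `score_metrics_defined`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  yt <- as.integer(y_true); yp <- as.integer(y_pred)
  tp <- sum(yt == 1 & yp == 1); fp <- sum(yt == 0 & yp == 1)
  fn <- sum(yt == 1 & yp == 0); tn <- sum(yt == 0 & yp == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  accuracy <- (tp + tn) / length(yt)
  conf <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                 dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  rs <- rowSums(conf)
  conf_norm <- conf / ifelse(rs == 0, NA_real_, rs)
  both <- length(unique(yt)) == 2L
  auroc <- auprc <- NA_real_
  if (both && !is.null(y_score)) {
    auroc <- auroc_rank(yt, y_score)
    auprc <- average_precision(yt, y_score)
  }
  list(f1 = f1, accuracy = accuracy, precision = precision, recall = recall,
       auroc = auroc, auprc = auprc, confusion = conf_norm,
       confusion_counts = conf,
       score_metrics_defined = both && !is.null(y_score))
}

# AUROC via the rank (Mann-Whitney U) statistic; ties handled by midranks.
auroc_rank <- function(y, score) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise area under the precision-recall curve).
average_precision <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; score <- score[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at distinct thresholds only (last index of each tied block)
  keep <- c(score[-1] != score[-length(score)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  n_pos <- sum(y)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

# Mean inner-CV F1 of the positive class for one parameter point.
inner_cv_f1 <- function(x, y, params, n_trees, inner_folds, seed) {
  with_seed(seed, {
    fold <- make_folds(y, inner_folds, stratified = TRUE)
    f1s <- rep(NA_real_, inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || !any(y[!tr] == 1L)) next
      fit <- fit_forest(x[tr, , drop = FALSE], as_binary_factor(y[tr]),
                        params, n_trees, seed = derive_seed(seed, f))
      prob <- positive_prob(fit, x[!tr, , drop = FALSE])
      f1s[f] <- compute_metrics(y[!tr], as.integer(prob >= 0.5), prob)$f1
    }
    mean(f1s, na.rm = TRUE)
  })
}

#' Tune forest hyperparameters by TPE on inner-CV F1
#'
#' Maximises the mean inner cross-validated F1 of the positive class over
#' the hyperparameter space using [tpe_optimize()].
#'
#' @param x Feature data.frame.
#' @param target 0/1 target vector (both classes must be present).
#' @param space A [hyperparameter_space()].
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Integer seed.
#' @param n_evaluations Budget override (defaults to `space$n_evaluations`).
#' @return List with `best_params`, `best_value` (mean inner F1), `trials`.
#' @export
tune_hyperparameters <- function(x, target, space = hyperparameter_space(),
                                 inner_folds = 5L, seed = 1L,
                                 n_evaluations = space$n_evaluations) {
  target <- as.integer(target)
  if (length(unique(target)) < 2L)
    stop2("training target contains a single class; cannot tune")
  objective <- function(params)
    inner_cv_f1(x, target, params, space$n_trees, inner_folds,
                seed = derive_seed(seed, 7L))
  tpe_optimize(objective, space$params, n_eval = n_evaluations, seed = seed)
}

#' Nested cross-validation of a one-vs-rest forest
#'
#' Outer folds estimate out-of-sample performance; within every outer
#' training set hyperparameters are tuned by inner-CV TPE (or frozen at
#' `params` when `tune = FALSE`), a forest is refit on the outer training
#' set and scored on the outer test set. Outer folds with no positive test
#' cases are skipped with a warning and reported.
#'
#' @param x Feature data.frame.
#' @param target 0/1 target vector.
#' @param plan A [cv_plan()].
#' @param space A [hyperparameter_space()].
#' @param tune Tune within each outer fold (default TRUE). When FALSE,
#'   `params` is used for every fold.
#' @param params Parameter point used when `tune = FALSE`.
#' @param seed Integer seed (defaults to the plan's).
#' @return Object of class `nested_cv`: `folds` (per-fold metric table),
#'   `aggregate` (mean and sd per metric), `confusion` (row-normalised
#'   pooled confusion matrix), `fold_assignments` (list of outer test index
#'   vectors), `best_params` per fold, `skipped` fold count.
#' @export
nested_cv_evaluate <- function(x, target, plan = cv_plan(),
                               space = hyperparameter_space(), tune = TRUE,
                               params = NULL, seed = plan$seed) {
  target <- as.integer(target)
  if (length(unique(target)) < 2L)
    stop2("target contains a single class")
  if (!tune && is.null(params)) params <- default_params()
  rows <- list(); assignments <- list(); tuned <- list()
  pooled_conf <- matrix(0, 2, 2)
  skipped <- 0L
  for (r in seq_len(plan$outer_repeats)) {
    fold <- with_seed(derive_seed(seed, r),
                      make_folds(target, plan$outer_folds, plan$stratified))
    for (f in seq_len(plan$outer_folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      tag <- sprintf("repeat %d fold %d", r, f)
      if (!any(target[te] == 1L) || length(unique(target[tr])) < 2L) {
        warning("outer ", tag, " has no positive cases; skipped",
                call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      p <- if (tune) {
        tune_hyperparameters(x[tr, , drop = FALSE], target[tr], space,
                             inner_folds = plan$inner_folds,
                             seed = derive_seed(seed, r, f))$best_params
      } else params
      fit <- fit_forest(x[tr, , drop = FALSE], as_binary_factor(target[tr]),
                        p, space$n_trees, seed = derive_seed(seed, r, f, 2L))
      prob <- positive_prob(fit, x[te, , drop = FALSE])
      m <- compute_metrics(target[te], as.integer(prob >= 0.5), prob)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f, n_test = length(te),
        n_pos = sum(target[te]), f1 = m$f1, accuracy = m$accuracy,
        auroc = m$auroc, auprc = m$auprc)
      pooled_conf <- pooled_conf + m$confusion_counts
      assignments[[length(assignments) + 1L]] <- te
      tuned[[length(tuned) + 1L]] <- p
    }
  }
  if (!length(rows)) stop2("every outer fold was skipped")
  folds <- do.call(rbind, rows)
  metrics <- c("f1", "accuracy", "auroc", "auprc")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) sd(folds[[m]], na.rm = TRUE), 0))
  rs <- rowSums(pooled_conf)
  structure(list(folds = folds, aggregate = aggregate,
                 confusion = pooled_conf / ifelse(rs == 0, NA_real_, rs),
                 fold_assignments = assignments, best_params = tuned,
                 skipped = skipped, plan = plan),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, digits = 3, ...) {
  cat(sprintf("Nested CV: %d outer evaluations (%d skipped)\n",
              nrow(x$folds), x$skipped))
  print(format(x$aggregate, digits = digits), row.names = FALSE)
  cat("pooled normalised confusion (rows = truth):\n")
  print(round(x$confusion, digits))
  invisible(x)
}

#' Refit the final one-vs-rest forest on the full data
#'
#' One forest refit on all rows with the tuned parameters; used for
#' impurity importance, SHAP attribution and the permutation null. The
#' training data is retained on the object (SHAP node weights are computed
#' by routing it through the trees).
#'
#' @param x Feature data.frame.
#' @param target 0/1 target vector.
#' @param params Tuned parameter point.
#' @param n_trees Trees (default 500).
#' @param seed Integer seed.
#' @param class_label Optional label naming which one-vs-rest model this is.
#' @return Object of class `ovr_forest`.
#' @export
fit_final_model <- function(x, target, params, n_trees = 500L, seed = 1L,
                            class_label = NA_character_) {
  target <- as.integer(target)
  if (length(unique(target)) < 2L) stop2("target contains a single class")
  fit <- fit_forest(x, as_binary_factor(target), params, n_trees, seed,
                    importance = "impurity")
  structure(list(forest = fit, params = params, n_trees = n_trees,
                 feature_names = colnames(x), x_train = x, target = target,
                 seed = seed, class_label = class_label),
            class = "ovr_forest")
}

#' @export
print.ovr_forest <- function(x, ...) {
  cat(sprintf("One-vs-rest forest%s: %d trees, %d features, n = %d\n",
              if (!is.na(x$class_label)) paste0(" [", x$class_label, "]") else "",
              x$n_trees, length(x$feature_names), nrow(x$x_train)))
  cat("params:", paste(names(x$params),
                       vapply(x$params, format, ""), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.ovr_forest <- function(object, newdata = object$x_train, ...) {
  positive_prob(object$forest, newdata)
}
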
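#' One-sided permutation p-value
#'
#' Add-one exceedance estimator `p = (1 + #{null >= true}) / (B + 1)`. Ties
#' count against the alternative (conservative); the add-one convention
#' avoids p = 0 and makes the estimator valid at any B.
#'
#' @param true_value Observed statistic.
#' @param null Numeric vector of B null draws.
#' @return p-value in `(0, 1]`.
#' @export
one_sided_p <- function(true_value, null) {
  null <- null[!is.na(null)]
  if (!length(null)) stop2("empty null distribution")
  (1 + sum(null >= true_value)) / (length(null) + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, `q_(i) = min_{j >= i} p_(j) m / j` capped at 1,
#' mapped back to input order (computed via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop2("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' One permutation-null draw for F1 and feature importance
#'
#' Shuffles the four-class trajectory label vector once (a whole-vector
#' permutation outside the cross-validation loop; the same permuted vector
#' feeds all four one-vs-rest targets) and recomputes, with hyperparameters
#' frozen at their previously tuned values and no re-tuning: the outer-CV
#' mean F1 per class and, optionally, the full-data refit importance vector
#' per class.
#'
#' @param x Feature data.frame.
#' @param labels Factor of trajectory labels.
#' @param frozen_params Named list (one entry per class in
#'   [trajectory_classes()]) of tuned parameter points. Required: re-tuning
#'   inside the null is not allowed.
#' @param plan A [cv_plan()] used for the F1 null.
#' @param seed Integer seed for this draw.
#' @param n_trees Trees per forest.
#' @param compute_f1,compute_importance Which statistics to draw.
#' @return List with `f1` (named 4-vector or NULL), `importance` (class x
#'   feature matrix or NULL), and `params_checksum` (md5 of the frozen
#'   parameter set, asserted constant across draws).
#' @export
permuted_run <- function(x, labels, frozen_params, plan, seed,
                         n_trees = 500L, compute_f1 = TRUE,
                         compute_importance = TRUE) {
  if (is.null(frozen_params))
    stop2("frozen_params missing: the permutation null must reuse the tuned ",
          "hyperparameters, not re-tune")
  if (!all(TRAJECTORY_CLASSES %in% names(frozen_params)))
    stop2("frozen_params must name all four classes")
  perm <- with_seed(seed, sample(as.character(labels)))
  targets <- make_binary_targets(perm)
  space <- hyperparameter_space(n_trees = n_trees)
  f1 <- NULL; imp <- NULL
  if (compute_f1) {
    f1 <- vapply(TRAJECTORY_CLASSES, function(cl) {
      cv <- suppressWarnings(nested_cv_evaluate(
        x, targets[[cl]], plan = plan, space = space, tune = FALSE,
        params = frozen_params[[cl]], seed = derive_seed(seed, match(cl, TRAJECTORY_CLASSES))))
      cv$aggregate$mean[cv$aggregate$metric == "f1"]
    }, numeric(1))
  }
  if (compute_importance) {
    imp <- t(vapply(TRAJECTORY_CLASSES, function(cl) {
      m <- fit_final_model(x, targets[[cl]], frozen_params[[cl]],
                           n_trees = n_trees,
                           seed = derive_seed(seed, 10L + match(cl, TRAJECTORY_CLASSES)),
                           class_label = cl)
      as.numeric(impurity_importance(m))
    }, numeric(ncol(x))))
    dimnames(imp) <- list(TRAJECTORY_CLASSES, colnames(x))
  }
  list(f1 = f1, importance = imp, permuted_labels = perm,
       params_checksum = object_md5(frozen_params[TRAJECTORY_CLASSES]))
}

#' Permutation inference with FDR control
#'
#' Builds B permutation-null draws (via [permuted_run()]) for the per-class
#' F1 and per-(class, feature) importance statistics, computes one-sided
#' p-values against the real-label values, and applies Benjamini-Hochberg
#' FDR correction separately within the performance family (4 tests) and the
#' importance family (4 x p tests).
#'
#' @param x Feature data.frame.
#' @param labels Factor of trajectory labels (real labels).
#' @param frozen_params Tuned parameter points per class (see
#'   [permuted_run()]).
#' @param real_f1 Named 4-vector of real-label mean outer F1.
#' @param real_importance Class x feature matrix of real-label importances.
#' @param B Number of permutation draws (default 1000).
#' @param plan A [cv_plan()] for the F1 nulls.
#' @param seed Integer seed.
#' @param n_trees Trees per forest.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `fdr_result`: `performance` and `importance`
#'   tables (statistic, true value, p, q, significant), `alpha`, `B`, and
#'   the raw null draws.
#' @export
run_inference <- function(x, labels, frozen_params, real_f1, real_importance,
                          B = 1000L, plan = cv_plan(), seed = 1L,
                          n_trees = 500L, alpha = 0.05) {
  if (length(real_f1) != 4L || !all(TRAJECTORY_CLASSES %in% names(real_f1)))
    stop2("real_f1 must be a named vector over the four classes")
  if (!identical(dim(real_importance),
                 c(4L, ncol(x))) ||
      !all(rownames(real_importance) == TRAJECTORY_CLASSES))
    stop2("real_importance must be a 4 x n_features matrix in class order")
  null_f1 <- matrix(NA_real_, B, 4, dimnames = list(NULL, TRAJECTORY_CLASSES))
  null_imp <- array(NA_real_, c(B, 4, ncol(x)),
                    dimnames = list(NULL, TRAJECTORY_CLASSES, colnames(x)))
  checksums <- character(B)
  for (b in seq_len(B)) {
    draw <- permuted_run(x, labels, frozen_params, plan,
                         seed = derive_seed(seed, b), n_trees = n_trees)
    null_f1[b, ] <- draw$f1
    null_imp[b, , ] <- draw$importance
    checksums[b] <- draw$params_checksum
  }
  if (length(unique(checksums)) != 1L)
    stop2("frozen-parameter checksum changed across permutation draws")
  perf <- data.frame(class = TRAJECTORY_CLASSES,
                     f1 = as.numeric(real_f1[TRAJECTORY_CLASSES]))
  perf$p <- vapply(seq_len(4), function(i)
    one_sided_p(perf$f1[i], null_f1[, i]), numeric(1))
  perf$q <- bh_fdr(perf$p)
  perf$significant <- perf$q <= alpha
  imp <- expand.grid(class = TRAJECTORY_CLASSES, feature = colnames(x),
                     stringsAsFactors = FALSE)
  imp$importance <- mapply(function(cl, ft) real_importance[cl, ft],
                           imp$class, imp$feature)
  imp$p <- mapply(function(cl, ft)
    one_sided_p(real_importance[cl, ft], null_imp[, cl, ft]),
    imp$class, imp$feature)
  imp$q <- bh_fdr(imp$p)
  imp$significant <- imp$q <= alpha
  structure(list(performance = perf, importance = imp, alpha = alpha, B = B,
                 null_f1 = null_f1, null_importance = null_imp,
                 params_checksum = checksums[1]),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("Permutation inference (B = %d, alpha = %.2f)\n", x$B, x$alpha))
  cat("performance family (4 tests):\n")
  print(format(x$performance, digits = 3), row.names = FALSE)
  sig <- x$importance[x$importance$significant, ]
  cat(sprintf("importance family (%d tests): %d significant\n",
              nrow(x$importance), nrow(sig)))
  if (nrow(sig)) print(format(sig, digits = 3), row.names = FALSE)
  invisible(x)
}
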
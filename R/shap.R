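#' Impurity-based feature importance
#'
#' Mean over trees of the total weighted impurity decrease at nodes
#' splitting on each feature. A feature that is constant across samples is
#' never chosen for a split and has importance exactly 0. The normalised
#' variant (the default report) divides by the total so the vector sums
#' to 1.
#'
#' @param model An [fit_final_model()] object.
#' @param normalise Return the normalised vector (default TRUE); the raw
#'   vector is attached as attribute `"raw"` either way.
#' @return Named numeric vector of per-feature importances.
#' @export
impurity_importance <- function(model, normalise = TRUE) {
  if (!inherits(model, "ovr_forest")) stop2("model must be a fitted ovr_forest")
  raw <- model$forest$variable.importance
  if (is.null(raw)) stop2("forest was fitted without impurity importance")
  out <- if (normalise && sum(raw) > 0) raw / sum(raw) else raw
  attr(out, "raw") <- raw
  attr(out, "normalised") <- normalise && sum(raw) > 0
  out
}

# Extract one ranger tree as flat arrays for the C++ TreeSHAP kernel, with
# node covers computed by routing the reference matrix through the tree.
extract_tree <- function(forest, tree_id, x_ref, value_col) {
  ti <- ranger::treeInfo(forest, tree_id)
  left <- ifelse(is.na(ti$leftChild), -1L, ti$leftChild)
  right <- ifelse(is.na(ti$rightChild), -1L, ti$rightChild)
  feature <- ifelse(is.na(ti$splitvarID), -1L, ti$splitvarID)
  threshold <- ifelse(is.na(ti$splitval), 0, ti$splitval)
  value <- ti[[value_col]]
  value[is.na(value)] <- 0
  cover <- tree_cover_cpp(as.integer(left), as.integer(right),
                          as.integer(feature), as.numeric(threshold), x_ref)
  list(left = as.integer(left), right = as.integer(right),
       feature = as.integer(feature), threshold = as.numeric(threshold),
       value = as.numeric(value), cover = cover)
}

#' SHAP attributions for a one-vs-rest forest
#'
#' Exact path-dependent TreeSHAP values for the forest's positive-class
#' probability output. For every sample the attributions satisfy local
#' additivity: base value + sum of per-feature attributions equals the
#' model's predicted score. Node weights are the counts of the model's
#' training data routed through each tree, and the base value is the
#' cover-weighted mean tree output (the mean model output over the training
#' data).
#'
#' @param model An [fit_final_model()] object.
#' @param newdata Data.frame of rows to explain (defaults to the training
#'   data). Column names must match the training schema.
#' @return Object of class `shap_matrix`: `attributions` (n x p matrix),
#'   `base_value`, `predicted` (model scores for the explained rows),
#'   `feature_values`, `class_label`.
#' @export
shap_attributions <- function(model, newdata = model$x_train) {
  if (!inherits(model, "ovr_forest")) stop2("model must be a fitted ovr_forest")
  if (!identical(colnames(newdata), model$feature_names))
    stop2("newdata columns do not match the training feature schema")
  x_ref <- as.matrix(model$x_train)
  x_new <- as.matrix(newdata)
  storage.mode(x_ref) <- "double"
  storage.mode(x_new) <- "double"
  value_col <- "pred.case"  # positive-class leaf probability
  trees <- lapply(seq_len(model$forest$num.trees), function(t)
    extract_tree(model$forest, t, x_ref, value_col))
  res <- treeshap_cpp(trees, x_new)
  phi <- res$phi
  dimnames(phi) <- list(rownames(newdata), model$feature_names)
  structure(list(attributions = phi, base_value = res$base,
                 predicted = positive_prob(model$forest, newdata),
                 feature_values = newdata,
                 class_label = model$class_label),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, n_top = 8, ...) {
  cat(sprintf("SHAP attributions%s: %d samples x %d features, base = %.4f\n",
              if (!is.na(x$class_label)) paste0(" [", x$class_label, "]") else "",
              nrow(x$attributions), ncol(x$attributions), x$base_value))
  magn <- sort(colMeans(abs(x$attributions)), decreasing = TRUE)
  cat("top mean |attribution|:\n")
  print(round(head(magn, n_top), 5))
  invisible(x)
}

#' Beeswarm-style attribution plot
#'
#' Jittered strip plot of per-sample attributions for the highest-magnitude
#' features, shaded by the (scaled) feature value.
#'
#' @param x A `shap_matrix`.
#' @param n_top Number of features to show.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.shap_matrix <- function(x, n_top = 10, ...) {
  magn <- colMeans(abs(x$attributions))
  keep <- names(sort(magn, decreasing = TRUE))[seq_len(min(n_top, length(magn)))]
  keep <- rev(keep)
  graphics::plot(NULL, xlim = range(x$attributions[, keep]),
                 ylim = c(0.5, length(keep) + 0.5), yaxt = "n",
                 xlab = "SHAP value", ylab = "", ...)
  graphics::axis(2, at = seq_along(keep), labels = keep, las = 1, cex.axis = 0.7)
  for (i in seq_along(keep)) {
    v <- x$feature_values[[keep[i]]]
    sv <- if (sd(v) > 0) (v - min(v)) / (max(v) - min(v)) else rep(0.5, length(v))
    graphics::points(x$attributions[, keep[i]],
                     i + stats::runif(nrow(x$attributions), -0.25, 0.25),
                     pch = 16, cex = 0.4,
                     col = grDevices::rgb(sv, 0.2, 1 - sv, alpha = 0.5))
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Directional summary of SHAP attributions
#'
#' Per feature, the Spearman rank correlation between feature values and
#' attributions and the resulting sign call: `positive` when an increase in
#' the feature drives the prediction towards the class (rank correlation at
#' or above `threshold`), `negative` when away from it, `mixed` otherwise. A
#' zero-variance attribution column cannot carry direction and is reported
#' `mixed` with a flag.
#'
#' @param shap A `shap_matrix`.
#' @param features Feature values (defaults to those stored on `shap`).
#' @param threshold Absolute rank-correlation threshold for a sign call
#'   (default 0.1).
#' @return data.frame with `feature`, `rank_correlation`, `sign`, `flagged`.
#' @export
direction_summary <- function(shap, features = shap$feature_values,
                              threshold = 0.1) {
  phi <- shap$attributions
  out <- lapply(colnames(phi), function(f) {
    col <- phi[, f]
    fv <- features[[f]]
    if (sd(col) == 0 || sd(fv) == 0)
      return(data.frame(feature = f, rank_correlation = NA_real_,
                        sign = "mixed", flagged = TRUE))
    rho <- suppressWarnings(cor(fv, col, method = "spearman"))
    sgn <- if (is.na(rho)) "mixed"
           else if (rho >= threshold) "positive"
           else if (rho <= -threshold) "negative" else "mixed"
    data.frame(feature = f, rank_correlation = rho, sign = sgn,
               flagged = is.na(rho))
  })
  do.call(rbind, out)
}
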
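# Independent oracles used across the suite. These deliberately take the
# slow, direct route (pairwise loops, coalition enumeration) so they share no
# code with the implementations they check.

# O(n^2) silhouette from the definition: per-point mean pairwise distances.
brute_silhouette <- function(values, assignments) {
  x <- as.numeric(values)
  g <- as.integer(factor(assignments))
  n <- length(x)
  d <- abs(outer(x, x, "-"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(g == g[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, setdiff(own, i)]) / (length(own) - 1L)
    b <- min(vapply(setdiff(unique(g), g[i]), function(c) {
      mean(d[i, g == c])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Flat arrays of a single ranger tree (1-based nodes, feature 0 = leaf).
extract_tree_arrays <- function(model, tree_id = 1) {
  ti <- ranger::treeInfo(model$forest, tree_id)
  xm <- as.matrix(model$x_train)
  storage.mode(xm) <- "double"
  feat0 <- ifelse(is.na(ti$splitvarID), -1L, as.integer(ti$splitvarID))
  left0 <- ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild))
  right0 <- ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild))
  thr <- ifelse(is.na(ti$splitval), 0, ti$splitval)
  val <- ti$pred.case
  val[is.na(val)] <- 0
  cover <- trajmix:::tree_cover_cpp(left0, right0, feat0, thr, xm)
  list(left = left0 + 1L, right = right0 + 1L, feature = feat0 + 1L,
       threshold = thr, value = val, cover = cover)
}

# Path-conditional expectation of a tree output given the coalition S of
# known features (by index); unknown splits average branches by cover.
tree_expvalue <- function(tr, xi, S, node = 1L) {
  f <- tr$feature[node]
  if (f < 1L) return(tr$value[node])
  l <- tr$left[node]; r <- tr$right[node]
  if (f %in% S) {
    if (xi[f] <= tr$threshold[node]) tree_expvalue(tr, xi, S, l)
    else tree_expvalue(tr, xi, S, r)
  } else {
    (tr$cover[l] * tree_expvalue(tr, xi, S, l) +
     tr$cover[r] * tree_expvalue(tr, xi, S, r)) / tr$cover[node]
  }
}

# Exact Shapley values by enumeration over all feature coalitions.
brute_shapley <- function(tr, xi) {
  p <- length(xi)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (sz in 0:length(others)) {
      combs <- if (sz == 0) list(integer(0))
               else utils::combn(others, sz, simplify = FALSE)
      wt <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (S in combs)
        phi[j] <- phi[j] + wt * (tree_expvalue(tr, xi, c(S, j)) -
                                 tree_expvalue(tr, xi, S))
    }
  }
  phi
}

# Small cohort configurations used by the slower suites.
small_cohort_config <- function(seed = 1L, n = 300L, strength = 1) {
  cohort_config(n_participants = n,
                effect_sizes = default_effect_sizes(strength = strength),
                seed = seed)
}

# Quick hyperparameter settings for tests that exercise machinery, not
# statistical power.
tiny_space <- function(n_trees = 64L, n_evaluations = 4L)
  hyperparameter_space(n_trees = n_trees, n_evaluations = n_evaluations)

fixed_point_space <- function(n_trees = 64L) {
  hyperparameter_space(n_trees = n_trees, n_evaluations = 1L, params = list(
    splitrule = list(type = "categorical", values = "gini"),
    class_weight = list(type = "categorical", values = "balanced"),
    max_depth = list(type = "integer", lower = 0L, upper = 0L),
    max_features = list(type = "numeric", lower = 0.33, upper = 0.33),
    min_samples_leaf = list(type = "integer", lower = 1L, upper = 1L),
    min_samples_split = list(type = "integer", lower = 5L, upper = 5L)))
}

# Adjusted Rand index from the contingency-table formula (Hubert & Arabie).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sij <- ch2(as.vector(tab))
  si <- ch2(rowSums(tab)); sj <- ch2(colSums(tab))
  expected <- si * sj / ch2(sum(tab))
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Planted, nearly separable binary-classification data: one informative
# feature among noise.
separable_data <- function(n = 160L, p = 8L, seed = 1L, gap = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("f", seq_len(p))
  x$f1 <- x$f1 + gap * y
  list(x = x, y = y)
}
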
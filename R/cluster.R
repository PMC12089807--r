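#' One-dimensional silhouette score
#'
#' Mean silhouette over all points of a crisp partition of a numeric vector,
#' with distance = absolute difference. For point i, `a` is the mean
#' distance to its own cluster (excluding itself), `b` the smallest mean
#' distance to another cluster, and `s = (b - a) / max(a, b)`; points in
#' singleton clusters contribute `s = 0`. Computed in O(n log n) per cluster
#' via sorted prefix sums (an O(n^2) pairwise implementation is used as the
#' test oracle).
#'
#' @param values Numeric vector.
#' @param assignments Cluster labels, one per value; at least two distinct
#'   clusters must be present.
#' @return The mean silhouette, a real in `[-1, 1]`.
#' @export
silhouette_score <- function(values, assignments) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop2("values must be finite")
  g <- as.integer(factor(assignments))
  if (length(g) != length(x)) stop2("values and assignments differ in length")
  k <- max(g)
  if (k < 2L)
    stop2("silhouette is undefined for a single cluster")
  n <- length(x)
  sizes <- tabulate(g, k)
  # Per cluster: sorted values + prefix sums, so that the summed absolute
  # distance from any point to the whole cluster is O(log n).
  srt <- lapply(seq_len(k), function(c) {
    xs <- sort(x[g == c])
    list(xs = xs, cs = cumsum(xs))
  })
  sumdist <- function(xi, c) {
    xs <- srt[[c]]$xs; cs <- srt[[c]]$cs
    m <- length(xs)
    pos <- findInterval(xi, xs)
    left <- if (pos > 0) xi * pos - cs[pos] else 0
    right <- (cs[m] - (if (pos > 0) cs[pos] else 0)) - xi * (m - pos)
    left + right
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- g[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sumdist(x[i], ci) / (sizes[ci] - 1L)
    b <- Inf
    for (c in seq_len(k)) {
      if (c == ci || sizes[c] == 0L) next
      b <- min(b, sumdist(x[i], c) / sizes[c])
    }
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(s)
}

#' Select the number of mixture components by silhouette
#'
#' Fits a univariate Gaussian mixture for every k in `k_range`, computes the
#' silhouette of the hard assignments, and returns the solution with the
#' highest silhouette (ties broken towards the smallest k). Log-likelihood,
#' AIC and BIC are recorded per candidate k as a diagnostics table so the
#' fit-vs-complexity trade-off can be inspected alongside the silhouette.
#'
#' @param values Numeric score vector.
#' @param k_range Candidate component counts (default `2:12`).
#' @param seed Integer seed for the EM restarts.
#' @param ... Passed to [fit_gmm1d()] (`tol`, `max_iter`, `n_restarts`, ...).
#' @return An object of class `cluster_solution`: `k_selected`, `fit` (the
#'   winning `gmm1d`), `assignments` (hard labels), `silhouette`,
#'   `severity_order`, and `diagnostics` (per-k silhouette, log-likelihood,
#'   AIC, BIC, convergence flag).
#' @export
select_k <- function(values, k_range = 2:12, seed = 1L, ...) {
  x <- as.numeric(values)
  fits <- vector("list", length(k_range))
  diag_rows <- vector("list", length(k_range))
  failures <- character(0)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    row <- data.frame(k = k, silhouette = NA_real_, log_likelihood = NA_real_,
                      aic = NA_real_, bic = NA_real_, converged = NA,
                      clusters_used = NA_integer_)
    fit <- tryCatch(fit_gmm1d(x, k, seed = derive_seed(seed, k), ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("k=%d: %s", k, conditionMessage(fit)))
    } else {
      lab <- hard_assignments(fit)
      used <- length(unique(lab))
      ic <- information_criteria(fit)
      row$log_likelihood <- fit$log_likelihood
      row$aic <- ic[["aic"]]; row$bic <- ic[["bic"]]
      row$converged <- fit$converged
      row$clusters_used <- used
      if (used >= 2L) {
        row$silhouette <- silhouette_score(x, lab)
        fits[[i]] <- fit
      } else {
        failures <- c(failures,
                      sprintf("k=%d: hard assignments collapse to a single cluster", k))
      }
    }
    diag_rows[[i]] <- row
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (all(is.na(diagnostics$silhouette)))
    stop2("no candidate k produced a valid clustering:\n  ",
          paste(failures, collapse = "\n  "))
  best_i <- choose_best_k(diagnostics)
  fit <- fits[[best_i]]
  sol <- list(k_selected = diagnostics$k[best_i], fit = fit,
              assignments = hard_assignments(fit),
              silhouette = diagnostics$silhouette[best_i],
              severity_order = order_by_severity(fit),
              diagnostics = diagnostics, failures = failures)
  class(sol) <- "cluster_solution"
  sol
}

# Index of the winning row of a diagnostics table: maximal silhouette,
# ties broken towards the smallest k (parsimony).
choose_best_k <- function(diagnostics) {
  sil <- diagnostics$silhouette
  ok <- which(!is.na(sil))
  best <- max(sil[ok])
  cand <- ok[sil[ok] >= best - 1e-12]
  cand[which.min(diagnostics$k[cand])]
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d selected by silhouette (%.4f)\n",
              x$k_selected, x$silhouette))
  print(format(x$diagnostics, digits = 4), row.names = FALSE)
  if (length(x$failures))
    cat("skipped:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.cluster_solution <- function(x, ...) {
  d <- x$diagnostics
  graphics::plot(d$k, d$silhouette, type = "b", xlab = "k",
                 ylab = "silhouette", ...)
  graphics::abline(v = x$k_selected, lty = 2)
  invisible(x)
}

#' Rank mixture components by severity
#'
#' Components are ranked by ascending mean (rank 1 = lowest severity); equal
#' means are tie-broken by ascending variance.
#'
#' @param fit A `gmm1d` fit.
#' @return Integer vector: `severity_order[j]` is the severity rank of
#'   component j. A bijection onto `1..k`.
#' @export
order_by_severity <- function(fit) {
  ord <- order(fit$means, fit$variances)
  rank <- integer(fit$k)
  rank[ord] <- seq_len(fit$k)
  rank
}

#' Binarise cluster assignments into low/high severity
#'
#' The lowest-severity cluster maps to `"low"`; every other cluster maps to
#' `"high"`. This is the merge rule used at follow-up, where the moderate
#' and severe clusters are combined under a single label because both
#' correspond to symptom levels needing clinical attention. The number of
#' clusters kept on the low side is configurable.
#'
#' @param solution A `cluster_solution`.
#' @param n_low How many of the lowest-severity ranks count as `"low"`
#'   (default 1).
#' @return Factor with levels `c("low", "high")`, one per participant.
#' @export
binarize_severity <- function(solution, n_low = 1L) {
  ranks <- solution$severity_order[solution$assignments]
  factor(ifelse(ranks <= n_low, "low", "high"), levels = c("low", "high"))
}

#' Derive the four trajectory labels
#'
#' Combines low/high severity at baseline and follow-up into the four
#' trajectory classes: (low, low) = good prognosis, (high, low) = remitting
#' course, (low, high) = clinical worsening, (high, high) = persistent
#' course.
#'
#' @param baseline_bin,followup_bin Factors with levels `c("low", "high")`,
#'   equal length.
#' @return Factor with the four trajectory class levels.
#' @export
derive_trajectory_labels <- function(baseline_bin, followup_bin) {
  if (length(baseline_bin) != length(followup_bin))
    stop2("baseline and follow-up binarisations differ in length")
  b <- as.character(baseline_bin); f <- as.character(followup_bin)
  lab <- ifelse(b == "low" & f == "low", "good_prognosis",
         ifelse(b == "high" & f == "low", "remitting_course",
         ifelse(b == "low" & f == "high", "clinical_worsening",
                "persistent_course")))
  factor(lab, levels = TRAJECTORY_CLASSES)
}

#' Summarise trajectory class counts and percentages
#'
#' Per-class n and percentage of the cohort, plus the implied marginal
#' percentages: the baseline-low share is (good prognosis + clinical
#' worsening)/n and the follow-up-low share is (good prognosis + remitting
#' course)/n. Percentages are reported to 2 decimal places.
#'
#' @param labels Factor of trajectory labels.
#' @return A list of class `trajectory_summary`: `table` (class, n, pct),
#'   `n`, `baseline_low_pct`, `followup_low_pct`.
#' @export
summarize_trajectories <- function(labels) {
  labels <- factor(labels, levels = TRAJECTORY_CLASSES)
  n <- length(labels)
  if (n == 0L) {
    out <- list(table = data.frame(class = character(0), n = integer(0),
                                   pct = numeric(0)),
                n = 0L, baseline_low_pct = NA_real_,
                followup_low_pct = NA_real_)
    class(out) <- "trajectory_summary"
    return(out)
  }
  counts <- table(labels)
  tab <- data.frame(class = names(counts), n = as.integer(counts),
                    pct = round(100 * as.integer(counts) / n, 2))
  bl_low <- round(100 * sum(counts[c("good_prognosis", "clinical_worsening")]) / n, 2)
  fu_low <- round(100 * sum(counts[c("good_prognosis", "remitting_course")]) / n, 2)
  out <- list(table = tab, n = n, baseline_low_pct = bl_low,
              followup_low_pct = fu_low)
  class(out) <- "trajectory_summary"
  out
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("Trajectory classes (n =", x$n, ")\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("baseline low severity: %.2f%% | follow-up low severity: %.2f%%\n",
              x$baseline_low_pct, x$followup_low_pct))
  invisible(x)
}
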
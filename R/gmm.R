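#' Fit a univariate Gaussian mixture by expectation-maximisation
#'
#' Maximum-likelihood fit of a k-component normal mixture to a numeric
#' vector. EM is run from `n_restarts` initialisations (the first spreads
#' initial means on the sample quantiles, the rest seed means on randomly
#' chosen distinct data points) and the restart with the highest final
#' log-likelihood is returned. Component variances are floored at
#' `var_floor_frac` times the sample variance to prevent degenerate spike
#' components. For `k = 1` the closed-form MLE (sample mean, biased sample
#' variance) is returned directly.
#'
#' @param values Numeric vector of observations (finite; at least `2k`
#'   distinct values).
#' @param k Number of mixture components (>= 1).
#' @param seed Integer seed controlling the restarts.
#' @param tol Convergence tolerance: EM stops when the absolute
#'   log-likelihood improvement falls below `tol`.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of EM restarts.
#' @param var_floor_frac Variance floor as a fraction of the sample variance.
#' @return An object of class `gmm1d`: a list with `k`, `weights`, `means`,
#'   `variances`, `log_likelihood`, `responsibilities` (n x k posterior
#'   membership matrix), `n_iterations`, `converged`, `ll_trace` (per-
#'   iteration log-likelihood of the winning restart), `n`, and the data.
#' @examples
#' x <- c(rnorm(300, 9, 4), rnorm(500, 24, 7))
#' fit <- fit_gmm1d(x, k = 2, seed = 1)
#' coef(fit)
#' @export
fit_gmm1d <- function(values, k, seed = 1L, tol = 1e-6, max_iter = 500L,
                      n_restarts = 10L, var_floor_frac = 1e-4) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop2("values must be finite")
  n <- length(x)
  k <- as.integer(k)
  if (k < 1L) stop2("k must be >= 1")
  n_distinct <- length(unique(x))
  if (n_distinct < 2L * k)
    stop2("degenerate input: ", n_distinct, " distinct values cannot ",
          "support a ", k, "-component mixture (need >= ", 2L * k, ")")

  if (k == 1L) {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    ll <- sum(dnorm(x, mu, sqrt(v), log = TRUE))
    return(new_gmm1d(k = 1L, weights = 1, means = mu, variances = v,
                     log_likelihood = ll,
                     responsibilities = matrix(1, n, 1),
                     n_iterations = 0L, converged = TRUE, ll_trace = ll,
                     x = x))
  }

  floor_v <- var_floor_frac * stats::var(x)
  # Duplicates are collapsed and the EM run weighted by multiplicity: exact,
  # and much faster on integer-valued scores.
  ux <- sort(unique(x))
  cnt <- as.numeric(tabulate(match(x, ux), length(ux)))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mu0 <- if (r == 1L) {
        as.numeric(quantile(x, (seq_len(k) - 0.5) / k, names = FALSE))
      } else sort(sample(ux, k))
      fit <- em_gmm1d(ux, cnt, mu0, tol, max_iter, floor_v)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood)
        best <- fit
    }
  })
  new_gmm1d(k = k, weights = best$weights, means = best$means,
            variances = best$variances, log_likelihood = best$log_likelihood,
            responsibilities = best$responsibilities[match(x, ux), ,
                                                     drop = FALSE],
            n_iterations = best$n_iterations, converged = best$converged,
            ll_trace = best$ll_trace, x = x)
}

# One weighted EM run from given initial means (compiled kernel). Returns
# parameters, responsibilities (one row per distinct value) and the
# per-iteration log-likelihood trace.
em_gmm1d <- function(ux, cnt, mu, tol, max_iter, floor_v) {
  em_gmm1d_cpp(as.numeric(ux), as.numeric(cnt), as.numeric(mu), tol,
               as.integer(max_iter), floor_v)
}

new_gmm1d <- function(k, weights, means, variances, log_likelihood,
                      responsibilities, n_iterations, converged, ll_trace,
                      x) {
  structure(list(k = k, weights = as.numeric(weights),
                 means = as.numeric(means),
                 variances = as.numeric(variances),
                 log_likelihood = log_likelihood,
                 responsibilities = responsibilities,
                 n_iterations = n_iterations, converged = converged,
                 ll_trace = ll_trace, n = length(x), data = x),
            class = "gmm1d")
}

#' Information criteria for a univariate Gaussian mixture
#'
#' AIC and BIC with `p = 3k - 1` free parameters (k means, k variances,
#' k - 1 free weights): `aic = 2p - 2*logLik`, `bic = p*log(n) - 2*logLik`.
#'
#' @param fit A `gmm1d` fit.
#' @param n Sample size (defaults to the fitted sample size).
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit, n = fit$n) {
  p <- 3 * fit$k - 1
  ll <- fit$log_likelihood
  c(aic = 2 * p - 2 * ll, bic = p * log(n) - 2 * ll)
}

#' @export
logLik.gmm1d <- function(object, ...) {
  structure(object$log_likelihood, df = 3 * object$k - 1, nobs = object$n,
            class = "logLik")
}

#' @export
coef.gmm1d <- function(object, ...) {
  data.frame(component = seq_len(object$k), weight = object$weights,
             mean = object$means, sd = sqrt(object$variances))
}

#' @export
print.gmm1d <- function(x, digits = 4, ...) {
  cat(sprintf("Univariate Gaussian mixture, k = %d (n = %d)\n", x$k, x$n))
  print(format(coef(x), digits = digits), row.names = FALSE)
  cat(sprintf("logLik %.3f after %d EM iterations (%s)\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.gmm1d <- function(object, ...) {
  ic <- information_criteria(object)
  out <- list(fit = object, aic = ic[["aic"]], bic = ic[["bic"]],
              severity_order = order_by_severity(object),
              hard_counts = tabulate(hard_assignments(object), object$k))
  class(out) <- "summary.gmm1d"
  out
}

#' @export
print.summary.gmm1d <- function(x, ...) {
  print(x$fit)
  cat(sprintf("AIC %.2f | BIC %.2f\n", x$aic, x$bic))
  cat("hard assignment counts:", paste(x$hard_counts, collapse = ", "), "\n")
  cat("severity order (1 = lowest mean):",
      paste(x$severity_order, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior membership and density for new observations
#'
#' @param object A `gmm1d` fit.
#' @param newdata Numeric vector (defaults to the training data).
#' @param type `"class"` for hard component assignments (argmax posterior),
#'   `"prob"` for the n x k posterior responsibility matrix, `"density"`
#'   for the mixture density.
#' @param ... Unused.
#' @export
predict.gmm1d <- function(object, newdata = object$data,
                          type = c("class", "prob", "density"), ...) {
  type <- match.arg(type)
  x <- as.numeric(newdata)
  comp <- vapply(seq_len(object$k), function(j)
    object$weights[j] * dnorm(x, object$means[j], sqrt(object$variances[j])),
    numeric(length(x)))
  comp <- matrix(comp, nrow = length(x))
  if (type == "density") return(rowSums(comp))
  post <- comp / pmax(rowSums(comp), .Machine$double.xmin)
  if (type == "prob") post else max.col(post, ties.method = "first")
}

#' @export
simulate.gmm1d <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  j <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
  rnorm(nsim, object$means[j], sqrt(object$variances[j]))
}

#' @export
plot.gmm1d <- function(x, breaks = 30, main = NULL, ...) {
  h <- graphics::hist(x$data, breaks = breaks, freq = FALSE,
                      main = main %||% sprintf("Gaussian mixture, k = %d", x$k),
                      xlab = "score", border = "grey60", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 400)
  for (j in seq_len(x$k))
    graphics::lines(xs, x$weights[j] * dnorm(xs, x$means[j],
                                             sqrt(x$variances[j])),
                    col = j + 1, lwd = 2)
  graphics::lines(xs, predict(x, xs, type = "density"), lwd = 2)
  invisible(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hard cluster assignment: row-wise argmax of the responsibilities.
hard_assignments <- function(fit) {
  max.col(fit$responsibilities, ties.method = "first")
}
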
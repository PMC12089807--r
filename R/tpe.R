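#' Tree-structured Parzen estimator optimisation
#'
#' Sequential model-based maximisation of an objective over a mixed
#' categorical/numeric parameter space. The first `n_startup` trials are
#' drawn uniformly at random; afterwards, trials are split by objective
#' value into a "good" top fraction (`gamma`) and the rest, one-dimensional
#' Parzen densities `l` (good) and `g` (bad) are built per parameter, and of
#' `n_candidates` draws from `l` the candidate maximising
#' `sum(log l - log g)` is evaluated next. Deterministic given `seed`.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar to maximise.
#' @param params Named list of parameter definitions; each is either
#'   `list(type = "categorical", values = c(...))` or
#'   `list(type = "integer"|"numeric", lower =, upper =)`.
#' @param n_eval Evaluation budget. A fully degenerate space (every
#'   parameter has a single admissible value) is evaluated exactly once.
#' @param seed Integer seed.
#' @param n_startup Random trials before the density model engages.
#' @param gamma Fraction of trials treated as "good".
#' @param n_candidates Candidates scored per proposal step.
#' @return List with `best_params`, `best_value`, and `trials` (a data.frame
#'   log with one row per evaluation: the parameter values and the objective).
#' @export
tpe_optimize <- function(objective, params, n_eval = 50L, seed = 1L,
                         n_startup = 10L, gamma = 0.25, n_candidates = 24L) {
  stopifnot(length(params) >= 1L, n_eval >= 1L)
  degenerate <- all(vapply(params, function(p) {
    if (p$type == "categorical") length(p$values) == 1L
    else p$lower == p$upper
  }, logical(1)))
  if (degenerate) n_eval <- 1L

  with_seed(seed, {
    trial_params <- vector("list", n_eval)
    values <- numeric(n_eval)
    for (t in seq_len(n_eval)) {
      cand <- if (t <= n_startup) sample_uniform(params) else {
        propose_tpe(params, trial_params[seq_len(t - 1L)],
                    values[seq_len(t - 1L)], gamma, n_candidates)
      }
      trial_params[[t]] <- cand
      values[t] <- objective(cand)
    }
    best <- which.max(values)
    log <- do.call(rbind, lapply(seq_len(n_eval), function(t)
      as.data.frame(trial_params[[t]], stringsAsFactors = FALSE)))
    log$objective <- values
    list(best_params = trial_params[[best]], best_value = values[best],
         trials = log)
  })
}

sample_uniform <- function(params) {
  lapply(params, function(p) {
    switch(p$type,
      categorical = sample(p$values, 1L),
      integer = sample(seq(p$lower, p$upper), 1L),
      numeric = stats::runif(1L, p$lower, p$upper),
      stop2("unknown parameter type: ", p$type))
  })
}

propose_tpe <- function(params, hist, values, gamma, n_candidates) {
  t <- length(values)
  n_good <- max(1L, ceiling(gamma * t))
  ord <- order(values, decreasing = TRUE)
  good <- ord[seq_len(n_good)]
  bad <- if (n_good < t) ord[(n_good + 1L):t] else good
  cands <- vector("list", n_candidates)
  scores <- numeric(n_candidates)
  for (c in seq_len(n_candidates)) {
    cand <- lapply(names(params), function(nm)
      sample_parzen(params[[nm]], lapply(hist[good], `[[`, nm)))
    names(cand) <- names(params)
    s <- 0
    for (nm in names(params)) {
      p <- params[[nm]]
      gx <- unlist(lapply(hist[good], `[[`, nm))
      bx <- unlist(lapply(hist[bad], `[[`, nm))
      s <- s + log(parzen_density(p, cand[[nm]], gx)) -
               log(parzen_density(p, cand[[nm]], bx))
    }
    cands[[c]] <- cand
    scores[c] <- s
  }
  cands[[which.max(scores)]]
}

# Draw one value from the Parzen model of the "good" observations: pick an
# observation (or the uniform prior, with weight 1/(m+1)) and jitter it.
sample_parzen <- function(p, obs) {
  m <- length(obs)
  use_prior <- stats::runif(1L) < 1 / (m + 1)
  if (p$type == "categorical") {
    if (use_prior) return(sample(p$values, 1L))
    return(obs[[sample.int(m, 1L)]])
  }
  lo <- p$lower; up <- p$upper
  if (use_prior) v <- stats::runif(1L, lo, up)
  else {
    bw <- max((up - lo) / 10, 1e-9)
    v <- stats::rnorm(1L, obs[[sample.int(m, 1L)]], bw)
    v <- min(up, max(lo, v))
  }
  if (p$type == "integer") as.integer(round(v)) else v
}

# Parzen mixture density of x under observations `obs` plus a uniform prior
# component (weight 1/(m+1)); categorical parameters use add-one counts.
parzen_density <- function(p, x, obs) {
  m <- length(obs)
  if (p$type == "categorical") {
    cnt <- sum(unlist(obs) == x)
    return((cnt + 1) / (m + length(p$values)))
  }
  lo <- p$lower; up <- p$upper
  width <- max(up - lo, 1e-9)
  bw <- max(width / 10, 1e-9)
  prior <- 1 / width
  if (m == 0L) return(prior)
  kern <- mean(dnorm(x, unlist(obs), bw))
  (prior + m * kern) / (m + 1)
}
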
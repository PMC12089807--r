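#' End-to-end run configuration
#'
#' Assembles the configuration for [run_pipeline()]. Two execution profiles
#' are provided: `"full"` mirrors the study budgets (10x5 outer folds, 5
#' inner folds, 500 TPE evaluations, 500 trees, B = 1000 permutations) and
#' is hours-scale on one CPU; `"ci"` is a scaled-down profile (3x1 outer
#' folds, 3 inner folds, 12 evaluations, 150 trees, B = 100) for smoke runs
#' and continuous testing. All budgets can be overridden individually; the
#' numbers actually used are recorded in the run manifest.
#'
#' @param cohort Either a [cohort_config()] (synthetic run) or a path to a
#'   cohort file for [ingest_cohort()].
#' @param k_range Candidate component counts for both timepoints.
#' @param profile `"full"` or `"ci"`.
#' @param plan,space Optional [cv_plan()] / [hyperparameter_space()]
#'   overrides.
#' @param B Permutation draws override.
#' @param alpha Significance level.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param shap_rows Number of rows SHAP is computed on (sampled without
#'   replacement when smaller than the cohort).
#' @param out_dir Optional output directory for delimited artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), k_range = 2:12,
                       profile = c("ci", "full"), plan = NULL, space = NULL,
                       B = NULL, alpha = 0.05, seed = 1L, shap_rows = NULL,
                       out_dir = NULL) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(plan = cv_plan(10L, 5L, 5L, seed = derive_seed(seed, 1L)),
         space = hyperparameter_space(500L, 500L), B = 1000L,
         shap_rows = Inf)
  } else {
    list(plan = cv_plan(3L, 1L, 3L, seed = derive_seed(seed, 1L)),
         space = hyperparameter_space(150L, 12L), B = 100L,
         shap_rows = 250L)
  }
  structure(list(cohort = cohort, k_range = k_range, profile = profile,
                 plan = plan %||% defaults$plan,
                 space = space %||% defaults$space,
                 B = as.integer(B %||% defaults$B), alpha = alpha,
                 seed = as.integer(seed),
                 shap_rows = shap_rows %||% defaults$shap_rows,
                 out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: generate or ingest the cohort; cluster the
#' baseline and follow-up severity scores (mixture fit + silhouette model
#' selection); binarise and derive the four trajectory labels; train and
#' evaluate one one-vs-rest forest per class with nested CV; tune and refit
#' a full-data model per class for impurity importance, SHAP attributions
#' and direction calls; run permutation inference with BH-FDR control. A
#' machine-readable manifest (config echo, seeds, content hash) makes reruns
#' verifiable: the same config and seed give the identical manifest hash.
#'
#' @param config A [run_config()].
#' @return Object of class `results_bundle`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- run_stage("cohort", {
    if (inherits(config$cohort, "cohort_config")) generate_cohort(config$cohort)
    else ingest_cohort(config$cohort)
  })
  x <- run_stage("features", feature_matrix(cohort))

  baseline <- run_stage("cluster_baseline",
    select_k(cohort$bdi_baseline, config$k_range, seed = derive_seed(seed, 2L)))
  followup <- run_stage("cluster_followup",
    select_k(cohort$bdi_followup, config$k_range, seed = derive_seed(seed, 3L)))
  labels <- run_stage("labels", derive_trajectory_labels(
    binarize_severity(baseline), binarize_severity(followup)))
  traj_summary <- summarize_trajectories(labels)
  targets <- run_stage("targets", make_binary_targets(labels))

  performance <- list(); tuned <- list(); models <- list()
  importance <- matrix(NA_real_, 4L, ncol(x),
                       dimnames = list(TRAJECTORY_CLASSES, colnames(x)))
  shap <- list(); direction <- list()
  shap_idx <- with_seed(derive_seed(seed, 4L), {
    n_shap <- min(nrow(x), config$shap_rows)
    sort(sample.int(nrow(x), n_shap))
  })
  for (cl in TRAJECTORY_CLASSES) {
    i <- match(cl, TRAJECTORY_CLASSES)
    performance[[cl]] <- run_stage(paste0("nested_cv_", cl),
      suppressWarnings(nested_cv_evaluate(
        x, targets[[cl]], plan = config$plan, space = config$space,
        tune = TRUE, seed = derive_seed(seed, 5L, i))))
    tuned[[cl]] <- run_stage(paste0("tune_", cl),
      tune_hyperparameters(x, targets[[cl]], config$space,
                           inner_folds = config$plan$inner_folds,
                           seed = derive_seed(seed, 6L, i))$best_params)
    models[[cl]] <- run_stage(paste0("final_model_", cl),
      fit_final_model(x, targets[[cl]], tuned[[cl]],
                      n_trees = config$space$n_trees,
                      seed = derive_seed(seed, 7L, i), class_label = cl))
    importance[cl, ] <- impurity_importance(models[[cl]])
    shap[[cl]] <- run_stage(paste0("shap_", cl),
      shap_attributions(models[[cl]], x[shap_idx, , drop = FALSE]))
    direction[[cl]] <- direction_summary(shap[[cl]])
  }
  real_f1 <- vapply(performance, function(p)
    p$aggregate$mean[p$aggregate$metric == "f1"], numeric(1))
  inference <- run_stage("inference", run_inference(
    x, labels, tuned, real_f1, importance, B = config$B, plan = config$plan,
    seed = derive_seed(seed, 8L), n_trees = config$space$n_trees,
    alpha = config$alpha))

  manifest <- build_manifest(config, labels, traj_summary, real_f1)
  bundle <- structure(list(
    cohort = cohort, baseline = baseline, followup = followup,
    labels = labels, trajectory_summary = traj_summary,
    performance = performance, tuned_params = tuned, models = models,
    importance = importance, shap = shap, direction = direction,
    inference = inference, manifest = manifest, config = config),
    class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Manifest: everything needed to verify a rerun. The hash covers the config
# and label-level results, not wall-clock time.
build_manifest <- function(config, labels, traj_summary, real_f1) {
  content <- list(
    profile = config$profile, seed = config$seed, k_range = config$k_range,
    plan = unclass(config$plan), n_trees = config$space$n_trees,
    n_evaluations = config$space$n_evaluations, B = config$B,
    alpha = config$alpha, labels = as.character(labels),
    counts = traj_summary$table$n, f1 = round(unname(real_f1), 10))
  list(content = content, hash = object_md5(content),
       package_version = as.character(utils::packageVersion("trajmix")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write.csv(bundle$baseline$diagnostics, p("cluster_diagnostics_baseline.csv"),
            row.names = FALSE)
  write.csv(bundle$followup$diagnostics, p("cluster_diagnostics_followup.csv"),
            row.names = FALSE)
  write.csv(data.frame(participant_id = bundle$cohort$participant_id,
                       trajectory = as.character(bundle$labels)),
            p("trajectory_labels.csv"), row.names = FALSE)
  write.csv(bundle$trajectory_summary$table, p("trajectory_summary.csv"),
            row.names = FALSE)
  perf <- do.call(rbind, lapply(names(bundle$performance), function(cl) {
    a <- bundle$performance[[cl]]$aggregate
    cbind(class = cl, a)
  }))
  write.csv(perf, p("performance.csv"), row.names = FALSE)
  imp <- data.frame(class = rep(rownames(bundle$importance),
                                ncol(bundle$importance)),
                    feature = rep(colnames(bundle$importance),
                                  each = nrow(bundle$importance)),
                    importance = as.vector(bundle$importance))
  write.csv(imp, p("importance.csv"), row.names = FALSE)
  dir_tab <- do.call(rbind, lapply(names(bundle$direction), function(cl)
    cbind(class = cl, bundle$direction[[cl]])))
  write.csv(dir_tab, p("direction.csv"), row.names = FALSE)
  write.csv(bundle$inference$performance, p("inference_performance.csv"),
            row.names = FALSE)
  write.csv(bundle$inference$importance, p("inference_importance.csv"),
            row.names = FALSE)
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("== Depressive-symptom trajectory analysis ==\n")
  cat(sprintf("profile: %s | seed: %d | manifest hash: %s\n",
              x$config$profile, x$config$seed, x$manifest$hash))
  cat(sprintf("baseline: k = %d (silhouette %.3f) | follow-up: k = %d (silhouette %.3f)\n",
              x$baseline$k_selected, x$baseline$silhouette,
              x$followup$k_selected, x$followup$silhouette))
  print(x$trajectory_summary)
  f1 <- vapply(x$performance, function(p)
    p$aggregate$mean[p$aggregate$metric == "f1"], numeric(1))
  cat("mean outer F1:",
      paste(sprintf("%s %.3f", names(f1), f1), collapse = ", "), "\n")
  nsig <- sum(x$inference$importance$significant)
  cat(sprintf("significant importances (q <= %.2f): %d of %d\n",
              x$inference$alpha, nsig, nrow(x$inference$importance)))
  invisible(x)
}
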
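#' Default baseline feature schema
#'
#' Thirty-two baseline features mirroring the variable mix of a congestive
#' heart failure cohort: 8 continuous clinical/behavioural scales, 20 binary
#' indicators (comorbidities, NYHA and ejection-fraction dummies, lifestyle
#' and medication flags) and 4 ordinal variables. Marginal parameters are
#' representative defaults, fully overridable.
#'
#' @return A data.frame with columns `name`, `type`
#'   (`"continuous"|"binary"|"ordinal"`), `loc` and `scale`. For continuous
#'   features `loc`/`scale` are the marginal mean/sd; for binary features
#'   `loc` is the base prevalence; for ordinal features `loc` is the number
#'   of levels (values `0 .. loc-1`).
#' @export
default_feature_schema <- function() {
  cont <- data.frame(
    name = c("eqvas_quality_of_life", "social_stress", "bdq_disability",
             "mspss_social_support", "lec_life_events", "age", "bmi",
             "systolic_bp"),
    type = "continuous",
    loc = c(60, 25, 10, 55, 3, 58, 26, 125),
    scale = c(20, 8, 4, 15, 2, 11, 4, 18))
  bin <- data.frame(
    name = c("nyha_class_2", "nyha_class_3", "ef_class_2", "ef_class_3",
             "sex_male", "smoking", "diabetes", "hypertension", "copd",
             "prior_mi", "stroke", "renal_disease", "anemia", "obesity",
             "alcohol_use", "betablocker_use", "ace_inhibitor_use",
             "diuretic_use", "unemployed", "married"),
    type = "binary",
    loc = c(0.45, 0.35, 0.40, 0.25, 0.55, 0.30, 0.35, 0.50, 0.12,
            0.28, 0.06, 0.10, 0.20, 0.25, 0.08, 0.60, 0.55, 0.65,
            0.40, 0.75),
    scale = NA_real_)
  ord <- data.frame(
    name = c("education_level", "income_bracket", "symptom_duration_band",
             "exercise_frequency"),
    type = "ordinal",
    loc = 5, scale = NA_real_)
  rbind(cont, bin, ord)
}

#' Default planted feature-class effects
#'
#' Effect-size matrix (feature x class) encoding the directional structure
#' reported for this cohort: higher quality of life is associated with good
#' prognosis and clinical worsening and against persistent course; higher
#' social stress with remitting and persistent courses and against the
#' minimal-baseline classes; higher disability with remitting and persistent
#' courses; NYHA class 3 with persistent course and against good
#' prognosis/remitting course. Continuous effects are standardized mean
#' shifts; binary effects are log-odds shifts.
#'
#' @param schema A feature schema (see [default_feature_schema()]).
#' @param strength Multiplier applied to all planted effects (default 1).
#' @return Numeric matrix, `nrow(schema)` x 4, rownames = feature names,
#'   colnames = [trajectory_classes()].
#' @export
default_effect_sizes <- function(schema = default_feature_schema(),
                                 strength = 1) {
  eff <- matrix(0, nrow(schema), 4,
                dimnames = list(schema$name, TRAJECTORY_CLASSES))
  set_eff <- function(feat, cls, v) eff[feat, cls] <<- v
  set_eff("eqvas_quality_of_life", "good_prognosis",      0.6)
  set_eff("eqvas_quality_of_life", "clinical_worsening",  0.6)
  set_eff("eqvas_quality_of_life", "persistent_course",  -0.6)
  set_eff("social_stress",         "good_prognosis",     -0.8)
  set_eff("social_stress",         "remitting_course",    0.8)
  set_eff("social_stress",         "clinical_worsening", -0.6)
  set_eff("social_stress",         "persistent_course",   0.5)
  set_eff("bdq_disability",        "good_prognosis",     -0.5)
  set_eff("bdq_disability",        "remitting_course",    0.6)
  set_eff("bdq_disability",        "persistent_course",   0.5)
  set_eff("nyha_class_3",          "good_prognosis",     -0.9)
  set_eff("nyha_class_3",          "remitting_course",   -0.9)
  set_eff("nyha_class_3",          "persistent_course",   0.9)
  eff * strength
}

#' Synthetic cohort configuration
#'
#' Parameters for [generate_cohort()]. Defaults emulate the reported cohort:
#' n = 783; a two-component baseline severity mixture (weights 0.31/0.69,
#' means 9/24, sds 4/7, matching the minimal-vs-moderate geometry of the
#' 30.65%/69.35% baseline split on a 0-63 BDI scale); class proportions
#' 155:174:85:369; follow-up severity drawn conditionally on trajectory
#' class; 32 features with planted directional effects.
#'
#' @param n_participants Cohort size (default 783).
#' @param baseline_mixture List of two numeric vectors `c(weight, mean, sd)`
#'   for the low- and high-severity baseline components.
#' @param followup_by_class Named list mapping each trajectory class to
#'   `c(mean, sd)` of its follow-up score distribution.
#' @param class_proportions Length-4 nonnegative vector summing to 1, in
#'   [trajectory_classes()] order.
#' @param feature_schema See [default_feature_schema()].
#' @param effect_sizes Feature x class matrix of planted effects
#'   (standardized mean shifts for continuous/ordinal features, log-odds
#'   shifts for binary ones).
#' @param score_floor,score_ceiling Score bounds (BDI scale: 0 and 63).
#' @param round_scores Round scores to integers (BDI is integer-valued);
#'   default TRUE.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 783,
                          baseline_mixture = list(
                            low  = c(weight = 0.31, mean = 9,  sd = 4),
                            high = c(weight = 0.69, mean = 24, sd = 7)),
                          followup_by_class = list(
                            good_prognosis     = c(mean = 6,  sd = 3),
                            remitting_course   = c(mean = 8,  sd = 3),
                            clinical_worsening = c(mean = 26, sd = 5),
                            persistent_course  = c(mean = 32, sd = 7)),
                          class_proportions = c(155, 174, 85, 369) / 783,
                          feature_schema = default_feature_schema(),
                          effect_sizes = default_effect_sizes(feature_schema),
                          score_floor = 0, score_ceiling = 63,
                          round_scores = TRUE, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              baseline_mixture = baseline_mixture,
              followup_by_class = followup_by_class,
              class_proportions = setNames(as.numeric(class_proportions),
                                           TRAJECTORY_CLASSES),
              feature_schema = feature_schema,
              effect_sizes = effect_sizes,
              score_floor = score_floor, score_ceiling = score_ceiling,
              round_scores = isTRUE(round_scores), seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1L) stop2("n_participants must be >= 1")
  w <- vapply(cfg$baseline_mixture, `[[`, 0, "weight")
  m <- vapply(cfg$baseline_mixture, `[[`, 0, "mean")
  s <- vapply(cfg$baseline_mixture, `[[`, 0, "sd")
  if (abs(sum(w) - 1) > 1e-10)
    stop2("baseline mixture weights must sum to 1")
  if (length(unique(m)) < length(m))
    stop2("degenerate baseline mixture: the two component means are equal; ",
          "low/high severity separation is undefined")
  if (!all(TRAJECTORY_CLASSES %in% names(cfg$followup_by_class)))
    stop2("followup_by_class must name all four trajectory classes")
  fs <- vapply(cfg$followup_by_class, `[[`, 0, "sd")
  if (any(c(s, fs) <= 0)) stop2("all component sds must be positive")
  p <- cfg$class_proportions
  if (any(p < 0)) stop2("class_proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-12) stop2("class_proportions must sum to 1")
  if (nrow(cfg$feature_schema) < 1L) stop2("need at least one feature")
  if (!identical(rownames(cfg$effect_sizes), cfg$feature_schema$name) ||
      ncol(cfg$effect_sizes) != 4L)
    stop2("effect_sizes must be a feature x class matrix matching the schema")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n =", x$n_participants, "| features =", nrow(x$feature_schema),
      "| seed =", x$seed, "\n")
  cat("  class proportions:",
      paste(sprintf("%s %.3f", names(x$class_proportions),
                    x$class_proportions), collapse = ", "), "\n")
  cat("  planted effects:", sum(x$effect_sizes != 0), "nonzero cells\n")
  invisible(x)
}

clip_scores <- function(x, lo, hi, round_scores) {
  if (round_scores) x <- round(x)
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic cohort
#'
#' Draws a seeded cohort with the structure the downstream analysis assumes:
#' trajectory classes from a multinomial over `class_proportions`; baseline
#' severity from the low baseline component for the minimal-baseline classes
#' (good prognosis, clinical worsening) and the high component otherwise;
#' follow-up severity from the class-specific follow-up component; features
#' from their marginals shifted by the class's planted effect. Scores are
#' clipped to the configured range.
#'
#' @param config A [cohort_config()].
#' @return A data.frame (class `cohort_table`) with columns
#'   `participant_id`, `bdi_baseline`, `bdi_followup`, the feature columns,
#'   and `true_class`; the schema, effect sizes and config are attached as
#'   attributes.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_participants
  with_seed(config$seed, {
    counts <- as.vector(rmultinom(1, n, config$class_proportions))
    cls <- factor(sample(rep(TRAJECTORY_CLASSES, counts)),
                  levels = TRAJECTORY_CLASSES)
    low_at_baseline <- cls %in% c("good_prognosis", "clinical_worsening")
    bl <- config$baseline_mixture
    base <- ifelse(low_at_baseline,
                   rnorm(n, bl$low["mean"],  bl$low["sd"]),
                   rnorm(n, bl$high["mean"], bl$high["sd"]))
    fu <- config$followup_by_class[TRAJECTORY_CLASSES]
    fu_mean <- vapply(fu, `[[`, 0, "mean")[as.integer(cls)]
    fu_sd   <- vapply(fu, `[[`, 0, "sd")[as.integer(cls)]
    fup <- rnorm(n, fu_mean, fu_sd)
    base <- clip_scores(base, config$score_floor, config$score_ceiling,
                        config$round_scores)
    fup  <- clip_scores(fup,  config$score_floor, config$score_ceiling,
                        config$round_scores)
    feats <- draw_features(config$feature_schema, config$effect_sizes, cls)
    out <- data.frame(participant_id = sprintf("P%05d", seq_len(n)),
                      bdi_baseline = base, bdi_followup = fup,
                      feats, true_class = cls,
                      stringsAsFactors = FALSE, check.names = FALSE)
    attr(out, "feature_schema") <- config$feature_schema
    attr(out, "effect_sizes") <- config$effect_sizes
    attr(out, "config") <- config
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

draw_features <- function(schema, eff, cls) {
  n <- length(cls)
  ci <- as.integer(cls)
  cols <- lapply(seq_len(nrow(schema)), function(j) {
    e <- eff[j, ci]  # per-row planted shift for this feature
    switch(schema$type[j],
      continuous = rnorm(n, schema$loc[j] + e * schema$scale[j],
                         schema$scale[j]),
      binary = rbinom(n, 1, plogis(qlogis(schema$loc[j]) + e)),
      ordinal = {
        # latent-normal shift cut into equiprobable levels 0..L-1
        L <- schema$loc[j]
        th <- qnorm(seq_len(L - 1) / L)
        findInterval(rnorm(n) + e, th)
      },
      stop2("unknown feature type: ", schema$type[j]))
  })
  names(cols) <- schema$name
  as.data.frame(cols, check.names = FALSE)
}

#' Null cohort (no feature-class signal)
#'
#' Returns [generate_cohort()] with all planted effect sizes forced to zero,
#' so every feature is exchangeable across trajectory classes by
#' construction. Used to calibrate the permutation-null inference.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_table`; `attr(, "effect_sizes")` is all-zero.
#' @export
null_cohort <- function(config) {
  config$effect_sizes[] <- 0
  generate_cohort(config)
}

#' Write a cohort table to delimited text
#'
#' @param cohort A `cohort_table` (or compatible data.frame).
#' @param path Output path (comma-separated, UTF-8, header row).
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Export synthetic ground truth
#'
#' Writes the participant-level true trajectory labels to `path` and the
#' planted per-feature effect sizes to a `_effects` sidecar file next to it.
#'
#' @param cohort A synthetic `cohort_table` (must carry `true_class`).
#' @param path Output path for the label file.
#' @return Invisibly, `c(labels = path, effects = effects_path)`.
#' @export
export_ground_truth <- function(cohort, path) {
  if (is.null(cohort$true_class))
    stop2("cohort has no true_class column; ground truth is only available ",
          "for synthetic cohorts")
  labs <- data.frame(participant_id = cohort$participant_id,
                     true_class = as.character(cohort$true_class))
  write.csv(labs, path, row.names = FALSE, fileEncoding = "UTF-8")
  eff <- attr(cohort, "effect_sizes")
  eff_path <- paste0(sub("\\.([^.]+)$", "", path), "_effects.",
                     ifelse(grepl("\\.", basename(path)),
                            sub(".*\\.([^.]+)$", "\\1", path), "csv"))
  if (!is.null(eff)) {
    ed <- data.frame(feature = rownames(eff), eff, check.names = FALSE)
    write.csv(ed, eff_path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(c(labels = path, effects = eff_path))
}

#' Read and validate a cohort table
#'
#' Reads a delimited cohort file, enforces the header contract
#' (`participant_id`, `bdi_baseline`, `bdi_followup` plus feature columns),
#' drops incomplete rows (complete-case analysis) with a warning stating the
#' count, and rejects out-of-range severity scores.
#'
#' @param path Path to a comma-separated cohort file with a header row.
#' @param score_floor,score_ceiling Valid score range (default 0-63).
#' @return A `cohort_table` data.frame.
#' @export
ingest_cohort <- function(path, score_floor = 0, score_ceiling = 63) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("participant_id", "bdi_baseline", "bdi_followup")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop2("cohort file is missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  cc <- complete.cases(x)
  if (any(!cc)) {
    warning(sum(!cc), " row(s) with missing values dropped (complete-case ",
            "analysis)", call. = FALSE)
    x <- x[cc, , drop = FALSE]
  }
  for (col in c("bdi_baseline", "bdi_followup")) {
    bad <- x[[col]] < score_floor | x[[col]] > score_ceiling
    if (any(bad))
      stop2(sum(bad), " value(s) of ", col, " outside the valid score range [",
            score_floor, ", ", score_ceiling, "]")
  }
  if (!is.null(x$true_class))
    x$true_class <- factor(x$true_class, levels = TRAJECTORY_CLASSES)
  rownames(x) <- NULL
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Extract the baseline feature matrix
#'
#' Returns the feature columns of a cohort as a numeric data.frame, always
#' excluding the severity scores (the baseline score defined the clustering,
#' so including it would leak the labels), participant id and true class.
#'
#' @param cohort A `cohort_table`.
#' @param exclude Additional column names to exclude.
#' @return A data.frame of features.
#' @export
feature_matrix <- function(cohort, exclude = character()) {
  drop_cols <- c("participant_id", "bdi_baseline", "bdi_followup",
                 "true_class", exclude)
  x <- as.data.frame(cohort)[, setdiff(names(cohort), drop_cols),
                             drop = FALSE]
  if (any(c("bdi_baseline", "bdi_followup") %in% names(x)))
    stop2("severity scores must never enter the feature matrix")
  x
}
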
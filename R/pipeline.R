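#' Configure an end-to-end pipeline run
#'
#' One object holding everything a full run needs: the synthetic cohort
#' specification (or a manifest of existing NIfTI files), the AEF and
#' texture parameters, the redundancy-filter threshold, the
#' cross-validation folds and the master seed.
#'
#' @param cohort A [cohort_spec()], or `NULL` when `manifest` is given.
#' @param manifest Optional path to a manifest CSV (`subject_id`, `label`,
#'   `group`, `ctu`, `cta`, `ctp`, `mask`) of existing NIfTI files.
#' @param texture A [texture_config()].
#' @param epsilon,clip_range AEF parameters ([compute_aef_map()]).
#' @param filter_threshold Spearman redundancy threshold in (0, 1].
#' @param n_folds LASSO cross-validation folds, >= 2.
#' @param seed Master seed for the run.
#' @param out_dir Output directory for artifacts.
#' @param write_nifti Write per-subject NIfTI volumes (synthetic cohorts
#'   only); default `FALSE` to keep runs light.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), manifest = NULL,
                            texture = texture_config(),
                            epsilon = 1, clip_range = c(0, 4),
                            filter_threshold = 0.9, n_folds = 5L,
                            seed = 1L, out_dir = tempfile("aeftex_run_"),
                            write_nifti = FALSE) {
  if (is.null(cohort) && is.null(manifest))
    stop("either a cohort spec or a manifest is required")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  if (filter_threshold <= 0 || filter_threshold > 1)
    stop("filter_threshold must lie in (0, 1]")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(cohort = cohort, manifest = manifest, texture = texture,
                 epsilon = epsilon, clip_range = clip_range,
                 filter_threshold = filter_threshold,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 out_dir = out_dir, write_nifti = isTRUE(write_nifti)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or manifest loading), AEF map
#' computation and 32-feature extraction per subject, the between-group
#' comparison table, standardization, Spearman redundancy filtering, LASSO
#' selection, the multivariate logistic fit, scoring, and ROC /
#' calibration / decision-curve evaluation. Every intermediate artifact is
#' written under `out_dir` (features and comparison CSVs, model and
#' evaluation JSON, a run manifest with the seed and a config fingerprint).
#' Reruns with the same config and seed reproduce the artifacts exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` holding the feature table,
#'   comparison table, retained/selected feature names, fitted model,
#'   scores and evaluation report, plus the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  report <- tryCatch({
    if (!is.null(config$manifest)) {
      features <- manifest_features(config)
    } else {
      cohort <- generate_cohort(config$cohort)
      if (config$write_nifti)
        write_cohort_nifti(cohort, file.path(config$out_dir, "nifti"))
      stage <- "features"
      features <- cohort_features(cohort, config = config$texture,
                                  epsilon = config$epsilon,
                                  clip_range = config$clip_range)
    }
    features_path <- file.path(config$out_dir, "features.csv")
    utils::write.csv(features, features_path, row.names = FALSE)

    stage <- "compare"
    comparison <- compare_feature_table(features)
    comparison_path <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(comparison, comparison_path, row.names = FALSE)

    stage <- "select"
    std <- standardize_features(features)
    retained <- spearman_filter(std, threshold = config$filter_threshold)
    selected <- lasso_select(std, feature_names = retained,
                             n_folds = config$n_folds, seed = config$seed)
    if (!length(selected)) selected <- retained[1]  # degenerate fallback

    stage <- "fit"
    model <- fit_logistic(std, feature_names = as.character(selected),
                          name = "fitted",
                          outcome_label = levels(factor(features$label))[1])
    model_path <- file.path(config$out_dir, "model.json")
    write_model_spec(model, model_path,
                     standardization = attr(std, "standardization"))

    stage <- "score"
    scores <- published_model_score(std, model)
    scores_df <- cbind(features[c("subject_id", "label", "group")], scores)
    scores_path <- file.path(config$out_dir, "scores.csv")
    utils::write.csv(scores_df, scores_path, row.names = FALSE)

    stage <- "evaluate"
    evaluation <- evaluate_model(scores$probability, features$group)
    eval_path <- file.path(config$out_dir, "evaluation.json")
    jsonlite::write_json(
      list(roc = unclass(evaluation$roc)[c("auc", "cutoff", "accuracy",
                                           "sensitivity", "specificity")],
           calibration = evaluation$calibration[c("slope", "intercept")],
           decision = as.data.frame(evaluation$decision),
           meta = evaluation$meta),
      eval_path, auto_unbox = TRUE, digits = NA)

    list(features = features, comparison = comparison,
         retained = retained, selected = as.character(selected),
         model = model, scores = scores_df, evaluation = evaluation,
         paths = list(features = features_path, comparison = comparison_path,
                      model = model_path, scores = scores_path,
                      evaluation = eval_path))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  config_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config_fingerprint_obj(config), config_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("aeftex")),
         r_version = as.character(getRversion()),
         seed = config$seed,
         config_md5 = unname(tools::md5sum(config_path)),
         artifacts = report$paths),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$paths$manifest <- manifest_path
  class(report) <- "pipeline_report"
  report
}

# Serializable view of the config (drops classes recursively, keeps values).
config_fingerprint_obj <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  strip(config)
}

# Feature extraction over a manifest of existing NIfTI studies.
manifest_features <- function(config) {
  man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "group", "ctu", "cta", "ctp", "mask")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(man)), function(i) {
    mv <- read_multiphase_nifti(man$ctu[i], man$cta[i], man$ctp[i])
    roi <- read_roi_nifti(man$mask[i])
    aef <- compute_aef_map(mv, epsilon = config$epsilon,
                           clip_range = config$clip_range)
    fv <- extract_features(aef, roi, config$texture)
    cbind(data.frame(subject_id = man$subject_id[i], label = man$label[i],
                     group = man$group[i],
                     tumor_area_cm2 = attr(fv, "tumor_area_cm2")),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects | %d features retained, %d selected\n",
              nrow(x$features), length(x$retained), length(x$selected)))
  print(x$evaluation$roc)
  invisible(x)
}
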
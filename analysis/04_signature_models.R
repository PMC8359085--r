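#!/usr/bin/env Rscript
# Build the radiomics signature models on the synthetic cohorts and load the
# published fixed-coefficient models.
#
# Per grouping scheme: standardize all 32 features, drop redundant ones
# (Spearman |rho| >= 0.9, keeping the stronger univariate association),
# select features by LASSO-penalized logistic regression (penalty tuned by
# stratified 5-fold cross-validation, minimum mean deviance), and refit an
# unpenalized multivariate logistic model on the selection. The published
# models A (Improved, 9 terms) and B (Un-worsened, 4 terms) are fixed
# coefficient sets shipped with the package.

suppressPackageStartupMessages(library(aeftex))

seed <- 20260924L

for (scheme in c("improved", "unworsened")) {
  path <- file.path("results", sprintf("features_%s.csv", scheme))
  if (!file.exists(path))
    stop("run analysis/02_compute_features.R first (missing ", path, ")")
  features <- read.csv(path)
  std <- standardize_features(features)
  retained <- spearman_filter(std)
  cat(sprintf("\n%s: %d/32 features survive the redundancy filter\n",
              scheme, length(retained)))
  selected <- lasso_select(std, feature_names = retained, seed = seed)
  cat(sprintf("  LASSO (lambda = %.4f) keeps %d: %s\n",
              attr(selected, "lambda"), length(selected),
              paste(selected, collapse = ", ")))
  model <- withCallingHandlers(
    fit_logistic(std, feature_names = as.character(selected),
                 name = sprintf("fitted_%s", scheme),
                 outcome_label = levels(factor(features$label))[1]),
    warning = function(w) {
      cat("  note:", conditionMessage(w), "\n")
      invokeRestart("muffleWarning")
    })
  print(model)
  out <- file.path("results", sprintf("model_%s.json", scheme))
  write_model_spec(model, out,
                   standardization = attr(std, "standardization"))
  cat(sprintf("  -> %s\n", out))
}

cat("\nPublished fixed-coefficient models shipped with the package:\n")
print(published_model("A"))
print(published_model("B"))
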
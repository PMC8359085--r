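#!/usr/bin/env Rscript
# Evaluate the fitted signature models: ROC with Youden-cutoff metrics,
# calibration, and decision-curve analysis.
#
# Discrimination is summarized by the AUC and by accuracy / sensitivity /
# specificity at the cutoff maximizing Youden's J; calibration by the
# recalibration slope (1 = perfect); clinical utility by the net benefit of
# model-guided treatment against treat-all and treat-none across threshold
# probabilities. Note these are apparent (resubstitution) estimates on the
# same synthetic cohort the models were fitted to.

suppressPackageStartupMessages(library(aeftex))

for (scheme in c("improved", "unworsened")) {
  fpath <- file.path("results", sprintf("features_%s.csv", scheme))
  mpath <- file.path("results", sprintf("model_%s.json", scheme))
  if (!file.exists(fpath) || !file.exists(mpath))
    stop("run analysis/02 and analysis/04 first")
  features <- read.csv(fpath)
  std <- standardize_features(features)
  raw <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  model <- model_spec(raw$name, raw$outcome, raw$intercept,
                      unlist(raw$coefficients))
  scores <- published_model_score(std, model)
  ev <- evaluate_model(scores$probability, features$group)
  cat(sprintf("\n%s grouping ('%s' model):\n", scheme, model$name))
  print(ev$roc)
  cat(sprintf("  calibration slope %.3f, intercept %.3f\n",
              ev$calibration$slope, ev$calibration$intercept))
  nb50 <- ev$decision[ev$decision$threshold == 0.5, ]
  cat(sprintf("  net benefit at pt = 0.5: model %.3f vs treat-all %.3f\n",
              nb50$nb_model, nb50$nb_all))
  out <- file.path("results", sprintf("evaluation_%s.json", scheme))
  jsonlite::write_json(
    list(roc = unclass(ev$roc)[c("auc", "cutoff", "accuracy", "sensitivity",
                                 "specificity")],
         calibration = ev$calibration[c("slope", "intercept")],
         decision = as.data.frame(ev$decision), meta = ev$meta),
    out, auto_unbox = TRUE, digits = NA)
  cat(sprintf("  -> %s\n", out))
}
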
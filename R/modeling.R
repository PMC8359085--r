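#' Standardize feature columns
#'
#' Centers and scales each feature column to mean 0, sd 1 (sample sd, n-1
#' denominator), recording the per-feature means and sds so new subjects
#' can be scored on the training scale.
#'
#' @param features Data frame holding the feature columns.
#' @param feature_names Columns to standardize; defaults to the 32-name
#'   catalogue intersected with the available columns.
#' @return The data frame with standardized columns and an attribute
#'   `standardization`: a data frame of `feature`, `mean`, `sd`.
#' @export
standardize_features <- function(features,
                                 feature_names =
                                   intersect(aef_feature_names(),
                                             names(features))) {
  stopifnot(is.data.frame(features))
  mu <- numeric(length(feature_names)); sdev <- numeric(length(feature_names))
  for (k in seq_along(feature_names)) {
    f <- feature_names[k]
    x <- features[[f]]
    mu[k] <- mean(x); sdev[k] <- stats::sd(x)
    if (is.na(sdev[k]) || sdev[k] == 0)
      stop(sprintf("feature '%s' has zero variance and cannot be standardized", f))
    features[[f]] <- (x - mu[k]) / sdev[k]
  }
  attr(features, "standardization") <-
    data.frame(feature = feature_names, mean = mu, sd = sdev)
  features
}

#' Spearman redundancy filter
#'
#' Greedy elimination of redundant features: among every pair with
#' `|rho| >= threshold` (Spearman rank correlation), the feature with the
#' weaker univariate outcome association (larger Mann-Whitney p against the
#' binary outcome) is dropped; ties break alphabetically (the
#' alphabetically earlier name is kept). No retained pair correlates at or
#' above the threshold. Rank-based, so standardization does not affect it.
#'
#' @param features Data frame with the feature columns and the outcome.
#' @param outcome Name of the binary 0/1 outcome column (default `"group"`).
#' @param feature_names Candidate features; default the 32-name catalogue.
#' @param threshold Absolute Spearman correlation at or above which a pair
#'   is redundant; default 0.9.
#' @return Character vector of retained feature names (original order).
#' @export
spearman_filter <- function(features, outcome = "group",
                            feature_names = aef_feature_names(),
                            threshold = 0.9) {
  stopifnot(is.data.frame(features), outcome %in% names(features))
  if (length(feature_names) < 2L) return(feature_names)
  y <- features[[outcome]]
  x <- as.matrix(features[feature_names])
  rho <- stats::cor(x, method = "spearman")
  # univariate association strength: Mann-Whitney p (smaller is stronger)
  assoc <- vapply(feature_names, function(f) {
    compare_groups_continuous(x[y == 0, f], x[y == 1, f],
                              force_test = "wilcox")$p
  }, numeric(1))
  keep <- feature_names
  repeat {
    sub <- abs(rho[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (all(sub < threshold)) break
    worst <- which(sub >= threshold, arr.ind = TRUE)[1, ]
    a <- keep[worst[1]]; b <- keep[worst[2]]
    drop <- if (assoc[a] < assoc[b]) b
            else if (assoc[b] < assoc[a]) a
            else sort(c(a, b))[2]  # tie: keep the alphabetically earlier
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Stratified cross-validation fold assignment
#'
#' Deterministic stratified fold ids: within each outcome class, subjects
#' are shuffled under the seed and dealt round-robin into folds, so both
#' classes appear in every fold whenever class sizes permit.
#'
#' @param y Binary outcome vector.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(y, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (min(table(y)) < n_folds)
    warning("fewer subjects in a class than folds: some folds lack a class")
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' LASSO feature selection with cross-validated penalty
#'
#' L1-penalized logistic regression over a descending penalty grid
#' (`glmnet`), with the penalty chosen to minimize the mean cross-validated
#' binomial deviance over stratified folds. Features with nonzero
#' coefficients at the chosen penalty are returned. Deterministic given the
#' seed (folds are fixed before fitting).
#'
#' @param features Data frame with standardized feature columns and the
#'   outcome.
#' @param outcome Binary 0/1 outcome column name (default `"group"`).
#' @param feature_names Candidate features.
#' @param n_folds Cross-validation folds; default 5.
#' @param seed Integer seed controlling the fold assignment.
#' @return Character vector of selected feature names, with attributes
#'   `lambda` (chosen penalty), `cvm` (mean CV deviance at the choice) and
#'   `fold` (the fold ids used). Empty selection (with a warning) when the
#'   penalized fit keeps no feature.
#' @export
lasso_select <- function(features, outcome = "group",
                         feature_names = aef_feature_names(),
                         n_folds = 5L, seed = 1L) {
  stopifnot(is.data.frame(features), outcome %in% names(features))
  if (length(feature_names) < 2L) stop("need at least 2 candidate features")
  x <- as.matrix(features[feature_names])
  y <- features[[outcome]]
  fold <- stratified_folds(y, n_folds = n_folds, seed = seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                          type.measure = "deviance", foldid = fold,
                          standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  selected <- names(co)[co != 0]
  if (!length(selected))
    warning("LASSO retained no feature at the chosen penalty")
  structure(selected, lambda = cv$lambda.min,
            cvm = min(cv$cvm), fold = fold)
}

#' Multivariate logistic fit
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' given feature subset, with Wald z and two-tailed p per term. Perfect
#' separation is detected (fitted probabilities numerically 0/1) and
#' recorded as a warning flag on the returned model rather than an error.
#'
#' @param features Data frame with (standardized) feature columns and the
#'   outcome.
#' @param outcome Binary 0/1 outcome column name (default `"group"`).
#' @param feature_names Non-empty feature subset to fit.
#' @param name Model name recorded in the result.
#' @param outcome_label Human-readable positive-outcome label.
#' @return A [model_spec()] with fitted intercept, coefficients, `z` and
#'   `p` per term, and `separation` flag.
#' @export
fit_logistic <- function(features, outcome = "group",
                         feature_names, name = "fitted",
                         outcome_label = outcome) {
  stopifnot(is.data.frame(features), outcome %in% names(features))
  if (!length(feature_names)) stop("feature subset must be non-empty")
  if (nrow(features) <= length(feature_names) + 1L)
    stop("more model terms than subjects")
  dat <- features[c(outcome, feature_names)]
  names(dat)[1] <- ".y"
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # glm can converge before its own 0/1 warning fires; check directly
  if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    sep <- TRUE
  if (sep)
    warning("perfect or quasi-perfect separation: coefficients are at the ",
            "iteration cap and standard errors are unreliable")
  sm <- summary(fit)$coefficients
  model_spec(name = name, outcome = outcome_label,
             intercept = unname(sm[1, 1]),
             coefficients = stats::setNames(sm[-1, 1], feature_names),
             z = stats::setNames(sm[-1, 3], feature_names),
             p = stats::setNames(sm[-1, 4], feature_names),
             separation = sep)
}

#' Construct a named logistic model specification
#'
#' A fixed logistic model: intercept plus one coefficient per named
#' feature, applied to standardized features. Houses both freshly fitted
#' models and the published fixed-coefficient models.
#'
#' @param name Model name (e.g. `"A"`, `"B"`).
#' @param outcome Positive-outcome label the model predicts.
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric vector; every name must belong to the
#'   32-feature catalogue.
#' @param z,p Optional named per-term Wald z and p.
#' @param separation Logical separation flag (fitted models only).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, outcome, intercept, coefficients,
                       z = NULL, p = NULL, separation = FALSE) {
  bad <- setdiff(names(coefficients), aef_feature_names())
  if (length(bad))
    stop("unknown feature names in coefficients: ", paste(bad, collapse = ", "))
  structure(list(name = name, outcome = outcome,
                 intercept = as.numeric(intercept),
                 coefficients = coefficients, z = z, p = p,
                 separation = isTRUE(separation)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> Model %s ('%s'): intercept %.4f + %d terms%s\n",
              x$name, x$outcome, x$intercept, length(x$coefficients),
              if (x$separation) " [separation warning]" else ""))
  for (f in names(x$coefficients))
    cat(sprintf("  %+10.4f x %s\n", x$coefficients[[f]], f))
  invisible(x)
}

#' Load a published fixed-coefficient prediction model
#'
#' The two published AEF texture models ship with the package as JSON
#' resources: Model A (9 terms) predicts the "Improved" (complete or
#' partial response) outcome and Model B (4 terms) the "Un-worsened"
#' (non-progressive) outcome. Both apply to standardized features.
#'
#' @param name `"A"` or `"B"`.
#' @return A [model_spec()].
#' @export
published_model <- function(name = c("A", "B")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models",
                      sprintf("model_%s.json", tolower(name)),
                      package = "aeftex", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(name = raw$name, outcome = raw$outcome,
             intercept = raw$intercept,
             coefficients = unlist(raw$coefficients),
             z = if (!is.null(raw$z)) unlist(raw$z),
             p = if (!is.null(raw$p)) unlist(raw$p))
}

#' Score subjects with a fixed logistic model
#'
#' Linear predictor `intercept + sum(coefficient * standardized feature)`
#' and the logistic probability `1 / (1 + exp(-lp))`.
#'
#' @param features Data frame (or named vector for one subject) of
#'   standardized feature values; every feature the model references must
#'   be present.
#' @param model A [model_spec()].
#' @return Data frame with `linear_predictor` and `probability`.
#' @export
published_model_score <- function(features, model) {
  stopifnot(inherits(model, "model_spec"))
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  need <- names(model$coefficients)
  missing_f <- setdiff(need, names(features))
  if (length(missing_f))
    stop("missing model feature(s): ", paste(missing_f, collapse = ", "))
  x <- as.matrix(features[need])
  lp <- as.numeric(model$intercept + x %*% model$coefficients[need])
  data.frame(linear_predictor = lp, probability = stats::plogis(lp))
}

#' Serialize a model specification to JSON
#'
#' @param model A [model_spec()].
#' @param path Output file path.
#' @param standardization Optional standardization record (data frame of
#'   `feature`, `mean`, `sd`) stored alongside the coefficients.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path, standardization = NULL) {
  stopifnot(inherits(model, "model_spec"))
  obj <- list(name = model$name, outcome = model$outcome,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients))
  if (!is.null(model$z)) obj$z <- as.list(model$z)
  if (!is.null(model$p)) obj$p <- as.list(model$p)
  if (!is.null(standardization)) {
    obj$standardization <- stats::setNames(
      lapply(seq_len(nrow(standardization)), function(i)
        list(mean = standardization$mean[i], sd = standardization$sd[i])),
      standardization$feature)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
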
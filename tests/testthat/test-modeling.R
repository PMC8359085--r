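make_feature_df <- function(n, p = 5, seed = 1, beta = NULL, names_ = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  nm <- if (is.null(names_)) aef_feature_names()[seq_len(p)] else names_
  colnames(x) <- nm
  lp <- if (is.null(beta)) rep(0, n) else drop(x %*% beta)
  y <- rbinom(n, 1, plogis(lp))
  cbind(data.frame(group = y), as.data.frame(x))
}

test_that("standardization centers and scales with the sample-sd convention", {
  df <- data.frame(MeanValue = c(2, 4, 6), Entropy = c(1, 5, 9))
  out <- standardize_features(df)
  expect_equal(out$MeanValue, c(-1, 0, 1))  # sd(c(2,4,6)) = 2
  rec <- attr(out, "standardization")
  expect_equal(rec$mean[rec$feature == "MeanValue"], 4)
  expect_equal(rec$sd[rec$feature == "MeanValue"], 2)
  # population-sd hand value for contrast: (2-4)/sd_pop = -1.2247; here n-1
  expect_equal(out$MeanValue[1], (2 - 4) / sd(c(2, 4, 6)))
  # idempotence
  again <- standardize_features(out)
  expect_equal(again$MeanValue, out$MeanValue, tolerance = 1e-12)
  expect_error(standardize_features(data.frame(Entropy = rep(1, 4))),
               "Entropy")
})

test_that("spearman filter removes duplicated and collinear features", {
  set.seed(2)
  n <- 40
  base <- rnorm(n)
  df <- data.frame(group = rep(0:1, each = n / 2),
                   MeanValue = base,
                   Entropy = base + 1e-9 * rnorm(n),     # rank-duplicate
                   Energy = 2 * base + 5,                 # monotone copy
                   Skewness = rnorm(n))
  keep <- spearman_filter(df, feature_names = c("MeanValue", "Entropy",
                                                "Energy", "Skewness"))
  expect_true("Skewness" %in% keep)
  expect_equal(sum(c("MeanValue", "Entropy", "Energy") %in% keep), 1)
  rho <- cor(as.matrix(df[keep]), method = "spearman")
  diag(rho) <- 0
  expect_true(all(abs(rho) < 0.9))
})

test_that("independent columns survive the filter", {
  set.seed(3)
  df <- make_feature_df(100, p = 8, seed = 3)
  keep <- spearman_filter(df, feature_names = names(df)[-1])
  expect_equal(sort(keep), sort(names(df)[-1]))
})

test_that("filter output is order-independent for distinct associations", {
  set.seed(4)
  n <- 40
  y <- rep(0:1, each = n / 2)
  strong <- as.numeric(1:n)          # perfect group separation
  weak <- strong
  weak[15:20] <- strong[21:26]       # swap six values across the groups:
  weak[21:26] <- strong[15:20]       # still |rho| >= 0.9, weaker association
  expect_gte(cor(strong, weak, method = "spearman"), 0.9)
  df <- data.frame(group = y, MeanValue = strong, Entropy = weak,
                   Skewness = rnorm(n))
  k1 <- spearman_filter(df, feature_names = c("MeanValue", "Entropy",
                                              "Skewness"))
  k2 <- spearman_filter(df, feature_names = c("Entropy", "Skewness",
                                              "MeanValue"))
  expect_setequal(k1, k2)
  expect_true("MeanValue" %in% k1)  # the stronger of the redundant pair
})

test_that("stratified folds are deterministic and cover both classes", {
  y <- rep(c(0, 1), c(30, 20))
  f1 <- stratified_folds(y, 5, seed = 9)
  f2 <- stratified_folds(y, 5, seed = 9)
  expect_identical(f1, f2)
  for (k in 1:5) expect_setequal(unique(y[f1 == k]), c(0, 1))
  expect_false(identical(f1, stratified_folds(y, 5, seed = 10)))
  expect_error(stratified_folds(y, 1), ">= 2")
})

test_that("LASSO recovers an informative feature and is seed-deterministic", {
  df <- make_feature_df(200, p = 10, seed = 5,
                        beta = c(2, rep(0, 9)))
  s1 <- lasso_select(df, feature_names = names(df)[-1], seed = 3)
  s2 <- lasso_select(df, feature_names = names(df)[-1], seed = 3)
  expect_identical(as.character(s1), as.character(s2))
  expect_true(names(df)[2] %in% s1)
})

test_that("LASSO under the pure null keeps few features", {
  sizes <- integer(20)
  for (r in seq_len(20)) {
    df <- make_feature_df(80, p = 10, seed = 200 + r)
    sel <- suppressWarnings(
      lasso_select(df, feature_names = names(df)[-1], seed = r))
    sizes[r] <- length(sel)
  }
  expect_lte(median(sizes), 2)
})

test_that("logistic fit recovers simulated coefficients within 3 SE", {
  beta <- c(0.8, -0.6, 0.3)
  df <- make_feature_df(2000, p = 3, seed = 6, beta = beta)
  m <- fit_logistic(df, feature_names = names(df)[-1])
  fit <- glm(group ~ ., data = df, family = binomial())
  se <- summary(fit)$coefficients[-1, 2]
  expect_true(all(abs(m$coefficients - beta) < 3 * se))
  expect_true(all(m$p[abs(beta) > 0.5] < 0.05))
})

test_that("balanced null data put the fitted intercept near logit(0.5) = 0", {
  set.seed(7)
  covered <- 0L
  for (r in 1:20) {
    df <- make_feature_df(300, p = 2, seed = 700 + r)
    m <- fit_logistic(df, feature_names = names(df)[-1])
    fit <- glm(group ~ ., data = df, family = binomial())
    se0 <- summary(fit)$coefficients[1, 2]
    if (abs(m$intercept) < 2.5 * se0) covered <- covered + 1L
  }
  expect_gte(covered, 17)
})

test_that("perfect separation is flagged, not fatal", {
  df <- data.frame(group = rep(c(0, 1), each = 10),
                   MeanValue = rep(c(-1, 1), each = 10))
  expect_warning(m <- fit_logistic(df, feature_names = "MeanValue"),
                 "separation")
  expect_true(m$separation)
})

test_that("published models carry the printed intercepts and term counts", {
  ma <- published_model("A")
  mb <- published_model("B")
  expect_length(ma$coefficients, 9)
  expect_length(mb$coefficients, 4)
  za <- setNames(rep(0, 9), names(ma$coefficients))
  zb <- setNames(rep(0, 4), names(mb$coefficients))
  expect_equal(published_model_score(za, ma)$linear_predictor, -7.1555)
  expect_equal(published_model_score(zb, mb)$linear_predictor, 3.1287)
  expect_equal(published_model_score(za, ma)$probability,
               plogis(-7.1555))
})

test_that("scoring is affine with slope equal to the printed coefficient", {
  ma <- published_model("A")
  mb <- published_model("B")
  for (m in list(ma, mb)) {
    z <- setNames(rep(0, length(m$coefficients)), names(m$coefficients))
    base <- published_model_score(z, m)$linear_predictor
    for (f in names(m$coefficients)) {
      z1 <- z; z1[f] <- 1
      expect_equal(published_model_score(z1, m)$linear_predictor - base,
                   unname(m$coefficients[f]))
    }
  }
  # positive ClusterProminence coefficient raises both models' predictor
  for (m in list(ma, mb)) expect_gt(m$coefficients[["ClusterProminence"]], 0)
})

test_that("scoring errors on a missing feature by name", {
  ma <- published_model("A")
  z <- setNames(rep(0, 8), names(ma$coefficients)[-1])
  expect_error(published_model_score(z, ma), "MinIntensity")
})

test_that("model specs round-trip through JSON", {
  m <- model_spec("X", "Improved", 1.5,
                  c(MeanValue = 2, Entropy = -1))
  path <- tempfile(fileext = ".json")
  write_model_spec(m, path,
                   standardization = data.frame(feature = c("MeanValue",
                                                            "Entropy"),
                                                mean = c(1, 2),
                                                sd = c(3, 4)))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(raw$intercept, 1.5)
  expect_equal(raw$coefficients$MeanValue, 2)
  expect_equal(raw$standardization$Entropy$sd, 4)
  expect_error(model_spec("X", "y", 0, c(NotAFeature = 1)), "NotAFeature")
})
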
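test_that("largest axial plane picks the max-count plane with low-index ties", {
  m <- array(FALSE, c(6, 6, 8))
  m[2:4, 2:4, 5] <- TRUE
  expect_equal(largest_axial_plane(roi_mask(m)), 5)
  # digital sphere: plane through the center carries the most pixels
  gp <- test_phantom(seed = 2, noise = 0, grid = c(32, 32, 11), radius = 7)
  counts <- apply(gp$mask$mask, 3, sum)  # brute-force per-plane count
  expect_equal(largest_axial_plane(gp$mask), which.max(counts))
  expect_equal(largest_axial_plane(gp$mask), 6)
  # exact tie: lower index wins
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1:2, 1:2, 2] <- TRUE
  m2[1:2, 1:2, 4] <- TRUE
  expect_equal(largest_axial_plane(roi_mask(m2)), 2)
  expect_error(largest_axial_plane(roi_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("tumor area is pixel count times pixel size in cm^2", {
  m <- array(FALSE, c(20, 20, 3))
  m[1:10, 1:10, 2] <- TRUE  # 100 pixels
  expect_equal(tumor_area(roi_mask(m, c(0.8, 0.8, 3))), 0.64)
  m1 <- array(FALSE, c(4, 4, 1)); m1[1, 1, 1] <- TRUE
  expect_equal(tumor_area(roi_mask(m1, c(1, 1, 1))), 0.01)
  mfull <- array(TRUE, c(64, 64, 1))
  expect_equal(tumor_area(roi_mask(mfull, c(0.8, 0.8, 3))), 26.2144)
})

test_that("quantization maps ranges onto 1..Ng with documented edge rules", {
  expect_equal(as.vector(quantize_levels(c(0.7, 0.7, 0.7), 4)), c(1L, 1L, 1L))
  expect_equal(as.vector(quantize_levels(c(0, 1), 2)), c(1L, 2L))
  # 64 equally spaced values with Ng = 64: each level used exactly once
  x <- seq(0, 1, length.out = 64)
  expect_equal(sort(unique(as.vector(quantize_levels(x, 64)))), 1:64)
  expect_equal(max(tabulate(quantize_levels(x, 64), 64)), 1L)
  # NAs pass through
  q <- quantize_levels(c(1, NA, 2), 2)
  expect_true(is.na(q[2]))
})

test_that("intensity features match hand-computed values", {
  cfg <- texture_config(n_hist_bins = 2, n_gray_levels = 2)
  f <- intensity_features(c(1, 1, 2, 2), cfg)
  expect_equal(unname(f["Entropy"]), 1)        # p = (0.5, 0.5), bits
  expect_equal(unname(f["Uniformity"]), 0.5)
  expect_equal(unname(f["Energy"]), 0.5)
  expect_equal(unname(f["MeanValue"]), 1.5)
  expect_equal(unname(f["Range"]), 1)
  expect_equal(unname(f["VoxelValueSum"]), 6)
  expect_equal(unname(f["VolumeCount"]), 4)
  expect_equal(unname(f["MeanDeviation"]), 0.5)
  expect_equal(unname(f["Variance"]), unname(f["StdDeviation"])^2)
  expect_equal(unname(f["RelativeDeviation"]),
               unname(f["StdDeviation"]) / 1.5)
  expect_equal(unname(f["Skewness"]), 0)  # symmetric sample
})

test_that("constant and single-pixel inputs take the degenerate conventions", {
  f <- intensity_features(rep(0.7, 9))
  expect_equal(unname(f[c("MinIntensity", "MaxIntensity", "MedianIntensity",
                          "MeanValue")]), rep(0.7, 4))
  expect_equal(unname(f[c("Variance", "Range", "Entropy", "Skewness",
                          "Kurtosis")]), rep(0, 5))
  expect_equal(unname(f["Uniformity"]), 1)
  f1 <- intensity_features(0.3)
  expect_equal(unname(f1[c("StdDeviation", "Variance", "Skewness",
                           "Kurtosis")]), rep(0, 4))
})

test_that("skewness is zero for symmetric samples and signed correctly", {
  set.seed(7)
  sym <- c(rnorm(50))
  sym <- c(sym, -sym)  # exactly symmetric about 0
  expect_equal(unname(intensity_features(sym)["Skewness"]), 0)
  right <- rexp(500)
  expect_gt(unname(intensity_features(right)["Skewness"]), 0)
})

test_that("co-occurrence matrices match the hand-enumerated 2x2 example", {
  lev <- matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE)
  cfg <- texture_config(n_gray_levels = 2,
                        directions = list(c(0L, 1L)))
  p <- glcm(lev, cfg)[[1]]
  # two horizontal pairs (1,1), (1,2); symmetrized
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[1, 2], 0.25)
  expect_equal(p[2, 1], 0.25)
  expect_equal(sum(p), 1)
  expect_equal(p, t(p))
})

test_that("constant plane: all GLCM mass on the diagonal, degenerate features", {
  lev <- matrix(1L, 4, 4)
  cfg <- texture_config(n_gray_levels = 3)
  ms <- glcm(lev, cfg)
  for (p in ms) expect_equal(p[1, 1], 1)
  f <- glcm_features(ms)
  expect_equal(unname(f["Inertia"]), 0)
  expect_equal(unname(f["InverseDifferenceMoment"]), 1)
  expect_equal(unname(f["Correlation"]), 1)
  expect_equal(unname(f["HaralickCorrelation"]), 1)
})

test_that("checkerboard inertia is 1: every horizontal pair differs by one level", {
  lev <- matrix(rep(c(1L, 2L), each = 4), 4, 4)  # columns alternate 1/2
  cfg <- texture_config(n_gray_levels = 2, directions = list(c(0L, 1L)))
  f <- glcm_features(glcm(lev, cfg))
  expect_equal(unname(f["Inertia"]), 1)
})

test_that("run-length matrices enumerate maximal runs and conserve pixels", {
  lev <- matrix(c(1L, 1L, 2L), 1, 3)
  cfg <- texture_config(n_gray_levels = 2, directions = list(c(0L, 1L)))
  r <- glrlm(lev, cfg)[[1]]
  expect_equal(r[1, 2], 1L)  # run of level 1, length 2
  expect_equal(r[2, 1], 1L)  # run of level 2, length 1
  expect_equal(sum(r), 2L)
  # constant row: one run of length N
  rN <- glrlm(matrix(2L, 1, 5), cfg)[[1]]
  expect_equal(rN[2, 5], 1L)
  expect_equal(sum(rN), 1L)
  # conservation per direction on a random plane, NA-broken runs included
  set.seed(11)
  lev2 <- random_levels_plane(6, 6, 4)
  cfg4 <- texture_config(n_gray_levels = 4)
  for (r2 in glrlm(lev2, cfg4)) {
    l <- matrix(seq_len(ncol(r2)), nrow(r2), ncol(r2), byrow = TRUE)
    expect_equal(sum(r2 * l), sum(!is.na(lev2)))
  }
})

test_that("run-length features match closed forms on degenerate planes", {
  cfg <- texture_config(n_gray_levels = 4, directions = list(c(0L, 1L)))
  # all runs length 1 (alternating levels): SRE = LRE = 1
  lev <- matrix(rep(c(1L, 2L), 4), 1, 8)
  f <- glrlm_features(glrlm(lev, cfg))
  expect_equal(unname(f["ShortRunEmphasis"]), 1)
  expect_equal(unname(f["LongRunEmphasis"]), 1)
  # single run of length 4
  f4 <- glrlm_features(glrlm(matrix(1L, 1, 4), cfg))
  expect_equal(unname(f4["ShortRunEmphasis"]), 1 / 16)
  expect_equal(unname(f4["LongRunEmphasis"]), 16)
  # constant plane at level g: HighGreyLevelRunEmphasis = g^2
  lev_g <- matrix(3L, 1, 6)
  fg <- glrlm_features(glrlm(lev_g, cfg))
  expect_equal(unname(fg["HighGreyLevelRunEmphasis"]), 9)
})

test_that("matrix builders and all 16 matrix features match brute force on random planes", {
  set.seed(21)
  for (rep in 1:40) {
    lev <- random_levels_plane(6, 6, sample(2:4, 1))
    cfg <- texture_config(n_gray_levels = max(lev, na.rm = TRUE),
                          directions = std_directions)
    ms <- glcm(lev, cfg)
    bfs <- Filter(Negate(is.null),
                  lapply(std_directions, function(d) bf_glcm(lev, d)))
    expect_equal(length(ms), length(bfs))
    for (k in seq_along(ms))
      expect_equal(unclass(ms[[k]]), bfs[[k]], tolerance = 1e-10,
                   ignore_attr = TRUE)
    expect_equal(unname(glcm_features(ms)),
                 unname(rowMeans(vapply(bfs, bf_glcm_features, numeric(6)))),
                 tolerance = 1e-10)
    rl <- glrlm(lev, cfg)
    bf_rl <- lapply(std_directions, function(d)
      bf_glrlm(lev, d, ng = cfg$n_gray_levels, lmax = max(dim(lev))))
    for (k in seq_along(rl))
      expect_equal(unclass(rl[[k]]), bf_rl[[k]], tolerance = 1e-10,
                   ignore_attr = TRUE)
    expect_equal(unname(glrlm_features(rl)),
                 unname(rowMeans(vapply(bf_rl, bf_glrlm_features,
                                        numeric(10)))),
                 tolerance = 1e-10)
  }
})

test_that("extract_features returns the frozen 32-name catalogue", {
  gp <- test_phantom(seed = 31)
  fv <- extract_features(compute_aef_map(gp$volume), gp$mask)
  expect_length(fv, 32)
  expect_identical(names(fv), aef_feature_names())
  expect_true(all(is.finite(fv)))
  expect_true(fv["Uniformity"] > 0 && fv["Uniformity"] <= 1)
  expect_true(fv["Energy"] > 0 && fv["Energy"] <= 1)
  expect_gte(fv["Entropy"], 0)
  expect_true(fv["ShortRunEmphasis"] > 0 && fv["ShortRunEmphasis"] <= 1)
  expect_gte(fv["LongRunEmphasis"], 1)
  expect_equal(unname(fv["Variance"]), unname(fv["StdDeviation"])^2)
})

test_that("intensity features are shuffle-invariant; matrix features are not", {
  gp <- test_phantom(seed = 32, frac = 0.5, cs = 2, noise = 4)
  aef <- compute_aef_map(gp$volume)
  fv <- extract_features(aef, gp$mask)
  plane <- attr(fv, "plane")
  vals <- aef$values[, , plane]
  vals[!gp$mask$mask[, , plane]] <- NA
  set.seed(1)
  shuf <- vals
  idx <- which(!is.na(vals))
  shuf[idx] <- vals[sample(idx)]
  fv_s <- extract_features(aef_from_values(shuf), full_mask(aef_from_values(shuf)))
  ibs <- c("MinIntensity", "MaxIntensity", "MedianIntensity", "MeanValue",
           "StdDeviation", "Variance", "VolumeCount", "VoxelValueSum",
           "Range", "MeanDeviation", "RelativeDeviation", "Skewness",
           "Kurtosis", "Uniformity", "Energy", "Entropy")
  expect_equal(fv[ibs], fv_s[ibs], tolerance = 1e-10)
  glcm_names <- c("Inertia", "InverseDifferenceMoment", "ClusterShade")
  expect_false(isTRUE(all.equal(fv[glcm_names], fv_s[glcm_names],
                                tolerance = 1e-6)))
})

test_that("higher lesion heterogeneity lowers Energy and raises Entropy", {
  n_rep <- 25L
  d_energy <- d_entropy <- d_idm <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    lo <- test_phantom(seed = 600 + r, frac = 0.15, cs = 3, noise = 4)
    hi <- test_phantom(seed = 600 + r, frac = 0.5, cs = 1.5, noise = 4)
    f_lo <- extract_features(compute_aef_map(lo$volume), lo$mask)
    f_hi <- extract_features(compute_aef_map(hi$volume), hi$mask)
    d_energy[r] <- f_hi["Energy"] - f_lo["Energy"]
    d_entropy[r] <- f_hi["Entropy"] - f_lo["Entropy"]
    d_idm[r] <- f_hi["InverseDifferenceMoment"] - f_lo["InverseDifferenceMoment"]
  }
  expect_lt(mean(d_energy), 0)
  expect_gt(mean(d_entropy), 0)
  expect_lt(mean(d_idm), 0)
})
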
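#' Region-of-interest mask
#'
#' A 3D logical mask delineating the lesion, with the physical voxel size
#' needed to convert pixel counts to areas.
#'
#' @param mask 3D logical array, same shape as the volumes it accompanies.
#' @param voxel_size Physical voxel size in mm (row, col, plane).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, voxel_size = c(0.8, 0.8, 3)) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d marked\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Texture extraction configuration
#'
#' Controls the discretization and spatial sampling of the matrix-based
#' texture features. Histogram features (Uniformity, Entropy) use
#' `n_hist_bins` equal-width bins over the ROI's value range; Energy and the
#' co-occurrence / run-length matrices use the coarser `n_gray_levels`
#' quantization. Matrices are built in 2D on the largest axial plane over
#' the four standard direction offsets at `glcm_distance`, symmetrized when
#' `symmetric_glcm`, and features are averaged over directions.
#'
#' @param n_hist_bins Histogram bins for Uniformity/Entropy; default 256.
#' @param hist_range Fixed value range for the Uniformity/Entropy histogram,
#'   defaulting to the default AEF clip range `c(0, 4)` so the histogram
#'   features are comparable across subjects; `NULL` bins over each ROI's
#'   own min-max instead (making them scale-free).
#' @param n_gray_levels Gray levels Ng for Energy and the GLCM/GLRLM;
#'   default 64.
#' @param glcm_distance Pixel offset distance; default 1.
#' @param directions List of (row, col) unit offsets; default the four
#'   standard 2D directions 0, 90, 45, 135 degrees.
#' @param symmetric_glcm Symmetrize the co-occurrence counts; default TRUE.
#' @param log_base Logarithm base for Entropy; default 2 (bits).
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(n_hist_bins = 256L, hist_range = c(0, 4),
                           n_gray_levels = 64L, glcm_distance = 1L,
                           directions = list(c(0L, 1L), c(1L, 0L),
                                             c(1L, 1L), c(1L, -1L)),
                           symmetric_glcm = TRUE, log_base = 2) {
  if (n_hist_bins < 2L) stop("n_hist_bins must be >= 2")
  if (n_gray_levels < 2L) stop("n_gray_levels must be >= 2")
  if (glcm_distance < 1L) stop("glcm_distance must be >= 1")
  if (!is.null(hist_range) &&
      (length(hist_range) != 2L || hist_range[1] >= hist_range[2]))
    stop("hist_range must be NULL or an increasing length-2 range")
  structure(list(n_hist_bins = as.integer(n_hist_bins),
                 hist_range = hist_range,
                 n_gray_levels = as.integer(n_gray_levels),
                 glcm_distance = as.integer(glcm_distance),
                 directions = directions,
                 symmetric_glcm = isTRUE(symmetric_glcm),
                 log_base = log_base),
            class = "texture_config")
}

#' The frozen 32-feature catalogue
#'
#' Names of the 32 AEF texture features, in catalogue order: 11
#' intensity-based statistical (IBS), 5 intensity-based histogram (IBH),
#' 6 gray-level co-occurrence matrix (GLCM) and 10 gray-level run-length
#' matrix (GLRLM) features.
#'
#' @return Character vector of length 32.
#' @export
aef_feature_names <- function() {
  c("MinIntensity", "MaxIntensity", "MedianIntensity", "MeanValue",
    "StdDeviation", "Variance", "VolumeCount", "VoxelValueSum", "Range",
    "MeanDeviation", "RelativeDeviation",
    "Skewness", "Kurtosis", "Uniformity", "Energy", "Entropy",
    "Inertia", "Correlation", "InverseDifferenceMoment", "ClusterShade",
    "ClusterProminence", "HaralickCorrelation",
    "ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
    "RunLengthNonuniformity", "LowGreyLevelRunEmphasis",
    "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
    "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
    "LongRunHighGreyLevelEmphasis")
}

#' Index of the largest axial plane of an ROI
#'
#' @param roi An [roi_mask()]; must mark at least one voxel.
#' @return Index of the axial plane with the most marked pixels; ties break
#'   to the lowest index.
#' @export
largest_axial_plane <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  counts <- apply(roi$mask, 3, sum)
  if (sum(counts) == 0L) stop("ROI mask is empty")
  which.max(counts)
}

#' Tumor area on one plane
#'
#' Pixel count on the plane multiplied by the in-plane pixel size,
#' reported in cm^2.
#'
#' @param roi An [roi_mask()].
#' @param plane Axial plane index; defaults to the largest plane.
#' @return Area in cm^2.
#' @export
tumor_area <- function(roi, plane = largest_axial_plane(roi)) {
  stopifnot(inherits(roi, "roi_mask"))
  n <- sum(roi$mask[, , plane])
  if (n == 0L) stop("no ROI pixels on the requested plane")
  n * roi$voxel_size[1] * roi$voxel_size[2] / 100
}

#' Quantize values into discrete gray levels
#'
#' Equal-width bins over the `[min, max]` of the finite input values; the
#' maximum maps to level `n_levels`, a constant input maps wholly to
#' level 1. `NA`s pass through (they mark out-of-ROI or invalid pixels).
#'
#' @param x Numeric vector, matrix or array.
#' @param n_levels Number of gray levels Ng, >= 2.
#' @return Integer levels in `1..n_levels`, same shape as `x`.
#' @export
quantize_levels <- function(x, n_levels) {
  if (n_levels < 2L) stop("n_levels must be >= 2")
  v <- x[!is.na(x)]
  if (!length(v)) stop("no non-missing values to quantize")
  lo <- min(v); hi <- max(v)
  out <- x
  if (hi == lo) {
    out[!is.na(x)] <- 1L
  } else {
    lev <- floor((x - lo) / (hi - lo) * n_levels) + 1L
    out[] <- pmin(lev, n_levels)
  }
  storage.mode(out) <- "integer"
  out
}

# Histogram probabilities over equal-width bins; a fixed range (values
# clamped into it) or the per-sample min-max when range is NULL.
hist_probs <- function(values, n_bins, range = NULL) {
  lev <- if (is.null(range)) {
    quantize_levels(values, n_bins)
  } else {
    v <- pmin(pmax(values, range[1]), range[2])
    pmin(floor((v - range[1]) / (range[2] - range[1]) * n_bins) + 1L, n_bins)
  }
  p <- tabulate(lev, nbins = n_bins)
  p / sum(p)
}

#' Intensity-based statistical and histogram features
#'
#' The 11 IBS features are computed on the raw (unquantized) values:
#' order statistics, sample moments (standard deviation with the n-1
#' denominator), `VolumeCount` (number of valid pixels), `VoxelValueSum`,
#' `Range`, `MeanDeviation` (mean absolute deviation from the mean) and
#' `RelativeDeviation` (coefficient of variation). The 5 IBH features come
#' from discretized distributions: Skewness and Kurtosis are standardized
#' third/fourth central moments of the raw values (Kurtosis in the Fisher,
#' excess form), Uniformity and Entropy are computed over the
#' `n_hist_bins`-bin histogram (binned over the fixed `hist_range` when one
#' is configured) and Energy over the per-ROI `n_gray_levels` quantization. Degenerate conventions: a constant (or single-pixel) input
#' has zero dispersion, Skewness = Kurtosis = 0, Uniformity = 1, Entropy = 0.
#'
#' @param values Numeric vector of valid AEF values within the plane ROI.
#' @param config A [texture_config()].
#' @return Named numeric vector of the 16 IBS + IBH features.
#' @export
intensity_features <- function(values, config = texture_config()) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) stop("intensity_features requires at least one valid value")
  m <- mean(values)
  sdev <- if (n > 1) stats::sd(values) else 0
  m2 <- mean((values - m)^2)
  skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - m)^4) / m2^2 - 3 else 0
  p_hist <- hist_probs(values, config$n_hist_bins, config$hist_range)
  p_gl <- hist_probs(values, config$n_gray_levels)
  pos <- p_hist[p_hist > 0]
  c(MinIntensity = min(values), MaxIntensity = max(values),
    MedianIntensity = stats::median(values), MeanValue = m,
    StdDeviation = sdev, Variance = sdev^2,
    VolumeCount = n, VoxelValueSum = sum(values),
    Range = max(values) - min(values),
    MeanDeviation = mean(abs(values - m)),
    RelativeDeviation = if (m != 0) sdev / m else 0,
    Skewness = skew, Kurtosis = kurt,
    Uniformity = sum(p_hist^2), Energy = sum(p_gl^2),
    Entropy = -sum(pos * log(pos, base = config$log_base)))
}

#' Gray-level co-occurrence matrices of a quantized plane
#'
#' For each direction offset, counts pairs of gray levels of in-ROI pixels
#' separated by `glcm_distance` along that offset; out-of-ROI pixels (`NA`)
#' contribute no pairs. Counts are symmetrized (each pair counted in both
#' orders) when `symmetric_glcm`, then normalized to sum to one.
#'
#' @param levels Integer matrix of gray levels in `1..Ng`, `NA` outside the
#'   ROI.
#' @param config A [texture_config()].
#' @return List of Ng x Ng probability matrices, one per direction with at
#'   least one pair; each carries its offset as attribute `direction`.
#' @export
glcm <- function(levels, config = texture_config()) {
  ng <- config$n_gray_levels
  if (any(levels > ng, na.rm = TRUE)) stop("levels exceed n_gray_levels")
  out <- list()
  for (dir in config$directions) {
    pr <- offset_pairs(levels, dir * config$glcm_distance)
    if (!nrow(pr)) next
    counts <- matrix(tabulate((pr[, 1] - 1L) * ng + pr[, 2], nbins = ng * ng),
                     nrow = ng, ncol = ng, byrow = TRUE)
    if (config$symmetric_glcm) counts <- counts + t(counts)
    p <- counts / sum(counts)
    attr(p, "direction") <- dir
    out[[length(out) + 1L]] <- p
  }
  if (!length(out)) stop("no valid pixel pairs in any direction")
  out
}

# All (level_i, level_j) pairs at offset (dr, dc) with both pixels in-ROI.
offset_pairs <- function(levels, off) {
  d <- dim(levels)
  r1 <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  c1 <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  if (!length(r1) || !length(c1) || r1[1] > r1[length(r1)] ||
      c1[1] > c1[length(c1)])
    return(matrix(integer(0), ncol = 2))
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' Haralick features of a set of co-occurrence matrices
#'
#' Computes Inertia (contrast), Correlation, InverseDifferenceMoment
#' (homogeneity), ClusterShade, ClusterProminence and HaralickCorrelation
#' from each matrix and averages over directions. HaralickCorrelation uses
#' the level-weighted marginal mean and variance,
#' `(sum ij p(i,j) - mu_t^2) / sigma_t^2`. For a constant plane (all mass at
#' one level) the marginal variance vanishes; Correlation and
#' HaralickCorrelation are then defined as 1.
#'
#' @param matrices List of GLCM probability matrices from [glcm()].
#' @return Named numeric vector of the 6 GLCM features.
#' @export
glcm_features <- function(matrices) {
  if (!length(matrices)) stop("at least one co-occurrence matrix required")
  per_dir <- vapply(matrices, glcm_features_one, numeric(6))
  rowMeans(per_dir)
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)       # row level
  j <- t(i)                              # col level
  px <- rowSums(p); py <- colSums(p)
  mui <- sum(seq_len(ng) * px); muj <- sum(seq_len(ng) * py)
  sdi <- sqrt(sum((seq_len(ng) - mui)^2 * px))
  sdj <- sqrt(sum((seq_len(ng) - muj)^2 * py))
  inertia <- sum((i - j)^2 * p)
  corr <- if (sdi > 0 && sdj > 0)
    sum((i - mui) * (j - muj) * p) / (sdi * sdj) else 1
  idm <- sum(p / (1 + (i - j)^2))
  shade <- sum((i + j - mui - muj)^3 * p)
  prom <- sum((i + j - mui - muj)^4 * p)
  # weighted marginal mean/variance of the (symmetrized) matrix
  mut <- mui; vart <- sdi^2
  hcorr <- if (vart > 0) (sum(i * j * p) - mut^2) / vart else 1
  c(Inertia = inertia, Correlation = corr, InverseDifferenceMoment = idm,
    ClusterShade = shade, ClusterProminence = prom,
    HaralickCorrelation = hcorr)
}

#' Gray-level run-length matrices of a quantized plane
#'
#' For each direction, maximal runs of consecutive equal gray levels along
#' the direction's scan lines are counted into `r[level, run_length]`.
#' Out-of-ROI pixels (`NA`) break runs and contribute none.
#'
#' @param levels Integer matrix of gray levels in `1..Ng`, `NA` outside the
#'   ROI.
#' @param config A [texture_config()].
#' @return List of Ng x Lmax run-count matrices, one per direction, each
#'   with attributes `direction` and `n_runs`.
#' @export
glrlm <- function(levels, config = texture_config()) {
  ng <- config$n_gray_levels
  if (any(levels > ng, na.rm = TRUE)) stop("levels exceed n_gray_levels")
  if (!any(!is.na(levels))) stop("no in-ROI pixels")
  lmax <- max(dim(levels))
  lapply(config$directions, function(dir) {
    runs <- matrix(0L, nrow = ng, ncol = lmax)
    for (line in direction_lines(levels, dir)) {
      # NAs (out-of-ROI pixels) break runs inside split_runs
      for (seg in split_runs(line)) {
        runs[seg["level"], seg["length"]] <-
          runs[seg["level"], seg["length"]] + 1L
      }
    }
    attr(runs, "direction") <- dir
    attr(runs, "n_runs") <- sum(runs)
    runs
  })
}

# Scan lines of a matrix along direction (dr, dc), with NAs preserved so
# they can break runs. Directions are the four standard ones.
direction_lines <- function(m, dir) {
  d <- dim(m)
  if (identical(as.integer(dir), c(0L, 1L))) {
    lapply(seq_len(d[1]), function(r) m[r, ])
  } else if (identical(as.integer(dir), c(1L, 0L))) {
    lapply(seq_len(d[2]), function(cc) m[, cc])
  } else if (identical(as.integer(dir), c(1L, 1L))) {
    idx <- row(m) - col(m)
    split(m, idx)
  } else if (identical(as.integer(dir), c(1L, -1L))) {
    idx <- row(m) + col(m)
    split(m, idx)
  } else stop("unsupported run-length direction")
}

# Maximal runs of a vector that may contain NAs; returns list of
# c(level, length) for each run of non-NA equal values.
split_runs <- function(line) {
  if (!length(line)) return(list())
  r <- rle(ifelse(is.na(line), -1L, as.integer(line)))
  keep <- r$values != -1L
  mapply(function(v, l) c(level = v, length = l),
         r$values[keep], r$lengths[keep], SIMPLIFY = FALSE)
}

#' Run-length features of a set of run-length matrices
#'
#' The ten standard run-length statistics (short/long run emphasis,
#' gray-level and run-length nonuniformity, low/high gray-level run
#' emphasis and the four joint short/long x low/high combinations), each
#' normalized by the direction's run count and averaged over directions.
#'
#' @param matrices List of run-count matrices from [glrlm()].
#' @return Named numeric vector of the 10 GLRLM features.
#' @export
glrlm_features <- function(matrices) {
  if (!length(matrices)) stop("at least one run-length matrix required")
  usable <- Filter(function(m) attr(m, "n_runs") > 0, matrices)
  if (!length(usable)) stop("no runs in any direction")
  per_dir <- vapply(usable, glrlm_features_one, numeric(10))
  rowMeans(per_dir)
}

glrlm_features_one <- function(r) {
  nr <- attr(r, "n_runs")
  g <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))        # gray level
  l <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)  # run length
  c(ShortRunEmphasis = sum(r / l^2) / nr,
    LongRunEmphasis = sum(r * l^2) / nr,
    GreyLevelNonuniformity = sum(rowSums(r)^2) / nr,
    RunLengthNonuniformity = sum(colSums(r)^2) / nr,
    LowGreyLevelRunEmphasis = sum(r / g^2) / nr,
    HighGreyLevelRunEmphasis = sum(r * g^2) / nr,
    ShortRunLowGreyLevelEmphasis = sum(r / (g^2 * l^2)) / nr,
    ShortRunHighGreyLevelEmphasis = sum(r * g^2 / l^2) / nr,
    LongRunLowGreyLevelEmphasis = sum(r * l^2 / g^2) / nr,
    LongRunHighGreyLevelEmphasis = sum(r * g^2 * l^2) / nr)
}

#' Extract the 32 AEF texture features of a lesion
#'
#' Selects the ROI's largest axial plane, restricts the AEF map to the
#' valid in-ROI pixels of that plane, computes the 16 intensity features on
#' the raw values and the 16 matrix features on the `n_gray_levels`
#' quantization, and returns the frozen 32-name catalogue.
#'
#' @param aef An [compute_aef_map()] result.
#' @param roi An [roi_mask()] of the same shape.
#' @param config A [texture_config()].
#' @return Named numeric vector of length 32 (names as in
#'   [aef_feature_names()]), with attributes `plane` (the plane index used)
#'   and `tumor_area_cm2`.
#' @export
extract_features <- function(aef, roi, config = texture_config()) {
  stopifnot(inherits(aef, "aef_map"), inherits(roi, "roi_mask"))
  if (!identical(dim(aef$values), dim(roi$mask)))
    stop("AEF map and ROI mask dimensions differ")
  plane <- largest_axial_plane(roi)
  vals <- aef$values[, , plane]
  vals[!roi$mask[, , plane]] <- NA_real_
  if (!any(!is.na(vals))) stop("no valid AEF voxels in ROI")
  # crop to the ROI bounding box: matrices stay small
  rr <- range(which(rowSums(!is.na(vals)) > 0))
  cc <- range(which(colSums(!is.na(vals)) > 0))
  vals <- vals[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  intens <- intensity_features(vals[!is.na(vals)], config)
  lev <- quantize_levels(vals, config$n_gray_levels)
  fv <- c(intens,
          glcm_features(glcm(lev, config)),
          glrlm_features(glrlm(lev, config)))
  fv <- fv[aef_feature_names()]
  attr(fv, "plane") <- plane
  attr(fv, "tumor_area_cm2") <- tumor_area(roi, plane)
  fv
}

#' Feature table of a synthetic cohort
#'
#' Runs the AEF map computation and feature extraction over every subject
#' of a generated cohort and assembles a data frame: `subject_id`, `label`,
#' `group`, `tumor_area_cm2` and the 32 feature columns.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [texture_config()].
#' @param epsilon,clip_range AEF parameters, as in [compute_aef_map()].
#' @return A data frame with one row per subject.
#' @export
cohort_features <- function(cohort, config = texture_config(),
                            epsilon = 1, clip_range = c(0, 4)) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort, function(s) {
    aef <- compute_aef_map(s$volume, epsilon = epsilon,
                           clip_range = clip_range)
    fv <- tryCatch(extract_features(aef, s$mask, config),
                   error = function(e)
                     stop(sprintf("subject %s: %s", s$id,
                                  conditionMessage(e)), call. = FALSE))
    cbind(data.frame(subject_id = s$id, label = as.character(s$label),
                     group = s$group,
                     tumor_area_cm2 = attr(fv, "tumor_area_cm2")),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
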
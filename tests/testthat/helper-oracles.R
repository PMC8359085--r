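# Independent brute-force reference implementations for the matrix texture
# features, written as plain pixel/cell loops so they share no code with the
# package's vectorized builders.

bf_glcm <- function(levels, dir, distance = 1L, symmetric = TRUE) {
  ng <- max(levels, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  d <- dim(levels)
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    r2 <- r + dir[1] * distance; c2 <- cc + dir[2] * distance
    if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
    a <- levels[r, cc]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

bf_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mui <- 0; muj <- 0
  for (i in seq_len(ng)) { mui <- mui + i * px[i]; muj <- muj + i * py[i] }
  vi <- 0; vj <- 0
  for (i in seq_len(ng)) {
    vi <- vi + (i - mui)^2 * px[i]; vj <- vj + (i - muj)^2 * py[i]
  }
  inertia <- corr_num <- idm <- shade <- prom <- sij <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    inertia <- inertia + (i - j)^2 * p[i, j]
    corr_num <- corr_num + (i - mui) * (j - muj) * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    shade <- shade + (i + j - mui - muj)^3 * p[i, j]
    prom <- prom + (i + j - mui - muj)^4 * p[i, j]
    sij <- sij + i * j * p[i, j]
  }
  corr <- if (vi > 0 && vj > 0) corr_num / sqrt(vi * vj) else 1
  hcorr <- if (vi > 0) (sij - mui^2) / vi else 1
  c(Inertia = inertia, Correlation = corr, InverseDifferenceMoment = idm,
    ClusterShade = shade, ClusterProminence = prom,
    HaralickCorrelation = hcorr)
}

# Walk every scan line of the direction pixel-by-pixel, accumulating runs.
bf_glrlm <- function(levels, dir, ng, lmax) {
  d <- dim(levels)
  runs <- matrix(0, ng, lmax)
  starts <- list()
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    pr <- r - dir[1]; pc <- cc - dir[2]
    if (pr < 1 || pr > d[1] || pc < 1 || pc > d[2])
      starts[[length(starts) + 1]] <- c(r, cc)
  }
  for (s in starts) {
    r <- s[1]; cc <- s[2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= d[1] && cc >= 1 && cc <= d[2]) {
      v <- levels[r, cc]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs[cur, len] <- runs[cur, len] + 1
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + dir[1]; cc <- cc + dir[2]
    }
    if (!is.na(cur)) runs[cur, len] <- runs[cur, len] + 1
  }
  runs
}

bf_glrlm_features <- function(r) {
  nr <- sum(r)
  ng <- nrow(r); lm <- ncol(r)
  acc <- c(sre = 0, lre = 0, lgl = 0, hgl = 0, srlgl = 0, srhgl = 0,
           lrlgl = 0, lrhgl = 0)
  for (g in seq_len(ng)) for (l in seq_len(lm)) {
    x <- r[g, l]
    if (x == 0) next
    acc["sre"] <- acc["sre"] + x / l^2
    acc["lre"] <- acc["lre"] + x * l^2
    acc["lgl"] <- acc["lgl"] + x / g^2
    acc["hgl"] <- acc["hgl"] + x * g^2
    acc["srlgl"] <- acc["srlgl"] + x / (g^2 * l^2)
    acc["srhgl"] <- acc["srhgl"] + x * g^2 / l^2
    acc["lrlgl"] <- acc["lrlgl"] + x * l^2 / g^2
    acc["lrhgl"] <- acc["lrhgl"] + x * g^2 * l^2
  }
  gln <- sum(sapply(seq_len(ng), function(g) sum(r[g, ])^2))
  rln <- sum(sapply(seq_len(lm), function(l) sum(r[, l])^2))
  c(ShortRunEmphasis = acc[["sre"]] / nr,
    LongRunEmphasis = acc[["lre"]] / nr,
    GreyLevelNonuniformity = gln / nr,
    RunLengthNonuniformity = rln / nr,
    LowGreyLevelRunEmphasis = acc[["lgl"]] / nr,
    HighGreyLevelRunEmphasis = acc[["hgl"]] / nr,
    ShortRunLowGreyLevelEmphasis = acc[["srlgl"]] / nr,
    ShortRunHighGreyLevelEmphasis = acc[["srhgl"]] / nr,
    LongRunLowGreyLevelEmphasis = acc[["lrlgl"]] / nr,
    LongRunHighGreyLevelEmphasis = acc[["lrhgl"]] / nr)
}

std_directions <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# Random quantized plane with a random ROI, for oracle-equivalence sweeps.
random_levels_plane <- function(nr = 6, nc = 6, ng = 4, p_roi = 0.8) {
  m <- matrix(sample(seq_len(ng), nr * nc, replace = TRUE), nr, nc)
  m[matrix(runif(nr * nc) > p_roi, nr, nc)] <- NA
  if (!any(!is.na(m))) m[1, 1] <- 1L
  m
}

# Build an AEF map whose valid values equal `values` (NA allowed), so texture
# tests can feed arbitrary planes through the real AEF stage.
aef_from_values <- function(values) {
  arr <- values
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  ctu <- array(0, dim = dim(arr))
  ctp <- array(10, dim = dim(arr))
  cta <- arr * 10
  cta[is.na(cta)] <- 0
  ctp[is.na(arr)] <- 0  # invalid: zero denominator
  mv <- multiphase_volume(ctu, cta, ctp, voxel_size = c(1, 1, 1))
  compute_aef_map(mv, epsilon = 1, clip_range = c(-1e6, 1e6))
}

full_mask <- function(aef) {
  roi_mask(array(TRUE, dim = dim(aef$values)), aef$voxel_size)
}

# A small heterogeneous test lesion used across test files.
test_phantom <- function(seed = 1, frac = 0.4, cs = 2, noise = 3,
                         grid = c(32, 32, 10), radius = 8) {
  les <- lesion_spec(center = c(grid[1] / 2, grid[2] / 2,
                                ceiling(grid[3] / 2)),
                     radius = radius, arterialized_fraction = frac,
                     cluster_scale = cs)
  generate_multiphase_phantom(
    phantom_spec(grid_shape = grid, lesions = list(les),
                 noise_sd = noise, seed = seed))
}
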
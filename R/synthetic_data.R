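#' Specify a synthetic lesion
#'
#' Describes one spherical lesion with patchy "arterialization": a fraction
#' of the lesion volume (spatially clustered patches) enhances strongly in
#' the arterial phase, the rest weakly, emulating the multifocal shift of a
#' hepatic lesion's blood supply from portal to arterial. The portal-phase
#' gain is uniform, so the within-lesion AEF contrast is controlled entirely
#' by `arterial_gain_fg` vs `arterial_gain_bg` and the spatial layout by
#' `arterialized_fraction` and `cluster_scale`.
#'
#' @param center Voxel coordinates (row, col, plane) of the lesion center.
#' @param radius Lesion radius in in-plane voxels (the sphere is isotropic in
#'   physical mm, so it spans fewer planes than in-plane voxels when planes
#'   are thicker).
#' @param baseline_hu Unenhanced attenuation of the lesion, HU.
#' @param portal_gain Mean portal-phase enhancement over baseline, HU; must
#'   be positive so the AEF denominator is defined inside the lesion.
#' @param arterial_gain_fg,arterial_gain_bg Arterial-phase enhancement (HU)
#'   in arterialized patches and elsewhere in the lesion.
#' @param arterialized_fraction Proportion of lesion voxels in arterialized
#'   patches, in `[0, 1]`.
#' @param cluster_scale Spatial granularity of the patches, in in-plane
#'   voxels (Gaussian correlation length of the thresholded random field);
#'   `0` gives voxel-wise salt-and-pepper patches.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, baseline_hu = 50, portal_gain = 60,
                        arterial_gain_fg = 90, arterial_gain_bg = 30,
                        arterialized_fraction = 0.2, cluster_scale = 3) {
  if (radius < 2) stop("lesion radius must be >= 2 voxels")
  if (arterialized_fraction < 0 || arterialized_fraction > 1)
    stop("arterialized_fraction must lie in [0, 1]")
  if (portal_gain <= 0) stop("portal_gain must be positive")
  if (cluster_scale < 0) stop("cluster_scale must be >= 0")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 baseline_hu = baseline_hu, portal_gain = portal_gain,
                 arterial_gain_fg = arterial_gain_fg,
                 arterial_gain_bg = arterial_gain_bg,
                 arterialized_fraction = arterialized_fraction,
                 cluster_scale = cluster_scale),
            class = "lesion_spec")
}

#' Specify a multiphase phantom
#'
#' @param grid_shape Integer length-3 (rows, cols, planes), each >= 8.
#' @param voxel_size Physical voxel size in mm (row, col, plane).
#' @param background_hu Length-3 named or ordered HU triple for the
#'   unenhanced, arterial and portal background (normal parenchyma).
#' @param lesions List of [lesion_spec()] objects (may be empty).
#' @param noise_sd Additive Gaussian HU noise, independent across phases.
#' @param seed Integer seed; identical specs with identical seeds produce
#'   bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 16),
                         voxel_size = c(0.8, 0.8, 3),
                         background_hu = c(ctu = 55, cta = 70, ctp = 105),
                         lesions = list(), noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three integers, all >= 8")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  stopifnot(all(vapply(lesions, inherits, logical(1), "lesion_spec")))
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 background_hu = as.numeric(background_hu), lesions = lesions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a three-phase phantom and its lesion mask
#'
#' Builds unenhanced/arterial/portal HU grids: uniform background per phase,
#' spherical lesions with the enhancement pattern of their [lesion_spec()],
#' and optional additive Gaussian noise (independent across phases). The
#' returned mask marks the union of the lesion spheres.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [multiphase_volume()]) and `mask`
#'   (an [roi_mask()]).
#' @export
generate_multiphase_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, build_phantom(spec))
}

build_phantom <- function(spec) {
  d <- spec$grid_shape; vs <- spec$voxel_size
  ctu <- array(spec$background_hu[1], dim = d)
  cta <- array(spec$background_hu[2], dim = d)
  ctp <- array(spec$background_hu[3], dim = d)
  mask <- array(FALSE, dim = d)
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    r_mm <- les$radius * vs[1]
    half <- r_mm / vs  # half-extent in voxels per axis
    if (any(les$center - half < 1) || any(les$center + half > d))
      stop(sprintf("lesion %d extends outside the grid", k))
    inside <- sphere_voxels(d, vs, les$center, r_mm)
    fg <- arterialized_patches(inside, les$arterialized_fraction,
                               les$cluster_scale, vs)
    ctu[inside] <- les$baseline_hu
    ctp[inside] <- les$baseline_hu + les$portal_gain
    cta[inside] <- les$baseline_hu + les$arterial_gain_bg
    cta[inside & fg] <- les$baseline_hu + les$arterial_gain_fg
    mask <- mask | inside
  }
  if (spec$noise_sd > 0) {
    n <- prod(d)
    ctu <- ctu + array(stats::rnorm(n, 0, spec$noise_sd), dim = d)
    cta <- cta + array(stats::rnorm(n, 0, spec$noise_sd), dim = d)
    ctp <- ctp + array(stats::rnorm(n, 0, spec$noise_sd), dim = d)
  }
  list(volume = multiphase_volume(ctu, cta, ctp, vs),
       mask = roi_mask(mask, vs))
}

# Logical array of voxels within physical distance r_mm of center.
sphere_voxels <- function(d, vs, center, r_mm) {
  dx <- (seq_len(d[1]) - center[1]) * vs[1]
  dy <- (seq_len(d[2]) - center[2]) * vs[2]
  dz <- (seq_len(d[3]) - center[3]) * vs[3]
  dist2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(dist2 <= r_mm^2, dim = d)
}

# Spatially clustered arterialized patches: threshold a Gaussian-smoothed
# white-noise field at the in-lesion quantile so the realized fraction
# matches the requested one.
arterialized_patches <- function(inside, fraction, cluster_scale, vs) {
  fg <- array(FALSE, dim = dim(inside))
  if (fraction <= 0 || !any(inside)) return(fg)
  if (fraction >= 1) { fg[inside] <- TRUE; return(fg) }
  field <- array(stats::rnorm(prod(dim(inside))), dim = dim(inside))
  if (cluster_scale > 0) {
    sigma <- cluster_scale * vs[1] / vs  # physically isotropic correlation
    field <- gaussian_smooth_3d(field, sigma)
  }
  cut <- stats::quantile(field[inside], probs = 1 - fraction,
                         names = FALSE, type = 7)
  fg[inside] <- field[inside] > cut
  fg
}

# Separable Gaussian smoothing with edge replication; sigma per axis, voxels.
gaussian_smooth_3d <- function(x, sigma) {
  for (axis in 1:3) {
    if (sigma[axis] < 1e-8) next
    r <- max(1L, ceiling(3 * sigma[axis]))
    w <- stats::dnorm(-r:r, sd = sigma[axis]); w <- w / sum(w)
    x <- convolve_axis(x, w, axis, r)
  }
  x
}

convolve_axis <- function(x, w, axis, r) {
  d <- dim(x)
  out <- array(0, dim = d)
  for (t in -r:r) {
    idx <- pmin(pmax(seq_len(d[axis]) + t, 1L), d[axis])
    shifted <- switch(axis,
                      x[idx, , , drop = FALSE],
                      x[, idx, , drop = FALSE],
                      x[, , idx, drop = FALSE])
    out <- out + w[t + r + 1L] * shifted
  }
  out
}

#' Specify a labeled synthetic cohort
#'
#' Two groups of subjects whose lesions are randomized around a common base
#' lesion, with the group means separated by `group_effect`. The positive
#' group (responders under the `"improved"` scheme, the non-worsened under
#' `"unworsened"`) receives `base + effect` for every named parameter, so a
#' positive `arterialized_fraction` effect with a negative `cluster_scale`
#' effect yields more, finer-grained arterialized patches — i.e. more
#' heterogeneous lesion AEF — in responders.
#'
#' @param n_per_group Integer pair: positive-group and negative-group sizes,
#'   each >= 2. Defaults to the 22 improved / 23 un-improved split under the
#'   `"improved"` scheme and 31/14 under `"unworsened"`.
#' @param group_effect Named list of additive deltas applied to the positive
#'   group's mean lesion parameters (`arterialized_fraction`,
#'   `cluster_scale`, `arterial_gain_fg`, `arterial_gain_bg`, `radius`).
#' @param base_lesion A [lesion_spec()]; per-subject parameters are jittered
#'   around it (and around `base + group_effect` in the positive group).
#' @param grid_shape,voxel_size,background_hu Phantom geometry, as in
#'   [phantom_spec()].
#' @param noise_sd Additive HU noise per phase.
#' @param seed Integer master seed; subject `i` uses `seed + i`.
#' @param label_scheme `"improved"` (Improved vs Un-improved, i.e. CR+PR vs
#'   SD+PD) or `"unworsened"` (Un-worsened vs Worsened, CR+PR+SD vs PD).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = NULL,
                        group_effect = list(arterialized_fraction = 0.3,
                                            cluster_scale = -1.5),
                        base_lesion = lesion_spec(center = c(32, 32, 8),
                                                  radius = 21),
                        grid_shape = c(64, 64, 16),
                        voxel_size = c(0.8, 0.8, 3),
                        background_hu = c(55, 70, 105),
                        noise_sd = 5, seed = 1L,
                        label_scheme = c("improved", "unworsened")) {
  label_scheme <- match.arg(label_scheme)
  if (is.null(n_per_group))
    n_per_group <- if (label_scheme == "improved") c(22L, 23L) else c(31L, 14L)
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 2L))
    stop("n_per_group must be two integers, each >= 2")
  stopifnot(inherits(base_lesion, "lesion_spec"))
  if (all(unlist(group_effect) == 0) && any(n_per_group < 4L))
    warning("zero group effect with fewer than 4 subjects per group: ",
            "between-group statistics will be degenerate")
  structure(list(n_per_group = n_per_group, group_effect = group_effect,
                 base_lesion = base_lesion, grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 background_hu = as.numeric(background_hu),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 label_scheme = label_scheme),
            class = "cohort_spec")
}

# Jitter scales for per-subject lesion randomization (chosen once; see the
# methods vignette for rationale).
.subject_jitter <- list(arterialized_fraction = 0.06, cluster_scale_log = 0.15,
                        radius = 1, gain = 5)

#' Generate a labeled synthetic cohort
#'
#' Draws `n1 + n0` subjects: per-subject lesion parameters are sampled
#' around the group mean (base lesion, plus `group_effect` in the positive
#' group), a phantom is generated for each, and the group label attached.
#' Each subject's randomness is seeded with `seed + subject index`, so any
#' subject is reproducible in isolation.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `cohort`: one element per subject, each a list with
#'   `id`, `label` (factor, positive level first), `group` (1 positive / 0
#'   negative), `volume`, `mask`, and `lesion` (the realized [lesion_spec()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- if (spec$label_scheme == "improved")
    c("Improved", "Un-improved") else c("Un-worsened", "Worsened")
  groups <- rep(c(1L, 0L), spec$n_per_group)
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    les <- with_local_seed(spec$seed + i,
                           draw_subject_lesion(spec, groups[i]))
    ph <- phantom_spec(grid_shape = spec$grid_shape,
                       voxel_size = spec$voxel_size,
                       background_hu = spec$background_hu,
                       lesions = list(les), noise_sd = spec$noise_sd,
                       seed = spec$seed + i)
    gp <- generate_multiphase_phantom(ph)
    subjects[[i]] <- list(id = sprintf("S%03d", i),
                          label = factor(labels[2L - groups[i]],
                                         levels = labels),
                          group = groups[i],
                          volume = gp$volume, mask = gp$mask,
                          lesion = les)
  }
  structure(subjects, class = "cohort",
            label_scheme = spec$label_scheme, seed = spec$seed)
}

draw_subject_lesion <- function(spec, group) {
  base <- spec$base_lesion
  eff <- function(name) {
    e <- spec$group_effect[[name]]
    if (is.null(e) || group == 0L) 0 else e
  }
  j <- .subject_jitter
  frac <- clamp(base$arterialized_fraction + eff("arterialized_fraction") +
                  stats::rnorm(1, 0, j$arterialized_fraction), 0.02, 0.98)
  cs <- max(0, (base$cluster_scale + eff("cluster_scale")) *
              exp(stats::rnorm(1, 0, j$cluster_scale_log)))
  rad <- max(2, base$radius + eff("radius") + stats::rnorm(1, 0, j$radius))
  fg <- base$arterial_gain_fg + eff("arterial_gain_fg") +
    stats::rnorm(1, 0, j$gain)
  bg <- base$arterial_gain_bg + eff("arterial_gain_bg") +
    stats::rnorm(1, 0, j$gain)
  lesion_spec(center = base$center, radius = rad,
              baseline_hu = base$baseline_hu, portal_gain = base$portal_gain,
              arterial_gain_fg = fg, arterial_gain_bg = bg,
              arterialized_fraction = frac, cluster_scale = cs)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.cohort <- function(x, ...) {
  labs <- table(vapply(x, function(s) as.character(s$label), character(1)))
  cat(sprintf("<cohort> %d subjects (%s), scheme '%s'\n", length(x),
              paste(sprintf("%s: %d", names(labs), labs), collapse = ", "),
              attr(x, "label_scheme")))
  invisible(x)
}
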
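#' Construct a three-phase CT volume
#'
#' Bundles the unenhanced (`ctu`), arterial (`cta`) and portal-venous
#' (`ctp`) phase grids of one contrast-enhanced CT study. All three grids
#' must be co-registered 3D arrays of Hounsfield units with identical
#' dimensions, indexed `[row, col, plane]` with the third index running
#' over axial planes.
#'
#' @param ctu,cta,ctp 3D numeric arrays (HU): unenhanced, arterial and
#'   portal phase.
#' @param voxel_size numeric length-3, physical voxel size in mm
#'   (row, col, plane). Default 0.8 x 0.8 mm in plane, 3 mm plane thickness.
#' @return An object of class `multiphase_volume`.
#' @export
multiphase_volume <- function(ctu, cta, ctp, voxel_size = c(0.8, 0.8, 3)) {
  ctu <- as_volume(ctu); cta <- as_volume(cta); ctp <- as_volume(ctp)
  if (!identical(dim(ctu), dim(cta)) || !identical(dim(ctu), dim(ctp)))
    stop("phase grids must have identical dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths in mm")
  structure(list(ctu = ctu, cta = cta, ctp = ctp, voxel_size = voxel_size),
            class = "multiphase_volume")
}

as_volume <- function(x) {
  if (is.null(dim(x))) stop("phase grid must be a 3D array")
  if (length(dim(x)) != 3L) stop("phase grid must be a 3D array")
  storage.mode(x) <- "double"
  x
}

#' @export
print.multiphase_volume <- function(x, ...) {
  d <- dim(x$ctu)
  cat(sprintf("<multiphase_volume> %d x %d x %d voxels, %.2g x %.2g x %.2g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Rigid integer-shift alignment of phase grids
#'
#' Translates the arterial and portal grids by the integer voxel shift that
#' minimizes the mean squared difference against the unenhanced grid over a
#' search window of `max_shift` voxels per axis. A deliberately simple rigid
#' surrogate for full deformable motion registration: on desk-scale phantom
#' data integer translation is the only misalignment mode worth modelling.
#' The unenhanced grid is never moved. Voxels shifted in from outside the
#' grid are filled with the phase's edge-nearest values of the original grid
#' replaced by the grid median, so similarity is scored on the overlap only.
#'
#' @param mv A [multiphase_volume()].
#' @param max_shift Non-negative integer, half-width of the search window in
#'   voxels (applied per axis). `0` returns the input unchanged.
#' @return A `multiphase_volume` with shifted arterial and portal grids; the
#'   chosen shifts are attached as attribute `shifts` (list with `cta`,
#'   `ctp`, each an integer length-3 vector).
#' @export
align_phases <- function(mv, max_shift = 2L) {
  stopifnot(inherits(mv, "multiphase_volume"))
  max_shift <- as.integer(max_shift)
  if (max_shift < 0L) stop("max_shift must be >= 0")
  if (max_shift == 0L) {
    attr(mv, "shifts") <- list(cta = c(0L, 0L, 0L), ctp = c(0L, 0L, 0L))
    return(mv)
  }
  sa <- best_shift(mv$ctu, mv$cta, max_shift)
  sp <- best_shift(mv$ctu, mv$ctp, max_shift)
  out <- multiphase_volume(mv$ctu,
                           shift_volume(mv$cta, sa),
                           shift_volume(mv$ctp, sp),
                           mv$voxel_size)
  attr(out, "shifts") <- list(cta = sa, ctp = sp)
  out
}

# Exhaustive integer search minimizing mean squared difference on the overlap.
best_shift <- function(ref, mov, w) {
  grid <- expand.grid(s1 = -w:w, s2 = -w:w, s3 = -w:w)
  score <- vapply(seq_len(nrow(grid)), function(k) {
    s <- as.integer(grid[k, ])
    overlap_msd(ref, mov, s)
  }, numeric(1))
  best <- which.min(score)
  s <- as.integer(grid[best, ])
  if (any(abs(s) == w))
    warning("best alignment shift lies on the search-window boundary; ",
            "consider a larger max_shift")
  s
}

# MSD between ref and mov translated by s, on the overlapping region.
overlap_msd <- function(ref, mov, s) {
  d <- dim(ref)
  i1 <- pmax(1L, 1L + s[1]):pmin(d[1], d[1] + s[1])
  i2 <- pmax(1L, 1L + s[2]):pmin(d[2], d[2] + s[2])
  i3 <- pmax(1L, 1L + s[3]):pmin(d[3], d[3] + s[3])
  if (!length(i1) || !length(i2) || !length(i3)) return(Inf)
  mean((ref[i1, i2, i3, drop = FALSE] -
          mov[i1 - s[1], i2 - s[2], i3 - s[3], drop = FALSE])^2)
}

# Translate a volume by integer shift s (destination[v] = source[v - s]);
# uncovered voxels take the volume median (neutral background fill).
shift_volume <- function(x, s) {
  d <- dim(x)
  out <- array(stats::median(x), dim = d)
  i1 <- pmax(1L, 1L + s[1]):pmin(d[1], d[1] + s[1])
  i2 <- pmax(1L, 1L + s[2]):pmin(d[2], d[2] + s[2])
  i3 <- pmax(1L, 1L + s[3]):pmin(d[3], d[3] + s[3])
  if (length(i1) && length(i2) && length(i3))
    out[i1, i2, i3] <- x[i1 - s[1], i2 - s[2], i3 - s[3], drop = FALSE]
  out
}

#' Compute the arterial enhancement fraction map
#'
#' Per-voxel AEF = (CTa - CTu) / (CTp - CTu): the arterial share of the
#' portal-phase enhancement, a unitless proxy for how arterialized the
#' tissue perfusion is. Voxels whose portal enhancement (CTp - CTu) does
#' not exceed `epsilon` have an undefined ratio; they are flagged invalid
#' (`NA` value) and are excluded, never zero-filled, from all downstream
#' statistics. Valid values are clipped to `clip_range`.
#'
#' @param mv A [multiphase_volume()] with co-registered phases.
#' @param epsilon Denominator guard in HU; portal enhancement must exceed it
#'   for the ratio to be considered defined. Default 1 HU.
#' @param clip_range Length-2 numeric, limits applied to valid AEF values.
#'   Default `c(0, 4)`: negative ratios (arterial de-enhancement) clip to 0
#'   and 4 is a generous physical ceiling for liver tissue.
#' @return An object of class `aef_map`: list with `values` (3D array, `NA`
#'   where invalid), `valid` (3D logical), `epsilon`, `clip_range`,
#'   `voxel_size`.
#' @export
compute_aef_map <- function(mv, epsilon = 1, clip_range = c(0, 4)) {
  stopifnot(inherits(mv, "multiphase_volume"))
  if (length(clip_range) != 2L || clip_range[1] >= clip_range[2])
    stop("clip_range must be increasing length-2")
  den <- mv$ctp - mv$ctu
  valid <- den > epsilon
  values <- array(NA_real_, dim = dim(mv$ctu))
  values[valid] <- pmin(pmax((mv$cta - mv$ctu)[valid] / den[valid],
                             clip_range[1]), clip_range[2])
  structure(list(values = values, valid = valid, epsilon = epsilon,
                 clip_range = clip_range, voxel_size = mv$voxel_size),
            class = "aef_map")
}

#' @export
print.aef_map <- function(x, ...) {
  cat(sprintf("<aef_map> %s voxels, %.1f%% valid, epsilon %g HU, clip [%g, %g]\n",
              paste(dim(x$values), collapse = " x "),
              100 * mean(x$valid), x$epsilon,
              x$clip_range[1], x$clip_range[2]))
  invisible(x)
}

# Valid AEF values inside an ROI; errors when the ROI holds none.
aef_values_in_roi <- function(aef, roi) {
  stopifnot(inherits(aef, "aef_map"), inherits(roi, "roi_mask"))
  if (!identical(dim(aef$values), dim(roi$mask)))
    stop("AEF map and ROI mask dimensions differ")
  v <- aef$values[roi$mask & aef$valid]
  if (!length(v)) stop("no valid AEF voxels in ROI")
  v
}
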
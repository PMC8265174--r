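# segmentation: dark-vessel extraction from autofluorescence volumes.
#
# Pipeline (VMI mode): rescale to full bit range (whole volume jointly) ->
# invert each slice (vessels become bright) -> rolling-ball background
# subtraction per slice -> final contrast stretch -> binarize -> optional
# region exclusion. The bright-structure variant (FITC airway, TdTomato red
# channel) is the identical pipeline without the inversion step.

#' Segmentation parameters
#'
#' @param rolling_ball_radius_um Rolling-ball radius in micrometres. Should
#'   be at least the largest expected vessel radius in the organ, so that
#'   the ball cannot roll into a vessel and absorb it into the background.
#' @param bit_depth Intensity bit depth (default 16).
#' @param binarization `"triangle"` (default), `"otsu"` or `"percentile"`.
#'   All are parameter-free except `"percentile"`. Triangle is the default
#'   because segmented vasculature occupies a small fraction of an organ
#'   volume, and Otsu's between-class criterion collapses into the
#'   background mode under such class imbalance.
#' @param percentile For `binarization = "percentile"`: voxels above this
#'   percentile (in (0, 100)) of the enhanced volume are foreground.
#' @param min_object_voxels Connected components (26-connectivity) smaller
#'   than this are removed from the final mask. Default 64.
#' @param invert `TRUE` (default) for the dark-vessel VMI mode; `FALSE` for
#'   bright structures (FITC airway, red channel).
#' @return An object of class `vmi_seg_params`.
#' @export
segmentation_params <- function(rolling_ball_radius_um,
                                bit_depth = 16L,
                                binarization = c("triangle", "otsu",
                                                 "percentile"),
                                percentile = NULL,
                                min_object_voxels = 64L,
                                invert = TRUE) {
  binarization <- match.arg(binarization)
  if (!is.numeric(rolling_ball_radius_um) || rolling_ball_radius_um <= 0)
    stop("rolling_ball_radius_um must be > 0", call. = FALSE)
  if (binarization == "percentile") {
    if (is.null(percentile) || percentile <= 0 || percentile >= 100)
      stop("percentile must lie in (0, 100)", call. = FALSE)
  }
  if (!.is_count(min_object_voxels))
    stop("min_object_voxels must be a non-negative integer", call. = FALSE)
  structure(list(rolling_ball_radius_um = rolling_ball_radius_um,
                 bit_depth = as.integer(bit_depth),
                 binarization = binarization,
                 percentile = percentile,
                 min_object_voxels = as.integer(min_object_voxels),
                 invert = isTRUE(invert)),
            class = "vmi_seg_params")
}

#' Organ presets for segmentation
#'
#' Presets differ only in the rolling-ball radius (set from typical largest
#' vessel calibres of each rat organ) and the default masking behaviour
#' (heart cavities are excluded via [cavity_mask_from_foreground()]).
#'
#' @param organ One of `"kidney"`, `"heart"`, `"liver"`, `"lung"`.
#' @param ... Overrides passed to [segmentation_params()].
#' @return A `vmi_seg_params` object with an `organ` attribute.
#' @export
organ_preset <- function(organ = c("kidney", "heart", "liver", "lung"), ...) {
  organ <- match.arg(organ)
  radius <- switch(organ, kidney = 300, heart = 250, liver = 500, lung = 300)
  args <- modifyList(list(rolling_ball_radius_um = radius), list(...))
  p <- do.call(segmentation_params, args)
  attr(p, "organ") <- organ
  attr(p, "mask_cavities") <- organ == "heart"
  p
}

#' Remap intensities to the full bit range
#'
#' Linear map over the whole 3D volume jointly, sending the global minimum
#' to 0 and the global maximum to `2^bit_depth - 1`, with round-half-up
#' rounding. Normalizes between-sample intensity variation. A constant
#' volume maps to all zeros.
#'
#' @param volume A [vmi_volume()].
#' @return The rescaled [vmi_volume()].
#' @export
rescale_intensity_3d <- function(volume) {
  stopifnot(inherits(volume, "vmi_volume"))
  v <- volume$voxels
  maxv <- 2^volume$bit_depth - 1
  rng <- range(v)
  out <- if (rng[2] > rng[1]) {
    .round_half_up((v - rng[1]) / (rng[2] - rng[1]) * maxv)
  } else {
    array(0, dim(v))
  }
  vmi_volume(array(out, dim(v)), volume$spacing, volume$channel,
             volume$bit_depth)
}

#' Invert intensities slice by slice
#'
#' `v -> (2^bit_depth - 1) - v`, applied per 2D slice (numerically identical
#' to a 3D inversion). After rescaling, the dark vasculature becomes the
#' bright structure of interest.
#'
#' @param volume A [vmi_volume()], already rescaled to the full bit range.
#' @return The inverted [vmi_volume()].
#' @export
invert_slices <- function(volume) {
  stopifnot(inherits(volume, "vmi_volume"))
  maxv <- 2^volume$bit_depth - 1
  vmi_volume(maxv - volume$voxels, volume$spacing, volume$channel,
             volume$bit_depth)
}

#' Rolling-ball background subtraction
#'
#' For each 2D slice independently, estimates the background as the surface
#' traced by rolling a ball of the given radius under the intensity
#' landscape (grayscale opening by a spherical structuring element) and
#' subtracts it. Removes slowly varying illumination while preserving
#' structures narrower than the ball. Output is non-negative by
#' construction.
#'
#' @param volume A [vmi_volume()] (inverted for the VMI mode, raw for the
#'   bright mode).
#' @param radius_um Ball radius in micrometres; converted to pixels via the
#'   in-plane spacing (rounded up, minimum 1 pixel).
#' @return The background-subtracted [vmi_volume()].
#' @export
rolling_ball_subtract <- function(volume, radius_um) {
  stopifnot(inherits(volume, "vmi_volume"))
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("radius_um must be > 0", call. = FALSE)
  rpx <- ceiling(radius_um / min(volume$spacing[2:3]))
  v <- volume$voxels
  out <- v
  for (z in seq_len(dim(v)[1])) {
    sl <- v[z, , ]
    bg <- .rollball_background_cpp(sl, rpx)
    out[z, , ] <- pmax(sl - bg, 0)
  }
  vmi_volume(out, volume$spacing, volume$channel, volume$bit_depth)
}

#' Final contrast enhancement
#'
#' Identical contract to [rescale_intensity_3d()], applied to the 3D volume
#' after background subtraction.
#'
#' @inheritParams rescale_intensity_3d
#' @export
enhance_contrast_3d <- function(volume) rescale_intensity_3d(volume)

#' Remove small connected components from a logical array
#' @noRd
.filter_small <- function(vox, min_voxels) {
  if (min_voxels <= 0L || !any(vox)) return(vox)
  lab <- .label3d_cpp(vox, dim(vox))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(vox))
}

#' Binarize an enhanced volume into a vessel mask
#'
#' Global threshold over the enhanced volume: the triangle method by
#' default (parameter-free, robust to the small volume fraction vessels
#' occupy), Otsu, or a fixed percentile. Components smaller than
#' `min_object_voxels` are removed.
#'
#' @param volume The enhanced [vmi_volume()] (output of
#'   [enhance_contrast_3d()]).
#' @param params A [segmentation_params()] object.
#' @return A [vmi_mask()].
#' @export
binarize <- function(volume, params) {
  stopifnot(inherits(volume, "vmi_volume"), inherits(params, "vmi_seg_params"))
  v <- volume$voxels
  maxv <- 2^volume$bit_depth - 1
  if (max(v) == 0) {
    m <- array(FALSE, dim(v))
  } else {
    thr <- switch(params$binarization,
                  triangle = .triangle(v, maxv),
                  otsu = .otsu(v, maxv),
                  percentile = quantile(v, params$percentile / 100,
                                        names = FALSE))
    m <- array(v > thr, dim(v))
  }
  m <- .filter_small(m, params$min_object_voxels)
  vmi_mask(m, volume$spacing, volume$channel)
}

#' Low-intensity cavity mask from the original autofluorescence channel
#'
#' Finds connected low-intensity regions (heart atria/ventricles, large
#' lumens) in the raw, non-inverted volume, eligible for exclusion from the
#' vessel mask. Components smaller than `min_object_voxels` are dropped.
#'
#' @param volume The original (non-inverted) autofluorescence [vmi_volume()].
#' @param threshold `"otsu"` or a numeric intensity; voxels strictly below
#'   it are cavity candidates.
#' @param min_object_voxels Minimum component size retained (default 64).
#' @return A [vmi_mask()] of the excludable regions.
#' @export
cavity_mask_from_foreground <- function(volume, threshold = "otsu",
                                        min_object_voxels = 64L) {
  stopifnot(inherits(volume, "vmi_volume"))
  maxv <- 2^volume$bit_depth - 1
  thr <- if (identical(threshold, "otsu")) {
    .otsu(volume$voxels, maxv)
  } else {
    if (!is.numeric(threshold) || threshold < 0 || threshold > maxv)
      stop("threshold outside intensity range [0, ", maxv, "]",
           call. = FALSE)
    threshold
  }
  m <- array(volume$voxels < thr, dim(volume$voxels))
  m <- .filter_small(m, min_object_voxels)
  vmi_mask(m, volume$spacing, volume$channel)
}

#' Exclude a region from a vessel mask
#'
#' Sets mask voxels inside `exclude` to `FALSE` and records the excluded
#' fraction of the original mask in the `"excluded_fraction"` attribute.
#'
#' @param mask,exclude [vmi_mask()] objects of identical shape.
#' @return The filtered [vmi_mask()].
#' @export
apply_exclusion_mask <- function(mask, exclude) {
  stopifnot(inherits(mask, "vmi_mask"), inherits(exclude, "vmi_mask"))
  if (!identical(dim(mask$voxels), dim(exclude$voxels)))
    stop("mask and exclusion mask shapes differ", call. = FALSE)
  n0 <- sum(mask$voxels)
  out <- mask$voxels & !exclude$voxels
  res <- vmi_mask(out, mask$spacing, mask$source_channel)
  attr(res, "excluded_fraction") <-
    if (n0 > 0) (n0 - sum(out)) / n0 else 0
  res
}

#' Segment the vasculature from an autofluorescence volume
#'
#' Full pipeline: [rescale_intensity_3d()] -> [invert_slices()] (iff
#' `params$invert`) -> [rolling_ball_subtract()] -> [enhance_contrast_3d()]
#' -> [binarize()] -> [apply_exclusion_mask()]. Output is invariant to a
#' global affine change `a * v + b` (`a > 0`) of the input intensities.
#'
#' @param volume Input [vmi_volume()].
#' @param params A [segmentation_params()] object.
#' @param exclude Optional [vmi_mask()] of regions to remove (heart
#'   cavities, renal medulla).
#' @param save_stages Optional directory: every intermediate stage is
#'   written there as TIFF for debugging.
#' @param verbose Log each stage to the console.
#' @return A [vmi_mask()]; the `"stages"` attribute names the stages run.
#' @export
segment_vasculature <- function(volume, params, exclude = NULL,
                                save_stages = NULL, verbose = FALSE) {
  stopifnot(inherits(volume, "vmi_volume"), inherits(params, "vmi_seg_params"))
  stages <- character(0)
  dump <- function(obj, name) {
    if (!is.null(save_stages)) {
      if (!dir.exists(save_stages)) dir.create(save_stages, recursive = TRUE)
      write_stack(obj, file.path(save_stages, paste0(name, ".tif")))
    }
  }
  step <- function(name, obj) {
    stages <<- c(stages, name)
    if (verbose) message("[segment] ", name)
    dump(obj, sprintf("%02d_%s", length(stages), name))
    obj
  }
  v <- step("rescale", rescale_intensity_3d(volume))
  if (params$invert) v <- step("invert", invert_slices(v))
  v <- step("rolling_ball",
            rolling_ball_subtract(v, params$rolling_ball_radius_um))
  v <- step("enhance", enhance_contrast_3d(v))
  m <- step("binarize", binarize(v, params))
  if (!is.null(exclude)) m <- step("exclude", apply_exclusion_mask(m, exclude))
  attr(m, "stages") <- stages
  m
}
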
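# volume_io: 3D fluorescence stacks and masks with physical voxel spacing.
#
# Axis order is fixed as (z, y, x): the slice index is the first array
# dimension, matching per-slice processing of cryo-imaging stacks.

.CHANNELS <- c("NADH", "FAD", "RED", "FITC", "OTHER")

#' 3D fluorescence image volume
#'
#' Container for a 3D scalar intensity grid with per-axis physical voxel
#' spacing. Axis order is `(z, y, x)`; the slice index is `z`.
#'
#' @param voxels Numeric 3D array, non-negative intensities, `dim = (nz, ny,
#'   nx)`. A matrix is promoted to a single-slice volume.
#' @param spacing Numeric length-3, `(z, y, x)` voxel edge lengths in
#'   micrometres, all strictly positive.
#' @param channel Channel label, one of `"NADH"`, `"FAD"`, `"RED"`,
#'   `"FITC"`, `"OTHER"`.
#' @param bit_depth Nominal bit depth of the intensity scale (default 16);
#'   intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `vmi_volume`: a list with elements `voxels`,
#'   `spacing`, `channel`, `bit_depth`.
#' @examples
#' v <- vmi_volume(array(100, c(4, 8, 8)), spacing = c(10, 10, 10), "NADH")
#' dim(v$voxels)
#' @export
vmi_volume <- function(voxels, spacing, channel = "OTHER", bit_depth = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (z, y, x)", call. = FALSE)
  spacing <- .check_spacing(spacing)
  channel <- match.arg(channel, .CHANNELS)
  if (!.is_count(bit_depth) || bit_depth < 1 || bit_depth > 32)
    stop("bit_depth must be a positive integer <= 32", call. = FALSE)
  if (anyNA(voxels)) stop("voxels must not contain NA", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (min(voxels) < 0 || max(voxels) > maxv)
    stop("intensities must lie in [0, 2^bit_depth - 1] = [0, ", maxv, "]",
         call. = FALSE)
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, channel = channel,
                 bit_depth = as.integer(bit_depth)),
            class = "vmi_volume")
}

#' @export
print.vmi_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<vmi_volume> %s  %d x %d x %d voxels (z,y,x)\n", x$channel,
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g um, %d-bit, range [%g, %g]\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$bit_depth,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary vessel (or airway) mask
#'
#' A boolean 3D grid marking vascular voxels, shape-matched to its source
#' volume and carrying the same `(z, y, x)` spacing.
#'
#' @param voxels Logical 3D array, `dim = (nz, ny, nx)`.
#' @param spacing `(z, y, x)` voxel sizes in micrometres.
#' @param source_channel Label of the channel the mask was derived from.
#' @return An object of class `vmi_mask`.
#' @export
vmi_mask <- function(voxels, spacing, source_channel = "OTHER") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask voxels must be a 3D array (z, y, x)", call. = FALSE)
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask voxels must be logical (or 0/1)", call. = FALSE)
    voxels <- array(as.logical(voxels), dim(voxels))
  }
  spacing <- .check_spacing(spacing)
  source_channel <- match.arg(source_channel, .CHANNELS)
  structure(list(voxels = voxels, spacing = spacing,
                 source_channel = source_channel),
            class = "vmi_mask")
}

#' @export
print.vmi_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<vmi_mask> from %s  %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              x$source_channel, d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

.resolve_slices <- function(path) {
  if (length(path) > 1L) {
    missing <- path[!file.exists(path)]
    if (length(missing))
      stop("file not found: ", missing[1], call. = FALSE)
    return(path)
  }
  if (file.exists(path)) return(path)
  hits <- Sys.glob(path)
  if (!length(hits)) stop("no slices found matching '", path, "'",
                          call. = FALSE)
  sort(hits)
}

#' Read a 3D stack from multi-page TIFF or a TIFF slice series
#'
#' Accepts a single multi-page TIFF, a character vector of slice files, or a
#' glob pattern (e.g. `"slices/img_*.tif"`, matched files sorted by name).
#' Slices are stacked in file/page order along `z`. Spacing is supplied by
#' the caller, never parsed from TIFF tags.
#'
#' @param path File path, glob pattern, or vector of slice file paths.
#' @param spacing `(z, y, x)` voxel sizes in micrometres.
#' @param channel Channel label.
#' @param bit_depth Bit depth for the returned volume; defaults to the TIFF
#'   sample size (16 for float data).
#' @return A [vmi_volume()].
#' @export
read_stack <- function(path, spacing, channel = "OTHER", bit_depth = NULL) {
  files <- .resolve_slices(path)
  pages <- list()
  bits <- NULL
  for (f in files) {
    tf <- .read_tiff(f)
    if (length(pages) &&
        !identical(dim(tf$pages[[1]]), dim(pages[[length(pages)]])))
      stop("inconsistent slice shapes across files", call. = FALSE)
    pages <- c(pages, tf$pages)
    if (is.null(bits)) bits <- tf$bits
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("inconsistent slice shapes across pages", call. = FALSE)
  d2 <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  if (is.null(bit_depth)) bit_depth <- if (bits == 32L) 16L else bits
  vmi_volume(vox, spacing, channel, bit_depth)
}

#' Write a volume or mask as multi-page TIFF
#'
#' Integer-valued volumes are stored at their nominal bit depth (8- or
#' 16-bit unsigned) and round-trip bit-exactly through [read_stack()].
#' Non-integer volumes are stored as 32-bit float. Masks are stored as 8-bit
#' `{0, 255}` for interoperability with common viewers; use [read_mask()] to
#' recover the boolean grid.
#'
#' @param volume A [vmi_volume()] or [vmi_mask()].
#' @param path Output file path; the parent directory must exist.
#' @return The path, invisibly.
#' @export
write_stack <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  if (inherits(volume, "vmi_mask")) {
    vox <- array(ifelse(volume$voxels, 255, 0), dim(volume$voxels))
    dtype <- "uint8"
  } else if (inherits(volume, "vmi_volume")) {
    vox <- volume$voxels
    dtype <- if (all(vox == floor(vox))) {
      if (volume$bit_depth <= 8L) "uint8" else "uint16"
    } else {
      "float32"
    }
  } else {
    stop("volume must be a vmi_volume or vmi_mask", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(vox)[1]), function(z) vox[z, , ])
  .write_tiff(pages, path, dtype)
  invisible(path)
}

#' Read a binary mask stored as 8-bit TIFF
#'
#' @inheritParams read_stack
#' @return A [vmi_mask()]; any voxel value above zero is foreground.
#' @export
read_mask <- function(path, spacing, channel = "OTHER") {
  v <- read_stack(path, spacing, channel)
  vmi_mask(v$voxels > 0, spacing, channel)
}

#' Flat-field (illumination) correction
#'
#' Divides each slice by the flat-field image scaled to unit mean, then
#' clips to the input bit range. Used on the redox path only: vascular
#' segmentation does not need it because intensity remapping and rolling-ball
#' subtraction absorb between-sample and illumination variation.
#'
#' @param volume A [vmi_volume()].
#' @param flat A 2D matrix (applied to every slice) or a [vmi_volume()] of
#'   the same shape. Must be strictly positive everywhere.
#' @return The corrected [vmi_volume()].
#' @export
flat_field_correct <- function(volume, flat) {
  stopifnot(inherits(volume, "vmi_volume"))
  fv <- if (inherits(flat, "vmi_volume")) flat$voxels else flat
  d <- dim(volume$voxels)
  if (is.matrix(fv)) {
    if (!identical(dim(fv), d[2:3]))
      stop("flat field shape does not match slice shape", call. = FALSE)
  } else if (!identical(dim(fv), d)) {
    stop("flat field shape does not match volume shape", call. = FALSE)
  }
  if (any(fv <= 0))
    stop("flat field contains zero or negative values within the volume ",
         "footprint", call. = FALSE)
  fn <- fv / mean(fv)
  out <- if (is.matrix(fn)) {
    sweep_arr <- volume$voxels
    for (z in seq_len(d[1])) sweep_arr[z, , ] <- sweep_arr[z, , ] / fn
    sweep_arr
  } else {
    volume$voxels / fn
  }
  maxv <- 2^volume$bit_depth - 1
  out <- pmin(pmax(out, 0), maxv)
  vmi_volume(array(out, d), volume$spacing, volume$channel, volume$bit_depth)
}
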
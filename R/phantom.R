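# phantom: synthetic whole-organ volumes with Murray-compliant vascular
# trees, the validation surface for the whole pipeline. Vessels are dark
# tubes (hemoglobin quenches autofluorescence) inside a bright, noisy,
# unevenly illuminated tissue foreground.

#' Specification of a synthetic vascular phantom
#'
#' Defaults describe a 1.28 mm^3-scale organ block at 10 um isotropic
#' resolution with a 4-generation binary tree: root diameter 60 um, exact
#' Murray exponent 3, branch length 8 diameters, Murray-optimal bifurcation
#' angles with mild angular jitter, tissue autofluorescence 30000 counts,
#' vessels 8000 counts, Gaussian noise 1500 counts and 15% smooth
#' illumination modulation.
#'
#' @param shape `(z, y, x)` voxel counts.
#' @param spacing `(z, y, x)` voxel sizes in micrometres.
#' @param levels Number of branch generations (`1` = a single unbranched
#'   root vessel).
#' @param root_diameter Root vessel diameter, um.
#' @param murray_exponent Exponent `m` of the generative branching rule
#'   `d1^m + d2^m = D^m` (default 3, Murray's law).
#' @param asymmetry Daughter imbalance in `[0, 1)`: the thinner daughter's
#'   diameter is `(1 - asymmetry)` times the thicker one's.
#' @param branch_length_ratio Branch length as a multiple of its diameter
#'   (default 8, self-similar).
#' @param tortuosity Standard deviation (radians) of the random angular
#'   jitter applied to each branch direction.
#' @param min_diameter Diameter cutoff in micrometres (default 0 = off): a
#'   branch whose prospective daughters would not both reach this calibre
#'   becomes terminal instead of bifurcating. With `asymmetry > 0` this
#'   spreads terminal branches across depths, as in real vasculature where
#'   thin lineages reach the capillary scale earlier; it also keeps the
#'   cubed-diameter conservation exact among the remaining bifurcations.
#' @param foreground_intensity Tissue intensity, counts.
#' @param vessel_intensity Vessel intensity, counts; must be darker than the
#'   tissue.
#' @param noise_sd Additive Gaussian noise SD, counts (0 disables).
#' @param illumination_amplitude Fractional amplitude in `[0, 1)` of the
#'   smooth (separable low-order polynomial) illumination field.
#' @param seed Integer seed; the same spec and seed reproduce the phantom
#'   bit for bit.
#' @return An object of class `vmi_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         spacing = c(10, 10, 10),
                         levels = 4L,
                         root_diameter = 60,
                         murray_exponent = 3,
                         asymmetry = 0,
                         branch_length_ratio = 8,
                         tortuosity = 0.15,
                         min_diameter = 0,
                         foreground_intensity = 30000,
                         vessel_intensity = 8000,
                         noise_sd = 1500,
                         illumination_amplitude = 0.15,
                         seed = 1L) {
  spacing <- .check_spacing(spacing)
  if (!is.numeric(shape) || length(shape) != 3L || any(shape < 4))
    stop("shape must be three voxel counts >= 4", call. = FALSE)
  if (!.is_count(levels) || levels < 1)
    stop("levels must be an integer >= 1", call. = FALSE)
  if (root_diameter <= 0) stop("root_diameter must be > 0", call. = FALSE)
  if (murray_exponent <= 0) stop("murray_exponent must be > 0", call. = FALSE)
  if (asymmetry < 0 || asymmetry >= 1)
    stop("asymmetry must lie in [0, 1)", call. = FALSE)
  if (branch_length_ratio <= 0)
    stop("branch_length_ratio must be > 0", call. = FALSE)
  if (tortuosity < 0) stop("tortuosity must be >= 0", call. = FALSE)
  if (min_diameter < 0) stop("min_diameter must be >= 0", call. = FALSE)
  if (vessel_intensity >= foreground_intensity)
    stop("vessel_intensity must be < foreground_intensity (vessels are dark)",
         call. = FALSE)
  if (vessel_intensity < 0 || foreground_intensity > 65535)
    stop("intensities must lie in [0, 65535]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (illumination_amplitude < 0 || illumination_amplitude >= 1)
    stop("illumination_amplitude must lie in [0, 1)", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 levels = as.integer(levels), root_diameter = root_diameter,
                 murray_exponent = murray_exponent, asymmetry = asymmetry,
                 branch_length_ratio = branch_length_ratio,
                 tortuosity = tortuosity,
                 min_diameter = min_diameter,
                 foreground_intensity = foreground_intensity,
                 vessel_intensity = vessel_intensity,
                 noise_sd = noise_sd,
                 illumination_amplitude = illumination_amplitude,
                 seed = as.integer(seed)),
            class = "vmi_phantom_spec")
}

# unit vector
.unit <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation of v by angle th about unit axis k
.rotate <- function(v, k, th) {
  v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                  k[3] * v[1] - k[1] * v[3],
                  k[1] * v[2] - k[2] * v[1]) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
}

# some unit vector perpendicular to u, at azimuth phi around u
.perp_at <- function(u, phi) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  e1 * cos(phi) + e2 * sin(phi)
}

# Murray-optimal bifurcation angle of daughter d1 against (d1, d2, D):
# cos(theta) = (D^4 + d1^4 - d2^4) / (2 D^2 d1^2)
.murray_angle <- function(D, d1, d2) {
  ct <- (D^4 + d1^4 - d2^4) / (2 * D^2 * d1^2)
  acos(pmin(1, pmax(-1, ct)))
}

#' Generate a Murray-compliant vascular tree
#'
#' Builds a rooted binary tree of `levels` generations: at every bifurcation
#' the daughter diameters satisfy `d1^m + d2^m = D^m` exactly, with the
#' diameter split set by `asymmetry` and branching angles from the
#' minimum-work optimum; branch directions receive angular jitter of
#' magnitude `tortuosity`. Fully deterministic for a given seed. If the
#' rasterized tree would escape the volume the branch lengths are shrunk in
#' steps of 15% (up to 8 attempts) before erroring.
#'
#' @param spec A [phantom_spec()].
#' @return A `vmi_tree` whose centerlines are straight segments.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "vmi_phantom_spec"))
  extent <- spec$shape * spec$spacing
  m <- spec$murray_exponent
  ratio <- 1 - spec$asymmetry
  margin <- min(spec$spacing)

  for (attempt in 0:7) {
    scale <- 0.85^attempt
    rows <- new.env()
    rows$start <- list()
    rows$end <- list()
    rows$D <- numeric(0)
    rows$depth <- integer(0)
    rows$parent <- integer(0)
    build <- .with_seed(spec$seed, {
      grow <- function(p0, u, D, depth, parent) {
        if (spec$tortuosity > 0) {
          jit <- abs(rnorm(1, 0, spec$tortuosity))
          phi <- runif(1, 0, 2 * pi)
          u <- .unit(.rotate(u, .perp_at(u, phi), jit))
        } else {
          # keep the RNG stream aligned across tortuosity settings
          invisible(rnorm(1))
          invisible(runif(1))
        }
        L <- spec$branch_length_ratio * D * scale
        p1 <- p0 + L * u
        id <- length(rows$D) + 1L
        rows$start[[id]] <- p0
        rows$end[[id]] <- p1
        rows$D[id] <- D
        rows$depth[id] <- depth
        rows$parent[id] <- parent
        d1 <- D / (1 + ratio^m)^(1 / m)
        d2 <- ratio * d1
        if (depth < spec$levels &&
            (spec$min_diameter <= 0 || min(d1, d2) >= spec$min_diameter)) {
          th1 <- .murray_angle(D, d1, d2)
          th2 <- .murray_angle(D, d2, d1)
          phi <- runif(1, 0, 2 * pi)
          ax <- .perp_at(u, phi)
          u1 <- .unit(.rotate(u, ax, th1))
          u2 <- .unit(.rotate(u, ax, -th2))
          grow(p1, u1, d1, depth + 1L, id)
          grow(p1, u2, d2, depth + 1L, id)
        }
      }
      p0 <- c(0.08 * extent[1], 0.5 * extent[2], 0.5 * extent[3])
      grow(p0, c(1, 0, 0), spec$root_diameter, 1L, NA_integer_)
      TRUE
    })
    pts <- do.call(rbind, c(rows$start, rows$end))
    r <- rep(rows$D / 2, 2)
    lo <- apply(pts - r, 2, min)
    hi <- sweep(pts + r, 2, extent)
    if (all(lo >= margin) && all(hi <= -margin)) break
    if (attempt == 7)
      stop("phantom tree escapes the volume after rescaling attempts",
           call. = FALSE)
  }

  n <- length(rows$D)
  centerlines <- lapply(seq_len(n), function(i)
    rbind(rows$start[[i]], rows$end[[i]]))
  lens <- vapply(seq_len(n), function(i)
    sqrt(sum((rows$end[[i]] - rows$start[[i]])^2)), numeric(1))
  df <- data.frame(id = seq_len(n), parent_id = rows$parent,
                   depth = rows$depth, mean_diameter_um = rows$D,
                   length_um = lens,
                   is_terminal = !(seq_len(n) %in% rows$parent),
                   component = 1L)
  structure(list(branches = df, centerlines = centerlines,
                 radii = lapply(rows$D, function(d) rep(d / 2, 2)),
                 spacing = spec$spacing, root_ids = 1L, broken_loops = 0L),
            class = "vmi_tree")
}

#' Rasterize a vascular tree into a phantom volume and ground-truth mask
#'
#' The ground-truth mask is the union of capsules (tubes with hemispherical
#' caps) along each branch centerline. The image is
#' `foreground_intensity` outside the mask and `vessel_intensity` inside,
#' multiplied by a smooth illumination field (`1 +
#' illumination_amplitude * low-order polynomial`), plus Gaussian noise,
#' clipped to `[0, 65535]` and rounded. Noise and illumination draw from a
#' stream derived from `spec$seed` that is independent of tree generation,
#' so the same tree rasterized under different seeds differs only in
#' intensities, never in the mask.
#'
#' @param tree A `vmi_tree`.
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [vmi_volume()], channel NADH) and `mask`
#'   (the ground-truth [vmi_mask()]).
#' @export
rasterize_tree <- function(tree, spec) {
  stopifnot(inherits(tree, "vmi_tree"), inherits(spec, "vmi_phantom_spec"))
  p0s <- list()
  p1s <- list()
  rad <- numeric(0)
  for (b in seq_along(tree$centerlines)) {
    cl <- tree$centerlines[[b]]
    r <- tree$branches$mean_diameter_um[tree$branches$id == b] / 2
    for (s in seq_len(nrow(cl) - 1)) {
      p0s[[length(p0s) + 1L]] <- cl[s, ]
      p1s[[length(p1s) + 1L]] <- cl[s + 1, ]
      rad <- c(rad, r)
    }
  }
  mask <- .rasterize_capsules_cpp(do.call(rbind, p0s), do.call(rbind, p1s),
                                  rad, spec$shape, spec$spacing)
  img <- array(spec$foreground_intensity, spec$shape)
  img[mask] <- spec$vessel_intensity

  .with_seed(spec$seed + 10007L, {
    if (spec$illumination_amplitude > 0) {
      cf <- runif(6, -1, 1)
      tz <- seq(-1, 1, length.out = spec$shape[1])
      ty <- seq(-1, 1, length.out = spec$shape[2])
      tx <- seq(-1, 1, length.out = spec$shape[3])
      f <- outer(outer(cf[1] * tz + cf[4] * tz^2,
                       cf[2] * ty + cf[5] * ty^2, `+`),
                 cf[3] * tx + cf[6] * tx^2, `+`)
      f <- 1 + spec$illumination_amplitude * f / max(abs(f))
      img <- img * f
    }
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sd)
  })
  img <- .round_half_up(pmin(pmax(img, 0), 65535))
  list(volume = vmi_volume(array(img, spec$shape), spec$spacing, "NADH", 16L),
       mask = vmi_mask(array(mask, spec$shape), spec$spacing, "NADH"))
}

#' Generate a complete phantom bundle
#'
#' [generate_tree()] followed by [rasterize_tree()]; the phantom spec
#' object travels with the outputs as provenance.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume`, `mask`, `tree`, `spec`. Identical spec and
#'   seed reproduce all three bit for bit.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  tree <- generate_tree(spec)
  ras <- rasterize_tree(tree, spec)
  list(volume = ras$volume, mask = ras$mask, tree = tree, spec = spec)
}
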
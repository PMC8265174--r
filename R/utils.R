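# Internal helpers shared across modules.

# Round half up to the nearest integer (pinned so intensity remapping is
# bit-exact and testable; R's round() rounds half to even).
.round_half_up <- function(x) floor(x + 0.5)

# Run expr with a private RNG stream: the global .Random.seed is restored
# afterwards so generators are deterministic without disturbing user code.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L || anyNA(spacing) ||
      any(spacing <= 0)) {
    stop("spacing must be three strictly positive (z, y, x) voxel sizes in um",
         call. = FALSE)
  }
  as.numeric(spacing)
}

# Otsu's threshold on a 256-bin histogram over [0, maxval]. Returns the bin
# upper edge maximizing between-class variance; voxels strictly above the
# returned value form the bright class.
.otsu <- function(v, maxval) {
  nb <- 256L
  if (maxval <= 0) return(0)
  h <- tabulate(pmin(nb, floor(as.numeric(v) / maxval * nb) + 1L), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  k / nb * maxval
}

# Triangle threshold (Zack) on a 256-bin histogram: normalize so the
# histogram peak is (0, 1) and the far end of the longer tail is (1, 0);
# the threshold is the bin farthest below the line joining them. Robust
# when the foreground is a tiny fraction of the voxels (sparse vessels),
# where Otsu's between-class criterion splits the background mode instead.
# Exact zeros are dropped first: after background subtraction they are
# background by definition and their spike would masquerade as the peak.
.triangle <- function(v, maxval) {
  nb <- 256L
  if (maxval <= 0) return(0)
  x <- as.numeric(v)
  x <- x[x > 0]
  if (!length(x)) return(0)
  h <- tabulate(pmin(nb, floor(x / maxval * nb) + 1L), nbins = nb)
  pk <- which.max(h)
  fn <- min(which(h > 0))
  ln <- max(which(h > 0))
  lower_edge <- function(k) max(0, (k - 1) / nb * maxval - 1)
  if (ln == fn) return(lower_edge(pk))  # single occupied bin
  if (ln - pk >= pk - fn) {
    # bright tail to the right of the peak (the usual case here)
    if (ln == pk) return(lower_edge(pk))
    xs <- pk:ln
    sc <- 1 - (xs - pk) / (ln - pk) - h[xs] / h[pk]
    k <- xs[which.max(sc)]
    k / nb * maxval
  } else {
    # mirrored: dark tail to the left (bright background)
    xs <- fn:pk
    sc <- 1 - (pk - xs) / (pk - fn) - h[xs] / h[pk]
    k <- xs[which.max(sc)]
    lower_edge(k)
  }
}

# Trilinear resampling of a numeric 3D array onto an isotropic grid at the
# finest spacing. Physical coordinates are preserved: voxel centers sit at
# (i - 0.5) * spacing. Used by the tracer for anisotropic inputs.
.resample_iso <- function(vox, spacing) {
  s <- min(spacing)
  dm <- dim(vox)
  extent <- dm * spacing
  ndm <- pmax(1L, as.integer(round(extent / s)))
  # target voxel centers in source fractional index space (1-based)
  ctr <- lapply(1:3, function(a) {
    ((seq_len(ndm[a]) - 0.5) * s) / spacing[a] + 0.5
  })
  out <- array(0, dim = ndm)
  f <- lapply(1:3, function(a) {
    x <- ctr[[a]]
    i0 <- pmax(1L, pmin(dm[a] - 1L, as.integer(floor(x))))
    if (dm[a] == 1L) i0 <- rep(1L, length(x))
    w <- x - i0
    w <- pmax(0, pmin(1, w))
    list(i0 = i0, i1 = pmin(dm[a], i0 + 1L), w = w)
  })
  # accumulate the 8 trilinear corners
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    iz <- if (cz == 0) f[[1]]$i0 else f[[1]]$i1
    iy <- if (cy == 0) f[[2]]$i0 else f[[2]]$i1
    ix <- if (cx == 0) f[[3]]$i0 else f[[3]]$i1
    wz <- if (cz == 0) 1 - f[[1]]$w else f[[1]]$w
    wy <- if (cy == 0) 1 - f[[2]]$w else f[[2]]$w
    wx <- if (cx == 0) 1 - f[[3]]$w else f[[3]]$w
    w3 <- outer(outer(wz, wy), wx)
    out <- out + vox[iz, iy, ix, drop = FALSE] * w3
  }
  list(vox = out, spacing = rep(s, 3))
}
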
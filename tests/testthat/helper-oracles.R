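# Independent oracles and small fixture builders, kept deliberately naive:
# they re-derive results from definitions and never call the code paths
# they check.

# Grayscale opening by a spherical element, straight from the definition,
# one pixel at a time.
rollball_oracle <- function(img, r) {
  ny <- nrow(img)
  nx <- ncol(img)
  off <- expand.grid(dy = -floor(r):floor(r), dx = -floor(r):floor(r))
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  h <- sqrt(r^2 - off$dy^2 - off$dx^2)
  ero <- matrix(NA_real_, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    yy <- y + off$dy
    xx <- x + off$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    ero[y, x] <- min(img[cbind(yy[ok], xx[ok])] - h[ok])
  }
  op <- matrix(NA_real_, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    yy <- y - off$dy
    xx <- x - off$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    op[y, x] <- max(ero[cbind(yy[ok], xx[ok])] + h[ok])
  }
  op
}

# Dice from explicit coordinate sets.
dice_oracle <- function(a, b) {
  ca <- apply(which(a, arr.ind = TRUE), 1, paste, collapse = ",")
  cb <- apply(which(b, arr.ind = TRUE), 1, paste, collapse = ",")
  if (length(ca) + length(cb) == 0) return(0)
  2 * length(intersect(ca, cb)) / (length(ca) + length(cb))
}

# Solid axis-aligned cylinder along z.
make_cylinder <- function(nz = 48, nyx = 15, radius_vox = 3,
                          z0 = 5, z1 = nz - 4, cyx = (nyx + 1) / 2,
                          spacing = c(10, 10, 10)) {
  vox <- array(FALSE, c(nz, nyx, nyx))
  for (y in seq_len(nyx)) for (x in seq_len(nyx)) {
    if ((y - cyx)^2 + (x - cyx)^2 <= radius_vox^2) vox[z0:z1, y, x] <- TRUE
  }
  vmi_mask(vox, spacing)
}

# Minimal vmi_tree from a hand-written branch data frame.
toy_tree <- function(df) {
  df$component <- 1L
  structure(list(branches = df, centerlines = NULL, radii = NULL,
                 spacing = c(1, 1, 1),
                 root_ids = df$id[is.na(df$parent_id)], broken_loops = 0L),
            class = "vmi_tree")
}

# Small phantom spec used by unit tests (fast; the acceptance suite uses
# the full default 128^3 world).
small_spec <- function(...) {
  args <- utils::modifyList(list(shape = c(64, 64, 64), levels = 3L,
                                 root_diameter = 50), list(...))
  do.call(phantom_spec, args)
}
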
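# SWC morphology export/import for vessel trees.
#
# SWC: one node per line, "id type x y z radius parent". Type code is fixed
# at 7 (custom); coordinates are physical micrometres with SWC (x, y, z)
# mapped from the internal (z, y, x) axis order; radius is the local
# inscribed radius.

#' Write a vessel tree in SWC format
#'
#' Centerline points become SWC nodes chained per branch; the first node of
#' a child branch attaches to the last node of its parent.
#'
#' @param tree A `vmi_tree` with centerlines (from [build_tree()] or
#'   [generate_tree()]).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "vmi_tree"))
  if (is.null(tree$centerlines))
    stop("tree has no centerline geometry", call. = FALSE)
  br <- tree$branches[order(tree$branches$id), ]
  lines <- character(0)
  nid <- 0L
  last_node <- integer(max(br$id))  # last SWC node id of each branch
  for (i in seq_len(nrow(br))) {
    b <- br$id[i]
    cl <- tree$centerlines[[b]]
    rr <- tree$radii[[b]]
    if (length(rr) != nrow(cl)) rr <- rep(rr[1], nrow(cl))
    parent_branch <- br$parent_id[i]
    prev <- if (is.na(parent_branch)) -1L else last_node[parent_branch]
    start <- 1L
    if (!is.na(parent_branch)) {
      # skip a first point duplicating the parent's junction point
      pcl <- tree$centerlines[[parent_branch]]
      if (all(abs(cl[1, ] - pcl[nrow(pcl), ]) < 1e-9) && nrow(cl) > 1)
        start <- 2L
    }
    for (p in start:nrow(cl)) {
      nid <- nid + 1L
      lines[nid] <- sprintf("%d 7 %.6g %.6g %.6g %.6g %d", nid,
                            cl[p, 3], cl[p, 2], cl[p, 1], rr[p], prev)
      prev <- nid
    }
    last_node[b] <- nid
  }
  writeLines(c("# SWC vessel tree (x y z in um, radius um)", lines), path)
  invisible(path)
}

#' Read an SWC file back into a vessel tree
#'
#' Reconstructs branches by cutting node chains at bifurcations; depths are
#' re-derived (root = 1, +1 per junction), diameters as twice the mean
#' node radius per branch.
#'
#' @param path SWC file.
#' @param spacing Voxel spacing to record on the tree (defaults to 1 um).
#' @return A `vmi_tree`.
#' @export
read_swc <- function(path, spacing = c(1, 1, 1)) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!length(ln)) stop("empty SWC file", call. = FALSE)
  m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  nodes <- data.frame(id = m[, 1], x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = m[, 7])
  nodes <- nodes[order(nodes$id), ]
  nchild <- table(factor(nodes$parent[nodes$parent > 0],
                         levels = nodes$id))
  nchild <- as.integer(nchild)
  is_branch_start <- nodes$parent <= 0 |
    nchild[match(nodes$parent, nodes$id)] >= 2
  is_branch_start[is.na(is_branch_start)] <- TRUE

  branches <- list()
  centerlines <- list()
  radii <- list()
  starts <- which(is_branch_start)
  node_branch <- integer(nrow(nodes))
  for (s in starts) {
    bid <- length(branches) + 1L
    chain <- s
    cur <- s
    repeat {
      kids <- which(nodes$parent == nodes$id[cur])
      if (length(kids) != 1 || is_branch_start[kids]) break
      cur <- kids
      chain <- c(chain, cur)
    }
    node_branch[chain] <- bid
    pid <- nodes$parent[s]
    parent_branch <- if (pid <= 0) NA_integer_ else
      node_branch[match(pid, nodes$id)]
    pts <- cbind(z = nodes$z[chain], y = nodes$y[chain], x = nodes$x[chain])
    if (!is.na(parent_branch)) {
      pprev <- match(pid, nodes$id)
      pts <- rbind(c(nodes$z[pprev], nodes$y[pprev], nodes$x[pprev]), pts)
    }
    branches[[bid]] <- list(parent = parent_branch, chainlen = nrow(pts),
                            radius = mean(nodes$radius[chain]))
    centerlines[[bid]] <- pts
    radii[[bid]] <- c(if (!is.na(parent_branch)) nodes$radius[match(pid, nodes$id)],
                      nodes$radius[chain])
  }
  n <- length(branches)
  depth <- integer(n)
  for (b in seq_len(n)) {
    p <- branches[[b]]$parent
    depth[b] <- if (is.na(p)) 1L else depth[p] + 1L
  }
  parent_ids <- vapply(branches, function(b)
    if (is.na(b$parent)) NA_integer_ else b$parent, integer(1))
  lens <- vapply(centerlines, function(cl) {
    if (nrow(cl) < 2) return(0)
    sum(sqrt(rowSums((cl[-1, , drop = FALSE] -
                      cl[-nrow(cl), , drop = FALSE])^2)))
  }, numeric(1))
  df <- data.frame(id = seq_len(n), parent_id = parent_ids, depth = depth,
                   mean_diameter_um = 2 * vapply(branches, `[[`, numeric(1),
                                                 "radius"),
                   length_um = lens,
                   is_terminal = !(seq_len(n) %in% parent_ids),
                   component = 1L)
  # component: inherit from parent, new component at each root
  df$component <- cumsum(is.na(parent_ids))
  for (b in seq_len(n)) {
    p <- parent_ids[b]
    if (!is.na(p)) df$component[b] <- df$component[p]
  }
  structure(list(branches = df, centerlines = centerlines, radii = radii,
                 spacing = .check_spacing(spacing),
                 root_ids = df$id[is.na(df$parent_id)], broken_loops = 0L),
            class = "vmi_tree")
}
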
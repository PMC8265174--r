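# tracing: from a binary vessel mask to a rooted branch tree.
#
# The mask is thinned to a curve skeleton (distance-ordered homotopic
# thinning), the skeleton voxels are contracted into a graph whose nodes
# are junction clusters and free endpoints and whose edges are centerline
# segments, loops are broken at the weakest-radius edge (Murray analysis
# assumes a tree), spurs are pruned, and each connected component is rooted
# at the endpoint with the largest inscribed radius -- the "largest starting
# point". Depth starts at 1 at the root and increments at every junction.

#' Skeletonize a vessel mask
#'
#' 3D topological thinning to a curve skeleton: simple voxels are deleted
#' outward-in (ordered by the Euclidean distance transform) while curve
#' endpoints are preserved, so connectivity and component count are
#' unchanged and every skeleton voxel lies inside the mask.
#'
#' @param mask A non-empty [vmi_mask()].
#' @return A [vmi_mask()] holding the skeleton voxels.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "vmi_mask"))
  if (!any(mask$voxels)) stop("empty mask", call. = FALSE)
  dm <- dim(mask$voxels)
  edt <- .edt3d_cpp(mask$voxels, dm, mask$spacing)
  sk <- .skeletonize3d_cpp(mask$voxels, dm, edt)
  vmi_mask(array(sk, dm), mask$spacing, mask$source_channel)
}

# 26-neighbor adjacency among a set of voxels. idx: sorted linear indices,
# co: arrayInd coords. Returns 2-column matrix of vertex pairs (i < j).
.skel_edges <- function(idx, co, dm) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # half-space of offsets to avoid duplicate edges
  keep <- offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)
  offs <- offs[keep, , drop = FALSE]
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    zz <- co[, 1] + offs[k, 1]
    yy <- co[, 2] + offs[k, 2]
    xx <- co[, 3] + offs[k, 3]
    ok <- zz >= 1 & zz <= dm[1] & yy >= 1 & yy <= dm[2] & xx >= 1 & xx <= dm[3]
    nlin <- (xx - 1) * dm[1] * dm[2] + (yy - 1) * dm[1] + zz
    j <- match(nlin, idx)
    sel <- ok & !is.na(j)
    if (any(sel)) out[[k]] <- cbind(which(sel), j[sel])
  }
  do.call(rbind, out)
}

# Order the voxels of a path (or cycle) component by walking from an end.
.walk_chain <- function(vs, adj, start) {
  visited <- logical(length(adj))
  chain <- integer(length(vs))
  chain[1] <- start
  visited[start] <- TRUE
  n <- 1L
  cur <- start
  repeat {
    nb <- adj[[cur]]
    nxt <- nb[!visited[nb]]
    if (!length(nxt)) break
    cur <- nxt[1]
    n <- n + 1L
    chain[n] <- cur
    visited[cur] <- TRUE
  }
  chain[seq_len(n)]
}

#' Trace a vessel tree from a binary mask
#'
#' Converts a [vmi_mask()] into a rooted branch forest with per-branch
#' depth, mean diameter and length. Anisotropic volumes are resampled to
#' isotropic resolution at the finest spacing before thinning; all reported
#' coordinates are physical micrometres. Per connected component the root is
#' the endpoint of the fattest vessel: leaves are scored by the largest
#' inscribed radius (distance-transform value) along their incident
#' centerline segment, ties broken by lexicographic `(z, y, x)` order; the
#' root branch
#' has depth 1 and depth increments once per junction (a trifurcation
#' increments once for all children). Branch diameter is twice the mean
#' distance-transform value along the centerline; graph cycles are broken
#' at the weakest-radius edge and counted in `broken_loops`.
#'
#' @param mask A non-empty [vmi_mask()].
#' @param prune_below Absolute spur-prune length in micrometres (default 0):
#'   terminal segments shorter than this are removed iteratively.
#' @param prune_rel Relative spur-prune factor (default 2): terminal
#'   segments shorter than `prune_rel` times the local vessel diameter at
#'   their attachment junction are removed. Set 0 to disable.
#' @return An object of class `vmi_tree`: `branches` (data frame),
#'   `centerlines` (list of `n x 3` matrices of `(z, y, x)` um), `radii`
#'   (per-point inscribed radii, um), `spacing`, `root_ids`, `broken_loops`.
#' @export
build_tree <- function(mask, prune_below = 0, prune_rel = 2) {
  stopifnot(inherits(mask, "vmi_mask"))
  if (!any(mask$voxels)) stop("empty mask", call. = FALSE)
  if (prune_below < 0) stop("prune_below must be >= 0", call. = FALSE)
  sp <- mask$spacing
  vox <- mask$voxels
  if (max(sp) / min(sp) > 1.001) {
    r <- .resample_iso(array(as.numeric(vox), dim(vox)), sp)
    vox <- array(r$vox >= 0.5, dim(r$vox))
    wsp <- r$spacing
    if (!any(vox)) stop("mask empty after isotropic resampling", call. = FALSE)
  } else {
    wsp <- sp
  }
  dm <- dim(vox)
  edt <- .edt3d_cpp(vox, dm, wsp)
  skel <- .skeletonize3d_cpp(vox, dm, edt)
  idx <- which(skel)
  co <- arrayInd(idx, dm)
  nv <- length(idx)
  ed <- .skel_edges(idx, co, dm)
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (!is.null(ed) && nrow(ed)) g <- igraph::add_edges(g, t(ed))
  deg <- igraph::degree(g)

  # --- junction clusters ---------------------------------------------------
  jflag <- deg >= 3
  jcl <- rep(NA_integer_, nv)
  jrep <- integer(0)  # representative voxel (vertex id) per cluster
  if (any(jflag)) {
    jv <- which(jflag)
    cj <- igraph::components(igraph::induced_subgraph(g, jv))
    jcl[jv] <- cj$membership
    jrep <- vapply(seq_len(cj$no), function(cl) {
      cand <- jv[cj$membership == cl]
      cand[order(-edt[idx[cand]], idx[cand])][1]
    }, integer(1))
  }
  njc <- length(jrep)

  # --- segments: maximal chains of non-junction voxels ---------------------
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  seg_chain <- list()    # ordered vertex ids (non-junction interiors)
  seg_nodeA <- character(0)
  seg_nodeB <- character(0)
  seg_endA_vox <- integer(0)  # attachment voxel inside cluster (or chain end)
  seg_endB_vox <- integer(0)
  adj_cluster <- function(v) {
    nb <- adj[[v]]
    cl <- unique(jcl[nb[jflag[nb]]])
    sort(cl)
  }
  njv <- which(!jflag)
  if (length(njv)) {
    gn_adj <- lapply(njv, function(v) {
      nb <- adj[[v]]
      match(nb[!jflag[nb]], njv)
    })
    degn <- lengths(gn_adj)
    compn <- rep(NA_integer_, length(njv))
    ccur <- 0L
    for (s in seq_along(njv)) {
      if (!is.na(compn[s])) next
      ccur <- ccur + 1L
      q <- s
      compn[s] <- ccur
      while (length(q)) {
        v <- q[[1]]
        q <- q[-1]
        for (w in gn_adj[[v]]) {
          if (is.na(compn[w])) {
            compn[w] <- ccur
            q <- c(q, w)
          }
        }
      }
    }
    for (cc in seq_len(ccur)) {
      vs <- which(compn == cc)
      ends <- vs[degn[vs] <= 1]
      start <- if (length(ends)) ends[order(idx[njv[ends]])][1] else
        vs[order(idx[njv[vs]])][1]  # pure cycle: break arbitrarily
      chain_loc <- .walk_chain(vs, gn_adj, start)
      chain <- njv[chain_loc]
      k <- length(chain)
      clA <- adj_cluster(chain[1])
      clB <- if (k > 1) adj_cluster(chain[k]) else integer(0)
      if (k == 1 && length(clA) >= 2) {
        clB <- clA[2]
        clA <- clA[1]
      } else {
        clA <- if (length(clA)) clA[1] else NA_integer_
        clB <- if (length(clB)) clB[1] else NA_integer_
      }
      sid <- length(seg_chain) + 1L
      seg_chain[[sid]] <- chain
      seg_nodeA[sid] <- if (!is.na(clA)) paste0("J", clA) else
        paste0("E", sid, "a")
      seg_nodeB[sid] <- if (!is.na(clB)) paste0("J", clB) else
        paste0("E", sid, "b")
      seg_endA_vox[sid] <- chain[1]
      seg_endB_vox[sid] <- chain[k]
    }
  }
  # direct junction-cluster adjacencies (no interior voxel between)
  if (njc && !is.null(ed) && nrow(ed)) {
    a <- ed[, 1]
    b <- ed[, 2]
    sel <- jflag[a] & jflag[b] & jcl[a] != jcl[b]
    if (any(sel)) {
      pa <- pmin(jcl[a[sel]], jcl[b[sel]])
      pb <- pmax(jcl[a[sel]], jcl[b[sel]])
      key <- paste(pa, pb)
      first <- !duplicated(key)
      for (i in which(first)) {
        sid <- length(seg_chain) + 1L
        seg_chain[[sid]] <- integer(0)
        seg_nodeA[sid] <- paste0("J", pa[i])
        seg_nodeB[sid] <- paste0("J", pb[i])
        va <- a[sel][i]
        vb <- b[sel][i]
        if (jcl[va] != pa[i]) {
          tmp <- va
          va <- vb
          vb <- tmp
        }
        seg_endA_vox[sid] <- va
        seg_endB_vox[sid] <- vb
      }
    }
  }
  nseg <- length(seg_chain)
  if (!nseg) {
    # mask thinned to junction voxels only (tiny blob): single-point branch
    v0 <- if (njc) jrep[1] else which.max(edt[idx])
    seg_chain[[1]] <- v0
    seg_nodeA[1] <- "E1a"
    seg_nodeB[1] <- "E1b"
    seg_endA_vox[1] <- v0
    seg_endB_vox[1] <- v0
    nseg <- 1L
  }

  seg_len <- numeric(nseg)
  seg_rad <- numeric(nseg)
  seg_maxrad <- numeric(nseg)
  coords_um <- sweep(co - 0.5, 2, wsp, `*`)
  for (s in seq_len(nseg)) {
    vs <- unique(c(seg_endA_vox[s], seg_chain[[s]], seg_endB_vox[s]))
    pts <- coords_um[vs, , drop = FALSE]
    seg_len[s] <- if (nrow(pts) > 1)
      sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2)))
    else mean(wsp)
    dv <- seg_chain[[s]]
    if (!length(dv)) dv <- vs
    seg_rad[s] <- mean(edt[idx[dv]])
    seg_maxrad[s] <- max(edt[idx[vs]])
  }

  # --- segment graph, loop breaking, pruning -------------------------------
  enames <- unique(c(seg_nodeA, seg_nodeB))
  sg <- igraph::graph_from_data_frame(
    data.frame(from = seg_nodeA, to = seg_nodeB, sid = seq_len(nseg),
               weight = -seg_rad, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = enames, stringsAsFactors = FALSE))
  nloops <- sum(igraph::which_loop(sg))
  sg <- igraph::delete_edges(sg, igraph::E(sg)[igraph::which_loop(sg)])
  before <- igraph::ecount(sg)
  sg <- igraph::mst(sg)
  nloops <- nloops + (before - igraph::ecount(sg))

  node_rep_vox <- function(name) {
    if (startsWith(name, "J")) return(jrep[as.integer(substring(name, 2))])
    sid <- as.integer(gsub("^E(\\d+)[ab]$", "\\1", name))
    if (endsWith(name, "a")) seg_endA_vox[sid] else seg_endB_vox[sid]
  }

  repeat {
    degs <- igraph::degree(sg)
    el <- igraph::as_edgelist(sg, names = TRUE)
    if (!nrow(el)) break
    esid <- igraph::E(sg)$sid
    drop <- logical(nrow(el))
    for (i in seq_len(nrow(el))) {
      na <- el[i, 1]
      nb <- el[i, 2]
      ea <- startsWith(na, "E")
      ebb <- startsWith(nb, "E")
      if (ea == ebb) next                      # J-J or isolated E-E: keep
      jn <- if (ea) nb else na
      if (degs[jn] < 2) next                   # junction would vanish: keep
      thr <- max(prune_below,
                 prune_rel * 2 * edt[idx[node_rep_vox(jn)]])
      if (seg_len[esid[i]] < thr) drop[i] <- TRUE
    }
    if (!any(drop)) break
    sg <- igraph::delete_edges(sg, igraph::E(sg)[which(drop)])
    iso <- which(igraph::degree(sg) == 0)
    if (length(iso)) sg <- igraph::delete_vertices(sg, iso)
    if (!igraph::vcount(sg)) break
  }
  if (!igraph::vcount(sg)) stop("mask pruned to nothing", call. = FALSE)

  # --- root each component, orient, merge pass-throughs --------------------
  vnames <- igraph::V(sg)$name
  compsg <- igraph::components(sg)
  comp_order <- order(vapply(seq_len(compsg$no), function(cmp) {
    min(idx[vapply(vnames[compsg$membership == cmp], node_rep_vox,
                   integer(1))])
  }, numeric(1)))

  branches <- list()
  centerlines <- list()
  radii_list <- list()
  root_ids <- integer(0)
  bid <- 0L

  inc_edges <- function(nname) {
    igraph::incident(sg, nname)
  }
  other_end <- function(e, nname) {
    ev <- igraph::ends(sg, e)[1, ]
    if (ev[1] == nname) ev[2] else ev[1]
  }

  for (ci in seq_along(comp_order)) {
    cmp <- comp_order[ci]
    members <- vnames[compsg$membership == cmp]
    # root candidates: leaves of the pruned segment tree (free endpoints,
    # or junctions reduced to degree 1 by spur pruning). The root is the
    # leaf whose vessel is fattest -- the "largest starting point" -- scored
    # by the maximum inscribed radius along the incident segment (the
    # endpoint voxel itself sits on the tapering vessel tip, so its own
    # distance value says nothing about the calibre). Ties break by
    # lexicographic (z, y, x) of the leaf voxel.
    degsg <- igraph::degree(sg)
    cands <- members[degsg[members] <= 1]
    if (!length(cands)) cands <- members
    score <- vapply(cands, function(nm) {
      es <- igraph::incident(sg, nm)
      if (!length(es)) return(edt[idx[node_rep_vox(nm)]])
      max(seg_maxrad[igraph::E(sg)$sid[as.integer(es)]])
    }, numeric(1))
    rvox <- vapply(cands, node_rep_vox, integer(1))
    ord <- order(-score, co[rvox, 1], co[rvox, 2], co[rvox, 3])
    root_name <- cands[ord][1]

    used <- rep(FALSE, igraph::ecount(sg))
    # each stack entry: node to expand, branch id under construction,
    # current chain (vertex ids), depth
    open_branch <- function(parent, depth, init_chain) {
      bid <<- bid + 1L
      branches[[bid]] <<- list(id = bid, parent = parent, depth = depth,
                               chain = init_chain, component = ci,
                               children = 0L)
      bid
    }
    append_seg <- function(b, e, from_name) {
      sid <- igraph::E(sg)$sid[as.integer(e)]
      ch <- seg_chain[[sid]]
      va <- seg_endA_vox[sid]
      vb <- seg_endB_vox[sid]
      # orient so the segment leaves from_name
      atA <- identical(seg_nodeA[sid], from_name)
      pts <- if (atA) c(va, ch, vb) else c(vb, rev(ch), va)
      pts <- pts[!duplicated(pts)]
      old <- branches[[b]]$chain
      tl <- old[length(old)]
      while (length(pts) && pts[1] == tl) pts <- pts[-1]
      branches[[b]]$chain <<- c(old, pts)
      sid
    }
    # DFS
    st <- list()
    root_vox <- node_rep_vox(root_name)
    rb <- open_branch(NA_integer_, 1L, root_vox)
    root_ids <- c(root_ids, rb)
    st[[1]] <- list(node = root_name, branch = rb)
    while (length(st)) {
      cur <- st[[length(st)]]
      st[[length(st)]] <- NULL
      es <- inc_edges(cur$node)
      es <- es[!used[as.integer(es)]]
      if (!length(es)) next
      if (length(es) > 1) {
        sids <- igraph::E(sg)$sid[as.integer(es)]
        es <- es[order(-seg_rad[sids], sids)]
      }
      brdepth <- branches[[cur$branch]]$depth
      single <- length(es) == 1
      if (!single) {
        # close the parent branch at the junction center, so child
        # centerlines (which start there) connect without a gap
        rv <- node_rep_vox(cur$node)
        old <- branches[[cur$branch]]$chain
        if (old[length(old)] != rv)
          branches[[cur$branch]]$chain <- c(old, rv)
      }
      for (k in seq_along(es)) {
        e <- es[[k]]
        used[as.integer(e)] <- TRUE
        if (single) {
          b <- cur$branch
        } else {
          b <- open_branch(cur$branch, brdepth + 1L,
                           node_rep_vox(cur$node))
        }
        append_seg(b, e, cur$node)
        nxt <- other_end(e, cur$node)
        if (startsWith(nxt, "J"))
          st[[length(st) + 1]] <- list(node = nxt, branch = b)
      }
    }
  }

  # --- branch statistics ---------------------------------------------------
  nbr <- length(branches)
  df <- data.frame(id = integer(nbr), parent_id = integer(nbr),
                   depth = integer(nbr), mean_diameter_um = numeric(nbr),
                   length_um = numeric(nbr), is_terminal = logical(nbr),
                   component = integer(nbr))
  has_child <- logical(nbr)
  for (b in seq_len(nbr)) {
    p <- branches[[b]]$parent
    if (!is.na(p)) has_child[p] <- TRUE
  }
  for (b in seq_len(nbr)) {
    ch <- branches[[b]]$chain
    pts <- coords_um[ch, , drop = FALSE]
    len <- if (nrow(pts) > 1)
      sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2)))
    else mean(wsp)
    dv <- ch[is.na(jcl[ch])]
    if (!length(dv)) dv <- ch
    df$id[b] <- branches[[b]]$id
    df$parent_id[b] <- branches[[b]]$parent
    df$depth[b] <- branches[[b]]$depth
    df$mean_diameter_um[b] <- 2 * mean(edt[idx[dv]])
    df$length_um[b] <- len
    df$is_terminal[b] <- !has_child[b]
    df$component[b] <- branches[[b]]$component
    centerlines[[b]] <- pts
    radii_list[[b]] <- edt[idx[ch]]
  }
  df <- df[order(df$component, df$depth, df$id), ]
  rownames(df) <- NULL
  structure(list(branches = df, centerlines = centerlines,
                 radii = radii_list, spacing = sp, root_ids = root_ids,
                 broken_loops = nloops),
            class = "vmi_tree")
}

#' @export
print.vmi_tree <- function(x, ...) {
  b <- x$branches
  cat(sprintf("<vmi_tree> %d branches in %d component(s), max depth %d\n",
              nrow(b), length(x$root_ids), max(b$depth)))
  cat(sprintf("  diameters %.1f-%.1f um, total length %.0f um",
              min(b$mean_diameter_um), max(b$mean_diameter_um),
              sum(b$length_um)))
  if (x$broken_loops > 0)
    cat(sprintf(", %d loop(s) broken", x$broken_loops))
  cat("\n")
  invisible(x)
}

#' Tabulate the branches of a vessel tree
#'
#' One row per branch with id, parent id, depth, mean diameter (um), length
#' (um) and terminal flag, in deterministic order (component, then depth,
#' then id).
#'
#' @param tree A `vmi_tree`.
#' @return A data frame.
#' @export
branch_table <- function(tree) {
  stopifnot(inherits(tree, "vmi_tree"))
  tree$branches[, c("id", "parent_id", "depth", "mean_diameter_um",
                    "length_um", "is_terminal")]
}

#' Write / read a branch table as CSV
#'
#' Numeric fields survive the round trip to at least 6 significant digits.
#'
#' @param tree A `vmi_tree`.
#' @param path CSV file path.
#' @return `write_branch_table` the path invisibly; `read_branch_table` a
#'   data frame usable by [murray_depth_sums()] (wrapped as a minimal
#'   `vmi_tree`).
#' @export
write_branch_table <- function(tree, path) {
  df <- branch_table(tree)
  df$mean_diameter_um <- signif(df$mean_diameter_um, 9)
  df$length_um <- signif(df$length_um, 9)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_branch_table
#' @export
read_branch_table <- function(path) {
  df <- read.csv(path)
  need <- c("id", "parent_id", "depth", "mean_diameter_um", "length_um",
            "is_terminal")
  if (!all(need %in% names(df)))
    stop("not a branch table: missing columns", call. = FALSE)
  df$component <- 1L
  structure(list(branches = df, centerlines = NULL, radii = NULL,
                 spacing = c(1, 1, 1),
                 root_ids = df$id[is.na(df$parent_id)], broken_loops = 0L),
            class = "vmi_tree")
}
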
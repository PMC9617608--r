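# Elementary loops, loop planarity, pore-size estimate, MST pruning.

#' Elementary loops of the network
#'
#' For every node v the subgraph lacking v is considered; for every pair of
#' branches incident to v, the shortest branch-length-weighted path between
#' their far endpoints (Dijkstra) plus the two incident branches forms a
#' candidate loop. Collecting over all nodes and deduplicating by the set of
#' member branch ids yields the elementary loops: for each branch, the
#' shortest cycle containing it appears in the set. Self-loop branches and
#' parallel branch pairs yield 1- and 2-node loops.
#'
#' @param g a [skeleton_graph].
#' @return data.frame `loop_id`, `circumference` (nm), `node_count`,
#'   `branch_count`, with attribute `members`: list of branch-id vectors,
#'   and attribute `node_members`: list of node-id vectors. Acyclic graphs
#'   return zero rows.
#' @export
elementary_loops <- function(g) {
  seen <- new.env(parent = emptyenv())
  loops <- list()
  add_loop <- function(branch_ids, circumference, node_ids) {
    key <- paste(sort(branch_ids), collapse = "-")
    if (!is.null(seen[[key]])) {
      if (circumference < seen[[key]]$circumference)
        seen[[key]] <- list(circumference = circumference,
                            branches = branch_ids, nodes = node_ids)
      return(invisible())
    }
    seen[[key]] <- list(circumference = circumference,
                        branches = branch_ids, nodes = node_ids)
  }

  ig <- as_igraph(g, weight = "length")
  for (vi in seq_len(nrow(g$nodes))) {
    v <- g$nodes$id[vi]
    inc <- which(g$branches$node_a == v | g$branches$node_b == v)
    if (length(inc) == 0) next
    # self-loop branches are loops on their own
    for (bi in inc) {
      if (g$branches$node_a[bi] == v && g$branches$node_b[bi] == v)
        add_loop(g$branches$id[bi], g$branches$arc_length[bi], v)
    }
    inc <- inc[!(g$branches$node_a[inc] == v & g$branches$node_b[inc] == v)]
    if (length(inc) < 2) next
    far <- ifelse(g$branches$node_a[inc] == v,
                  g$branches$node_b[inc], g$branches$node_a[inc])
    sub <- igraph::delete_vertices(ig, as.character(v))
    wts <- igraph::E(sub)$weight
    for (i in seq_len(length(inc) - 1)) {
      u <- far[i]
      rest <- (i + 1):length(inc)
      # parallel pairs through v need no pathfinding
      for (j in rest[far[rest] == u])
        add_loop(g$branches$id[inc[c(i, j)]],
                 g$branches$arc_length[inc[i]] + g$branches$arc_length[inc[j]],
                 c(v, u))
      rest <- rest[far[rest] != u]
      if (!length(rest)) next
      targets <- unique(far[rest])
      sp <- suppressWarnings(
        igraph::shortest_paths(sub, from = as.character(u),
                               to = as.character(targets),
                               weights = wts, output = "both"))
      for (ti in seq_along(targets)) {
        if (length(sp$vpath[[ti]]) == 0) next
        ep <- sp$epath[[ti]]
        path_br <- igraph::edge_attr(sub, "branch_id", ep)
        path_len <- sum(igraph::edge_attr(sub, "length", ep))
        node_ids <- c(v, as.integer(names(sp$vpath[[ti]])))
        for (j in rest[far[rest] == targets[ti]]) {
          extra <- g$branches$arc_length[inc[i]] +
                   g$branches$arc_length[inc[j]]
          add_loop(c(g$branches$id[inc[c(i, j)]], path_br),
                   extra + path_len, node_ids)
        }
      }
    }
  }
  keys <- ls(seen)
  if (length(keys) == 0)
    return(structure(data.frame(loop_id = integer(0),
                                circumference = numeric(0),
                                node_count = integer(0),
                                branch_count = integer(0)),
                     members = list(), node_members = list()))
  # canonical order independent of node iteration order
  keys <- sort(keys)
  recs <- lapply(keys, function(k) seen[[k]])
  o <- order(vapply(recs, `[[`, numeric(1), "circumference"),
             vapply(recs, function(r) paste(sort(r$branches), collapse = "-"),
                    character(1)))
  recs <- recs[o]
  out <- data.frame(
    loop_id = seq_along(recs),
    circumference = vapply(recs, `[[`, numeric(1), "circumference"),
    node_count = vapply(recs, function(r) length(unique(r$nodes)),
                        integer(1)),
    branch_count = vapply(recs, function(r) length(r$branches), integer(1)))
  attr(out, "members") <- lapply(recs, `[[`, "branches")
  attr(out, "node_members") <- lapply(recs, function(r) unique(r$nodes))
  out
}

#' Planarity analysis of an elementary loop
#'
#' PCA on the member-node positions. Planarity is the fraction of variance
#' in the first two components; the elongation epsilon is the primary/
#' secondary axis-length ratio (square root of the variance ratio by
#' default).
#'
#' @param node_ids node ids of the loop.
#' @param g the [skeleton_graph].
#' @param use_sd_ratio elongation from SD ratio (axis lengths) rather than
#'   the raw variance ratio.
#' @return list `variances` (3, descending), `planarity`, `epsilon`; `NULL`
#'   when the loop has fewer than 3 non-collinear nodes.
#' @export
loop_planarity_pca <- function(node_ids, g, use_sd_ratio = TRUE) {
  pts <- as.matrix(g$nodes[match(node_ids, g$nodes$id),
                           c("x", "y", "z"), drop = FALSE])
  if (nrow(pts) < 3) return(NULL)
  pc <- prcomp(pts, center = TRUE)
  v <- pc$sdev^2
  v <- c(v, rep(0, 3 - length(v)))[1:3]
  if (v[2] <= 1e-12) return(NULL)   # collinear
  eps <- if (use_sd_ratio) sqrt(v[1] / v[2]) else v[1] / v[2]
  list(variances = v, planarity = (v[1] + v[2]) / sum(v), epsilon = eps)
}

#' Planarity and elongation for every loop of a graph
#' @param loops result of [elementary_loops].
#' @param g the [skeleton_graph].
#' @inheritParams loop_planarity_pca
#' @return the loops data.frame with columns `planarity`, `epsilon` added
#'   (NA for degenerate loops).
#' @export
loop_planarity_table <- function(loops, g, use_sd_ratio = TRUE) {
  nm <- attr(loops, "node_members")
  loops$planarity <- NA_real_
  loops$epsilon <- NA_real_
  for (i in seq_len(nrow(loops))) {
    p <- loop_planarity_pca(nm[[i]], g, use_sd_ratio)
    if (!is.null(p)) {
      loops$planarity[i] <- p$planarity
      loops$epsilon[i] <- p$epsilon
    }
  }
  loops
}

#' Mesh pore diameter estimate
#'
#' Treats the typical elementary loop as an ellipse of circumference
#' `mean_loop_length` and axis ratio `epsilon`, inverts to the short-axis
#' diameter, and subtracts the filament width:
#' `mean_loop_length / (pi * epsilon) - filament_diameter`.
#'
#' @param mean_loop_length nm.
#' @param epsilon elongation (>= 1).
#' @param filament_diameter nm.
#' @return estimated pore diameter in nm (0 for a closed mesh).
#' @export
pore_diameter_estimate <- function(mean_loop_length, epsilon,
                                   filament_diameter = 8) {
  stopifnot(mean_loop_length > 0, epsilon > 0, filament_diameter >= 0)
  max(0, mean_loop_length / (pi * epsilon) - filament_diameter)
}

#' Minimum spanning tree pruning
#'
#' Per connected component, the minimum spanning tree under edge weight
#' 1/arc_length: short branches carry large weight and are dropped first,
#' implementing the hypothesis that short branches are cross-links rather
#' than actin. The result is acyclic with |nodes| = |branches| + 1 per
#' component.
#'
#' @param g a [skeleton_graph].
#' @return the pruned [skeleton_graph] (same nodes, subset of branches).
#' @export
minimum_spanning_tree_prune <- function(g) {
  if (n_branches(g) == 0) return(g)
  ig <- as_igraph(g, weight = "inverse_length")
  mst <- igraph::mst(ig, weights = igraph::E(ig)$weight)
  keep <- igraph::edge_attr(mst, "branch_id")
  subset_branches(g, keep)
}

#' Merge rank-2 nodes by concatenating their branches
#'
#' Every rank-2 node (as emerges after MST pruning) is removed and its two
#' branches joined into one (polylines concatenated, arc lengths summed),
#' repeated until no rank-2 node remains. A rank-2 node whose two branch
#' endpoints belong to a single self-loop branch is left untouched.
#'
#' @param g a [skeleton_graph].
#' @return a [skeleton_graph] without (mergeable) rank-2 nodes.
#' @export
merge_rank2_nodes <- function(g) {
  if (n_branches(g) == 0) return(g)
  nid <- g$nodes$id
  ba <- match(g$branches$node_a, nid)
  bb <- match(g$branches$node_b, nid)
  alive <- rep(TRUE, length(ba))
  polys <- g$polylines
  excl <- g$branches$excluded
  inc <- vector("list", length(nid))          # node -> incident branch ids
  for (b in seq_along(ba)) {
    inc[[ba[b]]] <- c(inc[[ba[b]]], b)
    if (bb[b] != ba[b]) inc[[bb[b]]] <- c(inc[[bb[b]]], b)
    else inc[[ba[b]]] <- c(inc[[ba[b]]], b)   # self-loop counts twice
  }
  node_alive <- rep(TRUE, length(nid))
  queue <- which(lengths(inc) == 2)
  for (v in queue) {
    bs <- inc[[v]]
    if (length(bs) != 2) next
    b1 <- bs[1]; b2 <- bs[2]
    if (b1 == b2) next                         # self-loop: degenerate, leave
    if (!alive[b1] || !alive[b2]) next
    p1 <- polys[[b1]]; p2 <- polys[[b2]]
    if (ba[b1] == v) { p1 <- p1[nrow(p1):1, , drop = FALSE]; a_end <- bb[b1] }
    else a_end <- ba[b1]
    if (bb[b2] == v) { p2 <- p2[nrow(p2):1, , drop = FALSE]; b_end <- ba[b2] }
    else b_end <- bb[b2]
    polys[[b1]] <- rbind(p1, p2[-1, , drop = FALSE])
    ba[b1] <- a_end; bb[b1] <- b_end
    excl[b1] <- excl[b1] || excl[b2]
    alive[b2] <- FALSE
    node_alive[v] <- FALSE
    ib <- inc[[b_end]]
    ib[ib == b2] <- b1
    inc[[b_end]] <- ib
    if (a_end == b_end) {                      # became a self-loop
      ia <- inc[[a_end]]
      ia[ia == b2] <- b1
      inc[[a_end]] <- ia
    }
    inc[[v]] <- integer(0)
  }
  nodes <- g$nodes[node_alive, , drop = FALSE]
  keep <- which(alive)
  branches <- data.frame(id = seq_along(keep),
                         node_a = nid[ba[keep]], node_b = nid[bb[keep]],
                         excluded = excl[keep])
  dom <- g$branches$domain[keep]
  if (!is.null(dom)) branches$domain <- dom
  skeleton_graph(nodes, branches, polys[keep])
}

#' Before/after statistics of MST pruning
#'
#' @param original the full [skeleton_graph].
#' @param pruned the result of [minimum_spanning_tree_prune] followed (or
#'   not) by [merge_rank2_nodes].
#' @param mask optional [label_mask]; adds reconstructed volume fractions.
#' @param sigma_vol Gaussian SD for the volume reconstruction, nm.
#' @return one-row data.frame: branch/node reduction percentages, mean
#'   branch length before/after, rank-1 node fractions, and volume
#'   fractions when a mask is given.
#' @export
prune_stats <- function(original, pruned, mask = NULL, sigma_vol = 4) {
  mean_len <- function(g) {
    ok <- !g$branches$excluded
    if (!any(ok)) return(NA_real_)
    mean(g$branches$arc_length[ok])
  }
  rank1_frac <- function(g) {
    if (n_nodes(g) == 0) return(NA_real_)
    sum(g$nodes$rank == 1) / n_nodes(g)
  }
  out <- data.frame(
    n_branches_before = n_branches(original),
    n_branches_after = n_branches(pruned),
    branch_reduction_pct =
      100 * (1 - n_branches(pruned) / max(1, n_branches(original))),
    n_nodes_before = n_nodes(original),
    n_nodes_after = n_nodes(pruned),
    node_reduction_pct =
      100 * (1 - n_nodes(pruned) / max(1, n_nodes(original))),
    mean_branch_length_before = mean_len(original),
    mean_branch_length_after = mean_len(pruned),
    rank1_fraction_before = rank1_frac(original),
    rank1_fraction_after = rank1_frac(pruned))
  if (!is.null(mask)) {
    out$volume_fraction_before <-
      cytoskeleton_volume_fraction(original, mask, sigma_vol)$fraction[1]
    out$volume_fraction_after <-
      cytoskeleton_volume_fraction(pruned, mask, sigma_vol)$fraction[1]
  }
  out
}
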
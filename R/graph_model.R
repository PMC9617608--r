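# Skeleton graph: attributed undirected multigraph of junction nodes and
# branch polylines. The central object of all statistics.

#' Construct a skeleton graph
#'
#' @param nodes data.frame with columns `id, x, y, z` and optionally
#'   `domain` (character, "head"/"neck"/NA) and `boundary` (logical).
#' @param branches data.frame with columns `id, node_a, node_b` and
#'   optionally `excluded` (logical, artificial-cut flag).
#' @param polylines list of (n x 3) numeric matrices, one per branch, in nm;
#'   if `NULL`, straight segments between node positions are used.
#' @return an object of class `skeleton_graph`. Branch arc length, Euclidean
#'   span, tortuosity and node ranks are (re)computed from the polylines.
#' @export
skeleton_graph <- function(nodes, branches, polylines = NULL) {
  nodes <- as.data.frame(nodes)
  branches <- as.data.frame(branches)
  if (is.null(nodes$domain)) nodes$domain <- rep(NA_character_, nrow(nodes))
  if (is.null(nodes$boundary)) nodes$boundary <- rep(FALSE, nrow(nodes))
  if (is.null(branches$excluded))
    branches$excluded <- rep(FALSE, nrow(branches))
  if (is.null(branches$domain))
    branches$domain <- rep(NA_character_, nrow(branches))
  if (is.null(polylines)) {
    polylines <- lapply(seq_len(nrow(branches)), function(i) {
      a <- match(branches$node_a[i], nodes$id)
      b <- match(branches$node_b[i], nodes$id)
      rbind(as.numeric(nodes[a, c("x", "y", "z")]),
            as.numeric(nodes[b, c("x", "y", "z")]))
    })
  }
  g <- structure(list(nodes = nodes, branches = branches,
                      polylines = polylines),
                 class = "skeleton_graph")
  finalize_graph(g)
}

# recompute ranks and branch geometry from current structure
finalize_graph <- function(g) {
  nb <- nrow(g$branches)
  if (nb > 0) {
    arc <- numeric(nb); span <- numeric(nb)
    for (i in seq_len(nb)) {
      p <- g$polylines[[i]]
      arc[i] <- branch_length(p)
      span[i] <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    }
    g$branches$arc_length <- arc
    g$branches$span <- span
    g$branches$tortuosity <- ifelse(span > 0, arc / span, NA_real_)
  } else {
    g$branches$arc_length <- numeric(0)
    g$branches$span <- numeric(0)
    g$branches$tortuosity <- numeric(0)
  }
  ends <- c(g$branches$node_a, g$branches$node_b)
  g$nodes$rank <- as.integer(tabulate(match(ends, g$nodes$id),
                                      nbins = nrow(g$nodes)))
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d branches\n",
              nrow(x$nodes), nrow(x$branches)))
  invisible(x)
}

#' Number of nodes / branches
#' @param g a [skeleton_graph].
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' @rdname n_nodes
#' @export
n_branches <- function(g) nrow(g$branches)

#' Arc length of a polyline
#' @param polyline (n x 3) numeric matrix of points, nm.
#' @return sum of segment Euclidean lengths, nm.
#' @export
branch_length <- function(polyline) {
  if (is.null(dim(polyline)) || nrow(polyline) < 2) return(0)
  sum(sqrt(rowSums(diff(polyline)^2)))
}

#' Tortuosity of a branch
#'
#' Ratio of the branch arc length to the Euclidean distance between its end
#' points; >= 1, undefined (NA) for closed branches with zero span.
#'
#' @param branch one row of a graph's branch table, or a polyline matrix.
#' @export
branch_tortuosity <- function(branch) {
  if (is.matrix(branch)) {
    arc <- branch_length(branch)
    span <- sqrt(sum((branch[nrow(branch), ] - branch[1, ])^2))
    return(if (span > 0) arc / span else NA_real_)
  }
  if (branch$span > 0) branch$arc_length / branch$span else NA_real_
}

#' Smooth a branch voxel chain into a polyline
#'
#' Interior points are replaced by a sliding weighted average with weights
#' (1,2,3,2,1)/9 over the original positions; near the ends the kernel is
#' truncated and renormalized. The first and last points are pinned to the
#' adjacent node positions.
#'
#' @param voxel_chain (m x 3) matrix of interior voxel positions, nm
#'   (may have 0 rows).
#' @param node_a,node_b fixed end positions (length-3 numeric), nm.
#' @return polyline matrix `(m + 2) x 3` with ends equal to the nodes.
#' @export
smooth_branch_curve <- function(voxel_chain, node_a, node_b) {
  if (is.null(voxel_chain) || length(voxel_chain) == 0)
    voxel_chain <- matrix(numeric(0), 0, 3)
  pts <- rbind(matrix(node_a, 1), voxel_chain, matrix(node_b, 1))
  n <- nrow(pts)
  if (n <= 2) return(pts)
  w <- c(1, 2, 3, 2, 1)
  out <- pts
  for (i in 2:(n - 1)) {
    r <- min(2, i - 1, n - i)        # symmetric truncation near the ends
    idx <- (i - r):(i + r)
    ww <- w[(3 - r):(3 + r)]
    out[i, ] <- colSums(pts[idx, , drop = FALSE] * ww) / sum(ww)
  }
  out[1, ] <- node_a
  out[n, ] <- node_b
  out
}

mask_domain_at <- function(mask, pos) {
  if (is.null(mask)) return(NA_character_)
  idx <- position_to_voxel(matrix(pos, ncol = 3), mask$pitch, dim(mask$labels),
                           mask$origin)
  d <- mask$domain[idx]
  c("head", "neck")[match(d, c(1L, 2L))]
}

#' Convert a voxel skeleton into an attributed multigraph
#'
#' Junction voxels (more than two neighbours) are clustered by 26-adjacency
#' into single nodes positioned at the cluster's centre of mass; maximal
#' chains of degree-2 voxels become branches with smoothed polylines; end
#' voxels become rank-1 nodes. Isolated chains become their own components;
#' pure voxel cycles are represented as one node carrying a self-loop branch.
#' Branches or nodes touching the bounding-box faces are flagged: such
#' branches are artificial cuts and get `excluded = TRUE` so that length and
#' tortuosity statistics skip them while connectivity is retained.
#'
#' @param s a [skeleton_voxels] object.
#' @param mask optional [label_mask] supplying head/neck domain tags.
#' @return a [skeleton_graph].
#' @export
build_graph <- function(s, mask = NULL) {
  fg <- s$fg
  dims <- dim(fg)
  pitch <- s$pitch
  sk <- skeleton_adjacency(fg)
  if (sk$n == 0) stop("empty skeleton")
  pos <- voxel_centers(sk$coords, pitch, s$origin)
  on_face <- sk$coords[, 1] <= 1 | sk$coords[, 1] >= dims[1] |
             sk$coords[, 2] <= 1 | sk$coords[, 2] >= dims[2] |
             sk$coords[, 3] <= 1 | sk$coords[, 3] >= dims[3]

  junction <- sk$deg > 2
  node_of_voxel <- integer(sk$n)      # node id per junction voxel
  node_pos <- list(); node_bound <- logical(0)
  nid <- 0L
  if (any(junction)) {
    jidx <- which(junction)
    jmap <- integer(sk$n); jmap[jidx] <- seq_along(jidx)
    # adjacency restricted to junction voxels
    jed <- do.call(rbind, lapply(jidx, function(v) {
      nb <- sk$adj[[v]]
      nb <- nb[junction[nb] & nb > v]
      if (length(nb)) cbind(jmap[v], jmap[nb]) else NULL
    }))
    jg <- igraph::make_empty_graph(n = length(jidx), directed = FALSE)
    if (!is.null(jed) && nrow(jed) > 0)
      jg <- igraph::add_edges(jg, t(jed))
    comp <- igraph::components(jg)$membership
    nid <- max(comp)
    node_of_voxel[jidx] <- comp
    for (cid in seq_len(nid)) {
      vv <- jidx[comp == cid]
      node_pos[[cid]] <- colMeans(pos[vv, , drop = FALSE])
      node_bound[cid] <- any(on_face[vv])
    }
  }

  new_node <- function(p, bound) {
    nid <<- nid + 1L
    node_pos[[nid]] <<- p
    node_bound[nid] <<- bound
    nid
  }

  assigned <- logical(sk$n)
  br_a <- integer(0); br_b <- integer(0)
  br_poly <- list(); br_face <- logical(0)

  add_branch <- function(na, nb, interior, touches) {
    poly <- smooth_branch_curve(
      if (length(interior)) pos[interior, , drop = FALSE] else NULL,
      node_pos[[na]], node_pos[[nb]])
    k <- length(br_a) + 1L
    br_a[k] <<- na; br_b[k] <<- nb
    br_poly[[k]] <<- poly
    br_face[k] <<- touches || node_bound[na] || node_bound[nb]
  }

  trace_chain <- function(start_vox, first) {
    # returns list(path = interior voxel ids, terminal = voxel id or 0 if end)
    path <- integer(0)
    prev <- start_vox; cur <- first
    repeat {
      path <- c(path, cur)
      assigned[cur] <<- TRUE
      nbrs <- sk$adj[[cur]]
      nxt <- nbrs[nbrs != prev]
      if (length(nxt) == 0) return(list(path = path, terminal = 0L))
      nxt <- nxt[1]
      if (junction[nxt]) return(list(path = path, terminal = nxt))
      if (assigned[nxt]) return(list(path = path, terminal = 0L))
      prev <- cur; cur <- nxt
    }
  }

  # branches emanating from junction clusters
  for (v in which(junction)) {
    for (nb in sk$adj[[v]]) {
      if (junction[nb] || assigned[nb]) next
      tc <- trace_chain(v, nb)
      na <- node_of_voxel[v]
      if (tc$terminal > 0L) {
        nbid <- node_of_voxel[tc$terminal]
      } else {
        endv <- tc$path[length(tc$path)]
        nbid <- new_node(pos[endv, ], on_face[endv])
        if (length(tc$path) > 1)
          tc$path <- tc$path[-length(tc$path)]
        else tc$path <- integer(0)
      }
      add_branch(na, nbid, tc$path, any(on_face[tc$path]))
    }
  }

  # leftover: isolated chains and pure cycles of degree <= 2 voxels
  left <- which(!assigned & !junction & sk$deg > 0)
  while (length(left)) {
    # collect the connected component of the first leftover voxel
    comp <- left[1]
    frontier <- comp
    seen <- logical(sk$n); seen[comp] <- TRUE
    while (length(frontier)) {
      nb <- unique(unlist(sk$adj[frontier]))
      nb <- nb[!seen[nb] & !junction[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    comp_ends <- comp[sk$deg[comp] == 1]
    if (length(comp_ends)) {
      # open chain: trace from one end to the other
      comp_end <- comp_ends[1]
      na <- new_node(pos[comp_end, ], on_face[comp_end])
      assigned[comp_end] <- TRUE
      tc <- trace_chain(comp_end, sk$adj[[comp_end]][1])
      endv <- tc$path[length(tc$path)]
      nbid <- new_node(pos[endv, ], on_face[endv])
      interior <- tc$path[-length(tc$path)]
      add_branch(na, nbid, interior, any(on_face[tc$path]))
    } else {
      # pure cycle: anchor one node, self-loop branch around the cycle
      v <- comp[1]
      na <- new_node(pos[v, ], on_face[v])
      assigned[v] <- TRUE
      tc <- trace_chain(v, sk$adj[[v]][1])
      add_branch(na, na, tc$path, any(on_face[tc$path]))
    }
    assigned[comp] <- TRUE
    left <- which(!assigned & !junction & sk$deg > 0)
  }

  npos <- do.call(rbind, node_pos)
  nodes <- data.frame(id = seq_len(nid),
                      x = npos[, 1], y = npos[, 2], z = npos[, 3],
                      boundary = node_bound)
  nodes$domain <- if (!is.null(mask))
    vapply(seq_len(nid), function(i)
      mask_domain_at(mask, npos[i, ]), character(1))
  else NA_character_
  branches <- data.frame(id = seq_along(br_a), node_a = br_a, node_b = br_b,
                         excluded = br_face)
  if (!is.null(mask) && length(br_a)) {
    branches$domain <- vapply(seq_along(br_a), function(i) {
      com <- colMeans(br_poly[[i]])
      mask_domain_at(mask, com)
    }, character(1))
  }
  skeleton_graph(nodes, branches, br_poly)
}

#' Convert a skeleton graph to an igraph object
#'
#' Vertex names are node ids (as character); edges carry `branch_id`,
#' `length` (arc length, nm) and `weight` attributes
#' (`weight = length` by default).
#'
#' @param g a [skeleton_graph].
#' @param weight `"length"` or `"inverse_length"` edge weights.
#' @export
as_igraph <- function(g, weight = c("length", "inverse_length")) {
  weight <- match.arg(weight)
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = as.character(g$nodes$id))
  if (nrow(g$branches) > 0) {
    ea <- match(g$branches$node_a, g$nodes$id)
    eb <- match(g$branches$node_b, g$nodes$id)
    ig <- igraph::add_edges(ig, rbind(ea, eb))
    ig <- igraph::set_edge_attr(ig, "branch_id", value = g$branches$id)
    ig <- igraph::set_edge_attr(ig, "length", value = g$branches$arc_length)
    w <- if (weight == "length") g$branches$arc_length
         else 1 / g$branches$arc_length
    ig <- igraph::set_edge_attr(ig, "weight", value = w)
  }
  ig
}

#' Restrict a graph to a subset of branches
#'
#' Nodes are kept (possible isolated nodes are dropped when `drop_isolated`).
#'
#' @param g a [skeleton_graph].
#' @param branch_ids branch ids to keep.
#' @param drop_isolated drop nodes that lose all branches.
#' @export
subset_branches <- function(g, branch_ids, drop_isolated = FALSE) {
  keep <- g$branches$id %in% branch_ids
  branches <- g$branches[keep, , drop = FALSE]
  polylines <- g$polylines[keep]
  nodes <- g$nodes
  if (drop_isolated) {
    used <- unique(c(branches$node_a, branches$node_b))
    nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  }
  branches$id <- seq_len(nrow(branches))
  skeleton_graph(nodes, branches, polylines)
}

poly_to_string <- function(p) {
  paste(apply(p, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")),
        collapse = ";")
}

string_to_poly <- function(s) {
  rows <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Export a skeleton graph
#'
#' `graphml` writes a single GraphML file (node positions, ranks, domains;
#' branch polylines as semicolon-separated coordinate strings). `csv-tables`
#' writes `nodes.csv` and `branches.csv` into the directory `path`.
#'
#' @param g a [skeleton_graph].
#' @param path file (graphml) or directory (csv-tables).
#' @param format `"graphml"` or `"csv-tables"`.
#' @export
export_graph <- function(g, path, format = c("graphml", "csv-tables")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- as_igraph(g)
    for (a in c("x", "y", "z", "rank", "boundary"))
      ig <- igraph::set_vertex_attr(ig, a, value = g$nodes[[a]])
    ig <- igraph::set_vertex_attr(ig, "domain",
            value = ifelse(is.na(g$nodes$domain), "", g$nodes$domain))
    if (nrow(g$branches) > 0) {
      ig <- igraph::set_edge_attr(ig, "tortuosity",
              value = ifelse(is.na(g$branches$tortuosity), -1,
                             g$branches$tortuosity))
      ig <- igraph::set_edge_attr(ig, "excluded", value = g$branches$excluded)
      ig <- igraph::set_edge_attr(ig, "polyline",
              value = vapply(g$polylines, poly_to_string, character(1)))
    }
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nodes <- g$nodes[, c("id", "x", "y", "z", "rank", "domain")]
    write.csv(nodes, file.path(path, "nodes.csv"), row.names = FALSE)
    br <- data.frame(id = g$branches$id, node_a = g$branches$node_a,
                     node_b = g$branches$node_b,
                     length_nm = g$branches$arc_length,
                     tortuosity = g$branches$tortuosity,
                     polyline = vapply(g$polylines, poly_to_string,
                                       character(1)))
    write.csv(br, file.path(path, "branches.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Import a skeleton graph written by [export_graph]
#'
#' @param path GraphML file or csv-tables directory.
#' @param format `"graphml"` or `"csv-tables"`.
#' @return a [skeleton_graph].
#' @export
import_graph <- function(path, format = c("graphml", "csv-tables")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(ig)
    nodes <- data.frame(id = as.integer(va$name), x = va$x, y = va$y,
                        z = va$z,
                        domain = ifelse(va$domain == "", NA, va$domain),
                        boundary = as.logical(va$boundary))
    el <- igraph::as_edgelist(ig, names = TRUE)
    ea <- igraph::edge_attr(ig)
    if (nrow(el) > 0) {
      branches <- data.frame(id = as.integer(ea$branch_id),
                             node_a = as.integer(el[, 1]),
                             node_b = as.integer(el[, 2]),
                             excluded = as.logical(ea$excluded))
      o <- order(branches$id)
      branches <- branches[o, , drop = FALSE]
      polylines <- lapply(ea$polyline[o], string_to_poly)
    } else {
      branches <- data.frame(id = integer(0), node_a = integer(0),
                             node_b = integer(0))
      polylines <- list()
    }
    skeleton_graph(nodes, branches, polylines)
  } else {
    nodes <- read.csv(file.path(path, "nodes.csv"))
    br <- read.csv(file.path(path, "branches.csv"))
    polylines <- if (nrow(br)) lapply(br$polyline, string_to_poly) else list()
    skeleton_graph(nodes[, c("id", "x", "y", "z", "domain")],
                   br[, c("id", "node_a", "node_b")], polylines)
  }
}
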
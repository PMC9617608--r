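# Node-rank statistics, node densities, branch-end clustering,
# and rank-3 branching-angle geometry.

#' Node rank distribution
#'
#' Counts and fractions of nodes of rank 3, 4, 5 and >= 6; rank-1 nodes
#' (branch ends) are reported separately and excluded from the junction
#' fractions.
#'
#' @param g a [skeleton_graph].
#' @param by_domain split by head/neck domain tags.
#' @return data.frame `domain`, `rank` ("1","3","4","5",">=6"), `count`,
#'   `fraction` (junction ranks only; the rank-1 row's fraction is relative
#'   to all nodes).
#' @export
node_rank_distribution <- function(g, by_domain = FALSE) {
  if (n_nodes(g) == 0) stop("empty graph")
  one <- function(nodes, dom) {
    r <- nodes$rank
    jr <- r[r >= 3]
    cnt <- c(sum(r == 1), sum(jr == 3), sum(jr == 4), sum(jr == 5),
             sum(jr >= 6))
    frac <- c(if (length(r)) sum(r == 1) / length(r) else NA,
              if (length(jr)) cnt[2:5] / length(jr) else rep(NA, 4))
    data.frame(domain = dom, rank = c("1", "3", "4", "5", ">=6"),
               count = cnt, fraction = frac)
  }
  out <- one(g$nodes, "all")
  if (by_domain) {
    for (dm in c("head", "neck")) {
      sel <- !is.na(g$nodes$domain) & g$nodes$domain == dm
      if (any(sel)) out <- rbind(out, one(g$nodes[sel, ], dm))
    }
  }
  out
}

#' Junction node density
#'
#' Number of rank >= 3 nodes per cubic micrometre of accessible cytosol
#' (organelles, PSD and membrane excluded).
#'
#' @param g a [skeleton_graph].
#' @param mask a [label_mask].
#' @return data.frame `domain`, `n_nodes`, `volume_um3`, `density_per_um3`.
#' @export
node_density <- function(g, mask) {
  jn <- g$nodes[g$nodes$rank >= 3, , drop = FALSE]
  rows <- list(data.frame(domain = "all", n_nodes = nrow(jn),
                          volume_um3 = cytosol_volume(mask) / 1e9))
  for (dm in c("head", "neck")) {
    vol <- cytosol_volume(mask, dm)
    if (vol > 0) {
      cnt <- sum(!is.na(jn$domain) & jn$domain == dm)
      rows[[length(rows) + 1]] <-
        data.frame(domain = dm, n_nodes = cnt, volume_um3 = vol / 1e9)
    }
  }
  out <- do.call(rbind, rows)
  out$density_per_um3 <- out$n_nodes / out$volume_um3
  out
}

#' Clustering test for branch ends near the membrane
#'
#' Observed nearest-neighbour distances among rank-1 nodes lying within
#' `shell` nm of a membrane are compared with `n_rand` replicates of the same
#' number of points placed uniformly at random in the same shell voxel set
#' (two-sided Mann-Whitney U on observed vs pooled random NN distances).
#'
#' @param g a [skeleton_graph].
#' @param field a [boundary_distance_field] result.
#' @param mask the [label_mask] (defines the shell voxel set).
#' @param shell shell width, nm.
#' @param seed RNG seed.
#' @param n_rand number of random replicates.
#' @return list with `observed_mean`, `random_mean`, `p_value`, `n_ends`,
#'   `observed_nn`, or `NULL` if fewer than 2 ends lie in the shell.
#' @export
branch_end_clustering_test <- function(g, field, mask, shell = 10,
                                       seed = 1L, n_rand = 100L) {
  ends <- g$nodes[g$nodes$rank == 1, c("x", "y", "z"), drop = FALSE]
  if (nrow(ends) < 2) return(NULL)
  dts <- field_at(field, as.matrix(ends), "dt")
  inshell <- which(dts < shell)
  if (length(inshell) < 2) return(NULL)
  obs <- nn_distances(as.matrix(ends[inshell, , drop = FALSE]))

  shell_vox <- which(cytosol_mask(mask) & field$dt < shell)
  ref <- random_branch_end_reference(shell_vox, dim(mask$labels),
                                     mask$pitch, mask$origin,
                                     n_points = length(inshell),
                                     n_reps = n_rand, seed = seed)
  pv <- suppressWarnings(wilcox.test(obs, ref$nn, exact = FALSE)$p.value)
  list(observed_mean = mean(obs), random_mean = mean(ref$nn),
       p_value = pv, n_ends = length(inshell), observed_nn = obs)
}

nn_distances <- function(pts) {
  dm <- as.matrix(dist(pts))
  diag(dm) <- Inf
  apply(dm, 1, min)
}

# tangent unit vectors of branches incident to a node: first principal
# direction of the first three polyline points starting at the node,
# oriented away from the node
node_branch_tangents <- function(g, node_id) {
  inc <- which(g$branches$node_a == node_id | g$branches$node_b == node_id)
  tangs <- NULL
  for (bi in inc) {
    p <- g$polylines[[bi]]
    # orient polyline to start at the node; a self-loop contributes twice
    starts <- c(g$branches$node_a[bi] == node_id,
                g$branches$node_b[bi] == node_id)
    if (starts[1]) tangs <- rbind(tangs, one_tangent(p))
    if (starts[2]) tangs <- rbind(tangs, one_tangent(p[nrow(p):1, ]))
  }
  tangs
}

one_tangent <- function(p) {
  k <- min(3, nrow(p))
  if (k < 2) return(rep(NA_real_, 3))
  pts <- p[seq_len(k), , drop = FALSE]
  if (k == 2) v <- pts[2, ] - pts[1, ]
  else {
    pc <- prcomp(pts, center = TRUE)
    v <- pc$rotation[, 1]
    if (sum(v * (pts[2, ] - pts[1, ])) < 0) v <- -v
  }
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(rep(NA_real_, 3))
  v / nv
}

angle_deg <- function(u, v) {
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

#' Branching angles at rank-3 nodes
#'
#' Per rank-3 node, the three branch tangents (first principal direction of
#' the first three polyline points, starting at the node position and
#' oriented away from it) define three pairwise angles, sorted into
#' smallest, intermediate and largest.
#'
#' @param g a [skeleton_graph].
#' @param include_excluded use nodes whose incident branches include
#'   artificial cuts.
#' @return data.frame `node_id`, `smallest`, `intermediate`, `largest`,
#'   `angle_sum` (degrees), plus a `tangents` attribute: list of 3x3
#'   matrices (rows = unit tangents).
#' @export
branching_angles_rank3 <- function(g, include_excluded = TRUE) {
  ids <- g$nodes$id[g$nodes$rank == 3]
  if (!include_excluded && length(ids)) {
    bad <- unique(c(g$branches$node_a[g$branches$excluded],
                    g$branches$node_b[g$branches$excluded]))
    ids <- setdiff(ids, bad)
  }
  rows <- NULL; tlist <- list()
  for (nd in ids) {
    tg <- node_branch_tangents(g, nd)
    if (is.null(tg) || nrow(tg) != 3 || any(is.na(tg))) next
    a <- sort(c(angle_deg(tg[1, ], tg[2, ]), angle_deg(tg[1, ], tg[3, ]),
                angle_deg(tg[2, ], tg[3, ])))
    rows <- rbind(rows, data.frame(node_id = nd, smallest = a[1],
                                   intermediate = a[2], largest = a[3],
                                   angle_sum = sum(a)))
    tlist[[length(tlist) + 1]] <- tg
  }
  if (is.null(rows))
    rows <- data.frame(node_id = integer(0), smallest = numeric(0),
                       intermediate = numeric(0), largest = numeric(0),
                       angle_sum = numeric(0))
  attr(rows, "tangents") <- tlist
  rows
}

#' Standardize a rank-3 tangent frame
#'
#' Rotates (and, if needed, reflects) three unit tangents into a canonical
#' frame: the vector making the largest summed angle with the other two goes
#' to (-1, 0, 0); the vector making the intermediate angle with it is placed
#' in the z = 0 plane with positive y; the third vector gets non-negative
#' elevation (z >= 0). Pairwise angles are preserved exactly.
#'
#' @param tangents 3 x 3 matrix, rows = unit vectors.
#' @return 3 x 3 matrix of standardized unit vectors (same row order:
#'   largest-angle vector first, intermediate second, third last), or `NULL`
#'   for degenerate (collinear) input.
#' @export
standardize_rank3_frame <- function(tangents) {
  stopifnot(nrow(tangents) == 3)
  a12 <- angle_deg(tangents[1, ], tangents[2, ])
  a13 <- angle_deg(tangents[1, ], tangents[3, ])
  a23 <- angle_deg(tangents[2, ], tangents[3, ])
  sums <- c(a12 + a13, a12 + a23, a13 + a23)
  i1 <- which.max(sums)                 # ties: lowest index, fixed rule
  rest <- setdiff(1:3, i1)
  ang_to_1 <- c(angle_deg(tangents[i1, ], tangents[rest[1], ]),
                angle_deg(tangents[i1, ], tangents[rest[2], ]))
  all_angles <- sort(c(a12, a13, a23))
  # the vector making the intermediate angle of the triple with vector 1
  d2 <- abs(ang_to_1 - all_angles[2])
  i2 <- rest[which.min(d2)]
  i3 <- setdiff(rest, i2)
  v1 <- tangents[i1, ]; v2 <- tangents[i2, ]; v3 <- tangents[i3, ]

  e1 <- -v1                                     # v1 -> (-1,0,0)
  w2 <- v2 - sum(v2 * e1) * e1
  if (sqrt(sum(w2^2)) < 1e-9) return(NULL)      # collinear
  e2 <- w2 / sqrt(sum(w2^2))                    # v2 in span(e1, e2), y > 0
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- rbind(e1, e2, e3)                        # maps e1->x, e2->y, e3->z
  out <- tangents[c(i1, i2, i3), , drop = FALSE] %*% t(R)
  out[1, ] <- c(-1, 0, 0)                       # exact
  if (out[3, 3] < 0) out[, 3] <- -out[, 3]      # reflect to z >= 0
  dimnames(out) <- NULL
  out
}
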
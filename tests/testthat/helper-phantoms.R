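# Voxel fixtures and cached phantoms used across test files.

# solid tube along x, circular cross-section of radius r_vox (in voxels)
tube_fg <- function(nx = 60, ny = 15, nz = 15, r_vox = 3) {
  fg <- array(FALSE, c(nx, ny, nz))
  cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  for (y in 1:ny) for (z in 1:nz)
    if ((y - cy)^2 + (z - cz)^2 <= r_vox^2) fg[, y, z] <- TRUE
  fg
}

# solid torus in the xy-plane (major radius R_nm, minor r_nm) at pitch 2
torus_fg <- function(R_nm = 20, r_nm = 6, pitch = 2) {
  half <- R_nm + r_nm + 2 * pitch
  n <- ceiling(2 * half / pitch)
  nzv <- ceiling(2 * (r_nm + 2 * pitch) / pitch)
  fg <- array(FALSE, c(n, n, nzv))
  for (x in 1:n) for (y in 1:n) for (z in 1:nzv) {
    px <- (x - 0.5) * pitch - half
    py <- (y - 0.5) * pitch - half
    pz <- (z - 0.5) * pitch - (nzv * pitch / 2)
    if ((sqrt(px^2 + py^2) - R_nm)^2 + pz^2 <= r_nm^2) fg[x, y, z] <- TRUE
  }
  fg
}

# three tubes meeting at a point (Y junction), pitch 2
y_junction_fg <- function() {
  d <- c(41, 41, 13)
  fg <- array(FALSE, d)
  ctr <- c(40, 40, 13)
  stamp <- function(dir, len) {
    for (t in seq(0, len, by = 1)) {
      p <- ctr + t * dir
      v0 <- round(p / 2 + 0.5)
      for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
        v <- v0 + c(dx, dy, dz)
        if (all(v >= 1 & v <= d)) {
          pc <- (v - 0.5) * 2
          if (sum((pc - p)^2) <= 16) fg[v[1], v[2], v[3]] <<- TRUE
        }
      }
    }
  }
  stamp(c(-1, 0, 0), 30)
  stamp(c(0.5, 0.866, 0), 30)
  stamp(c(0.5, -0.866, 0), 30)
  fg
}

# graph count helpers
graph_cycles <- function(g) {
  ig <- as_igraph(g)
  igraph::ecount(ig) - igraph::vcount(ig) + igraph::components(ig)$no
}
graph_components <- function(g) igraph::components(as_igraph(g))$no

# small straight-polyline test graph
toy_graph <- function(pos, edges, jitter_mid = NULL) {
  nodes <- data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3])
  branches <- data.frame(id = seq_len(nrow(edges)),
                         node_a = edges[, 1], node_b = edges[, 2])
  skeleton_graph(nodes, branches)
}

# cached small spine phantom (geometry + ground truth); built once per run
.phantom_cache <- new.env(parent = emptyenv())
small_phantom <- function() {
  if (is.null(.phantom_cache$small)) {
    spec <- spine_phantom_spec(head_radius = 70, neck_length = 80,
                               neck_radius = 32)
    mask <- generate_spine_geometry(spec, seed = 11)
    net <- grow_network(mask, spec, seed = 12)
    .phantom_cache$small <- list(spec = spec, mask = mask, net = net)
  }
  .phantom_cache$small
}

# brute-force elementary-loop oracle: exhaustive simple-cycle enumeration,
# then, for every node and every unordered pair of its incident branches,
# the minimum-circumference simple cycle using both; deduplicated by
# branch-id set. Independent of the Dijkstra-based implementation.
brute_force_loops <- function(g) {
  nb <- nrow(g$branches)
  if (nb == 0) return(list())
  ba <- g$branches$node_a; bb <- g$branches$node_b
  len <- g$branches$arc_length
  cycles <- list()
  add_cycle <- function(bids) {
    key <- paste(sort(bids), collapse = "-")
    if (is.null(cycles[[key]])) cycles[[key]] <<- sort(bids)
  }
  # self-loops
  for (b in which(ba == bb)) add_cycle(b)
  # DFS over edge sequences from each start node
  inc <- lapply(g$nodes$id, function(v) which(ba == v | bb == v))
  names(inc) <- as.character(g$nodes$id)
  start_nodes <- g$nodes$id
  dfs <- function(start, cur, used, visited) {
    for (b in inc[[as.character(cur)]]) {
      if (used[b] || ba[b] == bb[b]) next
      nxt <- if (ba[b] == cur) bb[b] else ba[b]
      if (nxt == start && sum(used) >= 1) {
        add_cycle(c(which(used), b))
      } else if (!(nxt %in% visited) && nxt > start) {
        # only extend through nodes > start to canonicalize
        used2 <- used; used2[b] <- TRUE
        dfs(start, nxt, used2, c(visited, nxt))
      }
    }
  }
  for (v in start_nodes)
    dfs(v, v, rep(FALSE, nb), v)
  all_cycles <- unname(cycles)
  if (!length(all_cycles)) return(list())
  clen <- vapply(all_cycles, function(cb) sum(len[cb]), numeric(1))
  picked <- list()
  for (v in g$nodes$id) {
    ib <- inc[[as.character(v)]]
    # self-loop at v is a loop by itself
    for (b in ib[ba[ib] == bb[ib]]) {
      key <- paste(b, collapse = "-")
      picked[[key]] <- b
    }
    ib <- ib[ba[ib] != bb[ib]]
    if (length(ib) < 2) next
    for (i in seq_len(length(ib) - 1)) for (j in (i + 1):length(ib)) {
      has <- vapply(all_cycles, function(cb)
        all(c(ib[i], ib[j]) %in% cb), logical(1))
      if (!any(has)) next
      cand <- which(has)
      best <- cand[which.min(clen[cand])]
      key <- paste(all_cycles[[best]], collapse = "-")
      picked[[key]] <- all_cycles[[best]]
    }
  }
  unname(picked)
}

loop_key_set <- function(loops) {
  members <- attr(loops, "members")
  sort(vapply(members, function(m) paste(sort(m), collapse = "-"),
              character(1)))
}

# random small multigraph with positive branch lengths (for loop/MST tests)
random_multigraph <- function(n_nodes, n_edges) {
  pos <- matrix(runif(3 * n_nodes, 0, 100), n_nodes, 3)
  ea <- sample.int(n_nodes, n_edges, replace = TRUE)
  eb <- sample.int(n_nodes, n_edges, replace = TRUE)
  nodes <- data.frame(id = seq_len(n_nodes), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3])
  branches <- data.frame(id = seq_len(n_edges), node_a = ea, node_b = eb)
  # bend self-loop polylines so they have positive arc length
  polys <- lapply(seq_len(n_edges), function(i) {
    a <- pos[ea[i], ]; b <- pos[eb[i], ]
    mid <- (a + b) / 2 + runif(3, 1, 5)
    rbind(a, mid, b)
  })
  skeleton_graph(nodes, branches, polys)
}
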
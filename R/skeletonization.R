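# Distance-transform-ordered topology-preserving thinning and stub pruning.

#' Binarized volume container
#' @param foreground logical 3D array.
#' @param pitch voxel pitch (nm).
#' @param origin physical offset (nm).
#' @param provenance named list of the parameters that produced it.
#' @return an object of class `binarized_volume`.
#' @export
binarized_volume <- function(foreground, pitch = 2, origin = c(0, 0, 0),
                             provenance = list()) {
  stopifnot(is.logical(foreground), length(dim(foreground)) == 3)
  structure(list(foreground = foreground, pitch = pitch, origin = origin,
                 provenance = provenance),
            class = "binarized_volume")
}

#' Skeleton voxel set
#' @param fg logical 3D array of skeleton voxels.
#' @param pitch voxel pitch (nm).
#' @param origin physical offset (nm).
#' @export
skeleton_voxels <- function(fg, pitch = 2, origin = c(0, 0, 0)) {
  structure(list(fg = fg, pitch = pitch, origin = origin),
            class = "skeleton_voxels")
}

#' @export
print.skeleton_voxels <- function(x, ...) {
  cat(sprintf("<skeleton_voxels> %d voxels on a %s grid\n",
              sum(x$fg), paste(dim(x$fg), collapse = "x")))
  invisible(x)
}

#' Euclidean distance transform of a binarized volume
#'
#' Distance (nm) of each foreground voxel to the nearest background voxel
#' centre; background voxels carry 0. A lone foreground voxel therefore gets
#' the value of one voxel pitch.
#'
#' @param b a [binarized_volume] or logical 3D array.
#' @param pitch voxel pitch (nm), used when `b` is a bare array.
#' @return a [volume_grid] of distances in nm.
#' @export
distance_transform_binary <- function(b, pitch = 2) {
  if (inherits(b, "binarized_volume")) { fg <- b$foreground; pitch <- b$pitch }
  else fg <- b
  if (!any(fg)) stop("empty foreground")
  d2 <- cpp_edt3d_sq(as.logical(fg), dim(fg))
  volume_grid(array(sqrt(d2) * pitch, dim(fg)), pitch = pitch)
}

#' Topology-preserving thinning of a binarized volume
#'
#' Removes voxels in ascending distance-transform order (ties broken in a
#' fixed z,y,x lexicographic scan order). A voxel is removed only if its
#' removal would not break a filament -- the foreground in its
#' 26-neighbourhood stays in a single 26-connected component -- and it is
#' not an endpoint (at most one foreground neighbour). This keep rule
#' preserves every filament cycle (a cycle voxel's two neighbours are
#' locally disconnected, so it can never be removed) while collapsing
#' membrane-like voxel sheets into curves. `rule = "simple-point"` instead
#' requires a full (26, 6) simple point, which additionally preserves
#' tunnels and cavities of the voxel set. With `protect_faces` (the
#' default), voxels outside the analyzed subvolume count as foreground, so
#' filaments exiting the volume can never be detached from the bounding
#' faces.
#'
#' @param b a [binarized_volume] or logical 3D array.
#' @param dt optional precomputed distance [volume_grid]; computed if absent.
#' @param pitch voxel pitch (nm) for a bare array.
#' @param protect_faces protect attachments to the bounding-box faces.
#' @param rule `"connectivity"` (default) or `"simple-point"`.
#' @return a [skeleton_voxels] object.
#' @export
topological_thinning <- function(b, dt = NULL, pitch = 2,
                                 protect_faces = TRUE,
                                 rule = c("connectivity", "simple-point")) {
  rule <- match.arg(rule)
  if (inherits(b, "binarized_volume")) { fg <- b$foreground; pitch <- b$pitch }
  else fg <- b
  if (!any(fg)) stop("empty foreground")
  if (is.null(dt)) dt <- distance_transform_binary(fg, pitch = pitch)
  dvec <- if (inherits(dt, "volume_grid")) dt$data else dt
  out <- cpp_thin3d(as.logical(fg), as.numeric(dvec), dim(fg), protect_faces,
                    rule == "connectivity")
  skeleton_voxels(array(out, dim(fg)), pitch = pitch)
}

# adjacency list of skeleton voxels; returns list(lin, coords, adj, deg)
skeleton_adjacency <- function(fg) {
  lin <- which(fg)
  n <- length(lin)
  coords <- arrayInd(lin, dim(fg))
  adj <- vector("list", n)
  deg <- integer(n)
  if (n > 0) {
    edges <- cpp_fg_edges(as.logical(fg), dim(fg))
    if (nrow(edges) > 0) {
      from <- c(edges[, 1], edges[, 2])
      to <- c(edges[, 2], edges[, 1])
      deg <- tabulate(from, nbins = n)
      o <- order(from)
      adj_split <- split(to[o], from[o])
      adj[as.integer(names(adj_split))] <- adj_split
    }
  }
  list(lin = lin, coords = coords, adj = adj, deg = deg, n = n)
}

# arc length (in voxel-step units * pitch) along a sequence of voxel coords
chain_arc_length <- function(coords, pitch) {
  if (nrow(coords) < 2) return(0)
  steps <- diff(coords)
  sum(sqrt(rowSums(steps^2))) * pitch
}

#' Prune short terminal stubs from a skeleton
#'
#' Terminal chains (from an end voxel to the nearest junction voxel) shorter
#' than `min_length` are removed in a single pass; junction voxels are
#' retained. Isolated chains that do not hang off a junction are kept.
#' Such stubs are almost always artifacts of imaging noise.
#'
#' @param s a [skeleton_voxels] object.
#' @param min_length minimum terminal chain length kept, nm.
#' @return a pruned [skeleton_voxels] object.
#' @export
prune_stubs <- function(s, min_length = 4) {
  stopifnot(min_length >= 0)
  if (min_length == 0) return(s)
  fg <- s$fg
  sk <- skeleton_adjacency(fg)
  if (sk$n == 0) return(s)
  ends <- which(sk$deg == 1)
  drop <- integer(0)
  for (e in ends) {
    path <- e
    prev <- 0L
    cur <- e
    reached_junction <- FALSE
    repeat {
      nbrs <- sk$adj[[cur]]
      nxt <- nbrs[nbrs != prev]
      if (length(nxt) == 0) break              # isolated chain: other end
      if (sk$deg[nxt[1]] > 2) { reached_junction <- TRUE; break }
      prev <- cur
      cur <- nxt[1]
      path <- c(path, cur)
      if (length(path) > sk$n) break           # safety
    }
    if (reached_junction) {
      # the stub's own extent: end voxel to the last chain voxel before the
      # junction (a 2-voxel stub at 2 nm pitch measures 2 nm)
      len <- chain_arc_length(sk$coords[path, , drop = FALSE], s$pitch)
      if (len < min_length) drop <- c(drop, path)
    }
  }
  if (length(drop)) fg[sk$lin[unique(drop)]] <- FALSE
  skeleton_voxels(fg, pitch = s$pitch, origin = s$origin)
}
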
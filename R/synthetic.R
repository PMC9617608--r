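# Synthetic spine phantoms: geometry, ground-truth filament network growth,
# and tomogram-like rendering. Every downstream stage is testable against
# the known network, and parameter recovery can be asserted.

#' Specification of a spine phantom
#'
#' Defaults emulate the measured regime of spine tomograms: a mid-sized
#' head, a neck in the pyramidal-cell range, mean inter-node spacing of
#' 15.4 nm, junction density in the middle of the observed
#' 91-181 x 10^3 um^-3 band, mild tortuosity, and a cross-link rate that
#' yields roughly a quarter as many rank-4 as rank-3 junctions.
#'
#' @param head_radius nm.
#' @param neck_length nm.
#' @param neck_radius nm.
#' @param organelle_fraction fraction of head cytosol replaced by
#'   ER-labelled inclusions.
#' @param target_node_density junction (rank >= 3) density, um^-3; must lie
#'   in \[1e4, 1e6\].
#' @param branch_length_mean mean inter-node spacing, nm.
#' @param branching_angle_law `"planar-70-110-180"`, `"isotropic"`, or
#'   `"empirical"` (sorted-angle normals given by `angle_mu`, `angle_sd`).
#' @param angle_mu,angle_sd means and SDs (degrees) of the sorted angle
#'   triple for the empirical law; defaults are the *in situ* values.
#' @param crosslink_rate per-junction probability of an extra short edge.
#' @param tortuosity_target mean branch tortuosity aimed for (>= 1).
#' @param filament_diameter nm.
#' @param fuse_radius capture radius at which a growing tip fuses onto an
#'   existing filament, nm; defaults to 1.75 filament diameters, the scale
#'   below which tomogram-resolution observation cannot separate passing
#'   filaments (tube diameter plus imaging blur), so every such pass is a
#'   network contact.
#' @param min_node_spacing minimum distance between junctions laid on one
#'   filament, nm; junctions closer than a filament width are not physically
#'   separable, so none are generated below it.
#' @param junction_min_separation minimum 3D distance between any two
#'   junctions, nm; the footprint of a branching complex keeps junctions
#'   apart in space.
#' @param membrane_deflect probability that a filament reaching the membrane
#'   deflects and continues parallel to it rather than anchoring; cortical
#'   guidance keeps filaments growing along the boundary, while anchoring
#'   leaves membrane-attached branch ends. Values much above 0.6 overweight
#'   the cortical shell relative to the bulk mesh.
#' @return an object of class `spine_phantom_spec`.
#' @export
spine_phantom_spec <- function(head_radius = 120, neck_length = 150,
                               neck_radius = 40, organelle_fraction = 0,
                               target_node_density = 1.3e5,
                               branch_length_mean = 15.4,
                               branching_angle_law = c("empirical",
                                                       "planar-70-110-180",
                                                       "isotropic"),
                               angle_mu = c(92.4, 116.2, 140.8),
                               angle_sd = c(14.3, 11.0, 13.9),
                               crosslink_rate = 0.35,
                               tortuosity_target = 1.05,
                               filament_diameter = 8,
                               fuse_radius = 1.75 * filament_diameter,
                               min_node_spacing = filament_diameter,
                               junction_min_separation = 0,
                               membrane_deflect = 0.6) {
  branching_angle_law <- match.arg(branching_angle_law)
  if (target_node_density < 1e4 || target_node_density > 1e6)
    stop("target_node_density outside [1e4, 1e6] um^-3")
  if (tortuosity_target < 1) stop("tortuosity_target must be >= 1")
  if (min(head_radius, neck_radius) <= filament_diameter / 2)
    stop("radii must exceed the filament radius")
  structure(list(head_radius = head_radius, neck_length = neck_length,
                 neck_radius = neck_radius,
                 organelle_fraction = organelle_fraction,
                 target_node_density = target_node_density,
                 branch_length_mean = branch_length_mean,
                 branching_angle_law = branching_angle_law,
                 angle_mu = angle_mu, angle_sd = angle_sd,
                 crosslink_rate = crosslink_rate,
                 tortuosity_target = tortuosity_target,
                 filament_diameter = filament_diameter,
                 fuse_radius = fuse_radius,
                 min_node_spacing = min_node_spacing,
                 junction_min_separation = junction_min_separation,
                 membrane_deflect = membrane_deflect),
            class = "spine_phantom_spec")
}

#' Generate the label mask of a spine phantom
#'
#' A spherical head sits on a cylindrical neck that opens onto the flat
#' dendrite face at z = 0 (the sphere centre is placed so its surface meets
#' the neck opening). Voxels just outside the cytosol get the membrane
#' label; optional spherical inclusions in the head are labelled ER. Head
#' and neck voxels carry domain tags.
#'
#' @param spec a [spine_phantom_spec].
#' @param seed RNG seed (used for organelle placement).
#' @param pitch voxel pitch, nm.
#' @return a [label_mask].
#' @export
generate_spine_geometry <- function(spec, seed = 1L, pitch = 2) {
  if (spec$neck_radius < spec$filament_diameter)
    stop("neck_radius below twice the filament radius: unbuildable phantom")
  set.seed(seed)
  hr <- spec$head_radius; nr <- spec$neck_radius; L <- spec$neck_length
  margin <- 4 * pitch
  zc <- L + sqrt(max(0, hr^2 - nr^2))   # head centre height
  half_xy <- hr + margin
  nx <- ceiling(2 * half_xy / pitch)
  nz <- ceiling((zc + hr + margin) / pitch)
  dims <- c(nx, nx, nz)
  cx <- half_xy; cy <- half_xy          # spine axis at (cx, cy)

  xs <- (seq_len(nx) - 0.5) * pitch
  zs <- (seq_len(nz) - 0.5) * pitch
  X <- array(rep(xs, times = nx * nz), dims)
  Y <- array(rep(rep(xs, each = nx), times = nz), dims)
  Z <- array(rep(zs, each = nx * nx), dims)

  r2xy <- (X - cx)^2 + (Y - cy)^2
  in_head <- r2xy + (Z - zc)^2 <= hr^2
  in_neck <- r2xy <= nr^2 & Z <= L & !in_head
  inside <- in_head | in_neck

  labels <- array(0L, dims)
  labels[inside] <- 1L
  # membrane: outside voxels 6-adjacent to the inside (the dendrite face at
  # z = 0 stays open)
  shifted <- array(FALSE, dims)
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    sh <- array(FALSE, dims)
    idx_src <- lapply(dims, seq_len)
    idx_dst <- idx_src
    n <- dims[ax]
    if (sgn > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    sh[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      inside[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    shifted <- shifted | sh
  }
  labels[!inside & shifted] <- 2L

  domain <- array(0L, dims)
  domain[in_head] <- 1L
  domain[in_neck] <- 2L

  if (spec$organelle_fraction > 0) {
    target <- spec$organelle_fraction * sum(in_head)
    placed <- 0
    tries <- 0
    orad <- max(3 * pitch, 0.3 * hr)
    while (placed < target && tries < 200) {
      tries <- tries + 1
      th <- runif(1, 0, 2 * pi); u <- runif(1, -1, 1)
      rr <- runif(1, 0, 0.6 * hr)
      ctr <- c(cx, cy, zc) + rr * c(sqrt(1 - u^2) * cos(th),
                                    sqrt(1 - u^2) * sin(th), u)
      o <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= orad^2
      sel <- o & labels == 1L & in_head
      labels[sel] <- 3L
      placed <- placed + sum(sel)
    }
  }
  label_mask(labels, pitch = pitch, domain = domain)
}

# rotation taking unit vector a onto unit vector b
rot_align <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {               # opposite: rotate about any orthogonal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(rot_axis(ax, pi))
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rot_axis <- function(axis, phi) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
}

# three unit vectors with prescribed pairwise angles (degrees, any order);
# NULL when not realizable as directions in 3-space
triple_from_angles <- function(a12, a13, a23) {
  r <- pi / 180
  v1 <- c(1, 0, 0)
  v2 <- c(cos(a12 * r), sin(a12 * r), 0)
  if (abs(sin(a12 * r)) < 1e-9) {
    # v2 collinear with v1: consistent only when a13 and a23 agree
    expected <- if (cos(a12 * r) > 0) a13 else 180 - a13
    if (abs(a23 - expected) > 1) return(NULL)
    v3 <- c(cos(a13 * r), sin(a13 * r), 0)
    return(unname(rbind(v1, v2, v3)))
  }
  x <- cos(a13 * r)
  y <- (cos(a23 * r) - cos(a12 * r) * cos(a13 * r)) / sin(a12 * r)
  z2 <- 1 - x^2 - y^2
  if (z2 < -1e-9) return(NULL)
  v3 <- c(x, y, sqrt(max(0, z2)))
  unname(rbind(v1, v2, v3))
}

# outgoing directions at a branch event given the incoming direction
branch_event_directions <- function(din, spec) {
  law <- spec$branching_angle_law
  if (law == "isotropic") {
    # mother continues straight, daughter uniformly random
    d2 <- as.numeric(random_unit_vectors(1))
    return(list(mother = din, daughter = d2))
  }
  if (law == "planar-70-110-180") angles <- c(70, 110, 180)
  else {
    angles <- NULL
    for (i in 1:100) {
      a <- sort(rnorm(3, spec$angle_mu, spec$angle_sd))
      if (a[1] > 5 && a[3] < 180 && sum(a) <= 360 &&
          !is.null(triple_from_angles(a[3], a[2], a[1]))) { angles <- a; break }
    }
    if (is.null(angles)) angles <- spec$angle_mu
  }
  # tangents away from the node: assign pairwise angles (a3 between the two
  # mother tangents when planar, but the assignment is randomized so only
  # the sorted triple is prescribed)
  tr <- triple_from_angles(angles[3], angles[2], angles[1])
  if (is.null(tr)) tr <- triple_from_angles(180, 110, 70)
  pick <- sample.int(3, 1)
  vin <- tr[pick, ]; vout <- tr[-pick, , drop = FALSE]
  Ra <- rot_align(vin, -din)            # incoming tangent points back along din
  Rs <- rot_axis(-din, runif(1, 0, 2 * pi))
  out <- vout %*% t(Ra) %*% t(Rs)
  list(mother = as.numeric(out[1, ]), daughter = as.numeric(out[2, ]))
}

# per-step turning SD (radians) giving the target mean branch tortuosity;
# quick fixed-seed simulation over a small grid
calibrate_turn_sd <- function(tortuosity_target, n_steps, step) {
  if (tortuosity_target <= 1.001) return(0)
  grid <- seq(0.02, 0.8, length.out = 14)
  best <- grid[1]; bestd <- Inf
  for (s in grid) {
    tt <- replicate(60, {
      d <- c(0, 0, 1)
      p <- matrix(0, n_steps + 1, 3)
      for (i in seq_len(n_steps)) {
        d <- d + rnorm(3, 0, s)
        d <- d / sqrt(sum(d^2))
        p[i + 1, ] <- p[i, ] + d * step
      }
      branch_length(p) / sqrt(sum((p[n_steps + 1, ] - p[1, ])^2))
    })
    dd <- abs(mean(tt) - tortuosity_target)
    if (dd < bestd) { bestd <- dd; best <- s }
  }
  best
}

#' Grow a ground-truth filament network inside a phantom
#'
#' Filaments are seeded at random cytosol positions and extended as
#' persistent random walks (turning noise calibrated to the target
#' tortuosity). Three processes shape the mesh: (i) branching into 3-way
#' junctions at a Poisson rate set by the mean inter-node spacing, with
#' outgoing directions drawn from the chosen angle law; (ii) fusion -- a
#' growing tip that comes within one filament diameter of an existing
#' filament terminates on it, creating a junction (this is what closes
#' loops and keeps free ends rare in the interior); (iii) termination on
#' the membrane, which leaves an anchored branch end (so ends concentrate
#' near the boundary). Growth stops when the junction density reaches the
#' target; remaining tips then run out without further branching.
#' Cross-links -- straight short extra edges from a junction to a nearby
#' filament point -- are added afterwards at the given per-junction rate,
#' creating rank-4 junctions.
#'
#' @param mask a [label_mask] from [generate_spine_geometry].
#' @param spec the [spine_phantom_spec].
#' @param seed RNG seed.
#' @return a [skeleton_graph] (the ground-truth network); nodes carry an
#'   `anchored` column for membrane-attached ends.
#' @export
grow_network <- function(mask, spec, seed = 1L) {
  target <- spec$branch_length_mean
  tail_mean <- max(target - spec$min_node_spacing, 0.2 * target)
  rate <- 1 / tail_mean
  scale <- 1
  dens_target <- spec$target_node_density
  measure <- function(g) {
    j <- sum(g$nodes$rank >= 3)
    c(len = mean(g$branches$arc_length),
      dens = j / (cytosol_volume(mask) / 1e9))
  }
  err_of <- function(m)
    abs(m["len"] - target) / target + abs(m["dens"] - dens_target) / dens_target
  g <- grow_network_once(mask, spec, seed, rate, scale)
  m <- measure(g)
  best <- g; best_err <- err_of(m)
  # the branching rate and the junction budget interact with the fusion
  # process; measure and recalibrate both, keeping the best draw
  for (pass in 1:4) {
    if (!any(is.finite(m)) ||
        (abs(m["len"] - target) <= 0.05 * target &&
         abs(m["dens"] - dens_target) <= 0.05 * dens_target)) break
    mu <- max(0, 1 / max(m["len"] - spec$min_node_spacing, 0.1 * target) -
                rate)
    rate <- max(1 / tail_mean - mu, 0.1 / tail_mean)
    scale <- min(4, max(0.25, scale * dens_target / max(m["dens"], 1)))
    g <- grow_network_once(mask, spec, seed, rate, scale)
    m <- measure(g)
    if (err_of(m) < best_err) { best <- g; best_err <- err_of(m) }
  }
  best
}

grow_network_once <- function(mask, spec, seed, branch_rate,
                              target_scale = 1) {
  set.seed(seed)
  cy <- cytosol_mask(mask)
  if (!any(cy)) stop("phantom has no cytosol")
  dims <- dim(cy)
  pitch <- mask$pitch
  V_um3 <- sum(cy) * pitch^3 / 1e9
  # cross-links each add one junction; aim the growth phase lower so the
  # final junction density lands on target (0.7 = typical cross-link success)
  # cross-links each add one junction on top (0.7 = typical success rate)
  target_density_nm3 <- spec$target_node_density / 1e9 /
    (1 + 0.7 * spec$crosslink_rate)
  target_junctions <- max(1, round(target_scale * target_density_nm3 *
                                     sum(cy) * pitch^3))
  step <- 3
  min_sp <- spec$min_node_spacing
  p_branch <- step * branch_rate
  sig <- calibrate_turn_sd(spec$tortuosity_target,
                           max(2, round(spec$branch_length_mean / step)), step)
  r_fuse <- spec$fuse_radius
  cypos <- voxel_centers(arrayInd(which(cy), dims), pitch, mask$origin)
  seedpos <- cypos
  inside <- function(p) {
    i <- floor(p / pitch) + 1
    if (any(i < 1) || any(i > dims)) return(FALSE)
    cy[i[1], i[2], i[3]]
  }
  inward_normal <- function(p) {
    v <- pmin(pmax(floor(p / pitch) + 1, 1), dims)
    acc <- c(0, 0, 0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > dims)) next
      if (cy[w[1], w[2], w[3]]) acc <- acc + c(dx, dy, dz)
    }
    nrm <- sqrt(sum(acc^2))
    if (nrm < 1e-9) NULL else acc / nrm
  }
  # neighbourhood offsets for the fusion search
  rv <- ceiling(r_fuse / pitch)
  offs <- as.matrix(expand.grid(-rv:rv, -rv:rv, -rv:rv))
  offs <- offs[rowSums(offs^2) <= (rv + 1)^2, , drop = FALSE]
  # offsets for the junction-exclusion search
  r_jx <- spec$junction_min_separation
  rj <- ceiling(r_jx / pitch)
  offs_j <- as.matrix(expand.grid(-rj:rj, -rj:rj, -rj:rj))
  offs_j <- offs_j[rowSums(offs_j^2) <= (rj + 1)^2, , drop = FALSE]

  # --- mutable stores ------------------------------------------------------
  cap <- 4096L
  pt_pos <- matrix(NA_real_, cap, 3)
  pt_branch <- integer(cap); pt_row <- integer(cap)
  pt_tip <- integer(cap); pt_step <- integer(cap)
  n_pts <- 0L
  occ <- array(0L, dims)                 # voxel -> last point id
  jocc <- array(0L, dims)                # voxel -> junction node id
  # coarse cubes for local density regulation (~40 nm edge)
  cube_vox <- max(8L, as.integer(round(40 / pitch)))
  cdims <- pmax(1L, as.integer(ceiling(dims / cube_vox)))
  cube_of <- function(p) {
    v <- pmin(pmax(floor(p / (pitch * cube_vox)) + 1, 1), cdims)
    v[1] + cdims[1] * ((v[2] - 1) + cdims[2] * (v[3] - 1))
  }
  cy_idx <- arrayInd(which(cy), dims)
  cube_idx <- (cy_idx[, 1] - 1) %/% cube_vox + 1 +
    cdims[1] * (((cy_idx[, 2] - 1) %/% cube_vox) +
                cdims[2] * ((cy_idx[, 3] - 1) %/% cube_vox))
  cube_cyto_nm3 <- tabulate(cube_idx, nbins = prod(cdims)) * pitch^3
  cube_j <- integer(prod(cdims))
  under_target <- function(p) {
    ci <- cube_of(p)
    cube_cyto_nm3[ci] > 0 &&
      cube_j[ci] / cube_cyto_nm3[ci] < target_density_nm3
  }
  node_pos <- list(); node_anch <- logical(0)
  branch_a <- integer(0); branch_b <- integer(0)
  branch_rows <- list()                  # point ids in order
  tips <- list()                         # id -> list(branch,pos,dir,step) or NULL
  junctions <- 0L

  live_count <- 0L
  node_deg <- integer(0)
  node_kind <- character(0)
  add_node <- function(pos, anchored = FALSE, kind = "end") {
    node_pos[[length(node_pos) + 1L]] <<- pos
    node_anch[length(node_pos)] <<- anchored
    node_deg[length(node_pos)] <<- 0L
    node_kind[length(node_pos)] <<- kind
    length(node_pos)
  }
  junction_clear <- function(p, except = 0L) {
    if (r_jx <= 0) return(TRUE)
    v <- floor(p / pitch) + 1
    idx <- sweep(offs_j, 2, v, `+`)
    ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
          idx[, 2] >= 1 & idx[, 2] <= dims[2] &
          idx[, 3] >= 1 & idx[, 3] <= dims[3]
    ids <- jocc[idx[ok, , drop = FALSE]]
    ids <- ids[ids > 0L & ids != except]
    if (!length(ids)) return(TRUE)
    pp <- do.call(rbind, node_pos[ids])
    all(sqrt(rowSums((pp - matrix(p, length(ids), 3, byrow = TRUE))^2)) >
          r_jx)
  }
  register_junction <- function(nid) {
    p <- node_pos[[nid]]
    v <- pmin(pmax(floor(p / pitch) + 1, 1), dims)
    jocc[v[1], v[2], v[3]] <<- nid
    ci <- cube_of(p)
    cube_j[ci] <<- cube_j[ci] + 1L
  }
  open_branch <- function(a) {
    branch_a[length(branch_a) + 1L] <<- a
    branch_b[length(branch_a)] <<- NA_integer_
    branch_rows[[length(branch_a)]] <<- integer(0)
    node_deg[a] <<- node_deg[a] + 1L
    length(branch_a)
  }
  close_branch <- function(bid, b) {
    branch_b[bid] <<- b
    node_deg[b] <<- node_deg[b] + 1L
  }
  lay_point <- function(p, bid, tip_id, stepno) {
    if (n_pts == nrow(pt_pos)) {
      add <- nrow(pt_pos)
      pt_pos <<- rbind(pt_pos, matrix(NA_real_, add, 3))
      pt_branch <<- c(pt_branch, integer(add))
      pt_row <<- c(pt_row, integer(add))
      pt_tip <<- c(pt_tip, integer(add))
      pt_step <<- c(pt_step, integer(add))
    }
    n_pts <<- n_pts + 1L
    pt_pos[n_pts, ] <<- p
    pt_branch[n_pts] <<- bid
    pt_row[n_pts] <<- length(branch_rows[[bid]]) + 1L
    pt_tip[n_pts] <<- tip_id
    pt_step[n_pts] <<- stepno
    branch_rows[[bid]] <<- c(branch_rows[[bid]], n_pts)
    v <- pmin(pmax(floor(p / pitch) + 1, 1), dims)
    occ[v[1], v[2], v[3]] <<- n_pts
    n_pts
  }
  fusion_candidate <- function(pn, tip_id, bid, stepno, origin) {
    v <- floor(pn / pitch) + 1
    idx <- sweep(offs, 2, v, `+`)
    ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
          idx[, 2] >= 1 & idx[, 2] <= dims[2] &
          idx[, 3] >= 1 & idx[, 3] <= dims[3]
    ids <- occ[idx[ok, , drop = FALSE]]
    ids <- ids[ids > 0L]
    if (!length(ids)) return(NULL)
    ids <- ids[pt_branch[ids] != bid]
    ids <- ids[!(pt_tip[ids] == tip_id & (stepno - pt_step[ids]) < 5L)]
    if (!length(ids)) return(NULL)
    dd <- sqrt(rowSums((pt_pos[ids, , drop = FALSE] -
                        matrix(pn, length(ids), 3, byrow = TRUE))^2))
    sel <- dd <= r_fuse
    if (!any(sel)) return(NULL)
    ids <- ids[sel]; dd <- dd[sel]
    gap <- max(1L, as.integer(ceiling(min_sp / step)) - 1L)
    nlen <- vapply(pt_branch[ids], function(b)
      length(branch_rows[[b]]), integer(1))
    o <- order(dd)
    for (k in o) {
      pid <- ids[k]
      if (pt_row[pid] > gap && pt_row[pid] <= nlen[k] - gap) {
        # interior: split the branch at this point
        if (junction_clear(pt_pos[pid, ], except = origin))
          return(list(type = "split", pid = pid))
      } else {
        # near an end: attach to the end node if it is already a junction
        bi <- pt_branch[pid]
        nid <- if (pt_row[pid] <= gap) branch_a[bi] else branch_b[bi]
        if (!is.na(nid) && nid != origin && node_deg[nid] >= 3L)
          return(list(type = "attach", nid = nid))
      }
    }
    NULL
  }
  split_branch_at <- function(pid) {
    # split branch at point pid; returns id of the new junction node
    bid <- pt_branch[pid]
    rows <- branch_rows[[bid]]
    k <- pt_row[pid]
    K <- add_node(pt_pos[pid, ], kind = "junction")
    tail_rows <- rows[(k + 1L):length(rows)]
    head_rows <- rows[seq_len(k - 1L)]
    b2 <- open_branch(K)                 # K degree +1
    branch_b[b2] <<- branch_b[bid]       # NA when bid still open
    if (!is.na(branch_b[bid]))
      node_deg[branch_b[bid]] <<- node_deg[branch_b[bid]]  # unchanged: moved
    branch_rows[[b2]] <<- tail_rows
    pt_branch[tail_rows] <<- b2
    pt_row[tail_rows] <<- seq_along(tail_rows)
    branch_rows[[bid]] <<- head_rows
    branch_b[bid] <<- K
    node_deg[K] <<- node_deg[K] + 1L     # bid now ends at K
    # if bid was open, its owning tip now grows b2
    for (ti in seq_along(tips)) {
      if (!is.null(tips[[ti]]) && tips[[ti]]$branch == bid) {
        tips[[ti]]$branch <<- b2
        break
      }
    }
    junctions <<- junctions + 1L
    register_junction(K)
    K
  }
  spawn_tip <- function(node, dir) {
    bid <- open_branch(node)
    tips[[length(tips) + 1L]] <<- list(branch = bid,
                                       pos = node_pos[[node]], dir = dir,
                                       step = 0L)
    live_count <<- live_count + 1L
    length(tips)
  }

  max_tips <- 100000L
  n_seeds <- max(8, ceiling(target_junctions / 15))
  seed_batch <- function(n) {
    for (s in seq_len(n)) {
      p0 <- seedpos[sample.int(nrow(seedpos), 1), ]
      nid <- add_node(p0, kind = "seed")
      spawn_tip(nid, as.numeric(random_unit_vectors(1)))
    }
  }
  seed_batch(n_seeds)

  step_tip <- function(ti, allow_branch) {
    tip <- tips[[ti]]
    tip_step <- tip$step + 1L
    d <- tip$dir + rnorm(3, 0, sig)
    d <- d / sqrt(sum(d^2))
    pn <- tip$pos + d * step
    if (!inside(pn)) {                   # membrane contact
      deflected <- FALSE
      if (runif(1) < spec$membrane_deflect) {
        nrm <- inward_normal(tip$pos)
        if (!is.null(nrm)) {
          d2 <- d - 2 * sum(d * nrm) * nrm     # reflect off the membrane
          d2 <- d2 / sqrt(sum(d2^2))
          pn2 <- tip$pos + d2 * step
          if (inside(pn2)) { d <- d2; pn <- pn2; deflected <- TRUE }
        }
      }
      if (!deflected) {                  # anchor on the membrane
        nid <- add_node(tip$pos, anchored = TRUE)
        close_branch(tip$branch, nid)
        tips[ti] <<- list(NULL)
        live_count <<- live_count - 1L
        return(invisible())
      }
    }
    grown <- length(branch_rows[[tip$branch]]) * step
    origin <- branch_a[tip$branch]
    cand <- if (grown >= min_sp)
      fusion_candidate(pn, ti, tip$branch, tip_step, origin) else NULL
    if (!is.null(cand)) {                # fuse onto an existing filament
      K <- if (cand$type == "split") split_branch_at(cand$pid) else cand$nid
      close_branch(tip$branch, K)
      tips[ti] <<- list(NULL)
      live_count <<- live_count - 1L
      return(invisible())
    }
    lay_point(pn, tip$branch, ti, tip_step)
    if (allow_branch && grown + step >= min_sp &&
        live_count < max_tips && runif(1) < p_branch &&
        junction_clear(pn, except = origin)) {
      J <- add_node(pn, kind = "junction")
      junctions <<- junctions + 1L
      register_junction(J)
      close_branch(tip$branch, J)
      dirs <- branch_event_directions(d, spec)
      b_new <- open_branch(J)
      tips[[ti]] <<- list(branch = b_new, pos = pn, dir = dirs$mother,
                          step = tip_step)
      spawn_tip(J, dirs$daughter)
    } else {
      tip$pos <- pn; tip$dir <- d; tip$step <- tip_step
      tips[[ti]] <<- tip
    }
  }

  # grow until the junction budget is met; unfinished tips are then
  # retracted (their open branches dropped and any rank-2 remnants merged),
  # so the laid filament length tracks the closed-branch census exactly
  live <- function() which(!vapply(tips, is.null, logical(1)))
  projected <- function() junctions
  max_iter <- 20 * (target_junctions * spec$branch_length_mean / step + 1000)
  iter <- 0
  rounds <- 0
  repeat {
    lv <- live()
    if (!length(lv)) {
      if (projected() >= 0.97 * target_junctions || rounds >= 60) break
      rounds <- rounds + 1
      seed_batch(max(4, ceiling((target_junctions - junctions) / 15)))
      lv <- live()
    }
    for (ti in lv) {
      iter <- iter + 1
      step_tip(ti, allow_branch = projected() < target_junctions)
    }
    if (iter > max_iter) {
      if (junctions < 0.9 * target_junctions)
        stop(sprintf(paste0("target node density unreachable: %d/%d ",
                            "junctions after %d growth steps"),
                     junctions, target_junctions, iter))
      break
    }
    if (projected() >= target_junctions) break
  }
  # run-out: remaining tips may still terminate naturally (fusion or
  # membrane) but no longer branch; whatever is left is then retracted
  guard <- 0
  while (length(lv <- live()) && guard < 200) {
    guard <- guard + 1
    for (ti in lv) step_tip(ti, allow_branch = FALSE)
  }
  for (ti in live()) tips[ti] <- list(NULL)   # retract unfinished tips

  # cross-link phase: extra short straight edges from junctions
  if (spec$crosslink_rate > 0) {
    deg <- tabulate(c(branch_a, branch_b), nbins = length(node_pos))
    for (j in which(deg >= 3)) {
      if (runif(1) > spec$crosslink_rate) next
      pj <- node_pos[[j]]
      v <- floor(pj / pitch) + 1
      idx <- sweep(offs, 2, v, `+`)
      ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
            idx[, 2] >= 1 & idx[, 2] <= dims[2] &
            idx[, 3] >= 1 & idx[, 3] <= dims[3]
      ids <- occ[idx[ok, , drop = FALSE]]
      ids <- ids[ids > 0L]
      ids <- ids[!is.na(branch_b[pt_branch[ids]])]
      if (!length(ids)) next
      dd <- sqrt(rowSums((pt_pos[ids, , drop = FALSE] -
                          matrix(pj, length(ids), 3, byrow = TRUE))^2))
      gap <- max(1L, as.integer(ceiling(spec$min_node_spacing / step)) - 1L)
      sel <- dd > 4 & dd <= 2.5 * r_fuse &
        pt_row[ids] > gap &
        pt_row[ids] <= vapply(pt_branch[ids], function(b)
          length(branch_rows[[b]]), integer(1)) - gap
      if (!any(sel)) next
      ids <- ids[sel]; dd <- dd[sel]
      pid <- NA
      for (cand in ids[order(dd)])
        if (junction_clear(pt_pos[cand, ], except = j)) { pid <- cand; break }
      if (is.na(pid)) next
      K <- split_branch_at(pid)
      bx <- open_branch(j)
      close_branch(bx, K)
    }
  }

  # --- finalize ------------------------------------------------------------
  npos <- do.call(rbind, node_pos)
  keep <- !is.na(branch_b)
  polys <- lapply(which(keep), function(bi) {
    rows <- branch_rows[[bi]]
    p <- rbind(matrix(npos[branch_a[bi], ], 1),
               pt_pos[rows, , drop = FALSE],
               matrix(npos[branch_b[bi], ], 1))
    # drop duplicated consecutive points (node coincides with a laid point)
    dup <- c(FALSE, rowSums(abs(diff(p))) < 1e-9)
    p <- p[!dup, , drop = FALSE]
    # the step-wise walk zigzags; represent branches by the same smoothed
    # curve the analysis uses, so lengths are on a common footing
    if (nrow(p) > 2)
      p <- smooth_branch_curve(p[2:(nrow(p) - 1), , drop = FALSE],
                               p[1, ], p[nrow(p), ])
    p
  })
  ndf <- data.frame(id = seq_len(nrow(npos)),
                    x = npos[, 1], y = npos[, 2], z = npos[, 3],
                    anchored = node_anch, kind = node_kind)
  ndf$domain <- vapply(seq_len(nrow(ndf)), function(i)
    mask_domain_at(mask, npos[i, ]), character(1))
  bdf <- data.frame(id = seq_along(polys),
                    node_a = branch_a[keep], node_b = branch_b[keep])
  bdf$domain <- vapply(polys, function(p)
    mask_domain_at(mask, colMeans(p)), character(1))
  g <- skeleton_graph(ndf, bdf, polys)
  # drop degenerate zero-length branches (coincident node positions)
  keepb <- g$branches$arc_length > 1e-6
  if (!all(keepb)) {
    g$branches <- g$branches[keepb, , drop = FALSE]
    g$polylines <- g$polylines[keepb]
    g$branches$id <- seq_len(nrow(g$branches))
    g <- finalize_graph(g)
  }
  # cascade the retraction: a branch event both of whose offspring were
  # retracted never happened, so its junction node and incoming branch go
  repeat {
    bad <- g$nodes$id[g$nodes$rank <= 1 & g$nodes$kind == "junction"]
    if (!length(bad)) break
    keep <- !(g$branches$node_a %in% bad | g$branches$node_b %in% bad)
    g$branches <- g$branches[keep, , drop = FALSE]
    g$polylines <- g$polylines[keep]
    g$nodes <- g$nodes[!(g$nodes$id %in% bad), , drop = FALSE]
    g$branches$id <- seq_len(nrow(g$branches))
    g <- finalize_graph(g)
  }
  # drop unused isolated nodes (seeds that never grew)
  used <- unique(c(g$branches$node_a, g$branches$node_b))
  g$nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  g <- finalize_graph(g)
  g <- merge_rank2_nodes(g)              # remnants of retracted tips
  attr(g, "spec") <- spec
  g
}

#' Render a ground-truth network into a tomogram-like volume
#'
#' Filaments are drawn as solid tubes of the spec's filament diameter with
#' unit absorption contrast over the cytosol, convolved with a Gaussian
#' point-spread function, given a smooth sinusoidal luminance drift along
#' z, and corrupted with i.i.d. Gaussian voxel noise; intensities are
#' clipped to \[-2, 3\].
#' Phantoms are generated in absorption polarity (filaments bright);
#' `polarity = "luminance"` negates the volume to mimic raw EM.
#'
#' @param net a ground-truth [skeleton_graph] from [grow_network].
#' @param mask the phantom's [label_mask].
#' @param psf_sigma Gaussian PSF SD, nm.
#' @param noise_sd additive Gaussian noise SD (tube contrast is 1).
#' @param z_drift_amplitude amplitude of the sinusoidal per-slice drift.
#' @param seed RNG seed for the noise.
#' @param drift_period period of the z drift, nm.
#' @param filament_diameter tube diameter, nm (default from the network's
#'   spec).
#' @param polarity `"absorption"` or `"luminance"`.
#' @return a [volume_grid]; attribute `contrast` holds the mean blurred
#'   on-axis tube intensity (so SNR = contrast / noise_sd).
#' @export
render_tomogram <- function(net, mask, psf_sigma = 2, noise_sd = 0.1,
                            z_drift_amplitude = 0, seed = 1L,
                            drift_period = 150, filament_diameter = NULL,
                            polarity = c("absorption", "luminance")) {
  polarity <- match.arg(polarity)
  spec <- attr(net, "spec")
  if (is.null(filament_diameter))
    filament_diameter <- if (!is.null(spec)) spec$filament_diameter else 8
  dims <- dim(mask$labels)
  pitch <- mask$pitch
  if (!is.null(spec) && psf_sigma >= spec$neck_radius)
    warning("PSF wider than the neck radius: structure unresolvable")
  center <- array(FALSE, dims)
  for (p in net$polylines) {
    sp <- resample_polyline(p, pitch / 2)
    idx <- position_to_voxel(sp, pitch, dims, mask$origin)
    center[idx] <- TRUE
  }
  dist_nm <- array(sqrt(cpp_edt3d_sq(!center, dims)) * pitch, dims)
  vol <- array(0, dims)
  vol[dist_nm <= filament_diameter / 2] <- 1
  if (psf_sigma > 0) {
    k <- gaussian_kernel_1d(psf_sigma / pitch)
    vol <- conv3d_separable(vol, k)
  }
  contrast <- mean(vol[center])
  if (z_drift_amplitude != 0) {
    zs <- (seq_len(dims[3]) - 0.5) * pitch
    drift <- z_drift_amplitude * sin(2 * pi * zs / drift_period)
    vol <- sweep(vol, 3, drift, `+`)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- vol + array(rnorm(length(vol), 0, noise_sd), dims)
  }
  vol[vol < -2] <- -2
  vol[vol > 3] <- 3
  if (polarity == "luminance") vol <- -vol
  out <- volume_grid(vol, pitch = pitch, origin = mask$origin)
  attr(out, "contrast") <- contrast
  out
}

#' Summary statistics of a ground-truth network
#'
#' @param net a [skeleton_graph] from [grow_network].
#' @param mask the phantom's [label_mask] (for densities).
#' @return one-row data.frame: junction count and density, mean branch
#'   length, mean tortuosity, rank-3 fraction of junctions.
#' @export
network_summary <- function(net, mask = NULL) {
  r <- net$nodes$rank
  jr <- r[r >= 3]
  data.frame(
    n_junctions = length(jr),
    junction_density_per_um3 = if (!is.null(mask))
      length(jr) / (cytosol_volume(mask) / 1e9) else NA_real_,
    mean_branch_length = mean(net$branches$arc_length),
    mean_tortuosity = mean(net$branches$tortuosity, na.rm = TRUE),
    rank3_fraction = if (length(jr)) sum(jr == 3) / length(jr) else NA_real_)
}
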
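# Distance-to-membrane fields and everything measured against them.

#' Distance field of the intracellular space
#'
#' Euclidean distance (nm) of each cytosol voxel to the nearest non-cytosol
#' voxel. Membrane, ER, PSD, mitochondria and the extracellular space all
#' count as boundary. The gradient (central differences, normalized) points
#' away from the membrane toward the centre of the volume. `dt_norm` divides
#' by the per-domain maximum (head and neck separately when tagged, else the
#' global maximum).
#'
#' @param mask a [label_mask].
#' @return an object of class `distance_field` with elements `dt`, `gx`,
#'   `gy`, `gz`, `dt_norm` (3D arrays), `pitch`, `origin`.
#' @export
boundary_distance_field <- function(mask) {
  cy <- cytosol_mask(mask)
  if (!any(cy)) stop("mask contains no cytosol voxels")
  d <- dim(cy)
  dt <- array(sqrt(cpp_edt3d_sq(as.logical(cy), d)) * mask$pitch, d)

  grad_axis <- function(a, axis) {
    dd <- dim(a)
    n <- dd[axis]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    if (axis == 1) g <- a[idx_p, , , drop = FALSE] - a[idx_m, , , drop = FALSE]
    else if (axis == 2) g <- a[, idx_p, , drop = FALSE] - a[, idx_m, , drop = FALSE]
    else g <- a[, , idx_p, drop = FALSE] - a[, , idx_m, drop = FALSE]
    # central difference step is 2*pitch except at the array faces
    step <- rep(2, n); step[1] <- 1; step[n] <- 1
    if (axis == 1) g <- sweep(g, 1, step * mask$pitch, `/`)
    else if (axis == 2) g <- sweep(g, 2, step * mask$pitch, `/`)
    else g <- sweep(g, 3, step * mask$pitch, `/`)
    g
  }
  gx <- grad_axis(dt, 1); gy <- grad_axis(dt, 2); gz <- grad_axis(dt, 3)
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  ok <- nrm > 1e-12
  gx[ok] <- gx[ok] / nrm[ok]; gy[ok] <- gy[ok] / nrm[ok]
  gz[ok] <- gz[ok] / nrm[ok]
  gx[!ok] <- NA_real_; gy[!ok] <- NA_real_; gz[!ok] <- NA_real_

  dt_norm <- array(0, d)
  doms <- unique(mask$domain[cy])
  doms <- doms[doms > 0L]
  if (length(doms) == 0) {
    mx <- max(dt)
    if (mx > 0) dt_norm <- dt / mx
  } else {
    for (dm in doms) {
      sel <- cy & mask$domain == dm
      mx <- max(dt[sel])
      if (mx > 0) dt_norm[sel] <- dt[sel] / mx
    }
    untagged <- cy & !(mask$domain %in% doms)
    if (any(untagged)) dt_norm[untagged] <- dt[untagged] / max(dt)
  }
  structure(list(dt = dt, gx = gx, gy = gy, gz = gz, dt_norm = dt_norm,
                 pitch = mask$pitch, origin = mask$origin),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> max dt %.1f nm on a %s grid\n",
              max(x$dt), paste(dim(x$dt), collapse = "x")))
  invisible(x)
}

# nearest-voxel lookup of field quantities at physical positions
field_at <- function(field, pos, what = c("dt", "dt_norm", "grad")) {
  what <- match.arg(what)
  idx <- position_to_voxel(matrix(pos, ncol = 3), field$pitch, dim(field$dt),
                           field$origin)
  if (what == "grad")
    cbind(field$gx[idx], field$gy[idx], field$gz[idx])
  else field[[what]][idx]
}

#' Volume fraction occupied by the reconstructed cytoskeleton
#'
#' The skeleton polylines are rasterized as unit line density and convolved
#' with a 3D Gaussian of SD `sigma_vol`; voxels above `alpha * exp(-0.5)`
#' with `alpha = 1/(2*pi*sigma_vol^2)` -- the response level of an infinite
#' straight line at lateral distance sigma -- are counted as cytoskeleton.
#' This reconstructs tubes of radius `sigma_vol` (8 nm diameter at the
#' default), matching the assumed F-actin diameter.
#'
#' @param g a [skeleton_graph].
#' @param mask a [label_mask].
#' @param sigma_vol Gaussian SD, nm.
#' @return data.frame with rows for "all" plus any tagged domain, columns
#'   `domain`, `fraction`.
#' @export
cytoskeleton_volume_fraction <- function(g, mask, sigma_vol = 4) {
  stopifnot(sigma_vol > 0)
  d <- dim(mask$labels)
  pitch <- mask$pitch
  cy <- cytosol_mask(mask)
  dens <- array(0, d)
  if (n_branches(g) > 0) {
    for (p in g$polylines) {
      sp <- resample_polyline(p, pitch)
      idx <- position_to_voxel(sp, pitch, d, mask$origin)
      dens[idx] <- 1
    }
  }
  if (sum(dens) == 0) {
    out <- data.frame(domain = "all", fraction = 0)
  } else {
    # kernel: product of per-axis exp(-d^2/2s^2)/sqrt(2 pi s^2), times pitch,
    # so a voxel chain at unit spacing approximates a unit-density line
    r <- max(1L, ceiling(4 * sigma_vol / pitch))
    xs <- ((-r):r) * pitch
    k1 <- exp(-xs^2 / (2 * sigma_vol^2)) / sqrt(2 * pi * sigma_vol^2)
    f <- cpp_conv_axis(as.numeric(dens), d, k1 * pitch, 0L)
    f <- cpp_conv_axis(f, d, k1, 1L)
    f <- array(cpp_conv_axis(f, d, k1, 2L), d)
    # the 1e-3 slack keeps lattice voxels sitting exactly on the tube
    # surface robustly inside the reconstruction
    thr <- exp(-0.5) / (2 * pi * sigma_vol^2) * (1 - 1e-3)
    recon <- f >= thr
    out <- data.frame(domain = "all",
                      fraction = sum(recon & cy) / max(1, sum(cy)))
    for (dm in c(1L, 2L)) {
      sel <- cy & mask$domain == dm
      if (any(sel))
        out <- rbind(out, data.frame(domain = c("head", "neck")[dm],
                                     fraction = sum(recon & sel) / sum(sel)))
    }
    return(out)
  }
  for (dm in c(1L, 2L)) {
    sel <- cy & mask$domain == dm
    if (any(sel))
      out <- rbind(out, data.frame(domain = c("head", "neck")[dm],
                                   fraction = 0))
  }
  out
}

# resample a polyline at roughly `step` spacing (keeps original vertices)
resample_polyline <- function(p, step) {
  if (nrow(p) < 2) return(p)
  out <- list(p[1, , drop = FALSE])
  for (i in 2:nrow(p)) {
    seg <- p[i, ] - p[i - 1, ]
    len <- sqrt(sum(seg^2))
    if (len > step) {
      nsub <- ceiling(len / step)
      tt <- seq_len(nsub) / nsub
      out[[length(out) + 1]] <-
        matrix(rep(p[i - 1, ], nsub), ncol = 3, byrow = TRUE) + outer(tt, seg)
    } else {
      out[[length(out) + 1]] <- p[i, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

#' Membrane-relative orientation of a branch
#'
#' At each interior polyline point the local tangent (difference of the two
#' neighbouring points) is compared with the distance-transform gradient at
#' that point; the angle is folded to \[0, 90\] degrees and averaged along
#' the branch. Points on gradient plateaus (undefined direction) are
#' skipped.
#'
#' @param polyline branch polyline, (n x 3) matrix in nm.
#' @param field a [boundary_distance_field] result.
#' @return mean angle in degrees, or NA if no point had a defined gradient.
#' @export
branch_orientation <- function(polyline, field) {
  n <- nrow(polyline)
  if (n < 3) {
    # straight two-point branch: single tangent at the midpoint
    tang <- polyline[n, ] - polyline[1, ]
    mid <- colMeans(polyline)
    gr <- field_at(field, mid, "grad")
    return(fold_angle(tang, gr))
  }
  angs <- vapply(2:(n - 1), function(i) {
    tang <- polyline[i + 1, ] - polyline[i - 1, ]
    gr <- field_at(field, polyline[i, ], "grad")
    fold_angle(tang, gr)
  }, numeric(1))
  if (all(is.na(angs))) NA_real_ else mean(angs, na.rm = TRUE)
}

fold_angle <- function(v, g) {
  if (any(is.na(g)) || sum(v^2) == 0) return(NA_real_)
  cosang <- abs(sum(v * g)) / sqrt(sum(v^2) * sum(g^2))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Orientation of every branch in a graph
#' @param g a [skeleton_graph].
#' @param field a [boundary_distance_field] result.
#' @param include_excluded include artificial-cut branches.
#' @return data.frame `branch_id`, `orientation_deg`, `dt_nm` (at the branch
#'   centre of mass), `domain`.
#' @export
branch_orientations <- function(g, field, include_excluded = FALSE) {
  sel <- if (include_excluded) rep(TRUE, n_branches(g)) else !g$branches$excluded
  ids <- g$branches$id[sel]
  rows <- lapply(ids, function(i) {
    p <- g$polylines[[match(i, g$branches$id)]]
    com <- colMeans(p)
    data.frame(branch_id = i,
               orientation_deg = branch_orientation(p, field),
               dt_nm = field_at(field, com, "dt"),
               dt_norm = field_at(field, com, "dt_norm"),
               domain = g$branches$domain[match(i, g$branches$id)])
  })
  do.call(rbind, rows)
}

#' Profile of a quantity against distance to the membrane
#'
#' Items are binned by the distance-transform value at their reference point
#' (a branch's centre of mass, a node's position); per bin the mean, SD, SEM
#' and count are reported. With `density = TRUE` the per-bin count is divided
#' by the cytosol volume of that distance shell (um^-3), which requires
#' `mask`.
#'
#' @param values numeric vector (ignored when `density = TRUE`).
#' @param ref_points (n x 3) matrix of reference positions, nm.
#' @param field a [boundary_distance_field] result.
#' @param bin bin width (nm, or in normalized units when
#'   `normalized = TRUE`).
#' @param normalized bin by `dt_norm` instead of absolute distance.
#' @param density report per-bin number densities instead of means.
#' @param mask the [label_mask], needed for shell volumes.
#' @return data.frame with `bin_lo`, `bin_hi`, `mid`, `n`, and either
#'   `mean`, `sd`, `sem` or `density_per_um3`. Empty bins are absent.
#' @export
profile_vs_distance <- function(values, ref_points, field, bin = 3,
                                normalized = FALSE, density = FALSE,
                                mask = NULL) {
  ref_points <- matrix(ref_points, ncol = 3)
  if (nrow(ref_points) < 1) stop("need at least one item")
  dvals <- field_at(field, ref_points,
                    if (normalized) "dt_norm" else "dt")
  maxd <- if (normalized) 1 else max(field$dt)
  breaks <- seq(0, maxd + bin, by = bin)
  bi <- findInterval(dvals, breaks, rightmost.closed = FALSE)
  bi[bi < 1] <- 1
  out <- NULL
  if (density) {
    if (is.null(mask)) stop("density profiles need the label mask")
    cy <- cytosol_mask(mask)
    dall <- if (normalized) field$dt_norm[cy] else field$dt[cy]
    shell <- findInterval(dall, breaks, rightmost.closed = FALSE)
    shell_n <- tabulate(shell, nbins = length(breaks))
    for (b in sort(unique(bi))) {
      cnt <- sum(bi == b)
      vol_nm3 <- shell_n[b] * mask$pitch^3
      if (vol_nm3 == 0) next
      out <- rbind(out, data.frame(
        bin_lo = breaks[b], bin_hi = breaks[b + 1],
        mid = (breaks[b] + breaks[b + 1]) / 2, n = cnt,
        density_per_um3 = cnt / vol_nm3 * 1e9))
    }
  } else {
    stopifnot(length(values) == nrow(ref_points))
    for (b in sort(unique(bi))) {
      v <- values[bi == b]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      out <- rbind(out, data.frame(
        bin_lo = breaks[b], bin_hi = breaks[b + 1],
        mid = (breaks[b] + breaks[b + 1]) / 2, n = length(v),
        mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_))
    }
  }
  out
}

#' Automated spine neck width estimate
#'
#' Twice the minimum distance-transform value over the medial axis of the
#' neck-domain cytosol (the minimal inscribed diameter). This replaces a
#' manual minimum-diameter measurement with an automated estimator.
#'
#' @param mask a [label_mask] with a tagged neck domain.
#' @return width in nm, or `NA` when no neck domain exists (stubby spine).
#' @export
neck_width_estimate <- function(mask) {
  neck <- cytosol_mask(mask) & mask$domain == 2L
  if (!any(neck)) return(NA_real_)
  field <- boundary_distance_field(mask)
  sk <- topological_thinning(neck, dt = volume_grid(field$dt, mask$pitch),
                             pitch = mask$pitch, protect_faces = TRUE)
  med <- sk$fg & neck
  if (!any(med)) med <- neck
  2 * min(field$dt[med])
}
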
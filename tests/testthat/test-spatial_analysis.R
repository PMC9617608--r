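# Distance fields and measurements taken against them.

cyl_mask <- function(R = 25, nx = 31, nz = 21, pitch = 2) {
  labels <- array(0L, c(nx, nx, nz))
  c0 <- nx * pitch / 2
  for (x in 1:nx) for (y in 1:nx) {
    px <- (x - 0.5) * pitch - c0; py <- (y - 0.5) * pitch - c0
    if (px^2 + py^2 <= R^2) labels[x, y, ] <- 1L
  }
  label_mask(labels, pitch = pitch)
}

test_that("distance field of a cylinder peaks at its radius on the axis", {
  m <- cyl_mask(R = 25)
  f <- boundary_distance_field(m)
  # the open z-faces leak no boundary: dt measured to the lateral wall only
  expect_lt(abs(max(f$dt[, , 11]) - 25), 2.01)
  expect_equal(max(f$dt_norm), 1)
})

test_that("the gradient near a flat wall points inward", {
  labels <- array(0L, c(30, 20, 20))
  labels[2:29, , ] <- 1L     # wall at low/high x
  f <- boundary_distance_field(label_mask(labels, pitch = 2))
  g <- c(f$gx[6, 10, 10], f$gy[6, 10, 10], f$gz[6, 10, 10])
  ang <- acos(sum(g * c(1, 0, 0))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("volume fraction reconstructs a tube around a straight line", {
  # line spans the box; cytosol restricted to a central slab so end effects
  # of the finite line do not enter the count
  labels <- array(0L, c(40, 25, 25))
  labels[11:35, , ] <- 1L
  m <- label_mask(labels, pitch = 2)
  L <- 25 * 2
  net <- skeleton_graph(data.frame(id = 1:2, x = c(3, 77), y = 25, z = 25),
                        data.frame(id = 1, node_a = 1, node_b = 2))
  vf <- cytoskeleton_volume_fraction(net, m, sigma_vol = 4)
  got_nm3 <- vf$fraction[1] * cytosol_volume(m)
  expect_lt(abs(got_nm3 - pi * 16 * L) / (pi * 16 * L), 0.10)

  empty <- skeleton_graph(data.frame(id = 1, x = 10, y = 10, z = 10),
                          data.frame(id = integer(0), node_a = integer(0),
                                     node_b = integer(0)), list())
  expect_equal(cytoskeleton_volume_fraction(empty, m, 4)$fraction[1], 0)
})

test_that("orientations: radial 0, tangential 90, oblique 45", {
  # ball mask
  labels <- array(0L, c(41, 41, 41))
  xs <- (1:41 - 0.5) * 2 - 41
  R2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  labels[R2 <= 36^2] <- 1L
  m <- label_mask(labels, pitch = 2)
  f <- boundary_distance_field(m)
  ctr <- c(41, 41, 41)
  radial <- rbind(ctr + c(6, 0, 0), ctr + c(16, 0, 0), ctr + c(26, 0, 0))
  expect_lt(branch_orientation(radial, f), 6)
  th <- seq(0, pi / 3, length.out = 12)
  tang <- cbind(ctr[1] + 24 * cos(th), ctr[2] + 24 * sin(th), ctr[3])
  expect_gt(branch_orientation(tang, f), 80)

  # 45-degree rod near a flat wall
  labels <- array(0L, c(40, 30, 30))
  labels[2:39, , ] <- 1L
  fw <- boundary_distance_field(label_mask(labels, pitch = 2))
  rod <- cbind(10 + (0:10) * 2, 20 + (0:10) * 2, 30)
  expect_lt(abs(branch_orientation(rod, fw) - 45), 2)
})

test_that("profiles: uniform points are flat, constants stay constant", {
  labels0 <- array(0L, c(30, 30, 16)); labels0[, , 2:15] <- 1L
  m <- label_mask(labels0, pitch = 2)   # slab with two walls
  f <- boundary_distance_field(m)
  set.seed(3)
  pts <- cbind(runif(4000, 4, 56), runif(4000, 4, 56),
               runif(4000, 2.001, 29.999))
  prof <- profile_vs_distance(NULL, pts, f, bin = 4, density = TRUE, mask = m)
  inner <- prof[prof$mid < 12, ]
  expect_lt(max(inner$density_per_um3) / min(inner$density_per_um3), 1.35)

  vals <- rep(3.3, 200)
  prof2 <- profile_vs_distance(vals, pts[1:200, ], f, bin = 4)
  expect_true(all(abs(prof2$mean - 3.3) < 1e-12))
})

test_that("branch ends crowd the membrane; a depleted shell reads as a dip", {
  # anchor-dominated phantom: most membrane contacts terminate the filament
  spec <- spine_phantom_spec(head_radius = 70, neck_length = 80,
                             neck_radius = 32, membrane_deflect = 0.2)
  mask <- generate_spine_geometry(spec, seed = 11)
  net <- grow_network(mask, spec, seed = 12)
  f <- boundary_distance_field(mask)
  ends <- as.matrix(net$nodes[net$nodes$rank == 1 & net$nodes$anchored,
                              c("x", "y", "z")])
  pe <- profile_vs_distance(NULL, ends, f, bin = 8, density = TRUE,
                            mask = mask)
  # membrane-anchored ends peak in the first bin
  expect_equal(which.max(pe$density_per_um3), 1)
  ph <- small_phantom()

  # a point process depleted within 8 nm of the membrane profiles as a dip
  cy <- which(cytosol_mask(ph$mask) & f$dt > 8)
  set.seed(4)
  pts <- voxel_centers(arrayInd(sample(cy, 400), dim(ph$mask$labels)),
                       ph$mask$pitch)
  pd <- profile_vs_distance(NULL, pts, f, bin = 8, density = TRUE,
                            mask = ph$mask)
  expect_gt(pd$density_per_um3[2], pd$density_per_um3[1])
})

test_that("neck width estimates the minimal inscribed diameter", {
  m <- cyl_mask(R = 25)
  m$domain[cytosol_mask(m)] <- 2L    # all neck
  expect_lt(abs(neck_width_estimate(m) - 50), 4.01)

  # hourglass: radius 25 tapering to 15 at the waist
  labels <- array(0L, c(31, 31, 31))
  for (z in 1:31) {
    r <- 15 + 10 * abs(z - 16) / 15
    for (x in 1:31) for (y in 1:31) {
      px <- (x - 0.5) * 2 - 31; py <- (y - 0.5) * 2 - 31
      if (px^2 + py^2 <= r^2) labels[x, y, z] <- 1L
    }
  }
  mh <- label_mask(labels, pitch = 2)
  mh$domain[cytosol_mask(mh)] <- 2L
  expect_lt(abs(neck_width_estimate(mh) - 30), 4.01)

  # stubby phantom: no neck domain
  ms <- cyl_mask(R = 25)
  ms$domain[cytosol_mask(ms)] <- 1L
  expect_true(is.na(neck_width_estimate(ms)))
})

test_that("distance profiles are invariant to 90-degree rotations", {
  ph <- small_phantom()
  f <- boundary_distance_field(ph$mask)
  pts <- as.matrix(ph$net$nodes[ph$net$nodes$rank >= 3, c("x", "y", "z")])
  p0 <- profile_vs_distance(NULL, pts, f, bin = 8, density = TRUE,
                            mask = ph$mask)
  # rotate mask and points 90 degrees about z: (x,y) -> (y, X - x)
  labels_r <- aperm(ph$mask$labels[dim(ph$mask$labels)[1]:1, , ], c(2, 1, 3))
  dom_r <- aperm(ph$mask$domain[dim(ph$mask$domain)[1]:1, , ], c(2, 1, 3))
  m_r <- label_mask(labels_r, pitch = ph$mask$pitch, domain = dom_r)
  X <- dim(ph$mask$labels)[1] * ph$mask$pitch
  pts_r <- cbind(pts[, 2], X - pts[, 1], pts[, 3])
  f_r <- boundary_distance_field(m_r)
  p1 <- profile_vs_distance(NULL, pts_r, f_r, bin = 8, density = TRUE,
                            mask = m_r)
  expect_equal(p0$n, p1$n)
  expect_equal(p0$density_per_um3, p1$density_per_um3, tolerance = 1e-9)
})
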
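# Node ranks, densities, end clustering, branching-angle geometry.

test_that("rank distributions count junctions and ends correctly", {
  pos <- rbind(c(0, 0, 0), c(20, 0, 0), c(-10, 17, 0), c(-10, -17, 0))
  gY <- toy_graph(pos, rbind(c(1, 2), c(1, 3), c(1, 4)))
  rd <- node_rank_distribution(gY)
  expect_equal(rd$fraction[rd$rank == "3" & rd$domain == "all"], 1)

  posX <- rbind(c(0, 0, 0), c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0),
                c(0, -10, 0))
  gX <- toy_graph(posX, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  rdX <- node_rank_distribution(gX)
  expect_equal(rdX$fraction[rdX$rank == "4" & rdX$domain == "all"], 1)
})

test_that("node density converts counts to per-um3", {
  labels <- array(1L, c(10, 10, 10))          # 8000 nm^3... scale below
  # use pitch 5 -> volume = 1000 voxels * 125 nm^3 = 1.25e5 nm^3
  m <- label_mask(labels, pitch = 5)
  pos <- rbind(c(25, 25, 25), c(30, 25, 25), c(20, 25, 25), c(25, 30, 25),
               c(25, 20, 25))
  g <- toy_graph(pos, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  nd <- node_density(g, m)
  expect_equal(nd$n_nodes[1], 1)
  expect_equal(nd$density_per_um3[1], 1 / (1.25e5 / 1e9), tolerance = 1e-9)
})

test_that("branch-end clustering test flags constructed clustering", {
  labels <- array(0L, c(40, 40, 12))
  labels[4:37, 4:37, 2:11] <- 1L
  m <- label_mask(labels, pitch = 2)
  f <- boundary_distance_field(m)

  mk_ends <- function(pts) {
    hub <- c(40, 40, 12)
    nodes <- data.frame(id = seq_len(nrow(pts) + 1),
                        x = c(pts[, 1], hub[1]), y = c(pts[, 2], hub[2]),
                        z = c(pts[, 3], hub[3]))
    hubid <- nrow(pts) + 1
    branches <- data.frame(id = seq_len(nrow(pts)),
                           node_a = seq_len(nrow(pts)), node_b = hubid)
    skeleton_graph(nodes, branches)
  }
  # tight pairs 4 nm apart in the membrane shell
  set.seed(2)
  base <- cbind(runif(12, 12, 68), runif(12, 12, 68), 6.5)
  pts <- rbind(base, base + matrix(c(4, 0, 0), 12, 3, byrow = TRUE))
  g <- mk_ends(pts)
  res <- branch_end_clustering_test(g, f, m, shell = 10, seed = 7,
                                    n_rand = 60)
  expect_lt(res$observed_mean, res$random_mean)
  expect_lt(res$p_value, 0.05)

  # two ends only: observed mean equals their separation
  g2 <- mk_ends(rbind(c(20, 20, 6.5), c(20, 32, 6.5)))
  res2 <- branch_end_clustering_test(g2, f, m, shell = 10, seed = 7,
                                     n_rand = 10)
  expect_equal(res2$observed_mean, 12, tolerance = 1e-9)
})

test_that("the clustering null is calibrated", {
  labels <- array(0L, c(30, 30, 10))
  labels[3:28, 3:28, 2:9] <- 1L
  m <- label_mask(labels, pitch = 2)
  f <- boundary_distance_field(m)
  shell_vox <- which(cytosol_mask(m) & f$dt < 10)
  centers <- voxel_centers(arrayInd(shell_vox, dim(m$labels)), 2)
  set.seed(31)
  pvals <- replicate(40, {
    pts <- centers[sample.int(nrow(centers), 15), ] +
      matrix(runif(45, -1, 1), 15, 3)
    nodes <- data.frame(id = 1:16, x = c(pts[, 1], 60), y = c(pts[, 2], 60),
                        z = c(pts[, 3], 20))
    g <- skeleton_graph(nodes, data.frame(id = 1:15, node_a = 1:15,
                                          node_b = 16))
    branch_end_clustering_test(g, f, m, shell = 10, seed = sample.int(1e6, 1),
                               n_rand = 30)$p_value
  })
  # uniform p-values: rejection rate near alpha
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals < 0.5), 0.25)
})

test_that("branching angles at rank-3 nodes match constructions", {
  # +x, +y, +z: all pairwise 90, sum 270
  mk3 <- function(dirs, L = 12) {
    nodes <- data.frame(id = 1:4,
                        x = c(0, L * dirs[, 1]), y = c(0, L * dirs[, 2]),
                        z = c(0, L * dirs[, 3]))
    skeleton_graph(nodes, data.frame(id = 1:3, node_a = 1, node_b = 2:4))
  }
  a <- branching_angles_rank3(mk3(diag(3)))
  expect_equal(as.numeric(a[1, c("smallest", "intermediate", "largest")]),
               c(90, 90, 90), tolerance = 1e-9)
  expect_equal(a$angle_sum, 270, tolerance = 1e-9)

  # planar 70/110/180
  d70 <- rbind(c(1, 0, 0),
               c(cos(110 * pi / 180), sin(110 * pi / 180), 0),
               c(-1, 0, 0))
  a2 <- branching_angles_rank3(mk3(d70))
  expect_equal(as.numeric(a2[1, c("smallest", "intermediate", "largest")]),
               c(70, 110, 180), tolerance = 1e-9)
  expect_equal(a2$angle_sum, 360, tolerance = 1e-9)

  # coplanar 120s
  d120 <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  a3 <- branching_angles_rank3(mk3(d120))
  expect_equal(as.numeric(a3[1, 2:4]), c(120, 120, 120), tolerance = 1e-9)
})

test_that("angle sums never exceed the spherical bound", {
  set.seed(12)
  for (i in 1:200) {
    tg <- random_unit_vectors(3)
    a <- sort(c(acos(sum(tg[1, ] * tg[2, ])), acos(sum(tg[1, ] * tg[3, ])),
                acos(sum(tg[2, ] * tg[3, ])))) * 180 / pi
    expect_lte(sum(a), 360 + 1e-6)
  }
})

test_that("frame standardization is exact and rotation invariant", {
  d70 <- rbind(c(-1, 0, 0),
               c(cos(70 * pi / 180), sin(70 * pi / 180), 0),
               c(cos(150 * pi / 180), sin(150 * pi / 180), 0.0))
  f0 <- standardize_rank3_frame(d70)
  expect_equal(f0[1, ], c(-1, 0, 0), tolerance = 1e-12)
  expect_gte(f0[2, 2], 0)
  expect_equal(f0[2, 3], 0, tolerance = 1e-9)
  expect_gte(f0[3, 3], -1e-12)

  ang <- function(m) sort(c(acos(sum(m[1, ] * m[2, ])),
                            acos(sum(m[1, ] * m[3, ])),
                            acos(sum(m[2, ] * m[3, ]))))
  set.seed(14)
  for (i in 1:25) {
    tg <- random_unit_vectors(3)
    f1 <- standardize_rank3_frame(tg)
    if (is.null(f1)) next
    # random rotation leaves the standardized frame unchanged
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    f2 <- standardize_rank3_frame(tg %*% q)
    expect_equal(f1, f2, tolerance = 1e-8)
    # pairwise angles preserved exactly
    expect_equal(ang(f1), ang(tg), tolerance = 1e-9)
    # mirror image maps to the same frame (documented reflection rule)
    f3 <- standardize_rank3_frame(tg %*% diag(c(1, 1, -1)))
    expect_equal(f1, f3, tolerance = 1e-8)
  }
  # collinear tangents are rejected
  col <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))
  expect_null(standardize_rank3_frame(col))
})
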
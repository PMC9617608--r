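# Elementary loops, planarity, pore size, MST pruning.

tri_graph <- function(l1 = 10, l2 = 20, l3 = 30) {
  # triangle with prescribed branch lengths via bent polylines
  pos <- rbind(c(0, 0, 0), c(8, 0, 0), c(4, 6, 0))
  nodes <- data.frame(id = 1:3, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  branches <- data.frame(id = 1:3, node_a = c(1, 2, 3), node_b = c(2, 3, 1))
  bent <- function(a, b, L) {
    d <- sqrt(sum((b - a)^2))
    h <- sqrt(max(0, (L / 2)^2 - (d / 2)^2))
    rbind(a, (a + b) / 2 + c(0, 0, h), b)
  }
  skeleton_graph(nodes, branches,
                 list(bent(pos[1, ], pos[2, ], l1),
                      bent(pos[2, ], pos[3, ], l2),
                      bent(pos[3, ], pos[1, ], l3)))
}

test_that("a triangle yields exactly one loop with summed circumference", {
  g <- tri_graph()
  loops <- elementary_loops(g)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$circumference, sum(g$branches$arc_length),
               tolerance = 1e-9)
  expect_equal(loops$node_count, 3)
})

test_that("trees carry no loops", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 5, 0), c(20, -5, 0))
  g <- toy_graph(pos, rbind(c(1, 2), c(2, 3), c(2, 4)))
  expect_equal(nrow(elementary_loops(g)), 0)
})

test_that("cube-graph loops equal the brute-force minimal cycles", {
  v <- expand.grid(0:1, 0:1, 0:1)
  nodes <- data.frame(id = 1:8, x = v[, 1] * 10, y = v[, 2] * 10,
                      z = v[, 3] * 10)
  e <- NULL
  for (i in 1:7) for (j in (i + 1):8)
    if (sum(abs(v[i, ] - v[j, ])) == 1) e <- rbind(e, c(i, j))
  g <- skeleton_graph(nodes, data.frame(id = seq_len(nrow(e)),
                                        node_a = e[, 1], node_b = e[, 2]))
  loops <- elementary_loops(g)
  expect_true(all(loops$node_count == 4))
  expect_true(all(abs(loops$circumference - 40) < 1e-9))
  impl <- loop_key_set(loops)
  oracle <- sort(vapply(brute_force_loops(g), function(m)
    paste(sort(m), collapse = "-"), character(1)))
  expect_equal(impl, oracle)
})

test_that("loops match brute force on random small multigraphs", {
  set.seed(77)
  for (rep in 1:20) {
    g <- random_multigraph(sample(3:6, 1), sample(3:12, 1))
    impl <- loop_key_set(elementary_loops(g))
    oracle <- sort(vapply(brute_force_loops(g), function(m)
      paste(sort(m), collapse = "-"), character(1)))
    expect_equal(impl, oracle, info = paste("rep", rep))
  }
})

test_that("the loop list is independent of node relabelling", {
  set.seed(78)
  g <- random_multigraph(6, 10)
  perm <- sample(6)
  g2 <- g
  g2$nodes <- g$nodes[order(perm), ]
  g2$nodes$id <- seq_len(6)
  relab <- perm
  g2$branches$node_a <- relab[g$branches$node_a]
  g2$branches$node_b <- relab[g$branches$node_b]
  g2 <- skeleton_graph(g2$nodes, g2$branches, g$polylines)
  l1 <- elementary_loops(g)
  l2 <- elementary_loops(g2)
  expect_equal(sort(l1$circumference), sort(l2$circumference),
               tolerance = 1e-9)
})

test_that("loop planarity and elongation follow closed forms", {
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  nodes <- data.frame(id = 1:4, x = sq[, 1], y = sq[, 2], z = sq[, 3])
  g <- skeleton_graph(nodes, data.frame(id = 1:4, node_a = c(1, 2, 3, 4),
                                        node_b = c(2, 3, 4, 1)))
  p <- loop_planarity_pca(1:4, g)
  expect_equal(p$planarity, 1, tolerance = 1e-12)
  expect_equal(p$variances[3], 0, tolerance = 1e-12)

  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  circ <- data.frame(id = 1:12, x = 20 * cos(th), y = 20 * sin(th), z = 0)
  gc <- skeleton_graph(circ, data.frame(id = 1:12, node_a = 1:12,
                                        node_b = c(2:12, 1)))
  expect_equal(loop_planarity_pca(1:12, gc)$epsilon, 1, tolerance = 1e-6)

  th36 <- seq(0, 2 * pi, length.out = 37)[1:36]
  ell <- data.frame(id = 1:36, x = 40 * cos(th36), y = 20 * sin(th36), z = 0)
  ge <- skeleton_graph(ell, data.frame(id = 1:36, node_a = 1:36,
                                       node_b = c(2:36, 1)))
  expect_lt(abs(loop_planarity_pca(1:36, ge)$epsilon - 2) / 2, 0.05)

  # collinear loop nodes are rejected
  lin <- data.frame(id = 1:3, x = c(0, 5, 10), y = 0, z = 0)
  gl <- skeleton_graph(lin, data.frame(id = 1:3, node_a = c(1, 2, 3),
                                       node_b = c(2, 3, 1)))
  expect_null(loop_planarity_pca(1:3, gl))
})

test_that("pore diameter inverts the ellipse picture", {
  expect_equal(pore_diameter_estimate(120, 1.47, 8), 120 / (pi * 1.47) - 8,
               tolerance = 1e-12)
  expect_lt(abs(pore_diameter_estimate(120, 1.47, 8) - 18), 1)
  d <- 33
  expect_equal(pore_diameter_estimate(pi * d, 1, 0), d, tolerance = 1e-12)
  expect_equal(pore_diameter_estimate(100, 1, 8), 100 / pi - 8,
               tolerance = 1e-12)
  expect_equal(pore_diameter_estimate(10, 1.5, 8), 0)  # closed mesh
})

test_that("MST pruning drops the shortest triangle branch", {
  g <- tri_graph(10, 20, 30)
  pruned <- minimum_spanning_tree_prune(g)
  expect_equal(n_branches(pruned), 2)
  expect_false(any(abs(pruned$branches$arc_length - 10) < 1e-6))
})

test_that("MST is the identity on trees and kills all loops", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 5, 0), c(20, -5, 0))
  gt <- toy_graph(pos, rbind(c(1, 2), c(2, 3), c(2, 4)))
  expect_equal(n_branches(minimum_spanning_tree_prune(gt)), 3)

  ph <- small_phantom()
  pruned <- minimum_spanning_tree_prune(ph$net)
  expect_equal(graph_cycles(pruned), 0)
  expect_equal(nrow(elementary_loops(pruned)), 0)
  comp <- igraph::components(as_igraph(pruned))
  # per component: |nodes| = |branches| + 1
  expect_equal(n_branches(pruned), n_nodes(pruned) - comp$no)
})

test_that("MST minimizes total inverse-length weight (brute force)", {
  set.seed(80)
  for (rep in 1:10) {
    g <- random_multigraph(5, 8)
    ig <- as_igraph(g)
    comp <- igraph::components(ig)
    pruned <- minimum_spanning_tree_prune(g)
    got <- sum(1 / pruned$branches$arc_length)
    # brute force over all spanning forests via edge subsets
    nb <- n_branches(g)
    best <- Inf
    target_edges <- n_nodes(g) - comp$no
    for (mask in 0:(2^nb - 1)) {
      sel <- which(bitwAnd(mask, 2^(0:(nb - 1))) > 0)
      if (length(sel) != target_edges) next
      sub <- igraph::subgraph_from_edges(ig, sel, delete.vertices = FALSE)
      if (igraph::components(sub)$no != comp$no) next
      w <- sum(1 / g$branches$arc_length[sel])
      if (w < best) best <- w
    }
    expect_equal(got, best, tolerance = 1e-9, info = paste("rep", rep))
  }
})

test_that("rank-2 merging concatenates branches", {
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(12, 0, 0))
  g <- toy_graph(pos, rbind(c(1, 2), c(2, 3)))
  m <- merge_rank2_nodes(g)
  expect_equal(n_branches(m), 1)
  expect_equal(m$branches$arc_length, 12, tolerance = 1e-12)
  expect_equal(n_nodes(m), 2)

  # no rank-2 nodes: identity
  posY <- rbind(c(0, 0, 0), c(10, 0, 0), c(-5, 8, 0), c(-5, -8, 0))
  gY <- toy_graph(posY, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(n_branches(merge_rank2_nodes(gY)), 3)

  # chain of 5 rank-2 nodes collapses to one branch of summed length
  xs <- c(0, 3, 7, 10, 16, 21, 30)
  posC <- cbind(xs, 0, 0)
  gC <- toy_graph(posC, cbind(1:6, 2:7))
  mC <- merge_rank2_nodes(gC)
  expect_equal(n_branches(mC), 1)
  expect_equal(mC$branches$arc_length, 30, tolerance = 1e-12)
})

test_that("prune statistics report reductions and length growth", {
  g <- tri_graph(10, 20, 30)
  expect_equal(prune_stats(g, g)$branch_reduction_pct, 0)
  pruned <- minimum_spanning_tree_prune(g)
  ps <- prune_stats(g, pruned)
  expect_equal(ps$branch_reduction_pct, 100 / 3, tolerance = 1e-9)

  ph <- small_phantom()
  mst <- minimum_spanning_tree_prune(ph$net)
  merged <- merge_rank2_nodes(mst)
  ps2 <- prune_stats(ph$net, merged, ph$mask)
  if (n_branches(merged) < n_branches(mst)) {
    expect_gt(ps2$mean_branch_length_after,
              mean(mst$branches$arc_length[!mst$branches$excluded]))
  }
  expect_gt(ps2$node_reduction_pct, 0)
  expect_lte(ps2$volume_fraction_after, ps2$volume_fraction_before + 1e-9)
})
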
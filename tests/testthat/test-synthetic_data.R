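# Phantom generator: geometry, ground-truth network, rendering.

test_that("phantom geometry matches the analytic sphere+cylinder volume", {
  spec <- spine_phantom_spec(head_radius = 150, neck_radius = 50,
                             neck_length = 300)
  mask <- generate_spine_geometry(spec, seed = 1)
  va <- 4 / 3 * pi * 150^3 + pi * 50^2 * 300
  expect_lt(abs(cytosol_volume(mask) - va) / va, 0.05)
  expect_true(any(mask$labels == SPINE_LABELS["membrane"]))
  # domain tags cover the cytosol
  cy <- cytosol_mask(mask)
  expect_true(all(mask$domain[cy] %in% c(1L, 2L)))
})

test_that("organelle fraction 0 yields no ER label; >0 yields some", {
  spec0 <- spine_phantom_spec(organelle_fraction = 0)
  m0 <- generate_spine_geometry(spec0, seed = 2)
  expect_equal(sum(m0$labels == 3L), 0)
  spec1 <- spine_phantom_spec(organelle_fraction = 0.1)
  m1 <- generate_spine_geometry(spec1, seed = 2)
  expect_gt(sum(m1$labels == 3L), 0)
})

test_that("thin necks build down to the hippocampal range; thinner fail", {
  spec <- spine_phantom_spec(neck_radius = 20, filament_diameter = 8)
  m <- generate_spine_geometry(spec, seed = 3)
  expect_gt(sum(m$domain == 2L), 0)
  spec_bad <- spine_phantom_spec(neck_radius = 20, filament_diameter = 8)
  spec_bad$neck_radius <- 6   # below twice the filament radius
  expect_error(generate_spine_geometry(spec_bad, seed = 3), "unbuildable")
})

test_that("grown junction count tracks density x volume", {
  ph <- small_phantom()
  target <- ph$spec$target_node_density * cytosol_volume(ph$mask) / 1e9
  got <- sum(ph$net$nodes$rank >= 3)
  expect_lt(abs(got - target) / target, 0.25)
})

test_that("grown branch lengths and tortuosity track the spec", {
  ph <- small_phantom()
  expect_lt(abs(mean(ph$net$branches$arc_length) -
                  ph$spec$branch_length_mean) / ph$spec$branch_length_mean,
            0.25)
  mt <- mean(ph$net$branches$tortuosity, na.rm = TRUE)
  expect_gt(mt, 1.0)
  expect_lt(mt, 1.25)
})

test_that("tree growth without cross-links or fusion is acyclic", {
  spec <- spine_phantom_spec(head_radius = 70, neck_length = 60,
                             neck_radius = 30, crosslink_rate = 0,
                             fuse_radius = 0.5,
                             target_node_density = 6e4)
  mask <- generate_spine_geometry(spec, seed = 4)
  net <- grow_network(mask, spec, seed = 5)
  expect_equal(graph_cycles(net), 0)
})

test_that("planar 70-110-180 law reproduces its sorted angles", {
  spec <- spine_phantom_spec(head_radius = 80, neck_length = 60,
                             neck_radius = 35, crosslink_rate = 0,
                             fuse_radius = 0.5, target_node_density = 5e4,
                             branching_angle_law = "planar-70-110-180",
                             tortuosity_target = 1.0)
  mask <- generate_spine_geometry(spec, seed = 6)
  net <- grow_network(mask, spec, seed = 7)
  ang <- branching_angles_rank3(net)
  # interior nodes only: membrane deflection legitimately bends branches
  # that start within a few steps of the boundary
  f <- boundary_distance_field(mask)
  pos <- as.matrix(net$nodes[match(ang$node_id, net$nodes$id),
                             c("x", "y", "z")])
  ang <- ang[spinemesh:::field_at(f, pos, "dt") > 10, ]
  expect_gt(nrow(ang), 30)
  expect_lt(abs(mean(ang$smallest) - 70), 2)
  expect_lt(abs(mean(ang$intermediate) - 110), 2)
  expect_lt(abs(mean(ang$largest) - 180), 2)
})

test_that("rank-4 fraction rises with the cross-link rate", {
  frac4 <- sapply(c(0, 0.8), function(r) {
    spec <- spine_phantom_spec(head_radius = 70, neck_length = 60,
                               neck_radius = 30, crosslink_rate = r,
                               target_node_density = 8e4)
    mask <- generate_spine_geometry(spec, seed = 8)
    net <- grow_network(mask, spec, seed = 9)
    jr <- net$nodes$rank[net$nodes$rank >= 3]
    mean(jr >= 4)
  })
  expect_gt(frac4[2], frac4[1])
})

test_that("rendered straight tube has its intensity ridge on the true axis", {
  labels <- array(1L, c(40, 15, 15))
  mask <- label_mask(labels, pitch = 2)
  axis_y <- 15; axis_z <- 15    # nm (centre of voxel 8)
  poly <- rbind(c(2, axis_y, axis_z), c(78, axis_y, axis_z))
  net <- skeleton_graph(data.frame(id = 1:2, x = c(2, 78), y = axis_y,
                                   z = axis_z),
                        data.frame(id = 1, node_a = 1, node_b = 2),
                        list(poly))
  vol <- render_tomogram(net, mask, psf_sigma = 2, noise_sd = 0,
                         z_drift_amplitude = 0, seed = 1)
  for (x in c(10, 20, 30)) {
    sl <- vol$data[x, , ]
    peak <- which(sl == max(sl), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - c(8, 8))), 1)
  }
})

test_that("z drift imposes the programmed per-slice intensity profile", {
  labels <- array(1L, c(20, 20, 40))
  mask <- label_mask(labels, pitch = 2)
  net <- skeleton_graph(data.frame(id = 1:2, x = c(20, 20), y = 20,
                                   z = c(4, 76)),
                        data.frame(id = 1, node_a = 1, node_b = 2))
  v0 <- render_tomogram(net, mask, psf_sigma = 0, noise_sd = 0,
                        z_drift_amplitude = 0, seed = 1)
  v1 <- render_tomogram(net, mask, psf_sigma = 0, noise_sd = 0,
                        z_drift_amplitude = 0.2, seed = 1, drift_period = 100)
  dz <- apply(v1$data - v0$data, 3, mean)
  zs <- (seq_len(40) - 0.5) * 2
  expect_equal(dz, 0.2 * sin(2 * pi * zs / 100), tolerance = 1e-9)
})

test_that("two parallel tubes 20 nm apart are recovered as 2 filaments", {
  labels <- array(1L, c(40, 25, 15))
  mask <- label_mask(labels, pitch = 2)
  net <- skeleton_graph(
    data.frame(id = 1:4, x = c(6, 74, 6, 74), y = c(15, 15, 35, 35),
               z = 15),
    data.frame(id = 1:2, node_a = c(1, 3), node_b = c(2, 4)))
  attr(net, "spec") <- spine_phantom_spec()
  vol <- render_tomogram(net, mask, psf_sigma = 2, noise_sd = 0,
                         z_drift_amplitude = 0, seed = 1)
  sm <- gaussian_smooth(mask_intracellular(vol, mask), 2)
  b <- local_threshold_binarize(sm, 20, 0.1)
  sk <- topological_thinning(b, protect_faces = FALSE)
  g <- build_graph(prune_stubs(sk, 4))
  expect_equal(graph_components(g), 2)
  expect_equal(graph_cycles(g), 0)
})
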
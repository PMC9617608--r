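# End-to-end analysis pipeline: volume + mask -> report bundle of tables.

#' Run the full analysis pipeline
#'
#' Sequences the stages: cytosol masking, Gaussian smoothing,
#' local-threshold binarization, distance transform, topology-preserving
#' thinning, stub pruning, graph conversion, then every statistics module
#' (branch lengths/tortuosity, node ranks and densities, branching angles,
#' orientations, distance profiles, branch-end clustering, elementary loops,
#' MST pruning). Deterministic given `config$rng_seed`.
#'
#' @param config an [analysis_config].
#' @param volume a [volume_grid]; negated on entry when
#'   `config$polarity == "luminance"`.
#' @param mask a [label_mask].
#' @return a named list of data.frames (`summary`, `nodes`, `branches`,
#'   `rank_distribution`, `node_density`, `angles`, `orientations`,
#'   `tortuosity_profile`, `orientation_profile`, `end_density_profile`,
#'   `rank3_density_profile`, `loops`, `prune`), plus `graph`, `pruned_graph`
#'   and `clustering` (list).
#' @export
run_pipeline <- function(config, volume, mask) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(volume, "volume_grid"), inherits(mask, "label_mask"))
  if (!any(cytosol_mask(mask))) stop("mask contains no cytosol voxels")
  set.seed(config$rng_seed)
  v <- volume
  if (config$polarity == "luminance")
    v <- volume_grid(-v$data, v$pitch, v$origin)

  masked <- mask_intracellular(v, mask)
  sm <- gaussian_smooth(masked, config$sigma_smooth)
  b <- local_threshold_binarize(sm, config$window_size, config$k,
                                form = config$threshold_form)
  if (!any(b$foreground)) stop("binarization produced an empty foreground")
  dt <- distance_transform_binary(b)
  sk <- topological_thinning(b, dt = dt)
  sk <- prune_stubs(sk, config$stub_min)
  g <- build_graph(sk, mask)

  field <- boundary_distance_field(mask)
  ok <- !g$branches$excluded
  br_ok <- g$branches[ok, , drop = FALSE]
  br_com <- do.call(rbind, lapply(g$polylines[ok], colMeans))

  ranks <- node_rank_distribution(g, by_domain = TRUE)
  dens <- node_density(g, mask)
  angles <- branching_angles_rank3(g, include_excluded = FALSE)
  orients <- branch_orientations(g, field)
  volfrac <- cytoskeleton_volume_fraction(g, mask, config$sigma_vol)

  tort_prof <- if (nrow(br_ok))
    profile_vs_distance(br_ok$tortuosity, br_com, field,
                        bin = config$profile_bin) else NULL
  orient_prof <- if (nrow(orients))
    profile_vs_distance(orients$orientation_deg,
                        as.matrix(br_com), field,
                        bin = config$profile_bin) else NULL
  endpts <- as.matrix(g$nodes[g$nodes$rank == 1, c("x", "y", "z")])
  end_prof <- if (nrow(endpts))
    profile_vs_distance(NULL, endpts, field, bin = config$profile_bin,
                        density = TRUE, mask = mask) else NULL
  r3pts <- as.matrix(g$nodes[g$nodes$rank == 3, c("x", "y", "z")])
  r3_prof <- if (nrow(r3pts))
    profile_vs_distance(NULL, r3pts, field, bin = config$profile_bin,
                        density = TRUE, mask = mask) else NULL

  clust <- branch_end_clustering_test(g, field, mask,
                                      shell = config$shell_width,
                                      seed = config$rng_seed)
  loops <- elementary_loops(g)
  loops <- loop_planarity_table(loops, g)

  pruned <- merge_rank2_nodes(minimum_spanning_tree_prune(g))
  prune_tab <- prune_stats(g, pruned, mask, config$sigma_vol)

  summary <- data.frame(
    cytosol_volume_um3 = cytosol_volume(mask) / 1e9,
    neck_width_nm = neck_width_estimate(mask),
    n_nodes = n_nodes(g), n_branches = n_branches(g),
    mean_branch_length_nm = if (nrow(br_ok)) mean(br_ok$arc_length) else NA,
    mean_tortuosity = if (nrow(br_ok))
      mean(br_ok$tortuosity, na.rm = TRUE) else NA,
    mean_orientation_deg = mean(orients$orientation_deg, na.rm = TRUE),
    junction_density_per_um3 = dens$density_per_um3[1],
    volume_fraction = volfrac$fraction[1],
    mean_loop_length_nm = if (nrow(loops)) mean(loops$circumference) else NA,
    mean_loop_nodes = if (nrow(loops)) mean(loops$node_count) else NA)

  list(summary = summary,
       nodes = g$nodes, branches = g$branches,
       rank_distribution = ranks, node_density = dens,
       volume_fraction = volfrac, angles = angles, orientations = orients,
       tortuosity_profile = tort_prof, orientation_profile = orient_prof,
       end_density_profile = end_prof, rank3_density_profile = r3_prof,
       clustering = clust, loops = loops, prune = prune_tab,
       graph = g, pruned_graph = pruned)
}

#' Write a report bundle to CSV tables
#'
#' Every data.frame in the bundle becomes `<name>.csv` in `dir`; the graphs
#' are written as GraphML. Output is byte-identical across runs with the
#' same seed.
#'
#' @param bundle result of [run_pipeline].
#' @param dir output directory (created if needed).
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x)) {
      attr(x, "members") <- NULL
      attr(x, "node_members") <- NULL
      write.csv(format(x, digits = 10), file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    } else if (inherits(x, "skeleton_graph")) {
      export_graph(x, file.path(dir, paste0(nm, ".graphml")))
    }
  }
  invisible(dir)
}
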
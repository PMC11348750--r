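#' Pipeline configuration
#'
#' All tunable parameters of the detection pipeline, with the defaults used
#' throughout: in-stem thickness multiplier 1.2, RDP tolerance 3 voxels,
#' score clamp 10 voxels, voxel pitch 0.44 mm, mean-shift bandwidth 10 mm,
#' density-profile bin width 2 mm, soil-line sigma factor 2, automatic
#' soil-core radius.
#'
#' @param stem_multiplier in-stem thickness multiplier.
#' @param rdp_epsilon_voxels RDP tolerance in voxels.
#' @param clamp_voxels score clamp in voxels.
#' @param voxel_pitch_mm fallback voxel pitch when the skeleton lacks one.
#' @param bandwidth_mm mean-shift bandwidth (mm along the stem).
#' @param bin_width_mm depth-profile bin width (mm).
#' @param sigma_factor soil line = b - sigma_factor * c.
#' @param rld_radius `"auto"` or a radius in cm.
#' @param seed RNG seed recorded in run summaries.
#' @return list of class `run_config`.
#' @export
run_config <- function(stem_multiplier = 1.2, rdp_epsilon_voxels = 3,
                       clamp_voxels = 10, voxel_pitch_mm = 0.44,
                       bandwidth_mm = 10, bin_width_mm = 2,
                       sigma_factor = 2, rld_radius = "auto", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(stem_multiplier > 0, rdp_epsilon_voxels > 0, clamp_voxels > 0,
            voxel_pitch_mm > 0, bandwidth_mm > 0, bin_width_mm > 0,
            sigma_factor >= 0)
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "rootwhorl_stage_error")) stop(e)
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("rootwhorl_stage_error", class(e))))
  })
}

#' Run the whole detection pipeline in memory
#'
#' Stem classification, candidate-path search, scoring, per-boundary-edge
#' deduplication, persistence clustering into whorls, false-connection
#' pruning, cycle breaking, hierarchy labeling, soil-line detection, and
#' trait computation.
#'
#' @param skel a [skeleton()].
#' @param stem a [stem_path()].
#' @param config a [run_config()].
#' @return list with `classification`, `paths` (deduplicated candidates),
#'   `whorls`, `ladder`, `pruned` / `tree` skeletons, `labeling`,
#'   `profile`, `fit`, `soil_depth`, `whorl_indices`, `locations`,
#'   `internodes`, `whorl_traits`, `aggregates`, `rld`.
#' @export
run_crown <- function(skel, stem, config = run_config()) {
  pitch <- skel$voxel_pitch %||% config$voxel_pitch_mm
  cls <- stage("stem classification",
               classify_stem(skel, stem, config$stem_multiplier))
  paths <- stage("candidate paths", find_candidate_paths(
    skel, stem, cls, epsilon_mm = config$rdp_epsilon_voxels * pitch,
    clamp_voxels = config$clamp_voxels))
  paths <- stage("dedup", dedup_by_boundary_edge(paths))
  if (!length(paths))
    rw_error("no candidate paths found", "no_paths")
  cw <- stage("whorl clustering",
              cluster_whorls(paths, stem, config$bandwidth_mm))
  whorls <- cw$whorls
  nodal <- paths[sort(unique(unlist(lapply(whorls, `[[`, "members"))))]
  pruned <- stage("false-connection pruning",
                  prune_false_connections(skel, stem, nodal))
  tree <- stage("cycle breaking", break_cycles(pruned, stem))
  labeling <- stage("hierarchy labeling",
                    label_hierarchy(tree, stem, nodal))
  profile <- stage("density profile", lateral_density_profile(
    labeling, tree, stem, config$bin_width_mm))
  fit <- tryCatch(fit_gaussian(profile), rootwhorl_error = function(e) NULL)
  soil_depth <- if (!is.null(fit))
    soil_line_depth(fit, config$sigma_factor) else NA_real_
  idx <- if (!is.na(soil_depth))
    soil_relative_indexing(vapply(whorls, `[[`, 0, "location_depth"),
                           soil_depth) else rep(NA_integer_, length(whorls))
  li <- whorl_locations_and_internodes(whorls)
  wt <- stage("whorl traits", per_whorl_traits(labeling, tree, whorls, paths))
  agg <- if (!anyNA(idx) && nrow(wt))
    above_below_aggregates(wt, idx) else data.frame()
  rld <- if (!is.na(soil_depth))
    stage("root length density", root_length_density(
      labeling, tree, stem, soil_depth, config$rld_radius)) else NULL
  list(classification = cls, paths = paths, whorls = whorls,
       ladder = cw$ladder, pruned = pruned, tree = tree,
       labeling = labeling, profile = profile, fit = fit,
       soil_depth = soil_depth, whorl_indices = idx,
       locations = li$locations, internodes = li$internodes,
       whorl_traits = wt, aggregates = agg, rld = rld)
}

#' Run the pipeline on a skeleton file and write artifacts
#'
#' Writes `whorls.csv`, `candidate_paths.csv`, `traits.csv`,
#' `aggregates.csv`, `profile.csv`, `rld.csv`, `skeleton_labeled.txt`
#' (text dialect plus `label` lines), `run_log.txt` and `summary.json`
#' into `out_dir`.
#'
#' @param config a [run_config()].
#' @param skeleton_in input skeleton file (text or PLY dialect).
#' @param out_dir output directory (created if missing).
#' @param flip_stem reverse the stored stem orientation on read.
#' @return The [run_crown()] result, invisibly.
#' @export
run_pipeline <- function(config, skeleton_in, out_dir, flip_stem = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- stage("read", read_skeleton(skeleton_in, flip_stem = flip_stem))
  res <- run_crown(inp$skeleton, inp$stem, config)
  whorls_df <- data.frame(
    index = res$whorl_indices,
    location_arc_mm = vapply(res$whorls, `[[`, 0, "location_arc"),
    location_depth_mm = vapply(res$whorls, `[[`, 0, "location_depth"),
    n_nodal_roots = vapply(res$whorls, `[[`, 0, "n_roots"),
    min_member_arc_mm = vapply(res$whorls, function(w) w$arc_range[1L], 0),
    max_member_arc_mm = vapply(res$whorls, function(w) w$arc_range[2L], 0))
  utils::write.csv(whorls_df, file.path(out_dir, "whorls.csv"),
                   row.names = FALSE)
  member_of <- rep(NA_integer_, length(res$paths))
  for (w in seq_along(res$whorls))
    member_of[res$whorls[[w]]$members] <- w
  paths_df <- data.frame(
    path = seq_along(res$paths),
    start_vertex = vapply(res$paths, `[[`, 0L, "start_vertex"),
    start_arc_mm = vapply(res$paths, `[[`, 0, "start_arc"),
    turning_angle_rad = vapply(res$paths, `[[`, 0, "turning_angle"),
    score = vapply(res$paths, `[[`, 0, "score"),
    whorl = member_of)
  utils::write.csv(paths_df, file.path(out_dir, "candidate_paths.csv"),
                   row.names = FALSE)
  utils::write.csv(res$whorl_traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(res$aggregates, file.path(out_dir, "aggregates.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(depth_mm = res$profile$centers,
                              lateral_length_mm = res$profile$values),
                   file.path(out_dir, "profile.csv"), row.names = FALSE)
  if (!is.null(res$rld))
    utils::write.csv(res$rld$bins, file.path(out_dir, "rld.csv"),
                     row.names = FALSE)
  keys <- edge_key(res$tree$edges$v1, res$tree$edges$v2)
  write_skeleton(res$tree, inp$stem,
                 file.path(out_dir, "skeleton_labeled.txt"),
                 edge_labels = ifelse(is.na(res$labeling$edge_label[keys]),
                                      -1L, res$labeling$edge_label[keys]))
  removed_prune <- attr(res$pruned, "removed_edges")
  removed_mst <- attr(res$tree, "removed_edges")
  log_lines <- c(
    sprintf("input: %s", skeleton_in),
    sprintf("candidate paths (deduplicated): %d", length(res$paths)),
    sprintf("pruned false-connection edge: %d-%d",
            removed_prune$v1, removed_prune$v2),
    sprintf("cycle-break removed edge: %d-%d",
            removed_mst$v1, removed_mst$v2),
    sprintf("delta=%.6f n_paths=%d n_clusters=%d selected=%s sig=%s",
            res$ladder$delta, res$ladder$n_paths, res$ladder$n_clusters,
            res$ladder$selected, res$ladder$signature))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  summary <- list(
    config = unclass(config),
    n_candidate_paths = length(res$paths),
    n_whorls = length(res$whorls),
    whorl_locations_mm = res$locations,
    internode_distances_mm = res$internodes,
    whorl_indices = res$whorl_indices,
    soil_depth_mm = res$soil_depth,
    gaussian_fit = if (!is.null(res$fit))
      res$fit[c("a", "b", "c", "rss")] else NULL,
    rld_radius_cm = if (!is.null(res$rld)) res$rld$radius_cm else NULL,
    n_edges_pruned = nrow(removed_prune),
    n_edges_cycle_broken = nrow(removed_mst))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}
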
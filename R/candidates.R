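#' Find candidate nodal-root paths
#'
#' For each junction vertex on the stem path (skeleton degree >= 3), the
#' shortest skeleton paths (edge weight = Euclidean length) to every inside
#' vertex incident to a stem-boundary edge are computed with Dijkstra's
#' algorithm.  Stem-path edges and edges with both endpoints outside the
#' stem are unusable (infinite weight, implemented by omission).  Each found
#' path is extended by its boundary edge, unless that edge is already the
#' last path edge.  Paths whose simplified polyline has fewer than three
#' distinct points are discarded with a warning.
#'
#' @param skel a [skeleton()].
#' @param stem a [stem_path()].
#' @param classification result of [classify_stem()].
#' @param epsilon_mm RDP simplification tolerance; default 3 voxels times
#'   the skeleton voxel pitch (1.32 mm at pitch 0.44 mm).
#' @param clamp_voxels clamp of the turning-point-to-stem-surface distance
#'   in the score, in voxels (default 10, i.e. 4.4 mm at pitch 0.44 mm).
#' @return List of `candidate_path` objects, each with fields
#'   `start_vertex`, `vertex_ids`, `boundary_edge` (c(inside, outside)),
#'   `polyline`, `simplified`, `turning_point`, `turning_angle`, `score`,
#'   `start_arc`, `length_mm`.
#' @export
find_candidate_paths <- function(skel, stem, classification,
                                 epsilon_mm = 3 * skel$voxel_pitch,
                                 clamp_voxels = 10) {
  bnd <- classification$boundary_edges
  junctions <- classification$junctions_on_stem
  if (nrow(bnd) == 0L || length(junctions) == 0L) return(list())
  inside <- classification$inside
  stem_keys <- edge_key(stem$vertex_ids[-length(stem$vertex_ids)],
                        stem$vertex_ids[-1L])
  e <- skel$edges
  keys <- edge_key(e$v1, e$v2)
  out1 <- !inside[as.character(e$v1)]
  out2 <- !inside[as.character(e$v2)]
  usable <- !(keys %in% stem_keys) & !(out1 & out2)
  g <- skeleton_igraph(skel, e[usable, , drop = FALSE])
  # one target per boundary edge: its inside endpoint
  bnd$outside_vertex <- ifelse(bnd$inside_vertex == bnd$v1, bnd$v2, bnd$v1)
  targets <- unique(bnd$inside_vertex)
  paths <- list()
  for (v in junctions) {
    vs <- as.character(v)
    d <- suppressWarnings(
      igraph::distances(g, v = vs, to = as.character(targets)))[1L, ]
    reach <- targets[is.finite(d)]
    if (!length(reach)) next
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = vs, to = as.character(reach),
                             output = "vpath"))$vpath
    for (k in seq_along(reach)) {
      ids <- as.integer(igraph::as_ids(sp[[k]]))
      rows <- which(bnd$inside_vertex == reach[k])
      for (r in rows) {
        out_v <- bnd$outside_vertex[r]
        # extend by the boundary edge, unless the path already arrived at
        # the inside endpoint through that very edge
        nlast <- length(ids)
        already <- nlast >= 2L && ids[nlast - 1L] == out_v
        full <- if (already) ids else c(ids, out_v)
        if (length(full) < 2L) next
        paths[[length(paths) + 1L]] <- list(
          start_vertex = v,
          vertex_ids = full,
          boundary_edge = c(reach[k], out_v))
      }
    }
  }
  finalize_candidates(paths, skel, stem, epsilon_mm, clamp_voxels)
}

# Simplify, measure, and score raw candidate paths; drop degenerate ones.
finalize_candidates <- function(paths, skel, stem, epsilon_mm, clamp_voxels) {
  out <- list()
  dropped <- 0L
  for (p in paths) {
    poly <- vertex_positions(skel, p$vertex_ids)
    simp <- simplify_candidate(poly, epsilon_mm)
    if (nrow(unique(simp)) < 3L) { dropped <- dropped + 1L; next }
    tp <- turning_point(simp)
    start_idx <- match(p$start_vertex, stem$vertex_ids)
    r_v <- stem$thickness[start_idx]
    v_pos <- stem$positions[start_idx, ]
    p$polyline <- poly
    p$simplified <- simp
    p$turning_point <- tp$point
    p$turning_angle <- tp$angle
    p$score <- whorl_score(tp$angle, vec_norm(v_pos - tp$point), r_v,
                           pitch = skel$voxel_pitch,
                           clamp_voxels = clamp_voxels)
    p$start_arc <- stem$arc_lengths[start_idx]
    p$length_mm <- path_length(poly)
    class(p) <- "candidate_path"
    out[[length(out) + 1L]] <- p
  }
  if (dropped > 0L)
    warning(sprintf("discarded %d candidate path(s) with < 3 distinct points after simplification",
                    dropped), call. = FALSE)
  out
}

#' Ramer-Douglas-Peucker simplification with a forced first split
#'
#' Standard RDP, except the first split (inserting the input point farthest
#' from the end-to-end segment) is always performed, so the output has at
#' least three points whenever the input does.  Every input point lies
#' within `epsilon_mm` of the output polyline.
#'
#' @param points n x 3 matrix, n >= 2.
#' @param epsilon_mm distance tolerance in mm (> 0).
#' @return m x 3 matrix, a subset of the input points in order.
#' @export
simplify_candidate <- function(points, epsilon_mm) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) rw_error("polyline needs >= 2 points", "polyline_invalid")
  stopifnot(epsilon_mm > 0)
  n <- nrow(points)
  if (n == 2L) return(points)
  d <- point_segment_distance(points[2:(n - 1L), , drop = FALSE],
                              points[1L, ], points[n, ])
  split <- which.max(d) + 1L  # ties: smallest index
  keep <- sort(unique(c(1L, split, n,
                        rdp_keep(points, 1L, split, epsilon_mm),
                        rdp_keep(points, split, n, epsilon_mm))))
  points[keep, , drop = FALSE]
}

# Classical recursive RDP between indices i..j; returns kept interior indices.
rdp_keep <- function(points, i, j, eps) {
  if (j - i < 2L) return(integer())
  d <- point_segment_distance(points[(i + 1L):(j - 1L), , drop = FALSE],
                              points[i, ], points[j, ])
  mx <- which.max(d)
  if (d[mx] <= eps) return(integer())
  split <- i + mx
  c(split, rdp_keep(points, i, split, eps), rdp_keep(points, split, j, eps))
}

#' Turning point of a simplified path
#'
#' The interior vertex with the largest turning angle, where the turning
#' angle is the angle between the incoming and outgoing segment directions
#' (0 = straight, pi = full reversal).  Ties are broken toward the smallest
#' index (closest to the stem end).
#'
#' @param points m x 3 matrix with m >= 3.
#' @return list with `point` (3-vector), `angle` (radians), `index`.
#' @export
turning_point <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) rw_error("turning point needs >= 3 points", "polyline_invalid")
  ang <- vapply(2:(n - 1L), function(i)
    angle_between(points[i, ] - points[i - 1L, ],
                  points[i + 1L, ] - points[i, ]), 0)
  i <- which.max(ang)  # first maximum = smallest index
  list(point = points[i + 1L, ], angle = ang[i], index = i + 1L)
}

#' Candidate-path score
#'
#' S = exp(-2 a / pi - (10 - clamp(d, 0, 10)) / 10) where a is the turning
#' angle (radians) and d = (|v - v_P| - r_v) / pitch is the distance from
#' the turning point v_P to the stem surface at the start vertex v,
#' expressed in voxels and clamped to [0, 10].  The score is close to 1 for
#' gently bending paths that turn far from the stem, and bounded below by
#' exp(-3).
#'
#' @param turning_angle radians in `[0, pi]`.
#' @param dist_mm Euclidean distance |v - v_P| in mm.
#' @param r_v stem thickness at the start vertex, mm.
#' @param pitch voxel pitch, mm.
#' @param clamp_voxels clamp bound in voxels (default 10).
#' @return score in `[exp(-3), 1]`.
#' @export
whorl_score <- function(turning_angle, dist_mm, r_v, pitch = 0.44,
                        clamp_voxels = 10) {
  d_vox <- (dist_mm - r_v) / pitch
  cl <- clamp(d_vox, 0, clamp_voxels)
  exp(-2 * turning_angle / pi - (clamp_voxels - cl) / clamp_voxels)
}

#' Score a candidate path against a stem
#'
#' @param cand a `candidate_path` (see [find_candidate_paths()]).
#' @param stem the [stem_path()] it starts on.
#' @param clamp_voxels clamp bound in voxels (default 10).
#' @param pitch voxel pitch in mm.
#' @return numeric score.
#' @export
score_path <- function(cand, stem, clamp_voxels = 10, pitch = 0.44) {
  i <- match(cand$start_vertex, stem$vertex_ids)
  whorl_score(cand$turning_angle,
              vec_norm(stem$positions[i, ] - cand$turning_point),
              stem$thickness[i], pitch = pitch, clamp_voxels = clamp_voxels)
}

#' Keep one candidate path per boundary edge
#'
#' Multiple junctions can reach the same stem-boundary edge; only the
#' highest-scoring path containing that edge is kept.  Ties go to the
#' shorter path, then to the lexicographically smallest vertex-id sequence.
#'
#' @param paths list of `candidate_path`s with scores computed.
#' @return Filtered list, one path per boundary edge.
#' @export
dedup_by_boundary_edge <- function(paths) {
  if (!length(paths)) return(paths)
  keyf <- vapply(paths, function(p)
    edge_key(p$boundary_edge[1L], p$boundary_edge[2L]), "")
  picked <- vapply(split(seq_along(paths), keyf), function(idx) {
    if (length(idx) == 1L) return(idx)
    sc <- vapply(paths[idx], `[[`, 0, "score")
    best <- idx[sc == max(sc)]
    if (length(best) > 1L) {
      len <- vapply(paths[best], `[[`, 0, "length_mm")
      best <- best[len == min(len)]
    }
    if (length(best) > 1L) {
      seqs <- vapply(paths[best], function(p)
        paste(formatC(p$vertex_ids, width = 9, flag = "0"), collapse = ","), "")
      best <- best[order(seqs)][1L]
    }
    best[1L]
  }, 0L)
  paths[sort(unname(picked))]
}
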
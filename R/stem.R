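#' In-stem test for skeleton vertices
#'
#' A vertex is inside the stem if its Euclidean distance to the nearest stem
#' path vertex v is no more than `multiplier` times the thickness r_v at
#' that vertex (inclusive comparison).
#'
#' @param skel a [skeleton()].
#' @param stem a [stem_path()].
#' @param multiplier stem thickness multiplier (default 1.2).
#' @return Object of class `stem_classification`: `inside` (logical, named
#'   by vertex id), `boundary_edges` (data.frame `v1`, `v2`,
#'   `inside_vertex`), `junctions_on_stem` (stem vertex ids with skeleton
#'   degree >= 3, in stem order), `multiplier`.
#' @export
classify_stem <- function(skel, stem, multiplier = 1.2) {
  pos <- vertex_positions(skel)
  spos <- stem$positions
  # nearest stem vertex by exhaustive search; skeletons are small
  d2 <- outer(rowSums(pos^2), rep(1, nrow(spos))) -
    2 * pos %*% t(spos) + outer(rep(1, nrow(pos)), rowSums(spos^2))
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(pos)), nearest)])
  inside <- dist <= multiplier * stem$thickness[nearest]
  names(inside) <- as.character(skel$vertices$id)
  e <- skel$edges
  boundary <- data.frame(v1 = integer(), v2 = integer(),
                         inside_vertex = integer())
  if (nrow(e)) {
    i1 <- inside[as.character(e$v1)]
    i2 <- inside[as.character(e$v2)]
    sel <- xor(i1, i2)
    boundary <- data.frame(v1 = e$v1[sel], v2 = e$v2[sel],
                           inside_vertex = ifelse(i1[sel], e$v1[sel],
                                                  e$v2[sel]))
  }
  deg <- vertex_degrees(skel)
  junctions <- stem$vertex_ids[deg[as.character(stem$vertex_ids)] >= 3L]
  structure(list(inside = inside, boundary_edges = boundary,
                 junctions_on_stem = junctions, multiplier = multiplier),
            class = "stem_classification")
}

#' Test whether single vertices lie inside the stem
#'
#' Convenience wrapper around the rule used by [classify_stem()].
#'
#' @param position 3-vector or n x 3 matrix (mm).
#' @param stem a [stem_path()].
#' @param multiplier stem thickness multiplier (default 1.2).
#' @return logical.
#' @export
is_inside_stem <- function(position, stem, multiplier = 1.2) {
  pos <- if (is.matrix(position)) position else matrix(position, 1L)
  spos <- stem$positions
  d2 <- outer(rowSums(pos^2), rep(1, nrow(spos))) -
    2 * pos %*% t(spos) + outer(rep(1, nrow(pos)), rowSums(spos^2))
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(pos)), nearest)])
  unname(dist <= multiplier * stem$thickness[nearest])
}

#' Stem-boundary edges
#'
#' Edges with exactly one endpoint inside the stem.
#'
#' @param skel a [skeleton()].
#' @param classification result of [classify_stem()].
#' @return data.frame `v1`, `v2`, `inside_vertex`.
#' @export
stem_boundary_edges <- function(skel, classification) {
  classification$boundary_edges
}

#' Arc-length position of a stem vertex
#'
#' @param stem a [stem_path()].
#' @param stem_vertex_id vertex id(s) on the stem path.
#' @return Cumulative arc length (mm) from the top vertex.
#' @export
arc_position <- function(stem, stem_vertex_id) {
  m <- match(stem_vertex_id, stem$vertex_ids)
  if (anyNA(m))
    rw_error("vertex id not on the stem path", "not_on_stem")
  stem$arc_lengths[m]
}

#' Fallback stem-path heuristic for synthetic skeletons
#'
#' Traces a maximal-thickness path from the topmost (largest z) vertex:
#' Dijkstra with edge weight length / mean endpoint thickness, keeping the
#' path to the reachable vertex that is deepest among those at least 40% as
#' thick as the top.  Intended only for inputs lacking a stem record; real
#' pipelines receive the stem path from skeletonization.
#'
#' @param skel a [skeleton()].
#' @return a [stem_path()].
#' @export
infer_stem_path <- function(skel) {
  g <- skeleton_igraph(skel)
  th <- vertex_thickness(skel)
  ends <- igraph::ends(g, igraph::E(g))
  idx <- vertex_index(skel)
  w <- igraph::E(g)$weight /
    ((th[idx[ends[, 1L]]] + th[idx[ends[, 2L]]]) / 2)
  top <- skel$vertices$id[which.max(skel$vertices$z)]
  d <- igraph::distances(g, v = as.character(top), weights = w)[1L, ]
  cand <- names(d)[is.finite(d)]
  thick <- cand[th[idx[cand]] >= 0.4 * max(th[idx[cand]])]
  zs <- skel$vertices$z[idx[thick]]
  bottom <- thick[which.min(zs)]
  p <- igraph::shortest_paths(g, from = as.character(top), to = bottom,
                              weights = w)$vpath[[1L]]
  stem_path(skel, as.integer(igraph::as_ids(p)))
}

# igraph view of a skeleton; vertex names are ids, edge weight = length.
skeleton_igraph <- function(skel, edges = skel$edges) {
  idx <- vertex_index(skel)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$v1), to = as.character(edges$v2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(skel$vertices$id)))
  if (nrow(edges)) {
    p1 <- vertex_positions(skel, edges$v1)
    p2 <- vertex_positions(skel, edges$v2)
    igraph::E(g)$weight <- sqrt(rowSums((p1 - p2)^2))
  }
  g
}
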
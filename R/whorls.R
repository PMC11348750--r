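#' One-dimensional flat-kernel mean shift
#'
#' Each point is shifted to the mean of the points within `bandwidth` of it
#' until convergence; converged modes closer than `bandwidth / 2` are
#' merged.  Fully deterministic.
#'
#' @param x numeric vector.
#' @param bandwidth window half-width (mm here).
#' @return list with `cluster` (integer assignment, clusters ordered by
#'   ascending center) and `centers`.
#' @export
mean_shift_1d <- function(x, bandwidth, tol = 1e-9, max_iter = 200L) {
  stopifnot(length(x) > 0L, bandwidth > 0)
  modes <- vapply(x, function(y) {
    for (i in seq_len(max_iter)) {
      ny <- mean(x[abs(x - y) <= bandwidth])
      if (abs(ny - y) < tol) { y <- ny; break }
      y <- ny
    }
    y
  }, 0)
  o <- order(modes, x)
  sm <- modes[o]
  grp <- cumsum(c(1, diff(sm) >= bandwidth / 2))
  centers <- as.numeric(tapply(sm, grp, mean))
  cluster <- integer(length(x))
  cluster[o] <- grp
  list(cluster = cluster, centers = centers)
}

# Signature of one clustering: number of clusters plus, per cluster
# (ordered by center), the identity of its lowest- and highest-arc members.
clustering_signature <- function(cluster, arcs, ids) {
  parts <- vapply(sort(unique(cluster)), function(k) {
    m <- which(cluster == k)
    lo <- m[order(arcs[m], ids[m])][1L]
    hi <- m[order(-arcs[m], ids[m])][1L]
    paste0(ids[lo], ":", ids[hi])
  }, "")
  paste(parts, collapse = "|")
}

#' Cluster candidate paths into whorls by threshold persistence
#'
#' Let Delta be the candidate-path scores sorted ascending.  For every
#' threshold delta in Delta, the start-arc positions of the paths scoring at
#' least delta are clustered with 1-D mean shift.  Two clusterings are the
#' same iff they have the same number of clusters and each matched cluster
#' shares the same lowest and highest member (by arc).  The clustering that
#' persists over the most consecutive thresholds is selected, ties going to
#' the run at larger thresholds.  Each selected cluster becomes a whorl;
#' its final membership is every candidate path (regardless of score) whose
#' start arc lies within the cluster's `[min, max]` member arc range.
#'
#' @param paths list of deduplicated `candidate_path`s.
#' @param stem the [stem_path()] (for whorl depths).
#' @param bandwidth_mm mean-shift bandwidth (default 10 mm).
#' @return list with `whorls` (list of `whorl` objects: `members`
#'   (path indices into `paths`), `location_arc`, `location_depth`,
#'   `arc_range`, `n_roots`) ordered young (top) to old, and `ladder`
#'   (data.frame `delta`, `n_paths`, `n_clusters`, `signature`, `selected`).
#' @export
cluster_whorls <- function(paths, stem, bandwidth_mm = 10) {
  if (!length(paths)) rw_error("no candidate paths to cluster", "no_paths")
  arcs <- vapply(paths, `[[`, 0, "start_arc")
  scores <- vapply(paths, `[[`, 0, "score")
  ids <- seq_along(paths)
  deltas <- sort(scores)
  sigs <- character(length(deltas))
  nclust <- integer(length(deltas))
  clusterings <- vector("list", length(deltas))
  for (j in seq_along(deltas)) {
    sel <- which(scores >= deltas[j])
    ms <- mean_shift_1d(arcs[sel], bandwidth_mm)
    clusterings[[j]] <- list(sel = sel, cluster = ms$cluster)
    nclust[j] <- length(ms$centers)
    sigs[j] <- clustering_signature(ms$cluster, arcs[sel], ids[sel])
  }
  runs <- rle(sigs)
  best <- max(runs$lengths)
  pick <- max(which(runs$lengths == best))  # tie: larger thresholds
  last <- cumsum(runs$lengths)[pick]
  chosen <- clusterings[[last]]
  run_idx <- (last - runs$lengths[pick] + 1L):last
  whorls <- lapply(sort(unique(chosen$cluster)), function(k) {
    mem <- chosen$sel[chosen$cluster == k]
    rng <- range(arcs[mem])
    members <- ids[arcs >= rng[1L] & arcs <= rng[2L]]
    loc <- mean(arcs[members])
    pos <- point_at_arc(stem$positions, stem$arc_lengths, loc)
    structure(list(members = members, location_arc = loc,
                   location_depth = depth_of(pos, stem$positions[1L, ]),
                   arc_range = rng, n_roots = length(members)),
              class = "whorl")
  })
  whorls <- whorls[order(vapply(whorls, `[[`, 0, "location_arc"))]
  ladder <- data.frame(delta = deltas,
                       n_paths = vapply(clusterings, function(cl)
                         length(cl$sel), 0L),
                       n_clusters = nclust, signature = sigs,
                       selected = seq_along(deltas) %in% run_idx)
  list(whorls = whorls, ladder = ladder)
}

#' Remove false connections from the skeleton
#'
#' Starting at every stem junction, each incident non-stem edge that is not
#' used by any nodal candidate path (the final whorl members) begins a
#' trace through degree-2 vertices until the next junction (degree >= 3) or
#' a leaf.  Traced edges and interior vertices are removed; the two end
#' vertices are kept.  A trace that runs into a nodal-path edge is aborted
#' so nodal paths are never damaged; stem-path edges are never removed.
#'
#' @param skel a [skeleton()].
#' @param stem a [stem_path()].
#' @param nodal_paths list of `candidate_path`s representing nodal roots
#'   (the whorl members).
#' @return Pruned [skeleton()]; removed edges are recorded in the
#'   `"removed_edges"` attribute (data.frame `v1`, `v2`).
#' @export
prune_false_connections <- function(skel, stem, nodal_paths) {
  nodal_keys <- unique(unlist(lapply(nodal_paths, function(p)
    edge_key(p$vertex_ids[-length(p$vertex_ids)], p$vertex_ids[-1L]))))
  stem_keys <- edge_key(stem$vertex_ids[-length(stem$vertex_ids)],
                        stem$vertex_ids[-1L])
  adj <- adjacency_list(skel)
  deg <- vertex_degrees(skel)
  junctions <- stem$vertex_ids[deg[as.character(stem$vertex_ids)] >= 3L]
  drop_edges <- character()
  drop_vertices <- integer()
  for (j in junctions) {
    for (u in adj[[as.character(j)]]) {
      k0 <- edge_key(j, u)
      if (k0 %in% stem_keys || k0 %in% nodal_keys) next
      if (k0 %in% drop_edges) next
      trace_e <- k0
      trace_v <- integer()
      prev <- j; cur <- u
      ok <- TRUE
      while (deg[as.character(cur)] == 2L) {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        if (length(nxt) != 1L) break
        ke <- edge_key(cur, nxt)
        if (ke %in% nodal_keys || ke %in% stem_keys) { ok <- FALSE; break }
        trace_v <- c(trace_v, cur)
        trace_e <- c(trace_e, ke)
        prev <- cur; cur <- nxt
      }
      if (!ok) next
      if (deg[as.character(cur)] == 2L) next  # aborted mid-way
      drop_edges <- c(drop_edges, trace_e)
      drop_vertices <- c(drop_vertices, trace_v)
    }
  }
  keys <- edge_key(skel$edges$v1, skel$edges$v2)
  removed <- skel$edges[keys %in% drop_edges, , drop = FALSE]
  keep_e <- skel$edges[!(keys %in% drop_edges), , drop = FALSE]
  keep_v <- skel$vertices[!(skel$vertices$id %in% drop_vertices), ,
                          drop = FALSE]
  out <- skeleton(keep_v, keep_e, voxel_pitch = skel$voxel_pitch)
  attr(out, "removed_edges") <- removed
  out
}
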
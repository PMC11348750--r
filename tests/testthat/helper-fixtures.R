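# Fixtures and independent oracles used across the suite.

# Straight vertical stem of n vertices, spacing mm apart, uniform thickness.
straight_stem_skeleton <- function(n = 5, spacing = 2, thickness = 2,
                                   extra_vertices = NULL,
                                   extra_edges = NULL) {
  v <- data.frame(id = seq_len(n), x = 0, y = 0,
                  z = -(seq_len(n) - 1) * spacing, thickness = thickness)
  e <- data.frame(v1 = seq_len(n - 1), v2 = 2:n)
  if (!is.null(extra_vertices)) v <- rbind(v, extra_vertices)
  if (!is.null(extra_edges)) e <- rbind(e, extra_edges)
  skel <- skeleton(v, e)
  list(skeleton = skel, stem = stem_path(skel, seq_len(n)))
}

# Y-shaped fixture: vertical stem, junction at vertex 2, a two-edge branch
# leaving the stem region and crossing the boundary at its last edge.
y_fixture <- function() {
  extra_v <- data.frame(id = 6:8,
                        x = c(1.5, 2.2, 6.0), y = 0,
                        z = c(-2.5, -3.5, -5.0),
                        thickness = c(1.2, 1.0, 0.8))
  extra_e <- data.frame(v1 = c(2, 6, 7), v2 = c(6, 7, 8))
  straight_stem_skeleton(5, spacing = 2, thickness = 2,
                         extra_vertices = extra_v, extra_edges = extra_e)
}

# Random small skeleton with a stem and random off-stem structure; at most
# max_n vertices.  Geometry is generic (no collinear degeneracies).
random_small_skeleton <- function(max_n = 12) {
  ns <- sample(3:5, 1)
  fix <- straight_stem_skeleton(ns, spacing = 2,
                                thickness = runif(1, 0.8, 2.5))
  v <- fix$skeleton$vertices
  e <- fix$skeleton$edges
  n_extra <- sample(0:(max_n - ns), 1)
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      id <- ns + k
      v <- rbind(v, data.frame(id = id, x = runif(1, -8, 8),
                               y = runif(1, -8, 8), z = runif(1, -10, 2),
                               thickness = runif(1, 0.4, 1.5)))
      e <- rbind(e, data.frame(v1 = sample(v$id[v$id < id], 1), v2 = id))
    }
    # a few extra edges can create cycles
    for (k in seq_len(sample(0:2, 1))) {
      pair <- sample(v$id, 2)
      key <- paste(min(pair), max(pair))
      have <- paste(e$v1, e$v2)
      if (!(key %in% have) && pair[1] != pair[2])
        e <- rbind(e, data.frame(v1 = min(pair), v2 = max(pair)))
    }
  }
  skel <- skeleton(v, e)
  list(skeleton = skel, stem = stem_path(skel, seq_len(ns)))
}

# Brute-force single-source shortest distances over an allowed edge list by
# exhaustive enumeration of simple paths (DFS).  Returns a named vector of
# minimal distances (Inf where unreachable).
bf_shortest_distances <- function(vertex_ids, edges, weights, from) {
  adj <- lapply(vertex_ids, function(v) {
    sel <- which(edges$v1 == v | edges$v2 == v)
    list(nbr = ifelse(edges$v1[sel] == v, edges$v2[sel], edges$v1[sel]),
         w = weights[sel])
  })
  names(adj) <- as.character(vertex_ids)
  best <- rep(Inf, length(vertex_ids))
  names(best) <- as.character(vertex_ids)
  visit <- function(v, dist, seen) {
    key <- as.character(v)
    if (dist < best[[key]]) best[[key]] <<- dist
    a <- adj[[key]]
    for (i in seq_along(a$nbr)) {
      u <- a$nbr[i]
      if (!(u %in% seen)) visit(u, dist + a$w[i], c(seen, u))
    }
  }
  visit(from, 0, from)
  best
}

# Allowed (non-infinite-weight) edges for candidate search: drop stem-path
# edges and edges with both endpoints outside the stem.
allowed_candidate_edges <- function(skel, stem, cls) {
  e <- skel$edges
  stem_keys <- paste(pmin(stem$vertex_ids[-length(stem$vertex_ids)],
                          stem$vertex_ids[-1]),
                     pmax(stem$vertex_ids[-length(stem$vertex_ids)],
                          stem$vertex_ids[-1]))
  keys <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
  out1 <- !cls$inside[as.character(e$v1)]
  out2 <- !cls$inside[as.character(e$v2)]
  e[!(keys %in% stem_keys) & !(out1 & out2), , drop = FALSE]
}

edge_lengths_of <- function(skel, e) {
  i1 <- match(e$v1, skel$vertices$id)
  i2 <- match(e$v2, skel$vertices$id)
  p1 <- as.matrix(skel$vertices[i1, c("x", "y", "z")])
  p2 <- as.matrix(skel$vertices[i2, c("x", "y", "z")])
  sqrt(rowSums((p1 - p2)^2))
}

random_polyline <- function(n = 10, scale = 10) {
  matrix(runif(3 * n, -scale, scale), ncol = 3)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal stand-in candidate path for clustering tests.
fake_path <- function(start_arc, score, id) {
  structure(list(start_vertex = id, vertex_ids = c(id, id + 1000L),
                 boundary_edge = c(id, id + 1000L), start_arc = start_arc,
                 score = score, length_mm = 1, turning_angle = 0,
                 turning_point = c(0, 0, 0)),
            class = "candidate_path")
}

# Independent persistence sweep: returns the signature of the clustering
# that persists longest (ties to larger thresholds) plus its run indices.
oracle_persistence <- function(arcs, scores, bandwidth) {
  deltas <- sort(scores)
  sig <- vapply(deltas, function(d) {
    sel <- which(scores >= d)
    ms <- mean_shift_1d(arcs[sel], bandwidth)
    parts <- vapply(sort(unique(ms$cluster)), function(k) {
      m <- sel[ms$cluster == k]
      lo <- m[order(arcs[m], m)][1]
      hi <- m[order(-arcs[m], m)][1]
      paste0(lo, ":", hi)
    }, "")
    paste(parts, collapse = "|")
  }, "")
  # manual run-length scan
  runs <- list(); start <- 1
  for (i in seq_along(sig)[-1]) {
    if (sig[i] != sig[start]) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      start <- i
    }
  }
  runs[[length(runs) + 1]] <- c(start, length(sig))
  lens <- vapply(runs, function(r) r[2] - r[1] + 1, 0)
  best <- runs[[max(which(lens == max(lens)))]]
  list(signature = sig[best[1]], run = best[1]:best[2], signatures = sig)
}

# A small, fast synthetic spec for smoke tests.
small_spec <- function(...) {
  synthetic_spec(n_whorls = 2L, internode_mm = c(35, 40),
                 stem_length_mm = 120, soil_depth_mm = 55,
                 nodal_per_whorl = c(5L, 7L), lateral_amplitude = 0.6,
                 lateral_sd_mm = 10, ...)
}
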
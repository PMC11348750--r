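#' Break cycles with a thickness-aware spanning tree
#'
#' Per connected component, keeps the spanning tree that maximizes retained
#' thickness: a minimum spanning tree on edge weight = -(mean endpoint
#' thickness), so the thinnest edges of each cycle are removed.  Stem-path
#' edges are always retained.
#'
#' @param skel a [skeleton()].
#' @param stem optional [stem_path()] whose edges must survive.
#' @return Acyclic [skeleton()] (per component, E = V - 1); removed edges in
#'   the `"removed_edges"` attribute.
#' @export
break_cycles <- function(skel, stem = NULL) {
  if (nrow(skel$edges) == 0L) {
    attr(skel, "removed_edges") <- skel$edges
    return(skel)
  }
  th <- vertex_thickness(skel)
  idx <- vertex_index(skel)
  w <- -(th[idx[as.character(skel$edges$v1)]] +
           th[idx[as.character(skel$edges$v2)]]) / 2
  if (!is.null(stem)) {
    stem_keys <- edge_key(stem$vertex_ids[-length(stem$vertex_ids)],
                          stem$vertex_ids[-1L])
    keys <- edge_key(skel$edges$v1, skel$edges$v2)
    w[keys %in% stem_keys] <- w[keys %in% stem_keys] - 1e6
  }
  g <- skeleton_igraph(skel)
  t <- igraph::mst(g, weights = w)
  kept <- igraph::ends(t, igraph::E(t))
  kept_keys <- edge_key(as.integer(kept[, 1L]), as.integer(kept[, 2L]))
  keys <- edge_key(skel$edges$v1, skel$edges$v2)
  removed <- skel$edges[!(keys %in% kept_keys), , drop = FALSE]
  out <- skeleton(skel$vertices, skel$edges[keys %in% kept_keys, ,
                                            drop = FALSE],
                  voxel_pitch = skel$voxel_pitch)
  attr(out, "removed_edges") <- removed
  out
}

#' Hierarchy labeling of an acyclic skeleton
#'
#' Stem-path edges are labeled 0.  Every branch leaving the stem starts a
#' level-1 branch.  Walking outward, at each junction the child whose
#' direction deviates least from the incoming direction continues the
#' current branch (same label); every other child starts a new branch with
#' label + 1.  Children much thinner than the thickest child (below
#' `thickness_ratio` of it) are excluded from continuation, so a thin
#' lateral cannot capture the axis of a thick nodal root even when it
#' happens to align better.  This rule is a declared simplification of
#' full thickness-driven hierarchy optimization.
#'
#' @param tree an acyclic [skeleton()] (see [break_cycles()]).
#' @param stem a [stem_path()].
#' @param nodal_paths optional list of nodal `candidate_path`s; used only to
#'   warn when a nodal edge is missing from the tree.
#' @param thickness_ratio children thinner than this fraction of the
#'   thickest child cannot continue the current branch (default 0.7).
#' @return Object of class `hierarchy_labeling`: `edge_label` (integer named
#'   by edge key), `branches` (list of `id`, `label`, `parent`, `vertices` —
#'   first vertex is the attachment on the parent), `edge_branch` (branch id
#'   named by edge key).
#' @export
label_hierarchy <- function(tree, stem, nodal_paths = NULL,
                            thickness_ratio = 0.7) {
  keys <- edge_key(tree$edges$v1, tree$edges$v2)
  stem_keys <- edge_key(stem$vertex_ids[-length(stem$vertex_ids)],
                        stem$vertex_ids[-1L])
  if (!is.null(nodal_paths)) {
    nodal_keys <- unique(unlist(lapply(nodal_paths, function(p)
      edge_key(p$vertex_ids[-length(p$vertex_ids)], p$vertex_ids[-1L]))))
    missing <- setdiff(nodal_keys, keys)
    if (length(missing))
      warning(sprintf("%d nodal path edge(s) missing from tree; relabeling from stem attachment",
                      length(missing)), call. = FALSE)
  }
  edge_label <- integer(length(keys)); names(edge_label) <- keys
  edge_label[] <- NA_integer_
  edge_label[stem_keys[stem_keys %in% keys]] <- 0L
  edge_branch <- integer(length(keys)); names(edge_branch) <- keys
  edge_branch[] <- NA_integer_
  edge_branch[stem_keys[stem_keys %in% keys]] <- 0L
  adj <- adjacency_list(tree)
  pos <- vertex_positions(tree)
  idx <- vertex_index(tree)
  branches <- list()
  # seeds: every non-stem edge incident to a stem vertex starts level 1
  queue <- list()
  for (s in stem$vertex_ids) {
    for (u in adj[[as.character(s)]]) {
      k <- edge_key(s, u)
      if (k %in% stem_keys) next
      queue[[length(queue) + 1L]] <- list(prev = s, cur = u, label = 1L,
                                          parent = 0L)
    }
  }
  qi <- 1L
  while (qi <= length(queue)) {
    job <- queue[[qi]]; qi <- qi + 1L
    bid <- length(branches) + 1L
    verts <- c(job$prev, job$cur)
    prev <- job$prev; cur <- job$cur
    edge_label[edge_key(prev, cur)] <- job$label
    edge_branch[edge_key(prev, cur)] <- bid
    repeat {
      children <- setdiff(adj[[as.character(cur)]], prev)
      if (!length(children)) break
      dir_in <- pos[idx[as.character(cur)], ] - pos[idx[as.character(prev)], ]
      angs <- vapply(children, function(w)
        angle_between(dir_in,
                      pos[idx[as.character(w)], ] -
                        pos[idx[as.character(cur)], ]), 0)
      th <- vertex_thickness(tree, children)
      eligible <- th >= thickness_ratio * max(th)
      cand <- children[eligible]
      cont <- cand[which.min(angs[eligible])]  # tie: smallest id
      for (w in setdiff(children, cont))
        queue[[length(queue) + 1L]] <- list(prev = cur, cur = w,
                                            label = job$label + 1L,
                                            parent = bid)
      edge_label[edge_key(cur, cont)] <- job$label
      edge_branch[edge_key(cur, cont)] <- bid
      verts <- c(verts, cont)
      prev <- cur; cur <- cont
    }
    branches[[bid]] <- list(id = bid, label = job$label,
                            parent = job$parent, vertices = verts)
  }
  structure(list(edge_label = edge_label, branches = branches,
                 edge_branch = edge_branch),
            class = "hierarchy_labeling")
}

#' @export
print.hierarchy_labeling <- function(x, ...) {
  tab <- table(x$edge_label, useNA = "ifany")
  cat("hierarchy labeling:", length(x$branches), "branches; edges per label:\n")
  print(tab)
  invisible(x)
}
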
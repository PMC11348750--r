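# A straight dummy stem long enough for arc interpolation in clustering.
dummy_stem <- function(length_mm = 200) {
  n <- length_mm / 2 + 1
  straight_stem_skeleton(n, spacing = 2, thickness = 2)$stem
}

test_that("1-D mean shift finds the obvious modes deterministically", {
  x <- c(10, 11, 12, 50, 51, 52)
  ms <- mean_shift_1d(x, 10)
  expect_equal(length(ms$centers), 2L)
  expect_equal(ms$cluster, c(1, 1, 1, 2, 2, 2))
  expect_identical(mean_shift_1d(x, 10), mean_shift_1d(x, 10))
  expect_equal(length(mean_shift_1d(x, 100)$centers), 1L)
})

test_that("identical paths collapse to one whorl persisting over all thresholds", {
  paths <- lapply(1:5, function(i) fake_path(40, 0.7, as.integer(i)))
  cw <- cluster_whorls(paths, dummy_stem(), 10)
  expect_length(cw$whorls, 1L)
  expect_true(all(cw$ladder$selected))
  expect_equal(cw$whorls[[1L]]$n_roots, 5L)
  expect_equal(cw$whorls[[1L]]$location_arc, 40)
})

test_that("a low-score outlier between two arc groups is excluded by persistence", {
  # arc-extreme members carry the high scores, so the two-cluster result
  # persists while interior members drop out; the outlier drops first
  mk <- function(arcs, scores, ids)
    lapply(seq_along(arcs), function(i)
      fake_path(arcs[i], scores[i], as.integer(ids[i])))
  paths <- c(mk(c(20, 21, 22, 23), c(0.60, 0.30, 0.35, 0.61), 1:4),
             mk(c(60, 61, 62, 63), c(0.62, 0.40, 0.45, 0.63), 5:8),
             mk(40, 0.12, 9))
  cw <- cluster_whorls(paths, dummy_stem(), 10)
  expect_length(cw$whorls, 2L)
  members <- unlist(lapply(cw$whorls, `[[`, "members"))
  expect_false(9L %in% members)            # the outlier path
  expect_setequal(members, 1:8)            # both groups complete
  expect_equal(cw$ladder$n_clusters[1L], 3L)
  expect_equal(cw$ladder$n_clusters[nrow(cw$ladder)], 1L)
  expect_equal(vapply(cw$whorls, `[[`, 0, "location_arc"), c(21.5, 61.5))
})

test_that("whorl membership spans all paths inside the member arc range", {
  paths <- c(
    lapply(1:3, function(i) fake_path(20 + i, 0.6, as.integer(i))),
    list(fake_path(22, 0.05, 9L)))  # low score but inside the range
  cw <- cluster_whorls(paths, dummy_stem(), 10)
  expect_length(cw$whorls, 1L)
  expect_true(4L %in% cw$whorls[[1L]]$members)
  expect_equal(cw$whorls[[1L]]$n_roots, 4L)
})

test_that("persistence selection equals an exhaustive threshold sweep", {
  set.seed(51)
  stem <- dummy_stem()
  for (i in 1:30) {
    n <- sample(4:20, 1)
    arcs <- runif(n, 0, 180)
    scores <- runif(n, exp(-3), 1)
    paths <- lapply(seq_len(n), function(j)
      fake_path(arcs[j], scores[j], as.integer(j)))
    cw <- cluster_whorls(paths, stem, 10)
    oracle <- oracle_persistence(arcs, scores, 10)
    expect_equal(which(cw$ladder$selected), oracle$run)
    expect_equal(cw$ladder$signature[cw$ladder$selected][1L],
                 oracle$signature)
  }
})

test_that("clustering is deterministic for fixed input", {
  set.seed(52)
  paths <- lapply(1:12, function(j)
    fake_path(runif(1, 0, 150), runif(1, 0.1, 1), as.integer(j)))
  a <- cluster_whorls(paths, dummy_stem(), 10)
  b <- cluster_whorls(paths, dummy_stem(), 10)
  expect_identical(a$ladder, b$ladder)
  expect_identical(lapply(a$whorls, `[[`, "members"),
                   lapply(b$whorls, `[[`, "members"))
  expect_error(cluster_whorls(list(), dummy_stem(), 10), class = "no_paths")
})

# Stem plus a nodal root (ids 8:12) and a clinging-style bridge (vertex 13)
# that re-attaches the root to a lower stem junction, creating a cycle.
bridge_fixture <- function() {
  extra_v <- data.frame(id = 8:13,
                        x = c(1.5, 4.0, 4.2, 4.3, 4.4, 1.4),
                        y = 0,
                        z = c(-2.2, -3.0, -5.0, -7.0, -9.0, -8.2),
                        thickness = c(1, 1, 1, 1, 1, 0.5))
  extra_e <- data.frame(v1 = c(2, 8, 9, 10, 11, 5, 13),
                        v2 = c(8, 9, 10, 11, 12, 13, 10))
  straight_stem_skeleton(7, spacing = 2, thickness = 1.5,
                         extra_vertices = extra_v, extra_edges = extra_e)
}

test_that("pruning removes a clinging bridge and reduces the cycle count", {
  fix <- bridge_fixture()
  cls <- classify_stem(fix$skeleton, fix$stem)
  paths <- dedup_by_boundary_edge(suppressWarnings(
    find_candidate_paths(fix$skeleton, fix$stem, cls)))
  cw <- cluster_whorls(paths, fix$stem, 10)
  nodal <- paths[unique(unlist(lapply(cw$whorls, `[[`, "members")))]
  euler <- function(s) nrow(s$edges) - nrow(s$vertices) +
    igraph::count_components(rootwhorl:::skeleton_igraph(s))
  expect_gte(euler(fix$skeleton), 1L)  # the bridge creates a cycle
  pruned <- prune_false_connections(fix$skeleton, fix$stem, nodal)
  expect_equal(euler(pruned), euler(fix$skeleton) - 1L)
  expect_false(13L %in% pruned$vertices$id)  # bridge interior gone
  # nodal path edges all survive
  keys <- rootwhorl:::edge_key(pruned$edges$v1, pruned$edges$v2)
  for (p in nodal) {
    used <- rootwhorl:::edge_key(p$vertex_ids[-length(p$vertex_ids)],
                                 p$vertex_ids[-1])
    expect_true(all(used %in% keys))
  }
  # stem edges never removed
  stem_keys <- rootwhorl:::edge_key(
    fix$stem$vertex_ids[-length(fix$stem$vertex_ids)],
    fix$stem$vertex_ids[-1])
  expect_true(all(stem_keys %in% keys))
})

test_that("pruning leaves a skeleton unchanged when every branch is nodal", {
  fix <- y_fixture()
  cls <- classify_stem(fix$skeleton, fix$stem)
  paths <- find_candidate_paths(fix$skeleton, fix$stem, cls)
  pruned <- prune_false_connections(fix$skeleton, fix$stem, paths)
  expect_equal(pruned$edges, fix$skeleton$edges)
  expect_equal(nrow(attr(pruned, "removed_edges")), 0L)
})
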
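test_that("the Y fixture yields one candidate path ending in its boundary edge", {
  fix <- y_fixture()
  cls <- classify_stem(fix$skeleton, fix$stem)
  paths <- find_candidate_paths(fix$skeleton, fix$stem, cls)
  expect_length(paths, 1L)
  p <- paths[[1L]]
  expect_equal(p$start_vertex, 2L)
  expect_equal(p$vertex_ids, c(2L, 6L, 7L, 8L))  # 3 edges incl. boundary
  expect_equal(sort(p$boundary_edge), c(7L, 8L))
  expect_equal(p$vertex_ids[1L], p$start_vertex)
})

test_that("skeletons without boundary edges yield no candidate paths", {
  fix <- straight_stem_skeleton(4, spacing = 2, thickness = 10)
  cls <- classify_stem(fix$skeleton, fix$stem)
  expect_length(find_candidate_paths(fix$skeleton, fix$stem, cls), 0L)
})

test_that("candidate paths never traverse stem-path edges in the interior", {
  set.seed(41)
  for (i in 1:25) {
    fix <- random_small_skeleton()
    cls <- classify_stem(fix$skeleton, fix$stem)
    paths <- suppressWarnings(
      find_candidate_paths(fix$skeleton, fix$stem, cls))
    stem_keys <- paste(pmin(fix$stem$vertex_ids[-length(fix$stem$vertex_ids)],
                            fix$stem$vertex_ids[-1]),
                       pmax(fix$stem$vertex_ids[-length(fix$stem$vertex_ids)],
                            fix$stem$vertex_ids[-1]))
    for (p in paths) {
      ids <- p$vertex_ids
      used <- paste(pmin(ids[-length(ids)], ids[-1]),
                    pmax(ids[-length(ids)], ids[-1]))
      expect_false(any(used %in% stem_keys))
    }
  }
})

test_that("shortest-path lengths match brute-force enumeration on small graphs", {
  set.seed(42)
  for (i in 1:40) {
    fix <- random_small_skeleton()
    cls <- classify_stem(fix$skeleton, fix$stem)
    paths <- suppressWarnings(
      find_candidate_paths(fix$skeleton, fix$stem, cls))
    allowed <- allowed_candidate_edges(fix$skeleton, fix$stem, cls)
    w <- edge_lengths_of(fix$skeleton, allowed)
    for (p in paths) {
      bf <- bf_shortest_distances(fix$skeleton$vertices$id, allowed, w,
                                  p$start_vertex)
      target <- p$boundary_edge[1L]
      ids <- p$vertex_ids
      ti <- max(which(ids == target))
      dist_impl <- if (ti == 1L) 0 else
        path_length(p$polyline[1:ti, , drop = FALSE])
      expect_equal(dist_impl, unname(bf[as.character(target)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("RDP always performs the first split and respects the tolerance", {
  # 5 collinear points -> two ends plus the forced farthest point
  col <- cbind(0:4, 0, 0)
  out <- simplify_candidate(col, 0.5)
  expect_equal(nrow(out), 3L)
  expect_true(all(out[, 1] %in% 0:4))
  # right-angle elbow with 1 mm legs survives a 0.1 mm tolerance
  elbow <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(simplify_candidate(elbow, 0.1), elbow)
  expect_error(simplify_candidate(elbow[1, , drop = FALSE], 0.1),
               class = "polyline_invalid")
})

test_that("RDP output is a subset of input within the deviation bound", {
  set.seed(43)
  for (i in 1:100) {
    p <- random_polyline(sample(4:25, 1))
    eps <- runif(1, 0.1, 5)
    out <- simplify_candidate(p, eps)
    expect_gte(nrow(out), 3L)
    keys_in <- apply(p, 1, paste, collapse = ",")
    keys_out <- apply(out, 1, paste, collapse = ",")
    expect_true(all(keys_out %in% keys_in))
    # every input point within eps of the simplified polyline
    dev <- vapply(seq_len(nrow(p)), function(j) {
      min(vapply(seq_len(nrow(out) - 1), function(s)
        rootwhorl:::point_segment_distance(p[j, , drop = FALSE],
                                           out[s, ], out[s + 1, ]), 0))
    }, 0)
    expect_lte(max(dev), eps + 1e-9)
  }
})

test_that("turning point picks the interior vertex of maximal direction change", {
  straight <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  tp <- turning_point(straight)
  expect_equal(tp$angle, 0)
  expect_equal(tp$point, c(1, 0, 0))
  elbow <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  tp <- turning_point(elbow)
  expect_equal(tp$angle, pi / 2)
  expect_equal(tp$point, c(1, 0, 0))
  expect_error(turning_point(straight[1:2, ]), class = "polyline_invalid")
  # ties break to the smallest index
  zigzag <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  expect_equal(turning_point(zigzag)$index, 2L)
})

test_that("turning point matches a brute-force scan on random polylines", {
  set.seed(44)
  for (i in 1:50) {
    p <- random_polyline(6)
    tp <- turning_point(p)
    angs <- vapply(2:5, function(j)
      acos(max(-1, min(1, sum((p[j, ] - p[j - 1, ]) * (p[j + 1, ] - p[j, ])) /
                         (sqrt(sum((p[j, ] - p[j - 1, ])^2)) *
                            sqrt(sum((p[j + 1, ] - p[j, ])^2)))))), 0)
    expect_equal(tp$angle, max(angs), tolerance = 1e-9)
    expect_equal(tp$index, which.max(angs) + 1L)
  }
})

test_that("the score decreases with turning angle and grows with distance", {
  s0 <- whorl_score(0, dist_mm = 10, r_v = 1, pitch = 0.44)
  for (a in seq(0.1, pi, by = 0.3))
    expect_lt(whorl_score(a, 10, 1, 0.44), s0)
  d <- seq(0, 6, by = 0.5)
  s <- vapply(d, function(x) whorl_score(pi / 4, 1 + x, 1, 0.44), 0)
  expect_true(all(diff(s) >= 0))
  # beyond the clamp the distance term saturates
  expect_equal(whorl_score(0, 1 + 10 * 0.44, 1, 0.44),
               whorl_score(0, 1 + 20 * 0.44, 1, 0.44))
})

test_that("score_path reproduces the stored candidate scores", {
  fix <- y_fixture()
  cls <- classify_stem(fix$skeleton, fix$stem)
  paths <- find_candidate_paths(fix$skeleton, fix$stem, cls)
  p <- paths[[1L]]
  expect_equal(score_path(p, fix$stem, pitch = fix$skeleton$voxel_pitch),
               p$score)
  expect_gte(p$score, exp(-3))
  expect_lte(p$score, 1)
})

test_that("deduplication keeps the best path per boundary edge", {
  p1 <- fake_path(10, 0.9, 1L); p1$boundary_edge <- c(7L, 8L)
  p2 <- fake_path(12, 0.4, 2L); p2$boundary_edge <- c(7L, 8L)
  out <- dedup_by_boundary_edge(list(p1, p2))
  expect_length(out, 1L)
  expect_equal(out[[1L]]$score, 0.9)
  expect_length(dedup_by_boundary_edge(list(p1)), 1L)
  # random collections against a group-by argmax oracle
  set.seed(45)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    paths <- lapply(seq_len(n), function(j) {
      p <- fake_path(runif(1, 0, 100), runif(1, exp(-3), 1), as.integer(j))
      p$boundary_edge <- sort(c(sample(1:4, 1), 99L))
      p
    })
    out <- dedup_by_boundary_edge(paths)
    keys <- vapply(paths, function(p) paste(p$boundary_edge, collapse = "-"), "")
    for (k in unique(keys)) {
      grp <- paths[keys == k]
      best <- max(vapply(grp, `[[`, 0, "score"))
      kept <- Filter(function(p)
        paste(p$boundary_edge, collapse = "-") == k, out)
      expect_length(kept, 1L)
      expect_equal(kept[[1L]]$score, best)
    }
  }
})

test_that("ties in deduplication go to the shorter path", {
  p1 <- fake_path(10, 0.5, 1L); p1$boundary_edge <- c(7L, 8L); p1$length_mm <- 9
  p2 <- fake_path(12, 0.5, 2L); p2$boundary_edge <- c(7L, 8L); p2$length_mm <- 4
  out <- dedup_by_boundary_edge(list(p1, p2))
  expect_equal(out[[1L]]$length_mm, 4)
})
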
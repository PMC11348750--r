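test_that("whorl locations and internode distances follow the arc ordering", {
  w <- function(arc) structure(list(members = 1L, location_arc = arc,
                                    location_depth = arc, arc_range = c(arc, arc),
                                    n_roots = 1L), class = "whorl")
  li <- whorl_locations_and_internodes(list(w(35), w(10)))
  expect_equal(li$locations, c(10, 35))
  expect_equal(li$internodes, 25)
  expect_length(whorl_locations_and_internodes(list(w(10)))$internodes, 0L)
  expect_error(whorl_locations_and_internodes(list()), class = "no_whorls")
})

test_that("soil-relative indices decrease with depth and zero sits at the line", {
  expect_equal(soil_relative_indexing(c(40, 55, 70), 60), c(1, 0, -1))
  expect_equal(soil_relative_indexing(60, 60), 0L)      # exactly at the line
  idx <- soil_relative_indexing(c(80, 100), 60)         # all below ground
  expect_equal(idx, c(-1L, -2L), ignore_attr = TRUE)
  expect_true(isTRUE(attr(idx, "no_zero")))
  d <- sort(runif(6, 0, 150))
  idx <- soil_relative_indexing(d, 75)
  expect_true(all(diff(idx[order(d)]) == -1L))
})

test_that("branch geometry traits match closed forms", {
  # straight vertical 30 mm branch: tortuosity 1, all angles 0
  ids <- 1:16
  v <- data.frame(id = ids, x = 0, y = 0, z = -(ids - 1) * 2,
                  thickness = 1)
  skel <- skeleton(v, data.frame(v1 = ids[-16], v2 = ids[-1]))
  br <- list(id = 1L, label = 1L, parent = 0L, vertices = ids)
  tr <- rootwhorl:::branch_traits(br, skel)
  expect_equal(tr$length_mm, 30)
  expect_equal(tr$tortuosity, 1)
  expect_equal(tr$emergence_deg, 0)
  expect_equal(tr$midpoint_deg, 0)
  expect_equal(tr$tip_deg, 0)
  expect_equal(tr$thickness_mm, 1)

  # semicircular branch of radius 10: tortuosity pi / 2
  th <- seq(0, pi, length.out = 60)
  v <- data.frame(id = 1:60, x = 10 * sin(th), y = 0, z = -10 * (1 - cos(th)),
                  thickness = 1)
  skel <- skeleton(v, data.frame(v1 = 1:59, v2 = 2:60))
  br <- list(id = 1L, label = 1L, parent = 0L, vertices = 1:60)
  tr <- rootwhorl:::branch_traits(br, skel)
  expect_equal(tr$tortuosity, pi / 2, tolerance = 1e-3)
})

test_that("per-whorl trait rows match the generator's construction counts", {
  crown <- generate_crown(small_spec(fraction_clinging = 0), seed = 6)
  res <- suppressWarnings(run_crown(crown$skeleton, crown$stem))
  wt <- res$whorl_traits
  lvl1 <- wt[wt$level == 1L, ]
  expect_equal(nrow(lvl1), length(crown$truth$nodal_counts))
  # a low-scoring arc-extreme path can fall outside the selected member
  # range, so counts may miss a root; they must stay within one
  expect_true(all(abs(lvl1$count - crown$truth$nodal_counts) <= 1))
  expect_true(all(wt$avg_tortuosity >= 1))
  expect_true(all(wt$count >= 1))
})

test_that("above/below aggregates sum counts and pool means by weight", {
  rows <- data.frame(whorl = c(1, 2, 3), level = 1L, count = c(5, 7, 9),
                     total_length_mm = c(50, 140, 90),
                     avg_length_mm = c(10, 20, 10),
                     avg_tortuosity = c(1.1, 1.3, 1.2),
                     avg_thickness_mm = c(1, 2, 1),
                     avg_children = c(0, 1, 2),
                     avg_emergence_deg = c(10, 20, 30),
                     avg_midpoint_deg = c(10, 20, 30),
                     avg_tip_deg = c(10, 20, 30))
  agg <- above_below_aggregates(rows, indices = c(1L, 0L, -1L))
  above <- agg[agg$side == "above", ]
  below <- agg[agg$side == "below", ]
  expect_equal(above$count, 12)
  expect_equal(below$count, 9)
  expect_equal(above$total_length_mm, 190)
  expect_equal(above$avg_length_mm, 190 / 12)
  expect_equal(above$avg_tortuosity, (5 * 1.1 + 7 * 1.3) / 12)
  # weighted mean equals direct pooling of per-branch values
  expect_equal(above$avg_emergence_deg, (5 * 10 + 7 * 20) / 12)
})

test_that("RLD matches the closed-form cylinder volume and scaling law", {
  # one vertical root chain contributing 10 mm in the first bin below soil
  n <- 11
  v <- data.frame(id = 1:(n + 2), x = 0, y = 0,
                  z = c(0, -2, -(0:10) * 2 - 50), thickness = c(2, 2, rep(1, n)))
  e <- data.frame(v1 = c(1, 2, 2 + 1:(n - 1)), v2 = c(2, 3, 3 + 1:(n - 1)))
  skel <- skeleton(v, e)
  stem <- stem_path(skel, 1:2)
  labels <- c(0L, rep(1L, n))
  keys <- rootwhorl:::edge_key(skel$edges$v1, skel$edges$v2)
  names(labels) <- keys
  lab <- structure(list(edge_label = labels, branches = list(),
                        edge_branch = labels), class = "hierarchy_labeling")
  rld <- root_length_density(lab, skel, stem, soil_depth = 50,
                             radius_cm = 8.60)
  expect_equal(rld$bins$rld_cm_per_cm3[1L], 1 / (pi * 8.60^2),
               tolerance = 1e-9)
  expect_equal(sum(rld$bins$length_cm), 2)  # 20 mm of root below soil
  rld2 <- root_length_density(lab, skel, stem, soil_depth = 50,
                              radius_cm = 17.2)
  expect_equal(rld2$bins$rld_cm_per_cm3, rld$bins$rld_cm_per_cm3 / 4,
               tolerance = 1e-9)
  # soil below the deepest root -> no bins
  deep <- root_length_density(lab, skel, stem, soil_depth = 500,
                              radius_cm = 8.60)
  expect_equal(nrow(deep$bins), 0L)
})

test_that("cumulative internode error matches its formula", {
  expect_equal(cumulative_internode_error(c(10, 8), c(10, 10), 2), 0.10)
  expect_equal(cumulative_internode_error(c(5, 5), c(5, 5), 2), 0)
  # invariant to common rescaling
  c1 <- c(12, 9, 7); m1 <- c(11, 10, 8)
  expect_equal(cumulative_internode_error(c1, m1, 3),
               cumulative_internode_error(10 * c1, 10 * m1, 3))
  expect_error(cumulative_internode_error(c(1), c(1, 2), 2),
               class = "eval_invalid")
  expect_error(cumulative_internode_error(c(1, 2), c(0, 0), 2),
               class = "eval_invalid")
})
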
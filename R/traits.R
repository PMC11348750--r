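#' Whorl locations and internode distances
#'
#' Whorl location = mean member start arc (already stored on each whorl);
#' internode i is the along-stem distance between whorl i and whorl i + 1,
#' with whorls ordered youngest (smallest arc from the top) first.
#'
#' @param whorls list of `whorl` objects (see [cluster_whorls()]).
#' @return list with `locations` (mm, youngest first) and `internodes` (mm,
#'   empty when there is a single whorl).
#' @export
whorl_locations_and_internodes <- function(whorls) {
  if (!length(whorls)) rw_error("no whorls", "no_whorls")
  locs <- sort(vapply(whorls, `[[`, 0, "location_arc"))
  list(locations = locs, internodes = if (length(locs) > 1L) diff(locs)
       else numeric())
}

#' Soil-relative whorl indices
#'
#' The 0-th whorl is the deepest whorl at or above the soil line (depth <=
#' soil depth); indices decrease in the direction of gravity, so shallower
#' whorls get 1, 2, ... and deeper whorls -1, -2, ...  When every whorl is
#' below the soil line the shallowest gets -1, no whorl 0 exists, and the
#' result carries attribute `no_zero = TRUE`.
#'
#' @param whorl_depths depths of the whorls (mm, top-down), any order.
#' @param soil_depth soil-line depth (mm).
#' @return Integer indices aligned with `whorl_depths`.
#' @export
soil_relative_indexing <- function(whorl_depths, soil_depth) {
  o <- order(whorl_depths)
  n <- length(whorl_depths)
  z <- sum(whorl_depths <= soil_depth)
  idx <- integer(n)
  idx[o] <- z - seq_len(n)
  if (z == 0L) attr(idx, "no_zero") <- TRUE
  idx
}

# Direction of a polyline at a given arc position over a window (mm).
tangent_at <- function(points, cum_arc, s, window = 5) {
  total <- cum_arc[length(cum_arc)]
  a <- clamp(s - window / 2, 0, total)
  b <- clamp(s + window / 2, 0, total)
  if (b - a < 1e-9) { a <- max(0, total - window); b <- total }
  point_at_arc(points, cum_arc, b) - point_at_arc(points, cum_arc, a)
}

# Geometry summary of one branch: length, tortuosity, thickness, angles.
branch_traits <- function(branch, skel, window = 5) {
  pts <- vertex_positions(skel, branch$vertices)
  rownames(pts) <- NULL
  seg <- unname(sqrt(rowSums(diff(pts)^2)))
  cum <- c(0, cumsum(seg))
  len <- cum[length(cum)]
  chord <- max(vec_norm(pts[nrow(pts), ] - pts[1L, ]), 1e-9)
  down <- c(0, 0, -1)
  ang <- function(s) {
    v <- tangent_at(pts, cum, s, window)
    angle_between(v, down) * 180 / pi
  }
  own <- branch$vertices[-1L]  # first vertex belongs to the parent
  list(length_mm = len,
       tortuosity = len / chord,
       thickness_mm = mean(vertex_thickness(skel, own)),
       emergence_deg = ang(min(window / 2, len / 2)),
       midpoint_deg = ang(len / 2),
       tip_deg = ang(len - min(window / 2, len / 2)))
}

# Branch ids of the level-1 branches carrying each whorl's member paths.
whorl_level1_branches <- function(whorl, paths, labeling) {
  keys <- vapply(whorl$members, function(i) {
    ids <- paths[[i]]$vertex_ids
    edge_key(ids[1L], ids[2L])
  }, "")
  b <- labeling$edge_branch[keys]
  sort(unique(b[!is.na(b)]))
}

#' Per-whorl per-hierarchy-level traits
#'
#' For each whorl, its nodal branches (level 1, identified by the first
#' edges of the whorl's member candidate paths) and their descendants are
#' grouped by hierarchy level.  Per group: root count, total and average
#' length, average tortuosity (branch length over end-to-end distance),
#' average thickness, average number of children, and average emergence /
#' midpoint / tip angles (local tangent over a 5 mm window against the
#' downward vertical, degrees).
#'
#' @param labeling a [label_hierarchy()] result.
#' @param skel the labeled [skeleton()].
#' @param whorls list of `whorl` objects, youngest first.
#' @param paths the deduplicated candidate paths the whorls index into.
#' @param window_mm tangent window (default 5 mm).
#' @return data.frame, one row per whorl x level.
#' @export
per_whorl_traits <- function(labeling, skel, whorls, paths, window_mm = 5) {
  n_children <- table(vapply(labeling$branches, `[[`, 0L, "parent"))
  rows <- list()
  for (w in seq_along(whorls)) {
    b1 <- whorl_level1_branches(whorls[[w]], paths, labeling)
    group <- b1
    frontier <- b1
    while (length(frontier)) {
      kids <- which(vapply(labeling$branches, function(b)
        b$parent %in% frontier, TRUE))
      frontier <- setdiff(kids, group)
      group <- union(group, kids)
    }
    if (!length(group)) next
    labs <- vapply(labeling$branches[group], `[[`, 0L, "label")
    for (lv in sort(unique(labs))) {
      ids <- group[labs == lv]
      tr <- lapply(labeling$branches[ids], branch_traits, skel = skel,
                   window = window_mm)
      get <- function(f) vapply(tr, `[[`, 0, f)
      kid_counts <- as.numeric(n_children[as.character(ids)])
      kid_counts[is.na(kid_counts)] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        whorl = w, level = lv, count = length(ids),
        total_length_mm = sum(get("length_mm")),
        avg_length_mm = mean(get("length_mm")),
        avg_tortuosity = mean(get("tortuosity")),
        avg_thickness_mm = mean(get("thickness_mm")),
        avg_children = mean(kid_counts),
        avg_emergence_deg = mean(get("emergence_deg")),
        avg_midpoint_deg = mean(get("midpoint_deg")),
        avg_tip_deg = mean(get("tip_deg")))
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Above- and below-ground trait aggregates
#'
#' Whorls with soil-relative index >= 0 are above ground (brace whorls),
#' index < 0 below ground (crown whorls).  Counts and total lengths are
#' summed per hierarchy level; averaged traits are weighted by root count.
#'
#' @param rows output of [per_whorl_traits()].
#' @param indices soil-relative whorl indices aligned with whorl numbers in
#'   `rows` (index `i` of `indices` corresponds to `whorl == i`).
#' @return data.frame with a `side` column (`"above"` / `"below"`), one row
#'   per side x level.
#' @export
above_below_aggregates <- function(rows, indices) {
  if (!nrow(rows)) return(data.frame())
  side <- ifelse(indices[rows$whorl] >= 0L, "above", "below")
  agg <- lapply(split(seq_len(nrow(rows)), list(side, rows$level),
                      drop = TRUE), function(i) {
    r <- rows[i, , drop = FALSE]
    wts <- r$count / sum(r$count)
    data.frame(side = side[i[1L]], level = r$level[1L],
               count = sum(r$count),
               total_length_mm = sum(r$total_length_mm),
               avg_length_mm = sum(r$total_length_mm) / sum(r$count),
               avg_tortuosity = sum(wts * r$avg_tortuosity),
               avg_thickness_mm = sum(wts * r$avg_thickness_mm),
               avg_children = sum(wts * r$avg_children),
               avg_emergence_deg = sum(wts * r$avg_emergence_deg),
               avg_midpoint_deg = sum(wts * r$avg_midpoint_deg),
               avg_tip_deg = sum(wts * r$avg_tip_deg))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$side, out$level), , drop = FALSE]
}

#' Root length density in a virtual soil core
#'
#' Total length of nodal and lateral roots (hierarchy label >= 1) per unit
#' soil volume, for each centimeter of depth below the soil line, inside a
#' cylinder whose axis is the best-fit line through the stem-path vertices.
#' With `radius_cm = "auto"` the radius is the 95th percentile of the
#' radial distances of all root points from the axis.
#'
#' @param labeling a [label_hierarchy()] result.
#' @param skel the labeled [skeleton()].
#' @param stem the [stem_path()].
#' @param soil_depth soil-line depth, mm.
#' @param radius_cm cylinder radius in cm, or `"auto"`.
#' @return list with `radius_cm` and `bins` (data.frame `depth_from_cm`,
#'   `depth_to_cm` below the soil line, `length_cm`, `rld_cm_per_cm3`).
#' @export
root_length_density <- function(labeling, skel, stem, soil_depth,
                                radius_cm = "auto") {
  keys <- edge_key(skel$edges$v1, skel$edges$v2)
  lab <- labeling$edge_label[keys]
  sel <- which(!is.na(lab) & lab >= 1L)
  empty <- list(radius_cm = if (identical(radius_cm, "auto")) NA_real_
                else radius_cm,
                bins = data.frame(depth_from_cm = numeric(),
                                  depth_to_cm = numeric(),
                                  length_cm = numeric(),
                                  rld_cm_per_cm3 = numeric()))
  if (!length(sel)) return(empty)
  # stem axis: centroid + dominant principal direction, pointing down
  ctr <- colMeans(stem$positions)
  sv <- svd(sweep(stem$positions, 2L, ctr))
  axis <- sv$v[, 1L]
  if (axis[3L] > 0) axis <- -axis
  radial <- function(p) {
    rel <- sweep(p, 2L, ctr)
    t <- as.vector(rel %*% axis)
    sqrt(pmax(rowSums(rel^2) - t^2, 0))
  }
  p1 <- vertex_positions(skel, skel$edges$v1[sel])
  p2 <- vertex_positions(skel, skel$edges$v2[sel])
  if (identical(radius_cm, "auto")) {
    pts <- unique(rbind(p1, p2))
    radius_cm <- unname(stats::quantile(radial(pts), 0.95)) / 10
  }
  radius_mm <- radius_cm * 10
  top <- stem$positions[1L, ]
  len <- sqrt(rowSums((p1 - p2)^2))
  d1 <- depth_of(p1, top); d2 <- depth_of(p2, top)
  mid_ok <- radial((p1 + p2) / 2) <= radius_mm
  dlo <- pmin(d1, d2); dhi <- pmax(d1, d2)
  keep <- mid_ok & dhi > soil_depth
  if (!any(keep)) return(c(list(radius_cm = radius_cm), empty["bins"]))
  dlo <- dlo[keep]; dhi <- dhi[keep]; len <- len[keep]
  bw <- 10  # 1 cm bins, in mm
  nbins <- ceiling((max(dhi) - soil_depth) / bw)
  edges <- soil_depth + bw * (0:nbins)
  values <- numeric(nbins)
  for (i in seq_along(len)) {
    if (dhi[i] - dlo[i] <= 1e-12) {
      b <- findInterval(dlo[i], edges, rightmost.closed = TRUE)
      if (b >= 1L && b <= nbins) values[b] <- values[b] + len[i]
    } else {
      overlap <- pmax(0, pmin(edges[-1L], dhi[i]) -
                        pmax(edges[-length(edges)], dlo[i]))
      values <- values + len[i] * overlap / (dhi[i] - dlo[i])
    }
  }
  vol_cm3 <- pi * radius_cm^2 * 1
  list(radius_cm = radius_cm,
       bins = data.frame(depth_from_cm = (edges[-length(edges)] - soil_depth) / 10,
                         depth_to_cm = (edges[-1L] - soil_depth) / 10,
                         length_cm = values / 10,
                         rld_cm_per_cm3 = (values / 10) / vol_cm3))
}

#' Cumulative internode-distance error
#'
#' E_k = sum_{i=1..k} |c_i - m_i| / sum_{i=1..k} m_i, where c and m are the
#' computed and measured internode distances indexed from the youngest
#' whorl.
#'
#' @param computed numeric vector of computed internode distances.
#' @param measured numeric vector of measured internode distances.
#' @param k number of leading internodes to accumulate (>= 1).
#' @return E_k (dimensionless, >= 0).
#' @export
cumulative_internode_error <- function(computed, measured, k) {
  stopifnot(k >= 1L)
  if (length(computed) < k || length(measured) < k)
    rw_error("both lists must have at least k entries", "eval_invalid")
  m <- measured[seq_len(k)]
  if (sum(m) <= 0) rw_error("measured internode sum must be positive",
                            "eval_invalid")
  sum(abs(computed[seq_len(k)] - m)) / sum(m)
}
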
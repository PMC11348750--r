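#' Specification for a synthetic root crown
#'
#' Defines the study conditions emulated by the generator: a thick tapering
#' stem, whorls of nodal roots emerging circumferentially, "clinging" nodal
#' roots re-attached to the stem through short sharply bent bridges (false
#' connections that create cycles), and lateral roots whose depth density
#' follows a Gaussian rising below the soil line.  Defaults describe a
#' field-excavated maize crown: 4 whorls at 30-40 mm internodes, 6-10 nodal
#' roots per whorl, 15% clinging roots at above-ground whorls.
#'
#' @param n_whorls number of whorls.
#' @param internode_mm either a length-2 range to draw internode distances
#'   from, or `n_whorls - 1` fixed distances (mm).
#' @param first_whorl_arc_mm stem arc of the youngest whorl (mm from top).
#' @param nodal_per_whorl length-2 range or `n_whorls` fixed counts.
#' @param emergence_elev_deg range of initial root elevation below the
#'   horizontal, degrees.
#' @param nodal_curv_deg_mm downward bending rate of nodal roots, deg/mm.
#' @param nodal_length_mm range of nodal-root lengths (mm).
#' @param stem_length_mm,stem_top_thickness_mm,stem_taper_mm_per_mm stem
#'   geometry; thickness tapers linearly with arc, floored at 2.8 mm.
#' @param soil_depth_mm ground-truth soil-line depth (mm, top-down).
#' @param lateral_amplitude peak per-vertex probability of spawning a
#'   lateral root.
#' @param lateral_sd_mm standard deviation c of the lateral-density
#'   Gaussian; its peak sits at `soil_depth_mm + 2 * lateral_sd_mm` so that
#'   the ground-truth soil line equals b - 2c.
#' @param lateral_length_mm,lateral_elev_deg lateral geometry ranges.
#' @param fraction_clinging fraction of nodal roots at above-ground whorls
#'   that cling to the stem (each adds a false-connection bridge).
#' @param noise_sd_mm isotropic positional jitter (mm).
#' @param step_mm skeleton sampling step along roots (mm).
#' @param voxel_pitch_mm voxel pitch recorded on the skeleton.
#' @param seed default RNG seed for [generate_crown()].
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_whorls = 4L,
                           internode_mm = c(30, 40),
                           first_whorl_arc_mm = 25,
                           nodal_per_whorl = c(6L, 10L),
                           emergence_elev_deg = c(10, 40),
                           nodal_curv_deg_mm = 1.2,
                           nodal_length_mm = c(60, 110),
                           stem_length_mm = 175,
                           stem_top_thickness_mm = 6,
                           stem_taper_mm_per_mm = 0.015,
                           soil_depth_mm = 95,
                           lateral_amplitude = 1,
                           lateral_sd_mm = 12,
                           lateral_length_mm = c(8, 25),
                           lateral_elev_deg = c(5, 30),
                           fraction_clinging = 0.15,
                           noise_sd_mm = 0.12,
                           step_mm = 2,
                           voxel_pitch_mm = 0.44,
                           seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_whorls >= 1L, first_whorl_arc_mm > 0, stem_length_mm > 0,
            stem_top_thickness_mm > 0, soil_depth_mm > 0,
            lateral_amplitude >= 0, lateral_sd_mm > 0,
            fraction_clinging >= 0, fraction_clinging <= 1,
            noise_sd_mm >= 0, step_mm > 0, voxel_pitch_mm > 0)
  class(spec) <- "synthetic_spec"
  spec
}

# Length-2 inputs are ranges to draw from; otherwise n fixed values.
draw_range <- function(x, n, integer = FALSE) {
  if (length(x) == 2L) {
    if (integer) sample(seq.int(x[1L], x[2L]), n, replace = TRUE)
    else stats::runif(n, x[1L], x[2L])
  } else {
    stopifnot(length(x) == n)
    x
  }
}

#' Generate a synthetic root-crown skeleton with ground truth
#'
#' Deterministic for a fixed seed.  See [synthetic_spec()] for the
#' phenomena emulated.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `skeleton`, `stem` ([stem_path()], top to bottom) and
#'   `truth`: `whorl_arcs` (mean attachment arcs, youngest first),
#'   `internodes`, `nodal_counts`, `soil_depth`, `false_edges` (data.frame),
#'   `n_laterals`, `max_label`, `clinging_per_whorl`.
#' @export
generate_crown <- function(spec, seed = spec$seed) {
  set.seed(seed)
  step <- spec$step_mm
  ivals <- draw_range(spec$internode_mm, spec$n_whorls - 1L)
  whorl_arcs0 <- spec$first_whorl_arc_mm + c(0, cumsum(ivals))
  if (max(whorl_arcs0) + 10 > spec$stem_length_mm)
    rw_error("infeasible geometry: internodes exceed stem length",
             "infeasible_spec")
  counts <- draw_range(spec$nodal_per_whorl, spec$n_whorls, integer = TRUE)

  # --- stem ---
  nz <- floor(spec$stem_length_mm / step)
  sz <- -(0:nz) * step
  sx <- stats::rnorm(nz + 1L, 0, spec$noise_sd_mm)
  sy <- stats::rnorm(nz + 1L, 0, spec$noise_sd_mm)
  s_arc <- c(0, cumsum(sqrt(diff(sx)^2 + diff(sy)^2 + diff(sz)^2)))
  s_th <- pmax(spec$stem_top_thickness_mm -
                 spec$stem_taper_mm_per_mm * s_arc, 2.8) *
    stats::runif(nz + 1L, 0.98, 1.02)

  verts <- vector("list", 8192L); nverts <- 0L
  edges <- vector("list", 8192L); nedges <- 0L
  add_vertex <- function(x, y, z, th) {
    nverts <<- nverts + 1L
    verts[[nverts]] <<- c(nverts, x, y, z, th)
    nverts
  }
  add_edge <- function(a, b) {
    nedges <<- nedges + 1L
    edges[[nedges]] <<- c(a, b)
  }
  for (i in seq_len(nz + 1L)) add_vertex(sx[i], sy[i], sz[i], s_th[i])
  for (i in seq_len(nz)) add_edge(i, i + 1L)
  stem_ids <- seq_len(nz + 1L)

  jitter3 <- function(p) p + stats::rnorm(3L, 0, spec$noise_sd_mm)

  # grow a chain of vertices from an existing vertex; returns its ids
  grow_chain <- function(from_id, pts, th) {
    ids <- integer(nrow(pts))
    prev <- from_id
    for (i in seq_len(nrow(pts))) {
      ids[i] <- add_vertex(pts[i, 1L], pts[i, 2L], pts[i, 3L], th[i])
      add_edge(prev, ids[i])
      prev <- ids[i]
    }
    ids
  }

  curv <- spec$nodal_curv_deg_mm * pi / 180
  b_gauss <- spec$soil_depth_mm + 2 * spec$lateral_sd_mm

  root_records <- list()   # per nodal root: vertex ids + positions
  false_edges <- list()
  clinging_per_whorl <- integer(spec$n_whorls)
  attach_arcs <- vector("list", spec$n_whorls)

  for (w in seq_len(spec$n_whorls)) {
    k <- counts[w]
    azim0 <- stats::runif(1, 0, 2 * pi)
    above <- whorl_arcs0[w] < spec$soil_depth_mm
    for (j in seq_len(k)) {
      az <- azim0 + 2 * pi * (j - 1L) / k + stats::rnorm(1, 0, 0.08)
      target_arc <- whorl_arcs0[w] + stats::runif(1, -2, 2)
      si <- which.min(abs(s_arc - target_arc))
      attach_arcs[[w]] <- c(attach_arcs[[w]], s_arc[si])
      p0 <- c(sx[si], sy[si], sz[si])
      r_att <- s_th[si]
      len <- stats::runif(1, spec$nodal_length_mm[1L], spec$nodal_length_mm[2L])
      clinging <- above && stats::runif(1) < spec$fraction_clinging
      if (clinging) clinging_per_whorl[w] <- clinging_per_whorl[w] + 1L
      pts <- list(); ths <- c()
      hug_idx <- integer()   # indices (into pts) of hugging vertices
      if (!clinging) {
        elev <- stats::runif(1, spec$emergence_elev_deg[1L],
                             spec$emergence_elev_deg[2L]) * pi / 180
        p <- p0; a <- az; remaining <- len
        while (remaining > 0) {
          d <- c(cos(elev) * cos(a), cos(elev) * sin(a), -sin(elev))
          p <- p + d * step
          pts[[length(pts) + 1L]] <- jitter3(p)
          elev <- min(elev + curv * step, 85 * pi / 180)
          a <- a + stats::rnorm(1, 0, 0.02)
          remaining <- remaining - step
        }
      } else {
        hug_r <- 1.45 * r_att
        hug_len <- stats::runif(1, 20, 32)
        # phase A: leave radially at a shallow angle until the hug radius
        elevA <- 20 * pi / 180
        p <- p0; rad <- 0
        while (rad < hug_r) {
          d <- c(cos(elevA) * cos(az), cos(elevA) * sin(az), -sin(elevA))
          p <- p + d * step
          rad <- sqrt((p[1L] - p0[1L])^2 + (p[2L] - p0[2L])^2)
          pts[[length(pts) + 1L]] <- jitter3(p)
        }
        # phase B: hug the stem, descending at constant radius
        zb <- p[3L]
        nb <- max(2L, round(hug_len / step))
        for (t in seq_len(nb)) {
          zb <- zb - step
          ph <- c(p0[1L] + hug_r * cos(az), p0[2L] + hug_r * sin(az), zb)
          pts[[length(pts) + 1L]] <- jitter3(ph)
          hug_idx <- c(hug_idx, length(pts))
        }
        # phase C: bend away and continue downward
        elev <- 55 * pi / 180
        p <- pts[[length(pts)]]
        remaining <- len - (length(pts) * step)
        while (remaining > 0) {
          d <- c(cos(elev) * cos(az), cos(elev) * sin(az), -sin(elev))
          p <- p + d * step
          pts[[length(pts) + 1L]] <- jitter3(p)
          elev <- min(elev + curv * step, 85 * pi / 180)
          remaining <- remaining - step
        }
      }
      pm <- do.call(rbind, pts)
      ths <- seq(1.4, 0.9, length.out = nrow(pm)) *
        stats::runif(nrow(pm), 0.95, 1.05)
      ids <- grow_chain(si, pm, ths)
      root_records[[length(root_records) + 1L]] <-
        list(ids = ids, pts = pm, whorl = w)
      if (clinging && length(hug_idx) >= 3L) {
        # false-connection bridge: stem junction -> sharp bend near the
        # stem surface -> hugging root vertex ~10 mm above the bend
        depth_attach <- -p0[3L]
        target_depth <- depth_attach + 6 + 0.7 * hug_len
        s2 <- which.min(abs(-sz - target_depth))
        if (s2 != si) {
          m_pos <- c(sx[s2] + (s_th[s2] + spec$voxel_pitch_mm) * cos(az),
                     sy[s2] + (s_th[s2] + spec$voxel_pitch_mm) * sin(az),
                     sz[s2] - 2.5)
          hug_depths <- -pm[hug_idx, 3L]
          ci <- hug_idx[which.min(abs(hug_depths - (-m_pos[3L] - 10)))]
          m_id <- add_vertex(m_pos[1L], m_pos[2L], m_pos[3L], 0.5)
          add_edge(s2, m_id)
          add_edge(m_id, ids[ci])
          false_edges[[length(false_edges) + 1L]] <-
            data.frame(v1 = c(s2, m_id), v2 = c(m_id, ids[ci]))
        }
      }
    }
  }

  # --- laterals with Gaussian depth density below the soil line ---
  n_lat <- 0L; max_label <- 1L
  for (rec in root_records) {
    npts <- nrow(rec$pts)
    if (npts < 4L) next
    for (vi in 3:npts) {
      vpos <- rec$pts[vi, ]
      elev <- stats::runif(1, spec$lateral_elev_deg[1L],
                           spec$lateral_elev_deg[2L]) * pi / 180
      lat_len <- stats::runif(1, spec$lateral_length_mm[1L],
                              spec$lateral_length_mm[2L])
      mean_depth <- -vpos[3L] + 0.5 * lat_len * sin(elev)
      p_acc <- spec$lateral_amplitude *
        exp(-(mean_depth - b_gauss)^2 / (2 * spec$lateral_sd_mm^2))
      if (stats::runif(1) >= p_acc) next
      out_az <- atan2(vpos[2L] - sy[1L], vpos[1L] - sx[1L])
      a <- out_az + stats::runif(1, -70, 70) * pi / 180
      nstep <- max(2L, round(lat_len / 3))
      p <- vpos; lpts <- list()
      for (t in seq_len(nstep)) {
        d <- c(cos(elev) * cos(a), cos(elev) * sin(a), -sin(elev))
        p <- p + d * (lat_len / nstep)
        lpts[[t]] <- jitter3(p)
        a <- a + stats::rnorm(1, 0, 0.03)
      }
      lm <- do.call(rbind, lpts)
      lids <- grow_chain(rec$ids[vi], lm, rep(0.6, nrow(lm)))
      n_lat <- n_lat + 1L
      max_label <- max(max_label, 2L)
      if (stats::runif(1) < 0.12 && nrow(lm) >= 3L) {
        mid <- ceiling(nrow(lm) / 2)
        sl_len <- stats::runif(1, 5, 10)
        sl_az <- a + stats::runif(1, -1.2, 1.2)
        sl_elev <- stats::runif(1, 0.2, 0.7)
        sp <- lm[mid, ]; spts <- list()
        for (t in 1:2) {
          d <- c(cos(sl_elev) * cos(sl_az), cos(sl_elev) * sin(sl_az),
                 -sin(sl_elev))
          sp <- sp + d * (sl_len / 2)
          spts[[t]] <- jitter3(sp)
        }
        grow_chain(lids[mid], do.call(rbind, spts), rep(0.45, 2L))
        max_label <- max(max_label, 3L)
      }
    }
  }

  vm <- do.call(rbind, verts[seq_len(nverts)])
  em <- do.call(rbind, edges[seq_len(nedges)])
  skel <- skeleton(
    data.frame(id = as.integer(vm[, 1L]), x = vm[, 2L], y = vm[, 3L],
               z = vm[, 4L], thickness = vm[, 5L]),
    data.frame(v1 = em[, 1L], v2 = em[, 2L]),
    voxel_pitch = spec$voxel_pitch_mm)
  stem <- stem_path(skel, stem_ids)
  true_arcs <- vapply(attach_arcs, mean, 0)
  truth <- list(whorl_arcs = true_arcs,
                internodes = diff(true_arcs),
                nodal_counts = counts,
                soil_depth = spec$soil_depth_mm,
                false_edges = if (length(false_edges))
                  do.call(rbind, false_edges) else
                    data.frame(v1 = integer(), v2 = integer()),
                n_laterals = n_lat,
                max_label = max_label,
                clinging_per_whorl = clinging_per_whorl)
  list(skeleton = skel, stem = stem, truth = truth)
}

#' Measure pipeline recovery on synthetic crowns
#'
#' Runs the full detection pipeline on `n_seeds` generated crowns and
#' compares the results with the generator's ground truth: whorl-count
#' accuracy, cumulative internode errors E_1 and E_k (k = number of
#' comparable internodes), nodal-count recovery at the youngest whorl, and
#' the soil-line error distribution.
#'
#' @param spec a [synthetic_spec()].
#' @param n_seeds number of crowns.
#' @param seeds explicit seed vector (overrides `n_seeds`).
#' @param config a [run_config()].
#' @return list with `per_seed` (data.frame) and `summary` (list).
#' @export
measure_recovery <- function(spec, n_seeds = 20L, seeds = NULL,
                             config = run_config()) {
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  rows <- lapply(seeds, function(s) {
    crown <- generate_crown(spec, seed = s)
    res <- tryCatch(run_crown(crown$skeleton, crown$stem, config),
                    error = function(e) NULL)
    truth <- crown$truth
    out <- data.frame(seed = s, n_whorls_true = length(truth$nodal_counts),
                      n_whorls_detected = NA_integer_, e1 = NA_real_,
                      ek = NA_real_, youngest_true = truth$nodal_counts[1L],
                      youngest_detected = NA_integer_,
                      soil_true = truth$soil_depth, soil_est = NA_real_)
    if (is.null(res)) return(out)
    out$n_whorls_detected <- length(res$whorls)
    li <- whorl_locations_and_internodes(res$whorls)
    kc <- min(length(li$internodes), length(truth$internodes))
    if (kc >= 1L) {
      out$e1 <- cumulative_internode_error(li$internodes, truth$internodes, 1L)
      out$ek <- cumulative_internode_error(li$internodes, truth$internodes, kc)
    }
    out$youngest_detected <- res$whorls[[1L]]$n_roots
    out$soil_est <- res$soil_depth
    out
  })
  per_seed <- do.call(rbind, rows)
  soil_err <- per_seed$soil_est - per_seed$soil_true
  ok <- !is.na(per_seed$n_whorls_detected)
  summary <- list(
    n_seeds = length(seeds),
    n_completed = sum(ok),
    whorl_count_accuracy = mean(
      per_seed$n_whorls_detected == per_seed$n_whorls_true, na.rm = TRUE),
    mean_e1 = mean(per_seed$e1, na.rm = TRUE),
    mean_ek = mean(per_seed$ek, na.rm = TRUE),
    median_abs_soil_error_mm = stats::median(abs(soil_err), na.rm = TRUE),
    soil_within_5mm = mean(abs(soil_err) <= 5, na.rm = TRUE),
    soil_within_10mm = mean(abs(soil_err) <= 10, na.rm = TRUE),
    pearson_youngest = suppressWarnings(stats::cor(
      per_seed$youngest_detected, per_seed$youngest_true,
      use = "complete.obs")))
  list(per_seed = per_seed, summary = summary)
}
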
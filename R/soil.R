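#' Depth profile of lateral-root length
#'
#' Bins the skeleton length of all lateral-root edges (hierarchy label >= 2)
#' by top-down depth.  Each edge's length is apportioned pro-rata across the
#' depth bins spanned by its endpoints; horizontal edges fall entirely into
#' the bin containing their depth.  Bins are uniform, anchored at depth 0
#' (extended upward if laterals occur above the stem top).
#'
#' @param labeling a [label_hierarchy()] result.
#' @param skel the labeled [skeleton()].
#' @param stem the [stem_path()] (depth reference = its top vertex).
#' @param bin_width_mm bin width, default 2 mm.
#' @return Object of class `density_profile`: `bin_edges` (mm depths),
#'   `values` (lateral length per bin, mm), `centers`.
#' @export
lateral_density_profile <- function(labeling, skel, stem, bin_width_mm = 2) {
  stopifnot(bin_width_mm > 0)
  keys <- edge_key(skel$edges$v1, skel$edges$v2)
  lab <- labeling$edge_label[keys]
  sel <- which(!is.na(lab) & lab >= 2L)
  top <- stem$positions[1L, ]
  if (!length(sel)) {
    edges <- seq(0, bin_width_mm, by = bin_width_mm)
    return(structure(list(bin_edges = edges, values = 0,
                          centers = edges[-1L] - bin_width_mm / 2),
                     class = "density_profile"))
  }
  p1 <- vertex_positions(skel, skel$edges$v1[sel])
  p2 <- vertex_positions(skel, skel$edges$v2[sel])
  len <- sqrt(rowSums((p1 - p2)^2))
  d1 <- depth_of(p1, top); d2 <- depth_of(p2, top)
  dlo <- pmin(d1, d2); dhi <- pmax(d1, d2)
  lo_edge <- min(0, floor(min(dlo) / bin_width_mm) * bin_width_mm)
  hi_edge <- ceiling(max(dhi) / bin_width_mm) * bin_width_mm
  if (hi_edge <= lo_edge) hi_edge <- lo_edge + bin_width_mm
  edges <- seq(lo_edge, hi_edge, by = bin_width_mm)
  values <- numeric(length(edges) - 1L)
  for (i in seq_along(sel)) {
    if (dhi[i] - dlo[i] <= 1e-12) {
      b <- findInterval(dlo[i], edges, rightmost.closed = TRUE)
      b <- min(max(b, 1L), length(values))
      values[b] <- values[b] + len[i]
    } else {
      overlap <- pmax(0, pmin(edges[-1L], dhi[i]) - pmax(edges[-length(edges)], dlo[i]))
      values <- values + len[i] * overlap / (dhi[i] - dlo[i])
    }
  }
  structure(list(bin_edges = edges, values = values,
                 centers = edges[-length(edges)] + bin_width_mm / 2),
            class = "density_profile")
}

#' Fit a Gaussian to a density profile
#'
#' Nonlinear least squares of f(x) = a exp(-(x - b)^2 / (2 c^2)) at the bin
#' centers, by Levenberg-Marquardt.  Initialized at a = max value, b =
#' argmax center, c = profile standard deviation; iterations stop when the
#' relative change in the residual sum of squares falls below 1e-10 or
#' after 500 iterations.
#'
#' @param profile a [lateral_density_profile()] (or any list with `centers`
#'   and `values`).
#' @return Object of class `gaussian_fit`: `a`, `b`, `c` (mm), `rss`.
#' @export
fit_gaussian <- function(profile) {
  x <- profile$centers; y <- profile$values
  if (sum(y > 0) < 3L)
    rw_error("degenerate profile: fewer than 3 nonzero bins",
             "degenerate_profile")
  a0 <- max(y)
  b0 <- x[which.max(y)]
  w <- y / sum(y)
  c0 <- sqrt(max(sum(w * (x - sum(w * x))^2), mean(diff(x))^2))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - b)^2 / (2 * c^2)),
      start = list(a = a0, b = b0, c = c0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) rw_error(
      paste0("Gaussian fit did not converge: ", conditionMessage(e)),
      "fit_nonconvergence"))
  cf <- stats::coef(fit)
  structure(list(a = unname(abs(cf["a"])), b = unname(cf["b"]),
                 c = unname(abs(cf["c"])),
                 rss = sum(stats::resid(fit)^2)),
            class = "gaussian_fit")
}

#' Soil-line depth from a Gaussian fit
#'
#' The soil line sits `sigma_factor` standard deviations above the peak of
#' the lateral-root density: depth = b - sigma_factor * c.  The default
#' factor of 2 places it where the density starts to rise.  Negative depths
#' (above the stem top) are clamped to 0 with a warning.
#'
#' @param fit a [fit_gaussian()] result.
#' @param sigma_factor multiplier on c (default 2).
#' @return Soil-line depth in mm (top-down).
#' @export
soil_line_depth <- function(fit, sigma_factor = 2) {
  d <- fit$b - sigma_factor * fit$c
  if (d < 0) {
    warning("computed soil line above the stem top; clamped to 0 mm",
            call. = FALSE)
    d <- 0
  }
  d
}
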
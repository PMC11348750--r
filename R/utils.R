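# Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

# Angle in [0, pi] between two 3-vectors; robust near 0 and pi.
angle_between <- function(u, v) {
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0) return(0)
  cr <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  atan2(vec_norm(cr), sum(u * v))
}

# Canonical undirected edge key "lo-hi" used for set membership tests.
edge_key <- function(v1, v2) {
  paste(pmin(v1, v2), pmax(v1, v2), sep = "-")
}

rw_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rootwhorl_error")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Perpendicular distances from points (n x 3) to the segment a-b.
point_segment_distance <- function(points, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  rel <- sweep(points, 2L, a)
  if (len2 == 0) return(sqrt(rowSums(rel^2)))
  t <- clamp(as.vector(rel %*% ab) / len2, 0, 1)
  proj <- outer(t, ab)
  sqrt(rowSums((rel - proj)^2))
}

# Linear interpolation of a position at a given arc length along a polyline.
point_at_arc <- function(points, cum_arc, s) {
  n <- nrow(points)
  s <- clamp(s, cum_arc[1L], cum_arc[n])
  i <- findInterval(s, cum_arc, rightmost.closed = TRUE)
  i <- min(max(i, 1L), n - 1L)
  seg <- cum_arc[i + 1L] - cum_arc[i]
  f <- if (seg > 0) (s - cum_arc[i]) / seg else 0
  points[i, ] + f * (points[i + 1L, ] - points[i, ])
}
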
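#' Construct a root-crown curve skeleton
#'
#' A skeleton is an undirected spatial graph: vertices carry 3D positions
#' (mm) and a per-vertex thickness (mm), the radius-like measure produced by
#' skeletonization.  Cycles are allowed on input; they are removed later in
#' the pipeline.  `voxel_pitch` is the physical size of one voxel (mm) and
#' converts voxel-denominated algorithm constants into mm.
#'
#' @param vertices data.frame with columns `id` (unique integers), `x`, `y`,
#'   `z` (mm) and `thickness` (mm, positive).
#' @param edges data.frame with columns `v1`, `v2` referencing vertex ids;
#'   no self-loops or duplicates.
#' @param voxel_pitch voxel size in mm (default 0.44).
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(vertices, edges, voxel_pitch = 0.44) {
  vertices <- as.data.frame(vertices)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y", "z", "thickness") %in% names(vertices)))
  if (nrow(edges) > 0) stopifnot(all(c("v1", "v2") %in% names(edges)))
  else edges <- data.frame(v1 = integer(), v2 = integer())
  vertices$id <- as.integer(vertices$id)
  if (anyDuplicated(vertices$id))
    rw_error("duplicate vertex ids", "skeleton_invalid")
  if (any(vertices$thickness <= 0))
    rw_error("vertex thickness must be positive", "skeleton_invalid")
  edges$v1 <- as.integer(edges$v1); edges$v2 <- as.integer(edges$v2)
  unknown <- setdiff(c(edges$v1, edges$v2), vertices$id)
  if (length(unknown))
    rw_error(paste0("edge references unknown vertex id(s): ",
                    paste(utils::head(unknown, 5L), collapse = ", ")),
             "dangling_edge")
  if (any(edges$v1 == edges$v2))
    rw_error("self-loop edge", "skeleton_invalid")
  lo <- pmin(edges$v1, edges$v2); hi <- pmax(edges$v1, edges$v2)
  if (anyDuplicated(paste(lo, hi)))
    rw_error("duplicate edge", "skeleton_invalid")
  edges <- data.frame(v1 = lo, v2 = hi)
  structure(list(vertices = vertices, edges = edges,
                 voxel_pitch = voxel_pitch),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d vertices, %d edges, voxel pitch %.3f mm\n",
              nrow(x$vertices), nrow(x$edges), x$voxel_pitch))
  invisible(x)
}

# Row index of each vertex id; named integer vector.
vertex_index <- function(skel) {
  idx <- seq_len(nrow(skel$vertices))
  names(idx) <- as.character(skel$vertices$id)
  idx
}

# n x 3 matrix of positions for given ids (in that order).
vertex_positions <- function(skel, ids = skel$vertices$id) {
  idx <- vertex_index(skel)[as.character(ids)]
  as.matrix(skel$vertices[idx, c("x", "y", "z")])
}

vertex_thickness <- function(skel, ids = skel$vertices$id) {
  idx <- vertex_index(skel)[as.character(ids)]
  skel$vertices$thickness[idx]
}

# Skeleton degree of every vertex, named by id.
vertex_degrees <- function(skel) {
  ids <- as.character(skel$vertices$id)
  deg <- integer(length(ids)); names(deg) <- ids
  if (nrow(skel$edges)) {
    tab <- table(c(as.character(skel$edges$v1), as.character(skel$edges$v2)))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# Adjacency list: named list id -> integer vector of neighbour ids.
adjacency_list <- function(skel) {
  ids <- skel$vertices$id
  adj <- vector("list", length(ids)); names(adj) <- as.character(ids)
  if (nrow(skel$edges)) {
    both <- data.frame(a = c(skel$edges$v1, skel$edges$v2),
                       b = c(skel$edges$v2, skel$edges$v1))
    sp <- split(both$b, as.character(both$a))
    adj[names(sp)] <- lapply(sp, function(v) sort(as.integer(v)))
  }
  adj[vapply(adj, is.null, TRUE)] <- list(integer())
  adj
}

#' Construct a stem path
#'
#' The ordered chain of skeleton vertices representing the root stem, stored
#' top (stalk end) to bottom.  Arc lengths are cumulative mm from the top.
#'
#' @param skel a [skeleton()].
#' @param vertex_ids ordered vertex ids, first = top.
#' @return Object of class `stem_path` with fields `vertex_ids`,
#'   `arc_lengths`, `positions` (matrix), `thickness`.
#' @export
stem_path <- function(skel, vertex_ids) {
  vertex_ids <- as.integer(vertex_ids)
  if (length(vertex_ids) < 2L)
    rw_error("stem path needs at least two vertices", "stem_invalid")
  if (!all(vertex_ids %in% skel$vertices$id))
    rw_error("stem path references unknown vertex ids", "stem_invalid")
  keys <- edge_key(vertex_ids[-length(vertex_ids)], vertex_ids[-1L])
  have <- edge_key(skel$edges$v1, skel$edges$v2)
  if (!all(keys %in% have))
    rw_error("consecutive stem vertices must be skeleton edges",
             "stem_invalid")
  pos <- vertex_positions(skel, vertex_ids)
  rownames(pos) <- NULL
  seg <- unname(sqrt(rowSums(diff(pos)^2)))
  if (any(seg <= 0))
    rw_error("stem arc lengths must be strictly increasing", "stem_invalid")
  structure(list(vertex_ids = vertex_ids,
                 arc_lengths = c(0, cumsum(seg)),
                 positions = pos,
                 thickness = vertex_thickness(skel, vertex_ids)),
            class = "stem_path")
}

#' @export
print.stem_path <- function(x, ...) {
  cat(sprintf("stem path: %d vertices, %.1f mm top to bottom\n",
              length(x$vertex_ids), max(x$arc_lengths)))
  invisible(x)
}

#' Total length of a polyline
#'
#' @param points n x 3 matrix of points (mm), n >= 2.
#' @return Sum of Euclidean segment lengths in mm.
#' @export
path_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) rw_error("polyline needs >= 2 points", "polyline_invalid")
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Top-down depth of a position
#'
#' Depth is measured along the volume Z axis, zero at the stem-path top
#' vertex and increasing downward (decreasing z).  Points above the top have
#' negative depth.
#'
#' @param position 3-vector or n x 3 matrix (mm).
#' @param top_reference 3-vector: the stem-path top vertex position.
#' @return depth(s) in mm.
#' @export
depth_of <- function(position, top_reference) {
  if (is.matrix(position)) top_reference[3L] - position[, 3L]
  else top_reference[3L] - position[3L]
}

#' Read a skeleton file
#'
#' Two dialects are supported.  The text dialect is whitespace separated
#' with `#` comments: `pitch <mm>` (optional, default 0.44),
#' `v <id> <x> <y> <z> <thickness>`, `e <id1> <id2>`, and a single
#' `stem <id1> <id2> ...` record ordered top to bottom.  The PLY dialect is
#' ASCII PLY with vertex properties `x y z thickness`, an edge element with
#' `vertex1 vertex2` (0-based row indices), and the stem path in a
#' `comment stem <ids...>` line.
#'
#' @param path file path.
#' @param format `"text"` or `"ply"`; `"auto"` guesses from the extension.
#' @param flip_stem reverse the stored stem order (for files recorded
#'   bottom-to-top).
#' @return list with elements `skeleton` and `stem`.
#' @export
read_skeleton <- function(path, format = c("auto", "text", "ply"),
                          flip_stem = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) rw_error(paste0("no such file: ", path), "io_error")
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "text"
  out <- if (format == "text") read_skeleton_text(path) else read_skeleton_ply(path)
  if (flip_stem) out$stem_ids <- rev(out$stem_ids)
  if (is.null(out$stem_ids))
    rw_error(paste0(path, ": missing stem record"), "parse_error")
  skel <- skeleton(out$vertices, out$edges, voxel_pitch = out$pitch)
  list(skeleton = skel, stem = stem_path(skel, out$stem_ids))
}

read_skeleton_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- list(); es <- list(); stem_ids <- NULL; pitch <- 0.44
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (!length(tok)) next
    bad <- function(what) rw_error(
      sprintf("%s line %d: %s", path, i, what), "parse_error")
    switch(tok[1L],
      pitch = {
        if (length(tok) != 2L) bad("pitch expects one value")
        pitch <- as.numeric(tok[2L])
        if (is.na(pitch) || pitch <= 0) bad("invalid pitch")
      },
      v = {
        if (length(tok) != 6L) bad("v expects id x y z thickness")
        num <- suppressWarnings(as.numeric(tok[2:6]))
        if (anyNA(num)) bad("non-numeric vertex field")
        vs[[length(vs) + 1L]] <- num
      },
      e = {
        if (length(tok) != 3L) bad("e expects two ids")
        num <- suppressWarnings(as.integer(tok[2:3]))
        if (anyNA(num)) bad("non-integer edge id")
        es[[length(es) + 1L]] <- num
      },
      stem = {
        num <- suppressWarnings(as.integer(tok[-1L]))
        if (anyNA(num) || length(num) < 2L) bad("stem expects >= 2 ids")
        stem_ids <- num
      },
      bad(paste0("unknown record '", tok[1L], "'"))
    )
  }
  if (!length(vs)) rw_error(paste0(path, ": no vertices"), "parse_error")
  vm <- do.call(rbind, vs)
  em <- if (length(es)) do.call(rbind, es) else matrix(integer(), 0L, 2L)
  list(vertices = data.frame(id = as.integer(vm[, 1L]), x = vm[, 2L],
                             y = vm[, 3L], z = vm[, 4L], thickness = vm[, 5L]),
       edges = data.frame(v1 = em[, 1L], v2 = em[, 2L]),
       stem_ids = stem_ids, pitch = pitch)
}

read_skeleton_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply")
    rw_error(paste0(path, ": not a PLY file"), "parse_error")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) rw_error(paste0(path, ": no end_header"), "parse_error")
  header <- trimws(lines[seq_len(end)])
  nv <- ne <- 0L; stem_ids <- NULL; pitch <- 0.44
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1L]]
    if (length(tok) >= 3L && tok[1L] == "element") {
      if (tok[2L] == "vertex") nv <- as.integer(tok[3L])
      if (tok[2L] == "edge") ne <- as.integer(tok[3L])
    }
    if (length(tok) >= 2L && tok[1L] == "comment") {
      if (tok[2L] == "stem") stem_ids <- as.integer(tok[-(1:2)])
      if (tok[2L] == "pitch") pitch <- as.numeric(tok[3L])
    }
  }
  body <- lines[-seq_len(end)]
  if (length(body) < nv + ne)
    rw_error(paste0(path, ": truncated body"), "parse_error")
  vm <- do.call(rbind, lapply(body[seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]][1:4])))
  em <- if (ne > 0) do.call(rbind, lapply(body[nv + seq_len(ne)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1L]][1:2]))) else
      matrix(integer(), 0L, 2L)
  list(vertices = data.frame(id = seq_len(nv) - 1L, x = vm[, 1L], y = vm[, 2L],
                             z = vm[, 3L], thickness = vm[, 4L]),
       edges = data.frame(v1 = em[, 1L], v2 = em[, 2L]),
       stem_ids = stem_ids, pitch = pitch)
}

#' Write a skeleton file
#'
#' @param skel a [skeleton()].
#' @param stem a [stem_path()].
#' @param path output file.
#' @param format `"text"` or `"ply"` (see [read_skeleton()]).
#' @param edge_labels optional integer vector of hierarchy labels, one per
#'   edge row; written as `label <edge-index> <int>` lines (1-based index,
#'   text dialect only).
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(skel, stem, path, format = c("text", "ply"),
                           edge_labels = NULL) {
  format <- match.arg(format)
  v <- skel$vertices; e <- skel$edges
  if (format == "text") {
    lines <- c(
      sprintf("pitch %.6g", skel$voxel_pitch),
      sprintf("v %d %.6f %.6f %.6f %.6f", v$id, v$x, v$y, v$z, v$thickness),
      if (nrow(e)) sprintf("e %d %d", e$v1, e$v2),
      paste("stem", paste(stem$vertex_ids, collapse = " ")))
    if (!is.null(edge_labels)) {
      stopifnot(length(edge_labels) == nrow(e))
      lines <- c(lines, sprintf("label %d %d", seq_len(nrow(e)), edge_labels))
    }
  } else {
    idx0 <- seq_len(nrow(v)) - 1L
    names(idx0) <- as.character(v$id)
    lines <- c(
      "ply", "format ascii 1.0",
      sprintf("comment pitch %.6g", skel$voxel_pitch),
      paste("comment stem",
            paste(idx0[as.character(stem$vertex_ids)], collapse = " ")),
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      "property float thickness",
      sprintf("element edge %d", nrow(e)),
      "property int vertex1", "property int vertex2",
      "end_header",
      sprintf("%.6f %.6f %.6f %.6f", v$x, v$y, v$z, v$thickness),
      if (nrow(e)) sprintf("%d %d", idx0[as.character(e$v1)],
                           idx0[as.character(e$v2)]))
  }
  writeLines(lines, path)
  invisible(path)
}
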
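#' Triangulated surface mesh
#'
#' Constructs and validates a closed triangulated surface used to represent
#' the torso boundary or a cardiac surface.  Coordinates are in millimetres,
#' node indexing is 1-based, and triangles must be consistently oriented with
#' outward-pointing normals.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices.
#' @param role one of `"torso"`, `"epicardium"`, `"endocardium"`.
#' @param validate if `TRUE` (default) enforce the closed-manifold,
#'   orientation and non-degeneracy invariants; a violation is an error that
#'   names the offending element.
#' @return an object of class `tri_surface_mesh` with components
#'   `vertices`, `triangles` and `role`.
#' @seealso [icosphere()], [read_mesh()], [mesh_area()]
#' @export
tri_surface_mesh <- function(vertices, triangles,
                             role = c("torso", "epicardium", "endocardium"),
                             validate = TRUE) {
  role <- match.arg(role)
  vertices <- as_matrix3(vertices, "vertices")
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3) stopf("triangles must have 3 columns")
  storage.mode(triangles) <- "integer"
  mesh <- structure(list(vertices = vertices, triangles = unname(triangles),
                         role = role),
                    class = "tri_surface_mesh")
  if (validate) validate_surface(mesh)
  mesh
}

validate_surface <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  if (any(tr < 1L) || any(tr > n)) stopf("triangle indices out of range 1..%d", n)
  a <- triangle_areas(mesh)
  if (any(a <= 1e-12 * max(a)))
    stopf("degenerate (zero-area) triangle at index %d", which(a <= 1e-12 * max(a))[1])
  # each undirected edge must appear in exactly 2 triangles (closed 2-manifold)
  e1 <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key_u <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  cnt <- table(key_u)
  if (any(cnt != 2L)) {
    bad <- names(cnt)[cnt != 2L][1]
    tri_of <- which(key_u == bad)[1] %% nrow(tr)
    if (tri_of == 0) tri_of <- nrow(tr)
    stopf("surface is not a closed 2-manifold: edge (%s) lies on %d triangle(s), e.g. triangle %d",
          gsub(" ", ",", bad), cnt[[bad]], tri_of)
  }
  # consistent orientation: every directed edge appears exactly once
  key_d <- paste(e1[, 1], e1[, 2])
  dup <- duplicated(key_d)
  if (any(dup)) {
    bad <- which(dup)[1]
    tri_of <- bad %% nrow(tr); if (tri_of == 0) tri_of <- nrow(tr)
    stopf("inconsistent triangle orientation: directed edge (%d,%d) repeated, triangle %d is flipped",
          e1[bad, 1], e1[bad, 2], tri_of)
  }
  if (mesh_signed_volume(mesh) <= 0)
    stopf("surface normals are not outward oriented (signed volume <= 0)")
  invisible(mesh)
}

#' @export
print.tri_surface_mesh <- function(x, ...) {
  cat(sprintf("tri_surface_mesh (%s): %d vertices, %d triangles, area %.6g mm^2\n",
              x$role, nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Triangle areas of a surface mesh
#' @param mesh a `tri_surface_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  0.5 * row_norms(cross3(v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE],
                         v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]))
}

#' Total surface area
#' @inheritParams triangle_areas
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Signed enclosed volume of a closed oriented surface
#' @inheritParams triangle_areas
#' @return signed volume (mm^3); positive for outward orientation.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  sum(rowSums(p1 * cross3(p2, p3))) / 6
}

mean_edge_length <- function(vertices, edges) {
  mean(row_norms(vertices[edges[, 1], , drop = FALSE] -
                 vertices[edges[, 2], , drop = FALSE]))
}

surface_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mean edge length of a surface mesh
#' @inheritParams triangle_areas
#' @return mean edge length in mm.
#' @export
surface_mean_edge <- function(mesh) mean_edge_length(mesh$vertices, surface_edges(mesh))

# ---------------------------------------------------------------------------
# geodesic icosphere
# ---------------------------------------------------------------------------

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = normalize_rows(v), faces = f)
}

#' Geodesic icosphere surface mesh
#'
#' Builds a quasi-uniform triangulation of the sphere by frequency-`freq`
#' subdivision of the icosahedron (each icosahedral edge is split into
#' `freq` segments), giving `10*freq^2 + 2` vertices and edge lengths of
#' roughly `1.05 * radius / freq`.
#'
#' @param radius sphere radius in mm.
#' @param freq subdivision frequency (positive integer).
#' @param center 3-vector, sphere center (default origin).
#' @param role passed to [tri_surface_mesh()].
#' @return a `tri_surface_mesh`.
#' @export
icosphere <- function(radius = 1, freq = 4, center = c(0, 0, 0),
                      role = "torso") {
  stopifnot(freq >= 1, radius > 0)
  ico <- icosahedron()
  nv <- freq + 1L
  key_env <- new.env(hash = TRUE, size = 10 * freq^2 + 64)
  verts <- list(); nvert <- 0L
  get_vertex <- function(key, pos) {
    id <- key_env[[key]]
    if (is.null(id)) {
      nvert <<- nvert + 1L
      verts[[nvert]] <<- pos
      key_env[[key]] <- nvert
      id <- nvert
    }
    id
  }
  faces <- vector("list", 20L)
  for (fi in seq_len(20L)) {
    co <- ico$faces[fi, ]
    idx <- matrix(0L, nv, nv)   # idx[i+1, j+1] for lattice (i,j)
    for (i in 0:freq) for (j in 0:(freq - i)) {
      l <- c(freq - i - j, i, j)
      if (sum(l == 0) == 2) {               # corner
        key <- paste0("V", co[which(l == freq)])
      } else if (any(l == 0)) {             # edge point
        z <- which(l == 0)
        pair <- co[-z]; tt <- l[-z]
        if (pair[1] < pair[2]) key <- paste0("E", pair[1], "_", pair[2], "_", tt[2])
        else key <- paste0("E", pair[2], "_", pair[1], "_", tt[1])
      } else {
        key <- paste0("F", fi, "_", i, "_", j)
      }
      pos <- (l[1] * ico$vertices[co[1], ] + l[2] * ico$vertices[co[2], ] +
              l[3] * ico$vertices[co[3], ]) / freq
      idx[i + 1, j + 1] <- get_vertex(key, pos)
    }
    fl <- list(); nf <- 0L
    for (i in 0:(freq - 1)) for (j in 0:(freq - 1 - i)) {
      nf <- nf + 1L
      fl[[nf]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1], idx[i + 1, j + 2])
      if (j < freq - 1 - i) {
        nf <- nf + 1L
        fl[[nf]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2], idx[i + 1, j + 2])
      }
    }
    faces[[fi]] <- do.call(rbind, fl)
  }
  v <- normalize_rows(do.call(rbind, verts)) * radius
  v <- sweep(v, 2, center, "+")
  tri_surface_mesh(v, do.call(rbind, faces), role = role)
}

# unit directions and faces of a freq-nu icosphere (no dedup recompute cost)
icosphere_directions <- function(freq) {
  s <- icosphere(1, freq)
  list(dirs = s$vertices, faces = s$triangles)
}

# ---------------------------------------------------------------------------
# electrodes
# ---------------------------------------------------------------------------

#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @param radius sphere radius.
#' @param center sphere center.
#' @return n x 3 matrix of coordinates.
#' @export
fibonacci_sphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)        # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi * i), r * sin(phi * i), z) * radius
  sweep(p, 2, center, "+")
}

#' Electrode set attached to a torso surface
#'
#' Snaps each electrode position to the nearest torso-surface vertex.
#' Attached vertices are forced to be distinct (greedy nearest unclaimed
#' vertex), so that every electrode corresponds to a unique nodal load in
#' the finite element transfer computation.
#'
#' @param positions M x 3 matrix of electrode coordinates (mm).
#' @param surface torso `tri_surface_mesh` (or a `tet_volume_mesh`, in which
#'   case the boundary vertices are used).
#' @param boundary_vertices optional integer vector restricting candidate
#'   vertices (e.g. boundary vertex indices of a volume mesh).
#' @return an object of class `electrode_set` with `positions`,
#'   `attached_vertex` (index into the surface/volume vertex list) and
#'   `attached_position`.
#' @export
electrode_set <- function(positions, surface, boundary_vertices = NULL) {
  positions <- as_matrix3(positions, "electrode positions")
  if (nrow(positions) < 2) stopf("need at least 2 electrodes")
  verts <- surface$vertices
  cand <- boundary_vertices %||% seq_len(nrow(verts))
  taken <- logical(nrow(verts))
  att <- integer(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    d2 <- rowSums(sweep(verts[cand, , drop = FALSE], 2, positions[i, ])^2)
    ord <- order(d2)
    j <- 1L
    while (taken[cand[ord[j]]]) j <- j + 1L
    att[i] <- cand[ord[j]]
    taken[att[i]] <- TRUE
  }
  structure(list(positions = positions,
                 attached_vertex = att,
                 attached_position = verts[att, , drop = FALSE]),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("electrode_set: %d electrodes, max snap offset %.3g mm\n",
              nrow(x$positions),
              max(row_norms(x$positions - x$attached_position))))
  invisible(x)
}

#' Read electrode positions from CSV
#'
#' The file must have a header with columns `id,x,y,z` (coordinates in mm).
#'
#' @param path CSV file path.
#' @return matrix of positions with rownames from the `id` column.
#' @export
read_electrodes_csv <- function(path) {
  d <- read.csv(path)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(d)))
    stopf("electrode CSV must have header columns id,x,y,z")
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- as.character(d$id)
  m
}

#' Write electrode positions to CSV
#' @param positions M x 3 matrix.
#' @param path output file.
#' @export
write_electrodes_csv <- function(positions, path) {
  ids <- rownames(positions) %||% seq_len(nrow(positions))
  write.csv(data.frame(id = ids, x = positions[, 1], y = positions[, 2],
                       z = positions[, 3]),
            path, row.names = FALSE)
  invisible(path)
}
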
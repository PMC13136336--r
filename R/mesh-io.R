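#' Read a surface or volume mesh from file
#'
#' Supported formats: legacy ASCII VTK (`.vtk`, POLYDATA or
#' UNSTRUCTURED_GRID), OFF (`.off`) and ASCII STL (`.stl`; duplicate
#' vertices are welded).  Units are assumed to be millimetres.  The mesh is
#' validated on load; a non-manifold or inconsistently oriented surface, or
#' an inverted tetrahedron, raises an error naming the offending element.
#'
#' @param path file path.
#' @param role surface role (`"torso"`, `"epicardium"`, `"endocardium"`);
#'   ignored for volume meshes.
#' @param heart_node_mask optional logical mask for volume meshes; when
#'   absent it is read from a `heart` point-data array if present, else all
#'   nodes are marked.
#' @return a [tri_surface_mesh()] or [tet_volume_mesh()].
#' @export
read_mesh <- function(path, role = "torso", heart_node_mask = NULL) {
  if (!file.exists(path)) stopf("cannot read mesh file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    vtk = read_vtk_legacy(path),
    off = read_off(path),
    stl = read_stl_ascii(path),
    stopf("unsupported mesh format '.%s' (use .vtk, .off or .stl)", ext))
  if (!is.null(parsed$tets)) {
    hm <- heart_node_mask %||% parsed$heart %||% rep(TRUE, nrow(parsed$vertices))
    tet_volume_mesh(parsed$vertices, parsed$tets, hm)
  } else {
    tri_surface_mesh(parsed$vertices, parsed$triangles, role = role)
  }
}

read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!grepl("^OFF", ln[1])) stopf("'%s' is not an OFF file", path)
  cnt <- scan(text = ln[2], quiet = TRUE)
  nv <- cnt[1]; nf <- cnt[2]
  v <- matrix(scan(text = paste(ln[3:(2 + nv)], collapse = "\n"), quiet = TRUE),
              ncol = 3, byrow = TRUE)
  fc <- lapply(ln[(3 + nv):(2 + nv + nf)], function(s) scan(text = s, quiet = TRUE))
  if (any(vapply(fc, function(x) x[1], 0) != 3)) stopf("only triangle faces supported")
  f <- do.call(rbind, lapply(fc, function(x) x[2:4] + 1))
  list(vertices = v, triangles = f)
}

read_stl_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  xyz <- matrix(scan(text = gsub("^\\s*vertex", "", vl), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  if (nrow(xyz) %% 3 != 0) stopf("malformed ASCII STL '%s'", path)
  key <- paste(signif(xyz[, 1], 10), signif(xyz[, 2], 10), signif(xyz[, 3], 10))
  uid <- match(key, unique(key))
  v <- xyz[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = v, triangles = f)
}

read_vtk_legacy <- function(path) {
  ln <- readLines(path, warn = FALSE)
  grab_block <- function(start, n_items) {
    vals <- c(); i <- start
    while (length(vals) < n_items && i <= length(ln)) {
      vals <- c(vals, scan(text = ln[i], quiet = TRUE))
      i <- i + 1
    }
    vals
  }
  ip <- grep("^POINTS", ln)[1]
  if (is.na(ip)) stopf("no POINTS section in '%s'", path)
  np <- as.integer(strsplit(trimws(ln[ip]), "\\s+")[[1]][2])
  v <- matrix(grab_block(ip + 1, 3 * np), ncol = 3, byrow = TRUE)
  out <- list(vertices = v)
  icell <- grep("^(POLYGONS|CELLS)", ln)[1]
  if (is.na(icell)) stopf("no POLYGONS/CELLS section in '%s'", path)
  hdr <- strsplit(trimws(ln[icell]), "\\s+")[[1]]
  nc <- as.integer(hdr[2]); ntot <- as.integer(hdr[3])
  cells <- grab_block(icell + 1, ntot)
  # split into per-cell vectors
  conn <- vector("list", nc); pos <- 1
  for (k in seq_len(nc)) {
    m <- cells[pos]
    conn[[k]] <- cells[(pos + 1):(pos + m)] + 1
    pos <- pos + m + 1
  }
  sizes <- lengths(conn)
  types <- NULL
  it <- grep("^CELL_TYPES", ln)[1]
  if (!is.na(it)) types <- grab_block(it + 1, nc)
  if (!is.null(types) && any(types == 10)) {
    out$tets <- do.call(rbind, conn[types == 10])
  } else if (all(sizes == 3)) {
    out$triangles <- do.call(rbind, conn)
  } else if (all(sizes == 4)) {
    out$tets <- do.call(rbind, conn)
  } else stopf("mixed or unsupported cell types in '%s'", path)
  ipd <- grep("^POINT_DATA", ln)[1]
  if (!is.na(ipd)) {
    ih <- grep("^SCALARS heart", ln)
    if (length(ih) > 0) {
      vals <- grab_block(ih[1] + 2, np)  # skip LOOKUP_TABLE line
      out$heart <- vals > 0.5
    }
  }
  out
}

#' Write a mesh as legacy ASCII VTK
#'
#' Surfaces are written as POLYDATA, volume meshes as UNSTRUCTURED_GRID
#' (with a `heart` point-data array holding the heart node mask).  Optional
#' nodal scalar fields (e.g. an activation time map) are appended as
#' POINT_DATA arrays.  Coordinates are written with 17 significant digits so
#' a write/read round trip is exact to double precision.
#'
#' @param mesh a `tri_surface_mesh` or `tet_volume_mesh`.
#' @param path output file path.
#' @param point_data named list of numeric vectors (one value per node).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  v <- mesh$vertices
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c("# vtk DataFile Version 3.0", "volmap mesh", "ASCII"), con)
  is_vol <- inherits(mesh, "tet_volume_mesh")
  writeLines(sprintf("DATASET %s",
                     if (is_vol) "UNSTRUCTURED_GRID" else "POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", nrow(v)), con)
  writeLines(paste(fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
  if (is_vol) {
    tt <- mesh$tets
    writeLines(sprintf("CELLS %d %d", nrow(tt), 5 * nrow(tt)), con)
    writeLines(paste(4, tt[, 1] - 1, tt[, 2] - 1, tt[, 3] - 1, tt[, 4] - 1), con)
    writeLines(sprintf("CELL_TYPES %d", nrow(tt)), con)
    writeLines(as.character(rep(10L, nrow(tt))), con)
    point_data <- c(list(heart = as.numeric(mesh$heart_node_mask)), point_data)
  } else {
    tr <- mesh$triangles
    writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
    writeLines(paste(3, tr[, 1] - 1, tr[, 2] - 1, tr[, 3] - 1), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(fmt(as.numeric(point_data[[nm]])), con)
    }
  }
  invisible(path)
}
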
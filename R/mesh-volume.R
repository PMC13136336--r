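#' Tetrahedral volume mesh
#'
#' Constructs and validates a tetrahedral discretization of the full torso
#' interior.  The myocardial shell is marked by `heart_node_mask`; those P
#' nodes carry the unknown volumetric cardiac sources.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param tets integer matrix (m x 4) of 1-based node indices; all signed
#'   volumes must be positive.
#' @param heart_node_mask logical vector of length n marking myocardial nodes.
#' @param validate enforce invariants (positive volumes, closed boundary,
#'   connected heart subgraph).
#' @return object of class `tet_volume_mesh` with the fields above plus
#'   cached `boundary_faces` (closed outward-oriented boundary triangles).
#' @export
tet_volume_mesh <- function(vertices, tets, heart_node_mask, validate = TRUE) {
  vertices <- as_matrix3(vertices, "vertices")
  tets <- as.matrix(tets)
  if (ncol(tets) != 4) stopf("tets must have 4 columns")
  storage.mode(tets) <- "integer"
  heart_node_mask <- as.logical(heart_node_mask)
  if (length(heart_node_mask) != nrow(vertices))
    stopf("heart_node_mask length must equal vertex count")
  mesh <- structure(list(vertices = vertices, tets = unname(tets),
                         heart_node_mask = heart_node_mask),
                    class = "tet_volume_mesh")
  vol <- tet_volumes(mesh)
  if (validate && any(vol <= 0))
    stopf("inverted or degenerate tetrahedron at index %d (signed volume %.3g)",
          which(vol <= 0)[1], min(vol))
  mesh$boundary_faces <- boundary_faces(mesh)
  if (validate) {
    bf <- mesh$boundary_faces
    e1 <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(3, 1)])
    cnt <- table(paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2])))
    if (any(cnt != 2L)) stopf("boundary triangulation of the volume mesh is not closed")
    if (any(heart_node_mask) && !heart_connected(mesh))
      stopf("heart nodes do not form a connected subgraph")
  }
  mesh
}

#' @export
print.tet_volume_mesh <- function(x, ...) {
  cat(sprintf("tet_volume_mesh: %d nodes (%d heart), %d tets, volume %.6g mm^3\n",
              nrow(x$vertices), sum(x$heart_node_mask), nrow(x$tets),
              sum(tet_volumes(x))))
  invisible(x)
}

#' Signed tetrahedron volumes
#' @param mesh a `tet_volume_mesh`.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  v <- mesh$vertices; tt <- mesh$tets
  a <- v[tt[, 2], , drop = FALSE] - v[tt[, 1], , drop = FALSE]
  b <- v[tt[, 3], , drop = FALSE] - v[tt[, 1], , drop = FALSE]
  d <- v[tt[, 4], , drop = FALSE] - v[tt[, 1], , drop = FALSE]
  rowSums(a * cross3(b, d)) / 6
}

# swap nodes 3,4 of negatively oriented tets
orient_tets <- function(vertices, tets) {
  m <- structure(list(vertices = vertices, tets = tets), class = "tet_volume_mesh")
  neg <- tet_volumes(m) < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

# outward-oriented boundary triangles: faces belonging to exactly one tet.
# face k of a positively oriented tet, listed with outward orientation:
tet_faces_outward <- function(tets) {
  rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
        tets[, c(1, 4, 3)], tets[, c(2, 3, 4)])
}

boundary_faces <- function(mesh) {
  f <- tet_faces_outward(mesh$tets)
  key <- paste(pmin(f[, 1], pmin(f[, 2], f[, 3])),
               f[, 1] + f[, 2] + f[, 3],
               pmax(f[, 1], pmax(f[, 2], f[, 3])))
  cnt <- table(key)
  f[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

#' Boundary surface of a volume mesh
#' @param mesh a `tet_volume_mesh`.
#' @param role role for the extracted surface.
#' @return a `tri_surface_mesh` re-indexed over the boundary vertices, with
#'   attribute `"vertex_map"` giving the original node index per surface vertex.
#' @export
boundary_surface <- function(mesh, role = "torso") {
  bf <- mesh$boundary_faces
  vb <- sort(unique(as.vector(bf)))
  remap <- integer(nrow(mesh$vertices)); remap[vb] <- seq_along(vb)
  s <- tri_surface_mesh(mesh$vertices[vb, , drop = FALSE],
                        matrix(remap[bf], ncol = 3), role = role)
  attr(s, "vertex_map") <- vb
  s
}

boundary_vertex_ids <- function(mesh) sort(unique(as.vector(mesh$boundary_faces)))

heart_connected <- function(mesh) {
  g <- heart_edge_graph(mesh)
  igraph::count_components(g) == 1
}

#' Lumped nodal volume weights of the myocardium
#'
#' Each tetrahedron contributes a quarter of its volume to each of its nodes;
#' the result is restricted to heart nodes.  These weights are the discrete
#' quadrature of the volume integral in the source existence condition
#' `integral(f) dV = 0`, and the single constraint row used by the
#' constrained volumetric inverse solver.
#'
#' @param mesh a `tet_volume_mesh`.
#' @return object of class `volume_weights`: numeric vector (one weight per
#'   heart node, mm^3) with attribute `"nodes"` giving heart node indices.
#' @export
node_volume_weights <- function(mesh) {
  vol <- tet_volumes(mesh)
  w_all <- rep(0, nrow(mesh$vertices))
  for (k in 1:4) {
    acc <- rowsum(vol / 4, mesh$tets[, k])
    idx <- as.integer(rownames(acc))
    w_all[idx] <- w_all[idx] + acc[, 1]
  }
  nodes <- which(mesh$heart_node_mask)
  # restrict to the myocardial subdomain: only tets fully inside the heart
  ht <- heart_tets(mesh)
  if (length(ht) > 0) {
    vol_h <- vol[ht]
    w <- rep(0, nrow(mesh$vertices))
    for (k in 1:4) {
      acc <- rowsum(vol_h / 4, mesh$tets[ht, k])
      idx <- as.integer(rownames(acc))
      w[idx] <- w[idx] + acc[, 1]
    }
    w <- w[nodes]
  } else w <- w_all[nodes]
  if (any(w <= 0)) stopf("non-positive volume weight at heart node %d", nodes[which(w <= 0)[1]])
  structure(w, nodes = nodes, class = "volume_weights")
}

# indices of tets all four nodes of which are heart nodes
heart_tets <- function(mesh) {
  hm <- mesh$heart_node_mask
  which(hm[mesh$tets[, 1]] & hm[mesh$tets[, 2]] &
        hm[mesh$tets[, 3]] & hm[mesh$tets[, 4]])
}

# ---------------------------------------------------------------------------
# edge graphs and geodesics
# ---------------------------------------------------------------------------

unique_edges_from <- function(pairs) {
  e <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(e)
}

tet_edges <- function(tets) {
  unique_edges_from(rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                          tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)]))
}

edge_graph <- function(vertices, edges) {
  w <- row_norms(vertices[edges[, 1], , drop = FALSE] -
                 vertices[edges[, 2], , drop = FALSE])
  igraph::graph_from_edgelist(edges, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

# graph over heart nodes only (myocardial tet edge graph); vertex ids are
# global node indices
heart_edge_graph <- function(mesh) {
  hm <- mesh$heart_node_mask
  ed <- tet_edges(mesh$tets[heart_tets(mesh), , drop = FALSE])
  ed <- ed[hm[ed[, 1]] & hm[ed[, 2]], , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  w <- row_norms(mesh$vertices[ed[, 1], , drop = FALSE] -
                 mesh$vertices[ed[, 2], , drop = FALSE])
  g <- igraph::add_edges(g, t(ed), weight = w)
  igraph::induced_subgraph(g, which(hm))
}

mesh_graph <- function(mesh) {
  if (inherits(mesh, "tri_surface_mesh")) {
    g <- edge_graph(mesh$vertices, surface_edges(mesh))
    attr(g, "nodes") <- seq_len(nrow(mesh$vertices))
  } else if (inherits(mesh, "tet_volume_mesh")) {
    g <- heart_edge_graph(mesh)
    attr(g, "nodes") <- which(mesh$heart_node_mask)
  } else stopf("unsupported mesh class")
  g
}

#' Geodesic distance between two mesh nodes
#'
#' Shortest path over the mesh edge graph with Euclidean edge lengths.  For
#' a surface mesh the surface edge graph is used; for a volume mesh the
#' myocardial tetrahedral edge graph (restricted to heart nodes) is used.
#' The edge-graph geodesic overestimates the exact continuous geodesic by a
#' bounded lattice-inflation factor.
#'
#' @param mesh a `tri_surface_mesh` or `tet_volume_mesh`.
#' @param node_a,node_b node indices (global node indexing of the mesh).
#' @return distance in mm; `Inf` when the nodes are disconnected.
#' @export
geodesic_distance <- function(mesh, node_a, node_b) {
  if (node_a == node_b) return(0)
  g <- mesh_graph(mesh)
  nodes <- attr(g, "nodes")
  ia <- match(node_a, nodes); ib <- match(node_b, nodes)
  if (is.na(ia) || is.na(ib))
    stopf("node %d is not in the relevant structure (heart subgraph / surface)",
          if (is.na(ia)) node_a else node_b)
  as.numeric(igraph::distances(g, v = ia, to = ib))
}

# all-pairs from one source over a prebuilt graph (helper for benchmarks)
geodesic_from <- function(graph, node) {
  nodes <- attr(graph, "nodes")
  i <- match(node, nodes)
  d <- as.numeric(igraph::distances(graph, v = i))
  names(d) <- nodes
  d
}

# ---------------------------------------------------------------------------
# radial layered tetrahedralization (star-shaped domains)
# ---------------------------------------------------------------------------

# Build a conforming tet mesh of a star-shaped domain given radius functions.
# dirs: unit direction matrix (one ray per lattice direction); faces: their
# triangulation; radii_frac: per-layer list of per-direction radii (increasing
# along each ray).  Prisms between consecutive layers are split into three
# tets with the index-ordering rule of Dompierre et al., which guarantees
# matching diagonals on shared quadrilateral faces.
radial_layer_mesh <- function(dirs, faces, layer_radii, center = c(0, 0, 0),
                              heart_layers = integer(0)) {
  nd <- nrow(dirs); nl <- ncol(layer_radii)
  stopifnot(nrow(layer_radii) == nd)
  verts <- matrix(0, 1 + nd * nl, 3)
  verts[1, ] <- center
  for (l in seq_len(nl))
    verts[1 + (l - 1) * nd + seq_len(nd), ] <-
      sweep(dirs * layer_radii[, l], 2, center, "+")
  lid <- function(l) 1 + (l - 1) * nd   # offset of layer l
  tets <- vector("list", nl)
  # central fan: center to first layer
  f1 <- faces + lid(1)
  tets[[1]] <- cbind(1L, f1[, 1], f1[, 2], f1[, 3])
  split_prism <- function(bot, top) {
    # bot, top: m x 3 global indices, bot[k] below top[k]; smallest index is
    # always in bot since layer indices increase.  Vectorized index-ordering
    # rule (Dompierre et al.): rotate so the smallest bottom index leads,
    # then pick the diagonal by comparing shared quad-face indices.
    m <- nrow(bot)
    r <- max.col(-bot, ties.method = "first")          # which.min per row
    ord1 <- r; ord2 <- r %% 3 + 1; ord3 <- ord2 %% 3 + 1
    pick <- function(mat, ord) mat[cbind(seq_len(m), ord)]
    v1 <- pick(bot, ord1); v2 <- pick(bot, ord2); v3 <- pick(bot, ord3)
    v4 <- pick(top, ord1); v5 <- pick(top, ord2); v6 <- pick(top, ord3)
    caseA <- pmin(v2, v6) < pmin(v3, v5)
    out <- matrix(0L, 3 * m, 4)
    idx <- 3 * (seq_len(m) - 1)
    out[idx + 1, ] <- cbind(v1, v2, v3, ifelse(caseA, v6, v5))
    out[idx + 2, ] <- cbind(v1, ifelse(caseA, v2, v5), ifelse(caseA, v6, v3),
                            ifelse(caseA, v5, v6))
    out[idx + 3, ] <- cbind(v1, v5, v6, v4)
    out
  }
  for (l in seq_len(nl - 1)) {
    bot <- faces + lid(l); top <- faces + lid(l + 1)
    tets[[l + 1]] <- split_prism(bot, top)
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(verts, tets)
  hm <- logical(nrow(verts))
  for (l in heart_layers) hm[lid(l) + seq_len(nd)] <- TRUE
  tet_volume_mesh(verts, tets, hm)
}

# per-direction radius of a star-shaped closed surface seen from `center`
ray_surface_radius <- function(surface, dirs, center) {
  v <- sweep(surface$vertices, 2, center)
  tr <- surface$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - p1
  e2 <- v[tr[, 3], , drop = FALSE] - p1
  out <- rep(NA_real_, nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    # Moller-Trumbore, vectorized over triangles
    pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                d[3] * e2[, 1] - d[1] * e2[, 3],
                d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    tv <- -p1
    u <- rowSums(tv * pv) / det
    qv <- cross3(tv, e1)
    vv <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
    tt <- rowSums(e2 * qv) / det
    hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 0
    if (!any(hit)) stopf("ray %d does not intersect surface; domain not star-shaped from center", i)
    out[i] <- min(tt[hit])
  }
  out
}

# layer radius fractions for the three radial zones
radial_layer_plan <- function(mean_hi, mean_ho, mean_torso, target_heart, grade = 1.45) {
  n_heart <- max(2L, round((mean_ho - mean_hi) / target_heart))
  # inner zone: a few coarse layers from center to endocardium
  n_inner <- max(2L, round(mean_hi / (3 * target_heart)))
  inner <- seq_len(n_inner) / n_inner            # fractions of r_hi, exclusive of 0
  heart <- seq_len(n_heart) / n_heart            # fractions of (r_ho - r_hi)
  # outer zone: geometrically graded spacings from target_heart up, rescaled
  # to exactly fill the gap between epicardium and torso
  gap <- mean_torso - mean_ho
  sp <- target_heart * grade
  spac <- c()
  while (sum(spac) < gap) { spac <- c(spac, sp); sp <- sp * grade }
  outer <- cumsum(spac) / sum(spac)
  list(inner = inner, heart = heart, outer = outer,
       heart_layer_ids = n_inner + 0:n_heart)
}

#' Tetrahedralize a torso with an embedded myocardial shell
#'
#' Builds a conforming tetrahedral mesh of the full torso interior from
#' closed triangulated surfaces, with the myocardial shell (between
#' `heart_outer` and `heart_inner`) marked in the heart node mask.  The
#' mesher is a radially layered lattice: it requires all three surfaces to
#' be star-shaped as seen from the heart center (satisfied by the
#' sphere/ellipsoid phantoms this package targets); surface nodes are placed
#' exactly on the ray-surface intersections.
#'
#' @param torso,heart_outer closed `tri_surface_mesh` objects; `heart_outer`
#'   strictly inside `torso`.
#' @param heart_inner closed surface of the cavity, or `NULL` for a full
#'   (non-hollow) heart; when `NULL` the shell extends to 0.55 of the outer
#'   radius.
#' @param target_edge_mm target edge length in the myocardial shell (mm);
#'   edges coarsen geometrically away from the heart.
#' @param center ray origin; default the centroid of `heart_outer` vertices.
#' @param freq optional explicit angular subdivision frequency of the
#'   radial lattice (overrides the target-edge rule; mainly for deliberately
#'   coarse meshes).
#' @return a `tet_volume_mesh`.
#' @export
tetrahedralize <- function(torso, heart_outer, heart_inner = NULL,
                           target_edge_mm = 3.5, center = NULL, freq = NULL) {
  center <- center %||% colMeans(heart_outer$vertices)
  r_ho_mean <- mean(row_norms(sweep(heart_outer$vertices, 2, center)))
  # angular frequency: resolve the myocardial shell at the target edge, with
  # a floor of 10 so boundary faceting keeps the enclosed volume within ~1.5%
  freq <- freq %||% max(10L, round(1.2 * r_ho_mean * 0.85 / target_edge_mm))
  ic <- icosphere_directions(freq)
  r_t <- ray_surface_radius(torso, ic$dirs, center)
  r_ho <- ray_surface_radius(heart_outer, ic$dirs, center)
  if (any(r_ho >= r_t)) stopf("heart surface is not strictly inside the torso")
  if (!is.null(heart_inner)) {
    r_hi <- ray_surface_radius(heart_inner, ic$dirs, center)
    if (any(r_hi >= r_ho)) stopf("heart_inner is not strictly inside heart_outer")
  } else r_hi <- 0.55 * r_ho
  plan <- radial_layer_plan(mean(r_hi), mean(r_ho), mean(r_t), target_edge_mm)
  nlay <- length(plan$inner) + length(plan$heart) + length(plan$outer)
  radii <- matrix(0, nrow(ic$dirs), nlay)
  l <- 0
  for (fr in plan$inner) { l <- l + 1; radii[, l] <- fr * r_hi }
  for (fr in plan$heart) { l <- l + 1; radii[, l] <- r_hi + fr * (r_ho - r_hi) }
  for (fr in plan$outer) { l <- l + 1; radii[, l] <- r_ho + fr * (r_t - r_ho) }
  radial_layer_mesh(ic$dirs, ic$faces, radii, center = center,
                    heart_layers = plan$heart_layer_ids)
}

# ---------------------------------------------------------------------------
# structured box mesh (test fixture generator)
# ---------------------------------------------------------------------------

#' Structured tetrahedral box mesh
#'
#' Kuhn subdivision (6 tets per cell) of a structured grid; useful as an
#' analytically tractable fixture.  All nodes are marked as heart nodes.
#'
#' @param nx,ny,nz number of cells per axis.
#' @param spacing cell edge length in mm (scalar or 3-vector).
#' @return a `tet_volume_mesh`.
#' @export
box_tet_mesh <- function(nx = 4, ny = 2, nz = 2, spacing = 1) {
  spacing <- rep(spacing, length.out = 3)
  gx <- (0:nx) * spacing[1]; gy <- (0:ny) * spacing[2]; gz <- (0:nz) * spacing[3]
  id <- function(i, j, k) i + (nx + 1) * (j + (ny + 1) * k) + 1L
  verts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # Kuhn: 6 tets around the main diagonal (v0, v7)
  perms <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                 c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  tl <- list(); n <- 0L
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    corner <- c(id(i, j, k),     id(i + 1, j, k),     id(i, j + 1, k),     id(i + 1, j + 1, k),
                id(i, j, k + 1), id(i + 1, j, k + 1), id(i, j + 1, k + 1), id(i + 1, j + 1, k + 1))
    for (p in 1:6) { n <- n + 1L; tl[[n]] <- corner[perms[p, ]] }
  }
  tets <- orient_tets(verts, do.call(rbind, tl))
  tet_volume_mesh(verts, tets, rep(TRUE, nrow(verts)))
}
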
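# Boundary element discretization of the epicardial (Cauchy/Laplace) ECGI
# formulation: potentials on the torso surface T and the epicardial surface
# H bound by Green's representation in the source-free homogeneous domain
# between them, with an insulated torso (zero normal current).  Vertex
# collocation with panel-lumped linear weighting; the double-layer diagonal
# is closed by the solid-angle row-sum identity (the discrete statement
# that a constant potential with zero epicardial flux is an exact solution).

# solid angles of triangles (rows of idx into verts) seen from point y
# (van Oosterom & Strackee), vectorized over triangles; sign follows the
# triangle orientation
triangle_solid_angles <- function(y, verts, tris) {
  r1 <- sweep(verts[tris[, 1], , drop = FALSE], 2, y)
  r2 <- sweep(verts[tris[, 2], , drop = FALSE], 2, y)
  r3 <- sweep(verts[tris[, 3], , drop = FALSE], 2, y)
  n1 <- row_norms(r1); n2 <- row_norms(r2); n3 <- row_norms(r3)
  num <- rowSums(r1 * cross3(r2, r3))
  den <- n1 * n2 * n3 + rowSums(r1 * r2) * n3 +
         rowSums(r1 * r3) * n2 + rowSums(r2 * r3) * n1
  2 * atan2(num, den)
}

# single-layer potential row with linear (hat) vertex basis: the j-th entry
# approximates  int hat_j(x) / (4 pi |y - x|) dS  over the heart surface.
# Far panels use the vertex-charge rule (lumped area / r at each vertex,
# which unlike a centroid rule has no spurious null space on 3-colorable
# lattices); near and singular panels use hat-weighted subdivision
# quadrature.
single_layer_row <- function(y, verts, tris, cent, areas, areas_lumped,
                             vert_ids, depth_near = 4L) {
  r_v <- row_norms(sweep(verts[vert_ids, , drop = FALSE], 2, y))
  self <- r_v < 1e-9
  out <- ifelse(self, 0, areas_lumped / (4 * pi * pmax(r_v, 1e-300)))
  d <- row_norms(sweep(cent, 2, y))
  diam <- sqrt(areas)
  near <- which(d < 2.5 * diam)
  kernel <- function(x) 1 / (4 * pi * row_norms(sweep(matrix(x, ncol = 3), 2, y)))
  for (k in near) {
    tri_glob <- tris[k, ]
    jj <- match(tri_glob, vert_ids)
    tri <- verts[tri_glob, , drop = FALSE]
    rv <- row_norms(sweep(tri, 2, y))
    sing <- any(rv < 1e-9)
    # swap this panel's vertex-charge contribution for the accurate rule
    keep <- rv >= 1e-9
    out[jj[keep]] <- out[jj[keep]] - (areas[k] / 3) / (4 * pi * rv[keep])
    out[jj] <- out[jj] + quad_tri_hat(tri, kernel, depth = if (sing) 6L else depth_near)
  }
  out
}

#' Assemble the epicardial BEM/Laplace transfer matrix
#'
#' Discretizes the Cauchy problem for Laplace's equation between the
#' epicardium and the insulated torso with a collocation boundary element
#' method (homogeneous unit conductivity), eliminating the unknown
#' epicardial normal current to obtain the dense transfer matrix relating
#' epicardial potentials to potentials at the electrode-attached torso
#' vertices.
#'
#' @param torso closed outward-oriented torso `tri_surface_mesh`.
#' @param epicardium closed outward-oriented epicardial surface strictly
#'   inside the torso.
#' @param electrodes an [electrode_set()] attached to `torso` vertices.
#' @return object of class `transfer_epicardial`: list with the M x N dense
#'   matrix `A`, the full torso-to-heart matrix `A_full` (all torso
#'   vertices), mesh hashes, and the electrode attachment.
#' @export
assemble_bem_laplace <- function(torso, epicardium, electrodes) {
  vt <- torso$vertices; th <- epicardium$vertices
  if (max(row_norms(sweep(th, 2, colMeans(th)))) >
      min(row_norms(sweep(vt, 2, colMeans(th)))))
    stopf("epicardium does not lie strictly inside the torso")
  nt <- nrow(vt); nh <- nrow(th)
  verts <- rbind(vt, th)
  tris_t <- torso$triangles
  tris_h <- epicardium$triangles + nt
  # domain between the surfaces: its boundary normal is the torso's outward
  # normal on T and the reversed (inward) epicardial normal on H
  tris_h_dom <- tris_h[, c(1, 3, 2)]
  tris_all <- rbind(tris_t, tris_h_dom)
  n_all <- nt + nh
  cent_h <- (verts[tris_h_dom[, 1], , drop = FALSE] +
             verts[tris_h_dom[, 2], , drop = FALSE] +
             verts[tris_h_dom[, 3], , drop = FALSE]) / 3
  e1 <- verts[tris_h_dom[, 2], , drop = FALSE] - verts[tris_h_dom[, 1], , drop = FALSE]
  e2 <- verts[tris_h_dom[, 3], , drop = FALSE] - verts[tris_h_dom[, 1], , drop = FALSE]
  areas_h <- 0.5 * row_norms(cross3(e1, e2))
  # panel-to-vertex lumping operator for the double layer
  np_all <- nrow(tris_all)
  L_all <- Matrix::sparseMatrix(i = rep(seq_len(np_all), 3), j = as.vector(tris_all),
                                x = 1 / 3, dims = c(np_all, n_all))
  areas_h_lumped <- rep(0, nh)
  for (k in 1:3) {
    acc <- rowsum(areas_h / 3, tris_h_dom[, k] - nt)
    idx <- as.integer(rownames(acc))
    areas_h_lumped[idx] <- areas_h_lumped[idx] + acc[, 1]
  }
  vert_ids_h <- nt + seq_len(nh)
  P <- matrix(0, n_all, n_all)       # double layer (with diagonal closure)
  G <- matrix(0, n_all, nh)          # single layer over epicardial panels
  for (i in seq_len(n_all)) {
    y <- verts[i, ]
    om <- -triangle_solid_angles(y, verts, tris_all) / (4 * pi)
    P[i, ] <- as.numeric(om %*% L_all)
    G[i, ] <- single_layer_row(y, verts, tris_h_dom, cent_h, areas_h,
                               areas_h_lumped, vert_ids_h)
  }
  # solid-angle row-sum closure: P 1 = 0 (constants are exact solutions)
  diag(P) <- diag(P) - rowSums(P)
  it <- seq_len(nt); ih <- nt + seq_len(nh)
  # epicardial normal-current elimination:
  #   P_tt phi_t + P_th phi_h = G_t q ;  P_ht phi_t + P_hh phi_h = G_h q
  GhInv_Pht <- solve(G[ih, , drop = FALSE], P[ih, it, drop = FALSE])
  GhInv_Phh <- solve(G[ih, , drop = FALSE], P[ih, ih, drop = FALSE])
  lhs <- P[it, it, drop = FALSE] - G[it, , drop = FALSE] %*% GhInv_Pht
  rhs <- G[it, , drop = FALSE] %*% GhInv_Phh - P[it, ih, drop = FALSE]
  A_full <- solve(lhs, rhs)
  A <- A_full[match(electrodes$attached_vertex, seq_len(nt)), , drop = FALSE]
  if (anyNA(A)) stopf("electrode attachment outside the torso surface")
  structure(list(A = A, A_full = A_full,
                 n_torso = nt, n_heart = nh,
                 mesh_hash = object_hash(list(vt, th)),
                 electrode_hash = object_hash(electrodes$attached_vertex)),
            class = "transfer_epicardial")
}

#' @export
print.transfer_epicardial <- function(x, ...) {
  cat(sprintf("transfer_epicardial: %d electrodes x %d epicardial nodes\n",
              nrow(x$A), ncol(x$A)))
  invisible(x)
}
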
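# First-order (P1) tetrahedral finite elements for the Neumann Poisson
# problem on the torso domain.  The torso is a homogeneous unit-conductivity
# volume conductor, so the stiffness matrix is the plain Laplacian form;
# absolute source units are therefore arbitrary (documented in the vignette).

# vectorized P1 stiffness assembly; tet_subset restricts to a subdomain,
# conductivity is an optional per-tet scalar (full-mesh indexing)
fem_stiffness <- function(mesh, tet_subset = NULL, conductivity = NULL) {
  tt <- if (is.null(tet_subset)) mesh$tets else mesh$tets[tet_subset, , drop = FALSE]
  sig <- if (is.null(conductivity)) 1
         else if (is.null(tet_subset)) as.numeric(conductivity)
         else as.numeric(conductivity)[tet_subset]
  v <- mesh$vertices
  a <- v[tt[, 2], , drop = FALSE] - v[tt[, 1], , drop = FALSE]
  b <- v[tt[, 3], , drop = FALSE] - v[tt[, 1], , drop = FALSE]
  d <- v[tt[, 4], , drop = FALSE] - v[tt[, 1], , drop = FALSE]
  v6 <- rowSums(a * cross3(b, d))            # 6 * volume
  g2 <- cross3(b, d) / v6                    # grad of barycentric coords
  g3 <- cross3(d, a) / v6
  g4 <- cross3(a, b) / v6
  g1 <- -(g2 + g3 + g4)
  vol <- v6 / 6
  G <- list(g1, g2, g3, g4)
  nt <- nrow(tt); n16 <- 16L * nt
  ii <- integer(n16); jj <- integer(n16); xx <- numeric(n16)
  k <- 0L
  for (p in 1:4) for (q in 1:4) {
    idx <- k * nt + seq_len(nt)
    ii[idx] <- tt[, p]; jj[idx] <- tt[, q]
    xx[idx] <- sig * vol * rowSums(G[[p]] * G[[q]])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = rep(nrow(v), 2))
}

# lumped boundary vertex areas (mm^2) over the full mesh node indexing
boundary_lumped_areas <- function(mesh) {
  bf <- mesh$boundary_faces
  ar <- 0.5 * row_norms(cross3(
    mesh$vertices[bf[, 2], , drop = FALSE] - mesh$vertices[bf[, 1], , drop = FALSE],
    mesh$vertices[bf[, 3], , drop = FALSE] - mesh$vertices[bf[, 1], , drop = FALSE]))
  w <- rep(0, nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- rowsum(ar / 3, bf[, k])
    idx <- as.integer(rownames(acc))
    w[idx] <- w[idx] + acc[, 1]
  }
  w
}

#' Neumann Poisson operator for a tetrahedral torso mesh
#'
#' Assembles the P1 stiffness matrix of the insulated (pure-Neumann)
#' Poisson problem and factorizes the constant-nullspace-deflated system
#' once, so that many right-hand sides (one per time sample, or one per
#' electrode when building the Green's transfer matrix) reuse the same
#' factorization.  The one-dimensional nullspace of constants is removed by
#' a Lagrange-multiplier row enforcing zero mean over torso-boundary nodes,
#' which fixes the additive potential constant without pinning any vertex.
#'
#' @param mesh a `tet_volume_mesh`.
#' @param conductivity optional per-tet scalar conductivity (S/m) from
#'   [conductivity_regions()]; default homogeneous unit conductivity.  A
#'   heterogeneous forward operator paired with the homogeneous inverse
#'   transfer creates deliberate model mismatch for robustness studies.
#' @return an object of class `poisson_operator`.
#' @export
poisson_operator <- function(mesh, conductivity = NULL) {
  K <- fem_stiffness(mesh, conductivity = conductivity)
  n <- nrow(K)
  bidx <- boundary_vertex_ids(mesh)
  # deflate the constant nullspace by grounding one interior node during the
  # factorization; for compatible loads this equals the deflated solve up to
  # an additive constant, which the boundary zero-mean gauge then fixes
  pin <- setdiff(seq_len(n), bidx)[1] %||% 1L
  keep <- setdiff(seq_len(n), pin)
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(K[keep, keep]),
                                      "CsparseMatrix"), LDL = FALSE, perm = TRUE)
  barea <- boundary_lumped_areas(mesh)
  structure(list(K = K, factor = fac, n = n, pin = pin, keep = keep,
                 mesh_hash = object_hash(mesh$vertices),
                 homogeneous = is.null(conductivity),
                 boundary_vertices = bidx, boundary_areas = barea,
                 area = sum(barea)),
            class = "poisson_operator")
}

#' Per-tetrahedron conductivity from spherical regions
#'
#' Builds the piecewise-constant conductivity field used by the optional
#' heterogeneous forward model: each tetrahedron (by centroid) takes the
#' conductivity of the first spherical region containing it, or the torso
#' background otherwise.  Typical extracellular values are 0.7 S/m (blood),
#' 0.0389 S/m (lungs), 0.1667 S/m (liver) and 0.8 S/m (torso background).
#'
#' @param mesh a `tet_volume_mesh`.
#' @param regions list of `list(center = <3-vector mm>, radius = <mm>,
#'   sigma = <S/m>)`.
#' @param background torso conductivity (S/m).
#' @return numeric vector, one conductivity per tetrahedron.
#' @export
conductivity_regions <- function(mesh, regions = list(), background = 0.8) {
  v <- mesh$vertices; tt <- mesh$tets
  cent <- (v[tt[, 1], ] + v[tt[, 2], ] + v[tt[, 3], ] + v[tt[, 4], ]) / 4
  sig <- rep(background, nrow(tt))
  assigned <- rep(FALSE, nrow(tt))
  for (rg in regions) {
    if (rg$sigma <= 0) stopf("conductivities must be positive")
    inside <- !assigned &
      rowSums(sweep(cent, 2, rg$center)^2) <= rg$radius^2
    sig[inside] <- rg$sigma
    assigned <- assigned | inside
  }
  sig
}

# solve K u = rhs (rhs: vector or dense matrix of compatible loads);
# gauge: zero mean over torso-boundary nodes
poisson_solve <- function(op, rhs) {
  rhs <- as.matrix(rhs)
  u <- matrix(0, op$n, ncol(rhs))
  u[op$keep, ] <- as.matrix(Matrix::solve(op$factor, rhs[op$keep, , drop = FALSE]))
  u - rep(colMeans(u[op$boundary_vertices, , drop = FALSE]), each = op$n)
}

#' Forward projection of cardiac sources to body-surface potentials
#'
#' Solves the insulated-torso Poisson problem `-lap(phi) = f` per time
#' sample by P1 finite elements and samples the potential at the
#' electrode-attached boundary vertices.  The nodal load is the lumped
#' volume quadrature `w * f`, so each time slice must satisfy the source
#' existence (compatibility) condition `sum(w * f) = 0`.  Electrode signals
#' are re-referenced to zero mean across electrodes per sample.
#'
#' @param f source field: matrix P x T over heart nodes (or a `source_field`).
#' @param mesh the `tet_volume_mesh`; alternatively pass a prebuilt
#'   `poisson_operator` via `op` to reuse its factorization.
#' @param electrodes an [electrode_set()] attached to the mesh boundary.
#' @param weights heart node volume weights ([node_volume_weights()]);
#'   computed from the mesh when omitted.
#' @param op optional prebuilt [poisson_operator()].
#' @param sample_rate sampling rate (Hz) recorded in the output object.
#' @param compat_tol relative tolerance for the compatibility check.
#' @return a [bsp_signals()] object (electrodes x samples, zero electrode
#'   mean per sample).
#' @export
forward_solve <- function(f, mesh, electrodes, weights = NULL, op = NULL,
                          sample_rate = 1000, compat_tol = 1e-8) {
  if (inherits(f, "source_field")) { sample_rate <- f$sample_rate; f <- f$values }
  f <- as.matrix(f)
  weights <- weights %||% node_volume_weights(mesh)
  nodes <- attr(weights, "nodes")
  if (nrow(f) != length(nodes)) stopf("f has %d rows but mesh has %d heart nodes",
                                      nrow(f), length(nodes))
  load_h <- as.numeric(weights) * f
  bad <- colSums(load_h)
  l1ref <- max(colSums(abs(load_h)), .Machine$double.eps)
  viol <- abs(bad) > compat_tol * l1ref
  if (any(viol))
    stopf("source field violates the existence condition at sample %d (|integral f dV| = %.3g)",
          which(viol)[1], max(abs(bad)))
  op <- op %||% poisson_operator(mesh)
  rhs <- matrix(0, op$n, ncol(f))
  rhs[nodes, ] <- load_h
  u <- poisson_solve(op, rhs)
  g <- u[electrodes$attached_vertex, , drop = FALSE]
  g <- sweep(g, 2, colMeans(g))
  bsp_signals(g, sample_rate = sample_rate)
}

#' Assemble the volumetric Green's-function transfer matrix
#'
#' For each electrode i the Neumann Green's function `G(y_i, .)` of the
#' insulated torso is computed by one P1 finite element solve with a unit
#' nodal load at the attached boundary vertex and a uniform compensating
#' boundary flux `-1/Area` (the compatible pure-Neumann formulation); row i
#' of the matrix is that solution sampled at the P heart nodes.  Rows are
#' gauged to zero mean, which is provably irrelevant for compatible sources
#' (those with zero volume integral).  The cost is M solves with one shared
#' factorization, not P.
#'
#' Two singularity treatments are available.  `"subtract"` (default) splits
#' each Green's function into the exact half-space kernel
#' `S = 1/(2 pi |x - y_i|)` of a boundary point source plus a smooth FEM
#' remainder driven by the residual boundary flux of `S`; this removes the
#' dominant discretization error of the nodal Dirac load and is markedly
#' more accurate on coarse meshes.  `"plain"` keeps the fully discrete
#' formulation (lumped unit nodal load), which is exactly reciprocal to
#' [forward_solve()] on the same mesh (to solver precision) and is used for
#' discrete consistency checks.
#'
#' @param mesh a `tet_volume_mesh`.
#' @param electrodes an [electrode_set()] whose attached vertices lie on the
#'   mesh boundary.
#' @param op optional prebuilt [poisson_operator()].
#' @param singularity `"subtract"` (half-space kernel + smooth remainder) or
#'   `"plain"` (fully discrete nodal load).
#' @return object of class `transfer_volumetric`: list with the M x P dense
#'   matrix `B` (Green's function values), heart `weights`, `gauge` tag,
#'   heart node indices and provenance hashes.
#' @export
assemble_green_transfer <- function(mesh, electrodes, op = NULL,
                                    singularity = c("subtract", "plain")) {
  singularity <- match.arg(singularity)
  op <- op %||% poisson_operator(mesh)
  att <- electrodes$attached_vertex
  if (!all(att %in% op$boundary_vertices))
    stopf("electrode vertex %d is not on the mesh boundary",
          att[which(!(att %in% op$boundary_vertices))[1]])
  n <- op$n; m <- length(att)
  weights <- node_volume_weights(mesh)
  nodes <- attr(weights, "nodes")
  if (singularity == "plain") {
    rhs <- matrix(-op$boundary_areas / op$area, n, m)
    rhs[cbind(att, seq_len(m))] <- rhs[cbind(att, seq_len(m))] + 1
    u <- poisson_solve(op, rhs)                    # one solve per electrode
    B <- t(u[nodes, , drop = FALSE])
  } else {
    bf <- mesh$boundary_faces
    v <- mesh$vertices
    e1 <- v[bf[, 2], , drop = FALSE] - v[bf[, 1], , drop = FALSE]
    e2 <- v[bf[, 3], , drop = FALSE] - v[bf[, 1], , drop = FALSE]
    nrm <- cross3(e1, e2)                          # outward, |.| = 2 area
    farea <- 0.5 * row_norms(nrm)
    nunit <- nrm / (2 * farea)
    rhs <- matrix(0, n, m)
    Xh <- v[nodes, , drop = FALSE]
    Bs <- matrix(0, m, length(nodes))
    cent <- (v[bf[, 1], , drop = FALSE] + v[bf[, 2], , drop = FALSE] +
             v[bf[, 3], , drop = FALSE]) / 3
    diam <- sqrt(farea)
    for (i in seq_len(m)) {
      ye <- v[att[i], ]
      geom <- electrode_local_geometry(v, bf, nunit, farea, att[i])
      sfun <- singular_kernel(ye, geom$normal, geom$mean_curvature)
      incident <- bf[, 1] == att[i] | bf[, 2] == att[i] | bf[, 3] == att[i]
      dcent <- row_norms(sweep(cent, 2, ye))
      near <- incident | dcent < 4 * diam          # singular-flux neighborhood
      # residual Neumann data of the remainder problem; integrating the
      # uniform -1/Area together with the kernel flux in one rule lets the
      # smooth parts cancel inside the quadrature
      data_fun <- function(x, nrm) -1 / op$area - sfun$flux(x, nrm)
      t_acc <- rep(0, n)
      # consistent P1 rule, exact for linearly varying flux on each face:
      # integral(phi_i f) ~ (A/12) (2 f_i + f_j + f_k)
      fv <- sapply(1:3, function(k) {
        val <- data_fun(v[bf[, k], , drop = FALSE], nunit)
        val[near] <- 0
        val
      })
      for (k in 1:3) {
        w_k <- farea / 12 * (2 * fv[, k] + fv[, k %% 3 + 1] + fv[, (k + 1) %% 3 + 1])
        acc <- rowsum(w_k, bf[, k])
        idx <- as.integer(rownames(acc))
        t_acc[idx] <- t_acc[idx] + acc[, 1]
      }
      # near non-incident faces: adaptive subdivision quadrature of the
      # 1/r-type flux.  Faces incident to the electrode vertex carry no
      # residual load: there the half-space kernel is the correct local
      # model of the discrete boundary (its flux vanishes on the flat
      # incident patch) and the residual is higher-order.
      for (fidx in which(near & !incident)) {
        tri <- v[bf[fidx, ], , drop = FALSE]
        contrib <- flux_quad_tri(tri, nunit[fidx, ], data_fun,
                                 depth = 3L + (dcent[fidx] < 2 * diam[fidx]))
        t_acc[bf[fidx, ]] <- t_acc[bf[fidx, ]] + contrib
      }
      # rebalance the residual quadrature defect (compatibility)
      r_i <- t_acc - sum(t_acc) * op$boundary_areas / op$area
      rhs[, i] <- r_i
      Bs[i, ] <- sfun$value(Xh)
    }
    u <- poisson_solve(op, rhs)
    B <- Bs + t(u[nodes, , drop = FALSE])
  }
  B <- B - rowMeans(B)
  structure(list(B = B, weights = weights, heart_nodes = nodes,
                 gauge = "row-zero-mean", singularity = singularity,
                 n_solves = m,
                 mesh_hash = op$mesh_hash,
                 electrode_hash = object_hash(electrodes$attached_vertex)),
            class = "transfer_volumetric")
}

#' @export
print.transfer_volumetric <- function(x, ...) {
  cat(sprintf("transfer_volumetric: %d electrodes x %d heart nodes (gauge: %s)\n",
              nrow(x$B), ncol(x$B), x$gauge))
  invisible(x)
}

#' Predicted electrode potentials from a volumetric source field
#'
#' Applies the discrete volume quadrature `g = B (w * f)` and re-references
#' to zero electrode mean, matching the forward-solve convention.
#'
#' @param transfer a `transfer_volumetric`.
#' @param f P x T matrix of nodal source densities.
#' @return M x T matrix of predicted potentials.
#' @export
predict_signals <- function(transfer, f) {
  f <- as.matrix(f)
  g <- transfer$B %*% (as.numeric(transfer$weights) * f)
  sweep(g, 2, colMeans(g))
}

# singular part of the boundary-source Neumann Green's function: the
# half-space kernel plus the curvature-induced logarithmic term,
#   S(x) = 1/(2 pi r) - (H / 4 pi) log(r + d_n),
# with r = |x - ye|, d_n = (ye - x) . n_e, H the mean curvature at the
# electrode.  On a sphere of radius R (H = 1/R) this equals the exact
# Neumann function up to a smooth harmonic remainder.
singular_kernel <- function(ye, n_e, H) {
  value <- function(x) {
    d <- sweep(matrix(x, ncol = 3), 2, ye)
    r <- row_norms(d)
    dn <- -as.numeric(d %*% n_e)
    1 / (2 * pi * r) - (H / (4 * pi)) * log(pmax(r + dn, 1e-300))
  }
  grad <- function(x) {
    d <- sweep(matrix(x, ncol = 3), 2, ye)
    r <- row_norms(d)
    dn <- -as.numeric(d %*% n_e)
    g1 <- -d / (2 * pi * r^3)
    rp <- pmax(r + dn, 1e-300)
    g2 <- -(H / (4 * pi)) * (d / r - matrix(n_e, nrow(d), 3, byrow = TRUE)) / rp
    g1 + g2
  }
  flux <- function(x, nrm) {
    x <- matrix(x, ncol = 3)
    nrm <- matrix(nrm, ncol = 3)
    rowSums(grad(x) * nrm)
  }
  list(value = value, grad = grad, flux = flux)
}

# outward vertex normal and mean curvature at a boundary vertex, the latter
# from a least-squares osculating-sphere fit over the two-ring neighborhood
electrode_local_geometry <- function(v, bf, nunit, farea, vert) {
  inc <- which(bf[, 1] == vert | bf[, 2] == vert | bf[, 3] == vert)
  nrm <- colSums(nunit[inc, , drop = FALSE] * farea[inc])
  nrm <- nrm / sqrt(sum(nrm^2))
  ring1 <- unique(as.vector(bf[inc, ]))
  inc2 <- which(bf[, 1] %in% ring1 | bf[, 2] %in% ring1 | bf[, 3] %in% ring1)
  ring2 <- unique(as.vector(bf[inc2, ]))
  P <- v[ring2, , drop = FALSE]
  # |x - c|^2 = rho^2  linearized:  2 c.x + (rho^2 - c.c) = x.x
  A <- cbind(2 * P, 1)
  b <- rowSums(P * P)
  beta <- qr.solve(A, b)
  ctr <- beta[1:3]
  rho2 <- beta[4] + sum(ctr * ctr)
  H <- if (rho2 > 0) 1 / sqrt(rho2) else 0
  # sign: positive (convex toward the outward normal) when the center lies
  # inside, i.e. opposite the normal
  if (sum((ctr - v[vert, ]) * nrm) > 0) H <- -H
  list(normal = nrm, mean_curvature = H)
}

# integral of fun(x) * hat_j(x) over a triangle, by uniform 4^depth
# subdivision with centroid quadrature; returns per-vertex contributions
quad_tri_hat <- function(tri, fun, depth = 3L) {
  nsub <- 2L^depth
  # centroids of upward and downward subtriangles (lattice cells)
  up <- expand.grid(i = 0:(nsub - 1), j = 0:(nsub - 1))
  up <- up[up$i + up$j <= nsub - 1, ]
  dn <- up[up$i + up$j <= nsub - 2, , drop = FALSE]
  wup <- cbind(nsub - up$i - up$j - 2 / 3, up$i + 1 / 3, up$j + 1 / 3) / nsub
  wdn <- if (nrow(dn)) cbind(nsub - dn$i - dn$j - 4 / 3, dn$i + 2 / 3, dn$j + 2 / 3) / nsub
  W <- rbind(wup, wdn)
  X <- W %*% tri
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  area_sub <- 0.5 * sqrt(sum(cr^2)) / nsub^2
  as.numeric(crossprod(W, fun(X))) * area_sub
}

flux_quad_tri <- function(tri, nrm, flux_fun, depth = 3L) {
  quad_tri_hat(tri, function(X) flux_fun(X, matrix(nrm, nrow(X), 3, byrow = TRUE)),
               depth = depth)
}

#' Bidomain-surrogate cardiac sources from a transmembrane voltage field
#'
#' Computes the scalar net current-source density `f = div(sigma_i grad Vm)`
#' on the myocardial shell by the P1 weak form with natural (no-flux)
#' boundary conditions on the shell: the nodal load is minus the
#' heart-restricted stiffness action on Vm, divided by the lumped nodal
#' volume.  By the divergence theorem the weighted sum of every time slice
#' is zero to rounding, i.e. the source existence condition holds by
#' construction.
#'
#' @param vm `vm_field` object or P x T matrix of transmembrane voltages on
#'   heart nodes.
#' @param mesh the `tet_volume_mesh`.
#' @param sigma_i scalar intracellular conductivity (S/m); an overall
#'   amplitude factor in this homogeneous surrogate.
#' @return object of class `source_field`: list with `values` (P x T),
#'   `sample_rate`, and `constraint_residual` per sample.
#' @export
compute_sources <- function(vm, mesh, sigma_i = 0.2) {
  sample_rate <- NULL
  if (inherits(vm, "vm_field")) { sample_rate <- vm$sample_rate; vm <- vm$values }
  vm <- as.matrix(vm)
  weights <- node_volume_weights(mesh)
  nodes <- attr(weights, "nodes")
  if (nrow(vm) != length(nodes)) stopf("vm has %d rows but mesh has %d heart nodes",
                                       nrow(vm), length(nodes))
  Kh <- fem_stiffness(mesh, tet_subset = heart_tets(mesh))[nodes, nodes]
  Fload <- -sigma_i * as.matrix(Kh %*% vm)
  f <- Fload / as.numeric(weights)
  res <- abs(colSums(Fload)) / max(colSums(abs(Fload)), .Machine$double.eps)
  structure(list(values = f, sample_rate = sample_rate,
                 constraint_residual = res, heart_nodes = nodes),
            class = "source_field")
}

#' @export
print.source_field <- function(x, ...) {
  cat(sprintf("source_field: %d heart nodes x %d samples, max |sum w f|/||wf||_1 = %.2g\n",
              nrow(x$values), ncol(x$values), max(x$constraint_residual)))
  invisible(x)
}

#' Neumann Green's function of the sphere (truncated Legendre series)
#'
#' Closed-form series oracle for the insulated sphere: for a unit point
#' source at boundary point `electrode_pos` with uniform compensating flux
#' `-1/(4 pi R^2)`, the interior solution is
#' `G(r, theta) = sum_n (2n+1) / (4 pi R n) (r/R)^n P_n(cos theta)`
#' (gauge: zero n=0 term).  The truncation error at `|x| <= rho R` is
#' bounded by the geometric tail `O(rho^n_terms)`.
#'
#' @param electrode_pos 3-vector on the sphere surface.
#' @param field_pos 3-vector (or matrix of rows) strictly inside the sphere.
#' @param radius sphere radius.
#' @param n_terms number of series terms (>= 50 recommended).
#' @return Green's function value(s).
#' @export
analytic_sphere_green <- function(electrode_pos, field_pos, radius, n_terms = 200) {
  field_pos <- matrix(field_pos, ncol = 3)
  r <- row_norms(field_pos)
  if (any(r >= radius)) stopf("field point outside (or on) the sphere")
  e <- electrode_pos / sqrt(sum(electrode_pos^2))
  ct <- as.numeric(field_pos %*% e) / ifelse(r > 0, r, 1)
  ct[r == 0] <- 1
  x <- r / radius
  # Legendre recurrence, accumulating the series
  pm1 <- rep(1, length(r)); p0 <- ct
  acc <- 3 / (4 * pi * radius) * x * p0
  for (n in 2:n_terms) {
    pn <- ((2 * n - 1) * ct * p0 - (n - 1) * pm1) / n
    acc <- acc + (2 * n + 1) / (4 * pi * radius * n) * x^n * pn
    pm1 <- p0; p0 <- pn
  }
  acc
}
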
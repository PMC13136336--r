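test_that("analytic sphere Green series is symmetric and converged", {
  R <- 80
  e <- c(0, 0, R)
  x1 <- c(20, 0, 30); x2 <- c(-20, 0, 30)    # same radius, same polar angle
  expect_equal(analytic_sphere_green(e, x1, R),
               analytic_sphere_green(e, x2, R), tolerance = 1e-12)
  xs <- rbind(c(10, 5, -30), c(0, 30, 50), c(-40, 0, 0))
  v100 <- analytic_sphere_green(e, xs, R, 100)
  v200 <- analytic_sphere_green(e, xs, R, 200)
  expect_lt(max(abs(v100 - v200) / abs(v200)), 1e-6)
  expect_error(analytic_sphere_green(e, c(0, 0, 2 * R), R), "outside")
})

test_that("Green transfer matches the sphere series and is deterministic", {
  bl <- small_ball()
  B1 <- assemble_green_transfer(bl$mesh, bl$el, bl$op)
  B2 <- assemble_green_transfer(bl$mesh, bl$el, bl$op)
  expect_identical(B1$B, B2$B)
  expect_identical(B1$n_solves, nrow(bl$el$positions))  # M solves, not P

  X <- bl$mesh$vertices[B1$heart_nodes, ]
  errs <- vapply(seq_len(nrow(bl$el$positions)), function(i) {
    ser <- analytic_sphere_green(bl$mesh$vertices[bl$el$attached_vertex[i], ],
                                 X, bl$R, 300)
    bb <- B1$B[i, ] - mean(B1$B[i, ])
    ser <- ser - mean(ser)
    sqrt(sum((bb - ser)^2) / sum(ser^2))
  }, 0)
  expect_lt(mean(errs), 0.05)
  expect_true(all(abs(rowMeans(B1$B)) < 1e-12))         # row gauge
})

test_that("discrete Green transfer is reciprocal to the forward solve", {
  tb <- tiny_ball()
  expect_lt(nrow(tb$mesh$vertices), 500)
  B <- assemble_green_transfer(tb$mesh, tb$el, tb$op, singularity = "plain")
  w <- as.numeric(B$weights)
  set.seed(21)
  for (rep in 1:10) {
    f <- rnorm(length(w))
    f <- f - sum(w * f) / sum(w^2) * w
    g1 <- predict_signals(B, cbind(f, f))
    g2 <- forward_solve(cbind(f, f), tb$mesh, tb$el, op = tb$op)$values
    expect_lt(max(abs(g1 - g2)) / max(abs(g2)), 1e-8)
  }
})

test_that("per-row Green gauge constants cannot leak into predictions", {
  tb <- tiny_ball()
  B <- assemble_green_transfer(tb$mesh, tb$el, tb$op)
  w <- as.numeric(B$weights)
  # build f with exactly zero volume integral in floating point
  f <- rep(0, length(w))
  f[3] <- 1 / w[3]; f[17] <- -1 / w[17]
  B2 <- B
  B2$B <- B$B + matrix(rnorm(nrow(B$B)), ncol = 1) %*% rep(1, ncol(B$B))
  d <- max(abs(predict_signals(B2, cbind(f, f)) -
               predict_signals(B, cbind(f, f))))
  expect_lt(d, 1e-12 * max(abs(predict_signals(B, cbind(f, f)))) + 1e-12)
})

test_that("BEM transfer maps constants to constants and a central dipole", {
  Rt <- 150; Rh <- 50
  torso <- icosphere(Rt, 4)
  epi <- icosphere(Rh, 6, role = "epicardium")
  el <- electrode_set(fibonacci_sphere(32, Rt), torso)
  tr <- assemble_bem_laplace(torso, epi, el)
  cerr <- max(abs(tr$A %*% rep(2.5, ncol(tr$A)) - 2.5)) / 2.5
  expect_lt(cerr, 0.01)

  p <- 1e5
  phi_h <- p * epi$vertices[, 3] / Rh / (4 * pi) * (1 / Rh^2 + 2 * Rh / Rt^3)
  phi_t <- 3 * p * (el$attached_position[, 3] / Rt) / (4 * pi * Rt^2)
  g <- as.numeric(tr$A %*% phi_h); g <- g - mean(g)
  pe <- phi_t - mean(phi_t)
  expect_lt(sqrt(sum((g - pe)^2) / sum(pe^2)), 0.05)

  expect_error(assemble_bem_laplace(epi, torso, el), "inside")
})

test_that("BEM dipole error decreases under refinement", {
  Rt <- 150; Rh <- 50
  dip_err <- function(ft, fh) {
    torso <- icosphere(Rt, ft)
    epi <- icosphere(Rh, fh, role = "epicardium")
    el <- electrode_set(fibonacci_sphere(32, Rt), torso)
    tr <- assemble_bem_laplace(torso, epi, el)
    p <- 1e5
    phi_h <- p * epi$vertices[, 3] / Rh / (4 * pi) * (1 / Rh^2 + 2 * Rh / Rt^3)
    phi_t <- 3 * p * (el$attached_position[, 3] / Rt) / (4 * pi * Rt^2)
    g <- as.numeric(tr$A %*% phi_h); g <- g - mean(g)
    pe <- phi_t - mean(phi_t)
    sqrt(sum((g - pe)^2) / sum(pe^2))
  }
  e_coarse <- dip_err(3, 4)
  e_fine <- dip_err(5, 7)
  expect_lt(e_fine, e_coarse)
})

test_that("transfer operators round-trip through MatrixMarket + sidecar", {
  tb <- tiny_ball()
  B <- assemble_green_transfer(tb$mesh, tb$el, tb$op)
  p <- file.path(tempdir(), "B.mtx")
  write_transfer_mtx(B, p)
  B2 <- read_transfer_mtx(p)
  expect_equal(B2$B, B$B, tolerance = 1e-12)
  expect_identical(B2$heart_nodes, B$heart_nodes)
  expect_equal(as.numeric(B2$weights), as.numeric(B$weights), tolerance = 1e-12)
  expect_identical(B2$gauge, B$gauge)
  expect_identical(B2$mesh_hash, B$mesh_hash)
})

test_that("heterogeneous forward conductivity changes signals but stays compatible", {
  tb <- tiny_ball()
  sig <- conductivity_regions(tb$mesh,
                              regions = list(list(center = c(0, 0, 0),
                                                  radius = 35, sigma = 0.7)),
                              background = 0.8)
  expect_true(any(sig == 0.7) && any(sig == 0.8))
  op_het <- poisson_operator(tb$mesh, conductivity = sig)
  w <- node_volume_weights(tb$mesh)
  set.seed(77)
  f <- rnorm(length(w)); f <- f - sum(as.numeric(w) * f) / sum(w^2) * as.numeric(w)
  g_hom <- forward_solve(cbind(f, f), tb$mesh, tb$el, op = tb$op)$values
  g_het <- forward_solve(cbind(f, f), tb$mesh, tb$el, op = op_het)$values
  expect_gt(max(abs(g_het - g_hom)), 1e-6 * max(abs(g_hom)))
  expect_lt(max(abs(colMeans(g_het))), 1e-12)
  # uniform rescaling of the conductivity rescales potentials inversely
  op_2x <- poisson_operator(tb$mesh, conductivity = rep(2, nrow(tb$mesh$tets)))
  g_2x <- forward_solve(cbind(f, f), tb$mesh, tb$el, op = op_2x)$values
  expect_equal(g_2x, g_hom / 2, tolerance = 1e-9)
})
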
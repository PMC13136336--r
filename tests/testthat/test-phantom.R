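test_that("eikonal activation matches an independent Dijkstra oracle", {
  bl <- small_ball()
  hn <- which(bl$mesh$heart_node_mask)
  origin <- hn[17]
  gt <- simulate_activation(bl$mesh, origin, velocity = 0.8)
  expect_equal(gt$lat_ms[match(origin, hn)], 0)

  ht <- bl$mesh$tets[volmap:::heart_tets(bl$mesh), ]
  edges <- volmap:::tet_edges(ht)
  edges <- edges[bl$mesh$heart_node_mask[edges[, 1]] &
                 bl$mesh$heart_node_mask[edges[, 2]], ]
  d <- dijkstra_oracle(bl$mesh$vertices, edges, origin)
  expect_equal(gt$lat_ms, d[hn] / 0.8, tolerance = 1e-9)

  gt2 <- simulate_activation(bl$mesh, origin, velocity = 1.6)
  expect_equal(gt2$lat_ms, gt$lat_ms / 2, tolerance = 1e-12)
  expect_error(simulate_activation(bl$mesh, 1, 0.8), "heart node")
})

test_that("vm template rests, rises at LAT and plateaus exactly", {
  bl <- small_ball()
  hn <- which(bl$mesh$heart_node_mask)
  spec <- phantom_spec(upstroke_duration_ms = 5, onset_ms = 10,
                       sample_rate_hz = 1000)
  gt <- simulate_activation(bl$mesh, hn[1], velocity = 0.8)
  vm <- synthesize_vm(gt, spec)
  lat_glob <- gt$lat_ms + spec$onset_ms
  node <- which.min(abs(gt$lat_ms - 40))   # a node with LAT ~ 40 ms
  tr <- vm$values[node, ]
  dv <- diff(tr)
  expect_lt(abs(vm$times_ms[which.max(dv)] + 0.5 - lat_glob[node]), 1)
  before <- vm$times_ms < lat_glob[node] - 2.6
  after <- vm$times_ms > lat_glob[node] + 2.6
  expect_true(all(abs(tr[before]) < 1e-9))
  expect_true(all(abs(tr[after] - 1) < 1e-9))

  # identical LATs give identical traces
  gt0 <- gt; gt0$lat_ms[] <- 0
  vm0 <- synthesize_vm(gt0, spec)
  expect_true(all(vm0$values == rep(vm0$values[1, ], each = nrow(vm0$values))))

  spec_short <- phantom_spec(duration_ms = 5)
  expect_error(synthesize_vm(gt, spec_short), "duration")
})

test_that("sources vanish for uniform vm and satisfy the existence condition", {
  bl <- small_ball()
  hn <- which(bl$mesh$heart_node_mask)
  vm_const <- matrix(3.7, length(hn), 4)
  src <- compute_sources(vm_const, bl$mesh)
  expect_lt(max(abs(src$values)), 1e-12)

  gt <- simulate_activation(bl$mesh, hn[5], velocity = 0.8)
  vm <- synthesize_vm(gt, phantom_spec())
  src <- compute_sources(vm, bl$mesh, sigma_i = 0.2)
  expect_lt(max(src$constraint_residual), 1e-8)

  # amplitude linearity in sigma_i
  src2 <- compute_sources(vm, bl$mesh, sigma_i = 0.4)
  expect_equal(src2$values, 2 * src$values, tolerance = 1e-12)
})

test_that("linear vm on a structured bar yields boundary-only sources", {
  m <- box_tet_mesh(6, 2, 2, spacing = 2)
  vm <- matrix(m$vertices[, 1], ncol = 2, nrow = nrow(m$vertices))
  src <- compute_sources(vm, m, sigma_i = 1)
  interior <- setdiff(seq_len(nrow(m$vertices)),
                      volmap:::boundary_vertex_ids(m))
  expect_lt(max(abs(src$values[interior, ])), 1e-10)
  # weak-form boundary load integrates to the exact face flux sigma * area
  w <- node_volume_weights(m)
  load <- as.numeric(w) * src$values[, 1]
  xmin <- which(m$vertices[, 1] == 0)
  xmax <- which(m$vertices[, 1] == 12)
  expect_equal(sum(load[xmin]), 16, tolerance = 1e-9)   # 4x4 face, sigma 1
  expect_equal(sum(load[xmax]), -16, tolerance = 1e-9)
})

test_that("forward solve is zero for zero sources and referenced per sample", {
  bl <- small_ball()
  hn <- which(bl$mesh$heart_node_mask)
  f0 <- matrix(0, length(hn), 3)
  g0 <- forward_solve(f0, bl$mesh, bl$el, op = bl$op)
  expect_true(all(g0$values == 0))

  w <- node_volume_weights(bl$mesh)
  set.seed(12)
  f <- matrix(rnorm(length(hn) * 3), ncol = 3)
  f <- f - outer(as.numeric(w), colSums(as.numeric(w) * f) / sum(w^2))
  g <- forward_solve(f, bl$mesh, bl$el, op = bl$op)
  expect_lt(max(abs(colMeans(g$values))), 1e-12)

  f_bad <- f; f_bad[1, ] <- f_bad[1, ] + 100
  expect_error(forward_solve(f_bad, bl$mesh, bl$el, op = bl$op),
               "existence")
})

test_that("interior source/sink pair reproduces the insulated-sphere series", {
  bl <- small_ball()
  hn <- which(bl$mesh$heart_node_mask)
  verts <- bl$mesh$vertices
  w <- node_volume_weights(bl$mesh)
  # two heart nodes on roughly opposite sides
  i1 <- hn[which.max(verts[hn, 3])]
  i2 <- hn[which.min(verts[hn, 3])]
  f <- matrix(0, length(hn), 2)
  f[match(i1, hn), ] <- 1 / as.numeric(w)[match(i1, hn)]
  f[match(i2, hn), ] <- -1 / as.numeric(w)[match(i2, hn)]
  g <- forward_solve(f, bl$mesh, bl$el, op = bl$op)
  # reciprocity: boundary potential of interior sources equals the
  # boundary-source Neumann Green's function at those interior points
  ge <- vapply(seq_len(nrow(bl$el$positions)), function(k) {
    y <- verts[bl$el$attached_vertex[k], ]
    analytic_sphere_green(y, verts[i1, ], bl$R, 300) -
      analytic_sphere_green(y, verts[i2, ], bl$R, 300)
  }, 0)
  ge <- ge - mean(ge)
  err <- sqrt(sum((g$values[, 1] - ge)^2) / sum(ge^2))
  expect_lt(err, 0.05)
})

test_that("noise injection hits the target SNR deterministically", {
  set.seed(31)
  g <- bsp_signals(matrix(rnorm(64 * 400), 64), 1000)
  gn <- add_noise(g, 20, seed = 5)
  snr <- measured_snr_db(g, gn)
  expect_gt(snr, 19.5); expect_lt(snr, 20.5)
  gn2 <- add_noise(g, 20, seed = 5)
  expect_identical(gn$values, gn2$values)
  g60 <- add_noise(g, 60, seed = 5)
  expect_lt(max(abs(g60$values - g$values)) / max(abs(g$values)), 0.002 * 10)
  expect_lt(sqrt(mean((g60$values - g$values)^2) / mean(g$values^2)), 0.002)
  expect_error(add_noise(bsp_signals(matrix(0, 4, 10), 100), 20), "zero-power")
  expect_error(add_noise(g, Inf), "finite")
})

test_that("forward signals are time-equivariant and amplitude-linear", {
  bl <- small_ball()
  hn <- which(bl$mesh$heart_node_mask)
  spec1 <- phantom_spec(onset_ms = 10, duration_ms = 160)
  spec2 <- phantom_spec(onset_ms = 30, duration_ms = 180)
  gt <- simulate_activation(bl$mesh, hn[9], velocity = 1.5)
  g1 <- forward_solve(compute_sources(synthesize_vm(gt, spec1), bl$mesh),
                      bl$mesh, bl$el, op = bl$op)
  g2 <- forward_solve(compute_sources(synthesize_vm(gt, spec2), bl$mesh),
                      bl$mesh, bl$el, op = bl$op)
  # a 20 ms onset shift displaces every waveform by exactly 20 samples
  expect_equal(g2$values[, 21:161], g1$values[, 1:141], tolerance = 1e-10)
})

test_that("ellipsoidal and eccentric phantoms keep the shell inside the torso", {
  spec <- phantom_spec(torso_radius_mm = 100, heart_outer_radius_mm = 28,
                       heart_inner_radius_mm = 19,
                       heart_offset_mm = c(0, 0, 20),
                       torso_axes = c(1, 0.8, 1.1),
                       heart_axes = c(1, 1, 1.25),
                       electrode_count = 32,
                       heart_volume_edge_mm = 7, heart_surface_edge_mm = 8)
  geom <- build_phantom_geometry(spec)
  v <- geom$mesh$vertices
  # every node obeys the torso ellipsoid inequality
  q <- rowSums(sweep(v, 2, 100 * spec$torso_axes, "/")^2)
  expect_lt(max(q), 1 + 1e-6)
  hn <- which(geom$mesh$heart_node_mask)
  rel <- sweep(v[hn, ], 2, c(0, 0, 20))
  qh <- sqrt(rowSums(sweep(rel, 2, spec$heart_axes, "/")^2))
  expect_lt(max(qh), 28 + 1e-6)
  expect_gt(min(qh), 19 - 1)
  expect_false(any(duplicated(geom$electrodes$attached_vertex)))
})
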
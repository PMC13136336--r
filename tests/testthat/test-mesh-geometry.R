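cube_surface <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  list(vertices = v, faces = f)
}

test_that("surface validation enforces manifoldness, orientation and area", {
  cs <- cube_surface()
  m <- tri_surface_mesh(cs$vertices, cs$faces, role = "torso")
  expect_equal(mesh_area(m), 6)
  expect_equal(mesh_signed_volume(m), 1)

  bad <- cs$faces; bad[5, ] <- bad[5, c(1, 3, 2)]
  expect_error(tri_surface_mesh(cs$vertices, bad),
               "flipped|orientation")
  expect_error(tri_surface_mesh(cs$vertices, cs$faces[-1, , drop = FALSE]),
               "manifold")
  degen <- rbind(cs$faces, c(1, 1, 2))
  expect_error(tri_surface_mesh(cs$vertices, degen), "degenerate|manifold")
})

test_that("mesh files round-trip exactly and unreadable files error", {
  s <- icosphere(7.5, 3)
  p <- file.path(tempdir(), "rt.vtk")
  write_mesh_vtk(s, p)
  s2 <- read_mesh(p, role = "torso")
  expect_equal(s2$vertices, s$vertices, tolerance = 1e-12)
  expect_identical(s2$triangles, s$triangles)

  m <- box_tet_mesh(2, 2, 2)
  pv <- file.path(tempdir(), "rt_vol.vtk")
  write_mesh_vtk(m, pv)
  m2 <- read_mesh(pv)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(m2$tets, m$tets)
  expect_identical(m2$heart_node_mask, m$heart_node_mask)

  # OFF reader on a cube
  cs <- cube_surface()
  po <- file.path(tempdir(), "cube.off")
  writeLines(c("OFF", "8 12 0",
               apply(cs$vertices, 1, paste, collapse = " "),
               apply(cbind(3, cs$faces - 1), 1, paste, collapse = " ")), po)
  mo <- read_mesh(po)
  expect_equal(mesh_area(mo), 6)

  expect_error(read_mesh(file.path(tempdir(), "nope.vtk")), "cannot read")
})

test_that("tetrahedralize fills concentric spheres with a marked shell", {
  torso <- icosphere(200, 14)
  ho <- icosphere(60, 10, role = "epicardium")
  hi <- icosphere(40, 7, role = "endocardium")
  m <- tetrahedralize(torso, ho, hi, target_edge_mm = 8)
  expect_equal(sum(tet_volumes(m)), 4 / 3 * pi * 200^3, tolerance = 0.02)
  hn <- which(m$heart_node_mask)
  expect_gt(length(hn), 0)
  r <- sqrt(rowSums(m$vertices[hn, ]^2))
  expect_true(all(r <= 60 + 1e-6))
  expect_true(all(r >= 40 - 0.5))      # nodes on the faceted inner surface
  ht <- m$tets[volmap:::heart_tets(m), ]
  he <- volmap:::tet_edges(ht)
  me <- volmap:::mean_edge_length(m$vertices, he)
  expect_lt(abs(me - 8) / 8, 0.25)
  # heart-region boundary reproduces the input surfaces within mesh tolerance
  expect_lt(max(abs(r[r > 50] - 60)), 8)
  expect_error(tetrahedralize(ho, torso, NULL, 8), "inside")
})

test_that("volume weights are conserved and match a per-tet accumulation", {
  m1 <- box_tet_mesh(1, 1, 1, spacing = 2)  # 6 tets of one cube
  w <- node_volume_weights(m1)
  expect_equal(sum(w), 8, tolerance = 1e-12)

  set.seed(4)
  m <- box_tet_mesh(2, 2, 2)
  vj <- m$vertices + 0.08 * matrix(rnorm(length(m$vertices)), ncol = 3)
  mj <- tet_volume_mesh(vj, volmap:::orient_tets(vj, m$tets),
                        m$heart_node_mask)
  w <- node_volume_weights(mj)
  vol <- tet_volumes(mj)
  brute <- rep(0, nrow(vj))
  for (k in seq_len(nrow(mj$tets)))
    for (q in 1:4) brute[mj$tets[k, q]] <- brute[mj$tets[k, q]] + vol[k] / 4
  expect_equal(as.numeric(w), brute[attr(w, "nodes")], tolerance = 1e-12)
  expect_equal(sum(w), sum(vol), tolerance = 1e-9)

  # a single tetrahedron gives V/4 per node
  vt <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mt <- tet_volume_mesh(vt, matrix(1:4, 1), rep(TRUE, 4))
  expect_equal(as.numeric(node_volume_weights(mt)), rep(1 / 24, 4))
})

test_that("geodesic distances agree with an independent Dijkstra oracle", {
  m <- box_tet_mesh(6, 6, 1)
  expect_equal(geodesic_distance(m, 5, 5), 0)
  hn <- which(m$heart_node_mask)
  edges <- volmap:::tet_edges(m$tets)
  n_corner <- nrow(m$vertices)
  d_oracle <- dijkstra_oracle(m$vertices, edges, 1)
  expect_equal(geodesic_distance(m, 1, n_corner), d_oracle[n_corner],
               tolerance = 1e-10)
  # flat-grid inflation stays below 10% of the straight line
  straight <- sqrt(sum((m$vertices[n_corner, ] - m$vertices[1, ])^2))
  expect_lt(geodesic_distance(m, 1, n_corner) / straight, 1.1)

  # metric properties on random triples
  set.seed(7)
  for (rep in 1:10) {
    abc <- sample(nrow(m$vertices), 3)
    dab <- geodesic_distance(m, abc[1], abc[2])
    dbc <- geodesic_distance(m, abc[2], abc[3])
    dac <- geodesic_distance(m, abc[1], abc[3])
    expect_gte(dab + dbc + 1e-9, dac)
    expect_gte(dab + 1e-12,
               sqrt(sum((m$vertices[abc[1], ] - m$vertices[abc[2], ])^2)))
  }
})

test_that("antipodal icosphere geodesic approximates the great circle", {
  s <- icosphere(50, 8)
  i <- which.max(s$vertices[, 3])
  j <- which.min(rowSums(sweep(s$vertices, 2, -s$vertices[i, ])^2))
  d <- geodesic_distance(s, i, j)
  expect_lt(abs(d - pi * 50) / (pi * 50), 0.1)
})

test_that("phantom geometry is deterministic with valid electrodes", {
  spec <- phantom_spec(torso_radius_mm = 100, heart_outer_radius_mm = 30,
                       heart_inner_radius_mm = 20, electrode_count = 48,
                       heart_volume_edge_mm = 7, heart_surface_edge_mm = 7)
  g1 <- build_phantom_geometry(spec)
  g2 <- build_phantom_geometry(spec)
  expect_identical(g1$mesh$vertices, g2$mesh$vertices)
  expect_identical(g1$electrodes$attached_vertex, g2$electrodes$attached_vertex)
  expect_equal(nrow(g1$electrodes$positions), 48)
  expect_false(any(duplicated(g1$electrodes$attached_vertex)))
  bidx <- volmap:::boundary_vertex_ids(g1$mesh)
  expect_true(all(g1$electrodes$attached_vertex %in% bidx))

  spec_e <- phantom_spec(torso_radius_mm = 100, heart_outer_radius_mm = 30,
                         heart_inner_radius_mm = 20,
                         heart_offset_mm = c(0, 0, 30), electrode_count = 24,
                         heart_volume_edge_mm = 7, heart_surface_edge_mm = 7)
  ge <- build_phantom_geometry(spec_e)
  hn <- which(ge$mesh$heart_node_mask)
  expect_true(all(sqrt(rowSums(ge$mesh$vertices[hn, ]^2)) < 100))
  expect_error(phantom_spec(torso_radius_mm = 50, heart_outer_radius_mm = 60,
                            heart_inner_radius_mm = 20), "radii")
})
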
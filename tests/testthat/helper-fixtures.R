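# Shared fixtures, built once per test run and memoized.  All geometry is
# generated in code; sizes are kept small so the whole suite stays fast.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# uniform ball mesh of radius R: freq-nu angular lattice, equispaced layers
ball_mesh <- function(freq, n_layers, heart_layers, R = 100) {
  ic <- volmap:::icosphere_directions(freq)
  radii <- outer(rep(1, nrow(ic$dirs)), seq_len(n_layers) / n_layers * R)
  volmap:::radial_layer_mesh(ic$dirs, ic$faces, radii,
                             heart_layers = heart_layers)
}

# electrodes attached to the boundary of a volume mesh (global vertex ids)
ball_electrodes <- function(mesh, n, R = 100) {
  electrode_set(fibonacci_sphere(n, R), mesh,
                boundary_vertices = volmap:::boundary_vertex_ids(mesh))
}

# small ball phantom + operator, reused across transfer/phantom tests
small_ball <- function() memo("small_ball", function() {
  mesh <- ball_mesh(6, 4, heart_layers = 2:3)   # 7200 tets, heart 50-75 mm
  op <- poisson_operator(mesh)
  el <- ball_electrodes(mesh, 16)
  list(mesh = mesh, op = op, el = el, R = 100)
})

# tiny ball (< 500 nodes) for exact discrete-identity checks
tiny_ball <- function() memo("tiny_ball", function() {
  mesh <- ball_mesh(4, 3, heart_layers = 1:2)   # 487 nodes
  op <- poisson_operator(mesh)
  el <- ball_electrodes(mesh, 12)
  list(mesh = mesh, op = op, el = el, R = 100)
})

# coarse "resolvable" phantom: wide upstroke and coarse heart mesh so the
# visible subspace carries the source field (used for recovery checks)
coarse_phantom <- function() memo("coarse_phantom", function() {
  spec <- phantom_spec(torso_radius_mm = 120, heart_outer_radius_mm = 45,
                       heart_inner_radius_mm = 30, electrode_count = 64,
                       heart_volume_edge_mm = 9, heart_surface_edge_mm = 8,
                       upstroke_duration_ms = 20,
                       conduction_velocity_mm_ms = 1.2,
                       sample_rate_hz = 500, seed = 11)
  ops <- build_operators(spec, methods = "volumetric")
  list(spec = spec, ops = ops)
})

# independent O(n^2) Dijkstra used as the shortest-path oracle
dijkstra_oracle <- function(vertices, edges, from) {
  n <- nrow(vertices)
  wts <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                       vertices[edges[, 2], , drop = FALSE])^2))
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, wts[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, wts[k]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (dist[u] + nb[r, 2] < dist[v]) dist[v] <- dist[u] + nb[r, 2]
    }
  }
  dist
}
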
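# Synthetic torso/heart phantom: concentric (optionally eccentric)
# sphere geometry with a myocardial shell, quasi-uniform electrodes, an
# eikonal activation surrogate, a compact raised-cosine action-potential
# upstroke, bidomain-surrogate sources and forward-projected body-surface
# potentials with calibrated noise.  This is the package's stand-in for a
# bidomain simulation: it exercises the full inverse machinery with known
# ground truth, not a replica of ionic-model electrophysiology.

#' Phantom specification
#'
#' Collects the geometric, electrical and acquisition parameters of the
#' synthetic phantom.  Defaults mirror the desk-scale study conditions:
#' a 150 mm torso sphere, a 35-50 mm myocardial shell, 128 electrodes,
#' ~13 mm torso-surface and ~3.5 mm heart-volume edge lengths, 0.8 mm/ms
#' conduction velocity, 5 ms upstroke, 1 kHz sampling and 20 dB SNR.
#'
#' @param torso_radius_mm torso sphere radius.
#' @param heart_outer_radius_mm,heart_inner_radius_mm myocardial shell radii.
#' @param heart_offset_mm 3-vector displacement of the heart center
#'   (eccentric phantom); default concentric.
#' @param torso_axes,heart_axes relative semi-axis scale factors (3-vectors)
#'   turning the torso / heart spheres into ellipsoids; the radius
#'   parameters multiply these scales.  Default spherical.
#' @param electrode_count number of torso electrodes.
#' @param torso_edge_mm,heart_surface_edge_mm,heart_volume_edge_mm target
#'   edge lengths of the torso surface, the epicardial surface used by the
#'   boundary element baseline, and the myocardial tetrahedra.
#' @param conduction_velocity_mm_ms propagation speed of the eikonal
#'   activation surrogate.
#' @param upstroke_duration_ms duration of the raised-cosine upstroke.
#' @param onset_ms quiescent interval before the earliest activation.
#' @param sample_rate_hz sampling rate.
#' @param duration_ms recording length; `NULL` = cover the full activation
#'   plus upstroke and a 15 ms tail.
#' @param snr_db additive white Gaussian noise level (global SNR).
#' @param sigma_i intracellular conductivity scalar (S/m); a pure amplitude
#'   factor in this homogeneous surrogate.
#' @param seed base seed for all stochastic phantom operations.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(torso_radius_mm = 150,
                         heart_outer_radius_mm = 50,
                         heart_inner_radius_mm = 35,
                         heart_offset_mm = c(0, 0, 0),
                         torso_axes = c(1, 1, 1),
                         heart_axes = c(1, 1, 1),
                         electrode_count = 128,
                         torso_edge_mm = 13,
                         heart_surface_edge_mm = 3.5,
                         heart_volume_edge_mm = 3.5,
                         conduction_velocity_mm_ms = 0.8,
                         upstroke_duration_ms = 5,
                         onset_ms = 10,
                         sample_rate_hz = 1000,
                         duration_ms = NULL,
                         snr_db = 20,
                         sigma_i = 0.2,
                         seed = 1) {
  if (!(torso_radius_mm > heart_outer_radius_mm &&
        heart_outer_radius_mm > heart_inner_radius_mm &&
        heart_inner_radius_mm > 0))
    stopf("radii must satisfy torso > heart_outer > heart_inner > 0")
  if (any(torso_axes <= 0) || any(heart_axes <= 0))
    stopf("axis scale factors must be positive")
  if (sqrt(sum(heart_offset_mm^2)) + heart_outer_radius_mm * max(heart_axes) >=
      torso_radius_mm * min(torso_axes))
    stopf("eccentric heart is not strictly inside the torso")
  if (sample_rate_hz <= 0) stopf("sample_rate_hz must be positive")
  if (!is.finite(snr_db)) stopf("snr_db must be finite")
  structure(list(torso_radius_mm = torso_radius_mm,
                 heart_outer_radius_mm = heart_outer_radius_mm,
                 heart_inner_radius_mm = heart_inner_radius_mm,
                 heart_offset_mm = as.numeric(heart_offset_mm),
                 torso_axes = as.numeric(torso_axes),
                 heart_axes = as.numeric(heart_axes),
                 electrode_count = electrode_count,
                 torso_edge_mm = torso_edge_mm,
                 heart_surface_edge_mm = heart_surface_edge_mm,
                 heart_volume_edge_mm = heart_volume_edge_mm,
                 conduction_velocity_mm_ms = conduction_velocity_mm_ms,
                 upstroke_duration_ms = upstroke_duration_ms,
                 onset_ms = onset_ms,
                 sample_rate_hz = sample_rate_hz,
                 duration_ms = duration_ms,
                 snr_db = snr_db, sigma_i = sigma_i, seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom_spec: torso %g mm, heart shell %g-%g mm%s, ",
                     "%d electrodes, CV %g mm/ms, fs %g Hz, SNR %g dB\n"),
              x$torso_radius_mm, x$heart_inner_radius_mm, x$heart_outer_radius_mm,
              if (any(x$heart_offset_mm != 0)) " (eccentric)" else "",
              x$electrode_count, x$conduction_velocity_mm_ms,
              x$sample_rate_hz, x$snr_db))
  invisible(x)
}

#' Build the phantom geometry
#'
#' Constructs the tetrahedral torso mesh with the embedded myocardial
#' shell (radially layered lattice with analytically exact sphere radii),
#' the torso boundary surface, a matched epicardial surface for the
#' boundary-element baseline, and the electrode set (deterministic
#' Fibonacci lattice snapped to distinct torso-boundary vertices).
#' Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_geometry`: list with `mesh`
#'   (`tet_volume_mesh`), `torso_surface`, `epi_surface`, `electrodes`
#'   (attached to global mesh vertex ids), `heart_center`, `spec`.
#' @export
build_phantom_geometry <- function(spec = phantom_spec()) {
  Rt <- spec$torso_radius_mm
  Rho <- spec$heart_outer_radius_mm
  Rhi <- spec$heart_inner_radius_mm
  ctr <- spec$heart_offset_mm
  ta <- spec$torso_axes; ha <- spec$heart_axes
  r_mid <- (Rho + Rhi) / 2
  freq <- max(10L, round(1.2 * r_mid / spec$heart_volume_edge_mm))
  ic <- icosphere_directions(freq)
  # torso ellipsoid radius along each ray from the (possibly offset) heart
  # center: solve |E^-1 (ctr + t u)| = Rt with E = diag(torso_axes)
  ui <- sweep(ic$dirs, 2, ta, "/")
  ci <- ctr / ta
  a <- rowSums(ui^2)
  b <- 2 * as.numeric(ui %*% ci)
  cc <- sum(ci^2) - Rt^2
  r_t <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  # heart ellipsoid radii along each ray (centered at ctr)
  hi <- sweep(ic$dirs, 2, ha, "/")
  r_hscale <- 1 / row_norms(hi)
  r_ho <- Rho * r_hscale
  r_hi <- Rhi * r_hscale
  plan <- radial_layer_plan(mean(r_hi), mean(r_ho), mean(r_t),
                            spec$heart_volume_edge_mm)
  nlay <- length(plan$inner) + length(plan$heart) + length(plan$outer)
  radii <- matrix(0, nrow(ic$dirs), nlay)
  l <- 0
  for (fr in plan$inner) { l <- l + 1; radii[, l] <- fr * r_hi }
  for (fr in plan$heart) { l <- l + 1; radii[, l] <- r_hi + fr * (r_ho - r_hi) }
  for (fr in plan$outer) { l <- l + 1; radii[, l] <- r_ho + fr * (r_t - r_ho) }
  mesh <- radial_layer_mesh(ic$dirs, ic$faces, radii, center = ctr,
                            heart_layers = plan$heart_layer_ids)
  torso_surface <- boundary_surface(mesh, role = "torso")
  freq_epi <- max(6L, round(1.2 * Rho / spec$heart_surface_edge_mm))
  epi_sphere <- icosphere(Rho, freq_epi)
  epi_surface <- tri_surface_mesh(sweep(epi_sphere$vertices *
                                          rep(ha, each = nrow(epi_sphere$vertices)),
                                        2, ctr, "+"),
                                  epi_sphere$triangles, role = "epicardium")
  pos <- fibonacci_sphere(spec$electrode_count, Rt)
  pos <- pos * rep(ta, each = nrow(pos))
  electrodes <- electrode_set(pos, mesh,
                              boundary_vertices = boundary_vertex_ids(mesh))
  structure(list(mesh = mesh, torso_surface = torso_surface,
                 epi_surface = epi_surface, electrodes = electrodes,
                 heart_center = ctr, spec = spec),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat("phantom_geometry:\n  ")
  print(x$mesh)
  cat("  ")
  print(x$torso_surface)
  cat("  ")
  print(x$epi_surface)
  cat(sprintf("  %d electrodes\n", nrow(x$electrodes$positions)))
  invisible(x)
}

#' Eikonal activation surrogate
#'
#' Ground-truth activation times as shortest-path (Dijkstra) distances
#' from the origin node over the myocardial edge graph, divided by the
#' conduction velocity - a deterministic eikonal surrogate for wavefront
#' propagation.
#'
#' @param mesh a `tet_volume_mesh`.
#' @param origin_node global node index of the beat origin (must be a heart
#'   node).
#' @param velocity conduction velocity in mm/ms.
#' @param graph optional prebuilt heart edge graph (reused across cases).
#' @return object of class `activation_gt`: list with `origin_node`,
#'   `lat_ms` (per heart node, 0 at the origin), `heart_nodes`, `velocity`.
#' @export
simulate_activation <- function(mesh, origin_node, velocity = 0.8,
                                graph = NULL) {
  if (velocity <= 0) stopf("velocity must be positive")
  g <- graph %||% heart_edge_graph(mesh)
  nodes <- which(mesh$heart_node_mask)
  i <- match(origin_node, nodes)
  if (is.na(i)) stopf("origin node %d is not a heart node", origin_node)
  d <- as.numeric(igraph::distances(g, v = i))
  if (any(!is.finite(d))) stopf("heart subgraph is disconnected from the origin")
  structure(list(origin_node = origin_node, lat_ms = d / velocity,
                 heart_nodes = nodes, velocity = velocity),
            class = "activation_gt")
}

#' @export
print.activation_gt <- function(x, ...) {
  cat(sprintf("activation_gt: origin node %d, LAT range [0, %.1f] ms (v = %g mm/ms)\n",
              x$origin_node, max(x$lat_ms), x$velocity))
  invisible(x)
}

#' Transmembrane-voltage surrogate from ground-truth activation
#'
#' Each heart node receives a compact raised-cosine upstroke of unit
#' amplitude centered at its activation time (after the global onset
#' delay): exactly 0 before `LAT - D/2`, exactly 1 after `LAT + D/2`, with
#' the maximum temporal derivative at the activation time.
#'
#' @param gt an [simulate_activation()] result.
#' @param spec a [phantom_spec()] (upstroke duration, onset, sampling rate,
#'   optional fixed duration).
#' @return object of class `vm_field`: `values` (heart nodes x samples),
#'   `sample_rate`, `onset_ms`, `times_ms`.
#' @export
synthesize_vm <- function(gt, spec = phantom_spec()) {
  fs <- spec$sample_rate_hz
  D <- spec$upstroke_duration_ms
  lat <- gt$lat_ms + spec$onset_ms
  dur <- spec$duration_ms %||% (max(lat) + D + 15)
  if (dur < max(lat) + D / 2)
    stopf("duration %.1f ms does not cover the activation (needs %.1f ms)",
          dur, max(lat) + D / 2)
  tms <- seq(0, dur, by = 1000 / fs)
  ph <- outer(lat, tms, function(l, t) (t - (l - D / 2)) / D)   # 0..1 upstroke
  vm <- 0.5 * (1 - cospi(pmin(pmax(ph, 0), 1)))
  structure(list(values = vm, sample_rate = fs, onset_ms = spec$onset_ms,
                 times_ms = tms, heart_nodes = gt$heart_nodes),
            class = "vm_field")
}

#' @export
print.vm_field <- function(x, ...) {
  cat(sprintf("vm_field: %d heart nodes x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$sample_rate))
  invisible(x)
}

#' Simulate one phantom beat end to end
#'
#' Activation, transmembrane surrogate, bidomain-surrogate sources,
#' forward-projected clean electrode signals, and noisy signals at the
#' spec's SNR.
#'
#' @param geom a [build_phantom_geometry()] result.
#' @param origin_node beat origin (global node id; a heart node).
#' @param spec phantom spec (defaults to the one inside `geom`).
#' @param op optional prebuilt [poisson_operator()] for the mesh.
#' @param graph optional prebuilt heart edge graph.
#' @param seed noise seed (defaults to the spec seed).
#' @return list with `gt`, `vm`, `sources`, `clean` and `noisy`
#'   [bsp_signals()].
#' @export
simulate_phantom_beat <- function(geom, origin_node, spec = NULL, op = NULL,
                                  graph = NULL, seed = NULL) {
  spec <- spec %||% geom$spec
  gt <- simulate_activation(geom$mesh, origin_node,
                            spec$conduction_velocity_mm_ms, graph = graph)
  vm <- synthesize_vm(gt, spec)
  src <- compute_sources(vm, geom$mesh, sigma_i = spec$sigma_i)
  clean <- forward_solve(src, geom$mesh, geom$electrodes, op = op,
                         sample_rate = spec$sample_rate_hz)
  noisy <- add_noise(clean, spec$snr_db, seed = seed %||% spec$seed)
  list(gt = gt, vm = vm, sources = src, clean = clean, noisy = noisy)
}

#' Default 16-beat benchmark scenario
#'
#' Deterministic origin placements mirroring the three-region benchmark
#' layout: six beats from the basal-analog cap of the shell (around the
#' top pole, mid-wall), six from the inner (endocardial-facing,
#' septal-analog) wall, and four from the outer (free-wall-analog) wall.
#' Targets are placed on evenly spaced azimuths and snapped to the nearest
#' heart node.
#'
#' @param geom a [build_phantom_geometry()] result.
#' @param n_base,n_septal,n_freewall replicate counts per region.
#' @return data frame with columns `case`, `region`, `origin_node`.
#' @export
benchmark_scenario <- function(geom, n_base = 6, n_septal = 6, n_freewall = 4) {
  stopifnot(n_base >= 1, n_septal >= 1, n_freewall >= 1)
  spec <- geom$spec
  ctr <- geom$heart_center
  nodes <- which(geom$mesh$heart_node_mask)
  X <- sweep(geom$mesh$vertices[nodes, , drop = FALSE], 2, ctr)
  snap <- function(target) nodes[which.min(rowSums(sweep(X, 2, target)^2))]
  r_mid <- (spec$heart_outer_radius_mm + spec$heart_inner_radius_mm) / 2
  sph <- function(r, theta_deg, phi_deg) {
    th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
    r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  targets <- rbind(
    do.call(rbind, lapply(seq_len(n_base), function(k)
      sph(r_mid, 15, (k - 1) * 360 / n_base))),
    do.call(rbind, lapply(seq_len(n_septal), function(k)
      sph(spec$heart_inner_radius_mm, 95, 30 + (k - 1) * 360 / n_septal))),
    do.call(rbind, lapply(seq_len(n_freewall), function(k)
      sph(spec$heart_outer_radius_mm, 115, 45 + (k - 1) * 360 / n_freewall))))
  region <- c(rep("base", n_base), rep("septal", n_septal),
              rep("freewall", n_freewall))
  origin <- vapply(seq_len(nrow(targets)), function(i) snap(targets[i, ]), 0L)
  data.frame(case = seq_along(origin), region = region, origin_node = origin)
}
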
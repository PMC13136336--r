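# Localization and infarct-characterization metrics: Euclidean/geodesic
# origin errors, AHA 17-segment labeling of the left ventricle, infarct
# extent/center/overlap, TAT-based fibrosis flagging, and benchmark
# summary tables.

#' Euclidean and geodesic localization error between two points
#'
#' The Euclidean error is the straight-line distance.  The geodesic error
#' is the edge-graph shortest path between the mesh nodes nearest to the
#' two points, plus both snapping offsets; for a volume mesh the myocardial
#' tetrahedral edge graph is used, for a surface mesh the surface edge
#' graph.
#'
#' @param true_point,est_point 3-vectors (mm).
#' @param mesh a `tri_surface_mesh` or `tet_volume_mesh`; a prebuilt igraph
#'   from the internal graph builder can be supplied via `graph` to reuse
#'   it across many evaluations.
#' @param graph optional prebuilt mesh graph (with `nodes` attribute).
#' @return object of class `localization_error`: list with `euclidean_mm`,
#'   `geodesic_mm`, snapped node indices and snapping offsets.
#' @export
localization_error <- function(true_point, est_point, mesh, graph = NULL) {
  true_point <- as.numeric(true_point); est_point <- as.numeric(est_point)
  eu <- sqrt(sum((true_point - est_point)^2))
  g <- graph %||% mesh_graph(mesh)
  nodes <- attr(g, "nodes")
  verts <- mesh$vertices[nodes, , drop = FALSE]
  ia <- which.min(rowSums(sweep(verts, 2, true_point)^2))
  ib <- which.min(rowSums(sweep(verts, 2, est_point)^2))
  snap_a <- sqrt(sum((verts[ia, ] - true_point)^2))
  snap_b <- sqrt(sum((verts[ib, ] - est_point)^2))
  gd <- if (ia == ib) 0 else as.numeric(igraph::distances(g, v = ia, to = ib))
  if (!is.finite(gd)) stopf("points lie in disconnected mesh components")
  structure(list(euclidean_mm = eu, geodesic_mm = gd + snap_a + snap_b,
                 true_node = nodes[ia], est_node = nodes[ib],
                 snap_true_mm = snap_a, snap_est_mm = snap_b),
            class = "localization_error")
}

#' @export
print.localization_error <- function(x, ...) {
  cat(sprintf("localization_error: euclidean %.2f mm, geodesic %.2f mm\n",
              x$euclidean_mm, x$geodesic_mm))
  invisible(x)
}

#' AHA 17-segment labeling of left-ventricular nodes
#'
#' Nodes are binned by normalized long-axis position (apex cap, then
#' apical/mid/basal thirds) and by circumferential angle about the long
#' axis referenced to the right-ventricular insertion direction: six
#' sectors for the basal (1-6) and mid (7-12) rings, four for the apical
#' ring (13-16), and segment 17 for the apex cap.
#'
#' @param coords node coordinate matrix of the LV mesh (or a mesh object).
#' @param landmarks list with `apex` (3-vector), `base_centroid` (3-vector)
#'   and `rv_insertion_dir` (3-vector, need not be orthogonal to the axis).
#' @param apex_cap normalized long-axis height below which nodes belong to
#'   the apex segment (default 0.2).
#' @return object of class `aha17`: integer labels 1..17 per node plus the
#'   geometry used.
#' @export
aha17_assign <- function(coords, landmarks, apex_cap = 0.2) {
  if (inherits(coords, "tet_volume_mesh"))
    coords <- coords$vertices[coords$heart_node_mask, , drop = FALSE]
  if (inherits(coords, "tri_surface_mesh")) coords <- coords$vertices
  coords <- as_matrix3(coords, "LV node coordinates")
  apex <- as.numeric(landmarks$apex)
  base <- as.numeric(landmarks$base_centroid)
  rvd <- as.numeric(landmarks$rv_insertion_dir)
  axis <- base - apex
  L <- sqrt(sum(axis^2))
  if (L < 1e-9) stopf("degenerate long axis: apex coincides with base centroid")
  u <- axis / L
  e1 <- rvd - sum(rvd * u) * u
  if (sqrt(sum(e1^2)) < 1e-9) stopf("RV insertion direction is parallel to the long axis")
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rel <- sweep(coords, 2, apex)
  s <- pmin(pmax(as.numeric(rel %*% u) / L, 0), 1)
  ang <- atan2(as.numeric(rel %*% e2), as.numeric(rel %*% e1)) %% (2 * pi)
  lab <- integer(nrow(coords))
  ring_breaks <- apex_cap + (1 - apex_cap) * c(1 / 3, 2 / 3)
  for (i in seq_len(nrow(coords))) {
    if (s[i] < apex_cap) { lab[i] <- 17L; next }
    if (s[i] >= ring_breaks[2]) {        # basal ring: segments 1..6
      lab[i] <- 1L + (floor(ang[i] / (pi / 3)) %% 6)
    } else if (s[i] >= ring_breaks[1]) { # mid ring: 7..12
      lab[i] <- 7L + (floor(ang[i] / (pi / 3)) %% 6)
    } else {                             # apical ring: 13..16
      lab[i] <- 13L + (floor(ang[i] / (pi / 2)) %% 4)
    }
  }
  structure(list(labels = lab, height = s, angle = ang,
                 landmarks = landmarks, apex_cap = apex_cap),
            class = "aha17")
}

#' @export
print.aha17 <- function(x, ...) {
  cat("aha17 segmentation:\n")
  print(table(factor(x$labels, levels = 1:17)))
  invisible(x)
}

#' Infarct characterization metrics
#'
#' Computes the standard descriptors used to compare an estimated fibrotic
#' region with a reference annotation on the AHA 17-segment model: the
#' extent (fraction of myocardial tissue in the estimated segments), the
#' center (segment containing the centroid of the estimated region), and
#' the segment overlap.  Overlap defaults to the Jaccard index over segment
#' sets; a recall-style alternative (`|est & ref| / |ref|`) is also
#' reported.
#'
#' @param est_segments,ref_segments integer vectors of segment ids (1..17).
#' @param segment_node_counts named or length-17 vector of node counts per
#'   segment (used for the extent).
#' @param segmentation optional [aha17_assign()] result and `coords` node
#'   coordinates; when both are given the center segment is derived from
#'   the centroid of the estimated-region nodes, otherwise the largest
#'   estimated segment is used.
#' @param coords optional node coordinates matching `segmentation`.
#' @return object of class `infarct_metrics` with `extent`, `center`,
#'   `overlap_jaccard`, `overlap_recall`, and the input sets.
#' @export
infarct_metrics <- function(est_segments, ref_segments, segment_node_counts,
                            segmentation = NULL, coords = NULL) {
  est <- sort(unique(as.integer(est_segments)))
  ref <- sort(unique(as.integer(ref_segments)))
  if (length(ref) == 0) stopf("empty reference segment set")
  if (any(c(est, ref) < 1) || any(c(est, ref) > 17)) stopf("segment ids must be in 1..17")
  cnt <- rep(0, 17)
  if (!is.null(names(segment_node_counts))) {
    cnt[as.integer(names(segment_node_counts))] <- segment_node_counts
  } else cnt[seq_along(segment_node_counts)] <- segment_node_counts
  extent <- sum(cnt[est]) / sum(cnt)
  inter <- length(intersect(est, ref))
  overlap_j <- inter / length(union(est, ref))
  overlap_r <- inter / length(ref)
  center <- NA_integer_
  if (length(est) > 0) {
    if (!is.null(segmentation) && !is.null(coords)) {
      lab <- segmentation$labels
      sel <- which(lab %in% est)
      cen <- colMeans(coords[sel, , drop = FALSE])
      d2 <- rowSums(sweep(coords[sel, , drop = FALSE], 2, cen)^2)
      center <- lab[sel[which.min(d2)]]
    } else center <- est[which.max(cnt[est])]
  }
  structure(list(est_segments = est, ref_segments = ref, extent = extent,
                 center = center, overlap_jaccard = overlap_j,
                 overlap_recall = overlap_r),
            class = "infarct_metrics")
}

#' @export
print.infarct_metrics <- function(x, ...) {
  cat(sprintf("infarct_metrics: extent %.1f%%, center segment %d, overlap (Jaccard) %.2f, (recall) %.2f\n",
              100 * x$extent, x$center, x$overlap_jaccard, x$overlap_recall))
  invisible(x)
}

#' Flag slow-activation segments as fibrotic by total activation time
#'
#' Computes the total activation time (LAT range) within each AHA segment
#' and flags segments whose TAT exceeds a robust outlier threshold
#' (median + k * MAD across segments, by default k = 2).
#'
#' @param lat a [compute_lat()] result or numeric vector (ms).
#' @param seg an [aha17_assign()] result (labels matching `lat` nodes).
#' @param k MAD multiplier; `Inf` flags nothing.
#' @return integer vector of flagged segment ids.
#' @export
tat_fibrosis_label <- function(lat, seg, k = 2) {
  times <- if (inherits(lat, "lat_map")) lat$times else as.numeric(lat)
  lab <- if (inherits(seg, "aha17")) seg$labels else as.integer(seg)
  if (length(times) != length(lab)) stopf("lat/segmentation length mismatch")
  segs <- sort(unique(lab[is.finite(times)]))
  tats <- vapply(segs, function(sid) {
    tt <- times[lab == sid & is.finite(times)]
    if (length(tt) == 0) NA_real_ else max(tt) - min(tt)
  }, 0)
  ok <- is.finite(tats)
  if (sum(ok) < 3) stopf("need TATs in at least 3 segments")
  if (!is.finite(k)) return(integer(0))
  thr <- median(tats[ok]) + k * mad(tats[ok])
  sort(segs[ok & tats > thr])
}

#' Percentage error reduction between two methods
#'
#' `100 * (from - to) / from`: the reduction achieved by the second method
#' relative to the first.
#'
#' @param from,to error magnitudes (e.g. mean localization errors in mm).
#' @return reduction in percent.
#' @export
error_reduction <- function(from, to) 100 * (from - to) / from

#' Summary table of localization errors by region and method
#'
#' Produces per-region and global mean, SD (sample), median and IQR of the
#' Euclidean and geodesic errors for each method, and when exactly two
#' methods are present appends their percentage error reduction (first
#' method taken as reference).
#'
#' @param errors data frame with columns `method`, `region`,
#'   `euclidean_mm`, `geodesic_mm` (one row per benchmark case).
#' @return data frame of summary statistics; reduction rows have
#'   `statistic == "reduction_pct"`.
#' @export
benchmark_summary <- function(errors) {
  need <- c("method", "region", "euclidean_mm", "geodesic_mm")
  if (!all(need %in% names(errors))) stopf("errors must have columns %s",
                                           paste(need, collapse = ", "))
  regions <- c(sort(unique(as.character(errors$region))), "global")
  methods <- unique(as.character(errors$method))
  rows <- list()
  stat_row <- function(e, method, region, metric) {
    data.frame(method = method, region = region, metric = metric,
               n = length(e), mean = mean(e), sd = sd(e),
               median = median(e), iqr = IQR(e))
  }
  for (rg in regions) for (md in methods) for (mt in c("euclidean_mm", "geodesic_mm")) {
    sub <- errors[errors$method == md & (rg == "global" | errors$region == rg), ]
    if (nrow(sub) == 0) stopf("no cases for method '%s' in region '%s'", md, rg)
    rows[[length(rows) + 1]] <- stat_row(sub[[mt]], md, rg, mt)
  }
  out <- do.call(rbind, rows)
  out$statistic <- "summary"
  if (length(methods) == 2) {
    red <- list()
    for (rg in regions) for (mt in c("euclidean_mm", "geodesic_mm")) {
      a <- out$mean[out$method == methods[1] & out$region == rg & out$metric == mt]
      b <- out$mean[out$method == methods[2] & out$region == rg & out$metric == mt]
      red[[length(red) + 1]] <-
        data.frame(method = paste(methods, collapse = " -> "), region = rg,
                   metric = mt, n = NA, mean = error_reduction(a, b), sd = NA,
                   median = NA, iqr = NA, statistic = "reduction_pct")
    }
    out <- rbind(out, do.call(rbind, red))
  }
  rownames(out) <- NULL
  out
}

#' @importFrom stats IQR
NULL
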
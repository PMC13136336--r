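test_that("localization error satisfies metric identities on a flat grid", {
  m <- box_tet_mesh(8, 8, 1)
  p <- m$vertices[11, ]
  le0 <- localization_error(p, p, m)
  expect_equal(le0$euclidean_mm, 0)
  expect_equal(le0$geodesic_mm, 0)

  set.seed(5)
  for (r in 1:20) {
    ij <- sample(nrow(m$vertices), 2)
    le <- localization_error(m$vertices[ij[1], ], m$vertices[ij[2], ], m)
    expect_gte(le$geodesic_mm + 1e-9, le$euclidean_mm)
  }
  corner <- localization_error(m$vertices[1, ],
                               m$vertices[nrow(m$vertices), ], m)
  expect_lt(corner$geodesic_mm / corner$euclidean_mm, 1.1)
})

test_that("AHA 17-segment labels cover an idealized LV and match brute force", {
  set.seed(1)
  th <- runif(4000, 0, pi / 2 + 0.4); ph <- runif(4000, 0, 2 * pi)
  pts <- cbind(30 * sin(th) * cos(ph), 30 * sin(th) * sin(ph),
               60 * (1 - cos(th)))          # apex at z=0, base at z=60
  lm <- list(apex = c(0, 0, 0), base_centroid = c(0, 0, 60),
             rv_insertion_dir = c(1, 0, 0))
  seg <- aha17_assign(pts, lm)
  expect_setequal(unique(seg$labels), 1:17)
  expect_equal(seg$labels[which.min(pts[, 3])], 17)

  # brute-force per-node classifier oracle
  s <- pts[, 3] / 60
  ang <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  brute <- integer(nrow(pts))
  b1 <- 0.2 + 0.8 / 3; b2 <- 0.2 + 1.6 / 3
  for (i in seq_len(nrow(pts))) {
    if (s[i] < 0.2) brute[i] <- 17
    else if (s[i] >= b2) brute[i] <- 1 + floor(ang[i] / (pi / 3)) %% 6
    else if (s[i] >= b1) brute[i] <- 7 + floor(ang[i] / (pi / 3)) %% 6
    else brute[i] <- 13 + floor(ang[i] / (pi / 2)) %% 4
  }
  expect_equal(seg$labels, brute)

  # joint rigid rotation leaves labels unchanged
  R <- qr.Q(qr(matrix(c(0.2, -1, 0.4, 1.3, 0.1, 0.5, -0.3, 0.8, 1), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  lm_r <- list(apex = c(0, 0, 0), base_centroid = as.numeric(R %*% c(0, 0, 60)),
               rv_insertion_dir = as.numeric(R %*% c(1, 0, 0)))
  seg_r <- aha17_assign(pts %*% t(R), lm_r)
  expect_identical(seg_r$labels, seg$labels)

  expect_error(aha17_assign(pts, list(apex = c(0, 0, 0),
                                      base_centroid = c(0, 0, 0),
                                      rv_insertion_dir = c(1, 0, 0))),
               "degenerate")
})

test_that("infarct metrics reproduce set arithmetic and symmetry", {
  im <- infarct_metrics(c(4, 5, 9, 10, 11), c(3, 4, 9, 10, 11, 15),
                        rep(10, 17))
  expect_equal(im$overlap_jaccard, 4 / 7)
  im_id <- infarct_metrics(2:4, 2:4, rep(1, 17))
  expect_equal(im_id$overlap_jaccard, 1)
  expect_true(im_id$center %in% im_id$est_segments)
  im_disj <- infarct_metrics(1:2, 5:6, rep(1, 17))
  expect_equal(im_disj$overlap_jaccard, 0)
  # Jaccard symmetry
  a <- c(1, 4, 7); b <- c(4, 8, 9, 12)
  expect_equal(infarct_metrics(a, b, rep(2, 17))$overlap_jaccard,
               infarct_metrics(b, a, rep(2, 17))$overlap_jaccard)
  # extent is the node fraction of the estimated segments
  cnt <- c(rep(10, 16), 40)
  expect_equal(infarct_metrics(c(1, 17), 1, cnt)$extent, 50 / 200)
  expect_error(infarct_metrics(1:2, integer(0), cnt), "empty reference")
  expect_error(infarct_metrics(18, 1, cnt), "1..17")
})

test_that("TAT fibrosis labeling flags only delayed segments", {
  set.seed(1)
  th <- runif(3000, 0, pi / 2 + 0.4); ph <- runif(3000, 0, 2 * pi)
  pts <- cbind(30 * sin(th) * cos(ph), 30 * sin(th) * sin(ph),
               60 * (1 - cos(th)))
  seg <- aha17_assign(pts, list(apex = c(0, 0, 0), base_centroid = c(0, 0, 60),
                                rv_insertion_dir = c(1, 0, 0)))
  lats <- runif(3000, 0, 10)
  expect_length(tat_fibrosis_label(rep(5, 3000), seg), 0)   # uniform LAT
  lats[seg$labels == 9] <- lats[seg$labels == 9] + runif(sum(seg$labels == 9), 0, 100)
  expect_equal(tat_fibrosis_label(lats, seg, k = 2), 9)
  expect_length(tat_fibrosis_label(lats, seg, k = Inf), 0)
})

test_that("benchmark summary statistics and reductions are exact", {
  err <- data.frame(method = rep(c("epicardial", "volumetric"), each = 3),
                    region = "septal",
                    euclidean_mm = c(10, 20, 30, 5, 10, 15),
                    geodesic_mm = c(12, 24, 36, 6, 12, 18))
  s <- benchmark_summary(err)
  g <- s[s$statistic == "summary" & s$region == "global" &
         s$metric == "euclidean_mm", ]
  expect_equal(g$mean[g$method == "epicardial"], 20)
  expect_equal(g$sd[g$method == "epicardial"], 10)
  red <- s[s$statistic == "reduction_pct" & s$region == "global" &
           s$metric == "euclidean_mm", ]
  expect_equal(red$mean, 50)

  # identical methods give zero reduction
  err2 <- err; err2$euclidean_mm <- rep(c(10, 20, 30), 2)
  err2$geodesic_mm <- rep(c(12, 24, 36), 2)
  s2 <- benchmark_summary(err2)
  expect_equal(s2$mean[s2$statistic == "reduction_pct"], rep(0, 4))
})

test_that("reduction formula reproduces reference mean pairs", {
  expect_equal(round(error_reduction(41.28, 16.82), 1), 59.3)
  expect_equal(round(error_reduction(29.82, 13.53), 1), 54.6)
  expect_equal(round(error_reduction(46.65, 14.02), 1), 69.9)
  expect_equal(round(error_reduction(51.62, 20.65), 1), 60.0)
})
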
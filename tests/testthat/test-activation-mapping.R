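sigmoid_trace <- function(t0, tau = 2, n = 400) {
  t <- seq_len(n)
  1 / (1 + exp(-(t - t0) / tau))
}

test_that("single-deflection templates are marked at the inflection", {
  x <- rbind(-sigmoid_trace(120), -sigmoid_trace(200.3), -sigmoid_trace(77.7))
  lm <- compute_lat(x, 1000, polarity = "potential")
  # sample k sits at time (k-1)/fs, so the inflection at sample t0 is at
  # (t0-1) ms on the recording clock
  expect_lt(max(abs(lm$times - (c(120, 200.3, 77.7) - 1))), 1)
  # source polarity: positive-going upstroke, negated internally
  lm2 <- compute_lat(-x, 1000, polarity = "source")
  expect_equal(lm2$times, lm$times)
})

test_that("LAT matches the slope oracle on 100 random clean templates", {
  set.seed(9)
  for (r in 1:100) {
    t0 <- runif(1, 50, 350); tau <- runif(1, 1.5, 8); a <- runif(1, .5, 5)
    x <- matrix(-a * sigmoid_trace(t0, tau), 1)
    l <- compute_lat(x, 1000, polarity = "potential", smooth_cutoff = NULL)
    oracle <- which.min(diff(as.numeric(x))) - 0.5
    expect_lt(abs(l$times - oracle), 1)
  }
})

test_that("LAT is exactly shift-equivariant and scale-invariant", {
  x <- rbind(-sigmoid_trace(120), -sigmoid_trace(200.3), -sigmoid_trace(77.7))
  lm <- compute_lat(x, 1000, polarity = "potential")
  for (k in c(1, 37, 123)) {
    xs <- x[, c((400 - k + 1):400, 1:(400 - k))]
    lms <- compute_lat(xs, 1000, polarity = "potential")
    expect_equal((lms$times - lm$times) %% 400, rep(k, 3))
  }
  lmc <- compute_lat(3.7e4 * x, 1000, polarity = "potential")
  expect_identical(lmc$times, lm$times)
})

test_that("flat traces are masked invalid instead of erroring", {
  x <- rbind(-sigmoid_trace(120), rep(2.5, 400))
  lm <- compute_lat(x, 1000, polarity = "potential")
  expect_true(lm$valid[1])
  expect_false(lm$valid[2])
  expect_true(is.na(lm$times[2]))
})

test_that("earliest site equals a sort-based percentile-centroid oracle", {
  set.seed(2)
  n <- 200
  lats <- runif(n, 0, 100)
  coords <- matrix(rnorm(3 * n), n, 3)
  es <- earliest_site(lats, coords, 10)
  thr <- as.numeric(quantile(lats, 0.1, type = 7))
  nodes <- which(lats < thr)
  expect_setequal(es$nodes, nodes)
  expect_equal(es$centroid, colMeans(coords[nodes, , drop = FALSE]))

  # permutation invariance of the centroid
  p <- sample(n)
  es_p <- earliest_site(lats[p], coords[p, ], 10)
  expect_equal(sort(p[es_p$nodes]), sort(nodes))
  expect_equal(es_p$centroid, es$centroid)

  # constructed tie case: one strict minimum, a 9% block tied just above
  lats2 <- c(0, rep(5, 17), runif(182, 50, 100))
  es2 <- earliest_site(lats2, coords, 10)
  thr2 <- as.numeric(quantile(lats2, 0.1, type = 7))
  expect_setequal(es2$nodes, which(lats2 < thr2))

  # fully degenerate: all equal -> every valid node contributes
  es3 <- earliest_site(rep(7, 20), coords[1:20, ], 10)
  expect_equal(length(es3$nodes), 20)
  expect_equal(es3$centroid, colMeans(coords[1:20, ]))

  expect_error(earliest_site(rep(1, 5), coords[1:5, ]), "at least 10")
})

test_that("total activation time is the LAT range", {
  expect_equal(total_activation_time(c(10, 25, 40)), 30)
  expect_equal(total_activation_time(rep(12, 5)), 0)
  set.seed(3)
  lats <- runif(50, 0, 80)
  for (r in 1:5) {
    sub <- sample(50, sample(2:20, 1))
    expect_equal(total_activation_time(lats, sub),
                 max(lats[sub]) - min(lats[sub]))
  }
  expect_error(total_activation_time(c(NA_real_, NA_real_)), "empty")
})

test_that("volumetric reconstruction LATs track ground truth on clean data", {
  cp <- coarse_phantom()
  ops <- cp$ops
  sc <- benchmark_scenario(ops$geom)
  beat <- simulate_phantom_beat(ops$geom, sc$origin_node[8], op = ops$op,
                                graph = ops$graph)
  fit <- solve_volumetric(ops$prep_vol, beat$clean)
  lat <- compute_lat(fit)
  r <- cor(lat$times[lat$valid], beat$gt$lat_ms[lat$valid])
  expect_gt(r, 0.8)
})
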
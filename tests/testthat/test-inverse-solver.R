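test_that("epicardial Tikhonov equals the normal-equations solution", {
  set.seed(3)
  A <- matrix(rnorm(600), 20, 30)
  g <- matrix(rnorm(40), 20, 2)
  lam <- 0.37
  h1 <- coef(solve_epicardial(A, g, lambda = lam))
  gc <- sweep(g, 2, colMeans(g))
  Ac <- sweep(A, 2, colMeans(A))
  h2 <- solve(crossprod(Ac) + lam * diag(30), crossprod(Ac, gc))
  expect_lt(max(abs(h1 - h2)), 1e-12)

  # shrinkage limit
  s1 <- max(svd(Ac)$d)
  hbig <- coef(solve_epicardial(A, g, lambda = 1e6 * s1^2))
  expect_lt(max(abs(hbig)), 1e-4 * max(abs(h2)))

  # noiseless recovery with a well-conditioned square operator (solved in
  # the full space: the common mode is recoverable only without
  # re-referencing)
  A2 <- diag(10) + 0.1 * matrix(rnorm(100), 10, 10)
  h_true <- matrix(rnorm(20), 10, 2)
  g2 <- A2 %*% h_true
  h_rec <- coef(solve_epicardial(A2, g2, lambda = 1e-12, re_reference = FALSE))
  expect_lt(max(abs(h_rec - h_true)) / max(abs(h_true)), 1e-6)
})

test_that("constrained solution equals the dense KKT solve", {
  set.seed(13)
  worst <- 0
  for (rep in 1:100) {
    M <- sample(5:10, 1); P <- sample(11:20, 1)
    B <- matrix(rnorm(M * P), M, P)
    w <- runif(P, 0.5, 2)
    g <- matrix(rnorm(M * 2), M, 2)
    lam <- 10^runif(1, -3, 1)
    f1 <- coef(solve_volumetric(B, g, weights = w, lambda = lam))
    X <- B %*% diag(w)
    X <- sweep(X, 2, colMeans(X))
    gc <- sweep(g, 2, colMeans(g))
    KKT <- rbind(cbind(crossprod(X) + lam * diag(P), w), c(w, 0))
    f2 <- sapply(1:2, function(t) solve(KKT, c(crossprod(X, gc[, t]), 0))[1:P])
    worst <- max(worst, max(abs(f1 - f2)))
  }
  expect_lt(worst, 1e-9)
})

test_that("constraint residual and gauge robustness hold on the phantom", {
  tb <- tiny_ball()
  B <- assemble_green_transfer(tb$mesh, tb$el, tb$op)
  w <- as.numeric(B$weights)
  set.seed(15)
  hn <- which(tb$mesh$heart_node_mask)
  g <- bsp_signals(matrix(rnorm(nrow(tb$el$positions) * 6), ncol = 6), 1000)
  fit <- solve_volumetric(B, g, lambda = 1e-3)
  f <- coef(fit)
  for (t in seq_len(ncol(f)))
    expect_lt(abs(sum(w * f[, t])),
              1e-10 * sqrt(sum(w^2)) * sqrt(sum(f[, t]^2)) + 1e-300)
  expect_lt(max(fit$constraint_residual), 1e-9 * max(abs(f)) * sum(w))

  B2 <- B
  B2$B <- B$B + matrix(rnorm(nrow(B$B)), ncol = 1) %*% rep(1, ncol(B$B))
  f2 <- coef(solve_volumetric(B2, g, lambda = 1e-3))
  expect_lt(max(abs(f2 - f)), 1e-9 * max(abs(f)))
})

test_that("solutions scale linearly with the data at fixed lambda", {
  set.seed(16)
  A <- matrix(rnorm(200), 10, 20)
  g <- matrix(rnorm(30), 10, 3)
  f1 <- coef(solve_epicardial(A, g, lambda = 0.05))
  f2 <- coef(solve_epicardial(A, 4 * g, lambda = 0.05))
  expect_equal(f2, 4 * f1, tolerance = 1e-12)
})

test_that("L-curve trace is monotone and the corner matches brute force", {
  set.seed(17)
  n <- 50
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))
  V <- qr.Q(qr(matrix(rnorm(n * n), n)))
  s <- c(10 * 0.98^(1:20), 1e-3 * 0.9^(1:30))       # sharp spectral gap
  A <- U %*% (s * t(V))
  h_true <- rnorm(n)
  g <- A %*% h_true + 1e-3 * rnorm(n)
  fit <- solve_epicardial(A, cbind(g, g), lambda = "auto")
  tr <- fit$trace
  expect_true(all(diff(tr$residual) > -1e-9 * max(tr$residual)))
  expect_true(all(diff(tr$solution) < 1e-9 * max(tr$solution)))

  # brute-force curvature maximization on a dense grid
  Ac <- sweep(A, 2, colMeans(A))
  gc <- sweep(cbind(g, g), 2, colMeans(cbind(g, g)))
  sv <- svd(Ac)
  beta <- crossprod(sv$u, gc)
  dense <- max(sv$d)^2 * 10^seq(-8, 2, length.out = 4000)
  rho <- vapply(dense, function(l)
    sqrt(sum(((l / (sv$d^2 + l)) * beta)^2)), 0)
  eta <- vapply(dense, function(l)
    sqrt(sum(((sv$d / (sv$d^2 + l)) * beta)^2)), 0)
  x <- log(rho); y <- log(eta); t <- log(dense)
  i <- 2:(length(t) - 1)
  xp <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  yp <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  h <- diff(t)[1]
  xpp <- (x[i + 1] - 2 * x[i] + x[i - 1]) / h^2
  ypp <- (y[i + 1] - 2 * y[i] + y[i - 1]) / h^2
  kap <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  lam_brute <- dense[i][which.max(kap)]
  # within one grid step of the package grid
  grid <- fit$trace$lambda
  step <- diff(log(grid))[1]
  expect_lt(abs(log(fit$lambda) - log(lam_brute)), 1.5 * step)
})

test_that("degenerate flat L-curve falls back to the smallest lambda", {
  g <- matrix(rnorm(20), 10, 2)
  expect_warning(fit <- solve_epicardial(diag(10) - 1 / 10, g, lambda = "auto"),
                 "corner")
  expect_equal(fit$lambda, min(fit$trace$lambda))
})

test_that("inconsistent traces are rejected", {
  tr <- data.frame(lambda = c(1, 2, 3, 4),
                   residual = c(1, 2, 1.5, 3),
                   solution = c(3, 2.5, 2, 1))
  expect_error(lcurve_select(tr), "non-decreasing")
  tr2 <- data.frame(lambda = 1:2, residual = 1:2, solution = 2:1)
  expect_error(lcurve_select(tr2), "at least 3")
})

test_that("fit object methods are coherent", {
  set.seed(19)
  A <- matrix(rnorm(300), 15, 20)
  g <- matrix(rnorm(45), 15, 3)
  fit <- solve_epicardial(A, g, lambda = 0.1)
  expect_s3_class(fit, "ecgi_fit")
  expect_equal(dim(coef(fit)), c(20, 3))
  gc <- sweep(g, 2, colMeans(g))
  expect_equal(fitted(fit) + residuals(fit), gc, tolerance = 1e-12)
  expect_output(print(fit), "epicardial")
  expect_output(print(summary(fit)), "lambda")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
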
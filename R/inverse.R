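# Regularized inverse solvers: zero-order Tikhonov for epicardial
# potentials, and equality-constrained zero-order Tikhonov for volumetric
# sources (the source existence condition as a single linear constraint),
# with L-curve selection of the regularization parameter.  One SVD is
# factored per operator and reused across all time samples and all lambda
# values.

# Householder reflector mapping w to ||w|| e1; the null-space basis of w^T
# is columns 2..P of H.  Returns functions applying H[,2:P] and its
# transpose implicitly.
householder_nullspace <- function(w) {
  w <- as.numeric(w)
  p <- length(w)
  v <- w
  v[1] <- v[1] + sign(w[1] + (w[1] == 0)) * sqrt(sum(w^2))
  beta <- 2 / sum(v * v)
  list(
    # Z x  (x in R^{p-1})
    expand = function(x) {
      u <- rbind(0, x)
      u - v %o% (beta * as.numeric(crossprod(v, u)))
    },
    # Z^T y (y in R^p)
    reduce = function(y) {
      y <- as.matrix(y)
      u <- y - v %o% (beta * as.numeric(crossprod(v, y)))
      u[-1, , drop = FALSE]
    })
}

default_lambda_grid <- function(s1, n = 60) {
  s1^2 * 10^seq(-8, 2, length.out = n)
}

# SVD-filtered Tikhonov over a lambda grid: residual and solution norms
# aggregated over all samples, plus the solution for a given lambda.
# `dec` allows reusing a precomputed svd(X) across many recordings.
tikhonov_engine <- function(X, g, dec = NULL) {
  sv <- dec %||% svd(X)
  pos <- sv$d > max(sv$d) * 1e-14
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  s <- sv$d[pos]
  beta <- crossprod(U, g)                 # r x T
  g_perp2 <- pmax(colSums(g^2) - colSums(beta^2), 0)   # out-of-range residual
  trace_at <- function(lambda_grid) {
    res <- sol <- numeric(length(lambda_grid))
    for (k in seq_along(lambda_grid)) {
      lam <- lambda_grid[k]
      fr <- lam / (s^2 + lam)            # residual filter
      fs <- s / (s^2 + lam)              # solution filter
      res[k] <- sqrt(sum((fr * beta)^2) + sum(g_perp2))
      sol[k] <- sqrt(sum((fs * beta)^2))
    }
    list(residual = res, solution = sol)
  }
  solve_at <- function(lambda) V %*% ((s / (s^2 + lambda)) * beta)
  list(trace_at = trace_at, solve_at = solve_at, s1 = s[1], svd = sv)
}

#' L-curve corner selection
#'
#' Selects the regularization parameter at the point of maximum curvature of
#' the parametric curve (log residual norm, log solution norm) over a
#' log-spaced lambda grid, with curvature estimated by central finite
#' differences.  A degenerate (cornerless) curve, detected by a curvature
#' maximum below `curvature_min`, falls back to the smallest lambda with a
#' warning.
#'
#' @param trace data frame with columns `lambda`, `residual`, `solution`
#'   (as produced by the solvers), lambda increasing.
#' @param curvature_min smallest curvature accepted as a corner.
#' @return list with `lambda` (selected), `index`, and the `curvature`
#'   vector (NA at the end points).
#' @export
lcurve_select <- function(trace, curvature_min = 1e-2) {
  lam <- trace$lambda; rho <- trace$residual; eta <- trace$solution
  if (length(lam) < 3) stopf("need at least 3 lambda samples for the L-curve")
  if (any(diff(rho) < -1e-9 * max(rho)))
    stopf("residual norm is not non-decreasing in lambda: solver inconsistency")
  if (any(diff(eta) > 1e-9 * max(eta)))
    stopf("solution norm is not non-increasing in lambda: solver inconsistency")
  x <- log(pmax(rho, .Machine$double.xmin))
  y <- log(pmax(eta, .Machine$double.xmin))
  t <- log(lam)
  n <- length(t)
  i <- 2:(n - 1)
  xp <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  yp <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  h1 <- t[i] - t[i - 1]; h2 <- t[i + 1] - t[i]
  xpp <- 2 * (h1 * x[i + 1] - (h1 + h2) * x[i] + h2 * x[i - 1]) / (h1 * h2 * (h1 + h2))
  ypp <- 2 * (h1 * y[i + 1] - (h1 + h2) * y[i] + h2 * y[i - 1]) / (h1 * h2 * (h1 + h2))
  kappa <- rep(NA_real_, n)
  kappa[i] <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  kmax <- suppressWarnings(max(kappa, na.rm = TRUE))
  if (!is.finite(kmax) || kmax < curvature_min) {
    warning("L-curve has no well-defined corner; falling back to the smallest lambda",
            call. = FALSE)
    idx <- 1L
  } else idx <- which.max(replace(kappa, is.na(kappa), -Inf))
  list(lambda = lam[idx], index = idx, curvature = kappa)
}

#' Prepare a reusable epicardial solver (factorization reuse)
#'
#' Centers the operator, computes its SVD once, and returns an object that
#' [solve_epicardial()] accepts in place of the transfer matrix, so many
#' recordings can be inverted against one factorization.
#'
#' @param A a `transfer_epicardial` or M x N matrix.
#' @param re_reference remove the electrode common mode from the operator
#'   columns (and, during solving, from the data): work in the
#'   reference-free quotient space.  Default `TRUE`.
#' @return object of class `ecgi_prep_epicardial`.
#' @export
prepare_epicardial <- function(A, re_reference = TRUE) {
  X <- if (inherits(A, "transfer_epicardial")) A$A else as.matrix(A)
  if (re_reference) X <- sweep(X, 2, colMeans(X))
  structure(list(X = X, dec = svd(X), re_reference = re_reference),
            class = "ecgi_prep_epicardial")
}

#' Prepare a reusable volumetric solver (factorization reuse)
#'
#' Applies the volume quadrature and electrode-mean centering, reduces the
#' problem onto the constraint null space, and computes the SVD once.
#'
#' @param B a `transfer_volumetric` or M x P matrix.
#' @param weights heart-node volume weights (taken from `B` when possible).
#' @param re_reference remove the electrode common mode (quotient space).
#' @return object of class `ecgi_prep_volumetric`.
#' @export
prepare_volumetric <- function(B, weights = NULL, re_reference = TRUE) {
  if (inherits(B, "transfer_volumetric")) {
    weights <- weights %||% B$weights
    B <- B$B
  }
  w <- as.numeric(weights)
  if (any(w <= 0)) stopf("volume weights must be strictly positive")
  X <- as.matrix(B) * rep(w, each = nrow(B))
  if (re_reference) X <- sweep(X, 2, colMeans(X))
  hh <- householder_nullspace(w)
  Xred <- t(hh$reduce(t(X)))
  structure(list(Xred = Xred, dec = svd(Xred), hh = hh, w = w,
                 re_reference = re_reference),
            class = "ecgi_prep_volumetric")
}

ecgi_fit_object <- function(method, solution, trace, lambda, engine_meta,
                            g, ghat, fs, extra = list()) {
  structure(c(list(method = method, coefficients = solution,
                   trace = trace, lambda = lambda,
                   residual_matrix = g - ghat, fitted_signals = ghat,
                   sample_rate = fs), engine_meta, extra),
            class = "ecgi_fit")
}

#' Reconstruct epicardial potentials by zero-order Tikhonov inversion
#'
#' Solves `min ||A h - g||^2 + lambda ||h||^2` per time sample, sharing one
#' SVD of the transfer matrix across samples.  With `lambda = "auto"` the
#' parameter is chosen once for the whole recording by the L-curve
#' criterion over a log-spaced grid.
#'
#' @param A a `transfer_epicardial` (from [assemble_bem_laplace()]), a
#'   plain M x N matrix, or a prepared solver from [prepare_epicardial()].
#' @param g a [bsp_signals()] object or M x T matrix of conditioned
#'   body-surface potentials.
#' @param lambda `"auto"` (L-curve) or a non-negative number.
#' @param lambda_grid optional explicit grid for the trace.
#' @param n_lambda grid size when the default grid is used.
#' @param re_reference solve in the reference-free quotient space (remove
#'   the electrode common mode from data and operator).
#' @return an object of class `ecgi_fit`; `coef()` returns the N x T matrix
#'   of epicardial potentials.
#' @seealso [solve_volumetric()], [lcurve_select()]
#' @export
solve_epicardial <- function(A, g, lambda = "auto", lambda_grid = NULL,
                             n_lambda = 60, re_reference = TRUE) {
  prep <- if (inherits(A, "ecgi_prep_epicardial")) A
          else prepare_epicardial(A, re_reference = re_reference)
  X <- prep$X
  fs <- if (inherits(g, "bsp_signals")) g$sample_rate else NA_real_
  gm <- if (inherits(g, "bsp_signals")) g$values else as.matrix(g)
  if (ncol(X) < 1 || nrow(gm) != nrow(X))
    stopf("signal/operator dimension mismatch (%d electrodes vs %d rows)",
          nrow(gm), nrow(X))
  # reference-free quotient space (electrode common mode removed; the
  # operator columns are centered in the preparation step)
  if (prep$re_reference) gm <- sweep(gm, 2, colMeans(gm))
  eng <- tikhonov_engine(X, gm, dec = prep$dec)
  fit_tikhonov("epicardial", eng, gm, lambda, lambda_grid, n_lambda, fs,
               predictor = function(h) X %*% h, extra = list())
}

#' Reconstruct volumetric cardiac sources by constrained Tikhonov inversion
#'
#' Solves `min ||B W f - g||^2 + lambda ||f||^2` subject to the source
#' existence condition `w' f = 0` at every sample, where `W = diag(w)` is
#' the lumped nodal-volume quadrature.  The equality constraint is imposed
#' exactly by reducing the problem onto the null space of `w'` with a
#' Householder basis, then solving unconstrained Tikhonov in the reduced
#' space (one SVD shared across samples and lambda values).
#'
#' @param B a `transfer_volumetric` (from [assemble_green_transfer()]), a
#'   plain M x P matrix of Green's function values, or a prepared solver
#'   from [prepare_volumetric()].
#' @param g a [bsp_signals()] object or M x T matrix.
#' @param weights heart-node volume weights; taken from `B` when it is a
#'   `transfer_volumetric`.
#' @param lambda `"auto"` or a non-negative number.
#' @param lambda_grid optional explicit grid.
#' @param n_lambda grid size for the default grid.
#' @param re_reference solve in the reference-free quotient space.
#' @return an `ecgi_fit`; `coef()` returns the P x T source field.  The
#'   per-sample constraint residual `|w' f_t|` is stored as
#'   `$constraint_residual`.
#' @export
solve_volumetric <- function(B, g, weights = NULL, lambda = "auto",
                             lambda_grid = NULL, n_lambda = 60,
                             re_reference = TRUE) {
  prep <- if (inherits(B, "ecgi_prep_volumetric")) B
          else prepare_volumetric(B, weights, re_reference = re_reference)
  fs <- if (inherits(g, "bsp_signals")) g$sample_rate else NA_real_
  gm <- if (inherits(g, "bsp_signals")) g$values else as.matrix(g)
  if (nrow(gm) != nrow(prep$Xred)) stopf("signal/operator dimension mismatch")
  # reference-free quotient space (data re-referenced; operator columns are
  # centered in the preparation step)
  if (prep$re_reference) gm <- sweep(gm, 2, colMeans(gm))
  eng <- tikhonov_engine(prep$Xred, gm, dec = prep$dec)
  fit_tikhonov("volumetric", eng, gm, lambda, lambda_grid, n_lambda, fs,
               predictor = function(fred) prep$Xred %*% fred,
               expand = prep$hh$expand,
               extra = list(weights = prep$w))
}

# shared tail of both solvers: trace, lambda choice, solution, fit object
fit_tikhonov <- function(method, eng, gm, lambda, lambda_grid, n_lambda, fs,
                         predictor, expand = NULL, extra = list()) {
  grid <- lambda_grid %||% default_lambda_grid(eng$s1, n_lambda)
  grid <- sort(grid)
  tr <- eng$trace_at(grid)
  trace <- data.frame(lambda = grid, residual = tr$residual, solution = tr$solution)
  if (identical(lambda, "auto")) {
    sel <- lcurve_select(trace)
    lambda_val <- sel$lambda
    trace$curvature <- sel$curvature
  } else {
    lambda_val <- as.numeric(lambda)
    if (!is.finite(lambda_val) || lambda_val < 0) stopf("lambda must be >= 0")
    sel <- list(index = NA_integer_)
    trace$curvature <- NA_real_
  }
  trace$selected <- seq_len(nrow(trace)) == (sel$index %||% NA_integer_)
  sol_red <- eng$solve_at(lambda_val)
  ghat <- predictor(sol_red)
  sol <- if (is.null(expand)) sol_red else expand(sol_red)
  extra2 <- extra
  if (!is.null(expand)) {
    w <- extra$weights
    extra2$constraint_residual <- abs(as.numeric(crossprod(w, sol)))
  }
  ecgi_fit_object(method, sol, trace, lambda_val,
                  list(singular_values = eng$svd$d), gm, ghat, fs, extra2)
}

# ---------------------------------------------------------------------------
# S3 methods for the fitted object
# ---------------------------------------------------------------------------

#' @export
print.ecgi_fit <- function(x, ...) {
  cat(sprintf("ECGI %s reconstruction\n", x$method))
  cat(sprintf("  nodes x samples : %d x %d\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  cat(sprintf("  lambda          : %.4g%s\n", x$lambda,
              if (any(x$trace$selected, na.rm = TRUE)) " (L-curve)" else ""))
  cat(sprintf("  rel. residual   : %.4g\n",
              norm(x$residual_matrix, "F") /
              norm(x$residual_matrix + x$fitted_signals, "F")))
  if (!is.null(x$constraint_residual))
    cat(sprintf("  max |w'f|       : %.3g\n", max(x$constraint_residual)))
  invisible(x)
}

#' @export
summary.ecgi_fit <- function(object, ...) {
  out <- list(method = object$method, lambda = object$lambda,
              dim = dim(object$coefficients),
              rel_residual = norm(object$residual_matrix, "F") /
                norm(object$fitted_signals + object$residual_matrix, "F"),
              lambda_grid_range = range(object$trace$lambda),
              constraint_residual = object$constraint_residual,
              singular_value_range = range(object$singular_values))
  class(out) <- "summary.ecgi_fit"
  out
}

#' @export
print.summary.ecgi_fit <- function(x, ...) {
  cat(sprintf("ECGI %s fit: %d nodes x %d samples\n", x$method, x$dim[1], x$dim[2]))
  cat(sprintf("  lambda %.4g on grid [%.3g, %.3g]\n", x$lambda,
              x$lambda_grid_range[1], x$lambda_grid_range[2]))
  cat(sprintf("  relative residual %.4g\n", x$rel_residual))
  cat(sprintf("  singular values [%.3g, %.3g]\n",
              x$singular_value_range[1], x$singular_value_range[2]))
  if (!is.null(x$constraint_residual))
    cat(sprintf("  constraint residual max %.3g\n", max(x$constraint_residual)))
  invisible(x)
}

#' @export
coef.ecgi_fit <- function(object, ...) object$coefficients

#' @export
fitted.ecgi_fit <- function(object, ...) object$fitted_signals

#' @export
residuals.ecgi_fit <- function(object, ...) object$residual_matrix

#' Predicted electrode signals of a fitted reconstruction
#' @param object an `ecgi_fit`.
#' @param ... unused.
#' @return M x T matrix of model-predicted body-surface potentials.
#' @export
predict.ecgi_fit <- function(object, ...) object$fitted_signals

#' L-curve plot of a fitted reconstruction
#' @param x an `ecgi_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ecgi_fit <- function(x, ...) {
  tr <- x$trace
  plot(tr$residual, tr$solution, log = "xy", type = "b", pch = 16, cex = 0.6,
       xlab = "residual norm ||X f - g||", ylab = "solution norm ||f||",
       main = sprintf("L-curve (%s)", x$method), ...)
  if (any(tr$selected, na.rm = TRUE)) {
    i <- which(tr$selected)
    points(tr$residual[i], tr$solution[i], col = 2, pch = 19)
    legend("topright", legend = sprintf("lambda = %.3g", x$lambda),
           col = 2, pch = 19, bty = "n")
  }
  invisible(x)
}
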
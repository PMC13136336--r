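#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median mad sd coef predict residuals fitted approx rnorm runif
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics plot points lines abline legend
NULL

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(x) sqrt(rowSums(x * x))

normalize_rows <- function(x) x / row_norms(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

as_matrix3 <- function(x, what = "coordinates") {
  x <- as.matrix(x)
  if (ncol(x) != 3 || !is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stopf("%s must be a finite numeric matrix with 3 columns", what)
  storage.mode(x) <- "double"
  unname(x)
}

# stable content hash for provenance sidecars (md5 of serialized object)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# derive a reproducible child seed from a base seed and stream indices,
# kept within the 32-bit integer range
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) h <- (h * 69069 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(h)
}
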
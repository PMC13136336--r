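# Local activation time mapping.  Reconstructed per-node time signals are
# smoothed, differentiated, and transformed into a sum of sinusoidal
# wavelets centered at negative-slope samples and weighted by slope
# amplitude; the activation time is the maximum of the transformed signal.
# All convolutions are circular, which makes the marker exactly equivariant
# under circular time shifts.

# centered circular convolution of each row of x with symmetric kernel h
# (odd length).  Direct summation over taps: every output value is the same
# floating-point expression under a circular shift of the input, so the
# activation marker is exactly shift-equivariant (an FFT route is not).
circ_conv_rows <- function(x, h) {
  Tn <- ncol(x)
  half <- (length(h) - 1) / 2
  y <- matrix(0, nrow(x), Tn)
  for (k in seq_along(h)) {
    off <- k - 1 - half
    cols <- ((seq_len(Tn) - 1 - off) %% Tn) + 1
    y <- y + h[k] * x[, cols, drop = FALSE]
  }
  y
}

# windowed-sinc low-pass FIR kernel (Hamming), unit DC gain
fir_lowpass <- function(fc, fs, taps = NULL) {
  taps <- taps %||% (2 * round(1.5 * fs / fc) + 1)
  half <- (taps - 1) / 2
  k <- seq(-half, half)
  h <- 2 * fc / fs * ifelse(k == 0, 1, sin(2 * pi * fc / fs * k) / (2 * pi * fc / fs * k))
  h <- h * (0.54 + 0.46 * cos(pi * k / half))
  h / sum(h)
}

#' Local activation times from reconstructed per-node signals
#'
#' For every node the signal is low-pass smoothed, oriented so that the
#' activation deflection has negative slope (cardiac source and
#' transmembrane-voltage traces are negated; extracellular potentials pass
#' unchanged), and transformed into a sum of single-lobe sinusoidal
#' wavelets centered at negative-slope samples with weights proportional to
#' the slope amplitude.  The activation time is the argmax of the
#' transformed amplitude.  Nodes with flat signals are masked invalid
#' rather than raising an error.
#'
#' @param x nodes x samples matrix of reconstructed signals, or an
#'   `ecgi_fit` (its coefficient matrix and polarity are used).
#' @param fs sampling rate in Hz (taken from the fit when `x` is one).
#' @param polarity `"source"`, `"vm"` or `"potential"`; governs the sign
#'   convention of the activation deflection.
#' @param smooth_cutoff low-pass cutoff (Hz) of the pre-smoothing; `NULL`
#'   disables smoothing.
#' @param wavelet_halfwidth_ms half-width of the sinusoidal wavelet; by
#'   default twice the median upstroke width estimated from the data,
#'   clamped to [2, 30] ms.
#' @param domain label recorded in the result (`"heart volume"` or
#'   `"epicardial surface"`).
#' @return object of class `lat_map`: list with `times` (ms, per node),
#'   `valid` mask, `fs`, `domain`, `wavelet_halfwidth_ms`.
#' @export
compute_lat <- function(x, fs = NULL,
                        polarity = c("source", "potential", "vm"),
                        smooth_cutoff = 40, wavelet_halfwidth_ms = NULL,
                        domain = NULL) {
  if (inherits(x, "ecgi_fit")) {
    # reconstructed traces follow the unipolar-electrogram convention
    # (steepest negative deflection at activation) for both methods: the
    # regularized volumetric solution is a smoothed back-projection of the
    # surface potentials and inherits their deflection sign, unlike the
    # noiseless bidomain-surrogate source whose activation deflection is
    # positive-going
    if (missing(polarity)) polarity <- "potential"
    fs <- fs %||% x$sample_rate
    domain <- domain %||% switch(x$method, volumetric = "heart volume",
                                 epicardial = "epicardial surface", "unknown")
    x <- x$coefficients
  }
  polarity <- match.arg(polarity)
  if (is.null(fs) || fs <= 0) stopf("fs must be a positive sampling rate")
  x <- as.matrix(x)
  Tn <- ncol(x)
  if (Tn < 16) stopf("need at least 16 samples per node")
  if (!is.null(smooth_cutoff)) {
    if (smooth_cutoff >= fs / 2) stopf("smoothing cutoff must be below Nyquist")
    h <- fir_lowpass(smooth_cutoff, fs, taps = min(2 * floor((Tn - 1) / 2) + 1,
                                                   2 * round(1.5 * fs / smooth_cutoff) + 1))
    x <- circ_conv_rows(x, h)
  }
  d <- x[, c(2:Tn, 1), drop = FALSE] - x            # circular forward slope
  if (polarity %in% c("source", "vm")) d <- -d
  amp <- apply(abs(d), 1, max)
  valid <- amp > 1e-12 * max(amp, .Machine$double.eps)
  wgt <- pmax(-d, 0)                                # negative-slope weighting
  if (is.null(wavelet_halfwidth_ms)) {
    widths <- rowSums(abs(d) > 0.5 * amp)
    wms <- 2 * median(widths[valid]) * 1000 / fs
    wavelet_halfwidth_ms <- min(max(wms, 2), 30)
  }
  hw <- max(1L, round(wavelet_halfwidth_ms * fs / 1000))
  k <- seq(-hw, hw)
  wavelet <- cos(pi * k / (2 * hw))
  y <- circ_conv_rows(wgt, wavelet)
  # quantize to 2^-40 relative resolution before the argmax so that exact
  # ties (symmetric deflections) break identically under amplitude scaling
  ymax <- apply(y, 1, max)
  yq <- floor(y / pmax(ymax, .Machine$double.xmin) * 2^40 + 0.5)
  idx <- max.col(yq, ties.method = "first")
  valid <- valid & y[cbind(seq_len(nrow(y)), idx)] > 0
  times <- (idx - 0.5) * 1000 / fs                  # slope sample midpoint
  times[!valid] <- NA_real_
  structure(list(times = times, valid = valid, fs = fs,
                 domain = domain %||% "unknown",
                 wavelet_halfwidth_ms = wavelet_halfwidth_ms),
            class = "lat_map")
}

#' @export
print.lat_map <- function(x, ...) {
  cat(sprintf("lat_map (%s): %d nodes (%d valid), LAT range [%.1f, %.1f] ms\n",
              x$domain, length(x$times), sum(x$valid),
              min(x$times, na.rm = TRUE), max(x$times, na.rm = TRUE)))
  invisible(x)
}

#' Earliest-activation site (percentile-centroid rule)
#'
#' The site of earliest activation is the centroid of the coordinates of
#' the nodes whose activation time lies strictly below the given percentile
#' of valid activation times (linear-interpolation percentile).  When no
#' node lies strictly below the threshold (all activation times equal), the
#' rule falls back to the nodes attaining the minimum.
#'
#' @param lat a [compute_lat()] result or numeric vector of times (ms).
#' @param coords node coordinate matrix (rows match `lat`).
#' @param percentile percentile in (0, 100); default 10.
#' @return object of class `earliest_site`: list with `centroid` (mm),
#'   `nodes` (contributing node indices), `threshold_ms`, `percentile`.
#' @export
earliest_site <- function(lat, coords, percentile = 10) {
  times <- if (inherits(lat, "lat_map")) lat$times else as.numeric(lat)
  coords <- as_matrix3(coords, "node coordinates")
  if (length(times) != nrow(coords)) stopf("lat/coords length mismatch")
  ok <- which(is.finite(times))
  if (length(ok) < 10) stopf("need at least 10 valid nodes")
  thr <- as.numeric(quantile(times[ok], percentile / 100, type = 7))
  nodes <- ok[times[ok] < thr]
  if (length(nodes) == 0) nodes <- ok[times[ok] == min(times[ok])]
  structure(list(centroid = colMeans(coords[nodes, , drop = FALSE]),
                 nodes = nodes, threshold_ms = thr, percentile = percentile),
            class = "earliest_site")
}

#' @export
print.earliest_site <- function(x, ...) {
  cat(sprintf("earliest_site: centroid (%.2f, %.2f, %.2f) mm from %d nodes (< p%g)\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              length(x$nodes), x$percentile))
  invisible(x)
}

#' Total activation time over a node subset
#'
#' Range (max minus min) of valid activation times over the subset.
#'
#' @param lat a [compute_lat()] result or numeric vector (ms).
#' @param node_subset integer indices; default all nodes.
#' @return total activation time in ms.
#' @export
total_activation_time <- function(lat, node_subset = NULL) {
  times <- if (inherits(lat, "lat_map")) lat$times else as.numeric(lat)
  if (!is.null(node_subset)) times <- times[node_subset]
  times <- times[is.finite(times)]
  if (length(times) == 0) stopf("empty or all-invalid node subset")
  max(times) - min(times)
}
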
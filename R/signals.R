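#' Body-surface potential signals
#'
#' Container for multi-electrode torso recordings: a dense electrodes x
#' samples matrix (mV), the sampling rate, and a logical mask of excluded
#' channels (bad contact / excessive noise).
#'
#' @param values M x T numeric matrix.
#' @param sample_rate sampling rate in Hz.
#' @param mask logical vector of length M, `TRUE` = excluded channel.
#' @param electrode_ids optional channel identifiers.
#' @return object of class `bsp_signals`.
#' @export
bsp_signals <- function(values, sample_rate, mask = NULL, electrode_ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stopf("signals need at least 2 samples")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  mask <- mask %||% rep(FALSE, nrow(values))
  if (anyNA(values[!mask, , drop = FALSE]))
    stopf("NaN/NA in unmasked channels")
  structure(list(values = unname(values), sample_rate = sample_rate,
                 mask = mask,
                 electrode_ids = electrode_ids %||% as.character(seq_len(nrow(values)))),
            class = "bsp_signals")
}

#' @export
print.bsp_signals <- function(x, ...) {
  cat(sprintf("bsp_signals: %d channels (%d masked) x %d samples @ %g Hz\n",
              nrow(x$values), sum(x$mask), ncol(x$values), x$sample_rate))
  invisible(x)
}

#' @export
as.matrix.bsp_signals <- function(x, ...) x$values

# ---------------------------------------------------------------------------
# filter design: Butterworth as cascaded biquads (numerically robust at
# high order / low normalized cutoff), RBJ notch biquads for the comb
# ---------------------------------------------------------------------------

# n-th order Butterworth as second-order sections via per-section bilinear
# transform; returns list of list(b, a)
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stopf("cutoff %g Hz not below Nyquist (%g Hz)", fc, fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs)           # prewarped analog cutoff
  k <- seq_len(floor(n / 2))
  theta <- pi * (2 * k + n - 1) / (2 * n)
  poles <- complex(modulus = 1, argument = theta)   # upper-half prototype poles
  secs <- list()
  bilinear2 <- function(b2, b1, b0, a2, a1, a0) {
    K <- 2 * fs
    bz <- b2 * K^2 * c(1, -2, 1) + b1 * K * c(1, 0, -1) + b0 * c(1, 2, 1)
    az <- a2 * K^2 * c(1, -2, 1) + a1 * K * c(1, 0, -1) + a0 * c(1, 2, 1)
    list(b = bz / az[1], a = az / az[1])
  }
  for (p in poles) {
    if (type == "low") {
      ps <- wc * p
      secs[[length(secs) + 1]] <-
        bilinear2(0, 0, Mod(ps)^2, 1, -2 * Re(ps), Mod(ps)^2)
    } else {
      ps <- wc / p
      secs[[length(secs) + 1]] <-
        bilinear2(1, 0, 0, 1, -2 * Re(ps), Mod(ps)^2)
    }
  }
  if (n %% 2 == 1) {
    if (type == "low") secs[[length(secs) + 1]] <- bilinear2(0, 0, wc, 0, 1, wc)
    else secs[[length(secs) + 1]] <- bilinear2(0, 1, 0, 0, 1, wc)
  }
  secs
}

# RBJ notch biquad
notch_biquad <- function(f0, fs, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# zero-phase application of a biquad cascade to a channels x samples matrix
apply_sos_zerophase <- function(x, secs, skip = NULL) {
  for (ch in seq_len(nrow(x))) {
    if (!is.null(skip) && skip[ch]) next
    y <- x[ch, ]
    for (s in secs) y <- signal::filtfilt(s$b, s$a, y)
    x[ch, ] <- y
  }
  x
}

#' Condition body-surface signals (clinical / simulated chains)
#'
#' Clinical mode: a comb of zero-phase IIR notches at the 50 Hz powerline
#' frequency and its first three harmonics (100/150/200 Hz), then a
#' 10th-order Butterworth low-pass at 40 Hz, then a high-pass at 0.67 Hz
#' (order 3) to remove baseline wander.  Simulated mode: a 10th-order
#' Butterworth low-pass at 50 Hz only.  All filters are applied
#' forward-backward (zero phase), since activation-time markers are
#' phase-sensitive; the effective attenuation in dB is therefore doubled.
#' Masked channels pass through untouched.
#'
#' @param g a [bsp_signals()] object.
#' @param mode `"clinical"` or `"simulated"`.
#' @param powerline powerline frequency (Hz).
#' @param notch_q quality factor of each notch.
#' @return a conditioned `bsp_signals` object.
#' @export
condition_signals <- function(g, mode = c("clinical", "simulated"),
                              powerline = 50, notch_q = 35) {
  mode <- match.arg(mode)
  fs <- g$sample_rate
  x <- g$values
  if (mode == "clinical") {
    if (fs <= 2 * 200) stopf("sample rate %g Hz too low for the clinical chain", fs)
    secs <- c(lapply(powerline * 1:4, notch_biquad, fs = fs, Q = notch_q),
              butter_sos(10, 40, fs, "low"),
              butter_sos(3, 0.67, fs, "high"))
  } else {
    if (fs <= 2 * 50) stopf("sample rate %g Hz too low for the 50 Hz low-pass", fs)
    secs <- butter_sos(10, 50, fs, "low")
  }
  x <- apply_sos_zerophase(x, secs, skip = g$mask)
  bsp_signals(x, fs, mask = g$mask, electrode_ids = g$electrode_ids)
}

#' Flag bad channels by robust outlier rules
#'
#' Channels are flagged when flat (zero variance) or when the RMS amplitude
#' is a robust outlier (modified z-score against the median/MAD of channel
#' RMS).  The rule refuses to flag more than half of the channels unless
#' `override = TRUE`; if every channel would be flagged this is an error.
#'
#' @param g a [bsp_signals()] object.
#' @param z_threshold modified z-score threshold (default 5).
#' @param flat_tol absolute standard deviation below which a channel counts
#'   as flatline.
#' @param override allow flagging more than 50\% of channels.
#' @return logical mask vector (`TRUE` = flagged).
#' @export
channel_qc <- function(g, z_threshold = 5, flat_tol = 1e-12, override = FALSE) {
  x <- g$values
  if (nrow(x) < 2) stopf("need at least 2 channels")
  sds <- apply(x, 1, sd)
  flat <- sds <= flat_tol
  rms <- sqrt(rowMeans(x^2))
  z <- rep(0, length(rms))
  if (any(!flat)) {
    med <- median(rms[!flat]); madv <- mad(rms[!flat])
    if (is.finite(madv) && madv > 0) z <- abs(rms - med) / madv
  }
  flag <- flat | z > z_threshold
  if (all(flag)) stopf("all channels flagged by QC; inspect the recording")
  if (mean(flag) > 0.5 && !override)
    stopf("QC would flag %d/%d channels; pass override = TRUE to allow",
          sum(flag), length(flag))
  flag
}

#' Add white Gaussian noise at a prescribed signal-to-noise ratio
#'
#' The SNR is defined globally (signal power over all electrodes and
#' samples); drawn noise is rescaled so the realized global SNR equals
#' `snr_db` exactly.  Reproducible given `seed`.
#'
#' @param g a [bsp_signals()] object with nonzero power.
#' @param snr_db target SNR in dB (finite).
#' @param seed integer seed.
#' @param per_lead if `TRUE`, scale noise per channel instead of globally.
#' @return a noisy `bsp_signals` object.
#' @export
add_noise <- function(g, snr_db = 20, seed = 1, per_lead = FALSE) {
  if (!is.finite(snr_db)) stopf("snr_db must be finite")
  x <- g$values
  psig <- mean(x^2)
  if (psig <= 0) stopf("zero-power signals: SNR undefined")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  e <- matrix(rnorm(length(x)), nrow(x), ncol(x))
  scale_to <- function(sig_p, noise) noise * sqrt(sig_p / 10^(snr_db / 10) / mean(noise^2))
  if (per_lead) {
    for (ch in seq_len(nrow(x))) e[ch, ] <- scale_to(mean(x[ch, ]^2), e[ch, ])
  } else {
    e <- scale_to(psig, e)
  }
  bsp_signals(x + e, g$sample_rate, mask = g$mask, electrode_ids = g$electrode_ids)
}

#' Realized global signal-to-noise ratio
#' @param clean,noisy `bsp_signals` with identical layout.
#' @return SNR in dB.
#' @export
measured_snr_db <- function(clean, noisy) {
  10 * log10(mean(clean$values^2) / mean((noisy$values - clean$values)^2))
}

#' Read signals from CSV (channels x samples, one row per electrode)
#' @param path CSV path; first column must be the electrode id.
#' @param sample_rate sampling rate in Hz.
#' @return a [bsp_signals()] object.
#' @export
read_signals_csv <- function(path, sample_rate) {
  d <- read.csv(path, check.names = FALSE)
  bsp_signals(as.matrix(d[, -1, drop = FALSE]), sample_rate,
              electrode_ids = as.character(d[[1]]))
}

#' Write signals to CSV
#' @param g a [bsp_signals()] object.
#' @param path output path.
#' @export
write_signals_csv <- function(g, path) {
  write.csv(data.frame(id = g$electrode_ids, g$values, check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}
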
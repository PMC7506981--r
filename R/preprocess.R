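#' Preprocessing configuration
#'
#' Bundles the conditioning chain that turns raw sEMG into the RMS-envelope
#' signals the augmentation methods operate on: optional notch + band-pass
#' (for noisy high-rate recordings), sliding RMS, a low-order Butterworth
#' low-pass smoothing of the envelope, and decimation to a common rate.
#'
#' Two presets cover the usual acquisition styles:
#' * `preprocess_config()` — envelope-style chain: 100 ms RMS, 1st-order
#'   1 Hz low-pass, resample to 100 Hz (Ninapro-like recordings).
#' * `preprocess_config(notch_hz = 50, bandpass = c(20, 700, 5))` — adds
#'   50 Hz notch and a 5th-order 20–700 Hz band-pass before the RMS
#'   (putEMG-like recordings).
#'
#' @param rms_window_ms RMS window duration in milliseconds (default 100).
#' @param lowpass_fc_hz envelope low-pass corner in Hz (default 1).
#' @param lowpass_order envelope low-pass order (default 1).
#' @param notch_hz optional power-line notch frequency in Hz (default `NULL`).
#' @param bandpass optional `c(low_hz, high_hz, order)` band-pass applied
#'   before the RMS (default `NULL`).
#' @param target_fs_hz final sampling rate in Hz (default 100).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(rms_window_ms = 100, lowpass_fc_hz = 1,
                              lowpass_order = 1, notch_hz = NULL,
                              bandpass = NULL, target_fs_hz = 100) {
  assert_scalar_number(rms_window_ms, "rms_window_ms", lower = 0, strict = TRUE)
  assert_scalar_number(lowpass_fc_hz, "lowpass_fc_hz", lower = 0, strict = TRUE)
  assert_scalar_number(lowpass_order, "lowpass_order", lower = 1)
  if (!is.null(bandpass) && length(bandpass) != 3L)
    stop_config("bandpass must be c(low_hz, high_hz, order)")
  assert_scalar_number(target_fs_hz, "target_fs_hz", lower = 0, strict = TRUE)
  structure(list(rms_window_ms = rms_window_ms, lowpass_fc_hz = lowpass_fc_hz,
                 lowpass_order = as.integer(lowpass_order), notch_hz = notch_hz,
                 bandpass = bandpass, target_fs_hz = target_fs_hz),
            class = "preprocess_config")
}

# scipy-style zero-phase filtering: odd extension at both ends plus
# steady-state initial conditions, then forward and backward passes.
# Plain signal::filtfilt pads with zeros, which leaves large edge
# transients for narrow filters; this variant is exact for DC input.
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  ord <- max(length(b), length(a)) - 1L
  padlen <- min(max(3L * ord * 10L, 30L), n - 1L)
  if (padlen < 1L) stop_numeric("signal too short for zero-phase filtering")
  ext <- c(2 * x[1] - rev(x[2:(padlen + 1)]),
           x,
           2 * x[n] - rev(x[(n - padlen):(n - 1)]))
  dc <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1L),
                              init.y = rep(z[1] * dc, length(a) - 1L)))
  }
  y <- pass(ext)
  y <- rev(pass(rev(y)))
  y[(padlen + 1):(padlen + n)]
}

apply_per_channel <- function(x, fun) {
  out <- x$samples
  for (ch in seq_len(ncol(out))) out[, ch] <- fun(x$samples[, ch])
  signal_like(x, out)
}

# centered sliding window bounds for window of w samples at each index
window_bounds <- function(n, w) {
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  idx <- seq_len(n)
  list(lo = pmax(1L, idx - hl), hi = pmin(n, idx + hr))
}

#' Sliding RMS envelope
#'
#' Per-channel root-mean-square over a centered window of
#' `round(window_ms * fs / 1000)` samples. Output has the same length as the
#' input; at the edges the window is truncated to the available samples.
#'
#' @param x an [emg_signal()].
#' @param window_ms window duration in milliseconds.
#' @return An [emg_signal()] of the same shape, non-negative.
#' @examples
#' x <- emg_signal(sin(2 * pi * 5 * (0:999) / 1000), fs = 1000)
#' e <- rms_envelope(x, 200)   # interior ~ 1/sqrt(2)
#' @export
rms_envelope <- function(x, window_ms) {
  w <- as.integer(round(window_ms * x$fs / 1000))
  if (w < 1L) stop_config("RMS window shorter than one sample at fs = ", x$fs, " Hz")
  if (w > n_samples(x)) stop_config("RMS window (", w, " samples) longer than signal (",
                                    n_samples(x), " samples)")
  b <- window_bounds(n_samples(x), w)
  apply_per_channel(x, function(col) {
    cs <- c(0, cumsum(col^2))
    sqrt(pmax(0, (cs[b$hi + 1L] - cs[b$lo]) / (b$hi - b$lo + 1L)))
  })
}

#' Centered moving-average envelope
#'
#' Per-channel moving average over a centered window (truncated at the
#' edges), as used for the amplitude-modulation envelope of the sEMG
#' simulators. Unlike [rms_envelope()] this is a plain mean, not an RMS.
#'
#' @inheritParams rms_envelope
#' @return An [emg_signal()] of the same shape.
#' @export
envelope_ma <- function(x, window_ms) {
  w <- as.integer(round(window_ms * x$fs / 1000))
  if (w < 1L) stop_config("moving-average window shorter than one sample at fs = ",
                          x$fs, " Hz")
  b <- window_bounds(n_samples(x), w)
  apply_per_channel(x, function(col) {
    cs <- c(0, cumsum(col))
    (cs[b$hi + 1L] - cs[b$lo]) / (b$hi - b$lo + 1L)
  })
}

#' Zero-phase Butterworth / notch filtering
#'
#' Applies a Butterworth low-pass or band-pass, or a second-order IIR notch,
#' forward and backward (zero phase) per channel. Zero-phase filtering is
#' used throughout because augmentation targets envelope shape, not causal
#' streaming; the effective magnitude response is the squared single-pass
#' response.
#'
#' @param x an [emg_signal()].
#' @param kind `"lowpass"`, `"bandpass"`, or `"notch"`.
#' @param fc_hz low-pass corner frequency in Hz (`kind = "lowpass"`).
#' @param band_hz `c(low, high)` corner frequencies in Hz (`kind = "bandpass"`).
#' @param order filter order (low-/band-pass; default 1).
#' @param notch_hz notch center frequency in Hz (`kind = "notch"`).
#' @param q notch quality factor (default 30).
#' @return An [emg_signal()] of the same shape.
#' @export
butterworth_filter <- function(x, kind = c("lowpass", "bandpass", "notch"),
                               fc_hz = NULL, band_hz = NULL, order = 1,
                               notch_hz = NULL, q = 30) {
  kind <- match.arg(kind)
  nyq <- x$fs / 2
  coefs <- switch(kind,
    lowpass = {
      assert_scalar_number(fc_hz, "fc_hz", lower = 0, strict = TRUE)
      if (fc_hz >= nyq) stop_config("low-pass corner ", fc_hz,
                                    " Hz is at or above Nyquist (", nyq, " Hz)")
      bt <- signal::butter(order, fc_hz / nyq, type = "low")
      list(b = bt$b, a = bt$a)
    },
    bandpass = {
      if (length(band_hz) != 2L) stop_config("band_hz must be c(low, high)")
      if (band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
        stop_config("band-pass corners must satisfy 0 < low < high")
      if (band_hz[2] >= nyq) stop_config("band-pass upper corner ", band_hz[2],
                                         " Hz is at or above Nyquist (", nyq, " Hz)")
      bt <- signal::butter(order, band_hz / nyq, type = "pass")
      list(b = bt$b, a = bt$a)
    },
    notch = {
      assert_scalar_number(notch_hz, "notch_hz", lower = 0, strict = TRUE)
      if (notch_hz >= nyq) stop_config("notch frequency ", notch_hz,
                                       " Hz is at or above Nyquist (", nyq, " Hz)")
      w0 <- 2 * pi * notch_hz / x$fs
      al <- sin(w0) / (2 * q)
      list(b = c(1, -2 * cos(w0), 1) / (1 + al),
           a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
    })
  apply_per_channel(x, function(col) filtfilt_ss(coefs$b, coefs$a, col))
}

#' Resample a signal to a lower rate
#'
#' Integer decimation applies an 8th-order Butterworth anti-aliasing
#' low-pass (zero phase, corner at 80% of the target Nyquist) before taking
#' every q-th sample; non-integer ratios use polyphase resampling. The
#' output length is `floor(n_samples * target_fs / fs)`. Upsampling is out
#' of scope and raises an error.
#'
#' @param x an [emg_signal()].
#' @param target_fs_hz target sampling rate, `<= fs`.
#' @return An [emg_signal()] at `target_fs_hz`.
#' @export
resample_to <- function(x, target_fs_hz) {
  assert_scalar_number(target_fs_hz, "target_fs_hz", lower = 0, strict = TRUE)
  fs <- x$fs
  if (target_fs_hz > fs)
    stop_config("target rate ", target_fs_hz, " Hz exceeds signal rate ", fs,
                " Hz (upsampling not supported)")
  if (target_fs_hz == fs) return(x)
  n_out <- floor(n_samples(x) * target_fs_hz / fs)
  if (n_out < 1L) stop_config("signal too short to resample to ", target_fs_hz, " Hz")
  ratio <- fs / target_fs_hz
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    aa <- signal::butter(8, 0.8 / q, type = "low")
    out <- apply_per_channel(x, function(col) filtfilt_ss(aa$b, aa$a, col))
    keep <- seq.int(1L, by = q, length.out = n_out)
    emg_signal(out$samples[keep, , drop = FALSE], target_fs_hz)
  } else {
    frac <- .rat_approx(target_fs_hz / fs)
    res <- x$samples
    cols <- lapply(seq_len(ncol(res)), function(ch)
      as.numeric(signal::resample(res[, ch], frac[1], frac[2])))
    m <- do.call(cbind, lapply(cols, function(col) col[seq_len(min(n_out, length(col)))]))
    emg_signal(m, target_fs_hz)
  }
}

# small continued-fraction rational approximation p/q of a ratio in (0,1)
.rat_approx <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err) { err <- e; best <- c(as.integer(p), q) }
    if (e < 1e-12) break
  }
  best
}

#' Full preprocessing chain
#'
#' Runs the configured conditioning steps in order: notch, band-pass,
#' sliding RMS, envelope low-pass, resampling. Steps configured as `NULL`
#' are skipped. Applied to every record of a dataset; metadata is preserved.
#'
#' @param ds an [emg_dataset()] (or a single [emg_signal()]).
#' @param config a [preprocess_config()].
#' @return The preprocessed dataset (or signal).
#' @export
preprocess_dataset <- function(ds, config = preprocess_config()) {
  if (inherits(ds, "emg_signal")) return(.preprocess_signal(ds, config))
  recs <- lapply(ds$records, function(r) {
    r$signal <- .preprocess_signal(r$signal, config)
    r
  })
  emg_dataset(recs)
}

.preprocess_signal <- function(x, config) {
  if (!is.null(config$notch_hz))
    x <- butterworth_filter(x, "notch", notch_hz = config$notch_hz)
  if (!is.null(config$bandpass))
    x <- butterworth_filter(x, "bandpass", band_hz = config$bandpass[1:2],
                            order = config$bandpass[3])
  x <- rms_envelope(x, config$rms_window_ms)
  x <- butterworth_filter(x, "lowpass", fc_hz = config$lowpass_fc_hz,
                          order = config$lowpass_order)
  if (config$target_fs_hz < x$fs) x <- resample_to(x, config$target_fs_hz)
  x
}
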
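#' Augmentation method specifications
#'
#' Each constructor returns a tagged parameter record for one augmentation
#' method, applied to a signal with [apply_augmentation()] or composed with
#' [augmentor_policy()]. Defaults are the grid-selected values for
#' envelope-style recordings: `snr = 30` for Gaussian noise, `sigma = 0.1`
#' for magnitude warping, and `sym4`, level 5, `b = 3` for the wavelet
#' perturbation.
#'
#' @param snr target signal-to-noise ratio. Interpreted as a linear power
#'   ratio (noise variance = signal power / snr); set `snr_db = TRUE` to
#'   interpret the value in decibels instead.
#' @param snr_db logical; treat `snr` as dB (default `FALSE`).
#' @param pooled logical; if `TRUE` a single noise power is computed from
#'   all channels pooled, otherwise per channel (default). Channels differ
#'   in activation by an order of magnitude, so pooled power would drown
#'   quiet channels.
#' @param sigma standard deviation of the warp-knot values around 1.
#' @param knots number `T >= 2` of equidistant spline knots (default 4).
#' @param per_channel logical; if `TRUE` an independent warp curve is drawn
#'   per channel; default `FALSE` (one curve shared by all channels, which
#'   preserves the gesture's inter-channel amplitude signature).
#' @param wavelet wavelet name, one of [supported_wavelets()].
#' @param level decomposition level, `>= 1`.
#' @param b detail-coefficient scaling factor, `>= 0`.
#' @return An object of class `c("<method>_spec", "aug_spec")`.
#' @name augmentation_specs
NULL

#' @rdname augmentation_specs
#' @export
gn_spec <- function(snr = 30, snr_db = FALSE, pooled = FALSE) {
  assert_scalar_number(snr, "snr", lower = 0, strict = TRUE)
  structure(list(method = "gn", snr = snr, snr_db = isTRUE(snr_db),
                 pooled = isTRUE(pooled)),
            class = c("gn_spec", "aug_spec"))
}

#' @rdname augmentation_specs
#' @export
mw_spec <- function(sigma = 0.1, knots = 4, per_channel = FALSE) {
  assert_scalar_number(sigma, "sigma", lower = 0)
  knots <- as.integer(knots)
  if (is.na(knots) || knots < 2L)
    stop_config("magnitude warping needs at least 2 spline knots")
  structure(list(method = "mw", sigma = sigma, knots = knots,
                 per_channel = isTRUE(per_channel)),
            class = c("mw_spec", "aug_spec"))
}

#' @rdname augmentation_specs
#' @export
wd_spec <- function(wavelet = "sym4", level = 5, b = 3) {
  wavelet_filters(wavelet)  # validates the name
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop_config("level must be an integer >= 1")
  assert_scalar_number(b, "b", lower = 0)
  structure(list(method = "wd", wavelet = wavelet, level = level, b = b),
            class = c("wd_spec", "aug_spec"))
}

#' @export
print.aug_spec <- function(x, ...) {
  ps <- x[setdiff(names(x), "method")]
  cat(sprintf("<aug_spec:%s> %s\n", x$method,
              paste(names(ps), unlist(lapply(ps, format)), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Additive Gaussian noise at a target SNR
#'
#' Adds zero-mean white Gaussian noise whose variance is the mean signal
#' power divided by the target SNR, independently per channel (or pooled
#' over channels with `pooled = TRUE` in the spec). A zero channel receives
#' zero noise, since its power is zero.
#'
#' @param x an [emg_signal()].
#' @param spec a [gn_spec()].
#' @param seed RNG seed; the operation is deterministic given the seed.
#' @return An [emg_signal()] of the same shape.
#' @export
gaussian_noise <- function(x, spec = gn_spec(), seed = 1L) {
  snr <- if (spec$snr_db) 10^(spec$snr / 10) else spec$snr
  m <- x$samples
  pw <- colMeans(m^2)
  if (spec$pooled) pw[] <- mean(m^2)
  sd_ch <- sqrt(pw / snr)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(m)), nrow = nrow(m))
    noise <- sweep(noise, 2L, sd_ch, `*`)
    signal_like(x, m + noise)
  })
}

# natural cubic spline through T equidistant knots spanning [0, n-1],
# evaluated at every sample index
.warp_curve <- function(n, knots, sigma) {
  tk <- seq(0, n - 1, length.out = knots)
  rk <- stats::rnorm(knots, mean = 1, sd = sigma)
  if (sigma == 0) return(rep(1, n))
  f <- stats::splinefun(tk, rk, method = "natural")
  f(0:(n - 1))
}

#' Magnitude warping with a random cubic-spline curve
#'
#' Multiplies the signal elementwise with a smooth random curve: `T`
#' equidistant knots spanning the record, knot values drawn from
#' `N(1, sigma^2)`, joined by a natural cubic spline. By default one curve
#' is shared by all channels.
#'
#' @param x an [emg_signal()].
#' @param spec an [mw_spec()].
#' @param seed RNG seed.
#' @return An [emg_signal()] of the same shape.
#' @export
magnitude_warp <- function(x, spec = mw_spec(), seed = 1L) {
  n <- n_samples(x)
  if (spec$knots > n)
    stop_config("cannot place ", spec$knots, " warp knots on a ", n, "-sample record")
  with_seed(seed, {
    m <- x$samples
    if (spec$per_channel) {
      for (ch in seq_len(ncol(m)))
        m[, ch] <- m[, ch] * .warp_curve(n, spec$knots, spec$sigma)
    } else {
      m <- m * .warp_curve(n, spec$knots, spec$sigma)
    }
    signal_like(x, m)
  })
}

#' Wavelet-decomposition perturbation
#'
#' Per channel: multi-level periodized DWT, every detail band at every
#' level scaled by the factor `b`, approximation band untouched, inverse
#' transform. `b = 1` is the identity (to machine precision); `b = 0`
#' reconstructs from the approximation band alone, i.e. a wavelet-domain
#' low-pass; `b > 1` exaggerates fine structure.
#'
#' Deterministic: the randomness of this method in a composition policy
#' lies in *which* spec is used, not in the transform itself.
#'
#' @param x an [emg_signal()].
#' @param spec a [wd_spec()].
#' @param seed ignored (kept for the common augmentation signature).
#' @return An [emg_signal()] of the same shape.
#' @export
wavelet_perturb <- function(x, spec = wd_spec(), seed = 1L) {
  n <- n_samples(x)
  lmax <- max_dwt_level(n, spec$wavelet)
  if (spec$level > lmax)
    stop_config("level ", spec$level, " too deep for ", n, " samples with ",
                spec$wavelet, " (max ", lmax, ")")
  apply_per_channel(x, function(col) {
    dec <- wave_dec(col, spec$wavelet, spec$level)
    dec$cd <- lapply(dec$cd, function(cd) spec$b * cd)
    wave_rec(dec)
  })
}

#' Apply an augmentation spec to a signal
#'
#' Generic dispatcher used by the composition policies; each method's
#' underlying function can also be called directly.
#'
#' @param x an [emg_signal()].
#' @param spec an augmentation spec (see [augmentation_specs]).
#' @param seed RNG seed for the stochastic methods.
#' @return An [emg_signal()] of the same shape.
#' @export
apply_augmentation <- function(x, spec, seed = 1L) {
  UseMethod("apply_augmentation", spec)
}

#' @export
apply_augmentation.gn_spec <- function(x, spec, seed = 1L) gaussian_noise(x, spec, seed)

#' @export
apply_augmentation.mw_spec <- function(x, spec, seed = 1L) magnitude_warp(x, spec, seed)

#' @export
apply_augmentation.wd_spec <- function(x, spec, seed = 1L) wavelet_perturb(x, spec, seed)

#' @export
apply_augmentation.default <- function(x, spec, seed = 1L) {
  stop_config("not an augmentation spec: ", paste(class(spec), collapse = "/"))
}
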
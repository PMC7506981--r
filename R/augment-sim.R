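#' Shaping-filter specification for the sEMG simulators
#'
#' The simulators colour white noise with a linear-phase FIR filter whose
#' squared magnitude follows the two-corner sEMG power spectral density
#'
#' \deqn{PSD_g(f) = \frac{f_h^2 f^2}{(f^2 + f_l^2)(f^2 + f_h^2)^2}}
#'
#' which vanishes at DC, peaks between the corners and rolls off above
#' `fh`. The corners are free parameters of the model: the shipped default
#' `fl = 2`, `fh = 20` Hz places the peak inside the band of 100 Hz
#' RMS-envelope signals; for raw sEMG at 2 kHz the conventional simulation
#' corners are `fl = 60`, `fh = 120` Hz.
#'
#' @param fl lower corner frequency in Hz, `0 < fl < fh`.
#' @param fh upper corner frequency in Hz, `fh < fs/2`.
#' @param fs sampling rate in Hz.
#' @param n_taps FIR length (odd; default 129).
#' @return A `shaping_filter` object.
#' @export
shaping_filter <- function(fl = 2, fh = 20, fs = 100, n_taps = 129) {
  assert_scalar_number(fl, "fl", lower = 0, strict = TRUE)
  assert_scalar_number(fh, "fh", lower = 0, strict = TRUE)
  assert_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  if (fl >= fh) stop_config("shaping filter needs fl < fh (got fl = ", fl,
                            ", fh = ", fh, ")")
  if (fh >= fs / 2) stop_config("fh = ", fh, " Hz is at or above Nyquist (",
                                fs / 2, " Hz)")
  n_taps <- as.integer(n_taps)
  if (n_taps < 9L || n_taps %% 2L == 0L) stop_config("n_taps must be odd and >= 9")
  structure(list(fl = fl, fh = fh, fs = fs, n_taps = n_taps),
            class = "shaping_filter")
}

#' Analytic shaping-filter power spectral density
#'
#' @param f frequency (Hz), vectorized.
#' @param fl,fh corner frequencies in Hz.
#' @return `PSD_g(f)`, unnormalized.
#' @export
shaping_psd <- function(f, fl, fh) {
  fh^2 * f^2 / ((f^2 + fl^2) * (f^2 + fh^2)^2)
}

#' Impulse response of the shaping filter
#'
#' Linear-phase (type I) FIR approximation of `sqrt(PSD_g)`, designed by
#' least squares on a dense frequency grid. The response is zero at DC and
#' tracks the analytic magnitude closely through the passband.
#'
#' @param filter a [shaping_filter()].
#' @return Numeric vector of `n_taps` symmetric filter taps.
#' @export
shaping_filter_response <- function(filter) {
  stopifnot(inherits(filter, "shaping_filter"))
  M <- (filter$n_taps - 1L) %/% 2L
  w <- seq(0, pi, length.out = 16L * filter$n_taps)
  fgrid <- w / (2 * pi) * filter$fs
  target <- sqrt(shaping_psd(fgrid, filter$fl, filter$fh))
  target <- target / max(target)
  X <- cbind(1, 2 * cos(outer(w, seq_len(M))))
  # weighted least squares: the passband [fl/2, min(2 fh, 0.45 fs)] is fit
  # in relative error (capped where the target gets small), the stopband
  # in absolute error; constrained to an exact zero at DC, matching the
  # analytic PSD which vanishes at f = 0
  inband <- fgrid >= filter$fl / 2 & fgrid <= min(2 * filter$fh, 0.45 * filter$fs)
  wt <- rep(1, length(w))
  wt[inband] <- 4 / pmax(target[inband], 0.1)
  con <- c(1, rep(2, M))
  N <- qr.Q(qr(matrix(con)), complete = TRUE)[, -1, drop = FALSE]
  amp <- as.numeric(N %*% qr.solve((X * wt) %*% N, target * wt))
  c(rev(amp[-1]), amp[1], amp[-1])
}

# centered "same"-mode convolution with zero padding outside the signal
conv_same <- function(x, g) {
  n <- length(x); L <- length(g)
  full <- stats::convolve(x, rev(g), type = "open")
  off <- (L - 1L) %/% 2L
  full[(off + 1L):(off + n)]
}

#' SS1 / SS2 simulator parameters
#'
#' @param filter a [shaping_filter()] (its `fs` is checked against the
#'   input signal when the simulator runs).
#' @param noise_sigma standard deviation of the additive measurement noise
#'   term (default 0.1).
#' @param envelope_window_ms moving-average window for the amplitude
#'   envelope (SS1) or for smoothing the drawn variance sequence (SS2);
#'   default 15 ms.
#' @param literal_variance SS2 only: if `TRUE`, multiply the carrier by the
#'   drawn variance itself rather than by its square root. The default
#'   (`FALSE`) is the variance-consistent reading: the carrier has unit
#'   variance, so multiplying by the square root makes the instantaneous
#'   output variance equal the drawn value.
#' @return An `ss1_spec` / `ss2_spec` object (also an `aug_spec`).
#' @name simulator_specs
NULL

#' @rdname simulator_specs
#' @export
ss1_spec <- function(filter = shaping_filter(), noise_sigma = 0.1,
                     envelope_window_ms = 15) {
  assert_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  structure(list(method = "ss1", filter = filter, noise_sigma = noise_sigma,
                 envelope_window_ms = envelope_window_ms),
            class = c("ss1_spec", "aug_spec"))
}

#' @rdname simulator_specs
#' @export
ss2_spec <- function(filter = shaping_filter(), noise_sigma = 0.1,
                     envelope_window_ms = 15, literal_variance = FALSE) {
  assert_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  structure(list(method = "ss2", filter = filter, noise_sigma = noise_sigma,
                 envelope_window_ms = envelope_window_ms,
                 literal_variance = isTRUE(literal_variance)),
            class = c("ss2_spec", "aug_spec"))
}

# channel covariance with epsilon*I regularization for rank-deficient
# short records
.regularized_cov <- function(m) {
  S <- stats::cov(m)
  if (any(!is.finite(S))) stop_numeric("channel covariance is non-finite")
  C <- ncol(S)
  # absolute floor keeps the factorization defined for all-zero records,
  # whose carrier is then numerically zero
  eps <- max(1e-8 * sum(diag(S)) / C, 1e-30)
  S + diag(eps, C)
}

#' Components of the SS1 simulator
#'
#' Exposes the intermediate quantities of [simulate_ss1()] for audit: the
#' covariance-matched filtered carrier, the moving-average amplitude
#' envelope, and the additive noise field. `carrier * envelope + noise`
#' reconstructs the simulator output exactly.
#'
#' @inheritParams simulate_ss1
#' @return List with `carrier`, `envelope`, `noise` (matrices) and
#'   `covariance` (the regularized channel covariance used).
#' @export
ss1_components <- function(x, spec = ss1_spec(), seed = 1L) {
  if (abs(spec$filter$fs - x$fs) > 1e-9)
    stop_config("shaping filter designed for fs = ", spec$filter$fs,
                " Hz but signal is ", x$fs, " Hz")
  m <- x$samples
  n <- nrow(m); C <- ncol(m)
  S <- .regularized_cov(m)
  U <- chol(S)
  g <- shaping_filter_response(spec$filter)
  env <- envelope_ma(x, spec$envelope_window_ms)$samples
  with_seed(seed, {
    w <- matrix(stats::rnorm(n * C), nrow = n) %*% U
    carrier <- apply(w, 2L, conv_same, g = g)
    if (!is.matrix(carrier)) carrier <- matrix(carrier, nrow = n)
    noise <- matrix(stats::rnorm(n * C, sd = spec$noise_sigma), nrow = n)
    list(carrier = carrier, envelope = env, noise = noise, covariance = S)
  })
}

#' sEMG simulation by shaping filter and covariance-matched carrier (SS1)
#'
#' Generates a synthetic record from a real one: a multichannel Gaussian
#' carrier with the real record's channel covariance is coloured by the
#' shaping filter, amplitude-modulated by the record's moving-average
#' envelope, and overlaid with white measurement noise. The channel
#' covariance reproduces the correlation between adjacent electrodes; the
#' envelope carries the gesture's activation timing, which is what keeps
#' the label valid.
#'
#' @param x an [emg_signal()] (the real record).
#' @param spec an [ss1_spec()].
#' @param seed RNG seed; output is bit-reproducible given the seed.
#' @return An [emg_signal()] of the same shape.
#' @export
simulate_ss1 <- function(x, spec = ss1_spec(), seed = 1L) {
  parts <- ss1_components(x, spec, seed)
  signal_like(x, parts$carrier * parts$envelope + parts$noise)
}

# inverse-gamma sampler: X ~ IG(shape, scale) iff 1/X ~ Gamma(shape, rate = scale)
rinvgamma <- function(n, shape, scale) 1 / stats::rgamma(n, shape = shape, rate = scale)

# marginal log-likelihood of zero-mean normal samples with IG(a, b) variance
.ig_marginal_loglik <- function(x2half, a, b) {
  sum(lgamma(a + 0.5) - lgamma(a) + a * log(b) - 0.5 * log(2 * pi) -
        (a + 0.5) * log(b + x2half))
}

#' Fit the inverse-gamma variance model by expectation maximization
#'
#' Model: each sample is zero-mean Gaussian with its own variance, and the
#' variances are i.i.d. inverse-gamma `IG(alpha, beta)`. The E-step uses the
#' conjugate posterior `IG(alpha + 1/2, beta + x_t^2/2)` per sample to form
#' `E[1/sigma_t^2]` and `E[log sigma_t^2]`; the M-step solves the
#' inverse-gamma maximum-likelihood equations (1-D root-find on the digamma
#' equation for `alpha`, closed form for `beta`). The marginal log-likelihood
#' is non-decreasing across iterations (EM guarantee) and is recorded in
#' `loglik_trace`.
#'
#' @param x numeric vector of sEMG samples (one channel), length >= 10,
#'   not identically zero.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-8).
#' @return An object of class `ig_fit`: list with `alpha`, `beta`,
#'   `loglik_trace`, `iterations`, `converged`.
#' @export
fit_inverse_gamma_em <- function(x, max_iter = 200, tol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) < 10L) stop_config("need at least 10 samples to fit the variance model")
  if (stats::var(x) == 0) stop_numeric("degenerate input: zero sample variance")
  x2half <- x^2 / 2
  # moment-matched init: marginal kurtosis 3(a-1)/(a-2) pins alpha
  m2 <- mean(x^2); m4 <- mean(x^4)
  k <- m4 / m2^2
  a <- if (is.finite(k) && k > 3.2) (2 * k / 3 - 1) / (k / 3 - 1) else 3
  a <- min(max(a, 1.1), 100)
  b <- max((a - 1) * m2, .Machine$double.eps)
  ll <- .ig_marginal_loglik(x2half, a, b)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: posterior expectations under IG(a + 1/2, b + x^2/2)
    s1 <- mean((a + 0.5) / (b + x2half))          # E[1/sigma^2]
    s2 <- mean(log(b + x2half)) - digamma(a + 0.5) # E[log sigma^2]
    # M-step: log(a) - digamma(a) = s2 + log(s1), then b = a / s1
    rhs <- s2 + log(s1)
    if (!is.finite(rhs) || rhs <= 0)
      stop_numeric("EM M-step infeasible (rhs = ", format(rhs), ")")
    f <- function(av) log(av) - digamma(av) - rhs
    lo <- 1e-8; hi <- 1
    while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
    if (f(hi) > 0)
      stop_numeric("alpha root-find failed to bracket; loglik trace: ",
                   paste(format(trace), collapse = ", "))
    a <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    b <- a / s1
    ll_new <- .ig_marginal_loglik(x2half, a, b)
    trace <- c(trace, ll_new)
    if (is.finite(ll_new) && ll_new - ll < tol) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  structure(list(alpha = a, beta = b, loglik_trace = trace,
                 iterations = length(trace) - 1L, converged = converged),
            class = "ig_fit")
}

#' @export
print.ig_fit <- function(x, ...) {
  cat(sprintf("<ig_fit> alpha = %.4f, beta = %.4f (%d EM iterations, loglik %.4f)\n",
              x$alpha, x$beta, x$iterations, utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' sEMG simulation with an inverse-gamma variance model (SS2)
#'
#' Per channel: fits `IG(alpha, beta)` to the real channel by EM
#' ([fit_inverse_gamma_em()]), draws an i.i.d. variance sequence from the
#' fitted distribution, smooths it with the moving-average window, colours
#' a unit-variance Gaussian carrier with the shaping filter, scales the
#' carrier by the square root of the smoothed variance sequence (so the
#' instantaneous variance equals the drawn value; see `literal_variance`
#' in [ss2_spec()] for the alternative reading), and adds white
#' measurement noise.
#'
#' @param x an [emg_signal()] (the real record).
#' @param spec an [ss2_spec()].
#' @param seed RNG seed.
#' @return An [emg_signal()] of the same shape.
#' @export
simulate_ss2 <- function(x, spec = ss2_spec(), seed = 1L) {
  if (abs(spec$filter$fs - x$fs) > 1e-9)
    stop_config("shaping filter designed for fs = ", spec$filter$fs,
                " Hz but signal is ", x$fs, " Hz")
  m <- x$samples
  n <- nrow(m); C <- ncol(m)
  g <- shaping_filter_response(spec$filter)
  fits <- lapply(seq_len(C), function(ch) fit_inverse_gamma_em(m[, ch]))
  out <- m
  for (ch in seq_len(C)) {
    fit <- fits[[ch]]
    ch_seed <- derive_seed(seed, ch)
    out[, ch] <- with_seed(ch_seed, {
      v <- rinvgamma(n, fit$alpha, fit$beta)
      v <- envelope_ma(emg_signal(v, x$fs), spec$envelope_window_ms)$samples[, 1L]
      carrier <- conv_same(stats::rnorm(n), g)
      scale <- if (spec$literal_variance) v else sqrt(v)
      carrier * scale + stats::rnorm(n, sd = spec$noise_sigma)
    })
  }
  signal_like(x, out)
}

#' @export
apply_augmentation.ss1_spec <- function(x, spec, seed = 1L) simulate_ss1(x, spec, seed)

#' @export
apply_augmentation.ss2_spec <- function(x, spec, seed = 1L) simulate_ss2(x, spec, seed)
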
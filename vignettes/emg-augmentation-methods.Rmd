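---
title: "Augmenting sEMG gesture data: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmenting sEMG gesture data: models, parameters, and numerical choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`emgaug` generates label-preserving synthetic variants of multichannel
surface-electromyography (sEMG) recordings. This vignette is the package's
account of the science inside it: the generative assumptions each method
makes, the parameters that matter and why their defaults are what they are,
what the synthetic fixture generator does and does not emulate, and the
numerical decisions taken where the mathematics alone did not force a
choice.

## The augmentation contract

Every method maps a recording `x` (an `N_t x C` matrix at sampling rate
`fs`) to a new recording `x*` of identical shape, leaving the gesture label
untouched. The working assumption throughout is that the label lives in
*where* and *in what spatial pattern* muscles activate, while amplitude
detail, fine spectral texture, and sensor noise are nuisance dimensions a
classifier should become invariant to. Each method perturbs a different
nuisance dimension:

| method | nuisance dimension perturbed |
|--------|------------------------------|
| GN | sensor noise level |
| MW | slow amplitude drift (electrode contact, fatigue) |
| WD | fine-scale spectral texture |
| SS1 | the entire carrier process, keeping envelope + channel covariance |
| SS2 | the carrier and its amplitude statistics, keeping their distribution |

This assumption can fail: a warp curve with large variance can reshape an
envelope into one resembling a different gesture. The defaults below are
deliberately conservative for that reason.

## Gaussian noise (GN)

Noise is drawn i.i.d. `N(0, sigma^2)` with `sigma^2 = mean(x_c^2) / SNR`
**per channel** and added elementwise. Two decisions deserve comment.

*SNR is a linear power ratio.* `sigma^2 = power / SNR` is implemented
exactly as written, with the default `snr = 30`. Because values in the
25–35 range are also plausible decibel figures, `gn_spec(snr_db = TRUE)`
converts from dB explicitly rather than guessing.

*Noise power is per channel, not pooled.* Electrode channels in a gesture
recording differ in mean power by an order of magnitude. A single pooled
noise power would bury the quiet channels — which often carry the
discriminative pattern — under noise calibrated to the loud ones.
`gn_spec(pooled = TRUE)` restores the pooled behaviour when a uniform noise
field is wanted.

## Magnitude warping (MW)

`T` equidistant knots span the record (both endpoints included); knot
values are drawn `N(1, sigma^2)`; a **natural** cubic spline through the
knots is evaluated at every sample and multiplied in. Defaults:
`sigma = 0.1` (a ±10% one-sigma amplitude deformation — large enough to
matter, small enough not to mimic a different gesture) and `T = 4` knots.
The knot count is the one genuinely free structural parameter: it is not
derivable from anything else, so it is surfaced prominently in
`mw_spec()`. Four knots over a record gives roughly one inflection per
second on a 5 s gesture — slow drift, not tremor.

One curve is shared by all channels by default, because the inter-channel
amplitude ratio is the gesture's spatial signature; warping channels
independently would corrupt exactly the feature the label depends on.
`mw_spec(per_channel = TRUE)` exists for experiments that want the
stronger perturbation. Natural boundary conditions were chosen over
not-a-knot so the curve stays tame beyond the outermost knots.

## Wavelet decomposition (WD)

Per channel the signal is decomposed to level `l` with an orthogonal
wavelet, every detail band at every level is multiplied by `b`, and the
signal is re-synthesized. "All detail coefficients" is read as all levels,
not only the deepest — scaling one band only would be a different (and
weaker) operation.

The transform is implemented in the package (Mallat pyramid, Daubechies
1–10, Symlet 2–10, Coiflet 1–5) with **periodized** signal extension.
Periodization keeps the transform square and orthogonal, which buys two
exact identities the test suite leans on: `b = 1` reproduces the input to
machine precision, and the energy removed at `b = 0` equals the summed
detail-band energy (Parseval). Symmetric extension — the common default in
general-purpose wavelet software — is expansive: it stores more
coefficients than samples, the energy identity holds only approximately
(percent-level error at typical record lengths), and an audit of "how much
energy did this augmentation move" becomes mushy. The wrap-around artefact
periodization introduces at the record boundary is immaterial here because
records begin and end near rest. Odd-length signals are padded by
repeating the final sample at each level, and the pre-padding lengths are
replayed at reconstruction, so perfect reconstruction holds for every
length.

A level too deep for the record length raises an error rather than
silently reducing `l`: silently changing a user's augmentation strength is
worse than failing loudly.

## The shaping filter (SS1/SS2 carrier)

Both simulators colour white noise with a filter `g` whose squared
magnitude follows the two-corner spectrum

$$PSD_g(f) = \frac{f_h^2\, f^2}{(f^2+f_l^2)(f^2+f_h^2)^2},$$

zero at DC, peaked between the corners. The corners are *not* determined
by the spectrum's printed form; they are model parameters. The shipped
default `fl = 2 Hz`, `fh = 20 Hz` places the peak inside the band of
100 Hz envelope-domain signals (the package's primary operating point);
`fl = 60`, `fh = 120` Hz is the conventional choice for raw sEMG at
2 kHz sampling and is documented in `shaping_filter()`.

`g` is realized as a 129-tap linear-phase (type I) FIR whose amplitude is
fitted to `sqrt(PSD_g)` by weighted least squares with an exact DC-zero
constraint. The weighting fits the band `[fl/2, min(2 fh, 0.45 fs)]` in
*relative* error and the stopband in absolute error; with uniform weights
the DC constraint pushes percent-level error into the lower band edge.
At the default configuration the realized magnitude stays within 5% of
the analytic curve over that band (the test suite measures ~3.7%). The
filter length is configurable: when `fs` is large relative to the band
(raw-sEMG presets), 129 taps cannot resolve the low corner and ~500 taps
are appropriate.

## SS1: covariance-matched carrier simulation

Per generated record: a `N_t x C` matrix of i.i.d. standard normals is
multiplied by the Cholesky factor of the real record's channel covariance
(regularized by `eps * I`, `eps = 1e-8 * trace/C`, with an absolute floor
so an all-zero record degenerates gracefully to a zero carrier rather
than a factorization error); each channel is convolved with `g`
(centered, zero-padded "same" convolution); the result is multiplied by
the record's 15 ms moving-average envelope and overlaid with
`N(0, 0.1^2)` measurement noise.

The channel covariance is what makes the output multichannel-plausible:
adjacent electrodes see correlated activity, and a classifier trained on
uncorrelated synthetic channels would learn a tell. `ss1_components()`
exposes carrier, envelope and noise separately so this can be audited —
the test suite checks that a configured channel correlation of 0.8
survives into the carrier within ±0.05.

## SS2: the inverse-gamma variance model and its EM fit

SS2 replaces SS1's deterministic envelope with a stochastic amplitude
model: samples are zero-mean Gaussian with per-sample variance
`sigma_t^2 ~ IG(alpha, beta)`, i.i.d., fitted per channel per record. The
marginal of that model is a scaled Student-t — heavy tails, which is what
distinguishes real sEMG amplitude statistics from Gaussian noise.

The EM fit uses the conjugate posterior
`sigma_t^2 | x_t ~ IG(alpha + 1/2, beta + x_t^2/2)` in the E-step and
solves the inverse-gamma MLE in the M-step: `log(alpha) - digamma(alpha)`
equals a data constant (1-D monotone root-find, bracket grown by powers of
ten, `uniroot` at `1e-12`), then `beta = alpha / E[1/sigma^2]` in closed
form. Initialization is moment matching through the marginal kurtosis
`3(alpha-1)/(alpha-2)`, clamped to `[1.1, 100]`, falling back to
`alpha = 3` when the sample kurtosis is too close to Gaussian for the
moment equation to be solvable. Termination: marginal log-likelihood
improvement below `1e-8`, cap of 200 iterations. The likelihood trace is
stored on the fit object, and monotonicity (the EM guarantee) is asserted
on every fixture in the test corpus. Constant input has no variance to
model and errors out; the simulator propagates that error rather than
fabricating a fit.

Generation draws the variance sequence i.i.d. from the fitted
distribution and smooths it with the same 15 ms moving average SS1 uses
for its envelope — the model itself says nothing about the temporal
structure of the variance, and an unsmoothed i.i.d. sequence would make
the output's amplitude flicker at sample rate, which real sEMG does not.
The carrier is scaled by `sqrt(sigma_t^2)`: the printed model form is
ambiguous between multiplying by the variance or its square root, and the
square-root reading is the one under which the instantaneous output
variance actually equals the drawn value (the carrier having unit
variance). The literal reading remains available via
`ss2_spec(literal_variance = TRUE)`.

## Composition policies and the skip-probability convention

`Augmentor.Random` applies method `k` iff a uniform draw satisfies
`u_k > p_k`. Read literally this makes `p_k` a probability of *skipping*,
and `emgaug` implements exactly that, because at the conventional
operating point `p_k = 0.5` the two readings coincide and the literal
reading is the only one that is unambiguous. The `apply_prob` argument of
`augmentor_policy()` lets users state application probabilities directly.

Seeding is structured so that dataset-level results are order-invariant
and policy modes are comparable: method `k` always draws from a stream
derived from `(seed, k)`, the policy's own selection draws use a separate
stream, and each (record, replicate) pair of `build_augmented_dataset()`
derives an independent seed. Two consequences are tested explicitly:
`Random` with all thresholds 0 is bit-identical to `All` under the same
seed, and re-running any augmentation with the same master seed is
bit-reproducible regardless of record order.

`SSx` in the default chain is SS2; which simulator fills the slot is a
configuration choice (`default_methods(ssx = "ss1")`).

## Windowing, splitting, balancing

Windows are half-open `[start, start + L)` on 0-based sample indices,
starting at multiples of the step `tau`; a record of length `N_t` yields
`floor((N_t - L)/tau) + 1` windows, verified exhaustively against
enumeration for all `1 <= tau <= L <= N_t <= 200`. Trailing samples are
dropped, never padded — padding would fabricate signal. Windows cannot
span record boundaries because segmentation is per record, which is what
makes repetition-based splitting leak-proof: a generated record carries
its source's repetition index, so all windows that share ancestry land in
the same partition. The split errors on overlapping repetition sets and
on any repetition present in the data but assigned to no partition. A
documented default split (test = repetition 5, validation = repetition 4,
remainder training) is provided in the CLI; the assignment is otherwise
fully user-configured. Class balancing removes segments uniformly at
random (seeded) down to the minimum per-label count — it never
upsamples.

## The fixture generator

`generate_fixture()` produces the study conditions for every test in the
package: per gesture, a row of a gesture-by-channel gain matrix; per
repetition, a sum of Gaussian activation bursts (random centers in the
middle 80% of the record, widths 5–15% of its length) scaled by that row,
plus a rectified-Gaussian noise floor (`noise_std = 0.02` against unit
burst amplitude). Defaults — 8 gestures, 10 electrodes, 10 repetitions,
5 s at 100 Hz — mirror a typical envelope-domain gesture corpus.

What it emulates: non-negativity, slow envelope dynamics, per-gesture
spatial activation patterns, repetition structure, amplitude variability.
What it does not: motor-unit interference structure, fatigue drift,
electrode-shift artefacts, inter-subject variability, or any spectral
realism above the envelope band. Tests passing on fixtures therefore
demonstrate the *mechanics* of the pipeline — shape preservation,
determinism, bookkeeping, metric correctness — not classification gains
on real recordings, which depend on data the package deliberately does
not ship.

## Numerical choices elsewhere

* **Zero-phase filtering.** All IIR filtering (envelope low-pass, notch,
  band-pass, anti-aliasing) runs forward and backward with odd-extension
  padding and steady-state initial conditions, so DC passes exactly and a
  band-interior sine emerges with zero lag. Phase handling matters here
  because augmentation compares envelopes pointwise; a causal filter's
  group delay would shift every envelope against its windows.
* **Notch.** Second-order IIR (bi-quad) at the configured frequency with
  quality factor Q = 30 — narrow enough to leave 45/55 Hz content
  essentially untouched.
* **RMS and moving-average windows** are centered and truncated at the
  edges (not discarded), keeping output length equal to input length so
  windowing arithmetic is unaffected by preprocessing.
* **Resampling** only decimates; integer factors use an 8th-order
  zero-phase Butterworth anti-aliasing filter at 80% of the target
  Nyquist, non-integer ratios fall back to polyphase resampling.
  Upsampling is refused.
* **Cluster metrics** use Euclidean distance (the conventional choice;
  nothing in the definitions forces it), assign silhouette 0 to singleton
  clusters, and raise a named error for coincident centroids
  (Davies–Bouldin would divide by zero) and for single-cluster input.

## Problem sizes used in verification

The test-suite and acceptance-script operating points are: Monte-Carlo
noise calibration at `N_t = 1e5` over 200 seeded runs; carrier-correlation
checks at `N_t = 1e5`; EM parameter recovery at `N = 20000` from
`IG(3, 2)` with a 15% band; window combinatorics exhaustive to
`N_t = 200`; metric cross-validation on 50 random instances up to 200
points against an external reference implementation at `1e-9`. These
sizes make every stochastic tolerance comfortably concentrated while the
whole suite completes in well under a minute.

## Known limitations

* The augmentations assume envelope-domain input; applying MW or GN to
  raw interference-pattern sEMG is mathematically fine but the defaults
  (knot count, SNR) were chosen for envelopes.
* SS1/SS2 fit their statistics per record; very short records give noisy
  covariance and variance estimates (the covariance is regularized, the
  EM requires only 10 samples, but quality degrades).
* The inverse-gamma variance sequence is i.i.d. before smoothing; real
  amplitude dynamics have longer-range dependence than a 15 ms moving
  average induces.
* Cluster metrics on raw flattened windows measure geometric separability
  of signals, not of any learned feature space; they are a diagnostic,
  not a proxy for classifier accuracy.
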
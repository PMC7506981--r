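#' Composition policy over a set of augmentation methods
#'
#' Three ways of combining `K` configured augmentation methods when
#' generating one synthetic record:
#'
#' * `"one"` — apply exactly one method, chosen uniformly at random; over a
#'   dataset this amounts to applying each method to an equal share of the
#'   records.
#' * `"all"` — apply all `K` methods consecutively, in the configured order.
#' * `"random"` — walk the methods in order and apply method `k` iff a
#'   uniform draw `u_k` exceeds its threshold `p_k`. Note the printed
#'   convention makes `p_k` a *skip* probability (a method runs with
#'   probability `1 - p_k`); at the default `p_k = 0.5` the two readings
#'   coincide. Pass `apply_prob` instead of `p` to specify application
#'   probabilities directly.
#'
#' The conventional method order is simulator first, then wavelet, warp,
#' noise (`SSx-WD-MW-GN`), which [default_methods()] provides.
#'
#' @param mode `"one"`, `"all"`, or `"random"`.
#' @param methods non-empty ordered list of augmentation specs (see
#'   [augmentation_specs], [simulator_specs]).
#' @param p per-method skip thresholds in `[0,1]` (`"random"` mode only;
#'   default 0.5 for every method).
#' @param apply_prob alternative to `p`: per-method application
#'   probabilities (`p = 1 - apply_prob`).
#' @return An `augmentor_policy` object.
#' @export
augmentor_policy <- function(mode = c("one", "all", "random"),
                             methods = default_methods(),
                             p = NULL, apply_prob = NULL) {
  mode <- match.arg(mode)
  if (!is.list(methods) || length(methods) == 0L)
    stop_config("methods must be a non-empty list of augmentation specs")
  for (sp in methods) if (!inherits(sp, "aug_spec"))
    stop_config("methods must all be augmentation specs")
  K <- length(methods)
  if (!is.null(p) && !is.null(apply_prob))
    stop_config("give either p or apply_prob, not both")
  if (!is.null(apply_prob)) p <- 1 - apply_prob
  if (is.null(p)) p <- rep(0.5, K)
  if (length(p) == 1L) p <- rep(p, K)
  if (length(p) != K)
    stop_config("need one threshold per method (", K, "), got ", length(p))
  if (any(p < 0 | p > 1)) stop_config("thresholds must lie in [0, 1]")
  structure(list(mode = mode, methods = methods, p = p),
            class = "augmentor_policy")
}

#' Default augmentation method set, in SSx-WD-MW-GN order
#'
#' @param ssx which simulator fills the SSx slot, `"ss2"` (default; the
#'   stronger of the two) or `"ss1"`.
#' @param fs sampling rate the simulator's shaping filter is designed for.
#' @return List of four augmentation specs.
#' @export
default_methods <- function(ssx = c("ss2", "ss1"), fs = 100) {
  ssx <- match.arg(ssx)
  sf <- shaping_filter(fs = fs)
  list(if (ssx == "ss2") ss2_spec(filter = sf) else ss1_spec(filter = sf),
       wd_spec(), mw_spec(), gn_spec())
}

#' Apply a composition policy to one signal
#'
#' Method `k` always draws from an RNG stream derived from
#' `(seed, k)` regardless of mode, and the policy's own selection draws use
#' a separate stream; consequently `"random"` with all thresholds 0
#' reproduces `"all"` exactly under the same seed.
#'
#' @param x an [emg_signal()].
#' @param policy an [augmentor_policy()] .
#' @param seed RNG seed.
#' @return List with `signal` (the augmented [emg_signal()]) and
#'   `realized` (character vector of method tags actually applied, in
#'   application order; may be empty in `"random"` mode).
#' @export
apply_policy <- function(x, policy, seed = 1L) {
  stopifnot(inherits(policy, "augmentor_policy"))
  K <- length(policy$methods)
  tags <- vapply(policy$methods, `[[`, character(1), "method")
  selector_seed <- derive_seed(seed, 0L)
  run <- switch(policy$mode,
    one = {
      j <- with_seed(selector_seed, sample.int(K, 1L))
      j
    },
    all = seq_len(K),
    random = {
      u <- with_seed(selector_seed, stats::runif(K))
      which(u > policy$p)
    })
  out <- x
  for (j in run) out <- apply_augmentation(out, policy$methods[[j]],
                                           seed = derive_seed(seed, j))
  list(signal = out, realized = tags[run])
}

#' Inflate a dataset by an augmentation ratio R
#'
#' Appends `R` generated records per original record, so the output holds
#' `(R + 1) * n` records in total: the augmentation ratio `R` is the number
#' of generated signals divided by the number of initial signals. For
#' example, a 364-record training set at `R = 9` gains `364 * 9 = 3276`
#' generated records for a total of 3640. Generated records keep the
#' source's subject, gesture and repetition (so they follow their source
#' through a repetition-based split), are flagged `origin = "augmented"`,
#' and carry the realized method tags as lineage.
#'
#' @param ds an [emg_dataset()].
#' @param policy an [augmentor_policy()], or a single augmentation spec.
#' @param R augmentation ratio, integer >= 0.
#' @param seed master seed; each (record, replicate) pair gets an
#'   independent derived stream, so results do not depend on processing
#'   order.
#' @return An [emg_dataset()] with `(R + 1) * n_records(ds)` records.
#' @export
build_augmented_dataset <- function(ds, policy, R, seed = 1L) {
  R <- as.integer(R)
  if (is.na(R) || R < 0L) stop_config("augmentation ratio R must be an integer >= 0")
  if (inherits(policy, "aug_spec"))
    policy <- augmentor_policy("all", methods = list(policy))
  stopifnot(inherits(policy, "augmentor_policy"))
  n <- n_records(ds)
  out <- vector("list", n * (R + 1L))
  out[seq_len(n)] <- ds$records
  k <- n
  for (i in seq_len(n)) {
    src <- ds$records[[i]]
    for (r in seq_len(R)) {
      res <- apply_policy(src$signal, policy, seed = derive_seed(seed, i, r))
      lin <- c(src$lineage, res$realized)
      # a "random" draw may skip every method; the copy is still a
      # generated record, tagged explicitly so the real/augmented
      # invariant holds
      if (length(lin) == 0L) lin <- "identity"
      k <- k + 1L
      out[[k]] <- emg_record(res$signal, subject = src$subject,
                             gesture = src$gesture, repetition = src$repetition,
                             origin = "augmented", lineage = lin)
    }
  }
  emg_dataset(out)
}
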
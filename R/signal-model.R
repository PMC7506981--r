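#' Multichannel sEMG signal
#'
#' The basic container of the package: a time-by-channel numeric matrix with
#' its sampling rate. Rows are samples, columns are electrodes. Amplitude
#' units are arbitrary (raw volts or RMS-envelope units); all augmentation
#' methods are unit-agnostic.
#'
#' @param samples numeric matrix (or vector, treated as single channel),
#'   one row per sample and one column per electrode.
#' @param fs sampling rate in Hz, positive.
#' @return An object of class `emg_signal`: a list with elements `samples`
#'   (matrix) and `fs`.
#' @examples
#' x <- emg_signal(matrix(rnorm(200), ncol = 2), fs = 100)
#' n_samples(x)
#' n_channels(x)
#' @export
emg_signal <- function(samples, fs) {
  if (is.vector(samples) && is.numeric(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_config("samples must be a numeric matrix (time x channel)")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop_config("signal must have at least one sample and one channel")
  if (any(!is.finite(samples)))
    stop_config("signal contains non-finite values")
  assert_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  structure(list(samples = samples, fs = as.numeric(fs)), class = "emg_signal")
}

#' @rdname emg_signal
#' @param x an `emg_signal`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname emg_signal
#' @export
n_channels <- function(x) ncol(x$samples)

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf("<emg_signal> %d samples x %d channels @ %g Hz (%.3f s)\n",
              n_samples(x), n_channels(x), x$fs, n_samples(x) / x$fs))
  invisible(x)
}

as_emg_signal <- function(x, fs) {
  if (inherits(x, "emg_signal")) x else emg_signal(x, fs)
}

# rebuild a signal with new samples, keeping fs
signal_like <- function(x, samples) emg_signal(samples, x$fs)

#' A labelled sEMG recording
#'
#' Couples an [emg_signal()] with its metadata: subject, gesture label,
#' repetition index, whether it is a real or an augmented recording, and --
#' for augmented recordings -- the lineage of augmentation methods that
#' produced it (in application order).
#'
#' @param signal an [emg_signal()].
#' @param subject subject identifier (string).
#' @param gesture gesture label, integer >= 0.
#' @param repetition repetition index, integer >= 1.
#' @param origin `"real"` or `"augmented"`.
#' @param lineage character vector of method tags applied (must be empty
#'   iff `origin == "real"`).
#' @return An object of class `emg_record`.
#' @export
emg_record <- function(signal, subject, gesture, repetition,
                       origin = "real", lineage = character()) {
  if (!inherits(signal, "emg_signal")) stop_config("signal must be an emg_signal")
  if (!is.character(subject) || length(subject) != 1L)
    stop_config("subject must be a single string")
  gesture <- as.integer(gesture); repetition <- as.integer(repetition)
  if (is.na(gesture) || gesture < 0L) stop_config("gesture must be an integer >= 0")
  if (is.na(repetition) || repetition < 1L) stop_config("repetition must be an integer >= 1")
  origin <- match.arg(origin, c("real", "augmented"))
  lineage <- as.character(lineage)
  if ((origin == "real") != (length(lineage) == 0L))
    stop_config("origin = 'real' requires empty lineage, and vice versa")
  structure(list(signal = signal, subject = subject, gesture = gesture,
                 repetition = repetition, origin = origin, lineage = lineage),
            class = "emg_record")
}

#' A collection of labelled sEMG recordings
#'
#' All records must share the same sampling rate and channel count.
#'
#' @param records list of [emg_record()] objects (may be empty).
#' @return An object of class `emg_dataset` with elements `records` and `fs`
#'   (`NA` for an empty dataset).
#' @export
emg_dataset <- function(records = list()) {
  if (!is.list(records)) stop_config("records must be a list of emg_record")
  for (r in records) if (!inherits(r, "emg_record"))
    stop_config("records must all be emg_record objects")
  fs <- NA_real_
  if (length(records)) {
    fss <- vapply(records, function(r) r$signal$fs, numeric(1))
    if (length(unique(fss)) > 1L)
      stop_io("records disagree on sampling rate: ",
              paste(unique(fss), collapse = " Hz vs "), " Hz")
    ccs <- vapply(records, function(r) n_channels(r$signal), integer(1))
    if (length(unique(ccs)) > 1L)
      stop_io("records disagree on channel count: ",
              paste(unique(ccs), collapse = " vs "))
    fs <- fss[[1L]]
  }
  structure(list(records = records, fs = fs), class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  n <- length(x$records)
  if (n == 0L) { cat("<emg_dataset> empty\n"); return(invisible(x)) }
  g <- vapply(x$records, `[[`, integer(1), "gesture")
  aug <- sum(vapply(x$records, `[[`, character(1), "origin") == "augmented")
  cat(sprintf("<emg_dataset> %d records (%d augmented), %d gestures, %d channels @ %g Hz\n",
              n, aug, length(unique(g)), n_channels(x$records[[1]]$signal), x$fs))
  invisible(x)
}

#' @rdname emg_dataset
#' @param ds an `emg_dataset`.
#' @export
n_records <- function(ds) length(ds$records)

#' Metadata of all records as a data frame
#'
#' @param ds an [emg_dataset()].
#' @return A data frame with one row per record: `subject`, `gesture`,
#'   `repetition`, `origin`, `lineage` (methods joined by `+`), `n_samples`.
#' @export
dataset_meta <- function(ds) {
  if (!n_records(ds)) {
    return(data.frame(subject = character(), gesture = integer(),
                      repetition = integer(), origin = character(),
                      lineage = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    subject = vapply(ds$records, `[[`, character(1), "subject"),
    gesture = vapply(ds$records, `[[`, integer(1), "gesture"),
    repetition = vapply(ds$records, `[[`, integer(1), "repetition"),
    origin = vapply(ds$records, `[[`, character(1), "origin"),
    lineage = vapply(ds$records, function(r) paste(r$lineage, collapse = "+"), character(1)),
    n_samples = vapply(ds$records, function(r) n_samples(r$signal), integer(1)),
    stringsAsFactors = FALSE)
}

#' Split a dataset into train / validation / test by gesture repetition
#'
#' Whole repetitions (not windows) are routed to one of the three partitions,
#' so that segments cut later from the same recording can never leak across
#' the split. Augmented records inherit the split of their source repetition,
#' because they carry its repetition index.
#'
#' @param ds an [emg_dataset()].
#' @param train_reps,val_reps,test_reps integer vectors of repetition indices.
#'   Must be pairwise disjoint, and every repetition present in `ds` must be
#'   covered by exactly one of them.
#' @return A list with elements `train`, `val`, `test`, each an `emg_dataset`.
#' @examples
#' ds <- generate_fixture(fixture_config(n_gestures = 2, n_repetitions = 5,
#'                                       n_channels = 3, duration_s = 1))
#' parts <- split_by_repetition(ds, train_reps = 1:3, val_reps = 4, test_reps = 5)
#' n_records(parts$test)
#' @export
split_by_repetition <- function(ds, train_reps, val_reps, test_reps) {
  train_reps <- as.integer(train_reps); val_reps <- as.integer(val_reps)
  test_reps <- as.integer(test_reps)
  sets <- list(train = train_reps, val = val_reps, test = test_reps)
  all_assigned <- c(train_reps, val_reps, test_reps)
  if (anyDuplicated(all_assigned))
    stop_config("repetition sets overlap: repetition(s) ",
                paste(unique(all_assigned[duplicated(all_assigned)]), collapse = ", "),
                " assigned to more than one partition")
  present <- unique(vapply(ds$records, `[[`, integer(1), "repetition"))
  uncovered <- setdiff(present, all_assigned)
  if (length(uncovered))
    stop_config("repetition(s) present in dataset but not assigned to any partition: ",
                paste(sort(uncovered), collapse = ", "))
  pick <- function(reps) emg_dataset(Filter(function(r) r$repetition %in% reps, ds$records))
  lapply(sets, pick)
}
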
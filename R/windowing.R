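#' Number of sliding windows that fit in a record
#'
#' Closed form behind [segment_dataset()]: windows of `L` samples starting
#' at `0, tau, 2*tau, ...` (0-based, half-open `[start, start + L)`) while
#' they fit entirely inside the record.
#'
#' @param n_t record length in samples.
#' @param L window length in samples.
#' @param tau window step in samples, `1 <= tau <= L`.
#' @return `floor((n_t - L) / tau) + 1` if `n_t >= L`, else 0.
#' @export
count_windows <- function(n_t, L, tau) {
  L <- as.integer(L); tau <- as.integer(tau)
  if (L < 1L) stop_config("window length L must be >= 1")
  if (tau < 1L || tau > L) stop_config("window step tau must lie in [1, L] (got tau = ",
                                       tau, ", L = ", L, ")")
  ifelse(n_t >= L, (as.integer(n_t) - L) %/% tau + 1L, 0L)
}

#' Windowing presets
#'
#' The two baseline configurations for 150 ms windows at 100 Hz:
#' `sw_preset("15")` tiles without overlap (`L = 15, tau = 15`),
#' `sw_preset("01")` uses maximum overlap (`L = 15, tau = 1`).
#'
#' @param which `"15"` (no overlap) or `"01"` (maximum overlap).
#' @return List with `L` and `tau`.
#' @export
sw_preset <- function(which = c("15", "01")) {
  which <- match.arg(which)
  list(L = 15L, tau = if (which == "15") 15L else 1L)
}

#' Cut a dataset into fixed-size windows
#'
#' Slices every record into `L x C` images with step `tau`. Windows never
#' cross record boundaries (segmentation is per record), which structurally
#' enforces the leakage rule of repetition-based splitting. Records shorter
#' than `L` yield no windows and are reported with a warning. Trailing
#' samples that do not fill a window are dropped.
#'
#' @param ds an [emg_dataset()].
#' @param L window length in samples.
#' @param tau window step in samples, `1 <= tau <= L`.
#' @return An `emg_segments` object: list with `images` (list of `L x C`
#'   matrices), `meta` (data frame: `segment_id`, `source_record`, `start`
#'   -- 0-based --, `subject`, `gesture`, `repetition`, `origin`), `L`,
#'   `tau`, `fs`.
#' @export
segment_dataset <- function(ds, L, tau) {
  L <- as.integer(L); tau <- as.integer(tau)
  count_windows(L, L, tau)  # validates L and tau
  images <- list()
  meta_rows <- list()
  short <- integer()
  sid <- 0L
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    n <- n_samples(r$signal)
    k <- count_windows(n, L, tau)
    if (k == 0L) { short <- c(short, i); next }
    starts <- seq.int(0L, by = tau, length.out = k)
    for (s in starts) {
      sid <- sid + 1L
      images[[sid]] <- r$signal$samples[(s + 1L):(s + L), , drop = FALSE]
      meta_rows[[sid]] <- data.frame(
        segment_id = sid, source_record = i, start = s,
        subject = r$subject, gesture = r$gesture,
        repetition = r$repetition, origin = r$origin,
        stringsAsFactors = FALSE)
    }
  }
  if (length(short))
    warning("skipped ", length(short), " record(s) shorter than L = ", L,
            " samples: ", paste(short, collapse = ", "))
  meta <- if (length(meta_rows)) do.call(rbind, meta_rows) else
    data.frame(segment_id = integer(), source_record = integer(),
               start = integer(), subject = character(), gesture = integer(),
               repetition = integer(), origin = character(),
               stringsAsFactors = FALSE)
  structure(list(images = images, meta = meta, L = L, tau = tau, fs = ds$fs),
            class = "emg_segments")
}

#' @export
print.emg_segments <- function(x, ...) {
  cat(sprintf("<emg_segments> %d windows of %d x %d (step %d)\n",
              length(x$images), x$L,
              if (length(x$images)) ncol(x$images[[1]]) else 0L, x$tau))
  invisible(x)
}

#' Number of segments per gesture label
#'
#' @param segs an `emg_segments` object.
#' @return Named integer vector of counts, sorted by label.
#' @export
segment_counts <- function(segs) {
  tab <- table(segs$meta$gesture)
  stats::setNames(as.integer(tab), names(tab))
}

#' Equalize per-gesture segment counts by random removal
#'
#' Gesture duration varies, so window counts per class do after
#' segmentation. Balancing removes segments uniformly at random from every
#' over-represented gesture until all labels match the pre-balance minimum
#' count. Deterministic given the seed; never adds segments.
#'
#' @param segs an `emg_segments` object (non-empty).
#' @param seed RNG seed.
#' @return A balanced `emg_segments` object; surviving segments keep their
#'   original `segment_id` and relative order.
#' @export
balance_classes <- function(segs, seed = 1L) {
  stopifnot(inherits(segs, "emg_segments"))
  if (!length(segs$images)) stop_config("cannot balance an empty segment set")
  labels <- segs$meta$gesture
  target <- min(table(labels))
  keep <- with_seed(seed, {
    unlist(lapply(sort(unique(labels)), function(l) {
      idx <- which(labels == l)
      if (length(idx) > target) sort(sample(idx, target)) else idx
    }))
  })
  keep <- sort(keep)
  out <- segs
  out$images <- segs$images[keep]
  out$meta <- segs$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Flatten segments into a feature matrix
#'
#' Each `L x C` window becomes one row of length `L * C` (column-major,
#' i.e. channel blocks). Convenient as a raw feature space for the
#' cluster-quality metrics.
#'
#' @param segs an `emg_segments` object.
#' @return List with `features` (matrix, one row per window) and `labels`
#'   (gesture vector).
#' @export
flatten_segments <- function(segs) {
  if (!length(segs$images)) stop_config("no segments to flatten")
  list(features = t(vapply(segs$images, as.numeric,
                           numeric(segs$L * ncol(segs$images[[1]])))),
       labels = segs$meta$gesture)
}

#' Write / read a segment set as a directory of CSVs
#'
#' One CSV per window plus `segments.json` holding the metadata table and
#' the windowing configuration. Values are written with 17 significant
#' digits, so the round trip is lossless.
#'
#' @param segs an `emg_segments` object.
#' @param dir_path output directory.
#' @return `write_segments` returns the metadata path invisibly;
#'   `read_segments` returns an `emg_segments` object.
#' @export
write_segments <- function(segs, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(segs$images)) {
    m <- segs$images[[i]]
    txt <- apply(m, 2L, function(col) sprintf("%.17g", col))
    if (!is.matrix(txt)) txt <- matrix(txt, ncol = ncol(m))
    con <- file(file.path(dir_path, sprintf("segment_%06d.csv", i)), "w")
    writeLines(paste(paste0("ch", seq_len(ncol(m))), collapse = ","), con)
    writeLines(apply(txt, 1L, paste, collapse = ","), con)
    close(con)
  }
  meta_path <- file.path(dir_path, "segments.json")
  jsonlite::write_json(list(L = segs$L, tau = segs$tau, fs = segs$fs,
                            meta = segs$meta),
                       meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta_path)
}

#' @rdname write_segments
#' @export
read_segments <- function(dir_path) {
  meta_path <- file.path(dir_path, "segments.json")
  if (!file.exists(meta_path)) stop_io("segments.json not found in ", dir_path)
  info <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- nrow(info$meta)
  images <- lapply(seq_len(n), function(i) {
    m <- as.matrix(utils::read.csv(file.path(dir_path, sprintf("segment_%06d.csv", i)),
                                   check.names = FALSE))
    storage.mode(m) <- "double"
    m
  })
  structure(list(images = images, meta = as.data.frame(info$meta),
                 L = as.integer(info$L), tau = as.integer(info$tau),
                 fs = as.numeric(info$fs)),
            class = "emg_segments")
}
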
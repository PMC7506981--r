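#' Read a labelled sEMG dataset from a JSON manifest
#'
#' The on-disk layout is one CSV per recording (no index column, one row per
#' sample, one column per channel, header row = channel names) plus a JSON
#' manifest:
#'
#' ```
#' {"fs_hz": 100,
#'  "records": [{"path": "rec1.csv", "subject": "s1",
#'               "gesture": 0, "repetition": 1,
#'               "origin": "real", "lineage": []}, ...]}
#' ```
#'
#' `origin`/`lineage` are optional in the manifest (default real / empty).
#' Relative record paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest JSON.
#' @return An [emg_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_io("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (length(man$records) == 0L) return(emg_dataset())
  if (is.null(man$fs_hz) || is.na(man$fs_hz))
    stop_io("manifest is missing fs_hz: ", manifest_path)
  fs <- as.numeric(man$fs_hz)
  base <- dirname(normalizePath(manifest_path))
  recs <- lapply(man$records, function(entry) {
    path <- entry$path
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base, path)
    if (!file.exists(path)) stop_io("record file not found: ", path)
    if (!is.null(entry$fs_hz) && as.numeric(entry$fs_hz) != fs)
      stop_io("sampling-rate mismatch: manifest declares ", fs,
              " Hz but record '", entry$path, "' declares ",
              as.numeric(entry$fs_hz), " Hz")
    m <- as.matrix(utils::read.csv(path, check.names = FALSE))
    storage.mode(m) <- "double"
    lineage <- as.character(unlist(entry$lineage))
    emg_record(emg_signal(m, fs),
               subject = as.character(entry$subject),
               gesture = as.integer(entry$gesture),
               repetition = as.integer(entry$repetition),
               origin = if (is.null(entry$origin)) "real" else entry$origin,
               lineage = lineage)
  })
  emg_dataset(recs)
}

#' Write a labelled sEMG dataset to a directory
#'
#' Writes one CSV per record plus `manifest.json` in the format documented
#' in [read_dataset()]. Samples are written with 17 significant digits so a
#' write / read round trip reproduces double-precision values exactly.
#'
#' @param ds an [emg_dataset()].
#' @param dir_path output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n_records(ds))
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    fn <- sprintf("record_%04d.csv", i)
    m <- r$signal$samples
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(m)))
    txt <- apply(m, 2L, function(col) sprintf("%.17g", col))
    if (!is.matrix(txt)) txt <- matrix(txt, ncol = ncol(m))
    con <- file(file.path(dir_path, fn), "w")
    writeLines(paste(cn, collapse = ","), con)
    writeLines(apply(txt, 1L, paste, collapse = ","), con)
    close(con)
    entries[[i]] <- list(path = fn, subject = r$subject, gesture = r$gesture,
                         repetition = r$repetition, origin = r$origin,
                         lineage = as.list(r$lineage))
  }
  manifest <- file.path(dir_path, "manifest.json")
  jsonlite::write_json(list(fs_hz = ds$fs, records = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
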
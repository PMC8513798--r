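#' Multichannel recordings
#'
#' A `meg_recording` is a channels x samples matrix in native sensor units
#' (T for magnetometers, T/m for planar gradiometers) with a sampling rate,
#' channel names matching a [meg_sensor_array], and a provenance list that
#' accumulates every processing/generation step (parameters and seeds
#' included), so that any recording is reproducible from its provenance.
#'
#' @param data numeric matrix, channels x samples.
#' @param sfreq sampling frequency, Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param provenance list of provenance entries.
#' @return an object of class `meg_recording`.
#' @export
new_recording <- function(data, sfreq, channel_names,
                          provenance = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names)) {
    stop_megshield("data has ", nrow(data), " rows but ",
                   length(channel_names), " channel names were given")
  }
  if (!all(is.finite(data))) stop_megshield("recording contains non-finite values")
  if (sfreq <= 0) stop_megshield("sfreq must be positive")
  structure(list(data = data, sfreq = as.numeric(sfreq),
                 channel_names = as.character(channel_names),
                 provenance = provenance),
            class = "meg_recording")
}

n_samples <- function(rec) ncol(rec$data)

add_provenance <- function(rec, step, ...) {
  rec$provenance[[length(rec$provenance) + 1]] <- c(list(step = step),
                                                    list(...))
  rec
}

check_channels_match <- function(names_a, names_b, what = "recording") {
  if (length(names_a) != length(names_b)) {
    stop_megshield(what, " has ", length(names_b), " channels, expected ",
                   length(names_a))
  }
  bad <- which(names_a != names_b)
  if (length(bad)) {
    stop_megshield("channel order mismatch starting at '", names_b[bad[1]],
                   "' (expected '", names_a[bad[1]], "')")
  }
  invisible(TRUE)
}

#' @export
print.meg_recording <- function(x, ...) {
  cat("<meg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sfreq, " Hz (", signif(ncol(x$data) / x$sfreq, 4),
      " s)\n", sep = "")
  if (length(x$provenance)) {
    steps <- vapply(x$provenance, function(p) p$step, character(1))
    cat("  provenance:", paste(steps, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Plain-text recording container
#'
#' Serializes a [new_recording] as a pair of text files: `<path>` holds the
#' channels x samples matrix as headerless CSV (one row per channel) and
#' `<path>.json` holds the sampling rate, channel names and provenance.
#' Intended for small fixtures; large inputs are generated in code.
#'
#' @param rec a `meg_recording`; @param path CSV file path.
#' @return `read_recording_csv` returns a `meg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(sfreq = rec$sfreq,
                            channel_names = rec$channel_names,
                            provenance = rec$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(data) <- NULL
  new_recording(data, meta$sfreq, meta$channel_names,
                provenance = if (is.null(meta$provenance)) list() else
                  as.list(meta$provenance))
}
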
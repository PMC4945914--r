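#' Multichannel recording object
#'
#' A `recording` holds one subject's channels-by-samples matrix (in microvolts)
#' together with its sampling rate, channel labels, subject id and group label.
#'
#' @param data numeric matrix, channels in rows, samples in columns (uV).
#' @param fs_hz sampling rate in Hz.
#' @param channel_labels character vector, one per channel. Defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param subject_id subject identifier string.
#' @param group group label string (e.g. `"A"`/`"B"`); `"unknown"` if absent.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs_hz, channel_labels = NULL,
                      subject_id = "s01", group = "unknown") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_fc("`data` must be a numeric channels x samples matrix")
  }
  if (nrow(data) < 2) stop_fc("`data` must have at least 2 channels")
  if (anyNA(data)) stop_fc("`data` contains NA values")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0) {
    stop_fc("`fs_hz` must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop_fc("`channel_labels` length (%d) != number of channels (%d)",
            length(channel_labels), nrow(data))
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs_hz = fs_hz, channel_labels = channel_labels,
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> subject=%s group=%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs_hz,
    ncol(x$data) / x$fs_hz
  ))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
rec_duration_s <- function(rec) ncol(rec$data) / rec$fs_hz
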
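#' Write a recording as channels-by-samples CSV plus JSON sidecar
#'
#' The CSV holds the raw channels x samples matrix (no header); the sidecar
#' `<path>.json` records `fs_hz`, `channel_labels`, `subject_id` and
#' `group`. This plain-text pair is the package's canonical interchange
#' format and round-trips losslessly.
#'
#' @param rec a [recording()].
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  header <- list(fs_hz = rec$fs_hz, channel_labels = rec$channel_labels,
                 subject_id = rec$subject_id, group = rec$group)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_recording_csv <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_fc("missing JSON sidecar %s (fs_hz unknown)", side)
  header <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(header$fs_hz)) stop_fc("sidecar %s lacks fs_hz", side)
  dat <- tryCatch(
    as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
    error = function(e) stop_fc("malformed CSV %s: %s", path, conditionMessage(e)))
  storage.mode(dat) <- "double"
  recording(unname(dat), header$fs_hz,
            channel_labels = header$channel_labels,
            subject_id = header$subject_id %||% "s01",
            group = header$group %||% "unknown")
}

#' Read a multichannel recording
#'
#' Dispatches on the file extension: `.edf` files are parsed as European
#' Data Format continuous recordings, anything else as the CSV+JSON dialect
#' written by [write_recording_csv()].
#'
#' @param path input file.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fc("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") read_recording_edf(path) else read_recording_csv(path)
}

# --- minimal EDF (European Data Format) support ------------------------------
# Fixed-width ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian int16 samples, one contiguous block per signal.
# Continuous recordings with a common sampling rate only.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Minimal EDF writer: one data record per second, all channels at the
#' recording's sampling rate, 16-bit samples scaled over the observed
#' physical range. Quantization error is bounded by the physical range
#' divided by 2^16.
#'
#' @param rec a [recording()]; `fs_hz` must be a whole number.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stop_fc("EDF writer needs an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- n_channels(rec)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop_fc("recording shorter than one 1-s EDF data record")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  phys_min <- floor(min(data)); phys_max <- ceiling(max(data))
  if (phys_max == phys_min) phys_max <- phys_min + 1
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8)                                   # version
  wr(paste("X X X", rec$subject_id), 80)        # patient id
  wr(paste("Startdate X X X X group", rec$group), 80)  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)          # date, time
  wr(256 + 256 * ns, 8)                         # header bytes
  wr("", 44)                                    # reserved
  wr(n_rec, 8)                                  # number of data records
  wr("1", 8)                                    # record duration (s)
  wr(ns, 4)                                     # number of signals
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("synthetic EEG", 80)   # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)             # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)              # samples per record
  for (i in seq_len(ns)) wr("", 32)             # reserved
  for (r in seq_len(n_rec)) {
    block <- data[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    dig <- round((t(block) - phys_min) * scale) + dig_min
    writeBin(as.integer(as.vector(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                         # version
  patient <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                                  # date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_fc("malformed EDF header: signal count unreadable")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)                  # units
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(n_rec, dur, spr)) || length(unique(spr)) != 1) {
    stop_fc("malformed or unsupported EDF header (need one common sampling rate)")
  }
  fs <- spr[1] / dur
  seek(con, header_bytes)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      data[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  group <- if (grepl("group ", rec_id)) sub(".*group ", "", rec_id) else "unknown"
  subject <- {
    parts <- strsplit(patient, " +")[[1]]
    if (length(parts) >= 4) parts[4] else "s01"
  }
  recording(data, fs, channel_labels = labels, subject_id = subject, group = group)
}

#' Write a network report (and its configuration) to disk
#'
#' Deterministic file layout: `report.json` (the full report),
#' `config.json` / `config_hash.txt` (provenance), and one
#' `{estimator}_{binarizer}_{metric}.csv` summary table per cell. Refuses
#' to write into an existing directory unless `force = TRUE`.
#'
#' @param report a [assemble_report()] result.
#' @param outdir output directory.
#' @param config the run configuration list that produced the report.
#' @param force overwrite an existing directory.
#' @return `outdir`, invisibly.
#' @export
write_results <- function(report, outdir, config = list(), force = FALSE) {
  stopifnot(inherits(report, "network_report"))
  if (dir.exists(outdir)) {
    if (!force) stop_fc("output directory %s exists; use force = TRUE to overwrite", outdir)
  } else {
    dir.create(outdir, recursive = TRUE)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(cfg_json, file.path(outdir, "config.json"))
  writeLines(content_hash(cfg_json), file.path(outdir, "config_hash.txt"))
  jsonlite::write_json(
    list(alpha = report$alpha, p_adjust = report$p_adjust,
         groups = report$groups, n_subjects = report$n_subjects,
         n_epochs_used = as.list(report$n_epochs_used),
         cells = lapply(report$cells, function(cl) {
           list(estimator = cl$estimator, binarizer = cl$binarizer,
                metric = cl$metric, n_missing = cl$n_missing,
                summary = cl$summary)
         })),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  for (key in names(report$cells)) {
    utils::write.csv(report$cells[[key]]$summary,
                     file.path(outdir, paste0(key, ".csv")), row.names = FALSE)
  }
  invisible(outdir)
}

# Tiny deterministic content hash (djb2 over bytes, hex) for provenance
# stamps; not cryptographic.
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
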
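# Containers (recording, event stream, GPS track) and their plain-text
# serialization.  The recording container is a documented CSV dialect:
# '#'-prefixed key=value metadata lines (fs, t0, units) followed by a
# header of channel ids and one row per sample, values in microvolts.

#' Multichannel LFP recording container
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids character vector of unique channel labels (defaults
#'   to `ch1..chK`).
#' @param t0 session-relative start time of the first sample, in seconds.
#' @return object of class `"pac_recording"`.
#' @export
recording <- function(data, fs, channel_ids = NULL, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(data)))
  if (length(channel_ids) != ncol(data))
    stop("channel_ids length (", length(channel_ids),
         ") does not match channel count (", ncol(data), ")")
  if (anyDuplicated(channel_ids)) stop("channel_ids must be unique")
  colnames(data) <- channel_ids
  structure(list(data = data, fs = fs,
                 channel_ids = as.character(channel_ids), t0 = t0),
            class = "pac_recording")
}

#' @export
print.pac_recording <- function(x, ...) {
  cat("LFP recording:", nrow(x$data), "samples x", ncol(x$data),
      "channels @", x$fs, "Hz (", round(nrow(x$data) / x$fs, 2),
      "s, t0 =", x$t0, "s)\n")
  invisible(x)
}

#' Event stream: timestamped position labels
#'
#' @param df data.frame with columns `time_s` and `label` (extra columns
#'   such as `trial` and `path` are preserved).  Times must be strictly
#'   increasing.
#' @return object of class `"event_stream"` (a data.frame).
#' @export
event_stream <- function(df) {
  stopifnot(is.data.frame(df), all(c("time_s", "label") %in% names(df)))
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    stop("event times must be strictly increasing")
  df$label <- as.character(df$label)
  class(df) <- c("event_stream", "data.frame")
  df
}

#' GPS track: time-ordered fixes
#'
#' @param df data.frame with columns `time_s`, `lon`, `lat`, `speed`
#'   (speed in m/s).  Times must be strictly increasing and coordinates
#'   within range.
#' @return object of class `"gps_track"` (a data.frame).
#' @export
gps_track <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("time_s", "lon", "lat", "speed") %in% names(df)))
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    stop("fix times must be strictly increasing")
  if (any(abs(df$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(df$lon) > 180)) stop("longitude outside [-180, 180]")
  class(df) <- c("gps_track", "data.frame")
  df
}

#' Write / read a recording in the package's CSV dialect
#'
#' The on-disk format is plain text: comment lines `# key=value` carrying
#' `format`, `fs`, `t0` and `units`, then a CSV header of channel ids and
#' one row per sample.  Values are written with 9 significant digits
#' (beyond single precision).  A file without an `fs` line is rejected.
#' On read, any channel containing a contiguous NaN run longer than 1 s
#' triggers a warning and a logical `bad_mask` attribute marking the
#' masked samples.
#'
#' @param rec a [recording()].
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pac_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pacnav_recording=1",
               paste0("# fs=", format(rec$fs, digits = 12)),
               paste0("# t0=", format(rec$t0, digits = 12)),
               "# units=uV",
               paste(rec$channel_ids, collapse = ",")), con)
  utils::write.table(format(rec$data, digits = 9, trim = TRUE,
                            scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$fs))
    stop("recording file is missing the required 'fs' (sampling rate) field")
  fs <- as.numeric(meta$fs)
  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else 0
  df <- utils::read.csv(path, comment.char = "#", header = TRUE,
                        check.names = FALSE)
  data <- as.matrix(df)
  rec <- recording(data, fs = fs, channel_ids = colnames(df), t0 = t0)
  nn <- is.na(rec$data)
  if (any(nn)) {
    mask <- matrix(FALSE, nrow(rec$data), ncol(rec$data))
    long_run <- FALSE
    for (j in seq_len(ncol(rec$data))) {
      r <- rle(nn[, j])
      if (any(r$values & r$lengths > fs)) long_run <- TRUE
      mask[, j] <- nn[, j]
    }
    if (long_run)
      warning("NaN runs longer than 1 s found; samples masked in ",
              "attr(rec, 'bad_mask')")
    attr(rec, "bad_mask") <- mask
  }
  rec
}

#' Read / write GPS tracks as CSV
#'
#' CSV with header `time_s,lon,lat,speed`.  Rows must be strictly
#' increasing in time; a duplicated or decreasing timestamp is rejected
#' with the offending line number, and non-numeric fields are rejected
#' likewise (no silent coercion).
#'
#' @param path file path.
#' @param track a [gps_track()].
#' @return `read_gps_csv` returns a [gps_track()].
#' @export
read_gps_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("time_s", "lon", "lat", "speed")
  if (!all(need %in% names(df)))
    stop("GPS CSV must declare header columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), " missing")
  num <- suppressWarnings(lapply(df[need], as.numeric))
  for (col in need) {
    bad <- which(is.na(num[[col]]) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop("malformed '", col, "' value at line ", bad[1] + 1,
           ": '", df[[col]][bad[1]], "'")
    bad <- which(is.na(num[[col]]))
    if (length(bad))
      stop("missing '", col, "' value at line ", bad[1] + 1)
  }
  tm <- num$time_s
  if (length(tm) > 1) {
    viol <- which(diff(tm) <= 0)
    if (length(viol))
      stop("timestamps not strictly increasing at line ", viol[1] + 2,
           " (t = ", tm[viol[1] + 1], " follows t = ", tm[viol[1]], ")")
  }
  gps_track(data.frame(time_s = tm, lon = num$lon, lat = num$lat,
                       speed = num$speed))
}

#' @rdname read_gps_csv
#' @export
write_gps_csv <- function(track, path) {
  stopifnot(inherits(track, "gps_track"))
  df <- as.data.frame(track)[, c("time_s", "lon", "lat", "speed")]
  df$lon <- format(df$lon, digits = 12, trim = TRUE)
  df$lat <- format(df$lat, digits = 12, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write event streams as CSV
#'
#' CSV with header `time_s,label` (extra columns preserved).  Times must
#' be strictly increasing; violations are reported with line numbers.
#'
#' @param path file path.
#' @param ev an [event_stream()].
#' @return `read_events_csv` returns an [event_stream()].
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "label") %in% names(df)))
    stop("events CSV must declare header columns time_s,label")
  tm <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(tm))
  if (length(bad)) stop("malformed time_s at line ", bad[1] + 1)
  if (length(tm) > 1) {
    viol <- which(diff(tm) <= 0)
    if (length(viol))
      stop("event times not strictly increasing at line ", viol[1] + 2,
           " (t = ", tm[viol[1] + 1], ")")
  }
  df$time_s <- tm
  event_stream(df)
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(ev, path) {
  stopifnot(inherits(ev, "event_stream"))
  utils::write.csv(as.data.frame(ev), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export / import a comodulogram as a CSV matrix
#'
#' Phase-frequency centers run across the columns and amplitude-frequency
#' centers down the rows; the first column (`fa_hz`) holds the amplitude
#' centers and the header row the phase centers.
#'
#' @param cm a [comodulogram()].
#' @param path file path.
#' @export
write_comodulogram_csv <- function(cm, path) {
  stopifnot(inherits(cm, "comodulogram"))
  m <- t(cm$mi)  # rows = amplitude frequencies
  df <- data.frame(fa_hz = cm$amp_freqs, m, check.names = FALSE)
  colnames(df) <- c("fa_hz", cm$phase_freqs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comodulogram_csv
#' @export
read_comodulogram_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  amp <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  phase <- as.numeric(colnames(m))
  structure(list(mi = t(unname(m)), phase_freqs = phase, amp_freqs = amp,
                 phase_halfbw = NA, amp_halfbw = NA),
            class = "comodulogram")
}
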
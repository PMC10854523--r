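# Behavioural segmentation: event-locked maze epochs, GPS flight phases,
# speed series, bad-channel detection, and trajectory similarity.

#' Haversine distance in meters
#'
#' Great-circle distance on a sphere of radius 6371 km (mean Earth
#' radius), via [geosphere::distHaversine()].
#'
#' @param p1,p2 `(lon, lat)` numeric pairs, or two-column matrices.
#' @return distance(s) in meters.
#' @export
haversine_m <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371000)
}

#' Extract event-locked maze epochs
#'
#' One 1000 ms epoch per beam-crossing event, from 250 ms before first
#' detector contact to 750 ms after.  Only the first contact per detector
#' per trial is used (repeat crossings within a trial are ignored); events
#' whose window would be truncated by the recording edges are dropped with
#' a message.
#'
#' @param rec a [recording()].
#' @param ev an [event_stream()]; a `trial` column scopes the
#'   first-contact rule (without one, all events are treated as one
#'   trial), and a `path` column is carried through.
#' @return an `"epoch_set"`: list with `epochs` (list of samples x
#'   channels matrices), `info` (data.frame `trial_id`, `label`,
#'   `start_s`, `path_id`), and `fs`.
#' @export
extract_maze_epochs <- function(rec, ev) {
  stopifnot(inherits(rec, "pac_recording"), inherits(ev, "event_stream"))
  df <- as.data.frame(ev)
  if (is.null(df$trial)) df$trial <- 1L
  if (is.null(df$path)) df$path <- 1L
  first <- !duplicated(df[, c("trial", "label")])
  n_rep <- sum(!first)
  if (n_rep) message(n_rep, " repeat detector contact(s) ignored")
  df <- df[first, , drop = FALSE]
  n <- nrow(rec$data)
  epochs <- list(); keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    i0 <- round((df$time_s[i] - rec$t0 - 0.25) * rec$fs) + 1
    i1 <- i0 + round(rec$fs) - 1
    if (i0 < 1 || i1 > n) {
      message("event at t = ", df$time_s[i],
              " s dropped: window outside recording")
      next
    }
    keep[i] <- TRUE
    epochs[[length(epochs) + 1]] <- rec$data[i0:i1, , drop = FALSE]
  }
  info <- data.frame(trial_id = df$trial[keep], label = df$label[keep],
                     start_s = df$time_s[keep] - 0.25,
                     path_id = df$path[keep])
  structure(list(epochs = epochs, info = info, fs = rec$fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set:", length(x$epochs), "epochs of",
      round(1000 * nrow(x$epochs[[1]]) / x$fs), "ms @", x$fs, "Hz\n")
  print(table(x$info$label))
  invisible(x)
}

#' Maze running speed from consecutive detector crossings
#'
#' Speed over each consecutive detector pair within a trial: the
#' detector-to-detector path distance divided by the crossing interval.
#'
#' @param ev an [event_stream()] (a `trial` column scopes consecutive
#'   pairs).
#' @param geom maze geometry: data.frame with columns `from`, `to`,
#'   `distance_m` giving positive path distances between detectors
#'   (treated as symmetric).
#' @return data.frame with `trial`, `from`, `to`, `dt_s`, `speed_mps`.
#' @export
maze_speed <- function(ev, geom) {
  stopifnot(inherits(ev, "event_stream"), is.data.frame(geom),
            all(c("from", "to", "distance_m") %in% names(geom)))
  if (any(geom$distance_m <= 0)) stop("geometry distances must be positive")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  dist_lookup <- stats::setNames(geom$distance_m, key(geom$from, geom$to))
  df <- as.data.frame(ev)
  if (is.null(df$trial)) df$trial <- 1L
  out <- NULL
  for (tr in unique(df$trial)) {
    d <- df[df$trial == tr, , drop = FALSE]
    if (nrow(d) < 2) next
    for (i in seq_len(nrow(d) - 1)) {
      dt <- d$time_s[i + 1] - d$time_s[i]
      if (dt <= 0) stop("non-positive crossing interval between ",
                        d$label[i], " and ", d$label[i + 1])
      k <- key(d$label[i], d$label[i + 1])
      if (!k %in% names(dist_lookup))
        stop("no geometry distance for detector pair ", d$label[i], " -> ",
             d$label[i + 1])
      out <- rbind(out, data.frame(trial = tr, from = d$label[i],
                                   to = d$label[i + 1], dt_s = dt,
                                   speed_mps = dist_lookup[[k]] / dt))
    }
  }
  if (is.null(out)) out <- data.frame(trial = integer(), from = character(),
                                      to = character(), dt_s = numeric(),
                                      speed_mps = numeric())
  rownames(out) <- NULL
  out
}

#' Label flight phases along a GPS track
#'
#' Each fix gets exactly one of three labels: `DM` (decision-making,
#' within `r_dm` of the release site), `LN` (local navigation, within
#' `r_ln` of the loft), or `ER` (en route, everything between).  If a fix
#' falls inside both radii (only possible for short release-loft
#' separations), temporal precedence decides: `DM` before the first
#' en-route fix, `LN` after it.
#'
#' @param track a [gps_track()].
#' @param release,loft `(lon, lat)` pairs in degrees.
#' @param r_dm radius (m) around the release site (default 300).
#' @param r_ln radius (m) around the loft (default 200).
#' @return character vector of labels, one per fix.
#' @export
label_flight_phases <- function(track, release, loft, r_dm = 300,
                                r_ln = 200) {
  stopifnot(inherits(track, "gps_track"), nrow(track) > 0)
  pts <- cbind(track$lon, track$lat)
  d_rel <- haversine_m(pts, release)
  d_loft <- haversine_m(pts, loft)
  in_dm <- d_rel < r_dm
  in_ln <- d_loft < r_ln
  lab <- character(nrow(track))
  seen_er <- FALSE
  for (i in seq_len(nrow(track))) {
    lab[i] <- if (in_dm[i] && in_ln[i]) { if (seen_er) "LN" else "DM" }
      else if (in_dm[i]) "DM"
      else if (in_ln[i]) "LN"
      else { seen_er <- TRUE; "ER" }
  }
  lab
}

#' Extract 1000 ms flight epochs labeled by phase
#'
#' Slices the recording into consecutive non-overlapping 1 s windows
#' (shared time base with the GPS) and labels each window with the flight
#' phase of its fixes; windows that straddle a phase boundary (mixed fix
#' labels) are dropped.
#'
#' @param rec a [recording()].
#' @param track a [gps_track()] on the same time base.
#' @param labels per-fix labels from [label_flight_phases()].
#' @param path_id path identifier stored with every epoch (default 1).
#' @return an `"epoch_set"` (see [extract_maze_epochs()]).
#' @export
extract_flight_epochs <- function(rec, track, labels, path_id = 1L) {
  stopifnot(inherits(rec, "pac_recording"), inherits(track, "gps_track"),
            length(labels) == nrow(track))
  dur <- nrow(rec$data) / rec$fs
  n_win <- floor(dur)
  epochs <- list(); info <- NULL
  for (k in seq_len(n_win)) {
    w0 <- rec$t0 + (k - 1)
    sel <- track$time_s >= w0 & track$time_s < w0 + 1
    if (!any(sel)) next
    labs <- unique(labels[sel])
    if (length(labs) != 1) next  # straddles a phase boundary
    i0 <- round((k - 1) * rec$fs) + 1
    epochs[[length(epochs) + 1]] <- rec$data[i0:(i0 + round(rec$fs) - 1),
                                             , drop = FALSE]
    info <- rbind(info, data.frame(trial_id = k, label = labs,
                                   start_s = w0, path_id = path_id))
  }
  if (is.null(info)) info <- data.frame(trial_id = integer(),
                                        label = character(),
                                        start_s = numeric(),
                                        path_id = integer())
  structure(list(epochs = epochs, info = info, fs = rec$fs),
            class = "epoch_set")
}

#' Flag undesirable channels
#'
#' A channel is flagged bad if more than `flat_frac` of its consecutive
#' sample differences are exactly zero (flatline: dropped connection), or
#' if its robust standard deviation (MAD) exceeds `sd_factor` times the
#' median robust SD across channels (motion/connection artifacts).
#'
#' @param rec a [recording()] with at least 1 s of data.
#' @param flat_frac flatline fraction threshold (default 0.1).
#' @param sd_factor robust-SD ratio threshold (default 5).
#' @return logical vector, `TRUE` for bad channels (named by channel id).
#' @export
detect_bad_channels <- function(rec, flat_frac = 0.1, sd_factor = 5) {
  stopifnot(inherits(rec, "pac_recording"))
  if (nrow(rec$data) < rec$fs) stop("need at least 1 s of data")
  flat <- apply(rec$data, 2, function(x) mean(diff(x) == 0))
  rsd <- apply(rec$data, 2, stats::mad)
  med <- stats::median(rsd)
  bad <- flat > flat_frac | (med > 0 & rsd > sd_factor * med)
  names(bad) <- rec$channel_ids
  if (all(bad)) stop("all channels flagged bad")
  bad
}

#' Per-second flight speed series
#'
#' Mean of the GPS-reported fix speeds in each consecutive 1 s window
#' (about 10 fixes per window at 10 Hz); windows without fixes are
#' omitted.
#'
#' @param track a [gps_track()] with at least 10 fixes.
#' @return data.frame with `window_start_s` and `speed_mps`.
#' @export
flight_speed <- function(track) {
  stopifnot(inherits(track, "gps_track"))
  if (nrow(track) < 10) stop("need at least 10 fixes")
  w <- floor(track$time_s - track$time_s[1])
  agg <- tapply(track$speed, w, mean)
  data.frame(window_start_s = as.numeric(names(agg)) + track$time_s[1],
             speed_mps = as.numeric(agg), row.names = NULL)
}

#' Distance between two flight trajectories
#'
#' Symmetric mean nearest-neighbour haversine distance: for each fix of
#' one track, the distance to the nearest fix of the other, averaged over
#' both directions.  Two tracks closer than `threshold_m` are classified
#' as the same path (trained pigeons fly corridors of roughly 100-200 m).
#'
#' @param track_a,track_b [gps_track()] objects.
#' @param threshold_m same-path threshold in meters (default 200).
#' @return list with `distance_m` and logical `same_path`.
#' @export
path_distance <- function(track_a, track_b, threshold_m = 200) {
  stopifnot(inherits(track_a, "gps_track"), inherits(track_b, "gps_track"),
            nrow(track_a) > 0, nrow(track_b) > 0)
  pa <- cbind(track_a$lon, track_a$lat)
  pb <- cbind(track_b$lon, track_b$lat)
  D <- geosphere::distm(pa, pb,
                        fun = function(p, q) haversine_m(p, q))
  d_ab <- mean(apply(D, 1, min))
  d_ba <- mean(apply(D, 2, min))
  d <- (d_ab + d_ba) / 2
  list(distance_m = d, same_path = d < threshold_m)
}
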
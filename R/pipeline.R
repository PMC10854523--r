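# End-to-end analyses for the two study arms: ground-maze sessions
# (event-locked epochs, position-wise PAC statistics) and homing flights
# (GPS-phase epochs, ER/LN contrasts, speed correlations).

#' Analysis configuration for a maze session
#'
#' Bands follow the maze findings: theta phase 3-6 Hz modulating
#' high-frequency oscillations 140-180 Hz.
#'
#' @param theta_band,amp_band length-2 numeric bands in Hz.
#' @param goal goal position label (excluded from "navigation").
#' @param standard_position position whose mean distribution serves as
#'   the session standard (`NULL`: first non-goal position encountered).
#' @param standard_path path id for the standard distribution (`NULL`:
#'   lowest path id).
#' @param n_bins phase bins (default 18).
#' @param peak_threshold_sd envelope-peak threshold for the circular
#'   analysis (default 2).
#' @param corr_method correlation type for distribution similarity.
#' @param n_surrogates circular-shift surrogates per session (0 = off).
#' @param seed integer seed for any stochastic step (surrogates).
#' @return a `"maze_config"` list.
#' @export
maze_config <- function(theta_band = c(3, 6), amp_band = c(140, 180),
                        goal = "G1", standard_position = NULL,
                        standard_path = NULL, n_bins = 18,
                        peak_threshold_sd = 2,
                        corr_method = "pearson", n_surrogates = 0,
                        seed = 1) {
  structure(list(theta_band = theta_band, amp_band = amp_band, goal = goal,
                 standard_position = standard_position,
                 standard_path = standard_path, n_bins = n_bins,
                 peak_threshold_sd = peak_threshold_sd,
                 corr_method = corr_method, n_surrogates = n_surrogates,
                 seed = seed),
            class = "maze_config")
}

#' Analysis configuration for flight sessions
#'
#' Bands follow the flight findings: theta phase 5-10 Hz modulating the
#' beta2 band 20-30 Hz.  Decision-making (DM) epochs are labeled but
#' excluded from statistics by default.
#'
#' @param theta_band,amp_band length-2 numeric bands in Hz.
#' @param r_dm,r_ln phase radii in meters (defaults 300 and 200).
#' @param include_dm include DM epochs in the statistics (default FALSE).
#' @param path_threshold_m same-path trajectory threshold (default 200).
#' @inheritParams maze_config
#' @return a `"flight_config"` list.
#' @export
flight_config <- function(theta_band = c(5, 10), amp_band = c(20, 30),
                          r_dm = 300, r_ln = 200, include_dm = FALSE,
                          path_threshold_m = 200, n_bins = 18,
                          peak_threshold_sd = 2,
                          corr_method = "pearson", n_surrogates = 0,
                          seed = 1) {
  structure(list(theta_band = theta_band, amp_band = amp_band,
                 r_dm = r_dm, r_ln = r_ln, include_dm = include_dm,
                 path_threshold_m = path_threshold_m, n_bins = n_bins,
                 peak_threshold_sd = peak_threshold_sd,
                 corr_method = corr_method, n_surrogates = n_surrogates,
                 seed = seed),
            class = "flight_config")
}

# continuous phase and amplitude series for one channel
band_series <- function(x, fs, theta_band, amp_band) {
  list(phase = extract_phase(bandpass(x, theta_band[1], theta_band[2], fs)),
       amp = extract_amplitude(bandpass(x, amp_band[1], amp_band[2], fs)))
}

# per-epoch distributions/MI from continuous series (no per-epoch filter
# edges, so no trim inside epochs)
epoch_pac_table <- function(series, info, fs, n_bins) {
  Ps <- vector("list", nrow(info))
  mi <- numeric(nrow(info))
  for (i in seq_len(nrow(info))) {
    i0 <- round(info$start_rel_s[i] * fs) + 1
    idx <- i0:(i0 + round(fs) - 1)
    Ps[[i]] <- phase_amplitude_distribution(series$phase[idx],
                                            series$amp[idx], n_bins)
    mi[i] <- modulation_index(Ps[[i]])
  }
  list(Ps = Ps, mi = mi)
}

#' Run the complete maze-arm analysis
#'
#' From a multichannel recording and a beam-crossing event stream to the
#' per-epoch PAC table and the position/path statistics: bad channels are
#' masked, the channel with the highest mean epoch MI in the configured
#' band pair is selected, per-epoch phase-amplitude distributions and
#' modulation indices are computed (theta and amplitude bands filtered
#' once over the continuous recording, then sliced per epoch), each
#' epoch's distribution is correlated with the session-standard
#' distribution (mean distribution at the standard position on the
#' standard path), positions are compared with Kruskal-Wallis + Dunn, and
#' theta phases at fast-envelope peaks (navigation epochs) are summarized
#' circularly.  Deterministic given the config seed.
#'
#' @param rec a [recording()].
#' @param events an [event_stream()].
#' @param config a [maze_config()].
#' @param comodulograms compute per-position mean comodulograms (slower;
#'   default FALSE).
#' @param phase_freqs,amp_freqs comodulogram grids (defaults per
#'   [default_comodulogram_grid()]).
#' @return list of class `"maze_analysis"`: `epoch_table` (data.frame
#'   `trial_id`, `label`, `path_id`, `start_s`, `mi`, `corr`),
#'   `distributions` (per-epoch P matrix, rows = epochs),
#'   `standard` (the standard `"pa_distribution"`), `tests` (list:
#'   `positions_mi`, `positions_corr`, and `paths_mi`/`paths_corr` when
#'   more than one path is present), `circular` (a
#'   [circular_summary()]), `surrogate` (when configured), `best_channel`,
#'   `bad_channels`, `comodulograms`, `config`.
#' @export
run_maze_analysis <- function(rec, events, config = maze_config(),
                              comodulograms = FALSE,
                              phase_freqs = default_comodulogram_grid()$phase_freqs,
                              amp_freqs = default_comodulogram_grid()$amp_freqs) {
  stopifnot(inherits(rec, "pac_recording"), inherits(events, "event_stream"),
            inherits(config, "maze_config"))
  es <- extract_maze_epochs(rec, events)
  if (!length(es$epochs)) stop("segmentation stage: no usable epochs")
  info <- es$info
  info$start_rel_s <- info$start_s - rec$t0

  bad <- if (ncol(rec$data) > 1) detect_bad_channels(rec)
         else stats::setNames(FALSE, rec$channel_ids)
  good <- which(!bad)
  # channel selection: mean per-epoch MI in the configured band pair
  per_channel <- lapply(good, function(ch) {
    s <- band_series(rec$data[, ch], rec$fs, config$theta_band,
                     config$amp_band)
    epoch_pac_table(s, info, rec$fs, config$n_bins)
  })
  mi_means <- vapply(per_channel, function(z) mean(z$mi), numeric(1))
  names(mi_means) <- rec$channel_ids[good]
  best_id <- select_best_channel(cbind(mi_means))
  best <- which(names(mi_means) == best_id)
  pac <- per_channel[[best]]

  nav_labels <- setdiff(unique(info$label), config$goal)
  std_pos <- config$standard_position %||% nav_labels[1]
  std_path <- config$standard_path %||% min(info$path_id)
  std_sel <- info$label == std_pos & info$path_id == std_path
  if (!any(std_sel))
    stop("no epochs at standard position ", std_pos, " on path ", std_path)
  standard <- standard_distribution(pac$Ps[std_sel])
  corr <- vapply(pac$Ps, distribution_correlation, numeric(1),
                 P_standard = standard, method = config$corr_method)

  epoch_table <- data.frame(trial_id = info$trial_id, label = info$label,
                            path_id = info$path_id, start_s = info$start_s,
                            mi = pac$mi, corr = corr)

  tests <- list()
  if (length(unique(info$label)) >= 3) {
    tests$positions_mi <- kruskal_wallis_dunn(split(pac$mi, info$label))
    tests$positions_corr <- kruskal_wallis_dunn(split(corr, info$label))
  } else if (length(unique(info$label)) == 2) {
    sp <- split(pac$mi, info$label)
    tests$positions_mi <- mann_whitney(sp[[1]], sp[[2]])
    sp <- split(corr, info$label)
    tests$positions_corr <- mann_whitney(sp[[1]], sp[[2]])
  }
  at_std <- info$label == std_pos
  n_paths <- length(unique(info$path_id[at_std]))
  if (n_paths >= 3) {
    tests$paths_mi <- kruskal_wallis_dunn(split(pac$mi[at_std],
                                                info$path_id[at_std]))
    tests$paths_corr <- kruskal_wallis_dunn(split(corr[at_std],
                                                  info$path_id[at_std]))
  } else if (n_paths == 2) {
    sp <- split(pac$mi[at_std], info$path_id[at_std])
    tests$paths_mi <- mann_whitney(sp[[1]], sp[[2]])
    sp <- split(corr[at_std], info$path_id[at_std])
    tests$paths_corr <- mann_whitney(sp[[1]], sp[[2]])
  }

  # theta phase at fast-envelope peaks, pooled over navigation epochs
  s_best <- band_series(rec$data[, good[best]], rec$fs, config$theta_band,
                        config$amp_band)
  nav_idx <- unlist(lapply(which(info$label != config$goal), function(i) {
    i0 <- round(info$start_rel_s[i] * rec$fs) + 1
    i0:(i0 + round(rec$fs) - 1)
  }))
  angles <- phases_at_hf_peaks(s_best$phase[nav_idx], s_best$amp[nav_idx],
                               config$peak_threshold_sd)
  circ <- circular_summary(angles)

  surrogate <- NULL
  if (config$n_surrogates > 0)
    surrogate <- surrogate_mi_null(s_best$phase[nav_idx],
                                   s_best$amp[nav_idx], rec$fs,
                                   n_surrogates = config$n_surrogates,
                                   seed = config$seed)

  cms <- NULL
  if (comodulograms) {
    cms <- lapply(split(seq_len(nrow(info)), info$label), function(rows) {
      mean_comodulogram(es$epochs[rows], rec$fs, good[best],
                        phase_freqs, amp_freqs)
    })
  }

  structure(list(epoch_table = epoch_table,
                 distributions = do.call(rbind, lapply(pac$Ps, `[[`, "p")),
                 standard = standard, tests = tests, circular = circ,
                 surrogate = surrogate,
                 best_channel = best_id, bad_channels = bad,
                 comodulograms = cms, config = config),
            class = "maze_analysis")
}

# mean comodulogram across epochs (MI per cell per epoch, then averaged)
mean_comodulogram <- function(epochs, fs, channel, phase_freqs, amp_freqs) {
  acc <- NULL; nacc <- 0
  for (e in epochs) {
    cm <- comodulogram(e[, channel], fs, phase_freqs, amp_freqs)
    if (is.null(acc)) acc <- cm$mi * 0
    acc <- acc + cm$mi
    nacc <- nacc + 1
  }
  cm$mi <- acc / nacc
  cm
}

#' Run the complete flight-arm analysis
#'
#' From one or more synchronized recording/GPS pairs to phase-labeled
#' epochs and the ER/LN and path statistics: each track is labeled
#' DM/ER/LN (a track that never leaves the DM radius is an error),
#' non-overlapping 1 s epochs are labeled and (by default) DM epochs are
#' excluded, per-epoch distributions, modulation indices and
#' correlations against the session standard (mean ER distribution on
#' the first path) are computed, ER vs LN is compared with Mann-Whitney
#' on the correlation, paths are compared on ER modulation indices, and
#' per-second GPS speed is correlated (Spearman) with epoch MI and epoch
#' theta power.
#'
#' @param flights a single `list(recording =, track =)` or a list of
#'   such lists, each optionally carrying `path` (integer id).
#' @param release,loft `(lon, lat)` pairs in degrees.
#' @param config a [flight_config()].
#' @param comodulograms compute mean ER and LN comodulograms (slower).
#' @param phase_freqs,amp_freqs comodulogram grids.
#' @return list of class `"flight_analysis"`: `epoch_table` (`path_id`,
#'   `label`, `start_s`, `mi`, `corr`, `speed_mps`, `theta_power`),
#'   `distributions` (per-epoch P matrix in time order, the
#'   amplitude-vs-phase heatmap), `standard`, `tests` (`er_vs_ln_corr`,
#'   `er_vs_ln_mi`, `paths_mi` when two paths, `speed_mi`,
#'   `speed_theta_power`), `circular`, `comodulograms`, `config`.
#' @export
run_flight_analysis <- function(flights, release, loft,
                                config = flight_config(),
                                comodulograms = FALSE,
                                phase_freqs = default_comodulogram_grid()$phase_freqs,
                                amp_freqs = default_comodulogram_grid()$amp_freqs) {
  stopifnot(inherits(config, "flight_config"))
  if (!is.null(flights$recording)) flights <- list(flights)
  tables <- list(); Ps_all <- list(); angle_pool <- numeric(0)
  epochs_by_label <- list(ER = list(), LN = list())
  for (k in seq_along(flights)) {
    fl <- flights[[k]]
    rec <- fl$recording; track <- fl$track
    stopifnot(inherits(rec, "pac_recording"), inherits(track, "gps_track"))
    path_id <- fl$path %||% k
    labels <- label_flight_phases(track, release, loft, config$r_dm,
                                  config$r_ln)
    if (all(labels == "DM"))
      stop("flight ", k, " never leaves the ", config$r_dm,
           " m decision-making radius: no en-route data")
    es <- extract_flight_epochs(rec, track, labels, path_id)
    info <- es$info
    info$start_rel_s <- info$start_s - rec$t0
    if (!config$include_dm) {
      keep <- info$label != "DM"
      es$epochs <- es$epochs[keep]; info <- info[keep, , drop = FALSE]
    }
    if (!nrow(info)) next
    bad <- if (ncol(rec$data) > 1) detect_bad_channels(rec)
           else stats::setNames(FALSE, rec$channel_ids)
    good <- which(!bad)
    per_channel <- lapply(good, function(ch) {
      s <- band_series(rec$data[, ch], rec$fs, config$theta_band,
                       config$amp_band)
      list(series = s,
           pac = epoch_pac_table(s, info, rec$fs, config$n_bins))
    })
    mi_means <- vapply(per_channel, function(z) mean(z$pac$mi), numeric(1))
    names(mi_means) <- rec$channel_ids[good]
    best_id <- select_best_channel(cbind(mi_means))
    best <- which(names(mi_means) == best_id)
    pac <- per_channel[[best]]$pac
    series <- per_channel[[best]]$series

    # per-epoch theta power and GPS speed
    theta_pow <- vapply(seq_len(nrow(info)), function(i) {
      i0 <- round(info$start_rel_s[i] * rec$fs) + 1
      seg <- rec$data[i0:(i0 + round(rec$fs) - 1), good[best]]
      band_power(psd_welch(seg, rec$fs, window_s = 1), config$theta_band)
    }, numeric(1))
    sp <- flight_speed(track)
    speed <- sp$speed_mps[match(floor(info$start_s),
                                floor(sp$window_start_s))]

    er_idx <- unlist(lapply(which(info$label == "ER"), function(i) {
      i0 <- round(info$start_rel_s[i] * rec$fs) + 1
      i0:(i0 + round(rec$fs) - 1)
    }))
    if (length(er_idx))
      angle_pool <- c(angle_pool,
                      phases_at_hf_peaks(series$phase[er_idx],
                                         series$amp[er_idx],
                                         config$peak_threshold_sd))

    tables[[k]] <- data.frame(flight = k, path_id = info$path_id,
                              label = info$label, start_s = info$start_s,
                              mi = pac$mi, theta_power = theta_pow,
                              speed_mps = speed)
    Ps_all[[k]] <- pac$Ps
    for (lab in c("ER", "LN")) {
      rows <- which(info$label == lab)
      if (length(rows))
        epochs_by_label[[lab]] <- c(epochs_by_label[[lab]],
                                    lapply(es$epochs[rows], function(e)
                                      e[, good[best], drop = FALSE]))
    }
  }
  tab <- do.call(rbind, tables)
  Ps <- do.call(c, Ps_all)
  if (is.null(tab) || !nrow(tab)) stop("no usable flight epochs")

  std_sel <- tab$label == "ER" & tab$path_id == min(tab$path_id)
  if (!any(std_sel)) stop("no ER epochs on the standard path")
  standard <- standard_distribution(Ps[std_sel])
  tab$corr <- vapply(Ps, distribution_correlation, numeric(1),
                     P_standard = standard, method = config$corr_method)

  tests <- list()
  if (all(c("ER", "LN") %in% tab$label)) {
    tests$er_vs_ln_corr <- mann_whitney(tab$corr[tab$label == "ER"],
                                        tab$corr[tab$label == "LN"])
    tests$er_vs_ln_mi <- mann_whitney(tab$mi[tab$label == "ER"],
                                      tab$mi[tab$label == "LN"])
  }
  er <- tab$label == "ER"
  if (length(unique(tab$path_id[er])) == 2) {
    sp2 <- split(tab$mi[er], tab$path_id[er])
    tests$paths_mi <- mann_whitney(sp2[[1]], sp2[[2]])
  }
  ok <- er & is.finite(tab$speed_mps)
  if (sum(ok) >= 3) {
    tests$speed_mi <- spearman_cor(tab$speed_mps[ok], tab$mi[ok])
    tests$speed_theta_power <- spearman_cor(tab$speed_mps[ok],
                                            tab$theta_power[ok])
  }

  cms <- NULL
  if (comodulograms) {
    fs <- flights[[1]]$recording$fs
    cms <- lapply(epochs_by_label[lengths(epochs_by_label) > 0],
                  function(eps) mean_comodulogram(eps, fs, 1,
                                                  phase_freqs, amp_freqs))
  }

  structure(list(epoch_table = tab,
                 distributions = do.call(rbind, lapply(Ps, `[[`, "p")),
                 standard = standard, tests = tests,
                 circular = circular_summary(angle_pool),
                 comodulograms = cms, config = config),
            class = "flight_analysis")
}

config_hash <- function(config) {
  f <- tempfile()
  writeLines(deparse(unclass(config)), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Export analysis results as CSV tables
#'
#' Writes the canonical outputs of [run_maze_analysis()] /
#' [run_flight_analysis()] to a directory: `epoch_table.csv`,
#' `distributions.csv` (per-epoch bin masses), `tests.csv` (one row per
#' test), and `circular.csv`.  Every file starts with a comment line
#' carrying the MD5 hash of the analysis configuration, so outputs are
#' traceable to their parameters.
#'
#' @param res a `"maze_analysis"` or `"flight_analysis"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_results <- function(res, dir) {
  stopifnot(inherits(res, c("maze_analysis", "flight_analysis")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(res$config)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  paths <- c(emit(res$epoch_table, "epoch_table.csv"),
             emit(as.data.frame(res$distributions), "distributions.csv"))
  trows <- lapply(names(res$tests), function(nm) {
    t <- res$tests[[nm]]
    data.frame(test = nm,
               statistic = if (!is.null(t$statistic)) t$statistic else t$rho,
               z = if (!is.null(t$z)) t$z else NA,
               df = if (!is.null(t$df)) t$df else NA,
               p = t$p)
  })
  if (length(trows))
    paths <- c(paths, emit(do.call(rbind, trows), "tests.csv"))
  ci <- res$circular
  paths <- c(paths, emit(data.frame(n = ci$n, avg_ang_deg = ci$avg_ang * 180 / pi,
                                    r = ci$r,
                                    ci_lo_deg = ci$ci95[["lo"]] * 180 / pi,
                                    ci_hi_deg = ci$ci95[["hi"]] * 180 / pi,
                                    rayleigh_z = ci$rayleigh_z,
                                    rayleigh_p = ci$rayleigh_p),
                         "circular.csv"))
  invisible(paths)
}
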
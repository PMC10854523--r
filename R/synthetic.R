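# Synthetic LFP, maze-session, and homing-flight generators.  Every
# stochastic generator requires an explicit seed; unseeded calls error.

#' Configuration for a simulated phase-amplitude coupled LFP
#'
#' Parameters of the generative model used by [simulate_pac_signal()]:
#' a theta-band carrier whose instantaneous phase modulates the envelope
#' of a fast carrier with a raised-cosine law of controllable depth,
#' plus additive white Gaussian noise.  Default amplitudes (theta 50 uV,
#' fast 10 uV, noise 15 uV) are plausible values for hippocampal LFP
#' recordings.
#'
#' @param fs sampling rate in Hz (must exceed `2 * f_A`).
#' @param duration signal length in seconds.
#' @param f_p phase (slow) frequency in Hz.
#' @param f_A amplitude (fast) frequency in Hz.
#' @param depth coupling depth in `[0, 1]`; 0 = no coupling, 1 = the fast
#'   envelope goes to zero at the anti-preferred phase.
#' @param preferred_phase theta phase (radians, analytic-signal
#'   convention: 0 = theta positive peak) at which the fast envelope is
#'   maximal.
#' @param theta_amp,hf_amp,noise_sd amplitudes in microvolts.
#' @param hf_carrier `"sine"` (default; pure tone at `f_A`) or `"noise"`
#'   (narrowband noise of bandwidth `hf_bw` centered on `f_A`, emulating
#'   a broadband fast rhythm whose modulation sidebands stay inside the
#'   analysis band even for narrow bands such as beta2).
#' @param hf_bw carrier bandwidth in Hz for `hf_carrier = "noise"`.
#' @param seed integer seed (mandatory whenever the generator draws
#'   random numbers, i.e. `noise_sd > 0` or `hf_carrier = "noise"`).
#' @return a `"pac_sim_config"` list.
#' @export
pac_sim_config <- function(fs = 2000, duration = 10, f_p = 6, f_A = 150,
                           depth = 0.9, preferred_phase = 0,
                           theta_amp = 50, hf_amp = 10, noise_sd = 15,
                           hf_carrier = c("sine", "noise"), hf_bw = 8,
                           seed = NULL) {
  hf_carrier <- match.arg(hf_carrier)
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  if (fs <= 2 * f_A)
    stop("fs = ", fs, " Hz aliases f_A = ", f_A, " Hz: need fs > 2 * f_A")
  if (duration <= 0) stop("duration must be positive")
  structure(list(fs = fs, duration = duration, f_p = f_p, f_A = f_A,
                 depth = depth, preferred_phase = preferred_phase,
                 theta_amp = theta_amp, hf_amp = hf_amp,
                 noise_sd = noise_sd, hf_carrier = hf_carrier,
                 hf_bw = hf_bw, seed = seed),
            class = "pac_sim_config")
}

# core waveform shared by all LFP generators; t in seconds (uniformly
# spaced).  Draws from the RNG when the carrier is "noise": callers seed.
pac_waveform <- function(t, cfg) {
  # instantaneous (analytic) phase of the sine theta carrier
  theta_phase <- (2 * pi * cfg$f_p * t - pi / 2 + pi) %% (2 * pi) - pi
  modulator <- (1 - cfg$depth) +
    cfg$depth * (1 + cos(theta_phase - cfg$preferred_phase)) / 2
  carrier <- if (identical(cfg$hf_carrier, "noise")) {
    fs <- 1 / (t[2] - t[1])
    z <- bandpass(stats::rnorm(length(t)), cfg$f_A - cfg$hf_bw / 2,
                  cfg$f_A + cfg$hf_bw / 2, fs)
    z / sqrt(2 * mean(z^2))  # RMS matched to the unit sine carrier
  } else {
    sin(2 * pi * cfg$f_A * t)
  }
  cfg$theta_amp * sin(2 * pi * cfg$f_p * t) +
    cfg$hf_amp * modulator * carrier
}

#' Simulate a single-channel LFP with known phase-amplitude coupling
#'
#' Generates `x(t) = theta_amp sin(2 pi f_p t) + hf_amp m(t)
#' sin(2 pi f_A t) + e(t)` where the fast-carrier envelope
#' `m(t) = (1 - depth) + depth (1 + cos(phi_theta(t) - preferred_phase)) / 2`
#' is a raised cosine of the theta carrier's instantaneous phase
#' `phi_theta`, and `e ~ N(0, noise_sd^2)` i.i.d.  At `depth = 0` the fast
#' envelope is constant (no coupling); at `depth = 1` it vanishes at the
#' anti-preferred phase.  Deterministic given the seed.
#'
#' @param cfg a [pac_sim_config()].
#' @return a single-channel [recording()].
#' @examples
#' rec <- simulate_pac_signal(pac_sim_config(duration = 2, seed = 1))
#' mi_for_pair(rec$data[, 1], rec$fs, c(5, 7), c(135, 165))
#' @export
simulate_pac_signal <- function(cfg) {
  stopifnot(inherits(cfg, "pac_sim_config"))
  stochastic <- cfg$noise_sd > 0 || identical(cfg$hf_carrier, "noise")
  if (stochastic && is.null(cfg$seed))
    stop("seed is required: the generator is stochastic")
  if (stochastic) set.seed(as.integer(cfg$seed))
  n <- round(cfg$duration * cfg$fs)
  t <- (0:(n - 1)) / cfg$fs
  x <- pac_waveform(t, cfg)
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  recording(matrix(x, ncol = 1), fs = cfg$fs, channel_ids = "ch1")
}

#' Simulate a maze session: recording plus beam-crossing events
#'
#' Emulates a ground-maze session in which infrared beam crossings mark
#' the animal's passage through labeled positions.  Around every
#' navigation-position event the injected signal carries phase-amplitude
#' coupling at the configured depth; around the goal-position event the
#' coupling depth is zero and theta amplitude is halved (goal arrival:
#' coupling and theta power drop).  Elsewhere the recording is broadband
#' noise.  Events are strictly increasing with at least 1 s spacing, and
#' every event has a full -250/+750 ms analysis window inside the
#' recording.
#'
#' @param n_trials number of maze traversals.
#' @param positions character vector of position labels crossed in order
#'   each trial (at least 2).
#' @param goal the goal label (must be in `positions`); coupling is absent
#'   there.
#' @param pac a [pac_sim_config()] giving band frequencies, depth and
#'   amplitudes (its `fs`, `duration` fields are ignored).
#' @param fs sampling rate in Hz (default 2000).
#' @param n_channels channels in the recording; coupling is injected on
#'   `pac_channel`, the rest are noise.
#' @param pac_channel index of the coupled channel.
#' @param event_spacing_s time between consecutive events in a trial
#'   (seconds, >= 1).
#' @param paths optional integer vector (length `n_trials`) of path ids.
#' @param seed integer seed (mandatory).
#' @return list with `recording` (a [recording()]) and `events` (an
#'   [event_stream()] with columns `time_s`, `label`, `trial`, `path`).
#' @export
simulate_maze_session <- function(n_trials, positions = c("S8", "S9", "S10", "G1"),
                                  goal = "G1", pac = pac_sim_config(),
                                  fs = 2000, n_channels = 1, pac_channel = 1,
                                  event_spacing_s = 2, paths = NULL,
                                  seed = NULL) {
  if (is.null(seed)) stop("seed is required: the generator is stochastic")
  if (length(unique(positions)) < 2)
    stop("need at least 2 distinct position labels")
  if (!goal %in% positions) stop("goal label must be one of `positions`")
  if (event_spacing_s < 1) stop("event spacing below 1 s is rejected")
  if (is.null(paths)) paths <- rep(1L, n_trials)
  if (n_trials > 0 && length(paths) != n_trials)
    stop("paths must have one entry per trial")
  set.seed(as.integer(seed))

  np <- length(positions)
  trial_len <- (np - 1) * event_spacing_s + 0.75 + 2  # events + tail + gap
  duration <- 1 + max(n_trials, 1) * trial_len
  n <- round(duration * fs)
  data <- matrix(stats::rnorm(n * n_channels, 0, pac$noise_sd), n, n_channels)

  times <- numeric(0); labs <- character(0); trial_id <- integer(0)
  if (n_trials > 0) {
    for (tr in seq_len(n_trials)) {
      t0 <- 1 + (tr - 1) * trial_len
      ev_t <- t0 + (seq_len(np) - 1) * event_spacing_s
      times <- c(times, ev_t)
      labs <- c(labs, positions)
      trial_id <- c(trial_id, rep(tr, np))
      for (j in seq_len(np)) {
        i0 <- round((ev_t[j] - 0.25) * fs) + 1
        idx <- i0:(i0 + fs - 1)
        cfg <- pac
        if (positions[j] == goal) {
          cfg$depth <- 0
          cfg$theta_amp <- pac$theta_amp / 2
        }
        tt <- (idx - 1) / fs
        data[idx, pac_channel] <- data[idx, pac_channel] +
          pac_waveform(tt, cfg)
      }
    }
  }
  ev <- event_stream(data.frame(time_s = times, label = labs,
                                trial = trial_id,
                                path = if (n_trials > 0) paths[trial_id]
                                       else integer(0)))
  list(recording = recording(data, fs = fs,
                             channel_ids = paste0("ch", seq_len(n_channels))),
       events = ev)
}

#' Configuration for a simulated homing-flight GPS track
#'
#' @param release,loft `(lon, lat)` numeric pairs in degrees; must be more
#'   than 500 m apart so the decision-making, en-route and local
#'   navigation phases are all non-empty.
#' @param speed_mps ground speed in m/s (default 15, a typical pigeon
#'   cruise speed).
#' @param lateral_jitter_m standard deviation (m) of the smooth lateral
#'   deviation from the direct release-to-loft line.
#' @param speed_sd standard deviation (m/s) of smooth along-track speed
#'   variation (default 0: constant ground speed).
#' @param n_fixes number of 10 Hz fixes; `NULL` (default) covers the whole
#'   route at `speed_mps`.
#' @param seed integer seed (mandatory when `lateral_jitter_m > 0` or
#'   `speed_sd > 0`).
#' @return a `"flight_sim_config"` list.
#' @export
flight_sim_config <- function(release, loft, speed_mps = 15,
                              lateral_jitter_m = 20, speed_sd = 0,
                              n_fixes = NULL, seed = NULL) {
  stopifnot(length(release) == 2, length(loft) == 2)
  D <- haversine_m(release, loft)
  if (D <= 500)
    stop("release and loft are ", round(D), " m apart; need > 500 m so ",
         "all three flight phases are non-empty")
  if (is.null(n_fixes)) n_fixes <- floor(D / (0.1 * speed_mps)) + 1L
  if (n_fixes < 10) stop("need at least 10 fixes")
  structure(list(release = release, loft = loft, speed_mps = speed_mps,
                 lateral_jitter_m = lateral_jitter_m, speed_sd = speed_sd,
                 n_fixes = as.integer(n_fixes), seed = seed,
                 distance_m = D),
            class = "flight_sim_config")
}

#' Simulate a homing-flight GPS track
#'
#' Fixes advance along the great circle from the release point toward the
#' loft at the configured speed, sampled at 10 Hz, with a smooth
#' (5 s moving-average) Gaussian lateral deviation of standard deviation
#' `lateral_jitter_m` applied perpendicular to the track, emulating the
#' 100-200 m route corridor of trained pigeons.  The speed column carries
#' the nominal GPS-reported ground speed.
#'
#' @param cfg a [flight_sim_config()].
#' @return a [gps_track()] (columns `time_s`, `lon`, `lat`, `speed`).
#' @export
simulate_flight_track <- function(cfg) {
  stopifnot(inherits(cfg, "flight_sim_config"))
  stochastic <- cfg$lateral_jitter_m > 0 || cfg$speed_sd > 0
  if (stochastic && is.null(cfg$seed))
    stop("seed is required: the generator is stochastic")
  if (stochastic) set.seed(as.integer(cfg$seed))
  n <- cfg$n_fixes
  k <- 50  # 5 s moving average at 10 Hz keeps deviations smooth
  smooth_noise <- function(sd_target) {
    raw <- stats::rnorm(n + k)
    sm <- as.numeric(stats::filter(raw, rep(1 / k, k),
                                   sides = 1))[(k + 1):(k + n)]
    sm / stats::sd(sm) * sd_target
  }
  speed <- rep(cfg$speed_mps, n)
  if (cfg$speed_sd > 0)
    speed <- pmax(speed + smooth_noise(cfg$speed_sd), 1)
  along <- pmin(cumsum(c(0, speed[-n])) * 0.1, cfg$distance_m)
  brg <- geosphere::bearing(cfg$release, cfg$loft)
  pos <- geosphere::destPoint(cfg$release, brg, along)
  if (cfg$lateral_jitter_m > 0)
    pos <- geosphere::destPoint(pos, brg + 90,
                                smooth_noise(cfg$lateral_jitter_m))
  gps_track(data.frame(time_s = (0:(n - 1)) * 0.1,
                       lon = pos[, 1], lat = pos[, 2],
                       speed = speed))
}

#' Simulate a complete flight session: LFP recording plus GPS track
#'
#' Convenience generator for end-to-end testing of the flight arm:
#' simulates the track, labels its phases, and builds a time-locked LFP
#' recording in which phase-amplitude coupling at `pac$depth` is present
#' during the en-route (ER) phase and absent (depth 0, halved theta)
#' during decision-making (DM) and local navigation (LN).
#'
#' @param cfg a [flight_sim_config()].
#' @param pac a [pac_sim_config()] for the coupled bands (flight defaults:
#'   theta 7.5 Hz carrier, beta2 25 Hz carrier).
#' @param fs recording sampling rate in Hz (default 1000).
#' @param er_depth,other_depth coupling depth during ER and during DM/LN.
#' @param seed integer seed (mandatory).
#' @return list with `recording`, `track`, and `labels` (per-fix phase
#'   labels).
#' @export
simulate_flight_session <- function(cfg,
                                    pac = pac_sim_config(fs = 1000, f_p = 7.5,
                                                         f_A = 25,
                                                         hf_carrier = "noise"),
                                    fs = 1000, er_depth = pac$depth,
                                    other_depth = 0, seed = NULL) {
  if (is.null(seed)) stop("seed is required: the generator is stochastic")
  set.seed(as.integer(seed))
  track_cfg <- cfg
  if (is.null(track_cfg$seed)) track_cfg$seed <- as.integer(seed) + 1L
  track <- simulate_flight_track(track_cfg)
  labels <- label_flight_phases(track, cfg$release, cfg$loft)
  duration <- max(track$time_s) + 0.1
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  # per-sample flight phase from the enclosing fix
  fix_of <- pmin(floor(t * 10) + 1L, nrow(track))
  lab_t <- labels[fix_of]
  base <- pac; base$fs <- fs
  cfg_er <- base; cfg_er$depth <- er_depth
  cfg_ot <- base; cfg_ot$depth <- other_depth
  cfg_ot$theta_amp <- base$theta_amp / 2
  x <- ifelse(lab_t == "ER", pac_waveform(t, cfg_er), pac_waveform(t, cfg_ot))
  x <- x + stats::rnorm(n, 0, pac$noise_sd)
  list(recording = recording(matrix(x, ncol = 1), fs = fs,
                             channel_ids = "ch1"),
       track = track, labels = labels)
}
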
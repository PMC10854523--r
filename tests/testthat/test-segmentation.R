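test_that("maze epochs cover -250/+750 ms around first detector contact", {
  set.seed(1)
  rec <- recording(matrix(seq_len(24000), ncol = 1), fs = 2000)
  ev <- event_stream(data.frame(time_s = c(0.1, 10.0),
                                label = c("S7", "S8")))
  expect_message(es <- extract_maze_epochs(rec, ev), "dropped")
  expect_length(es$epochs, 1)
  expect_equal(nrow(es$epochs[[1]]), 2000)
  # window [9.75, 10.75): sample indices 19501..21500 of the ramp
  expect_equal(unname(es$epochs[[1]][1, 1]), 19501)
  expect_equal(es$info$start_s, 9.75)

  # repeat contacts with the same detector in a trial are ignored
  ev2 <- event_stream(data.frame(time_s = c(2, 4, 6), label = c("S8", "S8", "S9"),
                                 trial = 1L))
  expect_message(es2 <- extract_maze_epochs(rec, ev2), "repeat")
  expect_length(es2$epochs, 2)
})

test_that("a full simulated session yields one epoch per event", {
  sim <- simulate_maze_session(20, seed = 3)
  es <- extract_maze_epochs(sim$recording, sim$events)
  expect_length(es$epochs, 80)
  expect_equal(sort(unique(es$info$label)), sort(c("G1", "S10", "S8", "S9")))
})

test_that("maze speed divides detector distance by crossing interval", {
  geom <- data.frame(from = c("S8", "S9"), to = c("S9", "S10"),
                     distance_m = c(1.0, 2.0))
  ev <- event_stream(data.frame(time_s = c(1, 3, 4), label = c("S8", "S9", "S10")))
  sp <- maze_speed(ev, geom)
  expect_equal(sp$speed_mps, c(0.5, 2.0))

  # constant-rate walk is inverted exactly
  v <- 0.8
  ev2 <- event_stream(data.frame(time_s = 1 + c(0, 1.0 / v, 1.0 / v + 2.0 / v),
                                 label = c("S8", "S9", "S10")))
  expect_equal(maze_speed(ev2, geom)$speed_mps, c(v, v), tolerance = 1e-9)

  expect_error(maze_speed(event_stream(data.frame(time_s = c(1, 2),
                                                  label = c("S8", "G9"))),
                          geom), "geometry")
  expect_error(maze_speed(structure(data.frame(time_s = c(1, 1),
                                               label = c("S8", "S9")),
                                    class = c("event_stream", "data.frame")),
                          geom), "non-positive")
})

test_that("haversine distance matches closed-form values", {
  expect_equal(haversine_m(c(10, 20), c(10, 20)), 0)
  expect_equal(haversine_m(c(0, 0), c(0, 1)), 6371000 * pi / 180,
               tolerance = 0.1 / 111194)
  expect_equal(haversine_m(c(0, 0), c(180, 0)), pi * 6371000,
               tolerance = 1 / 20015086)
  # symmetry
  expect_equal(haversine_m(c(3, 47), c(8, 46)), haversine_m(c(8, 46), c(3, 47)))
})

test_that("flight-phase labels partition every fix with DM/LN precedence", {
  cfg <- flight_sim_config(test_release, test_loft, lateral_jitter_m = 10,
                           seed = 4)
  tr <- simulate_flight_track(cfg)
  lab <- label_flight_phases(tr, test_release, test_loft)
  expect_length(lab, nrow(tr))
  expect_true(all(lab %in% c("DM", "ER", "LN")))
  expect_true(all(c("DM", "ER", "LN") %in% lab))
  # spot checks against the radii
  d_rel <- haversine_m(cbind(tr$lon, tr$lat), test_release)
  d_loft <- haversine_m(cbind(tr$lon, tr$lat), test_loft)
  expect_true(all(lab[d_rel < 300] == "DM"))
  expect_true(all(lab[d_loft < 200 & d_rel >= 300] == "LN"))
  expect_true(all(lab[d_rel >= 300 & d_loft >= 200] == "ER"))
})

test_that("flight epochs: pure windows kept, boundary windows dropped", {
  fs <- 500
  rec <- recording(matrix(rnorm(60 * fs), ncol = 1), fs = fs)
  tr <- gps_track(data.frame(time_s = seq(0, 59.9, by = 0.1),
                             lon = 113.55, lat = 34.83, speed = 15))
  es <- extract_flight_epochs(rec, tr, rep("ER", nrow(tr)))
  expect_length(es$epochs, 60)
  expect_true(all(es$info$label == "ER"))

  lab <- rep("ER", nrow(tr))
  lab[tr$time_s >= 30.5] <- "LN"   # boundary falls inside window [30, 31)
  es2 <- extract_flight_epochs(rec, tr, lab)
  expect_length(es2$epochs, 59)
  expect_false(30 %in% es2$info$start_s)
})

test_that("simulated 1.5 km flight produces epochs in all three phases", {
  cfg <- flight_sim_config(test_release, test_loft, lateral_jitter_m = 10,
                           seed = 6)
  tr <- simulate_flight_track(cfg)
  lab <- label_flight_phases(tr, test_release, test_loft)
  rec <- recording(matrix(rnorm(ceiling(max(tr$time_s) + 0.1) * 250),
                          ncol = 1), fs = 250)
  es <- extract_flight_epochs(rec, tr, lab)
  counts <- table(es$info$label)
  expect_true(all(c("DM", "ER", "LN") %in% names(counts)))
  expect_true(all(counts >= 1))
})

test_that("bad channels: flatline and amplitude outliers flagged, clean
          channels retained", {
  set.seed(9)
  n <- 4000
  clean <- replicate(4, rnorm(n))
  rec <- recording(cbind(clean, 0), fs = 1000)
  bad <- detect_bad_channels(rec)
  expect_identical(unname(bad), c(rep(FALSE, 4), TRUE))

  # sustained 20x amplitude fault (robust SD deliberately ignores brief
  # transients, so the criterion targets persistent gain/motion faults)
  rec2 <- recording(cbind(clean, rnorm(n) * 20), fs = 1000)
  bad2 <- detect_bad_channels(rec2)
  expect_identical(unname(bad2), c(rep(FALSE, 4), TRUE))

  rec3 <- recording(clean, fs = 1000)
  expect_true(!any(detect_bad_channels(rec3)))
  expect_error(detect_bad_channels(recording(matrix(0, 2000, 2), fs = 1000)),
               "all channels")
})

test_that("per-second flight speed averages the fixes in each window", {
  tr <- gps_track(data.frame(time_s = seq(0, 4.9, by = 0.1), lon = 113.5,
                             lat = 34.8, speed = 15))
  sp <- flight_speed(tr)
  expect_equal(nrow(sp), 5)
  expect_true(all(sp$speed_mps == 15))

  tr2 <- gps_track(data.frame(time_s = seq(0, 0.9, by = 0.1), lon = 113.5,
                              lat = 34.8, speed = 1:10))
  expect_equal(flight_speed(tr2)$speed_mps, 5.5)
})

test_that("path distance separates same-path from different-path flights", {
  cfg <- flight_sim_config(test_release, test_loft, lateral_jitter_m = 20,
                           seed = 11)
  a <- simulate_flight_track(cfg)
  expect_equal(path_distance(a, a)$distance_m, 0)
  expect_true(path_distance(a, a)$same_path)

  cfg2 <- cfg; cfg2$seed <- 12
  b <- simulate_flight_track(cfg2)
  pd <- path_distance(a, b)
  expect_lt(pd$distance_m, 200)
  expect_true(pd$same_path)

  # parallel track offset by 500 m
  brg <- geosphere::bearing(test_release, test_loft)
  off <- geosphere::destPoint(cbind(a$lon, a$lat), brg + 90, 500)
  c500 <- gps_track(data.frame(time_s = a$time_s, lon = off[, 1],
                               lat = off[, 2], speed = a$speed))
  pd2 <- path_distance(a, c500)
  expect_equal(pd2$distance_m, 500, tolerance = 0.05 * 500)
  expect_false(pd2$same_path)
})
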
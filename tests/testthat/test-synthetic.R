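test_that("simulation is deterministic and stays inside the arena", {
  arena <- arena_config(duration = 30)
  beh <- behavior_params()
  s1 <- simulate_dyad(arena, beh, seed = 7)
  s2 <- simulate_dyad(arena, beh, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_dyad(arena, beh, seed = 8)
  expect_false(identical(s1$tracks, s3$tracks))
  for (col in c("centroid_x_cm", "centroid_y_cm", "nose_x_cm", "nose_y_cm")) {
    expect_true(all(s1$tracks[[col]] >= 0 & s1$tracks[[col]] <= 76))
  }
  expect_true(all(s1$events$time_s >= 0 & s1$events$time_s < 30))
  expect_true(all(s1$events$vocalizer_id %in% 1:2))
})

test_that("zero-duration recording gives empty tracks and no events", {
  s <- simulate_dyad(arena_config(duration = 0), behavior_params(), seed = 1)
  expect_equal(nrow(s$tracks), 0L)
  expect_equal(nrow(s$events), 0L)
  expect_error(arena_config(duration = -1))
})

test_that("invalid hazards are rejected", {
  expect_error(behavior_params(emission_hazard_near = 1.2), "emission_hazard_near")
  expect_error(behavior_params(emission_hazard_far = -0.1), "emission_hazard_far")
  expect_error(behavior_params(near_threshold = 0), "near_threshold")
})

test_that("zero far-hazard forces all emissions below the near threshold", {
  beh <- behavior_params(emission_hazard_near = 0.05, emission_hazard_far = 0,
                         near_threshold = 5, attraction_start = 0.3,
                         attraction_end = 0.3)
  s <- simulate_dyad(arena_config(duration = 120), beh, seed = 3)
  expect_gt(nrow(s$events), 0)
  d <- interanimal_distance(s$tracks)
  expect_true(all(d[s$events$frame] < 5))
})

test_that("event count matches the binomial expectation when always near", {
  # near_threshold larger than the arena diagonal => hazard 0.01 every frame
  beh <- behavior_params(emission_hazard_near = 0.01,
                         emission_hazard_far = 0.01, near_threshold = 1e6)
  s <- simulate_dyad(arena_config(duration = 1800), beh, seed = 5)
  n_frames <- 1800 * 30
  expected <- n_frames * 0.01
  sd3 <- 3 * sqrt(n_frames * 0.01 * 0.99)
  expect_lt(abs(nrow(s$events) - expected), sd3)
})

test_that("step vectors of the two mice are uncorrelated without attraction", {
  beh <- behavior_params(attraction_start = 0, attraction_end = 0)
  cors <- vapply(1:10, function(seed) {
    s <- simulate_dyad(arena_config(duration = 60), beh, seed = seed)
    t1 <- s$tracks[s$tracks$mouse_id == 1, ]
    t2 <- s$tracks[s$tracks$mouse_id == 2, ]
    dx1 <- diff(t1$centroid_x_cm); dx2 <- diff(t2$centroid_x_cm)
    dy1 <- diff(t1$centroid_y_cm); dy2 <- diff(t2$centroid_y_cm)
    (cor(dx1, dx2) + cor(dy1, dy2)) / 2
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("zero-magnitude kick returns tracks unchanged", {
  s <- simulate_dyad(arena_config(duration = 10), behavior_params(), seed = 2)
  expect_identical(inject_response_kick(s$tracks, s$events, 0), s$tracks)
})

test_that("kick on a constant-speed track is recovered in closed form", {
  tr <- straight_tracks(n = 200, speed_cm_s = 6)
  ev <- event_at(100, voc = 2)  # receiver = mouse 1
  tr2 <- inject_response_kick(tr, ev, kick_magnitude = 1, kick_window = 5,
                              side_length = 200)
  v <- compute_speeds(tr2, 1)
  expect_equal(post_acceleration(v[95:105]), 1.0, tolerance = 1e-8)
  # vocalizer's track untouched
  expect_equal(tr2[tr2$mouse_id == 2, ], tr[tr$mouse_id == 2, ])
})

test_that("overlapping kicks superpose additively", {
  tr <- straight_tracks(n = 300, speed_cm_s = 6)
  ev1 <- event_at(100, voc = 2)
  ev2 <- event_at(c(100, 102), voc = 2)
  one <- inject_response_kick(tr, ev1, 1, 5, side_length = 500)
  both <- inject_response_kick(tr, ev2, 1, 5, side_length = 500)
  v_base <- compute_speeds(tr, 1)
  v_one <- compute_speeds(one, 1)
  v_both <- compute_speeds(both, 1)
  gain_one <- v_one - v_base
  gain_both <- v_both - v_base
  # second kick's gain alone
  only2 <- compute_speeds(inject_response_kick(tr, event_at(102, voc = 2),
                                               1, 5, side_length = 500), 1)
  gain_two <- only2 - v_base
  expect_equal(gain_both[-1], (gain_one + gain_two)[-1], tolerance = 1e-9)
})

test_that("kick at the recording tail is truncated with a note", {
  tr <- straight_tracks(n = 50)
  ev <- event_at(48, voc = 2)
  expect_message(inject_response_kick(tr, ev, 1, 10, side_length = 500),
                 "truncated")
})

test_that("audio without events is pure noise at the specified level", {
  arena <- arena_config(duration = 1)
  sim <- manual_sim(event_at(1)[0, ], list(), arena)
  aud <- synthesize_audio(sim, snr_db = 20, seed = 9, duration_s = 0.5)
  rms <- apply(aud$samples, 2, sd)
  expect_true(all(abs(rms - aud$noise_sd) / aud$noise_sd < 0.01))
})

test_that("audio is reproducible from the seed", {
  arena <- arena_config(duration = 1)
  a1 <- chirp_audio(c(40, 40), arena, seed = 3)
  a2 <- chirp_audio(c(40, 40), arena, seed = 3)
  expect_identical(a1$samples, a2$samples)
})

test_that("propagation delays match geometry at the sample level", {
  # planar mics so distances are exactly 2-D
  mics <- cbind(rbind(c(0, 38), c(76, 38), c(38, 0), c(38, 76),
                      c(0, 0), c(76, 0), c(0, 76), c(76, 76)), 0)
  arena <- arena_config(duration = 1, mic_positions = mics, mic_height = 0)
  xcl <- function(a, b, maxlag = 600) {
    cc <- vapply(-maxlag:maxlag, function(l) {
      ia <- max(1, 1 + l):min(length(a), length(b) + l)
      sum(a[ia] * b[ia - l])
    }, numeric(1))
    (-maxlag:maxlag)[which.max(cc)]
  }
  # equidistant from mics 1 and 2 (both at y = 38, x = 0 / 76)
  aud <- chirp_audio(c(38, 38), arena, snr_db = 60, seed = 2)
  i <- seq(floor(0.04 * aud$fs), ceiling(0.12 * aud$fs))
  expect_equal(xcl(aud$samples[i, 1], aud$samples[i, 2]), 0)
  # source on the mic1-mic2 axis: d1 = 20.85, d2 = 55.15 -> diff 34.3 cm
  aud2 <- chirp_audio(c(20.85, 38), arena, snr_db = 60, seed = 2)
  lag <- xcl(aud2$samples[i, 1], aud2$samples[i, 2])
  # channel 2 receives 250 samples later (34.3 cm / 343 m/s at 250 kHz)
  expect_equal(abs(lag), 250, tolerance = 1e-8)
})

test_that("out-of-band contours are rejected and late events truncated", {
  arena <- arena_config(duration = 1)
  ev <- event_at(1)
  bad <- list(data.frame(t_s = c(0, 0.05), freq_khz = c(20, 80)))
  expect_error(synthesize_audio(manual_sim(ev, bad, arena), duration_s = 0.2),
               "30-110")
  late <- event_at(1); late$time_s <- 0.19
  ok <- list(data.frame(t_s = c(0, 0.05), freq_khz = c(60, 80)))
  expect_message(synthesize_audio(manual_sim(late, ok, arena),
                                  duration_s = 0.2, seed = 1), "truncated")
})

test_that("wav round-trip preserves samples and rate", {
  x <- matrix(rnorm(800), 100, 8)
  f <- tempfile(fileext = ".wav")
  write_multiwav(x, f, fs = 250000)
  back <- read_multiwav(f)
  expect_equal(back$fs, 250000)
  expect_equal(back$samples, x, tolerance = 1e-6)  # float32 precision
  unlink(f)
})
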
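# shared fixtures built in code at test time

# straight constant-speed track for two mice, far from walls
straight_tracks <- function(n = 200, speed_cm_s = 6, fps = 30,
                            y1 = 30, y2 = 35, x0 = 5) {
  x <- x0 + (seq_len(n) - 1) * speed_cm_s / fps
  data.frame(
    frame = rep(seq_len(n), 2L),
    mouse_id = rep(1:2, each = n),
    nose_x_cm = c(x + 1, x + 1), nose_y_cm = c(rep(y1, n), rep(y2, n)),
    centroid_x_cm = c(x, x),
    centroid_y_cm = c(rep(y1, n), rep(y2, n)))
}

# one event emitted by `voc` at a given frame
event_at <- function(frame, voc = 1, fps = 30) {
  data.frame(event_id = seq_along(frame), time_s = (frame - 1) / fps,
             frame = frame, vocalizer_id = voc,
             source_x_cm = 38, source_y_cm = 38)
}

# minimal dyad_sim carrying hand-set events/contours for audio rendering
manual_sim <- function(events, contours, arena) {
  structure(list(events = events, contours = contours, arena = arena),
            class = "dyad_sim")
}

# render one chirp from a known position into 8-channel audio
chirp_audio <- function(src_xy, arena, t0 = 0.05, dur = 0.05,
                        f0 = 60, f1 = 80, snr_db = 40, seed = 1,
                        duration_s = 0.2) {
  ev <- data.frame(event_id = 1, time_s = t0, frame = floor(t0 * 30) + 1,
                   vocalizer_id = 1,
                   source_x_cm = src_xy[1], source_y_cm = src_xy[2])
  ct <- list(data.frame(t_s = c(0, dur), freq_khz = c(f0, f1)))
  synthesize_audio(manual_sim(ev, ct, arena), snr_db = snr_db, seed = seed,
                   duration_s = duration_s)
}

expect_frac_between <- function(x, lo, hi) {
  expect_gte(x, lo); expect_lte(x, hi)
}
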
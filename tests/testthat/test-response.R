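test_that("speeds follow displacement times frame rate", {
  tr <- straight_tracks(n = 50, speed_cm_s = 30)   # 1 cm/frame
  v <- compute_speeds(tr, 1)
  expect_true(is.na(v[1]))
  expect_equal(v[-1], rep(30, 49))
  still <- straight_tracks(n = 20, speed_cm_s = 0)
  expect_equal(compute_speeds(still, 1)[-1], rep(0, 19))
  # circular motion: chord-length speed 2 r sin(w/2) * fps
  n <- 100; r <- 10; w <- 0.2
  ang <- w * seq_len(n)
  circ <- two_mouse <- data.frame(
    frame = rep(seq_len(n), 2), mouse_id = rep(1:2, each = n),
    nose_x_cm = 0, nose_y_cm = 0,
    centroid_x_cm = c(40 + r * cos(ang), rep(10, n)),
    centroid_y_cm = c(40 + r * sin(ang), rep(10, n)))
  vc <- compute_speeds(circ, 1)
  expect_equal(vc[-1], rep(2 * r * sin(w / 2) * 30, n - 1), tolerance = 1e-9)
})

test_that("trajectory construction enforces the proximity and edge rules", {
  tr <- straight_tracks(n = 300, speed_cm_s = 6, y1 = 30, y2 = 35)
  # mouse 2 far away for one stretch
  far <- tr
  far$centroid_y_cm[far$mouse_id == 2 & far$frame %in% 100:120] <- 80
  ev <- event_at(c(3, 110, 150), voc = 2)
  vt <- build_vocal_trajectories(ev, far)
  expect_equal(nrow(vt$trajectories), 1L)   # frame 3 near edge, 110 far
  expect_equal(vt$trajectories$frame, 150)
  expect_equal(unname(vt$qc["edge"]), 1)
  expect_equal(unname(vt$qc["far"]), 1)
})

test_that("temporal isolation and relative-speed labels are correct", {
  tr <- straight_tracks(n = 600)
  ev <- event_at(c(100, 106, 300), voc = 2)   # 5 frames apart = 200 ms
  vt <- build_vocal_trajectories(ev, tr)
  expect_equal(vt$trajectories$isolated, c(FALSE, FALSE, TRUE))
  # make vocalizer (mouse 2) faster than receiver while staying within 20 cm
  tr2 <- tr
  m2 <- tr2$mouse_id == 2
  tr2$centroid_x_cm[m2] <- 1 + (seq_len(600) - 1) * 10 / 30  # 10 cm/s
  vt2 <- build_vocal_trajectories(event_at(60, voc = 2), tr2)
  expect_equal(vt2$trajectories$relative_speed, "faster")
  vt3 <- build_vocal_trajectories(event_at(60, voc = 1), tr2)
  expect_equal(vt3$trajectories$relative_speed, "slower")
  # exact tie counts as slower
  vt4 <- build_vocal_trajectories(event_at(300, voc = 2), tr)
  expect_equal(vt4$trajectories$relative_speed, "slower")
})

test_that("control pool excludes event windows and undefined speeds", {
  n <- 100
  sp <- c(NA, rep(6, n - 1))
  pool <- build_control_pool(sp, integer(0))
  expect_equal(length(pool$starts), n - 11)  # n-10 windows minus the NA one
  pool2 <- build_control_pool(sp, 50)
  expect_false(any(pool2$starts %in% 40:50))
  expect_equal(length(pool2$starts), n - 11 - 11)
  # fully masked speeds -> empty pool
  expect_equal(length(build_control_pool(rep(NA_real_, 50), integer(0))$starts), 0)
})

test_that("greedy matching picks the exact-copy window at zero cost", {
  tr <- straight_tracks(n = 300)
  ev <- event_at(100, voc = 2)
  vt <- build_vocal_trajectories(ev, tr)
  sp <- compute_speeds(tr, 1)
  pool <- build_control_pool(sp, 100)
  mc <- match_controls(vt$trajectories, pool)
  expect_lt(mc$pairs$match_cost, 1e-9)  # constant speed: exact copy exists
  # explicit tie: identical windows -> earliest start wins
  v <- as.numeric(vt$trajectories[1, paste0("v", 1:11)])
  tie_pool <- list(starts = c(40, 7, 90),
                   windows = matrix(rep(v, 3), 3, byrow = TRUE))
  mc2 <- match_controls(vt$trajectories, tie_pool)
  expect_equal(mc2$pairs$control_start, 7)
  expect_equal(mc2$pairs$match_cost, 0)
})

test_that("greedy matching equals a brute-force sequential oracle", {
  set.seed(13)
  for (rep in 1:20) {
    n_traj <- sample(2:6, 1)
    n_pool <- sample(n_traj:20, 1)
    traj <- as.data.frame(matrix(rnorm(n_traj * 11), n_traj))
    names(traj) <- paste0("v", 1:11)
    traj$frame <- seq_len(n_traj) * 20
    win <- matrix(rnorm(n_pool * 11), n_pool)
    pool <- list(starts = seq_len(n_pool), windows = win)
    mc <- match_controls(traj, pool)
    # oracle: independent sequential minimization with explicit loops
    used <- logical(n_pool); oracle <- integer(n_traj)
    for (i in seq_len(n_traj)) {
      best <- NA; bc <- Inf
      for (j in seq_len(n_pool)) {
        if (used[j]) next
        cost <- sum(abs(win[j, 1:6] - as.numeric(traj[i, 1:6])))
        if (cost < bc - 1e-12) { bc <- cost; best <- j }
      }
      used[best] <- TRUE; oracle[i] <- best
    }
    expect_equal(mc$pairs$control_start, oracle)
    expect_equal(anyDuplicated(mc$pairs$control_start), 0L)
  }
})

test_that("no remaining pool window beats a chosen control", {
  set.seed(14)
  traj <- as.data.frame(matrix(rnorm(4 * 11), 4))
  names(traj) <- paste0("v", 1:11)
  traj$frame <- 1:4
  win <- matrix(rnorm(18 * 11), 18)
  pool <- list(starts = 1:18, windows = win)
  mc <- match_controls(traj, pool)
  taken <- mc$pairs$control_start
  for (i in seq_len(nrow(mc$pairs))) {
    later_taken <- taken[seq_len(nrow(mc$pairs)) > i]
    free <- setdiff(seq_len(18), taken[seq_len(i)])
    costs <- apply(win[free, 1:6, drop = FALSE], 1, function(w)
      sum(abs(w - as.numeric(mc$pairs[i, paste0("v", 1:6)]))))
    expect_gte(min(costs) + 1e-12, mc$pairs$match_cost[i])
  }
})

test_that("pool exhaustion leaves trajectories unmatched but reported", {
  traj <- as.data.frame(matrix(rnorm(3 * 11), 3))
  names(traj) <- paste0("v", 1:11)
  traj$frame <- 1:3
  pool <- list(starts = 1:2, windows = matrix(rnorm(22), 2))
  mc <- match_controls(traj, pool)
  expect_equal(nrow(mc$pairs), 2)
  expect_equal(mc$unmatched, 1L)
})

test_that("post-acceleration matches its closed forms", {
  expect_equal(post_acceleration(rep(7, 11)), 0)
  ramp <- c(rep(10, 6), 11, 12, 13, 14, 15)
  expect_equal(post_acceleration(ramp), 30)   # 1 cm/s per frame
  # telescoping identity on random windows
  set.seed(15)
  for (i in 1:25) {
    w <- rnorm(11)
    expect_equal(post_acceleration(w), (w[11] - w[6]) * 30 / 5,
                 tolerance = 1e-12)
  }
  # matrix form agrees with the vector form
  M <- matrix(rnorm(33), 3)
  expect_equal(post_acceleration(M),
               apply(M, 1, post_acceleration))
})

test_that("stratum test handles identity and degenerate inputs", {
  a <- rnorm(10)
  r0 <- stratum_test(a, a)
  expect_equal(r0$t, 0); expect_equal(r0$p.value, 1)
  r1 <- stratum_test(a + 1, a)     # certain constant offset
  expect_equal(r1$p.value, 0)
  expect_true(is.infinite(r1$t))
  r2 <- stratum_test(1, 2)
  expect_false(r2$testable)
  # ordinary case agrees with stats::t.test
  set.seed(16)
  x <- rnorm(20, 0.5); y <- rnorm(20)
  rt <- stratum_test(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(rt$t, unname(tt$statistic))
  expect_equal(rt$p.value, tt$p.value)
})

test_that("subsampling null behaves at its boundary cases and is seeded", {
  d <- rep(1, 40)
  r <- subsample_null(d, reps = 200, seed = 3)
  expect_equal(r$m, 10)              # 25% default
  expect_lt(r$p.value, 1 / 200)
  expect_true(all(r$means == 1))
  # m = n: degenerate at the grand mean
  dd <- rnorm(12)
  r2 <- subsample_null(dd, m = 12, reps = 50, seed = 4)
  expect_true(all(abs(r2$means - mean(dd)) < 1e-12))
  expect_error(subsample_null(dd, m = 13), "exceeds")
  # reproducibility to full precision
  set.seed(99); dr <- rnorm(60)
  p1 <- subsample_null(dr, reps = 500, seed = 7)$p.value
  p2 <- subsample_null(dr, reps = 500, seed = 7)$p.value
  expect_identical(p1, p2)
  # symmetric differences are rarely significant
  sig <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    subsample_null(rnorm(80), reps = 200, seed = s)$p.value < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.05 + 0.2)
})

test_that("epoch boundaries are half-open and controls stay in-epoch", {
  # event in the first frame of minute 10 belongs to epoch 2
  tr <- straight_tracks(n = 54000, speed_cm_s = 3, x0 = 5)
  tr$centroid_x_cm <- 5 + ((tr$frame - 1) %% 9000) * 0.1 / 30  # stay in arena
  tr$nose_x_cm <- tr$centroid_x_cm + 1
  ev <- event_at(c(9000, 18001, 40000), voc = 2)
  vt <- build_vocal_trajectories(ev, tr)
  expect_equal(vt$trajectories$epoch, c(1L, 2L, 3L))
  ea <- epoch_analysis(ev, tr)
  expect_true(all(ea$pairs$control_start >= (ea$pairs$epoch - 1) * 18000 + 1))
  expect_true(all(ea$pairs$control_start + 10 <= ea$pairs$epoch * 18000))
})

test_that("a kick confined to one epoch is detected only there", {
  arena <- arena_config(duration = 1800)
  beh <- behavior_params(emission_hazard_near = 0.03,
                         emission_hazard_far = 0.003)
  sim <- simulate_dyad(arena, beh, seed = 31)
  early <- sim$events[sim$events$time_s < 600, ]
  tr <- inject_response_kick(sim$tracks, early, 2.0, 5, 30, 76)
  ea <- epoch_analysis(sim$events, tr)
  tab <- ea$table
  agg <- vapply(1:3, function(ep) {
    rows <- tab[tab$epoch == ep & tab$testable, ]
    sum(rows$mean_diff * rows$n) / sum(rows$n)
  }, numeric(1))
  expect_gt(agg[1], 1)          # near the injected 2 cm/s^2
  expect_lt(max(abs(agg[2:3])), 0.5)
})

test_that("short recordings fall back to proportional epochs with a warning", {
  tr <- straight_tracks(n = 900)
  ev <- event_at(c(100, 400, 800), voc = 2)
  expect_warning(ea <- epoch_analysis(ev, tr), "proportional")
  expect_equal(sort(unique(ea$pairs$epoch)), 1:3)
})
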
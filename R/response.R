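#' Per-frame speed of one mouse
#'
#' Speed at frame i is the centroid displacement from frame i-1 to i times
#' the frame rate (cm/s); undefined (`NA`) at the first frame and wherever
#' positions are missing.
#'
#' @param tracks tracks data.frame.
#' @param mouse_id 1 or 2.
#' @param frame_rate frames per second.
#' @return numeric vector indexed by frame, cm/s.
#' @export
compute_speeds <- function(tracks, mouse_id, frame_rate = 30) {
  tm <- tracks[tracks$mouse_id == mouse_id, ]
  tm <- tm[order(tm$frame), ]
  n <- max(tracks$frame)
  px <- rep(NA_real_, n); py <- rep(NA_real_, n)
  px[tm$frame] <- tm$centroid_x_cm
  py[tm$frame] <- tm$centroid_y_cm
  v <- rep(NA_real_, n)
  if (n >= 2) {
    d <- sqrt(diff(px)^2 + diff(py)^2)
    v[-1] <- d * frame_rate
  }
  v
}

#' Build receiver-speed vocal trajectories around emissions
#'
#' One 11-frame (367 ms at 30 Hz) receiver-speed window per qualifying
#' emission: frames e-5 ... e+5 around the emission frame e (the video
#' frame whose interval contains the signal start). Events are dropped when
#' the mice are 20 cm or more apart at frame e, when the window leaves the
#' recording, or when any speed in the window is undefined (counted in the
#' QC summary). Each trajectory is labeled with the vocalizer, the relative
#' speed of the vocalizer versus the receiver at frame e (ties count as
#' "slower"), whether it is temporally isolated (no other signal from
#' either mouse starting within 367 ms), and its 10-minute epoch.
#'
#' @param events attributed events data.frame with `time_s` and a
#'   vocalizer column (`vocalizer_id` or `assigned_to`); unassigned events
#'   are dropped.
#' @param tracks tracks data.frame.
#' @param frame_rate frames per second.
#' @param max_dist_cm proximity criterion at the emission frame, cm.
#' @param isolation_s temporal-isolation window, s (11 frames).
#' @param epoch_s epoch length, s.
#' @return list of class `vocal_trajectories`: `trajectories` data.frame
#'   (`event_id`, `frame`, `vocalizer`, `receiver`, `relative_speed`,
#'   `isolated`, `epoch`, speeds `v1`..`v11`) and `qc` counts.
#' @export
build_vocal_trajectories <- function(events, tracks, frame_rate = 30,
                                     max_dist_cm = 20,
                                     isolation_s = 11 / 30,
                                     epoch_s = 600) {
  voc <- events$vocalizer_id %||% events$assigned_to
  keep <- !is.na(voc)
  ev <- events[keep, , drop = FALSE]
  voc <- voc[keep]
  time_s <- ev$time_s
  eframe <- floor(time_s * frame_rate) + 1L
  n <- max(tracks$frame)
  v1 <- compute_speeds(tracks, 1, frame_rate)
  v2 <- compute_speeds(tracks, 2, frame_rate)
  dist <- interanimal_distance(tracks)
  all_times <- events$time_s  # isolation considers every signal, either mouse
  qc <- c(total = nrow(ev), edge = 0, far = 0, undefined_speed = 0)
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    e <- eframe[i]
    if (e - 5 < 1 || e + 5 > n) { qc["edge"] <- qc["edge"] + 1; next }
    if (is.na(dist[e]) || dist[e] >= max_dist_cm) { qc["far"] <- qc["far"] + 1; next }
    rec <- 3L - voc[i]
    vr <- if (rec == 1) v1 else v2
    vv <- if (rec == 1) v2 else v1
    w <- vr[(e - 5):(e + 5)]
    if (anyNA(w) || is.na(vv[e])) {
      qc["undefined_speed"] <- qc["undefined_speed"] + 1; next
    }
    iso <- sum(abs(all_times - time_s[i]) <= isolation_s) == 1L
    rows[[length(rows) + 1]] <- data.frame(
      event_id = ev$event_id[i] %||% i,
      frame = e, vocalizer = voc[i], receiver = rec,
      relative_speed = if (vv[e] > vr[e]) "faster" else "slower",
      isolated = iso,
      epoch = floor(time_s[i] / epoch_s) + 1L,
      t(stats::setNames(w, paste0("v", 1:11))))
  }
  traj <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(), frame = integer(), vocalizer = integer(),
               receiver = integer(), relative_speed = character(),
               isolated = logical(), epoch = integer())
  structure(list(trajectories = traj, qc = qc), class = "vocal_trajectories")
}

#' Candidate non-vocal (control) windows for one receiver
#'
#' Every 11-frame window (stride 1) of the receiver's speed series that is
#' fully defined and contains no emission start by either mouse.
#'
#' @param speeds receiver speed series (from [compute_speeds()]).
#' @param event_frames emission frames of all signals from both mice.
#' @param frame_range optional `c(first, last)` frame; windows must lie
#'   fully inside it (used by the epoch analysis).
#' @return list: `starts` (window start frames), `windows` (n x 11 matrix).
#' @export
build_control_pool <- function(speeds, event_frames, frame_range = NULL) {
  n <- length(speeds)
  lo <- 1L; hi <- n
  if (!is.null(frame_range)) { lo <- frame_range[1]; hi <- frame_range[2] }
  starts <- seq.int(lo, hi - 10L)
  starts <- starts[starts >= 1 & starts + 10 <= n]
  if (!length(starts))
    return(list(starts = integer(0), windows = matrix(0, 0, 11)))
  has_event <- rep(FALSE, n + 11L)
  has_event[event_frames] <- TRUE
  bad <- vapply(starts, function(s) any(has_event[s:(s + 10)]), logical(1))
  win <- t(vapply(starts, function(s) speeds[s:(s + 10)], numeric(11)))
  ok <- !bad & !apply(win, 1, anyNA)
  list(starts = starts[ok], windows = win[ok, , drop = FALSE])
}

#' Speed-match control windows to vocal trajectories
#'
#' Trajectories are processed in chronological order. Each is paired with
#' the remaining pool window minimizing the summed absolute speed
#' difference over the first six samples (200 ms, the time up to and
#' including emission); ties go to the earliest window start, and every
#' window is used at most once.
#'
#' @param traj trajectories data.frame (one receiver) with `v1`..`v11`.
#' @param pool control pool from [build_control_pool()].
#' @return list: `pairs` (data.frame with trajectory columns plus
#'   `control_start`, `match_cost` and control speeds `c1`..`c11`),
#'   `unmatched` (number of trajectories left without a control).
#' @export
match_controls <- function(traj, pool) {
  traj <- traj[order(traj$frame), , drop = FALSE]
  vcols <- paste0("v", 1:11)
  avail <- rep(TRUE, length(pool$starts))
  out <- list(); unmatched <- 0L
  for (i in seq_len(nrow(traj))) {
    if (!any(avail)) { unmatched <- unmatched + 1L; next }
    v <- as.numeric(traj[i, vcols])
    idx <- which(avail)
    cost <- rowSums(abs(pool$windows[idx, 1:6, drop = FALSE] -
                          matrix(v[1:6], length(idx), 6, byrow = TRUE)))
    best <- idx[order(cost, pool$starts[idx])[1]]
    avail[best] <- FALSE
    row <- traj[i, , drop = FALSE]
    row$control_start <- pool$starts[best]
    row$match_cost <- min(cost)
    cw <- stats::setNames(as.list(pool$windows[best, ]), paste0("c", 1:11))
    out[[length(out) + 1]] <- cbind(row, as.data.frame(cw))
  }
  pairs <- if (length(out)) do.call(rbind, out) else NULL
  list(pairs = pairs, unmatched = unmatched)
}

#' Post-emission acceleration of an 11-sample speed window
#'
#' Mean of the five consecutive frame-to-frame speed changes in the 167 ms
#' after the emission sample (samples 6..11), times the frame rate:
#' `mean(diff(v[6:11])) * frame_rate`, cm/s^2. Algebraically equal to
#' `(v[11] - v[6]) * frame_rate / 5`.
#'
#' @param window numeric vector of 11 speeds, or an n x 11 matrix.
#' @param frame_rate frames per second.
#' @return acceleration(s), cm/s^2.
#' @export
post_acceleration <- function(window, frame_rate = 30) {
  if (is.matrix(window) || is.data.frame(window)) {
    w <- as.matrix(window)
    stopifnot(ncol(w) == 11)
    return(rowMeans(w[, 7:11, drop = FALSE] - w[, 6:10, drop = FALSE]) * frame_rate)
  }
  stopifnot(length(window) == 11)
  mean(diff(window[6:11])) * frame_rate
}

#' Paired comparison of vocal and control accelerations in one stratum
#'
#' Paired t-test on (vocal minus control) post-emission accelerations.
#' Zero-variance differences are handled as a degenerate t: p = 1 when all
#' differences are zero, p = 0 ("difference certain") when they share a
#' nonzero constant value.
#'
#' @param vocal_acc,control_acc equal-length acceleration vectors, cm/s^2.
#' @return list: `n`, `vocal_mean`, `vocal_sd`, `control_mean`,
#'   `control_sd`, `t`, `p.value`, `mean_diff`, `testable`.
#' @export
stratum_test <- function(vocal_acc, control_acc) {
  stopifnot(length(vocal_acc) == length(control_acc))
  n <- length(vocal_acc)
  base <- list(n = n, vocal_mean = mean(vocal_acc), vocal_sd = stats::sd(vocal_acc),
               control_mean = mean(control_acc), control_sd = stats::sd(control_acc),
               mean_diff = mean(vocal_acc - control_acc))
  if (n < 2) return(c(base, list(t = NA_real_, p.value = NA_real_, testable = FALSE)))
  d <- vocal_acc - control_acc
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    d <- round(d - mean(d), 10) + mean(d)  # collapse float dust
  }
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(c(base, list(t = 0, p.value = 1, testable = TRUE)))
    return(c(base, list(t = sign(mean(d)) * Inf, p.value = 0, testable = TRUE)))
  }
  tt <- stats::t.test(d, mu = 0)
  c(base, list(t = unname(tt$statistic), p.value = tt$p.value, testable = TRUE))
}

#' Stratum tests across vocalizer and relative-speed cells
#'
#' Applies [stratum_test()] within each (vocalizer, relative speed and
#' optionally epoch) cell of a matched-pairs table, mirroring the standard results
#' layout (vocal mean/SD, control mean/SD, t, p per row).
#'
#' @param pairs matched-pairs data.frame from [match_controls()] (rows may
#'   come from several receivers, concatenated).
#' @param by grouping columns.
#' @param frame_rate frames per second.
#' @return data.frame, one row per stratum.
#' @export
strata_tests <- function(pairs, by = c("vocalizer", "relative_speed"),
                         frame_rate = 30) {
  if (is.null(pairs) || !nrow(pairs)) return(NULL)
  va <- post_acceleration(pairs[, paste0("v", 1:11)], frame_rate)
  ca <- post_acceleration(pairs[, paste0("c", 1:11)], frame_rate)
  key <- interaction(pairs[, by, drop = FALSE], drop = TRUE, sep = "|")
  out <- lapply(levels(key), function(k) {
    sel <- key == k
    st <- stratum_test(va[sel], ca[sel])
    lab <- pairs[which(sel)[1], by, drop = FALSE]
    cbind(lab, data.frame(n = st$n, vocal_mean = st$vocal_mean,
                          vocal_sd = st$vocal_sd,
                          control_mean = st$control_mean,
                          control_sd = st$control_sd,
                          mean_diff = st$mean_diff,
                          t = st$t, p = st$p.value, testable = st$testable))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subsampling null distribution of the vocal minus control difference
#'
#' Repeatedly draws `m` matched pairs without replacement and records the
#' mean (vocal minus control) acceleration difference. The reported p value
#' is twice the smaller tail fraction at zero, clipped to 1; a value of 0
#' means no replicate mean crossed zero (p below 1/reps).
#'
#' @param diffs per-pair acceleration differences (vocal minus control),
#'   cm/s^2.
#' @param m subsample size; defaults to `ceiling(0.25 * n)` (the
#'   25-percent mode); pass a size-matched count for the size-matched mode.
#' @param reps number of replicates.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list: `means` (length `reps`), `p.value`, `m`, `reps`.
#' @export
subsample_null <- function(diffs, m = NULL, reps = 1000, seed = 1) {
  n <- length(diffs)
  m <- m %||% ceiling(0.25 * n)
  if (m > n) stop("subsample size exceeds number of pairs", call. = FALSE)
  stopifnot(reps >= 1)
  with_seed(seed, {
    means <- vapply(seq_len(reps), function(r) mean(diffs[sample.int(n, m)]),
                    numeric(1))
    p <- 2 * min(mean(means <= 0), mean(means >= 0))
    list(means = means, p.value = min(p, 1), m = m, reps = reps)
  })
}

#' Epoch-resolved trajectory analysis
#'
#' Splits the recording into three 10-minute epochs (shorter recordings
#' get three proportional bins, with a warning), restricts temporally
#' isolated trajectories and control pools to each epoch before matching
#' (controls are never drawn from another epoch), and runs the stratum
#' tests per epoch.
#'
#' @param events attributed events data.frame.
#' @param tracks tracks data.frame.
#' @param frame_rate frames per second.
#' @param n_epochs number of bins.
#' @param epoch_s epoch length, s.
#' @param isolated_only restrict to temporally isolated signals (standard).
#' @return list: `table` (strata x epoch results), `pairs` (matched pairs
#'   with epoch labels).
#' @export
epoch_analysis <- function(events, tracks, frame_rate = 30, n_epochs = 3,
                           epoch_s = 600, isolated_only = TRUE) {
  n <- max(tracks$frame)
  total_s <- n / frame_rate
  if (total_s < n_epochs * epoch_s) {
    warning("recording shorter than ", n_epochs * epoch_s,
            " s; using proportional epochs")
    epoch_s <- total_s / n_epochs
  }
  vt <- build_vocal_trajectories(events, tracks, frame_rate,
                                 epoch_s = epoch_s)
  traj <- vt$trajectories
  if (isolated_only) traj <- traj[traj$isolated, , drop = FALSE]
  voc <- events$vocalizer_id %||% events$assigned_to
  ev_frames <- floor(events$time_s * frame_rate) + 1L  # all signals, assigned or not
  all_pairs <- list()
  for (ep in seq_len(n_epochs)) {
    f0 <- floor((ep - 1) * epoch_s * frame_rate) + 1L
    f1 <- min(floor(ep * epoch_s * frame_rate), n)
    te <- traj[traj$epoch == ep, , drop = FALSE]
    if (!nrow(te)) next
    for (rec in unique(te$receiver)) {
      tr <- te[te$receiver == rec, , drop = FALSE]
      sp <- compute_speeds(tracks, rec, frame_rate)
      pool <- build_control_pool(sp, ev_frames, frame_range = c(f0, f1))
      mc <- match_controls(tr, pool)
      if (!is.null(mc$pairs)) all_pairs[[length(all_pairs) + 1]] <- mc$pairs
    }
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else NULL
  list(table = strata_tests(pairs,
                            by = c("vocalizer", "relative_speed", "epoch"),
                            frame_rate = frame_rate),
       pairs = pairs)
}

#' Full matched-pairs analysis for one recording
#'
#' Builds trajectories, matches controls per receiver over the whole
#' recording, and returns the matched pairs plus the stratum table.
#'
#' @param events attributed events data.frame.
#' @param tracks tracks data.frame.
#' @param mode `"isolated"` (temporally isolated signals only) or `"all"`.
#' @param frame_rate frames per second.
#' @return list: `pairs`, `table`, `qc`.
#' @export
response_analysis <- function(events, tracks, mode = c("isolated", "all"),
                              frame_rate = 30) {
  mode <- match.arg(mode)
  vt <- build_vocal_trajectories(events, tracks, frame_rate)
  traj <- vt$trajectories
  if (mode == "isolated") traj <- traj[traj$isolated, , drop = FALSE]
  ev_frames <- floor(events$time_s * frame_rate) + 1L  # all signals, assigned or not
  all_pairs <- list(); unmatched <- 0L
  for (rec in unique(traj$receiver)) {
    tr <- traj[traj$receiver == rec, , drop = FALSE]
    sp <- compute_speeds(tracks, rec, frame_rate)
    pool <- build_control_pool(sp, ev_frames)
    mc <- match_controls(tr, pool)
    unmatched <- unmatched + mc$unmatched
    if (!is.null(mc$pairs)) all_pairs[[length(all_pairs) + 1]] <- mc$pairs
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else NULL
  list(pairs = pairs, table = strata_tests(pairs, frame_rate = frame_rate),
       qc = c(vt$qc, unmatched = unmatched))
}
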
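#' Simulate a dyadic recording with ground truth
#'
#' Two mice perform biased correlated random walks with reflecting
#' boundaries: persistent headings steered toward the partner with the
#' attraction gain, plus a smooth mean-reverting speed process (see
#' [behavior_params()]). Each frame, a vocal signal is emitted with
#' probability `emission_hazard_near` when the inter-mouse distance is
#' below `near_threshold` and `emission_hazard_far` otherwise; the
#' vocalizer is chosen uniformly and the source is placed at the
#' vocalizer's nose. Every event carries a frequency contour (a
#' piecewise-linear sweep within 30-110 kHz) used later for audio
#' rendering.
#'
#' @param arena an [arena_config()].
#' @param behavior a [behavior_params()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list of class `dyad_sim` with elements:
#'   \describe{
#'     \item{tracks}{data.frame with columns `frame`, `mouse_id`,
#'       `nose_x_cm`, `nose_y_cm`, `centroid_x_cm`, `centroid_y_cm`.}
#'     \item{events}{data.frame with `event_id`, `time_s`, `frame`,
#'       `vocalizer_id`, `source_x_cm`, `source_y_cm`.}
#'     \item{contours}{list (one per event) of data.frames `t_s`, `freq_khz`
#'       with `t_s` relative to signal onset.}
#'     \item{arena, behavior}{the inputs.}
#'   }
#' @examples
#' sim <- simulate_dyad(arena_config(duration = 10), behavior_params(), seed = 1)
#' nrow(sim$events)
#' @export
simulate_dyad <- function(arena, behavior, seed) {
  stopifnot(inherits(arena, "arena_config"), inherits(behavior, "behavior_params"))
  if (arena$duration < 0) stop("duration must be non-negative", call. = FALSE)
  n <- floor(arena$duration * arena$frame_rate)
  side <- arena$side_length
  empty_tracks <- data.frame(frame = integer(), mouse_id = integer(),
                             nose_x_cm = numeric(), nose_y_cm = numeric(),
                             centroid_x_cm = numeric(), centroid_y_cm = numeric())
  empty_events <- data.frame(event_id = integer(), time_s = numeric(),
                             frame = integer(), vocalizer_id = integer(),
                             source_x_cm = numeric(), source_y_cm = numeric())
  if (n < 1L)
    return(structure(list(tracks = empty_tracks, events = empty_events,
                          contours = list(), arena = arena, behavior = behavior),
                     class = "dyad_sim"))

  fps <- arena$frame_rate
  b <- behavior
  with_seed(seed, {
    pos <- array(NA_real_, c(n, 2, 2))            # frame x (x,y) x mouse
    theta <- stats::runif(2, 0, 2 * pi)           # headings
    spd <- stats::rnorm(2, b$speed_mean_cm_s,
                        b$speed_noise_sd / sqrt(max(1 - b$speed_rho^2, 1e-9)))
    spd <- pmax(spd, 0)
    pos[1, , 1] <- stats::runif(2, 0, side)
    pos[1, , 2] <- stats::runif(2, 0, side)
    voc_frame <- integer(0); voc_id <- integer(0)
    attr_sched <- if (n > 1)
      seq(b$attraction_start, b$attraction_end, length.out = n) else b$attraction_start
    headings <- matrix(NA_real_, n, 2)
    headings[1, ] <- theta

    for (t in seq_len(n)) {
      if (t > 1L) {
        a <- attr_sched[t]
        for (m in 1:2) {
          self <- pos[t - 1, , m]; partner <- pos[t - 1, , 3 - m]
          bearing <- atan2(partner[2] - self[2], partner[1] - self[1])
          dtheta <- ((bearing - theta[m] + pi) %% (2 * pi)) - pi
          theta[m] <- theta[m] + a * dtheta + stats::rnorm(1, 0, b$turn_sd)
          spd[m] <- max(0, b$speed_mean_cm_s +
                          b$speed_rho * (spd[m] - b$speed_mean_cm_s) +
                          stats::rnorm(1, 0, b$speed_noise_sd))
          step <- spd[m] / fps * c(cos(theta[m]), sin(theta[m]))
          p <- self + step
          # reflecting boundaries: fold position, flip heading component
          if (p[1] < 0 || p[1] > side) {
            p[1] <- if (p[1] < 0) -p[1] else 2 * side - p[1]
            theta[m] <- pi - theta[m]
          }
          if (p[2] < 0 || p[2] > side) {
            p[2] <- if (p[2] < 0) -p[2] else 2 * side - p[2]
            theta[m] <- -theta[m]
          }
          pos[t, , m] <- pmin(pmax(p, 0), side)
          headings[t, m] <- theta[m]
        }
      }
      dist_t <- sqrt(sum((pos[t, , 1] - pos[t, , 2])^2))
      hz <- if (dist_t < b$near_threshold) b$emission_hazard_near else b$emission_hazard_far
      if (stats::runif(1) < hz) {
        voc_frame <- c(voc_frame, t)
        voc_id <- c(voc_id, sample.int(2L, 1L))
      }
    }

    # nose = centroid + nose_offset along heading
    nose <- array(NA_real_, c(n, 2, 2))
    for (m in 1:2) {
      u <- cbind(cos(headings[, m]), sin(headings[, m]))
      nose[, , m] <- pmin(pmax(pos[, , m] + b$nose_offset * u, 0), side)
    }

    ne <- length(voc_frame)
    contours <- vector("list", ne)
    events <- empty_events
    if (ne > 0) {
      src <- t(vapply(seq_len(ne), function(i)
        nose[voc_frame[i], , voc_id[i]], numeric(2)))
      events <- data.frame(event_id = seq_len(ne),
                           time_s = (voc_frame - 1) / fps,
                           frame = voc_frame,
                           vocalizer_id = voc_id,
                           source_x_cm = src[, 1], source_y_cm = src[, 2])
      for (i in seq_len(ne)) {
        dur <- stats::runif(1, 0.03, 0.07)
        f0 <- stats::runif(1, 45, 95)
        f1 <- min(max(f0 + stats::runif(1, -20, 20), 32), 108)
        contours[[i]] <- data.frame(t_s = c(0, dur), freq_khz = c(f0, f1))
      }
    }

    tracks <- data.frame(
      frame = rep(seq_len(n), 2L),
      mouse_id = rep(1:2, each = n),
      nose_x_cm = c(nose[, 1, 1], nose[, 1, 2]),
      nose_y_cm = c(nose[, 2, 1], nose[, 2, 2]),
      centroid_x_cm = c(pos[, 1, 1], pos[, 1, 2]),
      centroid_y_cm = c(pos[, 2, 1], pos[, 2, 2]))

    structure(list(tracks = tracks, events = events, contours = contours,
                   arena = arena, behavior = behavior),
              class = "dyad_sim")
  })
}

#' Inject a post-emission acceleration "kick" into the receiving mouse
#'
#' After each attributed emission, the non-vocalizing (receiving) mouse's
#' speed is increased at a constant rate `kick_magnitude` (cm/s^2) for
#' `kick_window` frames: at the j-th frame after emission the speed gain is
#' `j * kick_magnitude / frame_rate` cm/s. Overlapping kicks superpose
#' additively. Positions are re-integrated from the scaled per-frame
#' displacements (direction preserved) and folded back into the arena, and
#' nose markers keep their offset from the centroid.
#'
#' @param tracks tracks data.frame as produced by [simulate_dyad()].
#' @param events events data.frame with `frame` and `vocalizer_id`.
#' @param kick_magnitude acceleration, cm/s^2; 0 returns `tracks` unchanged.
#' @param kick_window frames the kick acts over (>= 1).
#' @param frame_rate video frame rate, Hz.
#' @param side_length arena side for boundary folding, cm.
#' @return tracks data.frame of the same shape.
#' @export
inject_response_kick <- function(tracks, events, kick_magnitude,
                                 kick_window = 5, frame_rate = 30,
                                 side_length = 76) {
  if (kick_magnitude == 0) return(tracks)
  if (kick_window < 1) stop("kick_window must be >= 1", call. = FALSE)
  kick_window <- as.integer(kick_window)
  frames <- sort(unique(tracks$frame))
  n <- length(frames)
  out <- tracks
  for (m in 1:2) {
    sel <- tracks$mouse_id == m
    tm <- tracks[sel, ]
    tm <- tm[order(tm$frame), ]
    dv <- numeric(n)  # speed increment, cm/s
    ev_m <- events[events$vocalizer_id == (3 - m), , drop = FALSE]
    for (e in ev_m$frame) {
      j_end <- min(e + kick_window, n)
      if (j_end <= e) { message("kick truncated at recording tail"); next }
      j <- seq(e + 1L, j_end)
      if (j_end < e + kick_window) message("kick truncated at recording tail")
      dv[j] <- dv[j] + (j - e) * kick_magnitude / frame_rate
    }
    if (all(dv == 0)) next
    p <- cbind(tm$centroid_x_cm, tm$centroid_y_cm)
    noff <- cbind(tm$nose_x_cm, tm$nose_y_cm) - p
    d <- rbind(c(0, 0), diff(p))
    len <- sqrt(rowSums(d^2))
    new_len <- len + dv / frame_rate  # dv [cm/s] -> cm/frame
    scale <- ifelse(len > 0, new_len / len, 0)
    d2 <- d * scale
    # zero-length steps that must gain speed move along the previous heading
    need <- which(len == 0 & new_len > 0)
    if (length(need)) {
      u <- c(1, 0)
      for (t in seq_len(n)) {
        if (len[t] > 0) u <- d[t, ] / len[t]
        if (t %in% need) d2[t, ] <- u * new_len[t]
      }
    }
    p2 <- apply(d2, 2, cumsum) + rep(p[1, ], each = n)
    p2 <- fold_into(p2, side_length)
    out[sel, c("centroid_x_cm", "centroid_y_cm")][order(tracks$frame[sel]), ] <- p2
    np <- pmin(pmax(p2 + noff, 0), side_length)
    out[sel, c("nose_x_cm", "nose_y_cm")][order(tracks$frame[sel]), ] <- np
  }
  out
}

# fold coordinates back into [0, side] by reflection
fold_into <- function(p, side) {
  q <- p %% (2 * side)
  q <- ifelse(q > side, 2 * side - q, q)
  q
}
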
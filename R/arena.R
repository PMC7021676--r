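#' Recording-arena configuration
#'
#' Describes the square arena, video frame rate, recording duration and the
#' eight-microphone array geometry. Defaults follow a typical mouse
#' social-interaction setup: a 76 x 76 cm arena, 30 Hz video, 30 min
#' recordings, and eight microphones evenly spaced around the arena
#' perimeter at a fixed height.
#'
#' @param side_length arena side, cm.
#' @param frame_rate video frame rate, Hz.
#' @param duration recording duration, s.
#' @param mic_positions 8 x 3 matrix of microphone (x, y, z) positions in cm,
#'   or `NULL` for the default perimeter layout.
#' @param mic_height height used for the default microphone layout, cm.
#' @return an object of class `arena_config`.
#' @examples
#' arena <- arena_config(duration = 60)
#' arena$mic_positions
#' @export
arena_config <- function(side_length = 76, frame_rate = 30, duration = 1800,
                         mic_positions = NULL, mic_height = 40) {
  stopifnot_scalar_num(side_length, "side_length", lo = 1e-6)
  stopifnot_scalar_num(frame_rate, "frame_rate", lo = 1e-6)
  stopifnot_scalar_num(duration, "duration", lo = 0)
  if (is.null(mic_positions))
    mic_positions <- default_mic_positions(side_length, mic_height)
  mic_positions <- as.matrix(mic_positions)
  if (nrow(mic_positions) != 8L || ncol(mic_positions) != 3L)
    stop("`mic_positions` must be an 8 x 3 matrix of (x, y, z) in cm",
         call. = FALSE)
  if (any(mic_positions[, 1] < -1e-9 | mic_positions[, 1] > side_length + 1e-9) ||
      any(mic_positions[, 2] < -1e-9 | mic_positions[, 2] > side_length + 1e-9))
    stop("microphone x/y must lie within or on the arena boundary", call. = FALSE)
  structure(list(side_length = side_length, frame_rate = frame_rate,
                 duration = duration, mic_positions = mic_positions),
            class = "arena_config")
}

#' Default eight-microphone perimeter layout
#'
#' Corners plus edge midpoints of the arena, all at one height. Any
#' non-degenerate (non-collinear) layout works for localization; this one is
#' symmetric and surrounds every source position.
#'
#' @param side_length arena side, cm.
#' @param height microphone height above the floor, cm.
#' @return 8 x 3 matrix.
#' @export
default_mic_positions <- function(side_length = 76, height = 40) {
  s <- side_length
  xy <- rbind(c(0, 0), c(s / 2, 0), c(s, 0), c(s, s / 2),
              c(s, s), c(s / 2, s), c(0, s), c(0, s / 2))
  cbind(xy, rep(height, 8L))
}

#' Behavioral parameters for the dyad simulator
#'
#' The simulator emulates two freely moving mice as biased correlated
#' random walks: each animal keeps a persistent heading that is steered
#' toward the partner with gain `attraction` and perturbed by turn noise,
#' while its speed follows a smooth mean-reverting (Ornstein-Uhlenbeck)
#' process. Smooth speeds matter: real mouse speed varies slowly at the
#' video frame scale, and the post-emission acceleration statistic assumes
#' frame-to-frame speed changes far smaller than the speed itself.
#'
#' Contexts (same-sex vs opposite-sex) differ only through parameter
#' values: opposite-sex pairs are attracted from the start, same-sex pairs
#' ramp attraction up over the recording, which reproduces the later
#' proximity build-up and later vocal emission seen in same-sex pairs.
#'
#' @param context `"opposite_sex"` or `"same_sex"`.
#' @param attraction_start,attraction_end heading-steering gain toward the
#'   partner (0 = ignore partner, 1 = turn straight at it each frame) at
#'   the start/end of the recording, linearly interpolated in between.
#' @param speed_mean_cm_s mean speed of the OU speed process, cm/s.
#' @param speed_rho per-frame autocorrelation of the speed process.
#' @param speed_noise_sd per-frame speed innovation SD, cm/s; sets the
#'   acceleration noise floor of the trajectory statistics.
#' @param turn_sd heading noise per frame, radians.
#' @param emission_hazard_near,emission_hazard_far per-frame emission
#'   probability when the mice are closer/farther than `near_threshold`.
#' @param near_threshold distance threshold for the emission hazard, cm.
#' @param kick_magnitude post-emission acceleration injected into the
#'   receiving mouse, cm/s^2 (0 disables the kick).
#' @param kick_window number of frames over which the kick acts.
#' @param nose_offset distance from centroid to nose marker, cm.
#' @return object of class `behavior_params`.
#' @export
behavior_params <- function(context = c("opposite_sex", "same_sex"),
                            attraction_start = NULL, attraction_end = NULL,
                            speed_mean_cm_s = 8, speed_rho = 0.98,
                            speed_noise_sd = 0.025, turn_sd = 0.4,
                            emission_hazard_near = 0.02,
                            emission_hazard_far = 0.002,
                            near_threshold = 20,
                            kick_magnitude = 0, kick_window = 5,
                            nose_offset = 3) {
  context <- match.arg(context)
  if (is.null(attraction_start))
    attraction_start <- if (context == "opposite_sex") 0.08 else 0
  if (is.null(attraction_end))
    attraction_end <- 0.08
  stopifnot_scalar_num(emission_hazard_near, "emission_hazard_near", 0, 1)
  stopifnot_scalar_num(emission_hazard_far, "emission_hazard_far", 0, 1)
  stopifnot_scalar_num(near_threshold, "near_threshold", lo = 1e-9)
  stopifnot_scalar_num(speed_mean_cm_s, "speed_mean_cm_s", lo = 0)
  stopifnot_scalar_num(speed_rho, "speed_rho", 0, 1)
  stopifnot_scalar_num(speed_noise_sd, "speed_noise_sd", lo = 0)
  stopifnot_scalar_num(turn_sd, "turn_sd", lo = 0)
  stopifnot_scalar_num(kick_window, "kick_window", lo = 1)
  structure(list(context = context,
                 attraction_start = attraction_start,
                 attraction_end = attraction_end,
                 speed_mean_cm_s = speed_mean_cm_s,
                 speed_rho = speed_rho,
                 speed_noise_sd = speed_noise_sd,
                 turn_sd = turn_sd,
                 emission_hazard_near = emission_hazard_near,
                 emission_hazard_far = emission_hazard_far,
                 near_threshold = near_threshold,
                 kick_magnitude = kick_magnitude,
                 kick_window = as.integer(kick_window),
                 nose_offset = nose_offset),
            class = "behavior_params")
}
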
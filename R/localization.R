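SPEED_OF_SOUND_CM_S <- 34300  # 343 m/s in cm/s

# pairwise arrival-time differences (s) between channels by windowed
# cross-correlation with parabolic sub-sample peak interpolation.
# tau[i,j] > 0 means the signal reached channel i later than channel j.
pair_delays <- function(x, fs, start_s, stop_s, band_khz = c(30, 110),
                        max_delay_s = NULL) {
  nch <- ncol(x)
  pad <- max_delay_s %||% (150 / SPEED_OF_SOUND_CM_S)
  i0 <- max(1L, floor((start_s - pad) * fs))
  i1 <- min(nrow(x), ceiling((stop_s + pad) * fs))
  seg <- x[i0:i1, , drop = FALSE]
  n <- nrow(seg)
  maxlag <- min(n - 1L, ceiling(pad * fs))
  nfft <- stats::nextn(n + maxlag, 2)
  Fx <- stats::mvfft(rbind(seg, matrix(0, nfft - n, nch)))
  tau <- matrix(0, nch, nch)
  peak <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1)) for (j in seq(i + 1, nch)) {
    cc <- Re(stats::fft(Fx[, i] * Conj(Fx[, j]), inverse = TRUE)) / nfft
    lags <- c(0:maxlag, -(maxlag:1))
    vals <- cc[c(seq_len(maxlag + 1), nfft - maxlag + seq_len(maxlag) - 0)]
    k <- which.max(vals)
    lag <- lags[k]
    # parabolic interpolation around the peak (wrap-safe via modular index)
    km <- ((k - 2) %% length(vals)) + 1; kp <- (k %% length(vals)) + 1
    y1 <- vals[km]; y2 <- vals[k]; y3 <- vals[kp]
    denom <- y1 - 2 * y2 + y3
    frac <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
    frac <- max(min(frac, 0.5), -0.5)
    tau[i, j] <- (lag + frac) / fs
    tau[j, i] <- -tau[i, j]
    peak[i, j] <- peak[j, i] <-
      y2 / sqrt(sum(seg[, i]^2) * sum(seg[, j]^2) + .Machine$double.eps)
  }
  list(tau = tau, peak = peak)
}

# least-squares hyperbolic positioning: find (x, y) on the floor minimizing
# sum over microphone pairs of (c * tau_ij - (d_i - d_j))^2.
solve_tdoa <- function(tau, mics, side, pairs) {
  cc <- SPEED_OF_SOUND_CM_S
  obj <- function(p) {
    d <- sqrt((p[1] - mics[, 1])^2 + (p[2] - mics[, 2])^2 + mics[, 3]^2)
    r <- cc * tau[pairs] - (d[pairs[, 1]] - d[pairs[, 2]])
    sum(r^2)
  }
  g <- seq(2, side - 2, by = 4)
  grid <- as.matrix(expand.grid(g, g))
  vals <- apply(grid, 1, obj)
  p0 <- grid[which.min(vals), ]
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  pmin(pmax(fit$par, 0), side)
}

#' Jackknife (leave-one-microphone-out) source localization
#'
#' Pairwise time delays among the eight channels are estimated once by
#' cross-correlation restricted to the signal's time support (audio is
#' assumed band-passed to the signal band). Eight source estimates are then
#' produced, each omitting one microphone and solving a hyperbolic
#' least-squares problem over the remaining seven; the coordinate-wise mean
#' of the eight estimates is the sound-source estimate.
#'
#' @param audio `multichannel_audio` or samples x 8 matrix (band-passed).
#' @param signal one row of a segmentation result (needs `start_s`,
#'   `stop_s`), or a list with those fields.
#' @param arena [arena_config()] supplying microphone geometry.
#' @param fs sampling rate, Hz.
#' @param min_peak normalized cross-correlation floor below which a pair is
#'   counted as unreliable; more than 3 unreliable pairs per subset flags
#'   the estimate `low_confidence`.
#' @return object of class `jackknife_set`: `estimates` (8 x 2 matrix, cm),
#'   `mean_estimate` (length-2), `low_confidence` (logical).
#' @export
jackknife_localize <- function(audio, signal, arena, fs = NULL,
                               min_peak = 0.05) {
  if (inherits(audio, "multichannel_audio")) {
    fs <- fs %||% audio$fs
    x <- audio$samples
  } else x <- as.matrix(audio)
  mics <- arena$mic_positions
  if (nrow(mics) != 8L) stop("eight microphones required", call. = FALSE)
  if (qr(cbind(1, mics[, 1:2]))$rank < 3)
    stop("degenerate (collinear) microphone geometry", call. = FALSE)
  if (signal$stop_s - signal$start_s < 0.005)
    stop("signal support shorter than 5 ms", call. = FALSE)
  pd <- pair_delays(x, fs, signal$start_s, signal$stop_s)
  est <- matrix(NA_real_, 8, 2)
  low <- FALSE
  for (omit in 1:8) {
    keep <- setdiff(1:8, omit)
    pairs <- t(utils::combn(keep, 2))
    if (sum(pd$peak[pairs] < min_peak) > 3) low <- TRUE
    est[omit, ] <- solve_tdoa(pd$tau, mics, arena$side_length, pairs)
  }
  new_jackknife_set(est, low)
}

new_jackknife_set <- function(estimates, low_confidence = FALSE) {
  stopifnot(nrow(estimates) == 8L, ncol(estimates) == 2L)
  structure(list(estimates = estimates, mean_estimate = colMeans(estimates),
                 low_confidence = low_confidence),
            class = "jackknife_set")
}

#' Simulate a jackknife estimate set from a known source
#'
#' Places the eight leave-one-out estimates at the true source plus
#' independent isotropic Gaussian scatter. Used to validate the density /
#' Mouse Probability Index layer at a controlled localization noise level
#' without rendering audio.
#'
#' @param source_xy true source position, cm.
#' @param sigma_cm estimate scatter SD per coordinate, cm.
#' @param seed integer seed.
#' @return `jackknife_set`.
#' @export
jackknife_from_truth <- function(source_xy, sigma_cm = 1, seed = 1) {
  with_seed(seed, {
    est <- cbind(source_xy[1] + stats::rnorm(8, 0, sigma_cm),
                 source_xy[2] + stats::rnorm(8, 0, sigma_cm))
    new_jackknife_set(est)
  })
}

#' Spatial probability density of a signal's origin
#'
#' A bivariate Gaussian with mean at the sound-source estimate and
#' covariance equal to the sample covariance of the eight jackknife
#' estimates (regularized by +0.25 cm^2 on the diagonal so eight identical
#' points still give a proper density), evaluated on a raster over the
#' arena, floored at a small positive value and renormalized so the density
#' integrates to one over the arena.
#'
#' @param jack `jackknife_set`.
#' @param arena [arena_config()].
#' @param cell_cm grid cell size, cm (<= 1 cm).
#' @param floor_density minimum density, 1/cm^2.
#' @return object of class `source_density`: `values` (x-index by y-index
#'   matrix, 1/cm^2), `grid_x`, `grid_y` (cell centers), `cell_cm`.
#' @export
build_density <- function(jack, arena, cell_cm = 0.5, floor_density = 1e-12) {
  est <- jack$estimates
  mu <- jack$mean_estimate
  S <- stats::cov(est) + diag(0.25, 2)
  Sinv <- solve(S)
  dt <- det(S)
  gx <- seq(cell_cm / 2, arena$side_length - cell_cm / 2, by = cell_cm)
  gy <- gx
  dx <- outer(gx - mu[1], rep(1, length(gy)))
  dy <- outer(rep(1, length(gx)), gy - mu[2])
  q <- Sinv[1, 1] * dx^2 + 2 * Sinv[1, 2] * dx * dy + Sinv[2, 2] * dy^2
  v <- exp(-q / 2) / (2 * pi * sqrt(dt))
  v <- pmax(v, floor_density)
  v <- v / (sum(v) * cell_cm^2)
  structure(list(values = v, grid_x = gx, grid_y = gy, cell_cm = cell_cm,
                 floor = min(v)),
            class = "source_density")
}

#' Mouse Probability Index from per-mouse density values
#'
#' `MPI_n = D_n / sum_i D_i`: each mouse's share of the source-density
#' values read at the animals' nose positions. Values sum to one exactly.
#'
#' @param d vector of per-mouse density values (1/cm^2).
#' @return vector of MPI values in `[0, 1]`.
#' @examples
#' mpi_index(c(19, 1))  # 0.95, 0.05
#' @export
mpi_index <- function(d) {
  if (any(d < 0) || sum(d) <= 0) stop("density values must be positive")
  d / sum(d)
}

#' Read nose densities, compute the MPI, and assign a vocalizer
#'
#' Each mouse receives the density value at its nose cell (positions
#' outside the grid are clamped to the nearest cell). The signal is
#' assigned to the mouse with the largest Mouse Probability Index only if
#' that index reaches `threshold` (0.95 by default); otherwise it is left
#' unassigned.
#'
#' @param density `source_density`.
#' @param nose_positions 2 x 2 matrix, one row per mouse, (x, y) cm.
#' @param threshold assignment threshold on the maximum MPI.
#' @return object of class `mpi_result`: `D`, `mpi`, `assigned_to` (mouse
#'   index or `NA`), `threshold`.
#' @export
compute_mpi_and_assign <- function(density, nose_positions, threshold = 0.95) {
  np <- as.matrix(nose_positions)
  idx <- function(v, grid) pmin(pmax(round((v - grid[1]) / diff(grid[1:2])) + 1, 1),
                                length(grid))
  ix <- idx(np[, 1], density$grid_x)
  iy <- idx(np[, 2], density$grid_y)
  D <- density$values[cbind(ix, iy)]
  mpi <- mpi_index(D)
  assigned <- if (max(mpi) >= threshold) which.max(mpi) else NA_integer_
  structure(list(D = D, mpi = mpi, assigned_to = assigned,
                 threshold = threshold),
            class = "mpi_result")
}

#' Attribute segmented signals to mice
#'
#' Runs the jackknife-density-MPI chain for each signal and pairs the
#' result with the tracked nose positions at the video frame containing the
#' signal start.
#'
#' @param signals data.frame with `signal_id`, `start_s`, `stop_s`.
#' @param tracks tracks data.frame (see [simulate_dyad()]).
#' @param arena [arena_config()].
#' @param jackknife_fun function(signal_row) -> `jackknife_set`; either a
#'   closure over audio calling [jackknife_localize()], or a simulator such
#'   as [jackknife_from_truth()] bound to ground truth.
#' @param frame_rate video frame rate, Hz.
#' @param threshold MPI assignment threshold.
#' @param cell_cm density grid cell, cm.
#' @return data.frame: `signal_id`, `time_s`, `mpi_mouse1`, `mpi_mouse2`,
#'   `assigned_to` (NA when unassigned).
#' @export
attribute_events <- function(signals, tracks, arena, jackknife_fun,
                             frame_rate = 30, threshold = 0.95,
                             cell_cm = 0.5) {
  n_frames <- max(tracks$frame)
  res <- lapply(seq_len(nrow(signals)), function(i) {
    sg <- signals[i, ]
    jack <- jackknife_fun(sg)
    dens <- build_density(jack, arena, cell_cm = cell_cm)
    fr <- min(max(floor(sg$start_s * frame_rate) + 1, 1), n_frames)
    noses <- as.matrix(tracks[tracks$frame == fr, ][
      order(tracks$mouse_id[tracks$frame == fr]),
      c("nose_x_cm", "nose_y_cm")])
    m <- compute_mpi_and_assign(dens, noses, threshold)
    data.frame(signal_id = sg$signal_id, time_s = sg$start_s,
               mpi_mouse1 = m$mpi[1], mpi_mouse2 = m$mpi[2],
               assigned_to = ifelse(is.na(m$assigned_to), NA_integer_,
                                    m$assigned_to))
  })
  do.call(rbind, res)
}
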
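#' Render a dyadic recording to eight-channel audio
#'
#' Each ground-truth event is rendered as a frequency-modulated tone
#' following its contour (piecewise-linear frequency, phase integrated
#' analytically), delayed at each microphone by the source-microphone
#' distance over the speed of sound (343 m/s; fractional delays are exact
#' because the tone is evaluated in continuous time) and scaled by 1/r.
#' Independent Gaussian noise is added per channel.
#'
#' The nominal SNR is defined at a reference propagation distance
#' `ref_dist_cm`: a tone received from that distance has RMS
#' `10^(snr_db/20)` times the per-channel noise RMS. Closer microphones see
#' higher SNR, farther ones lower.
#'
#' @param sim a `dyad_sim` (or any list with `events`, `contours`, `arena`).
#' @param snr_db nominal signal-to-noise ratio, dB.
#' @param seed integer seed for the noise.
#' @param fs audio sampling rate, Hz (250 kHz standard for USV work).
#' @param ref_dist_cm reference distance for the SNR definition, cm.
#' @param duration_s optional audio duration; defaults to the arena duration.
#' @return list of class `multichannel_audio` with `samples` (n x 8 matrix),
#'   `fs`, and `noise_sd`.
#' @export
synthesize_audio <- function(sim, snr_db = 20, seed = 1, fs = 250000,
                             ref_dist_cm = 25, duration_s = NULL) {
  arena <- sim$arena
  mics <- arena$mic_positions
  dur <- duration_s %||% arena$duration
  n <- floor(dur * fs)
  amp_ref <- 1                                   # tone amplitude at ref distance
  noise_sd <- (amp_ref / sqrt(2)) / 10^(snr_db / 20)
  c_cm <- 34300                                  # speed of sound, cm/s
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * 8L, 0, noise_sd), n, 8L)
    ev <- sim$events
    for (i in seq_len(nrow(ev))) {
      ct <- sim$contours[[i]]
      if (any(ct$freq_khz < 30 | ct$freq_khz > 110))
        stop("contour frequencies must lie within 30-110 kHz", call. = FALSE)
      t0 <- ev$time_s[i]
      sig_dur <- max(ct$t_s)
      if (t0 + sig_dur > dur) message("event ", i, " truncated at recording end")
      src <- c(ev$source_x_cm[i], ev$source_y_cm[i], 0)
      for (ch in 1:8) {
        r <- sqrt(sum((src - mics[ch, ])^2))
        tau <- r / c_cm
        amp <- amp_ref * ref_dist_cm / max(r, 1)
        i0 <- max(1L, floor((t0 + tau) * fs) + 1L)
        i1 <- min(n, ceiling((t0 + sig_dur + tau) * fs) + 1L)
        if (i1 < i0) next
        ts <- (seq(i0, i1) - 1) / fs
        u <- ts - t0 - tau
        ok <- u >= 0 & u <= sig_dur
        if (!any(ok)) next
        s <- amp * taper_env(u[ok], sig_dur) * sin(contour_phase(u[ok], ct))
        x[seq(i0, i1)[ok], ch] <- x[seq(i0, i1)[ok], ch] + s
      }
    }
    structure(list(samples = x, fs = fs, noise_sd = noise_sd),
              class = "multichannel_audio")
  })
}

# phase (rad) of a piecewise-linear frequency contour at times u >= 0
contour_phase <- function(u, contour) {
  tk <- contour$t_s
  fk <- contour$freq_khz * 1000
  if (length(tk) == 1L) return(2 * pi * fk * u)
  # cumulative integral of f at the breakpoints
  Fi <- c(0, cumsum(diff(tk) * (head(fk, -1) + tail(fk, -1)) / 2))
  seg <- findInterval(u, tk, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(tk) - 1L)
  slope <- (fk[seg + 1] - fk[seg]) / (tk[seg + 1] - tk[seg])
  du <- u - tk[seg]
  2 * pi * (Fi[seg] + fk[seg] * du + 0.5 * slope * du^2)
}

# raised-cosine onset/offset ramp (2 ms or 10% of the call, whichever smaller)
taper_env <- function(u, dur) {
  ramp <- min(0.002, 0.1 * dur)
  env <- rep(1, length(u))
  a <- u < ramp
  env[a] <- 0.5 * (1 - cos(pi * u[a] / ramp))
  b <- u > dur - ramp
  env[b] <- 0.5 * (1 - cos(pi * (dur - u[b]) / ramp))
  env
}
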
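#' Zero-phase FFT band filter
#'
#' Frequency-domain band-pass with raised-cosine transition edges: unity
#' gain on `[low_hz, high_hz]`, cosine roll-off over a short transition
#' band just outside each edge, and exactly zero beyond it — so stop-band
#' attenuation outside the transition regions is unbounded (certainly
#' >= 40 dB). Zero-phase by construction; an online port would need a
#' causal realization instead.
#'
#' @param x numeric vector, or channels x samples matrix (filtered per row)
#' @param rate sampling rate in Hz
#' @param low_hz,high_hz pass-band edges in Hz
#' @param trans_low,trans_high transition widths in Hz (defaults: 40% of the
#'   low edge capped at 10 Hz; 7% of the high edge)
#' @return filtered object of the same shape
#' @export
fft_bandfilter <- function(x, rate, low_hz, high_hz,
                           trans_low = min(10, 0.4 * low_hz),
                           trans_high = 0.07 * high_hz) {
  if (low_hz >= high_hz) stop("band edges inverted", call. = FALSE)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(m)
  f <- abs(seq(0, n - 1) * rate / n)
  f <- pmin(f, rate - f)                       # two-sided frequency axis
  g <- numeric(n)
  g[f >= low_hz & f <= high_hz] <- 1
  lo <- f < low_hz & f > low_hz - trans_low
  g[lo] <- 0.5 * (1 - cos(pi * (f[lo] - (low_hz - trans_low)) / trans_low))
  hi <- f > high_hz & f < high_hz + trans_high
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - high_hz) / trans_high))
  X <- stats::mvfft(t(m))        # columns = channels; g recycles per column
  y <- t(Re(stats::mvfft(X * g, inverse = TRUE))) / n
  if (vec) as.vector(y) else y
}

# Zero-phase FFT low-pass (anti-alias helper), cosine roll-off ending at
# `stop_hz`.
fft_lowpass <- function(m, rate, pass_hz, stop_hz) {
  n <- ncol(m)
  f <- abs(seq(0, n - 1) * rate / n)
  f <- pmin(f, rate - f)
  g <- numeric(n)
  g[f <= pass_hz] <- 1
  tr <- f > pass_hz & f < stop_hz
  g[tr] <- 0.5 * (1 + cos(pi * (f[tr] - pass_hz) / (stop_hz - pass_hz)))
  X <- stats::mvfft(t(m))
  t(Re(stats::mvfft(X * g, inverse = TRUE))) / n
}

#' Band-limit and resample a recording
#'
#' Converts a raw recording (e.g. 40 kHz) to the processed stream: the data
#' are first low-pass anti-alias filtered and decimated to `target_rate`,
#' then band-passed to `[low_hz, high_hz]` — the band that carries most of
#' the decodable power. Channel count and nerve map are preserved.
#'
#' @param recording a [nerve_recording()]
#' @param low_hz,high_hz band edges (defaults 25 and 600 Hz)
#' @param target_rate output rate; the input rate must be an integer
#'   multiple of it, and `high_hz < target_rate / 2`
#' @return a [nerve_recording()] at `target_rate`
#' @export
bandlimit <- function(recording, low_hz = 25, high_hz = 600,
                      target_rate = 5000) {
  stopifnot(inherits(recording, "nd_recording"))
  if (low_hz >= high_hz) stop("band edges inverted", call. = FALSE)
  if (high_hz >= target_rate / 2)
    stop("high_hz must be below the output Nyquist rate", call. = FALSE)
  r <- recording$sample_rate / target_rate
  if (abs(r - round(r)) > 1e-9)
    stop("input rate must be an integer multiple of target_rate", call. = FALSE)
  r <- as.integer(round(r))
  m <- recording$samples
  if (r > 1L) {
    m <- fft_lowpass(m, recording$sample_rate,
                     pass_hz = 0.4 * target_rate, stop_hz = 0.5 * target_rate)
    m <- m[, seq(1L, ncol(m), by = r), drop = FALSE]
  }
  m <- fft_bandfilter(m, target_rate, low_hz, high_hz)
  nerve_recording(m, target_rate, recording$channel_nerve)
}

#' Cut a recording into pseudo-online trials
#'
#' Slides a causal window of `window_s` seconds along the recording in
#' steps of `step_s`, mimicking real-time decoding where only past samples
#' are visible. Each trial carries its signal slice (by reference into the
#' parent recording), its ground-truth trajectory resampled to the 20 ms
#' feature step (one value at each feature-window end), and a finger-state
#' label: a finger is active if either of its two DOF exceeds
#' `activity_threshold` anywhere in the trial.
#'
#' @param recording a [nerve_recording()]
#' @param trajectories a [trajectory_set()] sample-aligned with `recording`
#' @param window_s window length in seconds (default 4)
#' @param step_s increment in seconds (default 0.1)
#' @param activity_threshold trajectory level above which a DOF counts as
#'   active (default 0.1)
#' @param feature_step_s spacing of the stored trajectory columns
#'   (default 0.02, i.e. 200 columns for a 4 s trial)
#' @return list of `nd_trial` objects; each has `$start`, `$end` (sample
#'   indices), `$t_end` (seconds), `$trajectory` (10 x window/feature_step),
#'   `$finger_state`, and `$recording` (shared parent)
#' @export
cut_trials <- function(recording, trajectories, window_s = 4, step_s = 0.1,
                       activity_threshold = 0.1, feature_step_s = 0.02) {
  stopifnot(inherits(recording, "nd_recording"),
            inherits(trajectories, "nd_trajectories"))
  if (ncol(recording$samples) != ncol(trajectories$values) ||
      recording$sample_rate != trajectories$sample_rate)
    stop("recording and trajectories are misaligned", call. = FALSE)
  rate <- recording$sample_rate
  n <- ncol(recording$samples)
  duration <- n / rate
  if (window_s > duration + 1e-9)
    stop("window longer than recording", call. = FALSE)
  win_n <- round(window_s * rate)
  step_n <- round(step_s * rate)
  fstep_n <- round(feature_step_s * rate)
  n_cols <- win_n %/% fstep_n
  ends <- seq(win_n, n, by = step_n)
  lapply(ends, function(e) {
    s <- e - win_n + 1L
    col_idx <- s - 1L + fstep_n * seq_len(n_cols)
    tr <- trajectories$values[, col_idx, drop = FALSE]
    full <- trajectories$values[, s:e, drop = FALSE]
    dof_max <- apply(full, 1, max)
    fs <- as.integer(pmax(dof_max[seq(1, 9, 2)], dof_max[seq(2, 10, 2)]) >
                       activity_threshold)
    structure(list(start = as.integer(s), end = as.integer(e),
                   t_end = e / rate, trajectory = tr, finger_state = fs,
                   recording = recording),
              class = "nd_trial")
  })
}

#' Extract the raw signal slice of a trial
#'
#' @param trial an `nd_trial`
#' @return channels x samples matrix for the trial window
#' @export
trial_signal <- function(trial) {
  trial$recording$samples[, trial$start:trial$end, drop = FALSE]
}

#' @export
print.nd_trial <- function(x, ...) {
  cat(sprintf("<trial ending at %.2f s, state %s>\n", x$t_end,
              paste(x$finger_state, collapse = "")))
  invisible(x)
}

#' Stream bit rate
#'
#' Bit rate of a multi-channel stream in kbps: at 40 kHz and 12 bits the
#' raw 16-channel stream runs at 7680 kbps; after down-sampling to 5 kHz
#' and 16 bits it is 1280 kbps; the 14-features-per-20-ms feature stream is
#' 179.2 kbps — a more than 40-fold compression of the raw stream.
#'
#' @param n_channels number of channels
#' @param rate_per_channel_hz values per second per channel
#' @param bits_per_value bits per value
#' @return rate in kbps
#' @examples
#' bitrate(16, 5000, 16)            # 1280
#' bitrate(16, 14 / 0.020, 16)      # 179.2
#' @export
bitrate <- function(n_channels, rate_per_channel_hz, bits_per_value) {
  stopifnot(n_channels > 0, rate_per_channel_hz > 0, bits_per_value >= 0)
  n_channels * rate_per_channel_hz * bits_per_value / 1000
}
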
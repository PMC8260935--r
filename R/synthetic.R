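#' Multi-channel nerve recording container
#'
#' A light container for a 16-channel extracellular recording: a channels x
#' samples matrix, its sampling rate, and the nerve each channel sits on.
#' Channels 1-8 are on the median nerve, 9-16 on the ulnar nerve.
#'
#' @param samples numeric matrix, channels x samples
#' @param sample_rate sampling rate in Hz
#' @param channel_nerve character vector, one of `"median"`/`"ulnar"` per
#'   channel; defaults to the 8+8 median/ulnar split.
#' @export
nerve_recording <- function(samples, sample_rate,
                            channel_nerve = default_channel_nerve(nrow(samples))) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), sample_rate > 0,
            length(channel_nerve) == nrow(samples),
            all(channel_nerve %in% c("median", "ulnar")))
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_nerve = channel_nerve),
            class = "nd_recording")
}

default_channel_nerve <- function(n_channels = 16L) {
  rep(c("median", "ulnar"), each = ceiling(n_channels / 2))[seq_len(n_channels)]
}

#' @export
print.nd_recording <- function(x, ...) {
  cat(sprintf("<nerve recording: %d ch x %d samples @ %g Hz (%.1f s)>\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate))
  invisible(x)
}

#' Finger-joint trajectory container
#'
#' Ten degrees of freedom (DOF): the metacarpophalangeal (MCP) and proximal
#' interphalangeal (PIP) joint of each finger, thumb to little. Rows
#' `2k - 1` and `2k` belong to finger `k`. Values are glove-normalized to
#' `[0, 1]`, 0 being the resting position.
#'
#' @param values numeric matrix, 10 x samples, in `[0, 1]`
#' @param sample_rate sampling rate in Hz
#' @export
trajectory_set <- function(values, sample_rate) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == 10L, all(values >= 0), all(values <= 1),
            sample_rate > 0)
  rownames(values) <- dof_names()
  structure(list(values = values, sample_rate = sample_rate),
            class = "nd_trajectories")
}

#' @rdname trajectory_set
#' @export
dof_names <- function() {
  as.vector(t(outer(FINGERS, c("mcp", "pip"), paste, sep = "_")))
}

#' Synthetic session configuration
#'
#' Describes the stated world the simulator emulates: a training session in
#' which each gesture is repeated `n_repetitions` times, each repetition a
#' 4 s cycle alternating rest and flexion. Nerve channels carry a 25-600 Hz
#' band-limited stochastic carrier whose instantaneous amplitude is
#' modulated by the intent envelopes of the active fingers, plus white
#' noise at `snr_db` (ratio of modulated-carrier variance to noise
#' variance, per channel, in dB).
#'
#' @param n_repetitions cycles per gesture
#' @param sample_rate Hz; must exceed 1200 (twice the 600 Hz band edge)
#' @param cycle_duration seconds per rest/flex cycle
#' @param snr_db per-channel signal-to-noise ratio in dB (`Inf` = noiseless)
#' @param channel_gain_map 16 x 5 non-negative matrix of finger-to-channel
#'   modulation gains; the thumb column must be (near) zero on the ulnar
#'   channels 9-16, reflecting median-nerve localization of the thumb.
#' @param baseline carrier amplitude at rest (arbitrary units)
#' @param flex_fraction fraction of the cycle spent away from rest
#'   (ramps + plateau); the default 0.5 mirrors a protocol that alternates
#'   resting and flexing within each 4 s cycle.
#' @param rng_seed integer seed; identical seed and config give
#'   byte-identical sessions
#' @export
session_config <- function(n_repetitions = 10L,
                           sample_rate = 5000,
                           cycle_duration = 4,
                           snr_db = 20,
                           channel_gain_map = default_gain_map(),
                           baseline = 0.2,
                           flex_fraction = 0.5,
                           rng_seed = 1L) {
  if (!is.finite(snr_db) && !identical(snr_db, Inf))
    stop("snr_db must be finite or +Inf", call. = FALSE)
  stopifnot(sample_rate > 1200, n_repetitions >= 1, cycle_duration > 0,
            is.matrix(channel_gain_map), all(dim(channel_gain_map) == c(16L, 5L)),
            all(channel_gain_map >= 0), baseline >= 0,
            flex_fraction > 0, flex_fraction < 1)
  if (any(channel_gain_map[9:16, 1] > 1e-6 * max(channel_gain_map)))
    stop("thumb gains on ulnar channels 9-16 must be near zero", call. = FALSE)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 sample_rate = sample_rate, cycle_duration = cycle_duration,
                 snr_db = snr_db, channel_gain_map = channel_gain_map,
                 baseline = baseline, flex_fraction = flex_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "nd_session_config")
}

#' Default finger-to-channel gain map
#'
#' Median-nerve fingers (thumb, index, middle) drive channels 1-8 and
#' ulnar-nerve fingers (ring, little) drive channels 9-16, each with a
#' smooth tuning profile across its bank so that channels are informative
#' but not redundant. The thumb has exactly zero gain on ulnar channels.
#'
#' @return a 16 x 5 non-negative matrix (channels x fingers)
#' @export
default_gain_map <- function() {
  g <- matrix(0, 16, 5, dimnames = list(NULL, FINGERS))
  centers <- c(thumb = 2.5, index = 4.5, middle = 6.5, ring = 10.5, little = 13.5)
  banks <- list(1:8, 1:8, 1:8, 9:16, 9:16)
  for (f in 1:5) {
    ch <- banks[[f]]
    g[ch, f] <- 0.4 + 1.1 * exp(-((ch - centers[f])^2) / (2 * 2.2^2))
  }
  g
}

# Intent envelope of one rest->flex->rest cycle, sampled at `rate`.
# Raised-cosine ramps into and out of a plateau, centered in the cycle;
# `flex_fraction` of the cycle is spent off rest.
cycle_envelope <- function(cycle_duration, rate, flex_fraction = 0.5) {
  n <- round(cycle_duration * rate)
  t <- (seq_len(n) - 0.5) / rate
  flex <- flex_fraction * cycle_duration
  ramp <- 0.25 * flex                    # each ramp is a quarter of flex time
  t0 <- (cycle_duration - flex) / 2      # flexion centered in the cycle
  env <- numeric(n)
  up <- t >= t0 & t < t0 + ramp
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  env[t >= t0 + ramp & t <= t0 + flex - ramp] <- 1
  dn <- t > t0 + flex - ramp & t <= t0 + flex
  env[dn] <- 0.5 * (1 - cos(pi * (t0 + flex - t[dn]) / ramp))
  env
}

#' Generate a synthetic training session
#'
#' Simulates one recording session: the gestures are performed in the given
#' order, `n_repetitions` cycles each. Active fingers follow a smooth
#' rest-flex-rest envelope within each cycle; each channel is a 25-600 Hz
#' band-limited Gaussian carrier amplitude-modulated by
#' `baseline + sum_f gain[ch, f] * envelope_f(t)`, plus white noise scaled
#' to `snr_db`. The glove trajectories are the envelopes themselves, with
#' the MCP joint at full scale and the PIP joint at 0.9 scale.
#'
#' @param config a [session_config()]
#' @param gestures character vector of gesture names (drawn from
#'   [codebook()]), or a list of `gesture_code` objects
#' @return a list with `recording` ([nerve_recording()]), `trajectories`
#'   ([trajectory_set()]), and `schedule` (data frame: gesture, repetition,
#'   start and end time in seconds)
#' @export
generate_session <- function(config, gestures = names(codebook())) {
  stopifnot(inherits(config, "nd_session_config"))
  cb <- codebook()
  gl <- lapply(gestures, function(g)
    if (inherits(g, "nd_gesture_code")) g else lookup_gesture(g, cb))

  rate <- config$sample_rate
  n_cyc <- round(config$cycle_duration * rate)
  n_total <- n_cyc * config$n_repetitions * length(gl)
  env1 <- cycle_envelope(config$cycle_duration, rate, config$flex_fraction)

  # Per-finger intent envelope over the whole session.
  fing_env <- matrix(0, 5, n_total)
  sched <- vector("list", length(gl) * config$n_repetitions)
  k <- 0L
  for (gi in seq_along(gl)) {
    st <- gl[[gi]]$finger_state
    for (r in seq_len(config$n_repetitions)) {
      k <- k + 1L
      i0 <- (k - 1L) * n_cyc
      act <- which(st == 1L)
      if (length(act))
        fing_env[act, i0 + seq_len(n_cyc)] <-
          matrix(env1, length(act), n_cyc, byrow = TRUE)
      sched[[k]] <- data.frame(gesture = gl[[gi]]$name, repetition = r,
                               start = i0 / rate, end = (i0 + n_cyc) / rate)
    }
  }
  schedule <- do.call(rbind, sched)

  traj <- matrix(0, 10, n_total)
  traj[seq(1, 9, 2), ] <- fing_env          # MCP
  traj[seq(2, 10, 2), ] <- 0.9 * fing_env   # PIP

  amp <- config$baseline + config$channel_gain_map %*% fing_env  # 16 x T
  samples <- with_seed(config$rng_seed, {
    carrier <- fft_bandfilter(matrix(stats::rnorm(16 * n_total), 16, n_total),
                              rate, 25, 600)
    sig <- carrier * amp
    if (is.finite(config$snr_db)) {
      nvar <- apply(sig, 1, stats::var) / 10^(config$snr_db / 10)
      sig + matrix(stats::rnorm(16 * n_total), 16, n_total) * sqrt(nvar)
    } else sig
  })

  list(recording = nerve_recording(samples, rate),
       trajectories = trajectory_set(traj, rate),
       schedule = schedule)
}

#' Export / import a session container
#'
#' `write_session()` stores the recording and trajectories as raw float64
#' arrays (`<basename>_samples.bin`, `<basename>_trajectories.bin`) with a
#' JSON sidecar (`<basename>.json`) holding dimensions, rates, the gesture
#' schedule, the seed and a config digest; `read_session()` restores them.
#' `write_trajectory_csv()` writes the trajectories as CSV, one column per
#' DOF.
#'
#' @param session result of [generate_session()]
#' @param basename path prefix for the three files
#' @param config the [session_config()] used (stored for provenance)
#' @export
write_session <- function(session, basename, config = NULL) {
  wbin <- function(m, path) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.vector(m), con, size = 8, endian = "little")
  }
  wbin(session$recording$samples, paste0(basename, "_samples.bin"))
  wbin(session$trajectories$values, paste0(basename, "_trajectories.bin"))
  meta <- list(
    n_channels = nrow(session$recording$samples),
    n_samples = ncol(session$recording$samples),
    sample_rate = session$recording$sample_rate,
    channel_nerve = session$recording$channel_nerve,
    trajectory_rate = session$trajectories$sample_rate,
    schedule = session$schedule,
    seed = if (!is.null(config)) config$rng_seed else NA,
    config_hash = if (!is.null(config)) config_hash(config) else NA)
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' @rdname write_session
#' @export
read_session <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  rbin <- function(path, nr, nc) {
    con <- file(path, "rb"); on.exit(close(con))
    matrix(readBin(con, "double", nr * nc, size = 8, endian = "little"), nr, nc)
  }
  rec <- nerve_recording(
    rbin(paste0(basename, "_samples.bin"), meta$n_channels, meta$n_samples),
    meta$sample_rate, meta$channel_nerve)
  trj <- trajectory_set(
    rbin(paste0(basename, "_trajectories.bin"), 10L, meta$n_samples),
    meta$trajectory_rate)
  list(recording = rec, trajectories = trj, schedule = meta$schedule,
       meta = meta)
}

#' @rdname write_session
#' @export
write_trajectory_csv <- function(session, path) {
  df <- as.data.frame(t(session$trajectories$values))
  names(df) <- dof_names()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
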
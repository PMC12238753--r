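#' Zero-lag low-pass Butterworth filtering
#'
#' Fourth-order (by default) Butterworth low-pass applied forward and
#' backward, the conventional zero-phase smoothing for force-plate data
#' (e.g. 300 Hz cutoff at 1000 Hz sampling). Marker trajectories at 100 Hz
#' use a much lower cutoff (6 Hz default elsewhere); the cutoff must always
#' be below the Nyquist frequency of the series it is applied to.
#'
#' @param x uniformly sampled series.
#' @param order filter order (default 4).
#' @param cutoff low-pass cutoff in Hz.
#' @param fs sampling rate in Hz.
#' @return filtered series, same length as `x`.
#' @export
lowpass_filter_zero_lag <- function(x, order = 4L, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must satisfy 0 < cutoff < fs/2 (fs/2 = ", fs / 2,
         " Hz); got ", cutoff, " Hz")
  bf <- butter_design(order, cutoff, fs, type = "low")
  filtfilt_zero_lag(bf$b, bf$a, x)
}

#' Detect heel strikes from vertical ground reaction force
#'
#' A heel strike is an upward crossing of the force threshold that stays
#' above threshold for at least the refractory period (so sub-threshold
#' jitter and double bumps within one stance produce a single event).
#'
#' @param vgrf vertical ground reaction force (N), one belt/limb,
#'   preferably low-pass filtered.
#' @param fs sampling rate in Hz (default 1000).
#' @param threshold contact threshold in N (default 20).
#' @param refractory minimum time above threshold in s (default 0.2).
#' @return integer sample indices of heel strikes (class `gait_events`,
#'   with `fs` attribute). Zero crossings yield an empty result with a
#'   warning.
#' @export
detect_heel_strikes <- function(vgrf, fs = 1000, threshold = 20,
                                refractory = 0.2) {
  stopifnot(threshold > 0, fs > 0, refractory >= 0)
  above <- vgrf > threshold
  ups <- which(diff(c(FALSE, above)) == 1L)
  need <- max(1L, round(refractory * fs))
  keep <- vapply(ups, function(i) {
    seg <- above[i:min(length(above), i + need - 1L)]
    length(seg) >= need && all(seg)
  }, logical(1))
  events <- ups[keep]
  if (length(events) == 0L)
    warning("no threshold crossings found: returning zero heel strikes")
  structure(events, fs = fs, class = "gait_events")
}

#' Step lengths from heel-marker trajectories at heel strikes
#'
#' Step length at a fast-limb heel strike is the anterior-posterior (AP)
#' distance between the two heel markers at that instant,
#' `AP(fast) - AP(slow)` (and symmetrically at slow-limb strikes). Because
#' the measure is a between-heel difference, any common body translation on
#' the treadmill cancels (the body-centred reading). Marker positions are
#' linearly interpolated at the event times, which live on the (faster)
#' force-plate clock.
#'
#' @param heel_fast,heel_slow AP heel-marker positions in mm, sampled at
#'   `fs_marker`; positive along the walking direction.
#' @param events_fast,events_slow `gait_events` for the two limbs (indices
#'   on the force clock, with `fs` attributes).
#' @param fs_marker marker sampling rate in Hz (default 100).
#' @return list with `step_fast`, `step_slow` (mm) and `n_skipped` (events
#'   outside the marker record, skipped with a message).
#' @export
compute_step_lengths <- function(heel_fast, heel_slow, events_fast,
                                 events_slow, fs_marker = 100) {
  t_marker <- (seq_along(heel_fast) - 1) / fs_marker
  stopifnot(length(heel_slow) == length(heel_fast))
  value_at <- function(trace, t) {
    stats::approx(t_marker, trace, xout = t, rule = 1)$y
  }
  ev_time <- function(ev) (unclass(ev) - 1) / attr(ev, "fs")
  tf <- ev_time(events_fast); ts <- ev_time(events_slow)
  sf <- value_at(heel_fast, tf) - value_at(heel_slow, tf)
  ss <- value_at(heel_slow, ts) - value_at(heel_fast, ts)
  skip_f <- is.na(sf); skip_s <- is.na(ss)
  n_skipped <- sum(skip_f) + sum(skip_s)
  if (n_skipped > 0)
    message(n_skipped, " event(s) outside the marker record were skipped")
  list(step_fast = sf[!skip_f], step_slow = ss[!skip_s],
       n_skipped = n_skipped)
}

#' Simulate raw treadmill traces with known gait events
#'
#' A small fixture generator for the event-detection stage: per-belt
#' vertical ground reaction forces with a double-bump stance profile at
#' 1000 Hz, and sinusoidal AP heel-marker trajectories at 100 Hz whose
#' positions at the true heel-strike times are known in closed form.
#'
#' @param n_steps strides per limb.
#' @param cadence strides per second (default 0.9).
#' @param fs_force,fs_marker sampling rates (Hz).
#' @param amp_fast,amp_slow marker oscillation amplitudes (mm).
#' @param offset_mm common AP offset added to both heel markers (cancels in
#'   step length).
#' @param noise_n force noise sd in N.
#' @param seed RNG seed.
#' @return list with `vgrf_fast`, `vgrf_slow`, `heel_fast`, `heel_slow`,
#'   true event indices and the closed-form step lengths.
#' @export
simulate_gait_traces <- function(n_steps = 10L, cadence = 0.9,
                                 fs_force = 1000, fs_marker = 100,
                                 amp_fast = 350, amp_slow = 250,
                                 offset_mm = 0, noise_n = 0, seed = 1L) {
  period <- 1 / cadence
  dur <- (n_steps + 1) * period
  t_f <- seq(0, dur, by = 1 / fs_force)
  t_m <- seq(0, dur, by = 1 / fs_marker)
  stance <- 0.6 * period
  ## fast strikes at the positive peak of the marker sinusoid (phase 1/4),
  ## slow strikes half a period later, at the negative peak
  strike_fast <- period * (seq_len(n_steps) - 0.75)
  strike_slow <- strike_fast + period / 2

  bump <- function(tt, strikes) {
    f <- numeric(length(tt))
    for (s in strikes) {
      ph <- (tt - s) / stance
      in_st <- ph >= 0 & ph <= 1
      ## double-bump vertical load profile (weight ~ 700 N)
      f[in_st] <- f[in_st] + 700 * (sin(pi * ph[in_st]) +
                                      0.25 * sin(2 * pi * ph[in_st])^2)
    }
    f
  }
  with_local_seed(seed, {
    vgrf_fast <- bump(t_f, strike_fast) + stats::rnorm(length(t_f), sd = noise_n)
    vgrf_slow <- bump(t_f, strike_slow) + stats::rnorm(length(t_f), sd = noise_n)
    ## AP heel markers: anti-phase sinusoids about a common offset
    heel_fast <- offset_mm + amp_fast * sin(2 * pi * cadence * t_m)
    heel_slow <- offset_mm - amp_slow * sin(2 * pi * cadence * t_m)
    step_fast_true <- (amp_fast + amp_slow) * sin(2 * pi * cadence * strike_fast)
    step_slow_true <- -(amp_fast + amp_slow) * sin(2 * pi * cadence * strike_slow)
    list(vgrf_fast = vgrf_fast, vgrf_slow = vgrf_slow,
         heel_fast = heel_fast, heel_slow = heel_slow,
         fs_force = fs_force, fs_marker = fs_marker,
         events_fast = round(strike_fast * fs_force) + 1L,
         events_slow = round(strike_slow * fs_force) + 1L,
         step_fast_true = step_fast_true, step_slow_true = step_slow_true)
  })
}
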
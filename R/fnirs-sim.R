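#' fNIRS noise settings for the simulator
#'
#' The physiological/instrumental noise model of the synthetic recordings:
#' a shared scalp component (slow perfusion drift + Mayer wave + cardiac
#' pulsation) seen by short channels directly and by long channels with
#' weight `scalp_weight`; per-channel linear drift; sparse motion spikes;
#' and white measurement noise. The 1.1 Hz cardiac fundamental is below the
#' 3.05 Hz Nyquist of 6.1 Hz sampling, so it is represented without
#' aliasing (harmonics are not simulated).
#'
#' @param drift_amp slope range of per-channel linear drift (units per
#'   recording).
#' @param cardiac_amp,cardiac_freq cardiac sinusoid amplitude and frequency
#'   (Hz, default 1.1).
#' @param mayer_amp,mayer_freq Mayer-wave sinusoid (Hz, default 0.1).
#' @param scalp_slow_amp amplitude of the slow scalp perfusion component.
#' @param spike_rate expected motion spikes per minute per channel.
#' @param spike_amp spike amplitude in multiples of `white_sd`.
#' @param scalp_weight weight of the scalp component in long channels.
#' @param white_sd white noise sd.
#' @return an `fnirs_noise` list.
#' @export
fnirs_noise <- function(drift_amp = 0.05, cardiac_amp = 0.04,
                        cardiac_freq = 1.1, mayer_amp = 0.03,
                        mayer_freq = 0.1, scalp_slow_amp = 0.05,
                        spike_rate = 0.5, spike_amp = 8,
                        scalp_weight = 1, white_sd = 0.02) {
  structure(as.list(environment()), class = "fnirs_noise")
}

#' No-noise settings (all components off)
#' @return an `fnirs_noise` with every amplitude zero.
#' @export
fnirs_noise_off <- function() {
  fnirs_noise(drift_amp = 0, cardiac_amp = 0, mayer_amp = 0,
              scalp_slow_amp = 0, spike_rate = 0, scalp_weight = 0,
              white_sd = 0)
}

#' Simulate a dual-wavelength block-design fNIRS recording
#'
#' Generates haemoglobin dynamics (HRF-convolved block activation in long
#' channels, shared scalp physiology, drift, spikes, white noise), then
#' forward-projects them through the Beer-Lambert relation to optical
#' density and raw intensity at 760/850 nm. Short channels carry the scalp
#' component but no activation. All generating quantities are stored in
#' `meta$truth`.
#'
#' @param design event table from [make_block_design()] (its `duration`
#'   attribute sets the record length).
#' @param beta_map matrix of HbO activation amplitudes, long channels in
#'   rows, timepoints in columns (column names must match the design's
#'   timepoints). A single number is recycled.
#' @param noise an [fnirs_noise()] object.
#' @param montage source-detector table from [default_montage()].
#' @param fs sampling rate in Hz (default 6.1).
#' @param hbr_ratio HbR activation amplitude as a negative fraction of HbO.
#' @param hrf_params optional list overriding [double_gamma_hrf()] defaults.
#' @param seed integer seed; the simulation is bit-reproducible.
#' @return an intensity-type [fnirs_recording()].
#' @export
simulate_fnirs_recording <- function(design, beta_map = 0.3,
                                     noise = fnirs_noise(),
                                     montage = default_montage(),
                                     fs = 6.1, hbr_ratio = 0.4,
                                     hrf_params = list(), seed = 1L) {
  duration <- attr(design, "duration")
  if (is.null(duration))
    duration <- max(design$onset + design$duration) + 30
  validate_events(design, duration)
  n <- floor(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  long <- montage[!montage$is_short, , drop = FALSE]
  short <- montage[montage$is_short, , drop = FALSE]
  if (nrow(short) < 1L) stop("montage needs at least one short channel")
  tps <- unique(design$timepoint)
  nL <- nrow(long); nS <- nrow(short)

  if (is.matrix(beta_map)) {
    stopifnot(nrow(beta_map) == nL, all(tps %in% colnames(beta_map)))
    B <- beta_map[, tps, drop = FALSE]
  } else {
    B <- matrix(beta_map, nL, length(tps), dimnames = list(NULL, tps))
  }

  with_local_seed(seed, {
    ## task regressors per block, shared across channels
    regs <- mapply(function(on, du) block_regressor(on, du, n, fs, hrf_params),
                   design$onset, design$duration)
    act <- matrix(0, n, nL)
    for (j in seq_len(nL)) {
      amp <- B[j, match(design$timepoint, tps)]
      act[, j] <- regs %*% amp
    }

    ## shared scalp component: slow perfusion + Mayer + cardiac
    slow <- if (noise$scalp_slow_amp > 0) {
      s <- gaussian_smooth(cumsum(stats::rnorm(n)), fs, f3db = 0.03)
      noise$scalp_slow_amp * as.numeric(scale(s))
    } else numeric(n)
    scalp <- slow +
      noise$mayer_amp * sin(2 * pi * noise$mayer_freq * tt +
                              stats::runif(1, 0, 2 * pi)) +
      noise$cardiac_amp * sin(2 * pi * noise$cardiac_freq * tt +
                                stats::runif(1, 0, 2 * pi))

    add_noise <- function(base, with_scalp_w, white_sd = noise$white_sd) {
      drift <- noise$drift_amp * stats::runif(1, -1, 1) *
        (tt - mean(tt)) / (duration / 2)
      spikes <- numeric(n)
      n_spk <- stats::rpois(1, noise$spike_rate * duration / 60)
      spk_idx <- if (n_spk > 0) sample.int(n, n_spk) else integer(0)
      if (n_spk > 0)
        spikes[spk_idx] <- noise$spike_amp * max(noise$white_sd, 1e-3) *
          sample(c(-1, 1), n_spk, replace = TRUE)
      list(x = base + with_scalp_w * scalp + drift + spikes +
             stats::rnorm(n, sd = white_sd),
           spikes = spk_idx)
    }

    hbo <- matrix(0, n, nL + nS); hbr <- matrix(0, n, nL + nS)
    spike_idx <- vector("list", nL + nS)
    for (j in seq_len(nL)) {
      lo <- add_noise(act[, j], noise$scalp_weight)
      hbo[, j] <- lo$x; spike_idx[[j]] <- lo$spikes
      hbr[, j] <- -hbr_ratio * act[, j] + 0.3 * noise$scalp_weight * scalp +
        stats::rnorm(n, sd = 0.5 * noise$white_sd)
    }
    for (k in seq_len(nS)) {
      j <- nL + k
      ## short separations see scalp physiology at high SNR: half the
      ## measurement noise of the long channels
      sh <- add_noise(numeric(n), 1, white_sd = noise$white_sd / 2)
      hbo[, j] <- sh$x; spike_idx[[j]] <- sh$spikes
      hbr[, j] <- 0.3 * scalp + stats::rnorm(n, sd = 0.5 * noise$white_sd)
    }

    ## forward Beer-Lambert (unit pathlength): OD_lambda = E %*% [HbO; HbR]
    E <- extinction_coefficients()
    pairs <- rbind(long, short)
    ch_rows <- list(); dat <- list()
    for (j in seq_len(nrow(pairs))) {
      od760 <- E["760", "HbO"] * hbo[, j] + E["760", "HbR"] * hbr[, j]
      od850 <- E["850", "HbO"] * hbo[, j] + E["850", "HbR"] * hbr[, j]
      for (wl in c(760, 850)) {
        od <- if (wl == 760) od760 else od850
        ch_rows[[length(ch_rows) + 1L]] <- data.frame(
          name = paste0(pairs$name[j], "_", wl),
          source = pairs$source[j], detector = pairs$detector[j],
          wavelength = wl, chromophore = NA_character_,
          is_short = pairs$is_short[j], roi = pairs$roi[j],
          stringsAsFactors = FALSE)
        dat[[length(dat) + 1L]] <- 10^(-od)   # I0 = 1
      }
    }
    channels <- do.call(rbind, ch_rows)
    data <- do.call(cbind, dat)
    colnames(data) <- channels$name

    truth <- list(beta = B, hbo = hbo, scalp = scalp,
                  scalp_weight = noise$scalp_weight,
                  spike_idx = spike_idx, pairs = pairs,
                  regressors = regs, seed = seed)
    fnirs_recording(data, channels, fs, design, type = "intensity",
                    meta = list(truth = truth, noise = noise))
  })
}
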
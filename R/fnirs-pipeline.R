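#' Convert raw intensity to optical density
#'
#' `OD(t) = -log10(I(t) / mean(I))` per channel: optical density changes
#' relative to the channel's mean intensity, so each OD series has
#' zero-mean log by construction.
#'
#' @param rec an intensity-type [fnirs_recording()].
#' @return an OD-type recording; channels with any non-positive sample are
#'   refused (error) since log is undefined.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"), rec$type == "intensity")
  bad <- which(apply(rec$data, 2, function(x) any(!is.finite(x) | x <= 0)))
  if (length(bad) > 0)
    stop("non-positive intensity in channel(s): ",
         paste(rec$channels$name[bad], collapse = ", "))
  od <- -log10(sweep(rec$data, 2, colMeans(rec$data), "/"))
  out <- rec; out$data <- od; out$type <- "od"
  out
}

#' Optical density to haemoglobin concentration changes
#'
#' Modified Beer-Lambert inversion per source-detector pair with unit
#' pathlength (no differential pathlength factor; with a uniform
#' source-detector separation only relative amplitudes matter):
#' `[dHbO; dHbR] = E^-1 [dOD760; dOD850]`.
#'
#' @param rec an OD-type recording with both wavelengths per pair.
#' @param extinction 2x2 extinction matrix, rows wavelengths (760, 850),
#'   columns chromophores (HbO, HbR); default [extinction_coefficients()].
#' @return a haemo-type recording with `HbO` and `HbR` channels per pair.
#' @export
od_to_haemo <- function(rec, extinction = extinction_coefficients()) {
  stopifnot(inherits(rec, "fnirs_recording"), rec$type == "od")
  cond <- kappa(extinction, exact = TRUE)
  if (!is.finite(cond) || cond > 1e6)
    stop("extinction matrix is singular or ill-conditioned (condition ",
         "number ", format(cond), ")")
  Einv <- solve(extinction)
  ch <- rec$channels
  key <- paste(ch$source, ch$detector)
  pairs <- unique(key)
  dat <- list(); rows <- list()
  for (pk in pairs) {
    idx <- which(key == pk)
    wl <- ch$wavelength[idx]
    i760 <- idx[wl == 760]; i850 <- idx[wl == 850]
    if (length(i760) != 1L || length(i850) != 1L)
      stop("pair ", pk, " lacks one of the two wavelengths")
    conc <- rec$data[, c(i760, i850)] %*% t(Einv)
    stem <- sub("_[78][56]0$", "", ch$name[i760])
    for (m in 1:2) {
      chrom <- c("HbO", "HbR")[m]
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(stem, "_", chrom),
        source = ch$source[i760], detector = ch$detector[i760],
        wavelength = NA_real_, chromophore = chrom,
        is_short = ch$is_short[i760], roi = ch$roi[i760],
        stringsAsFactors = FALSE)
      dat[[length(dat) + 1L]] <- conc[, m]
    }
  }
  channels <- do.call(rbind, rows)
  data <- do.call(cbind, dat)
  colnames(data) <- channels$name
  out <- rec; out$data <- data; out$channels <- channels; out$type <- "haemo"
  out
}

#' Scalp coupling index
#'
#' Pearson correlation between a channel's two wavelengths after band-pass
#' filtering to the cardiac band (default 0.5-2.0 Hz, fully below the
#' 3.05 Hz Nyquist of 6.1 Hz sampling). A quality metric only -- no
#' automatic rejection is performed anywhere in the pipeline.
#'
#' @param x760,x850 the two wavelength series of one source-detector pair.
#' @param fs sampling rate in Hz.
#' @param band cardiac band in Hz.
#' @return SCI in \[-1, 1\]; `NA` (with warning) if under 60 s of data.
#' @export
compute_sci <- function(x760, x850, fs, band = c(0.5, 2.0)) {
  if (length(x760) < 60 * fs) {
    warning("less than 60 s of data: SCI undefined")
    return(NA_real_)
  }
  bf <- butter_design(2, band, fs, type = "pass")
  f1 <- filtfilt_zero_lag(bf$b, bf$a, x760, padlen = min(length(x760) - 1L, 100L))
  f2 <- filtfilt_zero_lag(bf$b, bf$a, x850, padlen = min(length(x850) - 1L, 100L))
  stats::cor(f1, f2)
}

#' Robust moving-window spike detection
#'
#' Flags samples deviating more than `threshold` standard deviations from
#' the mean of a trailing lag window of the smoothed series; flagged
#' samples enter the running statistics down-weighted by `influence`. The
#' detector is re-run `iterations` times on its own influence-filtered
#' output, accumulating the mask.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param lag_s trailing window in s (default 5; converted to
#'   `round(lag_s * fs)` samples).
#' @param threshold z-score threshold (default 3.5).
#' @param influence weight of flagged samples in the running statistics
#'   (default 0.5).
#' @param iterations detector passes (default 10).
#' @return logical spike mask, same length as `x`.
#' @export
detect_spikes <- function(x, fs, lag_s = 5, threshold = 3.5,
                          influence = 0.5, iterations = 10L) {
  lag <- round(lag_s * fs)
  if (lag >= length(x))
    stop("lag window (", lag, " samples) must be shorter than the series (",
         length(x), ")")
  if (lag < 2L) stop("lag window too short")
  mask <- rep(FALSE, length(x))
  y <- x
  for (it in seq_len(iterations)) {
    filt <- y
    m <- mean(filt[1:lag]); s <- stats::sd(filt[1:lag])
    this_mask <- rep(FALSE, length(y))
    for (i in (lag + 1L):length(y)) {
      if (s > 0 && abs(y[i] - m) > threshold * s) {
        this_mask[i] <- TRUE
        filt[i] <- influence * y[i] + (1 - influence) * filt[i - 1L]
      } else {
        filt[i] <- y[i]
      }
      w <- filt[(i - lag + 1L):i]
      m <- mean(w); s <- stats::sd(w)
    }
    mask <- mask | this_mask
    if (!any(this_mask)) break
    y <- filt
  }
  mask
}

#' Motion correction by temporal derivative distribution repair
#'
#' Robustly re-estimates the distribution of the temporal derivative of the
#' low-frequency signal component (iterative Tukey biweight), reintegrates
#' the down-weighted derivative, and restores the untouched high-frequency
#' band. Samples in `spike_mask` are additionally bridged by monotone
#' shape-preserving (Hermite) interpolation.
#'
#' @param x numeric series, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param spike_mask optional logical mask from [detect_spikes()].
#' @param split_hz low/high frequency split (default 0.5 Hz); below
#'   `2 * split_hz` sampling the split is skipped.
#' @return cleaned series. An all-flagged mask degenerates to the
#'   interpolated trend with a warning.
#' @export
correct_motion_tddr <- function(x, fs, spike_mask = NULL, split_hz = 0.5) {
  n <- length(x)
  if (!is.null(spike_mask) && all(spike_mask)) {
    warning("all samples flagged: returning linear trend")
    return(seq(x[1], x[n], length.out = n))
  }
  if (stats::sd(x) == 0) return(x)
  ## split into low and high bands; repair operates on the low band
  if (fs > 2 * split_hz) {
    bf <- butter_design(2, split_hz, fs, type = "low")
    lo <- filtfilt_zero_lag(bf$b, bf$a, x,
                            padlen = min(n - 1L, as.integer(10 * fs)))
    hi <- x - lo
  } else {
    lo <- x; hi <- numeric(n)
  }
  d <- diff(lo)
  w <- rep(1, length(d))
  tune <- 4.685
  mu <- 0
  for (it in 1:50) {
    mu_new <- sum(w * d) / sum(w)
    r <- d - mu_new
    s <- 1.4826 * stats::median(abs(r))
    if (s <= .Machine$double.eps^0.5) { w <- rep(1, length(d)); mu <- mu_new; break }
    u <- r / (tune * s)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (max(abs(w_new - w)) < 1e-4 && it > 1) { w <- w_new; mu <- mu_new; break }
    w <- w_new; mu <- mu_new
  }
  d_corr <- w * (d - mu)
  lo_corr <- cumsum(c(lo[1], d_corr))
  lo_corr <- lo_corr - mean(lo_corr) + mean(lo)
  out <- lo_corr + hi
  if (!is.null(spike_mask) && any(spike_mask)) {
    good <- which(!spike_mask)
    if (length(good) >= 2) {
      f <- stats::splinefun(good, out[good], method = "monoH.FC")
      out[spike_mask] <- f(which(spike_mask))
    }
  }
  out
}

#' Short-channel regression
#'
#' For each long channel, selects the short (scalp) channel with the
#' largest absolute Pearson correlation and subtracts its least-squares
#' projection (with intercept); the residual is exactly orthogonal to the
#' chosen short channel.
#'
#' @param long matrix of long-channel series (columns) or a single vector.
#' @param shorts matrix of candidate short-channel series (columns).
#' @return list with `residual` (same shape as `long`), `chosen` (index of
#'   the selected short channel per long channel) and `coef` (slope per
#'   long channel). All-zero short channels pass the data through with a
#'   warning.
#' @export
short_channel_regress <- function(long, shorts) {
  long <- as.matrix(long); shorts <- as.matrix(shorts)
  if (ncol(shorts) < 1L) stop("need at least one short channel")
  sds <- apply(shorts, 2, stats::sd)
  if (all(sds == 0)) {
    warning("all short channels are constant: passing long channels through")
    return(list(residual = long, chosen = rep(NA_integer_, ncol(long)),
                coef = rep(0, ncol(long))))
  }
  usable <- which(sds > 0)
  chosen <- integer(ncol(long)); beta <- numeric(ncol(long))
  res <- long
  for (j in seq_len(ncol(long))) {
    cors <- abs(suppressWarnings(stats::cor(long[, j], shorts[, usable])))
    cors[is.na(cors)] <- 0
    k <- usable[which.max(cors)]
    s <- shorts[, k]
    fit <- stats::lm.fit(cbind(1, s), long[, j])
    res[, j] <- fit$residuals
    chosen[j] <- k; beta[j] <- fit$coefficients[2]
  }
  list(residual = res, chosen = chosen, coef = beta)
}

#' Temporal filtering: high-pass Butterworth + Gaussian smoothing
#'
#' Zero-phase second-order Butterworth high-pass (default 0.01 Hz) to
#' remove drift, followed by Gaussian low-pass smoothing with -3 dB at
#' 0.4 Hz (see [gaussian_smooth()]).
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz (must exceed 0.8 Hz so the smoother band
#'   is representable).
#' @param highpass_hz high-pass corner (default 0.01).
#' @param lowpass_3db_hz Gaussian -3 dB point (default 0.4).
#' @return filtered series.
#' @export
temporal_filter <- function(x, fs, highpass_hz = 0.01, lowpass_3db_hz = 0.4) {
  if (fs <= 0.8) stop("fs must exceed 0.8 Hz")
  if (length(x) < 3 / highpass_hz * fs / 10)
    warning("series shorter than ~3 high-pass time constants: ",
            "edge transients may dominate")
  bf <- butter_design(2, highpass_hz, fs, type = "high")
  y <- filtfilt_zero_lag(bf$b, bf$a, x,
                         padlen = min(length(x) - 1L,
                                      as.integer(0.3 / highpass_hz * fs)))
  gaussian_smooth(y, fs, f3db = lowpass_3db_hz)
}

#' Z-transform normalisation
#'
#' @param x numeric series with nonzero variance.
#' @return list with `x` (mean 0, sd 1), `center`, `scale` (kept so betas
#'   can be mapped back to concentration units).
#' @export
z_normalize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance series cannot be z-normalised")
  m <- mean(x)
  list(x = (x - m) / s, center = m, scale = s)
}

#' Block-design GLM betas for one channel
#'
#' Ordinary least squares on a design with one HRF-convolved boxcar
#' regressor per 30-s block, an intercept and a linear drift term. The two
#' block betas of each timepoint are averaged into the timepoint beta. When
#' the data have been temporally filtered, the same filter should be
#' applied to the block regressors (`filter_design`), which keeps noiseless
#' recovery exact.
#'
#' @param x cleaned channel series.
#' @param events event table (`timepoint`, `block`, `onset`, `duration`).
#' @param fs sampling rate in Hz.
#' @param hrf_params optional [double_gamma_hrf()] overrides.
#' @param filter_design apply [temporal_filter()] to the block regressors
#'   (set to the same options used on the data); `FALSE` to disable.
#' @param filter_args list of arguments for the design filter.
#' @param per_block_regressors `FALSE` collapses each timepoint's pair of
#'   blocks into a single regressor instead of averaging two betas.
#' @return list with `beta` (named per-timepoint), `beta_block`, `se`,
#'   `sigma`, `residuals`, `design`.
#' @export
fit_glm_betas <- function(x, events, fs, hrf_params = list(),
                          filter_design = FALSE, filter_args = list(),
                          per_block_regressors = TRUE) {
  n <- length(x)
  validate_events(events, n / fs)
  tps <- unique(events$timepoint)
  if (per_block_regressors) {
    regs <- sapply(seq_len(nrow(events)), function(i)
      block_regressor(events$onset[i], events$duration[i], n, fs, hrf_params))
    colnames(regs) <- paste0(events$timepoint, "_b", events$block)
    reg_tp <- events$timepoint
  } else {
    regs <- sapply(tps, function(tp) {
      ev <- events[events$timepoint == tp, ]
      rowSums(sapply(seq_len(nrow(ev)), function(i)
        block_regressor(ev$onset[i], ev$duration[i], n, fs, hrf_params)))
    })
    colnames(regs) <- tps
    reg_tp <- tps
  }
  if (filter_design)
    regs <- apply(regs, 2, function(r)
      do.call(temporal_filter, c(list(x = r, fs = fs), filter_args)))
  tt <- (seq_len(n) - 1) / fs
  X <- cbind(intercept = 1, drift = tt - mean(tt), regs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient GLM design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, x)
  cf <- fit$coefficients
  block_beta <- cf[colnames(regs)]
  beta <- vapply(tps, function(tp) mean(block_beta[reg_tp == tp]), numeric(1))
  names(beta) <- tps
  dfres <- n - ncol(X)
  sigma <- sqrt(sum(fit$residuals^2) / dfres)
  XtXinv <- chol2inv(qr.R(qrX))
  se_all <- sigma * sqrt(diag(XtXinv))
  names(se_all) <- colnames(X)
  list(beta = beta, beta_block = block_beta, se = se_all[colnames(regs)],
       sigma = sigma, residuals = fit$residuals, design = X)
}

#' Aggregate channel betas into ROI means
#'
#' @param beta_table data frame with columns `channel`, `roi`, `timepoint`,
#'   `beta` (long channels only).
#' @return data frame of per-ROI mean betas per timepoint plus a
#'   `channel_wide` row (mean over all long channels). Empty ROIs are
#'   flagged `NA`.
#' @export
roi_betas <- function(beta_table) {
  tps <- unique(beta_table$timepoint)
  rois <- unique(stats::na.omit(beta_table$roi))
  rows <- list()
  for (tp in tps) {
    sub <- beta_table[beta_table$timepoint == tp, ]
    for (r in rois) {
      v <- sub$beta[!is.na(sub$roi) & sub$roi == r]
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, timepoint = tp,
        beta = if (length(v)) mean(v) else NA_real_,
        n_channels = length(v))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      roi = "channel_wide", timepoint = tp, beta = mean(sub$beta),
      n_channels = nrow(sub))
  }
  do.call(rbind, rows)
}

#' Baseline-versus-task contrasts
#'
#' `c1 = beta(task) - beta(reference)` per channel or ROI, isolating
#' activation specific to the task timepoint.
#'
#' @param beta_table data frame with `timepoint`, `beta` and an identifier
#'   column (`channel` or `roi`).
#' @param task,reference timepoint labels (defaults `"EarlyAdapt"` vs
#'   `"Baseline"`).
#' @return input identifiers with a `contrast` column; units missing either
#'   timepoint are skipped with a message.
#' @export
compute_contrasts <- function(beta_table, task = "EarlyAdapt",
                              reference = "Baseline") {
  idcol <- intersect(c("channel", "roi"), names(beta_table))[1]
  if (is.na(idcol)) stop("beta_table needs a 'channel' or 'roi' column")
  ids <- unique(beta_table[[idcol]])
  rows <- list(); skipped <- 0L
  for (id in ids) {
    sub <- beta_table[beta_table[[idcol]] == id, ]
    bt <- sub$beta[sub$timepoint == task]
    br <- sub$beta[sub$timepoint == reference]
    if (length(bt) != 1L || length(br) != 1L) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <-
      stats::setNames(data.frame(id = id, contrast = bt - br),
                      c(idcol, "contrast"))
  }
  if (skipped > 0)
    message(skipped, " unit(s) missing a timepoint were skipped")
  do.call(rbind, rows)
}

#' Pipeline options for [process_fnirs()]
#'
#' @param spikes,tddr,short_regression,filter,znorm stage toggles.
#' @param filter_design filter the GLM block regressors like the data.
#' @param highpass_hz,lowpass_3db_hz temporal-filter settings.
#' @param hrf_params HRF overrides.
#' @param per_block_regressors see [fit_glm_betas()].
#' @return an `fnirs_control` list.
#' @export
fnirs_control <- function(spikes = TRUE, tddr = TRUE,
                          short_regression = TRUE, filter = TRUE,
                          znorm = TRUE, filter_design = TRUE,
                          highpass_hz = 0.01, lowpass_3db_hz = 0.4,
                          hrf_params = list(), per_block_regressors = TRUE) {
  structure(as.list(environment()), class = "fnirs_control")
}

#' Full fNIRS processing chain for one recording
#'
#' intensity -> optical density -> haemoglobin (MBLL, no DPF) -> robust
#' spike detection -> TDDR motion correction -> short-channel regression
#' (highest-correlated short) -> high-pass + Gaussian temporal filtering ->
#' z-normalisation -> block-design GLM -> ROI aggregation -> task
#' contrasts. HbR is converted and carried in the output but only HbO is
#' analysed. SCI is reported as QC only; no channel is rejected.
#'
#' @param rec an intensity- or haemo-type [fnirs_recording()].
#' @param control an [fnirs_control()].
#' @return list with `beta_table` (per long channel x timepoint, z units
#'   and concentration units), `roi` (ROI means), `contrast_channel`,
#'   `contrast_roi`, `qc` (SCI per pair, spike counts, z scales) and
#'   `haemo` (the cleaned HbO matrix).
#' @export
process_fnirs <- function(rec, control = fnirs_control()) {
  stopifnot(inherits(rec, "fnirs_recording"))
  qc <- list()
  if (rec$type == "intensity") {
    ## SCI from the raw optical signals, cardiac band
    ch <- rec$channels
    key <- paste(ch$source, ch$detector)
    sci <- vapply(unique(key), function(pk) {
      idx <- which(key == pk)
      i760 <- idx[ch$wavelength[idx] == 760]
      i850 <- idx[ch$wavelength[idx] == 850]
      suppressWarnings(compute_sci(rec$data[, i760], rec$data[, i850], rec$fs))
    }, numeric(1))
    qc$sci <- sci
    haemo <- od_to_haemo(intensity_to_od(rec))
  } else if (rec$type == "haemo") {
    haemo <- rec
  } else stop("recording must be intensity or haemo type")

  hbo_idx <- which(haemo$channels$chromophore == "HbO")
  hch <- haemo$channels[hbo_idx, ]
  X <- haemo$data[, hbo_idx, drop = FALSE]
  fs <- haemo$fs

  spike_counts <- integer(ncol(X))
  if (isTRUE(control$spikes) || isTRUE(control$tddr)) {
    for (j in seq_len(ncol(X))) {
      mask <- if (isTRUE(control$spikes))
        detect_spikes(X[, j], fs) else NULL
      spike_counts[j] <- sum(mask)
      if (isTRUE(control$tddr))
        X[, j] <- correct_motion_tddr(X[, j], fs, spike_mask = mask)
      else if (!is.null(mask) && any(mask) && sum(!mask) >= 2) {
        good <- which(!mask)
        f <- stats::splinefun(good, X[good, j], method = "monoH.FC")
        X[mask, j] <- f(which(mask))
      }
    }
  }
  qc$spike_counts <- stats::setNames(spike_counts, hch$name)

  long_idx <- which(!hch$is_short)
  short_idx <- which(hch$is_short)
  if (isTRUE(control$short_regression) && length(short_idx) > 0) {
    scr <- short_channel_regress(X[, long_idx, drop = FALSE],
                                 X[, short_idx, drop = FALSE])
    X[, long_idx] <- scr$residual
    qc$short_chosen <- stats::setNames(scr$chosen, hch$name[long_idx])
  }
  if (isTRUE(control$filter)) {
    for (j in long_idx)
      X[, j] <- temporal_filter(X[, j], fs,
                                highpass_hz = control$highpass_hz,
                                lowpass_3db_hz = control$lowpass_3db_hz)
  }
  scales <- rep(1, length(long_idx)); centers <- rep(0, length(long_idx))
  if (isTRUE(control$znorm)) {
    for (k in seq_along(long_idx)) {
      z <- z_normalize(X[, long_idx[k]])
      X[, long_idx[k]] <- z$x
      scales[k] <- z$scale; centers[k] <- z$center
    }
  }
  qc$z_scale <- stats::setNames(scales, hch$name[long_idx])

  rows <- list()
  for (k in seq_along(long_idx)) {
    j <- long_idx[k]
    glm <- fit_glm_betas(
      X[, j], haemo$events, fs, hrf_params = control$hrf_params,
      filter_design = isTRUE(control$filter) && isTRUE(control$filter_design),
      filter_args = list(highpass_hz = control$highpass_hz,
                         lowpass_3db_hz = control$lowpass_3db_hz),
      per_block_regressors = control$per_block_regressors)
    rows[[k]] <- data.frame(
      channel = hch$name[j], roi = hch$roi[j],
      timepoint = names(glm$beta), beta = unname(glm$beta),
      beta_conc = unname(glm$beta) * scales[k],
      stringsAsFactors = FALSE)
  }
  beta_table <- do.call(rbind, rows)
  roi <- roi_betas(beta_table)
  tps <- unique(haemo$events$timepoint)
  ct_ch <- ct_roi <- NULL
  if (all(c("Baseline", "EarlyAdapt") %in% tps)) {
    ct_ch <- compute_contrasts(beta_table)
    ct_roi <- compute_contrasts(roi)
  }
  list(beta_table = beta_table, roi = roi, contrast_channel = ct_ch,
       contrast_roi = ct_roi, qc = qc, haemo = X,
       haemo_channels = hch)
}
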
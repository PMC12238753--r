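#' fNIRS recording container
#'
#' Holds a multichannel optical or haemoglobin time series with its channel
#' table, sampling rate, event table and montage metadata.
#'
#' @param data numeric matrix, time in rows, one column per channel row of
#'   `channels`.
#' @param channels data frame with columns `name`, `source`, `detector`,
#'   `wavelength` (nm; NA for haemoglobin data), `chromophore` (`"HbO"`,
#'   `"HbR"` or NA for intensity/OD), `is_short` (logical) and `roi`
#'   (NA for short channels and unassigned channels).
#' @param fs sampling rate in Hz (6.1 for the supported device).
#' @param events data frame with columns `timepoint`, `block`, `onset` (s)
#'   and `duration` (s); blocks must not overlap and must fit the record.
#' @param type `"intensity"`, `"od"` or `"haemo"`.
#' @param meta free-form list (synthetic ground truth lives in
#'   `meta$truth`).
#' @return an `fnirs_recording`.
#' @export
fnirs_recording <- function(data, channels, fs, events,
                            type = c("intensity", "od", "haemo"),
                            meta = list()) {
  type <- match.arg(type)
  data <- as.matrix(data)
  stopifnot(ncol(data) == nrow(channels), fs > 0)
  validate_events(events, nrow(data) / fs)
  if (!any(channels$is_short))
    stop("recording needs at least one short channel")
  structure(list(data = data, channels = channels, fs = fs,
                 events = events, type = type, meta = meta),
            class = "fnirs_recording")
}

validate_events <- function(events, duration_s) {
  stopifnot(all(c("timepoint", "block", "onset", "duration") %in%
                  names(events)))
  if (any(events$onset < 0) ||
      any(events$onset + events$duration > duration_s + 1e-9))
    stop("event blocks exceed the recording duration (", duration_s, " s)")
  ev <- events[order(events$onset), ]
  if (nrow(ev) > 1) {
    ends <- ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)]
    if (any(ends > ev$onset[-1] + 1e-9))
      stop("event blocks overlap")
  }
  invisible(events)
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fnirs_recording (%s): %d samples x %d channels @ %.1f Hz, %d events\n",
              x$type, nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Default cortical montage
#'
#' A 48-long-channel, 8-short-channel montage over sensorimotor cortex:
#' six bilateral regions of interest (PMd, PMv, M1, S1, SPL, IPL via their
#' Brodmann areas) with eight channels each, four per hemisphere, from 16
#' sources and 15 detectors. Channel-to-optode pairing is schematic; the
#' downstream pipeline uses only the channel/ROI structure.
#'
#' @param n_per_roi channels per ROI (default 8; must be even for bilateral
#'   symmetry).
#' @return data frame of source-detector pairs with ROI labels and short
#'   flags (one row per pair, not per wavelength).
#' @export
default_montage <- function(n_per_roi = 8L) {
  if (n_per_roi %% 2L != 0L) stop("n_per_roi must be even (bilateral symmetry)")
  rois <- c("PMd", "PMv", "M1", "S1", "SPL", "IPL")
  n_long <- n_per_roi * length(rois)
  long <- data.frame(
    name = sprintf("S%d_D%d", ((seq_len(n_long) - 1L) %% 16L) + 1L,
                   ((seq_len(n_long) - 1L) %% 15L) + 1L),
    source = ((seq_len(n_long) - 1L) %% 16L) + 1L,
    detector = ((seq_len(n_long) - 1L) %% 15L) + 1L,
    is_short = FALSE,
    roi = rep(rois, each = n_per_roi),
    hemisphere = rep(c("L", "R"), times = n_long / 2),
    stringsAsFactors = FALSE
  )
  long$name <- sprintf("ch%02d_%s", seq_len(n_long), long$name)
  short <- data.frame(
    name = sprintf("sc%02d_S%d_SD%d", 1:8, (1:8) * 2, 1:8),
    source = (1:8) * 2, detector = 100L + 1:8,
    is_short = TRUE, roi = NA_character_,
    hemisphere = rep(c("L", "R"), 4),
    stringsAsFactors = FALSE
  )
  rbind(long, short)
}

#' Block-design event table
#'
#' Builds the paired-block design: each timepoint starts with a standing
#' rest (default 60 s) followed by two 30-s task blocks separated by a rest
#' gap.
#'
#' @param timepoints character vector of timepoint labels in order.
#' @param rest leading rest per timepoint in s (default 60).
#' @param block block duration in s (default 30).
#' @param gap rest between the paired blocks and after the second (s).
#' @return event data frame plus attribute `duration` (total record length
#'   in s).
#' @export
make_block_design <- function(timepoints = c("Baseline", "EarlyAdapt"),
                              rest = 60, block = 30, gap = 15) {
  onsets <- list(); t0 <- 0
  for (tp in timepoints) {
    t0 <- t0 + rest
    onsets[[length(onsets) + 1L]] <-
      data.frame(timepoint = tp, block = 1:2,
                 onset = c(t0, t0 + block + gap), duration = block)
    t0 <- t0 + 2 * block + 2 * gap
  }
  ev <- do.call(rbind, onsets)
  attr(ev, "duration") <- t0
  ev
}

#' Tabulated extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhaemoglobin at the two
#' device wavelengths, in mM^-1 cm^-1 (from the standard compiled tables of
#' haemoglobin spectra used across fNIRS software). Rows are wavelengths
#' (760, 850 nm), columns chromophores (HbO, HbR).
#'
#' @return 2x2 numeric matrix with dimnames.
#' @export
extinction_coefficients <- function() {
  matrix(c(0.14866, 0.38437,
           0.25264, 0.17986),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}
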
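#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities parameterised by peak times: positive
#' response peaking at `peak1` s minus an undershoot peaking at `peak2` s at
#' `1/ratio` of the response amplitude (defaults: 6 s, 16 s, dispersions
#' 1 s, ratio 6 -- the canonical parameterisation). The kernel is normalised
#' to unit peak amplitude.
#'
#' @param t time in s (vectorised, `t >= 0`; negative times return 0).
#' @param peak1,peak2 response and undershoot peak times (s).
#' @param disp1,disp2 dispersions (gamma scale parameters, s).
#' @param ratio response-to-undershoot amplitude ratio.
#' @return HRF values.
#' @export
double_gamma_hrf <- function(t, peak1 = 6, peak2 = 16,
                             disp1 = 1, disp2 = 1, ratio = 6) {
  shape1 <- peak1 / disp1 + 1   # gamma density peaks at (shape - 1) * scale
  shape2 <- peak2 / disp2 + 1
  h <- stats::dgamma(t, shape = shape1, scale = disp1) -
    stats::dgamma(t, shape = shape2, scale = disp2) / ratio
  h[t < 0] <- 0
  h / max(h)
}

## boxcar for one block convolved with the HRF, sampled on the record grid;
## the kernel is normalised to unit sum so a sustained block reaches unit
## plateau -- betas are then sustained-response amplitudes in data units
block_regressor <- function(onset, duration, n_samples, fs, hrf_params = list()) {
  tt <- (seq_len(n_samples) - 1) / fs
  box <- as.numeric(tt >= onset & tt < onset + duration)
  hrf_t <- seq(0, 32, by = 1 / fs)
  h <- do.call(double_gamma_hrf, c(list(t = hrf_t), hrf_params))
  h <- h / sum(h)
  stats::convolve(box, rev(h), type = "open")[seq_len(n_samples)]
}
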
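#' Digital Butterworth filter design
#'
#' Designs an IIR Butterworth filter by bilinear transform of the analog
#' prototype, returning transfer-function coefficients normalised so that
#' `a[1] == 1`. Low-pass and high-pass designs have the requested order;
#' a band-pass design has twice the prototype order.
#'
#' @param order prototype filter order (positive integer).
#' @param cutoff cutoff frequency in Hz; a length-2 vector for `type = "pass"`.
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return list with numerator `b` and denominator `a` coefficient vectors.
#' @examples
#' bf <- butter_design(4, 300, fs = 1000, type = "low")
#' @export
butter_design <- function(order, cutoff, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0, all(cutoff > 0))
  if (any(cutoff >= fs / 2)) {
    stop("cutoff must be strictly below the Nyquist frequency (fs/2 = ",
         fs / 2, " Hz)")
  }
  if (type == "pass" && length(cutoff) != 2L)
    stop("band-pass design needs two cutoff frequencies")

  ## analog Butterworth prototype poles (left half plane, radius 1)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  warp <- function(f) 2 * fs * tan(pi * f / fs)  # bilinear pre-warp

  if (type == "low") {
    wc <- warp(cutoff)
    sp <- p * wc
    sz <- complex(0)
    sk <- wc^order
  } else if (type == "high") {
    wc <- warp(cutoff)
    sp <- wc / p
    sz <- rep(0 + 0i, order)
    sk <- 1
  } else {
    w1 <- warp(min(cutoff)); w2 <- warp(max(cutoff))
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    half <- p * bw / 2
    disc <- sqrt(half^2 - w0^2)
    sp <- c(half + disc, half - disc)
    sz <- rep(0 + 0i, order)
    sk <- bw^order
  }

  ## bilinear transform s -> z
  fs2 <- 2 * fs
  zp <- (fs2 + sp) / (fs2 - sp)
  zz <- (fs2 + sz) / (fs2 - sz)
  ## transform maps remaining zeros at analog infinity to z = -1
  zz <- c(zz, rep(-1 + 0i, length(sp) - length(sz)))
  kz <- sk * Re(prod(fs2 - sz) / prod(fs2 - sp))

  poly_from_roots <- function(r) {
    out <- 1 + 0i
    for (ri in r) out <- c(out, 0) - c(0, out * ri)
    Re(out)
  }
  b <- kz * poly_from_roots(zz)
  a <- poly_from_roots(zp)
  list(b = b, a = a)
}

#' Theoretical magnitude response of a digital Butterworth filter
#'
#' Closed-form single-pass magnitude at frequency `f`, accounting for the
#' bilinear-transform frequency warping. Zero-phase (forward-backward)
#' application squares this value.
#'
#' @param f frequency in Hz (vectorised).
#' @inheritParams butter_design
#' @return magnitude in \[0, 1\].
#' @export
butter_magnitude <- function(f, order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  ratio <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  if (type == "high") ratio <- 1 / ratio
  1 / sqrt(1 + ratio^(2 * order))
}

## steady-state initial state for direct-form-II-transposed filtering,
## scaled by the first input sample (same construction as scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)      # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

## direct-form-II-transposed IIR filter with explicit initial state
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(b[1] * x)
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[2 - 1] * xm + z[1]
    if (n > 2) {
      for (i in 1:(n - 2)) z[i] <- b[i + 1] * xm + z[i + 1] - a[i + 1] * ym
    }
    z[n - 1] <- b[n] * xm - a[n] * ym
    y[m] <- ym
  }
  y
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter forward and backward with odd-reflection end padding
#' and steady-state initial conditions, so the output has zero phase lag and
#' the squared magnitude response of a single pass.
#'
#' @param b,a transfer-function coefficients (e.g. from [butter_design()]).
#' @param x numeric series.
#' @param padlen padding length per end; default `3 * (max(length(a),
#'   length(b)) - 1)`, capped at `length(x) - 1`.
#' @return filtered series, same length as `x`.
#' @export
filtfilt_zero_lag <- function(b, a, x, padlen = NULL) {
  nx <- length(x)
  ntaps <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3L * (ntaps - 1L)
  padlen <- min(padlen, nx - 1L)
  if (padlen > 0) {
    ext <- c(2 * x[1] - x[(padlen + 1):2],
             x,
             2 * x[nx] - x[(nx - 1):(nx - padlen)])
  } else ext <- x
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + nx)]
  y
}

#' Gaussian low-pass smoothing
#'
#' Convolves a series with a normalised Gaussian kernel whose amplitude
#' response is -3 dB (1/sqrt(2)) at `f3db` Hz: the kernel standard deviation
#' in seconds is `sqrt(log(2)) / (2 * pi * f3db)`. Edges are handled by
#' reflection.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param f3db -3 dB frequency in Hz (default 0.4).
#' @return smoothed series, same length as `x`.
#' @export
gaussian_smooth <- function(x, fs, f3db = 0.4) {
  stopifnot(fs > 0, f3db > 0)
  sigma_t <- sqrt(log(2)) / (2 * pi * f3db)
  sigma <- sigma_t * fs
  radius <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-radius, radius), sd = sigma)
  kern <- kern / sum(kern)
  nx <- length(x)
  pad <- min(radius, nx - 1L)
  ext <- c(x[(pad + 1):2], x, x[(nx - 1):(nx - pad)])
  if (pad < radius) {  # very short series: extend by edge replication
    ext <- c(rep(ext[1], radius - pad), ext, rep(ext[length(ext)], radius - pad))
  }
  y <- stats::filter(ext, kern, method = "convolution", sides = 2)
  y <- y[!is.na(y)]
  stopifnot(length(y) == nx)
  as.numeric(y)
}

#' Theoretical Gaussian smoother magnitude response
#'
#' @param f frequency in Hz.
#' @param f3db -3 dB frequency of the smoother.
#' @return amplitude gain in \[0, 1\].
#' @export
gaussian_magnitude <- function(f, f3db = 0.4) {
  sigma_t <- sqrt(log(2)) / (2 * pi * f3db)
  exp(-2 * pi^2 * sigma_t^2 * f^2)
}
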
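## Independent oracles used by the tests. These deliberately avoid the code
## paths they check.

## Separable nonlinear least squares for y = a*exp(b*n) + c: for fixed b the
## optimal (a, c) solve a 2-column linear LS problem; b is found by a coarse
## grid plus golden-section refinement. Derivative-free and independent of
## the package's swarm optimizer.
oracle_fit_exp <- function(y, b_lo = -1, b_hi = -1e-6, n_grid = 400) {
  n <- seq_along(y)
  sse_b <- function(b) {
    X <- cbind(exp(b * n), 1)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  grid <- seq(b_lo, b_hi, length.out = n_grid)
  vals <- vapply(grid, sse_b, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  op <- stats::optimize(sse_b, c(lo, hi), tol = 1e-10)
  b <- op$minimum
  X <- cbind(exp(b * n), 1)
  cf <- stats::lm.fit(X, y)$coefficients
  list(a = cf[1], b = b, c = cf[2], sse = op$objective)
}

## Brute-force Benjamini-Hochberg step-up by its definition: find the
## largest k with p_(k) <= k/m * q by scanning; adjusted p_(i) =
## min over j >= i of (m/j) p_(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m / j * ps[j])
    adj[i] <- min(1, best)
  }
  adj[order(o)]
}

## Closed-form single-pass magnitude of a bilinear-designed digital
## Butterworth filter at frequency f (low-pass); squared for zero-phase
## forward-backward application.
oracle_butter_mag <- function(f, order, cutoff, fs) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * order))
}

## Gaussian smoother amplitude response with -3 dB point f3db.
oracle_gauss_mag <- function(f, f3db) {
  sigma_t <- sqrt(log(2)) / (2 * pi * f3db)
  exp(-2 * pi^2 * sigma_t^2 * f^2)
}

## Direct 2x2 linear solve for the Beer-Lambert inversion.
oracle_mbll <- function(od760, od850, E) {
  det <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  hbo <- (E[2, 2] * od760 - E[1, 2] * od850) / det
  hbr <- (-E[2, 1] * od760 + E[1, 1] * od850) / det
  cbind(HbO = hbo, HbR = hbr)
}

## Small standard fixtures -----------------------------------------------

## standard noisy fNIRS fixture: full session, full noise model
standard_fnirs_fixture <- function(seed = 1L, n_per_roi = 8L,
                                   timepoints = c("Baseline", "EarlyAdapt",
                                                  "LateAdapt", "EarlyDeadapt",
                                                  "LateDeadapt")) {
  des <- make_block_design(timepoints)
  mon <- default_montage(n_per_roi)
  simulate_fnirs_recording(des, beta_map = 0.1, noise = fnirs_noise(),
                           montage = mon, seed = seed)
}

## reduced swarm settings for replicate simulations (runtime scaling only;
## the polish step still converges to the local optimum)
sim_pso <- function() pso_control(n_particles = 12L, n_iter = 40L)
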
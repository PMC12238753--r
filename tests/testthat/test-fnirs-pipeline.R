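make_tiny_rec <- function(data, fs = 6.1, short_col = ncol(data)) {
  nc <- ncol(data)
  ch <- data.frame(name = paste0("ch", seq_len(nc)),
                   source = seq_len(nc), detector = seq_len(nc),
                   wavelength = NA_real_, chromophore = "HbO",
                   is_short = seq_len(nc) == short_col,
                   roi = NA_character_, stringsAsFactors = FALSE)
  ev <- data.frame(timepoint = "Baseline", block = 1, onset = 5, duration = 10)
  fnirs_recording(data, ch, fs, ev, type = "haemo")
}

test_that("optical density conversion: closed forms and refusals", {
  ev <- data.frame(timepoint = "Baseline", block = 1, onset = 1, duration = 2)
  ch <- data.frame(name = c("p_760", "p_850"), source = 1, detector = 1,
                   wavelength = c(760, 850), chromophore = NA_character_,
                   is_short = c(FALSE, TRUE), roi = NA_character_)
  ## constant intensity -> all-zero OD
  rec <- fnirs_recording(cbind(rep(2, 50), rep(3, 50)), ch, fs = 10, ev,
                         type = "intensity")
  od <- intensity_to_od(rec)
  expect_equal(max(abs(od$data)), 0, tolerance = 1e-12)
  expect_identical(od$type, "od")

  ## halving the intensity raises OD by log10(2)
  x <- rep(2, 50); x[30:50] <- 1
  rec2 <- fnirs_recording(cbind(x, rep(3, 50)), ch, fs = 10, ev,
                          type = "intensity")
  od2 <- intensity_to_od(rec2)
  expect_equal(unname(od2$data[30, 1] - od2$data[1, 1]), log10(2),
               tolerance = 1e-12)

  ## non-positive samples are refused with the channel named
  xneg <- x; xneg[5] <- 0
  rec3 <- fnirs_recording(cbind(xneg, rep(3, 50)), ch, fs = 10, ev,
                          type = "intensity")
  expect_error(intensity_to_od(rec3), "p_760")
})

test_that("Beer-Lambert inversion matches the independent 2x2 solve", {
  E <- extinction_coefficients()
  ev <- data.frame(timepoint = "Baseline", block = 1, onset = 1, duration = 2)
  ch <- data.frame(name = c("p_760", "p_850"), source = 1, detector = 1,
                   wavelength = c(760, 850), chromophore = NA_character_,
                   is_short = c(TRUE, TRUE), roi = NA_character_)
  ## zero OD -> zero concentrations
  rec0 <- fnirs_recording(matrix(0, 40, 2), ch, 10, ev, type = "od")
  rec0$type <- "od"
  h0 <- od_to_haemo(rec0)
  expect_equal(max(abs(h0$data)), 0)
  expect_identical(h0$channels$chromophore, c("HbO", "HbR"))

  ## OD constructed as E %*% [1; 0] inverts to HbO = 1, HbR = 0
  od1 <- matrix(rep(E %*% c(1, 0), each = 40), 40, 2)
  rec1 <- fnirs_recording(od1, ch, 10, ev, type = "od")
  h1 <- od_to_haemo(rec1)
  expect_equal(unname(h1$data[1, ]), c(1, 0), tolerance = 1e-12)

  ## random OD pairs equal the brute-force linear solve
  set.seed(4)
  od <- matrix(rnorm(80), 40, 2)
  rec <- fnirs_recording(od, ch, 10, ev, type = "od")
  h <- od_to_haemo(rec)
  orc <- oracle_mbll(od[, 1], od[, 2], E)
  expect_equal(unname(h$data), unname(orc), tolerance = 1e-12)

  ## singular extinction matrix refused with condition number
  expect_error(od_to_haemo(rec, extinction = matrix(1, 2, 2)),
               "condition")
})

test_that("scalp coupling index behaves at its limits", {
  fs <- 6.1; tt <- (0:999) / fs
  card <- sin(2 * pi * 1.1 * tt)
  set.seed(6)
  s1 <- card + rnorm(1000, sd = 0.1)
  s2 <- 0.7 * card + rnorm(1000, sd = 0.1)
  expect_gt(compute_sci(s1, s2, fs), 0.95)
  expect_equal(compute_sci(card, -card, fs), -1, tolerance = 1e-6)
  ## independent noise: near zero over a long record
  expect_lt(abs(compute_sci(rnorm(6000), rnorm(6000), fs)), 0.1)
  ## under 60 s: undefined, flagged
  expect_warning(v <- compute_sci(card[1:100], card[1:100], fs), "60 s")
  expect_true(is.na(v))
})

test_that("spike detector flags excursions and stays quiet on clean input", {
  fs <- 6.1
  set.seed(8)
  ## flat series with a single 10-sigma excursion: exactly that sample
  x <- rnorm(400, sd = 0.01)
  x[200] <- x[200] + 0.1
  m <- detect_spikes(x, fs)
  expect_true(m[200])
  expect_lt(sum(m), 6)  # ~2*pnorm(-3.5)*400*iters false alarms at most

  ## all-constant series: empty mask
  expect_identical(sum(detect_spikes(rep(2, 300), fs)), 0L)

  ## pure Gaussian noise: flagged fraction stays small
  frac <- mean(detect_spikes(rnorm(3000), fs))
  expect_lt(frac, 0.02)

  ## lag >= series length refused
  expect_error(detect_spikes(rnorm(20), fs, lag_s = 5), "shorter")
})

test_that("TDDR is near-identity on clean data and crushes step artefacts", {
  fs <- 6.1
  ## integer number of periods so the robust mean of the derivative is ~0
  ## (TDDR removes the net linear trend by design)
  t <- (0:2439) / fs  # 400 s = 20 periods of 0.05 Hz
  x <- sin(2 * pi * 0.05 * t)
  y <- correct_motion_tddr(x, fs)
  expect_gt(stats::cor(x, y), 0.99)

  ## step artefact of ~10 sigma: variance reduced by at least half
  set.seed(3)
  xs <- rnorm(2000, sd = 0.05)
  xs[900:2000] <- xs[900:2000] + 0.5
  ys <- correct_motion_tddr(xs, fs)
  expect_lt(stats::var(ys), 0.5 * stats::var(xs))

  ## zero in, zero out
  expect_identical(correct_motion_tddr(rep(0, 200), fs), rep(0, 200))

  ## all-flagged mask degenerates to the interpolated trend with a warning
  expect_warning(tr <- correct_motion_tddr(xs[1:100], fs,
                                           spike_mask = rep(TRUE, 100)),
                 "all samples")
  expect_length(tr, 100)
})

test_that("short-channel regression selects and orthogonalises correctly", {
  set.seed(10)
  n <- 1000
  scalp <- as.numeric(stats::filter(rnorm(n), rep(1, 20) / 20,
                                    circular = TRUE))
  neural <- sin(2 * pi * 0.02 * (1:n))
  long <- neural + 0.8 * scalp
  shorts <- cbind(scalp + rnorm(n, sd = 0.05), rnorm(n))
  res <- short_channel_regress(long, shorts)
  ## residual orthogonal to the chosen short
  expect_identical(res$chosen, 1L)
  expect_lt(abs(sum(res$residual * shorts[, 1])), 1e-6 * n)
  ## residual approximates the neural component
  expect_gt(stats::cor(res$residual[, 1], neural), 0.95)

  ## uncorrelated long passes through nearly unchanged
  iso <- rnorm(n)
  res2 <- short_channel_regress(iso, shorts)
  expect_gt(stats::cor(res2$residual[, 1], iso), 0.99)

  ## all-zero shorts: pass-through with warning
  expect_warning(res3 <- short_channel_regress(long, matrix(0, n, 2)),
                 "constant")
  expect_equal(res3$residual[, 1], long)

  ## the true scalp source wins the selection in almost all replicates
  wins <- vapply(1:40, function(k) {
    set.seed(100 + k)
    sc <- as.numeric(stats::filter(rnorm(n), rep(1, 20) / 20, circular = TRUE))
    lg <- 0.9 * sc + rnorm(n, sd = 0.5)
    sh <- cbind(sc + rnorm(n, sd = 0.1), rnorm(n), rnorm(n))
    short_channel_regress(lg, sh)$chosen == 1L
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("temporal filter removes drift and respects the stated bands", {
  fs <- 6.1
  t <- (0:5999) / fs
  ## DC offset removed
  y <- temporal_filter(rep(5, 6000), fs)
  expect_lt(max(abs(y[500:5500])), 1e-6)

  ## 0.05 Hz passes within 5%
  x1 <- sin(2 * pi * 0.05 * t)
  y1 <- temporal_filter(x1, fs)
  expect_equal(max(abs(y1[1500:4500])), 1, tolerance = 0.05)

  ## 1.5 Hz attenuated according to the Gaussian closed form
  x2 <- sin(2 * pi * 1.5 * t)
  y2 <- temporal_filter(x2, fs)
  expect_lt(max(abs(y2[1500:4500])), oracle_gauss_mag(1.5, 0.4) * 1.2)
  expect_lt(oracle_gauss_mag(1.5, 0.4), 0.01)
})

test_that("z-normalisation contracts", {
  set.seed(2)
  x <- rnorm(100, 5, 3)
  z <- z_normalize(x)
  expect_equal(mean(z$x), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$x), 1, tolerance = 1e-12)
  ## affine invariance
  z2 <- z_normalize(2.5 * x - 7)
  expect_equal(z$x, z2$x, tolerance = 1e-12)
  expect_error(z_normalize(rep(1, 10)), "zero-variance")
})

test_that("GLM betas: noiseless identities, drift immunity, SE-scaled recovery", {
  fs <- 6.1
  ev <- make_block_design(c("Baseline", "EarlyAdapt"))
  n <- floor(attr(ev, "duration") * fs)
  regs <- sapply(seq_len(nrow(ev)), function(i)
    gaitnirs:::block_regressor(ev$onset[i], ev$duration[i], n, fs))
  ## signal = 3 x regressor of block 2 -> beta 3 there, ~0 elsewhere
  g <- fit_glm_betas(3 * regs[, 2], ev, fs)
  expect_equal(unname(g$beta_block[2]), 3, tolerance = 1e-9)
  expect_equal(unname(g$beta_block[c(1, 3, 4)]), rep(0, 3), tolerance = 1e-9)
  ## timepoint beta = mean of its two block betas
  expect_equal(unname(g$beta["Baseline"]), mean(g$beta_block[1:2]),
               tolerance = 1e-12)

  ## pure drift: all block betas ~ 0
  tt <- (seq_len(n) - 1) / fs
  gd <- fit_glm_betas(0.3 * tt + 2, ev, fs)
  expect_equal(unname(gd$beta), c(0, 0), tolerance = 1e-9)

  ## white-noise recovery within 2x the noise-implied standard error
  set.seed(12)
  miss <- replicate(30, {
    y <- 0.05 * regs[, 1] + 0.05 * regs[, 2] +
      0.1 * regs[, 3] + 0.1 * regs[, 4] + rnorm(n, sd = 0.05)
    gn <- fit_glm_betas(y, ev, fs)
    any(abs(gn$beta_block - c(0.05, 0.05, 0.1, 0.1)) > 2 * gn$se)
  })
  ## ~5% of |z| > 2 per beta; 4 betas -> well under half the replicates
  expect_lt(mean(miss), 0.5)

  ## rank-deficient design refused with the offending column named
  ## (zero-duration block -> all-zero regressor)
  ev_bad <- rbind(ev, data.frame(timepoint = "LateAdapt", block = 1,
                                 onset = attr(ev, "duration") - 1,
                                 duration = 0))
  attr(ev_bad, "duration") <- attr(ev, "duration")
  expect_error(fit_glm_betas(rnorm(n), ev_bad, fs), "LateAdapt_b1")
})

test_that("ROI aggregation and contrasts are exact arithmetic", {
  bt <- data.frame(channel = c("c1", "c2", "c3", "c4"),
                   roi = c("M1", "M1", "M1", "S1"),
                   timepoint = "Baseline",
                   beta = c(1, 2, 3, 5))
  rb <- roi_betas(bt)
  expect_equal(rb$beta[rb$roi == "M1"], 2)
  expect_equal(rb$beta[rb$roi == "S1"], 5)          # single-channel ROI
  expect_equal(rb$beta[rb$roi == "channel_wide"], mean(c(1, 2, 3, 5)))
  ## permuting channel order changes nothing
  rb2 <- roi_betas(bt[c(3, 1, 4, 2), ])
  expect_equal(rb2$beta[rb2$roi == "M1"], 2)

  ## contrasts
  bt2 <- rbind(bt, transform(bt, timepoint = "EarlyAdapt",
                             beta = c(1.10, 2.04, 3.2, 5.0)))
  ct <- compute_contrasts(bt2)
  expect_equal(ct$contrast[ct$channel == "c1"], 0.10)
  expect_equal(ct$contrast[ct$channel == "c4"], 0)
  ## linearity: contrast(alpha*A + beta*B) = alpha*c(A) + beta*c(B)
  btB <- bt2; btB$beta <- rev(bt2$beta)
  mix <- bt2; mix$beta <- 2 * bt2$beta + 3 * btB$beta
  expect_equal(compute_contrasts(mix)$contrast,
               2 * compute_contrasts(bt2)$contrast +
                 3 * compute_contrasts(btB)$contrast, tolerance = 1e-12)
  ## missing timepoint skipped with message
  expect_message(ct2 <- compute_contrasts(rbind(bt2, data.frame(
    channel = "c9", roi = "M1", timepoint = "Baseline", beta = 1))),
    "skipped")
  expect_false("c9" %in% ct2$channel)
})

test_that("GLM residuals are orthogonal to the design columns", {
  fs <- 6.1
  ev <- make_block_design("Baseline")
  n <- floor(attr(ev, "duration") * fs)
  set.seed(3)
  g <- fit_glm_betas(rnorm(n), ev, fs)
  orth <- crossprod(g$design, g$residuals)
  expect_lt(max(abs(orth)), 1e-8 * n)
})
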
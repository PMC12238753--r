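test_that("SLA series generator follows the exponential model exactly", {
  pp <- participant_params("P1", phases = list(
    Baseline = list(a = 0, b = -0.01, c = 0.05),
    Adaptation = list(a = -0.15, b = -0.01, c = 0.02),
    Deadaptation = list(a = 0.1, b = -0.03, c = 0)),
    stride_noise_sd = 0)
  s <- simulate_sla_series(pp, "Adaptation", 100, seed = 1)
  expect_equal(s$sla[1], -0.15 * exp(-0.01) + 0.02, tolerance = 1e-12)
  expect_equal(s$sla[50], -0.15 * exp(-0.01 * 50) + 0.02, tolerance = 1e-12)

  ## degenerate amplitude: constant series at c
  sb <- simulate_sla_series(pp, "Baseline", 60, seed = 1)
  expect_equal(sb$sla, rep(0.05, 60))

  ## emitted step lengths are consistent with the SLA and the step scale
  expect_equal(compute_sla(s$step_fast_mm, s$step_slow_mm), s$sla,
               tolerance = 1e-12)
  expect_equal(mean(s$step_fast_mm + s$step_slow_mm) / 2,
               pp$mean_step_mm, tolerance = 1e-9)
})

test_that("generator refusals and invariants", {
  pp <- participant_params("P1")
  expect_error(simulate_sla_series(pp, "Adaptation", 59), ">= 60")
  bad <- participant_params("P2", phases = list(
    Baseline = list(a = 0, b = -0.01, c = 0),
    Adaptation = list(a = -0.7, b = -0.01, c = -0.4),
    Deadaptation = list(a = 0.1, b = -0.03, c = 0)))
  expect_error(simulate_sla_series(bad, "Adaptation", 100), "admissible range")
  expect_error(participant_params("P3", phases = list(
    Baseline = list(a = 0, b = -0.01, c = 0),
    Adaptation = list(a = -0.15, b = 0.01, c = 0),
    Deadaptation = list(a = 0.1, b = -0.03, c = 0))), "negative")

  ## bit-reproducibility and |SLA| < 1
  ppn <- participant_params("P4", stride_noise_sd = 0.05)
  s1 <- simulate_sla_series(ppn, "Adaptation", 500, seed = 33)
  s2 <- simulate_sla_series(ppn, "Adaptation", 500, seed = 33)
  expect_identical(s1, s2)
  expect_true(all(abs(s1$sla) < 1))
})

test_that("long-run noisy series converges to the asymptote c", {
  pp <- participant_params("P1", phases = list(
    Baseline = list(a = 0, b = -0.01, c = 0),
    Adaptation = list(a = -0.15, b = -0.01, c = 0.02),
    Deadaptation = list(a = 0.1, b = -0.03, c = 0)),
    stride_noise_sd = 0.02)
  s <- simulate_sla_series(pp, "Adaptation", 1000, seed = 5)
  ## Monte-Carlo check vs the generating model: 3*sd/sqrt(30) ~ 0.011,
  ## plus the residual exponential tail (< 1e-5 at stride 970)
  expect_lt(abs(mean(s$sla[971:1000]) - 0.02), 0.012)
})

test_that("cohort assembly: counts, counterbalance, truth, reproducibility", {
  cfg <- cohort_config(n_pwms = 6, n_hc = 4, n_strides = 80, n_baseline = 60,
                       include_fnirs = FALSE, seed = 2)
  co <- generate_cohort(cfg)
  ## 10 participants x 2 visits
  expect_length(co$trials, 20)
  expect_identical(nrow(co$manifest), 20L)
  ## counterbalanced order within group
  m <- co$manifest[!duplicated(co$manifest$participant), ]
  expect_identical(sum(m$group == "PwMS" & m$tens_order == "ON-first"), 3L)
  expect_identical(sum(m$group == "HC" & m$tens_order == "ON-first"), 2L)
  ## each participant: one ON and one OFF visit
  tab <- table(co$manifest$participant, co$manifest$tens)
  expect_true(all(tab == 1))
  ## ground truth stored for every trial
  expect_true(all(vapply(co$trials, function(tr)
    is.list(tr$truth$params) && !is.null(tr$truth$params$Adaptation$a),
    logical(1))))
  ## bit-for-bit regeneration
  co2 <- generate_cohort(cfg)
  expect_identical(co$trials[[7]]$series$Adaptation$sla,
                   co2$trials[[7]]$series$Adaptation$sla)
})

test_that("full-size cohort has the stated design shape", {
  cfg <- cohort_config(n_strides = 60, n_baseline = 60,
                       include_fnirs = FALSE, seed = 1)
  co <- generate_cohort(cfg)
  expect_length(co$trials, 96)  # 48 participants x 2 visits
  expect_identical(sum(co$manifest$group == "PwMS"), 56L)
  expect_identical(sum(co$manifest$group == "HC"), 40L)
})

test_that("injected effects land on the generating parameters as stated", {
  cfg <- cohort_config(n_pwms = 4, n_hc = 2, n_strides = 100,
                       n_baseline = 60, include_fnirs = FALSE, seed = 3)
  co <- generate_cohort(cfg)
  w <- stride_windows(100)
  f_init <- mean(exp(cfg$base$Adaptation$b * w$initial))
  for (pid in unique(co$manifest$participant)) {
    trs <- Filter(function(tr) tr$participant == pid, co$trials)
    v1 <- trs[[which(vapply(trs, `[[`, 1, "visit") == 1)]]
    v2 <- trs[[which(vapply(trs, `[[`, 2, "visit") == 2)]]
    da <- v2$truth$params$Adaptation$a - v1$truth$params$Adaptation$a
    ## Visit-2 amplitude shift = visit effect + relearning offset (+ TENS
    ## savings shift for PwMS with TENS ON at Visit 2), each scaled by its
    ## window factor
    f_early <- mean(exp(cfg$base$Adaptation$b * w$early))
    expected <- cfg$effects$visit_early_change / f_early +
      v2$truth$relearn_offset / f_init +
      v2$truth$injected$tens_savings / f_init
    expect_equal(da, expected, tolerance = 1e-12)
  }
})

test_that("fNIRS generator: flat channels without noise, refusals, truth", {
  des <- make_block_design("Baseline")
  mon <- default_montage(2)
  rec0 <- simulate_fnirs_recording(des, beta_map = 0,
                                   noise = fnirs_noise_off(),
                                   montage = mon, seed = 1)
  ## all-zero betas and no noise: constant intensities
  expect_lt(max(apply(rec0$data, 2, stats::sd)), 1e-12)
  expect_identical(rec0$type, "intensity")

  ## overlapping blocks are refused
  bad <- data.frame(timepoint = "Baseline", block = 1:2,
                    onset = c(60, 70), duration = 30)
  attr(bad, "duration") <- 200
  expect_error(simulate_fnirs_recording(bad, montage = mon), "overlap")

  ## blocks beyond the record are refused
  bad2 <- data.frame(timepoint = "Baseline", block = 1, onset = 500,
                     duration = 30)
  attr(bad2, "duration") <- 100
  expect_error(simulate_fnirs_recording(bad2, montage = mon), "duration")

  ## short channels carry no activation (ground truth), and the recording
  ## is reproducible under the seed
  rec1 <- simulate_fnirs_recording(make_block_design(), beta_map = 0.2,
                                   noise = fnirs_noise(), montage = mon,
                                   seed = 9)
  rec2 <- simulate_fnirs_recording(make_block_design(), beta_map = 0.2,
                                   noise = fnirs_noise(), montage = mon,
                                   seed = 9)
  expect_identical(rec1$data, rec2$data)
  truth <- rec1$meta$truth
  nL <- sum(!mon$is_short)
  expect_identical(dim(truth$beta), c(nL, 2L))
})

test_that("cohort files round-trip through the plain-text layout", {
  cfg <- cohort_config(n_pwms = 1, n_hc = 1, n_strides = 60, n_baseline = 60,
                       include_fnirs = TRUE,
                       fnirs = list(timepoints = c("Baseline", "EarlyAdapt"),
                                    beta = c(Baseline = 0.05, EarlyAdapt = 0.1),
                                    noise = fnirs_noise(),
                                    montage = default_montage(2)),
                       seed = 4)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  strides <- utils::read.csv(file.path(dir, "strides.csv"))
  expect_identical(nrow(strides), 4L * (60L + 60L + 60L))
  rec <- read_fnirs_tabular(file.path(dir, "fnirs_MS01_v1.csv"),
                            file.path(dir, "fnirs_MS01_v1.json"))
  orig <- co$trials[[1]]$fnirs
  expect_equal(rec$data, orig$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rec$fs, orig$fs)
  expect_identical(nrow(rec$events), nrow(orig$events))
})
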
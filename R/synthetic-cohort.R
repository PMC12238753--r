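#' Generating parameters for one participant
#'
#' Per-phase single-exponential parameters (`sla(n) = a * exp(b*n) + c`)
#' with stride noise and step-length scale, validated against the model's
#' admissible range.
#'
#' @param participant_id label.
#' @param group `"PwMS"` or `"HC"`.
#' @param tens_order `"ON-first"` or `"ON-second"` (crossover arm).
#' @param fast_limb `"left"` or `"right"`.
#' @param phases named list (`Baseline`, `Adaptation`, `Deadaptation`) of
#'   lists with `a`, `b`, `c`; `b < 0` required for the two dynamic phases.
#' @param stride_noise_sd independent Gaussian stride noise sd (SLA units).
#' @param mean_step_mm mean step length (mm) used to emit paired step
#'   lengths consistent with SLA.
#' @return a `participant_params` list.
#' @export
participant_params <- function(participant_id, group = c("PwMS", "HC"),
                               tens_order = c("ON-first", "ON-second"),
                               fast_limb = c("right", "left"),
                               phases = list(
                                 Baseline = list(a = 0, b = -0.01, c = 0),
                                 Adaptation = list(a = -0.15, b = -0.02, c = 0.02),
                                 Deadaptation = list(a = 0.10, b = -0.03, c = 0)),
                               stride_noise_sd = 0.02,
                               mean_step_mm = 563) {
  group <- match.arg(group)
  tens_order <- match.arg(tens_order)
  fast_limb <- match.arg(fast_limb)
  stopifnot(stride_noise_sd >= 0, mean_step_mm > 0)
  for (ph in c("Adaptation", "Deadaptation")) {
    if (phases[[ph]]$b >= 0)
      stop("phase ", ph, ": decay rate b must be negative")
  }
  for (ph in names(phases)) {
    p <- phases[[ph]]
    if (abs(p$a) >= 1 || abs(p$c) >= 1)
      stop("phase ", ph, ": |a| and |c| must be < 1 (SLA units)")
  }
  structure(list(participant_id = participant_id, group = group,
                 tens_order = tens_order, fast_limb = fast_limb,
                 phases = phases, stride_noise_sd = stride_noise_sd,
                 mean_step_mm = mean_step_mm),
            class = "participant_params")
}

#' Simulate a stride-level SLA series
#'
#' Draws `sla(n) = a*exp(b*n) + c + eps(n)` with independent Gaussian
#' stride noise (optionally AR(1)-autocorrelated), and emits paired step
#' lengths consistent with each SLA value around the participant's mean
#' step length: `fast = S*(1+sla)/2`, `slow = S*(1-sla)/2` with
#' `S = 2 * mean_step_mm`.
#'
#' @param params a [participant_params()].
#' @param phase phase label selecting the generating parameters.
#' @param n_strides number of strides (>= 60 so the Early and Late windows
#'   cannot overlap).
#' @param seed integer seed (bit-reproducible).
#' @param visit,tens metadata carried into the series.
#' @param ar1 lag-1 autocorrelation of the stride noise (default 0:
#'   independent noise).
#' @return a [stride_series()]; the generating parameters are attached as
#'   attribute `truth`.
#' @export
simulate_sla_series <- function(params, phase, n_strides, seed = 1L,
                                visit = 1L, tens = "OFF", ar1 = 0) {
  if (n_strides < 60L)
    stop("n_strides must be >= 60 (got ", n_strides,
         "): Early and Late windows would overlap")
  p <- params$phases[[phase]]
  if (is.null(p)) stop("unknown phase: ", phase)
  if (abs(p$a + p$c) >= 1)
    stop("|a + c| >= 1: initial SLA would leave the admissible range (-1, 1)")
  n <- seq_len(n_strides)
  mu <- p$a * exp(p$b * n) + p$c
  eps <- with_local_seed(seed, {
    e <- stats::rnorm(n_strides, sd = params$stride_noise_sd)
    if (ar1 != 0 && params$stride_noise_sd > 0) {
      e <- as.numeric(stats::filter(e, ar1, method = "recursive")) *
        sqrt(1 - ar1^2)
    }
    e
  })
  sla <- mu + eps
  sla <- pmin(pmax(sla, -0.999), 0.999)   # physical range guard
  S <- 2 * params$mean_step_mm
  out <- stride_series(step_fast = S * (1 + sla) / 2,
                       step_slow = S * (1 - sla) / 2,
                       sla = sla, phase = phase, visit = visit, tens = tens,
                       participant = params$participant_id)
  attr(out, "truth") <- list(a = p$a, b = p$b, c = p$c,
                             stride_noise_sd = params$stride_noise_sd,
                             seed = seed, ar1 = ar1)
  out
}

## mean of exp(b * n) over an integer stride window
window_factor <- function(b, window) mean(exp(b * window))

#' Cohort configuration
#'
#' The stated world of the synthetic crossover: 28 PwMS and 20 healthy
#' controls, two visits in a TENS ON/OFF crossover, 1000 strides per
#' adaptation/deadaptation phase, stride noise sd 0.02, between-participant
#' savings sd 0.037, and injected effects of group (adaptation-magnitude
#' gap 0.022), visit, and TENSxvisit (savings shift +0.05 for PwMS with
#' TENS ON at Visit 2). Effect sizes are stated in outcome units and
#' realized as shifts of the generating amplitude `a`, scaled by the exact
#' window factor so the injected outcome shift equals the stated value.
#'
#' @param n_pwms,n_hc group sizes.
#' @param n_strides strides per adaptation/deadaptation phase.
#' @param n_baseline baseline strides per visit.
#' @param effects list: `group_magnitude` (PwMS adaptation-magnitude
#'   deficit), `visit_early_change` (Visit-2 shift of Early Adapt),
#'   `visit_after_effect` (Visit-2 shift of the after-effect),
#'   `tens_savings` (Visit-2 Initial-Adapt shift for PwMS with TENS ON at
#'   Visit 2). SLA units.
#' @param sds list: `participant_a`, `participant_c` (stable
#'   between-participant parameter offsets), `savings` (between-participant
#'   sd of the Visit-2 relearning offset), `baseline` (sd of the baseline
#'   SLA level).
#' @param stride_noise_sd stride noise sd (SLA units).
#' @param base list of group-level generating parameters (HC reference).
#' @param mean_step_mm named vector of group mean step lengths (mm).
#' @param include_fnirs simulate an fNIRS recording per trial (disable for
#'   large replicate studies of the gait pipeline).
#' @param fnirs list: `timepoints`, `beta` (named per-timepoint long-channel
#'   activation), `noise` ([fnirs_noise()]), `montage`.
#' @param ar1 stride-noise autocorrelation (default 0, independent).
#' @param seed master seed.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_pwms = 28L, n_hc = 20L, n_strides = 1000L,
                          n_baseline = 120L,
                          effects = list(group_magnitude = 0.022,
                                         visit_early_change = 0.015,
                                         visit_after_effect = -0.01,
                                         tens_savings = 0.05),
                          sds = list(participant_a = 0.03,
                                     participant_c = 0.01,
                                     savings = 0.037,
                                     baseline = 0.01),
                          stride_noise_sd = 0.02,
                          base = list(
                            Adaptation = list(a = -0.15, b = -0.02, c = 0.02),
                            Deadaptation = list(a = 0.10, b = -0.03, c = 0),
                            deadapt_coupling = -0.65),
                          mean_step_mm = c(PwMS = 563.0, HC = 602.4),
                          include_fnirs = FALSE,
                          fnirs = list(timepoints = c("Baseline", "EarlyAdapt"),
                                       beta = c(Baseline = 0.05,
                                                EarlyAdapt = 0.1),
                                       noise = fnirs_noise(),
                                       montage = NULL),
                          ar1 = 0, seed = 1L) {
  stopifnot(n_pwms > 0, n_hc > 0, n_strides >= 60, n_baseline >= 30,
            stride_noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a full synthetic crossover cohort
#'
#' Assigns counterbalanced TENS order within each group, draws participant
#' random effects, injects the configured group/visit/TENS effects on the
#' generating parameters, and simulates every trial (both visits), each
#' with stored ground truth. Per-trial seeds derive deterministically from
#' the master seed, so regeneration is bit-for-bit reproducible.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `trials` (each a
#'   `synthetic_trial` holding the three phase [stride_series()], optional
#'   fNIRS recording, and a `truth` record), `manifest` data frame, and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("PwMS", config$n_pwms), rep("HC", config$n_hc))
  ids <- sprintf("%s%02d", ifelse(groups == "PwMS", "MS", "HC"),
                 c(seq_len(config$n_pwms), seq_len(config$n_hc)))
  ## counterbalanced crossover order within each group
  order_vec <- unlist(lapply(c(config$n_pwms, config$n_hc), function(k)
    rep_len(c("ON-first", "ON-second"), k)))

  eff <- config$effects; sds <- config$sds; base <- config$base
  b_ad <- base$Adaptation$b
  w <- stride_windows(config$n_strides)
  f_init <- window_factor(b_ad, w$initial)
  f_early <- window_factor(b_ad, w$early)
  f_late <- window_factor(b_ad, w$late)
  b_de <- base$Deadaptation$b
  f_early_de <- window_factor(b_de, w$early)

  n_part <- length(ids)
  cohort <- with_local_seed(config$seed, {
    part_a <- stats::rnorm(n_part, sd = sds$participant_a)
    part_c <- stats::rnorm(n_part, sd = sds$participant_c)
    part_b0 <- stats::rnorm(n_part, sd = sds$baseline)
    relearn <- stats::rnorm(n_part, sd = sds$savings)
    trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                     n_part * 2 * 4), nrow = n_part)
    fast_limb <- rep_len(c("right", "left"), n_part)

    trials <- list(); manifest <- list()
    for (i in seq_len(n_part)) {
      g <- groups[i]
      ## group effect: PwMS adaptation magnitude reduced by the stated gap
      a_base <- base$Adaptation$a + part_a[i] +
        if (g == "PwMS") eff$group_magnitude / (f_early - f_late) else 0
      c_base <- base$Adaptation$c + part_c[i]
      a_de_base <- base$deadapt_coupling * a_base
      for (v in 1:2) {
        tens <- if (order_vec[i] == "ON-first") c("ON", "OFF")[v]
        else c("OFF", "ON")[v]
        a_ad <- a_base
        a_de <- a_de_base
        if (v == 2L) {
          a_ad <- a_ad + eff$visit_early_change / f_early +
            relearn[i] / f_init +
            if (g == "PwMS" && tens == "ON")
              eff$tens_savings / f_init else 0
          a_de <- a_de + eff$visit_after_effect / f_early_de
        }
        pp <- participant_params(
          participant_id = ids[i], group = g, tens_order = order_vec[i],
          fast_limb = fast_limb[i],
          phases = list(
            Baseline = list(a = 0, b = -0.01, c = part_b0[i]),
            Adaptation = list(a = a_ad, b = b_ad, c = c_base),
            Deadaptation = list(a = a_de, b = b_de,
                                c = base$Deadaptation$c)),
          stride_noise_sd = config$stride_noise_sd,
          mean_step_mm = unname(config$mean_step_mm[g]))
        series <- list(
          Baseline = simulate_sla_series(pp, "Baseline", config$n_baseline,
                                         seed = trial_seeds[i, (v - 1) * 4 + 1],
                                         visit = v, tens = tens,
                                         ar1 = config$ar1),
          Adaptation = simulate_sla_series(pp, "Adaptation", config$n_strides,
                                           seed = trial_seeds[i, (v - 1) * 4 + 2],
                                           visit = v, tens = tens,
                                           ar1 = config$ar1),
          Deadaptation = simulate_sla_series(pp, "Deadaptation",
                                             config$n_strides,
                                             seed = trial_seeds[i, (v - 1) * 4 + 3],
                                             visit = v, tens = tens,
                                             ar1 = config$ar1))
        fnirs <- NULL
        if (isTRUE(config$include_fnirs)) {
          design <- make_block_design(config$fnirs$timepoints)
          montage <- config$fnirs$montage
          if (is.null(montage)) montage <- default_montage()
          beta <- config$fnirs$beta[config$fnirs$timepoints]
          bm <- matrix(rep(beta, each = sum(!montage$is_short)),
                       ncol = length(beta),
                       dimnames = list(NULL, names(beta)))
          fnirs <- simulate_fnirs_recording(
            design, beta_map = bm, noise = config$fnirs$noise,
            montage = montage, seed = trial_seeds[i, (v - 1) * 4 + 4])
        }
        truth <- list(params = pp$phases, tens_order = order_vec[i],
                      relearn_offset = relearn[i],
                      injected = list(
                        group_magnitude =
                          if (g == "PwMS") eff$group_magnitude else 0,
                        tens_savings =
                          if (v == 2 && g == "PwMS" && tens == "ON")
                            eff$tens_savings else 0))
        trials[[length(trials) + 1L]] <- structure(
          list(participant = ids[i], group = g, visit = v, tens = tens,
               tens_order = order_vec[i], series = series, fnirs = fnirs,
               truth = truth),
          class = "synthetic_trial")
        manifest[[length(manifest) + 1L]] <- data.frame(
          participant = ids[i], group = g, visit = v, tens = tens,
          tens_order = order_vec[i], fast_limb = fast_limb[i],
          n_strides = config$n_strides, stringsAsFactors = FALSE)
      }
    }
    list(trials = trials, manifest = do.call(rbind, manifest))
  })
  structure(list(trials = cohort$trials, manifest = cohort$manifest,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d trials (%d participants x 2 visits)\n",
              length(x$trials), nrow(x$manifest) / 2))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Stride tables as one CSV (`strides.csv`), the manifest as TSV, and each
#' fNIRS recording (when present) as a per-trial CSV time series plus a
#' JSON sidecar with montage and events.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strides <- do.call(rbind, lapply(cohort$trials, function(tr)
    do.call(rbind, tr$series)))
  rownames(strides) <- NULL
  utils::write.csv(strides, file.path(dir, "strides.csv"), row.names = FALSE)
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (tr in cohort$trials) {
    if (is.null(tr$fnirs)) next
    stem <- sprintf("fnirs_%s_v%d", tr$participant, tr$visit)
    utils::write.csv(as.data.frame(tr$fnirs$data),
                     file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
    side <- list(fs = tr$fnirs$fs, type = tr$fnirs$type,
                 channels = tr$fnirs$channels, events = tr$fnirs$events)
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an fNIRS recording from the tabular + JSON layout
#'
#' @param csv_path time-series CSV (columns = channels).
#' @param json_path JSON sidecar with `fs`, `type`, `channels`, `events`.
#' @return an [fnirs_recording()].
#' @export
read_fnirs_tabular <- function(csv_path, json_path) {
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dat <- as.matrix(utils::read.csv(csv_path, check.names = FALSE))
  fnirs_recording(dat, as.data.frame(side$channels), side$fs,
                  as.data.frame(side$events), type = side$type)
}
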
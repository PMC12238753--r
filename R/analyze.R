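#' Adaptation outcomes for every trial of a cohort
#'
#' Runs the full behavioural pipeline per participant-visit: baseline
#' adjustment (last 30 baseline strides), exponential fits of the
#' adaptation and deadaptation curves, model-based window means, outcomes
#' and -- once both visits are present -- savings.
#'
#' @param cohort a [generate_cohort()] result (or any list of trials with
#'   the same shape).
#' @param control a [pso_control()]; reduce the swarm for large replicate
#'   studies.
#' @param seed base seed for the fits (each fit gets a distinct derived
#'   seed).
#' @param fit_deadaptation set `FALSE` to skip deadaptation fits when only
#'   adaptation outcomes are needed (halves the cost).
#' @return list with `outcomes` (one row per trial) and `savings` (one row
#'   per participant with both visits; participants missing a visit are
#'   skipped and counted in `n_skipped`).
#' @export
analyze_cohort <- function(cohort, control = pso_control(), seed = 1L,
                           fit_deadaptation = TRUE) {
  trials <- cohort$trials
  rows <- list()
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    adapt <- baseline_adjust(tr$series$Adaptation, tr$series$Baseline)
    fit_a <- fit_exponential(adapt, control = control, seed = seed + 2L * k)
    if (fit_deadaptation) {
      deadapt <- baseline_adjust(tr$series$Deadaptation, tr$series$Baseline)
      fit_d <- fit_exponential(deadapt, control = control,
                               seed = seed + 2L * k + 1L)
      oc <- compute_outcomes(fit_a, fit_d,
                             baseline_mean = attr(adapt, "baseline_mean"))
    } else {
      wa <- window_means(fit_a)
      oc <- list(initial_adapt = wa[["initial"]], early_adapt = wa[["early"]],
                 late_adapt = wa[["late"]],
                 initial_deadapt = NA_real_, early_deadapt = NA_real_,
                 late_deadapt = NA_real_,
                 early_change_adapt = wa[["early"]],
                 early_change_deadapt = NA_real_,
                 adaptation_magnitude = wa[["late"]] - wa[["early"]],
                 deadaptation_magnitude = NA_real_, after_effect = NA_real_)
    }
    rows[[k]] <- data.frame(
      participant = tr$participant, group = tr$group, visit = tr$visit,
      tens = tr$tens, tens_order = tr$tens_order,
      as.data.frame(oc[c("initial_adapt", "early_adapt", "late_adapt",
                         "initial_deadapt", "early_deadapt", "late_deadapt",
                         "early_change_adapt", "early_change_deadapt",
                         "adaptation_magnitude", "deadaptation_magnitude",
                         "after_effect")]),
      stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, rows)
  sav <- list(); n_skipped <- 0L
  for (pid in unique(outcomes$participant)) {
    sub <- outcomes[outcomes$participant == pid, ]
    if (!all(1:2 %in% sub$visit)) { n_skipped <- n_skipped + 1L; next }
    v1 <- sub[sub$visit == 1, ]; v2 <- sub[sub$visit == 2, ]
    sav[[length(sav) + 1L]] <- data.frame(
      participant = pid, group = v1$group, tens_visit2 = v2$tens,
      savings_initial = v2$initial_adapt - v1$initial_adapt,
      savings_early = v2$early_adapt - v1$early_adapt,
      stringsAsFactors = FALSE)
  }
  list(outcomes = outcomes,
       savings = if (length(sav)) do.call(rbind, sav) else NULL,
       n_skipped = n_skipped)
}

#' Group/visit/TENS statistics for a cohort analysis
#'
#' Fits the mixed model (random participant intercept) for each requested
#' repeated outcome with Type III Satterthwaite tests, the fixed-effects
#' savings models (one record per participant), and EMM pairwise TENS
#' contrasts within group with BH adjustment and Cohen's d.
#'
#' @param analysis an [analyze_cohort()] result.
#' @param outcomes repeated outcomes to model.
#' @return list: `anova` (per outcome), `tens_contrasts` (per outcome, EMM
#'   TENS ON-OFF within group), `savings_anova`, `savings_contrasts`
#'   (TENS-at-Visit-2 ON-OFF within group, BH within group family).
#' @export
cohort_stats <- function(analysis,
                         outcomes = c("adaptation_magnitude",
                                      "early_change_adapt")) {
  res <- list(anova = list(), tens_contrasts = list())
  for (oc in outcomes) {
    mod <- fit_adaptation_lmm(analysis$outcomes, oc)
    res$anova[[oc]] <- anova_type3(mod)
    res$tens_contrasts[[oc]] <- emm_pairwise(mod, "tens", by = "group")
  }
  if (!is.null(analysis$savings)) {
    sv <- analysis$savings
    res$savings_anova <- list(); res$savings_contrasts <- list()
    for (oc in c("savings_initial", "savings_early")) {
      mod <- fit_adaptation_lmm(sv, oc, fixed = c("group", "tens_visit2"),
                                random = NULL)
      res$savings_anova[[oc]] <- anova_type3(mod)
      res$savings_contrasts[[oc]] <-
        emm_pairwise(mod, "tens_visit2", by = "group")
    }
  }
  res
}
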
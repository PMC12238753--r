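#' Step length asymmetry (SLA)
#'
#' SLA for a stride is the fast-minus-slow step-length difference normalised
#' by stride length: `(fast - slow) / (fast + slow)`. Zero is symmetric gait;
#' the measure is dimensionless, bounded in (-1, 1) for positive step
#' lengths, and antisymmetric in its arguments.
#'
#' @param step_fast,step_slow step lengths in mm (vectorised).
#' @return SLA values.
#' @examples
#' compute_sla(550, 450)  # 0.1
#' @export
compute_sla <- function(step_fast, step_slow) {
  denom <- step_fast + step_slow
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("step_fast + step_slow must be positive and finite for every stride")
  (step_fast - step_slow) / denom
}

#' Stride series container
#'
#' A data frame of per-stride step lengths and SLA with stride index starting
#' at 1, tagged with phase/visit/condition metadata.
#'
#' @param step_fast,step_slow step lengths in mm.
#' @param sla optional; recomputed from the step lengths when missing.
#' @param phase one of `"Baseline"`, `"Adaptation"`, `"Deadaptation"`.
#' @param visit,tens,participant metadata labels (recycled).
#' @return a `stride_series` data frame.
#' @export
stride_series <- function(step_fast, step_slow, sla = NULL,
                          phase = "Adaptation", visit = 1L, tens = "OFF",
                          participant = "P01") {
  n <- length(step_fast)
  stopifnot(length(step_slow) == n)
  if (is.null(sla)) sla <- compute_sla(step_fast, step_slow)
  stopifnot(length(sla) == n, all(abs(sla) < 1))
  out <- data.frame(
    participant = rep_len(participant, n),
    visit = rep_len(visit, n),
    tens = rep_len(tens, n),
    phase = rep_len(phase, n),
    stride_index = seq_len(n),
    step_fast_mm = step_fast,
    step_slow_mm = step_slow,
    sla = sla,
    stringsAsFactors = FALSE
  )
  class(out) <- c("stride_series", "data.frame")
  out
}

#' Baseline-adjust an SLA series
#'
#' Subtracts the participant/visit baseline SLA level -- the mean of the last
#' 30 baseline strides -- from every stride of the series, so that adaptation
#' and deadaptation curves reflect change from each visit's own tied-belt
#' walking. If fewer than 30 baseline strides are available all of them are
#' used, with a warning.
#'
#' @param series a `stride_series` (or data frame with an `sla` column) to
#'   adjust.
#' @param baseline the same-visit baseline series.
#' @param n_last number of final baseline strides defining the level
#'   (default 30).
#' @return `series` with adjusted `sla`; the subtracted constant is attached
#'   as attribute `baseline_mean`.
#' @export
baseline_adjust <- function(series, baseline, n_last = 30L) {
  bs <- baseline$sla
  if (length(bs) < n_last) {
    warning("baseline has only ", length(bs), " strides (< ", n_last,
            "); using all of them for the baseline level")
    n_last <- length(bs)
  }
  if (n_last < 1L) stop("baseline series is empty")
  level <- mean(bs[(length(bs) - n_last + 1L):length(bs)])
  series$sla <- series$sla - level
  attr(series, "baseline_mean") <- level
  series
}

#' PSO settings for the exponential fit
#'
#' @param n_particles swarm size (default 50).
#' @param n_iter swarm iterations (default 500).
#' @param bounds_a,bounds_b,bounds_c parameter boxes; `b` is constrained
#'   negative (decaying curve).
#' @param polish apply a bounded quasi-Newton local refinement after the
#'   swarm (default TRUE).
#' @return a `pso_control` list.
#' @export
pso_control <- function(n_particles = 50L, n_iter = 500L,
                        bounds_a = c(-1, 1), bounds_b = c(-1, -1e-6),
                        bounds_c = c(-1, 1), polish = TRUE) {
  structure(list(n_particles = n_particles, n_iter = n_iter,
                 bounds_a = bounds_a, bounds_b = bounds_b,
                 bounds_c = bounds_c, polish = polish),
            class = "pso_control")
}

#' Fit the single-exponential learning model
#'
#' Fits `sla(n) = a * exp(b * n) + c` (stride index `n` starting at 1) to a
#' baseline-adjusted SLA series by minimising the sum of squared errors with
#' a particle swarm, followed by a bounded local polish. One swarm particle
#' is always seeded at the best constant fit `(a = 0, c = mean(y))`, so the
#' returned SSE never exceeds the constant-fit SSE.
#'
#' @param sla numeric vector of baseline-adjusted SLA values, or a
#'   `stride_series`.
#' @param control a [pso_control()] object.
#' @param seed integer seed for the swarm (fits are reproducible).
#' @return an `exponential_fit` with elements `a`, `b`, `c`, `sse`,
#'   `n_strides`, `bound_hit` (optimizer at a box edge), `b_identifiable`
#'   (FALSE when `|a|` is negligible so the rate is meaningless),
#'   `polish_delta` (SSE improvement from the polish), `trace`, `seed`.
#' @export
fit_exponential <- function(sla, control = pso_control(), seed = 1L) {
  if (is.data.frame(sla)) sla <- sla$sla
  y <- as.numeric(sla)
  if (length(y) < 60L)
    stop("need at least 60 strides to fit the learning curve (got ",
         length(y), ")")
  if (any(!is.finite(y))) stop("SLA series contains non-finite values")
  n <- seq_along(y)

  cost <- function(theta) {
    ## theta: 3 x P matrix
    E <- exp(outer(n, theta[2, ]))
    pred <- E * rep(theta[1, ], each = length(n)) +
      rep(theta[3, ], each = length(n))
    colSums((y - pred)^2)
  }
  lower <- c(control$bounds_a[1], control$bounds_b[1], control$bounds_c[1])
  upper <- c(control$bounds_a[2], control$bounds_b[2], control$bounds_c[2])
  const_par <- c(0, -0.01, mean(y))
  sw <- pso_optimize(cost, lower, upper,
                     n_particles = control$n_particles,
                     n_iter = control$n_iter,
                     init = matrix(const_par, ncol = 1), seed = seed)
  par <- sw$par; val <- sw$value
  polish_delta <- 0
  if (isTRUE(control$polish)) {
    sc <- function(p) cost(matrix(p, ncol = 1))
    gr <- function(p) {
      e <- exp(p[2] * n)
      r <- y - (p[1] * e + p[3])
      c(-2 * sum(r * e), -2 * p[1] * sum(r * n * e), -2 * sum(r))
    }
    op <- stats::optim(par, sc, gr, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(factr = 1e4, maxit = 500))
    if (op$value <= val) {
      polish_delta <- val - op$value
      par <- op$par; val <- op$value
    }
  }
  tol <- 1e-8 * pmax(1, abs(upper - lower))
  bound_hit <- any(par - lower < tol | upper - par < tol)
  structure(list(a = par[1], b = par[2], c = par[3], sse = val,
                 n_strides = length(y), bound_hit = bound_hit,
                 b_identifiable = abs(par[1]) > 1e-4,
                 polish_delta = polish_delta, trace = sw$trace, seed = seed),
            class = "exponential_fit")
}

#' @export
predict.exponential_fit <- function(object, strides = seq_len(object$n_strides),
                                    ...) {
  object$a * exp(object$b * strides) + object$c
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("single-exponential fit: a = %.4f, b = %.5f, c = %.4f\n",
              x$a, x$b, x$c))
  cat(sprintf("  SSE %.5g over %d strides%s%s\n", x$sse, x$n_strides,
              if (x$bound_hit) " [bound hit]" else "",
              if (!x$b_identifiable) " [rate unidentifiable: a ~ 0]" else ""))
  invisible(x)
}

#' Standard stride windows
#'
#' Initial (strides 1-5), Early (6-30) and Late (last 30) windows for a
#' phase of `n_strides` strides. Initial and Early are disjoint by
#' construction; Late is disjoint from Early whenever `n_strides >= 60`.
#'
#' @param n_strides phase length.
#' @return named list of integer stride vectors.
#' @export
stride_windows <- function(n_strides) {
  if (n_strides < 60L)
    stop("windows need n_strides >= 60 so Early and Late do not overlap")
  list(initial = 1:5, early = 6:30, late = (n_strides - 29L):n_strides)
}

#' Window means from a fitted learning curve
#'
#' Evaluates the fitted model at the integer strides of each window and
#' averages -- the model-based summary of the phase. A raw-data variant
#' (`source = "raw"`, mean of observed SLA in the window) is provided for
#' sensitivity analysis.
#'
#' @param fit an [fit_exponential()] result.
#' @param windows list of stride windows, e.g. [stride_windows()].
#' @param source `"model"` (default) or `"raw"`.
#' @param series raw SLA values, required for `source = "raw"`.
#' @return named numeric vector of window means.
#' @export
window_means <- function(fit, windows = stride_windows(fit$n_strides),
                         source = c("model", "raw"), series = NULL) {
  source <- match.arg(source)
  bad <- vapply(windows, function(w) max(w) > fit$n_strides || min(w) < 1,
                logical(1))
  if (any(bad))
    stop("window(s) ", paste(names(windows)[bad], collapse = ", "),
         " exceed the fitted stride range 1..", fit$n_strides)
  if (source == "model") {
    vapply(windows, function(w) mean(predict(fit, w)), numeric(1))
  } else {
    if (is.null(series)) stop("source = 'raw' needs the observed series")
    if (is.data.frame(series)) series <- series$sla
    vapply(windows, function(w) mean(series[w]), numeric(1))
  }
}

#' Adaptation outcomes for one participant-visit
#'
#' Derives the four behavioural outcomes from the fitted adaptation and
#' deadaptation curves (both baseline-adjusted):
#' * early change: Early-window mean of each phase;
#' * adaptation magnitude: Late Adapt minus Early Adapt (positive as SLA
#'   rises toward symmetry); deadaptation magnitude is Early Deadapt minus
#'   Late Deadapt (positive decay);
#' * after-effect: Early Deadapt mean relative to baseline (zero after
#'   adjustment, so it equals the Early Deadapt mean).
#'
#' @param adapt_fit,deadapt_fit `exponential_fit`s for the two phases.
#' @param baseline_mean baseline level already subtracted from the curves
#'   (kept for bookkeeping; outcomes use 0 as the adjusted baseline).
#' @param source window-mean source, passed to [window_means()].
#' @param adapt_series,deadapt_series raw series for `source = "raw"`.
#' @return an `adaptation_outcomes` list of the six window means and the
#'   derived outcomes.
#' @export
compute_outcomes <- function(adapt_fit, deadapt_fit, baseline_mean = 0,
                             source = "model",
                             adapt_series = NULL, deadapt_series = NULL) {
  wa <- window_means(adapt_fit, source = source, series = adapt_series)
  wd <- window_means(deadapt_fit, source = source, series = deadapt_series)
  out <- list(
    initial_adapt = wa[["initial"]], early_adapt = wa[["early"]],
    late_adapt = wa[["late"]],
    initial_deadapt = wd[["initial"]], early_deadapt = wd[["early"]],
    late_deadapt = wd[["late"]],
    early_change_adapt = wa[["early"]],
    early_change_deadapt = wd[["early"]],
    adaptation_magnitude = wa[["late"]] - wa[["early"]],
    deadaptation_magnitude = wd[["early"]] - wd[["late"]],
    after_effect = wd[["early"]] - 0,
    baseline_mean = baseline_mean
  )
  class(out) <- "adaptation_outcomes"
  out
}

#' Savings between two visits
#'
#' Savings quantifies faster relearning on re-exposure: the Visit-2 minus
#' Visit-1 difference in SLA at the Initial and Early Adapt windows.
#' Positive savings means the participant started less asymmetric (higher
#' SLA) on the second visit.
#'
#' @param outcomes_v1,outcomes_v2 [compute_outcomes()] results for visits 1
#'   and 2 of the same participant.
#' @param participant participant label.
#' @param tens_visit2 TENS condition at Visit 2 (`"ON"` or `"OFF"`).
#' @return a `savings_record` list with `savings_initial` and
#'   `savings_early`.
#' @export
compute_savings <- function(outcomes_v1, outcomes_v2, participant = NA,
                            tens_visit2 = NA) {
  structure(list(
    participant = participant,
    tens_visit2 = tens_visit2,
    savings_initial = outcomes_v2$initial_adapt - outcomes_v1$initial_adapt,
    savings_early = outcomes_v2$early_adapt - outcomes_v1$early_adapt
  ), class = "savings_record")
}
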
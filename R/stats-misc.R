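#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values of the BH false-discovery-rate procedure within one
#' declared family: `p_(i) * m / i` from the largest p downwards with a
#' running minimum, capped at 1. The family (e.g. one outcome within one
#' group) is whatever vector the caller passes -- it is never inferred.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.005, 0.03, 0.04))  # 0.015 0.040 0.040
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Cohen's d
#'
#' Two-sample standardized mean difference with the pooled-variance
#' denominator, or the paired-difference variant
#' (`mean(x - y) / sd(x - y)`).
#'
#' @param x,y numeric samples (equal length if `paired`).
#' @param paired use the paired-difference formula.
#' @return d; `NA` with a warning when the denominator sd is zero.
#' @examples
#' cohens_d(c(2, 4, 6), c(1, 3, 5))  # 0.5
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    s <- stats::sd(x - y)
    if (!is.finite(s) || s == 0) { warning("zero sd: d undefined"); return(NA_real_) }
    return(mean(x - y) / s)
  }
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (!is.finite(sp) || sp == 0) { warning("zero pooled sd: d undefined"); return(NA_real_) }
  (mean(x) - mean(y)) / sp
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Backward stepwise regression
#'
#' Starts from the full linear model on all candidate predictors and
#' repeatedly removes the least significant term (marginal F test via
#' `drop1`) whose p-value exceeds the exit threshold, until every retained
#' term passes. Perfectly collinear (aliased) predictors are dropped with a
#' warning before stepping. The full elimination path is returned.
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictor names.
#' @param exit_p exit threshold (default 0.05).
#' @return list with `model` (the retained `lm`), `retained`, `dropped`,
#'   `path` (data frame of each elimination step) and `summary` (terms, t,
#'   p, R-squared, adjusted R-squared, overall F).
#' @export
backward_stepwise <- function(data, outcome, candidates, exit_p = 0.05) {
  stopifnot(nrow(data) > length(candidates) + 1)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(candidates, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("dropping collinear predictor(s): ", paste(bad, collapse = ", "))
    candidates <- setdiff(candidates, bad)
    fit <- stats::lm(stats::as.formula(paste(
      outcome, "~", paste(c("1", candidates), collapse = " + "))), data = data)
  }
  path <- list(); current <- candidates
  repeat {
    if (length(current) == 0L) break
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]]; names(pv) <- rownames(dr)
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0L || max(pv) <= exit_p) break
    worst <- names(pv)[which.max(pv)]
    path[[length(path) + 1L]] <- data.frame(step = length(path) + 1L,
                                            dropped = worst,
                                            p = max(pv))
    current <- setdiff(current, worst)
    fit <- stats::lm(stats::as.formula(paste(
      outcome, "~", paste(c("1", current), collapse = " + "))), data = data)
  }
  sm <- summary(fit)
  list(model = fit, retained = current,
       dropped = setdiff(candidates, current),
       path = if (length(path)) do.call(rbind, path) else
         data.frame(step = integer(0), dropped = character(0), p = numeric(0)),
       summary = list(coefficients = stats::coef(sm),
                      r_squared = sm$r.squared,
                      adj_r_squared = sm$adj.r.squared,
                      f = sm$fstatistic))
}
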
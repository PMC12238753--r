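#' Fit the group x visit x TENS linear mixed model
#'
#' REML fit of `outcome ~ group * visit * tens + (1 | participant)` with
#' sum-to-zero factor coding (so the Type III tests below are the marginal
#' tests of each term). Estimation is delegated to `lme4`; inference
#' (Satterthwaite degrees of freedom, Type III F tests, EMM contrasts) is
#' computed in-package. A singular random-effect variance triggers a
#' fixed-effects (`lm`) refit with a warning. Outcomes with one record per
#' participant (savings) should be fitted with `random = NULL`, which goes
#' straight to `lm`.
#'
#' @param data data frame in long format.
#' @param outcome name of the numeric outcome column.
#' @param fixed character vector of fixed-effect factors, fully crossed
#'   (default `c("group", "visit", "tens")`; factors with < 2 observed
#'   levels are dropped with a message).
#' @param random name of the random-intercept grouping factor
#'   (`"participant"`), or `NULL` for a fixed-effects model.
#' @return an `adaptation_lmm` wrapper holding the fit, design pieces and
#'   factor metadata.
#' @export
fit_adaptation_lmm <- function(data, outcome, fixed = c("group", "visit", "tens"),
                               random = "participant") {
  stopifnot(outcome %in% names(data), is.numeric(data[[outcome]]))
  keep <- character(0)
  for (f in fixed) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) >= 2L) keep <- c(keep, f)
    else message("dropping factor '", f, "': fewer than 2 observed levels")
  }
  fixed <- keep
  if (length(fixed) == 0L) stop("no usable fixed-effect factors")
  contr <- stats::setNames(rep(list("contr.sum"), length(fixed)), fixed)
  fml_fixed <- paste(outcome, "~", paste(fixed, collapse = " * "))
  is_mixed <- !is.null(random)
  if (is_mixed) {
    data[[random]] <- factor(data[[random]])
    fml <- stats::as.formula(paste(fml_fixed, "+ (1 |", random, ")"))
    fit <- lme4::lmer(fml, data = data, REML = TRUE,
                      contrasts = contr,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-effect variance: refitting as a ",
              "fixed-effects model")
      is_mixed <- FALSE
    }
  }
  if (!is_mixed) {
    fit <- stats::lm(stats::as.formula(fml_fixed), data = data,
                     contrasts = contr)
  }
  structure(list(fit = fit, data = data, outcome = outcome, fixed = fixed,
                 random = if (is_mixed) random else NULL,
                 is_mixed = is_mixed, contrasts = contr),
            class = "adaptation_lmm")
}

## design pieces of the fitted model, in a uniform shape
model_pieces <- function(mod) {
  if (mod$is_mixed) {
    fit <- mod$fit
    X <- lme4::getME(fit, "X")
    y <- lme4::getME(fit, "y")
    id <- lme4::getME(fit, "flist")[[1]]
    vc <- lme4::VarCorr(fit)
    sigma2_b <- as.numeric(vc[[1]])
    sigma2_e <- stats::sigma(fit)^2
    Z <- stats::model.matrix(~ 0 + id)
    list(X = X, y = y, Z = Z, theta = c(sigma2_b, sigma2_e),
         beta = lme4::fixef(fit))
  } else {
    X <- stats::model.matrix(mod$fit)
    list(X = X, y = stats::model.response(stats::model.frame(mod$fit)),
         Z = NULL, theta = NULL, beta = stats::coef(mod$fit))
  }
}

## restricted log-likelihood of the random-intercept Gaussian model as a
## function of the variance components (sigma2_b, sigma2_e); used only for
## the curvature that feeds the Satterthwaite approximation
reml_loglik <- function(theta, X, y, ZZt) {
  n <- length(y)
  V <- theta[2] * diag(n) + theta[1] * ZZt
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtVinvX <- crossprod(X, Vinv_X)
  beta <- solve(XtVinvX, crossprod(X, Vinv_y))
  r <- y - X %*% beta
  Vinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (logdetV + determinant(XtVinvX, logarithm = TRUE)$modulus +
            sum(r * Vinv_r))
}

## vcov of the fixed effects as a function of the variance components
beta_vcov_fun <- function(X, ZZt) {
  n <- nrow(X)
  function(theta) {
    V <- theta[2] * diag(n) + theta[1] * ZZt
    ch <- chol(V)
    Vinv_X <- backsolve(ch, forwardsolve(t(ch), X))
    solve(crossprod(X, Vinv_X))
  }
}

## Satterthwaite machinery for a fitted adaptation_lmm: returns a function
## giving (df) for any single contrast vector, plus the beta vcov
satterthwaite_engine <- function(mod) {
  p <- model_pieces(mod)
  if (!mod$is_mixed) {
    Cb <- stats::vcov(mod$fit)
    dfres <- stats::df.residual(mod$fit)
    return(list(beta = p$beta, vcov = Cb,
                df_contrast = function(l) dfres))
  }
  ZZt <- tcrossprod(p$Z)
  vfun <- beta_vcov_fun(p$X, ZZt)
  H <- numDeriv::hessian(function(th) reml_loglik(th, p$X, p$y, ZZt),
                         p$theta)
  A <- tryCatch(solve(-H), error = function(e) NULL)
  Cb <- vfun(p$theta)
  df_contrast <- function(l) {
    v <- drop(t(l) %*% Cb %*% l)
    if (is.null(A)) return(NA_real_)
    g <- numDeriv::grad(function(th) drop(t(l) %*% vfun(th) %*% l), p$theta)
    denom <- drop(t(g) %*% A %*% g)
    if (denom <= 0) return(Inf)
    2 * v^2 / denom
  }
  list(beta = p$beta, vcov = Cb, df_contrast = df_contrast)
}

#' Type III ANOVA with Satterthwaite degrees of freedom
#'
#' Marginal (Type III) F test of every fixed-effect term. With the
#' sum-to-zero coding used by [fit_adaptation_lmm()], each term's test is a
#' Wald F on its own coefficients; for mixed fits the denominator df comes
#' from the Satterthwaite approximation (per-eigenvector single-df
#' Satterthwaite combined across the term's contrasts), for fixed-effects
#' fits it is the residual df.
#'
#' @param mod an [fit_adaptation_lmm()] result.
#' @param terms optional subset of term labels to test (default all).
#' @return data frame with `term`, `F`, `df1`, `df2`, `p`.
#' @export
anova_type3 <- function(mod, terms = NULL) {
  eng <- satterthwaite_engine(mod)
  X <- if (mod$is_mixed) lme4::getME(mod$fit, "X") else
    stats::model.matrix(mod$fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(stats::as.formula(
    paste("~", paste(mod$fixed, collapse = " * ")))), "term.labels")
  out <- list()
  for (ti in seq_along(labels)) {
    if (!is.null(terms) && !labels[ti] %in% terms) next
    idx <- which(asgn == ti)
    if (length(idx) == 0L) next
    L <- matrix(0, length(idx), ncol(X))
    L[cbind(seq_along(idx), idx)] <- 1
    res <- wald_f(eng, L)
    out[[length(out) + 1L]] <- data.frame(
      term = labels[ti], F = res$F, df1 = res$df1, df2 = res$df2, p = res$p)
  }
  do.call(rbind, out)
}

## multi-df Wald F with combined Satterthwaite denominator df
wald_f <- function(eng, L) {
  L <- matrix(L, ncol = length(eng$beta))
  q <- nrow(L)
  M <- L %*% eng$vcov %*% t(L)
  ei <- eigen(M, symmetric = TRUE)
  pos <- ei$values > max(ei$values) * 1e-10
  q_eff <- sum(pos)
  Ltil <- diag(1 / sqrt(ei$values[pos]), q_eff) %*%
    t(ei$vectors[, pos, drop = FALSE]) %*% L
  t2 <- drop(Ltil %*% eng$beta)^2
  Fstat <- sum(t2) / q_eff
  nus <- apply(Ltil, 1, function(l) eng$df_contrast(l))
  if (q_eff == 1L) {
    df2 <- nus[1]
  } else {
    ## Satterthwaite combination: E[F] matching over the term's contrasts;
    ## an infinite single-df limit contributes ratio 1
    ratio <- ifelse(is.finite(nus), ifelse(nus > 2, nus / (nus - 2), NA_real_), 1)
    if (anyNA(ratio)) {
      df2 <- NA_real_
    } else {
      E <- sum(ratio)
      df2 <- if (E > q_eff) 2 * E / (E - q_eff) else Inf
    }
  }
  p <- stats::pf(Fstat, q_eff, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = q_eff, df2 = df2, p = p)
}
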
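## small balanced crossover outcome table with known structure
make_crossover_data <- function(n_per_arm = 6, group_gap = 0, tens_gap = 0,
                                subj_sd = 0.03, resid_sd = 0.02, seed = 1) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (g in c("PwMS", "HC")) for (ord in c("ON-first", "ON-second")) {
    for (i in seq_len(n_per_arm)) {
      pid <- pid + 1
      u <- rnorm(1, sd = subj_sd)
      for (v in 1:2) {
        tens <- if (ord == "ON-first") c("ON", "OFF")[v] else c("OFF", "ON")[v]
        y <- u + (g == "PwMS") * group_gap + (tens == "ON") * tens_gap +
          rnorm(1, sd = resid_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = sprintf("P%02d", pid), group = g, visit = v,
          tens = tens, y = y)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("balanced two-level single-factor model reduces to classical ANOVA", {
  set.seed(5)
  d <- data.frame(g = rep(c("A", "B"), each = 12),
                  y = rnorm(24) + rep(c(0, 0.5), each = 12))
  mod <- fit_adaptation_lmm(d, "y", fixed = "g", random = NULL)
  a3 <- anova_type3(mod)
  cl <- anova(lm(y ~ g, data = d))
  expect_equal(a3$F, cl$`F value`[1], tolerance = 1e-9)
  expect_equal(a3$df2, cl$Df[2])
  expect_equal(a3$p, cl$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("Satterthwaite df reproduce the classical balanced crossover df", {
  d <- make_crossover_data(n_per_arm = 6, tens_gap = 0.02, seed = 2)
  mod <- fit_adaptation_lmm(d, "y")
  expect_true(mod$is_mixed)
  a3 <- anova_type3(mod)
  ## 24 participants in 4 group x order cells, 2 visits each:
  ## between-subject error df = 24 - 4 = 20; within error df = 48 - 24 - 4
  ## = 20. In this balanced design Satterthwaite recovers both exactly.
  expect_equal(a3$df2[a3$term == "group"], 20, tolerance = 0.1)
  expect_equal(a3$df2[a3$term == "tens"], 20, tolerance = 0.1)
  expect_true(all(a3$df1 == 1))
})

test_that("singular random effect falls back to a fixed-effects fit", {
  d <- make_crossover_data(n_per_arm = 4, subj_sd = 0, resid_sd = 0.05,
                           seed = 2)
  expect_warning(mod <- fit_adaptation_lmm(d, "y"), "singular")
  expect_false(mod$is_mixed)
  expect_s3_class(mod$fit, "lm")
  expect_silent(anova_type3(mod))
})

test_that("EMMs equal raw cell means under balance", {
  d <- make_crossover_data(n_per_arm = 5, group_gap = 0.05, tens_gap = 0.02,
                           seed = 4)
  mod <- fit_adaptation_lmm(d, "y")
  e <- emm(mod, "group")
  raw <- tapply(d$y, d$group, mean)
  expect_equal(e$emmean[match(names(raw), e$group)], as.vector(raw),
               tolerance = 1e-9)
  ## single-factor model: EMM of its only level-set averages to grand mean
  mod1 <- fit_adaptation_lmm(d, "y", fixed = "group", random = NULL)
  e1 <- emm(mod1, "group")
  expect_equal(mean(e1$emmean), mean(raw), tolerance = 1e-9)
})

test_that("EMM pairwise contrasts recover an injected shift", {
  d <- make_crossover_data(n_per_arm = 8, tens_gap = 0.05, subj_sd = 0.03,
                           resid_sd = 0.01, seed = 6)
  mod <- fit_adaptation_lmm(d, "y")
  pw <- emm_pairwise(mod, "tens")
  expect_identical(nrow(pw), 1L)
  est <- pw$estimate * (if (startsWith(pw$contrast, "OFF")) -1 else 1)
  expect_lt(abs(est - 0.05), 0.012)   # ~3 standard errors at this n
  expect_lt(pw$p_adj, 0.001)
  ## within-group conditioning returns one contrast per group
  pw2 <- emm_pairwise(mod, "tens", by = "group")
  expect_identical(nrow(pw2), 2L)
})

test_that("BH adjustment matches hand and brute-force computations", {
  expect_equal(bh_adjust(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)                  # single p unchanged
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))  # ties unchanged
  expect_error(bh_adjust(c(0.5, 1.2)), "within")
  set.seed(11)
  for (k in 1:25) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  ## adjusted never below raw
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p - 1e-12))
})

test_that("Cohen's d: hand value, antisymmetry, degenerate cases", {
  expect_equal(cohens_d(c(2, 4, 6), c(1, 3, 5)), 0.5)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- rnorm(10); y <- rnorm(10, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_warning(d0 <- cohens_d(rep(1, 5), rep(1, 5)), "zero")
  expect_true(is.na(d0))
  ## paired variant uses the difference sd
  a <- c(1, 2, 3, 4); b <- a - c(0.1, 0.2, 0.1, 0.2)
  expect_equal(cohens_d(a, b, paired = TRUE),
               mean(a - b) / sd(a - b), tolerance = 1e-12)
})

test_that("Pearson correlation wrapper: exact lines and degeneracies", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(13)
  out <- pearson_correlation(rnorm(10000), rnorm(10000))
  expect_lt(abs(out$r), 0.03)
  expect_warning(z <- pearson_correlation(rep(1, 5), rnorm(5)), "zero")
  expect_true(is.na(z$r))
})

test_that("backward stepwise keeps real predictors and discards noise", {
  gen <- function(seed, beta1 = 1) {
    set.seed(seed)
    d <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
    names(d) <- paste0("x", 1:6)
    d$y <- beta1 * d$x1 + rnorm(200, sd = 0.1)
    d
  }
  keeps <- vapply(1:10, function(s) {
    res <- backward_stepwise(gen(s), "y", paste0("x", 1:6))
    "x1" %in% res$retained
  }, logical(1))
  expect_gte(mean(keeps), 0.95)

  ## all-noise predictors: typically everything is eliminated
  res0 <- backward_stepwise(gen(99, beta1 = 0), "y", paste0("x", 2:6))
  expect_length(res0$retained, 0)

  ## a single predictor already below the threshold is returned unchanged
  d <- gen(7)
  res1 <- backward_stepwise(d, "y", "x1")
  expect_identical(res1$retained, "x1")
  expect_identical(nrow(res1$path), 0L)

  ## collinear predictors are dropped with a warning before stepping
  d$x7 <- d$x1
  expect_warning(res2 <- backward_stepwise(d, "y", c("x1", "x7", "x2")),
                 "collinear")
})

test_that("savings models use residual df matching the crossover design", {
  ## 48 participants, savings ~ group * tens_visit2 via lm: t df = 44
  set.seed(21)
  sv <- data.frame(
    participant = sprintf("P%02d", 1:48),
    group = rep(c("PwMS", "HC"), c(28, 20)),
    tens_visit2 = c(rep(c("ON", "OFF"), 14), rep(c("ON", "OFF"), 10)),
    savings_initial = rnorm(48, sd = 0.037))
  mod <- fit_adaptation_lmm(sv, "savings_initial",
                            fixed = c("group", "tens_visit2"), random = NULL)
  pw <- emm_pairwise(mod, "tens_visit2", by = "group")
  expect_true(all(pw$df == 44))
})
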
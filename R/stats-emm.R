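#' Estimated marginal means
#'
#' Model-based cell means for the levels of one or more factors, averaged
#' over all other fixed-effect factors with equal weights (the reference
#' grid). Under a balanced design these coincide with raw cell means; in
#' unbalanced designs they remain defined from the model (empty cells are
#' flagged).
#'
#' @param mod an [fit_adaptation_lmm()] result.
#' @param specs character vector of factor names whose marginal means are
#'   wanted.
#' @return data frame of levels, `emmean`, `se`, `df`.
#' @export
emm <- function(mod, specs) {
  eng <- satterthwaite_engine(mod)
  gr <- emm_grid(mod)
  key <- interaction(gr$grid[specs], drop = FALSE, sep = ":")
  out <- list()
  for (lev in levels(key)) {
    rows <- which(key == lev)
    l <- colMeans(gr$X[rows, , drop = FALSE])
    est <- drop(l %*% eng$beta)
    se <- sqrt(drop(t(l) %*% eng$vcov %*% l))
    cells <- gr$grid[rows, , drop = FALSE]
    empty <- !all(apply(cells, 1, function(rw)
      cell_present(mod$data, names(gr$grid), rw)))
    out[[length(out) + 1L]] <- cbind(
      gr$grid[rows[1], specs, drop = FALSE],
      data.frame(emmean = est, se = se, df = eng$df_contrast(l),
                 empty_cells = empty, row.names = NULL))
  }
  do.call(rbind, out)
}

cell_present <- function(data, factors, rw) {
  m <- rep(TRUE, nrow(data))
  for (f in factors) m <- m & data[[f]] == rw[[f]]
  any(m)
}

## the reference grid and its model matrix, using the fit's contrasts
emm_grid <- function(mod) {
  data <- mod$data
  levs <- lapply(mod$fixed, function(f) levels(data[[f]]))
  names(levs) <- mod$fixed
  grid <- expand.grid(levs, stringsAsFactors = TRUE)
  tms <- stats::delete.response(stats::terms(stats::as.formula(
    paste("~", paste(mod$fixed, collapse = " * ")))))
  X <- stats::model.matrix(tms, grid, contrasts.arg = mod$contrasts)
  list(grid = grid, X = X)
}

#' Pairwise EMM contrasts
#'
#' All pairwise differences of the estimated marginal means of `specs`,
#' optionally within levels of a `by` factor, with Satterthwaite df
#' (mixed fits) or residual df, raw and BH-adjusted p-values, and a
#' data-based Cohen's d for each contrast (pooled-sd formula over the
#' observed records of the two cells; the model-SE variant is available
#' via `d_method = "model"`).
#'
#' @param mod an [fit_adaptation_lmm()] result.
#' @param specs factor(s) to contrast.
#' @param by optional conditioning factor: contrasts are computed within
#'   each of its levels and the BH family is the full returned set.
#' @param adjust `"BH"` (default) or `"none"`.
#' @param d_method `"data"` (pooled observed sd) or `"model"`
#'   (estimate / model-implied population sd).
#' @return data frame with one row per contrast.
#' @export
emm_pairwise <- function(mod, specs, by = NULL, adjust = c("BH", "none"),
                         d_method = c("data", "model")) {
  adjust <- match.arg(adjust)
  d_method <- match.arg(d_method)
  eng <- satterthwaite_engine(mod)
  gr <- emm_grid(mod)
  data <- mod$data
  by_levels <- if (is.null(by)) NA_character_ else levels(data[[by]])
  rows_out <- list()
  for (bl in by_levels) {
    sel <- if (is.null(by)) rep(TRUE, nrow(gr$grid)) else gr$grid[[by]] == bl
    key <- interaction(gr$grid[sel, specs, drop = FALSE], drop = TRUE, sep = ":")
    lv <- levels(key)
    lvecs <- lapply(lv, function(k)
      colMeans(gr$X[sel, , drop = FALSE][key == k, , drop = FALSE]))
    names(lvecs) <- lv
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (i >= j) next
      l <- lvecs[[i]] - lvecs[[j]]
      est <- drop(l %*% eng$beta)
      se <- sqrt(drop(t(l) %*% eng$vcov %*% l))
      df <- eng$df_contrast(l)
      tval <- est / se
      p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
      d <- contrast_d(mod, specs, lv[i], lv[j], by, bl, d_method, est)
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        contrast = paste(lv[i], "-", lv[j]),
        by = if (is.null(by)) NA_character_ else bl,
        estimate = est, se = se, df = df, t = tval, p_raw = p, d = d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows_out)
  out$p_adj <- if (adjust == "BH") bh_adjust(out$p_raw) else out$p_raw
  out
}

## data-based (pooled observed sd) or model-based d for one EMM contrast
contrast_d <- function(mod, specs, lev_i, lev_j, by, bl, d_method, est) {
  data <- mod$data
  key <- interaction(data[specs], drop = FALSE, sep = ":")
  sel <- if (is.null(by)) rep(TRUE, nrow(data)) else data[[by]] == bl
  xi <- data[[mod$outcome]][sel & key == lev_i]
  xj <- data[[mod$outcome]][sel & key == lev_j]
  if (d_method == "data") {
    if (length(xi) < 2 || length(xj) < 2) return(NA_real_)
    cohens_d(xi, xj)
  } else {
    sp <- sqrt((stats::var(xi) * (length(xi) - 1) +
                  stats::var(xj) * (length(xj) - 1)) /
                 (length(xi) + length(xj) - 2))
    if (!is.finite(sp) || sp == 0) return(NA_real_)
    est / sp
  }
}
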
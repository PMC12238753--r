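#' Particle swarm optimisation
#'
#' Minimises a vectorised objective over a box. Standard constricted swarm
#' (Clerc-Kennedy coefficients): velocities updated from inertia, cognitive
#' and social pulls; positions clipped to the box; velocity clamped to the
#' box range. Deterministic under a fixed seed.
#'
#' @param fn objective: receives a `d x P` matrix of particle positions and
#'   must return a length-`P` vector of costs.
#' @param lower,upper box bounds (length `d`).
#' @param n_particles swarm size (default 50).
#' @param n_iter iterations (default 500).
#' @param inertia,c_cog,c_soc swarm coefficients (defaults 0.7298, 1.49618,
#'   1.49618).
#' @param init optional matrix (`d x k`) of positions to seed into the
#'   initial swarm (e.g. a known feasible baseline).
#' @param seed integer seed; the swarm RNG is local and does not disturb the
#'   caller's RNG state.
#' @return list with `par`, `value`, `trace` (best value per 10 iterations),
#'   `n_iter`, `n_particles`.
#' @export
pso_optimize <- function(fn, lower, upper, n_particles = 50L, n_iter = 500L,
                         inertia = 0.7298, c_cog = 1.49618, c_soc = 1.49618,
                         init = NULL, seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower),
            n_particles >= 2L, n_iter >= 1L)
  run <- function() {
    range <- upper - lower
    X <- matrix(stats::runif(d * n_particles, lower, upper), nrow = d)
    if (!is.null(init)) {
      init <- as.matrix(init)
      k <- min(ncol(init), n_particles)
      X[, seq_len(k)] <- pmin(pmax(init[, seq_len(k), drop = FALSE], lower), upper)
    }
    V <- matrix(stats::runif(d * n_particles, -range, range), nrow = d) * 0.1
    vmax <- range
    cost <- fn(X)
    Pb <- X; pbest <- cost
    g <- which.min(pbest)
    gpar <- Pb[, g]; gval <- pbest[g]
    trace <- numeric(0)
    for (it in seq_len(n_iter)) {
      r1 <- matrix(stats::runif(d * n_particles), nrow = d)
      r2 <- matrix(stats::runif(d * n_particles), nrow = d)
      V <- inertia * V + c_cog * r1 * (Pb - X) + c_soc * r2 * (gpar - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- pmin(pmax(X + V, lower), upper)
      cost <- fn(X)
      imp <- cost < pbest
      if (any(imp)) {
        Pb[, imp] <- X[, imp]
        pbest[imp] <- cost[imp]
        g <- which.min(pbest)
        if (pbest[g] < gval) { gpar <- Pb[, g]; gval <- pbest[g] }
      }
      if (it %% 10L == 0L) trace <- c(trace, gval)
    }
    list(par = gpar, value = gval, trace = trace,
         n_iter = n_iter, n_particles = n_particles)
  }
  with_local_seed(seed, run())
}

## evaluate `expr` under a temporary RNG seed, restoring caller state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
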
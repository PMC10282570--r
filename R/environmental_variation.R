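#' Lognormal resource-year model from mean and CV
#'
#' Interannual resource availability (e.g. a mast-seeding food supply) is
#' modelled as a lognormal juvenile growth rate `r_Y` with a fixed mean and
#' a coefficient of variation that dials the strength of environmental
#' stochasticity. Moment matching is exact:
#' `sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean_r) - sdlog^2 / 2`.
#' `cv = 0` degenerates to a point mass at `mean_r`.
#'
#' @param mean_r Mean juvenile growth rate `E(r_Y)` (time^-1), positive.
#' @param cv Coefficient of variation `sd/mean`, `>= 0`.
#' @return An object of class `"resource_model"` with fields `mean_r`, `cv`,
#'   `meanlog`, `sdlog`.
#' @examples
#' resource_model(mean_r = 0.5, cv = 1)
#' @export
resource_model <- function(mean_r, cv) {
  stopifnot(is.numeric(mean_r), length(mean_r) == 1L,
            is.numeric(cv), length(cv) == 1L)
  if (mean_r <= 0) stop("'mean_r' must be positive", call. = FALSE)
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  sdlog <- sqrt(log(1 + cv^2))
  structure(list(mean_r = mean_r, cv = cv,
                 meanlog = log(mean_r) - sdlog^2 / 2, sdlog = sdlog),
            class = "resource_model")
}

#' @export
print.resource_model <- function(x, ...) {
  cat(sprintf(
    "Lognormal resource model: mean %.4g, CV %.4g (meanlog %.4g, sdlog %.4g)\n",
    x$mean_r, x$cv, x$meanlog, x$sdlog))
  invisible(x)
}

#' Draw resource years from a resource model
#'
#' @param env A [resource_model()].
#' @param n Number of draws.
#' @return Numeric vector of `n` positive resource (growth-rate) values; all
#'   equal to `mean_r` when `cv = 0`.
#' @export
resource_draws <- function(env, n) {
  stopifnot(inherits(env, "resource_model"), n >= 0)
  if (env$cv == 0) return(rep(env$mean_r, n))
  stats::rlnorm(n, env$meanlog, env$sdlog)
}

# Expectation of g(X) for X lognormal, by Gauss-Hermite quadrature in the
# log-resource variable. Node count doubles until two consecutive levels
# agree to rel_tol; integrands with sharp transitions (large constant broods
# at high CV) instead go to adaptive quadrature in the standard-normal
# variable, and an error with diagnostics is raised if neither converges.
.lognormal_expect <- function(g, env, nodes = 128L, rel_tol = 1e-8,
                              max_nodes = 256L) {
  if (env$cv == 0) return(g(env$mean_r))
  gh_value <- function(n) {
    gh <- pracma::gaussHermite(n)
    x <- exp(env$meanlog + env$sdlog * sqrt(2) * gh$x)
    sum(gh$w * g(x)) / sqrt(pi)
  }
  prev <- gh_value(nodes)
  n <- nodes
  while (n < max_nodes) {
    n <- 2L * n
    cur <- gh_value(n)
    if (abs(cur - prev) <= rel_tol * (abs(cur) + 1e-300)) return(cur)
    prev <- cur
  }
  # adaptive fallback in the standard-normal variable (mass beyond |z| = 8.5
  # is < 1e-16); Gauss-Hermite underresolves integrands with sharp
  # transitions, so the fallback is trusted on its own error estimate
  int <- tryCatch(
    stats::integrate(function(z)
      g(exp(env$meanlog + env$sdlog * z)) * stats::dnorm(z),
      lower = -8.5, upper = 8.5, rel.tol = 10 * rel_tol,
      subdivisions = 1000L),
    error = function(e) NULL)
  if (!is.null(int) && is.finite(int$value) &&
      int$abs.error <= pmax(1e-8, 1e-6 * abs(int$value)))
    return(int$value)
  stop(sprintf(paste0(
    "quadrature did not converge (GH at %d nodes: %.12g; adaptive: %s); ",
    "mean_r = %g, cv = %g"), n, prev,
    if (is.null(int)) "failed" else sprintf("%.12g", int$value),
    env$mean_r, env$cv), call. = FALSE)
}

#' Lyapunov growth rate of a constant brood strategy in a variable environment
#'
#' Resource years are i.i.d. draws `X ~` [resource_model()]; the brood size is
#' held fixed across years. The long-run growth rate is
#' `R0 = exp( E[ log R0_det(B0; X) ] )`, the expectation taken over the
#' resource distribution by Gauss-Hermite quadrature (deterministic and
#' repeatable). At `cv = 0` this reduces exactly to [annual_growth_rate()].
#'
#' @param B0 Constant brood size, `>= 0`.
#' @param lh A [life_history()] object.
#' @param env A [resource_model()].
#' @param nodes Initial Gauss-Hermite node count (doubled until stable).
#' @return Long-run multiplicative growth rate per interval.
#' @examples
#' lyapunov_env_constant(2, life_history(), resource_model(0.5, 1))
#' @export
lyapunov_env_constant <- function(B0, lh, env, nodes = 128L) {
  stopifnot(is.numeric(B0), length(B0) == 1L, B0 >= 0,
            inherits(lh, "life_history"), inherits(env, "resource_model"))
  if (B0 == 0) return(1 - lh$adult$muA0)  # kernel is resource-independent
  exp(.lognormal_expect(function(x) log(annual_growth_rate(B0, lh, x)),
                        env, nodes))
}

#' Optimal constant brood size in a variable environment
#'
#' Maximizes [lyapunov_env_constant()] over brood size. Increasing the
#' resource CV lowers the achievable growth and (for `alpha > 0`) the optimal
#' brood size; at high enough cost and variability the boundary `B0 = 0`
#' takes over.
#'
#' @inheritParams lyapunov_env_constant
#' @param search_max Upper search bound; defaults to ten times the cost-free
#'   optimum at the mean resource level.
#' @return A `brood_optimum` (see [optimal_constant_brood()]).
#' @export
optimal_constant_brood_env <- function(lh, env,
    search_max = .default_search_max(lh, env$mean_r)) {
  stopifnot(inherits(lh, "life_history"), inherits(env, "resource_model"))
  .maximize_brood(function(b) lyapunov_env_constant(b, lh, env), search_max,
                  grid_n = 32L)
}

#' CV threshold above which zero reproduction is optimal
#'
#' Sweeps a grid of resource CVs and finds the smallest at which the optimal
#' constant brood size drops to the `B0 = 0` boundary, refining the switch
#' point by bisection between the bracketing grid values.
#'
#' @param lh A [life_history()] object.
#' @param cv_grid Increasing vector of CVs to scan.
#' @param mean_r Mean resource level; defaults to `lh$juvenile$r0`.
#' @param tol Bisection tolerance on CV.
#' @return The threshold CV, or `NA_real_` when no switch occurs on the grid.
#' @export
zero_brood_cv_threshold <- function(lh, cv_grid, mean_r = lh$juvenile$r0,
                                    tol = 1e-3) {
  stopifnot(all(diff(cv_grid) > 0))
  zero_at <- function(cv)
    !optimal_constant_brood_env(lh, resource_model(mean_r, cv))$is_interior
  z <- vapply(cv_grid, zero_at, logical(1))
  if (!any(z)) return(NA_real_)
  i <- which(z)[1L]
  if (i == 1L) return(cv_grid[1L])
  lo <- cv_grid[i - 1L]
  hi <- cv_grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (zero_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Sweep optimal constant brood over brood cost and environmental variability
#'
#' @param lh A [life_history()] object (its `alpha` is replaced per row).
#' @param alphas Brood-cost values.
#' @param cvs Resource CV values.
#' @param mean_r Mean resource level.
#' @return Data frame with columns `alpha`, `cv`, `brood_size`, `growth_rate`.
#' @export
sweep_alpha_cv_env <- function(lh, alphas, cvs, mean_r = lh$juvenile$r0) {
  grid <- expand.grid(alpha = alphas, cv = cvs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    opt <- optimal_constant_brood_env(
      .with_alpha(lh, grid$alpha[i]), resource_model(mean_r, grid$cv[i]))
    data.frame(alpha = grid$alpha[i], cv = grid$cv[i],
               brood_size = opt$brood_size, growth_rate = opt$growth_rate)
  })
  do.call(rbind, rows)
}
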
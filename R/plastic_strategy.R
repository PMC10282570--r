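#' Optimal brood size for a single resource year
#'
#' A plastic breeder chooses each year's brood size to maximize that year's
#' annual growth kernel given the realized resource level `X`. With no brood
#' cost (`alpha = 0`) the optimum has the closed form `X / (muJ * (1 - L0))`;
#' with `alpha > 0` sufficiently poor years make zero reproduction optimal.
#'
#' @param X Resource level (realized juvenile growth rate, time^-1), positive;
#'   vectorized.
#' @param lh A [life_history()] object.
#' @return Optimal brood size(s), `>= 0`.
#' @examples
#' per_year_optimal_brood(0.5, life_history())   # 0.5 / (0.2 * 0.99)
#' @export
per_year_optimal_brood <- function(X, lh) {
  stopifnot(is.numeric(X), inherits(lh, "life_history"))
  if (any(X <= 0)) stop("'X' must be positive", call. = FALSE)
  ju <- lh$juvenile
  if (lh$adult$alpha == 0) return(X / (ju$muJ * (1 - ju$L0)))
  vapply(X, function(x) {
    .maximize_brood(function(b) annual_growth_rate(b, lh, x),
                    .default_search_max(lh, x), vectorized = TRUE)$brood_size
  }, numeric(1))
}

# Resource level below which a plastic breeder's optimal brood is 0 (only
# relevant for alpha > 0). Depends on the life history alone, so callers
# evaluating many environments can compute it once. Returns 0 when
# reproduction pays at every level probed, Inf when it never does.
.plastic_switch_level <- function(lh) {
  reproduces <- function(x) per_year_optimal_brood(x, lh) > 0
  lo <- 1e-8
  hi <- 1e4
  if (reproduces(lo)) return(0)
  if (!reproduces(hi)) return(Inf)
  while (hi - lo > 1e-9 * hi) {
    mid <- sqrt(lo * hi)
    if (reproduces(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Lyapunov growth rate of the plastic (resource-synchronized) strategy
#'
#' Each year the brood size is re-optimized for the realized resource level
#' before the annual kernel is applied:
#' `R0 = exp( E[ log R0_det(B0*(X); X) ] )`. Because the plastic kernel
#' dominates the constant-brood kernel pointwise in `X`, this growth rate is
#' at least [lyapunov_env_constant()] at every fixed brood size.
#'
#' @param lh A [life_history()] object.
#' @param env A [resource_model()].
#' @param nodes Initial Gauss-Hermite node count. Brood sizes are optimized
#'   at the quadrature nodes only, so the integral is deterministic.
#' @param switch_level Optional precomputed resource level below which the
#'   per-year optimum is 0 (it depends on `lh` alone); computed when `NULL`.
#'   Callers sweeping many environments can compute it once.
#' @return Long-run multiplicative growth rate per interval.
#' @export
lyapunov_env_plastic <- function(lh, env, nodes = 128L, switch_level = NULL) {
  stopifnot(inherits(lh, "life_history"), inherits(env, "resource_model"))
  h <- function(x)
    log(annual_growth_rate(per_year_optimal_brood(x, lh), lh, x))
  if (env$cv == 0) return(exp(h(env$mean_r)))
  if (lh$adult$alpha == 0) return(exp(.lognormal_expect(h, env, nodes)))

  # With alpha > 0 the per-year optimum is 0 below a switch resource level,
  # where the integrand kinks; split the expectation there so each piece is
  # smooth. Below the switch the log growth is the constant log(1 - muA0).
  x0 <- if (is.null(switch_level)) .plastic_switch_level(lh) else switch_level
  log_floor <- log(1 - lh$adult$muA0)
  lo <- stats::qlnorm(1e-13, env$meanlog, env$sdlog)
  hi <- stats::qlnorm(1 - 1e-13, env$meanlog, env$sdlog)
  if (x0 <= lo) return(exp(.lognormal_expect(h, env, nodes)))
  if (x0 >= hi) return(1 - lh$adult$muA0)
  tail <- stats::integrate(function(x)
    h(x) * stats::dlnorm(x, env$meanlog, env$sdlog),
    lower = x0, upper = hi, rel.tol = 1e-9, subdivisions = 500L)
  exp(stats::plnorm(x0, env$meanlog, env$sdlog) * log_floor + tail$value)
}

#' Optimal level of environmental variation for a plastic breeder
#'
#' Maximizes [lyapunov_env_plastic()] over the resource CV at a fixed mean
#' resource level. With no brood cost a constant environment (CV = 0) is
#' best; with high brood cost the ability to sit out bad years makes a
#' strictly positive CV optimal.
#'
#' @param lh A [life_history()] object.
#' @param cv_range Closed search interval for the CV, starting at 0.
#' @param mean_r Mean resource level; defaults to `lh$juvenile$r0`.
#' @param step Coarse-scan step preceding the local refinement.
#' @return A list with `cv` (best CV, 0 when the deterministic world wins)
#'   and `growth`.
#' @export
optimal_cv <- function(lh, cv_range = c(0, 3), mean_r = lh$juvenile$r0,
                       step = 0.05) {
  stopifnot(length(cv_range) == 2L, cv_range[1] == 0, cv_range[2] > 0)
  x0 <- if (lh$adult$alpha > 0) .plastic_switch_level(lh) else NULL
  f <- function(cv) lyapunov_env_plastic(lh, resource_model(mean_r, cv),
                                         switch_level = x0)
  grid <- seq(cv_range[1], cv_range[2], by = step)
  fg <- vapply(grid, f, numeric(1))
  i <- which.max(fg)
  if (i == 1L) {
    # boundary at 0 unless a refinement inside the first cell beats it
    opt <- stats::optimize(f, lower = 0, upper = grid[2L], maximum = TRUE,
                           tol = 1e-6)
    if (opt$objective > fg[1L] + 1e-10)
      return(list(cv = opt$maximum, growth = opt$objective))
    return(list(cv = 0, growth = fg[1L]))
  }
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  list(cv = opt$maximum, growth = opt$objective)
}

#' Paired plastic and constant strategy trajectories
#'
#' Simulates one realization of the resource process and evolves two
#' populations through it: one re-optimizing its brood each year (plastic)
#' and one using the best constant brood for that environment. Both see the
#' same resource draws, so the comparison is paired.
#'
#' @param lh A [life_history()] object.
#' @param env A [resource_model()].
#' @param n_years Horizon, `>= 1`.
#' @param seed RNG seed for the resource draws.
#' @param N0 Initial population size for both strategies.
#' @return A list of two data frames, `plastic` and `constant`, each with
#'   columns `year`, `resource`, `brood`, `population`, `strategy`; the seed
#'   and constant brood size are attached as attributes `seed` and
#'   `constant_brood`.
#' @export
simulate_strategy_trajectories <- function(lh, env, n_years, seed = 1L,
                                           N0 = 1) {
  stopifnot(n_years >= 1, N0 > 0)
  set.seed(seed)
  X <- resource_draws(env, n_years)
  b_const <- optimal_constant_brood_env(lh, env)$brood_size
  b_plast <- per_year_optimal_brood(X, lh)
  make_traj <- function(brood, label) {
    R <- annual_growth_rate(brood, lh, X)
    data.frame(year = seq_len(n_years), resource = X,
               brood = if (length(brood) == 1L) rep(brood, n_years) else brood,
               population = N0 * cumprod(R), strategy = label)
  }
  out <- list(plastic = make_traj(b_plast, "plastic"),
              constant = make_traj(b_const, "constant"))
  attr(out, "seed") <- seed
  attr(out, "constant_brood") <- b_const
  out
}

#' Plastic versus best-constant growth across brood cost and variability
#'
#' @param lh A [life_history()] object (its `alpha` is replaced per row).
#' @param alphas Brood-cost values.
#' @param cvs Resource CV values.
#' @param mean_r Mean resource level.
#' @return Data frame with columns `alpha`, `cv`, `plastic_growth`,
#'   `constant_growth` (best constant strategy), `constant_brood`.
#' @export
sweep_plastic_vs_constant <- function(lh, alphas, cvs,
                                      mean_r = lh$juvenile$r0) {
  grid <- expand.grid(alpha = alphas, cv = cvs)
  x0s <- lapply(stats::setNames(alphas, alphas), function(a) {
    if (a > 0) .plastic_switch_level(.with_alpha(lh, a)) else NULL
  })
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lh_a <- .with_alpha(lh, grid$alpha[i])
    env <- resource_model(mean_r, grid$cv[i])
    const <- optimal_constant_brood_env(lh_a, env)
    data.frame(alpha = grid$alpha[i], cv = grid$cv[i],
               plastic_growth = lyapunov_env_plastic(
                 lh_a, env, switch_level = x0s[[as.character(grid$alpha[i])]]),
               constant_growth = const$growth_rate,
               constant_brood = const$brood_size)
  })
  do.call(rbind, rows)
}
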
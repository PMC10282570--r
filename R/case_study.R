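#' Two-state masting environment
#'
#' A world of i.i.d. good (mast) and bad years. Good years have probability
#' `p_good`, high juvenile growth and low (typically zero) brood-cost
#' mortality; bad years the reverse.
#'
#' @param p_good Probability a year is good, in `[0, 1]`.
#' @param r_good,r_bad Juvenile growth rates in good/bad years (time^-1),
#'   with `r_good >= r_bad > 0`.
#' @param alpha_good,alpha_bad Brood-cost mortality in good/bad years, `>= 0`.
#' @return An object of class `"two_state_environment"`.
#' @examples
#' two_state_environment(0.25, 0.2, 0.05)
#' @export
two_state_environment <- function(p_good, r_good, r_bad, alpha_good = 0,
                                  alpha_bad = 0.5) {
  stopifnot(p_good >= 0, p_good <= 1, r_bad > 0, r_good >= r_bad,
            alpha_good >= 0, alpha_bad >= 0)
  structure(list(p_good = p_good, r_good = r_good, r_bad = r_bad,
                 alpha_good = alpha_good, alpha_bad = alpha_bad),
            class = "two_state_environment")
}

#' Probability-weighted geometric-mean growth rate
#'
#' The long-run growth rate of a population whose annual multiplier is `R_i`
#' with probability `p_i` (i.i.d. years) is the geometric mean
#' `exp(sum p_i * log R_i)` — the exponential of the expected log growth,
#' consistent with the Lyapunov-exponent definition. The arithmetic mean
#' overstates long-run growth whenever the `R_i` differ.
#'
#' @param p Probabilities, summing to 1.
#' @param R Positive annual growth rates, same length as `p`.
#' @return The geometric-mean growth rate.
#' @examples
#' geometric_mean_growth(c(0.25, 0.75), c(1.6432, 0.9490))  # about 1.09
#' @export
geometric_mean_growth <- function(p, R) {
  stopifnot(is.numeric(p), is.numeric(R), length(p) == length(R))
  if (abs(sum(p) - 1) > 1e-12) stop("'p' must sum to 1", call. = FALSE)
  if (any(R <= 0)) stop("all growth rates must be positive", call. = FALSE)
  exp(sum(p * log(R)))
}

#' Strategy of a masting-adapted species
#'
#' In each year type the species uses the brood size optimal for that type's
#' resource level and brood cost; overall growth combines the per-state
#' growth rates geometrically with the year-type probabilities.
#'
#' @param env A [two_state_environment()].
#' @param lh A [life_history()] supplying `muA0`, `muJ`, `L0` (its `alpha`
#'   is overridden per state).
#' @return A list with `good` and `bad` (`brood_optimum` objects, see
#'   [optimal_constant_brood()]) and `overall_growth`.
#' @examples
#' lh <- life_history(juvenile_params(0.2, 0.1, 0.01), adult_params(0.1))
#' masting_species_strategy(two_state_environment(0.25, 0.2, 0.05), lh)
#' @export
masting_species_strategy <- function(env, lh) {
  stopifnot(inherits(env, "two_state_environment"),
            inherits(lh, "life_history"))
  good <- optimal_constant_brood(.with_alpha(lh, env$alpha_good), env$r_good)
  bad <- optimal_constant_brood(.with_alpha(lh, env$alpha_bad), env$r_bad)
  list(good = good, bad = bad,
       overall_growth = geometric_mean_growth(
         c(env$p_good, 1 - env$p_good),
         c(good$growth_rate, bad$growth_rate)))
}

#' Brood cost matching a target growth rate in a constant environment
#'
#' Finds the brood-cost coefficient `alpha` at which the best constant
#' strategy in a constant environment with resource level `r_const` attains
#' exactly `target_growth`. The optimal growth is continuous and strictly
#' decreasing in `alpha` on the interior branch, so the root is found by
#' [stats::uniroot()].
#'
#' @param target_growth Growth rate to match; must lie in
#'   `(1 - muA0, optimal growth at alpha = 0]`.
#' @param r_const Juvenile growth rate of the constant environment.
#' @param lh A [life_history()] supplying `muA0`, `muJ`, `L0`.
#' @return A list with `alpha` and `optimum` (the matching `brood_optimum`).
#' @export
match_alpha_constant <- function(target_growth, r_const, lh) {
  stopifnot(inherits(lh, "life_history"), r_const > 0, target_growth > 0)
  best <- function(a)
    optimal_constant_brood(.with_alpha(lh, a), r_const)$growth_rate
  floor_growth <- 1 - lh$adult$muA0
  top <- best(0)
  if (target_growth > top && target_growth <= top * (1 + 1e-9))
    target_growth <- top  # guard float round-off at the achievable ceiling
  if (target_growth > top || target_growth <= floor_growth)
    stop(sprintf(paste0(
      "target growth %.6g is not achievable in the constant environment: ",
      "attainable range is (%.6g, %.6g]"), target_growth, floor_growth, top),
      call. = FALSE)
  if (target_growth == top)
    return(list(alpha = 0,
                optimum = optimal_constant_brood(.with_alpha(lh, 0), r_const)))
  hi <- 1
  while (best(hi) > target_growth && hi < 64) hi <- 2 * hi
  a <- stats::uniroot(function(x) best(x) - target_growth, c(0, hi),
                      tol = 1e-10)$root
  list(alpha = a,
       optimum = optimal_constant_brood(.with_alpha(lh, a), r_const))
}

#' Growth after moving a masting-adapted species to a constant environment
#'
#' The species keeps switching between its evolved good-year and bad-year
#' brood sizes with the original year-type probabilities, but every year now
#' delivers the constant environment's resource level and brood cost.
#'
#' @param env The native [two_state_environment()].
#' @param matched_alpha Brood cost of the constant environment (from
#'   [match_alpha_constant()]).
#' @param r_const Resource level of the constant environment.
#' @param lh A [life_history()] supplying `muA0`, `muJ`, `L0`.
#' @param baseline Baseline overall growth for the percentage change.
#' @return A list with `growth` and `pct_change` (relative to `baseline`,
#'   in percent).
#' @export
translocate_masting_to_constant <- function(env, matched_alpha, r_const, lh,
                                            baseline) {
  strat <- masting_species_strategy(env, lh)
  lh_c <- .with_alpha(lh, matched_alpha)
  Rg <- annual_growth_rate(strat$good$brood_size, lh_c, r_const)
  Rb <- annual_growth_rate(strat$bad$brood_size, lh_c, r_const)
  g <- geometric_mean_growth(c(env$p_good, 1 - env$p_good), c(Rg, Rb))
  list(growth = g, pct_change = 100 * (g - baseline) / baseline)
}

#' Growth after moving a constant-environment species to a masting one
#'
#' The species does not perceive the environmental cues and keeps its evolved
#' constant brood size every year, while experiencing the masting world's
#' fluctuating resource levels and brood costs.
#'
#' @param env The destination [two_state_environment()].
#' @param brood The species' evolved constant brood size.
#' @param lh A [life_history()] supplying `muA0`, `muJ`, `L0`.
#' @param baseline Baseline overall growth for the percentage change.
#' @return A list with `growth` and `pct_change`.
#' @export
translocate_constant_to_masting <- function(env, brood, lh, baseline) {
  Rg <- annual_growth_rate(brood, .with_alpha(lh, env$alpha_good), env$r_good)
  Rb <- annual_growth_rate(brood, .with_alpha(lh, env$alpha_bad), env$r_bad)
  g <- geometric_mean_growth(c(env$p_good, 1 - env$p_good), c(Rg, Rb))
  list(growth = g, pct_change = 100 * (g - baseline) / baseline)
}

#' Full two-species translocation case study
#'
#' Contrasts a masting-adapted species (per-year-type optimal broods in a
#' two-state environment) with a constant-environment species whose brood
#' cost is solved so both have the same baseline overall growth rate. Then
#' swaps their environments: the masting species keeps switching broods in
#' the now-constant world; the constant species keeps its fixed brood in the
#' now-fluctuating world.
#'
#' @param env A [two_state_environment()].
#' @param lh A [life_history()] supplying `muA0`, `muJ`, `L0`.
#' @param r_const Resource level of the constant environment; defaults to the
#'   frequency-weighted average of `r_good` and `r_bad`.
#' @return An object of class `"case_study_result"`: a list with the masting
#'   strategy (`masting`), the matched constant-species parameters
#'   (`constant`), the shared `baseline_growth`, and both translocation
#'   outcomes (`masting_to_constant`, `constant_to_masting`).
#' @examples
#' lh <- life_history(juvenile_params(0.2, 0.1, 0.01), adult_params(0.1))
#' case_study(two_state_environment(0.25, 0.2, 0.05), lh)
#' @export
case_study <- function(env, lh,
                       r_const = env$p_good * env$r_good +
                         (1 - env$p_good) * env$r_bad) {
  strat <- masting_species_strategy(env, lh)
  matched <- match_alpha_constant(strat$overall_growth, r_const, lh)
  m2c <- translocate_masting_to_constant(env, matched$alpha, r_const, lh,
                                         strat$overall_growth)
  c2m <- translocate_constant_to_masting(env, matched$optimum$brood_size, lh,
                                         strat$overall_growth)
  structure(list(
    environment = env, r_const = r_const, masting = strat,
    constant = list(alpha = matched$alpha,
                    brood_size = matched$optimum$brood_size,
                    growth_rate = matched$optimum$growth_rate),
    baseline_growth = strat$overall_growth,
    masting_to_constant = m2c, constant_to_masting = c2m),
    class = "case_study_result")
}

#' @export
print.case_study_result <- function(x, ...) {
  e <- x$environment
  cat("Two-environment translocation case study\n")
  cat(sprintf("  masting species: good-year brood %.2f (R %.2f), bad-year brood %.2f (R %.2f)\n",
              x$masting$good$brood_size, x$masting$good$growth_rate,
              x$masting$bad$brood_size, x$masting$bad$growth_rate))
  cat(sprintf("  overall growth (p_good = %.2f): %.2f\n",
              e$p_good, x$baseline_growth))
  cat(sprintf("  constant species: matched alpha %.2f, brood %.2f, growth %.2f\n",
              x$constant$alpha, x$constant$brood_size, x$constant$growth_rate))
  cat(sprintf("  masting -> constant: growth %.2f (%.0f%%)\n",
              x$masting_to_constant$growth, x$masting_to_constant$pct_change))
  cat(sprintf("  constant -> masting: growth %.2f (%.0f%%)\n",
              x$constant_to_masting$growth, x$constant_to_masting$pct_change))
  invisible(x)
}

#' Translocation impact over a grid of environments
#'
#' For each combination of good/bad resource ratio and good-year frequency,
#' rebuilds the paired species and records the percentage growth change of
#' each translocation direction. Cells where no brood cost can match the
#' masting species' growth in the constant environment are `NA`.
#'
#' @param r_ratios Values of `r_good / r_bad`, `>= 1`.
#' @param p_goods Good-year probabilities in `[0, 1]`.
#' @param lh A [life_history()] supplying `muA0`, `muJ`, `L0`.
#' @param r_bad Bad-year resource level.
#' @param alpha_good,alpha_bad Per-state brood costs of the masting world.
#' @return A list of two matrices (`constant_to_masting`,
#'   `masting_to_constant`) with rows indexed by `r_ratios` and columns by
#'   `p_goods`, holding percentage changes (`<= 0`).
#' @export
sweep_translocation_grid <- function(r_ratios, p_goods, lh, r_bad = 0.05,
                                     alpha_good = 0, alpha_bad = 0.5) {
  stopifnot(all(r_ratios >= 1), all(p_goods >= 0 & p_goods <= 1))
  c2m <- m2c <- matrix(NA_real_, length(r_ratios), length(p_goods),
                       dimnames = list(r_ratios, p_goods))
  for (i in seq_along(r_ratios)) {
    for (j in seq_along(p_goods)) {
      env <- two_state_environment(p_goods[j], r_ratios[i] * r_bad, r_bad,
                                   alpha_good, alpha_bad)
      res <- tryCatch(case_study(env, lh), error = function(e) NULL)
      if (!is.null(res)) {
        c2m[i, j] <- res$constant_to_masting$pct_change
        m2c[i, j] <- res$masting_to_constant$pct_change
      }
    }
  }
  list(constant_to_masting = c2m, masting_to_constant = m2c)
}
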
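#' Annual population growth rate of the linear map
#'
#' One breeding interval multiplies the adult population by
#' `R0(B0) = (1 - muA0) * exp(-alpha * B0) + B0 * exp(-muJ * B0 * (1 - L0) / r)`:
#' surviving adults plus offspring that reached maturity. `r` is the baseline
#' juvenile growth rate for that year, so the same kernel serves the
#' deterministic model and every stochastic variant (where `r` is a draw from
#' a resource distribution).
#'
#' @param B0 Brood size, non-negative; vectorized.
#' @param lh A [life_history()] object.
#' @param r Baseline juvenile growth rate for the interval (time^-1),
#'   positive; defaults to `lh$juvenile$r0`.
#' @return Multiplicative growth per interval, `> 0`; equals `1 - muA0` at
#'   `B0 = 0`.
#' @examples
#' lh <- life_history()
#' annual_growth_rate(2.5253, lh)  # about 1.859 at alpha = 0
#' @export
annual_growth_rate <- function(B0, lh, r = lh$juvenile$r0) {
  stopifnot(inherits(lh, "life_history"), is.numeric(B0), is.numeric(r))
  if (any(B0 < 0)) stop("'B0' must be non-negative", call. = FALSE)
  if (any(r <= 0)) stop("'r' must be positive", call. = FALSE)
  ad <- lh$adult
  ju <- lh$juvenile
  (1 - ad$muA0) * exp(-ad$alpha * B0) +
    B0 * exp(-ju$muJ * B0 * (1 - ju$L0) / r)
}

#' Iterate the deterministic population map
#'
#' `N[G+1] = R0(B0) * N[G]` — a linear map, so the trajectory is exactly
#' `N0 * R0^G`.
#'
#' @param N0 Initial population size, positive.
#' @param B0 Constant brood size used every year.
#' @param lh A [life_history()] object.
#' @param r Baseline juvenile growth rate (time^-1).
#' @param n_years Number of intervals to iterate, `>= 0`.
#' @return Numeric vector of length `n_years + 1` starting at `N0`.
#' @export
iterate_population <- function(N0, B0, lh, r = lh$juvenile$r0, n_years) {
  stopifnot(is.numeric(N0), N0 > 0, is.numeric(n_years), n_years >= 0)
  R0 <- annual_growth_rate(B0, lh, r)
  N0 * R0^(0:n_years)
}

#' @rdname optimal_constant_brood
#' @param x,... A `brood_optimum` and further arguments (ignored).
#' @export
print.brood_optimum <- function(x, ...) {
  cat(sprintf("Optimal brood size: %.4f (growth rate %.4f, %s)\n",
              x$brood_size, x$growth_rate,
              if (x$is_interior) "interior optimum" else "boundary B0 = 0"))
  if (!is.null(x$interior_candidate) && !x$is_interior)
    cat(sprintf("  dominated interior candidate: brood %.4f, growth %.4f\n",
                x$interior_candidate$brood_size,
                x$interior_candidate$growth_rate))
  invisible(x)
}

# Scalar maximization of f over B0 in [0, search_max]. The objective can be
# bimodal (interior peak vs the zero-brood boundary), so optimize() is
# restarted from every local maximum of a coarse grid. Ties with the boundary
# within `tie_tol` go to B0 = 0: a strategy whose growth merely matches
# no-reproduction would never evolve.
.maximize_brood <- function(f, search_max, grid_n = 64L, tol = 1e-8,
                            tie_tol = 1e-9, vectorized = FALSE) {
  stopifnot(search_max > 0)
  grid <- seq(0, search_max, length.out = grid_n + 1L)
  fg <- if (vectorized) f(grid) else vapply(grid, f, numeric(1))
  f0 <- fg[1L]

  # indices of interior grid-local maxima (including plateaus at the ends)
  n <- length(grid)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) fg[i] >= fg[i - 1L] else TRUE
    right <- if (i < n) fg[i] >= fg[i + 1L] else TRUE
    left && right
  }, logical(1))
  cand_idx <- which(is_max & seq_len(n) > 1L)

  best_int <- NULL
  for (i in cand_idx) {
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, n)]
    opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                           tol = tol)
    if (is.null(best_int) || opt$objective > best_int$growth_rate)
      best_int <- list(brood_size = opt$maximum, growth_rate = opt$objective)
  }

  if (!is.null(best_int) &&
      best_int$brood_size > search_max - (grid[2L] - grid[1L]) / 2 &&
      f(search_max) >= best_int$growth_rate - tol)
    warning("interior optimum may lie beyond 'search_max'; ",
            "result reported at the search bound", call. = FALSE)

  interior <- !is.null(best_int) && best_int$brood_size > tol &&
    best_int$growth_rate > f0 + tie_tol
  if (interior) {
    out <- list(brood_size = best_int$brood_size,
                growth_rate = best_int$growth_rate,
                is_interior = TRUE,
                interior_candidate = best_int)
  } else {
    cand <- if (!is.null(best_int) && best_int$brood_size > tol) best_int
    out <- list(brood_size = 0, growth_rate = f0, is_interior = FALSE,
                interior_candidate = cand)
  }
  structure(out, class = "brood_optimum")
}

.default_search_max <- function(lh, r) {
  10 * r / (lh$juvenile$muJ * (1 - lh$juvenile$L0))
}

#' Optimal constant brood size in a deterministic environment
#'
#' Maximizes [annual_growth_rate()] over continuous brood sizes
#' `B0 in [0, search_max]`. When an interior local maximum exists but is
#' dominated by (or ties) the zero-brood boundary, the boundary is returned
#' as the optimum and the interior peak is reported separately as
#' `interior_candidate`.
#'
#' @param lh A [life_history()] object.
#' @param r Baseline juvenile growth rate (time^-1).
#' @param search_max Upper bound of the brood-size search; defaults to ten
#'   times the cost-free optimum `r / (muJ * (1 - L0))`.
#' @return A `brood_optimum`: list with `brood_size`, `growth_rate`,
#'   `is_interior` and (possibly `NULL`) `interior_candidate`.
#' @examples
#' lh <- life_history(juvenile_params(0.2, 0.1, 0.01),
#'                    adult_params(muA0 = 0.1, alpha = 0))
#' optimal_constant_brood(lh)  # brood 2.02, growth 1.64
#' @export
optimal_constant_brood <- function(lh, r = lh$juvenile$r0,
                                   search_max = .default_search_max(lh, r)) {
  stopifnot(inherits(lh, "life_history"), r > 0)
  if (lh$juvenile$muJ == 0)
    stop("no finite optimum: with muJ = 0 growth increases without bound",
         call. = FALSE)
  .maximize_brood(function(b) annual_growth_rate(b, lh, r), search_max,
                  vectorized = TRUE)
}

#' Sweep the optimal constant brood over brood-cost values
#'
#' Convenience sweep backing the optimal-brood-versus-alpha curves: for each
#' `alpha`, re-optimizes the constant brood size and records the optimum.
#'
#' @param lh A [life_history()] object (its `alpha` is replaced per row).
#' @param alphas Numeric vector of brood-cost coefficients.
#' @param r Baseline juvenile growth rate.
#' @return A data frame with columns `alpha`, `brood_size`, `growth_rate`,
#'   `is_interior`.
#' @export
sweep_alpha_deterministic <- function(lh, alphas, r = lh$juvenile$r0) {
  rows <- lapply(alphas, function(a) {
    opt <- optimal_constant_brood(.with_alpha(lh, a), r)
    data.frame(alpha = a, brood_size = opt$brood_size,
               growth_rate = opt$growth_rate, is_interior = opt$is_interior)
  })
  do.call(rbind, rows)
}
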
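test_that("per-year optimal brood follows the closed form and collapses in famine", {
  lh <- baseline_lh()
  X <- c(0.1, 0.5, 2)
  expect_equal(per_year_optimal_brood(X, lh), X / (0.2 * 0.99),
               tolerance = 1e-12)
  # reproduction shuts off entirely in poor years only when the kernel slope
  # at zero brood is negative, i.e. alpha * (1 - muA0) > 1
  lh_cost <- baseline_lh(alpha = 1.5)
  expect_identical(per_year_optimal_brood(1e-4, lh_cost), 0)
  expect_gt(per_year_optimal_brood(1, lh_cost), 0)
  # below that slope threshold the optimum stays positive but vanishes with X
  expect_lt(per_year_optimal_brood(1e-4, baseline_lh(alpha = 0.8)), 1e-3)
  # grid + refine oracle over random resource levels and costs
  set.seed(9)
  for (k in 1:20) {
    x <- runif(1, 0.02, 2)
    lh_k <- baseline_lh(alpha = runif(1, 0, 2))
    b <- per_year_optimal_brood(x, lh_k)
    oracle <- grid_argmax(function(bb) annual_growth_rate(bb, lh_k, x),
                          upper = broodopt:::.default_search_max(lh_k, x))
    expect_equal(b, oracle$brood, tolerance = 1e-4)
  }
})

test_that("plastic growth dominates any constant strategy and equals it at cv = 0", {
  lh <- baseline_lh(alpha = 0.5)
  env <- resource_model(0.5, 1)
  plast <- lyapunov_env_plastic(lh, env)
  for (b in c(0, 0.5, 1, 2, 4))
    expect_gte(plast, lyapunov_env_constant(b, lh, env) - 1e-9)
  # single-resource world: plastic = deterministic optimum
  expect_equal(lyapunov_env_plastic(lh, resource_model(0.5, 0)),
               optimal_constant_brood(lh)$growth_rate, tolerance = 1e-10)
  # quadrature against a seeded Monte-Carlo oracle
  set.seed(42)
  X <- resource_draws(env, 2e4)
  lg <- log(annual_growth_rate(per_year_optimal_brood(X, lh), lh, X))
  expect_lt(abs(log(plast) - mean(lg)), 3 * sd(lg) / sqrt(length(lg)))
})

test_that("costless plastic breeders still prefer a constant world", {
  g <- vapply(c(0, 0.5, 1, 2), function(cv)
    lyapunov_env_plastic(baseline_lh(), resource_model(0.5, cv)), numeric(1))
  expect_true(all(diff(g) < 0))
  best <- optimal_cv(baseline_lh(), cv_range = c(0, 1.5))
  expect_identical(best$cv, 0)
})

test_that("high brood cost makes a variable world optimal, more so for long-lived adults", {
  best1 <- optimal_cv(baseline_lh(alpha = 1))
  expect_gt(best1$cv, 0)
  expect_gt(best1$growth, lyapunov_env_plastic(baseline_lh(alpha = 1),
                                               resource_model(0.5, 0)))
  best_lowmu <- optimal_cv(baseline_lh(alpha = 1, muA0 = 0.03))
  expect_gt(best_lowmu$cv, best1$cv)
})

test_that("optimized log growth is convex in log resource at high brood cost", {
  lh <- baseline_lh(alpha = 1.5)
  lx <- seq(log(0.3), log(5), length.out = 40)
  h <- vapply(exp(lx), function(x)
    log(annual_growth_rate(per_year_optimal_brood(x, lh), lh, x)), numeric(1))
  expect_true(all(diff(h, differences = 2) >= -1e-9))
})

test_that("paired trajectories are reproducible and consistent with the integrals", {
  lh <- baseline_lh(alpha = 1.5)
  env <- resource_model(0.5, 1)
  t1 <- simulate_strategy_trajectories(lh, env, n_years = 50, seed = 4)
  t2 <- simulate_strategy_trajectories(lh, env, n_years = 50, seed = 4)
  expect_identical(t1, t2)
  expect_identical(t1$plastic$resource, t1$constant$resource)
  # plastic broods obey the per-year rule
  expect_equal(t1$plastic$brood, per_year_optimal_brood(t1$plastic$resource, lh),
               tolerance = 1e-12)

  # long-run: plastic grows where the constant strategy declines (log growth
  # recomputed from the kernel; the raw population overflows at this horizon)
  long <- simulate_strategy_trajectories(lh, env, n_years = 2e4, seed = 8)
  lg_p <- log(annual_growth_rate(long$plastic$brood, lh,
                                 long$plastic$resource))
  lg_c <- log(annual_growth_rate(long$constant$brood, lh,
                                 long$constant$resource))
  plast <- lyapunov_env_plastic(lh, env)
  const <- optimal_constant_brood_env(lh, env)$growth_rate
  expect_lt(abs(mean(lg_p) - log(plast)), 3 * sd(lg_p) / sqrt(length(lg_p)))
  expect_gt(plast, 1)
  expect_lt(const, 1)
  expect_gt(mean(lg_p), 0)
  expect_lt(mean(lg_c), 0)
})

test_that("plastic beats the best constant strategy across the cost/CV grid", {
  sw <- sweep_plastic_vs_constant(baseline_lh(), alphas = c(0, 1, 2),
                                  cvs = c(0.25, 1))
  expect_true(all(sw$plastic_growth >= sw$constant_growth - 1e-9))
})
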
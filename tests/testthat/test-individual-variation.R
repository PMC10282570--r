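test_that("Poisson Lyapunov growth reduces correctly and obeys Jensen", {
  lh <- baseline_lh(alpha = 0.3)
  expect_equal(lyapunov_poisson(0, lh), 1 - 0.07)
  # geometric-mean growth never exceeds the arithmetic-mean growth
  set.seed(5)
  for (k in 1:10) {
    lh_k <- baseline_lh(alpha = runif(1, 0, 2))
    m <- runif(1, 0.5, 5)
    j <- 0:60
    arith <- sum(dpois(j, m) * annual_growth_rate(j, lh_k))
    expect_lte(lyapunov_poisson(m, lh_k), arith + 1e-12)
  }
  # individual variation lowers growth below the deterministic kernel
  expect_lt(lyapunov_poisson(2, baseline_lh()),
            annual_growth_rate(2, baseline_lh()))
  # truncation is converged
  expect_lt(abs(lyapunov_poisson(2, lh, tail_tol = 1e-10) -
                  lyapunov_poisson(2, lh, tail_tol = 1e-12)), 1e-9)
})

test_that("annual-draw map is seed-reproducible and matches the analytic sum", {
  lh <- baseline_lh(alpha = 0.3)
  cfg <- stochastic_run_config(n_individuals = 100, n_years = 100,
                               n_replicates = 3, seed = 99)
  r1 <- simulate_annual_draw_map(2, lh, cfg)
  r2 <- simulate_annual_draw_map(2, lh, cfg)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(r1$seeds, r2$seeds)

  cfg_long <- stochastic_run_config(n_individuals = 1, n_years = 2e5,
                                    n_replicates = 1, seed = 7)
  est <- simulate_annual_draw_map(2, lh, cfg_long)
  expect_lt(abs(est$log_growth - log(lyapunov_poisson(2, lh))),
            3 * est$log_growth_se)
})

test_that("annual-draw map declines at the intrinsic rate without reproduction", {
  lh <- baseline_lh(muA0 = 0.99)
  cfg <- stochastic_run_config(n_individuals = 1000, n_years = 10,
                               n_replicates = 1, seed = 3)
  est <- simulate_annual_draw_map(0, lh, cfg)
  expect_equal(est$growth, 0.01, tolerance = 1e-12)
})

test_that("branching process matches its law-of-large-numbers expectation", {
  lh <- baseline_lh(alpha = 0.3)
  # no offspring: one year is a pure survival binomial
  cfg1 <- stochastic_run_config(n_individuals = 1e5, n_years = 1,
                                n_replicates = 1, seed = 21)
  surv <- simulate_branching(0, lh, cfg1)
  expect_lt(abs(exp(surv$log_growth) - 0.93),
            3 * sqrt(0.93 * 0.07 / 1e5))
  # one generation at large N: realized growth near the arithmetic mean
  j <- 0:60
  arith <- sum(dpois(j, 2) * annual_growth_rate(j, lh))
  cfg2 <- stochastic_run_config(n_individuals = 2e4, n_years = 1,
                                n_replicates = 50, seed = 22)
  gen <- simulate_branching(2, lh, cfg2)
  steps <- exp(unlist(lapply(split(gen$trajectories,
                                   gen$trajectories$replicate),
                             function(d) diff(log(d$N)))))
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - arith), 3 * se)
})

test_that("branching trajectories hold non-negative integer counts below the cap", {
  lh <- baseline_lh(alpha = 1)   # modest growth keeps counts below thinning
  cfg <- stochastic_run_config(n_individuals = 50, n_years = 30,
                               n_replicates = 5, seed = 13)
  out <- simulate_branching(1, lh, cfg)
  expect_true(all(out$trajectories$N >= 0))
  expect_true(all(out$trajectories$N == floor(out$trajectories$N)))
  expect_gte(out$extinct_fraction, 0)
})

test_that("the two simulators and the analytic sum tell one consistent story", {
  # The annual-draw map estimates the geometric-mean (Lyapunov) growth; the
  # branching process at large N realizes the arithmetic-mean growth. Their
  # gap is the analytic Jensen gap, so all three routes are cross-checked.
  lh <- baseline_lh(alpha = 0.1)
  m <- 2
  j <- 0:60
  arith <- sum(dpois(j, m) * annual_growth_rate(j, lh))
  lyap <- lyapunov_poisson(m, lh)
  cfg <- stochastic_run_config(n_individuals = 1000, n_years = 200,
                               n_replicates = 100, seed = 31)
  br <- simulate_branching(m, lh, cfg)
  dr <- simulate_annual_draw_map(m, lh, cfg)
  expect_lt(abs(dr$log_growth - log(lyap)), 3 * dr$log_growth_se)
  expect_lt(abs(br$log_growth - log(arith)),
            3 * br$log_growth_se + 0.005)  # early small-N transient allowance
  gap_sim <- br$log_growth - dr$log_growth
  gap_analytic <- log(arith) - log(lyap)
  expect_lt(abs(gap_sim - gap_analytic),
            3 * (br$log_growth_se + dr$log_growth_se) + 0.005)
})

test_that("Poisson variation pushes the zero-brood switch to smaller brood cost", {
  opt_pois <- optimal_mean_brood_individual(baseline_lh(2))
  opt_det <- optimal_constant_brood(baseline_lh(2))
  expect_false(opt_pois$is_interior)  # already collapsed at alpha = 2
  expect_true(opt_det$is_interior)    # deterministic optimum still interior
  # zero-cost optimum agrees with a grid oracle
  oracle <- grid_argmax(function(b)
    vapply(b, function(bi) lyapunov_poisson(bi, baseline_lh()), numeric(1)),
    upper = 10, step = 0.01)
  opt0 <- optimal_mean_brood_individual(baseline_lh())
  expect_equal(opt0$brood_size, oracle$brood, tolerance = 1e-3)
})
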
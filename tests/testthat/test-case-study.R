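test_that("geometric-mean growth combines year types like a Lyapunov exponent", {
  expect_equal(geometric_mean_growth(1, 1.3), 1.3)
  expect_equal(geometric_mean_growth(c(0.5, 0.5), c(2, 0.5)), 1)
  expect_equal(round(geometric_mean_growth(c(0.25, 0.75),
                                           c(1.6432, 0.9489)), 2), 1.09)
  expect_error(geometric_mean_growth(c(0.5, 0.4), c(1, 1)), "sum to 1")
  expect_error(geometric_mean_growth(c(0.5, 0.5), c(1, -1)), "positive")
})

test_that("masting species per-state optima match the worked example", {
  strat <- masting_species_strategy(casestudy_env(), casestudy_lh())
  expect_equal(round(strat$good$brood_size, 2), 2.02)
  expect_equal(round(strat$good$growth_rate, 2), 1.64)
  expect_equal(round(strat$bad$growth_rate, 2), 0.95)
  expect_equal(strat$bad$brood_size, 0.1996, tolerance = 0.01)
  expect_equal(round(strat$overall_growth, 2), 1.09)
  # good year has zero cost, so its optimum is the closed form
  expect_equal(strat$good$brood_size, 0.2 / (0.1 * 0.99), tolerance = 1e-6)
  # always-good world: overall growth is the good-year growth
  all_good <- masting_species_strategy(casestudy_env(p_good = 1),
                                       casestudy_lh())
  expect_equal(all_good$overall_growth, all_good$good$growth_rate,
               tolerance = 1e-12)
})

test_that("brood-cost matching hits the target growth and is monotone", {
  lh <- casestudy_lh()
  r_const <- 0.25 * 0.2 + 0.75 * 0.05
  top <- optimal_constant_brood(lh, r = r_const)$growth_rate
  expect_equal(match_alpha_constant(top, r_const, lh)$alpha, 0)

  strat <- masting_species_strategy(casestudy_env(), lh)
  m <- match_alpha_constant(strat$overall_growth, r_const, lh)
  expect_equal(m$alpha, 0.2299, tolerance = 1e-3)
  expect_equal(m$optimum$brood_size, 0.5764, tolerance = 1e-3)
  # baseline equality after matching
  expect_equal(m$optimum$growth_rate, strat$overall_growth, tolerance = 1e-8)
  # a higher target needs a smaller cost
  m_hi <- match_alpha_constant(strat$overall_growth * 1.02, r_const, lh)
  expect_lt(m_hi$alpha, m$alpha)
  expect_error(match_alpha_constant(0.5, r_const, lh), "not achievable")
})

test_that("both translocation directions lose growth as in the worked example", {
  res <- case_study(casestudy_env(), casestudy_lh())
  expect_equal(res$baseline_growth, 1.0886, tolerance = 1e-3)
  # masting-adapted species moved to the constant world: 0.95, almost -13%
  expect_equal(res$masting_to_constant$growth, 0.9503, tolerance = 1e-3)
  expect_equal(res$masting_to_constant$pct_change, -12.70, tolerance = 0.05)
  # constant-world species moved to the masting world: 0.96, about -12%
  expect_equal(res$constant_to_masting$growth, 0.9586, tolerance = 1e-3)
  expect_equal(res$constant_to_masting$pct_change, -11.94, tolerance = 0.05)
})

test_that("translocation is neutral when the environments coincide", {
  lh <- casestudy_lh()
  env <- casestudy_env()
  strat <- masting_species_strategy(env, lh)
  # same r and alpha on both sides of the move: no change
  env_flat <- two_state_environment(0.25, 0.1, 0.1, alpha_good = 0.3,
                                    alpha_bad = 0.3)
  strat_flat <- masting_species_strategy(env_flat, lh)
  m2c <- translocate_masting_to_constant(env_flat, 0.3, 0.1, lh,
                                         strat_flat$overall_growth)
  expect_equal(m2c$pct_change, 0, tolerance = 1e-6)
  # constant brood moved into a two-state world with identical states
  c2m <- translocate_constant_to_masting(env_flat, 1.01, lh,
    geometric_mean_growth(c(0.25, 0.75), rep(annual_growth_rate(
      1.01, broodopt:::.with_alpha(lh, 0.3), 0.1), 2)))
  expect_equal(c2m$pct_change, 0, tolerance = 1e-6)
})

test_that("translocation losses peak at intermediate vs rare mast frequencies", {
  ps <- seq(0.05, 0.95, by = 0.1)
  g <- sweep_translocation_grid(r_ratios = c(1, 6), p_goods = ps,
                                lh = casestudy_lh())
  expect_true(all(unlist(g) <= 1e-9, na.rm = TRUE))
  # near-equal year types: the move barely matters
  expect_true(all(abs(g$constant_to_masting[1, ]) < 2.5))
  expect_true(all(abs(g$masting_to_constant[1, ]) < 2.5))
  # strong masting contrast: much larger losses
  expect_gt(max(abs(g$constant_to_masting[2, ])), 10)
  # worst case for the naive constant breeder sits at interior frequencies;
  # the masting-adapted species suffers most when good years are rarer
  p_c2m <- ps[which.min(g$constant_to_masting[2, ])]
  p_m2c <- ps[which.min(g$masting_to_constant[2, ])]
  expect_gte(p_c2m, 0.35)
  expect_lte(p_c2m, 0.7)
  expect_lt(p_m2c, p_c2m)
})
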
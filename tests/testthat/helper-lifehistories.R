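# baseline illustrative parameter set used throughout the examples
baseline_lh <- function(alpha = 0, muA0 = 0.07) {
  life_history(juvenile_params(r0 = 0.5, muJ = 0.2, L0 = 0.01),
               adult_params(muA0 = muA0, alpha = alpha))
}

# parameter set of the two-species translocation case study
casestudy_lh <- function() {
  life_history(juvenile_params(r0 = 0.2, muJ = 0.1, L0 = 0.01),
               adult_params(muA0 = 0.1, alpha = 0))
}

casestudy_env <- function(p_good = 0.25) {
  two_state_environment(p_good, r_good = 0.2, r_bad = 0.05,
                        alpha_good = 0, alpha_bad = 0.5)
}

# brute-force argmax of a vectorized objective over a brood-size grid,
# followed by local refinement; independent oracle for the optimizers
grid_argmax <- function(f, upper, step = 1e-3) {
  grid <- seq(0, upper, by = step)
  fg <- f(grid)
  i <- which.max(fg)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  if (opt$objective >= fg[i]) {
    list(brood = opt$maximum, value = opt$objective)
  } else {
    list(brood = grid[i], value = fg[i])
  }
}
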
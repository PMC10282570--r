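---
title: "Optimal brood size in stochastic environments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal brood size in stochastic environments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broodopt)
```

## The question

How many offspring should an organism produce per breeding season when
producing more is costly — to each offspring (less care, slower growth,
higher juvenile mortality) and to the parent (higher adult mortality) — and
when the resources that fuel juvenile growth fluctuate unpredictably from
year to year, as under mast seeding? `broodopt` answers this with a
deliberately small, fully analysable life-history model whose long-run
growth rates are geometric-mean (Lyapunov-exponent) quantities, not
arithmetic averages.

## The deterministic core

**Juvenile growth and survival.** A juvenile's size $L(t)$, measured as a
fraction of the maturity size (so $L_\infty = 1$), follows von Bertalanffy
growth $\mathrm{d}L/\mathrm{d}t = r(1 - L)$ from birth size $L_0$, giving
$L(t) = 1 - (1 - L_0)e^{-rt}$ (`length_at_time()`). Juvenile mortality is
size-dependent, $\mu_J (1 - L)$, so small juveniles are the most exposed.
Integrating mortality along the growth curve gives the survivors
(`survivors_at_time()`), and letting $t \to \infty$ the expected number of
offspring reaching maturity. Parental care enters through a shared growth
rate: a brood of $B_0$ grows at $r_0 / B_0$, so

$$B_\infty(B_0) = B_0 \exp\!\left(-\frac{\mu_J B_0 (1 - L_0)}{r_0}\right),$$

which is unimodal with the closed-form optimum
$B_0^* = r_0 / (\mu_J(1 - L_0))$ and maximum $B_0^* / e$
(`offspring_optimal_brood()`). Brood size is treated as a continuous
non-negative quantity throughout — the optima of interest (2.02, 0.78, …)
are not integers — and only the individual-based simulator draws integer
broods. $B_\infty(0)$ is defined as 0 by continuity so population formulas
are valid at zero brood.

**Adult survival.** Reproduction costs the parent survival:
$\mu_A(B_0) = 1 - (1 - \mu_{A0})e^{-\alpha B_0}$ (`annual_mortality()`),
where $\mu_{A0}$ is the intrinsic annual mortality and $\alpha$ the
brood-cost coefficient per offspring. The first offspring is always the most
expensive; marginal cost declines with brood size. Expected lifespan is the
geometric-survival value $1/\mu_A$ in breeding intervals
(`expected_lifespan()`); it is kept as a real number internally and rounded
only for display.

**The population map.** With non-overlapping juvenile development and
discrete breeding seasons, adults obey the linear map
$N_{G+1} = [(1 - \mu_A(B_0)) + B_\infty(B_0)]\,N_G$, so the annual growth
rate is

$$R_0(B_0; r) = (1 - \mu_{A0})e^{-\alpha B_0}
  + B_0 \exp\!\left(-\frac{\mu_J B_0 (1 - L_0)}{r}\right)$$

(`annual_growth_rate()`), written with a general resource-year growth rate
$r$ so the same kernel serves every stochastic variant. There is no density
dependence: populations are assumed small relative to carrying capacity.

**Optimization.** `optimal_constant_brood()` maximizes $R_0$ over
$B_0 \in [0, B_{\max}]$. The objective can be bimodal — an interior peak
competing against the zero-brood boundary $R_0(0) = 1 - \mu_{A0}$ — so the
optimizer restarts `stats::optimize()` (golden-section/parabolic, tolerance
$10^{-8}$) from every local maximum of a 64-point coarse grid. The default
bound $B_{\max} = 10\, r / (\mu_J (1 - L_0))$ is ten times the cost-free
optimum, which brackets every optimum arising in the parameter ranges
explored here; if the argmax lands at the bound a warning is raised. When an
interior peak only ties the boundary (within $10^{-9}$), the boundary is
returned: a strategy whose deterministic growth merely equals
no-reproduction would never evolve, but the dominated interior peak is still
reported as `interior_candidate` for inspection.

As brood cost $\alpha$ rises the optimal brood first falls, then rises again
(once adult death is near-certain whatever the brood, offspring are the only
currency left), and finally collapses to zero at extreme cost — the package
asserts this shape as an ordering of optima at $\alpha \in
\{0, 0.5, 1.2, 3\}$ under the baseline parameters.

## Individual (demographic) stochasticity

Brood sizes vary between individuals as Poisson draws with mean $B_0$. The
exact process is a branching process: each adult draws $j \sim
\mathrm{Pois}(B_0)$, survives with probability $(1 - \mu_{A0})e^{-\alpha j}$,
and each of its $j$ offspring matures independently with probability
$\exp(-\mu_J j (1 - L_0)/r_0)$. `simulate_branching()` implements this
exactly but groups individuals by brood-size class (a multinomial over the
truncated Poisson pmf plus binomial survival within class), which is
distributionally identical to per-individual draws at $O(j_{\max})$ cost per
year. Populations above $10^6$ are binomially thinned with the scale factor
carried separately; thinning happens between years, so per-year growth
increments are untouched.

The approximating *annual-draw map* instead applies one Poisson draw to the
whole population each year (`simulate_annual_draw_map()`). Its long-run
growth rate is the Lyapunov exponent

$$R_0 = \exp\Big(\sum_j f(j) \log R_0(j)\Big)$$

computed analytically by `lyapunov_poisson()` with the Poisson sum truncated
where the upper tail falls below `tail_tol` ($10^{-12}$ by default; the
$j = 0$ term is safe because the kernel there is $1 - \mu_{A0} > 0$).

**A deliberate reporting choice.** The two simulators do not estimate the
same quantity. At large populations the branching process realizes the
*arithmetic* mean growth $\sum_j f(j) R_0(j)$ (a law-of-large-numbers
consequence of independent individual draws), while the annual-draw map
realizes the *geometric* mean. The gap between them is exactly the Jensen
gap, a few percent at low brood cost and growing with $\alpha$. Both
averaging modes are therefore computed and reported (`growth` for the
geometric route, `arithmetic_growth` for diagnostics), and the test suite
asserts each simulator against its own analytic oracle and the gap between
them against the analytic Jensen gap, rather than pretending the two
coincide.

Individual variation always lowers the optimal growth (Jensen), removes the
intermediate-$\alpha$ rise in optimal brood size, and pushes the collapse to
zero brood to distinctly smaller $\alpha$ than in the deterministic model —
the suite verifies the switch points by scanning $\alpha$ in steps of 0.25.

## Environmental stochasticity

Resource availability — equivalently the baseline juvenile growth rate — is
an i.i.d. lognormal draw $r_Y$ each year (`resource_model()`), the standard
model for mast-seeding food supplies. The distribution is parameterized by
its mean (held fixed so stochastic and deterministic worlds are comparable)
and its coefficient of variation, the strength-of-variability dial. Moment
matching is exact: $\sigma_{\log}^2 = \log(1 + \mathrm{CV}^2)$,
$\mu_{\log} = \log \bar r - \sigma_{\log}^2/2$; $\mathrm{CV} = 0$
degenerates to a point mass and bypasses all quadrature. Adult mortality is
held resource-independent here; resource-dependent brood costs appear only
in the two-state case study.

For a constant brood strategy the growth rate is again a Lyapunov exponent,
now an integral (`lyapunov_env_constant()`), evaluated by Gauss–Hermite
quadrature in the log-resource variable: 128 nodes by default, doubled once
and accepted when two levels agree to $10^{-8}$ relative. For large broods
at high CV the integrand $\log R_0(B_0; X)$ develops a sharp transition
(the juvenile term dies double-exponentially as $X \to 0$) that
Gauss–Hermite underresolves; such cases fall back to adaptive quadrature in
the standard-normal variable over $|z| \le 8.5$ (omitted mass $<10^{-16}$),
trusted on the integrator's own error estimate. If neither route converges
an error with diagnostics is raised rather than returning a doubtful
number.

Key verified behaviour: with any positive brood cost, optimal growth is
strictly decreasing in CV; with no cost, the optimal brood changes only
weakly and non-monotonically (minimum at intermediate CV); for high enough
cost there is a threshold CV above which zero reproduction is optimal,
found by grid scan plus bisection in `zero_brood_cv_threshold()`, and this
threshold shrinks as $\alpha$ grows.

## Plastic (resource-synchronized) strategies

A plastic breeder re-optimizes its brood each year after observing the
resource level: `per_year_optimal_brood()`. At $\alpha = 0$ the optimum has
the closed form $X / (\mu_J (1 - L_0))$. With costly reproduction the
optimum hits exactly zero in poor years only when
$\alpha (1 - \mu_{A0}) > 1$ — the slope of the kernel at zero brood is
$1 - \alpha(1 - \mu_{A0})$ — otherwise it merely vanishes continuously with
$X$. Environmental perception is assumed perfect; mistimed responses and
false alarms are outside this model.

The plastic growth rate `lyapunov_env_plastic()` integrates the log of the
per-year-optimized kernel. Below the shut-off resource level the integrand
is the constant $\log(1 - \mu_{A0})$ and kinks there, so the integral is
split at that level: the closed lower part is a lognormal CDF weight, and
the smooth upper part goes to adaptive quadrature. The switch level depends
on the life history alone, so sweeps over many environments compute it once
(`switch_level` argument). The inner per-year optimizations happen only at
quadrature abscissae, making the whole integral deterministic and
repeatable.

Pointwise domination of the plastic kernel guarantees plastic $\ge$ best
constant for every $(\alpha, \mathrm{CV})$, and the suite also asserts it
numerically. The more surprising verified result is `optimal_cv()`: with no
brood cost the best world is a constant one, but at high cost the
probability-weighted boom of good years outweighs sitting out bad ones —
the per-year-optimized log growth is convex in log resource (checked by
second differences) — so a strictly positive CV maximizes growth, the more
so the lower the intrinsic adult mortality. `simulate_strategy_trajectories()`
generates the paired illustration: identical resource draws, one population
synchronizing its brood, one holding the best constant brood.

## The two-environment case study

`case_study()` contrasts a masting-adapted species (per-year-type optimal
broods in a two-state good/bad world; defaults $p_{\text{good}} = 0.25$,
$r_{\text{good}} = 0.2$, $r_{\text{bad}} = 0.05$,
$\alpha_{\text{good}} = 0$, $\alpha_{\text{bad}} = 0.5$, with
$\mu_{A0} = 0.1$, $\mu_J = 0.1$, $L_0 = 0.01$) with a constant-environment
species at the frequency-weighted mean resource level. Overall growth across
year types is the probability-weighted *geometric* mean
(`geometric_mean_growth()`), the Lyapunov-consistent choice: under the
default parameters it gives 1.09 where the arithmetic mean would give 1.12.

The constant species' brood cost is always *solved* —
`match_alpha_constant()` bisects $\alpha$ until the best constant growth
equals the masting species' overall growth (the optimal growth is
continuous and strictly decreasing in $\alpha$ on the interior branch) —
rather than taken as a fixed input. Under the default parameters the solved
match is $\alpha \approx 0.230$ with optimal brood $\approx 0.58$, and this
internally consistent route reproduces the downstream translocation
outcomes (growth 0.95, a drop of almost 13%, for the masting species moved
to the constant world; 0.96, about 12%, for the reverse move).

`sweep_translocation_grid()` maps both percentage changes over the
resource-ratio × mast-frequency plane. The change is never positive; the
naive constant breeder suffers most near even mast frequencies, while the
masting-adapted species suffers most when good years are rare. At resource
ratio 1 the change is small but not exactly zero (about −1% under the
defaults) because the two year types still differ in brood cost; cells where
no $\alpha$ can match the target growth are reported `NA`, never fabricated.

## What the stochastic generators do and do not emulate

All randomness is generated inside the package from seeded RNG: Poisson
brood draws, lognormal resource years, and two-state year sequences. Years
are i.i.d. — there is no temporal autocorrelation, although real mast series
are often negatively autocorrelated — and there is no density dependence, no
age structure beyond the adult/juvenile split, no individual heterogeneity
beyond the Poisson brood draw, and perfect environmental perception.
Passing tests therefore validate the model's internal mathematics and its
qualitative mechanisms (geometric-mean fitness, Jensen effects, plasticity
premiums), not quantitative predictions for any particular species.

## Numerical choices and problem sizes

* Optimizer: coarse-grid restarts (64 points deterministic, 32 for the
  quadrature-backed objectives) + `stats::optimize`, tolerance $10^{-8}$;
  boundary ties resolved to zero brood.
* Quadrature: Gauss–Hermite 128→256 nodes with agreement check, adaptive
  fallback in $z$; $\mathrm{CV}=0$ bypass; plastic integral split at the
  reproduction shut-off level.
* Poisson sums truncated at upper-tail mass $10^{-12}$; halving the
  tolerance moves results by $<10^{-9}$.
* Monte-Carlo oracle checks in the test suite use $2 \times 10^5$ annual
  draws, $10^5$-adult single generations, $2 \times 10^4$-year plastic
  trajectories, and a 200-year × 100-replicate branching experiment — sizes
  chosen so every 3-standard-error comparison is sharp while the whole
  suite stays fast.
* Simulation growth estimates average $\log(N_{G+1}/N_G)$ over years and
  replicates (the Lyapunov definition); replicates that go extinct
  contribute their pre-extinction years and the extinction fraction is
  reported.
* Root RNG seeds spawn logged per-replicate sub-seeds, so any replicate can
  be reproduced in isolation.

## Limitations

The adult-cost function is one plausible concave choice; threshold-like
(logistic) costs would need one more parameter and could change where the
plasticity premium appears. The model optimizes population growth rate, not
an explicitly evolutionary (ESS/invasion) criterion, and strategies do not
adapt within a run. Brood sizes are continuous; integer constraints matter
for very small broods. All conclusions are asymptotic growth-rate
statements; finite-time extinction risk is only visible through the
branching simulator's extinction fraction.
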
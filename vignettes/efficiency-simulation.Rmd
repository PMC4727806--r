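---
title: "Benchmarking technical-efficiency estimators for health facilities"
author: "effsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking technical-efficiency estimators for health facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effsim)
```

## The problem

Health facilities in low- and middle-income settings convert staff, beds and
supplies into services — outpatient visits, deliveries, ART visits. A
facility's *technical efficiency* $\theta_i \in (0, 1]$ is the fraction of
its feasible output it actually produces. Efficiency is never observed
directly; it must be estimated from an input/output panel, and the two main
estimator families — data envelopment analysis (DEA) and stochastic frontier
/ distance-function regression (SDF) — can disagree sharply on the same
data. A simulation laboratory settles the question empirically: generate
panels whose true $\theta_i$ is known, run the estimators, and measure their
errors. `effsim` implements such a laboratory end to end, with a
data-generating process designed around features of low-resource health
systems: highly dispersed efficiency, facilities that produce only a subset
of possible outputs, and technologies that need not be Cobb-Douglas.

## The data-generating process

The baseline design draws, for each of $n = 200$ facilities, three inputs
$x_1 \sim \mathrm{unif}(0,5)$, $x_2 \sim \mathrm{unif}(0,10)$,
$x_3 \sim \mathrm{unif}(0,8)$, and converts them into total productive
capacity by a linear constant-returns technology

$$Y_i = 0.2\,x_{1i} + 0.5\,x_{2i} + 0.3\,x_{3i}.$$

True efficiency $\theta_i \sim \mathrm{unif}(0,1)$ scales capacity down to
$Y_i' = \theta_i Y_i$. Every facility produces output 3; outputs 1 and 2
each enter a facility's portfolio independently with probability 0.5. The
effective capacity is split over the portfolio by a flat Dirichlet draw, and
output $j$'s observed volume is its capacity share divided by its resource
intensity $(0.25, 0.5, 1.0)$ — output 3 is the most resource-intensive. By
construction $\sum_j I_j\, y_{ji}^{obs} = \theta_i Y_i$ holds exactly in
error-free linear scenarios, which the test suite checks to machine
precision.

Two allocation details — the portfolio probabilities and the share rule —
are design choices of this package: 0.5/0.5 portfolio probabilities and the
flat Dirichlet split are the least-informative rules consistent with the
constraints above ("one universal output, the others produced by subsets").
Rate criteria that depend on the tails of the estimated-score distribution
are sensitive to these choices, which is why the package's own acceptance
checks give baseline rate criteria a wider tolerance band than the
functional-form scenarios, which are insensitive to allocation.

Scenario presets vary one ingredient at a time (see `scenario_presets()`):
sample size; rank-targeted input correlations through a Gaussian copula
(latent correlation $2\sin(\pi r/6)$ so the uniform margins hit the target
$r$); fixed input components $(0.5, 2.0, 0.1)$ subtracted before the linear
technology applies; additive, multiplicative or mixed measurement error
($\sigma = 0.02$ low, $0.08$ high, 15% of facilities high under the mixed
kind, negatives clamped to 0.01 after additive noise); half-normal
efficiency $\theta_i = \exp(-|N(0, \sigma_u^2)|)$ with $\sigma_u \in \{0.05,
0.20\}$; and Cobb-Douglas or piecewise Cobb-Douglas technologies.

### Cobb-Douglas scenarios and the radial construction

For Cobb-Douglas technologies (input exponents $0.2, 0.5, 0.3$, scale
constant 1, inputs $\mathrm{unif}(1,15)$, output exponents $-1/3$ each) the
portfolio-and-shares mechanism is replaced by the standard distance-function
construction: a provisional output vector is drawn uniformly on $(1, 15)^3$
to fix the facility's output *mix*, and is then rescaled radially so that
the output distance function equals $\theta_i$ exactly. Two properties drove
this choice. First, the mix ratios must be independent of $\theta_i$: if
instead one output is solved from the distance identity while the others
stay fixed, the inefficiency term enters the ratio regressors of the
distance regression and the regression becomes endogenous — per-facility
efficiency recovery then collapses even though the frontier is exact.
Second, radial rescaling keeps the Cobb-Douglas distance regression exact by
construction, which is what makes these scenarios a correctly-specified
best case for the regression estimator. The piecewise technology bends the
input aggregate's exponents by $\pm 0.1$ at the support midpoint
(continuously joined), so the fitted Cobb-Douglas form is mildly
misspecified in the inputs there. All facilities produce all three outputs
in these scenarios, since a Cobb-Douglas technology produces nothing when
any output is pinned at zero.

## The estimators

**DEA (CCR multiplier form).** Facility $o$'s score solves
$$\max_{u, v \ge 0} \; u'y_o \quad \text{s.t.} \quad v'x_o = 1, \quad
u'y_k - v'x_k \le 0 \;\; \forall k,$$
which under constant returns to scale equals the output-oriented efficiency
measure on $(0,1]$. The implementation solves the (much smaller)
envelopment dual — $R + J$ rows instead of $n + 1$ — with a dense two-phase
simplex written for this package, and reads the multiplier weights off the
dual prices. The test suite verifies the two formulations agree to $10^{-6}$
on random panels and against brute-force vertex enumeration. Multiplier
solutions are generally non-unique at degenerate vertices; the solver's
returned optimal vertex is used as-is, with a fixed deterministic pivoting
rule (largest reduced cost, Bland's rule after a cap), and ratio pooling
over hundreds of facilities dampens the vertex arbitrariness.

**Super-efficiency outlier filter.** Each facility is scored against the
frontier of all *other* facilities (scores may exceed 1, or be infinite if
no peer spans its mix — treated as an extreme outlier). While any
super-score exceeds 1.5 and fewer than $\lfloor 0.05\,n \rfloor$ facilities
have been removed, the largest is removed and the analysis repeated — one
facility per iteration, since removing the most extreme point changes every
remaining leave-one-out frontier. Removed facilities are flagged and
assigned a score of one; everyone else is scored against the filtered
reference set. The same filter output is shared by DEA and rDEA (the filter
is not re-run under the restricted technology; restrictions only shrink
scores, so a unit that survives unrestricted filtering cannot become more
extreme).

**rDEA (percentile assurance regions).** First-stage unrestricted weights
are pooled within each replication: for each output $j \ge 2$ the ratios
$u_{ij}/u_{i1}$ over facilities where both weights exceed $10^{-9}$ (after
the $v'x_o = 1$ normalization), likewise for inputs. The $p$-th and
$(100-p)$-th percentiles of each ratio distribution (linear interpolation
between order statistics, the `quantile` type-7 convention) become bounds
$L_j \le u_{ij}/u_{i1} \le U_j$ added to the multiplier program. The default
pair (40, 60) is where the percentile sweep on the baseline scenario
minimizes MAD; the sweep's U-shape — restriction helps until the bounds
collapse to a single common weight vector at (50, 50) — is an acceptance
check.

**rSDF-CD.** The Cobb-Douglas output distance function normalized on output
1 is linear in logs:
$$-\ln y_{1i} = \beta_0 + \sum_r \beta_r \ln x_{ri} +
\sum_{j \ge 2} \alpha_j \ln (y_{ji}/y_{1i}) + \varepsilon_i,$$
with composed error $\varepsilon_i = u_i + v_i$: $v_i \sim N(0,\sigma_v^2)$
is noise and $u_i \ge 0$ half-normal inefficiency, which *raises* the
distance residual. (Sign conventions differ across the literature; this one
is forced by the dependent variable being a distance, and is validated by
parameter recovery.) Zeros in inputs or outputs — a designed feature of the
portfolio mechanism — are replaced by $10^{-10}$ before logs. The
log-likelihood is maximized under the economic-interpretability constraints
$\alpha_j > 0$, $\beta_r < 0$, $\lambda = \sigma_u/\sigma_v > 0$, enforced
as box constraints offset $10^{-8}$ from zero (bounds rather than penalties,
so the constraints hold strictly at the optimum). Starting values come from
OLS with the variance split by method-of-moments on the residual skewness
(for $\varepsilon = u + v$ the third central moment is
$\sqrt{2/\pi}\,(4/\pi - 1)\,\sigma_u^3$); four additional jittered restarts
guard against local optima and the best converged likelihood wins. When the
optimum lies on the boundary — $\sigma_v \to 0$ in noise-free scenarios
drives $\lambda \to \infty$ — the quasi-Newton line search can abort just
short of the optimum, so a Nelder-Mead polish on the box-projected
objective finishes the job (accepted only if it does not worsen the
likelihood). Optimizer stalls are reported via `converged = FALSE`, never
raised; the replication engine excludes such replications with an accounting
message and aborts if more than 5% fail.

Per-facility efficiency uses the JLMS conditional mean
$$E(u_i \mid \varepsilon_i) = \frac{\sigma \lambda}{1 + \lambda^2}
\left[ \frac{\phi(\gamma_i)}{\Phi(\gamma_i)} + \gamma_i \right], \qquad
\gamma_i = \frac{\varepsilon_i \lambda}{\sigma},$$
and $\theta_i = e^{-E(u_i|\varepsilon_i)}$ clipped to $(0,1]$. The inverse
Mills ratio switches to its asymptotic expansion below $\gamma = -15$,
where the difference of log-scale tail probabilities cancels
catastrophically; the implementation is tested against numeric integration
of $u\,f(u\mid\varepsilon)$ to $10^{-6}$.

**ENS.** The ensemble score is the per-facility arithmetic mean of the rDEA
and rSDF-CD scores — a hedge for the realistic case where the true
functional form is unknown: rDEA wins under linear technologies, rSDF-CD
under Cobb-Douglas ones, and the average is robust across both.

## Performance criteria

Per replication, against the known truth: `mad`, the median absolute
deviation (robust to the outlier scores DEA produces); `pu20`/`po20`, the
percentage of facilities whose efficiency is under-/over-estimated by more
than 20 *percent of its true value* — deviations of that size would
typically move a facility across efficiency-grade boundaries; `notfront`,
the percentage scored fully efficient (within $10^{-6}$ of one, absorbing
LP round-off) whose true efficiency is below 0.80; and the Spearman rank
correlation (average ranks on ties; undefined with fewer than two distinct
values, in which case the replication is excluded from that criterion's
average with a warning). Criteria are averaged unweighted over
replications. The relative reading of the 20% threshold is deliberate: the
three criteria are mutually consistent only under it (an absolute reading
would force the median absolute deviation above 0.2 whenever more than half
the sample is flagged, a combination the criteria are expected to produce
under misspecified regressions).

## Replication engine and numerical choices

- **Seeding.** Replication $k$ of base seed $s$ uses the derived child seed
  $(1009 s + 7919 k) \bmod (2^{31}-1)$, independent of the total replication
  count, so a run is reproducible replication by replication whether
  executed serially or in parallel. One `set.seed()` at the top of
  `generate_panel()` makes each panel a pure function of its seed; the
  optimizer's jittered restarts draw from the same replication stream.
- **LP tolerances.** Pivot tolerance $10^{-9}$; ties in the ratio test break
  toward the smallest basis index; Bland's rule engages after $10(m+N)$
  iterations to preclude cycling. Scores are clipped to $[0, 1]$ for
  in-sample runs (round-off only); weights with magnitude below $10^{-9}$
  count as zero in the ratio pooling.
- **Degenerate inputs.** An all-zero output row scores its LP optimum
  ($\approx 0$) rather than erroring; infeasible leave-one-out programs
  score $+\infty$ and are removed by the filter's threshold rule; a ratio
  pool that is empty for some dimension is an estimation error naming that
  dimension.
- **Problem sizes.** The package's acceptance checks run the baseline
  comparison at 100 replications, the percentile sweep at 40, the
  functional-form scenarios at 60 and the $n = 20$ scenario at 500; the
  acceptance script uses 200 replications (2,000 for $n = 20$). These sizes
  put the Monte-Carlo standard error of every criterion well inside the
  tolerance bands used to compare against the published values, which were
  computed at 2,000 replications.

## What passing tests do and do not show

The generator emulates dispersed efficiency, partial output portfolios,
fixed input components, noisy measurement and non-linear technologies. It
does not emulate: time dynamics or panel structure, variable returns to
scale, demand-side constraints (outputs here are supply-determined),
correlated efficiency and inputs, or real reporting artifacts such as
heaping and missingness. Agreement with the published comparison therefore
validates the estimators' relative behaviour under these stylized
conditions, not their absolute accuracy on any real facility census.
Two further caveats: the output-allocation rule is a reconstruction (see
above), so baseline tail-rate criteria are matched only within a widened
band; and all DEA-based conclusions inherit the multiplier-vertex
non-uniqueness noted earlier, a known source of small cross-implementation
variation.

## A worked example

```{r example, eval = FALSE}
library(effsim)
cfg <- scenario_preset("baseline", reps = 100, seed = 1)
res <- run_scenario(cfg)
res[, c("method", "mad", "notfront", "pu20", "po20", "spearman")]
```

At 100 replications this prints (seed 1; values move by a few tenths with
the seed): DEA overestimates more than 40% of facilities by over a fifth of
their true efficiency and misclassifies ~12% as fully efficient; rDEA cuts
overestimation to a few percent with rank correlation ~0.96; rSDF-CD —
misspecified for a linear technology — underestimates about half the
sample; the ensemble sits between. The same table at 2,000 replications is
the package's reproduction of the published baseline comparison.
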
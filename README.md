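# effsim — a Monte-Carlo laboratory for health-facility efficiency estimators

Health facilities turn inputs (staff, beds, supplies) into services
(outpatient visits, deliveries, ART visits). A facility's *technical
efficiency* θ ∈ (0, 1] is the share of its feasible output it actually
produces — never observed, always estimated. The two standard estimator
families, data envelopment analysis (DEA) and stochastic distance-function
regression (SDF), can disagree sharply on the same data, and their error
behaviour in low-resource settings — dispersed efficiency, facilities
producing only a subset of outputs, non-Cobb-Douglas technologies — is not
well understood.

`effsim` settles the comparison by simulation. It generates facility panels
with **known** true efficiency under a family of data-generating processes,
runs four estimators, and scores them against the truth:

- **DEA** — output-oriented, constant returns to scale, CCR multiplier form

  maximize `u'y_o` s.t. `v'x_o = 1`, `u'y_k − v'x_k ≤ 0` for all peers k,
  `u, v ≥ 0`

  with iterative super-efficiency outlier filtering (leave-one-out scores;
  while any exceed 1.5 and fewer than 5% of facilities are removed, drop the
  largest and repeat; removed facilities score 1).
- **rDEA** — the same program with data-driven assurance regions
  `L_j ≤ u_j/u_1 ≤ U_j` (and likewise for inputs), where L and U are the
  40th/60th percentiles of the first-stage non-zero relative weights.
- **rSDF-CD** — the Cobb-Douglas output distance function
  `−ln y1 = β0 + Σ β_r ln x_r + Σ α_j ln(y_j/y1) + ε`, `ε = u + v`,
  fitted by constrained maximum likelihood (α > 0, β < 0, λ = σu/σv > 0)
  under a normal/half-normal composed error, with per-facility efficiency
  from the JLMS conditional mean `E(u|ε)` and `θ = exp(−E(u|ε))`.
- **ENS** — the per-facility mean of rDEA and rSDF-CD scores.

Accuracy is summarised by five criteria, averaged over replications: MAD
(median absolute deviation), PU20/PO20 (share of facilities under-/
over-estimated by more than 20% of true efficiency), NOTFront (share scored
fully efficient whose true efficiency is below 0.80), and the Spearman rank
correlation.

The linear programs behind DEA are solved by a dense two-phase simplex
written for this package (compiled code under `src/`): each facility's
envelopment dual has only R+J rows, and the multiplier weights needed for
the rDEA restrictions are read off its dual prices.

## Worked example

```r
library(effsim)
cfg <- scenario_preset("baseline", reps = 100, seed = 1)
res <- run_scenario(cfg)
res[, c("method", "mad", "notfront", "pu20", "po20", "spearman")]
#>    method     mad notfront  pu20   po20 spearman
#> 1     DEA 0.06451   11.370  0.00 40.975   0.8513
#> 2    rDEA 0.01732    3.160  0.04  5.760   0.9513
#> 3 rSDF-CD 0.12730    0.015 58.38  9.100   0.6925
#> 4     ENS 0.06073    0.005 32.35  6.625   0.9178
```

Reading: on the baseline low-resource design (n = 200, linear technology,
θ ~ unif(0,1), partial output portfolios) unrestricted DEA overestimates
41% of facilities by more than a fifth of their true efficiency and
misclassifies 11.4% as fully efficient; percentile weight restrictions
(rDEA) cut overestimation to ~6% and raise the rank correlation to 0.95;
the distance-function regression — misspecified for a linear technology —
underestimates over half the sample; the ensemble hedges between the two.
Other presets (`scenario_presets()`) vary sample size, input correlation,
fixed inputs, measurement error, the efficiency distribution and the
functional form; under the `cobb_douglas` preset the correctly-specified
rSDF-CD nearly recovers the truth (MAD ≈ 0.01, rank correlation ≈ 1.0),
reversing the ranking.

A thin command-line front-end ships in `inst/cli/effsim`:

```sh
Rscript inst/cli/effsim run --scenario baseline --reps 100 --seed 1 --out results/
Rscript inst/cli/effsim sweep --scenario baseline --pairs 0:0,20:80,40:60 --reps 50
Rscript inst/cli/effsim simulate --scenario cobb_douglas --seed 7 --out panel.csv
Rscript inst/cli/effsim estimate --panel panel.csv --method ens --out scores.csv
```

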
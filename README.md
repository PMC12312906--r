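# locolearn

Hierarchical Bayesian analysis of trial-by-trial **locomotor skill
learning** in obstacle-crossing tasks with two interleaved obstacle
heights — the kind of protocol used to compare skill acquisition and
retention between people with early-stage Parkinson's disease (PD) and
age-matched controls. Because such studies rarely deposit their human
kinematic data, the package ships a synthetic-cohort generator with known
ground truth, so the entire pipeline is testable end to end.

## The model

Each participant `p` tracks one internal state per obstacle height,
`x = (x_LOW, x_HIGH)` — their estimate of the rewarded clearance threshold.
On trial `n` with context vector `c = (1, q_p)` for LOW or `(q_p, 1)` for
HIGH obstacles:

```
FC_est = x · c                                  (motor output)
e      = dead-zone error of FC_est w.r.t. [H_lower, H_upper]
x     <- x + B_p · e · c                        (state update)
FC     ~ StudentT(FC_est, tau_p, nu)            (observed clearance)
```

`B_p ∈ [0,1]` is the learning rate, `q_p ∈ [0,1]` the contextual
interference between the two heights. A three-level hierarchy ties
participants together: `B_p = logistic(N(θ_B[g], σ_B[g]))` per group `g`
(same for `q_p`), with vague hyper-priors (`θ ~ N(0, √1000)`,
`σ², ν ~ Inv-Gamma(10⁻³, 10⁻³)`). Estimation is adaptive
Metropolis-within-Gibbs (C++ backend), checked with split and
rank-normalized R-hat; models are compared by WAIC; group contrasts use the
probability of direction on sigmoid-transformed population differences and
ROPE tests on standardized effect sizes. See the methods vignette
(`vignettes/locolearn-methods.Rmd`) for assumptions, priors, and design
decisions.

## Worked example

```r
library(locolearn)

# a small synthetic study: 8 controls + 8 PD, 96 acquisition obstacles
ch  <- generate_cohort(design = cohort_design(n_control = 8, n_pd = 8,
                                              n_bouts = 3,
                                              no_feedback_bout = 2),
                       seed = 1)
fit <- loco_fit(ch$trials, chains = 3, iter = 10000, burn_in = 6000,
                thin = 4, seed = 2)
fit
#> Hierarchical Bayesian state-space fit (full, dot output)
#>   participants: 16 in groups CONTROL, PD
#>   retained draws: 3000 (3 chains x 1000)
#>   max split R-hat: 1.046 (converged)

ct <- group_contrast(fit, "learning_rate")   # control - PD, sigmoid scale
#> pd = 100.0% (negative), diff median = -0.112 [-0.171, -0.064]
#> ROPE: 99.9% outside [-0.1, 0.1] -> meaningful
```

The direction is *negative*: the PD group's population learning rate is
higher (the generator's defaults embed the medians 0.08 vs 0.14, so this
cohort really does contain a group difference; the trimmed pd then
saturates at 100%). Recovery against the generator's ground truth:

```r
med <- participant_medians(fit)
cor(ch$truth$B, med$B, method = "spearman")
#> [1] 0.9

summ <- summarize_cohort(ch$trials, ch$specs, fit)
round(mean(summ$online_improvement), 3)   # no-feedback minus baseline error
#> [1] -0.044                              # meters; negative = improvement
round(mean(summ$retention_delta), 3)      # Day-2 minus end-of-practice
#> [1] 0                                   # forgetting factor 1: no loss
```

`association_models(summ)` fits the learning-parameter association
regressions (improvement ~ B × group, retention ~ q × group, retention
error ~ model-based end error).

## Command line

```sh
inst/cli/locolearn cohort  --seed 1 --out-dir runs/demo
inst/cli/locolearn fit     --data runs/demo/trials.csv --model full \
    --chains 3 --iter 20000 --burnin 10000 --thin 10 --seed 2 \
    --out runs/demo/posterior.csv
inst/cli/locolearn diagnose --posterior runs/demo/posterior.csv
inst/cli/locolearn test     --posterior runs/demo/posterior.csv \
    --out runs/demo/contrasts.json
inst/cli/locolearn run      --seed 1 --out-dir runs/full   # whole pipeline
```

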
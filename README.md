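# exemplarmix

Latent-mixture exemplar models of multiple-cue judgment.

## The problem

In multiple-cue judgment experiments, participants first learn a small set
of exemplars — stimuli described by binary cues together with a continuous
criterion value on a 0–100 scale (the toxicity of a bug, the quality of a
job candidate) — and then judge both the trained exemplars and new stimuli.
The standard process account is the context model extended to continuous
criteria: the judged value of a probe is the similarity-weighted average of
all stored exemplar criterion values,

    S(p, e_j) = s^(D - m)                       similarity, m matching cues of D
    c'(p)     = Σ_j S(p, e_j) c_j / Σ_j S(p, e_j)

with a single mismatch parameter `s ∈ [0, 1]`: small `s` means sharp
discrimination between exemplars, `s = 1` makes every prediction the plain
mean of the stored criteria.

A participant who has overlearned an exemplar, however, does not integrate:
they simply **recall** its learned criterion value and report it. A judgment
data set is therefore a mixture of two processes — similarity-based judgment
and direct recall — and fitting the pure exemplar model to such data biases
the estimate of `s` toward 0, because exact reproduction of a trained
exemplar's criterion is only reachable by the model when `s` is tiny.

`exemplarmix` provides:

* the exemplar-model math (`similarity`, `predict_criterion`, `predict_batch`);
* a synthetic judgment-experiment generator (`simulate_design`,
  `generate_judgments`): 2^D binary cue patterns, criterion values from a
  linear cue-weight rule with a criterion swap between one pair of stimuli,
  random exemplar selection that avoids the four most extreme criterion
  values, and a per-exemplar recall probability `P_r`;
* Bayesian estimation by adaptive MCMC (compiled sampler) for three
  estimators of `s`: the conventional fit on all trials (`fit_original`),
  the split estimator that discards exactly recalled trials (`fit_split`
  with `split_trials`), and the latent-mixture extension that models the
  recall process explicitly with a latent memory probability `phi`
  (`fit_mixture`);
* model comparison via Savage–Dickey log Bayes factors
  (`savage_dickey_log_bf`) and posterior-predictive RMSE
  (`posterior_predictive_rmse`), plus split-chain R-hat diagnostics;
* a Monte-Carlo parameter-recovery pipeline over an `s × P_r` grid
  (`run_cell`, `run_grid`) producing machine-readable summary tables;
* a command-line interface (`cli_main`, launcher in `inst/scripts/`) with
  `simulate`, `fit`, `recover`, and `report` subcommands.

## Worked example

Two exemplars with cue patterns `(0,1)` and `(1,1)` and criterion values 3
and 7; the probe is identical to the first exemplar:

```r
library(exemplarmix)
mem <- exemplar_memory(rbind(c(0, 1), c(1, 1)), c(3, 7))
predict_criterion(c(0, 1), mem, s = 1)
#> [1] 5
predict_criterion(c(0, 1), mem, s = 0)
#> [1] 3
```

At `s = 1` the model predicts the mean of the stored criteria; at `s = 0` it
reproduces the matching exemplar exactly. Reversing this logic, data that
contain exact reproductions drag the estimate of `s` down. A full-recall
synthetic experiment makes the bias and its remedy visible:

```r
set.seed(1)
design <- simulate_design()          # 5 cues, 32 stimuli, 12 exemplars
data <- generate_judgments(design, generation_regime(s_true = 0.8, recall_prob = 1))
fit_orig <- fit_original(data, fit_config(seed = 1))
fit_mix  <- fit_mixture(data, fit_config(seed = 1))
print(fit_orig)
#> original exemplar-model fit (32 trials, 2 chains x 5000 draws)
#>     median   mean     sd   rhat
#> s   0.3130 0.3159 0.0647 0.9999
#> tau 0.0232 0.0237 0.0061 1.0000
print(fit_mix)
#> mixture exemplar-model fit (32 trials, 2 chains x 5000 draws)
#>         median      mean        sd   rhat
#> s       0.8000    0.8000    0.0003 1.0000
#> phi     0.9488    0.9285    0.0668 1.0000
#> tau0 9182.6518 9488.6633 3055.6261 1.0003
#> tau1 5665.6193 5970.3005 2421.5808 0.9998
savage_dickey_log_bf(fit_mix)        # ~17: strong evidence for the mixture
posterior_predictive_rmse(fit_orig)  # ~6.4 criterion units
posterior_predictive_rmse(fit_mix)   # ~2e-4
```

The data were generated at `s = 0.8` with every exemplar recalled. The
conventional fit collapses to `s ≈ 0.31`; the latent-mixture model recovers
`s = 0.800` exactly, estimates the memory probability `phi ≈ 0.95`, and
predicts the data essentially perfectly.

The same study at scale, over a grid of true `s` values and recall
probabilities:

```r
cells <- run_grid(grid_config(reps = 30, seed = 1), out_dir = "recovery")
# writes table2.csv (estimators), table3.csv (log BF), table4.csv (RMSE),
# cells.json, run.log
```

or from a shell:

```sh
Rscript inst/scripts/exemplarmix simulate --d 5 --s .3 --pr .5 --seed 1 --out data.csv
Rscript inst/scripts/exemplarmix fit --model mixture --data data.csv --out summary.json
Rscript inst/scripts/exemplarmix recover --reps 30 --seed 1 --out recovery/
```

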
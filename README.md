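# laryngobn

Treatment-decision support for primary laryngeal carcinoma, modelled as a
discrete Bayesian network. The package is aimed at clinical-informatics
researchers who want a fully scripted, testable counterpart to
GUI-based network modellers: it bundles a generic exact-inference engine, a
compiler that turns declarative guideline-style treatment rules into
conditional probability tables (CPTs), a packaged 9-node larynx model, the
standard validation workflow for decision-support classifiers, and a
synthetic tumor-board cohort simulator.

## The model

A Bayesian network is a directed acyclic graph of categorical variables
where each node `X` carries one conditional distribution `P(X | pa(X))` per
combination of its parents' states, and the joint factorizes by the chain
rule

```
P(X1, ..., Xn) = prod_i P(Xi | pa(Xi)).
```

The packaged larynx model has nine nodes and eighteen edges:

* **Observables** — TNM staging (`T`: TX, T0, TIS, T1, T1a, T1b, T2, T3,
  T4a, T4b; `N`: NX–N3b; `M`: MX, M0, M1) and a binary
  chemotherapy-tolerance prerequisite node.
* **Targets** — five binary treatment nodes (`larynx_surgery`,
  `radiotherapy`, `radiochemotherapy`, `chemotherapy`, `immunotherapy`),
  each a child of `T`, `N`, `M`; tolerance additionally feeds surgery,
  chemotherapy and radiochemotherapy.

Treatment CPTs are not entered cell by cell: they are compiled from an
ordered rule set (`inst/extdata/larynx_nccn_like.yaml`), where each rule
maps a set of staging constellations to `P(treatment = true)` and the most
specific (highest-priority) matching rule wins. Two probabilities are fixed
anchors of the packaged model: `P(surgery | T2, N2a, M0, tolerant) = 0.74`
and `P(surgery | T2, N2a, M1, tolerant) = 0.17`.

Posteriors are computed exactly by variable elimination
(`bn_posterior()`), verified against a full-joint enumeration oracle
(`bn_enumerate_posterior()`, 15,360 joint states for the packaged model).
Validation follows the usual decision-support recipe: per (case, target)
argmax prediction vs. recorded therapy, accuracy, per-class F1, ROC/AUC,
precision-recall/AP, and 10-fold cross-validation in which CPTs are
re-learned from data (`bn_fit()`: Dirichlet-smoothed counting, EM under
missingness).

## Worked example

```r
library(laryngobn)

net <- larynx_model()
print(net)
#> Discrete Bayesian network: 9 nodes, 18 edges
#>   observable: T, N, M, chemo_tolerance
#>   target: larynx_surgery, radiotherapy, radiochemotherapy, chemotherapy, immunotherapy

# posterior treatment profile for one staging constellation
sapply(bn_targets(net), function(trt)
  bn_posterior(net, c(T = "T2", N = "N2a", M = "M0",
                      chemo_tolerance = "tolerant"), trt)[["true"]])
#>    larynx_surgery      radiotherapy radiochemotherapy      chemotherapy
#>              0.74              0.40              0.55              0.05
#>     immunotherapy
#>              0.08
```

The `0.74` is the anchor probability above: for a tolerant T2 N2a M0
patient the model considers surgery indicated with probability 74%; the
same patient with distant metastases (M1) drops to 17%.

```r
cohort <- simulate(net, nsim = 92, seed = 1)     # synthetic tumor-board cohort
preds  <- predict(net, cohort)                   # 92 x 5 = 460 decisions
report <- metrics_report(preds, cv = kfold_cv(net, cohort, k = 10, seed = 1))
print(report$accuracy)
#> Accuracy (absolute and relative numbers)
#>             target fraction     accuracy
#>          all nodes  356/460 0.7739 (77%)
#>     larynx_surgery    67/92 0.7283 (73%)
#>       radiotherapy    65/92 0.7065 (71%)
#>  radiochemotherapy    72/92 0.7826 (78%)
#>       chemotherapy    80/92 0.8696 (87%)
#>      immunotherapy    72/92 0.7826 (78%)
print(report$cv)
#> 10-fold cross-validation (seed 1)
#> fold accuracies: 0.700 0.700 0.711 0.667 0.600 0.689 0.756 0.800 0.778 0.800
#> mean accuracy: 0.7200
```

Here the cohort's treatment labels were *sampled* from the model's own
CPTs, so even the generating model cannot score 100%: its expected accuracy
is the mean of `max(p, 1-p)` over the cohort. The cross-validated,
data-learned model scores lower than the expert-built one (0.72 vs. 0.77) —
with 92 cases spread over hundreds of staging combinations, counting-based
learning cannot populate the tables. The property tests around this
behaviour live in `tests/testthat/test-acceptance.R`.

A command-line front end over the same functions is installed at
`inst/cli/larynxbn` (subcommands `model`, `infer`, `simulate`, `validate`,
`crossval`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","larynxbn",package="laryngobn"))')" \
  infer --T T2 --N N2a --M M0 --tolerance tolerant
```

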
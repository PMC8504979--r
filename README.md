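# bnimpute

Score-based Bayesian network structure learning for mixed
discrete/continuous data, with a nearest-neighbour imputation of missing
data that is guided by the network itself.

## Who this is for

Analysts exploring candidate causal relationships in individual-level
multi-omics data (SNP dosages, methylation, expression, traits), where
genetic variables serve as causal anchors (edges may only leave them) and
where many individuals are missing a few measurements. Dropping every
incomplete individual can shrink a 2000-person study to a 200-person one;
`bnimpute` instead imputes each missing value from a nearest neighbour
chosen using the variables that a resampled best-fit network says are
informative, and this markedly improves the recall and precision of the
directed edges recovered downstream.

## The method in brief

Networks are scored decomposably: multinomial local distributions for
discrete nodes, Gaussian regressions (one per discrete-parent configuration)
for continuous nodes, penalised as BIC = log L&#770; − (d/2) log n by
default. A greedy hill climber with random and jitter restarts maximises the
score subject to hard constraints (white/black lists, no edge into a genetic
node, no continuous parent of a discrete node) and optional soft constraints:
a directed edge e with prior p(e) (reverse direction 1 − p(e)) enters the
score as

    WeightedScore = BIC + sum_e log p(e)

Uncertainty is summarised by bootstrap average networks: per node pair, the
*strength* (proportion of 1000 bootstrap best-fit networks containing an
edge), the *direction* (proportion of those in the reference orientation),
and the directed-edge probability strength × direction, with an L1-optimal
data-driven strength threshold.

Missing data are imputed per index individual: draw a 90% training subset
(randomly filling its remaining holes, or drawing from complete cases only
in the CT variant), learn an inner network on it by greedy BIC search, take
the variables adjacent to the missing variable that the individual observes
as *nearby variables* (continuous children may be replaced by
regression-adjusted versions v = y − Σ β_x x that track the missing parent
specifically), and copy the value from the candidate minimising the
variance-normalised distance over those variables. A simulator (structural
models with effect strength β, SNP dosages, BIF benchmark networks, MAR
missingness injectors) and a recall/precision harness reproduce the
method's evaluation design.

## Worked example

Simulate the 31-variable omics scenario (20 SNP dosages feeding 10
expression variables, which feed one trait; expression entries missing with
probability 0.2 so that 445 of 500 individuals are incomplete), then learn
networks from the reduced data versus the imputed data:

```r
library(bnimpute)
sc  <- builtin_scenario("omics31", beta = 0.3, seed = 11)
imp <- impute_nn(sc$data, imputation_config(seed = 3))
recall_precision(sc$truth,
                 greedy_search(imp$data, config = search_config(seed = 5))$dag)
#> recall 0.967  precision 0.853  (TP 29 / true 30 / retrieved 34)
recall_precision(sc$truth,
                 greedy_search(complete_rows(sc$data),
                               config = search_config(seed = 5))$dag)
#> recall 0.533  precision 0.516  (TP 16 / true 30 / retrieved 31)
```

Imputation recovers 29 of the 30 true directed edges; the 55 complete cases
alone recover 16. `run_comparison()` repeats this over replicates, β values
and competing strategies (full, reduced, random, mean, all-NN, imputed,
imputed-CT) and `summarise_comparison()` reports means with Monte-Carlo
standard errors. `bootstrap_average()`, `strength_threshold()` and
`write_dot()` turn a dataset into a thresholded average network for
plotting; `prior_sweep()` quantifies how soft priors change edge detection.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the package's own operations, the directed-edge
probabilities of reported average-network pair records (instantiating each
pair's printed bootstrap strength and direction and applying
`directed_edge_probability()` at the table's display precision) and writes
them keyed by target id.
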
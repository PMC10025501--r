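# irtreesim

Monte Carlo parameter-recovery study machinery for the five-category
**midpoint-primary-process (MPP) IRTree model**.

## The problem

Item response tree (IRTree) models explain a Likert response as a sequence
of binary decisions, each governed by its own latent trait. For a 5-point
scale the MPP tree is:

1. **midpoint** — answer "3", or give a directed response;
2. **agreement** — given a directed response, agree (4/5) or disagree (1/2);
3. **extreme** — given a directed response, pick the endpoint (1/5) or not.

Each node is a 2PL model: the probability of taking branch 1 at node
*k* for person *i* and item *j* is
`plogis(alpha[k,j] * theta[i,k] + d[k,j])`, with intercept `d = alpha * b`
and `b` the difficulty on the trait scale. Category 3 terminates the tree,
so the agreement and extreme *pseudo-items* are structurally missing for
every midpoint response:

| category | midpoint | agreement | extreme |
|---------:|:--------:|:---------:|:-------:|
| 1 | 0 | 0 | 1 |
| 2 | 0 | 0 | 0 |
| 3 | 1 | — | — |
| 4 | 0 | 1 | 0 |
| 5 | 0 | 1 | 1 |

Psychometricians use the later nodes to measure midpoint/extreme response
styles — but can the model actually *recover* its own item parameters from
realistic sample sizes and test lengths, given that missingness thins the
data as the tree deepens? This package implements the full simulation
study that answers that question: generate data from the MPP model across
a sample-size × test-length grid, decompose to pseudo-items, fit the
three-node model by MCMC, and quantify recovery (RMSE, bias, CIs) and
design effects (factorial ANOVA, partial eta-squared).

## Worked example

Simulate one design cell, fit it, and inspect recovery:

```r
library(irtreesim)

params <- draw_item_params(10, seed = 11)     # truth: 3 nodes x 10 items
traits <- draw_thetas(1000, seed = 12)        # correlated latent traits
y      <- simulate_responses(params, traits, seed = 13)
codes  <- decompose_responses(y)              # binary pseudo-items + NA

fit <- fit_irtree_mcmc(codes,
                       chains = chain_config(chains = 2, iterations = 1500,
                                             burnin = 750),
                       seed = 42)
fit
```

```
MPP IRTree fit: 1000 persons x 10 items, 2 chain(s) x 750 draws kept
posterior mean alpha by node: midpoint 0.64, agreement 1.36, extreme 1.70 
no convergence flags
```

The posterior mean discriminations sit near the generating log-normal
means (0.65, 1.37, 1.87). A scaled-down version of the full study — every
(N, J) condition, a handful of replicates — and the comparison against the
published full-scale node means:

```r
rep_run <- replicate_study(scale = 3 / 2000, seed = 1)  # 3 replicates/cell
rep_run
```

```
Scaled-down replication: 3 replicates/cell
node       alpha RMSE obs/ref     d RMSE obs/ref
midpoint      0.087 / 0.13        0.063 / 0.09   
agreement     0.123 / 0.42        0.116 / 0.93   
extreme       0.206 / 0.94        0.187 / 3.13   
node ordering midpoint < agreement < extreme: alpha RMSE holds; d RMSE holds
```

Reading the table: recovery error *grows down the decision hierarchy* —
the study's headline finding. The midpoint error magnitudes match the
published full-scale values; the agreement and extreme nodes come out
markedly better here than in the published fits, whose later-node
estimates carry a large parameterization-induced bias that a
self-consistent implementation does not reproduce (see the methods
vignette). `rep_run$study` holds the per-cell recovery table
(`$recovery`), the per-item records (`$detail`), and the factorial ANOVA
with partial eta-squared (`$anova_alpha`, `$anova_d`), where the node
effect dominates sample size and test length.

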
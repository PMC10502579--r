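# litprop

Suggesting disease associations for **overlooked metabolites** by
propagating the literature of their metabolic neighborhood.

Most metabolites in genome-scale metabolic networks have little or no
dedicated literature: the corpus is dominated by a handful of
over-studied compounds, and the majority of network metabolites have no
annotated article at all. When a metabolomics study highlights such a
compound, there is nothing to read. `litprop` implements a Bayesian
guilt-by-association method for this situation: the literature of a
metabolite's *metabolic neighbors* is propagated along the compound
graph and turned into an explainable prior on the probability that an
article mentioning the metabolite also mentions a given disease
descriptor. Whatever literature the metabolite does have then updates
the prior into a posterior. The package is aimed at researchers
interpreting metabolomics signatures and at anyone building literature-
based prioritization tools over metabolic networks.

## The model

Let `n_i` be the number of articles mentioning metabolite `i`,
`N = Σ n_i`, `y_i` the number of articles co-mentioning `i` and a
disease descriptor, `m = Σ y_i` and `P = m/N` the descriptor's
background rate. For a target metabolite `k`, the quantity of interest
is `p_k`, the probability that an article mentioning `k` also mentions
the disease.

1. **Propagation.** A random walk with restart (damping factor `α`)
   models a mention sent by metabolite `i` through the compound graph;
   the walker takes one step first, so at `α = 0` exactly the direct
   neighbors are reached. `i` is allowed to contribute to `k`'s prior
   only when its reach probability beats a uniformly random pick,
   `π_ik/(1 − π_ii) > 1/(M−1)` (strict). Its corpus is distributed over
   that influence neighborhood, `t_ik = n_i π_ik / Σ_{k'∈H_i} π_ik'`,
   and contributor weights are the shares of literature reaching `k`:
   `w_ik = t_ik / Σ_{i'} t_i'k`. A metabolite never contributes to its
   own prior.
2. **Shrunken prior mixture.** Each contributor's co-mention rate is a
   Beta-binomial estimate shrunk toward the background,
   `Beta(Pν + y_i, (1−P)ν + n_i − y_i)` with `ν` pseudo-observations
   (default 1000); the prior on `p_k` is the `w_ik`-weighted mixture of
   these components.
3. **Posterior update.** The target's own counts `(n_k, y_k)` update
   every component conjugately and reweight the mixture by each
   component's Beta-binomial marginal likelihood (computed in log
   space): contributors whose literature explains the observations gain
   weight.
4. **Predictors and diagnostics.** With `CDF = Pr(p_k ≤ P)` and
   `q = 1 − CDF`: `LogOdds = log(q/(1−q))` (significance-like) and
   `Log2FC = log2(E[p_k]/P)` (effect size). The Shannon entropy of the
   contributor weights plus weight-averaged contributor distance and
   corpus size flag priors dominated by a single over-studied neighbor.
   The default screen keeps predictions with `LogOdds > 2`,
   `Log2FC > 1` and `Entropy > 1`, and a right-tailed Fisher exact test
   with Benjamini-Hochberg correction re-evaluates pairs that have
   their own literature.

Every prediction carries a contributor profile — who contributed, with
which weight, pulling in which direction — so suggestions can be
audited against the underlying biology.

## Worked example

Synthetic data stand in for the real inputs (a pruned compound graph, a
mention corpus and a co-occurrence table, all plain TSV): a scale-free
network in which 15-member modules co-mention each descriptor at 12
times its background rate.

```r
library(litprop)

cfg <- simulation_config(n_nodes = 300, n_descriptors = 6,
                         background_rate = 0.02, module_size = 15,
                         theta = 12, module_corpus_min = 1000, seed = 42)
g   <- simulate_network(cfg)
lit <- simulate_literature(g, cfg)
res <- run_screen(g, lit$corpus, lit$cooc)
#> screen: 1392 pairs scored, 31 pass the thresholds
#>   no literature: 792 | few articles (co-mention yes/no): 49/551 |
#>   no neighborhood literature: 0 | no information (discarded): 0

print(subset(res$predictions, passes_filter)[1:2, c(1:5, 7, 8, 11)],
      digits = 3)
#>   metabolite descriptor      scenario n y LogOdds Log2FC Entropy
#> 1      m0238        D01  few_articles 4 0    6.53   1.21    1.23
#> 2      m0289        D01 no_literature 0 0    6.52   1.17    1.33
```

`m0289` has no literature of its own; the screen still suggests
descriptor `D01` with posterior error `≈ exp(−6.52)` and a mention rate
`2^1.17 ≈ 2.3` times the background. The contributor profile explains
why:

```r
prop <- propagate(g, lit$corpus, alpha = 0.4)
prof <- build_profile("m0289", "D01", prop, lit$corpus, lit$cooc)
print(as.data.frame(prof)[5:8, c("contributor", "weight_prior",
                                 "prior_Log2FC", "distance",
                                 "n_articles")], digits = 3)
#>   contributor weight_prior prior_Log2FC distance n_articles
#> 5       m0012       0.0661         1.13        2       1000
#> 6       m0089       0.0666         1.24        2       1000
#> 7       m0108       0.1635         1.16        2       1000
#> 8       m0022       0.7011         1.17        1       1000
attr(prof, "Entropy")
#> [1] 1.332836
```

99.7% of the prior weight comes from four well-described neighbors (one
direct, three at two reactions) that each co-mention `D01` at more than
twice the background rate — all four are members of the planted `D01`
module, so the suggestion recovers the planted association from the
neighborhood alone. The entropy of 1.33 bits shows the prior is not a
single-contributor artifact.

The same operations are available from a shell:

```sh
Rscript inst/cli/litprop.R simulate --n-nodes 300 --theta 12 --seed 42 --out-dir sim
Rscript inst/cli/litprop.R screen --graph sim/graph.tsv --corpus sim/corpus.tsv \
    --cooccurrence sim/cooccurrence.tsv --alpha 0.4 --out-dir out
Rscript inst/cli/litprop.R profile --graph sim/graph.tsv --corpus sim/corpus.tsv \
    --cooccurrence sim/cooccurrence.tsv --metabolite m0289 --descriptor D01
```

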
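---
title: "Propagating neighborhood literature to suggest disease associations for overlooked metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating neighborhood literature to suggest disease associations for overlooked metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litprop)
```

## The problem

Literature about metabolites is extremely unevenly distributed: a few
compounds (glucose, cholesterol, the amino acids) account for most
annotated articles, while the majority of metabolites in a genome-scale
network have few or none. For those *overlooked* metabolites — in this
package, fewer than 100 mentioning articles, used purely as a
prioritization cutoff — classical co-occurrence mining has nothing to
work with. `litprop` transfers information along the metabolic network
instead: metabolites connected by substrate-product relationships tend
to share biomedical context, so the literature of the neighborhood can
serve as a prior for the compound itself.

## Model

For a descriptor with background rate $P = m/N$, the probability $p_k$
that an article mentioning metabolite $k$ also mentions the descriptor
is modeled hierarchically.

**Propagation.** Mentions travel by a random walk with restart in which
the walker *first steps away* from its source and is only then counted:
$\pi_i = (1-\alpha)\, e_i T (I - \alpha T)^{-1}$, with $T$ the
uniform-neighbor transition matrix of the undirected compound graph and
$\alpha$ the damping factor. This variant is chosen deliberately: at
$\alpha = 0$ it reduces to the direct-neighbor distribution, so the
"only direct neighbors contribute" regime is the exact $\alpha = 0$
limit, whereas standard personalized PageRank would put all mass on the
source itself. Contributions are restricted to the influence
neighborhood $H_i = \{k \neq i :
\pi_{ik}/(1-\pi_{ii}) > 1/(M-1)\}$ — a metabolite may only contribute
where it reaches a target more probably than a uniformly random pick.
The inequality is strict and evaluated after the division with no
epsilon slack, so exact floating-point ties (the center of a star graph
at $\alpha = 0$ reaches every leaf at exactly $1/(M-1)$) are
*excluded*; this is a documented sharp edge, not an accident. Each
source's corpus $n_i$ is then shared over $H_i$ proportionally to
$\pi_{ik}$ (so literature is conserved row-wise), and the prior weight
$w_{ik}$ of contributor $i$ for target $k$ is its share of all
literature reaching $k$. Self-contribution is structurally impossible
($k \notin H_k$).

**Shrinkage and mixing.** A contributor's own evidence $(n_i, y_i)$ is
combined with the a-priori independence assumption
$E[p] = P$ through the conjugate update of
$\mathrm{Beta}(P\nu, (1-P)\nu)$, giving
$\mathrm{Beta}(P\nu + y_i,\ (1-P)\nu + n_i - y_i)$. The
pseudo-observation count $\nu$ sets how much evidence a contributor
needs before its raw rate $y_i/n_i$ displaces the background: the prior
variance is $P(1-P)/(1+\nu)$, and a contributor with $n_i \ll \nu$ is
pulled almost entirely back to $P$. The prior on $p_k$ is the
$w_{ik}$-weighted mixture of these shrunken components.

**Posterior.** The target's own counts $(n_k, y_k)$ update every
component conjugately and reweight the mixture by the Beta-binomial
marginal likelihood $C_{ik} = \binom{n_k}{y_k}
B(\alpha^{(2)}_i, \beta^{(2)}_i)/B(\alpha^{(1)}_i, \beta^{(1)}_i)$:
the posterior weight of a contributor grows when its component explains
the observations well. With $n_k = 0$ the posterior equals the prior
exactly; with $n_k$ large the data dominate and the posterior mean
converges to $y_k/n_k$ at rate (prior pseudo-mass)$/n_k$ — note this
means convergence statements only hold once $n_k$ dwarfs
$\nu\ (+\ n_i)$, which the tests make explicit.

**Predictors.** $\mathrm{CDF} = \Pr(p_k \le P)$ under the mixture,
$q = 1 - \mathrm{CDF}$, $\mathrm{LogOdds} = \log(q/(1-q))$ and
$\mathrm{Log2FC} = \log_2(E[p_k]/P)$. `LogOdds` behaves like a
significance measure and is robust to outlier contributors; `Log2FC`
is an effect size and remains informative when the CDF underflows.
Both are reported per contributor as well, which is what makes the
predictions auditable.

## Scenarios

Per (metabolite, descriptor) pair the method dispatches on the
available information:

| own literature | neighborhood literature | behavior |
|---|---|---|
| no  | yes | predictors from the prior mixture (`no_literature`) |
| yes | yes | predictors from the posterior; `priorLogOdds`/`priorLog2FC` report the neighborhood's belief alone (`few_articles`) |
| yes | no  | degenerate null prior, single conjugate posterior (`no_neighbor_literature`) |
| no  | no  | bare null component, prediction automatically discarded (`no_information`) |

## Parameters

* `alpha` (damping, default **0.4**): average distance literature
  travels. 0 restricts to direct neighbors; 0.4 balances direct and
  indirect contributions.
* `nu` (pseudo-observations, default **1000**): strength of the
  shrinkage toward $P$. With corpora of a few hundred articles or
  less, $\nu = 1000$ suppresses most individual-contributor signal —
  deliberately conservative.
* Screening thresholds (defaults **LogOdds > 2, Log2FC > 1,
  Entropy > 1**, all strict): the entropy threshold, in bits, reads
  "more diverse than two equally weighted contributors" and flags
  single-contributor priors.
* `logodds_cap` (default **709**, roughly the log of the largest
  double): `LogOdds` is clamped there and flagged instead of returning
  infinities when the CDF underflows; `Log2FC` should be used to rank
  such cases. We chose clamp-and-flag over arbitrary-precision
  arithmetic because an underflowing CDF already means "beyond any
  conventional significance".
* `max_articles` (default **100**, strict): the overlooked-metabolite
  cutoff. It selects which targets are *reported* by default, never
  which are computable.

## Numerical choices

* Marginal likelihoods use log-binomial coefficients and log-Beta
  functions, normalized by log-sum-exp; corpora up to $10^5$ articles
  overflow direct factorials.
* Reach probabilities come from a dense factorization below 2000 nodes
  and a sparse LU factorization above; both solve the same system and
  are tested to agree within $10^{-8}$. A direct sparse factorization
  was preferred over an iterative solver: the systems are well
  conditioned ($\|\alpha T\| < 1$), the factorization is
  deterministic, and there are no convergence knobs to document.
* Mixture components are kept sorted by contributor id, so serialized
  outputs are byte-stable; a full screen on fixed inputs is
  byte-identical across runs.
* Degenerate inputs are flags, not errors: isolated sources get
  all-zero reach rows, empty influence neighborhoods give all-zero
  contribution rows, and targets without contributors take the
  degenerate-prior route. Descriptors with $P \in \{0, 1\}$ are
  refused at scoring time.
* The log base of `LogOdds` is natural (the conventional definition of
  log-odds) and configurable to base 10; entropy is base 2 so the
  threshold has the two-contributor reading. Neither base is forced by
  the model.

## Masking semantics

Validation uses a ground-truth protocol: a well-described metabolite is
scored *as if it had no literature*, and its real literature judges the
prediction. Masking here means the corpus disappears **everywhere**:
the metabolite carries no own evidence, contributes to no prior, and
its mentions leave the global bookkeeping — so $P$ becomes
$(m - y_k)/(N - n_k)$. With that definition, masking is provably
identical to physically deleting the metabolite's rows from the input
files (the test suite asserts this pairwise). For the masked metabolite
itself no re-propagation is needed, because a metabolite never enters
its own prior; scoring *other* metabolites under the mask requires
re-propagating on the masked corpus (`mask_corpus()`).

## What the synthetic data emulates — and what it does not

`simulate_literature()` reproduces the two structural features of real
metabolite literature that drive the method's behavior: **zero
inflation** (by default 62% of metabolites have no annotated article)
and a **top-heavy corpus distribution** (discrete power law, default
tail exponent 2, capped at $10^6$). Disease signal is planted in
connected modules grown breadth-first, whose members co-mention a
descriptor at $\theta$ times its background rate, with corpora
optionally floored so the planted signal survives shrinkage — planted
corpora must comfortably exceed $\nu$, otherwise every contributor is
pulled back to $P$ and no effect can clear the screening thresholds.

It does **not** model: shared articles between metabolites (mentions
are drawn independently per pair, while real corpora overlap), MeSH
hierarchies, reaction stoichiometry or directionality, or the
correlation between a metabolite's degree and its corpus size. Passing
tests on this generator therefore demonstrate that the machinery
recovers plantable neighborhood signal under realistic sparsity and
skew — not that predictions over a real knowledge-base-scale corpus
would reach the same operating points.

## The recovery experiment and its controls

`recovery_experiment()` masks each planted-module member in turn and
scores it prior-only against its descriptor (positives) and against
descriptors of foreign modules (negatives), reporting the AUC of
`Log2FC`. Two design points matter:

* At desk scale the planted modules tile a substantial fraction of the
  graph, so a uniformly sampled member x foreign-descriptor pair often
  sits *directly adjacent* to that descriptor's module. Such a pair
  receives elevated neighborhood literature by construction — it is
  signal mislabeled as noise, not a control. Negative pairs are
  therefore sampled only from pairs whose metabolite is neither in nor
  adjacent to the descriptor's module; at realistic scales (thousands
  of nodes, sparse signal) uniformly random pairs have this property
  almost surely.
* The matched null configuration is identical except $\theta = 1$, so
  its labels carry no signal and the AUC should sit at chance; it
  guards against the harness leaking labels through anything but the
  planted rates.

## Problem sizes

The test suite works on graphs of 3-40 nodes (oracle comparisons run
exhaustively on all graphs up to 25 nodes), Bayes-rule checks on 200
randomized mixture configurations against panel-quadrature
renormalization, and the recovery experiment on a 750-node scale-free
network with 25 planted modules of 20 members (500 positive and 500
negative pairs) — sizes at which every oracle can be recomputed
exactly while still exhibiting the sparsity and skew the method is
built for.

## Known limitations

* The compound graph is consumed as-is; the carbon-skeleton pruning
  that removes spurious connections (cofactors, side compounds) is
  upstream of this package, and an unpruned graph will produce
  metabolically irrelevant contributors.
* Contributor corpora are treated as independent evidence; overlapping
  corpora (the same article mentioning several neighbors) double-count.
* A dominant contributor with off-context literature (e.g. a compound
  known for non-metabolic uses) propagates that context; the entropy
  and contributor-size diagnostics flag, but do not fix, such priors.
* `Baseline-DN` and the masked method coincide in ranking only in the
  regime of equal-degree, equal-corpus direct neighborhoods at
  $\alpha = 0$ (tested on a cycle); in general the method's weighting
  by reach probability and corpus size is the point of difference.
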
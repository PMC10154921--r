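---
title: "Trait co-occurrence networks and response diversity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait co-occurrence networks and response diversity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
library(dplyr)
```

## The problem this package addresses

Communities facing a stressor differ in their *response diversity*: the
variety of resistance and recovery strategies carried by the species that
sustain ecosystem functions. traitnet quantifies response diversity through
**trait co-occurrence networks**. Each species in a community is coded for a
set of trait modalities, each modality tagged with one of five categories:

* `REG` — ecosystem-regulating ("effect") traits,
* `REC_e` / `REC_i` — recovery-enhancing / recovery-inhibiting traits,
* `RES_e` / `RES_i` — resistance-enhancing / resistance-inhibiting traits.

For one community (here: one site under one experimental treatment), the
nodes of the network are trait modalities and an edge connects two modalities
when enough species bear both. The edge weight is the number of species
sharing the pair, a direct count of the redundancy behind that combination:
a regulating modality connected to many enhancing response modalities has
many "options" for persisting under stress.

## The co-occurrence model and edge filter

Whether a pair of modalities co-occurs more than trivially is judged with an
exact probabilistic model. In a community of $N$ species where $N_i$ bear
modality $i$ and $N_j$ bear modality $j$, random placement of memberships
makes the number of species bearing both hypergeometric:

$$P(Q = q) = \frac{\binom{N_i}{q}\binom{N-N_i}{N_j-q}}{\binom{N}{N_j}},
\qquad E[Q] = \frac{N_i N_j}{N}.$$

`cooccurrence_pmf()` computes this by log-factorial accumulation (exact in
double precision to community sizes far beyond what field data reach), and
`cooccurrence_pvalues()` returns the lower/upper tail sums at the observed
count. The edge filter (`filter_trait_pairs()`) retains a pair when:

1. $E[Q] \ge 1$: a pair *expected* to be shared by fewer than one species
   carries no response diversity even in principle; and
2. $Q_{\mathrm{obs}} \ge 1$: the edge weight is the observed shared-species
   count, and a zero-weight connection is meaningless.

The second condition is our addition: only the expectation threshold is part
of the published filtering idea, but a retained pair with no observed
sharing would create an edge of weight zero. Tail probabilities are computed
and reported for every pair, but significance is *not* a retention criterion
by default; `sig_level` enables a $p_{\ge}$ cut for sensitivity analysis.
Pairs of modalities within the same parent trait are retained by default
(`exclude_within_trait` turns this off) — nothing in the model distinguishes
them, and excluding them is a coding-scheme decision best left explicit.

## Pooling and the network per site-treatment

Community data are long-form `(site, treatment, plot, taxon, count)`
records. Each site-treatment has several field plots; `pool_plots()` unions
the species observed across them, which maximises the species pool behind
each network and mirrors how replicate cores are pooled in benthic
sampling. Presence/absence is all the model consumes — every downstream
statistic is presence-based, so abundances beyond presence are not used.
A site-treatment whose records are all zero counts is an *empty community*
(it yields an empty network with zero metrics), which is different from a
site lacking a control treatment altogether — the latter aborts the
pipeline naming the site.

## Network complexity: pooled eigencentrality

Eigenvector centrality scores a node by its connection to other
well-connected nodes. Because it is a relative measure, scores for all
networks are computed **on one pooled graph** whose disconnected components
are the individual site-treatment networks (each network keeps its own copy
of every modality node). The mean of a network's node scores is its
*network complexity*; the control network's value is the site's *baseline
network complexity*.

The default solver mirrors the fixed-round power method popularised by
desktop network tools: 100 iterations of $x \leftarrow Ax$ with
max-normalisation after each round, unweighted adjacency, and a final
rescale so the global maximum is exactly 1. The fixed iteration count is a
deliberate modelling choice, not a numerical shortcut. Run to convergence,
a disconnected graph's subdominant components are driven to zero and all
cross-component contrast collapses; stopped at a fixed count, components
retain scores that reflect their relative density, which is exactly what a
cross-site complexity proxy needs. Two alternatives are provided:

* `mode = "converged"` — a shifted power iteration ($A + I$, which has the
  same dominant eigenvector but also converges on bipartite components)
  run to a $10^{-13}$ fixed-point tolerance, per connected component. On a
  single connected graph this equals the dominant eigenvector of the
  adjacency matrix, max-normalised — the mode the test suite checks against
  a dense eigen-decomposition.
* `mode = "per_component_scaled"` — each component's converged eigenvector
  scaled by its dominant eigenvalue relative to the global maximum
  eigenvalue, a convergent alternative that preserves cross-component
  contrast on an interpretable (eigenvalue) scale.

A caveat of the faithful fixed-count default: on bipartite components the
unshifted iteration oscillates with period two rather than converging, and
weak components are suppressed geometrically (a component whose dominant
eigenvalue is half the global maximum ends up near $2^{-100}$). Both are
properties of the tool behaviour being reproduced; use the alternative
modes when convergence matters more than fidelity.

`network_metrics()` reports, per site-treatment: node count, connection
count, REG~REC\_e and REG~RES\_e connection counts, and mean node
eigencentrality.

## Stress response analysis

`effect_sizes()` forms, per site, enrichment level and metric, the ratio
treatment value / control value (1 = no change; below 1 = loss), joined to
the site's baseline complexity. Sites whose control metric is 0 have an
undefined ratio; they are emitted as `NA` with a warning and excluded from
tests and fits rather than imputed. Effect ratios are scale-free, so any
per-site normalisation cancels.

`effect_size_tests()` runs two-sided one-sample t-tests of each level's
effect sizes against 1 and a two-sample comparison of medium against high
(Welch by default; `var_equal = TRUE` for the pooled-variance form — the
choice is not identifiable from published summaries, and Welch is the safer
default). No multiple-testing correction is applied by default, mirroring
raw per-test reporting; `p_adjust = "BH"` is available.

`quantile_fits()` fits linear regression quantiles of effect size on
baseline complexity at $\tau = 0.1, \dots, 0.9$ by minimising the pinball
loss $\sum_k \rho_\tau(y_k - a - b x_k)$. The minimiser enumerates every
line through two data points (plus horizontal lines through each point):
the linear-program optimum is attained at such a vertex, so the enumeration
is exact. It is $O(n^3)$, which is immaterial at the tens of points this
analysis produces; fits on thousands of points would want a proper LP
solver. Coefficients are reported through loss-optimality only — at a
vertex tie any optimal line may be returned.

`convergence_summary()` evaluates the fitted $\tau = 0.9$ and $\tau = 0.1$
lines at the observed extremes of baseline complexity and reports the
inter-quantile spread at each end and their difference (positive =
convergence: response variance shrinks as baseline complexity grows). Raw
quantile fits may cross; predictions are monotone-rearranged across the
$\tau$ ladder at each evaluation point before spreads are taken, so
reported spreads are never negative — the rearrangement is applied at
reporting time only and the raw coefficients are untouched.

## The synthetic-data generator

Field data of this design are not shipped; `generate_dataset()` produces a
seeded stand-in with the statistical structure the analysis assumes, used
by every end-to-end test. The defaults encode the emulated study design: 24
sites, three treatments (control, medium, high enrichment), 3 plots per
site-treatment, and control richness spanning 19–48 taxa per site.

Each site carries a latent complexity $u \in [0,1]$ (uniform). Control
richness interpolates across the richness band with $u$, and higher-$u$
sites preferentially sample modality-rich species (`generalist_bias`), so
$u$ drives a gradient from simple to complex trait networks. The species
pool (140 species over 26 modalities: 8 REG, 5 REC\_e, 4 REC\_i, 5 RES\_e,
4 RES\_i — a size and category balance typical of benthic trait tables)
draws each modality independently with probability
$\sqrt{(1+r)/n_{\mathrm{species}}}$, so a modality pair is shared by $1+r$
pool species in expectation; the redundancy default $r = 2.5$ yields
networks that are connected but not saturated. Every species is forced to
bear at least one REG modality (a species with no regulating trait has no
place in an effect-trait network), which intentionally inflates REG margins
above the pairwise-sharing calibration.

Stress acts by species loss — the response mode documented for moderate
nutrient enrichment of sediments, which reduces richness without
defaunation — not abundance decline, since every downstream statistic is
presence-based. A species' loss probability at a site is
$\min(b_\ell \cdot m_s \cdot \beta_k, 1)$: the level's base rate
($b_{\mathrm{med}} = 0.12$, $b_{\mathrm{high}} = 0.35$), a site-level
lognormal multiplier $m_s$ with scale
$\sigma(u) = \sigma_0 (1 - d\,u)$ ($\sigma_0 = 0.8$, decay $d = 0.85$), and
$\beta_k = 2$ for species bearing a resistance-inhibiting modality. The
decay term makes complex sites respond less variably — the variance
structure the quantile analysis is designed to detect; setting
`variance_decay = 0` removes it. Medium enrichment additionally admits
opportunist colonisers at an expected rate of 6% of control richness
(scaled to community size so small sites are not swamped), letting medium
treatments sometimes *gain* connections. Per-site PAR (decreasing in $u$)
and porewater ammonium (increasing in $u$) covariates are emitted for
descriptive plots only; no analysis stage consumes them.

What the generator does *not* emulate: spatial structure, abundance
dynamics, trait-dependent colonisation order, or any biogeochemistry.
Passing pattern-recovery tests on this generator shows the pipeline detects
the constructed structure; it does not validate the ecological model on
real communities.

### A limitation worth knowing

Even with `variance_decay = 0`, replicate runs show a residual positive
bias in the quantile-spread difference (sign fraction ~0.8 over 20
replicates, mean +0.29 vs +0.34 with decay on). The analysis itself
manufactures some variance convergence: simple networks sit near the
$E \ge 1$ retention threshold, so their count metrics react more variably
to species loss, and the pooled eigencentrality couples the complexity axis
to treatment outcomes. Interpreting observed convergence as purely a
response-variance phenomenon therefore overstates it; part is intrinsic to
presence-based trait networks along a richness gradient.

## Numerical choices and degenerate inputs

* Co-occurrence combinatorics via `lchoose` sums: exact-in-double for
  $N \lesssim 1000$; infeasible counts get probability 0, and an observed
  count outside the feasible range is an error, not a 0.
* The pooled eigencentrality returns all-zero scores only when every
  network is empty, which is an error; an empty *individual* network has
  mean complexity 0 with a warning.
* t-tests refuse samples smaller than 2 or with zero variance rather than
  returning infinities.
* Quantile fits refuse degenerate regressors (all $x$ equal) and fewer than
  3 points; ties between optimal vertex lines are broken arbitrarily and
  only the loss is contractual.
* All generator randomness flows from the single config seed (two
  decoupled streams: species pool, and communities) so datasets are
  byte-reproducible from `(config, seed)`.

## Problem sizes used in the shipped checks

The test suite exercises the co-occurrence model exhaustively to $N = 8$
against enumeration, the eigencentrality solver against dense
eigen-decompositions on all labeled connected graphs to 5 nodes plus seeded
random graphs of 6–8 nodes, the t statistics against direct arithmetic on
100 random fixtures, quantile fits against a dense grid oracle on fixtures
of up to 20 points, and the full pipeline on 20 seeded generator replicates
per variance condition at the default 24-site design — sizes chosen so the
whole suite completes in a few minutes while still covering every contract.
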
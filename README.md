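# traitnet

Network analysis of biological traits for quantifying community response
diversity and its erosion under stress.

Ecological communities absorb stress through *response diversity*: when the
species sustaining an ecosystem function differ in their resistance and
recovery strategies, the function has many routes to persist. traitnet
turns species-by-trait data and community samples into **trait
co-occurrence networks** and analyses how their architecture responds to an
experimental stressor (here, the motivating design is sediment nutrient
enrichment at many intertidal sites, but nothing in the package is specific
to it). It is aimed at community ecologists working with biological traits
analysis (BTA) data: a taxa × trait-modality table and per-plot abundance
records.

## The model

For one community of $N$ species, trait modalities are nodes and an edge
joins modalities $i$ and $j$ when species share them. With $N_i$ and $N_j$
bearers, the shared count under random membership is hypergeometric,

$$P(Q=q) = \binom{N_i}{q}\binom{N-N_i}{N_j-q}\Big/\binom{N}{N_j},
\qquad E[Q] = N_i N_j / N,$$

and a pair becomes an edge only if $E[Q] \ge 1$ and $Q_{\mathrm{obs}} \ge 1$;
the edge weight is $Q_{\mathrm{obs}}$, the number of species bearing both.
Modalities are tagged REG (ecosystem-regulating), REC_e/REC_i
(recovery-enhancing/-inhibiting) and RES_e/RES_i (resistance variants), so
REG~REC_e and REG~RES_e edge counts index response diversity directly.

Network *complexity* is summarised as mean node eigenvector centrality,
computed on a single pooled graph containing every site-treatment network
as its own component (centrality is relative, so cross-network comparison
requires one graph). Stress responses are then analysed as effect sizes —
each metric's treatment value divided by its control value at the same
site — with one- and two-sample t-tests, and quantile regressions
($\tau = 0.1, \dots, 0.9$) of effect size on baseline (control) complexity
that reveal whether response *variance* shrinks as baseline complexity
grows.

A seeded synthetic-data generator emulates the multi-site enrichment
design (24 sites × control/medium/high × 3 plots, 19–48 taxa per site)
with a built-in complexity gradient and a species-loss stress model, so
the full pipeline is testable without field data. See the methods
vignette (`vignettes/trait-networks.Rmd`) for the model details and every
tunable default.

## Worked example

```r
library(traitnet)
library(dplyr)

dat <- generate_dataset(nat_config(seed = 42, n_sites = 6))
res <- run_nat(dat$traits, dat$community)

res$metrics
#> # A tibble: 18 × 7
#>   site   treatment n_nodes n_connections n_reg_rece n_reg_rese
#> 1 site01 control        26           254         32         22
#> 2 site01 high           25           171         22         11
#> 3 site01 medium         26           219         24         24
#> 4 site02 control        24           211         22         23
#> 5 site02 high           10            11          0          3
#> 6 site02 medium         24           155         19         20
#> # … mean_eigencentrality <dbl>
```

One row per site-treatment network: site01 (a complex network, baseline
complexity 0.83) barely changes under enrichment, while site02 (baseline
complexity ≈ 0) collapses from 211 connections to 11 under high nutrients.
The effect sizes make that contrast explicit:

```r
res$effects %>% filter(metric == "n_connections")
#> 1 site01 high   n_connections 0.673            0.829
#> 2 site01 medium n_connections 0.862            0.829
#> 3 site02 high   n_connections 0.0521           0.0000269
#> 4 site02 medium n_connections 0.735            0.0000269
```

Values below 1 are losses relative to control. Across sites, high
enrichment significantly reduces connection counts (mean effect 0.25,
one-sample t vs 1: p = 0.0004) and differs from medium (p = 0.005):

```r
tidy(res$tests) %>% filter(metric == "n_connections")
#>   metric        comparison     estimate statistic    df  p_value     n
#> 1 n_connections high vs 1         0.252     -8.28  5    0.000420     6
#> 2 n_connections medium vs 1       0.722     -2.96  5    0.0315       6
#> 3 n_connections medium vs high    0.469      3.60  9.98 0.00488     12
```

Finally, the quantile-regression summary shows variance convergence: the
spread between the 90th and 10th quantile lines of effect size is wide at
low baseline complexity and narrow at high,

```r
res$convergence %>% select(metric, spread_at_min, spread_at_max, spread_difference)
#>   metric        spread_at_min spread_at_max spread_difference
#> 1 n_connections         0.819        0.189              0.630
#> 2 n_nodes               0.797        0.0385             0.758
#> 3 n_reg_rece            2.00         0.0625             1.94
#> 4 n_reg_rese            1.11         0.591              0.520
```

i.e. simple networks respond unpredictably to enrichment while complex
ones respond little and consistently. `autoplot(res, "effects")` and
`autoplot(res, "convergence")` draw the corresponding box plots and
quantile-line figures, and `write_nat_results(res, "out/")` exports every
table, GraphML network files and a JSON run manifest.

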
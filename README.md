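# floodnet

Multi-scale analysis of epilithic biofilm microbiomes in riverine
floodplains: who lives where across nested spatial scales (biome >
floodplain > lateral zone > habitat), which environmental gradients sort
taxa, and how community-wide co-occurrence structure reorganises under
nitrogen limitation.

The package is written for microbial ecologists working with 16S-derived
count tables from hierarchical field designs. It implements, as one
tested chain:

- **Table preparation** — prevalence/read-count filtering (taxa in < 25%
  of samples or with < 20 reads removed), seeded rarefaction to a common
  depth, family-level collapse with guild tags.
- **Flow predictability** — Colwell's decomposition of a daily discharge
  series into constancy *C* and seasonality (contingency) *M*,
  `P = C + M` with `C = 1 − H(Y)/log s` and
  `M = (H(X)+H(Y)−H(XY))/log s` over the month-by-flow-class table, with
  year-block bootstrap CIs.
- **Diversity** — Shannon *H′*; Baselga partition of pairwise and
  multi-site beta diversity into turnover and nestedness
  (β_sor = β_sim + β_sne, and the abundance-based Bray–Curtis analogue);
  SCBD/LCBD contributions; guild read fractions.
- **Ordination** — NIPALS PCA (missing-cell tolerant), floodplain
  environmental heterogeneity as dispersion about group centroids,
  Bray–Curtis NMDS, ANOSIM, environmental vector fitting.
- **Scale partitioning** — REML variance components across the nested
  design; db-MEM spatial eigenvectors (MST-truncated PCoA); forward
  selection with double stopping; adjusted-R² partition of community
  variation into environment-unique, shared, space-unique and residual
  fractions.
- **Co-occurrence networks** — C-score screening against a fixed-fixed
  swap null; networks from Pearson correlations of read fractions
  (|r| ≥ 0.6, p ≤ 0.01); degree, Wasserman–Faust closeness, Brandes
  betweenness; greedy Newman modularity `Q = Σ(e_ii − a_i²)`; keystone
  taxa as nodes above the 75th percentile of all three centralities;
  zone-resolved edge tallies.
- **A synthetic-data generator** with full ground truth (nested
  environmental variance, three sub-biome N:P regimes, cyanobacterial
  niche slopes, latent co-abundance modules, flow regimes), so every
  stage is verifiable without field data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated ten-floodplain landscape (three nitrogen-limited montane,
three nitrogen-rich montane, four grassland floodplains; 114 biofilm
samples):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_flow_predictability.R
Rscript analysis/03_diversity.R
Rscript analysis/04_ordination.R
Rscript analysis/05_scale_partitioning.R
Rscript analysis/06_networks.R
```

Stage 2 prints the flow contrast — dam regulation strips the snowmelt
seasonality out of the discharge series:

```
Colwell seasonality M by flow regime:
        regime     M
1       dammed 0.078
2 free-flowing 0.715
M vs habitat diversity: r = 0.55 (p = 0.0964, n = 10)
```

Stage 3 shows species sorting of the cyanobacterial guild along the
nitrogen-to-phosphorus gradient, and turnover-dominated beta diversity:

```
Shannon H ranges 1.86-3.66 across floodplain means
Multi-site Sorensen 0.08-0.44; turnover carries 76% of it
Cyanobacterial fraction vs log N:P: r = -0.74 (p = 4.94e-21)
```

Stage 6 builds one co-occurrence network per sub-biome. Under nitrogen
limitation the network is sparser, carries a large negative-association
share (competition/resource partitioning), and is far more modular:

```
             group n_samples nodes edges pct_negative modularity keystones
 montane-n-limited        54    64   116     23.27586  0.7551278         5
    montane-n-rich        36    84   826      0.00000  0.4113416         5
         grassland        24    86   694      0.00000  0.4251748         5
```

The same chain is available in code via `run_pipeline()`, a pure
function of (inputs, config, seed) whose every stochastic stage receives
a recorded sub-seed.

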
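---
title: "Niche partitioning and co-occurrence networks in floodplain biofilms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche partitioning and co-occurrence networks in floodplain biofilms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

floodnet analyses epilithic biofilm communities sampled across a nested
riverine-floodplain design — biomes containing floodplains, floodplains
containing main-channel and off-channel zones, zones containing habitat
types — together with water chemistry, site coordinates and daily river
discharge. This vignette documents the models and procedures, the choices
made where the design was genuinely open, and what the synthetic study the
package ships with does and does not demonstrate.

## The analysis chain

**Table preparation.** OTU-level count tables are filtered (a taxon is
removed when it occurs in fewer than 25% of samples or carries fewer than
20 reads; the two conditions combine as OR-removal by default, with an
AND option), rarefied once to a common depth (default 10,000 reads,
single seeded draw without replacement — multiple-draw averaging changes
little and breaks integer counts), and collapsed to family-level rows by
summing counts over taxa sharing the family label. Guild tags
(heterocystous cyanobacteria, other cyanobacteria, diatoms) propagate
through collapse when unanimous. The prevalence rule is applied globally
across the table; a per-group application would interact with rarefaction
dropouts and is left to the caller by pre-subsetting.

**Flow predictability.** Colwell's decomposition classifies monthly mean
discharge into time states (calendar months) and flow classes
(`floor(log2(q/mean q))`, which makes the classification scale-free) and
computes constancy `C = 1 - H(Y)/log s`, contingency
`M = (H(X) + H(Y) - H(XY))/log s` and predictability `P = C + M` from the
entropies of the month-by-class table. The source material does not state
the time resolution or binning; monthly states with log2 classes are the
classical convention and both are arguments. Uncertainty for `M` comes
from resampling whole years with replacement (999 replicates), which
preserves within-year seasonal structure; percentile 95% intervals are
reported.

**Diversity.** Alpha diversity is Shannon H (natural log). Pairwise and
multi-site beta diversity follow Baselga's partition: in incidence mode
Sørensen dissimilarity splits into Simpson turnover and a nestedness
remainder; in abundance mode Bray–Curtis splits into balanced-variation
and abundance-gradient components built from the per-taxon shared and
unshared abundance sums. The identity total = turnover + nestedness holds
to machine precision by construction and is asserted in the tests on
random tables. Per-taxon (SCBD) and per-sample (LCBD) contributions to
beta diversity come from the column/row sums of squares of the centred,
Hellinger-transformed abundance matrix; the transform is an argument.

**Ordination.** Environmental PCA uses NIPALS — alternating least squares
per axis with deflation — because the chemistry tables of such studies
routinely contain missing cells; on complete matrices it agrees with the
SVD to 1e-8 (tested). Sign is fixed by making each axis's largest
absolute loading positive. Environmental heterogeneity per floodplain is
the mean and CV of the distance from each site's scores to the floodplain
centroid. Community ordination is Bray–Curtis NMDS (k = 2, 20 starts,
best stress kept, configuration centred and rotated to principal axes;
vegan's monoMDS engine does the isotonic-regression optimisation).
ANOSIM and the environmental-vector fitting are authored in the package —
the rank statistic `R = (mean between - mean within)/(n(n-1)/4)` with an
exhaustive-enumeration option used by the tests, and least-squares vector
fitting with permutation p-values — so that vegan's implementations can
serve as independent cross-checks rather than as the code under test.
Permutation p-values everywhere use the `(b+1)/(m+1)` estimator.

**Scale partitioning.** Variance components for each (log-transformed)
chemistry variable are estimated by REML (lme4, bobyqa with a tight
convergence radius so balanced designs reproduce the method-of-moments
estimators to 1e-6) under a fully random nested model
biome / floodplain / zone / habitat + residual, and reported as
percentages. The biome level has only two units in a study-like design;
its variance is weakly identified, is flagged `low_replication`, and in
simulations absorbs a noticeable share whenever the handful of floodplain
means happen to differ between biomes — reading it as anything more than
a screening quantity is discouraged. Spatial predictors are distance-based
Moran eigenvector maps: Euclidean distances truncated at the longest
minimum-spanning-tree edge (distances beyond it set to four times the
threshold), double-centred, eigendecomposed, positive-eigenvalue vectors
kept. db-MEMs are built jointly across floodplains, matching the use of
geography as a regional predictor. Forward selection uses Blanchet's
double stopping rule with one deliberate deviation: the adjusted-R²
ceiling applies from the second step onward. At step 1 the expected gap
between the global model's adjusted R² and that of a single true
predictor is zero, so a step-1 ceiling rejects a lone genuine predictor
about half the time; the global permutation gate (selection is abandoned
unless the full model is significant) already protects that step. The
environment-versus-space partition is computed from the adjusted R² of
the env, space and joint RDAs; unique fractions may be slightly negative
and are reported as computed.

**Co-occurrence networks.** Before network inference each group is
screened with a C-score test: the mean checkerboard score over taxon
pairs compared with a fixed-row, fixed-column null generated by
sequential checkerboard swaps (burn-in, then thinned samples), with a
two-sided permutation p-value. The screen is reported, not used as a
gate. Networks connect family pairs whose Pearson correlation of read
fractions satisfies |r| ≥ 0.6 with a t-test p ≤ 0.01 (two-sided; the
boundary is inclusive on both thresholds). No compositional transform and
no multiple-testing correction are applied by default, matching the
field-standard construction; CLR and Benjamini–Hochberg options exist
but are off. Node metrics are degree, Wasserman–Faust closeness (scaled
by component reachability so values are comparable in the disconnected
graphs these thresholds produce) and Brandes betweenness normalised by
`(n-1)(n-2)/2`. Modules maximise Newman modularity by greedy
agglomeration (Louvain optional); modules under 2.5% of nodes are flagged
small. Keystone taxa are nodes strictly exceeding the within-network 75th
percentile (linear-interpolation quantile) of all three centralities.
Zone affinity of a node is the floodplain zone where its mean read
fraction is higher, feeding the same-zone/cross-zone edge tallies.

## The synthetic study and its ground truth

The generator exists so every stage can be tested against known truth.
Its defaults encode the study conditions: ten floodplains (3 N-limited
montane, 3 N-rich montane, 4 grassland), both lateral zones, three
habitat units per zone with 1–3 replicate samples (group sizes 54, 36 and
24 samples), ten chemistry variables whose log-scale variance is split
across biome/floodplain/zone/habitat/residual according to a fixed
fraction table (e.g. dissolved organic carbon 0/63/4/13/20), molar N:P
regimes centred on 1.8, 12.7 and 30.7 by shifting total phosphorus, and
90 taxa with log-normal baselines, niche slopes (heterocystous
cyanobacteria at −1 on standardised log N:P, other cyanobacteria at
−0.5), latent-factor co-abundance modules, zone-affinity offsets, and
multinomial read sampling at log-normal depth (median 20,000).

Three generator choices deserve explanation because they were forced by
the arithmetic of read fractions rather than by convenience:

* **Latent factors are binary bloom states (±1), not Gaussian.** A
  Gaussian factor passed through the exponential link produces strongly
  right-skewed abundances, and the Pearson correlation between `e^W` and
  `e^-W` is bounded well above −1 (about −0.37 for unit-variance Gaussian
  W); anti-correlated log-abundances therefore cannot reach the −0.6 edge
  threshold on the fraction scale. A two-state driver transmits both
  positive and negative associations essentially undamped, the way
  bloom/no-bloom regime shifts do in real assemblages.
* **Dense all-positive networks arise through closure, not through a
  shared factor.** A factor loading positively on most taxa cancels in
  the read-fraction denominator. The N-rich and grassland presets instead
  include a few dominant "suppressor" taxa whose independent blooms absorb
  read share; when they wane, every other taxon's fraction rises together,
  producing the dense, almost entirely positive, weakly modular networks.
  Each dominant has its own bloom factor so no single dominant's
  anti-correlation with the rest crosses the threshold.
* **Negative edges ride on a single binary axis.** In the N-limited
  preset module loadings are mixed-sign on one strong binary factor
  (loading 1.1) with a small zone offset (0.2); spreading the opposition
  over two independent binaries re-introduces the skew bound and caps
  negative correlations near −0.59.

Unstructured taxa additionally carry habitat-unit-level occupancy
(presence probability 0.8, shared by replicates of a unit), which is what
creates realistic Sørensen dissimilarity (~0.1–0.45 per floodplain) and
its turnover-dominated partition; module and dominant taxa are never
dropped, so network ground truth is unaffected. Habitat types are drawn
with regime-dependent evenness — free-flowing floodplains sample types
nearly uniformly, dam-regulated ones from a skewed distribution — so
habitat diversity co-varies positively with flow seasonality. Flow series
are daily log-discharge with a snowmelt harmonic (amplitude 1.2) plus
AR(1) noise for free-flowing rivers, versus a nearly flat harmonic
(0.15) plus irregular square release pulses for regulated ones. The
`null` preset removes all niche, module, zone and occupancy structure and
is used for type-I checks.

What passing the synthetic suite shows: the estimators recover the
quantities the generator encodes, at study-like sample sizes, under
multinomial read noise and compositional closure. What it does not show:
robustness to the long-tailed richness of real 16S tables (90 families
versus hundreds), to sequencing-platform artefacts, to spatial
autocorrelation of chemistry beyond the nested design, or to non-Pearson
dependence structures; the fraction-scale correlation thresholds in
particular behave differently when thousands of rare taxa are present.

## Numerical choices and degenerate inputs

Rarefaction drops (and names) samples below depth; an all-zero sample's
Shannon H is missing, not zero. Colwell's `C` is defined as 1 when a
series occupies a single flow class; a degenerate class structure with
varying flow raises an error. ANOSIM requires two members per group;
exhaustive enumeration is used for n ≤ 8. NIPALS convergence is a 1e-9
relative change in the score vector with a 500-iteration cap per axis.
The C-score null uses 5,000 burn-in swap attempts and 100-attempt
thinning by default; taxa present everywhere or nowhere are excluded with
a warning since swaps cannot move them. Keystone detection needs at least
4 nodes. Variance-component percentages are renormalised after truncating
estimates at zero. Fractions in the variance partition are reported as
computed even when slightly negative, with the offending fractions named.

Problem sizes throughout the tests and the acceptance script — 90 taxa,
114 samples, 199–999 permutations, 10–50 replicate simulations — are the
package's chosen scaled-down study conditions: large enough that every
directional claim is stable across seeds, small enough that the whole
verification suite runs interactively.

## Reproducing the full analysis

The numbered scripts under `analysis/` run the study end to end on the
synthetic inputs (`01_simulate.R` writes them; the later stages read,
prepare, and analyse), writing tables under `results/`. The same chain is
available programmatically through `run_pipeline()`, which derives a
recorded sub-seed for every stochastic stage from one global seed and is
byte-reproducible given (inputs, config, seed).
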
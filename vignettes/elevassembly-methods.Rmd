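---
title: "Methods: inferring community assembly along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring community assembly along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevassembly)
```

## The scientific problem

Soil bacterial communities on mountainsides turn over with elevation, and the
central inferential question is *why*: how much of the turnover reflects
deterministic environmental filtering (soil pH, vegetation, climate selecting
community members) and how much reflects spatial processes such as dispersal
limitation. elevassembly implements the full statistical chain used to answer
that question from an OTU table, sample metadata, and a phylogeny:

1. α-diversity (richness, Faith's PD) with rarefaction;
2. β-diversity (Jaccard, Bray–Curtis) with ordination (PCoA, NMDS, CCA,
   dbRDA) and permutation tests (PERMANOVA, ANOSIM, MRPP, Mantel, PERMDISP,
   Kruskal–Wallis with rank-based multiple comparisons);
3. a richness-conserving null model yielding β-deviation z-scores — the
   β-diversity left after α-diversity differences are controlled;
4. PCNM spatial eigenvectors, forward selection, and four-fraction variation
   partitioning of the β-deviation into pure environmental \[a\], shared
   \[b\], pure spatial \[c\] and residual \[d\] adjusted-R² fractions, with a
   bootstrap test comparing \[a\] and \[c\];
5. a PLS path model propagating climate effects through vegetation and soil
   to community structure.

Because the raw study data of any particular survey are upstream products of
sequence processing pipelines, the package ships a synthetic gradient
generator with known ground truth; every stage is tested against it and
against independent oracles (exhaustive enumeration, dense eigendecomposition,
closed forms, and the reference implementations in vegan/picante).

## The synthetic gradient generator

`gradient_scenario()` encodes the study design the analyses assume: 12 sites
at ~200 m elevational intervals spanning 1800–4100 m, 8 soil samples per
site (96 samples), a regional pool of 1500 OTUs, soil pH spanning 7.23 at
the bottom to 3.53 at the top with an abrupt drop between 2600 and 2800 m
(so pH 6.0 separates the lower from the higher section), five vegetation
types in elevational bands, and monotone climate covariates (MAP increasing,
MAT and soil temperature decreasing, deterministically at site level). Sites
sit on a ~14 km north–south transect, about 7 km per elevational section;
geographic distances are haversine on a 6371 km sphere.

Community structure arises from three *separable* channels, so that
variation-partitioning ground truth is known by construction:

* **Environment**: each OTU has a pH optimum drawn uniformly over the pH
  range and a Gaussian niche of width `env_filter_strength` (σ, pH units;
  default 0.5, a moderate filter — 0.25 is a strong one, `Inf` disables the
  channel).
* **Vegetation**: each OTU prefers one vegetation type; elsewhere its
  abundance is multiplied by `vegetation_affinity` (default 0.4; 1 disables).
* **Space**: an exponential kernel `exp(-d / spatial_decay_range_km)` on the
  distance to an OTU-specific home location (default e-folding range 15 km,
  a weak-to-moderate spatial signal; `Inf` disables).

Expected relative abundances are the product of a lognormal base abundance
(meanlog 0, sdlog 1.2 — a realistic rank-abundance skew) and the three
kernels, row-normalised; counts are multinomial at a uniform depth of 2000
reads per sample, so each sample total equals the depth exactly and
rarefaction is an identity by default (a depth-jitter option exercises it).

What the generator deliberately does **not** emulate: a systematic richness
decline with elevation (pH optima are uniform, so α-diversity is roughly
flat), phylogenetically conserved niches (the coalescent tree is independent
of the pH optima), read-depth artefacts, and taxonomic structure. Passing
tests therefore demonstrate that the *inference machinery* recovers known
structure — not that any particular field system behaves this way.

`simulate_sem_data()` plays the same role for the path model: latent scores
follow a recursive linear system with variance-completing residuals (so the
supplied coefficients are standardized path coefficients and every latent
has unit population variance), and each latent gets manifest indicators
`loading * latent + noise_sd * e` (defaults: loadings 0.9/0.8, indicator
noise 0.1 — high reliability, so PLS attenuation stays ≪ the ±0.05 recovery
band).

## Diversity choices

* **Faith's PD** uses the rooted convention: the minimal subtree connecting
  a sample's OTUs *and the root*, so a single-taxon sample has PD equal to
  its root-to-tip path. This matches the common default of the standard PD
  implementations and makes PD monotone under adding taxa.
* **Jaccard** comes in two flavours because field usage is ambiguous:
  presence/absence (`jaccard_binary`, the default for community-structure
  testing and the only meaningful choice for the null model, whose
  randomised communities carry no abundances) and the abundance-weighted
  Ružička form (`jaccard_abundance`), which on relative abundances equals
  `2B/(1+B)` for Bray–Curtis `B`.
* **Distance decay** regresses similarity (1 − dissimilarity) on geographic
  distance untransformed, by OLS, separately within the lower and higher
  sections (threshold 2700 m, the midpoint of the pH regime change,
  user-overridable).

## The null model and β-deviation

The regional pool is every OTU observed in any sample. For each of 999
iterations (default) and each sample, a species set of exactly the observed
richness is drawn without replacement, with probability proportional to each
species' occupancy frequency across samples (the classical richness- and
occupancy-conserving randomisation; equiprobable and abundance-weighted
variants are selectable). One shared ensemble serves all pairs. Per pair,

> z = (J_obs − mean J_null) / sd J_null,

with J the presence/absence Jaccard similarity; pairs with zero null SD are
flagged as undefined rather than inflated. Positive z means the two
communities share more species than expected given their richness — the
signature of common environmental filtering.

**Observed-versus-null dispersion (the per-site test).** For each site, the
observed members are pooled with an equally sized set of their own null
communities (one ensemble iteration), Jaccard distances computed, samples
embedded by principal coordinates keeping real and imaginary parts, and
distance-to-centroid values compared by an ANOVA F. The p-value uses a
*paired* permutation: each sample's observed and null community share its
richness by construction, so the permutation independently swaps the two
members of each pair and recomputes the centroid distances. Two design
points matter here:

* permuting the distance-to-centroid *values* (rather than group
  memberships) is badly conservative, because distances to a shared centroid
  are positively correlated within a group;
* permuting labels *freely* (ignoring the pairing) over-disperses the null,
  because a free relabelling can concentrate both members of high-richness
  pairs in one group.

With the paired swap the test is exact under exchangeability; calibration
simulations in the test suite confirm a rejection rate of about 0.05 at
α = 0.05 when the "observed" table is itself a null draw. The generic
`permdisp()` (groups of real samples, no pairing) permutes group labels and
recomputes centroid distances, for the same reason.

## Ordination and variation partitioning

* **PCoA** eigendecomposes the double-centred −½D² matrix; negative
  eigenvalues are reported and their axes discarded (no correction by
  default; Cailliez is available by flag).
* **NMDS** minimises Kruskal stress-1 by alternating isotonic regression
  (primary tie handling) with Guttman-transform updates, from one PCoA start
  plus 20 random starts, up to 300 iterations per start, stopping when the
  stress change falls below 1e-7. The best configuration is centred, rotated
  to principal axes, and scaled to unit RMS. On small problems the attained
  stress matches vegan's metaMDS to ~1e-6.
* **PCNM** truncates the geographic distance matrix at the longest minimum-
  spanning-tree edge, replaces larger distances by four times the threshold,
  and keeps the orthonormal eigenvectors with positive eigenvalues.
* **dbRDA** regresses the positive-eigenvalue PCoA axes on predictors;
  R² is constrained over total inertia in that space. β-deviation matrices
  (which may be negative) are first reflected: d′ = max(z) − z with a zero
  diagonal, so that higher-than-expected similarity becomes smaller
  distance; the applied shift is recorded on the result.
* **Forward selection** implements the double-stopping rule: a candidate
  enters only if its marginal permutation p ≤ α (999 permutations, α = 0.05
  by default) *and* the cumulative adjusted R² does not exceed the global
  (all-candidate) adjusted R². A significant global pre-test is required
  before any candidate is considered. One documented edge: with strongly
  collinear candidates a single variable's adjusted R² can exceed the
  junk-penalised global model's, so the ceiling can stop selection
  immediately; the acceptance pipeline then falls back to the best single
  candidate, since a significant full model should not reduce to an empty
  one.
* **Variation partitioning** computes adjusted R² (Ezekiel) for the
  environmental, spatial, and joint models; fractions follow by subtraction
  and satisfy a+b+c+d = 1 to 1e-10 by construction.
* **The bootstrap fraction test** resamples samples with replacement
  (default 999 replicates), recomputes the pure fractions a and c on each
  resample of the distance matrix and predictor rows, and reports the
  two-sided p = 2·min(P(a−c ≤ 0), P(a−c ≥ 0)). Degenerate resamples (too few
  distinct samples to fit the models) are redrawn with a capped retry count.
  The statistic, resampling unit and sidedness are this package's
  definitions, stated here because bootstrap procedures for fraction
  comparisons are not standardised.

## Permutation test conventions

All random-permutation p-values use the add-one convention
(b+1)/(m+1), so p has resolution 1/(m+1) and never reaches zero — at 999
permutations the smallest reportable value is 0.001. PERMANOVA is the
one-factor pseudo-F from squared dissimilarities; ANOSIM uses the rank-based
R with denominator n(n−1)/4; MRPP weights group mean within-distances by
n_i/N and estimates the chance-corrected A against the permutation mean.
For n ≤ 7 each test also offers complete label enumeration (`exhaustive =
TRUE`), where p is the exact proportion over all n! permutations (the
identity included). Kruskal–Wallis reports the tie-corrected H with a
chi-square p by default and an exact enumeration p on request; its multiple
comparisons use the rank-based critical-difference procedure with a normal
critical value, Bonferroni-adjusted over the k(k−1)/2 pairs.

## The PLS path model

`fit_plspm()` implements the classical iterative algorithm with reflective
(mode A) outer estimation and the path weighting scheme — the standard
defaults of the methodology — with globally standardised manifests.
Convergence requires the maximum outer-weight change to fall below 1e-7
within 300 iterations (non-convergence is an error, not a silent result).
Path coefficients are OLS regressions of each endogenous latent score on its
predecessors; GOF is √(mean communality × mean R²), with values above 0.7
conventionally acceptable. On single-indicator blocks the whole procedure
reduces exactly to classical path analysis on standardised variables, which
the tests verify to 1e-8. Bootstrap resampling (default 999 in analyses;
199 in the acceptance pipeline for speed) gives standard errors, percentile
intervals, and a significance flag per path. Latent and NMDS axis signs are
intrinsically arbitrary; the acceptance pipeline orients NMDS axes along
increasing elevation so path signs are reproducible across seeds.

## Problem sizes used by the test suite

The suite exercises every stage at sizes chosen to make the Monte Carlo
assertions sharp while keeping a full run around two minutes: null-model
self-consistency uses 100 runs × 999 iterations on 12 samples × 80 OTUs;
filtering detection uses 100 runs of a 2-site × 8-sample scenario with
σ = 0.25; variation-partition recovery uses 100 runs of a 4-site scenario
with spatially shuffled pH (an orthogonalised design, so the environmental
channel carries no spatial structure); type-I calibration uses 500
simulations × 199 permutations per test; PLS-PM recovery uses 100 seeds at
n = 500 with generating paths (0.6, 0.5, 0.4, 0.49, 0.54). The acceptance
script runs the full default scenario (96 samples × 1500 OTUs, 999
iterations/permutations/bootstraps) in a few minutes.

## Known limitations

* The null model conserves per-sample richness and species occupancy but not
  per-species abundance structure; abundance-preserving swap algorithms are
  out of scope.
* dbRDA discards negative-eigenvalue axes; for strongly non-Euclidean
  dissimilarities the reported fractions refer to the positive-eigenvalue
  subspace (a Cailliez correction is available in `pcoa()` but is not the
  default).
* The generator's channels are independent by design; real gradients
  confound pH, vegetation and space, which is why the pipeline's shared
  fraction \[b\] typically dominates on the default (confounded) transect
  and only an orthogonalised design recovers a dominant pure-env fraction.
* PLS-PM assumes linear latent relations and reflective indicators;
  covariance-based SEM is out of scope.
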
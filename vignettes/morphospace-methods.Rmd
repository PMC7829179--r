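---
title: "Morphospace methods: indices, null models, and the packing/expansion decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphospace methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphospace)
```

## The problem

Fern assemblages sampled along tropical elevational transects differ
enormously in species richness, and most functional diversity indices
respond mechanically to richness.  This package implements a pipeline
that (i) embeds mixed-scale morphological traits in a common
morphospace, (ii) quantifies the volume, evenness, and density of each
elevational assemblage's occupation of that space, (iii) removes the
mechanical richness effect with a trait-label randomization null model,
(iv) asks whether the traits carry phylogenetic signal, and (v)
decomposes richness differences between adjacent elevational bands into
morphoniche *expansion* (new species requiring more trait volume) and
*packing* (new species accommodated inside the existing volume).

## Trait space

Five resource-acquisition morphotraits are modelled: rhizome type
(categorical, codes 0–3), laminar dissection (ordinal, 0–2), laminar
texture (ordinal, 1–3), laminar length (continuous, cm), and hydathodes
(binary).  Pairwise dissimilarity is Gower's coefficient with equal
trait weights: categorical and binary traits score 0/1 (binary traits
symmetric by default — joint absence counts as similarity, switchable
with `binary_asymmetric`), ordinal traits use absolute code differences
normalized by the declared domain range (the codes *are* the measurement
scale, so they are not re-ranked within a sample), and continuous traits
use absolute differences over the observed range.

Laminar length is approximately log-normal across species.  On the raw
scale, range normalization lets a few very long-bladed species compress
almost all other pairwise length differences toward zero, effectively
deleting the trait from the analysis.  `gower_dissimilarity(...,
log_length = TRUE)` log-transforms length first; the analyses in this
vignette, the test suite's calibration experiments, and the acceptance
script all use the log scale, while the function default remains the raw
scale so the choice is always explicit.

Principal coordinates analysis (`trait_pcoa`) is classical metric
scaling via `stats::cmdscale`.  Gower matrices are generally
non-Euclidean, so negative eigenvalues occur; they are discarded without
Cailliez or Lingoes correction, their count is reported for audit, and
variance fractions are expressed relative to the positive part of the
spectrum.  Indices use the first five axes by convention; the
two leading axes are used for the kernel hypervolume and the
phylogenetic-signal tests.

## Functional diversity indices

For an assemblage of `S` species embedded as points in `k` axes:

* **FRic** — the exact volume of the convex hull.  General-dimension
  hull volumes are computed by an incremental beneath-beyond
  construction in compiled code (`convhull_volume`); 2-D results match a
  shoelace/`chull` oracle to 1e-10 and rotated unit cubes, simplices and
  cross-polytopes in 3–5 dimensions are recovered exactly.  A hull needs
  `S >= k + 1` points, so `k` is reduced to `min(k, S - 1)` for small
  assemblages and the reduction recorded; affinely degenerate point sets
  return volume 0 with a flag rather than an error.
* **Hyp** — a two-axis Gaussian kernel density estimate (per-axis
  Silverman bandwidths) evaluated on a grid padded by three bandwidths;
  the index is the area of the highest-density region holding 95% of the
  probability mass.  This is a deliberate simplification of
  importance-sampling box-kernel hypervolume algorithms: with two axes a
  dense grid is exact enough (grid refinement from 200^2 to 400^2 moves
  the area by < 2%) and has no stochastic component.  The mass threshold
  and bandwidth are exposed and should be treated as assumptions.  Note
  that areas are additive over well-separated modes only at a *fixed*
  bandwidth: pooled Silverman bandwidths grow with mode separation.
* **FEve** — branch-length evenness of the minimum spanning tree
  (`vegan::spantree`) with equal species weights, as appropriate for
  presence/absence data; 1 when all branches are equal, approaching 0
  for extreme clumping.
* **mNND / sdNND** — mean and standard deviation (n − 1 divisor, so the
  observed and null values are computed identically) of each species'
  nearest-neighbour distance.

## The null model and SES

The null model randomizes species labels on the trait table: richness
patterns, range contiguity, trait co-variances, and the set of realized
phenotypes are all preserved, and only the species-to-phenotype map is
broken.  One global permutation is drawn per replicate and shared by all
assemblages.  Because Gower + PCoA depend only on trait rows and not on
labels, shuffling labels is equivalent to permuting rows of the observed
ordination; the package proves this equivalence in a test and exploits
it, computing the ordination once (study settings: 5000 replicates per
index, 500 for the hypervolume; the calibration experiments below use
999).  Permutations are drawn sequentially from a single seeded stream,
so a seed fully determines the analysis.

`ses()` reports `(obs - null mean)/null sd` and a two-sided rank
p-value `p = 2 min(r_lo, r_up)/(n + 1)` with `r_lo = 1 + #{null <= obs}`
and `r_up = 1 + #{null >= obs}`, which cannot reach 0 by construction.
When an assemblage contains the entire pool every permutation returns
the same point set; the null standard deviation is then 0 and the SES is
flagged rather than reported.

## The synthetic generator as the testbed

Because the pipeline's field data are not redistributable, the
generator (`sim_config`, `gen_trait_table`, `gen_transect`,
`gen_phylo_bm`, `gen_climate`, `simulate_fourtransects`) produces data
with exactly the structure the analysis assumes:

* traits drawn independently from configurable marginals (length
  log-normal, truncated to 1–600 cm);
* elevational bands of 500 m after an irregular first band (0–400 m),
  four plots per band, species lists pooled per band;
* per-band richness *imposed* by a Gaussian hump (peak height, peak
  elevation, width), because the scientific questions condition on
  richness — four-transect presets reproduce the contrasting magnitudes
  of very rich Andean/New Guinean versus poor Mexican/Ugandan transects
  (pools 343/198/97/76, peaks ~120/62/33/31);
* an environmental-filtering dial `phi`: members of a band are sampled
  with weight `(1 - phi) + phi * exp(-(opt - mid)^2/(2 tau^2))`, where a
  species' optimal elevation follows the rank of a latent morphological
  axis (standardized laminar texture + standardized log length).  At
  `phi = 0` community assembly is independent of traits, which is
  *exactly* the null model's world; at `phi = 1` with `tau = 100` m
  co-occurring species are morphologically similar;
* per-species plot occupancy drawn as 1–4 plots with probabilities
  (0.35, 0.30, 0.20, 0.15), giving a uniques/duplicates structure whose
  Chao2 excess over observed richness is of the field-typical order
  (roughly ten to twenty-five percent, depending on assemblage size);
* pure-birth phylogenies (`ape::rphylo`) with Brownian tip traits
  (`ape::rTraitCont`) for the phylogenetic-signal calibrations.

What the generator does *not* emulate: dispersal limitation, abundance
structure, intraspecific trait variation, correlated trait evolution,
and realistic climate surfaces.  Tests passing on these worlds show the
statistical machinery is correct and calibrated, not that real fern
assemblages behave like the generator.

### Calibration and power

On `phi = 0` worlds (pool 100, per-band richness 10–40, 999 replicates,
200 worlds) the mNND SES is calibrated: mean ~0, standard deviation
~1, and |SES| > 1.96 in ~5% of assemblages.  On `phi = 1`, `tau = 100`
worlds the per-assemblage SES averages about −2.2 but saturates there:
only the texture/length combination carries the filtering signature
while the other three traits stay random, so individual assemblages
reject at roughly 60%.  The power claim is therefore evaluated at the
level of a simulated world, pooling its intervals with a Stouffer
statistic `z = mean(SES) * sqrt(n_intervals)` (whose
`phi = 0` lower-tail rejection is controlled); detection of filtering at
the world level exceeds 80% by a wide margin.  Both the per-assemblage
and the world-level rates are reported by the acceptance script.

## Phylogenetic signal

`blomberg_k` implements the variance-ratio K statistic directly from
the phylogenetic covariance matrix (observed MSE ratio over its
Brownian-motion expectation); it matches an independent implementation
(`picante::Kcalc`) to 1e-10 and averages ~1 over 500 Brownian
simulations on 64-tip pure-birth trees.  Significance (`k_test`)
shuffles taxa labels across tips 999 times and compares the variance of
phylogenetically independent contrasts (`ape::pic`; polytomies resolved
with zero-length branches).  Low observed contrast variance indicates
signal.  A near-zero K can be extreme in either tail, so both
`p_signal` (signal: observed variance low) and `p_anti` (anti-signal)
are reported rather than guessing a direction.  Signal is tested on
PCoA axes 1 and 2 separately (`axis_signal`).

## Packing versus expansion

Between a richer assemblage E1 and a poorer adjacent assemblage E2
(pairs oriented from the transect's elevational extremes toward the
richness peak by `order_packing_pairs`; equal-richness pairs are emitted
with status `"none"`), `decompose_packing` searches for the largest
subset of E1 whose hull volume is at most `V2 (1 + tol)`, with
`tol = 0.01` as the tolerance for "equivalent to or in the vicinity of"
the target volume.  Removed species count as *expansion*; retained
species beyond `S2` count as *packing*; the two always sum to the
richness difference.  Species turnover between bands can make packing
negative (E2's species need not sit inside E1's reduced hull); this is
flagged, not clamped.

The search removes hull vertices (interior points never change the
volume) and is run as a beam over removal orders: at each depth the
`n_starts` lowest-volume candidate subsets are kept, exact ties broken
randomly, and the first subset inside the ceiling wins.  A plain greedy
"remove the vertex that shrinks the volume most", even restarted
hundreds of times with randomized tie-breaks, can end two species short
of the optimum on small random instances, while the beam matches an
exhaustive search over all subsets to within one species on 200 random
instances (S1 <= 12) and exactly on the constructed pure-packing,
pure-expansion and nested-square cases.  Axes are shared per pair with
`k = min(5, S2 - 1)` so both hulls are defined, and recorded.

## Model-comparison layer

The information-theoretic utilities operate on fitted-model summaries
(`model_summary`, or `summarize_fit` for `lm`/`lme4` fits), keeping the
comparison design separate from any particular estimator: `aicc`,
`akaike_weights`, summed-weight `variable_importance` over the
`delta AICc < 2` set (weights renormalized within the retained set by
default, switchable, with the mean marginal R2 attached), and
`nakagawa_r2` for the marginal/conditional variance decomposition of
mixed models.  `predictor_subsets` enumerates dredge-style all-subsets
candidate sets (the study design uses six predictors: species richness,
bryophyte cover, MAT, TS, AP, PS, with transect as a random intercept).

## Numerical choices and limitations

* Elevation bands are half-open `[lower, upper)`, guaranteeing a
  partition; a plot at exactly 400 m belongs to the 400–900 m band.
* Hull computations use tolerances scaled to the coordinate range
  (1e-9 relative) for visibility tests; degenerate inputs return flagged
  zero volumes.
* The problem sizes in the test-suite experiments (200 worlds for
  calibration and power, 500/400 simulations for the K calibrations,
  150/100 worlds in the acceptance script) were chosen to bound Monte
  Carlo error on the reported rates at roughly one percentage point.
* Missing trait values are rejected, not imputed.
* Abundances are binarized everywhere; abundance-weighted index variants
  are out of scope.
* The Chao2 estimator is the bias-corrected incidence form; downstream
  analyses use observed richness only.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_fourtransects(seed = 1, scale = 0.5)
ord <- trait_pcoa(gower_dissimilarity(sim$traits, log_length = TRUE),
                  n_axes = 5)
asm <- bin_plots_to_intervals(sim$community)
fd_indices(asm, ord)
ses(asm, ord, index = "mNND", n_reps = 999, seed = 2)
packing_transect(Filter(function(a) a$transect == "ECU", asm), ord,
                 seed = 3)
```
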
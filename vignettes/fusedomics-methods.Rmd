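---
title: "Methods: paired multi-omics fusion discrimination and microbiome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired multi-omics fusion discrimination and microbiome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusedomics)
```

## The problem and the study design

`fusedomics` implements a discrimination analysis for detecting a covert
chemical treatment of fish (a sodium-citrate/hydrogen-peroxide mixture used
to mask spoilage) from molecular profiles of the animal. The experimental
design it targets is strictly paired: on each sampling day one treated fish
and one control fish are processed together, six days per exposure time
(3 h and 24 h), giving 24 fish across 12 day-pairs; each fish is profiled
at up to four anatomical sites (muscle, skin, gills, eye) on up to three
platforms (lipidomics, metabolomics, proteomics), and three sites are also
characterized by family-level 16S community profiling.

The pairing is the central statistical fact: day-to-day batch variation
(instrument drift, storage time, biological day effects) is shared by the
two members of a pair, so subtracting each day-pair's mean from both its
samples ("day-pair centering") removes it exactly, leaving the within-pair
contrast that carries the treatment signal. Every analysis set is then one
site at one exposure time — 12 samples in 6 day-pairs — or, for the
exploratory factor analysis, one site across both times (24 samples).

## Preprocessing

Preprocessing is fixed as day-pair centering first, then autoscaling
(global centering and unit-variance scaling with the n−1 denominator),
then low-level fusion (column-wise concatenation of the blocks in the
deterministic order lipidomics, metabolomics, proteomics, then others
alphabetically). Autoscaling is applied over the analysis set in scope: the
12 samples of one time × site for discriminant modelling, the 24 samples of
one site for MFA. The population over which to autoscale was a genuinely
open choice; we scale over the full analysis set because the factor
analysis displays all four class groups jointly, and flag it as worth a
sensitivity check on real data. Constant columns are dropped with a warning
rather than imputed — they carry no discriminant information and break
unit-variance scaling. Missing intensities are an error: the method is
defined for complete intensity tables.

## Multiple Factor Analysis

MFA is PCA over the concatenation of variable blocks where each block is
first multiplied by the square root of its weight, the weight being the
inverse of the first PCA eigenvalue of that block alone. After weighting,
every block's first-axis inertia is exactly 1, so no source can dominate
the first dimension by scale or width alone. A single qualitative "classes"
variable (time × treatment, four levels) can be included: its indicator
matrix is rescaled by the inverse square root of each level's proportion
and column-centered (the correspondence-analysis metric for one categorical
variable), then weighted like any other block. We include it as an active
block by default — the block-contribution reading of the analysis treats
class membership as one more information source — with
`class_active = FALSE` available to keep it supplementary, since either
convention is defensible.

Contributions follow the standard convention: variable j's contribution to
dimension s is 100 times its squared loading in the weighted global PCA, so
variable and block contributions each sum to 100% per dimension. Dimension
signs are fixed by making the largest-magnitude loading positive, which
makes score plots reproducible. Five dimensions are computed by default;
the informative ones in this design are typically the first two.

## PLS-DA, VIP, and venetian-blind cross-validation

The discriminant core is two-class PLS-DA fit by NIPALS with X deflation,
response coded control = +1, treated = −1 and class assignment by the sign
of the predicted response (an exact zero goes to control, deterministically
and with a warning). The first latent variable's weight vector is
proportional to X'y; weight vectors are unit-norm and score vectors
mutually orthogonal. Variable importance in projection is

VIP_j = sqrt( p · Σ_a SSY_a w_ja² / Σ_a SSY_a ),

with SSY_a the response variance captured by latent variable a; squared
VIPs average to 1 over the p variables.

Cross-validation uses venetian blinds whose deletion groups are the
day-pairs: the control and treated sample of one day are held out together,
six groups for a six-day analysis set (equivalently leave-one-pair-out;
day d goes to fold ((d−1) mod 6) + 1). Preprocessing is fold-safe:
pair-centering uses only each pair's own mean (no labels, no other
samples), and autoscaling parameters are re-estimated on the training folds
only. The number of latent variables is chosen as the argmin of the
cross-validated classification error, ties to the smallest count. That the
fold-safe pipeline does not leak is checked by a permutation null: with
treatment labels randomly flipped within pairs, cross-validated accuracy of
a fixed model averages ~50%.

## Backward elimination and the selection rule

Backward elimination wraps the above: at each cycle the current variable
set is cross-validated (choosing the LV count), VIP scores are computed on
the full-data fit at that LV count, and the minimum-VIP variable is removed
(ties: lexicographically smallest identifier), down to a single variable.
The retained set with the best cross-validated prediction error over the
whole trace is selected and refit.

"Best prediction error" needs care. The cross-validated classification
error is coarse — over long stretches of the trace it sits at zero whenever
the classes are separable — so using it alone with a fewest-features
tie-break degenerates to single-variable models. We therefore rank cycles
first by classification error, then by the continuous cross-validated RMSE
of the predicted response, then by fewer features. The RMSE secondary
criterion keeps variables that sharpen out-of-fold predictions and pushes
pure-noise variables out, and it reproduces the qualitative behaviour
expected of this procedure (selected sets of one to a few dozen variables
per source, one latent variable, perfect classification on strongly
separated data).

Two structural limitations at this sample size are worth stating plainly,
because the package's own simulations expose them:

* **Selection instability.** With 6 day-pairs, the RMSE curve along the
  trace is flat over a wide region, and the realized importance of a
  genuinely affected variable overlaps the tail of 5-degree-of-freedom
  noise. Selected sets therefore recover most, but not reliably all,
  planted variables, and can carry substantial noise admixture. Selected
  variable lists from 12-sample designs should be read as candidate sets,
  not as complete or pure recoveries.
* **Winner's-curse accuracy.** The reported cross-validated accuracy of the
  *selected* model is the best value over the elimination trace. Because a
  held-out pair is centered by its own mean, its two predictions are exactly
  antisymmetric and cross-validation makes only six effective binary
  decisions; the minimum error over hundreds of nested subsets is then
  optimistically biased — on pure-noise data the selected model still shows
  ~100% cross-validated accuracy. The per-cycle cross-validation itself is
  unbiased (the permutation null above is at chance); it is the selection
  step that inflates. Perfect-classification claims for selected models in
  designs of this size should be interpreted with this in mind; an unbiased
  error estimate would need an outer cross-validation loop around the whole
  elimination, which this design cannot afford.

One variable is removed per cycle by default, making the trace minimum
exact. For wide fused matrices a percent-elimination mode
(`remove_frac`, e.g. 0.2) removes the bottom fraction by VIP per cycle
while more than `min_exact` (default 50) variables remain, then reverts to
one-at-a-time; results can differ slightly from the exact trace. The LV
count is re-chosen by cross-validation at every cycle (the alternative —
fixing it once — is a flag-worthy variant we did not take, since the
optimal count can shrink as variables are removed).

## Microbiome statistics

The 16S chain mirrors standard community analysis. Alpha diversity:
bias-corrected Chao1 (S_obs + f₁(f₁−1)/(2(f₂+1))), Shannon entropy
(natural log by default; a base switch is provided), and Simpson's index
in the Gini–Simpson form 1 − Σp² (a switch returns Σp²); groups are
compared by Kruskal–Wallis. Beta diversity: Bray–Curtis dissimilarities on
relative abundances, principal coordinates by Gower double-centering
(negative eigenvalues are reported and their axes dropped with a warning),
and PERMANOVA with seeded permutations, p = (1 + #{F* ≥ F})/(1 + n_perm).
Rarefaction to a fixed depth (default 10,000 reads, seeded subsampling
without replacement) is applied before diversity estimation only — never
before differential abundance, where normalization handles depth — and can
be disabled.

Differential abundance: TMM normalization (trimming 30% of M-values and 5%
of A-values, precision weights, factors renormalized to geometric mean 1,
reference sample chosen by the upper-quartile rule) via edgeR's
implementation of the method, then a per-taxon negative-binomial GLM with
log link and offset log(library size × factor), dispersion estimated per
taxon by maximum likelihood without shrinkage, and a Wald z-test of the
group coefficient with a two-sided normal p-value; Benjamini–Hochberg FDR
is applied within each contrast (each tissue/comparison is its own family).
Fold changes are reported as 2^log2FC at two significant figures. The
standard contrast set comprises, per site, control vs treated at each
exposure time and 3 h vs 24 h within each condition, plus the pooled
all-site control vs treated contrast at each time — six contrast types.

A calibration caveat the simulations make explicit: with 6 + 6 samples the
per-taxon ML dispersion is biased low, so the normal-reference Wald test is
anticonservative (empirical type-I error ≈ 0.09–0.11 at nominal 0.05). The
test calibrates at larger group sizes (≈ 0.05–0.06 at 30 + 30, verified in
the test suite). Small-sample differential-abundance p-values from this
estimator class should be treated as screening values; the FDR-adjusted
discovery fraction under the null remains small because the inflation is
spread over many taxa.

## The synthetic-data generator

Every stage is tested against data with known planted structure. Feature
values are global feature mean (log-normal, mimicking intensity spread) +
additive day effect (Gaussian, sd `day_effect_sd`, drawn per day × feature
and shared exactly by the day's pair) + treatment effect (±`effect_size` ×
`noise_sd` on the planted features of treated samples, random signs) +
Gaussian noise. The exactly pair-shared day effect makes pair-centering
provably optimal, which is what gives the preprocessing a sharp test. OTU
tables are negative-binomial (variance μ + φμ²; φ = 0 gives Poisson) with
per-taxon expected counts following a skewed power-law community profile, a
group-specific fold change on planted taxa, and log-normal library sizes
around 10,000 reads (σ = 0.3), keeping counts at the scale of a rarefied
16S family table. All randomness flows through one seed per generator call;
identical spec + seed gives byte-identical output.

What the generator does **not** emulate: correlated features (real lipid
and metabolite intensities are strongly collinear), heteroscedastic or
multiplicative batch effects, missing values, compositional closure of
intensities, or taxonomic assignment error. Passing parameter-recovery
tests on this generator therefore demonstrates the machinery is correct
under the design's idealized assumptions, not that real data meet them.

Default study conditions follow the emulated design throughout: 6 day-pairs
per time; block widths muscle 921/464/66, skin 944/384/99, gills 380/108,
eye 340; standardized planted effect 3 with day-effect and noise sd 1;
OTU dispersion 0.1. Simulation-based checks use 20 seeded replicates;
full-width backward eliminations use `remove_frac = 0.2` with exact
elimination below 50 variables.

## Numerical choices and degenerate inputs

* PCA is SVD-based; eigenvalues are squared singular values over n−1;
  components are truncated at numerical rank (singular values below
  1e−12 × the largest are zero).
* Zero-variance blocks, all-constant matrices, single-class responses,
  unpaired days, NA intensities, all-zero OTU samples, and out-of-range
  planted indices are errors with named offenders, not silent fixes.
* Taxa with zero counts in both groups of a contrast are excluded from
  differential abundance with a message; per-taxon NB fits that fail to
  converge fall back to the Poisson GLM (dispersion → 0 limit).
* All tie-breaks (equal VIP, equal CV error, ŷ = 0) are deterministic and
  documented at the function level.
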
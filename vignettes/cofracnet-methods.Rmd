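---
title: "Inferring and comparing co-fractionation interactomes with CoFracNet"
author: "CoFracNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and comparing co-fractionation interactomes with CoFracNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein correlation profiling by size-exclusion chromatography (SEC-PCP)
separates native protein assemblies across elution fractions and quantifies
each protein's abundance profile — its *chromatogram* — along the gradient,
typically as SILAC ratios against a pooled internal standard. Proteins that
belong to the same complex co-elute, so the similarity of two chromatograms
carries evidence for a physical association. When two biological conditions
are multiplexed into separate isotope channels (here: medium = unstimulated,
heavy = stimulated), the same experiment yields a condition-resolved
interactome and, by contrasting conditions, a map of interactome *rewiring*.

CoFracNet implements the complete computational path: a synthetic-data
generator with planted ground truth, chromatogram cleaning, single-point
quantitation-error removal (MODERN), Gaussian mixture modeling of elution
peaks, a naive Bayes co-complex classifier with precision thresholding, and
a family of rewiring statistics built on degree-preserving network nulls.

## The synthetic-data generator

Real deposited chromatogram matrices are large and not redistributable here,
so every stage is validated against `simulateChromatograms()`, which plants
known structure:

* Each complex assembled in a condition elutes as one shared Gaussian peak
  $A_p \exp(-(x-\mu_c)^2 / 2\sigma_c^2)$; a member's noiseless profile is
  the complex peak scaled by a member-specific amplitude $A_p$. This is
  exactly the structure the classifier's features are designed to detect,
  which is the point: the generator defines what "recoverable signal" means.
* Complex peak centers sit on a permuted, jittered grid across the middle
  70% of the gradient rather than being drawn independently. Distinct
  assemblies of different size are chromatographically resolvable; fully
  coincident peaks would plant label noise no method could overcome.
* Monomeric proteins — singletons, and members of dissolved complexes in
  the stimulated condition — elute as independent peaks in the late
  (small-hydrodynamic-size) 60% of the gradient, with the same widths a
  column produces for any analyte (2–3.5 fractions here, 2.5–4.5 for
  complexes).
* A controllable fraction of complexes is *rewired*: assembled without
  stimulation, dissolved into monomers with it. Protein identities persist
  across conditions, so rewiring moves edges, not nodes.
* Noise is multiplicative log-normal with coefficient of variation
  `noiseSd` (default 0.05): a SILAC ratio is a ratio of measured peptide
  intensities and its error scales with the signal. Values below the
  detection limit (default 0.02, i.e. 2% of a unit amplitude) are censored
  to missing — a protein simply is not quantified in fractions where it is
  absent — and a further `missingRate` (default 0.2) of points is removed
  at random.
* Quantitation errors are planted as exact-count spikes: exactly
  `round(spikeRate * nObserved)` observed positive points per matrix are
  multiplied by `spikeMagnitude` (defaults 0.002 and 50). Spikes land only
  on positive values because multiplying zero models no error. The exact
  count (rather than Bernoulli draws) gives tests exact expectations.

All per-complex and per-protein peak parameters are drawn once and shared
across replicates — replicates re-measure the same biology and differ only
in noise, missingness and spikes. The seed fully determines all output.

What the generator does **not** emulate: peptide-level quantitation and
rollup, correlated (structured) noise across proteins, partial complex
disassembly or stoichiometry changes, overlapping-complex deconvolution,
and the light internal-standard chemistry. Passing tests therefore show
that the algorithms recover planted structure of the assumed form, not that
real chromatograms satisfy these assumptions.

## Cleaning, smoothing and peak fitting

Cleaning follows the standard co-fractionation rules, in this order:
single missing points with observed immediate neighbors are imputed as the
neighbor mean (`imputeSingleMissing()`; runs of two or more, and endpoints,
are untouched); proteins with fewer than five observed points are dropped
(`filterMinObservations()`); profiles are smoothed with a centered
five-fraction sliding average that truncates at the ends and leaves missing
points missing (`smoothChromatograms()`). The order — impute, then filter,
then smooth — matters only at the filter boundary and is fixed as the order
in which the rules are naturally stated.

`fitGaussianMixture()` fits $f(x) = \sum_k A_k e^{-(x-\mu_k)^2/2\sigma_k^2}$
for $k = 1..5$ by bounded Levenberg–Marquardt least squares
(**minpack.lm**), choosing $k$ with the bias-corrected Akaike criterion
for Gaussian-error least squares:
$$AICc = n\ln(SSE/n) + 2p + \frac{2p(p+1)}{n-p-1}, \qquad p = 3k.$$
Numerical choices: centers initialize at the $k$ largest local maxima of
the smoothed profile (ties to the lowest fraction), amplitudes at those
heights, widths at 2 fractions; bounds $A > 0$,
$\mu \in [-4, N+5]$ (peaks may sit just outside the collected range),
$\sigma \in [0.5, N]$; at most 500 iterations with relative SSE tolerance
$10^{-8}$; component counts with $n - p - 1 \le 0$ are not attempted.
Chromatograms for which no candidate converges — all-zero profiles,
fewer than four points — are *discarded*, a normal outcome reported as
`NULL`, never an error.

## MODERN: single-point quantitation-error removal

A protein's *interaction profile* is its vector of Pearson correlations to
every other protein, over jointly observed fractions (at least 3, else the
entry is missing). Each observed point is removed in turn and the profile
recomputed; the correlation between the original and leave-one-out profiles
is that point's *autocorrelation*. A sound measurement barely moves the
profile (autocorrelation near 1); a high-magnitude quantitation error
rewires it globally.

`detectOutliers()` pools all autocorrelations of a matrix, standardizes
them with the pooled mean and standard deviation, and flags points with
$z < \Phi^{-1}\!\big((\alpha/2)/N\big)$, where $\alpha$ is the two-tailed
family-wise error rate (default 0.05) and $N$ the total observed points.
Only the lower tail flags (a point whose removal *improves* self-agreement
beyond expectation is not an error), the two-tailed rate is honored by
halving $\alpha$, and a single pass is made — flags are not re-derived
after removal. The implementation maintains running pairwise sums so the
full leave-one-out scan costs $O(P^2 F)$ rather than a correlation pass per
point; a brute-force `cor()`-based reimplementation in the test suite
checks exact agreement.

A known limitation, documented rather than hidden: the null distribution
of leave-one-out autocorrelations is left-skewed, because removal leverage
grows with a point's magnitude and edge position. The normal-quantile
threshold therefore does not strictly control the family-wise error rate —
on clean structured matrices a small fraction of legitimate points
(typically high-leverage peak-edge points of short profiles) is flagged.
The acceptance suite measures both spike recall and this false-flag rate
honestly instead of asserting an unattainable zero.

## Co-complex classification and precision thresholding

For every protein pair and replicate, six features are computed over
pairwise-complete fractions: raw-profile Pearson $r$ and its two-tailed
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$, raw Euclidean distance, smoothed
Pearson $r$, the separation in fractions of the profile maxima (ties to the
lowest fraction), and the smallest Euclidean distance between fitted
Gaussian components in $(\mu, A)$ coordinates ($\sigma$ is excluded: peak
position and height identify a co-eluting component; widths are dominated
by the column). Replicate features are concatenated per isotope channel —
eighteen features for three replicates — and each channel is scored
independently by its own classifier.

Labels come from a complex-derived gold standard: intra-complex pairs are
positives, pairs of gold-standard proteins that never share a complex are
negatives. `scorePairs()` trains Gaussian naive Bayes classifiers under
tenfold cross-validation, stratified by label, with folds assigned by pair;
missing features drop out of the likelihood product pair-wise; a feature
constant within a class has its variance floored at $10^{-12}$. Every pair
is scored by every fold's classifier and the final interaction score is the
fold median.

`precisionThreshold()` sorts pairs by score and computes cumulative
precision over *labeled* pairs only; unlabeled pairs ride along. The
network keeps the largest prefix whose cumulative precision meets the
target (default 0.70), with equal-score blocks entering or leaving
atomically; an unreachable target yields an empty network with a warning.
The labeled-precision estimate generalizes to the whole network only to the
degree that the scored universe resembles the gold universe — in
simulations with many never-labeled singleton monomers, chance co-elution
enters the network invisibly to the estimate. The calibration tests
therefore use fully-complexed universes, and the same caveat applies to
real data.

## Differential-network statistics

All permutation nulls use degree-preserving rewiring:
`round(6.9 * |E|)` attempted double-edge swaps via **igraph**, preserving
every node's degree and the edge count (asserted on every permutation in
the tests).

* `deltaNppiTest()` counts, per gene set, the interactions among members in
  each condition and their difference $\Delta n_{PPI}$. Each of `nPerm`
  (default 1000) permutations rewires *both* networks and recomputes the
  paired difference; the observed difference's z-score against this null is
  converted to a two-tailed normal p-value (enrichment and depletion are
  both of interest) and BH-adjusted across terms. Terms with a zero-spread
  null get $p = 1$; terms with fewer than two members in the networks are
  skipped and reported. Significant terms are reported at a 20% FDR by
  default (a 10% cut is the documented alternative; it is a report-time
  parameter, not baked into the statistic).
* `pairAnnotationSharingEnrichment()` compares the fraction of edges whose
  endpoints share an annotation against rewired networks, with the add-one
  empirical p-value $(1 + \#\{null \ge obs\})/(1 + nPerm)$, never zero.
* `proteinAutocorrelation()` correlates each protein's stimulated and
  unstimulated chromatograms per replicate (at least five shared
  fractions), converts correlations to z-scores by a rank-based
  inverse-normal transform within replicate — robust to the heavy left
  tail of rewired proteins — and combines replicates with Stouffer's
  $\sum z_i / \sqrt{k}$. Tiering of low-autocorrelation proteins is left to
  the caller; the ranking is the interface.
* `correlationShiftTest()` compares within-set pair correlation
  distributions between conditions with a Brunner–Munzel test (implemented
  here with midranks and Satterthwaite degrees of freedom; verified against
  an independent reference implementation), excluding correlations with
  fewer than five pairwise observations.
* `logOddsEnrichment()` is the Woolf z-test of the log odds ratio,
  $SE = \sqrt{\sum 1/n_{ij}}$, with the Haldane–Anscombe $+0.5$ correction
  when any cell is zero.
* `enrichmentMapEdges()` connects gene sets at Jaccard index $\ge 0.33$;
  the boundary is inclusive, so two 2-sets sharing one member (Jaccard
  exactly 1/3) are connected.
* GO-style ingestion (`buildGeneSetsFromAnnotations()`) optionally filters
  evidence codes IPI, IEA, NAS, ND and the NOT qualifier and propagates
  annotations up a parent map; all statistics consume only the resulting
  named list, filtered to sizes 2–100 (`filterGeneSets()`).

## The pipeline

`runPipeline()` composes the stages in a fixed order — simulate (or read),
clean, MODERN, smooth and fit, features, scoring, thresholding, comparison,
rewiring statistics, report — writing every intermediate artifact as TSV
plus a JSON manifest of counts, timings and stage seeds. Stage seeds are
fixed offsets of the master seed, so a rerun with the same configuration
reproduces the outputs; a completed run is skipped unless forced. The YAML
configuration round-trips losslessly and rejects unknown keys.

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` run at deliberately small,
fixed sizes chosen to exercise every code path with stable statistics:
MODERN at 200 proteins × 60 fractions; classifier calibration and rewiring
recovery on 48-protein studies of twelve 4-member complexes (a
fully-complexed universe, for the calibration reasons above) with three
replicates and two channels; rewiring-test calibration on 150-node,
400-edge networks with 50 random terms and 200 permutations. These sizes
are the package's validation conditions, not limits of the implementation.

## Known limitations

Beyond those noted inline: the classifier assumes feature independence
(naive Bayes) and Gaussian class-conditionals; the precision estimate is
conditional on the gold standard's representativeness; the rewiring z-test
relies on a normal summary of the permutation null, which the calibration
test checks only under the degree-conditioned model; and condition-specific
edges conflate genuine rewiring with threshold effects near the precision
cutoff — the recovery test quantifies exactly this.
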
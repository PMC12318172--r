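---
title: "Methods: intersubject similarity, trait models, and individual-differences scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intersubject similarity, trait models, and individual-differences scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isrsa)
```

## The scientific question

When people imagine future events, do individuals who share a positive
trait — here, optimism — represent those events in neurally similar ways,
while low-trait individuals each diverge in their own direction? This
"Anna Karenina" hypothesis (all high-trait individuals alike; each
low-trait individual idiosyncratic) makes a specific prediction about the
*pairwise structure* of intersubject similarity: only pairs in which both
members score high should show similar neural representations. That is
distinct from the simpler "nearest-neighbor" prediction that any two
people with *close* scores — high or low — should look alike.

`isrsa` implements the full analysis path for testing these hypotheses on
condition-by-voxel activation patterns (t-statistic maps from a
first-level GLM, one pattern per experimental condition per participant,
restricted to a region of interest), together with a synthetic-data
generator that plants known structure so every stage can be validated
end to end.

## The pipeline, stage by stage

### Condition RDMs and the intersubject matrix

For each participant, the condition-level representational dissimilarity
matrix (RDM) has entries \(\delta_{ab} = 1 - r(\mathbf{p}_a,
\mathbf{p}_b)\), the Pearson correlation distance between the voxel
patterns of conditions \(a\) and \(b\) (`neural_rdm()`). Entries lie in
\([0, 2]\). The intersubject matrix (`subject_dissimilarity()`) has
entries \(D_{ij} = 1 - \rho\big(v(\mathrm{RDM}_i), v(\mathrm{RDM}_j)\big)\),
one minus the Spearman correlation of the vectorized lower triangles.
Two conventions are fixed package-wide and matter for reproducibility:

* `vectorize_lower()` walks the strict lower triangle row by row —
  for a \(3\times 3\) matrix the order is (2,1), (3,1), (3,2);
* Spearman ranks use average ranks for ties.

The transform \(1 - \rho\) is one of several monotone choices; every
downstream statistic here is rank-based, so the choice does not affect
any test result. A control variant (`univariate_distance()`) replaces the
multivariate RDM by absolute differences of one scalar activation level
per condition, to ask whether overall activity alone could explain a
pattern-level finding.

### Trait models

From a table of integer trait scores \(s_i\):

* **Nearest neighbor** (`nn_model()`): \(D_{ij} = |s_i - s_j| / \max_{kl}
  |s_k - s_l|\).
* **Anna Karenina, rank form** (`annak_rank_model()`, the pipeline
  default): ranks are normalized to \(u_i = (r_i - 1)/(n - 1)\) and
  \(D_{ij} = 1 - (u_i + u_j)/2\). Only pairs of two high-ranked
  participants reach small values.
* **Anna Karenina, mean-score form** (`annak_mean_model()`): pair means
  min-max normalized over unordered pairs, subtracted from 1. This
  variant is exposed because both formulations circulate in the
  literature; the two coincide up to a positive affine map (hence give
  identical rank-based test results) exactly when scores are equally
  spaced without ties, and differ otherwise. The package computes both
  rather than guessing which one a given study used.

The rank normalization \((r-1)/(n-1)\) was chosen so normalized ranks
span exactly \([0, 1]\). The diagonal of the AnnaK matrices is left at
its formula value; all matrix statistics use only off-diagonal cells.

### Mantel and partial Mantel tests

`mantel_test()` uses the Spearman correlation between vectorized lower
triangles as its statistic and builds the null by jointly relabeling the
rows and columns of one matrix. The sampled p-value includes the observed
statistic in the null set, \(p = (1 + \#\{\rho^* \ge \rho\})/(1 +
n_{perm})\), so \(p \ge 1/(1+n_{perm})\) and the test is never
anti-conservative at the floor. For \(n \le 8\) participants the test
switches to exhaustive enumeration of all \(n!\) relabelings and reports
the exact permutation p-value. The default tail is upper one-tailed (the
convention of the ecosystem's standard Mantel implementations);
`two_sided` is available. Bonferroni correction across regions uses
`p_corrected = min(1, p × n_tests)` with a default of 11 tests, the size
of the default-mode-network ROI set this analysis is typically run over.

`partial_mantel_test()` computes the Spearman partial correlation of two
matrices given a covariate matrix, permuting the first matrix's labels
and recomputing the partial statistic each draw (Legendre-style). An
exactly collinear control matrix is an error: the partial correlation is
undefined there (zero denominator), which is also why "controlling a
matrix for itself" must be probed with a near-copy rather than an exact
copy.

### Nonmetric MDS and the convergence analysis

`nonmetric_mds()` is ordinal (nonmetric) scaling by SMACOF: each
iteration fits disparities by isotonic regression of the current
configuration distances onto the dissimilarity order (primary tie
handling — ties may untie freely), then applies one Guttman transform.
Kruskal stress-1, \(\sqrt{\sum (\hat d - d)^2 / \sum d^2}\), is recorded
per iteration and is non-increasing; iteration stops when the decrease
falls below `tol` (default `1e-6`) or at `max_iter` (default 300), with
non-convergence reported in the result rather than raised.
Initialization is classical (Torgerson) scaling, which makes the
embedding deterministic; a seeded random initialization exists for
stress-sensitivity checks. On noisy 15-point problems the solution
agrees with `MASS::isoMDS` in both stress and configuration (Procrustes
sum of squares below \(10^{-3}\) in the test suite).

The convergence analysis (`densest_point()`,
`distance_trait_correlation()`) evaluates a product-Gaussian kernel
density estimate of the 2-D embedding on a regular grid (default
200×200) spanning the bounding box padded by 5% per side, with Scott's
rule per axis (\(h_j = \hat\sigma_j n^{-1/6}\)) as the default
bandwidth; the mode is the center of the argmax cell, ties broken toward
the lowest grid index with a warning. Each participant's Euclidean
distance from the mode is then Spearman-correlated with the trait score
(two-sided p). A negative correlation is the convergence signature:
high-trait participants sit closer to the most populated region.

Two numerical caveats are documented deliberately. First, the KDE
bandwidth is axis-aligned, so mode distances are only approximately
invariant under rotation of the embedding; the tests assert order- and
scale-stability rather than exact invariance. Second, ordinal MDS has a
known degenerate regime at small sample sizes with strongly clustered
dissimilarities: all but one point can collapse to near-coincidence at
near-zero stress, leaving the distance profile dominated by ties and the
trait correlation unstable. At the sample sizes this analysis targets
(about 37–50 participants) the degeneracy did not occur in any of the
package's replicate simulations.

### INDSCAL

`fit_indscal()` fits the weighted-Euclidean individual-differences
model: a configuration \(X\) of conditions shared by all subjects, and
non-negative per-subject dimension weights \(w_{kd}\), with model
distances \(d^{(k)}_{ab} = \sqrt{\sum_d w_{kd} (x_{ad} - x_{bd})^2}\).
The algorithm alternates (i) a disparity transform, (ii) one Guttman
majorization step per subject in the subject's stretched space, and
(iii) closed-form least-squares updates of the shared configuration and
the per-subject dimension scales \(c_{kd} = \sqrt{w_{kd}}\), clipped at
zero. Both updates are column-separable, so no general non-negative
least-squares solver is needed; stress-1 is monotone non-increasing and
a brute-force multistart minimizer over all free parameters reaches the
same stress on small instances (within \(10^{-3}\) in the tests).

Design choices that were genuinely open:

* **Disparity transform.** Default `ratio` (distances fitted to raw
  dissimilarities up to one scale factor); `interval` and `ordinal` are
  available. Critically, the transform is applied **unconditionally** —
  one transform pooled over all subjects — not per subject. A
  per-subject ratio would absorb each subject's overall weight magnitude
  into its scale factor, leaving only weight *ratios* identified and
  destroying the weight–trait analysis this model exists for.
* **Identification.** Configuration columns are normalized to unit root
  mean square with scale absorbed into the weights; dimensions are
  ordered by total subject weight, descending; each dimension's sign is
  fixed by making the first condition's coordinate non-negative. The
  sign of a dimension remains scientifically arbitrary, which is why
  `interpret_dimension()` reports \(|\rho|\) alongside the signed
  Spearman correlation (one-tailed in the direction of the observed
  sign, following the reporting convention for these analyses).
* **Rotational identifiability.** INDSCAL axes are non-rotatable only
  when subject weights actually vary; with identical weights for all
  subjects any rotation fits equally well. Recovery tests therefore
  assert axis-wise recovery only for varying-weight ground truths.
* **Dimensionality.** `stress_scree()` tabulates stress across candidate
  dimensionalities and deliberately applies no automatic elbow rule:
  the choice trades fit against interpretability and is left to the
  analyst.
* **Convergence.** Stress decrease below `1e-6` or 500 iterations;
  non-convergence is reported, not raised. SMACOF creeps slowly near
  flat optima, so parameter-recovery work benchmarked against direct
  minimizers uses a tighter `tol` and larger `max_iter`.

### Reliability checks

`split_half_rsa()` enumerates all unordered ways of splitting an even
number of runs in half (10 runs → 126 splits), averages patterns within
each half, and correlates the two half-RDMs per participant.
`cross_run_rsa()` correlates condition patterns across run pairs only,
so run-specific noise attenuates rather than inflates similarity; with
identical runs it reproduces the within-run RDM exactly.
`split_by_condition()` restricts RDMs to one referential target and
refuses designs with fewer than four conditions per target, where the
resulting 3×3 block has only three unique cells — too few for a
rank-based matrix statistic.

## The synthetic generator: what it emulates and what it does not

`simulate_dataset()` reproduces the study conditions: an 8-condition
(4 valence × 2 target, 10 runs, 16 trials/run) or 6-condition
(3 × 2, 12 trials/run) design; integer trait scores built as sums of six
items each uniform on 1–5 (range 6–30, mean 18 — the instrument's
structure, since score distributions are rarely reported); and 60 voxels
per region by default.

Under the planted `annak` structure, participant \(k\)'s pattern is

\[ P_k = a(u_k)\, S_k + (1 - u_k)\,\sigma\, E_k, \qquad
   a(u) = 0.15 + 0.85\,u , \]

where \(u_k\) is the normalized trait rank, \(E_k\) a participant-unique
Gaussian template, \(\sigma\) = `noise_sd` (default 1), and \(S_k\) the
embedding of a shared 2-D condition configuration (standardized rated
valence; standardized target code) stretched by the participant's
planted dimension weights \(w_{kd} = \max(0.05,\ 1 + \beta_d (u_k -
1/2))\), with defaults \(\beta_1 = 1.2\), \(\beta_2 = -0.8\). The voxel
embedding is a random orthonormal map orthogonal to the constant vector,
so condition correlations reflect the planted weighted geometry. The
floor in \(a(u)\) exists because pure rank mixing would hand the
lowest-ranked participant an exactly zero pattern, for which correlation
is undefined. `nn` structure makes similarity track score proximity at
any level; `null` makes patterns exchangeable with respect to the trait.

Known properties worth stating plainly:

* With `noise_sd = 0` and weight slopes 0, all participants' RDMs are
  exactly identical (pure noiseless convergence). With nonzero slopes,
  noiseless RDM differences come only from the planted weights — weight
  planting and perfect pairwise convergence are mutually exclusive by
  construction, and the tests treat them as separate configurations.
* Because noise scales with \(1 - u_k\), low-trait participants' RDMs
  are noisier, which flattens their fitted INDSCAL weights on *every*
  dimension. At the default noise level this masks the planted negative
  dim-2 slope (both weight–trait correlations come out positive);
  recovery of weight signs and magnitudes is therefore validated at
  small noise, where the generator's geometry dominates.
* The generator emulates t-statistic patterns directly; it contains no
  hemodynamics, no spatial autocorrelation, no motion artifacts, and no
  between-region structure. Passing tests demonstrate the statistical
  machinery is correct and calibrated, not that real fMRI data satisfy
  the planted model.

## Problem sizes and calibration evidence

The test suite validates, on these scales:

* Type-I error: 500 null-structure replicates (20 subjects, 8
  conditions, 30 voxels) for the Mantel test and the partial Mantel
  test, and 500 (15 subjects, 6 conditions) for INDSCAL weight–trait
  correlations; rejection at \(\alpha = 0.05\) must fall inside the 99%
  binomial interval.
* Power/model comparison: 100 planted-convergence replicates at 40
  subjects; the AnnaK model's Mantel \(\rho\) exceeds the NN model's,
  and the MDS distance–trait correlation is negative, in at least 90%.
* Exactness: the sampled permutation p agrees with exhaustive
  enumeration over all 120 relabelings at \(n = 5\) within Monte-Carlo
  error, and with `vegan::mantel` to machine precision where both
  enumerate.
* Recovery: INDSCAL reattains a planted 2-D weighted-Euclidean geometry
  with stress below 0.01 at zero noise and axis-wise Spearman
  \(|\rho| \ge 0.9\) for configuration and weights at low noise.

`scripts/acceptance.R` reruns the full pipeline at the two study scales
(37 and 50 participants) and writes every headline quantity it computes
to JSON.

## Interfaces

The package is an R library: the exported functions compose the
pipeline, `run_pipeline()` orchestrates it into a single JSON report
(schema shipped under `inst/schema/`), and TSV readers/writers
(`read_matrix_tsv()`, `read_traits()`, `write_fixture()`, …) plus
optional NIfTI extraction (`extract_roi_patterns()`) handle exchange
with other tools. No shell entry point is shipped; users of this kind of
analysis work from R scripts, and the report/TSV surface is the
machine interface.

## Limitations

* The Mantel family tests association between dissimilarity structures;
  it does not model dyadic non-independence beyond what the permutation
  scheme captures, and no GLM-based permutation variants are provided.
* The densest-point analysis depends on bandwidth and grid choices;
  defaults are documented above and stability is tested, but the mode of
  a KDE is inherently less stable than the correlations built on it.
* Stress values from different studies are comparable only under the
  same disparity transform and dissimilarity metric; the scree table is
  descriptive, not an automatic model-selection rule.
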
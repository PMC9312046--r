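---
title: "Integrative taxonomy with intaxa: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative taxonomy with intaxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intaxa)
```

## The problem

Subspecies boundaries in morphologically variable plant complexes are often
drawn from qualitative impressions. `intaxa` treats a circumscription as a
falsifiable *grouping hypothesis* — a mapping from sampled populations to
putative taxa — and scores competing hypotheses against independent
evidence streams: mixed-type morphometry, karyotype asymmetry, seed
morpho-colorimetry and climatic niche overlap. The streams are juxtaposed,
never aggregated into a single index: consilience is judged by the reader,
and the package's only automatic verdict is the conventional kappa > 0.75
flag for excellent chance-corrected agreement.

## Morphometric dissimilarity

Field datasets of this kind mix binary morphs (e.g. leaf apex shape),
nominal colours, ordered factors (bract apex from round to apiculate) and
quantitative measures. The pairwise dissimilarity is Gower's coefficient:
each character contributes a partial dissimilarity in [0, 1] —
range-scaled absolute difference for quantitative characters, 0/1
match/mismatch for binary and nominal ones — averaged over the characters
comparable for that pair. Binary characters are treated symmetrically
(mismatch = 1 in both directions) because two-state morphs carry no
presence/absence asymmetry. Ordinal characters use Podani's tie-corrected
rank formula with mid-ranks computed **globally** across all individuals;
without ties it reduces to plain rank-range scaling. Missing cells simply
drop the character from that pair's average (no imputation); a character
with a single observed qualitative state still counts as a comparison
(partial dissimilarity 0), while a zero-range quantitative character is
excluded — otherwise two identical individuals would have an undefined
rather than zero distance.

Gower matrices usually violate Euclidean embeddability. `euclidean_check()`
diagnoses this from the spectrum of the double-centred −½D∘D matrix, with a
relative tolerance of 1e-8 times the leading eigenvalue (eigensolver noise
at double precision). `cailliez_correction()` then adds the smallest
constant c to all off-diagonal entries that restores embeddability, computed
as the largest real eigenvalue of the 2n × 2n companion matrix built from
the centred matrices of D and D²; the diagonal stays zero and the operation
is idempotent (a second pass adds c = 0). Principal coordinates follow by
classical scaling; axis signs are arbitrary, so all tests compare
distances, never raw coordinates. Suitability of the quantitative block for
factor-analytic summaries is reported by the Kaiser–Meyer–Olkin MSA and
Bartlett's sphericity test on the correlation matrix, with a pseudo-inverse
fallback (flagged) when the correlation matrix is singular.

## Hypothesis competition

ANOSIM ranks all n(n−1)/2 dissimilarities (mid-ranks on ties) and compares
mean between- and within-group ranks, scaled by M/2 so that R ∈ [−1, 1];
being rank-based, R is invariant under any monotone transform of the
distances. P-values use the add-one permutation estimator
(1 + #{R* ≥ R})/(1 + n_perm), which can never report an impossible zero.

Classification uses linear discriminant analysis with pooled within-group
covariance and priors proportional to training-fold class frequencies
(matching the asymmetric class sizes such studies produce), validated by
leave-one-out: the model never sees the individual it predicts. Columns
that are constant in a fold are dropped for that fold; if the pooled
covariance is singular (collinear descriptor blocks), a small ridge
(1e-8 × mean diagonal) is added and the report flags it. Cohen's kappa
corrects the percent-correct score for chance agreement; it is undefined
(reported as `NA`) for a degenerate single-cell table. Per-class
sensitivity follows the row (recall) convention, diagonal over a-priori
row total.

For high-dimensional seed feature tables, `stepwise_lda()` performs
forward–backward selection on Wilks' lambda with partial-F thresholds
F-to-enter 3.84 and F-to-remove 2.71 — the long-standing defaults of the
commercial package that popularized stepwise discriminant analysis — then
evaluates the selected model by the same leave-one-out scheme.

## The univariate cascade

Each character is tested separately across populations, with the test
chosen by a decision tree. Quantitative characters are screened with
Shapiro–Wilk on residuals that are centred **and scaled** per group before
pooling: pooled residuals of normal but heteroscedastic groups form a scale
mixture that Shapiro–Wilk correctly rejects, which would otherwise starve
the Welch/Games–Howell branch that heteroscedastic-normal data should
reach. If raw values fail and all are positive, the screen is repeated on
logs (the log-normal branch). Normal or log-normal characters go to
Bartlett's test and then ANOVA + Tukey–Kramer or Welch + Games–Howell;
non-normal ones to Levene–Brown–Forsythe (median-centred) and then
Kruskal–Wallis + pairwise Wilcoxon or a seeded pairwise permutation test on
the difference of means (10,000 resamples by default). Nominal characters
use Fisher's exact test per pair (Monte-Carlo p-values for large tables);
ordinal characters use a linear-by-linear association statistic on level
scores with a seeded permutation null — the closest analogue of exact
ordinal independence testing that stays assumption-free.

Diagnostics run at α = 0.01. At that level the Shapiro–Wilk screen has
roughly 88% power against t₂-tailed data at 3 × 30 observations, so a small
fraction of genuinely heavy-tailed characters will still take the
parametric branch; the tests encode that measured rate rather than a
nominal aspiration. Holm's step-down correction is applied within each
character's family of pairwise comparisons (not across characters — the
between-character count matrix is descriptive, not inferential), and
significant differences at α = 0.01 are tallied into a symmetric
population-pair matrix ready for heatmap display.

## Karyotype asymmetry

Measured metaphase plates list all 2n chromosomes, but the indices are
defined on the haploid complement, so homologues are paired by sorting on
total length (descending, centromeric index as tie-break) and averaging
adjacent pairs. This pairing is a modelling choice: it is exact whenever
homologues are more similar to each other than to other chromosomes, the
usual case at these noise levels. THL is the haploid length sum; M_CA the
mean of 100(L−S)/(L+S); CV_CL and CV_CI the percentage coefficients of
variation (sample sd) of chromosome length and centromeric index. Levan
classes cut the arm ratio at 1.7, 3 and 7, with boundary values assigned to
the more asymmetric class so classification is deterministic. Groups are
compared per index by pooled two-sample t-tests (two groups) or one-way
ANOVA with Tukey–Kramer contrasts (more), the standard treatment for
normal, homoscedastic index data.

## Seed outlines and elliptic Fourier descriptors

Scanned seeds are dark on white; Otsu's threshold, connected-component
labelling and Moore boundary tracing yield one closed pixel-centre polygon
per seed (components touching the border are excluded, as are specks below
the minimum area). Geometry corrects for two discretization biases: the
stair-step boundary inflates perimeters by ~5%, so vertices are smoothed by
a window-3 circular moving average, and the polygon through boundary-pixel
centres misses a half-pixel rim, so half the perimeter is added back to the
shoelace area (Feret diameters gain one pixel for the same reason). With
these corrections a rendered disc recovers area within 0.1% and
circularity within 0.5%.

Shape is encoded by Kuhl–Giardina elliptic Fourier coefficients — chain
integrals of the polygon under its chord-length parametrization.
Normalization standardizes start point, rotation and size so that a₁ = 1
and b₁ = c₁ = 0; the remaining half-turn start-point ambiguity (which would
flip the sign of even harmonics) is resolved by taking the candidate with
the lexicographically larger coefficient vector, making the descriptors
invariant under rotation, translation, scaling and cyclic vertex shift to
1e-6. With 20 harmonics this yields 78 informative coefficients. One
caveat the tests encode explicitly: under chord-length parametrization the
*first harmonic alone* underestimates the axes of an eccentric ellipse
(8.6% at 2:1 — an exact property of the arc-length Fourier series, verified
against dense quadrature), so axis recovery is asserted on the full
harmonic reconstruction, which is also what the classifier consumes.

## Niche overlap

Environmental space is the first two components of a PCA (centred, scaled)
fitted on the pooled background cells of both taxa — the available
environment, not the presences, defines the axes. Occupancy is the ratio of
a Gaussian kernel density of presence scores to one of background scores,
evaluated on a 100 × 100 grid spanning the pooled background range plus a
5% margin (avoiding kernel truncation), zeroed where the environment is
unavailable, and normalized to sum to one. Bandwidths follow Silverman's
robust rule per axis with the two-dimensional exponent n^(−1/6); the 1-D
exponent under-smooths planar score clouds and visibly depresses overlap
between replicate samples of the same niche. Bandwidths are computed on
*distinct* presence scores, so duplicated records do not sharpen the
density. Overlap is Schoener's D = 1 − ½Σ|z₁ − z₂| ∈ [0, 1]. The
similarity test re-draws one taxon's presences uniformly from its own
background cells (the planar analogue of sampling within a fixed-radius
buffer), recomputes D each time, and reports the one-sided add-one p-value
in both directions; it asks whether niches are more similar than their
available environments would produce at random, not whether they are
identical.

## Synthetic data: what it does and does not show

The generators are pure functions of a root seed (per-stream offsets keep
streams independent) and default to the study's natural scale: 12
populations × 20 individuals × 49 characters (28 quantitative, 15 binary,
2 nominal, 4 ordinal), 2n = 18 karyotypes with ~4.7 µm chromosomes, seeds
rendered at 1200-dpi pixel scale, and two-taxon Gaussian niches on smoothed
white-noise landscapes. Group structure is planted as mean shifts in sd
units (quantitative), state-probability tilts (qualitative), harmonic
amplitudes (seeds) and niche centres (ecology). Passing tests on these data
demonstrate correctness of the statistics and recoverability of planted
structure; they do not demonstrate robustness to what real data add —
character correlations, measurement error structure, spatial sampling bias,
or seeds that touch on the scanner tray (the generators guarantee
separation, as careful scanning protocols do).

## Numerical and design notes

- Simulation sizes in the test-suite (e.g. 1000 null datasets for the
  ANOSIM calibration at 99 permutations each, 200 cascade null replicates,
  100 competition replicates) were chosen as the smallest runs whose
  Monte-Carlo error is well inside the asserted bands.
- Permutation p-values everywhere use (1 + x)/(1 + N); seeds are explicit
  arguments and derived deterministically inside composite runs.
- The Euclidean/PSD tolerance (1e-8 relative), LDA ridge (1e-8 × mean
  diagonal) and EFD invariance tolerance (1e-6) reflect double-precision
  eigensolver and quadrature noise, not statistical judgments.
- Ordinal integer codes follow the declared level order in the descriptor
  file; for nominal characters the encoding is order-arbitrary, and because
  downstream discriminant axes depend on it, the order must be declared
  explicitly rather than inferred.
- `run_competition()` requires only the morphometric stream; karyology,
  seed and niche streams are optional and may cover different population
  subsets, reflecting how such studies sample unevenly across streams.
  Population codes must be mappable by every hypothesis, and mismatches are
  reported by name.

## Known limitations

- No geographic projections or real climate layers: niche grids are
  abstract planar rasters, and buffers are circular in cell units.
- The seed descriptor set is a representative subset (geometry, colour
  moments, EFDs), not a re-implementation of any particular imaging
  plugin's full feature list.
- Only leave-one-out cross-validation is offered (no k-fold), and only
  linear discriminants (no QDA) — matching the methods this workflow is
  meant to reproduce and compare against.
- The missing-data path is defensive: it keeps the pipeline well-defined
  when cells are absent, but no claim is made about missingness mechanisms.
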
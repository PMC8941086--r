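---
title: "Methods: data-driven meta-analytic grouping with ALE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven meta-analytic grouping with ALE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Classical coordinate-based meta-analysis pools experiments by a label the
analyst chooses in advance — a diagnosis, a task family, a contrast
direction. When the literatures of interest are heterogeneous and heavily
comorbid (as in pediatric psychiatry, the motivating use case), that choice
itself shapes the result. **magale** inverts the workflow: experiments are
first grouped purely by the spatial similarity of their reported activation
topography, and the labels are interrogated afterwards, as phenotypes that
may be enriched or depleted in each data-driven grouping.

## Model and assumptions

### Modeled activation

An experiment contributes a set of peak coordinates (foci) in MNI mm, not a
statistical map. Each focus is blurred with an isotropic 3-D Gaussian whose
full width at half maximum reflects two uncertainty sources: between-subject
anatomical variability, which averages out with the case sample size `n`,
and between-template variability, which does not:

    FWHM(n) = sqrt(FWHM_subject^2 / n + FWHM_template^2)

Defaults are 11.6 mm and 5.7 mm (the empirical constants standard in the
ALE literature); both are `kernel_spec()` parameters, so the package is not
tied to those constants. By default `n` is the *case* sample size — the map
encodes the uncertainty of a case-vs-control contrast — with
`sample_size = "total"` available.

The kernel is discretized on the 2 mm grid, truncated at 3.5 standard
deviations, and renormalized to unit mass over its truncated support, so
each value is a probability-per-voxel. Within an experiment, foci combine
by voxel-wise **maximum**: an experiment reporting five peaks in one region
contributes no more there than an experiment reporting one. Foci outside
the grey-matter mask are retained; their kernels contribute wherever the
truncated support intersects the mask.

Hypo- and hyper-activation contrasts are pooled into a single
aberrant-activation map per experiment; effect direction is deliberately
out of scope.

### Similarity and clustering

MA maps are flattened over the mask (column-major volume order; all
downstream statistics are invariant to this order, which the test suite
checks by permuting it) and compared by Spearman rank correlation with
average ranks for ties — essential because most voxels are exactly zero.
Clustering is agglomerative with average linkage on the correlation
distance `1 - rho`. Merge ties (within 1e-12) are broken by the
lexicographically smallest pair of cluster keys, each cluster keyed by its
smallest member ID, which makes dendrograms deterministic and
order-invariant.

K is selected over a range (default 2–15) from a subsample stability
analysis (default: 90% subsamples, 5000 iterations; tests use far fewer):
at each K we record mean silhouette (on `1 - rho`), Calinski–Harabasz (on
the MA feature rows), and the adjusted Rand index and variation of
information (in nats) between the subsample solution and the full solution
restricted to the subsample. Consecutive-K aRI/VI between full-data
solutions are reported alongside, because the reference analysis appears to
have read VI that way; both are available and neither is asserted as "the"
convention. `select_k()` is a mechanical majority vote — silhouette argmax,
aRI argmax, VI smallest consecutive change, CH argmax only when CH is not
monotone over the range (a monotone CH carries no optimum and is excluded
with a message); ties resolve to the smaller K, and an `override` preserves
investigator judgment, since the reference choice was ultimately by
inspection.

Groups with fewer than `min_size = 10` experiments are excluded before
meta-analysis: below that size a single experiment can drive an ALE result.

### ALE and inference

The group-level ALE at a voxel is the union `1 - prod(1 - MA_i)` across the
group's experiments, i.e. the probability that at least one experiment
truly activates there under independence. Two voxel-level nulls are
provided:

* **histogram** (default): the analytic union convolution of the
  per-experiment MA-value histograms under spatial independence. The
  implementation keeps an exact sparse (value, probability) support while
  it is small and collapses to bins of width 1e-5 (configurable) only when
  the support outgrows a cap; on tiny problems the null is therefore exact,
  which the enumeration-oracle tests exploit.
* **permutation**: ALE values pooled over the mask across foci-shuffled
  pseudo-datasets.

The two agree in the tail (where the p < 0.001 cluster-forming threshold
operates); in the mid-range they deviate systematically because both pool
over a spatially heterogeneous mask — voxels near the mask boundary can
reach fewer kernels — and the convolution of pooled histograms is not the
pooled convolution. This is a property of the analytic ALE null in general,
not of this implementation; the test suite asserts tail agreement within
Monte-Carlo error.

Cluster-level inference is always permutation-based: pseudo-datasets keep
every experiment's focus count and kernel width but redraw focus locations
uniformly over in-mask voxel centres (consistent with the grid
discretization of observed foci); each permutation records its maximum
suprathreshold cluster size at the same ALE cutoff as the observed
analysis. A candidate cluster is significant when its size exceeds the
(1 − alpha) empirical quantile of that null, and its p-value uses the
add-one convention `(1 + #{null >= size}) / (1 + n_perm)`, which cannot be
zero. Connectivity for clusters defaults to 26 (vertex-connected),
configurable to 6 or 18; the reference analysis does not state a choice.
Peak coordinates break ties toward the smallest x, then y, then z.

### Phenotype statistics

Two denominators coexist deliberately, because only that combination
reproduces the published statistics: one-tailed exact binomial tests
compare a MAG's prevalence of a characteristic with the base rate over the
**full** corpus (e.g. 147 experiments), while one-vs-rest Pearson
chi-squares (no continuity correction, df = 1) compare a MAG against the
other **retained** MAGs only (e.g. 133). The binomial tail is chosen by the
observed direction when unspecified. Phenotype p-values are reported
unadjusted, as in the reference analysis, with an optional `p_adjust`
flag. Unknowns (medication status, % boys) are excluded pairwise.

The functional-characterization z-score is a transparent binomial
approximation — `z = (obs - exp) / sqrt(exp (1 - p_mask))` with `p_mask`
the fraction of all database foci inside the cluster mask — a clearly
labeled generic stand-in for the proprietary tool the reference analysis
used; the z >= 3 significance convention is kept.

Two printed values in the reference table do not verify against their own
counts and are reproduced here as computed, not tuned: the one-tailed
binomial for 0/21 at base rate 15.0% is 0.85^21 = 0.033 (printed: 0.028),
and the chi-square for 18/87 vs 1/46 is 8.4247, which rounds to 8.42
(printed: 8.43). Three further printed chi-squares (3.97, 3.31, 4.20) could
not be reproduced from the printed counts under any denominator convention
tried and are excluded from acceptance checking.

## Coordinate conventions

Voxel indices are 0-based (NIfTI convention); `world_to_voxel()` rounds
halves away from zero. Talairach-space foci are converted to MNI on load
with the Lancaster `tal2icbm` transform (inverse of the pooled icbm2tal
affine — the de-facto standard of the ALE ecosystem), configurable to the
SPM-specific fit, the Brett piecewise transform (branch chosen by the sign
of the Talairach z), or identity; the choice is recorded in the corpus
provenance. NIfTI-1 I/O is implemented natively (no R NIfTI dependency is
assumed available) and validated in the test suite against nibabel as an
independent reference.

## The synthetic generator: what a green test establishes

`generate_corpus()` plants topographic groups: each experiment draws its
total focus count (default 4–10, matching ~7 foci/experiment = 1030/147 of
the reference corpus), a binomial share of which (default rate 0.15) is
uniform background clutter; the rest cycle through the group's centres with
isotropic Gaussian jitter (default 5 mm SD, the separation scale used in
the recovery criteria), redrawn until inside the mask (100 attempts, then
nearest in-mask voxel). Default group sizes {21, 87, 13, 12} and case
sample sizes 10–35 mirror the reference corpus shape. The background rate
is a package choice — the reference corpus does not quantify its
"non-convergent" foci fraction — fixed at 0.15 as a realistic noise floor
for task-fMRI coordinate data and not revisited.

The generator emulates the *coordinate-level geometry* of a foci corpus:
clustered convergence, sample-size-dependent uncertainty, uniform clutter,
category enrichments. It does not emulate spatially structured noise,
anatomically realistic grey-matter geometry (the built-in mask is an
ellipsoid), correlated task/diagnosis sampling biases, or publication bias.
A green recovery test therefore establishes that the pipeline recovers
planted structure of the stated geometry — not that any particular real
corpus would yield stable groupings.

The `synthetic_reference_corpus()` is a different kind of stand-in: a
deterministic 147-experiment corpus whose category margins equal the
published characteristics-table counts (with placeholder foci), so the
phenotype machinery can be checked against the printed statistics exactly.
Two internal inconsistencies of the printed table (medication-naive
per-group counts sum to 65 against a printed total of 61; valence rows sum
to 70 against an emotion row of 71) are resolved in favour of the per-group
counts, which the acceptance targets depend on.

## Numerical choices

* ALE histogram bin width 1e-5; exact sparse support kept up to 131072
  values (per-experiment histograms dense-binned above 4096 voxels).
* Similarity matrices are symmetrized and clipped to [−1, 1] after the
  rank-correlation product; the diagonal is set to exactly 1.
* Silhouette of a singleton cluster is 0; Kruskal–Wallis with all values
  identical is H = 0 (tie-correction denominator would vanish); an
  experiment whose MA map is all-zero warns at map construction and is
  fatal at the similarity stage (its ranks are constant).
* Cluster-size nulls with fewer than 100 permutations warn (unstable
  quantile).
* The pipeline fans a single seed out to per-stage seeds via a polynomial
  hash of the stage name, so stages are independently rerunnable yet the
  whole run is bit-reproducible; all seeds stay below 2^31.

## Limitations

* The analytic voxel null assumes spatial homogeneity over the mask; near
  mask boundaries it is only an approximation (the permutation voxel null
  and the always-permutation cluster null do not share this assumption).
* Average linkage with Spearman distance is the implemented and tested
  path; no k-means/spectral alternatives, no consensus clustering beyond
  the described subsampling.
* No effect sizes, no hypo/hyper direction, no between-group ALE subtraction
  or conjunction analyses, no anatomical labelling of peaks.
* The reference corpus itself is not deposited; reproduction of its peak
  tables is explicitly out of scope, replaced by property-based recovery
  and calibration criteria on synthetic corpora.
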
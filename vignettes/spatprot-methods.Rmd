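---
title: "Organelle maps from fraction profiles: models and methods"
author: "spatprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle maps from fraction profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatprot)
```

# The measurement model

Correlation-profiling spatial proteomics separates a cell lysate into
centrifugation fractions, labels each fraction with one TMT reporter
channel, and quantifies thousands of proteins across all channels in a
single MS run. Because an organelle pellets (or floats) as a unit, all
proteins resident in it share a characteristic *fraction profile*. The
analysis chain supported here starts from reporter intensities that
have already been identified and quantified:

1. **Sum-normalisation** (`sumNormalizeRows`): each PSM's reporter
   intensities are divided by their total, making profiles relative and
   comparable across proteins of very different absolute abundance.
2. **Protein-group aggregation** (`aggregateProteinGroups`): the
   protein-level value per channel is the *median* of its PSM ratios —
   robust against outlier spectra. No renormalisation is applied after
   aggregation: medians of simplex rows are close to, but not exactly
   on, the simplex, and re-closing them would change the quantity being
   summarised. (An optional `renormalize` flag restores per-block
   closure for users who prefer it.)
3. **Full-reporter-series filter** (`filterCompleteProfiles`): any
   protein missing a value in any channel of any replicate is removed.
   Missing reporter values in these designs are not missing at random,
   and a partial profile cannot be compared against marker profiles;
   row deletion is the only missing-data policy — no imputation
   anywhere.
4. **Channel exclusion and contaminant removal** (`dropChannels`,
   `removeContaminants`): both take explicit user lists. Low-intensity
   channels are a judgement call made while inspecting the data (no
   published quantitative rule exists, so none is invented here), and
   contaminant databases are version-dependent, so no copy is bundled.
5. **Replicate concatenation** (`concatenateReplicates`): replicates
   are joined over the *intersection* of their accessions and channels
   are concatenated, widening the profile rather than averaging it.
   Accessions are compared as exact strings: protein isoforms carry
   distinct accessions and genuinely distinct localisations, so no
   isoform collapsing is performed.

Principal component projection (`pcaProject`) is mean-centred but never
variance-scaled — after sum-normalisation all channels already live on
a common ratio scale, and scaling would inflate noisy channels. The
sign of each component is fixed (largest-magnitude loading positive) so
plots are reproducible across sessions and BLAS implementations.

# Marker-based classification

Curated marker proteins — proteins with unambiguous, literature-backed
residence in one compartment — are the labelled training data.
Classification uses a support vector machine with the radial kernel

$$K(x, y) = \exp(-\sigma \lVert x - y \rVert^2),$$

written with $\sigma$ multiplying the squared distance so that printed
values of $\sigma$ (e.g. 0.01) are meaningful under this package's
convention; other libraries write the same kernel as
$\gamma = 1/(2s^2)$, which differs. No SVM implementation suitable for
this design was available among the package's allowed dependencies, so
the C-SVC dual is solved in compiled code by sequential minimal
optimisation with maximal-violating-pair working-set selection; the
test suite pins it against an independent quadratic-programming solve
(quadprog) and frozen reference decision values.

**Scores.** The per-protein, per-class score is a calibrated
probability: one-vs-one decision values are passed through Platt
sigmoids (fitted on the training decisions with Platt's regularised
targets) and coupled into a single simplex vector by the Wu–Lin
fixed-point method. A probability, rather than a raw decision value,
makes the downstream FDR walk well-defined and scores comparable
across classes. This is a documented choice: the ranking score used by
the original analysis software is not published, and any monotone
per-class score yields the same thresholding behaviour.

**Tuning** (`tuneSvm`) follows the nested protocol: in each of 100
rounds (default), markers are split into stratified test/train
partitions; an inner fivefold cross-validation on the training
partition selects $(\sigma, C)$ from the grid by macro F1 — the
unweighted mean over classes of the harmonic mean of precision and
recall, which weights a 20-protein organelle equally with a
500-protein one; the winner is retrained and assessed on the held-out
markers. The default grids, $\sigma \in 10^{\{-3..2\}}$ and
$C \in 2^{\{-4..4\}}$, bracket the optima reported for both
fractionation chemistries in the motivating study ($\sigma = 0.01$
with $C = 8$ or $16$). Round $r$ seeds its RNG with `seed + r`, and
markers are processed in accession order, so results are independent
of input row order. Grid ties resolve to the first (smallest) grid
point; the selected pair is the modal per-round winner.

**FDR thresholding** (`applyFdrThreshold`). Per class, assignments
covered by a reference annotation are ranked by descending score and
the threshold is the smallest score whose accepted prefix keeps the
disagreement fraction at or below the target $q$ (default 5%),
maximising the accepted set. Proteins tied at the boundary score share
its fate. Every protein assigned to the class — referenced or not —
below the threshold becomes `"unknown"`; thresholding only ever
demotes, so the classified set shrinks monotonically as $q$ falls.
Estimation is per class, matching the practice of thresholding each
subcellular niche separately; classes with no referenced assignment
are left unthresholded with a warning rather than silently emptied.

# QSep: experiment-wide resolution

`qsep` summarises how well an experiment separates its niches. The raw
matrix holds mean Euclidean distances between marker clusters (cross
pairs) and within them (unordered distinct pairs; self-distances are
excluded because they would deflate the reference). The normalised
matrix divides entry $(i, j)$ by the within-cluster distance of the
*row* class, so the diagonal is exactly 1 and entry $(i, j)$ reads "how
many of cluster $i$'s spreads lie between $i$ and $j$". The reference
orientation (row vs column) is not fixed by any published description;
row-wise is the default here and the column convention is exposed via a
flag, since the matrix is genuinely asymmetric. Distance ratios are
invariant to global rescaling and rigid motion of the profile space,
which the suite verifies. Markers absent from a dataset are dropped
from their cluster with a message; classes reduced below two present
markers are an error, not a silent NA.

# Transfer learning between two maps

Two maps made with different fractionation chemistries resolve
different niches. The k-nearest-neighbour transfer scheme scores a
query against the shared markers in each map separately (class score =
fraction of the $k$ nearest markers in that class; $k$ tuned by CV,
default 5 and 5) and blends the two score vectors class-wise:

$$s_c = \theta_c \, p_c + (1 - \theta_c)\, a_c, \qquad \theta_c \in \{0, 0.5, 1\}.$$

`optimizeTheta` searches weight vectors by cross-validated macro F1
over 100 iterations. The full grid has $3^{12} \approx 5\times10^5$
combinations at study scale, beyond desk budgets, so the search is
exhaustive when $|{\rm candidates}|^{C}$ fits a configurable budget
(default 10,000) and coordinate ascent (random class order, at most 5
sweeps) otherwise; the two agree on separable fixtures, which is
tested. Tie-breaks are deliberate and deterministic: equal-F1 weight
vectors resolve toward larger $\theta$ (prefer the higher-resolution
primary map), and arg-max class ties resolve lexicographically. The
per-class *interpolating median* over iterations is the headline
vector — which is how a median of 0.75 can arise from candidates
{0, 0.5, 1}.

Two behaviours deserve explicit note. First, with per-class weights
the blended scores do not generally sum to 1 (they do for a uniform
$\theta$); predictions use the arg max, which is unaffected. Second,
when a class pair overlaps in the primary map only, zeroing *either*
member's weight repairs both classes' confusion — once one class is
scored from the auxiliary map, its competitor's markers are no longer
attracted to it — so the optimiser, preferring primary on ties, drives
exactly one member of the pair to 0 and leaves the other high. The
synthetic paired-map tests assert precisely this asymmetric signature.

# Enrichment of the unclassified proteome

More than half the proteome typically remains unclassified —
multilocalising proteins, trafficking proteins, compartments without
markers. Asking which categories are over-represented among the
unclassified must account for a selection bias: abundant proteins are
quantified more completely and classified more confidently, so
"unclassified" is abundance-biased before any biology enters.

`fitPwf` estimates $P(\text{selected} \mid \text{abundance})$ by
isotonic regression on log abundance (a small weighted
pool-adjacent-violators routine; the base-R `isoreg` has no weights and
unspecified tie handling). The monotonicity direction follows the sign
of the rank correlation, and the fit preserves the overall selection
rate exactly. The abundance convention is the maximum recorded across
replicates; proteins without an abundance value are excluded.
`categoryTest`/`enrichmentTest` then draw null selections *without
replacement with inclusion probability proportional to the fitted
weights* (exponential-keys sampling in compiled code) and report the
empirical tail probability with the $+1$ correction, so p-values are
never zero. The sampling null is used rather than a Wallenius
approximation: it is exact in the Monte-Carlo limit and dependency
free; the draw count is configurable (default 10,000) and all
categories in one batch share the null draws, the standard strategy
for this family of tests. With uniform weights the sampling p-values
match the closed-form hypergeometric tail, which the suite checks.
Significance follows the strict rule: BH-adjusted $p < 0.01$ *and* at
least 5 proteins.

# The synthetic world

`generateDataset` emulates what the pipeline needs and nothing more:

- **Templates**: one simplex profile per class per replicate block,
  each a discretised Gaussian bump peaking at a distinct fraction —
  the signature of differential pelleting. The default peak width
  (0.55 channels) is the widest at which 10 classes across 10
  fractions respect the pairwise cosine-similarity bound of 0.5;
  infeasible requests error rather than degrade.
- **Noise**: additive Gaussian (sd 0.05 per channel), clipped at zero,
  renormalised per replicate block — small relative to template peaks
  (~0.5), giving the tight, well-separated marker clusters of a good
  experiment. A Dirichlet noise model is available behind a flag.
- **Proteins**: 30 markers and 200 unknowns per class, 300
  multilocalising proteins (convex mixtures $\alpha t_1 + (1-\alpha)
  t_2$, $\alpha \in [0.3, 0.7]$, ground truth recorded as
  `mixed(c1,c2,alpha)`, never in the marker set — they exist to
  populate the unclassified region), and 200 structureless proteins.
  Abundances are log-normal (meanlog `log(1000)`, sdlog 1.5, arbitrary
  units — only the log-scale shape matters downstream).
- **Paired maps** (`generatePairedMaps`): one shared roster, two
  independently drawn maps. A designated *overlap pair* has its
  templates pushed together; by default until their separation equals
  one per-channel noise sd (pair Bayes error $\approx \Phi(-1/2)
  \approx 31\%$), the decision-theoretic reading of "overlapping
  distributions" — a fixed cosine target is also accepted. All
  generation is bit-reproducible from the seed.

What a green test on this world does **not** establish: robustness to
non-Gaussian, intensity-dependent MS noise; missing-value structure
(the generator emits complete profiles; the filter is tested on
constructed missingness); chromatographic or labelling batch effects;
marker curation errors; or classes absent from the marker set. Those
belong to real-data validation, not to this generator.

# Numerical choices and degenerate inputs

- SMO stopping tolerance 1e-3 (1e-6 in oracle comparisons); kernel
  matrices are computed once per $\sigma$ from a shared squared
  distance matrix during tuning.
- Platt fitting uses BFGS on a numerically stable log-sum-exp
  cross-entropy; pairwise probabilities are clipped to
  $[10^{-12}, 1-10^{-12}]$ before coupling.
- All stochastic steps take explicit seeds; round/iteration $r$ uses
  `seed + r`.
- Empty marker intersections, singleton QSep clusters, all-zero rows,
  degenerate (all/none selected) PWF inputs, and invalid pipeline
  configurations all error with the offending item named, before any
  partial computation is written.
- `runPipeline` writes a manifest (parameters, seed, md5 checksums,
  package version) next to its outputs and reproduces byte-identical
  outputs from an identical configuration.

# Known limitations

- The SVM score is a calibrated probability; analyses that depend on
  the *absolute* scale of a different score convention will not match
  numerically, though rankings — and therefore thresholded sets —
  behave the same.
- Per-class FDR estimation requires reference coverage in every
  class; sparsely referenced classes are left unthresholded (with a
  warning) rather than guessed.
- The enrichment module treats categories as flat sets; ontology
  structure (term graphs, propagation) is out of scope.
- QSep's orientation convention is a package choice; comparisons
  across tools should state the orientation used.
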
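---
title: "Models and methods behind nicheatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nicheatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheatlas)
```

# Scope

`nicheatlas` re-implements, as a tested and reusable pipeline, a
spatial-transcriptomics analysis workflow for pancreatic ductal
adenocarcinoma (PDAC): per-patient spot clustering and cell-type
annotation, cross-patient marker meta-analysis, basal/classical subtype
calling, a linear classical-to-basal pseudotime trajectory, gene-set
enrichment and ligand–receptor testing, and grade-graded multiplex niche
statistics with survival comparison. Because every stage needs a
recoverable right answer to be testable, the package ships a seeded
synthetic cohort generator that plants known ground truth; the generator is
first-class, tested code, not a fixture.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohorts do and do
not emulate.

# The synthetic cohort model

`cohort_config()` / `generate_cohort()` produce a multi-patient spot cohort:

* **Spatial layout.** Spots are uniform on the unit square per patient. The
  locally dominant cell type comes from patient-specific Voronoi patches
  (cancer receives three seed points, every other type one), so neighboring
  spots share a type and patch borders produce genuinely mixed spots.
  Voronoi patches were chosen over Gaussian random fields: they are simple,
  exactly reproducible, and give crisp region boundaries like real tissue
  sections.
* **Spot composition.** Each spot's mixture over the five cell types
  (cancer, fibroblast, acinar/ductal, immune, endocrine) is
  Dirichlet-distributed with concentration `dirichlet_purity` (default 10)
  on the dominant type plus a background 0.3 on every component. As purity
  grows the mixture converges to one-hot; at the default the dominant type
  holds ~90% of a spot on average, emulating 55-µm spots that always
  capture several overlapping cells.
* **Expression programs.** Every type elevates its program genes 4-fold
  over baseline; each type additionally plants 10 *congruent markers* at
  8-fold — the pan-patient markers downstream meta-analysis must recover.
  Marker lists are disjoint across types, and marker and signature genes
  have their baseline abundance floored at the cohort median: a canonical
  marker that nobody can detect would not be a marker.
* **The classical-to-basal continuum.** Cancer-dominant spots carry a
  latent coordinate t ∈ [0, 1] (uniform by default,
  `continuum_fraction = 1`). The 50-gene classical arm decays linearly from
  8× at t = 0 to baseline at t = 1; the basal arm mirrors it. The 8× dynamic
  range (log2FC = 3) matches strong published basal-vs-classical markers. A
  sigmoidal ramp is available behind `sigmoid_mixing = TRUE`.
* **Counts.** Expected expression is the mixture-weighted sum of programs
  times a per-patient log-normal batch factor (`batch_sd = 0.1`) and a
  log-normal library size (mean 20,000, typical spot depth). Counts are
  negative binomial with gene-shared dispersion φ = 0.1
  (variance μ + φμ²). All randomness flows from one seed with derived
  per-patient streams; identical configurations are bitwise reproducible.

The defaults are deliberately calibrated so that the planted continuum is
the *leading* axis of cancer-spot variation — as subtype identity is in
real PDAC — and batch variation is subordinate to it. That is what makes
the planted answer recoverable by an unsupervised pipeline. Real cohorts
are not guaranteed to satisfy this: with `batch_sd` at 0.2 the
patient effect overtakes the continuum in the pooled embedding and pooled
trajectory recovery degrades sharply (per-patient trajectories, as used in
practice, are then the right tool). Passing tests on the default cohort
therefore demonstrate correctness of the machinery under conditions where
the signal is recoverable, not robustness to arbitrary batch structure,
dropout chemistry, or segmentation artifacts, none of which are modeled.

`generate_multiplex_cells()` emulates segmented-cell intensity tables from
cyclic immunofluorescence: log-normal intensities (sdlog 0.5), declared
markers carry multiplicative grade-monotone median shifts across the grade
groups G1-2 / G2 / G2-3, and a 25% stromal contaminant (collagen-high,
MUC1-low) gives the default cancer gate something to remove. Cell counts
default to roughly one tenth of a realistic graded-region census so the
test suite stays fast; the statistics are sample-size-calibrated, not
tuned to these counts.

`generate_bulk_cohort()` mixes the two subtype programs into
negative-binomial bulk libraries (mixed samples sit halfway on both arms)
and draws overall survival from subtype-specific exponential hazards
(classical 0.02/month, basal 0.06/month, mixed 0.035) with independent
exponential censoring plus a 120-month administrative horizon — a hazard
ratio of 3 between poles, in the range reported for basal-like disease.

# The spot pipeline

Quality control removes spots detecting fewer than 200 genes (a spot at
exactly 200 is retained) plus a user-supplied exclusion list standing in
for morphology- and fold-based manual exclusion. Normalization is
library-size scaling to 10⁴ followed by log1p; the upstream platform's
proprietary pretreatment is not recoverable, so this standard choice is
fixed and documented. Highly variable genes are ranked by
variance-over-mean dispersion computed on de-logged normalized expression
(the classic Seurat flavor); computing dispersion on the log scale instead
inverts the ranking toward low-abundance sampling noise. Auto-scaling is
per-gene z-scoring with clipping at ±10. PCA (30 components) fixes each
component's sign so its largest-magnitude loading is positive. The kNN
graph (k = 10, Euclidean metric in PCA space, unweighted union of directed
relations) feeds Louvain at resolution 0.8; the implementation canonicalizes
vertex order by spot name (making the pipeline equivariant to spot order)
and takes the best of five randomized restarts under the given seed.
Cluster annotation scores each cluster by mean auto-scaled expression of
each canonical marker panel: argmax assigns the type, a second-best score
within 75% of the best flags `mixed`, and a nonpositive best score flags
`ambiguous`.

Clustering runs on the PCA-space graph, not on any 2-D embedding:
low-dimensional projections are for display only.

# Marker meta-analysis

Per-cluster markers come from a one-vs-rest two-sided Wilcoxon rank-sum
test plus log2 fold change of means (pseudocount 1e-9); markers are the
positive-fold-change genes ordered by p, then fold change, then gene id,
with Benjamini–Hochberg adjustment across all tested genes.

Cross-patient congruence takes the top-50 markers per patient (top-100 for
similarity analyses): exclusive intersection sizes for every patient subset
(the counts behind an UpSet plot; bitmask enumeration, refused above 24
patients), the congruent set of genes present in at least `min_patients`
lists, pairwise Jaccard similarity |A∩B| / |A∪B| with a 3-component PCA of
the similarity matrix, and a penalized rank product: within each
comparison all genes are ranked ascending by fold change (ties get average
ranks, the strongest gene the highest number), genes absent from a
comparison receive rank 1 — the strongest reading of penalizing
inconsistent up-regulation — and the meta-order is by descending product.
The rank product consumes the *full* per-comparison fold-change vector so
down-regulated genes keep their low ranks.

# Subtype calling

Bulk cohorts are TMM-normalized (Robinson–Oshlack trimmed mean of
M-values via edgeR: 30% log-ratio trim, 5% abundance trim, precision
weights, factors renormalized to geometric mean 1). Signature scoring
averages expression per unit first — damping cell-to-cell stochasticity —
then auto-scales each signature gene across units; a unit's arm score is
the mean scaled expression of that arm. Units are clustered with Euclidean
distance and complete linkage; where the source workflow cut the dendrogram
by hand, `call_subtypes()` automates it: cut into two primary clusters,
label each by its higher mean arm score, and relabel any unit whose
classical–basal score gap falls below τ = 0.5 (in auto-scaled score units)
as `mixed`. Bootstrap clade support (default 10,000 row resamples,
threshold 0.95) reports how often each 2-cut cluster recurs as an exact
clade.

Differential expression between subtype pseudobulks uses log2-CPM with a
per-gene Welch t whose group variances are shrunk halfway toward the mean
variance across genes. The half-weight shrinkage corresponds to a prior
with as many degrees of freedom as the residual, so the reference
distribution uses twice the Welch–Satterthwaite degrees of freedom — a
fixed-weight stand-in for a full empirical-Bayes fit, calibrated by
null simulation rather than by equivalence to any particular
implementation. The shrinkage assumes roughly exchangeable gene-wise
variances; heavily heteroscedastic inputs (orders-of-magnitude spread in
expression) will miscalibrate it, which is one reason DGEA operates on
pseudobulk profiles of moderately expressed genes.

For pathway mapping, log fold changes A are compressed with

f(A) = −0.5 + 1 / (1 + e^(−10·A)),

an odd, strictly increasing sigmoid bounded by ±0.5, matching a pathway
color scale from −0.5 to 0.5.

# Trajectory inference

The linear pseudotime stage works in three steps, re-implemented rather
than delegated so every numerical choice is explicit:

1. **Spearman distance** d = (1 − ρ)/2 between spot profiles over the
   highly variable genes (midranks for ties), mapping identical profiles
   to 0 and perfectly reversed rankings to 1.
2. **Classical (Torgerson) MDS** into 3 components; nonpositive
   eigenvalues are truncated and padded with zeros.
3. **Principal curve.** k-means (k = 4, 10 restarts, seeded) summarizes
   the embedding; the shortest Hamiltonian path through the centroids
   (exhaustive for k ≤ 8, greedy + 2-opt beyond) seeds a piecewise-linear
   backbone, refined by up to 10 iterations of project-order-smooth:
   points are projected onto the curve, ordered by arc length, the curve
   is recomputed as centered moving averages (window = 10% of n, minimum
   3) and resampled to 100 points, stopping when the mean curve shift
   drops below 1e-4. Both curve ends are then extended — along a
   direction taken a few resampled points inward, far enough to cover
   only the points that project onto the endpoints — so boundary spots
   keep distinct arc positions. Pseudotime is the normalized arc-length
   position (min 0, max 1).

Orientation is by the classical program: if the mean classical-arm score
in the first pseudotime quartile is below that in the last quartile, the
axis is flipped, so classical expression always declines along pseudotime.
The rule is idempotent. Marker kinetics use a degree-0 LOESS-style
smoother: at each of 100 grid points the span fraction (default 0.75) of
nearest observations are tricube-weighted, w = (1 − (d/dmax)³)³, and
averaged. Degree-0 local averaging has edge bias like any moving average;
its 5%-accuracy band for smooth signals is roughly the middle half of the
axis. Methods defaults select the top 2000 highly variable genes for the
distance; the full-gene-set variant used by some displays is a flag, not
the default.

# Enrichment and interactions

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum with
weight exponent 1: walking down the ranking, set members add
|s| / Σ|s over members| and non-members subtract 1/(N − n); the enrichment
score is the signed extremum. Sets with fewer than 5 detected genes are
skipped. The null permutes gene labels; NES divides ES by the mean
|null ES| of matching sign, and p is the add-one same-sign tail. Per-sample
set scores z-score each sample across genes and subtract the non-set mean z
from the set mean z — shift-invariant per sample and sufficient for
downstream set-level differential testing; the full kernel-CDF scorer of
GSVA is deliberately not reproduced.

The ligand–receptor test scores a pair as ½(mean ligand in sender + mean
receptor in receiver), builds the null by shuffling the full cell-type
label vector 1,000 times (the same shuffles for every pair, so null
sender/receiver groups stay disjoint), and retains interactions with mean
> 0.5 and add-one permutation p < 0.05, directionally. Ligand–receptor
pairs are a user-supplied table; no curated interaction database is
bundled. Optional subsampling of cells is exposed as a flag.

# Niche and survival statistics

Cancer cells in graded regions are gated by the conjunction MUC1 > 50 and
Collagen I < 500 (defaults, overridable as explicit rules). Intensities
are normalized per marker to the median of the pooled G1/G1-2 reference
group. Per marker: a tie-corrected Kruskal–Wallis test across grade
groups, Dunn's pairwise z with the standard tie correction
T = Σ(t³ − t)/(12(N − 1)), and log2 fold changes of median normalized
intensity versus the reference. All Dunn p-values — across markers and
pairs jointly — enter one two-stage step-up FDR adjustment: stage-1 BH at
q/(1+q), null count estimated as m − r₁, stage-2 BH at (q/(1+q))·m/m₀,
with adjusted p defined as BH-adjusted p × (m₀/m)(1+q) so that
`adjusted ≤ q` reproduces the two-stage rejection set exactly. Pooling
across markers is a deliberate choice (the alternative, adjusting within
marker, controls a different error rate per marker; pooled control is the
stricter, simpler guarantee). Spearman correlations are classified
moderate above |ρ| = 0.3 and strong above 0.5.

Survival uses the Kaplan–Meier product-limit estimator and a
Gehan–Breslow–Wilcoxon test: a weighted log-rank with weight equal to the
total number at risk at each event time (Breslow convention), emphasizing
early deaths; the statistic is the quadratic form over g − 1 groups with a
generalized inverse guarding degenerate configurations, chi-square with
g − 1 degrees of freedom. `survdiff`'s rho family implements Peto–Peto,
not n-at-risk weights, hence the from-scratch implementation —
cross-checked in the tests against an independent evaluation of the
defining sums and calibrated by null simulation (type-I error 0.05 ± 0.02
at hazard ratio 1).

# Problem sizes and determinism

The default synthetic cohort is 6 patients × 400 spots × 1,200 genes
(~1,000 cancer spots), chosen as the smallest scale at which every planted
structure — five cell types per patient, 50 congruent markers, a
continuum over ~100 genes, subtype survival differences — is comfortably
identifiable; trajectory recovery uses 800 cancer spots. Bootstrap and
permutation defaults follow the documented settings (10,000 / 1,000);
tests use smaller replicate counts where the property under test is
calibration rather than precision. Every stochastic stage takes an
explicit seed, and the full pipeline writes a checksum manifest so a rerun
with the same seed is verifiably identical.

# Known limitations

* The generator plants linear (optionally sigmoidal) continua and
  homogeneous NB dispersion; it does not emulate platform-specific dropout,
  spatial autocorrelation beyond Voronoi patches, or realistic gene names.
* Subtype calling automates a dendrogram cut that was originally manual;
  on cohorts whose signature structure is not bimodal the 2-cut labeling
  degrades to the τ-margin rule alone.
* The fixed-weight moderated t is not an empirical-Bayes fit; see above
  for its exchangeable-variance assumption.
* Pooled trajectories assume batch variation subordinate to the biological
  continuum; otherwise infer per patient.
* Branching trajectories, RNA velocity, UMAP embeddings, and image
  segmentation are out of scope.
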
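---
title: "Integrative species delimitation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intdelim)
```

`intdelim` implements a species-delimitation workflow for closely related
diploid plant lineages that weighs four layers of evidence — genealogy
(RADseq SNPs), leaf morphometry, ecological niches, and geographic overlap
— and turns them into a per-taxon-pair evidence table and a taxonomic rank
decision. This vignette documents the statistical models, the parameters
that matter, the numerical choices, and what the synthetic-data generators
do and do not emulate.

## The genealogical layer

**Distances.** Concatenated-SNP matrices (one IUPAC-coded character per
diploid call) yield pairwise distances in two flavors. The Kimura
two-parameter distance treats calls as haploid bases with pairwise
deletion and separates transition (P) and transversion (Q) fractions:
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$. Heterozygous ambiguity
codes are deleted pairwise by default because the K2P substitution model
is defined on haploid sequences; a `split_alleles` mode that doubles each
site into its two alleles is available instead. The SNP-level Nei distance
keeps diploid information: each individual's genotype is an
allele-frequency vector (1 / 0.5 / 0), and
$d = -\ln\left(J_{xy}/\sqrt{J_x J_y}\right)$ over sites shared by the pair.
Pairs with no shared sites, or with a non-positive logarithm argument, are
*flagged undefined* rather than set to zero; downstream ordination refuses
undefined cells and a greedy `drop_undefined_samples()` helper removes the
fewest samples needed.

**Ordination.** Principal coordinates analysis double-centers the squared
distances and eigen-decomposes. Negative eigenvalues (non-Euclidean
residue) are dropped from both the coordinates and the variance
denominator — the simplest defensible reading of a "retain axes explaining
at least 80% of variance" rule; no Cailliez correction is applied. The
retained-axis count is the shortest prefix reaching the threshold
(default 0.8).

**Consensus K-means.** Species discovery runs K-means on random subsamples
of the retained principal coordinates: per replicate, 80% of observations
and 80% of features (both configurable), k-means++ initialization, one
start per replicate — the randomness budget is spent across replicates
(default 5000), not restarts. Co-clustering counts over co-sampling counts
form the consensus matrix; final labels cut an average-linkage
agglomeration of `1 - consensus` at *k* (the linkage is configurable; the
reference literature leaves it unspecified). Cluster-number selection
computes the silhouette index (singletons contribute 0) and the
Davies–Bouldin index *in the retained coordinate space on the final
labels* — the standard definitions — rather than on the consensus matrix;
the scan reports the SIL-optimal and DB-optimal *k* plus local DB optima
and never arbitrates when they disagree, mirroring how such disagreements
are interpreted by eye. Runs can exclude flagged hybrid samples via an
exclusion list so that scans with and without hybrids are one-liners.

**Hybrid screening.** Patterson's D over individual triplets plus an
outgroup: with derived-allele frequencies polarized by the per-site
majority consensus of a designated outgroup taxon (tied or missing
consensus drops the site, as do sites that are not biallelic across the
four roles), $D = (\mathrm{ABBA} - \mathrm{BABA})/(\mathrm{ABBA} +
\mathrm{BABA})$ with frequency-weighted pattern sums. Significance comes
from bootstrap resampling of sites (or of loci when locus ids are
supplied, respecting within-locus linkage), $Z = D/\hat\sigma_{boot}$ and a
two-sided normal p-value. The screen enumerates, for every pair of focal
taxa, all within-taxon individual pairs against every individual of the
other taxon, Bonferroni-corrects over the executed test count, and flags
the introgressed candidate of each significant triplet (the pair member
sharing excess derived alleles with p3 — p2 when D > 0, p1 when D < 0).
Within one screen a single shared site-resampling plan is drawn and reused
by every test; each test's bootstrap remains a valid site bootstrap while
the screen stays fast, and a per-test multinomial plan is used whenever a
test is run on its own. The default screen alpha is 0.01 on corrected
values; both uncapped and capped-at-1 corrected p-values are stored.

## Assembly scoring and model-complexity knees

RADseq assembler parameter sweeps are scored from in-vitro replicates:
locus error `EL` (loci recovered in exactly one replicate over loci in at
least one), SNP error `ES` (mismatching calls at shared loci), and the
missing-data percentage `MS`, combined as
$(1-EL)\,(1-ES)\,\exp\!\big(-(MS-\mu)^2/(2\sigma^2)\big)$ with
$\mu = 50,\ \sigma = 50$. The Gaussian factor is an *unnormalized* kernel
(1 at the target), keeping the score in [0, 1]. Two deliberate quirks are
worth flagging: the expression is a score to *maximize* (the literature
labels it a cost function but selects the maximizer), and the kernel
center at 50% means an assembly with *less* missing data than the target
scores lower, all else equal — the target encodes a trade-off against
overly strict locus filtering. Ties in the grid selection break by lower
EL, then lower ES, then MS nearest the target.

Marginal-likelihood-versus-complexity curves from coalescent species
delimitation are summarized by their knee, found with the Kneedle
algorithm: min–max normalize both axes, orient to concave-increasing,
form the difference curve $y_d = y_n - x_n$, and accept the first local
maximum whose following values drop by more than
$S \cdot \overline{\Delta x_n}$ before the next local maximum
(sensitivity $S = 1$ by default; no pre-smoothing, since the curves here
have few points). Curves that are straight or convex-increasing have no
knee and say so, and the result is invariant to affine rescaling of
either axis.

## The morphometric layer

Leaves arrive as CVAT-style annotations: a contour polygon and a midvein
polyline per leaf, in pixel units with the image y-axis pointing down.
The reader pairs shapes by containment and orients midveins base-to-tip
by comparing the local contour width near the two polyline ends (the base
of these leaves is the wider end).

**Straightening.** Herbarium leaves are often bent, which distorts
outline descriptors. The reconstruction is: (1) a conforming constrained
Delaunay triangulation of the contour interior with the contour and
midvein segments as constraints — incremental Bowyer–Watson with
constraint midpoints inserted (Steiner points) until every constraint is
a mesh edge, a jittered interior grid plus centroid splitting keeping
triangles below the area target; (2) midvein vertices pinned to the
horizontal axis with their original consecutive spacing (arc length is
conserved exactly by construction); (3) the remaining vertices solved by
as-rigid-as-possible (ARAP) local–global iterations with cotangent
weights; (4) optional texture transfer through shared barycentric
coordinates. Numerical choices: cotangent weights clamped at zero (no
negative weights), hard midvein constraints eliminated from the sparse
system, one Cholesky factorization reused across iterations, convergence
when the largest per-iteration vertex displacement falls below `1e-6`
(pixels) with a 100-iteration cap — non-convergence returns the last
iterate with a warning flag and the residual. The initial guess places
each vertex at its arc-length/signed-offset coordinates about the
midvein, which is the exact inverse of a constant-curvature bend and in
practice a few dozen iterations from the fixed point. Midvein vertices
within a scale-relative snap tolerance (`2e-4` of the leaf extent) of a
contour vertex are merged so that annotation endpoints on the outline do
not create degenerate slivers.

**Descriptors.** Elliptic Fourier analysis (Kuhl–Giardina) on the
(straightened) contour with 15 harmonics by default; descriptors are
normalized for size, rotation and starting point by first-harmonic
standardization, after which $a_1 = 1$ and $b_1 = c_1 = 0$. The residual
half-turn ambiguity of the orientation (which negates even harmonics
only) is resolved by making the dominant even-harmonic coefficient
positive. The non-constant coefficients feed a centered, *unscaled* PCA
(covariance, not correlation — the coefficients share units, and the
first harmonics should dominate); the first two PC scores feed the shape
test. The leaf-dissection index is
$\mathrm{LDI} = \mathrm{perimeter}/(2\sqrt{\pi \cdot \mathrm{area}})$
(1 for a circle).

**Tests.** The shape permutation test uses the mean Euclidean distance
between all cross-group pairs in the 2-PC plane (the centroid distance is
available behind a flag); the null permutes pooled labels preserving
group sizes, with the add-one correction
$p = (1 + \#\{null \ge obs\})/(B + 1)$, one-sided toward "distinct".
The pooled rows are canonicalized before permuting so the test is exactly
symmetric in its two arguments. Dissection differences use Welch's
unequal-variance t-test. Bonferroni correction uses a caller-supplied
multiplier — 6 for a Table-1-style family of six pairwise comparisons —
and values are reported both uncapped and truncated at 1.

## The ecological and geographical layers

Environmental stacks are plain lon/lat rasters (ESRI ASCII grid I/O);
soil variables sampled at several depths are depth-averaged cell-wise
ignoring no-data. Stacks are z-score normalized per layer and reduced by
PCA across cells, keeping the leading component rasters (default 3) with
the no-data mask propagated exactly.

The ecological niche model interface is pluggable: the builtin model is a
Gaussian envelope (per-layer mean/sd on the occurrence cells, suitability
the product of per-layer responses rescaled to a maximum of 1; background
points are accepted for provenance but unused), and `external-raster`
validates and passes through a suitability raster from any external ENM
such as MaxEnt. Niche overlap is Schoener's
$D = 1 - \tfrac12\sum_i |p_a(i) - p_b(i)|$ on sum-normalized
suitabilities; the niche-equivalency test pools the two occurrence sets,
reassigns them randomly at the original sizes, refits both models, and
compares observed D against the null with a one-sided lower tail.

Approximate species distributions come from a thresholded flood fill: a
depth-first search from every occurrence cell through grid-connected
cells with suitability at or above 0.25 (8-neighborhood by default —
diagonal adjacency matters at coarse cells; 4-neighborhood available).
Unvisited cells are zeroed, visited cells keep their suitability values,
and occurrence cells are set to 1. Keeping values (rather than
binarizing) is the only reading consistent with the overlap recipe that
follows, which *multiplies* the two distribution rasters, re-thresholds
the product at 0.25, counts non-zero cells, and divides by the smaller
species' non-zero cell count. A consequence worth knowing: the overlap of
a distribution with itself is below 1 whenever cells with suitability
under 0.5 are present, so "complete sympatry" manifests as the maximal
overlap attainable for the data rather than exactly 1. The sympatry test
permutes taxon labels over pooled occurrences and redoes the whole
ENM-to-overlap chain (with longitude/latitude rasters appended to the
predictors for this chain only), one-sided toward *lower* overlap: a
significant result is an allopatry signal.

## Integration and ranking

The evidence table holds, per unordered taxon pair, the raw p-values of
the four tests (niche D, EFA shape, LDI, geographic overlap), corrected
with one shared Bonferroni multiplier and stored uncapped and capped,
with significance flags at the configured alpha (default 0.05; the
D-statistic screen uses 0.01). The rank rules follow the
morpho-geographical species concept: genealogically distinct and
sympatric lineages are species (cryptic when not morphologically
distinct); genealogically distinct allopatric lineages are species only
when ecologically distinct, otherwise subspecies; without genealogical
independence, ecological distinctness supports at most an
ecotype/subspecies, and with no independence on any axis the pair merges.
"Sympatric" is operationalized as *failure to reject* sympatry at the
configured alpha — an absence-of-evidence caveat that the report records.
Unknown inputs make a pair `undecided`, listing the gaps; an unknown
morphology flag does not block decisions for which morphology is not
pivotal. Genealogical distinctness is an input flag: the bundled pipeline
derives it from the consensus labels (a pair is distinct when clusters
and taxa form a bijection at the pair's natural *k*), and external
coalescent-based validation can override it.

## What the synthetic data emulate — and what they do not

The generators exist so the whole pipeline runs and is testable with no
downloads; their defaults are the study conditions used throughout the
tests.

* **SNP matrices** follow a Balding–Nichols-style drift model down a
  population tree: ancestral frequencies uniform on [0.05, 0.95] per
  site, child frequencies Beta-distributed with drift F per branch,
  diploid genotypes Binomial(2, p) encoded as IUPAC characters, missing
  calls masked independently. This produces the hierarchical structure,
  heterozygosity and missingness that the distance/clustering/D-statistic
  stages assume, but *not* linkage within RAD loci, coalescent gene-tree
  variance, sequencing error, or allele dropout. F1 hybrids draw one
  allele per site from each parent's empirical frequencies — the
  strongest, cleanest ABBA-BABA signal; backcrosses dilute it.
* **Leaves** are parametric pinnately-lobed silhouettes (asymmetric width
  profile, cosine lobes with depth saturating in the dissection
  parameter, small seeded shape jitter) bent through a constant-curvature
  arc map with arc length preserved; the bent midvein is chord-corrected
  so its polyline length equals the straight one's exactly. Real leaves
  bend irregularly and tear; constant curvature is used because it has an
  analytic inverse, giving exact ground truth for the straightening
  tests. Passing those tests shows the geometry pipeline is correct, not
  that every herbarium leaf straightens within 2%.
* **Landscapes** are sums of seeded Gaussian bumps; the first two layers
  carry deterministic west-east / south-north gradients so environmental
  similarity correlates with geography (as it does for real climate
  surfaces). True suitabilities are Gaussian responses around
  scenario-dependent anchors (identical / adjacent / opposite corners for
  sympatric / parapatric / allopatric), and occurrences are sampled
  without replacement proportional to suitability. No spatial sampling
  bias, no projection issues, no collinear predictor pathologies.

## Problem sizes used in the bundled checks

The package's own test-suite and the acceptance script run everything on
reduced but statistically meaningful sizes chosen to keep a full run in
the minutes range: population recovery uses 5 populations x 6 diploids x
2000 SNPs at F = 0.3 with 500 consensus replicates over a k range of 2-8;
the hybrid screen uses 3 focal taxa x 4 individuals plus an outgroup at
5000 SNPs with a 100-replicate bootstrap; straightening fidelity uses
leaves of 128 contour points with curvature-length products up to 0.8;
the permutation-test calibrations use 99-permutation tests across
100-200 simulated null datasets; the three-scenario demo runs the full
chain with 300 consensus replicates, 999 shape permutations and 99
geographic permutations. The reference analyses these defaults stand in
for (5000 consensus replicates, 5000 shape permutations, 400 geographic
permutations) are one configuration argument away.

## Known limitations

* The conforming triangulation uses double-precision incidence tests, not
  exact geometric predicates; pathological annotations (near-duplicate
  vertices, hairpin polygons) can defeat it. It is robust on digitized
  leaf outlines and all bundled generators.
* The builtin Gaussian ENM is deliberately simple; it serves the
  permutation machinery and the pluggable interface, not as a MaxEnt
  substitute. Cross-validation AUC reporting is out of scope.
* Bootstrap significance for D assumes site (or locus) exchangeability;
  the screen's shared resampling plan correlates tests within a screen,
  which leaves each test's calibration intact (and the Bonferroni union
  bound valid) but makes test outcomes within one screen positively
  dependent.
* PCoA negative eigenvalues are dropped, not corrected; with strongly
  non-Euclidean distance matrices the retained-variance rule is then
  optimistic.
* The rank rules are a faithful mechanization of a verbal framework;
  borderline profiles (e.g. conflicting genealogical flags from different
  methods) surface as `undecided` rather than being resolved silently.
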
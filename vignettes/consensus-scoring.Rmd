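---
title: "Consensus scoring for multi-criteria protein structure comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scoring for multi-criteria protein structure comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpsc)
```

## Why consensus scores

No single protein structure comparison (PSC) algorithm dominates:
methods differ in their similarity metrics, their failure modes (some
binaries simply fail on a fraction of pairs), and the hierarchy level
at which they discriminate best. When the best method for a dataset is
unknown — the usual case — fusing several methods' pairwise scores
into a consensus is more robust than betting on one. `mcpsc`
implements that fusion and the analyses used to judge it, against a
4-level classification hierarchy (class, fold, superfamily, family;
labels written `a.1.1.1`).

The pipeline runs in a fixed order: raw pairwise scoring → conversion
to dissimilarities → per-method sigmoid autoscaling → mirroring to the
full ordered-pair matrix → local-average imputation → consensus
schemes M1–M5 and their median → evaluation and visualization.
Scaling precedes imputation deliberately, so imputation operates on
commensurable similarities in (0, 1) rather than on raw scores with
method-specific ranges.

## Score scaling

Methods report on incompatible scales and polarities. Raw similarity
scores are negated (any strictly decreasing map is equivalent after
the autoscaling that follows, and negation needs no assumption about
the score's range); dissimilarity scores pass through. Each method's
dissimilarities X are then autoscaled by their mean μ and standard
deviation σ and squashed:

$$S = 1 - \frac{1}{1 + e^{-(X-\mu)/\sigma}}$$

so every method contributes similarities in (0, 1) with its typical
score at 0.5. Two conventions are fixed here: σ is the *population*
standard deviation (the statistic is taken over all of the method's
scores, not a sample of them; the choice only rescales the sigmoid's
slope), and a degenerate method with σ = 0 maps to 0.5 everywhere —
the sigmoid's midpoint, keeping downstream weighted averages finite
and the method uninformative, which is what a constant scorer is.

A useful consequence checked by the test suite: the scaled scores are
invariant to any positive-slope affine transform of a method's raw
dissimilarities, so methods reporting in Å, normalized units, or
arbitrary gauges are treated identically.

## Missing pairs and imputation

Real PSC binaries fail on some pairs (structure-file quirks, internal
thresholds), so per-method *coverage* — the fraction of the
P = N² − N ordered pairs scored — varies. Classification and
clustering need complete matrices, hence local average fill: for a
missing ordered pair (dᵢ, dⱼ), take all of the method's scores where
dᵢ appears as first domain, merge with all scores where dⱼ appears as
second domain, and impute the mean of the merged multiset (a record
belonging to both directed sets contributes once); when both sets are
empty, fall back to the method's global mean. The directed
(first-domain / second-domain) reading is implemented literally; only
pre-imputation values feed the fill, so the result is deterministic
and independent of the order in which pairs are processed.

Downstream, three views of the data are kept and evaluated side by
side: **original** (missing values retained; per-pair weights
renormalize over the methods actually available), **common** (only
pairs scored by *every* method), and **imputed** (fully filled). The
distance matrices used by nearest-neighbor classification and the
visualizations set missing entries to the maximum dissimilarity 1, so
that proximity always reflects an observed similarity.

## The consensus schemes

Per pair, with m ≤ M methods available and weights renormalized to
sum to one over those m:

* **M1** — generalized mean $((1/m)\sum S_i^q)^{1/q}$ with q = 1 by
  default, i.e. the plain average. q is exposed as a parameter but no
  alternative value is tuned or validated here.
* **M2** — coverage weighting, $w_i = s_i / P$: methods that scored
  more of the dataset count more.
* **M3** — M2 multiplied by per-method expert priors. The default
  prior is 1; the built-in compression-based scorer defaults to 0.5,
  the conventional discount for a structure-agnostic method.
* **M4** — divergence weighting. For methods i, j the divergence
  $RMSD_{ij} = \sqrt{\tfrac{1}{P'}\sum_k (S_{ki}-S_{kj})^2}$ is
  computed over the P′ pairs where **both** methods have
  pre-imputation scores (pairs with either score missing are excluded,
  and the normalization uses the count of included pairs, so
  divergence is not conflated with coverage). Then
  $r_i = \tfrac{1}{M}\sum_j RMSD_{ij}$ and $w_i = r_i/\max_i r_i$ —
  an outlier method is *up*-weighted, valuing the independent signal
  it contributes. When all methods agree exactly (all $r_i = 0$) the
  scheme degenerates to equal weights.
* **M5** — user-supplied relative weights, or weights learned from the
  ground truth: a logistic regression of same-vs-different (at a
  chosen level) on the imputed score matrix, trained on a seeded
  random 10% of pairs by default, returning normalized absolute
  coefficients. The learning variant is this package's own
  reconstruction of the idea (feature construction and regularization
  were open design choices; plain unregularized `glm` on the scaled
  scores is used); with no weights and no training request, M5 falls
  back to equal weights.
* **median** — the middle order statistic of M1..M5, the recommended
  single consensus when nothing is known in advance: it tracks the
  majority of schemes and is insensitive to one scheme misbehaving.

Every scheme is a convex combination of the available scaled scores,
so consensus values stay in [0, 1] and within the per-pair score
envelope — a property the test suite checks, along with exact
agreement (to 1e−12) between the pipeline and an independent
brute-force transcription of all the formulas on hundreds of small
random tables.

## Built-in scorers

So that consensus can be exercised with no third-party binaries, two
genuinely heterogeneous scorers are built in:

* **usm** — a universal-similarity-metric style compression distance
  over Cα contact maps (8 Å cutoff, sequence separation ≥ 2). With
  C(x) the compressed byte length of a map's row-major serialization,
  the distance is `max(C(ab) − C(a), C(ba) − C(b)) / max(C(a), C(b))`,
  clamped at 0. Values depend on the compressor; it is pinned per run
  (gzip by default) and recorded in the run metadata. Real compressors
  do not give exactly 0 on self-comparison, only values near 0.
* **kabsch** — both Cα traces are truncated to their common leading
  length, optimally superposed (Kabsch algorithm; the rotation is
  reflection-corrected to determinant +1, which also resolves
  rank-deficient degenerate inputs), and the RMSD is mapped to
  `1/(1 + RMSD/R0)` with R0 = 3 Å — a bounded similarity on a scale
  where 3 Å, a typical "same fold" RMSD, maps to 0.5. Truncation
  rather than alignment is a deliberate simplification: these scorers
  exist to feed the consensus machinery, not to compete with dedicated
  aligners.

External methods are declared with a command template containing
`{pdb1}`/`{pdb2}` placeholders and a stdout regex; non-zero exits,
timeouts (120 s default) and unmatched output become missing scores
rather than errors, surfacing as reduced coverage exactly like a real
binary's failures. All |pairs| × |methods| jobs are distributed over p
worker processes; results are keyed by (pair, method), never by
completion order, so the output is bit-identical for any p.

## Evaluation

**ROC/AUC.** Pairs are positive when their domains match at the chosen
level (default 3, superfamily). The similarity threshold sweeps from
above the maximum score to below the minimum; the set of observed
unique scores is used as the threshold grid — exact and
resolution-independent, equivalent to an arbitrarily fine sweep. "Score
strictly greater than the threshold" is called positive; scores equal
to the threshold fall on the negative side. AUC is the trapezoidal
area; the suite verifies it against the rank-sum identity and its
invariance under monotone transforms. ROC uses unordered pairs only
(the mirrored orientation duplicates the information).

**Nearest-neighbor classification.** Each domain in turn is a query;
its nearest non-self neighbor (distance 1 − S) donates its label, and
the prediction is scored at each level. Distance ties break to the
lexicographically smallest neighbor id — a deterministic stand-in for
unspecified behavior. Domains whose distances are all at the missing
sentinel are still classified (their prediction is
arbitrary-but-deterministic), so every domain is counted.

## Visualization choices

**MDS.** Metric multidimensional scaling by SMACOF stress
majorization, implemented directly (repeated Guttman transforms, which
never increase the stress). Starts are random but seeded, and several
restarts (default 4) are run with the lowest-stress result kept, so
coordinates are deterministic given the seed while local minima are
avoided; convergence is declared when the relative stress decrease
falls below 1e−12. Reported stress is normalized,
`sqrt(Σ(d−δ)² / Σδ²)`.

**Neighbor-joining trees.** Canonical Saitou–Nei neighbor joining (via
`ape`), exact on additive distances; negative branch lengths are
clamped to 0 afterward. Trees are written as Newick and rendered
unrooted with tips colored by class (colors assigned by sorted class
name, hence deterministic).

**Heatmaps.** Domain-level and group-level; the group-level entry for
folds F, G is the *mean* pairwise distance between their domains
(self-pairs excluded on the diagonal; a singleton group's diagonal is
0 and flagged). The mean is one of several defensible summaries; it is
labeled as such.

## The synthetic generator, and what the tests show

`planted_config()` defines a planted 4-level hierarchy; its defaults
are the package's reference study conditions: 2 classes × 2 folds × 2
superfamilies × 2 families × 4 domains = 64 domains, level
separations (4, 2, 1, 0.5) dissimilarity units (so same-family pairs
sit at 0 and different-class pairs at 7.5), Gaussian per-method noise
with sd 0.25, and full coverage unless thinned. Those sizes keep every
property of interest visible (all four levels populated, class
structure recoverable) while the full test suite runs in well under a
minute; the acceptance script uses the same 64-domain default plus a
270-domain pair-count recomputation, 50 random 4–8-taxon trees for
neighbor joining, and 10-point embeddable sets for MDS.

The generator emulates the *statistical* structure the analyses
assume — similarity concentrated within classes and folds, per-method
noise and heterogeneous coverage — not real protein data: noise is
Gaussian (no heavy tails), thinning is independent per pair (real
failures correlate with particular structures), and the toy PDB
structures are ideal helix/strand Cα traces with family-level
deformations, not physical decoys. Green tests therefore demonstrate
that the machinery is correct and that consensus behaves as designed
under planted signal; they do not certify accuracy numbers on any real
dataset.

## Known limitations

* The built-in scorers are deliberately simple; no alignment search,
  no sequence-order-independent comparison.
* Consensus alignments (as opposed to consensus scores) are out of
  scope.
* M5's learned variant assumes the imputed matrix as features; with
  extreme class imbalance at high levels the seeded 10% sample can
  contain one class only, which is reported as an error rather than
  silently refit.
* Ground truth is required for evaluation; without it the pipeline
  stops after writing the consensus tables.
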
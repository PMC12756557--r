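---
title: "VAF-based genetic distances and Ward clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VAF-based genetic distances and Ward clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vafclust)
```

## The problem

Closely related tree species such as poplars hybridize freely and carry high
intraspecific polymorphism, which makes taxon assignment from morphology
unreliable. Whole-genome sequencing offers a direct route: after mapping
reads to a common reference and calling variants per sample, each sample is
summarized by its vector of variant allele frequencies (VAFs) — the fraction
of reads supporting the alternate allele at each variant site. For a diploid
these concentrate near 0, 0.5 and 1 according to genotype, and an F1 hybrid
of two taxa fixed for alternative alleles shows VAF near 0.5 at every such
site, which is what lets this representation place hybrids between their
parents. vafclust implements the full analysis from called variants to an
annotated dendrogram, plus a simulator that generates cohorts with known
structure so every stage can be validated.

## The distance

Samples differ in coverage, so a fixed site set would either discard most
data or mix well- and poorly-measured positions. The package instead uses
*pairwise-complete* masking: for samples $i, j$ let

$$P_{ij} = \{\, p : D_i(p) \ge t \ \wedge\ D_j(p) \ge t \,\}$$

be the positions with depth at least $t$ (default $t = 8$ reads) in **both**
samples, and

$$d_{ij} = \sqrt{ \frac{1}{|P_{ij}|} \sum_{p \in P_{ij}}
  \bigl(v_i(p) - v_j(p)\bigr)^2 }.$$

The per-pair normalization sits *inside* the square root (a root-mean-square
difference), so $d_{ij} \in [0, 1]$ and pairs with different numbers of
usable positions are on one scale. Three closed forms pin the geometry down:
identical VAF vectors give $d = 0$; vectors of all 0 vs all 1 give $d = 1$
for any mask size; and an F1 hybrid at parental fixed differences sits at
$d = 0.5$ from either parent, half the parent–parent distance.

A pair whose usable-position set is empty has no defined distance. Such
pairs are flagged, and clustering refuses a flagged matrix rather than
imputing — a deliberately conservative choice, since any imputation would
fabricate relatedness exactly where the data say nothing.

## Input filters

Variant records enter the analysis only if they pass, in any order (the
filters commute):

| filter | default | meaning |
|---|---|---|
| quality | qual > 25 | Phred-scaled call quality, *strictly* greater |
| alternate observations | AO ≥ 4 | reads supporting the alternate allele |
| total depth | DP ≥ 5 | reads covering the record |
| VAF | AO/DP ≥ 0.2 | minimum allele frequency |
| CDS restriction | optional | 1-based position p inside a 0-based half-open BED interval iff start < p ≤ end |

These mirror common Freebayes settings for this kind of cohort analysis;
the threshold minima are inclusive while the quality cutoff is exclusive.
Mapping- and base-quality settings belong to the upstream caller and are
not applied here.

A covered position at which a sample has *no* surviving variant record is
assigned VAF 0 (reference-homozygous) by default: the coverage mask already
excludes positions the sample cannot speak to, so an adequately covered,
uncalled position is evidence of the reference allele. Because one could
also argue for excluding such positions outright, `build_vaf_matrix()`
exposes `uncalled = "missing"` to mask them instead; both behaviors are
tested. This is the one place where the package had to choose between two
defensible conventions, and the default follows from the fact that the
per-pair position count excludes only low-coverage positions.

## Clustering and clade support

The distance matrix is clustered with Ward's minimum-variance method in its
ward.D2 form — the Lance–Williams update on squared dissimilarities

$$d(k, i \cup j) = \sqrt{\frac{(n_i + n_k)\, d^2(k,i) + (n_j + n_k)\, d^2(k,j)
  - n_k\, d^2(i,j)}{n_i + n_j + n_k}}$$

with merge heights equal to the merging distance. `ward_cluster()` delegates
to `stats::hclust(method = "ward.D2")`; the test suite verifies it against
an independent per-step recomputation of every cluster-pair cost from the
original dissimilarities (the minimum-variance closed form), to 1e-10 on
random instances. Ties between candidate merges are resolved by `hclust`'s
internal order; on the continuous distances this package produces, exact
ties have probability zero, so no additional tie-breaking rule is imposed.

Clade stability is assessed by a position bootstrap: sites (columns of the
VAF matrix) are resampled with replacement to the original count, each
resampled site keeping its depth column, the per-pair mask is re-applied,
and distances and the tree are recomputed. The support of a reference-tree
clade is the fraction of replicate trees containing a clade with *exactly*
the same leaf set. Sites are the only replication unit available to a
distance built from one genome alignment per sample, which is why samples
are never resampled. A replicate in which some pair loses all usable
positions is dropped and counted; supports are reported over the retained
replicates, and the run aborts if more than 10% are dropped, because
supports over a shrinking denominator stop being comparable. One RNG stream
is seeded once and each replicate draws from a sub-seed keyed by its index,
so results are reproducible regardless of evaluation order.

Trees are exported as ultrametric Newick with leaf height 0 and branch
length equal to the difference of merge heights. The exporter quotes labels
containing Newick metacharacters (single quotes, doubled internally), since
field names like "P. x canadensis Voronezh_548" are not otherwise
serializable.

## The simulator

`simulate_cohort()` emulates the data structure the analysis assumes, with
known truth:

* **Species frequencies** follow the Balding–Nichols model: per site an
  ancestral frequency $p \sim U(0.1, 0.9)$, and per species
  $q \sim \mathrm{Beta}\bigl(p\,\tfrac{1-F}{F},\, (1-p)\tfrac{1-F}{F}\bigr)$.
  The drift parameter $F \in (0,1)$ is the single knob for divergence:
  $F \to 1$ drives species to fixed differences, $F \to 0$ makes them
  indistinguishable. Defaults ($F = 0.3$, 3 species, 4 diploid samples per
  species, 2000 sites, Poisson depth 30, error rate 0.005) describe a
  moderately diverged cohort at typical whole-genome coverage — strong
  enough structure that failures indicate bugs, weak enough that the
  analysis is not trivially easy.
* **Genotypes**: pure samples draw $g \sim \mathrm{Binomial}(2, q_s)$;
  an F1 hybrid draws one allele from each parent species, which forces
  heterozygosity at parental fixed differences and hence intermediate VAF.
* **Reads**: depth $D \sim \mathrm{Poisson}(\text{mean depth})$, alternate
  reads $A \sim \mathrm{Binomial}\bigl(D, \tfrac{g}{2}(1-e) +
  (1-\tfrac{g}{2})e\bigr)$ with error rate $e$.
* **Caller emulation**: a record is emitted iff $A \ge 4$, $D \ge 5$ and
  $A/D \ge 0.2$, with a fixed quality placeholder of 60 (the quality filter
  path is exercised separately by a packaged low-quality fixture). The
  depth table reports $D$ for every sample at the union of emitted sites —
  including samples without a record — which is what makes the pair mask
  computable downstream.

All draws come from one stream seeded once, in a fixed order (ancestral
frequencies; species frequencies, species by species; then per sample in
manifest order: genotypes, depths, alternate reads). Identical config and
seed give byte-identical serialized output. Changing the sample count
changes all downstream draws; prefix stability is not guaranteed and not
promised.

The simulator deliberately omits linkage and coalescent genealogy, indels,
multi-allelic sites and mapping error. Sites are exchangeable and
independent, which matches the bootstrap's assumption exactly — real
genomes violate it through linkage, so support values on real data are
optimistic relative to what these tests demonstrate. Passing the recovery
tests therefore shows the machinery is correct, not that real cohorts of a
given divergence will be resolved.

## Validation sizes and numerical choices

The packaged validation uses cohorts of 3–5 species × 4 samples with 1–2
F1 hybrid pairs, 2000 sites, depth 30, error 0.005 and drift 0.3–0.5 across
five seeds — sizes chosen so the full suite exercises every stage,
including a 200-replicate bootstrap per cohort, in well under a minute.
Under these conditions cutting the pure-sample tree at the species count
recovers the species partition exactly (adjusted Rand index 1), every
hybrid lies closer to each parent than the parents are to each other, and
every species clade reaches bootstrap support ≥ 0.95.

Numerical details worth knowing:

* distances are computed by cross-product algebra over the masked matrix;
  tiny negative sums from floating-point cancellation are clamped at 0, and
  agreement with a literal double loop is tested at 1e-12;
* the distance TSV export is rounded to 6 decimals for human consumption; a
  `.full` sidecar holds `%.17g` values, and re-clustering from it
  reproduces the original Newick byte-for-byte;
* `rbeta` underflows to NaN when both shape parameters underflow at extreme
  $F$; those sites are resolved as a Bernoulli draw of fixation, the exact
  limit of the Beta;
* bootstrap sub-seeds are drawn from one seeded stream; the same seed gives
  an identical support table.

## Limitations

* The distance treats sites as independent and unweighted; no linkage
  correction or site-quality weighting is attempted.
* Clade identity for support is exact leaf-set equality; no unrooted-split
  matching or multiscale (AU) correction is provided.
* No alternative linkages or metrics are exposed: the package implements
  one analysis well rather than a framework.
* Real-cohort interpretation (which clusters correspond to which taxa)
  is the analyst's task; the package reports structure, not systematics.
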
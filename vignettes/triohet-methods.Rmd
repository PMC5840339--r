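---
title: "Trio-based fidelity and heterogeneity analysis: models and methods"
author: "triohet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based fidelity and heterogeneity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triohet)
```

## The question the package answers

Patient-derived cell cultures — for example conditionally reprogrammed (CR)
cultures grown from resected tumors — are only useful as preclinical models
if they preserve the genetics of the tumor they came from. Given matched
whole-exome variant calls from three conditions per patient (Normal tissue,
primary Tumor, derived Culture — a *trio*), `triohet` quantifies two
properties of each culture:

* **genetic identity**: does the culture's SNV repertoire resemble the
  tumor's more than the normal tissue's? (Jaccard similarity, shared-SNV
  percentages, gene-panel Venn overlaps, presence/absence PCA);
* **intra-tumor heterogeneity (ITH)**: does the culture retain the tumor's
  subclonal diversity? (MATH score on tumor-specific variant allele
  fractions).

The package operates downstream of read mapping and primary variant
calling: its native input is a per-patient VCF with three sample columns
and per-strand, base-quality-filtered allele depths (`DP` and a
four-integer `DP4` field: ref-forward, ref-reverse, alt-forward,
alt-reverse, counting reads with base quality above Q30). Mapping-quality
filtering and duplicate removal are the VCF producer's responsibility and
are documented as an input contract.

## SNV acceptance rules

A candidate site enters a condition's SNV set when both rules hold:

1. **support** — at least 3 quality-passing (Q > 30) reads carry the
   variant allele in that condition, with the variant observed on both
   genome strands (at least one quality-passing alt read per strand). The
   strand clause is read as an additional condition on top of the
   3-read total, not as a per-strand minimum of three.
2. **trio coverage** — at least 3 reads cover the position in *all three*
   conditions, so that absence of a call in one condition is
   interpretable as absence of the variant, not absence of data.

Coverage counts raw depth by default: the rule concerns whether the
position was sequenced at all, and no quality qualifier is attached to it
in the convention we follow. Because the choice is genuinely ambiguous, a
`useQualityDepth` switch makes coverage count only quality-passing reads.
All three sets are computed on the same site universe, which makes
between-condition set algebra well defined. Thresholds (`minAltReads = 3`,
`minPerStrand = 1`, `minDepth = 3`) are exposed as arguments and config
keys.

## Similarity statistics

For SNV key sets $A$ and $B$ (keys are `chrom:pos_ref/alt`):

* Jaccard similarity $J(A,B) = |A \cap B| / |A \cup B|$, symmetric; the
  Jaccard distance is $1 - J$. $J$ is undefined for two empty sets and the
  package returns `NA` with a warning rather than a silent 0 or 1.
* Shared percentage $S(Q,R) = 100\,|Q \cap R| / |Q|$, asymmetric; in the
  fidelity analysis $Q$ is the culture set and $R$ the tumor (or normal)
  set.

The cohort-level shared percentage can be defined two ways, and they
differ whenever culture set sizes differ across patients. `triohet`
reports both, labeled: the **pooled** value
$100 \sum_p |Q_p \cap R_p| / \sum_p |Q_p|$, which is the natural reading
of "in total, cultures share X% of their SNVs", and the **mean** of
per-patient percentages. Tests pin the distinction on a two-patient
fixture with unequal set sizes.

Similarity can be computed genome-wide or restricted to a cancer-gene
panel (e.g. the 125 driver genes of Vogelstein and colleagues) supplied as
a BED file (0-based half-open, fourth column the gene symbol) or a
`gene/chrom/start/end` TSV in the same convention. Whether headline shared
percentages should be genome-wide or panel-restricted is not fixed by
convention, so both modes exist behind per-analysis `panel_restrict`
flags; the panel file itself is an external input — the package ships only
a small constructed stand-in (`inst/extdata/synthetic_panel.bed`) for
demonstrations, since the true panel coordinates depend on genome build
and boundary choices. Chromosome-name dialects (`chr1` vs `1`) are
normalized on load, and a set/panel pair with no chromosome names in
common raises an error instead of silently returning an empty overlap.

## MATH: mutant-allele tumor heterogeneity

For a sample's *tumor-specific* VAFs — sites accepted in that sample but
absent from the patient's matched-normal SNV set, with
$\mathrm{VAF} = q_{alt} / (q_{alt} + q_{ref})$ over quality-filtered
counts summed across strands —

$$\mathrm{MATH} = 100 \cdot \frac{\mathrm{MAD}(\mathrm{VAF})}{\mathrm{median}(\mathrm{VAF})}.$$

Germline exclusion is set subtraction of the normal SNV set as called by
this pipeline, not a VAF threshold in the normal sample. The MAD is scaled
by 1.4826 by default, the constant that makes it a consistent estimator of
the standard deviation under normality and the convention of the original
MATH formulation; because some descriptions print only "MAD/median", the
factor is configurable (`scaleFactor = 1` gives the raw MAD) and recorded
in every output row. MATH is scale-free — multiplying all VAFs by a
constant leaves it unchanged — which is why roughly uniform normal-cell
contamination of a culture dilutes every VAF but leaves its expected MATH
intact, and why tumor and culture MATH are comparable despite different
purities. A result computed from fewer than `minSites = 5` VAFs is kept
but flagged unreliable; the threshold is a package addition, chosen
because a median/MAD ratio on a handful of points is dominated by noise.

## Cohort relatedness by PCA

Samples are embedded as rows of a binary matrix over the union of
accepted site keys (1 = key in that sample's SNV set). Presence/absence
encoding is used rather than VAF dosage because the object of interest is
the SNV *profile*; a VAF-valued matrix can be assembled from
`tumorSpecificVafs()` output by users who want dosage. Columns constant
across all samples carry no variance and are dropped; the matrix is
column-mean-centered and decomposed by SVD (`stats::prcomp`). Component
signs are fixed by making each component's largest-magnitude loading
positive, so results are reproducible and invariant (up to that
convention) under row reordering. `k = 2` components are retained by
default, matching how such cohorts are usually plotted.

Triplet grouping is summarized by the ratio of the mean within-patient
pairwise distance to the mean between-patient pairwise distance in the
retained PCA space: below 1 means each patient's three samples sit closer
to each other than to other patients' samples. When patients differ
mostly by germline background — the regime of matched trios, where shared
germline SNVs dominate somatic differences — the ratio is far below 1;
random label permutations give a ratio near 1.

## The synthetic trio simulator

The simulator provides cohorts with known truth for validation. Its model:

* **Germline**: each patient carries `germlineSnvCount` heterozygous SNVs
  with true VAF 0.5 in all three conditions (diploid model); sites are
  drawn independently per patient, so germline backgrounds are essentially
  private to a patient, as between unrelated individuals.
* **Somatic clones**: each patient has a clone list; every clone has a
  cancer-cell fraction (CCF; at least one truncal clone with CCF 1 per
  patient) and a number of private mutations, and flags saying whether it
  is present in the tumor sample and in the culture. The flags encode the
  discordance modes seen in real trios — subclones that fail to propagate
  in culture, and rare clones below detection in the tumor that expand
  under culture conditions. Spatial tissue-piece heterogeneity is modeled
  through the same flags rather than explicit spatial sampling, since the
  observable consequence (a clone visible in one sample and not the
  other) is identical.
* **Expected VAF**: copy-neutral diploid throughout (multiplicity 1,
  total copy number 2), so the truth is closed-form:
  $\mathrm{VAF} = m \cdot \mathrm{ccf} \cdot f \,/\, (2(1-f) + C_t f)$
  with $f$ the sample's cancer-cell fraction (tumor purity, or one minus
  the culture's normal-cell fraction). CNV-driven VAF shifts are out of
  scope.
* **Read sampling**: per site and sample, depth is Poisson(`meanDepth`)
  (or fixed), alt reads Binomial(depth, true VAF); a `lowQualityReadRate`
  fraction of reads falls below the base-quality threshold (they inflate
  raw depth but never the quality-filtered counts, matching the Q > 30
  support rule downstream); quality-passing reads split across strands as
  Binomial(count, `strandBias`). Depth is drawn independently per site
  and sample — a standard whole-exome approximation.
* **Determinism**: all draws flow from the single config seed; identical
  configs produce byte-identical files.

### Default study conditions

The defaults emulate the regime of a resected-NSCLC trio cohort:
10 patients in the reference cohort, 2000 germline SNVs per patient
against 100 truncal + 60 subclonal somatic mutations (germline burden far
exceeding somatic burden, as in exome data), tumor purity 0.7 (typical of
resections), culture normal-cell fraction 0.5 (the contamination level
reported for CR cultures), Poisson mean depth 80, low-quality read rate
0.05, strand bias 0.5. The default clone layout
(`defaultCloneScenarios()`) makes every third patient starting at the
second a subclone-dropout patient and patient 4 a rare-clone-expansion
patient, so a default cohort exercises all the qualitative patterns:
cultures more similar to tumor than normal, trio triplets grouping in
PCA, culture MATH below tumor MATH after dropout and above it after rare
clone expansion.

What the simulator does **not** emulate: sequencing error (no false
alt reads at VAF-0 sites), mapping artifacts, strand-biased error,
CNVs and loss of heterozygosity, shared germline variation between
patients, indels or multi-allelic sites, and spatial subsampling of the
tumor. Tests passing on simulated cohorts therefore validate the
pipeline's statistics and rule composition, not robustness to those
real-data artifacts; in particular, recall/precision of the acceptance
filters against callers' error modes is outside what the simulation can
show.

## Numerical choices and degenerate inputs

* Jaccard of two empty sets: `NA` plus warning; shared percentage of an
  empty query: error (caller bug).
* Site identity is `(chrom, pos, ref, alt)`; multi-allelic records must be
  pre-split, and the reader skips non-SNV records with a counted warning.
  Coordinates are 1-based fully closed (VCF convention); BED panels are
  converted from 0-based half-open on load.
* PCA: sign convention as above; explained-variance fractions are taken
  relative to total variance and defined as 0 for an all-constant matrix.
* MATH: undefined for an empty VAF vector (error); a zero median cannot
  occur because accepted sites have at least 3 alt reads, so VAFs lie in
  (0, 1].
* Pipeline determinism: a rerun with the same config and seed reproduces
  every table exactly; each stage failure leaves a `FAILED_<stage>`
  marker so partial output is identifiable.

## Problem sizes in the test suite

The suite validates concentration properties at fixed depth 1000–2000
(where binomial noise is a few percent), uses a 10-patient default cohort
for the qualitative fidelity patterns, 10 replicate seeds for the
two-clone MATH recovery (closed-form limit
$100 \cdot 0.125/0.375 = 33.3$), and 1000 random set pairs for the
set-identity properties. These sizes were chosen so that every
statistical check has comfortable margin (3 standard errors or better)
while the whole suite runs in well under a minute per file.

## Known limitations

* No clonality deconvolution: MATH summarizes dispersion without
  assigning mutations to subclones.
* No confidence intervals on MATH (a bootstrap would be a natural
  extension).
* Panel restriction is interval containment, not transcript-model
  annotation.
* The similarity analysis has no significance testing; it is descriptive,
  as is the triplet-grouping ratio.

## Session info

```{r}
sessionInfo()
```
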
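# triohet

Trio-based genomic fidelity and intra-tumor heterogeneity analysis for
patient-derived cultures.

## The problem

Primary cultures derived from a patient's tumor (for example,
conditionally reprogrammed cell cultures) are only useful preclinical
models if they keep the tumor's genetics — both its mutation repertoire
and its subclonal diversity. Given whole-exome variant calls for matched
**Normal tissue / primary Tumor / derived Culture** samples (a *trio*)
per patient, `triohet` answers two questions for every patient and for
the cohort:

* **Identity**: is the culture's SNV set more similar to its tumor of
  origin than to the matched normal? Quantified by the Jaccard index
  `|A∩B| / |A∪B|`, by asymmetric shared-SNV percentages
  `100·|culture ∩ reference| / |culture|` (reported both pooled across
  the cohort and as a per-patient mean), by gene-panel Venn overlap
  counts, and by PCA of the binary sample × SNV presence matrix, where
  each patient's three samples should group together.
* **Heterogeneity**: does the culture retain the tumor's intra-tumor
  heterogeneity? Quantified by the MATH score of the tumor-specific
  variant allele fractions (sites accepted in the sample but absent
  from the matched-normal SNV set):

  ```
  MATH = 100 · MAD(VAF) / median(VAF)
  ```

  with the MAD scaled by 1.4826 by default (configurable).

SNVs enter a sample's set only if they pass the acceptance rules: ≥ 3
variant-supporting reads at base quality Q > 30 with support on both
genome strands, and ≥ 3 reads covering the position in all three
conditions of the trio.

The package also ships a synthetic trio-cohort simulator (subclones with
known cancer-cell fractions, tumor purity, culture normal-cell
contamination, Poisson depth and per-strand binomial read sampling) that
emits the same VCF dialect the pipeline reads, plus a ground-truth
sidecar — so every statistic can be validated against known truth.

## Worked example

Simulate a 4-patient cohort under the default study conditions (2000
germline SNVs per patient, truncal + subclonal somatic mutations, tumor
purity 0.7, 50% culture contamination, Poisson depth 80), then run the
analysis:

```r
library(triohet)

cfg    <- TrioSimConfig(nPatients = 4, germlineSnvCount = 2000, seed = 1)
sim    <- simulateTrioCohort(cfg, tempfile("cohort"))
cohort <- readTrioCohort(sim$vcf)        # read VCFs + apply SNV filters

cohortSimilarityTable(cohort)
#>   patient_id sim_culture_tumor sim_culture_normal shared_pct_culture_in_tumor
#> 1        P01            0.9986             0.9272                       99.95
#> 2        P02            0.9722             0.9524                      100.00
#> 3        P03            0.9972             0.9276                       99.91
#> 4        P04            0.9740             0.9276                       97.40
#>   shared_pct_culture_in_normal panel_restricted
#> 1                        92.72            FALSE
#> ...
```

Every culture is more similar to its tumor (Jaccard ≈ 0.97–1.00) than to
its normal (≈ 0.93): the simulated cultures preserve tumor identity, and
the gap reflects the somatic mutations cultures share with tumors but
not with normal tissue. The pooled aggregate
(`attr(tab, "aggregate")`) reports the cohort totals: cultures share
99.3% of their SNVs with tumors but only 93.4% with normals.

```r
cohortMathTable(cohort)
#>   patient_id  sample n_sites median_vaf mad_vaf  math scale_factor reliable
#> 1        P01   Tumor     158     0.3138 0.11439 36.45        1.483     TRUE
#> 2        P01 Culture     157     0.2222 0.10659 47.97        1.483     TRUE
#> 3        P02   Tumor     160     0.3020 0.13398 44.37        1.483     TRUE
#> 4        P02 Culture     100     0.2485 0.04351 17.51        1.483     TRUE
#> 7        P04   Tumor     100     0.3413 0.06383 18.70        1.483     TRUE
#> 8        P04 Culture     156     0.2113 0.10648 50.40        1.483     TRUE
```

Patient P02's culture dropped a subclone, so its culture MATH (17.5) falls
well below its tumor's (44.4); patient P04 had a rare clone expand in
culture, so the pattern reverses (50.4 vs 18.7) — the two discordance
modes the simulator encodes.

```r
pca <- runPca(buildGenotypeMatrix(cohort), k = 2)
tripletGroupingScore(pca)
#> [1] 0.0207
```

A grouping score far below 1 means each patient's Normal/Tumor/Culture
triplet clusters tightly in PCA space relative to between-patient
distances, as expected when patients differ mainly by germline
background.

The whole analysis (plus TSV/JSON reports) can be driven from one YAML
config: `runPipeline("inst/extdata/demo_config.yaml", outDir = "out")`,
or from the shell via the thin wrapper `inst/scripts/triohet.R`.

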
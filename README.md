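# cishap

Haplotype-based analysis of rare variants at the *OCA2* locus, the second most
common cause of oculocutaneous albinism (OCA). Rare *OCA2* disease alleles do
not occur on a blank background: they travel in cis with common
pigmentation-trait GWAS alleles — the synonymous exon-10 allele rs1800404-A
and the distal *HERC2* enhancer allele rs12913832-G each reduce correct
full-length *OCA2* expression by roughly 20% per allele — so pathogenicity
assessment of a chromosome should consider the whole multi-variant haplotype,
not each variant in isolation. `cishap` packages that analysis for
geneticists working on recessive loci with common functional modifiers.

## What the package computes

* **Cohort model** — parses a proband genotype table (two allele calls per
  proband, each a cis list of variants) against a variant annotation table;
  computes allele counts, distinct-variant and distinct-allele tallies by
  class, SV carrier counts, rarity classification (strict MAF < 0.01), and
  repeat-element overlap of SV junction breakpoints (half-open BED
  convention).
* **Phasing** — cis/trans resolution of variant pairs by exhaustive
  enumeration of Mendelian transmissions in family trios and by
  co-observation counts in sequencing read fragments, with evidence
  combination and conflict flagging.
* **Haplotype catalog** — maximal pairwise-cis cliques per proband merged
  into a catalog of recurring multi-variant haplotypes, with
  phase-validated / genotype-consistent / inconsistent observation counts at
  chromosome level, protein-style display names, cohort allele-frequency
  enrichment, and haplotype frequencies in phased population panels.
* **Splice scoring** — donor/acceptor weight-matrix (WMM) and first-order
  weight-array (WAM) models trained from aligned sites and decoys; scoring of
  162-bp splice windows (80 bp per flank) with arbitrary substitution
  haplotypes; the compound cis-impact of a variant together with an anchor
  allele; and the strongest-site rule for variants hitting two windows.
* **Saturation screen** — every flank position of a splice window mutated to
  all three alternatives (477 substitutions per 162-bp window with one
  anchor), scored alone and in cis with the anchor, classified against the
  identity diagonal and the reference score.
* **Dosage model** — multiplicative allele-dosage expression model
  `TPM = baseline * retention^dosage * exp(noise)`; log-linear OLS fitting
  returns the per-allele percent reduction; the effective-expression calculus
  multiplies per-anchor retention factors (two 0.80 anchors -> 0.64).
* **CNV calling** — exon-level copy number from SNP-array Log R Ratios via a
  z-score against control-sample means (defaults: z <= -3 calls one copy,
  mean LRR <= -1.5 calls zero copies).
* **Synthetic data** — seeded generators for every input above (cohorts with
  exact-Mendelian trios and error-prone read fragments, phased panels, splice
  motif training sets and windows, expression tables, LRR tables), each a
  pure function of its seed.

The packaged fixtures under `inst/extdata/` include a transcription of the
published 106-proband cohort table and its variant annotation (genomic
coordinates of small variants are synthetic, order-faithful approximations;
see the variant table's `note` column).

## Worked example

```r
library(cishap)

variants <- read_variants(system.file("extdata", "table1_variants.tsv", package = "cishap"))
cohort   <- read_cohort(system.file("extdata", "table1_cohort.tsv", package = "cishap"), variants)

length(cohort)                                 # 106 probands
length(distinct_alleles(cohort))               # 74 distinct alleles
allele_count(cohort, "c.1327G>A")              # 37
sv_carrier_count(cohort)                       # 41

# trio phasing: father carries a only, mother carries b only -> trans
t <- trio(proband = c(a = 1, b = 1), father = c(a = 1, b = 0), mother = c(a = 0, b = 1))
phase_trio(t, "a", "b")$relation               # "trans"

# effective expression of a haplotype carrying both 20%-reduction anchors
effective_expression(c(rs1800404 = 0.80, rs12913832 = 0.80))   # 0.64

# dosage fit on synthetic expression (retention truth 0.73)
fit <- fit_dosage(gen_expression(scenario_config(seed = 1)))
round(fit$percent_reduction, 1)                # 28.4 (one replicate)
```

A full synthetic pipeline run — cohort generation, phasing, catalog — is in
the methods vignette (`vignettes/cishap-methods.Rmd`).

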
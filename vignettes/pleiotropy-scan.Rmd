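---
title: "A two-stage genome-wide pleiotropy scan for bone mineral density"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage genome-wide pleiotropy scan for bone mineral density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The question and the design

A variant is *pleiotropic* when it is independently associated with two or
more distinct phenotypes. `pleioscan` implements a two-stage design for
finding variants that are pleiotropic for bone mineral density (BMD):

1. **Curation.** Start from a catalog of established (genome-wide
   significant, p < 5×10⁻⁸) SNP–trait associations for *non-bone*
   phenotypes, and remove entries that cannot support a pleiotropy claim:
   sub-threshold associations, gene–gene-interaction and haplotype-based
   entries, records without an rsID, traits that are bone-related
   (BMD, osteoporosis, fracture, calcium levels, ...), SNPs already known
   to be BMD-associated, traits excluded by the pleiotropy criteria
   (phenotypes that are pathophysiological counterparts of BMD, subsets,
   derived measures, strongly correlated readouts or known causal factors),
   and duplicate rsIDs.
2. **Proxy expansion.** Add every *perfect proxy* (r² = 1 in a genotype
   reference panel, within a 500 kb window) of the curated SNPs, so that a
   signal indexed by a different tag SNP in the BMD data is not missed.
3. **Discovery.** Intersect the candidate set with femoral-neck (FN) and
   lumbar-spine (LS) BMD GWAS summary statistics and apply the
   Simes/Benjamini–Hochberg FDR step-up at q = 5% per trait. A SNP
   significant for either trait is carried forward (union). The
   data-dependent threshold is p₍k₎ with
   k = max{ i : p₍ᵢ₎ ≤ (i/m)·q }; with the published test-set sizes
   (m = 23 204 FN, 23 203 LS) and discovery counts (k = 630, 709), the
   reported rank bound (k/m)·q rounds to 1.4×10⁻³ and 1.5×10⁻³.
4. **Independence pruning.** Greedy best-first clumping at r² < 0.2:
   candidates are visited in ascending p-value order and kept only if
   independent of everything already kept. SNPs whose perfect proxies are
   already established BMD loci are then removed.
5. **Replication.** In an individual-level cohort with heel quantitative
   ultrasound: outlier QC on speed of sound (SOS), broadband ultrasound
   attenuation (BUA) and BMD with boundary-inclusive per-sex bounds;
   KING-robust kinship estimation over all sample pairs and greedy removal
   of one member of every pair at or above the degree-3 cutoff
   φ ≥ 1/2^{9/2}; per-sex standardized Z-scores of BMD residualized on
   age, age² and weight, with |Z| > 4 excluded; and per-SNP ordinary least
   squares of Z on allele dosage plus 15 ancestry principal components,
   declaring replication at p < 5×10⁻⁸. Direction-of-effect concordance
   between stages is reported after allele harmonization, excluding
   strand-ambiguous palindromic SNPs with MAF > 0.4.

The heel ultrasound phenotype is the device-calculated BMD; a sensitivity
mode (`use_ebmd`) instead recomputes estimated BMD from the printed
calibration

> eBMD (g·cm⁻²) = 0.002592 · (BUA + SOS) − 3.687.

## Statistical components authored here

**FDR step-up.** `bhThreshold()` implements exact step-up semantics: all
p-values at or below the passing rank's p-value are significant, even those
failing their own bound. It is validated against an exhaustive rank-bound
oracle and `stats::p.adjust(, "BH")` in the test suite.

**KING-robust kinship.** No installed package provides the estimator, so it
is implemented directly from heterozygosity and opposite-homozygosity
counts over shared non-missing sites:

φ̂ = (N_Aa,Aa − 2·N_AA,aa) / (N_Aa⁽ⁱ⁾ + N_Aa⁽ʲ⁾)

the symmetric between-family form with expectation 0.5 for duplicates,
0.25 for parent–offspring and full siblings, 0.125 and 0.0625 for second
and third degree, and 0 for unrelated pairs regardless of allele labeling.
`estimateKinship()` is the plain-R per-pair reference; `kinshipPairs()`
bit-packs genotypes (64 sites per machine word) and scans all pairs in
compiled code with cache tiling, which keeps a cohort-scale scan
(2×10⁸ pairs at 16 000 markers) around a minute — the same place
SNPRelate or PLINK reach for compiled kernels. The two implementations are
cross-checked to 10⁻¹² in the tests.

A statistical caveat drives one simulator default: with m markers the
unrelated-pair estimator has SD ≈ 0.75/√m, and an all-pairs scan multiplies
its tail probability by ~n²/2. At n = 20 000 the degree-3 cutoff (0.0442)
is only reliably separable from noise with m in the ten-thousands, which is
why the generator emits a dedicated genome-wide relatedness marker set
(default 16 000 markers) rather than reusing the ~2 000 candidate variants.

**LD.** r² is the squared Pearson correlation of dosages over
pairwise-complete samples (composite, phase-free LD) — the reproducible
choice for panel-based proxy servers, exact on the synthetic panel, and
invariant to allele relabeling. Monomorphic variants have undefined LD:
`computeR2()` errors, proxy search skips them, pruning treats them as
r² = 0. Candidates absent from the panel are kept with a flag rather than
silently dropped.

**Pruning order.** The published analysis does not state the clumping
rule of the LD tool it used; greedy best-first selection on ascending
p-value (ties by chromosome, position, rsID) is the standard clumping
convention and is what `pruneIndependent()` implements. Likewise, the
FN/LS union is pruned once using each SNP's minimum p across traits — the
source describes combining the two traits' discoveries into one
independent set without specifying the interleaving.

**Association.** Two-sided p-values for the dosage term use the t
distribution with n − 17 degrees of freedom (intercept + dosage + 15 PCs),
which is exact at small fixture sizes rather than relying on a normal
approximation. Missing dosages are mean-imputed per SNP by default, with a
complete-case mode available.

**Unrelated-set selection.** "Retain one member of each pair" is made
deterministic: repeatedly remove the sample with the most related
partners, breaking ties toward the lexicographically larger sample ID.
Reproducibility is preferred over fidelity to an unstated arbitrary
choice; the result provably contains no pair at or above the cutoff.

## The synthetic study generator

`simulateStudy()` generates all four pipeline inputs with a single seed;
every operation draws from its own named substream, so outputs are
byte-identical for a given configuration regardless of call order.

*LD blocks.* Variants come in blocks spread across chromosomes 1–22
(>1 Mb apart, so the 500 kb proxy window never crosses blocks). Within a
block, a per-chromosome anchor haplotype is drawn at the block's allele
frequency; the first two SNPs copy it exactly — one block in two with
complemented labels — forming a guaranteed perfect-LD pair, and the
remaining SNPs copy it with probability √`within_block_r2`, giving r² ≈
`within_block_r2` against the anchors and its square between non-anchor
pairs. This haplotype-copy scheme is deliberately simpler than a
coalescent simulation: it is sufficient to exercise r² logic exactly.

*Signals.* Planted pleiotropic SNPs receive a standardized effect of fixed
magnitude `effect_size_sd` (default 0.08) and random sign, shared between
the two BMD traits and the cohort phenotype; the fixed magnitude makes
the planted set's power a design property rather than a draw. Decoy
signals appear only in the summary statistics (discovery-only false
signals that must fail replication), and one signal's perfect proxy is
declared a known BMD SNP to exercise the known-locus drop. Summary-stat
effects propagate to block-mates attenuated by the signed panel
correlation r, as marginal GWAS effects do under LD; each SNP's estimate is
drawn with SE = 1/√(2·MAF·(1−MAF)·n). Estimation noise is drawn
independently per SNP — real summary statistics of perfect proxies would
be almost perfectly correlated; this simplification leaves marginal
calibration intact (null p-values are uniform, verified by a
Kolmogorov–Smirnov check) and only understates the correlation of test
statistics within blocks.

*Cohort.* Age is uniform on 40–69 years (the stated recruitment window),
weight normal (78, 15²) kg truncated at 30 kg, sex balanced. The latent
standardized phenotype sums the genetic score, covariate effects (age
−0.02/yr and −0.0005/yr² around 55, weight +0.01/kg around 78 kg, male
+0.3) and unit-SD noise, and maps to the BMD scale as 0.55 + 0.10·raw
g·cm⁻², keeping virtually all records inside the printed QC bounds. SOS is
half the required (BUA + SOS) total plus 733 m/s with 8 m/s of noise, and
BUA is the remainder — so inverting the eBMD formula reproduces the latent
value to machine precision, a property the tests assert at 10⁻¹². A
configurable record fraction (default 0.5%) is pushed exactly onto or
strictly beyond alternating QC bounds, with reasons recorded in the truth
table. Related pairs share genotypes per relationship via per-locus
identity-by-descent (duplicates copy; parent–offspring share one allele
per locus; siblings 0/1/2 with probability ¼/½/¼; second/third degree one
allele with probability ½/¼) across both the candidate variants and the
relatedness markers; per-locus sharing ignores haplotype segments, which
matters for none of the moment-based kinship statistics used here.

*What passing tests do and do not show.* The generator reproduces the
statistical structure the pipeline relies on — LD, effect attenuation,
sampling noise, relatedness, covariate confounding, outliers — but not
realistic human LD maps, imputation uncertainty, genotyping error,
population stratification (PCs are pure noise with zero effect), or
X-chromosome inheritance. Recovery of planted effects here validates the
machinery, not the biology of any real cohort.

## Problem sizes and numerical choices

The reference study conditions (`simulationConfig()` defaults) are a
1000-sample reference panel, 401 blocks × 5 SNPs = 2005 variants (3
planted, 2 decoys, one known-BMD-proxied signal, 2000 nulls), GWAS n =
80 000 per trait (the discovery consortium's scale), and a 20 000-sample
cohort with 60 related pairs and 16 000 relatedness markers. At these
settings the planted standardized effect of 0.08 gives noncentrality ≈ 22
in discovery and ≈ 11 in replication — power > 99% at 5×10⁻⁸ — and the
full scan runs in about two minutes.

Other numerical choices: p-values produced by the generator are clamped
to the smallest positive double (an effect of noncentrality ≳ 39
underflows two-sided normal p-values; ties at the clamp are broken by the
pruner's positional tie-break); the proxy search guards the r² = 1
boundary with a 10⁻¹² tolerance; Z-scores standardize by the sample SD so
each sex stratum has mean 0 and SD 1 before exclusions; and the FDR
report keeps full precision internally, rounding to two significant
figures only for display.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 42, n_blocks = 30, snps_per_block = 5,
                        n_panel_samples = 400, n_biobank_samples = 4000,
                        n_planted_pleiotropic = 2, n_decoy_signals = 1,
                        n_known_bmd_planted = 1, effect_size_sd = 0.2,
                        gwas_n = 20000, n_related_pairs = 10,
                        n_kinship_snps = 6000)
study <- simulateStudy(cfg)
params <- pipelineParams(
  curation = curationConfig(known_bmd_snps = study$truth$known_bmd_snps))
report <- runPipeline(study, params)
report
renderReport(report, "pleio-report")
```

## Known limitations

- The pleiotropy criteria and the bone-relatedness of a trait are
  judgment calls; they are encoded as auditable keyword rules with
  extensible defaults, not an ontology. The default lists are not claimed
  exhaustive.
- Records with missing rsIDs are dropped with a warning; no attempt is
  made to rescue them from positional information.
- Summary statistics are taken at face value (a validator warns when p is
  inconsistent with beta/SE); no genomic-control or sample-overlap
  correction is applied.
- Conditional/joint multi-SNP modelling, colocalization, LD-score
  regression, mixed-model association and X-chromosome analysis are out
  of scope.
- The kinship scan assumes hard-call genotypes; dosage uncertainty is not
  modelled.
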
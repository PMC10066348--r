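---
title: "Methods: classification and carrier-burden estimation in PanelBurden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification and carrier-burden estimation in PanelBurden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

PanelBurden estimates the population burden of pathogenic germline variation
in a fixed panel of 17 hereditary breast, ovarian and endometrial cancer
predisposition genes (ATM, BARD1, BRCA1, BRCA2, BRIP1, CDH1, CHEK2, MLH1,
MSH2, MSH6, PALB2, PMS2, PTEN, RAD51C, RAD51D, STK11, TP53). Given a table
of annotated germline variants observed in a cohort of N exome-sequenced
individuals, the pipeline (i) prefilters to rare, functionally plausible
candidates, (ii) classifies each candidate into the five clinical tiers
(pathogenic, likely pathogenic, uncertain, likely benign, benign) with a
customised ACMG/AMP evidence framework, and (iii) compares per-gene
heterozygote carrier frequencies of pathogenic/likely pathogenic (P/LP)
variants against a control population.

## Prefiltering

A variant is retained for classification when it passes all three stages,
or unconditionally when it is a *known pathogenic* variant (multiple
unanimous pathogenic submissions in ClinVar) — the bypass reflects the fact
that some established pathogenic variants (e.g. founder alleles) are too
common for a rare-variant frequency filter.

1. **Effect**: consequence with moderate/high predicted protein impact
   (inframe indel, frameshift, missense, canonical splice site, stop/start
   loss, stop gain, UTR-region deletion) *or* predicted splice impact,
   dbscSNV ada or rf score strictly above 0.5. An absent score is treated
   as 0: no score can never rescue a variant, because rescue requires
   exceeding a strict threshold. UTR deletions are the only UTR consequence
   on the impact list; UTR point variants fall under "noncoding".
2. **Frequency**: excluded above any of four ceilings — more than 10 gnomAD
   heterozygotes, more than 20 carrier individuals in the local cohort
   (carrier means heterozygous or homozygous), or more than 3 homozygotes
   in either population. All ceilings are strict (`> k` excludes; `= k`
   is kept).
3. **ClinVar**: excluded when recorded benign, likely benign, or
   conflicting between benign/likely benign and VUS; also excluded when a
   noncoding or synonymous variant without predicted splice impact is
   absent from ClinVar or recorded there as VUS. Conflicts involving P/LP
   calls are *retained* — only the specific B/LB-vs-VUS conflict category
   is filtered.

The retained set is a pure set union, so it does not depend on the order in
which the three predicates are evaluated; for the audit trail, exclusions
are attributed in the fixed order effect → frequency → ClinVar, and the
cascade reports retained totals both with and without the bypass.

## The classification engine

Criteria are assigned from annotation fields; the engine never computes
predictions (splice scores, conservation, pext, in silico consensus are
inputs). The criteria used, at their customised strengths:

| Criterion | Strength | Trigger |
|---|---|---|
| PVS1 | very strong / strong / moderate | loss-of-function decision tree, below |
| PS1 | strong | same amino-acid change known pathogenic |
| PS3 / BS3 | strong | published functional studies (damaging / benign) |
| PS4 | strong / moderate / supporting | case–control OR or reported patients, below |
| PM1 | moderate | missense in an annotated functional domain |
| PM2 | supporting | gnomAD AF ≤ 2 × 10⁻⁵ or absent from gnomAD |
| PM4 | moderate | protein-length change (inframe indel, stop loss) outside a repeat |
| PM5 | moderate | different pathogenic missense at the residue (not with PS1) |
| PP1 / BS4 | supporting / strong | published segregation / non-segregation |
| PP2 | supporting | missense in a gene with constraint z > 3.09 |
| PP3 / BP4 | supporting | in silico consensus (input field) deleterious / benign |
| BA1 | stand-alone | gnomAD AF ≥ 5% |
| BS1 | strong | gnomAD AF above the per-gene benign cut-off |
| BP3 | supporting | inframe indel inside a repeat region |
| BP7 | supporting | synonymous, PhastCons < 0.2, no predicted splice impact |

PP5/BP6 (database-only assertions) and the phenotype-dependent criteria
(PS2, PM3, PM6, PP4, BP2, BP5) are deliberately outside the framework: the
analysis is designed for de-identified cohorts without phenotypes.

**PVS1 decision tree.** Only in genes where loss of function is an
established disease mechanism (the `haploinsufficient` profile flag), only
for null consequences, and only when the exon's pext
(proportion-expressed-across-transcripts) exceeds 0.5, i.e. the variant
hits a biologically relevant transcript. Frameshift/stop-gain variants
predicted to undergo nonsense-mediated decay — premature stop 5′ of the
last 50 nt of the penultimate exon, or known pathogenic variants further
downstream — take very strong; NMD-escaping nulls in a relevant exon take
strong (the decision-tree default; a lower strength is defensible but the
tree's is used). Canonical splice variants substitute reading-frame
disruption for the NMD position rule; when frame impact was not assessed
the evidence is withheld and the audit carries an explicit
"unassessable" note, which in practice leaves such variants at VUS.
Start-loss is in the null gate but has no printed strength path in the
framework this engine customises; the initiation-codon branch default
(moderate) was chosen and is recorded here as a design decision.

**PS4.** Variants at gnomAD AF above 0.001% take strong only with a
literature case–control odds ratio above 5. Extremely rare variants tier
on previously reported patient counts: > 4 strong, > 2 moderate, > 1
supporting. A frequency exactly at the 0.001% boundary falls into the
common-variant branch — the source rules use strict inequalities on both
sides and leave equality unassigned, so one side had to be chosen.

**Frequency criteria** are mutually exclusive: BA1 at ≥ 5% (the canonical
stand-alone threshold; configurable), else BS1 above the per-gene benign
cut-off, else PM2 at supporting strength at ≤ 2 × 10⁻⁵ or absence from
gnomAD. The shipped BS1 cut-offs are uniform placeholders (10⁻³) — the
per-gene calculated cut-offs this models are not published as a table, so
users with access to calculated values should override
`geneProfiles(overrides = ...)`. PM2's ceiling is likewise configurable;
only its supporting strength is fixed by the framework.

**PMS2** is special-cased: variants in regions homologous to the PMS2CL
pseudogene cannot be reliably called from short-read data, so any PMS2
variant not flagged `pms2_unique_region` is dropped before classification
and burden counting. Gene-specific strength adjustments (e.g. for ATM) are
supported through profile overrides rather than a re-implementation of any
full gene-specific ruleset.

**Combination.** Evidence is combined on the point scale: very strong 8,
strong 4, moderate 2, supporting 1; benign evidence counts negative (strong
−4, supporting −1); BA1 short-circuits to benign. Totals map to tiers:
pathogenic ≥ 10, likely pathogenic 6–9, VUS 0–5, likely benign −6…−1,
benign ≤ −7. The scale reproduces the three customisations pinned in the
test suite: very strong + moderate → pathogenic (10), two strong → likely
pathogenic (8), and PVS1 + PM2_supporting alone → likely pathogenic (9).
It also implies that PVS1 alone (8) reaches likely pathogenic and a single
benign criterion reaches likely benign — places where the arithmetic is
more decisive than the qualitative combining list. The test suite
enumerates every evidence subset of size ≤ 5 against an independently coded
qualitative rule list and whitelists exactly five principled disagreement
categories (conflicting-evidence adjudication, very-strong-alone,
two-strong-plus-extras, single-benign, and benign tier-crossing).

## Burden statistics

Per gene, the number of *distinct* individuals carrying ≥ 1 P/LP variant is
counted (two P/LP variants in one gene in one individual count once).
Carrier frequencies are displayed as percentages rounded half-up to two
decimals — the convention of the clinical literature, not banker's
rounding. The control population usually arrives as published per-gene
frequencies with a population size; counts are reconstructed by half-up
rounding of `freq × N`, which is why reconstructed per-gene statistics can
differ in the last digit from values computed on unpublished exact counts.

Each gene contributes a 2 × 2 table (carriers/non-carriers × study/control)
tested with the two-tailed Pearson chi-square without continuity correction
(df = 1); Yates correction is available via
`pipelineThresholds(chi2_continuity_correction = TRUE)` but off by default,
matching the uncorrected statistic's behaviour on large-N aggregate tables.
Odds ratios use the cross-product estimate with the Woolf log-normal 95%
interval, `exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d))`; any zero cell yields NA,
which is also the display convention for genes without study carriers. The
`Sum` row totals per-gene carrier counts, so an individual with P/LP
variants in two genes is counted once per gene — this matches how published
per-gene counts add up, and is documented rather than "fixed". No
multiple-testing correction is applied, deliberately mirroring the
single-gene hypothesis-generating use of such tables.

## The synthetic cohort generator

The generator's defaults are the study conditions the package models: a
7091-individual cohort against a 134,187-individual non-cancer control,
603 distinct variants in a truth-class mix of 60 pathogenic, 14 likely
pathogenic, 396 VUS, 127 likely benign and 6 benign, and per-gene carrier
prevalences equal to the observed per-gene P/LP carrier frequencies (e.g.
ATM 0.51%, BRCA1 0.40%, CHEK2 0.31%; zero for PTEN, RAD51D, STK11, TP53).

Truth classes map to annotation regimes constructed so the engine must
agree with the truth label: P/LP variants are NMD nulls (or
frame-disrupting canonical splice variants) absent from gnomAD in
haploinsufficient genes, with P additionally carrying damaging functional
evidence; B/LB variants are common and/or ClinVar-benign-side and are
removed by the prefilter; VUS variants are rare missense (or
frame-unassessed splice) variants with no criterion beyond PM2. A
configurable `borderline_fraction` (default 1%) of LP-truth variants is
generated just below the pext relevance threshold, so the engine demotes
them to VUS — these deliberate borderline bundles are what the 95%
truth-compatibility tolerance absorbs.

Carriage is gene-wise independent Bernoulli per individual, with gene
carriers partitioned uniformly over the gene's P/LP variants; each
individual carries at most one variant per gene, matching heterozygote
counting. Background (non-P/LP) variants receive carriers at rates
proportional to the same per-gene prevalence (×0.5 for VUS/LB, ×2 for
benign), drawn from individuals without an existing variant in that gene;
a zero-prevalence configuration therefore yields a cohort with no carriers
anywhere. When fewer P/LP variants are requested than there are genes with
positive prevalence, the first panel genes (panel order) receive them;
recovery analyses should request at least one P/LP variant per prevalent
gene (the default 603-variant mix does).

What the generator does **not** emulate: linkage and compound genotypes,
population structure, sequencing error and genotype uncertainty, coverage
differences between cohort and control, copy-number and methylation events,
and any correlation between a variant's cohort carriage and its gnomAD
frequency. Passing tests therefore demonstrate internal correctness of the
filtering/classification/counting machinery under idealised annotation,
not robustness to noisy real-world annotation.

## Numerical and reproducibility choices

* Half-up rounding everywhere a display value is produced (two decimals
  for percentages and odds ratios, three for chi-square), with a
  snap-to-grid guard so exact decimal halves round up despite binary
  floating point.
* Determinism: `generateCohort()` seeds the RNG from the configuration;
  the control sampler uses a stream derived from `seed + 1` so cohort and
  control draws are independent at the same seed. Fixed seed and
  configuration give byte-identical outputs, including the written TSV/JSON
  files (no timestamps are embedded).
* Degenerate inputs: empty variant tables flow through to an all-NA burden
  table; zero-margin chi-square tables return NA with an audit note rather
  than NaN; variants with missing mandatory annotation are reported
  unclassifiable with the offending field named, never silently dropped.
* Every numeric cut-off is carried in `pipelineThresholds()` and echoed
  into the audit JSON, so a run's effective configuration is fully
  recorded.

## Validation problem sizes

The shipped checks use: exhaustive enumeration of all 12,616 evidence
subsets of size ≤ 5 for the combination oracle; 500 replicate cohorts at
N = 7091 for generator-level binomial recovery of a single-gene prevalence;
one full-size simulated cohort (7091 individuals, 603 variants) for
end-to-end per-gene recovery within exact binomial 99% confidence
intervals; 1000 simulated null tables for the chi-square type-I error rate;
and 5000 simulated tables at a true odds ratio of 2 for Woolf-interval
coverage.

## Known limitations

* The shipped gene profiles (haploinsufficiency flags, constraint
  z-scores, BS1 cut-offs) are defaults to be overridden with curated
  values; only TP53 and PTEN clear the PP2 constraint threshold under the
  defaults.
* The engine classifies known-pathogenic bypass variants on assigned
  criteria only; community consensus itself carries no evidence weight,
  and the audit flags the bypass provenance so such variants can be
  reviewed (a common benign-frequency founder variant can legitimately
  classify below P/LP on criteria alone).
* Per-gene control statistics computed from rounded published frequencies
  are best-effort reconstructions; exact control counts were not published
  and the last digit of chi-square/OR values can differ.
* The VCF adapter is a convenience (annotation bundles sit more naturally
  in a TSV); it round-trips through `VariantAnnotation` in the test suite
  but is not the primary interchange format.
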
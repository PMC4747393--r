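---
title: "Rare-variant risk-modifier burden analysis in Lynch syndrome carriers: methods"
author: "lynchburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant risk-modifier burden analysis in Lynch syndrome carriers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchburden)
```

## The scientific problem

Women carrying a pathogenic mismatch-repair (MMR) mutation — in *MLH1*,
*MSH2*, *MSH6* or *PMS2*, the Lynch syndrome genes — face a high but highly
variable risk of endometrial and colorectal cancer. Part of that
variability is thought to come from *genetic risk modifiers*: rare germline
variants that are not pathogenic on their own but shift the risk conferred
by the penetrant familial mutation. Because modifiers are individually rare
and of modest effect, genome-wide scans miss them; a family-based design
over a targeted panel of genes with a plausible mechanistic link to the
disease (here, estrogen signaling and cancer-associated genes) is a
pragmatic alternative.

`lynchburden` implements that design as a reusable pipeline:

1. **Phenotype classification.** Each carrier is labeled *poor* (endometrial
   cancer diagnosed at 49 or younger, or more than one cancer diagnosis) or
   *neutral* (endometrial cancer only, at 50 or later).
2. **Variant prioritization.** Panel variant calls are filtered on minor
   allele frequency (MAF strictly below 0.001, with a rescue rule), classed
   into the five clinical-genetics tiers by a deterministic rules engine,
   and reduced to *risk-variants*: class 4/5 variants plus class-3 variants
   whose protein change is non-conservative.
3. **Burden association.** The per-subject count of independent
   risk-variants outside the MMR genes is dichotomized (fewer than two
   versus two or more) and tested against the phenotype with Fisher's exact
   test, the full burden distribution with Pearson's chi-square, and the
   age-at-first-event distributions with Kaplan-Meier curves and the
   Mantel-Cox log-rank test.

## Phenotype rules

The young-onset cutoff is *exclusive at 50*: a diagnosis at 49 counts as
young onset, one at 50 does not. The cutoff is a parameter (`age_cutoff`)
but its default is the definition above. Two further conventions matter
and are covered by tests:

* A second diagnosis at the *same* site (metachronous colorectal cancer,
  for example) counts as multiple cancers. The packaged cohort labels the
  subject with two colorectal diagnoses as poor, which forces this reading.
* A tumor whose diagnosis age is unknown (`C-na` in the compact tumor
  dialect) still counts toward multiple cancers; unknown ages never
  disqualify a tumor.
* A subject with an unknown endometrial-cancer age and no other tumor
  cannot be classified; `classify_phenotype()` either errors or labels her
  `indeterminate`, and indeterminate subjects are excluded from the
  association (never silently counted in either group).

## The rare-variant filter

Variants are retained when their MAF is *strictly* below the threshold
(default 0.001) or unknown. Variants absent from the frequency table are
treated as "not deposited in dbSNP" and therefore kept — a deliberately
inclusive choice: absence from a population catalogue is evidence of
rarity, not of artifact (upstream QC is out of scope here). A *rescue
rule* retains common variants previously reported as pathogenic or
disease-associated, since a modifier catalogued in a disease context may
legitimately exceed the frequency cutoff. Rescued records are flagged so
reports can display them separately.

## Substitution conservativeness

The class boundary between "no effect" (class 2) and "unknown
significance" (class 3) for missense changes rests on whether the
amino-acid substitution is conservative. Two schemes are provided:

* **Physicochemical groups** (default): a substitution is conservative iff
  both residues fall in one of the fixed groups
  `{A,V,L,I,M,F,W}`, `{G,P,C}`, `{S,T,N,Q,Y}`, `{D,E}`, `{K,R,H}`.
  The grouping reproduces the curated calls the pipeline is built around
  (Asp→Gly, Asp→Ser and Ala→Ser all non-conservative) while remaining a
  simple, auditable rule.
* **Grantham distance** (`"grantham:<threshold>"`): conservative iff the
  Grantham (1974) distance, recomputed from side-chain composition,
  polarity and volume with the published constants
  (rho = 50.723, alpha = 1.833, beta = 0.1018, gamma = 0.000399), is at or
  below the threshold. A threshold near 100 approximates the conventional
  moderate/radical boundary. The historical published table rounds a few
  entries one unit away from the recomputed value; the tests pin both the
  exactly-reproduced entries and a ±1 band for the rest.

Both schemes are symmetric and identity-conservative, and the choice is a
single `scheme` argument throughout.

## The five-tier rules engine

`assign_category()` is a pure function of (consequence, conservativeness,
prior annotations). Rules fire in order and the *highest* class wins:

| rule | condition | class |
|------|-----------|-------|
| R1 | silent, or in the non-coding flank of an exon | 1 |
| R2 | conservative missense | 2 |
| R3 | conservative missense with a disease-associated or predicted-damaging prior | 3 |
| R4 | non-conservative missense, in-frame indel, nonsense, frameshift | 3 |
| R5 | prior likely-pathogenic | 4 |
| R6 | prior pathogenic *for another disorder* | 4 |
| R7 | prior pathogenic for the study disease | 5 |

Highest-wins mirrors clinical-genetics escalation: curated annotations
dominate sequence features (a variant known to be pathogenic elsewhere is
not "just" a missense change), and the demotion of other-disorder
pathogenic variants to class 4 reflects that pathogenicity for an
unrelated phenotype is supporting, not conclusive, evidence here. The
annotation vocabulary therefore distinguishes `pathogenic` from
`pathogenic_other_disorder` — the five-tier outcome depends on that
distinction. Every assignment records the full list of fired rules
(`rule_trace`), and an audit-replay test asserts that every trace
re-derives its class.

Risk-variant selection keeps class 4 and 5 plus class-3 protein-altering
changes that are non-conservative (nonsense, frameshift and in-frame
indels qualify by nature). Silent and flanking variants are *never*
selected, even when a prior promoted them above class 1: a risk modifier
must at least alter the protein.

## Co-segregation and burden

Risk-variants are counted per subject, excluding MMR genes, because an
extra variant inside an MMR gene cannot be cleanly separated from the
familial mutation's effect. Two linkage flags refine the count:

* an MMR-gene risk-variant on the *same chromosome* as the carrier's
  familial mutation may co-segregate with it and is excluded everywhere
  (`possible_linkage_with_familial_mutation`); independent MMR variants
  are reported separately (`n_risk_variants_mmr_extra`), never in the
  headline burden;
* two non-MMR risk-variants of one subject sharing a chromosome are
  flagged, and the `collapse_same_chromosome` mode counts each such group
  once — the haplotype-collapse sensitivity analysis. Collapse can only
  decrease a burden (a tested invariant).

Variants are sorted by (chromosome, position, ref, alt) before any
iteration that affects output, so all results are order-deterministic.

## Association statistics

All tests are implemented from first principles and cross-checked in the
test suite against independent implementations (`stats::fisher.test`,
`stats::chisq.test`, `stats::t.test`, `survival::survfit`,
`survival::survdiff`) — the library routines are oracles, never the
implementation.

* **Fisher's exact test** (two-sided) uses probability-mass ordering: the
  p-value is the total hypergeometric probability of all tables with the
  observed margins whose probability does not exceed the observed table's.
  This is the dominant software convention (not tail doubling) and
  reproduces the published 0.0016 on the reference table. Probabilities
  are computed in log space via `lchoose`; ties are compared with a 1e-7
  log-tolerance so floating-point noise cannot flip a tie.
* **Pearson's chi-square** uses no continuity correction; the p-value is
  the upper tail of the chi-square distribution. Expected counts below 5
  produce a warning, not an error: the 6×2 reference distribution itself
  has small expecteds, and the exact test is the primary inference.
  All-zero burden rows are dropped before the test in the pipeline (they
  carry no information and would zero a margin).
* **Kaplan-Meier / log-rank** run on the age scale (origin at birth),
  with events before censorings at tied times and at most one event per
  subject (first events only). The log-rank statistic is the classic
  Mantel-Cox form, referred to chi-square with one degree of freedom.
  Endpoints: any poor-phenotype feature, the early endometrial cancer
  alone, or the second tumor alone; censoring at the age at last
  follow-up. The packaged cohort table does not include per-subject
  follow-up ages, so survival comparisons on it are exercised through the
  synthetic cohorts rather than pinned to published curves.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage — ingestion, annotation,
curation, association — can be tested end to end with a known truth. Its
defaults are the study conditions of the motivating cohort: 35 carriers
from 29 families; diagnosis ages from a normal(53.1, 10.7²) truncated to
[31, 81] and rounded to years; familial mutations distributed roughly as
observed (about two-thirds *MSH6*); about half of rare variants absent
from the frequency table; a mean planted burden of 1.7 (Poisson, capped at
5, matching the observed burden distribution's mean); and a logistic
phenotype model

$$P(\text{poor}) = \operatorname{expit}\!\big(\beta_0 + \log(\text{OR})\cdot
\mathbf{1}[\text{burden} \ge k]\big)$$

with baseline 0.35 (the observed poor fraction among low-burden carriers)
and a default odds ratio of 8 — the planted-effect condition of the power
study below.

Design choices worth knowing:

* **Ages versus phenotype.** Ages are drawn *unconditionally* from the
  truncated normal, and the below-cutoff ages are then assigned to poor
  subjects; a poor subject without a young age receives a second tumor so
  her label is realizable from the clinical record. This keeps the cohort
  age marginal equal to the configured distribution (a CLT test on the
  n = 2000 sample mean holds) while the pipeline's phenotype classifier
  recovers the drawn labels exactly. When the null model produces fewer
  poor subjects than young ages, the excess young ages are redrawn above
  the cutoff — a small distortion confined to the null.
* **Toy genes.** Each panel gene is a two-exon transcript (360-nt CDS,
  60-nt intron, 30-nt flanks) on its own chromosome, half on the minus
  strand; the two `other`-group genes share a chromosome so the haplotype
  collapse path is exercised. The four MMR genes sit on their real
  chromosomes (chr3, chr2, chr2, chr7). Stop codons are patched out of the
  toy CDS, which models an internal coding segment.
* **Planted classes.** Risk variants are non-conservative missense (80%),
  nonsense (10%), frameshift (5%) or in-frame indels (5%); noise includes
  silent, conservative-missense, exon-flank and common (MAF ≥ 0.001)
  variants, rescue variants (common + disease-associated prior, which are
  retained but — being conservative — never selected, so the rescue path
  is tested without touching the burden), extra MMR-gene variants (subject
  one always receives one in her familial gene, guaranteeing the linkage
  path fires), and shared family variants. Common noise is drawn from a
  candidate pool disjoint from the risk pool so a key collision can never
  hand a planted risk-variant a common allele frequency.
* **Determinism.** The seed is mandatory; each stage derives its own seed
  from it, and two runs with one seed are byte-identical.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and realistic haplotype
structure (chromosomes are independent by construction), sequencing error
and coverage variation (calls are taken as given; QC is out of scope),
realistic site-frequency spectra (rare MAFs are uniform below the
threshold), annotation error (priors are planted, not predicted), and
population stratification. The recovery results below are statements
about the pipeline's correctness, not about the field performance of the
design.

## Recovery studies and problem sizes

The test suite and the acceptance script run two operating-characteristic
studies, sized to finish comfortably on one CPU:

* **Type-I error:** 2,000 replicates of the study-sized cohort (n = 35)
  with odds ratio 1. The Fisher rejection rate at α = 0.05 must not
  exceed 0.07; in practice it is near 0.03–0.04, the expected conservatism
  of an exact test on small tables.
* **Power:** 500 replicates with n = 200, odds ratio 8, dichotomy at
  k = 2. Power must reach 0.80; in practice it is essentially 1.

Each replicate runs the full pipeline (annotation, filter, classification,
selection, linkage, burden, dichotomization, Fisher) on in-memory records,
not a shortcut on the truth table; a separate invariant asserts that the
pipeline's burden equals the generator's truth for every subject.

## Numerical and degenerate-input choices

* Strict inequality at the MAF threshold (`maf < 0.001`), exclusive age
  cutoff at 50, inclusive Grantham threshold (`distance <= t`).
* Fisher requires positive margins and errors otherwise; `dichotomize()`
  errors when a cut leaves an empty side; `burden_table()` errors when a
  subject lacks a phenotype, listing the subjects.
* Multi-allelic VCF sites are split per alternate allele on reading and
  re-merged onto one line on writing; positions are 1-based (VCF), panel
  intervals half-open 0-based (BED), converted at the boundary and covered
  by round-trip tests.
* The toy-transcript annotator rejects positions outside the CDS plus
  10-nt flanks and reference alleles contradicting the transcript, rather
  than guessing.

## Known limitations

* The consequence annotator handles SNVs exactly (codon-level, strand
  aware) but classifies indels by length arithmetic only; it does not
  recompute the downstream protein of a frameshift.
* Splice-effect prediction is out of scope; flanking variants are class 1
  unless a prior promotes them.
* Interspecies conservation and protein-domain context enter only as
  precomputed columns of the user-supplied evidence tables.
* The packaged cohort ships without per-subject follow-up ages, so the
  published survival curves are not desk-reproducible; the survival
  machinery is validated against an independent implementation and on
  synthetic cohorts instead.
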
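---
title: "Mapping staygreen mutations by bulk segregant analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping staygreen mutations by bulk segregant analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staygreenBSA)
```

## The problem

Monocarpic senescence in wheat remobilizes leaf nitrogen into developing
grain; mutants that delay its onset ("staygreen") can extend grain fill.
Mapping such a mutation in a hexaploid genome is hard: the trait is
quantitative, scored visually at the plot level, and the mutagenized
background carries thousands of incidental EMS lesions. The workflow this
package implements reduces the problem in three steps:

1. **Phenology**: visual senescence scores (0–100, steps of 5) taken every
   2–4 days are placed on a thermal-time axis from ear emergence (GS55)
   and condensed into a metric panel per line and season. Metrics drive
   classification of recombinant inbred lines (RILs) into staygreen and
   non-staygreen extremes, and multi-year concordance selects the lines
   pooled into two sequencing bulks.
2. **Bulk segregant analysis**: at every biallelic variant the SNP index
   DV/DP (alternate reads over total reads) is computed per bulk; the
   delta SNP index is the staygreen index minus the non-staygreen index.
   A variant fully linked to the causal mutation tends to 1; varietal
   variants (cultivar vs. reference assembly) sit at index 1 in *both*
   bulks and cancel to 0. After varietal removal, EMS-characteristic G>A
   / C>T transitions are filtered for joint enrichment/depletion, and
   maximal runs of completely enriched SNPs form candidate regions.
3. **Confirmation**: candidate SNPs are annotated against gene models
   (missense calls plus supplied deleteriousness scores), markers are
   placed on a small Kosambi genetic map, and single-marker dosage
   regression with Holm correction locates the peak association;
   heterozygote phenotype-by-genotype comparisons classify the mode of
   inheritance.

## Phenology model and conventions

Thermal time between dates is the sum of daily means `(tmin + tmax)/2`
over `(t0, t]`, clamped below at 0 °C. The base temperature is a
convention: senescence scoring happens in early summer, so the clamp is
rarely active, but it keeps the accumulation monotone.

Two different threshold definitions coexist deliberately:

* **Onset / termination** are the thermal times of the *first recorded*
  score strictly above 10 / 90 — no interpolation. On a step-5 scale this
  means 15 / 95 trigger. Using recorded observations mirrors how the
  scores were taken and avoids inventing sub-interval precision for a
  threshold crossing that is itself a convention.
* **TT scores** (TT30 … TT90) assume linear progression between scoring
  points and interpolate. An exact hit returns the first matching
  observation; a non-monotone wiggle resolves to the first upward
  crossing; a first observation already above the target returns that
  observation's thermal time as the earliest bound.

These two conventions make onset and TT10 (if computed) intentionally
different quantities. TT scores are monotone in the target wherever
defined — a property the test suite checks on simulated courses.

Classification of a line compares each metric in a configurable rule
(default: mean senescence, duration from ear emergence, TT70) to the two
parental values and votes for the closer parent; a class is called when
the vote threshold is met and the other side receives no more votes,
otherwise the line is ambiguous. Bulk selection then requires identical,
non-ambiguous classification in at least `min_years` seasons and never a
contradicting season; over-full bulks are trimmed deterministically by
the largest mean TT70 deviation from the mid-parent, favouring extremes.

Grain moisture is `100 (fresh − dry)/fresh` percent. The dry/fresh ratio
is the dry-matter fraction, not moisture — moisture must decline toward
maturity — but a `literal` flag computes `100 dry/fresh` for comparison
with sources that phrase the computation as a dry-by-fresh division.

Mixed models with plot random effects are out of scope here; the
time-point comparison helper uses fixed-effects Welch t-tests plus a
one-way F-test, which is what the package's own analyses and tests rely
on.

## The synthetic-data generator

The generator is first-class code: it defines the statistical structure
every downstream stage assumes, and its ground truth powers the recovery
tests. Defaults encode the study design the package targets:

| parameter | default | rationale |
|---|---|---|
| genome | 5 chromosomes × 200 Mb | desk-scale; ~1 cM/Mb gives realistic ~200 cM chromosomes |
| EMS SNPs | 500 (one causal) | G>A / C>T only, the EMS alkylation spectrum |
| varietal SNPs | 200 | fixed dosage 2 in every line |
| population | 96 F4 RILs | single seed descent from a biparental F1 |
| dominance | dominant | heterozygotes shift fully; semi-dominant = half, recessive = none |
| onset delay | 8 days | converted to thermal time at the season's mean daily temperature |
| bulks | 17 + 17 | homozygous lines only, by default |
| depth | Poisson, mean 20, min 1 | negative binomial available; the floor reflects that called variant sites have coverage |
| sequencing error | 0.001 | per-read allele flip |
| t50 noise | 15 day °C | plot-level Gaussian noise on the logistic midpoint |

Meiosis draws a Poisson number of crossovers in map length with uniform
placement — no interference. The paper trail for the estimation side uses
Kosambi, but generation and estimation are distinct: the simplest
generative model is used for gametes, and Kosambi only to convert
estimated recombination fractions into map distances. At unlinked loci the
expected heterozygote fraction at generation F_g is `(1/2)^(g-1)`, which
the tests verify for g ∈ {2, 3, 4, 6}.

Senescence curves are logistic in thermal time,
`score(t) = 100 / (1 + exp(-k (t - t50)))`, snapped to the step-5 scale.
The mutation shifts `t50`; the rate `k` is shared, matching the
observation that the mutations delay onset without changing the rate of
progression. The scoring grid (default every 3 days) is a protocol
choice, not a claim — the real protocol was "two to four times per week".

Bulk pooling defaults to homozygous lines only. This mirrors the design
under which complete enrichment (delta = 1) is attainable: under a
dominant mutation, heterozygotes are phenotypically staygreen and a
purely phenotypic selection would dilute the staygreen bulk's causal
allele frequency below 1. Heterozygote inclusion and a misclassification
rate are switches for studying exactly that degradation.

What the generator does *not* emulate: capture-efficiency variation along
the genome, read-level errors correlated within fragments, multi-trait
pleiotropy, and spatial field trends in scoring. Passing recovery tests
therefore show the estimators are correct under the declared model, not
that the workflow is robust to every artefact of real exome data.

## BSA filtering choices

* QUAL > 20 (strict) and removal of sites with missing genotypes happen
  at VCF read time; multi-allelic sites are skipped and counted, since
  the DV/DP index logic presumes biallelic records.
* Two enrichment presets ship because the source workflow used two
  threshold sets: `"methods"` (SNP index > 0.9 / < 0.1, DP > 3, strict
  inequalities) and the stricter `"results"` default (≥ 0.95 / ≤ 0.05,
  DP ≥ 5). Depth applies per bulk — both bulks must pass.
* Varietal removal uses both-bulk index ≥ 0.9 by default rather than
  exactly 1, tolerating sequencing error; `varietal_threshold = 1` gives
  the exact rule.
* Candidate regions are maximal runs of delta ≥ `delta_exact` (default 1)
  *within the supplied filtered SNP list*, broken by any listed SNP below
  the threshold (`max_gap_snps = 0`). On the published chromosome-6A
  candidate table this yields the 16.7 Mb block of five completely
  enriched SNPs while leaving the later isolated delta-1 SNP as a
  singleton — which is the behaviour the table's own highlighting
  implies. No sliding-window smoothing is applied; the per-SNP filter is
  the method.

## Annotation and mapping conventions

Consequence calling is deliberately minimal: precedence CDS > UTR >
intron > upstream/downstream > intergenic; a splice-region flag within
3 bp of an exon–intron junction (a documented constant — broader
definitions exist); upstream/downstream within 5 kb (the source tables
name the classes but not a distance). Codons are built strand-aware from
CDS coordinates and translated with the standard genetic code; a
brute-force codon-table oracle checks all nine single-base changes of
random codons on both strands. Deleteriousness (SIFT-style, 0 =
deleterious) is consumed from an input column, never computed.

Recombination fractions count recombinant homozygote pairs; heterozygous
calls are excluded because phase is not knowable from a single biallelic
call at F4. The RIL-at-fixation correction `r = R/(2(1-R))` is available
but off by default — at F4 inbreeding is incomplete and the correction
is biased. Marker ordering minimizes total Kosambi length, exhaustively
up to 8 markers (checked against a permutation oracle) and by greedy +
2-opt beyond. Association is dosage regression (0/1/2) per marker with
Holm correction across markers within a metric; the acceptance surface is
peak-marker identity, not exact p-values, since the original tooling's
test statistic is not reproducible from its name alone. The Holm step is
hand-implemented to the step-down definition and cross-checked against
`stats::p.adjust` in the tests.

Inheritance classification runs Welch tests of heterozygotes against each
homozygote class, with an explicit "no trait signal" escape when the
homozygote classes do not separate.

## Numerical and degenerate-input conventions

* Zero-depth records are skipped (with counts), never divided through.
* Undefined metrics (threshold never crossed) propagate as `NA`, never 0.
* Region membership uses a `1e-9` tolerance below `delta_exact` to keep
  exact-equality semantics robust to floating-point representation.
* Tie-breaks are deterministic: region ranking by member count then span;
  bulk trimming by TT70 deviation then line id; peak marker by first
  minimum.
* Zero-variance groups in the time-point test return p = 1 when means
  are equal.

## Problem sizes

The package's own test and acceptance runs use desk-scale sizes chosen to
make every stochastic check statistically comfortable: populations of
48–500 lines, genomes of 60–700 SNPs, 50–100 seed replicates for recovery
rates, 100 permutation runs for the association null, and 200 random
p-vectors for the Holm oracle. The end-to-end recovery criterion (top
region contains the causal locus) is evaluated over 50 seeded runs of the
default configuration with error-free reads.

## Known limitations

* Contiguity of candidate regions is defined over the filtered SNP list,
  so region extent depends on the filter that produced the list.
* The phenotype-based bulk route in `run_pipeline()` cannot reach
  delta = 1 under full dominance when heterozygotes are admitted — this
  is a property of the design, not a defect, and is why the default bulk
  source is the simulator's homozygous-only selection.
* The consequence caller handles one transcript per gene and SNVs only.
* Senescence classification assumes parents bracket the RILs; transgressive
  segregation lands in the ambiguous class.
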
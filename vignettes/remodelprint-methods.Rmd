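---
title: "Comparative exome analysis of remodelled airway epithelia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative exome analysis of remodelled airway epithelia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remodelprint)
```

## The scientific problem

Airway remodelling — basal and secretory cell hyperplasia, squamous
metaplasia — is a hallmark of chronic obstructive pulmonary disease
(COPD), yet remodelled and morphologically normal epithelium coexist and
intertwine in the same bronchi, in COPD and non-COPD lungs alike. A
natural question is whether remodelling leaves a *genetic* print: do
remodelled (R) epithelial patches carry somatic alterations that the
adjacent non-remodelled (N) epithelium of the same patient lacks, and is
that print stronger in COPD?

`remodelprint` implements the downstream analysis for this design: each
patient contributes a paired N and R sample (in practice isolated by
laser-capture microdissection and exome sequenced), patients fall into
two clinical groups (non-COPD and COPD), and the inputs are per-sample
small-variant calls (VCF 4.2) and copy-number-alteration (CNA) segments
(SEG-like TSV), plus a gene model (BED), optional gene-set annotations
(GMT) and an optional whole-lung expression matrix. Upstream alignment,
variant calling and CNA segmentation are out of scope by design: the
pipeline starts from call sets.

## Identity rules

Everything in the package reduces to set operations on identity keys,
so the identity rules matter more than anything else.

**Variants.** Two calls are "the same variant" when their normalized
`(chrom, pos, ref, alt)` tuples are equal. Normalization trims the
common suffix first, then the common prefix while advancing the
position, always leaving at least one base in each allele
(`ATT>AT` at 100 becomes `AT>A` at 100, not `TT>T` at 101).
Multi-allelic records are split into one key per alternate allele;
symbolic and breakend alleles (`<DEL>`, `]...[`, `*`) are outside the
SNV/insertion/deletion model and skipped with a warning. Identity
includes the alleles, not the position alone: two different
substitutions at one site are different variants, and "identical"
between two samples means identical alleles at the same normalized
position.

**CNA loci.** Two segments are "the same locus" when their chromosome,
start and end coordinates are exactly equal. This strict rule is
deliberate: the locus-recurrence analyses are about *exact-coordinate*
recurrence between a patient's N and R samples, where shared germline
or clonal segments are expected to reproduce coordinates exactly. The
copy state (gain/loss) is not part of the default identity, because a
locus is a place, not a direction; a `strict = TRUE` switch adds the
state for users who want it. Reciprocal-overlap matching, common in CNA
tool comparisons, is intentionally not the default — fuzzy matching
would blur the within-patient identity the comparative analysis relies
on. All internal coordinates are 0-based half-open; the SEG dialect
(1-based inclusive) and VCF positions (1-based) are converted exactly
once, at the file boundary.

**Genes.** Gene symbols, upper-cased on read, are the join key across
variants, CNA, gene sets and expression. A variant with reference
allele of length L occupies `[pos-1, pos-1+L)` and is assigned every
overlapping gene model; segments likewise. Strand is read but ignored:
all analyses are gene-level and strand-agnostic.

## Global and comparative counting

For each sample the *global* analysis counts distinct variant keys (or
CNA loci) and distinct genes carrying at least one of them. The
*comparative* analysis removes keys identical to a reference before
counting:

* `within_patient` (default): the reference for a sample is its paired
  sample of the other morphology, so identical positions/loci between a
  patient's N and R are removed. This isolates morphology-private
  alterations.
* `cross_group`: the reference is the union of all samples of the other
  clinical group, which isolates group-private alterations.

Both modes satisfy a conservation identity per sample — global count =
comparative count + count of keys shared with the reference — which the
test suite asserts against brute-force recomputation. Counts are
summarized per stratum (group × morphology) as mean ± SEM (sd/√n, 0 for
a single sample), compared with pooled-variance t-tests, and ratios of
stratum means are reported as fold changes rounded half-up to one
decimal (conventional rounding, not banker's, so reported ratios are
reproducible from the printed means).

## Gene-of-interest filters

**Remodelled-only genes.** A variant key qualifies for a clinical group
when it is present in exactly one R sample of that group and absent
from that patient's paired N sample. Genes carrying at least one
qualifying key are reported with their supporting sample, keys, and
maximum impact tier; HIGH-impact genes are flagged (rendered underlined
in reports). Whether "exactly one R sample" should be scoped to the
clinical group or to the whole cohort is genuinely open; the default is
within-group (a variant private to one COPD R sample remains
interesting even if a non-COPD R sample happens to carry it — they
cannot share a clonal origin), and `r1_scope = "cohort"` is exposed for
the stricter reading.

**Group-exclusive recurrent genes.** A key qualifies when it is present
in *both* N and R of at least `min_samples` (default 2) patients of one
group and absent from every sample of the other group — a
germline-style signature of group susceptibility rather than of
remodelling. Genes supported by 3 or more patients carry a bold flag.

**Recurrent CNA genes.** For COPD R samples, loci identical to the
reference side (COPD N, or non-COPD R) are removed, and a gene
qualifies when a retained segment overlaps it in at least `min_samples`
COPD R samples; 3 supporting samples set the bold flag. Both reference
sides are computed, since they answer different questions (remodelling
within COPD vs COPD-specific remodelling).

Impact tiers come from a shipped, editable consequence-to-impact table
(`default_impact_table()`); unknown terms fall back to MODIFIER with a
warning rather than failing, because consequence vocabularies drift
between annotators.

## Integration statistics

Variant and CNA gene-of-interest sets are intersected and united
(`joint_genes()`). Over-representation of the union in user-supplied
gene sets uses the hypergeometric upper tail
P(X ≥ observed) with population |background|, successes |term| and
draws |query|, plus an effect size, the *strength*
log10(observed/expected) with expected = |query|·|term|/|background|.
Strength is 0 when the observation matches expectation and invariant to
uniform scaling of the universe. The background defaults to all genes
of the supplied gene model: the alternative (all genes in any term)
depends on the annotation file's coverage and is less reproducible.
FDR is Benjamini–Hochberg over the reported terms (those with at least
one observed gene; unobserved terms carry no evidence and are omitted
before correction).

The expression cross-reference computes, per gene of interest present
in a log2 expression matrix, log2FC = mean(COPD) − mean(non-COPD), a
two-sample t-test, and BH FDR across detected genes; genes below
FDR < 0.05 are called deregulated. The default test is Welch's
unequal-variance t-test rather than a paired test: the intended use is
an external whole-lung cohort with unequal group sizes (on the order of
108 vs 133 lungs), which cannot be paired. `test_mode = "paired"` is
retained for genuinely paired matrices (samples matched by order within
group), and `"student"` for the pooled form. Degenerate inputs are
guarded explicitly: when both groups are constant the p-value is 1 for
equal means and the p → 0 limit (flagged) otherwise, and zero p-values
are floored at the smallest positive double before FDR correction.

## The synthetic cohort generator

Because the real cohort is patient data, every stage is validated on
synthetic cohorts with known truth. `sim_config()` fixes the study
conditions; `generate_cohort()` writes a complete input set (manifest,
VCFs, SEGs, BED, GMT, expression matrix, reference list) plus truth
tables. The generator emulates:

* a germline background of `germline_shared_per_patient` keys identical
  between a patient's N and R (default 440, so samples carry roughly
  455–480 calls, the magnitude the analysis is designed for);
* morphology-private calls: N samples carry
  `private_variants_per_sample` untracked private calls (default 25);
  R samples' private calls are exactly the planted remodelled-only
  calls (defaults 15 per non-COPD and 40 per COPD patient);
* planted group-exclusive keys shared by the N and R of 2–3 patients of
  one group and absent from the other;
* CNA: `cna_background_per_sample` segments (default 100) with exact
  coordinates shared between a patient's N and R, plus R-unique
  segments, Poisson-distributed with mean `cna_r_unique_mean`
  (default 65) in non-COPD and that mean times
  `copd_r_unique_cna_excess` (default 2.4) in COPD — the fold excess
  the pipeline exists to detect; plus `cna_recurrent_planted` genes
  (default 10) with R-unique segments in 2 or 3 COPD patients;
* an expression matrix with planted signed log2 fold changes (default
  30 genes at ±1.0 log2, Gaussian noise sd 0.2, 20 samples per group).

Two generator design choices deserve justification. First, R samples
have no *untracked* private calls: any private R call satisfies the
remodelled-only predicate by definition, so an untracked one would be
an unlabelled true positive and truth recovery could never be exact.
The generator therefore treats all morphology-private R calls as the
remodelled-specific signal and records every one in the truth table.
Second, variant positions are drawn without replacement across the
whole cohort, and CNA gene territories are handed out without
replacement across samples (planted recurrent genes excepted), so the
only cross-sample identities are the deliberately planted ones. Both
choices make recovery an exact set property — recovered = planted, no
false positives — rather than a statistical one.

What the generator does **not** emulate: linkage and mutation
signatures, FFPE deamination artifacts, caller-specific error modes,
multi-gene CNA segments, overlapping transcripts, copy-number dosage
effects on expression, or any correlation between a gene's variant
status and its expression shift beyond the planted overlap. Passing
tests therefore demonstrate that the *set logic and statistics* are
correct under the assumed structure, not that the pipeline is robust to
upstream calling artifacts — on real data, the quality of the call sets
dominates.

## Numerical choices and degenerate inputs

* Variant normalization order is fixed (suffix, then prefix) so that
  the minimal representation is unique and documented.
* Fold changes and percentages are rounded half-up at one decimal;
  all other statistics are reported at full precision.
* SEM of a singleton stratum is 0 by convention; an empty stratum is an
  error, not a silent NA.
* `unique_fraction()` refuses an empty target set; against an empty
  reference it is 100% by the set definition.
* BH correction validates p ∈ (0, 1] and preserves input order.
* Abutting CNA segments are legal; overlapping segments within one
  sample are a validation error at read time.
* All randomness flows from a single integer seed; identical
  configurations produce byte-identical files, and pipeline reruns
  produce byte-identical TSVs.

## Problem sizes used in the tests

The bundled test-suite and acceptance checks run on cohorts of 7
patients (4 non-COPD + 3 COPD, 14 samples). Property and oracle suites
use a reduced configuration (about 68 variants and 25–45 CNA segments
per sample, 400 genes over 5 Mb) so that brute-force nested-loop
oracles stay exact and fast; recovery checks run the full default
configuration (about 465–480 variants and 100–260 segments per sample,
2000 genes over 30 Mb) across 10 seeds. These sizes were chosen to
match the magnitudes the method targets while keeping every oracle
re-computable by enumeration.

## Known limitations

* Exact-coordinate locus identity is correct for the within-patient
  design but will under-match CNA calls produced by different
  segmentations; use the strict/overlap switches with care.
* The remodelled-only filter is a presence/absence rule; it does not
  model sequencing depth, VAF, or tumor-in-normal contamination.
* Enrichment assumes the query is a subset of the background; genes
  outside it are dropped with a warning rather than silently extending
  the universe.
* With 3–4 patients per group the stratum t-tests are descriptive, not
  confirmatory; they are reported with significance stars because that
  is the field's reporting convention, not as a claim of power.
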
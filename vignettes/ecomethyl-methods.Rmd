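---
title: "Methods: windowed ecotype-comparative methylome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed ecotype-comparative methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `ecomethyl`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the underlying method
description left genuine freedom. It states no empirical result that the
package's tests do not themselves compute.

## The measurement model

The primary observable is a strand-resolved cytosine with methylated and
unmethylated read counts `(m, u)` in one of the three plant contexts
(CG, CHG, CHH; H = A/C/T). Its methylation fraction is `m/(m+u)`,
defined only at depth > 0. Windows of 50 bp tile each chromosome from
coordinate 0 without overlap; the window statistic is the **unweighted
mean of per-site fractions** over *qualifying* sites (depth ≥
`min_reads`, default 10), not a depth-weighted pool of counts. This
matches the stated "mean level of each cytosine" convention and makes
the window mean insensitive to depth imbalance between sites. Sites
below the depth cutoff are excluded from both the mean and the
qualifying-site count — the validity clause qualifies which cytosines
are analyzed at all, not just how many are counted. A window is *valid*
at ≥ `min_sites` qualifying sites (default 3); features (genes/TEs) use
≥ 5 sites, the 5-kb chromosomal view ≥ 10.

Two readings of the coarse-view depth clause exist ("more than 10
reads" vs "at least 10 reads"); they differ by a single read and are
unified as ≥ 10, configurable. Likewise "more than 5 sites" vs "at
least 5 cytosine sites" for features defaults to ≥ 5 and is exposed as
an argument rather than silently resolved. Opposite-strand CG sites are
kept as independent records throughout: the input dialect is
strand-resolved and no strand-collapsing step is part of the method.
Coordinates are 0-based half-open internally and in all BED output;
cytosine-report input positions are 1-based.

## Region partition

Validity is evaluated per window, context and sample (2 ecotypes × 3
stages). The partition rule is:

* **CR** — valid in all six samples;
* **Col SR** — valid in ≥ k Col samples (k = 1 by default) and *no* Cvi
  sample; **Cvi SR** mirrored;
* **MIXED** — valid in ≥ 1 sample of each ecotype but not all six;
* **NONE** — valid nowhere.

The source method defines only CR and Col SR; `MIXED`/`NONE` are added
so the partition is exhaustive and conservation is testable. The
Col-validity threshold k is ambiguous in the original description
("only in Col" vs "more than one stage"); the default k = 1 follows the
at-least-one-of-six framing and k is configurable 1–3. For k > 1,
windows valid in 1..k−1 samples of a single ecotype fit none of the
five labels read literally; they are assigned `NONE` to preserve
exhaustiveness. Under the default k = 1 the 64-pattern truth table of
the rule is exact (and asserted exhaustively in the tests).

Region sets are merged with `bedtools merge -d 1` semantics (gaps ≤ 1 bp
fused) before being used as loci, and per-context SR sets can be
combined at base-pair resolution as a union ("CG|CHG|CHH") or
intersection ("CG∩CHG∩CHH").

## eDMR calling

For each stage, Δ = fraction(Col) − fraction(Cvi) over CR windows with a
defined fraction in both samples. Within each context × stage group the
caller computes the mean m and **population** standard deviation σ of
all Δ and flags windows with Δ > m + kσ (Col-hyper) or Δ < m − kσ
(Col-hypo), strict inequalities, k = 1 by default. Choices made
explicit:

* population (n) rather than sample (n−1) SD — numerically negligible at
  genome scale, declared so tests can be exact;
* strict inequalities — "more than / less than" a standard deviation;
* m, σ are computed per context and stage over all CR deltas, so a
  global ecotype offset (e.g. Cvi-lower genic CG) shifts the thresholds
  rather than flagging half the genome;
* σ = 0 (degenerate input) yields zero calls with a warning rather than
  calling everything or erroring.

Under an approximately normal null the rule flags 2·Φ(−1) ≈ 31.7% of
windows; this is a property of the mean ± SD construction, asserted by
the null-calibration test, not a tuning target. Stage-consistent
("R&G") eDMRs are windows called at all three stages with the same
direction — a direction flip is not a maintained ecotype difference.
Feature classes (Gene / Gene&TE / TE / IGR) are assigned by ≥ 1 bp
overlap and partition the call set; the summary reports the four-class
counts and their sum without attempting the source tables' unstated
deduplication conventions.

Gene-body methylation sections (anchor stage AR) use hi/lo thresholds
0.6/0.2 by default: the original figure distinguishes the four classes
by color on a scatter without printing cutoffs, so the thresholds are
package defaults exposed as arguments, with an explicit `unassigned`
class for points in neither region.

## Small RNA clusters

24-nt cluster counts are consumed as a cluster × sample matrix
(clusters themselves are discovered upstream, e.g. by ShortStack —
out of scope here). Differential expression between ecotypes at each
stage uses edgeR's two-group machinery — TMM normalization, tagwise
moderated dispersion, exact negative-binomial test, BH correction per
contrast. This is a deliberate stand-in: the original analysis used
edgeR's quasi-likelihood F-test, which this package does not
re-implement because the comparative method consumed, not defined, the
GLM machinery; `import_de_table()` accepts externally computed DE
tables when exact fidelity to a particular GLM pipeline is required.
With fewer than two replicates per group, dispersion cannot be
estimated and a near-Poisson fallback is used with a warning.

"Fold-change ≥ 2" is interpreted on the normalized scale as
|log2FC| ≥ 1. Classification: significant (FDR < 0.05 and |FC| ≥ 2) at
all three stages with Col-higher everywhere → `e24sRC_Col`; Cvi-higher
everywhere → `e24sRC_Cvi`; significant at one or two stages — or at all
three with mixed direction, which is neither consistently Col- nor
Cvi-higher — → `e24sRC_1_2`; never significant → `non_e24sRC`. BH is
applied per contrast (per stage), the default reading where the
original pooling is unstated.

## Permutation enrichment

`permutation_test()` mirrors regioneR's `overlapPermTest` with
`non.overlapping`, `per.chromosome` and `count.once` behaviour: each
query interval is re-placed uniformly on its own chromosome with its
length preserved, placements mutually disjoint by rejection sampling
(bounded retries, clear failure on over-crowded chromosomes), and the
statistic is the number of query intervals hitting ≥ 1 target interval.
Both inputs are merged (gap ≤ 1) first so fragmented windows do not
overstate significance. The empirical p-value uses the conservative
pseudocount convention `(1 + #{null ≥ obs})/(n + 1)` — never 0, ties
count against significance — and `log2(observed/expected)` is reported
with the null mean as "expected" (undefined and flagged when the null
mean is 0). No mappability/gap mask is modeled, as none is stated in
the source method. Both enrichment and depletion alternatives are
exposed.

## Variant and HOT summaries

SNPs are counted per half-open window span. Methylation by SNP-count
strata pools counts ≥ 6 into one open-ended stratum (the original
figures show a bounded axis without stating the cap; it is
configurable). Substitution-type analysis z-normalizes window fractions
against the mean and population SD of *all* analyzed windows of the
same region class and context, and a window containing SNPs of several
substitution codes contributes its z once to each code; AG and TC (and
other reverse-complement pairs) are deliberately kept distinct. SV
records are positional intervals with category labels (DEL, INS, DUP,
BRK, INV, SEQ, UNCLASSIFIED); windows overlapping several categories
count in each. HOT coverage is base-pair coverage of the merged HOT set
by each merged feature set.

## The synthetic world

The generator emits what the pipeline observes: per-cytosine reports
for 6 samples on a toy genome (default 2 × 500 kb with central 50-kb
pericentromeres — desk-scale, yet ~10,000 50-bp windows per chromosome
per context for stable statistics). Its fixed defaults state the world
being emulated:

* site densities 0.08/0.08/0.20 per bp (CG/CHG/CHH), giving realistic
  proportions of windows that fail the 3-site criterion in the sparser
  contexts;
* stratum baselines (gene CG 0.30 — gene-body methylation; TE
  0.90/0.70/0.40; intergenic 0.10/0.05/0.05) with TE > gene precedence;
* Cvi genic CG lower by 0.10 (the chief stable ecotype difference) and
  a +0.05 non-CG gain at AR (non-CG methylation peaks at after-ripening);
* depth = 10 + NB(mu = 20, size = 10): with the floor at the read
  criterion, validity is governed by site counts and dropout, and tests
  can exercise depth filtering by lowering the floor;
* Col SR arises from **coverage dropout** (Cvi depth 0 in 50 × 1 kb
  arm blocks), not sequence divergence — the pipeline only ever
  observes mappability through coverage, so this is the observable
  equivalent;
* 100 planted eDMR windows (|Δ| = 0.40 around a 0.45 midpoint, 60%
  Col-hyper), constant across stages, each coupled to a 24-nt cluster
  with an 8-fold ecotype change in the matching direction; 200
  additional background clusters; NB counts with dispersion 0.1 around
  a log-normal baseline of mean 200.

Planted windows are guaranteed ≥ 5 cytosines of the planted context:
a planted effect in a window with no measurable cytosines would not be
an eDMR under any caller, so the guarantee makes the truth table
well-defined rather than easier to hit. Dropout blocks avoid planted
windows for the same reason. The truth table (TSV) records every
planted locus; recovery tests assert > 95% recall at these settings.

What the generator does **not** emulate: sequence content (reads,
bisulfite conversion failure, alignment artifacts), replicate-level
WGBS variation (the emitted reports are one pooled library per
ecotype × stage, matching the pooled-library design of the source
data), mappability structure beyond dropout, linkage between SNP/SV
placement and methylation (so association tests on default data are
null by construction), and TE sequence realism. A green recovery test
therefore establishes that the pipeline's arithmetic and rules recover
what they are defined to recover under binomial/NB noise — not that the
biological effect sizes are realistic beyond the stated defaults.

## Numerical conventions and degenerate inputs

Empty windows are emitted as invalid with undefined fraction; all-zero
clusters are excluded from DE with a message; zero-variance samples
yield flagged NA correlations; constant rows are dropped (with a
message) before z-standardization, which uses the population SD so
standardization is idempotent. Interval joins implemented over
closed-coordinate machinery subtract 1 bp from interval ends where
needed so that all overlap semantics are strictly half-open (bookended
intervals do not overlap). Randomization retries are capped (default
1000 per interval) to bound runtime with an explicit error rather than
hanging on infeasible packings.

## Known limitations

* The DE stand-in is exactTest-based, not quasi-likelihood; borderline
  FDRs can differ from a glmQLF pipeline (use `import_de_table()` for
  fidelity).
* SR detection is purely coverage-based; it cannot distinguish dropout
  from true sequence absence.
* The permutation null does not model masked or unmappable regions.
* `partition_regions()` with k > 1 routes sub-threshold single-ecotype
  windows to `NONE` (documented above).
* Printed-table worked examples in the acceptance suite validate the
  arithmetic of published summary counts; genome-scale counts
  themselves are not reproducible at desk scale and are not targeted.
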
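# ecomethyl

Ecotype-comparative analysis of plant seed methylomes and small RNAomes.

Two *Arabidopsis* ecotypes (Columbia "Col" and Cape Verde Islands "Cvi")
profiled by whole-genome bisulfite sequencing across three seed stages —
freshly harvested (FH), after-ripened (AR), germination-stimulated (GS) —
differ both in where the genome can be measured at all and in how
methylated the measurable part is. `ecomethyl` implements the windowed
comparative pipeline for this design, end to end, plus a synthetic data
generator with a machine-readable truth table so every stage is testable
without any sequencing data.

## What it computes

* **Windowed methylation.** Fractional methylation of non-overlapping
  50-bp windows per cytosine context (CG/CHG/CHH), as the *unweighted
  mean* of per-site fractions `m/(m+u)` over qualifying sites. A window is
  *valid* when it has ≥ 3 sites of the context with depth ≥ 10 reads each;
  gene/TE features use a ≥ 5-site rule, 5-kb chromosomal-view windows a
  ≥ 10-site rule.
* **Region partition.** From the 6-sample validity matrix (2 ecotypes × 3
  stages): **CR** (common region, valid in all six samples), **Col SR** /
  **Cvi SR** (valid only in one ecotype), plus exhaustive `MIXED`/`NONE`
  labels.
* **eDMR calling.** Per stage and context, Δ = mCol − mCvi over CR
  windows; a window is an ecotype-differential methylated region when
  Δ > m + σ (Col-hyper) or Δ < m − σ (Col-hypo), with m and σ the mean and
  population SD of all Δ in that context × stage. Stage-consistent
  ("R&G") eDMRs keep the same direction at FH, AR and GS. Feature
  breakdown: Gene / Gene&TE / TE / IGR.
* **24-nt small RNA clusters.** RPM length × 5′-nucleotide profiles,
  CP10M normalization, two-group negative-binomial differential
  expression (edgeR exact test, BH), and e24sRC classification:
  significant (FDR < 0.05, |FC| ≥ 2) at all three stages with consistent
  direction → `e24sRC_Col` / `e24sRC_Cvi`; 1–2 stages (or mixed
  direction) → `e24sRC_1_2`; otherwise `non_e24sRC`.
* **Permutation enrichment.** regioneR-style randomization tests
  (lengths preserved, per-chromosome, non-overlapping, count-once), with
  `p = (1 + #{null ≥ obs}) / (n_perm + 1)` and `log2(obs/expected)`.
* **Variant summaries.** SNPs per window, methylation by SNP-count
  strata, per-substitution-type mean z-scores `(x − m)/σ`, SV-category
  methylation summaries, and HOT-region coverage accounting.
* **Simulator.** Two-ecotype, three-stage cytosine reports (binomial
  sampling at stratum-specific true fractions, NB depth with a floor),
  gene/TE/SNP/SV/HOT tracks, Cvi coverage-dropout blocks (the source of
  Col SR), planted eDMRs coupled to 8-fold 24-nt clusters, and a truth
  TSV for recovery testing.

## Worked example

Simulate a small two-chromosome dataset, window it, partition the genome
and call eDMRs:

```r
library(ecomethyl); library(data.table)

genome <- genome_spec(c(chr1 = 100000L, chr2 = 100000L),
                      pericentromeres = data.frame(chrom = c("chr1", "chr2"),
                                                   start = 45000L, end = 55000L))
config <- simulation_config(seed = 42L, edmr_n = 20L, sr_dropout_n = 8L,
                            cluster_n = 60L, n_genes_per_chrom = 25L,
                            n_tes_per_chrom = 15L, sv_n = 8L,
                            sv_len_range = c(1000L, 3000L),
                            hot_n = 2L, hot_len = 5000L)
sim <- simulate_cytosine_reports(config, genome)
sites <- rbindlist(lapply(names(sim$sites), function(s)
  copy(sim$sites[[s]])[, sample_id := s]))
w <- compute_window_methylation(sites, window_criteria(), genome = genome)
vm <- build_validity_matrix(w)
part <- partition_regions(vm, paste0("Col_", c("FH", "AR", "GS")),
                          paste0("Cvi_", c("FH", "AR", "GS")))
dcast(part[, .N, by = .(context, label)], label ~ context, value.var = "N", fill = 0)
#>     label    CG   CHG   CHH
#> 1:     CR  2989  2933  3837
#> 2: COL_SR   119   115   159
#> 3:   NONE   892   952     4
```

Each chromosome holds 2000 windows per context; most are CR (measurable
in all six samples), the planted Cvi coverage-dropout blocks surface as
Col SR, and sparse-cytosine windows (mostly CG/CHG on arms) are NONE.
Calling eDMRs on CR windows:

```r
cr <- part[label == "CR", .(chrom, start, end, context)]
deltas <- rbindlist(lapply(c("FH", "AR", "GS"), function(s)
  compute_deltas(w[sample_id == paste0("Col_", s)],
                 w[sample_id == paste0("Cvi_", s)], s, cr)))
res <- call_edmrs(deltas)
res$thresholds[context == "CG"]
#>    context stage      m      sigma    n    lower  upper
#> 1:      CG    FH 0.0480  0.0751  2989  -0.0271  0.1231
#> 2:      CG    AR 0.0500  0.0771  2989  -0.0271  0.1271
#> 3:      CG    GS 0.0492  0.0763  2989  -0.0271  0.1254
rg <- stage_consistent_edmrs(res$calls)
```

The positive CG mean (m ≈ 0.05) is the genome-wide trace of Cvi's lower
genic CG methylation; the thresholds m ± σ adapt to it. In this run 136
windows are stage-consistent eDMRs, and all 20 planted eDMR windows are
recovered with the correct direction (`merge(rg, sim$truth$edmr)`).

A full run — including cluster DE/classification, the eDMR × e24sRC
permutation test and variant summaries — is one call:

```r
jsonlite::write_json(list(seed = 11), "config.json", auto_unbox = TRUE)
run_pipeline("config.json", "out/")   # writes tables + out/manifest.json
```

or from the shell via the installed script
(`system.file("exec/ecomethyl", package = "ecomethyl")`):

```sh
ecomethyl run --config config.json --outdir out/
ecomethyl permtest --query a.bed --target b.bed --genome chrom.sizes \
  --out pr.json --seed 3 -n 1000
```

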
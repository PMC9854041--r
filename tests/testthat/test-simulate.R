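stages <- c("FH", "AR", "GS")
col_s <- paste0("Col_", stages)
cvi_s <- paste0("Cvi_", stages)

partition_sim <- function(sim, genome, criteria = window_criteria()) {
  all_sites <- rbindlist(lapply(names(sim$sites), function(sid)
    copy(sim$sites[[sid]])[, sample_id := sid]))
  w <- compute_window_methylation(all_sites, criteria, genome = genome)
  vm <- build_validity_matrix(w, c(col_s, cvi_s))
  list(windows = w, partition = partition_regions(vm, col_s, cvi_s))
}

test_that("config validation rejects out-of-range parameters by name", {
  expect_error(simulation_config(ar_noncg_gain = 1.4), "ar_noncg_gain")
  expect_error(simulation_config(cvi_gene_cg_offset = 0.5),
               "cvi_gene_cg_offset")
  expect_error(simulation_config(edmr_base = 0.1, edmr_delta = 0.4),
               "edmr_base")
  expect_error(simulation_config(cluster_dispersion = 0), "dispersion")
  expect_error(simulation_config(edmr_context = "CX"), "edmr_context")
  expect_error(genome_spec(c(chr1 = -5L)), "positive")
  expect_error(genome_spec(c(chr1 = 100L),
                           data.frame(chrom = "chr1", start = 50L,
                                      end = 200L)), "bounds")
})

test_that("identical seed and config give byte-identical outputs", {
  g <- tiny_genome(30000L)
  cfg <- tiny_config(seed = 5L, edmr_n = 5L, sr_dropout_n = 4L,
                     cluster_n = 20L, n_genes_per_chrom = 8L,
                     n_tes_per_chrom = 6L, sv_n = 5L, hot_n = 2L,
                     hot_len = 2000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, g, d1)
  simulate_dataset(cfg, g, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
})

test_that("no dropout and depth floor >= 10 yields zero Col-SR windows", {
  g <- tiny_genome(20000L)
  cfg <- tiny_config(seed = 2L, sr_dropout_n = 0L, edmr_n = 5L,
                     cluster_n = 10L, n_genes_per_chrom = 5L,
                     n_tes_per_chrom = 4L, sv_n = 3L, hot_n = 2L,
                     hot_len = 1000L)
  sim <- simulate_cytosine_reports(cfg, g)
  res <- partition_sim(list(sites = sim$sites), g)
  expect_equal(nrow(res$partition[label %in% c("COL_SR", "CVI_SR")]), 0L)
})

test_that("increasing dropout weakly increases Col-SR; Cvi-SR stays empty", {
  g <- tiny_genome(20000L)
  n_sr <- vapply(c(0L, 4L, 10L), function(nd) {
    cfg <- tiny_config(seed = 3L, sr_dropout_n = nd, edmr_n = 5L,
                       cluster_n = 10L, n_genes_per_chrom = 5L,
                       n_tes_per_chrom = 4L, sv_n = 3L, hot_n = 2L,
                       hot_len = 1000L)
    sim <- simulate_cytosine_reports(cfg, g)
    p <- partition_sim(list(sites = sim$sites), g)$partition
    expect_equal(nrow(p[label == "CVI_SR"]), 0L)
    nrow(p[label == "COL_SR"])
  }, integer(1))
  expect_true(all(diff(n_sr) >= 0))
  expect_gt(n_sr[3], n_sr[1])
})

test_that("every truth entry maps to exactly one emitted locus", {
  g <- tiny_genome(30000L)
  cfg <- tiny_config(seed = 9L, edmr_n = 8L, sr_dropout_n = 4L,
                     cluster_n = 20L, n_genes_per_chrom = 8L,
                     n_tes_per_chrom = 6L, sv_n = 5L, hot_n = 2L,
                     hot_len = 2000L)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, g, d)
  truth <- fread(file.path(d, "truth.tsv"))
  # planted eDMR windows each hold >= 5 sites of the planted context
  s <- sim$data$sites$Col_FH
  for (i in which(truth$kind == "edmr")) {
    n <- nrow(s[chrom == truth$chrom[i] & context == truth$context[i] &
                  pos > truth$start[i] & pos <= truth$end[i]])
    expect_gte(n, 5L)
  }
  # truth clusters exactly match the emitted cluster BED
  bed <- read_bed(file.path(d, "clusters_24nt.bed"))
  tc <- truth[kind == "cluster"]
  expect_equal(nrow(tc), nrow(bed))
  expect_equal(as.data.frame(tc[order(cluster_id), .(chrom, start, end)]),
               as.data.frame(bed[order(name), .(chrom, start, end)]))
  # dropout blocks have zero Cvi depth and positive Col depth
  cvi <- sim$data$sites$Cvi_FH
  dr <- truth[kind == "sr_dropout"][1]
  inside_cvi <- cvi[chrom == dr$chrom & pos > dr$start & pos <= dr$end]
  expect_true(all(inside_cvi$meth + inside_cvi$unmeth == 0))
  inside_col <- s[chrom == dr$chrom & pos > dr$start & pos <= dr$end]
  expect_true(all(inside_col$meth + inside_col$unmeth >= 10))
})

test_that("annotation generator honours degenerate weights and densities", {
  g <- tiny_genome(20000L)
  cfg <- tiny_config(seed = 4L, te_pericentromere_weight = 1,
                     snp_density = 0, n_genes_per_chrom = 5L,
                     n_tes_per_chrom = 6L, sv_n = 20L, hot_n = 2L,
                     hot_len = 1000L)
  ann <- simulate_annotations(cfg, g)
  peri <- g$pericentromeres
  for (i in seq_len(nrow(ann$tes))) {
    pc <- peri[chrom == ann$tes$chrom[i]]
    expect_true(any(ann$tes$start[i] >= pc$start & ann$tes$end[i] <= pc$end))
  }
  expect_equal(nrow(ann$snps), 0L)
  # SV categories reproduce the same multinomial draw under the same seed
  ann2 <- simulate_annotations(cfg, g)
  expect_equal(table(ann$svs$category), table(ann2$svs$category))
  expect_equal(nrow(ann$svs), 20L)
})

test_that("null cluster simulation yields mostly non-e24sRC", {
  g <- tiny_genome(20000L)
  cfg <- tiny_config(seed = 6L, edmr_n = 0L, cluster_n = 60L,
                     sr_dropout_n = 0L, n_genes_per_chrom = 5L,
                     n_tes_per_chrom = 4L, sv_n = 3L, hot_n = 2L,
                     hot_len = 1000L)
  srna <- simulate_srna_counts(cfg, g)
  expect_true(all(srna$clusters$true_class == "non_e24sRC"))
  de <- setNames(lapply(stages, function(s) {
    test_differential_expression(
      srna$counts,
      grep(paste0("^Col_", s), colnames(srna$counts), value = TRUE),
      grep(paste0("^Cvi_", s), colnames(srna$counts), value = TRUE))
  }), stages)
  cls <- classify_e24src(de)
  expect_gte(mean(cls$class == "non_e24sRC"), 0.90)
})

test_that("GFF3 and CX outputs round-trip through their readers", {
  g <- tiny_genome(20000L)
  cfg <- tiny_config(seed = 8L, edmr_n = 3L, sr_dropout_n = 2L,
                     cluster_n = 10L, n_genes_per_chrom = 4L,
                     n_tes_per_chrom = 3L, sv_n = 3L, hot_n = 2L,
                     hot_len = 1000L)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, g, d)
  feats <- read_feature_gff3(file.path(d, "features.gff3"))
  expect_equal(nrow(feats), 2 * (4 + 3))
  expect_setequal(unique(feats$feature_kind), c("gene", "te"))
  back <- read_cytosine_report(file.path(d, "Col_FH.CX_report.txt"))
  expect_equal(as.data.frame(back), as.data.frame(sim$data$sites$Col_FH))
  snps <- read_snp_table(file.path(d, "snps.tsv"))
  expect_equal(nrow(snps), nrow(sim$data$annotations$snps))
  svs <- read_sv_bed(file.path(d, "svs.bed"))
  expect_equal(nrow(svs), 3L)
})
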
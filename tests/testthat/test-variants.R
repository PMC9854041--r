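mk_valid_windows <- function(fracs, context = "CG", sample_id = "Col_FH",
                             label = "CR") {
  data.table(chrom = "chr1", start = seq_along(fracs) * 50L - 50L,
             end = seq_along(fracs) * 50L, context = context,
             sample_id = sample_id, fraction = fracs, valid = TRUE,
             label = label)
}

test_that("SNP-per-window counts conserve totals and match a scan oracle", {
  w <- mk_valid_windows(rep(0.5, 5))
  snps <- data.table(chrom = "chr1", pos = c(1L, 50L, 51L, 130L, 131L, 500L),
                     col_base = "A", cvi_base = "G", code = "AG")
  got <- count_snps_per_window(snps, w)
  # pos 50 is in [0,50); 51 in [50,100); 500 outside all windows
  expect_equal(got$n_snp, c(2L, 1L, 2L, 0L, 0L))
  in_any <- sum(vapply(snps$pos, function(p)
    any(p - 1 >= w$start & p - 1 < w$end), logical(1)))
  expect_equal(sum(got$n_snp), in_any)
  expect_equal(count_snps_per_window(snps[0], w)$n_snp, rep(0L, 5))

  set.seed(31)
  w2 <- mk_valid_windows(runif(20))
  s2 <- data.table(chrom = "chr1", pos = sample.int(1200, 60), code = "CT")
  got <- count_snps_per_window(s2, w2)
  want <- vapply(seq_len(nrow(w2)), function(i)
    sum(s2$pos - 1 >= w2$start[i] & s2$pos - 1 < w2$end[i]), integer(1))
  expect_equal(got$n_snp, want)
})

test_that("SNP strata summarize mean and SD per group", {
  w <- mk_valid_windows(rep(0.4, 6))
  w[, n_snp := c(0L, 0L, 1L, 2L, 7L, 9L)]
  s <- methylation_by_snp_strata(w)
  expect_equal(s[stratum == "0", mean], 0.4)
  expect_equal(s[stratum == "0", sd], 0)
  expect_equal(s[stratum == ">=6", n], 2L)
  # hand grouping oracle with varying fractions
  w2 <- mk_valid_windows(c(0.1, 0.3, 0.5, 0.7))
  w2[, n_snp := c(0L, 0L, 1L, 1L)]
  s2 <- methylation_by_snp_strata(w2)
  expect_equal(s2[stratum == "0", mean], 0.2)
  expect_equal(s2[stratum == "1", mean], 0.6)
  expect_equal(s2[stratum == "0", sd], 0.1, tolerance = 1e-12)
})

test_that("substitution z-scores use the population SD of all windows", {
  w <- mk_valid_windows(c(0.1, 0.2, 0.3))
  snps <- data.table(chrom = "chr1", pos = c(105L, 110L, 55L),
                     code = c("AG", "TC", "AG"))
  z <- substitution_zscore(w, snps)
  # window 3 (0.3): z = (0.3-0.2)/sqrt(2/300) = 1.2247; window 2 (0.2): z = 0
  expect_equal(z[code == "TC", mean_z], 1.2247449, tolerance = 1e-6)
  expect_equal(z[code == "AG", mean_z], (1.2247449 + 0) / 2,
               tolerance = 1e-6)
  # multi-SNP same-code window counted once per code
  expect_equal(z[code == "AG", n_windows], 2L)
  # order invariance
  z2 <- substitution_zscore(w[c(3, 1, 2)], snps)
  expect_equal(z, z2)
  # population z-scores have mean 0, SD 1 by construction
  fr <- w$fraction
  zz <- (fr - mean(fr)) / sqrt(mean((fr - mean(fr))^2))
  expect_equal(mean(zz), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zz^2)), 1, tolerance = 1e-12)
  expect_error(substitution_zscore(mk_valid_windows(rep(0.5, 3)), snps),
               "sigma")
})

test_that("SV methylation summary joins categories to windows", {
  w <- rbind(mk_valid_windows(c(1, 1), sample_id = "Col_FH"),
             mk_valid_windows(c(0.2, 0.4), sample_id = "Col_AR"))
  svs <- data.table(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L),
                    category = factor(c("DUP", "DEL"),
                                      levels = c("DEL", "DUP")))
  s <- sv_methylation_summary(svs, w)
  expect_equal(s[category == "DUP" & sample_id == "Col_FH", mean], 1.0)
  expect_equal(s[category == "DUP" & sample_id == "Col_AR", mean], 0.3)
  expect_true(is.na(s[category == "DEL" & sample_id == "Col_FH", mean]))
  expect_equal(s[category == "DEL" & sample_id == "Col_FH", n], 0L)
  # brute-force join oracle
  set.seed(41)
  w2 <- mk_valid_windows(runif(20))
  sv2 <- data.table(chrom = "chr1",
                    start = sample(0:900, 6), end = 0L)
  sv2[, end := start + sample(50:200, 6)]
  sv2[, category := factor(sample(c("INS", "INV"), 6, replace = TRUE))]
  got <- sv_methylation_summary(sv2, w2)
  for (cat in levels(sv2$category)) {
    hits <- unique(unlist(lapply(which(sv2$category == cat), function(j)
      which(w2$start < sv2$end[j] & sv2$start[j] < w2$end))))
    want <- if (length(hits)) mean(w2$fraction[hits]) else NA_real_
    expect_equal(got[category == cat, mean], want, tolerance = 1e-12)
  }
})

test_that("HOT coverage fractions behave on designed fixtures and bitmaps", {
  hot <- data.table(chrom = "chrA", start = c(0L, 200L), end = c(100L, 300L))
  self <- hot_coverage(hot, list(self = hot))
  expect_equal(self$fraction, 1.0)
  disj <- hot_coverage(hot, list(d = data.table(chrom = "chrA", start = 400L,
                                                end = 500L)))
  expect_equal(disj$covered_bp, 0)
  set.seed(51)
  sizes <- c(chrA = 600L)
  for (rep in 1:5) {
    f <- random_intervals(6, sizes, max_len = 150)
    hm <- oracle_bitmap(hot, sizes)[[1]]
    fm <- oracle_bitmap(f, sizes)[[1]]
    want <- sum(hm & fm)
    got <- hot_coverage(hot, list(f = f))
    expect_equal(got$covered_bp, want)
    expect_gte(hot_coverage(hot, list(u = rbind(f, hot)))$covered_bp,
               got$covered_bp)
    expect_true(got$fraction >= 0 && got$fraction <= 1)
  }
})

test_that("SNP and SV table readers validate their dialects", {
  p <- withr::local_tempfile(fileext = ".tsv")
  fwrite(data.table(chrom = "chr1", pos = 5L, col_base = "A",
                    cvi_base = "G"), p, sep = "\t")
  s <- read_snp_table(p)
  expect_equal(s$code, "AG")
  fwrite(data.table(chrom = "chr1", pos = 5L, col_base = "A",
                    cvi_base = "A"), p, sep = "\t")
  expect_error(read_snp_table(p), "differ")
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tDUP", b)
  expect_equal(as.character(read_sv_bed(b)$category), "DUP")
  writeLines("chr1\t0\t100\tWEIRD", b)
  expect_error(read_sv_bed(b), "unknown SV category")
})
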
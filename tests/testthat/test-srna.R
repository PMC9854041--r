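test_that("length/5'-nt profile computes RPM by definition", {
  rc <- data.table(length_nt = c(24L, 24L, 21L),
                   five_prime_nt = c("A", "A", "U"),
                   count = c(150000L, 100000L, 50000L))
  pr <- length_5p_profile(rc, total_mapped = 1e6)
  expect_equal(pr[length_nt == 24 & five_prime_nt == "A", rpm], 250000)
  expect_equal(pr[length_nt == 21 & five_prime_nt == "U", rpm], 50000)
  expect_equal(pr[length_nt == 20 & five_prime_nt == "G", rpm], 0)
  expect_equal(nrow(pr), 9 * 4)
  # profiling all mapped reads sums to 1e6 RPM
  expect_equal(sum(length_5p_profile(rc, sum(rc$count))$rpm), 1e6)
  expect_error(length_5p_profile(rc, 0), "total_mapped")
  expect_error(length_5p_profile(data.table(length_nt = 30L,
                                            five_prime_nt = "A",
                                            count = 1L), 10), "18-26")
})

test_that("normalize_counts is scale-correct and depth-invariant", {
  m <- matrix(c(100, 0, 0, 0), nrow = 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2")))
  expect_equal(normalize_counts(m[, 1, drop = FALSE], scale = 1e7)[1, 1], 1e7)
  m2 <- matrix(c(10, 30, 20, 60), nrow = 2,
               dimnames = list(c("c1", "c2"), c("s1", "s2")))
  expect_equal(normalize_counts(m2), normalize_counts(m2 * 2))
  expect_equal(normalize_counts(m2, scale = 1e6)[1, 1], 10 / 40 * 1e6)
  expect_error(normalize_counts(matrix(0, 2, 2)), "library")
})

test_that("DE stand-in: null behaviour, effect recovery, FDR calibration", {
  set.seed(101)
  # identical groups: logFC ~ 0, p ~ 1
  m <- matrix(rep(c(100L, 200L, 400L), each = 6), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:6)))
  # (edgeR's dispersion smoother warns on this degenerate zero-variance
  # fixture; the estimates themselves are what is under test)
  de <- suppressWarnings(
    test_differential_expression(m, paste0("s", 1:3), paste0("s", 4:6)))
  expect_equal(de$logFC, rep(0, 3), tolerance = 1e-6)
  expect_true(all(de$PValue > 0.99))

  # planted 4-fold difference in 200 clusters, dispersion 0.05, 3v3;
  # 800 additional null clusters anchor the library normalization
  k <- 200; k0 <- 800
  mu <- 500
  a <- rbind(matrix(rnbinom(3 * k, size = 20, mu = mu * 2), ncol = 3),
             matrix(rnbinom(3 * k0, size = 20, mu = mu), ncol = 3))
  b <- rbind(matrix(rnbinom(3 * k, size = 20, mu = mu / 2), ncol = 3),
             matrix(rnbinom(3 * k0, size = 20, mu = mu), ncol = 3))
  cnt <- cbind(a, b)
  rownames(cnt) <- paste0("c", seq_len(k + k0))
  colnames(cnt) <- paste0("s", 1:6)
  de <- test_differential_expression(cnt, paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(abs(median(de[cluster_id %in% paste0("c", 1:k), logFC]) - 2),
            0.3)

  # complete null at FDR 0.05: few discoveries among tests
  null <- matrix(rnbinom(6 * 400, size = 10, mu = 200), ncol = 6,
                 dimnames = list(paste0("c", 1:400), paste0("s", 1:6)))
  de0 <- test_differential_expression(null, paste0("s", 1:3),
                                      paste0("s", 4:6))
  expect_lte(mean(de0$FDR < 0.05), 0.05 + 0.02)

  # all-zero clusters are excluded with a message
  z <- rbind(m, c0 = rep(0L, 6))
  expect_message(
    dez <- suppressWarnings(
      test_differential_expression(z, paste0("s", 1:3), paste0("s", 4:6))),
    "all-zero")
  expect_false("c0" %in% dez$cluster_id)
})

test_that("e24sRC classification follows the three-stage rule", {
  mk_de <- function(fdr, lfc) data.table(cluster_id = paste0("c", seq_along(fdr)),
                                         logFC = lfc, PValue = fdr, FDR = fdr)
  de <- list(FH = mk_de(c(0.01, 0.5, 0.01, 0.01), c(1.6, 0.2, -2, 3)),
             AR = mk_de(c(0.01, 0.5, 0.01, 0.2), c(1.6, 0.2, -2, 3)),
             GS = mk_de(c(0.01, 0.5, 0.01, 0.01), c(1.6, 0.2, -2, 3)))
  cls <- classify_e24src(de)
  expect_equal(as.character(cls[order(cluster_id)]$class),
               c("e24sRC_Col", "non_e24sRC", "e24sRC_Cvi", "e24sRC_1_2"))
  # c4: sig at FH and GS only -> 1_2; c2 never sig -> non
  expect_equal(cls[cluster_id == "c4", n_sig], 2L)
  # three-stage significant but direction-mixed -> 1_2
  de$GS[cluster_id == "c1", logFC := -1.6]
  cls2 <- classify_e24src(de)
  expect_equal(as.character(cls2[cluster_id == "c1", class]), "e24sRC_1_2")
  # FDR 0.5 everywhere -> all non_e24sRC
  cls3 <- classify_e24src(lapply(de, function(d) copy(d)[, FDR := 0.5]))
  expect_true(all(cls3$class == "non_e24sRC"))
  expect_error(classify_e24src(de[1:2]), "three")

  # swapping the contrast direction swaps Col and Cvi classes
  flip <- lapply(de, function(d) copy(d)[, logFC := -logFC])
  c1 <- classify_e24src(de); c2 <- classify_e24src(flip)
  tr <- c(e24sRC_Col = "e24sRC_Cvi", e24sRC_Cvi = "e24sRC_Col",
          e24sRC_1_2 = "e24sRC_1_2", non_e24sRC = "non_e24sRC")
  expect_equal(unname(tr[as.character(c1$class)]), as.character(c2$class))
  # the four classes partition the cluster set
  expect_equal(sum(table(c1$class)), 4L)
})

test_that("sample correlation and z-score standardization", {
  set.seed(2)
  x <- rnorm(50)
  m <- cbind(a = x, b = -x, c = rnorm(50))
  r <- correlate_samples(m)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], -1)
  expect_true(isSymmetric(r))
  # textbook formula oracle
  num <- sum((m[, "a"] - mean(m[, "a"])) * (m[, "c"] - mean(m[, "c"])))
  den <- sqrt(sum((m[, "a"] - mean(m[, "a"]))^2) *
                sum((m[, "c"] - mean(m[, "c"]))^2))
  expect_equal(r["a", "c"], num / den, tolerance = 1e-12)
  expect_warning(correlate_samples(cbind(a = rep(1, 5), b = rnorm(5))),
                 "zero-variance")

  z <- zscore_standardize(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(as.vector(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  mm <- matrix(rnorm(20), nrow = 4)
  expect_equal(zscore_standardize(zscore_standardize(mm)),
               zscore_standardize(mm), tolerance = 1e-12)
  expect_message(zc <- zscore_standardize(rbind(mm, rep(5, 5))), "constant")
  expect_equal(nrow(zc), 4L)
})
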
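#' Small RNA length x 5'-nucleotide profile
#'
#' Reads-per-million-mapped (RPM) matrix over read lengths 18-26 nt and
#' 5'-end nucleotide {A, C, G, U}; the 21-U and 24-A cells track the
#' AGO1- and AGO4-loaded populations respectively.
#'
#' @param read_classes table with `length_nt`, `five_prime_nt`, `count`.
#' @param total_mapped total mapped reads of the library (> 0).
#' @return data.table `length_nt` x `five_prime_nt` with an `rpm` column
#'   (all 36 cells emitted, absent classes 0).
#' @export
length_5p_profile <- function(read_classes, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  dt <- as.data.table(read_classes)
  if (nrow(dt) && (any(dt$length_nt < 18L) || any(dt$length_nt > 26L))) {
    stop("read lengths must be within 18-26 nt")
  }
  grid <- CJ(length_nt = 18:26, five_prime_nt = c("A", "C", "G", "U"))
  agg <- dt[, .(count = sum(count)), by = .(length_nt, five_prime_nt)]
  out <- merge(grid, agg, by = c("length_nt", "five_prime_nt"), all.x = TRUE)
  out[is.na(count), count := 0]
  out[, rpm := count / total_mapped * 1e6]
  out[]
}

#' Library-size normalization of a count matrix
#'
#' Counts per `scale` units of library size (RPM for 1e6, CP10M for 1e7),
#' optionally log2(x + 1)-transformed. Library sizes default to column sums.
#'
#' @param counts numeric matrix, clusters x samples.
#' @param scale normalization unit (1e6 or 1e7).
#' @param lib_sizes optional per-sample library sizes (must be > 0).
#' @param log logical; apply `log2(x + 1)` after scaling.
#' @return matrix of the same shape.
#' @export
normalize_counts <- function(counts, scale = 1e6, lib_sizes = NULL,
                             log = FALSE) {
  m <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  out <- sweep(m, 2, lib_sizes / scale, "/")
  if (log) out <- log2(out + 1)
  out
}

#' Two-group differential expression of cluster counts
#'
#' Negative-binomial exact test with TMM normalization and
#' tagwise-moderated dispersion (edgeR machinery) between two replicate
#' groups; with fewer than two replicates in a group the dispersion cannot
#' be estimated and a Poisson fallback (dispersion ~ 0) is used with a
#' warning. Clusters with zero counts everywhere are excluded (message).
#' For pipelines that ran their own GLM-based testing, see
#' [import_de_table()].
#'
#' @param counts integer matrix, clusters x samples (rownames = cluster
#'   ids).
#' @param group_a,group_b column names (or indices) of the two groups;
#'   `logFC` is log2(A / B).
#' @return data.table `cluster_id`, `logFC`, `PValue`, `FDR` (BH within
#'   this contrast).
#' @export
test_differential_expression <- function(counts, group_a, group_b) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) rownames(m) <- paste0("cluster_", seq_len(nrow(m)))
  a <- m[, group_a, drop = FALSE]; b <- m[, group_b, drop = FALSE]
  sub <- cbind(b, a)  # edgeR pair = c(group1, group2): logFC = group2/group1
  grp <- factor(rep(c("B", "A"), c(ncol(b), ncol(a))), levels = c("B", "A"))
  keep <- rowSums(sub) > 0
  if (any(!keep)) {
    message(sum(!keep), " all-zero cluster(s) excluded from DE testing")
  }
  sub <- sub[keep, , drop = FALSE]
  if (!nrow(sub)) {
    return(data.table(cluster_id = character(), logFC = numeric(),
                      PValue = numeric(), FDR = numeric()))
  }
  y <- edgeR::DGEList(counts = sub, group = grp)
  y <- edgeR::calcNormFactors(y)
  if (min(ncol(a), ncol(b)) >= 2L) {
    y <- edgeR::estimateDisp(y)
    et <- edgeR::exactTest(y, pair = c("B", "A"))
  } else {
    warning("fewer than 2 replicates in a group; Poisson fallback")
    et <- edgeR::exactTest(y, pair = c("B", "A"), dispersion = 1e-4)
  }
  tab <- et$table
  out <- data.table(cluster_id = rownames(sub), logFC = tab$logFC,
                    PValue = tab$PValue,
                    FDR = p.adjust(tab$PValue, method = "BH"))
  out[]
}

#' Import an externally computed differential-expression table
#'
#' TSV with columns `cluster_id`, `logFC`, `PValue` and optionally `FDR`
#' (recomputed by BH when absent), e.g. an edgeR glmQLFTest export.
#'
#' @param path file path.
#' @return data.table matching [test_differential_expression()] output.
#' @export
import_de_table <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("cluster_id", "logFC", "PValue")
  if (!all(need %in% names(dt))) {
    stop("DE table needs columns ", paste(need, collapse = ", "))
  }
  if (!"FDR" %in% names(dt)) dt[, FDR := p.adjust(PValue, method = "BH")]
  dt[, .(cluster_id = as.character(cluster_id), logFC, PValue, FDR)]
}

#' Classify 24-nt clusters into e24sRC groups
#'
#' From the ecotype (Col vs Cvi) contrast at each of the three stages, a
#' cluster is significant at a stage when `FDR < fdr` and `|FC| >= fc`
#' (i.e. `|logFC| >= log2(fc)`). Classes:
#' * `e24sRC_Col`: significant at all three stages, Col-higher at all;
#' * `e24sRC_Cvi`: significant at all three stages, Cvi-higher at all;
#' * `e24sRC_1_2`: significant at one or two stages, or at all three with
#'   mixed direction;
#' * `non_e24sRC`: significant nowhere.
#'
#' @param de_by_stage named list of three DE tables
#'   ([test_differential_expression()] with Col as group A), names = stage
#'   labels.
#' @param fdr,fc significance cutoffs.
#' @return data.table `cluster_id`, `n_sig`, `class` (factor; clusters
#'   absent from some stage table are classified from the stages present
#'   after an error-free three-stage check).
#' @export
classify_e24src <- function(de_by_stage, fdr = 0.05, fc = 2) {
  if (length(de_by_stage) != 3L || is.null(names(de_by_stage))) {
    stop("a named list of three stage contrasts is required")
  }
  lfc <- log2(fc)
  long <- rbindlist(lapply(names(de_by_stage), function(s) {
    d <- as.data.table(de_by_stage[[s]])
    d[, .(cluster_id, stage = s, sig = FDR < fdr & abs(logFC) >= lfc,
          up = logFC > 0)]
  }))
  agg <- long[, .(n_sig = sum(sig), n_up = sum(sig & up),
                  n_dn = sum(sig & !up)), by = cluster_id]
  lv <- c("e24sRC_Col", "e24sRC_Cvi", "e24sRC_1_2", "non_e24sRC")
  agg[, class := fifelse(n_sig == 3L & n_up == 3L, "e24sRC_Col",
               fifelse(n_sig == 3L & n_dn == 3L, "e24sRC_Cvi",
               fifelse(n_sig >= 1L, "e24sRC_1_2", "non_e24sRC")))]
  agg[, class := factor(class, levels = lv)]
  agg[, .(cluster_id, n_sig, class)]
}

#' Pairwise Pearson correlation of expression columns
#'
#' @param m numeric matrix, features x samples.
#' @return symmetric correlation matrix (diagonal 1); zero-variance samples
#'   yield `NA` entries with a warning.
#' @export
correlate_samples <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least two samples")
  zv <- apply(m, 2, function(x) stats::var(x) == 0)
  r <- suppressWarnings(cor(m, method = "pearson"))
  if (any(zv)) {
    warning("zero-variance sample(s): ",
            paste(colnames(m)[zv], collapse = ", "))
  }
  diag(r)[!zv] <- 1
  r
}

#' Row-wise z-score standardization
#'
#' Each feature row is centred and scaled to mean 0, SD 1 (population SD).
#' Constant rows cannot be standardized and are dropped with a message.
#'
#' @param m numeric matrix, features x samples.
#' @return matrix with the surviving rows standardized.
#' @export
zscore_standardize <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  keep <- s > 0
  if (any(!keep)) message(sum(!keep), " constant row(s) dropped")
  (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
}
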
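#' Per-stage methylation differences over common-region windows
#'
#' For one developmental stage, joins the Col and Cvi window tables on
#' (chrom, start, end, context), restricts to common-region (CR) windows,
#' and returns `delta = fraction(Col) - fraction(Cvi)`. Windows present in
#' only one ecotype table (or with undefined fraction) are excluded and the
#' exclusion count reported via message.
#'
#' @param col_windows,cvi_windows window tables
#'   ([compute_window_methylation()]) for the same stage and criteria.
#' @param stage stage label recorded on the output (e.g. "FH").
#' @param cr_windows optional interval-key table (`chrom`,`start`,`end`,
#'   `context`) restricting the join to CR windows; when `NULL`, all joint
#'   valid windows are used.
#' @return data.table with `chrom`, `start`, `end`, `context`, `stage`,
#'   `col_frac`, `cvi_frac`, `delta`.
#' @export
compute_deltas <- function(col_windows, cvi_windows, stage,
                           cr_windows = NULL) {
  key <- c("chrom", "start", "end", "context")
  a <- as.data.table(col_windows)[valid == TRUE,
                                  c(key, "fraction"), with = FALSE]
  b <- as.data.table(cvi_windows)[valid == TRUE,
                                  c(key, "fraction"), with = FALSE]
  setnames(a, "fraction", "col_frac"); setnames(b, "fraction", "cvi_frac")
  j <- merge(a, b, by = key)
  dropped <- nrow(a) + nrow(b) - 2L * nrow(j)
  if (dropped > 0L) {
    message(dropped, " single-ecotype window record(s) excluded at stage ",
            stage)
  }
  if (!is.null(cr_windows)) {
    crk <- unique(as.data.table(cr_windows)[, ..key])
    j <- merge(j, crk, by = key)
  }
  j[, `:=`(stage = stage, delta = col_frac - cvi_frac)]
  setorder(j, context, chrom, start)
  j[]
}

#' Call ecotype-differential methylated regions (eDMRs)
#'
#' Per context and stage, computes the mean `m` and population standard
#' deviation `sigma` of all window deltas, and calls a window hypermethylated
#' in Col ("hyper") when `delta > m + k * sigma` and hypermethylated in Cvi
#' ("hypo") when `delta < m - k * sigma` (strict inequalities, `k = 1` by
#' default). Under an approximately normal delta distribution the default
#' rule flags ~31.7% of windows; planted ecotype effects far exceed the
#' thresholds.
#'
#' @param deltas output of [compute_deltas()] (may hold several contexts and
#'   stages; thresholds are computed within each context x stage group).
#' @param k standard-deviation multiplier.
#' @return list with `calls` (the called windows plus `direction`) and
#'   `thresholds` (per context x stage: `m`, `sigma`, `lower`, `upper`,
#'   `n`). A group with `sigma = 0` yields no calls and a warning.
#' @export
call_edmrs <- function(deltas, k = 1) {
  dt <- as.data.table(deltas)
  if (nrow(dt) < 2L) stop("need at least two delta records")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  thr <- dt[, .(m = mean(delta), sigma = pop_sd(delta), n = .N),
            by = .(context, stage)]
  thr[, `:=`(lower = m - k * sigma, upper = m + k * sigma)]
  if (any(thr$sigma == 0)) {
    warning("sigma = 0 for ", sum(thr$sigma == 0),
            " context/stage group(s); no calls there")
  }
  calls <- merge(dt, thr[, .(context, stage, lower, upper, sigma)],
                 by = c("context", "stage"))
  calls <- calls[sigma > 0 & (delta > upper | delta < lower)]
  calls[, direction := ifelse(delta > upper, "hyper", "hypo")]
  calls[, c("lower", "upper", "sigma") := NULL]
  setorder(calls, context, stage, chrom, start)
  list(calls = calls[], thresholds = thr[])
}

#' Stage-consistent ("R&G") eDMRs
#'
#' Windows called as eDMR in all three stages with the same direction:
#' a maintained ecotype difference through seed ripening and germination.
#'
#' @param calls eDMR call table (`$calls` of [call_edmrs()]) containing all
#'   three stages.
#' @param stages the three required stage labels.
#' @return data.table of windows (`chrom`, `start`, `end`, `context`,
#'   `direction`) called consistently in every stage.
#' @export
stage_consistent_edmrs <- function(calls, stages = c("FH", "AR", "GS")) {
  dt <- as.data.table(calls)
  if (length(stages) < 3L || !all(stages %in% unique(dt$stage))) {
    stop("calls for all three stages are required")
  }
  dt <- dt[stage %in% stages]
  agg <- dt[, .(n_stage = uniqueN(stage), n_dir = uniqueN(direction),
                direction = direction[1]),
            by = .(chrom, start, end, context)]
  out <- agg[n_stage == length(stages) & n_dir == 1L,
             .(chrom, start, end, context, direction)]
  setorder(out, context, chrom, start)
  out[]
}

#' Classify eDMRs by overlapping genomic feature
#'
#' Each region is assigned to exactly one of four classes by >= 1 bp
#' overlap: `Gene` (gene only), `TE` (TE only), `Gene&TE` (both),
#' `IGR` (neither). The classes partition the input set.
#'
#' @param edmrs interval table of called regions.
#' @param genes,tes annotation interval tables.
#' @return list with `classified` (input plus `feature_class`) and `counts`
#'   (one row per class, zero-filled).
#' @export
classify_edmr_features <- function(edmrs, genes, tes) {
  e <- .as_intervals(edmrs)
  classes <- c("Gene", "Gene&TE", "TE", "IGR")
  if (!nrow(e)) {
    return(list(classified = e,
                counts = data.table(feature_class = classes, N = 0L)))
  }
  ge <- .as_intervals(genes); te <- .as_intervals(tes)
  gr <- .to_gr(e)
  in_gene <- if (nrow(ge)) GenomicRanges::countOverlaps(gr, .to_gr(ge)) > 0
             else rep(FALSE, nrow(e))
  in_te <- if (nrow(te)) GenomicRanges::countOverlaps(gr, .to_gr(te)) > 0
           else rep(FALSE, nrow(e))
  cls <- fifelse(in_gene & in_te, "Gene&TE",
                 fifelse(in_gene, "Gene", fifelse(in_te, "TE", "IGR")))
  out <- copy(e)[, feature_class := factor(cls, levels = classes)]
  counts <- out[, .N, by = feature_class][
    data.table(feature_class = factor(classes, levels = classes)),
    on = "feature_class"]
  counts[is.na(N), N := 0L]
  list(classified = out[], counts = counts[])
}

#' Section gene-body methylation scatter into four classes
#'
#' From anchor-stage (default AR) gene-body CG fractions of the two
#' ecotypes, assigns each gene to: `col_only` (methylated in Col, not Cvi:
#' Col >= hi and Cvi <= lo), `cvi_only` (mirror), `high_both` (both >= hi),
#' `mid_both` (both strictly between lo and hi), else `unassigned`. The
#' thresholds are package defaults (the source scatter gives colors, not
#' cutoffs) and are configurable.
#'
#' @param gene_fractions table with `gene_id`, `col_frac`, `cvi_frac`
#'   (anchor-stage fractions of genes valid in both ecotypes).
#' @param hi,lo thresholds, `hi > lo`.
#' @return input with a `section` factor column.
#' @export
section_gbm <- function(gene_fractions, hi = 0.6, lo = 0.2) {
  if (hi <= lo) stop("require hi > lo")
  dt <- as.data.table(gene_fractions)
  secs <- c("col_only", "cvi_only", "mid_both", "high_both", "unassigned")
  s <- rep("unassigned", nrow(dt))
  s[dt$col_frac >= hi & dt$cvi_frac <= lo] <- "col_only"
  s[dt$cvi_frac >= hi & dt$col_frac <= lo] <- "cvi_only"
  s[dt$col_frac >= hi & dt$cvi_frac >= hi] <- "high_both"
  s[dt$col_frac > lo & dt$col_frac < hi &
      dt$cvi_frac > lo & dt$cvi_frac < hi] <- "mid_both"
  out <- copy(dt)[, section := factor(s, levels = secs)]
  out[]
}

#' Write eDMR calls as BED
#'
#' name = direction, score = |delta| x 1000 (capped at 1000).
#'
#' @param calls eDMR call table.
#' @param path output path.
#' @export
write_edmr_bed <- function(calls, path) {
  dt <- as.data.table(calls)
  bed <- dt[, .(chrom, start, end, name = direction,
                score = pmin(1000L, as.integer(round(abs(delta) * 1000))),
                strand = ".")]
  write_bed(bed, path)
}
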
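#' Read a SNP table
#'
#' Tab-separated with header: `chrom`, `pos` (1-based), `col_base`,
#' `cvi_base`. The substitution code concatenates the two bases (Col base
#' first, e.g. "AG" = A in Col, G in Cvi); reverse-complement pairs (AG vs
#' TC) are deliberately kept distinct.
#'
#' @param path file path.
#' @return data.table with a derived `code` column.
#' @export
read_snp_table <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("chrom", "col_base",
                                              "cvi_base")))
  bad <- dt[!col_base %in% c("A", "C", "G", "T") |
              !cvi_base %in% c("A", "C", "G", "T") | col_base == cvi_base]
  if (nrow(bad)) stop("invalid SNP record(s): bases must differ and be ACGT")
  dt[, code := paste0(col_base, cvi_base)]
  dt[]
}

#' SNPs per window
#'
#' Counts SNP positions falling inside each window's half-open span.
#' Total counts are conserved: the sum over windows equals the number of
#' SNPs lying in any window.
#'
#' @param snps SNP table (`chrom`, `pos` 1-based).
#' @param windows interval table of windows.
#' @return `windows` with an integer `n_snp` column appended.
#' @export
count_snps_per_window <- function(snps, windows) {
  w <- as.data.table(windows)
  s <- as.data.table(snps)
  out <- copy(w)
  if (!nrow(s) || !nrow(w)) { out[, n_snp := 0L]; return(out[]) }
  sk <- s[, .(chrom = as.character(chrom), start = pos - 1L, end = pos)]
  wk <- out[, .(chrom, start, end, idx = .I)]
  setkey(wk, chrom, start, end)
  ov <- foverlaps(sk, wk, type = "within", by.x = c("chrom", "start", "end"), nomatch = NULL)
  cnt <- ov[, .N, by = idx]
  out[, n_snp := 0L]
  out[cnt$idx, n_snp := cnt$N]
  out[]
}

#' Methylation level by SNP-count stratum
#'
#' Groups valid windows by the number of SNPs they contain (counts at or
#' above `cap` pooled into one open-ended stratum, default ">=6") and
#' reports the mean and population SD of window methylation fractions,
#' stratified by region label, context and optionally by overlapping
#' feature kind (gene-only / TE-only / both / neither).
#'
#' @param windows window table with `fraction`, `valid`, `label`,
#'   `context` and `n_snp` columns (see [count_snps_per_window()] and
#'   [partition_regions()]).
#' @param cap SNP-count ceiling; strata are 0, 1, ..., cap-1, ">=cap".
#' @param genes,tes optional annotation interval tables for the feature
#'   split.
#' @return data.table with one row per (label, context, feature_kind,
#'   stratum): `n`, `mean`, `sd` (empty strata absent; `sd` is the
#'   population SD, 0 for singleton strata).
#' @export
methylation_by_snp_strata <- function(windows, cap = 6L, genes = NULL,
                                      tes = NULL) {
  dt <- as.data.table(windows)[valid == TRUE & !is.na(fraction)]
  dt <- copy(dt)
  dt[, stratum := ifelse(n_snp >= cap, paste0(">=", cap),
                         as.character(n_snp))]
  lv <- c(as.character(seq.int(0L, cap - 1L)), paste0(">=", cap))
  dt[, stratum := factor(stratum, levels = lv)]
  if (!is.null(genes) || !is.null(tes)) {
    gr <- .to_gr(dt)
    in_g <- if (!is.null(genes) && nrow(as.data.table(genes)))
      GenomicRanges::countOverlaps(gr, .to_gr(.as_intervals(genes))) > 0
      else rep(FALSE, nrow(dt))
    in_t <- if (!is.null(tes) && nrow(as.data.table(tes)))
      GenomicRanges::countOverlaps(gr, .to_gr(.as_intervals(tes))) > 0
      else rep(FALSE, nrow(dt))
    dt[, feature_kind := fifelse(in_g & in_t, "gene&te",
                         fifelse(in_g, "gene", fifelse(in_t, "te",
                                                       "neither")))]
  } else {
    dt[, feature_kind := "all"]
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- dt[, .(n = .N, mean = mean(fraction), sd = pop_sd(fraction)),
            by = .(label, context, feature_kind, stratum)]
  setorder(out, label, context, feature_kind, stratum)
  out[]
}

#' Mean methylation z-score by substitution type
#'
#' Within one region class and context, window fractions are z-normalized
#' against the mean and population SD of all analyzed windows of that
#' class, `z = (x - m) / sigma`. Each window containing >= 1 SNP of a
#' substitution code contributes its z once to that code (a multi-code
#' window contributes to every code present).
#'
#' @param windows valid window table of one region class and context
#'   (`chrom`, `start`, `end`, `fraction`).
#' @param snps SNP table with `code` ([read_snp_table()]).
#' @return data.table per substitution `code`: `n_windows`, `mean_z`.
#' @export
substitution_zscore <- function(windows, snps) {
  w <- as.data.table(windows)[!is.na(fraction)]
  if (!nrow(w)) stop("no analyzable windows")
  m <- mean(w$fraction)
  sigma <- sqrt(mean((w$fraction - m)^2))
  if (sigma == 0) stop("sigma = 0: fractions are constant")
  w <- copy(w)[, z := (fraction - m) / sigma]
  s <- as.data.table(snps)
  sk <- s[, .(chrom = as.character(chrom), start = pos - 1L, end = pos, code)]
  wk <- w[, .(chrom, start, end, z, idx = .I)]
  setkey(wk, chrom, start, end)
  ov <- foverlaps(sk, wk, type = "within", by.x = c("chrom", "start", "end"), nomatch = NULL)
  uni <- unique(ov[, .(idx, code, z)])
  out <- uni[, .(n_windows = .N, mean_z = mean(z)), by = code]
  setorder(out, code)
  out[]
}

#' Read an SV BED (category in column 4)
#'
#' @param path file path.
#' @return interval data.table with a `category` factor column.
#' @export
read_sv_bed <- function(path) {
  dt <- read_bed(path)
  if (!"name" %in% names(dt)) stop("SV BED needs a 4th (category) column")
  cats <- c("DEL", "INS", "DUP", "BRK", "INV", "SEQ", "UNCLASSIFIED")
  if (any(!dt$name %in% cats)) {
    stop("unknown SV category: ",
         paste(setdiff(unique(dt$name), cats), collapse = ", "))
  }
  dt[, category := factor(name, levels = cats)]
  dt[, .(chrom, start, end, category)]
}

#' Methylation summary per SV category
#'
#' Mean fraction of valid windows overlapping each SV category, per sample
#' (stage) and context; a window overlapping SVs of several categories
#' counts in each. Categories with no valid window are reported with
#' `n = 0` and `mean = NA`.
#'
#' @param svs SV table ([read_sv_bed()]).
#' @param windows valid window table with `fraction`, `context`,
#'   `sample_id`.
#' @return data.table per (category, sample_id, context): `n`, `mean`.
#' @export
sv_methylation_summary <- function(svs, windows) {
  sv <- as.data.table(svs)
  w <- as.data.table(windows)[valid == TRUE & !is.na(fraction)]
  cats <- levels(factor(sv$category))
  combos <- CJ(category = cats, sample_id = unique(w$sample_id),
               context = unique(w$context))
  if (!nrow(w) || !nrow(sv)) {
    combos[, `:=`(n = 0L, mean = NA_real_)]
    return(combos[])
  }
  ## foverlaps treats intervals as closed; joining on [start, end-1]
  ## restores half-open (>= 1 bp) overlap semantics
  wk <- w[, .(chrom, start, end = end - 1L, fraction, sample_id, context,
              idx = .I)]
  svk <- sv[, .(chrom = as.character(chrom), start, end = end - 1L,
                category)]
  setkey(svk, chrom, start, end)
  ov <- foverlaps(wk, svk, type = "any", by.x = c("chrom", "start", "end"), nomatch = NULL)
  uni <- unique(ov[, .(idx, category, fraction, sample_id, context)])
  agg <- uni[, .(n = .N, mean = mean(fraction)),
             by = .(category, sample_id, context)]
  out <- merge(combos, agg, by = c("category", "sample_id", "context"),
               all.x = TRUE)
  out[is.na(n), n := 0L]
  setorder(out, category, sample_id, context)
  out[]
}

#' HOT-region coverage accounting
#'
#' Base-pair coverage of the merged HOT regions by each named feature set
#' (SV categories, CR/SR context combinations, 24-nt cluster loci, ...).
#'
#' @param hot HOT-region interval table.
#' @param feature_sets named list of interval tables.
#' @return data.table per feature: `covered_bp`, `fraction` of total
#'   merged HOT bp (0 when the HOT set is empty).
#' @export
hot_coverage <- function(hot, feature_sets) {
  hm <- merge_intervals(hot, max_gap = 0L)
  tot <- total_bp(hm)
  out <- rbindlist(lapply(names(feature_sets), function(nm) {
    cb <- covered_bp(hm, feature_sets[[nm]])
    data.table(feature = nm, covered_bp = cb,
               fraction = if (tot > 0) cb / tot else 0)
  }))
  out[]
}
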
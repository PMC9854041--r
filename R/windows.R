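#' Window validity criteria
#'
#' A window is analyzable ("valid") when it holds at least `min_sites`
#' cytosines of the context, each covered by at least `min_reads` aligned
#' reads. Defaults are the 50-bp criteria (3 sites, 10 reads); the 5-kb
#' chromosomal-view variant uses (5000, 10, 10).
#'
#' @param window_size window width in bp.
#' @param min_sites minimum qualifying cytosines per window.
#' @param min_reads minimum read depth for a cytosine to qualify.
#' @return list of class `window_criteria`.
#' @export
window_criteria <- function(window_size = 50L, min_sites = 3L, min_reads = 10L) {
  window_size <- as.integer(window_size); min_sites <- as.integer(min_sites)
  min_reads <- as.integer(min_reads)
  if (anyNA(c(window_size, min_sites, min_reads)) ||
      any(c(window_size, min_sites, min_reads) < 1L)) {
    stop("window_size, min_sites and min_reads must all be >= 1")
  }
  structure(list(window_size = window_size, min_sites = min_sites,
                 min_reads = min_reads), class = "window_criteria")
}

.site_table <- function(sites) {
  dt <- as.data.table(sites)
  need <- c("chrom", "pos", "context", "meth", "unmeth")
  if (!all(need %in% names(dt))) {
    stop("sites need columns ", paste(need, collapse = ", "))
  }
  if (!"sample_id" %in% names(dt)) dt[, sample_id := "sample"]
  dt
}

#' Windowed fractional methylation
#'
#' Tiles each chromosome with non-overlapping windows from coordinate 0 and
#' computes, per (chromosome, window, context, sample), the unweighted mean
#' of per-site methylation fractions `meth / (meth + unmeth)` over
#' qualifying sites (depth >= `min_reads`). Sites below the depth cutoff
#' contribute neither to the mean nor to the qualifying-site count. A window
#' is `valid` when it holds >= `min_sites` qualifying sites; its `fraction`
#' is defined (non-NA) whenever it holds >= 1 qualifying site. Strand is
#' never used in the arithmetic: opposite-strand CG sites are independent
#' records.
#'
#' @param sites site table (see [read_cytosine_report()]); an optional
#'   `sample_id` column separates samples.
#' @param criteria a [window_criteria()].
#' @param genome optional [genome_spec()]; when given, the full tiling of
#'   every chromosome is emitted (site-free windows appear with
#'   `n_qual_sites = 0`, `valid = FALSE`), for every context in `contexts`
#'   and every sample present.
#' @param contexts contexts to emit when `genome` is given.
#' @return data.table with columns `chrom`, `start`, `end` (0-based
#'   half-open), `context`, `sample_id`, `n_qual_sites`, `fraction`, `valid`.
#' @examples
#' s <- data.frame(chrom = "c", pos = c(2, 10, 30), strand = "+",
#'                 meth = c(5, 10, 0), unmeth = c(5, 10, 10),
#'                 context = "CG", tri = "CGA")
#' compute_window_methylation(s)  # one window, fraction (0.5+0.5+0)/3
#' @export
compute_window_methylation <- function(sites, criteria = window_criteria(),
                                       genome = NULL,
                                       contexts = c("CG", "CHG", "CHH")) {
  stopifnot(inherits(criteria, "window_criteria"))
  dt <- .site_table(sites)
  size <- criteria$window_size
  dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
               context = as.character(context),
               depth = meth + unmeth,
               frac = ifelse(meth + unmeth > 0, meth / (meth + unmeth), NA_real_),
               sample_id = as.character(sample_id))]
  dt[, start := ((pos - 1L) %/% size) * size]
  qual <- dt[depth >= criteria$min_reads]
  agg <- qual[, .(n_qual_sites = .N, fraction = mean(frac)),
              by = .(chrom, start, context, sample_id)]
  if (!is.null(genome)) {
    sizes <- genome$chrom_sizes
    tiles <- rbindlist(lapply(names(sizes), function(cn) {
      st <- seq.int(0L, sizes[[cn]] - 1L, by = size)
      data.table(chrom = cn, start = st)
    }))
    samples <- unique(dt$sample_id)
    if (!length(samples)) samples <- "sample"
    full <- CJ(context = contexts, sample_id = samples)[
      , tiles[], by = .(context, sample_id)]
    agg <- merge(full, agg, by = c("chrom", "start", "context", "sample_id"),
                 all.x = TRUE)
    agg[is.na(n_qual_sites), n_qual_sites := 0L]
    agg[, end := pmin(start + size, sizes[chrom])]
  } else {
    agg[, end := start + size]
  }
  agg[, valid := n_qual_sites >= criteria$min_sites]
  setcolorder(agg, c("chrom", "start", "end", "context", "sample_id",
                     "n_qual_sites", "fraction", "valid"))
  setorder(agg, sample_id, context, chrom, start)
  agg[]
}

#' 5-kb chromosomal-view windows
#'
#' The coarse variant used for whole-chromosome methylation profiles:
#' 5-kb windows requiring >= 10 qualifying sites at depth >= 10.
#'
#' @inheritParams compute_window_methylation
#' @param window_size,min_sites,min_reads criteria for the coarse view.
#' @return as [compute_window_methylation()].
#' @export
chromosomal_view_windows <- function(sites, window_size = 5000L,
                                     min_sites = 10L, min_reads = 10L,
                                     genome = NULL) {
  compute_window_methylation(
    sites, window_criteria(window_size, min_sites, min_reads), genome = genome)
}

#' Feature-level fractional methylation
#'
#' Unweighted mean of qualifying per-site fractions over each annotated
#' feature span (gene or TE). A feature is valid for a context/sample when
#' it holds >= `min_sites` qualifying sites (default 5, depth >= 10).
#'
#' @param sites site table.
#' @param features interval table with `feature_id`, `feature_kind`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param min_sites minimum qualifying sites per feature.
#' @param min_reads minimum per-site depth.
#' @param genome optional [genome_spec()] used to bound-check features.
#' @return data.table with `feature_id`, `feature_kind`, `context`,
#'   `sample_id`, `n_qual_sites`, `fraction`, `valid` (all features emitted,
#'   site-free combinations only for observed context/sample pairs).
#' @export
compute_feature_methylation <- function(sites, features, min_sites = 5L,
                                        min_reads = 10L, genome = NULL) {
  dt <- .site_table(sites)
  ft <- .as_intervals(features)
  if (!all(c("feature_id", "feature_kind") %in% names(ft))) {
    stop("features need feature_id and feature_kind columns")
  }
  if (!is.null(genome)) .check_genome(ft, genome)
  dt <- dt[meth + unmeth >= min_reads]
  dt[, frac := meth / (meth + unmeth)]
  ## position pos (1-based) lies in feature [start, end) iff start < pos <= end
  dt[, `:=`(s = pos - 1L, e = pos)]
  ftk <- ft[, .(chrom, start, end, feature_id, feature_kind)]
  setkey(ftk, chrom, start, end)
  ov <- foverlaps(dt[, .(chrom, start = s, end = e, context, sample_id, frac)],
                  ftk, type = "within",
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  agg <- ov[, .(n_qual_sites = .N, fraction = mean(frac)),
            by = .(feature_id, feature_kind, context, sample_id)]
  pairs <- unique(dt[, .(context, sample_id)])
  if (!nrow(pairs)) pairs <- data.table(context = character(),
                                        sample_id = character())
  full <- pairs[, ft[, .(feature_id, feature_kind)], by = .(context, sample_id)]
  agg <- merge(full, agg,
               by = c("feature_id", "feature_kind", "context", "sample_id"),
               all.x = TRUE)
  agg[is.na(n_qual_sites), n_qual_sites := 0L]
  agg[, valid := n_qual_sites >= min_sites]
  setcolorder(agg, c("feature_id", "feature_kind", "context", "sample_id",
                     "n_qual_sites", "fraction", "valid"))
  agg[]
}

#' Write a window table / BEDGraph
#'
#' @param windows table from [compute_window_methylation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  fwrite(as.data.table(windows), path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("chrom", "context", "sample_id")))
  dt[, valid := as.logical(valid)]
  dt[]
}
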
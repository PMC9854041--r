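## Interval algebra over 0-based half-open (BED-style) tables.
## Backed by IRanges/GenomicRanges; all public functions take and return
## plain data.frames with columns chrom, start, end (extra columns allowed).

.as_intervals <- function(x) {
  dt <- as.data.table(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(dt))) {
    stop("interval table needs columns chrom, start, end")
  }
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end))]
  if (nrow(dt) && any(dt$start < 0L | dt$end <= dt$start)) {
    stop("invalid interval: require 0 <= start < end")
  }
  dt[]
}

.check_genome <- function(dt, genome) {
  sizes <- if (inherits(genome, "genome_spec")) genome$chrom_sizes else genome
  if (nrow(dt)) {
    if (any(!dt$chrom %in% names(sizes))) {
      stop("chromosome absent from genome spec: ",
           paste(setdiff(unique(dt$chrom), names(sizes)), collapse = ", "))
    }
    if (any(dt$end > sizes[dt$chrom])) stop("interval exceeds chromosome length")
  }
  sizes
}

.to_gr <- function(dt) {
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}

.from_gr <- function(gr) {
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Merge near-adjacent intervals
#'
#' Fuses intervals on the same chromosome separated by at most `max_gap` bp
#' (`bedtools merge -d` semantics; the default `max_gap = 1` mirrors the
#' merging applied to region sets before enrichment testing so bookended and
#' 1-bp-separated windows count as one locus).
#'
#' @param x interval table (`chrom`, `start`, `end`; 0-based half-open).
#' @param max_gap maximum separation (bp) fused across; 0 merges only
#'   overlapping/bookended intervals.
#' @return data.table of sorted, disjoint merged intervals.
#' @examples
#' merge_intervals(data.frame(chrom = "c", start = c(0, 50), end = c(50, 100)))
#' @export
merge_intervals <- function(x, max_gap = 1L) {
  dt <- .as_intervals(x)
  if (!nrow(dt)) return(dt[, .(chrom, start, end)])
  gr <- GenomicRanges::reduce(.to_gr(dt), min.gapwidth = max_gap + 1L)
  out <- .from_gr(gr)
  setorder(out, chrom, start)
  out[]
}

#' Combine per-context region sets
#'
#' Base-pair-level union or intersection of the three cytosine-context
#' region sets (e.g. Col SR called independently in CG, CHG and CHH).
#' Union: loci covered by at least one context ("CG|CHG|CHH"); intersection:
#' loci covered by all three ("CG&CHG&CHH"). Inputs are merged first so the
#' result is a disjoint locus set.
#'
#' @param context_sets named list of three interval tables (one per context).
#' @param mode `"union"` or `"intersection"`.
#' @return data.table of disjoint intervals.
#' @export
combine_context_regions <- function(context_sets, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(context_sets) != 3L) stop("three per-context sets required")
  grs <- lapply(context_sets, function(s) .to_gr(merge_intervals(s, max_gap = 0L)))
  out <- if (mode == "union") {
    GenomicRanges::reduce(do.call(c, unname(grs)))
  } else {
    Reduce(GenomicRanges::intersect, grs)
  }
  res <- .from_gr(out)
  setorder(res, chrom, start)
  res[]
}

#' Count interval overlaps
#'
#' With `count_once = TRUE` (the regioneR `count.once` convention used
#' throughout the enrichment tests) each query interval is counted at most
#' once, i.e. the result is the number of query intervals overlapping at
#' least one target interval by >= 1 bp. Otherwise every overlapping
#' (query, target) pair is counted.
#'
#' @param query,target interval tables.
#' @param count_once logical.
#' @param genome optional [genome_spec()] or named chrom-size vector; when
#'   supplied, intervals on unknown chromosomes are an error.
#' @return integer count.
#' @export
count_overlaps <- function(query, target, count_once = TRUE, genome = NULL) {
  q <- .as_intervals(query); t <- .as_intervals(target)
  if (!is.null(genome)) { .check_genome(q, genome); .check_genome(t, genome) }
  if (!nrow(q) || !nrow(t)) return(0L)
  hits <- GenomicRanges::findOverlaps(.to_gr(q), .to_gr(t))
  if (count_once) length(unique(S4Vectors::queryHits(hits))) else length(hits)
}

#' Base-pair coverage of one interval set by another
#'
#' @param x interval table whose covered length is measured.
#' @param by covering interval table.
#' @return total number of bp of (merged) `x` covered by (merged) `by`.
#' @export
covered_bp <- function(x, by) {
  xm <- merge_intervals(x, max_gap = 0L); bm <- merge_intervals(by, max_gap = 0L)
  if (!nrow(xm) || !nrow(bm)) return(0)
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(.to_gr(xm), .to_gr(bm)))))
}

#' Total bp spanned by a merged interval set
#' @param x interval table.
#' @return numeric total width after merging overlaps.
#' @export
total_bp <- function(x) {
  xm <- merge_intervals(x, max_gap = 0L)
  if (!nrow(xm)) return(0)
  sum(as.numeric(xm$end - xm$start))
}

#' Read/write BED interval tables
#'
#' Minimal BED3/BED6 reader/writer for the interval dialect produced by this
#' package: tab-separated, 0-based half-open, optional name/score/strand, no
#' header. Extra columns beyond 6 are kept as `V7`, `V8`, ...
#'
#' @param path file path.
#' @return `read_bed`: data.table with `chrom`, `start`, `end` and any of
#'   `name`, `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (!nrow(dt)) return(data.table(chrom = character(), start = integer(),
                                   end = integer()))
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, seq_len(min(ncol(dt), 6L)), cn[seq_len(min(ncol(dt), 6L))])
  .as_intervals(dt)
}

#' @param x interval table; columns beyond `chrom`,`start`,`end` are written
#'   in BED column order when named `name`, `score`, `strand`.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  dt <- .as_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  fwrite(dt[, ..cols], path, sep = "\t", col.names = FALSE,
         scipen = 50, quote = FALSE)
  invisible(path)
}
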
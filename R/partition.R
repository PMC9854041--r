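#' Build the six-sample validity matrix
#'
#' Casts long-format window tables (one row per window x sample) into one
#' row per window with a logical validity column per sample. Samples absent
#' for a window are invalid there.
#'
#' @param windows window table from [compute_window_methylation()] holding
#'   all six samples (`sample_id` = ecotype x stage).
#' @param samples character vector of the expected sample ids (order kept).
#' @return data.table keyed by (`chrom`, `start`, `end`, `context`) with one
#'   logical column per sample.
#' @export
build_validity_matrix <- function(windows,
                                  samples = unique(windows$sample_id)) {
  dt <- as.data.table(windows)
  missing <- setdiff(samples, unique(dt$sample_id))
  if (length(missing)) {
    stop("missing sample column(s): ", paste(missing, collapse = ", "))
  }
  wide <- dcast(dt[sample_id %in% samples],
                chrom + start + end + context ~ sample_id,
                value.var = "valid", fill = FALSE)
  for (s in samples) {
    v <- as.logical(wide[[s]])
    v[is.na(v)] <- FALSE
    set(wide, j = s, value = v)
  }
  setcolorder(wide, c("chrom", "start", "end", "context", samples))
  wide[]
}

#' Partition windows into common and ecotype-specific regions
#'
#' Applies the coverage-based region rule per window and context:
#' * `CR` (common region): valid in all six ecotype x stage samples;
#' * `COL_SR`: valid in >= `col_min_valid` Col samples and no Cvi sample;
#' * `CVI_SR`: the mirror image;
#' * `MIXED`: valid in >= 1 sample of each ecotype but not all six;
#' * `NONE`: valid nowhere (and, when `col_min_valid > 1`, windows whose
#'   single-ecotype validity count falls below the threshold).
#' The five labels are mutually exclusive and exhaustive.
#'
#' @param validity matrix from [build_validity_matrix()].
#' @param col_samples,cvi_samples character vectors naming the three validity
#'   columns of each ecotype.
#' @param col_min_valid minimum number of valid samples in the ecotype for an
#'   SR call (default 1; the same threshold is applied to both ecotypes).
#' @return the input with a `label` factor column appended.
#' @export
partition_regions <- function(validity, col_samples, cvi_samples,
                              col_min_valid = 1L) {
  dt <- as.data.table(validity)
  miss <- setdiff(c(col_samples, cvi_samples), names(dt))
  if (length(miss)) stop("missing sample column: ", paste(miss, collapse = ", "))
  if (length(col_samples) != 3L || length(cvi_samples) != 3L) {
    stop("expect three samples per ecotype")
  }
  nc <- rowSums(as.matrix(dt[, ..col_samples]))
  nv <- rowSums(as.matrix(dt[, ..cvi_samples]))
  lab <- rep("NONE", nrow(dt))
  lab[nc + nv == 6L] <- "CR"
  lab[nc >= col_min_valid & nv == 0L] <- "COL_SR"
  lab[nv >= col_min_valid & nc == 0L] <- "CVI_SR"
  lab[nc >= 1L & nv >= 1L & nc + nv < 6L] <- "MIXED"
  out <- copy(dt)
  out[, label := factor(lab, levels = c("CR", "COL_SR", "CVI_SR", "MIXED",
                                        "NONE"))]
  out[]
}

#' Extract a merged region set for one label
#'
#' Convenience accessor: the windows of one partition label and context,
#' merged with [merge_intervals()].
#'
#' @param partition output of [partition_regions()].
#' @param which_label one of CR, COL_SR, CVI_SR, MIXED, NONE.
#' @param which_context cytosine context to extract.
#' @param max_gap merge distance (bp).
#' @return merged interval data.table.
#' @export
region_set <- function(partition, which_label, which_context, max_gap = 1L) {
  dt <- as.data.table(partition)
  sel <- dt[label == which_label & context == which_context,
            .(chrom, start, end)]
  merge_intervals(sel, max_gap = max_gap)
}
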
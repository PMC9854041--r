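#' Genome specification
#'
#' A minimal genome geometry: chromosome names and lengths, plus optional
#' pericentromere intervals used by the simulator to concentrate TEs and by
#' chromosomal-view summaries.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp),
#'   names are chromosome identifiers.
#' @param pericentromeres optional `data.frame` with columns
#'   `chrom`, `start`, `end` (0-based half-open), one row per pericentromeric
#'   block; must lie within chromosome bounds.
#' @return An object of class `genome_spec`: a list with elements
#'   `chrom_sizes` (named integer vector) and `pericentromeres` (data.table).
#' @examples
#' genome_spec(c(chr1 = 500000L, chr2 = 500000L))
#' @export
genome_spec <- function(chrom_sizes, pericentromeres = NULL) {
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  if (anyNA(chrom_sizes) || any(chrom_sizes <= 0L)) {
    stop("chromosome lengths must be positive")
  }
  if (anyDuplicated(names(chrom_sizes))) stop("duplicate chromosome names")
  if (is.null(pericentromeres)) {
    peri <- data.table(chrom = character(), start = integer(), end = integer())
  } else {
    peri <- as.data.table(pericentromeres)[, .(chrom, start, end)]
    peri[, `:=`(chrom = as.character(chrom), start = as.integer(start),
                end = as.integer(end))]
    if (any(!peri$chrom %in% names(chrom_sizes))) {
      stop("pericentromere on unknown chromosome")
    }
    bad <- peri[start < 0L | end > chrom_sizes[chrom] | start >= end]
    if (nrow(bad)) stop("pericentromere interval outside chromosome bounds")
  }
  structure(list(chrom_sizes = chrom_sizes, pericentromeres = peri),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_sizes), "chromosome(s),",
      format(sum(as.numeric(x$chrom_sizes)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Default desk-scale toy genome
#'
#' Two chromosomes of 500 kb with a central 50 kb pericentromere each:
#' small enough for fast permutation statistics, large enough that windowed
#' summaries have genome-like sample sizes.
#'
#' @return A [genome_spec()].
#' @export
default_genome <- function() {
  genome_spec(
    c(chr1 = 500000L, chr2 = 500000L),
    pericentromeres = data.frame(
      chrom = c("chr1", "chr2"), start = c(225000L, 225000L),
      end = c(275000L, 275000L))
  )
}

#' Read/write a chrom.sizes table
#'
#' Two-column TSV (chromosome, length) as used by UCSC tools.
#'
#' @param path file path.
#' @return `read_chrom_sizes`: named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "size"))
  setNames(as.integer(dt$size), dt$chrom)
}

#' @param chrom_sizes named integer vector.
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  fwrite(data.table(chrom = names(chrom_sizes), size = as.integer(chrom_sizes)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
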
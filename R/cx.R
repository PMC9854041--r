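#' Read a per-cytosine methylation report (Bismark CX dialect)
#'
#' Seven tab-separated columns, no header: chromosome, 1-based position,
#' strand (+/-), methylated read count, unmethylated read count, context
#' (CG/CHG/CHH), trinucleotide. Zero-depth sites are retained (their
#' per-site fraction is undefined and they never qualify for a window).
#'
#' @param path path to the report.
#' @return data.table with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`, `context`, `tri` in file order.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer(), context = character(),
                      tri = character())
  if (file.size(path) == 0L) return(empty)
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = FALSE,
          colClasses = list(character = c(1, 3, 6, 7),
                            integer = c(2, 4, 5))),
    error = function(e) stop("malformed cytosine report '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!nrow(dt)) return(empty)
  if (ncol(dt) != 7L) {
    stop("cytosine report must have 7 columns, found ", ncol(dt))
  }
  setnames(dt, c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri"))
  .check_sites(dt, path)
  dt[]
}

.check_sites <- function(dt, what = "sites") {
  bad <- which(is.na(dt$pos) | dt$pos < 1L |
                 is.na(dt$meth) | dt$meth < 0L |
                 is.na(dt$unmeth) | dt$unmeth < 0L)
  if (length(bad)) {
    stop("invalid record in ", what, " at line ", bad[1],
         ": position must be >= 1 and counts non-negative")
  }
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) {
    stop("unknown context token in ", what, " at line ", bad[1], ": '",
         dt$context[bad[1]], "'")
  }
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("unknown strand in ", what, " at line ", bad[1])
  }
  invisible(TRUE)
}

#' @param sites data.table as returned by [read_cytosine_report()].
#' @rdname read_cytosine_report
#' @export
write_cytosine_report <- function(sites, path) {
  dt <- as.data.table(sites)
  fwrite(dt[, .(chrom, pos, strand, meth, unmeth, context, tri)], path,
         sep = "\t", col.names = FALSE, quote = FALSE, scipen = 50)
  invisible(path)
}
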
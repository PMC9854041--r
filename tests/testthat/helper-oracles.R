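## Independent brute-force oracles and small fixture generators.
## These deliberately avoid the package's interval/window machinery:
## plain loops and per-base bitmaps only.

library(data.table)

## per-window unweighted mean of qualifying site fractions, by direct loop
oracle_window_means <- function(sites, window_size, min_sites, min_reads,
                                chrom_len) {
  out <- list()
  starts <- seq(0, chrom_len - 1, by = window_size)
  for (cx in unique(sites$context)) {
    for (st in starts) {
      en <- min(st + window_size, chrom_len)
      fr <- numeric(0)
      for (i in seq_len(nrow(sites))) {
        s <- sites[i]
        if (s$context != cx) next
        if (s$pos - 1 < st || s$pos - 1 >= en) next
        d <- s$meth + s$unmeth
        if (d >= min_reads) fr <- c(fr, s$meth / d)
      }
      out[[length(out) + 1]] <- data.table(
        chrom = sites$chrom[1], start = st, end = en, context = cx,
        n_qual_sites = length(fr),
        fraction = if (length(fr)) mean(fr) else NA_real_,
        valid = length(fr) >= min_sites)
    }
  }
  rbindlist(out)
}

## pairwise fusion to fixpoint
oracle_merge <- function(iv, max_gap) {
  iv <- as.data.table(iv)[, .(chrom, start, end)]
  repeat {
    fused <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        if (iv$chrom[i] == iv$chrom[j] &&
            iv$start[j] - iv$end[i] <= max_gap &&
            iv$start[i] - iv$end[j] <= max_gap) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j]
          fused <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!fused) break
  }
  setorder(iv, chrom, start)
  iv[]
}

## per-base boolean bitmap of an interval set on a toy genome
oracle_bitmap <- function(iv, sizes) {
  maps <- lapply(sizes, function(L) rep(FALSE, L))
  iv <- as.data.table(iv)
  for (i in seq_len(nrow(iv))) {
    maps[[iv$chrom[i]]][(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  maps
}

bitmap_to_intervals <- function(maps) {
  out <- list()
  for (cn in names(maps)) {
    r <- rle(maps[[cn]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[cn]] <- data.table(chrom = cn, start = st[keep], end = en[keep])
    }
  }
  if (!length(out)) return(data.table(chrom = character(), start = integer(),
                                      end = integer()))
  rbindlist(out)
}

## O(n*m) pairwise overlap counting
oracle_count_overlaps <- function(q, t, count_once = TRUE) {
  q <- as.data.table(q); t <- as.data.table(t)
  n <- 0L
  for (i in seq_len(nrow(q))) {
    hits <- 0L
    for (j in seq_len(nrow(t))) {
      if (q$chrom[i] == t$chrom[j] &&
          q$start[i] < t$end[j] && t$start[j] < q$end[i]) {
        hits <- hits + 1L
      }
    }
    n <- n + if (count_once) as.integer(hits > 0L) else hits
  }
  n
}

## hand rule on one 6-bit validity pattern (3 Col, 3 Cvi), k = 1
oracle_region_label <- function(col3, cvi3) {
  nc <- sum(col3); nv <- sum(cvi3)
  if (nc + nv == 6) "CR"
  else if (nc >= 1 && nv == 0) "COL_SR"
  else if (nv >= 1 && nc == 0) "CVI_SR"
  else if (nc >= 1 && nv >= 1) "MIXED"
  else "NONE"
}

random_intervals <- function(n, sizes, max_len = 50) {
  cn <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i)
    sample.int(sizes[[cn[i]]] - len[i] + 1L, 1L) - 1L, integer(1))
  data.table(chrom = cn, start = st, end = st + len)
}

random_sites <- function(n, chrom_len, chrom = "chrX") {
  data.table(chrom = chrom,
             pos = sample.int(chrom_len, n),
             strand = sample(c("+", "-"), n, replace = TRUE),
             meth = sample(0:20, n, replace = TRUE),
             unmeth = sample(0:20, n, replace = TRUE),
             context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
             tri = "CGA")
}

## small simulation config for fast tests
tiny_genome <- function(len = 100000L) {
  genome_spec(c(chr1 = len, chr2 = len),
              pericentromeres = data.frame(
                chrom = c("chr1", "chr2"),
                start = as.integer(len * 0.45), end = as.integer(len * 0.55)))
}

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, edmr_n = 20L, sr_dropout_n = 10L,
                   sr_dropout_len = 500L, cluster_n = 60L,
                   n_genes_per_chrom = 30L, n_tes_per_chrom = 20L,
                   sv_n = 10L, sv_len_range = c(1000L, 3000L),
                   hot_n = 4L, hot_len = 5000L)
  do.call(simulation_config, modifyList(defaults, list(...)))
}
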
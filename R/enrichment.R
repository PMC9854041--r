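#' Randomize interval placements across the genome
#'
#' Re-places each interval uniformly at random with its length preserved.
#' With `per_chromosome = TRUE` each interval stays on its own chromosome;
#' otherwise the chromosome is drawn with probability proportional to the
#' number of feasible start positions. With `non_overlapping = TRUE`
#' placements are mutually disjoint, enforced by rejection sampling with a
#' bounded retry budget (clear error when a chromosome is too crowded).
#'
#' @param query interval table.
#' @param genome [genome_spec()] or named chrom-size vector.
#' @param per_chromosome keep each interval on its own chromosome.
#' @param non_overlapping forbid overlaps among the randomized intervals.
#' @param max_retries per-interval rejection budget.
#' @return data.table of randomized intervals (same widths, arbitrary
#'   order within chromosome).
#' @export
randomize_regions <- function(query, genome, per_chromosome = TRUE,
                              non_overlapping = TRUE, max_retries = 1000L) {
  q <- .as_intervals(query)
  sizes <- .check_genome(q, genome)
  if (!nrow(q)) return(q[, .(chrom, start, end)])
  widths <- q$end - q$start
  chroms <- q$chrom
  if (!per_chromosome) {
    chroms <- vapply(widths, function(w) {
      feas <- pmax(0, sizes - w + 1)
      if (all(feas == 0)) stop("interval wider than every chromosome")
      sample(names(sizes), 1L, prob = feas)
    }, character(1))
  }
  out_start <- integer(nrow(q))
  ## place longest first within each chromosome to ease packing
  ord <- order(chroms, -widths)
  placed <- new.env(parent = emptyenv())
  for (i in ord) {
    cn <- chroms[i]; w <- widths[i]; L <- sizes[[cn]]
    if (w > L) stop("interval wider than chromosome ", cn)
    prev <- placed[[cn]]  # matrix of (start, end) already placed
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      s <- as.integer(floor(runif(1, min = 0, max = L - w + 1)))
      if (s > L - w) s <- L - w  # guard the measure-zero boundary
      if (!non_overlapping || is.null(prev) ||
          !any(s < prev[, 2L] & prev[, 1L] < s + w)) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not place interval on ", cn, " after ", max_retries,
           " retries (chromosome too crowded)")
    }
    out_start[i] <- s
    if (non_overlapping) placed[[cn]] <- rbind(prev, c(s, s + w))
  }
  res <- data.table(chrom = chroms, start = out_start,
                    end = out_start + widths)
  setorder(res, chrom, start)
  res[]
}

#' Randomization-based interval overlap permutation test
#'
#' regioneR-style test of association between two region sets: the observed
#' count-once overlap (number of query intervals hitting >= 1 target
#' interval) is compared with a null distribution obtained by re-placing
#' the query intervals `n_perm` times ([randomize_regions()], lengths and
#' per-chromosome counts preserved, placements non-overlapping). Both sets
#' are merged (`max_gap = 1`) before testing so fragmented windows do not
#' overstate significance. The empirical p-value uses the conservative
#' pseudocount convention `p = (1 + #{null >= observed}) / (n_perm + 1)`
#' for `alternative = "greater"` (mirrored for `"less"`), so p is never 0.
#'
#' @param query,target interval tables.
#' @param genome [genome_spec()] or named chrom-size vector.
#' @param n_perm number of permutations (>= 1).
#' @param alternative `"greater"` (enrichment) or `"less"` (depletion).
#' @param per_chromosome,non_overlapping passed to [randomize_regions()].
#' @param merge_inputs merge both sets (`max_gap = 1`) first.
#' @return object of class `permutation_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `p_value`, `log2_ratio`
#'   (`log2(observed / null_mean)`, `NA` when the null mean is 0),
#'   `n_perm`, `alternative`, `null` (the permuted counts).
#' @export
permutation_test <- function(query, target, genome, n_perm = 1000L,
                             alternative = c("greater", "less"),
                             per_chromosome = TRUE, non_overlapping = TRUE,
                             merge_inputs = TRUE) {
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  q <- .as_intervals(query); t <- .as_intervals(target)
  .check_genome(q, genome); .check_genome(t, genome)
  if (merge_inputs) {
    q <- merge_intervals(q, max_gap = 1L)
    t <- merge_intervals(t, max_gap = 1L)
  }
  obs <- count_overlaps(q, t, count_once = TRUE)
  null <- vapply(seq_len(n_perm), function(i) {
    r <- randomize_regions(q, genome, per_chromosome = per_chromosome,
                           non_overlapping = non_overlapping)
    count_overlaps(r, t, count_once = TRUE)
  }, numeric(1))
  p <- if (alternative == "greater") {
    (1 + sum(null >= obs)) / (n_perm + 1)
  } else {
    (1 + sum(null <= obs)) / (n_perm + 1)
  }
  nm <- mean(null)
  lr <- if (nm > 0 && obs > 0) log2(obs / nm) else NA_real_
  structure(list(observed = obs, null_mean = nm, null_sd = sd(null),
                 p_value = p, log2_ratio = lr, n_perm = n_perm,
                 alternative = alternative, null = null),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation overlap test (", x$n_perm, " permutations, ",
      x$alternative, ")\n", sep = "")
  cat(sprintf("  observed: %d   null: %.2f +/- %.2f\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p = %.4g   log2(obs/exp) = %s\n", x$p_value,
              formatC(x$log2_ratio, digits = 3)))
  invisible(x)
}

#' @param x a `permutation_result`.
#' @param path output path.
#' @rdname permutation_test
#' @export
write_permutation_result <- function(x, path) {
  jsonlite::write_json(
    list(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, p_value = x$p_value,
         log2_ratio = x$log2_ratio, n_perm = x$n_perm,
         alternative = x$alternative),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
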
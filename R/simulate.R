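#' Simulation configuration
#'
#' Parameters of the two-ecotype (Col, Cvi), three-stage (FH, AR, GS)
#' synthetic seed methylome. Defaults encode the qualitative structure the
#' pipeline is meant to detect: two ecotypes differing chiefly in genic CG
#' methylation (Cvi lower), a stage-dependent non-CG gain at AR, TE-dense
#' pericentromeres, Cvi coverage-dropout blocks (the source of Col-specific
#' regions), planted eDMR windows with a fixed ecotype effect, and 24-nt
#' small RNA clusters whose ecotype fold-change is coupled to the planted
#' eDMRs (Col-hypermethylated window -> Col-up cluster).
#'
#' @param seed integer random seed; every generator derives its stream
#'   from it, so identical (config, genome) pairs yield identical files.
#' @param window_size analysis window width (bp).
#' @param site_density named per-bp cytosine density per context.
#' @param baseline 3x3 numeric matrix of true methylation fractions,
#'   rows `gene`, `te`, `igr`, columns `CG`, `CHG`, `CHH`.
#' @param cvi_gene_cg_offset genic-CG reduction in Cvi (fraction).
#' @param ar_noncg_gain CHG/CHH gain applied at the AR stage (fraction).
#' @param edmr_n,edmr_delta,edmr_hypo_frac,edmr_base,edmr_context planted
#'   eDMR windows: count, |effect| (Col-Cvi difference), fraction planted
#'   as Col-hypo, the shared midpoint methylation, and context.
#' @param sr_dropout_n,sr_dropout_len Cvi coverage-dropout blocks (count,
#'   bp); inside them all Cvi samples have depth 0 in every context.
#' @param snp_density per-bp SNP probability; `snp_code_weights` optional
#'   named weights over the 12 ordered substitution codes.
#' @param sv_n,sv_len_range,sv_category_weights structural variants.
#' @param hot_n,hot_len HOT-region blocks.
#' @param n_genes_per_chrom,gene_len,n_tes_per_chrom,te_len,
#'   te_pericentromere_weight,allow_gene_overlap annotation geometry;
#'   TEs fall inside pericentromeres with the given probability.
#' @param cluster_n,cluster_len,cluster_mean,cluster_dispersion,cluster_fc,
#'   n_reps 24-nt clusters: total count (couples one cluster to every
#'   planted eDMR, the rest are background), width, negative-binomial mean
#'   and dispersion, ecotype fold-change of coupled clusters, replicates
#'   per ecotype x stage.
#' @param depth_min,depth_mean,depth_size WGBS read depth per cytosine:
#'   `depth_min + NB(mu = depth_mean - depth_min, size = depth_size)`.
#'   The floor of 10 makes every sited window pass the depth criterion, so
#'   validity is governed by site counts (and by dropout).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    window_size = 50L,
    site_density = c(CG = 0.08, CHG = 0.08, CHH = 0.20),
    baseline = NULL,
    cvi_gene_cg_offset = 0.10,
    ar_noncg_gain = 0.05,
    edmr_n = 100L, edmr_delta = 0.40, edmr_hypo_frac = 0.4,
    edmr_base = 0.45, edmr_context = "CG",
    sr_dropout_n = 50L, sr_dropout_len = 1000L,
    snp_density = 0.005, snp_code_weights = NULL,
    sv_n = 40L, sv_len_range = c(2000L, 10000L),
    sv_category_weights = c(DEL = 0.25, INS = 0.2, DUP = 0.2, BRK = 0.1,
                            INV = 0.1, SEQ = 0.1, UNCLASSIFIED = 0.05),
    hot_n = 10L, hot_len = 10000L,
    n_genes_per_chrom = 120L, gene_len = 2000L,
    n_tes_per_chrom = 80L, te_len = 1000L,
    te_pericentromere_weight = 0.8, allow_gene_overlap = FALSE,
    cluster_n = 300L, cluster_len = 300L, cluster_mean = 200,
    cluster_dispersion = 0.1, cluster_fc = 8, n_reps = 3L,
    depth_min = 10L, depth_mean = 30, depth_size = 10) {
  if (is.null(baseline)) {
    baseline <- matrix(c(0.30, 0.02, 0.02,
                         0.90, 0.70, 0.40,
                         0.10, 0.05, 0.05),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(c("gene", "te", "igr"),
                                       c("CG", "CHG", "CHH")))
  }
  if (is.null(snp_code_weights)) {
    bases <- c("A", "C", "G", "T")
    codes <- as.vector(outer(bases, bases, paste0))
    codes <- codes[substr(codes, 1, 1) != substr(codes, 2, 2)]
    snp_code_weights <- setNames(rep(1 / 12, 12), codes)
  }
  cfg <- structure(as.list(environment()), class = "simulation_config")
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  for (f in c("cvi_gene_cg_offset", "ar_noncg_gain", "edmr_hypo_frac",
              "edmr_base", "te_pericentromere_weight", "snp_density")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop("config error: '", f, "' must be a fraction in [0, 1]")
    }
  }
  if (any(cfg$baseline < 0 | cfg$baseline > 1)) {
    stop("config error: 'baseline' fractions must lie in [0, 1]")
  }
  if (cfg$edmr_delta < 0 || cfg$edmr_base + cfg$edmr_delta / 2 > 1 ||
      cfg$edmr_base - cfg$edmr_delta / 2 < 0) {
    stop("config error: edmr_base +/- edmr_delta/2 leaves [0, 1]")
  }
  if (any(cfg$baseline[, c("CHG", "CHH")] + cfg$ar_noncg_gain > 1)) {
    stop("config error: ar_noncg_gain pushes a baseline above 1")
  }
  if (cfg$baseline["gene", "CG"] - cfg$cvi_gene_cg_offset < 0) {
    stop("config error: cvi_gene_cg_offset pushes genic CG below 0")
  }
  if (cfg$cluster_dispersion <= 0) stop("config error: dispersion must be > 0")
  if (!cfg$edmr_context %in% c("CG", "CHG", "CHH")) {
    stop("config error: unknown edmr_context")
  }
  if (cfg$depth_mean < cfg$depth_min) {
    stop("config error: depth_mean below depth_min")
  }
  invisible(TRUE)
}

## uniform non-overlapping block placement on one chromosome,
## avoiding an optional set of (start,end) exclusions
.place_blocks <- function(n, len, chrom_len, avoid = NULL,
                          max_retries = 2000L) {
  placed <- matrix(numeric(0), ncol = 2)
  if (!is.null(avoid) && nrow(avoid)) placed <- as.matrix(avoid)
  out <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      s <- sample.int(chrom_len - len + 1L, 1L) - 1L
      if (!nrow(placed) || !any(s < placed[, 2] & placed[, 1] < s + len)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place block: chromosome too crowded")
    out[i] <- s
    placed <- rbind(placed, c(s, s + len))
  }
  out
}

#' Simulate gene/TE annotations and SNP/SV/HOT tracks
#'
#' Genes are placed non-overlapping on chromosome arms; TEs fall inside
#' pericentromeres with probability `te_pericentromere_weight` (and may
#' overlap genes, producing Gene&TE loci). SNPs are Bernoulli per bp with
#' substitution codes drawn by weight; SVs get categories from a
#' multinomial draw; HOT blocks are placed non-overlapping.
#'
#' @param config a [simulation_config()].
#' @param genome a [genome_spec()].
#' @return list of data.tables: `genes`, `tes` (feature tables), `snps`,
#'   `svs`, `hot`.
#' @export
simulate_annotations <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "genome_spec"))
  set.seed(config$seed + 101L)
  sizes <- genome$chrom_sizes
  peri <- genome$pericentromeres
  genes <- rbindlist(lapply(names(sizes), function(cn) {
    L <- sizes[[cn]]
    pc <- peri[chrom == cn]
    avoid <- if (nrow(pc)) as.matrix(pc[, .(start, end)]) else NULL
    if (!config$allow_gene_overlap) {
      st <- .place_blocks(config$n_genes_per_chrom, config$gene_len, L, avoid)
    } else {
      st <- sample.int(L - config$gene_len + 1L,
                       config$n_genes_per_chrom, replace = TRUE) - 1L
    }
    data.table(chrom = cn, start = st, end = st + config$gene_len)
  }))
  setorder(genes, chrom, start)
  genes[, `:=`(feature_id = sprintf("gene_%05d", .I), feature_kind = "gene")]
  tes <- rbindlist(lapply(names(sizes), function(cn) {
    L <- sizes[[cn]]
    pc <- peri[chrom == cn]
    in_peri <- runif(config$n_tes_per_chrom) < config$te_pericentromere_weight
    st <- integer(config$n_tes_per_chrom)
    for (i in seq_along(st)) {
      if (in_peri[i] && nrow(pc)) {
        row <- pc[sample.int(nrow(pc), 1L)]
        st[i] <- row$start +
          sample.int(row$end - row$start - config$te_len + 1L, 1L) - 1L
      } else {
        st[i] <- sample.int(L - config$te_len + 1L, 1L) - 1L
      }
    }
    data.table(chrom = cn, start = st, end = st + config$te_len)
  }))
  setorder(tes, chrom, start)
  tes[, `:=`(feature_id = sprintf("te_%05d", .I), feature_kind = "te")]
  ## SNPs
  codes <- names(config$snp_code_weights)
  snps <- rbindlist(lapply(names(sizes), function(cn) {
    L <- sizes[[cn]]
    n <- rbinom(1L, L, config$snp_density)
    if (n == 0L) return(data.table(chrom = character(), pos = integer(),
                                   col_base = character(),
                                   cvi_base = character()))
    pos <- sort(sample.int(L, n))
    cd <- sample(codes, n, replace = TRUE, prob = config$snp_code_weights)
    data.table(chrom = cn, pos = pos,
               col_base = substr(cd, 1, 1), cvi_base = substr(cd, 2, 2))
  }))
  if (nrow(snps)) snps[, code := paste0(col_base, cvi_base)]
  ## SVs
  cats <- names(config$sv_category_weights)
  ncat <- as.vector(rmultinom(1, config$sv_n, config$sv_category_weights))
  sv_cat <- rep(cats, ncat)
  svs <- data.table(
    chrom = sample(names(sizes), config$sv_n, replace = TRUE),
    len = sample(seq.int(config$sv_len_range[1], config$sv_len_range[2]),
                 config$sv_n, replace = TRUE),
    category = sample(sv_cat))
  svs[, start := vapply(seq_len(.N), function(i)
    sample.int(sizes[[chrom[i]]] - len[i] + 1L, 1L) - 1L, integer(1))]
  svs[, end := start + len][, len := NULL]
  svs[, category := factor(category, levels = cats)]
  setorder(svs, chrom, start)
  ## HOT regions
  hot <- rbindlist(lapply(names(sizes), function(cn) {
    n <- config$hot_n %/% length(sizes) +
      as.integer(match(cn, names(sizes)) <= config$hot_n %% length(sizes))
    if (n == 0L) return(data.table(chrom = character(), start = integer(),
                                   end = integer()))
    st <- .place_blocks(n, config$hot_len, sizes[[cn]])
    data.table(chrom = cn, start = st, end = st + config$hot_len)
  }))
  setorder(hot, chrom, start)
  list(genes = genes[], tes = tes[], snps = snps[], svs = svs[, .(
    chrom, start, end, category)], hot = hot[])
}

#' Plant the ground-truth loci
#'
#' Chooses the planted eDMR windows (on chromosome arms), the Cvi
#' coverage-dropout blocks (arms, avoiding planted windows), and the 24-nt
#' cluster placements (one cluster centred on every planted eDMR window,
#' the remainder background), and returns the machine-readable truth
#' table used by the recovery tests.
#'
#' @param config a [simulation_config()].
#' @param genome a [genome_spec()].
#' @return list with data.tables `edmr` (window, direction, delta),
#'   `dropout` (blocks), `clusters` (interval, coupled flag, true class
#'   and log2 fold-change).
#' @export
plant_truth <- function(config, genome) {
  set.seed(config$seed + 202L)
  sizes <- genome$chrom_sizes
  peri <- genome$pericentromeres
  wsz <- config$window_size
  ## candidate windows: on arms, whole windows only
  cand <- rbindlist(lapply(names(sizes), function(cn) {
    st <- seq.int(0L, (sizes[[cn]] %/% wsz) * wsz - wsz, by = wsz)
    dt <- data.table(chrom = cn, start = st, end = st + wsz)
    pc <- peri[chrom == cn]
    if (nrow(pc)) {
      for (i in seq_len(nrow(pc))) {
        dt <- dt[end <= pc$start[i] | start >= pc$end[i]]
      }
    }
    dt
  }))
  if (config$edmr_n > nrow(cand)) stop("too many planted eDMRs for genome")
  edmr <- cand[sample.int(nrow(cand), config$edmr_n)]
  n_hypo <- round(config$edmr_n * config$edmr_hypo_frac)
  dir <- rep("hyper", config$edmr_n)
  if (n_hypo > 0L) dir[sample.int(config$edmr_n, n_hypo)] <- "hypo"
  edmr[, `:=`(context = config$edmr_context, direction = dir,
              delta = ifelse(dir == "hyper", config$edmr_delta,
                             -config$edmr_delta))]
  setorder(edmr, chrom, start)
  ## dropout blocks on arms, avoiding planted eDMR windows
  dropout <- rbindlist(lapply(names(sizes), function(cn) {
    n <- config$sr_dropout_n %/% length(sizes) +
      as.integer(match(cn, names(sizes)) <= config$sr_dropout_n %% length(sizes))
    if (n == 0L) return(data.table(chrom = character(), start = integer(),
                                   end = integer()))
    avoid <- rbind(as.matrix(edmr[chrom == cn, .(start, end)]),
                   as.matrix(peri[chrom == cn, .(start, end)]))
    st <- .place_blocks(n, config$sr_dropout_len, sizes[[cn]], avoid)
    data.table(chrom = cn, start = st, end = st + config$sr_dropout_len)
  }))
  setorder(dropout, chrom, start)
  ## clusters: coupled ones centred on planted eDMR windows
  half <- (config$cluster_len - wsz) %/% 2L
  coupled <- edmr[, .(chrom,
                      start = pmax(0L, start - half),
                      end = pmin(sizes[chrom], start - half + config$cluster_len),
                      coupled = TRUE, direction)]
  n_bg <- max(0L, config$cluster_n - nrow(coupled))
  bg <- rbindlist(lapply(names(sizes), function(cn) {
    n <- n_bg %/% length(sizes) +
      as.integer(match(cn, names(sizes)) <= n_bg %% length(sizes))
    if (n == 0L) return(NULL)
    avoid <- as.matrix(coupled[chrom == cn, .(start, end)])
    st <- .place_blocks(n, config$cluster_len, sizes[[cn]], avoid)
    data.table(chrom = cn, start = st, end = st + config$cluster_len,
               coupled = FALSE, direction = NA_character_)
  }))
  clusters <- rbind(coupled, bg)
  setorder(clusters, chrom, start)
  clusters[, cluster_id := sprintf("cluster_%05d", .I)]
  clusters[, `:=`(
    true_class = fifelse(!coupled, "non_e24sRC",
                         fifelse(direction == "hyper", "e24sRC_Col",
                                 "e24sRC_Cvi")),
    true_log2fc = fifelse(!coupled, 0,
                          fifelse(direction == "hyper", log2(config$cluster_fc),
                                  -log2(config$cluster_fc))))]
  list(edmr = edmr[], dropout = dropout[], clusters = clusters[])
}

.sim_samples <- function() {
  CJ(ecotype = c("Col", "Cvi"), stage = c("FH", "AR", "GS"))[
    , sample_id := paste(ecotype, stage, sep = "_")][]
}

.tri_pool <- list(CG = c("CGA", "CGT", "CGC", "CGG"),
                  CHG = c("CAG", "CTG", "CCG"),
                  CHH = c("CAA", "CAT", "CTA", "CTT", "CCA", "CCT"))

#' Simulate per-cytosine methylation reports
#'
#' Generates one CX-dialect site table per ecotype x stage. Cytosine
#' positions (shared by all six samples, as on a common reference) are
#' Bernoulli per bp and context; every planted eDMR window is guaranteed
#' >= 5 sites of the planted context so each truth entry is a measurable
#' locus. Per site and sample, depth is `depth_min + NB(mu, size)` (0 for
#' Cvi inside dropout blocks) and the methylated count is binomial at the
#' stratum's true fraction (TE > gene > intergenic precedence) after the
#' ecotype/stage modifiers and planted effects.
#'
#' @param config a [simulation_config()].
#' @param genome a [genome_spec()].
#' @param annotations optional [simulate_annotations()] output (regenerated
#'   deterministically from the config seed when `NULL`).
#' @param truth optional [plant_truth()] output (idem).
#' @return list with `sites` (named list of six site tables in
#'   [read_cytosine_report()] layout), `truth`, `annotations`.
#' @export
simulate_cytosine_reports <- function(config, genome, annotations = NULL,
                                      truth = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "genome_spec"))
  if (is.null(annotations)) annotations <- simulate_annotations(config, genome)
  if (is.null(truth)) truth <- plant_truth(config, genome)
  set.seed(config$seed + 303L)
  sizes <- genome$chrom_sizes
  wsz <- config$window_size
  ## site positions per chromosome x context
  sites <- rbindlist(lapply(names(sizes), function(cn) {
    L <- sizes[[cn]]
    rbindlist(lapply(names(config$site_density), function(cx) {
      n <- rbinom(1L, L, config$site_density[[cx]])
      if (n == 0L) return(NULL)
      data.table(chrom = cn, pos = sort(sample.int(L, n)), context = cx)
    }))
  }))
  ## guarantee >= 5 sites of the planted context in each planted window
  guar <- rbindlist(lapply(seq_len(nrow(truth$edmr)), function(i) {
    e <- truth$edmr[i]
    have <- sites[chrom == e$chrom & context == e$context &
                    pos > e$start & pos <= e$end, pos]
    need <- 5L - length(have)
    if (need <= 0L) return(NULL)
    avail <- setdiff(seq.int(e$start + 1L, e$end), have)
    data.table(chrom = e$chrom, pos = sample(avail, need),
               context = e$context)
  }))
  if (nrow(guar)) sites <- rbind(sites, guar)
  setorder(sites, context, chrom, pos)
  sites <- unique(sites, by = c("chrom", "pos", "context"))
  sites[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  sites[, tri := unlist(lapply(.tri_pool[context], sample, size = 1))]
  ## stratum per site: TE > gene > intergenic
  sites[, stratum := "igr"]
  mark <- function(feat, value) {
    if (!nrow(feat)) return()
    fk <- feat[, .(chrom, start, end)]
    setkey(fk, chrom, start, end)
    ov <- foverlaps(sites[, .(chrom, start = pos - 1L, end = pos,
                              idx = .I)],
                    fk, type = "within",
                     by.x = c("chrom", "start", "end"), nomatch = NULL)
    sites[unique(ov$idx), stratum := value]
  }
  mark(annotations$genes, "gene")
  mark(annotations$tes, "te")
  ## true fraction per site x ecotype x stage
  sites[, win := ((pos - 1L) %/% wsz) * wsz]
  edk <- truth$edmr[, .(chrom, start, context, delta)]
  sites <- merge(sites, edk,
                 by.x = c("chrom", "win", "context"),
                 by.y = c("chrom", "start", "context"), all.x = TRUE)
  drk <- truth$dropout[, .(chrom, start, end)]
  setkey(drk, chrom, start, end)
  ovd <- foverlaps(sites[, .(chrom, start = pos - 1L, end = pos, idx = .I)],
                   drk, type = "within",
                     by.x = c("chrom", "start", "end"), nomatch = NULL)
  sites[, dropout := FALSE]
  if (nrow(ovd)) sites[unique(ovd$idx), dropout := TRUE]
  samples <- .sim_samples()
  base <- config$baseline
  out <- setNames(vector("list", nrow(samples)), samples$sample_id)
  for (i in seq_len(nrow(samples))) {
    eco <- samples$ecotype[i]; stg <- samples$stage[i]
    p <- base[cbind(sites$stratum, sites$context)]
    if (eco == "Cvi") {
      sel <- sites$stratum == "gene" & sites$context == "CG"
      p[sel] <- p[sel] - config$cvi_gene_cg_offset
    }
    if (stg == "AR") {
      sel <- sites$context != "CG"
      p[sel] <- p[sel] + config$ar_noncg_gain
    }
    planted <- !is.na(sites$delta)
    p[planted] <- config$edmr_base +
      (if (eco == "Col") 0.5 else -0.5) * sites$delta[planted]
    p <- pmin(1, pmax(0, p))
    n <- nrow(sites)
    depth <- config$depth_min +
      rnbinom(n, size = config$depth_size,
              mu = config$depth_mean - config$depth_min)
    if (eco == "Cvi") depth[sites$dropout] <- 0L
    meth <- rbinom(n, depth, p)
    out[[samples$sample_id[i]]] <- data.table(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      meth = meth, unmeth = depth - meth, context = sites$context,
      tri = sites$tri)[order(chrom, pos)]
  }
  list(sites = out, truth = truth, annotations = annotations)
}

#' Simulate the 24-nt small RNA cluster count matrix
#'
#' Negative-binomial counts per cluster and sample (2 ecotypes x 3 stages
#' x `n_reps` replicates); per-cluster baseline means are log-normal
#' around `cluster_mean` and clusters coupled to a planted eDMR carry the
#' configured ecotype fold-change (up in the hypermethylated ecotype) at
#' every stage.
#'
#' @inheritParams simulate_cytosine_reports
#' @return list with `clusters` (truth-annotated cluster table) and
#'   `counts` (integer matrix, clusters x samples, e.g. column
#'   `Col_FH_r1`).
#' @export
simulate_srna_counts <- function(config, genome, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(truth)) truth <- plant_truth(config, genome)
  set.seed(config$seed + 404L)
  cl <- copy(truth$clusters)
  K <- nrow(cl)
  base_mu <- stats::rlnorm(K, meanlog = log(config$cluster_mean), sdlog = 0.5)
  samples <- .sim_samples()
  cols <- as.vector(outer(samples$sample_id,
                          paste0("r", seq_len(config$n_reps)), paste,
                          sep = "_"))
  counts <- matrix(0L, nrow = K, ncol = length(cols),
                   dimnames = list(cl$cluster_id, cols))
  fc <- 2^cl$true_log2fc  # Col/Cvi ratio; symmetric split around baseline
  for (j in seq_along(cols)) {
    eco <- sub("_.*", "", cols[j])
    mu <- base_mu * if (eco == "Col") sqrt(fc) else 1 / sqrt(fc)
    counts[, j] <- rnbinom(K, size = 1 / config$cluster_dispersion, mu = mu)
  }
  list(clusters = cl[], counts = counts)
}

#' Simulate and write the complete dataset
#'
#' Runs [simulate_annotations()], [plant_truth()],
#' [simulate_cytosine_reports()] and [simulate_srna_counts()] and writes
#' all artifacts to `outdir`: six CX reports, gene/TE GFF3 + BED, SNP TSV,
#' SV/HOT/cluster BEDs, the cluster count TSV, a chrom.sizes table, and
#' the truth table TSV.
#'
#' @inheritParams simulate_cytosine_reports
#' @param outdir output directory (created).
#' @return named list of written file paths plus the in-memory objects
#'   (`data`).
#' @export
simulate_dataset <- function(config, genome = default_genome(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotations(config, genome)
  truth <- plant_truth(config, genome)
  rep <- simulate_cytosine_reports(config, genome, ann, truth)
  srna <- simulate_srna_counts(config, genome, truth)
  paths <- list()
  for (sid in names(rep$sites)) {
    p <- file.path(outdir, paste0(sid, ".CX_report.txt"))
    write_cytosine_report(rep$sites[[sid]], p)
    paths[[paste0("cx_", sid)]] <- p
  }
  feat <- rbind(ann$genes, ann$tes)
  paths$features_gff3 <- .write_feature_gff3(feat, genome,
                                             file.path(outdir, "features.gff3"))
  paths$genes_bed <- write_bed(ann$genes[, .(chrom, start, end,
                                             name = feature_id, score = 0L,
                                             strand = "+")],
                               file.path(outdir, "genes.bed"))
  paths$tes_bed <- write_bed(ann$tes[, .(chrom, start, end,
                                         name = feature_id, score = 0L,
                                         strand = "+")],
                             file.path(outdir, "tes.bed"))
  paths$snps <- file.path(outdir, "snps.tsv")
  fwrite(ann$snps[, .(chrom, pos, col_base, cvi_base)], paths$snps,
         sep = "\t")
  paths$svs <- write_bed(ann$svs[, .(chrom, start, end,
                                     name = as.character(category))],
                         file.path(outdir, "svs.bed"))
  paths$hot <- write_bed(ann$hot, file.path(outdir, "hot.bed"))
  paths$clusters_bed <- write_bed(
    srna$clusters[, .(chrom, start, end, name = cluster_id)],
    file.path(outdir, "clusters_24nt.bed"))
  paths$cluster_counts <- file.path(outdir, "cluster_counts.tsv")
  fwrite(data.table(cluster_id = rownames(srna$counts), srna$counts),
         paths$cluster_counts, sep = "\t")
  paths$chrom_sizes <- write_chrom_sizes(genome$chrom_sizes,
                                         file.path(outdir, "chrom.sizes"))
  paths$truth <- file.path(outdir, "truth.tsv")
  tt <- rbind(
    truth$edmr[, .(kind = "edmr", chrom, start, end, context,
                   direction, delta, cluster_id = NA_character_,
                   true_class = NA_character_, true_log2fc = NA_real_)],
    truth$dropout[, .(kind = "sr_dropout", chrom, start, end,
                      context = NA_character_, direction = NA_character_,
                      delta = NA_real_, cluster_id = NA_character_,
                      true_class = NA_character_, true_log2fc = NA_real_)],
    truth$clusters[, .(kind = "cluster", chrom, start, end,
                       context = NA_character_, direction,
                       delta = NA_real_, cluster_id, true_class,
                       true_log2fc)])
  fwrite(tt, paths$truth, sep = "\t")
  c(paths, list(data = list(annotations = ann, truth = truth,
                            sites = rep$sites, clusters = srna$clusters,
                            counts = srna$counts)))
}

.write_feature_gff3 <- function(features, genome, path) {
  gr <- .to_gr(features)
  S4Vectors::mcols(gr)$type <- ifelse(features$feature_kind == "gene",
                                      "gene", "transposable_element")
  S4Vectors::mcols(gr)$ID <- features$feature_id
  S4Vectors::mcols(gr)$source <- "ecomethyl_sim"
  GenomeInfoDb::seqlengths(gr) <- genome$chrom_sizes[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  path
}

#' Read feature annotations from GFF3
#'
#' Imports a GFF3 and returns the gene / transposable-element intervals in
#' the feature-table layout used by [compute_feature_methylation()].
#'
#' @param path GFF3 file.
#' @return data.table `chrom`, `start`, `end`, `feature_id`,
#'   `feature_kind`.
#' @export
read_feature_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  dt <- .from_gr(gr)
  md <- S4Vectors::mcols(gr)
  dt[, feature_id := as.character(md$ID)]
  dt[, feature_kind := fifelse(as.character(md$type) == "gene", "gene", "te")]
  dt[]
}
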
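#' Read a pipeline configuration file
#'
#' JSON with optional sections `genome` (`chrom_sizes`, `pericentromeres`),
#' `simulation` (arguments of [simulation_config()]), `criteria`
#' (`window_size`, `min_sites`, `min_reads`), `edmr` (`k`), `srna`
#' (`fdr`, `fc`) and `permutation` (`n_perm`); a top-level `seed` overrides
#' the simulation seed. Unspecified values take the package defaults.
#'
#' @param path JSON config file.
#' @return list with validated `genome`, `simulation` config, `criteria`,
#'   and analysis parameters.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  genome <- if (!is.null(raw$genome)) {
    peri <- raw$genome$pericentromeres
    genome_spec(unlist(raw$genome$chrom_sizes),
                pericentromeres = if (!is.null(peri)) as.data.frame(peri))
  } else default_genome()
  sim_args <- if (is.null(raw$simulation)) list() else as.list(raw$simulation)
  if (!is.null(raw$seed)) sim_args$seed <- as.integer(raw$seed)
  if (!is.null(sim_args$baseline)) {
    sim_args$baseline <- matrix(unlist(sim_args$baseline), nrow = 3,
                                byrow = TRUE,
                                dimnames = list(c("gene", "te", "igr"),
                                                c("CG", "CHG", "CHH")))
  }
  config <- do.call(simulation_config, sim_args)
  crit_args <- if (is.null(raw$criteria)) list() else as.list(raw$criteria)
  criteria <- do.call(window_criteria, crit_args)
  list(genome = genome, simulation = config, criteria = criteria,
       edmr_k = if (is.null(raw$edmr$k)) 1 else raw$edmr$k,
       srna_fdr = if (is.null(raw$srna$fdr)) 0.05 else raw$srna$fdr,
       srna_fc = if (is.null(raw$srna$fc)) 2 else raw$srna$fc,
       n_perm = if (is.null(raw$permutation$n_perm)) 1000L
                else as.integer(raw$permutation$n_perm))
}

#' Run the full pipeline on a simulated dataset
#'
#' Orchestrates simulate -> windowed methylation -> CR/SR partition ->
#' eDMR calling (per stage, stage-consistent set, feature breakdown) ->
#' 24-nt cluster differential expression and e24sRC classification ->
#' permutation enrichment of stage-consistent eDMRs in e24sRC loci ->
#' SNP/SV/HOT methylation summaries, writing every table under `outdir`
#' and a JSON run manifest last. A failing stage aborts with the stage
#' name; files already written by the failing stage are renamed with a
#' `.partial` suffix.
#'
#' @param config path to a JSON config file, or a list as returned by
#'   [read_pipeline_config()].
#' @param outdir output directory.
#' @return the manifest, invisibly: config hash, seed, per-stage output
#'   paths, package version, timestamps.
#' @export
run_pipeline <- function(config, outdir) {
  t0 <- Sys.time()
  cfg_hash <- if (is.character(config)) unname(tools::md5sum(config))
              else NA_character_
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = cfg_hash, seed = cfg$simulation$seed,
                   version = as.character(packageVersion("ecomethyl")),
                   started = format(t0, usetz = TRUE), stages = list())
  run_stage <- function(name, paths, fun) {
    res <- tryCatch(fun(), error = function(e) {
      for (p in unlist(paths)) {
        if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- unlist(paths)
    res
  }
  stages <- c("FH", "AR", "GS")
  contexts <- c("CG", "CHG", "CHH")

  ## 1. simulate
  sim <- run_stage("simulate", list(), function()
    simulate_dataset(cfg$simulation, cfg$genome, file.path(outdir, "sim")))
  manifest$stages$simulate <-
    unlist(sim[setdiff(names(sim), "data")], use.names = FALSE)

  ## 2. windows
  win_path <- file.path(outdir, "windows.tsv")
  windows <- run_stage("windows", list(win_path), function() {
    all_sites <- rbindlist(lapply(names(sim$data$sites), function(sid) {
      copy(sim$data$sites[[sid]])[, sample_id := sid]
    }))
    w <- compute_window_methylation(all_sites, cfg$criteria,
                                    genome = cfg$genome)
    write_window_table(w, win_path)
    w
  })

  ## 3. partition
  part_path <- file.path(outdir, "partition.tsv")
  samples <- .sim_samples()
  part <- run_stage("partition", list(part_path), function() {
    vm <- build_validity_matrix(windows, samples$sample_id)
    p <- partition_regions(vm,
                           col_samples = paste0("Col_", stages),
                           cvi_samples = paste0("Cvi_", stages))
    fwrite(p, part_path, sep = "\t")
    p
  })

  ## 4. eDMR
  edmr_paths <- list(calls = file.path(outdir, "edmr_calls.tsv"),
                     rg = file.path(outdir, "edmr_rg.bed"),
                     summary = file.path(outdir, "edmr_summary.tsv"))
  edmr <- run_stage("edmr", edmr_paths, function() {
    cr <- part[label == "CR", .(chrom, start, end, context)]
    deltas <- rbindlist(lapply(stages, function(s) {
      compute_deltas(windows[sample_id == paste0("Col_", s)],
                     windows[sample_id == paste0("Cvi_", s)],
                     stage = s, cr_windows = cr)
    }))
    called <- call_edmrs(deltas, k = cfg$edmr_k)
    rg <- stage_consistent_edmrs(called$calls, stages)
    fwrite(called$calls, edmr_paths$calls, sep = "\t")
    write_bed(rg[, .(chrom, start, end, name = direction)], edmr_paths$rg)
    feat <- rbindlist(lapply(contexts, function(cx) {
      cl <- classify_edmr_features(rg[context == cx],
                                   sim$data$annotations$genes,
                                   sim$data$annotations$tes)$counts
      cl[, context := cx][]
    }))
    fwrite(feat, edmr_paths$summary, sep = "\t")
    list(calls = called$calls, thresholds = called$thresholds, rg = rg)
  })

  ## 5. small RNA classification
  srna_paths <- list(de = file.path(outdir, "srna_de.tsv"),
                     classes = file.path(outdir, "srna_classes.tsv"))
  srna <- run_stage("srna", srna_paths, function() {
    counts <- sim$data$counts
    de <- setNames(lapply(stages, function(s) {
      test_differential_expression(
        counts,
        group_a = grep(paste0("^Col_", s, "_"), colnames(counts),
                       value = TRUE),
        group_b = grep(paste0("^Cvi_", s, "_"), colnames(counts),
                       value = TRUE))
    }), stages)
    cls <- classify_e24src(de, fdr = cfg$srna_fdr, fc = cfg$srna_fc)
    fwrite(rbindlist(lapply(stages, function(s) copy(de[[s]])[, stage := s])),
           srna_paths$de, sep = "\t")
    fwrite(cls, srna_paths$classes, sep = "\t")
    list(de = de, classes = cls)
  })

  ## 6. permutation enrichment: stage-consistent eDMRs vs e24sRC loci
  perm_path <- file.path(outdir, "permtest.json")
  run_stage("permtest", list(perm_path), function() {
    e24 <- sim$data$clusters[
      cluster_id %in% srna$classes[class %in% c("e24sRC_Col", "e24sRC_Cvi"),
                                   cluster_id],
      .(chrom, start, end)]
    q <- edmr$rg[, .(chrom, start, end)]
    set.seed(cfg$simulation$seed + 505L)
    pr <- permutation_test(q, e24, cfg$genome, n_perm = cfg$n_perm)
    write_permutation_result(pr, perm_path)
    pr
  })

  ## 7. variant summaries
  var_paths <- list(snp = file.path(outdir, "snp_strata.tsv"),
                    subs = file.path(outdir, "substitution_z.tsv"),
                    sv = file.path(outdir, "sv_methylation.tsv"),
                    hot = file.path(outdir, "hot_coverage.tsv"))
  run_stage("variant_summary", var_paths, function() {
    ann <- sim$data$annotations
    wfh <- windows[sample_id == "Col_FH" & valid == TRUE]
    wl <- merge(wfh, part[, .(chrom, start, end, context, label)],
                by = c("chrom", "start", "end", "context"))
    wl <- count_snps_per_window(ann$snps, wl)
    strata <- methylation_by_snp_strata(wl[label %in% c("CR", "COL_SR")],
                                        genes = ann$genes, tes = ann$tes)
    fwrite(strata, var_paths$snp, sep = "\t")
    subs <- rbindlist(lapply(c("CR", "COL_SR"), function(lb) {
      rbindlist(lapply(contexts, function(cx) {
        w <- wl[label == lb & context == cx]
        if (nrow(w) < 2L || length(unique(w$fraction)) < 2L) return(NULL)
        substitution_zscore(w, ann$snps)[, `:=`(label = lb, context = cx)]
      }))
    }))
    fwrite(subs, var_paths$subs, sep = "\t")
    allw <- windows[valid == TRUE]
    fwrite(sv_methylation_summary(ann$svs, allw), var_paths$sv, sep = "\t")
    col_sr <- lapply(setNames(contexts, contexts), function(cx)
      region_set(part, "COL_SR", cx))
    cr <- lapply(setNames(contexts, contexts), function(cx)
      region_set(part, "CR", cx))
    feats <- c(
      split(ann$svs[, .(chrom, start, end)], ann$svs$category),
      list(`Col_SR_union` = combine_context_regions(col_sr, "union"),
           `Col_SR_intersection` = combine_context_regions(col_sr,
                                                           "intersection"),
           `CR_union` = combine_context_regions(cr, "union"),
           `24sRC` = sim$data$clusters[, .(chrom, start, end)]))
    fwrite(hot_coverage(ann$hot, feats), var_paths$hot, sep = "\t")
    NULL
  })

  manifest$finished <- format(Sys.time(), usetz = TRUE)
  man_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  manifest$path <- man_path
  invisible(manifest)
}
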
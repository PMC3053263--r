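## End-to-end orchestration of the synthetic comparison experiment:
## simulate -> profiles -> qc -> peaks -> metaprofiles, with deterministic
## seeded outputs and a manifest sufficient to re-run any stage.

#' Demo experiment configuration
#'
#' The default configuration runs the whole pipeline on a two-chromosome
#' 1 Mb genome with the package-default analysis parameters (50 bp bins,
#' bandwidth 50, 20-fold aggregation to 1 kb, k = 0, FDR 0.05, the
#' 0.9...0.01 subsampling ladder, 2 kb flanks and a 2 kb minimum gene
#' length).
#'
#' @param seed Master seed recorded in the configuration.
#' @return A nested configuration list for [run_experiment()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(n_chrom = 2, lengths = 5e5, gc_mean = 0.42,
                  gc_amplitude = 0.1, gc_scale = 10000, bin_size = 50),
    regions = list(n_regions = 40, narrow_range = c(500, 1500),
                   broad_range = c(2000, 8000), broad_fraction = 0.5,
                   effect_range = c(4, 8)),
    genes = list(n_genes = 150, length_range = c(1000, 8000),
                 min_length = 2000),
    reads = list(chip_depth = 1e6, input_depth = 1e6, shallow_depth = 5e4,
                 gc_beta_biased = 2, frag_len = 200, read_len = 36),
    array = list(probe_spacing = 50, coverage_target = 0.7,
                 noise_sd = 0.3, gamma = 1, dye_bias_sd = 0),
    analysis = list(bin_size = 50, bandwidth = 50, max_neighbors = 400,
                    aggregate = 20, pseudocount = 0.5, k = 0, fdr = 0.05,
                    ladder = depth_ladder(), flank = 2000,
                    variability_quantile = 0.95)
  )
}

check_config <- function(config, template = default_config()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  for (key in names(config))
    if (is.list(template[[key]])) {
      extra <- setdiff(names(config[[key]]), names(template[[key]]))
      if (length(extra))
        stop(sprintf("unknown configuration key(s) under '%s': %s", key,
                     paste(extra, collapse = ", ")))
    }
  merged <- template
  for (key in names(config)) {
    merged[[key]] <- if (is.list(template[[key]]))
      utils::modifyList(template[[key]], config[[key]])
    else config[[key]]
  }
  merged
}

write_df <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full synthetic comparison experiment
#'
#' Executes every stage on one synthetic dataset and writes plain-text
#' tables and tracks under `outdir`: the genome and truth, read and probe
#' libraries, enrichment profiles, input QC (skewness, GC correlation,
#' correlation heatmap, coverage curve), peak calls under two input
#' backgrounds with their overlap, and TSS/TES meta-profiles. Outputs are
#' byte-identical across runs with the same configuration and seed; the
#' manifest records parameters, seeds and versions.
#'
#' @param config Configuration list (see [default_config()]) or the path
#'   of a YAML file holding one. Unknown keys are rejected.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
run_experiment <- function(config = default_config(), outdir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("configuration file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  config <- check_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  an <- config$analysis

  ## -- simulate ----------------------------------------------------------
  sim <- stage("simulate", {
    g <- config$genome
    genome <- make_genome(g$n_chrom, g$lengths, g$gc_mean, g$gc_amplitude,
                          g$gc_scale, g$bin_size, seed = child_seed(seed, 1))
    r <- config$regions
    planted <- plant_regions(genome, r$n_regions, r$narrow_range,
                             r$broad_range, r$broad_fraction,
                             r$effect_range, seed = child_seed(seed, 2))
    genes <- make_genes(genome, config$genes$n_genes,
                        config$genes$length_range,
                        seed = child_seed(seed, 3))
    rd <- config$reads
    chip <- simulate_reads(planted$lambda, genome, rd$chip_depth,
                           frag_len = rd$frag_len, read_len = rd$read_len,
                           seed = child_seed(seed, 4))
    flat <- constant_track(genome)
    input_plain <- simulate_reads(flat, genome, rd$input_depth,
                                  frag_len = rd$frag_len,
                                  read_len = rd$read_len,
                                  seed = child_seed(seed, 5))
    input_biased <- simulate_reads(flat, genome, rd$input_depth,
                                   gc_beta = rd$gc_beta_biased,
                                   frag_len = rd$frag_len,
                                   read_len = rd$read_len,
                                   seed = child_seed(seed, 6))
    a <- config$array
    probes <- simulate_array(planted$lambda, flat, genome,
                             a$probe_spacing, a$coverage_target,
                             a$noise_sd, a$gamma, a$dye_bias_sd,
                             seed = child_seed(seed, 7))
    write_bedgraph(genome$gc_track, file.path(outdir, "gc.bedGraph"))
    write_bedgraph(planted$lambda, file.path(outdir, "lambda.bedGraph"))
    write_truth_bed(planted$truth, file.path(outdir, "truth.bed"))
    write_genes_bed(genes, file.path(outdir, "genes.bed"))
    write_reads_bed(chip, file.path(outdir, "chip.bed"))
    write_reads_bed(input_plain, file.path(outdir, "input_plain.bed"))
    write_reads_bed(input_biased, file.path(outdir, "input_biased.bed"))
    write_probes_tsv(probes, file.path(outdir, "probes.tsv"))
    list(genome = genome, planted = planted, genes = genes, chip = chip,
         inputs = list(plain = input_plain, biased = input_biased),
         probes = probes)
  })

  ## -- profiles ----------------------------------------------------------
  prof <- stage("profiles", {
    seq50 <- seq_enrichment(sim$chip, sim$inputs$plain, sim$genome,
                            an$bin_size, an$bandwidth, an$max_neighbors,
                            pseudocount = an$pseudocount)
    seq1k <- aggregate_bins(seq50, an$aggregate)
    chip50 <- array_enrichment(sim$probes, sim$genome, an$bin_size,
                               an$bandwidth, an$max_neighbors)
    chip1k <- aggregate_bins(chip50, an$aggregate)
    inputs1k <- lapply(sim$inputs, function(r)
      input_seq_profile(r, sim$genome, an$bin_size, an$bandwidth,
                        an$max_neighbors, aggregate = an$aggregate))
    write_bedgraph(seq50$track, file.path(outdir, "enrichment_seq_50bp.bedGraph"))
    write_bedgraph(seq1k$track, file.path(outdir, "enrichment_seq_1kb.bedGraph"))
    write_bedgraph(chip1k$track, file.path(outdir, "enrichment_chip_1kb.bedGraph"))
    list(seq50 = seq50, seq1k = seq1k, chip50 = chip50, chip1k = chip1k,
         inputs1k = inputs1k)
  })

  ## -- qc ----------------------------------------------------------------
  stage("qc", {
    gc1k <- aggregate_track(sim$genome$gc_track,
                            an$aggregate * an$bin_size %/%
                              sim$genome$gc_track$bin_size)
    skew <- data.frame(
      profile = c("seq_1kb", "chip_1kb"),
      skewness = c(truncated_skewness(prof$seq1k),
                   truncated_skewness(prof$chip1k)))
    write_df(skew, file.path(outdir, "skewness.tsv"))
    hm <- correlation_heatmap(prof$inputs1k, extra = list(GC = gc1k))
    write_df(as.data.frame(hm$matrix), file.path(outdir, "input_correlation.tsv"))
    writeLines(hm$order, file.path(outdir, "input_cluster_order.txt"))
    gcc <- data.frame(
      input = names(prof$inputs1k),
      spearman_gc = vapply(prof$inputs1k, gc_correlation, numeric(1),
                           gc = sim$genome$gc_track))
    write_df(gcc, file.path(outdir, "gc_correlation.tsv"))
    curve <- coverage_curve(sim$inputs$plain, sim$genome,
                            ladder = an$ladder,
                            seed = child_seed(seed, 8))
    write_df(as.data.frame(curve), file.path(outdir, "coverage_curve.tsv"))
    cross <- data.frame(
      pair = "seq_vs_chip_1kb",
      pearson = profile_correlation(prof$seq1k, prof$chip1k))
    write_df(cross, file.path(outdir, "cross_platform_correlation.tsv"))
  })

  ## -- peaks -------------------------------------------------------------
  stage("peaks", {
    swap <- input_swap_peaks(sim$chip, sim$inputs, sim$genome,
                             k = an$k, fdr = an$fdr,
                             bin_size = an$bin_size,
                             bandwidth = an$bandwidth,
                             max_neighbors = an$max_neighbors,
                             pseudocount = an$pseudocount)
    write_df(swap$table, file.path(outdir, "peak_stats.tsv"))
    ov <- as.data.frame(swap$overlap)
    ov <- cbind(input = rownames(swap$overlap), ov)
    write_df(ov, file.path(outdir, "peak_overlap.tsv"))
    for (id in names(swap$peaksets))
      write_peaks_bed(significant_peaks(swap$peaksets[[id]]),
                      file.path(outdir, sprintf("peaks_%s.bed", id)))
  })

  ## -- metaprofiles ------------------------------------------------------
  stage("metaprofiles", {
    genes <- select_genes(sim$genes, config$genes$min_length)
    for (anchor in c("tss", "tes")) {
      swap <- input_swap_metaprofile(sim$chip, sim$inputs, sim$genome,
                                     genes, anchor = anchor,
                                     flank = an$flank,
                                     bin_size = an$bin_size,
                                     bandwidth = an$bandwidth,
                                     max_neighbors = an$max_neighbors,
                                     pseudocount = an$pseudocount)
      for (id in names(swap$profiles))
        write_metaprofile_tsv(swap$profiles[[id]],
                              file.path(outdir,
                                        sprintf("metaprofile_%s_%s.tsv",
                                                anchor, id)))
      write_metaprofile_tsv(swap$gc_profile,
                            file.path(outdir,
                                      sprintf("metaprofile_%s_gc.tsv",
                                              anchor)))
      gcr <- data.frame(input = names(swap$gc_cor),
                        pearson_vs_gc = as.numeric(swap$gc_cor))
      write_df(gcr, file.path(outdir,
                              sprintf("metaprofile_%s_gc_cor.tsv", anchor)))
    }
  })

  manifest <- list(
    package = "chipcompare",
    version = as.character(utils::packageVersion("chipcompare")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    files = sort(list.files(outdir)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
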
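# End-to-end pipeline: simulate (or load) -> tiles -> enrichments ->
# bound-region calling -> methylome segmentation -> islands/bivalency ->
# profiles and clustering. Every stage appends a record-count line to
# pipeline.log (no timestamps, so reruns are bit-identical) and writes its
# artifacts as plain text under the output directory.

#' Fraction of tile CpGs with sufficient bisulfite coverage
#'
#' Per tile, the fraction of its CpGs whose total read count is at least
#' `min_cov`; tiles without CpGs get `NA` (treated as passing the coverage
#' filter, which only applies where bisulfite data exists).
#'
#' @param tiles Tile frame.
#' @param calls Raw (unfiltered) call frame with `total`.
#' @param min_cov Coverage threshold (default 10).
#' @return Numeric vector aligned with `tiles`.
#' @export
tile_cpg_coverage <- function(tiles, calls, min_cov = 10L) {
  pairs <- interval_overlap_pairs(tiles, calls)
  idx <- split(pairs$subject, factor(pairs$query,
                                     levels = seq_len(nrow(tiles))))
  unname(vapply(idx, function(i) {
    if (!length(i)) NA_real_ else mean(calls$total[i] >= min_cov)
  }, numeric(1)))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Simulates the configured genome, then runs every analysis stage in
#' order and writes all artifacts (fixture files, enrichment bedGraphs,
#' correlation matrix, called/exclusive region BEDs, Venn partition,
#' segment and border BEDs, island and shore annotations, profile and
#' cluster tables) under `outdir`. Rerunning with the same configuration
#' yields bit-identical output.
#'
#' @param synth A [synth_config()] describing the dataset.
#' @param config A [pipeline_config()] with analysis thresholds.
#' @param outdir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(synth = synth_config(), config = pipeline_config(),
                         outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  cat("", file = logfile)
  log_line <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  }
  log_line("config: seed=", synth$seed, " tile_width=", config$tile_width,
           " pseudocount=", config$pseudocount, " fold_min=",
           config$fold_min, " padj_max=", config$padj_max)

  # stage: simulate
  sim <- simulate_dataset(synth)
  truth <- sim$truth
  fixdir <- file.path(outdir, "fixture")
  write_fixture(truth, sim$tracks, sim$calls, fixdir)
  log_line("simulate: ", nrow(truth$tiles), " tiles, ",
           nrow(truth$cpgs), " CpGs, ", length(sim$tracks),
           " tracks, seed ", synth$seed)

  # stage: tiles + filters
  tiles <- truth$tiles[, c("chrom", "start", "end")]
  tiles$cpg_covered_fraction <-
    tile_cpg_coverage(tiles, sim$calls, config$tile_cpg_cov)
  no_cpg <- is.na(tiles$cpg_covered_fraction)
  tiles$cpg_covered_fraction[no_cpg] <- 1   # filter applies only with data
  tiles <- suppressMessages(
    filter_tiles(tiles, mappability_min = config$mappability_min,
                 meth_cov_min = config$meth_cov_min))
  keep_idx <- match(paste(tiles$chrom, tiles$start),
                    paste(truth$tiles$chrom, truth$tiles$start))
  log_line("tiles: ", nrow(tiles), "/", nrow(truth$tiles),
           " retained after filters")

  counts <- lapply(sim$tracks, function(x) x$count[keep_idx])
  libs <- lapply(sim$tracks, function(x) sum(x$count))

  # stage: enrichment + cross-correlation
  enr <- lapply(setdiff(CHIP_TRACKS, "input"), function(tr) {
    e <- log2_enrichment(counts[[tr]], counts$input, libs[[tr]],
                         libs$input, config$pseudocount)
    write_bedgraph(data.frame(chrom = tiles$chrom, start = tiles$start,
                              end = tiles$end, value = round(e, 6)),
                   file.path(outdir, paste0("enrichment_", tr, ".bedGraph")))
    e
  })
  names(enr) <- setdiff(CHIP_TRACKS, "input")
  cc <- cross_correlation(counts, config$pseudocount)
  utils::write.table(round(cc, 6), file.path(outdir, "cross_correlation.tsv"),
                     sep = "\t", quote = FALSE)
  log_line("enrich: ", length(enr), " tracks on ", nrow(tiles), " tiles")

  # stage: bound-region calling (each DNMT track, all replicates, vs input)
  dnmts <- c("DNMT3A1", "DNMT3A2", "DNMT3B")
  tests <- lapply(dnmts, function(tr) {
    reps <- grep(paste0("^", tr, "(\\.[0-9]+)?$"), names(counts),
                 value = TRUE)
    nb_test(do.call(cbind, counts[reps]), counts$input)
  })
  names(tests) <- dnmts
  calls_part <- call_and_partition(tests, config$fold_min, config$padj_max)
  for (tr in dnmts) {
    idx <- calls_part$exclusive[[tr]]
    df <- tiles[idx, c("chrom", "start", "end"), drop = FALSE]
    write_bed(if (nrow(df)) df else
                data.frame(chrom = character(), start = integer(),
                           end = integer()),
              file.path(outdir, paste0("exclusive_", tr, ".bed")))
  }
  venn <- data.frame(signature = names(calls_part$partition),
                     n_tiles = lengths(calls_part$partition))
  venn <- venn[order(venn$signature), , drop = FALSE]
  utils::write.table(venn, file.path(outdir, "venn_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("call-regions: ",
           paste(dnmts, vapply(calls_part$called, length, integer(1)),
                 sep = "=", collapse = " "),
           " (exclusive ",
           paste(vapply(calls_part$exclusive, length, integer(1)),
                 collapse = "/"), ")")

  # stage: methylome
  fcalls <- suppressMessages(
    load_calls(file.path(fixdir, "cpg_calls.tsv"), assay = "WGBS"))
  segments <- suppressWarnings(
    segment_methylome(fcalls, config$smooth_k, config$low_meth_cut,
                      config$umr_min_cpgs, config$run_min_cpgs,
                      config$max_cpg_gap))
  seg_bed <- segments
  seg_bed$name <- segments$class
  write_bed(seg_bed, file.path(outdir, "segments.bed"))
  fmrs <- segments[segments$class == "FMR", , drop = FALSE]
  prof_segs <- filter_segments_for_profiles(segments,
                                            config$min_segment_distance,
                                            config$fmr_min_len)
  big_fmrs <- prof_segs[prof_segs$class == "FMR", , drop = FALSE]
  if (nrow(big_fmrs) >= config$n_density_bins) {
    bins <- fmr_density_bins(big_fmrs, fcalls, config$n_density_bins)
    fb <- big_fmrs; fb$name <- paste0("FMR_bin", bins)
    write_bed(fb, file.path(outdir, "fmr_density_bins.bed"))
  }
  umrs <- segments[segments$class == "UMR", , drop = FALSE]
  borders <- umr_borders(umrs, fmrs, truth$genes, config$promoter_flank)
  if (nrow(borders)) {
    bb <- data.frame(chrom = borders$chrom, start = borders$pos,
                     end = borders$pos + 1L, name = borders$side,
                     score = 0, strand = borders$strand)
    write_bed(bb, file.path(outdir, "umr_borders.bed"))
  }
  log_line("segment: ", sum(segments$class == "UMR"), " UMR / ",
           sum(segments$class == "LMR"), " LMR / ",
           sum(segments$class == "FMR"), " FMR; ",
           nrow(borders), " oriented borders")

  # stage: islands + bivalency + shores
  islands <- detect_islands(fcalls, config$island_min_len,
                            config$island_min_cpgs)
  proms <- promoters_from_genes(truth$genes, config$promoter_flank)
  islands <- link_promoters(islands, proms)
  islands <- suppressMessages(
    classify_islands(islands, fcalls, tiles, enr$H3K4me3, enr$H3K27me3,
                     config$e_min))
  if (nrow(islands)) {
    ib <- islands
    ib$name <- paste(ib$gene, ib$meth_class, ib$chromatin_class, sep = "|")
    ib$score <- 0
    write_bed(ib, file.path(outdir, "islands.bed"))
    sh <- define_shores(islands, config$shore_width, truth$chrom_sizes)
    sh$name <- sh$side
    write_bed(sh, file.path(outdir, "shores.bed"))
  }
  log_line("islands: ", nrow(islands), " promoter islands (",
           sum(islands$chromatin_class %in% "bivalent"), " bivalent)")

  # stage: profiles + clustering
  reads_a1 <- expand_counts_to_reads(sim$tracks$DNMT3A1,
                                     substream_seed(synth$seed, "exp_A1"))
  reads_hmc <- expand_counts_to_reads(sim$tracks$`5hmC`,
                                      substream_seed(synth$seed, "exp_hmc"))
  cluster <- NULL
  if (nrow(borders)) {
    bprof <- anchor_profile(reads_hmc, data.frame(chrom = borders$chrom,
                                                  pos = borders$pos,
                                                  strand = borders$strand),
                            config$profile_flank, config$profile_bin,
                            library_size = libs$`5hmC`,
                            norm_constant = config$norm_constant,
                            chrom_sizes = truth$chrom_sizes,
                            track = "5hmC")
    utils::write.table(round(bprof$matrix, 4),
                       file.path(outdir, "border_profile_5hmC.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(umrs) >= config$k) {
    centers <- data.frame(chrom = umrs$chrom,
                          pos = (umrs$start + umrs$end) %/% 2L,
                          strand = "+")
    uprof <- anchor_profile(reads_a1, centers, config$profile_flank,
                            config$profile_bin, library_size = libs$DNMT3A1,
                            norm_constant = config$norm_constant,
                            chrom_sizes = truth$chrom_sizes,
                            track = "DNMT3A1")
    cluster <- cluster_umrs(uprof, k = config$k,
                            seed = substream_seed(synth$seed, "kmeans"),
                            restarts = config$cluster_restarts,
                            pseudocount = config$pseudocount)
    cl <- data.frame(chrom = umrs$chrom, start = umrs$start,
                     end = umrs$end,
                     name = paste0("cluster", cluster$labels))
    write_bed(cl, file.path(outdir, "umr_clusters.bed"))
  }
  log_line("profiles: ", nrow(borders), " border anchors, ",
           if (is.null(cluster)) 0 else cluster$k, " UMR clusters")

  invisible(list(tiles = tiles, enrichment = enr, correlation = cc,
                 calls = calls_part, segments = segments,
                 borders = borders, islands = islands,
                 cluster = cluster, truth = truth))
}
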
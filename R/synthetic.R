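# Seeded synthetic epigenome generator.
#
# Builds a small multi-chromosome genome carrying the structure the
# analysis is designed to detect: CpG islands at gene promoters with
# unmethylated centers and highly methylated shores, a subset of islands
# bivalent (H3K4me3 + H3K27me3) with DNMT3A1 planted at their shores and
# 5-hmC at the island borders, transcribed gene bodies carrying H3K36me3
# and DNMT3B, diffuse DNMT3A2, NB-dispersed ChIP counts and binomially
# sampled bisulfite calls. A ground-truth ledger (per-tile classes,
# expected bound tiles, per-CpG true methylation) supports recovery tests.
#
# One global seed fans out into named substreams (placement, one per ChIP
# track, bisulfite) so adding a track never perturbs the others.

CHIP_TRACKS <- c("DNMT3A1", "DNMT3A2", "DNMT3B", "H3K27me3", "H3K4me3",
                 "H3K36me3", "5hmC", "input")

# archetype patterns for DNMT3A1 binding around a bivalent island:
# columns = 5' shore, island center, 3' shore (strand-relative)
.ARCHETYPES <- matrix(c(1, 0, 0,
                        0, 0, 1,
                        1, 0, 1,
                        0, 1, 0,
                        0, 0, 0), nrow = 5, byrow = TRUE,
                      dimnames = list(NULL, c("shore_5p", "center",
                                              "shore_3p")))

.default_fold_map <- function(fold = 8) {
  list(DNMT3A1 = c(bivalent_shore = fold, umr_border = fold),
       DNMT3A2 = c(),
       DNMT3B = c(transcribed_body = fold),
       H3K27me3 = c(bivalent_island = fold, bivalent_shore = fold,
                    umr_border = fold),
       H3K4me3 = c(bivalent_island = fold, active_island = fold),
       H3K36me3 = c(transcribed_body = fold),
       `5hmC` = c(umr_border = fold),
       input = c())
}

#' Synthetic-genome configuration
#'
#' Defaults define the reference fixture: 2 chromosomes of 5 Mb, 20
#' promoter CpG islands (half bivalent), 40 genes (half of the island-free
#' ones transcribed), 30 reads per 1-kb tile per library, NB dispersion
#' 0.05, 8-fold planted enrichments, 30x bisulfite coverage and 2-kb
#' shores. CpG spacing is geometric with mean 100 bp in the background and
#' 12 bp inside islands.
#'
#' @param seed Global seed; all substreams derive from it.
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param n_islands Number of promoter CpG islands (must be <= `n_genes`).
#' @param bivalent_fraction Fraction of islands that are bivalent.
#' @param n_genes,transcribed_fraction Gene count and the transcribed
#'   fraction of island-free genes.
#' @param mean_tile_depth Expected reads per tile per library.
#' @param nb_dispersion NB dispersion of tile counts (0 gives Poisson).
#' @param fold_map Named list track -> named vector of per-class fold
#'   changes (classes default to fold 1).
#' @param meth_levels Named vector of true methylation fractions per
#'   region class (`UMR`, `LMR`, `shore`, `FMR`).
#' @param cpg_coverage_mean Mean bisulfite reads per CpG.
#' @param shore_width_bp Shore width (bp).
#' @param tile_width_bp,island_width_bp,gene_length_bp,n_lmrs,lmr_width_bp
#'   Geometry of the planted features (tile-grid multiples).
#' @param umr_archetypes Plant five distinct DNMT3A1-binding archetypes
#'   across bivalent islands (for profile-clustering studies).
#' @param chip_replicates Named integer vector of IP library replicates
#'   per track; DNMT3A1 defaults to 2, mirroring the two independent
#'   clones profiled for that isoform. Unnamed tracks get one library.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_chroms = 2L, chrom_length_bp = 5e6,
                         n_islands = 20L, bivalent_fraction = 0.5,
                         n_genes = 40L, transcribed_fraction = 0.5,
                         mean_tile_depth = 30, nb_dispersion = 0.05,
                         fold_map = .default_fold_map(),
                         meth_levels = c(UMR = 0.03, LMR = 0.25,
                                         shore = 0.85, FMR = 0.85),
                         cpg_coverage_mean = 30, shore_width_bp = 2000L,
                         tile_width_bp = 1000L, island_width_bp = 2000L,
                         gene_length_bp = 10000L, n_lmrs = 10L,
                         lmr_width_bp = 1200L, umr_archetypes = FALSE,
                         chip_replicates = c(DNMT3A1 = 2L)) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = chrom_length_bp,
              n_islands = as.integer(n_islands),
              bivalent_fraction = bivalent_fraction,
              n_genes = as.integer(n_genes),
              transcribed_fraction = transcribed_fraction,
              mean_tile_depth = mean_tile_depth,
              nb_dispersion = nb_dispersion, fold_map = fold_map,
              meth_levels = meth_levels,
              cpg_coverage_mean = cpg_coverage_mean,
              shore_width_bp = as.integer(shore_width_bp),
              tile_width_bp = as.integer(tile_width_bp),
              island_width_bp = as.integer(island_width_bp),
              gene_length_bp = as.integer(gene_length_bp),
              n_lmrs = as.integer(n_lmrs),
              lmr_width_bp = as.integer(lmr_width_bp),
              umr_archetypes = isTRUE(umr_archetypes),
              chip_replicates = chip_replicates)
  assert_fraction(cfg$bivalent_fraction, "bivalent_fraction")
  assert_fraction(cfg$transcribed_fraction, "transcribed_fraction")
  for (lv in names(cfg$meth_levels))
    assert_fraction(cfg$meth_levels[[lv]], paste0("meth_levels[", lv, "]"))
  if (!all(c("UMR", "LMR", "shore", "FMR") %in% names(cfg$meth_levels)))
    stop_config("meth_levels must name UMR, LMR, shore and FMR")
  assert_positive(cfg$mean_tile_depth, "mean_tile_depth")
  if (cfg$nb_dispersion < 0) stop_config("nb_dispersion must be >= 0")
  assert_positive(cfg$cpg_coverage_mean, "cpg_coverage_mean")
  if (cfg$chrom_length_bp < 50 * cfg$tile_width_bp)
    stop_config("chrom_length_bp must be at least 50 tile widths")
  if (cfg$n_islands > cfg$n_genes)
    stop_config("n_islands cannot exceed n_genes")
  for (tr in names(cfg$fold_map))
    if (length(cfg$fold_map[[tr]]) && any(cfg$fold_map[[tr]] < 1))
      stop_config("all folds must be >= 1 (track ", tr, ")")
  if (cfg$island_width_bp %% cfg$tile_width_bp != 0 ||
      cfg$shore_width_bp %% cfg$tile_width_bp != 0 ||
      cfg$gene_length_bp %% cfg$tile_width_bp != 0)
    stop_config("island, shore and gene sizes must be tile-width multiples")
  class(cfg) <- c("synth_config", "list")
  cfg
}

# geometric inter-CpG gaps (minimum 2 bp so CpGs never overlap)
.cpg_gaps <- function(n, mean_gap) {
  2L + stats::rgeom(n, 1 / (mean_gap - 1))
}

# non-overlapping placement of `n` footprints of width `w` on a tile grid,
# uniform over feasible grid starts, bounded rejection sampling
.place_on_grid <- function(n, n_tiles, w_tiles, margin_tiles, tile_w) {
  if (n == 0L) return(integer(0))
  lo <- margin_tiles
  hi <- n_tiles - w_tiles - margin_tiles
  if (hi < lo) stop_config("chromosome too short for requested features")
  placed <- integer(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      s <- sample(lo:hi, 1L)
      if (!any(abs(placed - s) < w_tiles + margin_tiles)) {
        placed <- c(placed, s); ok <- TRUE; break
      }
    }
    if (!ok)
      stop_config("could not place ", n, " features without overlap; ",
                  "feature density too high for the chromosome length")
  }
  placed * tile_w
}

#' Generate the planted ground truth
#'
#' Places genes (and their promoter islands, shores and border tiles),
#' distal low-methylated regions and the CpG landscape, assigns every tile
#' a region class and a per-track fold, and records the per-CpG true
#' methylation fraction. Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_truth` with elements `chrom_sizes`,
#'   `tiles` (frame plus `class` column), `fold` (tiles x tracks matrix),
#'   `islands`, `genes`, `umrs`, `shores`, `lmrs`, `cpgs` (with
#'   `true_fraction`), `expected_bound` (per track, tile indices with
#'   planted fold > 1) and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(substream_seed(config$seed, "truth"), {
    W <- config$tile_width_bp
    chroms <- paste0("chr", seq_len(config$n_chroms))
    chrom_sizes <- stats::setNames(rep(config$chrom_length_bp,
                                       config$n_chroms), chroms)
    tiles <- make_tiles(chrom_sizes, W)
    n_tiles_chrom <- floor(config$chrom_length_bp / W)

    G <- config$gene_length_bp %/% W          # gene length in tiles
    Iw <- config$island_width_bp %/% W        # island width in tiles
    Sw <- config$shore_width_bp %/% W         # shore width in tiles
    # inter-footprint margin: island half-width + shore + enough clearance
    # that planted islands stay > 2 shore widths apart and planted UMRs
    # survive the 6-kb profile distance filter
    margin <- Iw %/% 2 + 3L * Sw + 4L

    # genes round-robin across chromosomes
    gene_chrom <- chroms[(seq_len(config$n_genes) - 1L) %%
                         config$n_chroms + 1L]
    genes <- NULL
    for (ch in chroms) {
      n_ch <- sum(gene_chrom == ch)
      starts <- .place_on_grid(n_ch, n_tiles_chrom, G, margin, W)
      if (n_ch)
        genes <- rbind(genes, data.frame(chrom = ch, start = starts,
                                         end = starts + config$gene_length_bp))
    }
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genes$name <- sprintf("gene%03d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    perm <- sample(config$n_genes)
    island_genes <- sort(perm[seq_len(config$n_islands)])
    rest <- setdiff(perm, island_genes)
    n_tr <- round(config$transcribed_fraction * length(rest))
    transcribed <- sort(rest[seq_len(n_tr)])
    genes$transcribed <- seq_len(nrow(genes)) %in% transcribed
    rownames(genes) <- NULL

    # islands centered on the TSS of their gene
    islands <- NULL
    if (config$n_islands > 0L) {
      g <- genes[island_genes, , drop = FALSE]
      tss <- ifelse(g$strand == "-", g$end, g$start)
      half <- config$island_width_bp %/% 2L
      islands <- data.frame(chrom = g$chrom, start = tss - half,
                            end = tss + half, gene = g$name,
                            strand = g$strand)
      n_biv <- round(config$bivalent_fraction * config$n_islands)
      lab <- rep("active", config$n_islands)
      lab[sample(config$n_islands, n_biv)] <- "bivalent"
      islands$class <- lab
      islands$archetype <- NA_integer_
      if (config$umr_archetypes) {
        biv <- which(islands$class == "bivalent")
        islands$archetype[biv] <-
          rep_len(seq_len(nrow(.ARCHETYPES)), length(biv))
      }
      islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]
      rownames(islands) <- NULL
    } else {
      islands <- data.frame(chrom = character(), start = integer(),
                            end = integer(), gene = character(),
                            strand = character(), class = character(),
                            archetype = integer())
    }

    # distal low-methylated regions in the background
    lmrs <- NULL
    occupied <- rbind(
      data.frame(chrom = genes$chrom, start = genes$start - 4L * Sw * W,
                 end = genes$end + 4L * Sw * W),
      if (nrow(islands))
        data.frame(chrom = islands$chrom,
                   start = islands$start - 4L * Sw * W,
                   end = islands$end + 4L * Sw * W))
    if (config$n_lmrs > 0L) {
      lmr_chrom <- chroms[(seq_len(config$n_lmrs) - 1L) %%
                          config$n_chroms + 1L]
      for (ch in chroms) {
        n_ch <- sum(lmr_chrom == ch)
        if (!n_ch) next
        got <- 0L
        tries <- 0L
        while (got < n_ch && tries < 2000L) {
          tries <- tries + 1L
          s <- sample(2L:(n_tiles_chrom - 4L), 1L) * W
          cand <- data.frame(chrom = ch, start = s,
                             end = s + config$lmr_width_bp)
          near <- rbind(occupied,
                        if (!is.null(lmrs))
                          data.frame(chrom = lmrs$chrom,
                                     start = lmrs$start - 8000L,
                                     end = lmrs$end + 8000L))
          if (!interval_overlaps_any(cand, near)) {
            lmrs <- rbind(lmrs, cand)
            got <- got + 1L
          }
        }
        if (got < n_ch)
          stop_config("could not place LMRs; density too high")
      }
      lmrs <- lmrs[order(lmrs$chrom, lmrs$start), , drop = FALSE]
      rownames(lmrs) <- NULL
    } else {
      lmrs <- data.frame(chrom = character(), start = integer(),
                         end = integer())
    }

    # shores: fixed-width flanks of each island; the shore tile adjacent
    # to the island is the UMR-border tile (5-hmC territory)
    shores <- if (nrow(islands)) {
      s <- define_shores(islands, config$shore_width_bp, chrom_sizes)
      s$class <- islands$class[s$island]
      s
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 side = character(), island = integer(),
                 clipped = logical(), class = character())
    }

    # per-tile region class
    tile_class <- rep("background", nrow(tiles))
    tile_of <- function(chrom, pos) {
      match(paste(chrom, (pos %/% W) * W), paste(tiles$chrom, tiles$start))
    }
    span_tiles <- function(chrom, start, end) {
      unlist(lapply(seq_along(chrom), function(i) {
        s <- tile_of(chrom[i], start[i])
        s + seq_len((end[i] - start[i]) %/% W) - 1L
      }))
    }
    if (any(genes$transcribed))
      tile_class[span_tiles(genes$chrom[genes$transcribed],
                            genes$start[genes$transcribed],
                            genes$end[genes$transcribed])] <-
        "transcribed_body"
    part_of_tile <- rep(NA_character_, nrow(tiles))   # archetype geometry
    island_of_tile <- rep(NA_integer_, nrow(tiles))
    if (nrow(islands)) {
      for (i in seq_len(nrow(islands))) {
        it <- span_tiles(islands$chrom[i], islands$start[i], islands$end[i])
        tile_class[it] <- paste0(islands$class[i], "_island")
        part_of_tile[it] <- "center"
        island_of_tile[it] <- i
        left <- span_tiles(islands$chrom[i],
                           islands$start[i] - config$shore_width_bp,
                           islands$start[i])
        right <- span_tiles(islands$chrom[i], islands$end[i],
                            islands$end[i] + config$shore_width_bp)
        tile_class[c(left, right)] <- paste0(islands$class[i], "_shore")
        if (islands$class[i] == "bivalent") {
          # border tiles: the shore tile touching each island edge
          tile_class[c(left[length(left)], right[1])] <- "umr_border"
        }
        lab5 <- if (islands$strand[i] == "-") "shore_3p" else "shore_5p"
        lab3 <- if (islands$strand[i] == "-") "shore_5p" else "shore_3p"
        part_of_tile[left] <- lab5
        part_of_tile[right] <- lab3
        island_of_tile[c(left, right)] <- i
      }
    }
    tiles$class <- tile_class

    # per-track planted folds
    fold <- matrix(1, nrow(tiles), length(CHIP_TRACKS),
                   dimnames = list(NULL, CHIP_TRACKS))
    for (tr in CHIP_TRACKS) {
      fm <- config$fold_map[[tr]]
      if (!length(fm)) next
      hit <- tile_class %in% names(fm)
      fold[hit, tr] <- fm[tile_class[hit]]
    }
    if (config$umr_archetypes && nrow(islands)) {
      bound_fold <- max(config$fold_map$DNMT3A1, 1)
      f <- rep(1, nrow(tiles))
      arch_tiles <- which(!is.na(island_of_tile) &
                          islands$class[island_of_tile] == "bivalent")
      for (t in arch_tiles) {
        a <- islands$archetype[island_of_tile[t]]
        part <- if (part_of_tile[t] == "center") "center" else part_of_tile[t]
        if (.ARCHETYPES[a, part] == 1) f[t] <- bound_fold
      }
      fold[, "DNMT3A1"] <- f
    }
    expected_bound <- lapply(CHIP_TRACKS, function(tr) which(fold[, tr] > 1))
    names(expected_bound) <- CHIP_TRACKS

    # CpG landscape: geometric gaps, dense inside islands
    cpgs <- NULL
    for (ch in chroms) {
      len <- chrom_sizes[[ch]]
      n_bg <- ceiling(len / 80)
      pos <- cumsum(.cpg_gaps(n_bg, 100))
      pos <- pos[pos < len - 1L]
      isl <- islands[islands$chrom == ch, , drop = FALSE]
      if (nrow(isl)) {
        inside <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(isl)))
          inside <- inside | (pos >= isl$start[i] & pos < isl$end[i])
        pos <- pos[!inside]
        for (i in seq_len(nrow(isl))) {
          n_isl <- ceiling(config$island_width_bp / 8)
          ip <- isl$start[i] + c(0L, cumsum(.cpg_gaps(n_isl, 12)))
          pos <- c(pos, ip[ip < isl$end[i]])
        }
      }
      cpgs <- rbind(cpgs, data.frame(chrom = ch, start = sort(pos)))
    }
    cpgs$end <- cpgs$start + 1L

    lev <- config$meth_levels
    frac <- rep(lev[["FMR"]], nrow(cpgs))
    mark <- function(regions, value) {
      if (!nrow(regions)) return()
      hit <- interval_overlaps_any(cpgs, regions)
      frac[hit] <<- value
    }
    mark(shores, lev[["shore"]])
    mark(lmrs, lev[["LMR"]])
    mark(islands, lev[["UMR"]])
    cpgs$true_fraction <- frac

    umrs <- islands[, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(islands)) umrs$class <- islands$class

    structure(list(chrom_sizes = chrom_sizes, tiles = tiles, fold = fold,
                   islands = islands, genes = genes, umrs = umrs,
                   shores = shores, lmrs = lmrs, cpgs = cpgs,
                   expected_bound = expected_bound, config = config),
              class = "synthetic_truth")
  })
}

#' Simulate a ChIP (or input) library on the tile frame
#'
#' Each tile's count is drawn from a negative binomial with mean
#' `mean_tile_depth * fold(track, tile)` and the configured dispersion
#' (Poisson when the dispersion is 0). The input track has fold 1
#' everywhere. Seeded by a per-track substream of the global seed.
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [synth_config()].
#' @param track One of DNMT3A1, DNMT3A2, DNMT3B, H3K27me3, H3K4me3,
#'   H3K36me3, 5hmC, input.
#' @return Tile frame with a `count` column.
#' @export
simulate_chip <- function(truth, config, track, replicate = 1L) {
  if (!track %in% CHIP_TRACKS)
    stop_config("unknown track '", track, "'; expected one of ",
                paste(CHIP_TRACKS, collapse = ", "))
  mu <- config$mean_tile_depth * truth$fold[, track]
  stream <- if (replicate > 1L) paste0("chip_", track, "_rep", replicate)
            else paste0("chip_", track)
  with_local_seed(substream_seed(config$seed, stream), {
    n <- length(mu)
    counts <- as.integer(if (config$nb_dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    else stats::rpois(n, mu))
    out <- truth$tiles[, c("chrom", "start", "end")]
    out$count <- counts
    out
  })
}

#' Simulate bisulfite calls at the planted CpGs
#'
#' Per CpG: total coverage is Poisson with the configured mean, methylated
#' reads are binomial at the CpG's true methylation fraction.
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [synth_config()].
#' @return data.frame with `chrom`, `start`, `end`, `meth`, `total`,
#'   `percent`.
#' @export
simulate_bisulfite <- function(truth, config) {
  with_local_seed(substream_seed(config$seed, "bisulfite"), {
    n <- nrow(truth$cpgs)
    total <- stats::rpois(n, config$cpg_coverage_mean)
    meth <- stats::rbinom(n, total, truth$cpgs$true_fraction)
    data.frame(chrom = truth$cpgs$chrom, start = truth$cpgs$start,
               end = truth$cpgs$end, meth = meth, total = total,
               percent = ifelse(total > 0, 100 * meth / total, 0))
  })
}

#' Simulate the full dataset
#'
#' Ground truth, all ChIP/input tracks and bisulfite calls under one seed.
#' Tracks with more than one configured replicate get additional entries
#' named `<track>.<r>` (e.g. `DNMT3A1.2`).
#'
#' @param config A [synth_config()].
#' @return List with `truth`, `tracks` (named list of count frames) and
#'   `calls`.
#' @export
simulate_dataset <- function(config = synth_config()) {
  truth <- generate_truth(config)
  tracks <- list()
  for (tr in CHIP_TRACKS) {
    n_rep <- config$chip_replicates[tr]
    n_rep <- if (is.na(n_rep)) 1L else as.integer(n_rep)
    tracks[[tr]] <- simulate_chip(truth, config, tr)
    for (r in seq_len(n_rep)[-1])
      tracks[[paste(tr, r, sep = ".")]] <-
        simulate_chip(truth, config, tr, replicate = r)
  }
  list(truth = truth, tracks = tracks,
       calls = simulate_bisulfite(truth, config))
}

#' Write the synthetic fixture to disk
#'
#' Emits islands/genes/UMRs/LMRs/shores as BED, per-track tile counts as
#' TSV, per-CpG calls as 6-column bedGraph-style text, the truth ledger
#' (tile classes and expected bound flags, per-CpG true fractions) as TSV
#' and a manifest recording the seed and configuration.
#'
#' @param truth Output of [generate_truth()].
#' @param tracks Named list of count frames from [simulate_chip()].
#' @param calls Output of [simulate_bisulfite()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(truth, tracks, calls, outdir) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  cfg <- truth$config
  p <- function(f) file.path(outdir, f)
  if (nrow(truth$islands)) {
    isl <- truth$islands
    isl$name <- paste(isl$gene, isl$class, sep = "|")
    isl$score <- 0
    write_bed(isl, p("islands.bed"))
    um <- truth$umrs; um$name <- um$class
    write_bed(um, p("umrs.bed"))
    sh <- truth$shores
    sh$name <- paste(sh$side, sh$class, sep = "|")
    write_bed(sh, p("shores.bed"))
  } else {
    file.create(p("islands.bed")); file.create(p("umrs.bed"))
    file.create(p("shores.bed"))
  }
  g <- truth$genes
  g$score <- ifelse(g$transcribed, 1, 0)
  write_bed(g, p("genes.bed"))
  if (nrow(truth$lmrs)) write_bed(truth$lmrs, p("lmrs.bed"))
  else file.create(p("lmrs.bed"))
  for (tr in names(tracks))
    write_counts(tracks[[tr]], p(paste0("counts_", tr, ".tsv")))
  m <- data.frame(chrom = calls$chrom, start = fmt_num(calls$start),
                  end = fmt_num(calls$end), meth = fmt_num(calls$meth),
                  total = fmt_num(calls$total),
                  percent = fmt_num(calls$percent))
  utils::write.table(m, p("cpg_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tt <- truth$tiles
  for (tr in names(truth$expected_bound))
    if (length(truth$expected_bound[[tr]]))
      tt[[paste0("bound_", tr)]] <-
        as.integer(seq_len(nrow(tt)) %in% truth$expected_bound[[tr]])
  utils::write.table(tt, p("truth_tiles.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  tc <- data.frame(chrom = truth$cpgs$chrom,
                   start = fmt_num(truth$cpgs$start),
                   end = fmt_num(truth$cpgs$end),
                   true_fraction = fmt_num(truth$cpgs$true_fraction))
  utils::write.table(tc, p("truth_cpgs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  scalars <- cfg[!vapply(cfg, function(x) is.list(x) || length(x) > 1,
                         logical(1))]
  man <- data.frame(key = names(scalars),
                    value = vapply(scalars, function(x)
                      if (is.numeric(x)) fmt_num(x) else as.character(x),
                      character(1)))
  for (tr in names(cfg$fold_map)) {
    fm <- cfg$fold_map[[tr]]
    if (length(fm))
      man <- rbind(man, data.frame(
        key = paste0("fold_map.", tr, ".", names(fm)),
        value = fmt_num(fm)))
  }
  man <- rbind(man, data.frame(
    key = paste0("meth_levels.", names(cfg$meth_levels)),
    value = fmt_num(cfg$meth_levels)))
  utils::write.table(man, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(outdir)
}
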
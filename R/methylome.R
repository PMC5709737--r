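# Per-CpG bisulfite evidence and methylome segmentation.
#
# Retained CpGs (coverage-filtered, SNP-masked) are smoothed with a short
# running mean and partitioned into hypomethylated segments (UMR when CpG-
# rich, LMR otherwise) and their fully methylated complement (FMR). UMR
# borders - the transition points from FMR to UMR around promoters - are
# taken from the flanking FMRs and oriented by the linked gene's strand.

#' Load per-CpG bisulfite calls
#'
#' Reads the 6-column per-CpG text (chrom, pos0, pos1, methylated count,
#' total count, percent), applies the assay-specific coverage filter
#' (strictly more than 10 reads for WGBS, more than 20 for RRBS) and drops
#' CpGs overlapping the SNP mask. Dropped counts per reason are attached as
#' the `"dropped"` attribute.
#'
#' @param path Path to the per-CpG file.
#' @param assay `"WGBS"` or `"RRBS"`.
#' @param snp_mask Optional interval data.frame of SNP positions to drop.
#' @return data.frame with `chrom`, `start`, `end`, `meth`, `total`,
#'   `fraction`.
#' @export
load_calls <- function(path, assay = c("WGBS", "RRBS"), snp_mask = NULL) {
  assay <- match.arg(assay)
  lines <- .read_tsv_lines(path)
  f <- .split_fields(lines)
  nf <- lengths(f)
  if (any(nf < 5L))
    stop(path, " line ", which(nf < 5L)[1],
         ": expected >= 5 per-CpG fields", call. = FALSE)
  m <- t(vapply(f, function(x) x[1:5], character(5)))
  ln <- seq_along(lines)
  calls <- data.frame(chrom = m[, 1],
                      start = .num_or_stop(m[, 2], path, ln, "position"),
                      end = .num_or_stop(m[, 3], path, ln, "position"),
                      meth = .num_or_stop(m[, 4], path, ln, "methylated count"),
                      total = .num_or_stop(m[, 5], path, ln, "total count"))
  bad <- which(calls$meth > calls$total)
  if (length(bad))
    stop(path, " line ", bad[1], ": methylated count exceeds total",
         call. = FALSE)
  filter_calls(calls, assay = assay, snp_mask = snp_mask)
}

#' Coverage- and SNP-filter an in-memory call set
#'
#' @param calls data.frame with `chrom`, `start`, `end`, `meth`, `total`.
#' @inheritParams load_calls
#' @return Filtered calls with a `fraction` column and `"dropped"`
#'   attribute.
#' @export
filter_calls <- function(calls, assay = c("WGBS", "RRBS"), snp_mask = NULL) {
  assay <- match.arg(assay)
  min_cov <- if (assay == "WGBS") 10L else 20L
  low <- !(calls$total > min_cov)
  snp <- interval_overlaps_any(calls, snp_mask)
  keep <- !low & !snp
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$fraction <- out$meth / out$total
  attr(out, "dropped") <- c(coverage = sum(low), snp = sum(snp & !low))
  message("calls: kept ", nrow(out), "/", nrow(calls), " CpGs (",
          sum(low), " under-covered, ", sum(snp & !low), " SNP-masked)")
  out
}

# indices of retained CpGs inside each region (0-based half-open both)
.cpgs_in_region <- function(regions, calls) {
  pairs <- interval_overlap_pairs(regions, calls)
  split(pairs$subject, factor(pairs$query, levels = seq_len(nrow(regions))))
}

#' Mean DNA methylation of regions (percent)
#'
#' Unweighted mean of the per-CpG methylation fractions of retained CpGs in
#' each region, times 100. Regions without a retained CpG get `NA`, never
#' 0.
#'
#' @param regions Interval data.frame.
#' @param calls Filtered call set (see [filter_calls()]).
#' @return Numeric vector of percentages, one per region.
#' @export
region_methylation <- function(regions, calls) {
  idx <- .cpgs_in_region(regions, calls)
  unname(vapply(idx, function(i) {
    if (!length(i)) NA_real_ else 100 * mean(calls$fraction[i])
  }, numeric(1)))
}

#' CpG density of regions (CpGs per 100 bp)
#'
#' `100 * n_retained_CpGs / region_length`.
#'
#' @inheritParams region_methylation
#' @param methylated_only Count only CpGs with methylation fraction >= 0.5
#'   (methyl-CpG density).
#' @return Numeric vector of densities.
#' @export
cpg_density <- function(regions, calls, methylated_only = FALSE) {
  idx <- .cpgs_in_region(regions, calls)
  n <- unname(vapply(idx, function(i) {
    if (methylated_only) sum(calls$fraction[i] >= 0.5) else length(i)
  }, numeric(1)))
  100 * n / (regions$end - regions$start)
}

# centered running mean of window k, truncated at the ends
.running_mean <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment the methylome into UMR / LMR / FMR
#'
#' Per chromosome: (i) per-CpG methylation fractions are smoothed with a
#' centered running mean over `smooth_k` consecutive CpGs (truncated at the
#' ends); (ii) CpGs are linked into blocks wherever the inter-CpG gap is at
#' most `max_gap`; (iii) within each block, maximal runs of at least
#' `run_min_cpgs` consecutive CpGs with smoothed fraction <= `low_cut`
#' become hypomethylated segments - UMR when they contain at least
#' `umr_min_cpgs` CpGs, LMR otherwise; (iv) all remaining CpGs form the
#' complementary FMR runs. Segment bounds snap to the outermost member
#' CpGs (half-open, end = last CpG + 1).
#'
#' @param calls Filtered call set, position-sorted within chromosomes.
#' @param smooth_k Smoothing window in CpGs (default 3).
#' @param low_cut Smoothed-fraction cutoff for hypomethylation (default 0.5).
#' @param umr_min_cpgs UMR/LMR split on CpG count (default 30).
#' @param run_min_cpgs Minimum CpGs per hypomethylated segment (default 4).
#' @param max_gap Maximum intra-segment inter-CpG gap in bp (default 5000).
#' @return data.frame with `chrom`, `start`, `end`,
#'   `class` (`"UMR"|"LMR"|"FMR"`), `n_cpgs`, `mean_meth` (percent),
#'   `length`.
#' @export
segment_methylome <- function(calls, smooth_k = 3L, low_cut = 0.5,
                              umr_min_cpgs = 30L, run_min_cpgs = 4L,
                              max_gap = 5000L) {
  segs <- list()
  for (ch in unique(calls$chrom)) {
    d <- calls[calls$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < smooth_k) {
      warning("chromosome ", ch, " has fewer than ", smooth_k,
              " CpGs; skipped")
      next
    }
    sm <- .running_mean(d$fraction, smooth_k)
    hypo <- sm <= low_cut
    gap_break <- c(FALSE, diff(d$start) > max_gap)
    block <- cumsum(gap_break)
    # runs of constant (block, hypo)
    run_id <- cumsum(c(TRUE, diff(block) != 0 | diff(hypo) != 0))
    for (r in split(seq_len(nrow(d)), run_id)) {
      is_hypo <- hypo[r[1]] && length(r) >= run_min_cpgs
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = d$start[r[1]], end = d$start[r[length(r)]] + 1L,
        class = if (!is_hypo) "FMR"
                else if (length(r) >= umr_min_cpgs) "UMR" else "LMR",
        n_cpgs = length(r), mean_meth = 100 * mean(d$fraction[r]),
        block = paste(ch, block[r[1]]))
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), class = character(),
                      n_cpgs = integer(), mean_meth = numeric(),
                      length = integer()))
  out <- do.call(rbind, segs)
  # short hypo runs and consecutive FMR runs collapse into single FMRs
  out <- .merge_adjacent_fmr(out)
  out$block <- NULL
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

# merge consecutive FMR rows within a chromosome that came from the same
# gap-linked block neighborhood (a short hypo run sits between two FMR
# runs; the three form one complementary FMR run)
.merge_adjacent_fmr <- function(segs) {
  if (!nrow(segs)) return(segs)
  keep <- rep(TRUE, nrow(segs))
  i <- 1L
  while (i < nrow(segs)) {
    j <- i + 1L
    if (keep[i] && segs$class[i] == "FMR" && segs$class[j] == "FMR" &&
        segs$block[i] == segs$block[j]) {
      # merge j into i (n_cpgs-weighted mean methylation)
      n <- segs$n_cpgs[i] + segs$n_cpgs[j]
      segs$mean_meth[i] <- (segs$mean_meth[i] * segs$n_cpgs[i] +
                            segs$mean_meth[j] * segs$n_cpgs[j]) / n
      segs$n_cpgs[i] <- n
      segs$end[i] <- segs$end[j]
      segs <- segs[-j, , drop = FALSE]
      keep <- keep[-j]
    } else i <- i + 1L
  }
  segs
}

#' Distance/length filter for profile anchors
#'
#' Drops UMRs and LMRs that lie within `min_distance` of another UMR or LMR
#' (both members of a close pair are removed) and FMRs not longer than
#' `fmr_min_len`, so that meta-profiles around the survivors do not overlap
#' neighboring features.
#'
#' @param segments Output of [segment_methylome()].
#' @param min_distance Minimum gap between UMR/LMR neighbors (default 6000).
#' @param fmr_min_len Minimum FMR length kept (default 12000).
#' @return Filtered segment frame.
#' @export
filter_segments_for_profiles <- function(segments, min_distance = 6000,
                                         fmr_min_len = 12000) {
  keep <- rep(TRUE, nrow(segments))
  hypo <- which(segments$class %in% c("UMR", "LMR"))
  if (length(hypo) > 1L) {
    h <- segments[hypo, , drop = FALSE]
    o <- order(h$chrom, h$start)
    ho <- hypo[o]
    for (i in seq_len(length(ho) - 1L)) {
      a <- ho[i]; b <- ho[i + 1L]
      if (segments$chrom[a] == segments$chrom[b] &&
          segments$start[b] - segments$end[a] <= min_distance) {
        keep[a] <- FALSE
        keep[b] <- FALSE
      }
    }
  }
  keep[segments$class == "FMR" & segments$length <= fmr_min_len] <- FALSE
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin FMRs by methyl-CpG density
#'
#' Computes the methylated-CpG density (methyl-CpGs per 100 bp, methylation
#' fraction >= 0.5) of each FMR, ranks FMRs by it and splits them into
#' `n_bins` equal-size bins (bin 1 = lowest density). When the count does
#' not divide evenly the lower bins take the extra members (10 FMRs in 3
#' bins gives sizes 4/3/3); ties in density are broken by genomic order.
#'
#' @param fmrs FMR interval frame.
#' @param calls Filtered call set.
#' @param n_bins Number of bins (default 3).
#' @return Integer vector of bin labels (1..n_bins) aligned with `fmrs`.
#' @export
fmr_density_bins <- function(fmrs, calls, n_bins = 3L) {
  n <- nrow(fmrs)
  if (n < n_bins)
    stop("fewer FMRs (", n, ") than bins (", n_bins, ")", call. = FALSE)
  dens <- cpg_density(fmrs, calls, methylated_only = TRUE)
  o <- order(dens, fmrs$chrom, fmrs$start)   # ties by genomic order
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  lab <- integer(n)
  lab[o] <- rep(seq_len(n_bins), times = sizes)
  lab
}

#' Oriented UMR borders from flanking FMRs
#'
#' For every UMR overlapping a gene promoter (TSS +/- `promoter_flank`),
#' the two borders are the end coordinate of the nearest preceding FMR and
#' the start coordinate of the nearest following FMR; the labels `"5p"` /
#' `"3p"` follow the linked gene's strand (swapped for minus-strand genes).
#' A missing flanking FMR leaves that border out (logged).
#'
#' @param umrs UMR interval frame.
#' @param fmrs FMR interval frame.
#' @param genes Gene frame with `chrom`, `start`, `end`, `strand` (and
#'   optionally `name`).
#' @param promoter_flank Promoter half-width around the TSS (default 1000).
#' @return data.frame with `chrom`, `pos`, `side` (`"5p"|"3p"`), `umr`
#'   (row index into `umrs`), `gene`, `strand`.
#' @export
umr_borders <- function(umrs, fmrs, genes, promoter_flank = 1000L) {
  prom <- promoters_from_genes(genes, promoter_flank)
  pairs <- interval_overlap_pairs(umrs, prom)
  out <- list()
  missing_side <- 0L
  for (u in unique(pairs$query)) {
    g <- pairs$subject[pairs$query == u]
    # resolve multi-promoter overlap by largest overlap, ties to 5'-most TSS
    ow <- overlap_width(umrs$start[u], umrs$end[u],
                        prom$start[g], prom$end[g])
    g <- g[order(-ow, prom$tss[g])][1]
    ch <- umrs$chrom[u]
    prev <- which(fmrs$chrom == ch & fmrs$end <= umrs$start[u])
    nxt <- which(fmrs$chrom == ch & fmrs$start >= umrs$end[u])
    strand <- prom$strand[g]
    left_side <- if (strand == "-") "3p" else "5p"
    right_side <- if (strand == "-") "5p" else "3p"
    if (length(prev)) {
      p <- prev[which.max(fmrs$end[prev])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = fmrs$end[p], side = left_side, umr = u,
        gene = prom$name[g], strand = strand)
    } else missing_side <- missing_side + 1L
    if (length(nxt)) {
      p <- nxt[which.min(fmrs$start[nxt])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = fmrs$start[p], side = right_side, umr = u,
        gene = prom$name[g], strand = strand)
    } else missing_side <- missing_side + 1L
  }
  if (missing_side)
    message("umr_borders: ", missing_side,
            " border(s) missing (no flanking FMR)")
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      side = character(), umr = integer(),
                      gene = character(), strand = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Promoter intervals from gene models
#'
#' TSS +/- `flank` for each gene (TSS = `start` on plus strand, `end` on
#' minus strand), clipped at zero.
#'
#' @param genes Gene frame with `chrom`, `start`, `end`, `strand`,
#'   optionally `name`.
#' @param flank Half-width in bp (default 1000).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `strand`,
#'   `tss`.
#' @export
promoters_from_genes <- function(genes, flank = 1000L) {
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  data.frame(chrom = genes$chrom,
             start = pmax(0L, tss - flank),
             end = tss + flank,
             name = genes$name %||% paste0("gene", seq_len(nrow(genes))),
             strand = genes$strand,
             tss = tss)
}
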
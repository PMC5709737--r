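# CpG island detection, promoter linkage, methylation/bivalency
# classification and shore definition.
#
# Islands are distance clusters of CpGs: consecutive CpGs closer than the
# chromosome-wide median inter-CpG distance are merged, and clusters
# passing CpG-count and length filters are kept. Promoter islands with
# average methylation below 20% are unmethylated; among those, islands
# carrying both H3K4me3 and H3K27me3 tile enrichment are bivalent. Shores
# are the fixed-width intervals immediately flanking an island, labeled
# 5'/3' by the linked gene's strand.

#' Detect CpG islands by distance clustering
#'
#' Per chromosome, consecutive CpGs whose gap is at most the
#' chromosome-wide median inter-CpG distance are merged into clusters;
#' clusters with at least `min_cpgs` CpGs spanning at least `min_len` bp
#' are reported. Island bounds are the outermost member CpGs (half-open,
#' end = last CpG + 1).
#'
#' @param cpgs data.frame with `chrom` and `start` (CpG position, C of the
#'   CpG on the plus strand).
#' @param min_len Minimum island span in bp (default 200).
#' @param min_cpgs Minimum CpGs per island (default 10).
#' @return data.frame with `chrom`, `start`, `end`, `n_cpgs`.
#' @export
detect_islands <- function(cpgs, min_len = 200L, min_cpgs = 10L) {
  out <- list()
  for (ch in unique(cpgs$chrom)) {
    pos <- sort(cpgs$start[cpgs$chrom == ch])
    if (length(pos) < 2L) {
      warning("chromosome ", ch, " has < 2 CpGs; no islands")
      next
    }
    gaps <- diff(pos)
    thr <- stats::median(gaps)
    cl <- cumsum(c(TRUE, gaps > thr))
    for (idx in split(seq_along(pos), cl)) {
      span <- pos[idx[length(idx)]] - pos[idx[1]] + 1L
      if (length(idx) >= min_cpgs && span >= min_len)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[idx[1]], end = pos[idx[length(idx)]] + 1L,
          n_cpgs = length(idx))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep promoter islands and link them to genes
#'
#' Islands overlapping a promoter by at least 1 bp are retained and linked
#' to the overlapping gene; when several promoters overlap, the gene with
#' the largest overlap wins, ties going to the 5'-most (leftmost) TSS.
#'
#' @param islands Island frame from [detect_islands()].
#' @param promoters Promoter frame (see [promoters_from_genes()]).
#' @return Islands with added `gene` and `strand` columns.
#' @export
link_promoters <- function(islands, promoters) {
  pairs <- interval_overlap_pairs(islands, promoters)
  if (!nrow(pairs)) {
    out <- islands[integer(0), , drop = FALSE]
    out$gene <- character(0); out$strand <- character(0)
    return(out)
  }
  rows <- sort(unique(pairs$query))
  gene <- character(length(rows)); strand <- character(length(rows))
  for (k in seq_along(rows)) {
    u <- rows[k]
    g <- pairs$subject[pairs$query == u]
    ow <- overlap_width(islands$start[u], islands$end[u],
                        promoters$start[g], promoters$end[g])
    g <- g[order(-ow, promoters$tss[g])][1]
    gene[k] <- promoters$name[g]
    strand[k] <- promoters$strand[g]
  }
  out <- islands[rows, , drop = FALSE]
  out$gene <- gene
  out$strand <- strand
  rownames(out) <- NULL
  out
}

#' Classify promoter islands by methylation and bivalency
#'
#' Methylation class: unmethylated when the island's average CpG
#' methylation ([region_methylation()]) is below `meth_max` percent,
#' methylated otherwise. Among unmethylated islands, chromatin class is
#' `"bivalent"` when the mean H3K4me3 and mean H3K27me3 log2 enrichments
#' over island-overlapping tiles are both at least `e_min`;
#' `"K27-negative"` when only H3K4me3 passes; `"unclassified"` otherwise
#' (including islands without any overlapping filtered tile).
#'
#' @param islands Promoter-linked island frame.
#' @param calls Filtered call set.
#' @param tiles Filtered tile frame.
#' @param h3k4me3,h3k27me3 Per-tile log2 enrichments aligned with `tiles`.
#' @param e_min Enrichment cutoff in log2 units (default 1, i.e. 2-fold).
#' @param meth_max Unmethylated cutoff in percent (default 20).
#' @return Islands with added `meth_pct`, `meth_class`, `chromatin_class`.
#' @export
classify_islands <- function(islands, calls, tiles, h3k4me3, h3k27me3,
                             e_min = 1.0, meth_max = 20) {
  islands$meth_pct <- region_methylation(islands, calls)
  islands$meth_class <- ifelse(!is.na(islands$meth_pct) &
                               islands$meth_pct < meth_max,
                               "unmethylated", "methylated")
  pairs <- interval_overlap_pairs(islands, tiles)
  mean_enr <- function(e, u) {
    t <- pairs$subject[pairs$query == u]
    if (!length(t)) NA_real_ else mean(e[t])
  }
  cls <- character(nrow(islands))
  n_no_tile <- 0L
  for (u in seq_len(nrow(islands))) {
    if (islands$meth_class[u] != "unmethylated") { cls[u] <- NA; next }
    k4 <- mean_enr(h3k4me3, u); k27 <- mean_enr(h3k27me3, u)
    if (is.na(k4) || is.na(k27)) {
      cls[u] <- "unclassified"; n_no_tile <- n_no_tile + 1L
    } else if (k4 >= e_min && k27 >= e_min) cls[u] <- "bivalent"
    else if (k4 >= e_min) cls[u] <- "K27-negative"
    else cls[u] <- "unclassified"
  }
  if (n_no_tile)
    message("classify_islands: ", n_no_tile,
            " island(s) without overlapping filtered tile -> unclassified")
  islands$chromatin_class <- cls
  islands
}

#' Define oriented island shores
#'
#' The two fixed-width intervals flanking an island:
#' `[start - width, start)` and `[end, end + width)`, clipped at the
#' chromosome bounds; labels `"5p"` / `"3p"` follow the linked gene's
#' strand.
#'
#' @param islands Island frame (with a `strand` column when oriented
#'   labels are wanted; unstranded islands are labeled as plus-strand).
#' @param width Shore width in bp (default 2000).
#' @param chrom_sizes Optional named vector for right-clipping.
#' @return data.frame with `chrom`, `start`, `end`, `side`, `island`
#'   (row index into `islands`), `clipped`.
#' @export
define_shores <- function(islands, width = 2000L, chrom_sizes = NULL) {
  n <- nrow(islands)
  strand <- islands$strand %||% rep("+", n)
  left <- data.frame(chrom = islands$chrom,
                     start = islands$start - width, end = islands$start,
                     side = ifelse(strand == "-", "3p", "5p"),
                     island = seq_len(n))
  right <- data.frame(chrom = islands$chrom,
                      start = islands$end, end = islands$end + width,
                      side = ifelse(strand == "-", "5p", "3p"),
                      island = seq_len(n))
  out <- rbind(left, right)
  out <- out[order(out$island, out$start), , drop = FALSE]
  clipped <- out$start < 0
  out$start <- pmax(out$start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[out$chrom]
    clipped <- clipped | out$end > lim
    out$end <- pmin(out$end, lim)
  }
  out$clipped <- clipped
  if (any(clipped))
    message("define_shores: ", sum(clipped),
            " shore(s) clipped at chromosome bounds")
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}
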
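# Tile frame construction, filtering, read counting and log2 enrichment.
#
# The genome is partitioned into fixed-width windows (1 kb by default);
# per-track read counts on that frame are the common currency of every
# downstream statistic. Enrichment is the pseudocount-regularized log2
# ratio of library-size-normalized IP over input counts.

#' Partition chromosomes into fixed-width tiles
#'
#' Each chromosome is cut into `floor(size / width)` contiguous windows
#' starting at 0; the trailing sub-width fragment is dropped so that every
#' tile has identical width.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param width Tile width in bp (default 1000).
#' @return data.frame with `chrom`, `start`, `end` in genome order.
#' @export
make_tiles <- function(chrom_sizes, width = 1000L) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop_config("tile width must be a positive number")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop_config("chrom_sizes must be a named vector")
  if (any(chrom_sizes < width))
    stop_config("all chromosome sizes must be >= the tile width")
  width <- as.integer(width)
  pieces <- lapply(names(chrom_sizes), function(ch) {
    n <- floor(chrom_sizes[[ch]] / width)
    s <- (seq_len(n) - 1L) * width
    data.frame(chrom = ch, start = s, end = s + width)
  })
  do.call(rbind, pieces)
}

#' Filter tiles by blacklist, mappability and bisulfite coverage
#'
#' Removes tiles that overlap a blacklisted interval by >= 1 bp, tiles with
#' mappability below `mappability_min`, and (when a `cpg_covered_fraction`
#' column is present) tiles in which the fraction of CpGs with sufficient
#' bisulfite coverage is not greater than `meth_cov_min`. Removal counts
#' per category are attached as the `"removed"` attribute and reported.
#'
#' @param tiles Tile frame; optional columns `mappability`,
#'   `cpg_covered_fraction`.
#' @param blacklist Optional interval data.frame of regions to exclude.
#' @param mappability_min Minimum mappability kept (default 0.5).
#' @param meth_cov_min Coverage-fraction cutoff; tiles are kept when
#'   `cpg_covered_fraction > meth_cov_min` (default 0.5).
#' @return Filtered tile frame with a `"removed"` attribute.
#' @export
filter_tiles <- function(tiles, blacklist = NULL, mappability_min = 0.5,
                         meth_cov_min = 0.5) {
  n <- nrow(tiles)
  drop_bl <- interval_overlaps_any(tiles, blacklist)
  drop_map <- if ("mappability" %in% names(tiles))
    tiles$mappability < mappability_min else logical(n)
  drop_cov <- if ("cpg_covered_fraction" %in% names(tiles))
    !(tiles$cpg_covered_fraction > meth_cov_min) else logical(n)
  keep <- !(drop_bl | drop_map | drop_cov)
  removed <- c(blacklist = sum(drop_bl), mappability = sum(drop_map),
               meth_coverage = sum(drop_cov))
  message("filter_tiles: kept ", sum(keep), "/", n,
          " (blacklist ", removed[1], ", mappability ", removed[2],
          ", coverage ", removed[3], ")")
  out <- tiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no tiles retained after filtering")
  attr(out, "removed") <- removed
  out
}

# Resolve the 5' start position of each read interval.
.read_positions <- function(reads) {
  if (!is.null(reads$strand))
    ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  else reads$start
}

#' Count reads (or adopt precomputed counts) on a tile frame
#'
#' Reads are assigned to tiles by their 5' start position (the `end - 1`
#' coordinate for minus-strand reads); a position falling exactly on a tile
#' boundary belongs to the right-hand tile by the half-open convention.
#' Alternatively `reads` may be a precomputed count table
#' (`chrom`,`start`,`end`,`count`) matched to the frame by coordinates.
#'
#' @param reads Interval data.frame of reads (optionally stranded), or a
#'   count table.
#' @param tiles Tile frame.
#' @param track Column name for the counts (default `"count"`).
#' @return `tiles` with an added integer count column; the number of reads
#'   falling outside every tile is attached as attribute `"ignored"`.
#' @export
count_track <- function(reads, tiles, track = "count") {
  n <- nrow(tiles)
  if ("count" %in% names(reads)) {
    key_t <- paste(tiles$chrom, tiles$start)
    key_c <- paste(reads$chrom, reads$start)
    idx <- match(key_t, key_c)
    if (anyNA(idx))
      stop("precomputed counts do not cover the tile frame", call. = FALSE)
    tiles[[track]] <- as.integer(reads$count[idx])
    attr(tiles, "ignored") <-
      sum(reads$count[setdiff(seq_len(nrow(reads)), idx)])
    return(tiles)
  }
  pos <- .read_positions(reads)
  counts <- integer(n)
  ignored <- 0L
  unknown <- setdiff(unique(reads$chrom), unique(tiles$chrom))
  if (length(unknown)) {
    warning("reads on chromosome(s) absent from tiles skipped: ",
            paste(unknown, collapse = ", "))
    ignored <- ignored + sum(reads$chrom %in% unknown)
  }
  for (ch in intersect(unique(reads$chrom), unique(tiles$chrom))) {
    it <- which(tiles$chrom == ch)
    p <- pos[reads$chrom == ch]
    ov <- IRanges::findOverlaps(.as_ir(p, p + 1L),
                                .as_ir(tiles$start[it], tiles$end[it]))
    tab <- tabulate(S4Vectors::subjectHits(ov), nbins = length(it))
    counts[it] <- counts[it] + tab
    ignored <- ignored + (length(p) - length(ov))
  }
  tiles[[track]] <- counts
  attr(tiles, "ignored") <- ignored
  tiles
}

# Scale two raw count vectors to the mean of their two library sizes.
.normalize_pair <- function(ip, input, ip_lib, input_lib) {
  target <- (ip_lib + input_lib) / 2
  list(ip = ip * target / ip_lib, input = input * target / input_lib)
}

#' Pseudocount-regularized log2 enrichment of IP over input
#'
#' Both tracks are scaled to the mean of the two library sizes, then
#' `log2((ip + c) / (input + c))` is computed per tile with pseudocount
#' `c`. The pseudocount keeps the statistic finite and shrinks
#' low-coverage tiles toward zero.
#'
#' @param ip,input Raw per-tile counts on a common frame.
#' @param ip_lib,input_lib Library sizes; default to the sum of the counts.
#' @param pseudocount Regularizing constant `c` (default 8).
#' @return Numeric vector of per-tile log2 enrichments with attributes
#'   `pseudocount`, `ip_lib`, `input_lib`.
#' @export
log2_enrichment <- function(ip, input, ip_lib = sum(ip),
                            input_lib = sum(input), pseudocount = 8) {
  if (length(ip) != length(input))
    stop("ip and input must be on the same tile frame", call. = FALSE)
  assert_positive(pseudocount, "pseudocount")
  assert_positive(ip_lib, "ip library size")
  assert_positive(input_lib, "input library size")
  z <- .normalize_pair(ip, input, ip_lib, input_lib)
  e <- log2((z$ip + pseudocount) / (z$input + pseudocount))
  attr(e, "pseudocount") <- pseudocount
  attr(e, "ip_lib") <- ip_lib
  attr(e, "input_lib") <- input_lib
  e
}

#' Genome-wide cross-correlation of tracks
#'
#' Pearson correlation between all pairs of tracks computed on
#' log2-transformed per-tile counts (after adding the pseudocount).
#' Constant tracks have undefined correlation and are reported as `NA`.
#'
#' @param tracks Named list of per-tile count vectors on one filtered frame.
#' @param pseudocount Constant added before the log (default 8).
#' @return Symmetric correlation matrix with unit diagonal (entries
#'   involving constant tracks are `NA`).
#' @export
cross_correlation <- function(tracks, pseudocount = 8) {
  if (length(tracks) < 2L)
    stop("need at least two tracks", call. = FALSE)
  lens <- lengths(tracks)
  if (length(unique(lens)) != 1L)
    stop("all tracks must be on the same tile frame", call. = FALSE)
  m <- vapply(tracks, function(x) log2(x + pseudocount), numeric(lens[1]))
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  cc <- suppressWarnings(stats::cor(m))
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc)[!const] <- 1
  cc
}
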
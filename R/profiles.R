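# Anchored meta-profiles, scaled gene profiles, k-means signal clustering,
# condition dynamics and promoter-class enrichment.
#
# A profile matrix is anchors x position-bins of library-normalized read
# counts (reads per bin per 1e7 library reads); minus-strand anchor rows
# are reversed so that column 1 is always the 5' side. Column means give
# the average density plot.

#' Anchored profile matrix
#'
#' Counts read 5' starts in `bin_bp` bins covering `[-flank_bp, +flank_bp)`
#' around each anchor point, flips minus-strand rows and normalizes to
#' reads per bin per `norm_constant` library reads. Anchors whose window
#' runs off a chromosome get `NA` rows (ignored by [profile_means()]).
#'
#' @param reads Read interval frame (optionally stranded).
#' @param anchors data.frame with `chrom`, `pos` and optionally `strand`.
#' @param flank_bp Half-window in bp; must be divisible by `bin_bp`.
#' @param bin_bp Bin width in bp.
#' @param library_size Total reads in the library (default `nrow(reads)`).
#' @param norm_constant Library-normalization constant (default 1e7).
#' @param chrom_sizes Optional named vector to detect off-chromosome
#'   windows.
#' @param track Track name stored in the result.
#' @return A `profile_matrix`: list with `matrix` (anchors x bins),
#'   `anchors`, `bin_bp`, `flank_bp`, `track`, `norm_constant`,
#'   `library_size`.
#' @export
anchor_profile <- function(reads, anchors, flank_bp, bin_bp,
                           library_size = nrow(reads), norm_constant = 1e7,
                           chrom_sizes = NULL, track = "track") {
  if (flank_bp %% bin_bp != 0)
    stop_config("flank_bp must be divisible by bin_bp")
  n_bins <- as.integer(2 * flank_bp / bin_bp)
  n_a <- nrow(anchors)
  strand <- anchors$strand %||% rep("+", n_a)
  mat <- matrix(0, n_a, n_bins)
  pos <- .read_positions(reads)
  for (ch in intersect(unique(anchors$chrom), unique(reads$chrom))) {
    ia <- which(anchors$chrom == ch)
    p <- pos[reads$chrom == ch]
    win <- .as_ir(anchors$pos[ia] - flank_bp, anchors$pos[ia] + flank_bp)
    ov <- IRanges::findOverlaps(.as_ir(p, p + 1L), win)
    if (!length(ov)) next
    a <- ia[S4Vectors::subjectHits(ov)]
    rp <- p[S4Vectors::queryHits(ov)]
    off <- ifelse(strand[a] == "-",
                  anchors$pos[a] - rp - 1L,
                  rp - anchors$pos[a])
    bin <- floor((off + flank_bp) / bin_bp) + 1L
    keep <- bin >= 1L & bin <= n_bins
    idx <- a[keep] + (bin[keep] - 1L) * n_a   # column-major cell index
    mat <- mat + matrix(tabulate(idx, nbins = n_a * n_bins), n_a, n_bins)
  }
  # off-chromosome windows -> NA rows
  bad <- anchors$pos - flank_bp < 0
  if (!is.null(chrom_sizes))
    bad <- bad | anchors$pos + flank_bp > chrom_sizes[anchors$chrom]
  mat[bad, ] <- NA_real_
  mat <- mat * norm_constant / max(library_size, 1)
  structure(list(matrix = mat, anchors = anchors, bin_bp = bin_bp,
                 flank_bp = flank_bp, track = track,
                 norm_constant = norm_constant,
                 library_size = library_size),
            class = "profile_matrix")
}

#' Column means of a profile matrix (average density plot)
#'
#' @param profile A `profile_matrix`.
#' @return Numeric vector of per-bin means over anchors (`NA` rows
#'   excluded).
#' @export
profile_means <- function(profile) {
  colMeans(profile$matrix, na.rm = TRUE)
}

#' Gene-scaled profile matrix
#'
#' Fixed-width flank bins plus a gene body rescaled to `n_body_bins`
#' regardless of length, strand-oriented (column 1 is the 5' flank).
#' Entries are read densities expressed as reads per `bin_bp` bp per
#' `norm_constant` library reads, so a spatially constant track is flat
#' across flanks and body. Genes overlapping another gene, and genes
#' shorter than `n_body_bins` bp, are dropped (logged).
#'
#' @param reads Read interval frame.
#' @param genes Gene frame with `chrom`, `start`, `end`, `strand`.
#' @param n_body_bins Number of body bins (default 20).
#' @param flank_bp Flank width in bp (default 2000).
#' @param bin_bp Flank bin width in bp (default 200).
#' @inheritParams anchor_profile
#' @return A `profile_matrix` whose `anchors` are the retained genes, with
#'   an extra `section` attribute labeling columns as
#'   `upstream`/`body`/`downstream`.
#' @export
scaled_gene_profile <- function(reads, genes, n_body_bins = 20L,
                                flank_bp = 2000L, bin_bp = 200L,
                                library_size = nrow(reads),
                                norm_constant = 1e7) {
  if (flank_bp %% bin_bp != 0)
    stop_config("flank_bp must be divisible by bin_bp")
  ov_other <- vapply(seq_len(nrow(genes)), function(i) {
    any(genes$chrom[-i] == genes$chrom[i] &
        genes$start[-i] < genes$end[i] & genes$end[-i] > genes$start[i])
  }, logical(1))
  short <- (genes$end - genes$start) < n_body_bins
  if (any(ov_other))
    message("scaled_gene_profile: ", sum(ov_other),
            " overlapping gene(s) dropped")
  if (any(short & !ov_other))
    message("scaled_gene_profile: ", sum(short & !ov_other),
            " gene(s) shorter than ", n_body_bins, " bp dropped")
  genes <- genes[!ov_other & !short, , drop = FALSE]
  rownames(genes) <- NULL
  n_fl <- as.integer(flank_bp / bin_bp)
  n_bins <- 2L * n_fl + n_body_bins
  mat <- matrix(0, nrow(genes), n_bins)
  pos <- .read_positions(reads)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; s <- genes$start[i]; e <- genes$end[i]
    p <- pos[reads$chrom == ch]
    p <- p[p >= s - flank_bp & p < e + flank_bp]
    if (!length(p)) next
    glen <- e - s
    bw <- glen / n_body_bins
    # genomic bin index: upstream flank, body, downstream flank
    bin <- integer(length(p))
    up <- p < s; dn <- p >= e; body <- !up & !dn
    bin[up] <- floor((p[up] - (s - flank_bp)) / bin_bp) + 1L
    bin[body] <- n_fl + pmin(floor((p[body] - s) / bw) + 1L, n_body_bins)
    bin[dn] <- n_fl + n_body_bins + floor((p[dn] - e) / bin_bp) + 1L
    v <- tabulate(bin, nbins = n_bins)
    # density scaling: body bins cover bw bp, flanks bin_bp bp
    scale <- c(rep(1, n_fl), rep(bin_bp / bw, n_body_bins), rep(1, n_fl))
    row <- v * scale
    if (genes$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  mat <- mat * norm_constant / max(library_size, 1)
  section <- c(rep("upstream", n_fl), rep("body", n_body_bins),
               rep("downstream", n_fl))
  structure(list(matrix = mat, anchors = genes, bin_bp = bin_bp,
                 flank_bp = flank_bp, track = "track",
                 norm_constant = norm_constant, library_size = library_size,
                 section = section),
            class = "profile_matrix")
}

# k-means++ seeding on rows of x
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(0)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster anchors by their signal profile
#'
#' k-means (k-means++ seeding, multiple restarts keeping the lowest
#' within-cluster sum of squares) on log2-transformed profile rows
#' (`log2(x + pseudocount)`). Rows containing `NA` are excluded and get
#' label `NA`.
#'
#' @param profile A `profile_matrix`.
#' @param k Number of clusters (default 5).
#' @param seed RNG seed for reproducible clustering.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param pseudocount Constant inside the log (default 8).
#' @return List with `labels` (per anchor, `NA` for incomplete rows),
#'   `centers`, `k`, `seed`, `inertia`.
#' @export
cluster_umrs <- function(profile, k = 5L, seed = 1L, restarts = 10L,
                         pseudocount = 8) {
  mat <- profile$matrix
  complete <- stats::complete.cases(mat)
  x <- log2(mat[complete, , drop = FALSE] + pseudocount)
  if (nrow(x) < k)
    stop("fewer complete profile rows (", nrow(x), ") than clusters (",
         k, ")", call. = FALSE)
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- .kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  labels <- rep(NA_integer_, nrow(mat))
  labels[complete] <- best$cluster
  list(labels = labels, centers = best$centers, k = k, seed = seed,
       inertia = best$tot.withinss)
}

#' Differential binding between two conditions
#'
#' Per-tile `log2((B + c) / (A + c))` after scaling both libraries to the
#' mean of the two library sizes; positive values mean more signal in
#' condition B (e.g. neuronal progenitors over ES cells). Optionally
#' restricted to a tile subset (e.g. tiles H3K27me3-positive in either
#' condition), returning `NA` elsewhere.
#'
#' @param a_counts,b_counts Raw per-tile counts on one frame (A = baseline,
#'   B = comparison condition).
#' @param a_lib,b_lib Library sizes (default: count sums).
#' @param pseudocount Regularizing constant (default 8).
#' @param restrict Optional logical vector of tiles to evaluate.
#' @return Numeric vector of per-tile log2 fold changes B over A.
#' @export
differential_binding <- function(a_counts, b_counts, a_lib = sum(a_counts),
                                 b_lib = sum(b_counts), pseudocount = 8,
                                 restrict = NULL) {
  if (length(a_counts) != length(b_counts))
    stop("conditions must be on the same tile frame", call. = FALSE)
  fc <- -log2_enrichment(a_counts, b_counts, a_lib, b_lib, pseudocount)
  attributes(fc) <- NULL
  if (!is.null(restrict)) fc[!restrict] <- NA_real_
  fc
}

#' Block medians of a statistic over ranked windows
#'
#' Tiles are sorted by `rank_key` (ascending, ties by original order) and
#' cut into consecutive non-overlapping blocks of `block` tiles; the
#' median of `values` and the mean `rank_key` are reported per block. A
#' final short block is kept when it holds at least half a block and
#' merged into the previous block otherwise.
#'
#' @param values Per-tile statistic (e.g. log2 fold change).
#' @param rank_key Per-tile ranking variable (e.g. methylation gain).
#' @param block Block size (default 500).
#' @return data.frame with `block`, `n`, `median_value`, `mean_rank`.
#' @export
ranked_window_medians <- function(values, rank_key, block = 500L) {
  if (length(values) != length(rank_key))
    stop("values and rank_key must be aligned", call. = FALSE)
  ok <- !is.na(values) & !is.na(rank_key)
  v <- values[ok]; r <- rank_key[ok]
  n <- length(v)
  if (n < ceiling(block / 2))
    stop("need at least ", ceiling(block / 2), " tiles for one block",
         call. = FALSE)
  o <- order(r)
  v <- v[o]; r <- r[o]
  n_blocks <- max(1L, n %/% block)
  id <- pmin((seq_len(n) - 1L) %/% block + 1L, n_blocks)
  rem <- n - n_blocks * block
  if (rem >= ceiling(block / 2)) {
    id[seq.int(n_blocks * block + 1L, n)] <- n_blocks + 1L
    n_blocks <- n_blocks + 1L
  }
  data.frame(block = seq_len(n_blocks),
             n = as.integer(table(id)),
             median_value = as.numeric(tapply(v, id, stats::median)),
             mean_rank = as.numeric(tapply(r, id, mean)))
}

#' Promoter-class enrichment of a gene set
#'
#' For each promoter class, the fraction of class genes present in
#' `up_genes` and the upper-tail hypergeometric probability of drawing at
#' least that many `up_genes` members when sampling `|class|` genes from
#' the universe.
#'
#' @param up_genes Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param classes Named list of character vectors (promoter classes).
#' @param universe Character vector of all genes considered.
#' @param alpha Significance cutoff on the hypergeometric p (default 0.05).
#' @return data.frame with `class`, `n_class`, `n_up`, `fraction`,
#'   `p_value`, `significant`.
#' @export
promoter_class_enrichment <- function(up_genes, classes, universe,
                                      alpha = 0.05) {
  up_genes <- unique(up_genes)
  universe <- unique(universe)
  if (!all(up_genes %in% universe))
    stop("up_genes must be a subset of the universe", call. = FALSE)
  empty <- !vapply(classes, length, integer(1))
  if (any(empty)) {
    warning("empty class(es) skipped: ",
            paste(names(classes)[empty], collapse = ", "))
    classes <- classes[!empty]
  }
  rows <- lapply(names(classes), function(nm) {
    cls <- intersect(unique(classes[[nm]]), universe)
    n_up <- length(intersect(cls, up_genes))
    p <- stats::phyper(n_up - 1, length(up_genes),
                       length(universe) - length(up_genes), length(cls),
                       lower.tail = FALSE)
    data.frame(class = nm, n_class = length(cls), n_up = n_up,
               fraction = n_up / length(cls), p_value = p,
               significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand per-tile counts into synthetic read starts
#'
#' Places each tile's count as that many read-start positions uniformly at
#' random inside the tile (seeded). Lets tile-level simulations exercise
#' the read-counting and profile paths.
#'
#' @param counts data.frame with `chrom`, `start`, `end`, `count`.
#' @param seed RNG seed.
#' @return data.frame with `chrom`, `start`, `end` (1-bp read starts).
#' @export
expand_counts_to_reads <- function(counts, seed = 1L) {
  k <- as.integer(counts$count)
  total <- sum(k)
  idx <- rep.int(seq_len(nrow(counts)), k)
  with_local_seed(seed, {
    w <- counts$end[idx] - counts$start[idx]
    p <- counts$start[idx] + floor(stats::runif(total) * w)
    data.frame(chrom = counts$chrom[idx], start = p, end = p + 1L)
  })
}
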
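# Readers/writers for the plain-text formats the pipeline touches and the
# pipeline configuration object. Every interval on disk and in memory is
# 0-based half-open; a single pair of helpers (.as_ir in utils.R) converts
# to the 1-based closed convention of IRanges at overlap time.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines[nzchar(lines)]
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.num_or_stop <- function(x, path, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(path, " line ", line_no[bad[1]], ": non-numeric ", what, " '",
         x[bad[1]], "'", call. = FALSE)
  v
}

#' Read a BED3/BED6 file
#'
#' Parses tab-separated BED with 0-based half-open intervals. Columns beyond
#' the third are optional; `name`, `score` and `strand` are kept when
#' present. Malformed lines are reported with their line number.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- .read_tsv_lines(path)
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  f <- .split_fields(lines)
  nf <- lengths(f)
  if (any(nf < 3L))
    stop(path, " line ", which(nf < 3L)[1], ": fewer than 3 BED fields",
         call. = FALSE)
  ncol <- min(nf)
  m <- t(vapply(f, function(x) x[seq_len(ncol)], character(ncol)))
  out <- data.frame(chrom = m[, 1],
                    start = .num_or_stop(m[, 2], path, seq_along(lines), "start"),
                    end = .num_or_stop(m[, 3], path, seq_along(lines), "end"))
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop(path, " line ", bad[1], ": start >= end", call. = FALSE)
  if (ncol >= 4L) out$name <- m[, 4]
  if (ncol >= 5L) out$score <- .num_or_stop(m[, 5], path, seq_along(lines), "score")
  if (ncol >= 6L) {
    ok <- m[, 6] %in% c("+", "-", ".")
    if (any(!ok))
      stop(path, " line ", which(!ok)[1], ": bad strand '", m[!ok, 6][1],
           "'", call. = FALSE)
    out$strand <- m[, 6]
  }
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` and, when present, `name`, `score`,
#' `strand` as tab-separated BED (0-based half-open).
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED column order is positional: fill gaps with defaults
  if ("strand" %in% cols && !"score" %in% cols) x$score <- 0
  if (("score" %in% names(x) || "strand" %in% cols) && !"name" %in% cols)
    x$name <- "."
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  m <- x[, cols, drop = FALSE]
  m$start <- fmt_num(m$start)
  m$end <- fmt_num(m$end)
  if ("score" %in% cols) m$score <- fmt_num(m$score)
  ok <- try(utils::write.table(m, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write BED to ", path, call. = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph file
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- .read_tsv_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  f <- .split_fields(lines)
  nf <- lengths(f)
  if (any(nf < 4L))
    stop(path, " line ", which(nf < 4L)[1], ": fewer than 4 bedGraph fields",
         call. = FALSE)
  m <- t(vapply(f, function(x) x[1:4], character(4)))
  data.frame(chrom = m[, 1],
             start = .num_or_stop(m[, 2], path, seq_along(lines), "start"),
             end = .num_or_stop(m[, 3], path, seq_along(lines), "end"),
             value = .num_or_stop(m[, 4], path, seq_along(lines), "value"))
}

#' Write a 4-column bedGraph file
#'
#' @param x data.frame with `chrom`, `start`, `end` and a value column
#'   (named `value` or given by `value_col`).
#' @param path Output path.
#' @param value_col Name of the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, value_col = "value") {
  m <- data.frame(chrom = x$chrom, start = fmt_num(x$start),
                  end = fmt_num(x$end), value = fmt_num(x[[value_col]]))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-tile count table
#'
#' Tab-separated with header `chrom  start  end  count`.
#'
#' @param path Path to the TSV.
#' @return data.frame with integer counts.
#' @export
read_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(x)))
    stop(path, ": count table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  x
}

#' Write a per-tile count table
#'
#' @param x data.frame with `chrom`, `start`, `end`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  m <- data.frame(chrom = x$chrom, start = fmt_num(x$start),
                  end = fmt_num(x$end), count = fmt_num(x$count))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline, each defaulting to the
#' value used throughout the analysis: 1-kb tiles, 8 pseudocounts,
#' mappability >= 0.5, bisulfite coverage > 10 (WGBS) / > 20 (RRBS) per CpG
#' and > 50% of tile CpGs covered >= 10x, bound-region thresholds FC > 1
#' and adjusted p < 0.002, 200-bp / 10-CpG island filters, 20% island
#' methylation cutoff, 2-kb shores, 1-kb promoter flanks, 6-kb / 12-kb
#' profile distance filters, 3 FMR density bins, k = 5 profile clusters and
#' 500-window ranked medians.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of class `shoremap_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tile_width = 1000L,
    pseudocount = 8,
    mappability_min = 0.5,
    meth_cov_min = 0.5,
    cpg_min_cov_wgbs = 10L,     # strict >: keep total > 10
    cpg_min_cov_rrbs = 20L,     # strict >: keep total > 20
    tile_cpg_cov = 10L,         # tile filter: CpG covered >= 10x
    fold_min = 1,
    padj_max = 0.002,
    smooth_k = 3L,
    low_meth_cut = 0.5,
    umr_min_cpgs = 30L,
    run_min_cpgs = 4L,
    max_cpg_gap = 5000L,
    min_segment_distance = 6000L,
    fmr_min_len = 12000L,
    n_density_bins = 3L,
    island_min_len = 200L,
    island_min_cpgs = 10L,
    e_min = 1.0,
    shore_width = 2000L,
    promoter_flank = 1000L,
    profile_flank = 3000L,
    profile_bin = 1000L,
    norm_constant = 1e7,
    k = 5L,
    cluster_restarts = 10L,
    block = 500L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_config("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  assert_positive(cfg$tile_width, "tile_width")
  assert_positive(cfg$pseudocount, "pseudocount")
  assert_fraction(cfg$mappability_min, "mappability_min")
  assert_fraction(cfg$meth_cov_min, "meth_cov_min")
  assert_fraction(cfg$padj_max, "padj_max")
  class(cfg) <- c("shoremap_config", "list")
  cfg
}

#' Write / read a pipeline configuration
#'
#' Flat YAML serialization; `read_config(write_config(cfg, f))` restores the
#' configuration losslessly.
#'
#' @param cfg A `shoremap_config`.
#' @param path File path.
#' @return `read_config` returns the configuration; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
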
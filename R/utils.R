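# Internal helpers: interval plumbing, seeded substreams, validation.
# All user-facing coordinates are 0-based half-open [start, end).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# data.frame(chrom, start, end) -> IRanges on a single chromosome,
# shifted to the 1-based closed convention IRanges uses.
.as_ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# For each interval in `a`, does it overlap (>= 1 bp) any interval in `b`?
# Both are data.frames with chrom/start/end.
interval_overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  if (nrow(a) == 0L || is.null(b) || nrow(b) == 0L) return(hit)
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (!length(ib)) next
    ov <- IRanges::findOverlaps(.as_ir(a$start[ia], a$end[ia]),
                                .as_ir(b$start[ib], b$end[ib]))
    hit[ia[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

# All (query, subject) overlap pairs between two interval frames.
interval_overlap_pairs <- function(a, b) {
  out <- list()
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (!length(ib)) next
    ov <- IRanges::findOverlaps(.as_ir(a$start[ia], a$end[ia]),
                                .as_ir(b$start[ib], b$end[ib]))
    out[[ch]] <- data.frame(query = ia[S4Vectors::queryHits(ov)],
                            subject = ib[S4Vectors::subjectHits(ov)])
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  do.call(rbind, unname(out))
}

# Width of the overlap between one interval and a set of intervals (bp).
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Deterministic per-component substream seed derived from a global seed.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() accepts it.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 1103515245 + h * 12345) %% 2147483646) + 1L
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(what, " must be a fraction in [0, 1]")
  invisible(x)
}

assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(what, " must be a positive number")
  invisible(x)
}

# Numeric formatting that survives a write/read round trip exactly.
fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 2^53, sprintf("%.0f", x),
         sprintf("%.17g", x))
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
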
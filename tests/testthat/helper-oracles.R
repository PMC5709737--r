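# Independent oracles used to freeze expected values: brute-force
# enumerations and closed forms, deliberately written without reference to
# the package internals they check.

# Benjamini-Hochberg step-up, written directly from the definition:
# adj_(i) = min_{j >= i} ( p_(j) * n / j ), capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(ps[i:n] * n / (i:n), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact upper-tail hypergeometric by term-wise enumeration:
# P(X >= x) drawing n from a universe of N with K successes.
oracle_hyper_tail <- function(x, K, N, n) {
  lo <- max(x, 0)
  hi <- min(K, n)
  if (lo > hi) return(0)
  ks <- lo:hi
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Exact two-sided conditional test for two Poisson counts (conditional on
# the total, k1 ~ Binomial(k1 + k2, 1/2) under the null).
oracle_poisson_pair <- function(k1, k2) {
  n <- k1 + k2
  d <- stats::dbinom(0:n, n, 0.5)
  sum(d[d <= d[k1 + 1] + 1e-12])
}

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Brute-force UMR/LMR/FMR segmentation by exhaustive run enumeration.
# A hypo segment is any index window [i, j] such that every CpG has
# smoothed fraction <= low_cut, no internal gap exceeds max_gap, the
# window holds >= run_min CpGs, and it is maximal (not extendable across
# a qualifying neighbor). Remaining CpGs form maximal complementary runs
# within gap-linked blocks (FMR).
oracle_segment <- function(pos, frac, smooth_k = 3, low_cut = 0.5,
                           umr_min = 30, run_min = 4, max_gap = 5000) {
  n <- length(pos)
  half <- (smooth_k - 1) %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(frac[max(1, i - half):min(n, i + half)]), numeric(1))
  hypo <- sm <= low_cut
  linked <- c(FALSE, diff(pos) <= max_gap)   # linked[i]: i joins i-1
  segs <- list()
  in_hypo_seg <- logical(n)
  for (i in seq_len(n)) for (j in i:n) {
    win <- i:j
    if (!all(hypo[win])) next
    if (j > i && !all(linked[(i + 1):j])) next
    if (length(win) < run_min) next
    ext_l <- i > 1 && hypo[i - 1] && linked[i]
    ext_r <- j < n && hypo[j + 1] && linked[j + 1]
    if (ext_l || ext_r) next
    segs[[length(segs) + 1]] <- list(
      cls = if (length(win) >= umr_min) "UMR" else "LMR", i = i, j = j)
    in_hypo_seg[win] <- TRUE
  }
  rest <- which(!in_hypo_seg)
  while (length(rest)) {
    i <- rest[1]
    j <- i
    while (j < n && (j + 1) %in% rest && linked[j + 1]) j <- j + 1
    segs[[length(segs) + 1]] <- list(cls = "FMR", i = i, j = j)
    rest <- rest[rest > j]
  }
  ord <- order(vapply(segs, function(s) s$i, numeric(1)))
  data.frame(
    class = vapply(segs[ord], function(s) s$cls, character(1)),
    start = pos[vapply(segs[ord], function(s) s$i, numeric(1))],
    end = pos[vapply(segs[ord], function(s) s$j, numeric(1))] + 1,
    n_cpgs = vapply(segs[ord], function(s) s$j - s$i + 1, numeric(1)))
}

# Brute-force CpG-island clustering at a fixed gap threshold.
oracle_islands <- function(pos, min_len = 200, min_cpgs = 10) {
  pos <- sort(pos)
  thr <- stats::median(diff(pos))
  groups <- split(seq_along(pos), cumsum(c(TRUE, diff(pos) > thr)))
  out <- NULL
  for (g in groups) {
    span <- pos[g[length(g)]] - pos[g[1]] + 1
    if (length(g) >= min_cpgs && span >= min_len)
      out <- rbind(out, data.frame(start = pos[g[1]],
                                   end = pos[g[length(g)]] + 1,
                                   n_cpgs = length(g)))
  }
  out
}

# Small genome for fast unit fixtures (any synth_config field may be
# overridden).
tiny_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length_bp = 1e6,
               n_islands = 4, n_genes = 8, n_lmrs = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

# Random per-CpG call frame on one chromosome.
random_calls <- function(pos, frac, chrom = "chr1", total = 50L) {
  data.frame(chrom = rep_len(chrom, length(pos)), start = pos,
             end = pos + 1L, meth = round(frac * total),
             total = rep_len(total, length(pos)), fraction = frac)
}
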
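# Negative-binomial bound-region calling.
#
# Re-implements the minimal count-based testing machinery needed to call
# tiles significantly enriched in an IP library over input: median-of-ratios
# size factors, a per-tile NB Wald test on the log fold change with a
# moment-based dispersion shrunk toward a mean-dispersion trend,
# Benjamini-Hochberg adjustment, and the threshold FC > 1 with adjusted
# p < 0.002. Calls from several tracks are intersected into a Venn
# partition so that exclusively bound tiles can be extracted per track.

#' Median-of-ratios size factors
#'
#' For each library j, `s_j = median_i(k_ij / g_i)` where `g_i` is the
#' geometric mean of tile i across libraries and the median runs over tiles
#' with no zero count. When no tile has all-positive counts the function
#' falls back to total-count ratios (normalized to geometric mean 1) with a
#' warning.
#'
#' @param counts Matrix of raw counts, tiles x libraries.
#' @return Positive numeric vector of per-library scale factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("size factors need >= 2 libraries", call. = FALSE)
  logg <- rowMeans(log(counts))
  ok <- is.finite(logg)
  if (!any(ok)) {
    warning("no tile with all-positive counts; using total-count ratios")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts, 2, function(k) exp(stats::median(log(k[ok]) - logg[ok])))
}

# Piecewise-linear mean-dispersion trend from per-tile moment estimates.
# The sample variance of n normalized counts is Var * chisq_{n-1}/(n-1),
# so each tile's estimate is first divided by the median of that scaled
# chi-square (bias correction), then summarized per mean-expression bin by
# the median. The median makes the trend robust to the minority of truly
# differential tiles, whose blind cross-group variance is inflated by the
# group difference.
.dispersion_trend <- function(mu, v, df, inv_s, floor = 1e-8) {
  qfac <- stats::qchisq(0.5, df) / df
  a_tilde <- (v / qfac - mu * inv_s) / mu^2
  ok <- is.finite(mu) & mu > 0 & is.finite(a_tilde)
  if (sum(ok) < 10L) {
    a <- max(stats::median(a_tilde[ok]), floor)
    return(function(m) rep(a, length(m)))
  }
  lmu <- log(mu[ok])
  nb <- max(1L, min(20L, floor(sum(ok) / 50)))
  br <- unique(stats::quantile(lmu, probs = seq(0, 1, length.out = nb + 1)))
  bin <- findInterval(lmu, br, rightmost.closed = TRUE, all.inside = TRUE)
  bx <- tapply(lmu, bin, mean)
  by <- pmax(tapply(a_tilde[ok], bin, stats::median), floor)
  if (length(bx) == 1L) return(function(m) rep(by[[1]], length(m)))
  function(m) {
    y <- stats::approx(bx, by, xout = log(pmax(m, 1e-8)), rule = 2)$y
    pmax(y, floor)
  }
}

#' Per-tile negative-binomial Wald test of IP versus input
#'
#' Counts are normalized by size factors and pooled within condition by the
#' mean. Tiles with zero counts in every library are excluded up front
#' (`tested = FALSE`, `NA` statistics). The per-tile dispersion is a
#' method-of-moments estimate computed across all libraries, shrunk toward
#' a mean-dispersion trend; with few libraries the trend value is used
#' outright. The reported p-value is a two-sided Wald test on the log fold
#' change with a delta-method standard error under the NB variance
#' `mu + alpha * mu^2`.
#'
#' @param ip_counts,input_counts Vectors or tiles-x-replicates matrices of
#'   raw counts on a common frame.
#' @param sf Size factors for `cbind(ip, input)`; estimated by
#'   [size_factors()] when `NULL` (all-ones for single-library pairs whose
#'   totals are equal in expectation after normalization).
#' @param dispersion Optional fixed dispersion overriding estimation.
#' @param dispersion_floor Lower bound applied when the moment estimate is
#'   degenerate (variance below the mean).
#' @return data.frame with `baseMean`, `fold_change`, `log2fc`,
#'   `dispersion`, `stat`, `pvalue`, `tested`.
#' @export
nb_test <- function(ip_counts, input_counts, sf = NULL, dispersion = NULL,
                    dispersion_floor = 1e-8) {
  ip <- as.matrix(ip_counts)
  input <- as.matrix(input_counts)
  if (nrow(ip) != nrow(input))
    stop("ip and input must be on the same tile frame", call. = FALSE)
  k <- cbind(ip, input)
  n_ip <- ncol(ip); n_in <- ncol(input)
  if (is.null(sf)) {
    sf <- tryCatch(suppressWarnings(size_factors(k)),
                   error = function(e) rep(1, ncol(k)))
  }
  if (length(sf) != ncol(k) || any(sf <= 0))
    stop("need one positive size factor per library", call. = FALSE)
  tested <- rowSums(k) > 0          # drop all-zero windows up front
  q <- sweep(k, 2, sf, "/")
  mu_ip <- rowMeans(q[, seq_len(n_ip), drop = FALSE])
  mu_in <- rowMeans(q[, n_ip + seq_len(n_in), drop = FALSE])
  base_mean <- rowMeans(q)

  if (is.null(dispersion)) {
    # blind moment estimate across all libraries (with 1 vs 1 libraries
    # there are no within-group df, so the trend value is used outright)
    v <- row_vars(q)
    inv_s <- mean(1 / sf)
    disp_raw <- (v - base_mean * inv_s) / base_mean^2
    trend <- .dispersion_trend(base_mean[tested], v[tested],
                               df = ncol(k) - 1L, inv_s = inv_s,
                               floor = dispersion_floor)
    df_res <- ncol(k) - 2L
    w <- if (df_res >= 6L) 0.5 else 1   # shrinkage weight toward the trend
    alpha_t <- trend(base_mean)
    alpha <- exp(w * log(alpha_t) +
                 (1 - w) * log(pmax(disp_raw, dispersion_floor)))
    degen <- disp_raw < 0
    if (any(degen & tested))
      message("nb_test: ", sum(degen & tested),
              " tiles with variance < mean; dispersion floored/trended")
  } else {
    alpha <- rep(max(dispersion, dispersion_floor), nrow(k))
  }
  alpha <- pmax(alpha, dispersion_floor)

  # delta-method variance of log(group mean) under Var(K) = mu + a mu^2,
  # evaluated at the (floored) group means
  m_ip <- pmax(mu_ip, 0.5)
  m_in <- pmax(mu_in, 0.5)
  s_ip <- sf[seq_len(n_ip)]
  s_in <- sf[n_ip + seq_len(n_in)]
  var_ip <- (m_ip * sum(1 / s_ip) + alpha * m_ip^2 * n_ip) / n_ip^2
  var_in <- (m_in * sum(1 / s_in) + alpha * m_in^2 * n_in) / n_in^2
  se <- sqrt(var_ip / m_ip^2 + var_in / m_in^2)
  lfc <- log(m_ip) - log(m_in)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- data.frame(baseMean = base_mean,
                    fold_change = mu_ip / mu_in,
                    log2fc = lfc / log(2),
                    dispersion = alpha,
                    stat = stat,
                    pvalue = p,
                    tested = tested)
  out[!tested, c("baseMean", "fold_change", "log2fc", "dispersion",
                 "stat", "pvalue")] <- NA
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p Vector of p-values in (0, 1]; `NA`s are propagated.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Call bound tiles per track and partition the calls
#'
#' A tile is called bound when `fold_change > fold_min` and its adjusted
#' p-value is below `padj_max`. The called sets of all tracks are
#' intersected into the full Venn partition (one cell per non-empty
#' subset signature) and exclusive per-track sets are extracted.
#'
#' @param results Named list of [nb_test()] result frames on one tile
#'   frame (adjusted p-values are computed over each track's tested tiles).
#' @param fold_min Fold-change threshold on the natural scale (default 1).
#' @param padj_max Adjusted-p threshold (default 0.002).
#' @return List with `called` (per-track tile indices), `partition` (tile
#'   indices per subset signature such as `"A+B"`), `exclusive` (per-track
#'   exclusively called indices) and `thresholds`.
#' @export
call_and_partition <- function(results, fold_min = 1, padj_max = 0.002) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list", call. = FALSE)
  called <- lapply(results, function(r) {
    padj <- rep(NA_real_, nrow(r))
    padj[r$tested] <- bh_adjust(r$pvalue[r$tested])
    which(r$tested & r$fold_change > fold_min & padj < padj_max)
  })
  tracks <- names(results)
  all_tiles <- sort(unique(unlist(called)))
  sig <- vapply(all_tiles, function(t) {
    paste(tracks[vapply(called, function(s) t %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  partition <- split(all_tiles, sig)
  exclusive <- lapply(tracks, function(tr) partition[[tr]] %||% integer(0))
  names(exclusive) <- tracks
  list(called = called, partition = partition, exclusive = exclusive,
       thresholds = c(fold_min = fold_min, padj_max = padj_max))
}
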
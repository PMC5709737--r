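write_call_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

test_that("call loading applies strict coverage and SNP filters", {
  df <- data.frame(chrom = "chr1", start = c(10, 20, 30, 40, 50, 60),
                   end = c(11, 21, 31, 41, 51, 61),
                   meth = c(5, 8, 0, 9, 2, 11),
                   total = c(10, 16, 4, 12, 15, 21),
                   percent = 0)
  # WGBS: total 10 and 4 dropped (strictly more than ten), one SNP-masked
  snp <- data.frame(chrom = "chr1", start = 40, end = 41)
  calls <- suppressMessages(
    load_calls(write_call_file(df), "WGBS", snp_mask = snp))
  expect_equal(calls$start, c(20, 50, 60))
  expect_equal(attr(calls, "dropped"), c(coverage = 2, snp = 1))

  # RRBS boundary: total 21 kept, everything else under 20 dropped
  calls_r <- suppressMessages(load_calls(write_call_file(df), "RRBS"))
  expect_equal(calls_r$start, 60)
  expect_equal(calls_r$fraction, 11 / 21)

  # malformed input errors carry the line number
  p <- write_call_file(df)
  cat("chr1\t70\t71\tbad\t30\n", file = p, append = TRUE)
  expect_error(load_calls(p), "line 7")
  df_bad <- df; df_bad$meth[2] <- 99
  expect_error(load_calls(write_call_file(df_bad)), "line 2")
})

test_that("region methylation and CpG density follow their formulas", {
  calls <- random_calls(c(100, 200, 300), c(0.75, 0, 1))
  one <- data.frame(chrom = "chr1", start = 0, end = 1000)
  # single CpG 3/4 -> 75%
  expect_equal(region_methylation(one, calls[1, ]), 75)
  # 100% and 0% average to 50%
  expect_equal(region_methylation(one, calls[2:3, ]), 50)
  # (0.2, 0.4, 0.9) -> 50%
  calls2 <- random_calls(c(10, 20, 30), c(0.2, 0.4, 0.9))
  expect_equal(region_methylation(one, calls2), 50)
  # no retained CpG -> missing, not zero
  empty <- data.frame(chrom = "chr1", start = 5000, end = 6000)
  expect_true(is.na(region_methylation(empty, calls)))

  # densities: 5 CpGs / 1000 bp = 0.5; none = 0; 13 / 650 = 2
  c5 <- random_calls(seq(0, 800, length.out = 5), rep(1, 5))
  expect_equal(cpg_density(one, c5), 0.5)
  expect_equal(cpg_density(empty, c5), 0)
  c13 <- random_calls(seq(1000, 1640, length.out = 13), rep(1, 13))
  r650 <- data.frame(chrom = "chr1", start = 1000, end = 1650)
  expect_equal(cpg_density(r650, c13), 2)

  # scale-free: doubling all read counts changes nothing
  cd <- random_calls(c(100, 200, 300), c(0.2, 0.5, 0.8), total = 40L)
  cd2 <- cd; cd2$meth <- cd$meth * 2; cd2$total <- cd$total * 2
  cd2$fraction <- cd2$meth / cd2$total
  expect_equal(region_methylation(one, cd), region_methylation(one, cd2))
})

test_that("segmentation handles the all-low and all-high boundary cases", {
  pos <- cumsum(rep(50, 40))
  low <- random_calls(pos, rep(0, 40))
  s1 <- segment_methylome(low)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$class, "UMR")
  expect_equal(s1$n_cpgs, 40)
  expect_equal(c(s1$start, s1$end), c(pos[1], pos[40] + 1))

  high <- random_calls(pos, rep(0.9, 40))
  s2 <- segment_methylome(high)
  expect_equal(s2$class, "FMR")
  expect_equal(s2$n_cpgs, 40)

  # partition invariant: every CpG in exactly one segment
  set.seed(5)
  mixed <- random_calls(cumsum(sample(20:200, 200, TRUE)), runif(200))
  s3 <- segment_methylome(mixed, umr_min_cpgs = 10, max_gap = 10000)
  expect_equal(sum(s3$n_cpgs), 200)
  expect_true(all(s3$start[-1] > s3$end[-nrow(s3)] - 1))
})

test_that("segmentation equals the brute-force run-enumeration oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- 60
    pos <- cumsum(sample(c(10:150, 600, 900), n, TRUE))
    frac <- runif(n)
    calls <- random_calls(pos, frac)
    got <- segment_methylome(calls, smooth_k = 3, low_cut = 0.5,
                             umr_min_cpgs = 8, run_min_cpgs = 4,
                             max_gap = 500)
    want <- oracle_segment(pos, frac, smooth_k = 3, low_cut = 0.5,
                           umr_min = 8, run_min = 4, max_gap = 500)
    expect_equal(got[, c("class", "start", "end", "n_cpgs")], want,
                 ignore_attr = TRUE)
  }
})

test_that("profile distance/length filters drop crowded segments", {
  segs <- data.frame(
    chrom = "chr1",
    start = c(0, 30000, 35000, 60000, 100000, 120000),
    end = c(20000, 31000, 36000, 61000, 113000, 121000),
    class = c("FMR", "UMR", "UMR", "LMR", "FMR", "UMR"))
  segs$length <- segs$end - segs$start
  f <- filter_segments_for_profiles(segs)
  # the two UMRs 4 kb apart are both dropped; the LMR 24 kb away stays;
  # the 20-kb FMR stays, the 13-kb FMR stays, the isolated UMR stays
  expect_equal(f$start, c(0, 60000, 100000, 120000))

  # two UMRs 5 kb apart -> both dropped; 10 kb apart -> both kept
  s2 <- data.frame(chrom = "chr1", start = c(0, 6000), end = c(1000, 7000),
                   class = "UMR")
  s2$length <- 1000
  expect_equal(nrow(filter_segments_for_profiles(s2)), 0)
  s3 <- s2; s3$start[2] <- 11000; s3$end[2] <- 12000
  expect_equal(nrow(filter_segments_for_profiles(s3)), 2)
})

test_that("FMR density bins are equal-size with deterministic ties", {
  calls <- random_calls(seq(0, 20000, by = 97),
                        rep(0.9, length(seq(0, 20000, by = 97))))
  mk <- function(n) data.frame(chrom = "chr1",
                               start = seq(0, by = 2000, length.out = n),
                               end = seq(0, by = 2000, length.out = n) +
                                 seq(200, by = 150, length.out = n))
  b9 <- fmr_density_bins(mk(9), calls)
  expect_equal(as.integer(table(b9)), c(3, 3, 3))
  b10 <- fmr_density_bins(mk(10), calls)
  expect_equal(as.integer(table(b10)), c(4, 3, 3))

  # equal densities -> assignment by genomic order
  same <- data.frame(chrom = "chr1", start = c(0, 3000, 6000),
                     end = c(1000, 4000, 7000))
  empty_calls <- random_calls(integer(0), numeric(0))
  expect_equal(fmr_density_bins(same, empty_calls), c(1, 2, 3))
  expect_error(fmr_density_bins(same, empty_calls, n_bins = 5), "fewer")
})

test_that("UMR borders come from flanking FMRs with strand-aware labels", {
  genes <- data.frame(chrom = "chr1", start = 7000, end = 17000,
                      name = "g1", strand = "+")
  umrs <- data.frame(chrom = "chr1", start = 7000, end = 9000)
  fmrs <- data.frame(chrom = "chr1", start = c(0, 11000),
                     end = c(5000, 20000))
  b <- umr_borders(umrs, fmrs, genes)
  expect_equal(sort(b$pos), c(5000, 11000))
  expect_equal(b$side[b$pos == 5000], "5p")
  expect_equal(b$side[b$pos == 11000], "3p")

  # minus-strand gene swaps the labels
  genes$strand <- "-"
  genes$start <- 0; genes$end <- 8000    # TSS at 8000, inside the UMR
  b2 <- umr_borders(umrs, fmrs, genes)
  expect_equal(b2$side[b2$pos == 5000], "3p")
  expect_equal(b2$side[b2$pos == 11000], "5p")

  # missing flank: only one border, logged
  g_plus <- data.frame(chrom = "chr1", start = 7000, end = 17000,
                       name = "g1", strand = "+")
  expect_message(
    b3 <- umr_borders(umrs, fmrs[2, , drop = FALSE], g_plus),
    "missing")
  expect_equal(nrow(b3), 1)
  expect_equal(b3$pos, 11000)
})
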
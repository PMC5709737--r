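test_that("anchored profiles bin, flip and normalize correctly", {
  # single read 10 bp downstream of the anchor lands in the first
  # downstream bin; a minus-strand anchor sees it mirrored
  reads <- data.frame(chrom = "chr1", start = 1010, end = 1011)
  a_plus <- data.frame(chrom = "chr1", pos = 1000, strand = "+")
  a_minus <- data.frame(chrom = "chr1", pos = 1000, strand = "-")
  p1 <- anchor_profile(reads, a_plus, 300, 100, library_size = 1e7)
  expect_equal(p1$matrix[1, ], c(0, 0, 0, 1, 0, 0))
  p2 <- anchor_profile(reads, a_minus, 300, 100, library_size = 1e7)
  expect_equal(p2$matrix[1, ], c(0, 0, 1, 0, 0, 0))

  # spatially constant track -> flat column means
  dense <- data.frame(chrom = "chr1", start = 0:9999, end = 1:10000)
  anchors <- data.frame(chrom = "chr1", pos = c(3000, 5000, 7000),
                        strand = c("+", "-", "+"))
  pf <- anchor_profile(dense, anchors, 1000, 200, library_size = 1e7)
  expect_true(all(profile_means(pf) == 200))

  # off-chromosome windows become NA rows excluded from means
  a_edge <- data.frame(chrom = "chr1", pos = c(100, 5000), strand = "+")
  pe <- anchor_profile(dense, a_edge, 1000, 200, library_size = 1e7,
                       chrom_sizes = c(chr1 = 10000))
  expect_true(all(is.na(pe$matrix[1, ])))
  expect_equal(profile_means(pe), rep(200, 10))

  # library normalization cancels a global depth rescaling: the same
  # track at half depth gives identical normalized profiles
  pf_def <- anchor_profile(dense, anchors, 1000, 200)
  half <- dense[seq(1, 10000, by = 2), ]
  ph <- anchor_profile(half, anchors, 1000, 200)
  expect_equal(profile_means(ph), profile_means(pf_def))
})

test_that("mirroring the genome and flipping strands preserves profiles", {
  set.seed(3)
  L <- 20000
  reads <- data.frame(chrom = "chr1", start = sample(0:(L - 1), 500))
  reads$end <- reads$start + 1
  anchors <- data.frame(chrom = "chr1", pos = c(5000, 9000, 15000),
                        strand = c("+", "-", "+"))
  p <- anchor_profile(reads, anchors, 2000, 500)
  mirror <- data.frame(chrom = "chr1", start = L - 1 - reads$start)
  mirror$end <- mirror$start + 1
  m_anchors <- data.frame(chrom = "chr1", pos = L - anchors$pos,
                          strand = ifelse(anchors$strand == "+", "-", "+"))
  pm <- anchor_profile(mirror, m_anchors, 2000, 500)
  expect_equal(profile_means(pm), profile_means(p))
})

test_that("gene-scaled profiles are flat for constant tracks and oriented", {
  genes <- data.frame(chrom = "chr1", start = c(10000, 40000),
                      end = c(20000, 44000), strand = c("+", "-"))
  dense <- data.frame(chrom = "chr1", start = 0:59999)
  dense$end <- dense$start + 1
  p <- scaled_gene_profile(dense, genes, n_body_bins = 10,
                           flank_bp = 2000, bin_bp = 200)
  expect_equal(max(p$matrix) / min(p$matrix), 1, tolerance = 1e-12)

  # track present only inside gene bodies: flanks ~0, body > 0
  body_reads <- data.frame(chrom = "chr1",
                           start = c(10000:19999, 40000:43999))
  body_reads$end <- body_reads$start + 1
  pb <- scaled_gene_profile(body_reads, genes, n_body_bins = 10,
                            flank_bp = 2000, bin_bp = 200)
  cm <- profile_means(pb)
  expect_true(all(cm[pb$section == "body"] > 0))
  expect_true(all(cm[pb$section != "body"] == 0))

  # overlapping genes and sub-bin genes are dropped
  g2 <- rbind(genes, data.frame(chrom = "chr1", start = c(15000, 50000),
                                end = c(25000, 50005),
                                strand = c("+", "+")))
  expect_message(p2 <- scaled_gene_profile(dense, g2, n_body_bins = 10,
                                           flank_bp = 2000, bin_bp = 200),
                 "overlapping")
  expect_equal(nrow(p2$anchors), 1)
})

test_that("profile clustering recovers separable archetypes", {
  set.seed(8)
  # two well-separated archetypes, k = 2 -> perfect recovery
  a <- matrix(rpois(200, 5), 20, 10)
  b <- matrix(rpois(200, 200), 20, 10)
  prof <- structure(list(matrix = rbind(a, b)), class = "profile_matrix")
  cl <- cluster_umrs(prof, k = 2, seed = 1)
  truth <- rep(1:2, each = 20)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)

  # k = 1: centroid equals the column means of the transformed matrix
  cl1 <- cluster_umrs(prof, k = 1, seed = 1)
  expect_equal(as.numeric(cl1$centers),
               colMeans(log2(rbind(a, b) + 8)))

  # labels are reproducible under a fixed seed
  cl_again <- cluster_umrs(prof, k = 2, seed = 1)
  expect_identical(cl$labels, cl_again$labels)
  expect_error(cluster_umrs(prof, k = 50, seed = 1), "fewer")
})

test_that("differential binding is zero at identity and antisymmetric", {
  set.seed(9)
  x <- rpois(500, 60)
  expect_true(all(differential_binding(x, x) == 0))

  y <- rpois(500, 80)
  expect_equal(differential_binding(x, y), -differential_binding(y, x))

  # doubled counts with equal library sizes approach +1 for large counts
  big <- rep(5000, 10)
  fc <- differential_binding(big, big * 2, a_lib = 1e6, b_lib = 1e6)
  expect_equal(fc, rep(1, 10), tolerance = 2e-3)

  # restriction masks tiles outside the subset
  r <- differential_binding(x, y, restrict = c(TRUE, rep(FALSE, 499)))
  expect_true(is.na(r[2]) && !is.na(r[1]))
})

test_that("ranked-window medians follow the block rule", {
  # constant values -> every block median is that constant; a trailing
  # 200-tile remainder (< half a block) merges into the previous block
  rm1 <- ranked_window_medians(rep(3.5, 1700), runif(1700), block = 500)
  expect_equal(rm1$median_value, rep(3.5, 3))
  expect_equal(rm1$n, c(500, 500, 700))

  # monotone case: values = rank key -> strictly increasing medians
  v <- sample(1500)
  rm2 <- ranked_window_medians(v, v, block = 500)
  expect_equal(rm2$n, rep(500, 3))
  expect_true(all(diff(rm2$median_value) > 0))
  expect_true(all(diff(rm2$mean_rank) > 0))

  # brute force on 1000 hand-set tiles: a retained short block (>= 250)
  set.seed(17)
  vals <- rnorm(1250); key <- runif(1250)
  rm3 <- ranked_window_medians(vals, key, block = 500)
  o <- order(key)
  expect_equal(rm3$n, c(500, 500, 250))
  expect_equal(rm3$median_value[1], median(vals[o][1:500]))
  expect_equal(rm3$median_value[3], median(vals[o][1001:1250]))

  expect_error(ranked_window_medians(rnorm(100), runif(100), block = 500),
               "at least")
})

test_that("promoter-class enrichment equals exact hypergeometric tails", {
  # documented example: universe 20, up 5, class of 6 with 4 up
  up <- paste0("u", 1:5)
  uni <- c(up, paste0("g", 1:15))
  cls <- list(hot = c(up[1:4], "g1", "g2"))
  res <- promoter_class_enrichment(up, cls, uni)
  expect_equal(res$fraction, 4 / 6)
  expect_equal(res$p_value, oracle_hyper_tail(4, 5, 20, 6),
               tolerance = 1e-12)

  # class identical to the up set: fraction 1, minimal p
  res2 <- promoter_class_enrichment(up, list(all_up = up, none = "g1"), uni)
  expect_equal(res2$fraction, c(1, 0))
  expect_equal(res2$p_value[1], oracle_hyper_tail(5, 5, 20, 5),
               tolerance = 1e-12)
  expect_true(res2$significant[1])

  # class matching the global rate is unremarkable
  uni3 <- paste0("g", 1:200)
  up3 <- uni3[1:40]                       # 20% global rate
  cls3 <- list(avg = c(uni3[1:4], uni3[50:65]))   # 4/20 up
  res3 <- promoter_class_enrichment(up3, cls3, uni3)
  expect_gt(res3$p_value, 0.3)
  expect_false(res3$significant)

  expect_warning(promoter_class_enrichment(up, list(none = character(0),
                                                    ok = up), uni),
                 "empty")
  expect_error(promoter_class_enrichment("zz", list(a = "zz"), uni),
               "subset")
})
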
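test_that("truth generation is deterministic and counts labels exactly", {
  cfg <- tiny_config(seed = 4)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)

  # exact bivalent count from the configured fraction
  cfg20 <- synth_config(seed = 2, n_islands = 20, bivalent_fraction = 0.5,
                        n_genes = 30)
  t20 <- generate_truth(cfg20)
  expect_equal(sum(t20$islands$class == "bivalent"), 10)
  expect_equal(nrow(t20$islands), 20)

  # empty case: no islands, background-only methylome
  cfg0 <- tiny_config(n_islands = 0, n_lmrs = 0)
  t0 <- generate_truth(cfg0)
  expect_equal(nrow(t0$islands), 0)
  expect_true(all(t0$cpgs$true_fraction ==
                  cfg0$meth_levels[["FMR"]]))
})

test_that("planted structure is internally consistent", {
  truth <- generate_truth(tiny_config(seed = 9))
  cfg <- truth$config
  # every bivalent island has exactly two shore intervals, disjoint from
  # the island, forming a contiguous shore+island+shore block
  for (i in seq_len(nrow(truth$islands))) {
    sh <- truth$shores[truth$shores$island == i, ]
    expect_equal(nrow(sh), 2)
    expect_equal(sh$end[1], truth$islands$start[i])
    expect_equal(sh$start[2], truth$islands$end[i])
  }
  # islands are non-overlapping and separated by > 2 shore widths
  isl <- truth$islands[order(truth$islands$chrom, truth$islands$start), ]
  same <- isl$chrom[-1] == isl$chrom[-nrow(isl)]
  gaps <- (isl$start[-1] - isl$end[-nrow(isl)])[same]
  expect_true(all(gaps > 2 * cfg$shore_width_bp))
  # every planted UMR lies inside an island and contains no FMR CpG
  expect_equal(truth$umrs$start, truth$islands$start)
  in_umr <- rep(FALSE, nrow(truth$cpgs))
  for (i in seq_len(nrow(truth$umrs)))
    in_umr <- in_umr | (truth$cpgs$chrom == truth$umrs$chrom[i] &
                        truth$cpgs$start >= truth$umrs$start[i] &
                        truth$cpgs$start < truth$umrs$end[i])
  expect_true(all(truth$cpgs$true_fraction[in_umr] ==
                  cfg$meth_levels[["UMR"]]))
  # CpGs are denser inside islands than outside
  isl_len <- sum(truth$islands$end - truth$islands$start)
  bg_len <- sum(truth$chrom_sizes) - isl_len
  expect_gt((sum(in_umr) / isl_len) / (sum(!in_umr) / bg_len), 4)
})

test_that("ChIP counts have the configured NB moments", {
  cfg <- synth_config(seed = 6, fold_map = list(input = c()),
                      chip_replicates = c())
  truth <- generate_truth(cfg)
  # fold 1 everywhere: mean within 3 SE of the configured depth
  x <- simulate_chip(truth, cfg, "input")$count
  n <- length(x)
  expect_gte(n, 10000)
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - cfg$mean_tile_depth), 3 * se)
  # variance reflects the dispersion: var = mu + a mu^2
  expect_equal(var(x),
               cfg$mean_tile_depth + cfg$nb_dispersion * cfg$mean_tile_depth^2,
               tolerance = 0.1)

  # Poisson branch at dispersion zero: variance/mean ratio near 1
  cfg_p <- synth_config(seed = 6, nb_dispersion = 0,
                        fold_map = list(input = c()), chip_replicates = c())
  tp <- generate_truth(cfg_p)
  xp <- simulate_chip(tp, cfg_p, "input")$count
  expect_equal(var(xp) / mean(xp), 1, tolerance = 0.05)

  # fold 8 on bivalent shores at depth 30: shore/background ratio near 8
  cfg8 <- synth_config(seed = 6)
  t8 <- generate_truth(cfg8)
  c8 <- simulate_chip(t8, cfg8, "DNMT3A1")$count
  shore <- t8$tiles$class %in% c("bivalent_shore", "umr_border")
  bg <- t8$tiles$class == "background"
  expect_equal(mean(c8[shore]) / mean(c8[bg]), 8, tolerance = 0.1)

  expect_error(simulate_chip(t8, cfg8, "H3K9me3"), "unknown track")
})

test_that("bisulfite simulation respects boundaries and the mean", {
  cfg <- tiny_config(seed = 5,
                     meth_levels = c(UMR = 0, LMR = 0.25, shore = 1,
                                     FMR = 0.8))
  truth <- generate_truth(cfg)
  calls <- simulate_bisulfite(truth, cfg)
  umr_cpg <- truth$cpgs$true_fraction == 0
  shore_cpg <- truth$cpgs$true_fraction == 1
  expect_true(all(calls$meth[umr_cpg] == 0))
  expect_true(all(calls$meth[shore_cpg] == calls$total[shore_cpg]))

  # pooled fraction at a planted 0.8 level over >= 1000 CpGs
  fmr_cpg <- truth$cpgs$true_fraction == 0.8
  expect_gte(sum(fmr_cpg), 1000)
  pooled <- sum(calls$meth[fmr_cpg]) / sum(calls$total[fmr_cpg])
  expect_equal(pooled, 0.8, tolerance = 0.02)
})

test_that("substreams isolate tracks and fixtures round-trip exactly", {
  cfg <- tiny_config(seed = 12)
  sim1 <- simulate_dataset(cfg)
  # adding/removing a track does not perturb another track's stream
  truth <- sim1$truth
  expect_identical(simulate_chip(truth, cfg, "DNMT3B")$count,
                   sim1$tracks$DNMT3B$count)
  # replicates draw from distinct substreams
  expect_false(identical(sim1$tracks$DNMT3A1$count,
                         sim1$tracks$DNMT3A1.2$count))

  outdir <- file.path(tempdir(), "fixture_rt")
  unlink(outdir, recursive = TRUE)
  write_fixture(truth, sim1$tracks, sim1$calls, outdir)

  # BED validity: 0-based half-open with start < end
  for (f in c("islands.bed", "genes.bed", "umrs.bed", "shores.bed")) {
    b <- read_bed(file.path(outdir, f))
    expect_true(all(b$start < b$end))
    expect_true(all(b$start >= 0))
  }
  isl <- read_bed(file.path(outdir, "islands.bed"))
  expect_equal(isl$start, truth$islands$start)
  expect_equal(isl$end, truth$islands$end)

  # count tables and per-CpG calls reproduce in-memory values exactly
  ct <- read_counts(file.path(outdir, "counts_DNMT3A1.tsv"))
  expect_identical(ct$count, sim1$tracks$DNMT3A1$count)
  raw <- read.table(file.path(outdir, "cpg_calls.tsv"), sep = "\t")
  expect_identical(as.integer(raw$V4), sim1$calls$meth)
  expect_identical(as.integer(raw$V5), sim1$calls$total)
  expect_equal(raw$V6, sim1$calls$percent, tolerance = 0)

  # manifest records the generating seed
  man <- read.table(file.path(outdir, "manifest.tsv"), sep = "\t",
                    header = TRUE)
  expect_equal(as.integer(man$value[man$key == "seed"]), cfg$seed)

  # identical config -> byte-identical fixture set
  outdir2 <- file.path(tempdir(), "fixture_rt2")
  unlink(outdir2, recursive = TRUE)
  sim2 <- simulate_dataset(cfg)
  write_fixture(sim2$truth, sim2$tracks, sim2$calls, outdir2)
  for (f in list.files(outdir)) {
    expect_identical(unname(tools::md5sum(file.path(outdir, f))),
                     unname(tools::md5sum(file.path(outdir2, f))),
                     label = f)
  }
})
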
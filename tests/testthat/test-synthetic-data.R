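test_that("config validation: mandatory seed, genome bounds, degenerate inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(1, chromosomes = data.frame(name = character(),
                                                      length = numeric())),
               "at least one chromosome")
  expect_error(sim_config(1, sv = list(hotspot = data.frame(
    chrom = "chr1", start = 59e6, end = 61e6, excess = 10))), "bounds")
  expect_error(sim_config(1, te = list(families = data.frame(
    name = "f", class = "LTR", consensus_len = 300, divergence = 0.8))),
    "0.75")
  expect_error(sim_config(1, pirna = list(clusters = data.frame(
    chrom = "chr1", start = 0, end = 1000, depth = 0,
    strand_bias = 0.5, pingpong_fraction = 0.5))), "depth 0")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 99)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(g1$classes$class, c("macro", "intermediate", "micro"))
  sv1 <- simulate_sv_calls(cfg, g1$sizes)
  sv2 <- simulate_sv_calls(cfg, g1$sizes)
  expect_identical(sv1, sv2)
  r1 <- simulate_smallrna_reads(cfg, g1$sizes)
  r2 <- simulate_smallrna_reads(cfg, g1$sizes)
  expect_identical(r1, r2)
  t1 <- simulate_te_insertions(cfg)
  t2 <- simulate_te_insertions(cfg)
  expect_identical(t1, t2)
  # and a different seed moves the outputs
  other <- simulate_sv_calls(sim_config(seed = 100), g1$sizes)
  expect_false(identical(sv1$A$start, other$A$start))
  # byte-identical FASTA emission
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_te_simulation(t1, d1); p2 <- write_te_simulation(t2, d2)
  expect_identical(readLines(p1[["insertions"]]),
                   readLines(p2[["insertions"]]))
})

test_that("planted hotspot receives the closed-form share of SV midpoints", {
  # excess 10x over 100 kb of a 10 Mb chromosome: per-event hotspot
  # probability = m*w / (L - w + m*w) = 1e6 / 10.9e6
  cfg <- sim_config(seed = 7,
                    chromosomes = data.frame(name = "chr1", length = 10e6),
                    sv = list(n_per_type = c(INS = 0, DEL = 2000, INV = 0,
                                             DUP = 0),
                              hotspot = data.frame(chrom = "chr1",
                                                   start = 5e6, end = 5.1e6,
                                                   excess = 10)),
                    pirna = list(clusters = data.frame(
                      chrom = "chr1", start = 2e6, end = 2.01e6, depth = 0.01,
                      strand_bias = 0.5, pingpong_fraction = 0,
                      stringsAsFactors = FALSE)))
  sv <- simulate_sv_calls(cfg, chrom_sizes("chr1", 10e6))
  mids <- sv_midpoint(sv$A)
  n_in <- sum(mids >= 5e6 & mids < 5.1e6)
  p_expected <- 10 * 1e5 / (10e6 - 1e5 + 10 * 1e5)
  # binomial mean +- 4 sd
  tol <- 4 * sqrt(2000 * p_expected * (1 - p_expected))
  expect_lt(abs(n_in - 2000 * p_expected), tol)
  # excess 1x leaves the distribution uniform: hotspot share ~ w/L
  cfg1 <- sim_config(seed = 8,
                     chromosomes = data.frame(name = "chr1", length = 10e6),
                     sv = list(n_per_type = c(INS = 0, DEL = 2000, INV = 0,
                                              DUP = 0),
                               hotspot = data.frame(chrom = "chr1",
                                                    start = 5e6, end = 5.1e6,
                                                    excess = 1)),
                     pirna = cfg$pirna)
  sv1 <- simulate_sv_calls(cfg1, chrom_sizes("chr1", 10e6))
  mids1 <- sv_midpoint(sv1$A)
  n_in1 <- sum(mids1 >= 5e6 & mids1 < 5.1e6)
  expect_lt(abs(n_in1 - 2000 * 0.01), 4 * sqrt(2000 * 0.01 * 0.99))
})

test_that("both-caller fraction 1 with slop 0 makes consensus lossless", {
  cfg <- sim_config(seed = 12, sv = list(both_caller_fraction = 1, slop = 0))
  g <- simulate_genome(cfg)
  sv <- simulate_sv_calls(cfg, g$sizes)
  cons <- consensus_sv(sv$A, sv$B)
  expect_equal(nrow(cons), nrow(sv$A))
})

test_that("simulated read sets carry the planted structure", {
  cfg <- sim_config(seed = 3,
                    chromosomes = data.frame(name = "chr1", length = 1e6),
                    pirna = list(clusters = data.frame(
                      chrom = "chr1", start = 1e5, end = 1.2e5, depth = 0.05,
                      strand_bias = 0.8, pingpong_fraction = 0,
                      stringsAsFactors = FALSE),
                      background_rate = 0, multimap_fraction = 0.2),
                    sv = list(hotspot = data.frame(chrom = "chr1", start = 0,
                                                   end = 1000, excess = 1)),
                    mirna = list(n_species = 20, total_count = 5000))
  lib <- simulate_smallrna_reads(cfg, chrom_sizes("chr1", 1e6))
  sp <- lib$rna$species
  expect_equal(lib$mirna_total, 5000)
  mir <- sp$length <= 23
  expect_equal(sum(sp$count[mir]), 5000)
  pir <- sp[!mir, ]
  expect_true(all(pir$length >= 24 & pir$length <= 32))
  # strand bias of cluster reads approximates the configured 0.8
  mp <- lib$rna$mappings
  cl_reads <- mp[mp$pos5 >= 1e5 & mp$pos5 < 1.2e5 & mp$id %in% pir$id, ]
  expect_equal(mean(cl_reads$strand == "+"), 0.8, tolerance = 0.06)
  # multimap fraction reflected in n_mappings
  expect_gt(mean(pir$n_mappings > 1), 0.1)
  expect_true(all(pir$unique == (pir$n_mappings == 1)))
})

test_that("TE simulation hits classify 100% correctly against the truth labels", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_te_insertions(cfg)
  calls <- classify_insertions(sim$insertions, filter_hits(sim$hits),
                               reference_solo_ltrs = sim$ref_solo_ltrs)
  merged <- merge(calls, sim$truth, by = "insertion_id")
  expect_equal(merged$status, merged$expected_status)
  # 10 solo + 5 intact + 2 CR1 accepted; 3 decoys rejected
  acc <- c("solo_LTR", "intact_ERV", "nonLTR_transposition")
  expect_equal(sum(merged$status %in% acc), 17)
  expect_equal(sum(!merged$status %in% acc), 3)
})
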
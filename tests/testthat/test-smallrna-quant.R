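test_that("miRNA normalization scales counts linearly and errors on zero", {
  rna <- make_rna("chr1", c(100, 200), c("+", "+"), count = c(10, 4))
  lib <- smallrna_library("a", rna, mirna_total = 2e6)
  out <- normalize_to_mirna(list(lib), scale = 1e6)[[1]]
  expect_equal(out$rna$species$count, c(5, 2))
  expect_equal(out$mirna_total, 1e6)
  # idempotent at factor 1
  again <- normalize_to_mirna(list(out), scale = 1e6)[[1]]
  expect_equal(again$rna$species$count, out$rna$species$count)
  # cross-library ratio identity
  libB <- smallrna_library("b", rna, mirna_total = 5e5)
  nb <- normalize_to_mirna(list(libB), scale = 1e6)[[1]]
  expect_equal(nb$rna$species$count / out$rna$species$count,
               rep(2e6 / 5e5, 2))
  zero <- smallrna_library("z", rna, mirna_total = 0)
  expect_error(normalize_to_mirna(list(zero)), "'z'")
})

test_that("oxidized calibration matches shared piRNA sums and is idempotent", {
  rna_t <- make_rna("chr1", c(100, 200, 300), "+", count = c(120, 80, 10))
  rna_o <- rna_t
  rna_o$species$count <- c(60, 40, 999)     # shared species halved
  rna_o$species$seq[3] <- strrep("G", 26)   # third species not shared
  tot <- smallrna_library("total", rna_t, 1e6)
  oxi <- smallrna_library("ox", rna_o, 1e6, is_oxidized = TRUE)
  cal <- calibrate_oxidized(oxi, tot)
  expect_equal(attr(cal, "calibration_factor"), 2)
  expect_equal(cal$rna$species$count[1:2], c(120, 80))
  # second pass: shared sums now equal, f = 1
  cal2 <- calibrate_oxidized(cal, tot)
  expect_equal(attr(cal2, "calibration_factor"), 1)
  # identical libraries: f = 1
  expect_equal(attr(calibrate_oxidized(tot, tot), "calibration_factor"), 1)
  # disjoint species sets error
  rna_d <- make_rna("chr1", 1, "+", count = 5)
  rna_d$species$seq <- strrep("T", 26)
  expect_error(calibrate_oxidized(smallrna_library("d", rna_d, 1), tot),
               "no shared")
})

test_that("feature abundance: 5' assignment, length filter, fractional multimappers, pseudo-count", {
  sizes <- tiny_sizes()
  feat <- genomic_intervals("chr1", 0, 1000, sizes = sizes)
  # one unique 26-nt species count 10 inside; library total 1e6 via filler
  rna <- make_rna("chr1", c(500, 600, 700), c("+", "-", "+"),
                  count = c(10, 5, 1e6 - 15), len = c(26, 22, 26))
  rna$mappings$chrom[3] <- "chr2"   # filler elsewhere
  lib <- make_library(rna)
  fa <- feature_abundance(lib, feat)
  expect_equal(fa$count, 10)        # 22-nt species contributes 0
  expect_equal(fa$ppm, 10.001)
  expect_equal(fa$rpkm, 10.001)
  expect_equal(fa$watson_count, 10)
  expect_equal(fa$crick_count, 0)

  # multimapper: 2 genome mappings, one inside -> contributes count/2
  rna2 <- make_rna("chr1", 100, "+", count = 10, n_extra_mappings = 1)
  fa2 <- feature_abundance(make_library(rna2), feat)
  expect_equal(fa2$count, 5)

  # 5'-base containment decides membership (boundary cases)
  rna3 <- make_rna("chr1", c(999, 1000), "+", count = c(1, 1))
  fa3 <- feature_abundance(make_library(rna3), feat)
  expect_equal(fa3$count, 1)

  expect_equal(nrow(feature_abundance(lib, feat[0, ])), 0)
})

test_that("fractional apportionment conserves species totals across a partition", {
  sizes <- tiny_sizes()
  rna <- make_rna("chr1", c(100, 5000, 9000), "+", count = c(6, 9, 12),
                  n_extra_mappings = c(1, 2, 0))
  lib <- make_library(rna)
  parts <- genomic_intervals(c("chr1", "chr1", "chr2"), c(0, 5e5, 0),
                             c(5e5, 1e6, 5e5), sizes = sizes)
  fa <- feature_abundance(lib, parts)
  # every mapping of every species is inside the partition, so the summed
  # apportioned counts equal the species totals exactly
  expect_equal(sum(fa$count), 6 / 2 * 2 + 9 / 3 * 3 + 12)
  expect_lte(sum(fa$count), library_total(lib))
})

test_that("Shannon diversity matches closed forms and the vegan oracle", {
  expect_equal(shannon_diversity(5), 0)
  expect_equal(shannon_diversity(rep(7, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(3, 1)), 0.5623351446, tolerance = 1e-9)
  expect_equal(shannon_diversity(c(3, 0, 1)), shannon_diversity(c(3, 1)))
  expect_error(shannon_diversity(c(0, 0)), "zero")
  if (requireNamespace("vegan", quietly = TRUE)) {
    for (v in list(c(3, 1), c(10, 20, 30), runif(20))) {
      expect_equal(shannon_diversity(v), unname(vegan::diversity(v)),
                   tolerance = 1e-10)
    }
  }
})

test_that("strand bias is the Watson fraction", {
  expect_equal(strand_bias(10, 0), 1)
  expect_equal(strand_bias(5, 5), 0.5)
  expect_equal(strand_bias(30, 10), 0.75)
  expect_true(is.na(strand_bias(0, 0)))
})

test_that("Wootton-Federhen complexity: closed forms, invariance, maximality", {
  expect_equal(wf_complexity("AAAA"), 0, tolerance = 1e-12)
  expect_equal(wf_complexity("ACGT"), 0.5731203126, tolerance = 1e-9)
  expect_equal(wf_complexity("AACC"), 0.3231203126, tolerance = 1e-9)
  expect_error(wf_complexity("ACGN"), "non-ACGT")
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(wf_complexity(perm), wf_complexity(s))
    # balanced counts maximal at fixed length
    balanced <- strrep("ACGT", 10)
    expect_lte(wf_complexity(s), wf_complexity(balanced) + 1e-12)
  }
})

test_that("expression variance: degenerate matrix, zero-mean drop, planted recovery", {
  m <- matrix(5, nrow = 12, ncol = 4)
  ev <- expression_variance(m)
  expect_true(all(ev$cv == 0))
  expect_true(all(abs(ev$residual) < 1e-8))

  m2 <- rbind(m, 0)
  expect_warning(ev2 <- expression_variance(m2), "mean 0")
  expect_equal(nrow(ev2), 12)

  expect_error(expression_variance(matrix(1, 5, 5)), ">= 10 features")
  expect_error(expression_variance(matrix(1, 20, 2)), ">= 3 individuals")

  # planted high-variance subset has higher mean residual
  set.seed(11)
  n <- 300; k <- 30
  mu <- exp(rnorm(n, 3, 1))
  noise <- matrix(rnorm(n * 6, 0, 0.1), n)
  noise[1:k, ] <- noise[1:k, ] * 3
  mat <- mu * exp(noise)
  ev3 <- expression_variance(mat)
  expect_gt(mean(ev3$residual[1:k]), mean(ev3$residual[-(1:k)]))
})
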
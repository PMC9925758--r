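mk_hit <- function(id, family, class, q0, q1, s0, s1, clen,
                   pident = 95, evalue = 1e-30, gap = 0.02, orient = "+") {
  te_hits(id, family, class, q0, q1, s0, s1, pident = pident,
          aln_len = q1 - q0, gap_frac = gap, evalue = evalue,
          consensus_len = clen, orientation = orient)
}

test_that("hit filtering applies the e-value cutoff and the 80-80-80 rule", {
  base <- mk_hit("i1", "ERV1_LTR", "LTR", 0, 270, 0, 270, 300)
  expect_equal(nrow(filter_hits(base)), 1)
  # identity at the boundary is excluded (> 80 required)
  expect_equal(nrow(filter_hits(transform(base, pident = 79.9))), 0)
  expect_equal(nrow(filter_hits(transform(base, pident = 80))), 0)
  # alignment shorter than 80% of the consensus
  short <- mk_hit("i1", "ERV1_LTR", "LTR", 0, 150, 0, 150, 300)
  expect_equal(nrow(filter_hits(short)), 0)
  # gaps at or above 20%
  expect_equal(nrow(filter_hits(transform(base, gap_frac = 0.25))), 0)
  # e-value above the cutoff
  expect_equal(nrow(filter_hits(transform(base, evalue = 1e-5))), 0)
  # LINE hits are exempt from the length rule (5' truncation is expected)
  line <- mk_hit("i2", "CR1", "LINE", 0, 500, 4100, 4600, 4600)
  expect_equal(nrow(filter_hits(line)), 1)
})

test_that("classification: solo LTR, intact ERV and the reference solo-LTR veto", {
  # 300-bp insertion fully covered by a complete 300-bp LTR hit
  solo <- mk_hit("s1", "ERV1_LTR", "LTR", 0, 300, 0, 300, 300)
  expect_equal(classify_insertion(300, solo)$status, "solo_LTR")
  # LTR(0-300) + internal(300-5300) + LTR(5300-5600)
  erv <- rbind(mk_hit("e1", "ERV1_LTR", "LTR", 0, 300, 0, 300, 300),
               mk_hit("e1", "ERV1_I", "LTR_internal", 300, 5300, 0, 5000, 5000),
               mk_hit("e1", "ERV1_LTR", "LTR", 5300, 5600, 0, 300, 300))
  site <- data.frame(chrom = "chr1", start = 1000, end = 1001)
  expect_equal(classify_insertion(5600, erv, site)$status, "intact_ERV")
  # same structure sitting on an annotated reference solo LTR: rejected
  refsolo <- genomic_intervals("chr1", 900, 1100)
  expect_equal(classify_insertion(5600, erv, site, refsolo)$status,
               "rejected_reference_soloLTR")
  # incomplete LTR ends (alignment stops 50 bp short of the consensus end)
  trunc <- rbind(mk_hit("t1", "ERV1_LTR", "LTR", 0, 250, 0, 250, 300),
                 mk_hit("t1", "ERV1_LTR", "LTR", 250, 500, 50, 300, 300))
  expect_equal(classify_insertion(500, trunc)$status,
               "rejected_incomplete_ends")
})

test_that("classification: LINE 3'-anchoring, decoys, boundedness, ambiguity", {
  # valid CR1: 3' consensus end at the insertion terminus, 5' truncated
  cr1 <- mk_hit("c1", "CR1_F2", "LINE", 0, 1500, 3100, 4600, 4600)
  expect_equal(classify_insertion(1500, cr1)$status, "nonLTR_transposition")
  # 3' end lands 500 bp before both insertion ends: ancestral deletion decoy
  mid <- rbind(mk_hit("c2", "CR1_F2", "LINE", 0, 1500, 3100, 4600, 4600),
               mk_hit("c2", "CR1_F2", "LINE", 1500, 2000, 0, 500, 4600))
  expect_equal(classify_insertion(2000, mid)$status,
               "rejected_internal_3prime")
  # no hit at all
  no_hits <- mk_hit("x", "CR1_F2", "LINE", 0, 100, 0, 100, 4600)[0, ]
  expect_equal(classify_insertion(500, no_hits)$status, "rejected_no_hit")
  # insertion termini not covered by TE alignment
  unbounded <- mk_hit("u1", "CR1_F2", "LINE", 100, 1400, 3300, 4600, 4600)
  expect_equal(classify_insertion(1500, unbounded)$status,
               "rejected_not_TE_bounded")
  # unrelated families at the two termini
  amb <- rbind(mk_hit("a1", "ERV1_LTR", "LTR", 0, 300, 0, 300, 300),
               mk_hit("a1", "ERV2_LTR", "LTR", 300, 600, 0, 300, 300))
  cl <- classify_insertion(600, amb)
  expect_equal(cl$status, "rejected_filters")
  expect_equal(cl$note, "ambiguous")
  # minus-orientation LINE: 3' consensus end anchored at the left terminus
  rev <- mk_hit("r1", "CR1_F2", "LINE", 0, 1500, 3100, 4600, 4600,
                orient = "-")
  expect_equal(classify_insertion(1500, rev)$status, "nonLTR_transposition")
})

test_that("classification is invariant to hit order and statuses are exclusive", {
  erv <- rbind(mk_hit("e1", "ERV1_LTR", "LTR", 0, 300, 0, 300, 300),
               mk_hit("e1", "ERV1_I", "LTR_internal", 300, 5300, 0, 5000, 5000),
               mk_hit("e1", "ERV1_LTR", "LTR", 5300, 5600, 0, 300, 300))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(classify_insertion(5600, erv[perm, ])$status, "intact_ERV")
  }
})

test_that("active family reporting expands LTR-internal pairs and splits DNA", {
  calls <- data.frame(
    insertion_id = c("a", "b", "c", "d"),
    status = c("solo_LTR", "intact_ERV", "rejected_no_hit",
               "nonLTR_transposition"),
    families = c("ERV-L_LTR", "ERV-L_LTR,ERV-L_I", "", "CR1_F2"),
    note = "", stringsAsFactors = FALSE)
  map <- data.frame(ltr = "ERV-L_LTR", internal = "ERV-L_I",
                    stringsAsFactors = FALSE)
  fams <- call_active_families(calls, map)
  expect_setequal(fams$retrotransposon, c("ERV-L_LTR", "ERV-L_I", "CR1_F2"))
  # duplicate families counted once
  expect_equal(anyDuplicated(fams$retrotransposon), 0)
  # zero accepted calls: empty set
  none <- calls[calls$status == "rejected_no_hit", , drop = FALSE]
  expect_length(call_active_families(none, map)$retrotransposon, 0)
  # missing map entry: family kept with a warning
  calls2 <- calls[1, , drop = FALSE]
  expect_warning(f2 <- call_active_families(calls2, data.frame(
    ltr = "OTHER", internal = "OTHER_I")), "no internal counterpart")
  expect_equal(f2$retrotransposon, "ERV-L_LTR")
})

test_that("JC69 dating: closed forms, correction inequality, saturation error", {
  expect_equal(jc69_distance(0), 0)
  expect_equal(estimate_age(data.frame(family = "f", p = 0))$families$age_my, 0)
  a <- estimate_age(data.frame(family = "f", p = 0.04))
  expect_equal(a$families$K, 0.0411, tolerance = 1e-3)
  expect_equal(a$families$age_my, 21.6348, tolerance = 1e-3)
  expect_equal(a$median_age_my, a$families$age_my)
  for (p in c(0.01, 0.1, 0.3, 0.6)) expect_gte(jc69_distance(p), p)
  expect_error(jc69_distance(0.75), "0.75")
  expect_error(estimate_age(data.frame(family = "f", p = 0.8)), "0.75")
})

test_that("simulated copies recover the closed-form age within 5%", {
  cfg <- sim_config(seed = 404, te = list(
    families = data.frame(name = c("ERV1_LTR", "ERV1_I", "CR1_F2"),
                          class = c("LTR", "LTR_internal", "LINE"),
                          consensus_len = c(1000, 5000, 4600),
                          divergence = 0.04, stringsAsFactors = FALSE),
    n_solo = 0, n_intact = 25, n_cr1 = 0, n_decoy_cr1 = 0,
    n_decoy_refsolo = 0))
  sim <- simulate_te_insertions(cfg)
  internal <- sim$copies[sim$copies$family == "ERV1_I", , drop = FALSE]
  expect_gte(nrow(internal), 20)
  age <- estimate_age(internal)
  expect_equal(age$families$age_my, 21.6348, tolerance = 0.05)
})

test_that("hit tables round-trip through the TSV + sidecar interface", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_te_insertions(cfg)
  dir <- withr::local_tempdir()
  paths <- write_te_simulation(sim, dir)
  hits <- read_te_hits(paths[["hits"]], paths[["lengths"]])
  expect_equal(nrow(hits), nrow(sim$hits))
  expect_equal(hits$consensus_len, sim$hits$consensus_len)
  expect_equal(hits$pident, sim$hits$pident)
})
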
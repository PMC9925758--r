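test_that("BED reading honours format, strand, and bounds", {
  sizes <- tiny_sizes()
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100",
               "chr1\t200\t300\tlocusA\t0\t-",
               "chr2\t10\t20\tlocusB"), bed)
  x <- read_intervals(bed, sizes)
  expect_equal(nrow(x), 3)
  expect_equal(x$start, c(0, 200, 10))
  expect_equal(x$strand, c("*", "-", "*"))
  expect_equal(x$name, c(NA, "locusA", "locusB"))

  writeLines("chr1\t100\t100", bed)
  expect_error(read_intervals(bed, sizes), "line 1")
  writeLines("chr1\t0", bed)
  expect_error(read_intervals(bed, sizes), "fewer than 3")
  writeLines("chr1\t0\t2000000", bed)
  expect_error(read_intervals(bed, sizes), "bounds")
})

test_that("interval write/read round-trips and is sorted", {
  sizes <- tiny_sizes()
  x <- genomic_intervals(c("chr2", "chr1", "chr1"), c(5, 100, 0),
                         c(50, 400, 10), strand = c("+", "-", "*"),
                         name = c("c", "b", "a"), sizes = sizes)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_intervals(x, bed)
  y <- read_intervals(bed, sizes)
  xs <- x[order(x$chrom, x$start, x$end), ]
  rownames(xs) <- NULL
  expect_equal(y[, c("chrom", "start", "end", "name", "strand")],
               xs[, c("chrom", "start", "end", "name", "strand")])
})

test_that("SV TSV reading validates, rejects sub-50-bp records, round-trips", {
  sizes <- tiny_sizes()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\ttype\tlength\tsupport\tscore\tcaller\tseq",
               paste0("chr1\t1000\t1001\tINS\t300\t12\t20\tA\t",
                      strrep("A", 300)),
               "chr1\t5000\t5100\tDEL\t100\t15\t30\tA\t.",
               "chr1\t9000\t9049\tDEL\t49\t15\t30\tA\t."), tsv)
  expect_warning(x <- read_sv_calls(tsv, sizes), "shorter than 50")
  expect_equal(nrow(x), 2)
  expect_equal(attr(x, "n_rejected"), 1)
  expect_equal(x$sv_type, c("INS", "DEL"))
  expect_equal(nchar(x$seq[1]), 300)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_sv_calls(x, out)
  y <- read_sv_calls(out, sizes)
  expect_equal(y$start, x$start)
  expect_equal(y$sv_len, x$sv_len)
  expect_equal(y$seq, x$seq)

  writeLines(c("chrom\tstart\tend\ttype\tlength\tsupport\tscore\tcaller",
               "chr1\t1\t100\tBND\t99\t4\t4\tA"), tsv)
  expect_error(read_sv_calls(tsv), "unknown sv_type")
})

test_that("minimal VCF reading converts 1-based POS and parses INFO keys", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               paste0("chr1\t1001\tsv1\tN\t<INS>\t60\tPASS\t",
                      "SVTYPE=INS;SVLEN=300;RE=12;SEQ=", strrep("T", 300)),
               "chr1\t2001\tsv2\tN\t<DEL>\t45\tPASS\tSVTYPE=DEL;SVLEN=-500;END=2500;RE=9"),
             vcf)
  x <- read_sv_calls(vcf)
  expect_equal(x$start, c(1000, 2000))  # 0-based conversion
  expect_equal(x$sv_type, c("INS", "DEL"))
  expect_equal(x$sv_len, c(300, 500))
  expect_equal(x$support, c(12, 9))
  expect_equal(nchar(x$seq[1]), 300)
})

test_that("collapsed FASTA reading parses counts, merges duplicates, attaches mappings", {
  fa <- withr::local_tempfile(fileext = ".fa")
  seq26 <- strrep("TGCAAT", 5)  # 30 nt
  writeLines(c(">s1_count5", seq26,
               ">s2_count2", strrep("AC", 13),
               ">s3_count3", strrep("AC", 13)), fa)
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tchrom\tpos5\tstrand",
               "s1\tchr1\t100\t+",
               "s1\tchr2\t200\t-",
               "s2\tchr1\t50\t+"), mp)
  x <- read_collapsed_reads(fa, mp)
  expect_equal(nrow(x$species), 2)        # s2/s3 merged
  s1 <- x$species[x$species$id == "s1", ]
  expect_equal(s1$length, 30)
  expect_equal(s1$count, 5)
  expect_equal(s1$n_mappings, 2L)
  expect_false(s1$unique)
  merged <- x$species[x$species$id != "s1", ]
  expect_equal(merged$count, 5)           # 2 + 3

  writeLines(c(">bad_header", seq26), fa)
  expect_error(read_collapsed_reads(fa), "parseable count")
})

test_that("collapsed reads round-trip through FASTA + mappings TSV", {
  rna <- make_rna("chr1", c(100, 250, 300), c("+", "-", "+"),
                  count = c(5, 2, 7))
  fa <- withr::local_tempfile(fileext = ".fa")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_collapsed_reads(rna, fa, mp)
  back <- read_collapsed_reads(fa, mp)
  o1 <- rna$species[order(rna$species$id), ]
  o2 <- back$species[order(back$species$id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
  m1 <- rna$mappings[order(rna$mappings$id), ]
  m2 <- back$mappings[order(back$mappings$id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m2, m1)
})

test_that("score tracks average ranges with fill for uncovered bases", {
  sizes <- tiny_sizes()
  tr <- score_track(c("chr1", "chr1"), c(0, 100), c(10, 200),
                    c(1, 0.5), fill = 0, sizes = sizes)
  iv <- genomic_intervals("chr1", c(0, 0, 150), c(10, 20, 250), sizes = sizes)
  m <- track_mean(tr, iv)
  expect_equal(m[1], 1)
  expect_equal(m[2], 0.5)                       # half covered at 1, half fill
  expect_equal(m[3], (50 * 0.5) / 100)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, bg)
  tr2 <- read_bedgraph(bg, sizes = sizes)
  expect_equal(tr2$ranges$value, tr$ranges$value)
})

test_that("chrom sizes validate and round-trip", {
  expect_error(chrom_sizes(c("a", "a"), c(10, 20)), "duplicate")
  expect_error(chrom_sizes("a", 0), "positive")
  f <- withr::local_tempfile(fileext = ".tsv")
  s <- tiny_sizes()
  write_chrom_sizes(s, f)
  expect_equal(read_chrom_sizes(f), s)
})
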
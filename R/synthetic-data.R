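# Synthetic-data generation.
#
# Every generator is a pure function of its configuration (which carries a
# mandatory seed), emitting exactly the containers and formats the rest of
# the package consumes: an avian-style genome of macro-, intermediate- and
# micro-chromosomes; two SV call sets with a planted clustered hotspot and
# a configurable dual-caller fraction; collapsed small-RNA species with
# planted piRNA clusters, strand structure and 10-nt 5'-5' ping-pong
# pairs; and TE insertion sequences of each structural category with a
# configurable per-copy divergence from consensus.

#' Build a simulation configuration
#'
#' Unspecified components fall back to the package's stated world: a
#' three-chromosome genome (60 Mb macro, 30 Mb intermediate, 5 Mb micro),
#' 200 SVs per type with a 10x hotspot over 100 kb of the
#' macrochromosome, piRNA clusters at 20x background depth, and ERV/CR1
#' TE families at 4% per-site divergence.
#'
#' @param seed Mandatory integer seed.
#' @param chromosomes data.frame(name, length).
#' @param sv list: n_per_type (named INS/DEL/INV/DUP), hotspot (one-row
#'   interval df plus `excess` column), both_caller_fraction, slop,
#'   support_range, score_range, len_range.
#' @param pirna list: clusters (df chrom, start, end, depth reads/bp,
#'   strand_bias, pingpong_fraction), background_rate (reads/bp),
#'   multimap_fraction, len_range.
#' @param te list: families (df name, class, consensus_len, divergence),
#'   n_solo, n_intact, n_cr1, n_decoy_cr1, n_decoy_refsolo.
#' @param mirna list: n_species, total_count.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chromosomes = NULL, sv = list(), pirna = list(),
                       te = list(), mirna = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(chromosomes))
    chromosomes <- data.frame(name = c("chr1", "chr6", "chr13"),
                              length = c(60e6, 30e6, 5e6),
                              stringsAsFactors = FALSE)
  if (!nrow(chromosomes)) stop("at least one chromosome is required")
  # shallow merge: user components replace defaults wholesale (a recursive
  # merge would descend into data.frame columns)
  merge_shallow <- function(defaults, user) {
    for (k in names(user)) defaults[[k]] <- user[[k]]
    defaults
  }
  sv <- merge_shallow(list(
    n_per_type = c(INS = 200, DEL = 200, INV = 200, DUP = 200),
    hotspot = data.frame(chrom = chromosomes$name[1], start = 10e6,
                         end = 10.1e6, excess = 10),
    both_caller_fraction = 0.9, slop = 100,
    support_range = c(10, 30), score_range = c(10, 30),
    len_range = c(50, 5000)), sv)
  pirna <- merge_shallow(list(
    clusters = data.frame(chrom = chromosomes$name[1],
                          start = 2e6, end = 2.01e6, depth = 0.1,
                          strand_bias = 0.8, pingpong_fraction = 0,
                          stringsAsFactors = FALSE),
    background_rate = 2e-6, multimap_fraction = 0.1,
    len_range = c(24, 32)), pirna)
  te <- merge_shallow(list(
    families = data.frame(
      name = c("ERV1_LTR", "ERV1_I", "CR1_F2"),
      class = c("LTR", "LTR_internal", "LINE"),
      consensus_len = c(300, 5000, 4600),
      divergence = c(0.04, 0.04, 0.04), stringsAsFactors = FALSE),
    n_solo = 10, n_intact = 5, n_cr1 = 2,
    n_decoy_cr1 = 2, n_decoy_refsolo = 1), te)
  mirna <- merge_shallow(list(n_species = 50, total_count = 1e5), mirna)
  if (any(te$families$divergence >= 0.75))
    stop("divergence >= 0.75: JC69 correction undefined")
  if (any(pirna$clusters$depth == 0 & pirna$clusters$pingpong_fraction > 0))
    stop("cluster with depth 0 cannot carry a ping-pong fraction > 0")
  cfg <- list(seed = as.integer(seed), chromosomes = chromosomes, sv = sv,
              pirna = pirna, te = te, mirna = mirna)
  # planted intervals must live inside the declared genome
  sizes <- chrom_sizes(chromosomes$name, chromosomes$length)
  validate_intervals(sv$hotspot, sizes)
  validate_intervals(pirna$clusters, sizes)
  structure(cfg, class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with annotation intervals
#'
#' Chromosome classes follow avian convention: macro (> 40 Mb),
#' intermediate (20-40 Mb) and micro (< 20 Mb).  Gene and repeat
#' annotations are placed uniformly (5 genes and 50 repeats per Mb).
#'
#' @param config `sim_config`.
#' @return list: sizes (`chrom_sizes`), classes (data.frame name, class),
#'   genes and repeats (interval data.frames).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_local_seed(config$seed + 1L)
  sizes <- chrom_sizes(config$chromosomes$name, config$chromosomes$length)
  classes <- data.frame(
    name = names(sizes),
    class = ifelse(sizes > 40e6, "macro",
            ifelse(sizes >= 20e6, "intermediate", "micro")),
    stringsAsFactors = FALSE)
  place <- function(per_mb, wmin, wmax, prefix) {
    rows <- lapply(names(sizes), function(ch) {
      L <- sizes[[ch]]
      n <- max(1L, round(per_mb * L / 1e6))
      w <- round(stats::runif(n, wmin, wmax))
      s <- floor(stats::runif(n, 0, L - w))
      data.frame(chrom = ch, start = s, end = s + w,
                 name = paste0(prefix, "_", ch, "_", seq_len(n)),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    sort_intervals(do.call(rbind, rows))
  }
  genes <- place(5, 2000, 50000, "gene")
  repeats <- place(50, 200, 5000, "rep")
  list(sizes = sizes, classes = classes, genes = genes, repeats = repeats)
}

#' Simulate dual-caller SV call sets with a planted hotspot
#'
#' Background SVs land uniformly (chromosome chosen proportional to
#' length); within the planted hotspot interval the midpoint rate is
#' multiplied by the configured excess.  A configured fraction of events
#' appears in both callers with breakpoints jittered by at most `slop`;
#' the rest are caller-A only.
#'
#' @param config `sim_config`.
#' @param sizes `chrom_sizes` (e.g. from [simulate_genome()]).
#' @return list: A and B (SV data.frames), hotspot (the planted interval).
#' @export
simulate_sv_calls <- function(config, sizes) {
  stopifnot(inherits(config, "sim_config"))
  set_local_seed(config$seed + 2L)
  svc <- config$sv
  hs <- svc$hotspot
  if (!hs$chrom %in% names(sizes) || hs$end > sizes[[hs$chrom]])
    stop("hotspot outside the simulated genome")
  totL <- sum(sizes)
  recs <- list()
  for (type in names(svc$n_per_type)) {
    n <- svc$n_per_type[[type]]
    if (n == 0) next
    ch <- sample(names(sizes), n, replace = TRUE, prob = as.numeric(sizes))
    len <- round(stats::runif(n, max(50, svc$len_range[1]), svc$len_range[2]))
    mid <- numeric(n)
    for (i in seq_len(n)) {
      L <- sizes[[ch[i]]]
      if (ch[i] == hs$chrom) {
        w <- hs$end - hs$start
        ph <- hs$excess * w / ((L - w) + hs$excess * w)
        mid[i] <- if (stats::runif(1) < ph)
          floor(stats::runif(1, hs$start, hs$end))
        else {   # uniform outside the hotspot
          u <- floor(stats::runif(1, 0, L - w))
          if (u >= hs$start) u + w else u
        }
      } else mid[i] <- floor(stats::runif(1, 0, L))
    }
    if (type == "INS") {
      start <- pmin(pmax(mid, 0), as.numeric(sizes[ch]) - 1)
      end <- start + 1
    } else {
      start <- pmax(0, mid - floor(len / 2))
      end <- pmin(start + len, as.numeric(sizes[ch]))
      start <- end - len
      start <- pmax(start, 0); len <- end - start
      keep <- len >= 50
      start <- start[keep]; end <- end[keep]; ch <- ch[keep]
      len <- len[keep]; n <- sum(keep)
    }
    recs[[type]] <- data.frame(
      chrom = ch, start = start, end = end, sv_type = type, sv_len = len,
      support = round(stats::runif(n, svc$support_range[1],
                                   svc$support_range[2])),
      score = round(stats::runif(n, svc$score_range[1], svc$score_range[2])),
      caller = "callerA",
      seq = if (type == "INS")
        vapply(len, random_seq, "") else NA_character_,
      stringsAsFactors = FALSE)
  }
  A <- do.call(rbind, recs)
  rownames(A) <- NULL
  both <- stats::runif(nrow(A)) < svc$both_caller_fraction
  B <- A[both & A$sv_type != "INS", , drop = FALSE]
  if (nrow(B)) {
    js <- sample(-svc$slop:svc$slop, nrow(B), replace = TRUE)
    je <- sample(-svc$slop:svc$slop, nrow(B), replace = TRUE)
    B$start <- pmax(0, B$start + js)
    B$end <- pmax(B$start + 50, B$end + je)
    B$sv_len <- B$end - B$start
    B$score <- round(stats::runif(nrow(B), svc$score_range[1],
                                  svc$score_range[2]))
    B$caller <- "callerB"
    rownames(B) <- NULL
  }
  validate_sv(A, sizes)
  list(A = A, B = B, hotspot = hs)
}

#' Simulate collapsed small-RNA reads with planted piRNA clusters
#'
#' Background species are placed uniformly at a low rate; each planted
#' cluster receives `depth * width` reads of 24-32 nt at the configured
#' strand bias, of which the configured fraction is emitted as
#' plus/minus pairs whose 5' ends overlap by exactly 10 nt.  A separate
#' miRNA pool (21-23 nt) of the configured total count supports
#' normalization.  A configured fraction of piRNA species receives a
#' second decoy genomic mapping (multi-mappers).
#'
#' @param config `sim_config`.
#' @param sizes `chrom_sizes`.
#' @param label Library label.
#' @return `smallrna_library` with `mirna_total` set to the miRNA pool sum.
#' @export
simulate_smallrna_reads <- function(config, sizes, label = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set_local_seed(config$seed + 3L)
  pir <- config$pirna
  lmin <- pir$len_range[1]; lmax <- pir$len_range[2]
  sp_seq <- character(); sp_cnt <- numeric()
  mp_chrom <- character(); mp_pos <- numeric(); mp_str <- character()
  mp_sp <- integer()
  emit <- function(chrom, pos5, strand, count, len) {
    i <- length(sp_seq) + 1L
    sp_seq[[i]] <<- random_seq(len)
    sp_cnt[[i]] <<- count
    mp_chrom[[length(mp_chrom) + 1L]] <<- chrom
    mp_pos[[length(mp_pos) + 1L]] <<- pos5
    mp_str[[length(mp_str) + 1L]] <<- strand
    mp_sp[[length(mp_sp) + 1L]] <<- i
    i
  }
  cl <- pir$clusters
  if (any(cl$depth == 0 & cl$pingpong_fraction > 0))
    stop("cluster with depth 0 cannot carry a ping-pong fraction > 0")
  for (j in seq_len(nrow(cl))) {
    width <- cl$end[j] - cl$start[j]
    n_reads <- round(cl$depth[j] * width)
    if (n_reads == 0) next
    n_pairs <- round(cl$pingpong_fraction[j] * n_reads / 2)
    if (n_pairs > 0) {
      p <- floor(stats::runif(n_pairs, cl$start[j], cl$end[j] - 10))
      for (i in seq_len(n_pairs)) {
        emit(cl$chrom[j], p[i], "+", sample(1:3, 1),
             sample(lmin:lmax, 1))
        emit(cl$chrom[j], p[i] + 9, "-", sample(1:3, 1),
             sample(lmin:lmax, 1))
      }
    }
    n_single <- n_reads - 2 * n_pairs
    if (n_single > 0) {
      pos <- floor(stats::runif(n_single, cl$start[j], cl$end[j]))
      str <- ifelse(stats::runif(n_single) < cl$strand_bias[j], "+", "-")
      for (i in seq_len(n_single))
        emit(cl$chrom[j], pos[i], str[i], 1, sample(lmin:lmax, 1))
    }
  }
  n_bg <- round(pir$background_rate * sum(sizes))
  if (n_bg > 0) {
    ch <- sample(names(sizes), n_bg, replace = TRUE, prob = as.numeric(sizes))
    for (i in seq_len(n_bg))
      emit(ch[i], floor(stats::runif(1, 0, sizes[[ch[i]]] - lmax)),
           sample(c("+", "-"), 1), 1, sample(lmin:lmax, 1))
  }
  n_pirna_species <- length(sp_seq)
  # miRNA pool
  mir <- config$mirna
  if (mir$n_species > 0) {
    share <- as.numeric(stats::rmultinom(1, mir$total_count,
                                         rep(1, mir$n_species)))
    ch <- sample(names(sizes), mir$n_species, replace = TRUE,
                 prob = as.numeric(sizes))
    for (i in seq_len(mir$n_species))
      emit(ch[i], floor(stats::runif(1, 0, sizes[[ch[i]]] - 23)),
           sample(c("+", "-"), 1), share[i], sample(21:23, 1))
  }
  species <- data.frame(id = paste0("s", seq_along(sp_seq)), seq = sp_seq,
                        count = sp_cnt, stringsAsFactors = FALSE)
  mappings <- data.frame(id = paste0("s", mp_sp), chrom = mp_chrom,
                         pos5 = mp_pos, strand = mp_str,
                         stringsAsFactors = FALSE)
  # decoy second mappings for a fraction of piRNA species
  if (pir$multimap_fraction > 0 && n_pirna_species > 0) {
    mm <- which(stats::runif(n_pirna_species) < pir$multimap_fraction)
    if (length(mm)) {
      ch <- sample(names(sizes), length(mm), replace = TRUE,
                   prob = as.numeric(sizes))
      extra <- data.frame(id = paste0("s", mm), chrom = ch,
                          pos5 = floor(stats::runif(length(mm), 0,
                                                    as.numeric(sizes[ch]) - lmax)),
                          strand = sample(c("+", "-"), length(mm),
                                          replace = TRUE),
                          stringsAsFactors = FALSE)
      mappings <- rbind(mappings, extra)
    }
  }
  mirna_total <- if (mir$n_species > 0) mir$total_count else 0
  smallrna_library(label, smallrna_set(species, mappings),
                   mirna_total = mirna_total)
}

mutate_seq <- function(seq, p) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < p)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  list(seq = paste(bases, collapse = ""), n_sub = length(hit))
}

#' Simulate TE insertion sequences with labelled structural categories
#'
#' Emits, per configured counts: solo-LTR insertions (one complete LTR),
#' intact-ERV insertions (LTR-internal-LTR), CR1 insertions with the
#' consensus 3' end preserved at an insertion terminus and a random 5'
#' truncation, CR1 decoys whose 3' end is internal to the insertion, and
#' intact-ERV decoys planted on reference solo-LTR sites.  Per-copy
#' substitutions are drawn i.i.d. per site at the family's divergence
#' probability (matching the JC69 assumption used for dating).  The hit
#' table reflects the true alignments; no aligner is run.
#'
#' @param config `sim_config`.
#' @param sizes Optional `chrom_sizes` for insertion-site placement
#'   (defaults to the config's chromosomes).
#' @return list: consensus (named character), insertions (data.frame
#'   insertion_id, length, chrom, start, end, seq), hits (te_hits table),
#'   ref_solo_ltrs (interval df), truth (data.frame insertion_id,
#'   expected_status), copies (data.frame family, p observed divergence).
#' @export
simulate_te_insertions <- function(config, sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set_local_seed(config$seed + 4L)
  te <- config$te
  fam <- te$families
  if (any(fam$divergence >= 0.75))
    stop("divergence >= 0.75: JC69 correction undefined")
  if (is.null(sizes))
    sizes <- chrom_sizes(config$chromosomes$name, config$chromosomes$length)
  consensus <- stats::setNames(
    vapply(fam$consensus_len, random_seq, ""), fam$name)
  ltr <- fam$name[fam$class == "LTR"][1]
  int <- fam$name[fam$class == "LTR_internal"][1]
  line <- fam$name[fam$class == "LINE"][1]
  Lltr <- fam$consensus_len[fam$name == ltr]
  Lint <- fam$consensus_len[fam$name == int]
  Lline <- fam$consensus_len[fam$name == line]
  div <- stats::setNames(fam$divergence, fam$name)

  ins <- list(); hits <- list(); truth <- list(); copies <- list()
  ref_solo <- list()
  idc <- 0L
  next_id <- function() { idc <<- idc + 1L; sprintf("ins%03d", idc) }
  rand_site <- function() {
    ch <- sample(names(sizes), 1, prob = as.numeric(sizes))
    s <- floor(stats::runif(1, 0, sizes[[ch]] - 1))
    data.frame(chrom = ch, start = s, end = s + 1, stringsAsFactors = FALSE)
  }
  add_hit <- function(id, family, class, q0, q1, s0, s1, n_sub, orient = "+") {
    len <- q1 - q0
    hits[[length(hits) + 1L]] <<- te_hits(
      id, family, class, q0, q1, s0, s1,
      pident = 100 * (1 - n_sub / len), aln_len = len, gap_frac = 0,
      evalue = 1e-50, consensus_len = fam$consensus_len[fam$name == family],
      orientation = orient)
    copies[[length(copies) + 1L]] <<- data.frame(family = family,
                                                 p = n_sub / len)
  }
  add_ins <- function(seq, site, status) {
    id <- next_id()
    ins[[length(ins) + 1L]] <<- cbind(
      data.frame(insertion_id = id, length = nchar(seq),
                 stringsAsFactors = FALSE),
      site, data.frame(seq = seq, stringsAsFactors = FALSE))
    truth[[length(truth) + 1L]] <<- data.frame(insertion_id = id,
                                               expected_status = status,
                                               stringsAsFactors = FALSE)
    id
  }

  for (i in seq_len(te$n_solo)) {
    m <- mutate_seq(consensus[[ltr]], div[[ltr]])
    id <- add_ins(m$seq, rand_site(), "solo_LTR")
    add_hit(id, ltr, "LTR", 0, Lltr, 0, Lltr, m$n_sub)
  }
  make_erv <- function(site, status) {
    m1 <- mutate_seq(consensus[[ltr]], div[[ltr]])
    m2 <- mutate_seq(consensus[[int]], div[[int]])
    m3 <- mutate_seq(consensus[[ltr]], div[[ltr]])
    seq <- paste0(m1$seq, m2$seq, m3$seq)
    id <- add_ins(seq, site, status)
    add_hit(id, ltr, "LTR", 0, Lltr, 0, Lltr, m1$n_sub)
    add_hit(id, int, "LTR_internal", Lltr, Lltr + Lint, 0, Lint, m2$n_sub)
    add_hit(id, ltr, "LTR", Lltr + Lint, Lltr + Lint + Lltr, 0, Lltr,
            m3$n_sub)
    id
  }
  for (i in seq_len(te$n_intact)) make_erv(rand_site(), "intact_ERV")
  for (i in seq_len(te$n_cr1)) {
    keep <- round(stats::runif(1, max(300, 0.2 * Lline), 0.9 * Lline))
    frag <- substr(consensus[[line]], Lline - keep + 1, Lline)
    m <- mutate_seq(frag, div[[line]])
    id <- add_ins(m$seq, rand_site(), "nonLTR_transposition")
    add_hit(id, line, "LINE", 0, keep, Lline - keep, Lline, m$n_sub)
  }
  for (i in seq_len(te$n_decoy_cr1)) {
    # ancestral-deletion mimic: 3' end internal, yet TE at both termini
    keep <- round(stats::runif(1, max(300, 0.2 * Lline), 0.8 * Lline))
    frag <- substr(consensus[[line]], Lline - keep + 1, Lline)
    head5 <- substr(consensus[[line]], 1, 500)
    m1 <- mutate_seq(frag, div[[line]])
    m2 <- mutate_seq(head5, div[[line]])
    id <- add_ins(paste0(m1$seq, m2$seq), rand_site(),
                  "rejected_internal_3prime")
    add_hit(id, line, "LINE", 0, keep, Lline - keep, Lline, m1$n_sub)
    add_hit(id, line, "LINE", keep, keep + 500, 0, 500, m2$n_sub)
  }
  for (i in seq_len(te$n_decoy_refsolo)) {
    site <- rand_site()
    ref_solo[[length(ref_solo) + 1L]] <-
      data.frame(chrom = site$chrom, start = max(0, site$start - 100),
                 end = site$start + 100, name = paste0(ltr, "_refsolo"),
                 strand = "+", stringsAsFactors = FALSE)
    make_erv(site, "rejected_reference_soloLTR")
  }

  list(consensus = consensus,
       insertions = do.call(rbind, ins),
       hits = do.call(rbind, hits),
       ref_solo_ltrs = if (length(ref_solo)) do.call(rbind, ref_solo)
                       else data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), name = character(),
                                       strand = character(),
                                       stringsAsFactors = FALSE),
       truth = do.call(rbind, truth),
       copies = do.call(rbind, copies))
}

#' Write TE simulation outputs to files
#'
#' @param sim Output of [simulate_te_insertions()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths (consensus/insertions FASTA, hits
#'   TSV, consensus length sidecar, reference solo-LTR BED).
#' @export
write_te_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(consensus = file.path(dir, "consensus.fa"),
         insertions = file.path(dir, "insertions.fa"),
         insertion_table = file.path(dir, "insertions.tsv"),
         hits = file.path(dir, "hits.tsv"),
         lengths = file.path(dir, "consensus_lengths.tsv"),
         ref_solo = file.path(dir, "reference_solo_ltrs.bed"),
         truth = file.path(dir, "truth.tsv"))
  cs <- Biostrings::DNAStringSet(sim$consensus)
  Biostrings::writeXStringSet(cs, p[["consensus"]])
  is <- Biostrings::DNAStringSet(stats::setNames(sim$insertions$seq,
                                                 sim$insertions$insertion_id))
  Biostrings::writeXStringSet(is, p[["insertions"]])
  h <- sim$hits[setdiff(names(sim$hits), "consensus_len")]
  utils::write.table(h, p[["hits"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$insertions[, c("insertion_id", "length", "chrom",
                                        "start", "end")],
                     p[["insertion_table"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, p[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(family = names(sim$consensus),
                                length = nchar(sim$consensus)),
                     p[["lengths"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_intervals(sim$ref_solo_ltrs, p[["ref_solo"]])
  p
}
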
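# Small-RNA library normalization and per-feature statistics.
#
# Reads > 23 nt count as piRNAs; shorter species are retained in the
# library (they enter the ppm denominator) but never contribute to feature
# counts.  Multi-mapping species are apportioned fractionally:
# count / n_genome_mappings per mapping, which conserves each species'
# total exactly.

PIRNA_MIN_LEN <- 24          # "reads > 23 nt"
ABUND_PSEUDO <- 0.001        # pseudo-count added to ppm and rpkm

#' Normalize libraries to their miRNA totals
#'
#' Every species count is multiplied by `scale / mirna_total`, under the
#' assumption that total miRNA abundance is constant across libraries.
#'
#' @param libs List of `smallrna_library`.
#' @param scale Target miRNA total (reads) after normalization.
#' @return List of normalized libraries, each with `mirna_total == scale`.
#' @export
normalize_to_mirna <- function(libs, scale = 1e6) {
  if (inherits(libs, "smallrna_library")) libs <- list(libs)
  lapply(libs, function(lib) {
    if (lib$mirna_total <= 0)
      stop("library '", lib$label, "' has miRNA total 0; cannot normalize")
    f <- scale / lib$mirna_total
    lib$rna$species$count <- lib$rna$species$count * f
    lib$mirna_total <- scale
    lib
  })
}

#' Calibrate an oxidized library against its total-RNA counterpart
#'
#' Oxidation enriches 2'-O-methylated piRNAs but loses absolute scale.  The
#' calibration factor is the ratio of summed counts over piRNA species
#' (> 23 nt) shared between the two libraries:
#' `f = sum(shared in total) / sum(shared in oxidized)`.
#'
#' @param oxidized,total `smallrna_library` objects.
#' @return The oxidized library with all counts multiplied by `f`; the
#'   factor is attached as attribute `calibration_factor`.
#' @export
calibrate_oxidized <- function(oxidized, total) {
  so <- oxidized$rna$species; st <- total$rna$species
  shared <- intersect(so$seq[so$length > 23], st$seq[st$length > 23])
  if (!length(shared))
    stop("no shared piRNA species (> 23 nt) between '", oxidized$label,
         "' and '", total$label, "'")
  f <- sum(st$count[st$seq %in% shared]) / sum(so$count[so$seq %in% shared])
  oxidized$rna$species$count <- so$count * f
  attr(oxidized, "calibration_factor") <- f
  oxidized
}

#' Per-mapping fractional weights for piRNA-length species
#'
#' @param lib `smallrna_library`.
#' @param min_len Minimum species length in nt (default 24).
#' @param unique_only Keep only uniquely mapping species.
#' @return data.frame of mappings (chrom, pos5, strand) with a `weight`
#'   column equal to count / n_genome_mappings, plus species id and length.
#' @keywords internal
mapping_weights <- function(lib, min_len = PIRNA_MIN_LEN, unique_only = FALSE) {
  sp <- lib$rna$species
  keep <- sp$length >= min_len & sp$n_mappings > 0
  if (unique_only) keep <- keep & sp$unique
  sp <- sp[keep, , drop = FALSE]
  mp <- lib$rna$mappings
  mp <- mp[mp$id %in% sp$id, , drop = FALSE]
  i <- match(mp$id, sp$id)
  mp$weight <- sp$count[i] / sp$n_mappings[i]
  mp$length <- sp$length[i]
  mp
}

#' Per-feature piRNA abundance
#'
#' A read mapping is assigned to a feature when its 5' base lies within the
#' feature interval; multi-mappers contribute `count / n_genome_mappings`
#' per mapping.  ppm and rpkm use the library's total genome-mapping reads
#' (all lengths) as denominator, with a pseudo-count of 0.001 added to
#' both.
#'
#' @param lib `smallrna_library`.
#' @param features Interval data.frame.
#' @param min_len Minimum read length in nt counted (default 24, i.e.
#'   > 23 nt).
#' @return data.frame, one row per feature: chrom, start, end, name,
#'   count, watson_count, crick_count, unique_reads, ppm, rpkm.
#' @export
feature_abundance <- function(lib, features, min_len = PIRNA_MIN_LEN) {
  if (!nrow(features)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), count = numeric(),
                      watson_count = numeric(), crick_count = numeric(),
                      unique_reads = numeric(), ppm = numeric(),
                      rpkm = numeric()))
  }
  mp <- mapping_weights(lib, min_len = min_len)
  total <- library_total(lib)
  sp <- lib$rna$species
  uniq_ids <- sp$id[sp$unique]
  res <- lapply(seq_len(nrow(features)), function(i) {
    ch <- features$chrom[i]; s <- features$start[i]; e <- features$end[i]
    hit <- mp$chrom == ch & mp$pos5 >= s & mp$pos5 < e
    w <- mp$weight[hit]; str <- mp$strand[hit]
    cnt <- sum(w)
    watson <- sum(w[str == "+"])
    uniq <- sum(mp$id[hit] %in% uniq_ids)
    ppm <- cnt / total * 1e6 + ABUND_PSEUDO
    rpkm <- cnt / ((e - s) / 1e3) / total * 1e6 + ABUND_PSEUDO
    data.frame(count = cnt, watson_count = watson, crick_count = cnt - watson,
               unique_reads = uniq, ppm = ppm, rpkm = rpkm)
  })
  cbind(features[, c("chrom", "start", "end"),
                 drop = FALSE],
        name = if (is.null(features$name)) NA_character_ else features$name,
        do.call(rbind, res))
}

#' Shannon diversity index of species counts
#'
#' `H = -sum(p_i * ln p_i)` with `p_i = count_i / sum(count)`; zero-count
#' species are ignored.
#'
#' @param counts Non-negative numeric vector.
#' @return H (natural log units).
#' @export
shannon_diversity <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all species counts are zero")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Strand bias of a feature (Watson fraction)
#'
#' @param watson_count,crick_count Strand-split counts.
#' @return `watson / (watson + crick)` in `[0, 1]`; `NA` when the total is
#'   zero.
#' @export
strand_bias <- function(watson_count, crick_count) {
  tot <- watson_count + crick_count
  ifelse(tot > 0, watson_count / tot, NA_real_)
}

#' Expression variance relative to the mean-variance trend
#'
#' Per feature: median across individuals, CV = sample sd / mean, then a
#' LOESS fit of CV on log10(median + pseudo) whose residual measures
#' variability relative to what the feature's expression level predicts.
#'
#' @param mat Numeric matrix, features x individuals (>= 10 features,
#'   >= 3 individuals).
#' @param span LOESS span (default 0.75).
#' @param degree LOESS polynomial degree (default 2).
#' @param pseudo Pseudo-count added to the median before log10.
#' @return data.frame: feature, median_expr, cv, fitted, residual.
#'   Features with mean 0 are dropped with a warning.
#' @export
expression_variance <- function(mat, span = 0.75, degree = 2, pseudo = 0.001) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 10) stop("need >= 10 features")
  if (ncol(mat) < 3) stop("need >= 3 individuals")
  feat <- rownames(mat)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(mat)))
  mu <- rowMeans(mat)
  zero <- mu == 0
  if (any(zero)) {
    warning(sum(zero), " feature(s) with mean 0 dropped (CV undefined)")
    mat <- mat[!zero, , drop = FALSE]
    feat <- feat[!zero]; mu <- mu[!zero]
  }
  cv <- apply(mat, 1, stats::sd) / mu
  med <- apply(mat, 1, stats::median)
  x <- log10(med + pseudo)
  if (diff(range(x)) < sqrt(.Machine$double.eps)) {
    # degenerate: all features at one expression level
    fitted <- rep(mean(cv), length(cv))
  } else {
    fit <- stats::loess(cv ~ x, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    fitted <- stats::predict(fit, x)
  }
  data.frame(feature = feat, median_expr = med, cv = cv,
             fitted = fitted, residual = cv - fitted,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wootton-Federhen sequence complexity
#'
#' `cwf = (1/N) * log4( N! / prod_i n_i! )` over base counts n_i,
#' i in {A, C, G, T}; evaluated exactly via log-gamma so long sequences do
#' not overflow.  0 for a homopolymer, maximal for balanced base counts.
#'
#' @param seq Nucleotide string (ACGT only).
#' @return cwf in `[0, 1]`.
#' @export
wf_complexity <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (any(!bases %in% c("A", "C", "G", "T")))
    stop("sequence contains non-ACGT characters")
  n <- length(bases)
  ni <- table(factor(bases, levels = c("A", "C", "G", "T")))
  (lgamma(n + 1) - sum(lgamma(ni + 1))) / (n * log(4))
}
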
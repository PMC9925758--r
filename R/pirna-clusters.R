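# piRNA-producing locus detection.
#
# The genome is split into non-overlapping windows, piRNA 5'-end abundance
# is accumulated per window, and loci are extracted by an iterative
# linear-chain DP: s_i = max(0, s_{i-1} + a_i - penalty).  The maximal
# score marks the current cluster's last window; its first window is the
# one after the most recent zero score.  The cluster's windows are zeroed
# and the recursion repeated until every score is zero.  The penalty is
# the mean abundance of the top fraction (default 5%) of windows genome
# wide, reflecting an assumed upper bound on the genome fraction occupied
# by clusters.

#' Per-window piRNA abundance
#'
#' Counts 5' ends of reads > 23 nt into non-overlapping windows, with
#' fractional apportionment of multi-mappers.  Also tallies the number of
#' uniquely mapping reads per window (used by the min-unique filter).
#'
#' @param lib `smallrna_library`.
#' @param sizes `chrom_sizes`.
#' @param window Window size in bp (default 1000).
#' @param min_len Minimum read length counted (default 24).
#' @return Named list per chromosome, each element a list with numeric
#'   vectors `abundance` and `unique_reads` of length
#'   `ceiling(chrom_len / window)`.
#' @export
window_abundance <- function(lib, sizes, window = 1000, min_len = PIRNA_MIN_LEN) {
  stopifnot(window >= 1)
  mp <- mapping_weights(lib, min_len = min_len)
  sp <- lib$rna$species
  uniq_ids <- sp$id[sp$unique]
  out <- lapply(names(sizes), function(ch) {
    nw <- ceiling(sizes[[ch]] / window)
    ab <- numeric(nw); uq <- numeric(nw)
    sel <- mp$chrom == ch
    if (any(sel)) {
      w <- floor(mp$pos5[sel] / window) + 1
      ab <- as.numeric(tapply_sum(mp$weight[sel], w, nw))
      isu <- mp$id[sel] %in% uniq_ids
      if (any(isu)) uq <- as.numeric(tapply_sum(rep(1, sum(isu)), w[isu], nw))
    }
    list(abundance = ab, unique_reads = uq)
  })
  names(out) <- names(sizes)
  out
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Penalty score from the top fraction of windows
#'
#' @param windows List from [window_abundance()] or a numeric vector of
#'   window abundances.
#' @param genome_fraction Assumed maximal fraction of the genome inside
#'   clusters (default 0.05): the penalty is the mean of the top
#'   `ceiling(genome_fraction * n_windows)` windows.
#' @return Penalty (abundance per window).
#' @export
penalty_score <- function(windows, genome_fraction = 0.05) {
  stopifnot(genome_fraction > 0, genome_fraction < 1)
  a <- if (is.list(windows) && !is.null(windows[[1]]$abundance))
    unlist(lapply(windows, `[[`, "abundance"), use.names = FALSE)
  else as.numeric(unlist(windows, use.names = FALSE))
  if (length(a) < 20) stop("need >= 20 windows to estimate a penalty")
  if (all(a == 0)) stop("all windows are zero: no piRNA signal")
  k <- ceiling(genome_fraction * length(a))
  mean(sort(a, decreasing = TRUE)[seq_len(k)])
}

# One pass of the scoring recursion: s_i = max(0, s_{i-1} + a_i - penalty).
dp_scores <- function(a, penalty) {
  s <- numeric(length(a))
  prev <- 0
  for (i in seq_along(a)) {
    prev <- max(0, prev + a[i] - penalty)
    s[i] <- prev
  }
  s
}

# Extract segments from one chromosome's window vector.  Returns a
# data.frame of (first, last, score, abundance) in extraction order.
dp_extract <- function(a, penalty) {
  segs <- list()
  repeat {
    s <- dp_scores(a, penalty)
    smax <- max(s)
    if (smax <= 0) break
    last <- which.max(s)                       # leftmost maximal score
    zeros <- which(s[seq_len(last)] == 0)
    first <- if (length(zeros)) max(zeros) + 1L else 1L
    segs[[length(segs) + 1L]] <-
      data.frame(first = first, last = last, score = smax,
                 abundance = sum(a[first:last]))
    a[first:last] <- 0
  }
  if (!length(segs))
    return(data.frame(first = integer(), last = integer(),
                      score = numeric(), abundance = numeric()))
  do.call(rbind, segs)
}

#' Detect piRNA clusters by iterative DP segmentation
#'
#' @param windows Output of [window_abundance()].
#' @param penalty Penalty score (abundance per window) from
#'   [penalty_score()].
#' @param window Window size in bp used to build `windows`.
#' @param sizes `chrom_sizes` (interval ends are clipped to chromosome
#'   length).
#' @param min_unique_reads Minimum uniquely mapping reads per cluster
#'   (default 1).  Clusters failing the filter are discarded after
#'   extraction but still consume their windows.
#' @return Interval data.frame with extra columns `score`, `abundance`,
#'   `unique_reads`, ordered by extraction score within chromosome.
#' @export
detect_clusters <- function(windows, penalty, window = 1000, sizes = NULL,
                            min_unique_reads = 1) {
  stopifnot(penalty > 0)
  out <- lapply(names(windows), function(ch) {
    w <- windows[[ch]]
    segs <- dp_extract(w$abundance, penalty)
    if (!nrow(segs)) return(NULL)
    segs$unique_reads <- vapply(seq_len(nrow(segs)), function(i)
      sum(w$unique_reads[segs$first[i]:segs$last[i]]), numeric(1))
    segs <- segs[segs$unique_reads >= min_unique_reads, , drop = FALSE]
    if (!nrow(segs)) return(NULL)
    start <- (segs$first - 1) * window
    end <- segs$last * window
    if (!is.null(sizes)) end <- pmin(end, sizes[[ch]])
    data.frame(chrom = ch, start = start, end = end,
               name = NA_character_, strand = "*",
               score = segs$score, abundance = segs$abundance,
               unique_reads = segs$unique_reads, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), strand = character(),
                      score = numeric(), abundance = numeric(),
                      unique_reads = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-base 5'-end abundance over an interval
#'
#' @param lib `smallrna_library`.
#' @param interval One-row interval data.frame.
#' @param min_len Minimum read length counted (default 24).
#' @return Numeric vector, one value per base of the interval.
#' @export
base_abundance <- function(lib, interval, min_len = PIRNA_MIN_LEN) {
  mp <- mapping_weights(lib, min_len = min_len)
  s <- interval$start[1]; e <- interval$end[1]
  sel <- mp$chrom == interval$chrom[1] & mp$pos5 >= s & mp$pos5 < e
  out <- numeric(e - s)
  if (any(sel)) {
    idx <- mp$pos5[sel] - s + 1
    add <- tapply(mp$weight[sel], idx, sum)
    out[as.integer(names(add))] <- add
  }
  out
}

#' Refine cluster boundaries at base resolution
#'
#' Trims each end of the window-resolution interval to the outermost base
#' whose per-base abundance exceeds `penalty / window` (the per-base
#' equivalent of the per-window penalty).  If no base qualifies the
#' window-resolution interval is kept unchanged.
#'
#' @param cluster One-row cluster interval (from [detect_clusters()]).
#' @param per_base Per-base abundance over the cluster interval
#'   ([base_abundance()]).
#' @param penalty Window-level penalty score.
#' @param window Window size in bp.
#' @return One-row interval data.frame with refined start/end.
#' @export
refine_boundaries <- function(cluster, per_base, penalty, window = 1000) {
  stopifnot(nrow(cluster) == 1,
            length(per_base) == cluster$end - cluster$start)
  thr <- penalty / window
  qual <- which(per_base > thr)
  out <- cluster
  if (length(qual)) {
    out$start <- cluster$start + qual[1] - 1
    out$end <- cluster$start + qual[length(qual)]
  }
  out
}

#' End-to-end piRNA cluster calling
#'
#' Convenience wrapper: window counts, genome-wide penalty, DP extraction,
#' and optional base-resolution refinement.
#'
#' @param lib `smallrna_library` (pooled, calibrated counts).
#' @param sizes `chrom_sizes`.
#' @param window Window size (default 1000 bp).
#' @param genome_fraction Assumed maximal cluster fraction (default 0.05).
#' @param min_unique_reads Minimum unique reads per cluster (default 1).
#' @param refine Refine boundaries at base resolution (default TRUE).
#' @return Cluster interval data.frame as from [detect_clusters()].
#' @export
call_pirna_clusters <- function(lib, sizes, window = 1000,
                                genome_fraction = 0.05,
                                min_unique_reads = 1, refine = TRUE) {
  win <- window_abundance(lib, sizes, window = window)
  pen <- penalty_score(win, genome_fraction)
  cl <- detect_clusters(win, pen, window = window, sizes = sizes,
                        min_unique_reads = min_unique_reads)
  if (refine && nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      pb <- base_abundance(lib, cl[i, , drop = FALSE])
      r <- refine_boundaries(cl[i, , drop = FALSE], pb, pen, window)
      cl$start[i] <- r$start; cl$end[i] <- r$end
    }
  }
  cl
}
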
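# Same-chromosome interval-shuffling permutation tests.
#
# Each query interval is re-placed uniformly on its own chromosome with
# its length preserved (shuffled intervals may overlap each other).  The
# statistic is recomputed on every shuffle, and two P-value forms are
# reported: the symmetric form P = min{1, max{Pl, Pu}} with
# Pl = sum(M_i <= M_obs)/T and Pu = sum(M_i >= M_obs)/T (which by
# construction can never fall below 0.5), and the one-tailed form for a
# caller-declared direction, with zero exceedances reported as < 1/T.

#' Shuffle intervals on their own chromosomes
#'
#' @param query Interval data.frame.
#' @param sizes `chrom_sizes`.
#' @return Interval data.frame with identical chrom/length multiset and
#'   uniformly re-drawn starts.
#' @export
shuffle_intervals <- function(query, sizes) {
  len <- query$end - query$start
  L <- as.numeric(sizes[query$chrom])
  if (any(is.na(L))) stop("query chromosome missing from sizes")
  if (any(len > L))
    stop("interval longer than its chromosome at record ", which(len > L)[1])
  # uniform integer start in [0, L - len]
  start <- floor(stats::runif(nrow(query)) * (L - len + 1))
  start <- pmin(start, L - len)   # guard against runif returning 1
  out <- query
  out$start <- start
  out$end <- start + len
  out
}

#' Distance between two half-open intervals
#'
#' Gap in bp between closest ends; overlapping or boundary-sharing
#' intervals have distance 0.
#' @keywords internal
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

#' Enrichment/association statistics for shuffling tests
#'
#' * `count_in_features`: query elements landing in features - midpoints
#'   when `elements = "midpoint"`, or intervals with >= 1 bp overlap when
#'   `elements = "overlap"`.
#' * `n_overlapping`: query intervals overlapping >= 1 feature.
#' * `median_nearest_distance`: median over query intervals of the gap to
#'   the nearest feature on the same chromosome (0 if overlapping;
#'   features on other chromosomes are ignored, queries with no
#'   same-chromosome feature contribute NA and are dropped from the
#'   median).
#' * `median_mean_score`: median over query intervals of the mean track
#'   value within each.
#'
#' @param kind Statistic name (see above).
#' @param query Interval data.frame (SV sets: use their anchoring
#'   intervals; midpoints are derived internally).
#' @param features Feature interval data.frame.
#' @param track `score_track` (required for `median_mean_score`).
#' @param elements "midpoint" or "overlap" (for `count_in_features`).
#' @return Numeric scalar.
#' @export
compute_statistic <- function(kind = c("count_in_features", "n_overlapping",
                                       "median_nearest_distance",
                                       "median_mean_score"),
                              query, features = NULL, track = NULL,
                              elements = c("midpoint", "overlap")) {
  kind <- match.arg(kind)
  elements <- match.arg(elements)
  if (!nrow(query)) stop("empty query")
  if (kind == "median_mean_score") {
    if (is.null(track)) stop("median_mean_score requires a score track")
    return(stats::median(track_mean(track, query)))
  }
  if (is.null(features)) stop(kind, " requires a feature set")
  if (kind == "count_in_features") {
    if (elements == "midpoint") {
      mid <- floor((query$start + query$end) / 2)
      return(sum(points_in_intervals(query$chrom, mid, features)))
    }
    return(sum(overlaps_any(query, features)))
  }
  if (kind == "n_overlapping")
    return(sum(overlaps_any(query, features)))
  # median_nearest_distance
  d <- vapply(seq_len(nrow(query)), function(i) {
    fi <- features$chrom == query$chrom[i]
    if (!any(fi)) return(NA_real_)
    min(interval_gap(query$start[i], query$end[i],
                     features$start[fi], features$end[fi]))
  }, numeric(1))
  stats::median(d, na.rm = TRUE)
}

#' Same-chromosome shuffling permutation test
#'
#' @param query Interval data.frame to shuffle.
#' @param sizes `chrom_sizes`.
#' @param kind,features,track,elements Passed to [compute_statistic()].
#' @param trials Number of shuffles T (default 10000, >= 100).
#' @param direction Declared alternative for the one-tailed P: "greater"
#'   (observed larger than null) or "less".
#' @param seed RNG seed (bit-for-bit reproducible results).
#' @param keep_null Keep the full null distribution in the result.
#' @return list of class `shuffle_result`: m_obs, null (optional), pl, pu,
#'   p_printed = min(1, max(pl, pu)), p_one_tailed, p_one_label (zero
#'   exceedances reported as "< 1/T"), direction, trials.
#' @export
permutation_test <- function(query, sizes,
                             kind = "count_in_features", features = NULL,
                             track = NULL, elements = "midpoint",
                             trials = 10000, direction = c("greater", "less"),
                             seed = 1, keep_null = TRUE) {
  stopifnot(trials >= 100)
  direction <- match.arg(direction)
  set_local_seed(seed)
  m_obs <- compute_statistic(kind, query, features, track, elements)
  null <- vapply(seq_len(trials), function(i) {
    compute_statistic(kind, shuffle_intervals(query, sizes), features,
                      track, elements)
  }, numeric(1))
  pl <- sum(null <= m_obs) / trials
  pu <- sum(null >= m_obs) / trials
  n_extreme <- if (direction == "greater") sum(null >= m_obs)
               else sum(null <= m_obs)
  p_one <- n_extreme / trials
  structure(list(m_obs = m_obs,
                 null = if (keep_null) null else NULL,
                 pl = pl, pu = pu,
                 p_printed = min(1, max(pl, pu)),
                 p_one_tailed = p_one,
                 p_one_label = if (n_extreme == 0)
                   paste0("< ", format(1 / trials)) else format(p_one),
                 direction = direction, trials = trials),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat("shuffle test (", x$trials, " trials)\n",
      "  observed statistic: ", format(x$m_obs), "\n",
      "  Pl = ", format(x$pl), ", Pu = ", format(x$pu),
      ", P (printed form) = ", format(x$p_printed), "\n",
      "  one-tailed (", x$direction, "): ", x$p_one_label, "\n", sep = "")
  invisible(x)
}
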
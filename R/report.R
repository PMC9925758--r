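# Contingency reporting helpers.
#
# Published SV-vs-feature summaries are ratios of printed counts (e.g.
# "12.4% of tandem duplications (189 out of 1526) overlapped piRNA loci").
# These helpers turn observed counts into the same printed percentages, so
# a pipeline run and a published table can be compared number for number.

#' Percentage of counts, rounded as printed
#'
#' @param n_in Numerator count(s).
#' @param n_total Denominator count(s).
#' @param digits Decimal places to print (default 1).
#' @return Numeric percentage(s), `round(100 * n_in / n_total, digits)`.
#' @export
overlap_percentage <- function(n_in, n_total, digits = 1) {
  stopifnot(all(n_total > 0), all(n_in >= 0), all(n_in <= n_total))
  round(100 * n_in / n_total, digits)
}

#' SV-type by feature contingency report
#'
#' @param counts data.frame with columns `type`, `n_in` (events inside the
#'   feature set) and `n_total` (all events of that type).
#' @param digits Decimal places (default 1).
#' @return `counts` with a `pct` column appended.
#' @export
sv_overlap_report <- function(counts, digits = 1) {
  stopifnot(all(c("type", "n_in", "n_total") %in% names(counts)))
  counts$pct <- overlap_percentage(counts$n_in, counts$n_total, digits)
  counts
}

#' Count SV events per type falling into a feature set
#'
#' @param svs SV data.frame.
#' @param features Interval data.frame.
#' @param elements "midpoint" (events counted by midpoint containment) or
#'   "overlap" (by >= 1 bp interval overlap).
#' @return data.frame type, n_in, n_total, pct.
#' @export
sv_feature_counts <- function(svs, features, elements = c("midpoint", "overlap")) {
  elements <- match.arg(elements)
  types <- intersect(SV_TYPES, unique(svs$sv_type))
  rows <- lapply(types, function(tp) {
    x <- svs[svs$sv_type == tp, , drop = FALSE]
    n_in <- if (elements == "midpoint")
      sum(points_in_intervals(x$chrom, sv_midpoint(x), features))
    else sum(overlaps_any(x, features))
    data.frame(type = tp, n_in = n_in, n_total = nrow(x),
               stringsAsFactors = FALSE)
  })
  sv_overlap_report(do.call(rbind, rows))
}
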
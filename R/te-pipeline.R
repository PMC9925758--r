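# Classification of candidate TE-induced insertions and JC69 dating.
#
# Candidate insertion sequences come with BLAST-style hits against TE
# family consensus sequences.  After an e-value cutoff and the 80-80-80
# rule (> 80% identity, alignment > 80% of consensus length, < 20% gaps;
# the length rule is waived for LINEs, whose 5' ends are habitually
# truncated during target-primed reverse transcription), each insertion is
# pushed through an exclusive decision cascade:
#   solo LTR          - a single complete LTR spanning the insertion
#   intact ERV        - LTR-internal-LTR structure, with the extra
#                       requirement that the insertion site not fall on a
#                       solo LTR annotated in the reference (else it is an
#                       ancestral recombination/deletion, not a new hop)
#   non-LTR (LINE)    - the consensus 3' terminus must sit at an insertion
#                       end (reverse transcription starts from the 3' end,
#                       so a 3' end in the middle of the insertion betrays
#                       an ancestral deletion); 5' truncation is allowed,
#                       with a 200 bp minimum 3' block
# Everything else receives a specific rejected_* status.

TE_STATUSES <- c("solo_LTR", "intact_ERV", "nonLTR_transposition",
                 "rejected_no_hit", "rejected_incomplete_ends",
                 "rejected_internal_3prime", "rejected_not_TE_bounded",
                 "rejected_reference_soloLTR", "rejected_filters")

#' Construct a TE hit table
#'
#' BLAST-outfmt-6-like evidence of an insertion sequence aligned to a TE
#' family consensus.  Coordinates are 0-based half-open on both axes.
#'
#' @param insertion_id,family,te_class Identifiers; te_class one of LTR,
#'   LTR_internal, LINE, SINE, DNA.
#' @param q_start,q_end Alignment span on the insertion.
#' @param s_start,s_end Alignment span on the consensus.
#' @param pident Percent identity (0-100).
#' @param aln_len Alignment length (bp).
#' @param gap_frac Gap fraction of the alignment.
#' @param evalue E-value.
#' @param consensus_len Consensus length (bp).
#' @param orientation "+" or "-".
#' @return data.frame of hits.
#' @export
te_hits <- function(insertion_id, family, te_class, q_start, q_end,
                    s_start, s_end, pident, aln_len, gap_frac, evalue,
                    consensus_len, orientation = "+") {
  x <- data.frame(insertion_id = as.character(insertion_id),
                  family = as.character(family),
                  te_class = as.character(te_class),
                  q_start = as.numeric(q_start), q_end = as.numeric(q_end),
                  s_start = as.numeric(s_start), s_end = as.numeric(s_end),
                  pident = as.numeric(pident), aln_len = as.numeric(aln_len),
                  gap_frac = as.numeric(gap_frac),
                  evalue = as.numeric(evalue),
                  consensus_len = as.numeric(consensus_len),
                  orientation = rep_len(as.character(orientation),
                                        length(insertion_id)),
                  stringsAsFactors = FALSE)
  stopifnot(all(x$q_start < x$q_end), all(x$pident >= 0 & x$pident <= 100),
            all(x$evalue >= 0),
            all(x$te_class %in% c("LTR", "LTR_internal", "LINE", "SINE", "DNA")))
  x
}

#' Read a TE hit table (BLAST outfmt-6 style TSV + consensus sidecar)
#'
#' @param path Hits TSV with columns insertion_id, family, te_class,
#'   q_start, q_end, s_start, s_end, pident, aln_len, gap_frac, evalue,
#'   orientation.
#' @param consensus_lengths Named vector of consensus lengths, or a
#'   two-column TSV path (family, length).
#' @return Hit data.frame.
#' @export
read_te_hits <- function(path, consensus_lengths) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (is.character(consensus_lengths) && length(consensus_lengths) == 1) {
    cl <- utils::read.table(consensus_lengths, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    consensus_lengths <- stats::setNames(cl$length, cl$family)
  }
  df$consensus_len <- as.numeric(consensus_lengths[df$family])
  if (anyNA(df$consensus_len))
    stop("missing consensus length for family ",
         df$family[which(is.na(df$consensus_len))[1]])
  do.call(te_hits, df[c("insertion_id", "family", "te_class", "q_start",
                        "q_end", "s_start", "s_end", "pident", "aln_len",
                        "gap_frac", "evalue", "consensus_len",
                        "orientation")])
}

#' Filter TE hits: e-value cutoff and the 80-80-80 rule
#'
#' Keeps hits with `evalue <= evalue_max`, `pident > 80`,
#' `aln_len > 0.8 * consensus_len` and `gap_frac < 0.2`.  The alignment-
#' length rule is waived for classes in `waive_length_classes` (LINEs by
#' default: 5'-truncated copies are legitimate transposition products and
#' are instead held to the 3'-anchored rule by [classify_insertion()]).
#'
#' @param hits Hit data.frame.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @param min_pident,min_len_frac,max_gap_frac Rule thresholds.
#' @param waive_length_classes Classes exempt from the length rule.
#' @return Filtered hit data.frame.
#' @export
filter_hits <- function(hits, evalue_max = 1e-10, min_pident = 80,
                        min_len_frac = 0.8, max_gap_frac = 0.2,
                        waive_length_classes = "LINE") {
  keep <- hits$evalue <= evalue_max &
    hits$pident > min_pident &
    hits$gap_frac < max_gap_frac &
    (hits$te_class %in% waive_length_classes |
       hits$aln_len > min_len_frac * hits$consensus_len)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one candidate insertion
#'
#' @param insertion_len Length of the assembled insertion sequence (bp).
#' @param hits Filtered hits for this insertion ([filter_hits()] output).
#' @param insertion_site One-row interval: where the insertion sits on the
#'   reference.
#' @param reference_solo_ltrs Interval data.frame of solo LTRs annotated
#'   in the reference genome (used to reject ancestral ERV deletions).
#' @param end_tol Tolerance in bp for "reaches a terminus" checks
#'   (default 20).
#' @param min_line_3p_block Minimum 3'-anchored alignment block for the
#'   LINE path (default 200 bp).
#' @return list: insertion_id, status (one of the `TE_STATUSES`), families
#'   (character vector over contributing hits for accepted calls), note.
#' @export
classify_insertion <- function(insertion_len, hits, insertion_site = NULL,
                               reference_solo_ltrs = NULL, end_tol = 20,
                               min_line_3p_block = 200) {
  id <- if (nrow(hits)) hits$insertion_id[1] else NA_character_
  res <- function(status, families = character(), note = "")
    list(insertion_id = id, status = status, families = families, note = note)
  if (!nrow(hits)) return(res("rejected_no_hit"))

  # (b) the insertion must start and end with TE sequence
  if (min(hits$q_start) > end_tol || max(hits$q_end) < insertion_len - end_tol)
    return(res("rejected_not_TE_bounded"))

  at5 <- hits[hits$q_start <= end_tol, , drop = FALSE]
  at3 <- hits[hits$q_end >= insertion_len - end_tol, , drop = FALSE]
  term_classes <- unique(c(at5$te_class, at3$te_class))

  if ("LINE" %in% term_classes && length(setdiff(term_classes, "LINE")))
    return(res("rejected_filters", note = "ambiguous"))

  if (identical(term_classes, "LINE")) {
    lh <- hits[hits$te_class == "LINE", , drop = FALSE]
    # hits whose alignment reaches the consensus 3' terminus
    three <- lh[lh$s_end >= lh$consensus_len - end_tol, , drop = FALSE]
    if (!nrow(three)) return(res("rejected_incomplete_ends"))
    # orientation-aware: on "+" the element 3' end is at the q_end side
    at_end <- (three$orientation == "+" &
                 three$q_end >= insertion_len - end_tol) |
              (three$orientation == "-" & three$q_start <= end_tol)
    if (!any(at_end)) return(res("rejected_internal_3prime"))
    ok <- three[at_end & three$aln_len >= min_line_3p_block, , drop = FALSE]
    if (!nrow(ok))
      return(res("rejected_filters", note = "3' block below minimum"))
    return(res("nonLTR_transposition", families = unique(ok$family)))
  }

  # LTR / DNA path: terminal hits must be complete on the consensus
  ltr5 <- at5[at5$te_class %in% c("LTR", "DNA"), , drop = FALSE]
  ltr3 <- at3[at3$te_class %in% c("LTR", "DNA"), , drop = FALSE]
  if (!nrow(ltr5) || !nrow(ltr3))
    return(res("rejected_filters", note = "ambiguous"))
  complete <- function(h)
    h[h$s_start <= end_tol & h$s_end >= h$consensus_len - end_tol, ,
      drop = FALSE]
  c5 <- complete(ltr5); c3 <- complete(ltr3)
  if (!nrow(c5) || !nrow(c3)) return(res("rejected_incomplete_ends"))
  fams <- intersect(c5$family, c3$family)
  if (!length(fams))
    return(res("rejected_filters", note = "ambiguous"))

  internal <- hits[hits$te_class == "LTR_internal", , drop = FALSE]
  single_ltr <- any(c5$family %in% fams & c5$q_end >= insertion_len - end_tol)
  if (single_ltr && !nrow(internal))
    return(res("solo_LTR", families = fams))
  if (nrow(internal)) {
    # require LTR - internal - LTR order along the insertion
    ordered <- any(vapply(seq_len(nrow(internal)), function(i)
      any(c5$q_end <= internal$q_start[i] + end_tol) &&
        any(c3$q_start >= internal$q_end[i] - end_tol), logical(1)))
    if (!ordered) return(res("rejected_filters", note = "ambiguous"))
    if (!is.null(insertion_site) && !is.null(reference_solo_ltrs) &&
        nrow(reference_solo_ltrs) &&
        any(overlaps_any(insertion_site, reference_solo_ltrs)))
      return(res("rejected_reference_soloLTR",
                 note = "insertion site on a reference solo LTR"))
    return(res("intact_ERV",
               families = unique(c(fams, internal$family))))
  }
  # two complete LTRs but no internal sequence and no single spanning LTR
  res("rejected_filters", note = "LTRs without internal structure")
}

#' Classify a set of insertions
#'
#' @param insertions data.frame with columns insertion_id, length, chrom,
#'   start, end (reference anchor of each insertion).
#' @param hits Filtered hit table for all insertions.
#' @param reference_solo_ltrs Reference solo-LTR interval set.
#' @param ... Passed to [classify_insertion()].
#' @return data.frame: insertion_id, status, families (comma-joined),
#'   note.
#' @export
classify_insertions <- function(insertions, hits, reference_solo_ltrs = NULL,
                                ...) {
  rows <- lapply(seq_len(nrow(insertions)), function(i) {
    id <- insertions$insertion_id[i]
    h <- hits[hits$insertion_id == id, , drop = FALSE]
    site <- insertions[i, c("chrom", "start", "end"), drop = FALSE]
    cl <- classify_insertion(insertions$length[i], h, insertion_site = site,
                             reference_solo_ltrs = reference_solo_ltrs, ...)
    data.frame(insertion_id = id, status = cl$status,
               families = paste(sort(cl$families), collapse = ","),
               note = cl$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Active TE families from accepted insertion calls
#'
#' Unions families over accepted calls and, for accepted solo-LTR or
#' intact-ERV families, adds the internal counterpart from the supplied
#' LTR-internal name map (Repbase annotates LTRs and internal sequences as
#' separate families).  DNA-transposon families are reported separately
#' from the retrotransposon set.
#'
#' @param calls Output of [classify_insertions()].
#' @param ltr_internal_map data.frame with columns ltr, internal.
#' @param family_classes Optional named vector family -> te_class used to
#'   split DNA transposons out.
#' @return list: `retrotransposon` and `dna` character vectors of family
#'   names.
#' @export
call_active_families <- function(calls, ltr_internal_map = NULL,
                                 family_classes = NULL) {
  acc <- calls[calls$status %in% c("solo_LTR", "intact_ERV",
                                   "nonLTR_transposition"), , drop = FALSE]
  fams <- unique(unlist(strsplit(acc$families[nzchar(acc$families)], ",")))
  if (is.null(fams)) fams <- character()
  ltr_calls <- acc[acc$status %in% c("solo_LTR", "intact_ERV"), , drop = FALSE]
  ltr_fams <- unique(unlist(strsplit(ltr_calls$families[nzchar(ltr_calls$families)],
                                     ",")))
  if (!is.null(ltr_internal_map) && length(ltr_fams)) {
    hit <- ltr_internal_map$ltr %in% ltr_fams
    fams <- union(fams, ltr_internal_map$internal[hit])
    unmapped <- setdiff(ltr_fams, c(ltr_internal_map$ltr,
                                    ltr_internal_map$internal))
    if (length(unmapped))
      warning("no internal counterpart mapped for: ",
              paste(unmapped, collapse = ", "))
  }
  fams <- sort(fams)
  if (!is.null(family_classes)) {
    dna <- fams[!is.na(family_classes[fams]) & family_classes[fams] == "DNA"]
    list(retrotransposon = setdiff(fams, dna), dna = dna)
  } else {
    list(retrotransposon = fams, dna = character())
  }
}

#' Jukes-Cantor (1969) corrected divergence
#'
#' `K = -(3/4) ln(1 - (4/3) p)` for observed mismatch proportion p.
#' @param p Proportion of mismatched aligned sites, `0 <= p < 0.75`.
#' @return K, substitutions per site.
#' @export
jc69_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("JC69 undefined for divergence >= 0.75 (saturation)")
  -0.75 * log(1 - 4 * p / 3)
}

#' TE family age from consensus divergence
#'
#' Per family the mean per-copy divergence p is corrected with JC69 and
#' converted to age = K / r using a neutral substitution rate r (default
#' 1.9e-3 substitutions/site/My).  Divergence from the consensus proxies
#' single-lineage divergence from the ancestral state, hence K/r rather
#' than K/(2r).
#'
#' @param copies data.frame with columns family and p (per-copy mismatch
#'   proportion vs consensus, gaps excluded).
#' @param rate Substitutions per site per million years.
#' @return list with `families` (data.frame: family, n_copies, p_mean, K,
#'   age_my) and `median_age_my` (cohort median).
#' @export
estimate_age <- function(copies, rate = 1.9e-3) {
  stopifnot(is.data.frame(copies), all(c("family", "p") %in% names(copies)))
  if (any(copies$p < 0 | copies$p >= 0.75))
    stop("JC69 undefined for divergence >= 0.75 (saturation)")
  fam <- sort(unique(copies$family))
  rows <- lapply(fam, function(f) {
    p <- copies$p[copies$family == f]
    pm <- mean(p)
    K <- jc69_distance(pm)
    data.frame(family = f, n_copies = length(p), p_mean = pm, K = K,
               age_my = K / rate, stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, rows)
  list(families = families, median_age_my = stats::median(families$age_my))
}
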
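#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Chromosome sizes
# ---------------------------------------------------------------------------

#' Construct a chromosome-size map
#'
#' A named integer vector mapping chromosome names to lengths in bp.  All
#' coordinates in this package are 0-based half-open, so a chromosome of
#' length L spans positions [0, L).
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Positive integer lengths (bp), one per name.
#' @return Named numeric vector of class `chrom_sizes`.
#' @export
chrom_sizes <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths))
    stop("names and lengths must have equal length")
  if (anyDuplicated(names))
    stop("duplicate chromosome names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  structure(stats::setNames(lengths, names), class = "chrom_sizes")
}

#' Read a chrom.sizes file (name, length TSV)
#' @param path Path to a two-column TSV.
#' @return `chrom_sizes` vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  chrom_sizes(df$chrom, df$length)
}

#' Write a chrom.sizes file
#' @param sizes `chrom_sizes` vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  o <- order(names(sizes))
  utils::write.table(data.frame(names(sizes)[o], unname(sizes)[o]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genomic intervals (0-based half-open, BED-style)
# ---------------------------------------------------------------------------

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, matching BED.  Strand is
#' `"+"`, `"-"` or `"*"` (unstranded).
#'
#' @param chrom Chromosome names.
#' @param start,end Interval bounds, `0 <= start < end`.
#' @param strand Strand per interval (recycled).
#' @param name Optional labels (recycled).
#' @param sizes Optional `chrom_sizes` used to bounds-check.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NA_character_,
                              sizes = NULL) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  name = rep_len(as.character(name), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  validate_intervals(x, sizes)
  x
}

#' Validate an interval set
#' @param x Interval data.frame.
#' @param sizes Optional `chrom_sizes` for bounds checks.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x, sizes = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at record ", bad[1],
         ": ", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]])
  if (!is.null(x[["strand"]])) {
    badstr <- which(!x[["strand"]] %in% c("+", "-", "*"))
    if (length(badstr))
      stop("invalid strand at record ", badstr[1], ": ",
           x[["strand"]][badstr[1]])
  }
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(x$chrom), names(sizes))
    if (length(unknown))
      stop("chromosome not in sizes: ", unknown[1])
    oob <- which(x$end > sizes[x$chrom])
    if (length(oob))
      stop("interval out of chromosome bounds at record ", oob[1],
           ": ", x$chrom[oob[1]], ":", x$start[oob[1]], "-", x$end[oob[1]])
  }
  invisible(x)
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Read intervals from BED (3-6 columns)
#'
#' @param path BED file path.
#' @param sizes Optional `chrom_sizes`; intervals are bounds-checked.
#' @return Interval data.frame; strand honoured when a 6th column is
#'   present, otherwise `"*"`.
#' @export
read_intervals <- function(path, sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)|^\\s*$", lines)
  idx <- which(keep)
  if (!length(idx))
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", idx[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum))
    stop("malformed BED line ", idx[badnum[1]], ": non-numeric coordinates")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  name[name == "."] <- NA_character_
  strand <- rep("*", length(idx))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  x <- data.frame(chrom = chrom, start = start, end = end,
                  name = name, strand = strand, stringsAsFactors = FALSE)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop("invalid interval at BED line ", idx[bad[1]], ": ",
         x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]],
         " (zero/negative length)")
  validate_intervals(x, sizes)
  x
}

#' Write intervals as BED6 (sorted, deterministic)
#' @param x Interval data.frame.
#' @param path Output path.
#' @param extra Optional data.frame of extra columns appended after BED6.
#' @export
write_intervals <- function(x, path, extra = NULL) {
  x <- as.data.frame(x)
  if (is.null(x$name)) x$name <- NA_character_
  if (is.null(x$strand)) x$strand <- "*"
  o <- order(x$chrom, x$start, x$end)
  out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                    ifelse(is.na(x$name), ".", x$name), 0,
                    ifelse(x$strand == "*", ".", x$strand),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  utils::write.table(out[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Interval overlap test against a feature set
#'
#' @param x,features Interval data.frames (half-open coordinates).
#' @return Logical vector: does each interval of `x` overlap >= 1 bp of any
#'   feature?
#' @export
overlaps_any <- function(x, features) {
  out <- logical(nrow(x))
  if (!nrow(x) || !nrow(features)) return(out)
  for (ch in unique(x$chrom)) {
    fi <- features$chrom == ch
    if (!any(fi)) next
    xi <- which(x$chrom == ch)
    fs <- features$start[fi]; fe <- features$end[fi]
    out[xi] <- vapply(xi, function(i)
      any(x$start[i] < fe & x$end[i] > fs), logical(1))
  }
  out
}

#' Are points contained in a feature set?
#' @param chrom,pos Point coordinates (0-based).
#' @param features Interval data.frame.
#' @return Logical vector.
#' @export
points_in_intervals <- function(chrom, pos, features) {
  out <- logical(length(chrom))
  if (!length(chrom) || !nrow(features)) return(out)
  for (ch in unique(chrom)) {
    fi <- features$chrom == ch
    if (!any(fi)) next
    xi <- which(chrom == ch)
    fs <- features$start[fi]; fe <- features$end[fi]
    out[xi] <- vapply(pos[xi], function(p) any(p >= fs & p < fe), logical(1))
  }
  out
}

# ---------------------------------------------------------------------------
# Structural-variant records
# ---------------------------------------------------------------------------

SV_TYPES <- c("INS", "DEL", "INV", "DUP")
MIN_SV_LEN <- 50

#' Construct structural-variant records
#'
#' An SV is a mutation >= 50 bp.  For INS the interval is a 1-bp anchor at
#' the insertion point and `seq`, when present, has length `sv_len`; for
#' DEL/INV/DUP `end - start == sv_len`.
#'
#' @param chrom,start,end Anchoring interval (0-based half-open).
#' @param sv_type One of INS, DEL, INV, DUP.
#' @param sv_len Event length in bp (>= 50).
#' @param support Supporting read count.
#' @param score Caller score.
#' @param caller Caller label.
#' @param seq Optional inserted sequence (INS only), NA otherwise.
#' @param sizes Optional `chrom_sizes`.
#' @return data.frame of validated SV records.
#' @export
sv_records <- function(chrom, start, end, sv_type, sv_len, support, score,
                       caller = "caller", seq = NA_character_, sizes = NULL) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), sv_type = as.character(sv_type),
                  sv_len = as.numeric(sv_len), support = as.numeric(support),
                  score = as.numeric(score),
                  caller = rep_len(as.character(caller), n),
                  seq = rep_len(as.character(seq), n),
                  stringsAsFactors = FALSE)
  validate_sv(x, sizes)
  x
}

#' Validate SV records
#' @param x SV data.frame.
#' @param sizes Optional `chrom_sizes`.
#' @export
validate_sv <- function(x, sizes = NULL) {
  bad <- which(!x$sv_type %in% SV_TYPES)
  if (length(bad))
    stop("unknown sv_type at record ", bad[1], ": ", x$sv_type[bad[1]])
  if (any(x$sv_len < MIN_SV_LEN))
    stop("SV shorter than ", MIN_SV_LEN, " bp at record ",
         which(x$sv_len < MIN_SV_LEN)[1])
  ins <- x$sv_type == "INS"
  bad <- which(ins & (x$end - x$start) != 1)
  if (length(bad))
    stop("INS record ", bad[1], " must anchor on a 1-bp interval")
  bad <- which(ins & !is.na(x$seq) & nchar(x$seq) != x$sv_len)
  if (length(bad))
    stop("INS record ", bad[1], ": inserted_seq length != sv_len")
  bad <- which(!ins & (x$end - x$start) != x$sv_len)
  if (length(bad))
    stop("record ", bad[1], ": end - start != sv_len for ", x$sv_type[bad[1]])
  validate_intervals(x, sizes)
  invisible(x)
}

#' Midpoint (event point) of each SV
#'
#' INS events are represented by their anchor base; DEL/INV/DUP by the
#' midpoint of their span.
#' @param x SV data.frame.
#' @return Numeric vector of 0-based positions.
#' @export
sv_midpoint <- function(x) {
  ifelse(x$sv_type == "INS", x$start, floor((x$start + x$end) / 2))
}

#' Read SV calls from TSV or minimal VCF
#'
#' TSV columns: chrom, start, end, type, length, support, score, caller and
#' optional seq.  The VCF reader understands the SVTYPE/SVLEN/END/RE info
#' keys and a SEQ key for inserted sequence; VCF POS (1-based) is converted
#' to the package's 0-based convention on read.  Records shorter than 50 bp
#' are rejected with a warning reporting the rejection count.
#'
#' @param path Input file.
#' @param sizes Optional `chrom_sizes`.
#' @param format "auto" (by extension/content), "tsv" or "vcf".
#' @return Validated SV data.frame; attribute `n_rejected` carries the
#'   number of sub-50-bp records dropped.
#' @export
read_sv_calls <- function(path, sizes = NULL, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^##fileformat=VCF", first)) "vcf" else "tsv"
  }
  x <- if (format == "vcf") read_sv_vcf(path) else read_sv_tsv(path)
  short <- x$sv_len < MIN_SV_LEN
  n_rejected <- sum(short)
  if (n_rejected > 0) {
    warning(n_rejected, " SV record(s) shorter than ", MIN_SV_LEN,
            " bp rejected")
    x <- x[!short, , drop = FALSE]
    rownames(x) <- NULL
  }
  validate_sv(x, sizes)
  attr(x, "n_rejected") <- n_rejected
  x
}

read_sv_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "start", "end", "type", "length", "support", "score",
            "caller")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SV TSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$type %in% SV_TYPES)
  if (length(bad))
    stop("unknown sv_type at record ", bad[1], ": ", df$type[bad[1]])
  data.frame(chrom = as.character(df$chrom), start = as.numeric(df$start),
             end = as.numeric(df$end), sv_type = df$type,
             sv_len = as.numeric(df$length), support = as.numeric(df$support),
             score = as.numeric(df$score), caller = as.character(df$caller),
             seq = if ("seq" %in% names(df)) as.character(df$seq)
                   else NA_character_,
             stringsAsFactors = FALSE)
}

read_sv_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body))
    return(sv_records(character(), numeric(), numeric(), character(),
                      numeric(), numeric(), numeric()))
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  recs <- lapply(f, function(v) {
    if (length(v) < 8) stop("malformed VCF record: ", paste(v, collapse = " "))
    info <- v[8]
    svtype <- info_get(info, "SVTYPE")
    if (is.na(svtype) || !svtype %in% SV_TYPES)
      stop("unknown sv_type in VCF record at ", v[1], ":", v[2], ": ", svtype)
    pos0 <- as.numeric(v[2]) - 1   # 1-based VCF POS -> 0-based
    svlen <- abs(as.numeric(info_get(info, "SVLEN")))
    endf <- info_get(info, "END")
    seq <- info_get(info, "SEQ")
    re <- info_get(info, "RE")
    if (svtype == "INS") {
      start <- pos0; end <- pos0 + 1
      if (is.na(svlen) && !is.na(seq)) svlen <- nchar(seq)
    } else {
      start <- pos0
      end <- if (!is.na(endf)) as.numeric(endf) else pos0 + svlen
      svlen <- end - start
    }
    score <- suppressWarnings(as.numeric(v[6]))
    data.frame(chrom = v[1], start = start, end = end, sv_type = svtype,
               sv_len = svlen,
               support = if (!is.na(re)) as.numeric(re) else NA_real_,
               score = if (is.na(score)) NA_real_ else score,
               caller = "vcf",
               seq = if (svtype == "INS") seq else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write SV records as TSV (sorted, deterministic)
#' @param x SV data.frame.
#' @param path Output path.
#' @export
write_sv_calls <- function(x, path) {
  o <- order(x$chrom, x$start, x$end, x$sv_type)
  out <- data.frame(chrom = x$chrom, start = format_coord(x$start),
                    end = format_coord(x$end), type = x$sv_type,
                    length = format_coord(x$sv_len), support = x$support,
                    score = x$score, caller = x$caller,
                    seq = ifelse(is.na(x$seq), ".", x$seq))
  utils::write.table(out[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Collapsed small-RNA species
# ---------------------------------------------------------------------------

#' Construct a collapsed small-RNA species set
#'
#' Species are collapsed reads: one row per distinct sequence with a count
#' (real-valued, because oxidized-library calibration rescales counts) and a
#' table of genomic mappings.  For a minus-strand mapping `pos5` is the
#' highest genomic coordinate covered by the read (its 5' base).
#'
#' @param species data.frame with columns id, seq, count (length and
#'   n_mappings are derived).
#' @param mappings data.frame with columns id, chrom, pos5, strand; may be
#'   empty.
#' @return list of class `smallrna_set` with elements `species` (id, seq,
#'   length, count, n_mappings, unique) and `mappings`.
#' @export
smallrna_set <- function(species, mappings = NULL) {
  stopifnot(is.data.frame(species), all(c("id", "seq", "count") %in% names(species)))
  if (any(species$count < 0)) stop("species counts must be >= 0")
  if (anyDuplicated(species$id)) stop("duplicate species ids")
  if (is.null(mappings))
    mappings <- data.frame(id = character(), chrom = character(),
                           pos5 = numeric(), strand = character(),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos5", "strand") %in% names(mappings)))
  unknown <- setdiff(mappings$id, species$id)
  if (length(unknown)) stop("mapping refers to unknown species: ", unknown[1])
  nmap <- table(mappings$id)
  species$length <- nchar(species$seq)
  species$n_mappings <- as.integer(nmap[species$id])
  species$n_mappings[is.na(species$n_mappings)] <- 0L
  species$unique <- species$n_mappings == 1L
  structure(list(species = species[, c("id", "seq", "length", "count",
                                       "n_mappings", "unique")],
                 mappings = mappings),
            class = "smallrna_set")
}

#' @export
print.smallrna_set <- function(x, ...) {
  cat("smallrna_set:", nrow(x$species), "species,",
      nrow(x$mappings), "mappings, total count",
      format(sum(x$species$count)), "\n")
  invisible(x)
}

#' Read collapsed reads from FASTA (`>id_countN`) or TSV
#'
#' Duplicate sequences are merged by summing counts.  An optional mappings
#' TSV (columns id, chrom, pos5, strand) attaches genomic mappings; ids of
#' merged duplicates are remapped to the surviving species.
#'
#' @param path Collapsed FASTA (headers `>id_count<N>`) or TSV with columns
#'   id, seq, count.
#' @param mappings_path Optional mappings TSV.
#' @return `smallrna_set`.
#' @export
read_collapsed_reads <- function(path, mappings_path = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    headers <- names(ss)
    m <- regmatches(headers, regexec("^(.*)_count([0-9.]+)$", headers))
    badh <- which(lengths(m) != 3)
    if (length(badh))
      stop("FASTA header without parseable count: ", headers[badh[1]])
    id <- vapply(m, `[[`, "", 2L)
    count <- as.numeric(vapply(m, `[[`, "", 3L))
    species <- data.frame(id = id, seq = as.character(ss), count = count,
                          stringsAsFactors = FALSE)
  } else {
    species <- utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    stopifnot(all(c("id", "seq", "count") %in% names(species)))
  }
  if (any(is.na(species$count) | species$count <= 0))
    stop("non-positive or unparseable count in collapsed reads")
  # merge duplicate sequences, summing counts; keep first id
  alias <- stats::setNames(species$id, species$id)
  if (anyDuplicated(species$seq)) {
    keep_id <- tapply(species$id, species$seq, `[[`, 1L)
    alias <- stats::setNames(unname(keep_id[species$seq]), species$id)
    agg <- stats::aggregate(count ~ seq, data = species, FUN = sum)
    agg$id <- unname(keep_id[agg$seq])
    species <- agg[, c("id", "seq", "count")]
  }
  mappings <- NULL
  if (!is.null(mappings_path)) {
    mappings <- utils::read.table(mappings_path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    stopifnot(all(c("id", "chrom", "pos5", "strand") %in% names(mappings)))
    mappings$id <- unname(alias[mappings$id])
    mappings <- unique(mappings)
  }
  smallrna_set(species, mappings)
}

#' Write collapsed reads as FASTA plus optional mappings TSV
#' @param x `smallrna_set`.
#' @param path FASTA output path.
#' @param mappings_path Optional mappings TSV output path.
#' @export
write_collapsed_reads <- function(x, path, mappings_path = NULL) {
  sp <- x$species[order(x$species$id), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(sp$seq)
  names(seqs) <- paste0(sp$id, "_count", format_coord(sp$count))
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(mappings_path)) {
    mp <- x$mappings[order(x$mappings$id, x$mappings$chrom, x$mappings$pos5), ]
    utils::write.table(mp, mappings_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sparse per-base score tracks (bedGraph-backed)
# ---------------------------------------------------------------------------

#' Construct a score track
#'
#' Stored run-length style as bedGraph ranges; positions not covered by any
#' range carry `fill`.
#'
#' @param chrom,start,end,value Range-encoded per-base values.
#' @param fill Value for uncovered positions (default 0).
#' @param sizes Optional `chrom_sizes`.
#' @return list of class `score_track`.
#' @export
score_track <- function(chrom, start, end, value, fill = 0, sizes = NULL) {
  rng <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  validate_intervals(rng, sizes)
  structure(list(ranges = rng, fill = fill), class = "score_track")
}

#' Read a bedGraph file into a score track
#' @param path bedGraph path.
#' @param fill Fill value for uncovered positions.
#' @param sizes Optional `chrom_sizes`.
#' @return `score_track`.
#' @export
read_bedgraph <- function(path, fill = 0, sizes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", rep("numeric", 3)),
                          comment.char = "#")
  score_track(df$chrom, df$start, df$end, df$value, fill = fill, sizes = sizes)
}

#' Write a score track as bedGraph
#' @param track `score_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- track$ranges
  o <- order(r$chrom, r$start)
  out <- data.frame(r$chrom, format_coord(r$start), format_coord(r$end),
                    r$value)
  utils::write.table(out[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean track value over each interval
#'
#' Uncovered bases contribute the track's fill value.
#' @param track `score_track`.
#' @param intervals Interval data.frame.
#' @return Numeric vector of per-interval means.
#' @export
track_mean <- function(track, intervals) {
  r <- track$ranges
  vapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]; s <- intervals$start[i]; e <- intervals$end[i]
    ri <- which(r$chrom == ch & r$start < e & r$end > s)
    width <- e - s
    if (!length(ri)) return(track$fill)
    ov_s <- pmax(r$start[ri], s); ov_e <- pmin(r$end[ri], e)
    covered <- sum(ov_e - ov_s)
    (sum((ov_e - ov_s) * r$value[ri]) + (width - covered) * track$fill) / width
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Small-RNA library container
# ---------------------------------------------------------------------------

#' Construct a small-RNA library
#'
#' @param label Library name.
#' @param rna `smallrna_set` of genome-mapping species.
#' @param mirna_total Total reads assigned to the miRNA pool (used for
#'   between-library normalization).
#' @param is_oxidized Was the library oxidized (NaIO4-treated) to enrich
#'   2'-O-methylated piRNAs?
#' @return list of class `smallrna_library`.
#' @export
smallrna_library <- function(label, rna, mirna_total, is_oxidized = FALSE) {
  stopifnot(inherits(rna, "smallrna_set"), mirna_total >= 0)
  structure(list(label = label, rna = rna,
                 mirna_total = as.numeric(mirna_total),
                 is_oxidized = isTRUE(is_oxidized)),
            class = "smallrna_library")
}

#' Total genome-mapping read count of a library (all lengths)
#' @param lib `smallrna_library`.
#' @return Numeric scalar.
#' @export
library_total <- function(lib) sum(lib$rna$species$count)

#' @export
print.smallrna_library <- function(x, ...) {
  cat("smallrna_library '", x$label, "': ", nrow(x$rna$species),
      " species, total ", format(library_total(x)),
      if (x$is_oxidized) " (oxidized)", "\n", sep = "")
  invisible(x)
}
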
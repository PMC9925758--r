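# Ping-pong and periodicity signatures.
#
# The ping-pong signature of piRNA-guided cleavage is an excess of
# sense/antisense read pairs whose 5' ends overlap by exactly 10 nt.  For
# a plus-strand 5' end at p and a minus-strand 5' end at q on the same
# chromosome (q being the highest coordinate covered by the minus read),
# the overlap extension is k = q - p + 1; each pair contributes the
# product of the two species' read counts to S(k).  3'-end heterogeneity
# is ignored.  The Z-score at k = 10 uses k in {1..9, 11..30} as
# background with a population (n-denominator) standard deviation.

PP_KMAX <- 30L

#' 5'-5' overlap spectrum between opposite-strand reads
#'
#' @param rna `smallrna_set` (or the `rna` element of a library).
#' @param region Optional interval data.frame restricting the mappings
#'   considered (5'-base containment).
#' @return Named numeric vector `S` of length 30, `S[k]` = summed count
#'   products over pairs with overlap extension k.
#' @export
overlap_spectrum <- function(rna, region = NULL) {
  if (inherits(rna, "smallrna_library")) rna <- rna$rna
  mp <- rna$mappings
  sp <- rna$species
  S <- stats::setNames(numeric(PP_KMAX), seq_len(PP_KMAX))
  if (!nrow(mp)) return(S)
  cnt <- sp$count[match(mp$id, sp$id)]
  if (!is.null(region)) {
    keep <- points_in_intervals(mp$chrom, mp$pos5, region)
    mp <- mp[keep, , drop = FALSE]; cnt <- cnt[keep]
    if (!nrow(mp)) return(S)
  }
  for (ch in unique(mp$chrom)) {
    sel <- mp$chrom == ch
    plus <- mp$strand[sel] == "+"
    if (!any(plus) || all(plus)) next
    cp <- tapply(cnt[sel][plus], mp$pos5[sel][plus], sum)
    cm <- tapply(cnt[sel][!plus], mp$pos5[sel][!plus], sum)
    p <- as.numeric(names(cp)); q <- as.numeric(names(cm))
    for (k in seq_len(PP_KMAX)) {
      i <- match(p + k - 1, q)
      hit <- !is.na(i)
      if (any(hit)) S[k] <- S[k] + sum(cp[hit] * cm[i[hit]])
    }
  }
  S
}

#' Ping-pong Z-score at 10 nt overlap
#'
#' `Z10 = (S(10) - mean(bg)) / sd(bg)` with background k in
#' {1..9, 11..30} and the population standard deviation over those 29
#' values.  Degenerate rule: if `sd(bg) == 0`, Z10 is 0 when S(10) equals
#' the background mean and `Inf` (a flagged extreme) otherwise.
#'
#' @param S Overlap spectrum from [overlap_spectrum()].
#' @return Z10 (numeric scalar).
#' @export
pingpong_z <- function(S) {
  stopifnot(length(S) == PP_KMAX)
  bg <- S[c(1:9, 11:30)]
  m <- mean(bg)
  sdev <- sqrt(mean((bg - m)^2))
  if (sdev == 0) {
    if (S[10] == m) return(0)
    return(Inf)
  }
  (S[[10]] - m) / sdev
}

#' Nucleotide periodicity of ribosome footprints
#'
#' Aligns reads to each other by 5'-end overlap on the same strand and
#' reports the distance spectrum (summed count products at each 5'-5'
#' separation d in 0..D), then its periodogram: the squared modulus of the
#' discrete Fourier transform of the mean-subtracted spectrum, with
#' relative spectral density normalized to the first frequency position.
#'
#' @param rna `smallrna_set` of footprint species.  Enforces the
#'   footprint filter: 26-32 nt, uniquely mapping.
#' @param D Maximum separation in nt (default 100).
#' @return list with `distance_spectrum` (length D + 1, separations
#'   0..D), `freq` (cycles/nt), `power`, and `relative_density`
#'   (power / power at the first frequency).
#' @export
periodicity <- function(rna, D = 100) {
  if (inherits(rna, "smallrna_library")) rna <- rna$rna
  sp <- rna$species
  keep_ids <- sp$id[sp$length >= 26 & sp$length <= 32 & sp$unique]
  mp <- rna$mappings[rna$mappings$id %in% keep_ids, , drop = FALSE]
  if (!nrow(mp)) stop("no 26-32 nt uniquely mapping reads")
  cnt <- sp$count[match(mp$id, sp$id)]
  ds <- numeric(D + 1)
  for (ch in unique(mp$chrom)) {
    for (str in c("+", "-")) {
      sel <- mp$chrom == ch & mp$strand == str
      if (!any(sel)) next
      cp <- tapply(cnt[sel], mp$pos5[sel], sum)
      pos <- as.numeric(names(cp))
      for (d in 0:D) {
        i <- match(pos + d, pos)
        hit <- !is.na(i)
        if (any(hit)) ds[d + 1] <- ds[d + 1] + sum(cp[hit] * cp[i[hit]])
      }
    }
  }
  x <- ds - mean(ds)
  n <- length(x)
  ft <- stats::fft(x)
  nf <- floor(n / 2)
  freq <- seq_len(nf) / n
  power <- Mod(ft[seq_len(nf) + 1])^2 / n
  rel <- if (power[1] > 0) power / power[1] else rep(0, nf)
  if (power[1] == 0 && length(rel)) rel[1] <- 1
  list(distance_spectrum = stats::setNames(ds, 0:D),
       freq = freq, power = power, relative_density = rel)
}
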
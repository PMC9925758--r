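# Shared fixture builders and independent oracles.

tiny_sizes <- function() chrom_sizes(c("chr1", "chr2"), c(1e6, 5e5))

# Build a smallrna_set from parallel vectors of mappings; one species per
# mapping, sequences are arbitrary unique 26-mers unless lengths given.
make_rna <- function(chrom, pos5, strand, count = 1, len = 26,
                     n_extra_mappings = 0) {
  n <- length(pos5)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  count <- rep_len(count, n); len <- rep_len(len, n)
  n_extra <- rep_len(n_extra_mappings, n)
  seqs <- vapply(seq_len(n), function(i)
    paste(c(sample(c("A", "C", "G", "T"), len[i] - 8, replace = TRUE),
            strsplit(sprintf("%08d", i), "")[[1]]), collapse = ""), "")
  seqs <- chartr("0123456789", "ACGTACGTAC", seqs)
  species <- data.frame(id = paste0("r", seq_len(n)), seq = seqs,
                        count = count, stringsAsFactors = FALSE)
  maps <- data.frame(id = species$id, chrom = chrom, pos5 = pos5,
                     strand = strand, stringsAsFactors = FALSE)
  extra <- which(n_extra > 0)
  for (i in extra) {
    maps <- rbind(maps, data.frame(
      id = rep(species$id[i], n_extra[i]),
      chrom = "chr2", pos5 = 4e5 + seq_len(n_extra[i]) * 100 + i,
      strand = "+", stringsAsFactors = FALSE))
  }
  smallrna_set(species, maps)
}

make_library <- function(rna, mirna_total = 1e6, label = "test") {
  smallrna_library(label, rna, mirna_total = mirna_total)
}

# Brute-force maximum-sum contiguous subarray of (a - penalty): exhaustive
# enumeration of all (first, last) pairs via prefix sums, vectorized over
# the end index.  Ties broken by strict improvement only (callers use
# continuous abundances so ties have probability zero).
oracle_max_subarray <- function(a, penalty) {
  x <- a - penalty
  n <- length(x)
  cs <- cumsum(c(0, x))
  best <- list(first = NA, last = NA, sum = -Inf)
  for (i in seq_len(n)) {
    sums <- cs[(i + 1):(n + 1)] - cs[i]
    j <- which.max(sums)
    if (sums[j] > best$sum)
      best <- list(first = i, last = i + j - 1, sum = sums[j])
  }
  best
}

# Exhaustive O(n^2) 5'-5' overlap spectrum over all opposite-strand
# mapping pairs (the production code uses per-position count joins).
oracle_overlap_spectrum <- function(rna) {
  mp <- rna$mappings
  sp <- rna$species
  cnt <- sp$count[match(mp$id, sp$id)]
  S <- setNames(numeric(30), 1:30)
  if (nrow(mp) < 2) return(S)
  for (i in seq_len(nrow(mp))) for (j in seq_len(nrow(mp))) {
    if (mp$chrom[i] != mp$chrom[j]) next
    if (!(mp$strand[i] == "+" && mp$strand[j] == "-")) next
    k <- mp$pos5[j] - mp$pos5[i] + 1
    if (k >= 1 && k <= 30) S[k] <- S[k] + cnt[i] * cnt[j]
  }
  S
}

# Random read set on 1-2 chromosomes within a narrow window so overlaps
# in the 1..30 range actually occur.
random_rna <- function(n, span = 60) {
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  make_rna(chrom, sample.int(span, n, replace = TRUE),
           sample(c("+", "-"), n, replace = TRUE),
           count = sample(1:5, n, replace = TRUE))
}
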
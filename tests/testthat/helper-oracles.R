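# Independent brute-force oracle for the information-weighted
# similarity: evaluates the defining formula directly, sharing no code
# with the package implementation.
oracle_similarity <- function(profile, background, seq) {
  bases <- c("A", "C", "G", "T")
  l <- ncol(profile)
  Ij <- numeric(l)
  for (j in seq_len(l)) {
    s <- 0
    for (i in 1:4) {
      p <- profile[i, j]
      if (p > 0) s <- s + p * log2(p / background[i])
    }
    Ij[j] <- s
  }
  letters <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  num <- 0
  den <- 0
  for (j in seq_len(l)) {
    p_obs <- profile[match(letters[j], bases), j]
    num <- num + Ij[j] * (2 * p_obs - 1)
    den <- den + Ij[j] * (2 * max(profile[, j]) - 1)
  }
  num / den
}

# All DNA k-mers of length l, lexicographic.
all_kmers <- function(l) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(bases), l),
                                  stringsAsFactors = FALSE)))
}

# Random frequency PSFM of length l (normalized gamma draws per column).
random_psfm <- function(l, name = "rand") {
  m <- matrix(rgamma(4 * l, shape = 1), nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  PSFM(m, name = name)
}

reverse_complement_chr <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Small soft-maskable genome from explicit sequences.
make_genome <- function(...) {
  Biostrings::BStringSet(c(...))
}

make_regions <- function(chrom, start, end, summit = NA_real_,
                         fold = NA_real_, name = NA_character_) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  GenomicRanges::mcols(gr)$name <- rep_len(name, length(gr))
  GenomicRanges::mcols(gr)$summit <- rep_len(summit, length(gr))
  GenomicRanges::mcols(gr)$fold <- rep_len(fold, length(gr))
  gr
}

make_genes <- function(chrom, start, end, strand, name) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  GenomicRanges::mcols(gr)$name <- name
  gr
}
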
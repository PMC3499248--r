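# Independent oracles used to validate the implementation.  These are
# deliberately naive re-derivations (brute-force DP, codon scans, direct
# tallies) kept separate from the package code paths they check.

# Smith-Waterman score with affine gaps (Gotoh), O(nm) full matrices.
# Gap of length k costs gap_open + k * gap_extend, as in align_scoring().
sw_score_oracle <- function(a, b, scoring = align_scoring()) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) scoring$match else scoring$mismatch
      E[i, j] <- max(H[i, j - 1] - scoring$gap_open - scoring$gap_extend,
                     E[i, j - 1] - scoring$gap_extend)
      F[i, j] <- max(H[i - 1, j] - scoring$gap_open - scoring$gap_extend,
                     F[i - 1, j] - scoring$gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Codon-scan stop finder: positions (1-based codon index) of internal stops.
stop_scan_oracle <- function(seq) {
  n <- nchar(seq) %/% 3
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (substr(seq, 3 * i - 2, 3 * i) %in% c("TAA", "TAG", "TGA"))
      hits <- c(hits, i)
  }
  hits[hits < n]
}

# Fourfold-degeneracy oracle from exhaustive genetic-code lookup: a codon's
# third position is fourfold degenerate iff all four third-base variants
# encode the same amino acid.
fourfold_oracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))]
  if (gc[[codon]] == "*") return(FALSE)
  length(unique(aa)) == 1
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A tiny hand-built genome: two contigs, three genes (one on the minus
# strand, one flagged mobile).
make_toy_genome <- function() {
  g1 <- "ATGAAACCCGGGTAA"                      # 15 bp, + strand
  g2 <- "ATGTTTACACTGTGA"                      # 15 bp, placed on - strand
  g3 <- "ATGGGCGGCTAA"                         # 12 bp mobile element carrier
  c1 <- paste0("TTTTT", g1, "AAAAA",
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(g2))),
               "CCCCC")
  c2 <- paste0("GG", g3, "AT")
  orfs <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    contig_id = c("c1", "c1", "c2"),
    start = c(6, 26, 3),
    end = c(20, 40, 14),
    strand = c("+", "-", "+"),
    cog = c("J", "E", NA),
    is_mobile = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  genome_annotation("toy", c(c1 = c1, c2 = c2), orfs)
}

# Quiet wrapper: erosion fixtures for closed-loop tests.
erode_fixture <- function(seed, n_genes = 300, n_neutral = round(0.4 * n_genes),
                          mutation_budget = 2 * n_neutral, deletion_fraction = 0.1,
                          ...) {
  cfg <- erosion_config(seed = seed, n_genes = n_genes, n_neutral = n_neutral,
                        mutation_budget = mutation_budget,
                        deletion_fraction = deletion_fraction,
                        point_sub_rate_gc4 = 0, point_sub_rate_gc2 = 0,
                        relaxed_gc2_extra = 0, ...)
  anc <- generate_ancestral(cfg)
  er <- erode(anc, cfg)
  list(cfg = cfg, ancestral = anc, derived = er$derived, truth = er$truth)
}
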
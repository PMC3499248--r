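#' Classify genome sites into composition classes
#'
#' Per codon-complete ORF: every second codon position is a GC2 site; the
#' third position of a codon belonging to one of the eight fourfold-degenerate
#' families (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN, judged from the
#' ancestral codon) is a GC4 site.  Stop codons and two-fold families never
#' contribute GC4 sites.  Positions outside any ORF are intergenic (GCI).
#' ORFs whose length is not divisible by 3 are skipped with a warning.
#'
#' @param ann A [genome_annotation()].
#' @return List with `gc2` and `gc4` (named lists: gene_id -> integer vector
#'   of 1-based positions within the ORF sequence) and `intergenic` (named
#'   list: contig -> [IRanges::IRanges] of intergenic positions).
#' @export
classify_sites <- function(ann) {
  gc2 <- list(); gc4 <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(ann$orfs))) {
    seq_i <- ann$orfs$sequence[i]
    if (nchar(seq_i) %% 3 != 0) {
      skipped <- c(skipped, ann$orfs$gene_id[i])
      next
    }
    cls <- site_classes_seq(seq_i)
    gc2[[ann$orfs$gene_id[i]]] <- which(cls == 2L)
    gc4[[ann$orfs$gene_id[i]]] <- which(cls == 4L)
  }
  if (length(skipped))
    warning(length(skipped), " ORF(s) not codon-complete were skipped (",
            paste(utils::head(skipped, 3), collapse = ", "),
            if (length(skipped) > 3) ", ..." else "", ")")
  list(gc2 = gc2, gc4 = gc4, intergenic = intergenic_ranges(ann))
}

#' G+C percentage over a site class
#'
#' @param ann A [genome_annotation()].
#' @param sites A [classify_sites()] result.
#' @param class One of `"gc2"`, `"gc4"`, `"gci"`.
#' @return Percentage; `NA` with a message when the class is empty.
#' @export
gc_percent <- function(ann, sites, class = c("gc4", "gc2", "gci")) {
  class <- match.arg(class)
  if (class == "gci") {
    seqs <- unlist(lapply(names(sites$intergenic), function(ctg) {
      rg <- sites$intergenic[[ctg]]
      if (length(rg) == 0) return(character(0))
      as.character(Biostrings::DNAStringSet(ann$contigs[[ctg]],
                                            start = IRanges::start(rg),
                                            end = IRanges::end(rg)))
    }))
    if (length(seqs) == 0) return(NA_real_)
    return(gc_content(seqs))
  }
  pos <- sites[[class]]
  seqs <- setNames(ann$orfs$sequence, ann$orfs$gene_id)
  bases <- unlist(lapply(names(pos), function(g) {
    if (length(pos[[g]]) == 0) return(character(0))
    strsplit(seq_chars(seqs[[g]], pos[[g]]), "")[[1]]
  }), use.names = FALSE)
  if (length(bases) == 0) return(NA_real_)
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  100 * mean(bases %in% c("G", "C"))
}

# substring extraction of scattered positions as one string
seq_chars <- function(seq, pos) paste(substring(seq, pos, pos), collapse = "")

#' Pairwise divergence at a site class
#'
#' Uncorrected p-distance (substitutions per site) pooled over the chosen
#' genes: for each gene, the class sites of the ancestral ORF are projected
#' through gap-free alignment columns onto the derived locus, and mismatches
#' are counted over comparable sites.  A Jukes-Cantor correction is available
#' behind a flag but the default reports the raw proportion.
#'
#' @param alignments Named list of [align_orf()] objects (names = gene ids).
#' @param sites [classify_sites()] result for the ancestral genome.
#' @param class `"gc2"` or `"gc4"`.
#' @param gene_ids Genes to pool (e.g. the intact or the pseudogene set).
#' @param correction `"none"` (p-distance) or `"JC69"`.
#' @return List: `divergence`, `n_sites`, `n_mismatches` (`divergence` is
#'   `NA` when no comparable site exists).
#' @export
site_divergence <- function(alignments, sites, class = c("gc4", "gc2"),
                            gene_ids = names(alignments),
                            correction = c("none", "JC69")) {
  class <- match.arg(class)
  correction <- match.arg(correction)
  n_sites <- 0L; n_mm <- 0L
  for (g in intersect(gene_ids, names(alignments))) {
    al <- alignments[[g]]
    pos <- sites[[class]][[g]]
    if (is.null(pos) || length(pos) == 0 || length(al$ref_map) == 0) next
    cols <- match(pos, al$ref_map)
    cols <- cols[!is.na(cols)]
    if (!length(cols)) next
    refb <- substring(al$ref_seq, al$ref_map[cols], al$ref_map[cols])
    qryb <- al$qry_at[cols]
    cmp <- refb %in% c("A", "C", "G", "T") & qryb %in% c("A", "C", "G", "T")
    n_sites <- n_sites + sum(cmp)
    n_mm <- n_mm + sum(refb[cmp] != qryb[cmp])
  }
  if (n_sites == 0) return(list(divergence = NA_real_, n_sites = 0L,
                                n_mismatches = 0L))
  p <- n_mm / n_sites
  d <- if (correction == "JC69") -3 / 4 * log(1 - 4 * p / 3) else p
  list(divergence = d, n_sites = n_sites, n_mismatches = n_mm)
}

#' Composition and divergence metrics for an ancestral/derived genome pair
#'
#' Computes the composition box values (GC2, GC4, GCI of the derived genome)
#' and the divergence box values: substitutions per site at second-codon and
#' fourfold-degenerate sites, separately for intact genes (dGC2, dGC4) and
#' pseudogenes (dGC2_psi, dGC4_psi).
#'
#' @param ancestral,derived [genome_annotation()] objects.
#' @param comparison A [compare_genomes()] result for the pair.
#' @return One-row `data.frame`.
#' @export
composition_metrics <- function(ancestral, derived, comparison) {
  anc_sites <- classify_sites(ancestral)
  der_sites <- classify_sites(derived)
  cls <- comparison$classification
  intact <- cls$gene_id[cls$status == "intact"]
  pseudo <- cls$gene_id[cls$status == "pseudogene"]
  al <- comparison$alignments
  data.frame(
    genome_id = derived$genome_id,
    GC2 = gc_percent(derived, der_sites, "gc2"),
    GC4 = gc_percent(derived, der_sites, "gc4"),
    GCI = gc_percent(derived, der_sites, "gci"),
    dGC2 = site_divergence(al, anc_sites, "gc2", intact)$divergence,
    dGC4 = site_divergence(al, anc_sites, "gc4", intact)$divergence,
    dGC2_psi = site_divergence(al, anc_sites, "gc2", pseudo)$divergence,
    dGC4_psi = site_divergence(al, anc_sites, "gc4", pseudo)$divergence,
    stringsAsFactors = FALSE)
}

#' G+C skew in sliding windows
#'
#' `(G - C) / (G + C)` along a contig, the classic replichore-polarity track.
#'
#' @param contig Contig sequence (string or `DNAString`).
#' @param window Window size in bases (default 40 kb).
#' @param step Step between window starts; default half a window.
#' @return `data.frame`: `start`, `end`, `midpoint`, `skew` (`NaN` where a
#'   window holds no G or C).
#' @export
gc_skew <- function(contig, window = 40000, step = window / 2) {
  if (inherits(contig, "DNAString")) contig <- as.character(contig)
  L <- nchar(contig)
  stopifnot(window <= L)
  b <- strsplit(contig, "")[[1]]
  cumG <- c(0, cumsum(b == "G"))
  cumC <- c(0, cumsum(b == "C"))
  starts <- seq(1, L - window + 1, by = step)
  g <- cumG[starts + window] - cumG[starts]
  cc <- cumC[starts + window] - cumC[starts]
  data.frame(start = starts, end = starts + window - 1,
             midpoint = starts + (window - 1) / 2,
             skew = (g - cc) / (g + cc))
}

#' Convert silent-site divergence to an absolute divergence time
#'
#' `t = d4 / (2 * mu_s * generations_scaling)`: two lineages each accumulate
#' substitutions at `mu_s` per site per year, so their pairwise divergence
#' grows at twice that rate.  The optional scaling absorbs any difference
#' between calendar years and the generation count underlying `mu_s`; its
#' default of 1 makes no claim about host biology.
#'
#' @param d4 Substitutions per site at fourfold-degenerate sites (>= 0).
#' @param mu_s Substitution rate per site per year (> 0).
#' @param generations_scaling Optional multiplicative scaling (default 1).
#' @return Time in years.
#' @export
divergence_time <- function(d4, mu_s = 2.2e-7, generations_scaling = 1) {
  stopifnot(d4 >= 0, mu_s > 0, generations_scaling > 0)
  d4 / (2 * mu_s * generations_scaling)
}
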
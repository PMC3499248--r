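#' Construct a genome annotation bundle
#'
#' A `genome_annotation` couples contig sequences with the ORF records
#' annotated on them.  ORF coordinates are 1-based and inclusive (the GFF3
#' convention) on the forward strand of the contig; the stored `sequence`
#' column is spliced out of the contig and strand-corrected so that it always
#' starts with the annotated start codon.
#'
#' @param genome_id Single string naming the genome.
#' @param contigs Named [Biostrings::DNAStringSet] (or named character vector)
#'   of contig sequences.
#' @param orfs `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`) and optionally `cog` (single COG category
#'   letter, `NA` when unassigned) and `is_mobile` (logical flag for
#'   IS-element / prophage features).  A `sequence` column is derived from the
#'   contigs when missing.
#' @return Object of class `genome_annotation`: a list with elements
#'   `genome_id`, `contigs` and `orfs`.
#' @export
genome_annotation <- function(genome_id, contigs, orfs) {
  if (!inherits(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || anyNA(names(contigs)))
    stop("contigs must be named")
  orfs <- as.data.frame(orfs, stringsAsFactors = FALSE)
  needed <- c("gene_id", "contig_id", "start", "end", "strand")
  missing_cols <- setdiff(needed, names(orfs))
  if (length(missing_cols))
    stop("orfs is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(orfs$gene_id))
    stop("duplicated gene_id: ",
         paste(unique(orfs$gene_id[duplicated(orfs$gene_id)]), collapse = ", "))
  if (is.null(orfs$cog)) orfs$cog <- NA_character_
  if (is.null(orfs$is_mobile)) orfs$is_mobile <- FALSE
  orfs$is_mobile <- as.logical(orfs$is_mobile)
  orfs$is_mobile[is.na(orfs$is_mobile)] <- FALSE

  bad <- !(orfs$contig_id %in% names(contigs))
  if (any(bad))
    stop("feature(s) reference missing contig(s): ",
         paste(orfs$gene_id[bad], collapse = ", "))
  clen <- setNames(Biostrings::width(contigs), names(contigs))
  oob <- orfs$start < 1 | orfs$end > clen[orfs$contig_id] | orfs$start > orfs$end
  if (any(oob))
    stop("feature(s) with out-of-bounds coordinates: ",
         paste(orfs$gene_id[oob], collapse = ", "))
  if (any(orfs$end - orfs$start + 1 < 6))
    stop("ORFs must be at least 6 bases long")

  if (is.null(orfs$sequence)) orfs$sequence <- orf_sequences(contigs, orfs)
  rownames(orfs) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs, orfs = orfs),
            class = "genome_annotation")
}

# Splice out strand-corrected ORF sequences from the contig set.
orf_sequences <- function(contigs, orfs) {
  out <- character(nrow(orfs))
  for (ctg in unique(orfs$contig_id)) {
    i <- which(orfs$contig_id == ctg)
    seqs <- Biostrings::DNAStringSet(contigs[[ctg]],
                                     start = orfs$start[i], end = orfs$end[i])
    minus <- orfs$strand[i] == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    out[i] <- as.character(seqs)
  }
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d contig(s), %s bases, %d ORFs\n",
              x$genome_id, length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ","),
              nrow(x$orfs)))
  invisible(x)
}

#' Load a genome (FASTA + annotation) from disk
#'
#' The annotation may be GFF3 (features of type `gene` or `CDS`; attributes
#' `ID`, `cog`, `mobile`) or a tab-separated table with columns
#' `gene_id`, `contig_id`, `start`, `end`, `strand` and optionally `cog`,
#' `is_mobile`.  Features whose GFF3 `mobile` attribute is truthy, or whose
#' type is `mobile_element`, are flagged `is_mobile`.
#'
#' @param fasta_path Path to a (multi-)FASTA of contigs.
#' @param annotation_path Path to the GFF3 (`.gff`/`.gff3`) or TSV annotation.
#' @param genome_id Genome name; defaults to the FASTA file stem.
#' @return A [genome_annotation()].
#' @export
load_genome <- function(fasta_path, annotation_path,
                        genome_id = sub("\\.(fa|fasta|fna)$", "",
                                        basename(fasta_path))) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  ext <- tolower(tools::file_ext(annotation_path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(annotation_path)
    gr <- gr[gr$type %in% c("gene", "CDS", "mobile_element")]
    orfs <- data.frame(
      gene_id = as.character(gr$ID),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    orfs$cog <- if (!is.null(gr$cog)) as.character(gr$cog) else NA_character_
    mob <- rep(FALSE, length(gr))
    if (!is.null(gr$mobile)) mob <- tolower(as.character(gr$mobile)) %in% c("true", "1", "yes")
    orfs$is_mobile <- mob | as.character(gr$type) == "mobile_element"
  } else {
    orfs <- read.delim(annotation_path, stringsAsFactors = FALSE)
    if (!is.null(orfs$is_mobile)) orfs$is_mobile <- as.logical(orfs$is_mobile)
  }
  if (any(!orfs$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genome_annotation(genome_id, contigs, orfs)
}

#' Write a genome annotation bundle to disk
#'
#' The annotation format is chosen from the file extension: `.gff`/`.gff3`
#' writes GFF3 (type `gene`, attributes `ID`, `cog`, `mobile`), anything else
#' a header-bearing TSV.  Round-tripping through [load_genome()] reproduces
#' ORF sequences byte-identically.
#'
#' @param ann A [genome_annotation()].
#' @param fasta_path,annotation_path Output paths.
#' @return `ann`, invisibly.
#' @export
write_genome <- function(ann, fasta_path, annotation_path) {
  Biostrings::writeXStringSet(ann$contigs, fasta_path)
  ext <- tolower(tools::file_ext(annotation_path))
  if (ext %in% c("gff", "gff3")) {
    gr <- GenomicRanges::GRanges(
      seqnames = ann$orfs$contig_id,
      ranges = IRanges::IRanges(ann$orfs$start, ann$orfs$end),
      strand = ann$orfs$strand)
    gr$type <- "gene"
    gr$source <- "erosim"
    gr$ID <- ann$orfs$gene_id
    gr$cog <- ann$orfs$cog
    gr$mobile <- ifelse(ann$orfs$is_mobile, "true", "false")
    rtracklayer::export(gr, annotation_path, format = "gff3")
  } else {
    cols <- c("gene_id", "contig_id", "start", "end", "strand", "cog", "is_mobile")
    write.table(ann$orfs[, cols], annotation_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(ann)
}

#' Translate a nucleotide sequence in frame 0
#'
#' Standard bacterial genetic code, translated literally: alternative start
#' codons are not forced to methionine (GTG stays V), because frame-disruption
#' detection does not depend on initiator handling.  A trailing partial codon
#' is ignored; codons containing `N` translate to `X`.
#'
#' @param seq Nucleotide string (`A`/`C`/`G`/`T`/`N`).
#' @return List with `peptide` (string, stops as `*`) and `internal_stops`
#'   (1-based codon indices of stop codons other than a stop in the final
#'   complete codon).
#' @export
translate_frame <- function(seq) {
  seq <- toupper(seq)
  n_codon <- nchar(seq) %/% 3
  if (n_codon == 0) return(list(peptide = "", internal_stops = integer(0)))
  starts <- seq_len(n_codon) * 3 - 2
  codons <- substring(seq, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  internal <- stops[stops < n_codon]
  list(peptide = paste(aa, collapse = ""), internal_stops = internal)
}

#' Annotation-time intactness rule
#'
#' An annotated candidate ORF is considered putatively functional when its
#' length is at least 90% of that of its most closely related ortholog and it
#' carries no frameshifting indel.
#'
#' @param candidate_len,best_ortholog_len Lengths in bases (positive).
#' @param has_frameshift Logical flag.
#' @return Logical, vectorized over the inputs.
#' @export
annotation_intact <- function(candidate_len, best_ortholog_len, has_frameshift) {
  stopifnot(all(candidate_len > 0), all(best_ortholog_len > 0))
  candidate_len >= 0.9 * best_ortholog_len & !has_frameshift
}

#' G+C percentage of sequences
#'
#' Ambiguous bases (`N`) are excluded from the denominator.
#'
#' @param seqs Character vector or `DNAStringSet`.
#' @return Percentage in `[0, 100]` over the pooled sequence; `NA` when no
#'   unambiguous base is present.
#' @export
gc_content <- function(seqs) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  f <- colSums(Biostrings::letterFrequency(seqs, c("G", "C", "A", "T")))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  100 * (f[["G"]] + f[["C"]]) / denom
}

#' Intergenic positions of a genome
#'
#' @param ann A [genome_annotation()].
#' @return Named list of [IRanges::IRanges], one per contig, covering every
#'   position not covered by any ORF.
#' @export
intergenic_ranges <- function(ann) {
  out <- list()
  for (ctg in names(ann$contigs)) {
    i <- ann$orfs$contig_id == ctg
    covered <- IRanges::reduce(IRanges::IRanges(ann$orfs$start[i], ann$orfs$end[i]))
    out[[ctg]] <- IRanges::setdiff(
      IRanges::IRanges(1, Biostrings::width(ann$contigs)[names(ann$contigs) == ctg]),
      covered)
  }
  out
}

#' Genome summary table
#'
#' One-row summary of a genome: chromosome size (summed contig lengths),
#' intact gene and pseudogene counts, total mobile DNA (summed lengths of
#' features flagged as IS/prophage) and G+C percentage.  When an ortholog
#' classification is supplied the intact/pseudogene columns are taken from it;
#' otherwise all annotated ORFs are reported as `n_genes` and the status
#' columns are `NA`.
#'
#' @param ann A [genome_annotation()].
#' @param classifications Optional classification `data.frame` with columns
#'   `gene_id`, `status` (as produced by [compare_genomes()]).
#' @return One-row `data.frame`.
#' @export
genome_summary <- function(ann, classifications = NULL) {
  mobile_bp <- sum(ann$orfs$end[ann$orfs$is_mobile] -
                   ann$orfs$start[ann$orfs$is_mobile] + 1)
  n_intact <- n_pseudo <- NA_integer_
  if (!is.null(classifications)) {
    n_intact <- sum(classifications$status == "intact")
    n_pseudo <- sum(classifications$status == "pseudogene")
  }
  data.frame(genome_id = ann$genome_id,
             size_bp = sum(Biostrings::width(ann$contigs)),
             n_genes = nrow(ann$orfs),
             n_intact = n_intact,
             n_pseudogenes = n_pseudo,
             mobile_bp = mobile_bp,
             gc_percent = gc_content(ann$contigs),
             stringsAsFactors = FALSE)
}
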
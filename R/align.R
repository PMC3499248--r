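#' Default alignment scoring
#'
#' Affine-gap local alignment scores: a gap of length *k* costs
#' `gap_open + k * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Score components; penalties are
#'   given as positive numbers.
#' @return Named list.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = 5, gap_extend = 1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

.submat_cache <- new.env(parent = emptyenv())
.submat <- function(scoring) {
  key <- paste(scoring$match, scoring$mismatch)
  if (is.null(.submat_cache[[key]]))
    .submat_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch,
      baseOnly = FALSE, type = "DNA")
  .submat_cache[[key]]
}

# One local (Smith-Waterman, affine gap) alignment; returns NULL when the
# optimal local alignment is empty or below min_score, otherwise a segment
# record with 1-based inclusive ref/qry spans and the gapped strings.
local_segment <- function(ref, qry, scoring, min_score = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(qry),
    type = "local", substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(al)
  pat <- Biostrings::pattern(al)
  if (sc < min_score || Biostrings::nchar(pat) == 0) return(NULL)
  list(ref_start = Biostrings::start(pat), ref_end = Biostrings::end(pat),
       qry_start = Biostrings::start(Biostrings::subject(al)),
       qry_end = Biostrings::end(Biostrings::subject(al)),
       aligned_ref = as.character(Biostrings::alignedPattern(al)),
       aligned_qry = as.character(Biostrings::alignedSubject(al)),
       score = sc)
}

# Batched primary local alignments for many (ref, qry) pairs in one call;
# returns a list of segment records (NULL where below min_score).
batch_local <- function(refs, qrys, scoring, min_score = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAStringSet(qrys),
    type = "local", substitutionMatrix = .submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(al)
  pat <- Biostrings::pattern(al); sub <- Biostrings::subject(al)
  rs <- Biostrings::start(pat); re <- Biostrings::end(pat)
  qs <- Biostrings::start(sub); qe <- Biostrings::end(sub)
  ar <- as.character(Biostrings::alignedPattern(al))
  aq <- as.character(Biostrings::alignedSubject(al))
  lapply(seq_along(refs), function(i) {
    if (sc[i] < min_score || is.na(rs[i]) || re[i] < rs[i]) return(NULL)
    list(ref_start = rs[i], ref_end = re[i], qry_start = qs[i], qry_end = qe[i],
         aligned_ref = ar[i], aligned_qry = aq[i], score = sc[i])
  })
}

# Chain local alignments: align, then recurse into the (ref, qry) remainders
# left and right of the aligned block.  Mirrors how banded local aligners
# report a disrupted ortholog as several collinear matches, which is what
# lets a large insertion (an IS element) or deletion appear *between*
# segments instead of being silently clipped by a single local alignment.
chain_segments <- function(ref, qry, scoring, min_len = 12, min_score = 8,
                           primary = NULL, .top = TRUE) {
  # any positive-scoring primary alignment is kept; the min_score floor only
  # gates the recursive flank segments, where a weak hit is likely spurious
  seg <- if (is.null(primary))
    local_segment(ref, qry, scoring, if (.top) 1 else min_score)
  else primary
  if (is.null(seg)) return(list())
  left <- right <- list()
  if (seg$ref_start - 1 >= min_len && seg$qry_start - 1 >= min_len) {
    left <- chain_segments(substr(ref, 1, seg$ref_start - 1),
                           substr(qry, 1, seg$qry_start - 1),
                           scoring, min_len, min_score, .top = FALSE)
  }
  if (nchar(ref) - seg$ref_end >= min_len && nchar(qry) - seg$qry_end >= min_len) {
    right <- chain_segments(substr(ref, seg$ref_end + 1, nchar(ref)),
                            substr(qry, seg$qry_end + 1, nchar(qry)),
                            scoring, min_len, min_score, .top = FALSE)
    off_r <- seg$ref_end; off_q <- seg$qry_end
    right <- lapply(right, function(s) {
      s$ref_start <- s$ref_start + off_r; s$ref_end <- s$ref_end + off_r
      s$qry_start <- s$qry_start + off_q; s$qry_end <- s$qry_end + off_q
      s
    })
  }
  c(left, list(seg), right)
}

# Parse one gapped segment into indels (ref coordinates) and substitutions.
segment_edits <- function(seg) {
  r <- strsplit(seg$aligned_ref, "")[[1]]
  q <- strsplit(seg$aligned_qry, "")[[1]]
  refpos <- cumsum(r != "-") + seg$ref_start - 1L
  qrypos <- cumsum(q != "-") + seg$qry_start - 1L

  subs <- which(r != "-" & q != "-" & r != q)
  substitutions <- data.frame(ref_position = refpos[subs],
                              ref_base = r[subs], qry_base = q[subs],
                              stringsAsFactors = FALSE)

  indels <- data.frame(ref_position = integer(0), length = integer(0),
                       kind = character(0), stringsAsFactors = FALSE)
  gap <- r == "-" | q == "-"
  if (any(gap)) {
    runs <- rle(gap)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (k in which(runs$values)) {
      i <- idx_start[k]; j <- idx_end[k]
      if (r[i] == "-") {             # gap in ref: insertion in qry
        indels <- rbind(indels, data.frame(
          ref_position = refpos[i],  # ref base immediately left of insertion
          length = j - i + 1L, kind = "ins", stringsAsFactors = FALSE))
      } else {                       # gap in qry: deletion from ref
        indels <- rbind(indels, data.frame(
          ref_position = refpos[i], length = j - i + 1L, kind = "del",
          stringsAsFactors = FALSE))
      }
    }
  }
  # map from ref position to aligned qry base for gap-free columns
  ungapped <- r != "-" & q != "-"
  list(substitutions = substitutions, indels = indels,
       refpos = refpos[ungapped], qrybase = q[ungapped],
       qrypos = qrypos[ungapped])
}

#' Align an ancestral ORF against a derived locus
#'
#' Local (Smith-Waterman) alignment with affine gap penalties, extended by
#' segment chaining: after the optimal local alignment is found, the
#' unaligned flanks of both sequences are re-aligned recursively, so that a
#' locus interrupted by a large insertion or deletion is represented as an
#' ordered set of collinear aligned segments.  Reference coverage is the
#' fraction of the ancestral ORF covered by the union of the chained
#' segments, so a locus interrupted by an IS element is credited with both
#' flanks; unaligned ancestral termini (truncations) reduce it.
#'
#' @param ref_seq Ancestral ORF sequence (string).
#' @param qry_seq Derived locus sequence (string).
#' @param scoring An [align_scoring()] list.
#' @param gene_id Optional identifier carried through to downstream tables.
#' @param .primary Internal: a precomputed primary local-alignment segment
#'   (used by [compare_genomes()] to batch the expensive first pass).
#' @return Object of class `orf_alignment`: gapped strings of the primary
#'   segment (`aligned_ref`, `aligned_qry`), `ref_coverage`, `score`,
#'   `indels` and `substitutions` data.frames pooled over all segments (with
#'   between-segment gaps included as indels), and the `segments` list.
#' @export
align_orf <- function(ref_seq, qry_seq, scoring = align_scoring(),
                      gene_id = NA_character_, .primary = NULL) {
  stopifnot(nchar(ref_seq) > 0, nchar(qry_seq) > 0)
  ref_seq <- toupper(ref_seq); qry_seq <- toupper(qry_seq)
  if (ref_seq == qry_seq) {
    # identical sequences: the optimal local alignment is the full match
    L <- nchar(ref_seq)
    segs <- list(list(ref_start = 1L, ref_end = L, qry_start = 1L, qry_end = L,
                      aligned_ref = ref_seq, aligned_qry = qry_seq,
                      score = L * scoring$match))
    return(structure(list(
      gene_id = gene_id, ref_len = L, qry_len = L, ref_seq = ref_seq,
      segments = segs, aligned_ref = ref_seq, aligned_qry = qry_seq,
      ref_start = 1L, ref_end = L, qry_start = 1L, qry_end = L,
      ref_coverage = 1, score = L * scoring$match,
      indels = data.frame(ref_position = integer(0), length = integer(0),
                          kind = character(0), stringsAsFactors = FALSE),
      substitutions = data.frame(ref_position = integer(0),
                                 ref_base = character(0),
                                 qry_base = character(0),
                                 stringsAsFactors = FALSE),
      ref_map = seq_len(L), qry_at = strsplit(qry_seq, "")[[1]],
      qry_map = seq_len(L)), class = "orf_alignment"))
  }
  segs <- if (identical(.primary, NA)) list()  # batched pass found no alignment
          else chain_segments(ref_seq, qry_seq, scoring, primary = .primary)
  ref_len <- nchar(ref_seq)
  if (length(segs) == 0) {
    return(structure(list(gene_id = gene_id, ref_len = ref_len,
                          qry_len = nchar(qry_seq), ref_seq = ref_seq,
                          segments = list(),
                          aligned_ref = "", aligned_qry = "",
                          ref_coverage = 0, score = 0,
                          indels = data.frame(ref_position = integer(0),
                                              length = integer(0),
                                              kind = character(0)),
                          substitutions = data.frame(ref_position = integer(0),
                                                     ref_base = character(0),
                                                     qry_base = character(0)),
                          ref_map = integer(0), qry_at = character(0)),
                     class = "orf_alignment"))
  }
  primary <- segs[[which.max(vapply(segs, `[[`, numeric(1), "score"))]]
  edits <- lapply(segs, segment_edits)
  indels <- do.call(rbind, lapply(edits, `[[`, "indels"))
  substitutions <- do.call(rbind, lapply(edits, `[[`, "substitutions"))

  # between-segment implied indels
  if (length(segs) > 1) {
    for (k in seq_len(length(segs) - 1)) {
      a <- segs[[k]]; b <- segs[[k + 1]]
      ref_gap <- b$ref_start - a$ref_end - 1L
      qry_gap <- b$qry_start - a$qry_end - 1L
      if (ref_gap > 0)
        indels <- rbind(indels, data.frame(ref_position = a$ref_end + 1L,
                                           length = ref_gap, kind = "del",
                                           stringsAsFactors = FALSE))
      if (qry_gap > 0)
        indels <- rbind(indels, data.frame(ref_position = a$ref_end,
                                           length = qry_gap, kind = "ins",
                                           stringsAsFactors = FALSE))
    }
  }
  refpos <- unlist(lapply(edits, `[[`, "refpos"))
  qrybase <- unlist(lapply(edits, `[[`, "qrybase"))
  qrypos <- unlist(lapply(edits, `[[`, "qrypos"))
  ord <- order(refpos)

  # coverage over the union of collinear chained segments, so that a locus
  # interrupted by a large insertion is still credited with both flanks
  cov_ranges <- IRanges::reduce(IRanges::IRanges(
    vapply(segs, `[[`, numeric(1), "ref_start"),
    vapply(segs, `[[`, numeric(1), "ref_end")))

  structure(list(
    gene_id = gene_id, ref_len = ref_len, qry_len = nchar(qry_seq),
    ref_seq = ref_seq, segments = segs,
    aligned_ref = primary$aligned_ref, aligned_qry = primary$aligned_qry,
    ref_start = primary$ref_start, ref_end = primary$ref_end,
    qry_start = primary$qry_start, qry_end = primary$qry_end,
    ref_coverage = sum(IRanges::width(cov_ranges)) / ref_len,
    score = primary$score,
    indels = indels[order(indels$ref_position), , drop = FALSE],
    substitutions = substitutions,
    ref_map = refpos[ord], qry_at = qrybase[ord], qry_map = qrypos[ord]),
    class = "orf_alignment")
}

#' @export
print.orf_alignment <- function(x, ...) {
  cat(sprintf("<orf_alignment> %s: ref %d bp, coverage %.3f, score %.0f, %d indel(s), %d substitution(s), %d segment(s)\n",
              x$gene_id, x$ref_len, x$ref_coverage, x$score,
              nrow(x$indels), nrow(x$substitutions), length(x$segments)))
  invisible(x)
}
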
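#' Classify an ortholog as intact, pseudogene or absent
#'
#' A compared gene is *intact* when the alignment of its derived locus spans
#' more than 99% of the ancestral ORF length (90% for ORFs shorter than 300
#' nucleotides) and carries neither a frameshifting indel nor a premature
#' stop codon in the ancestral reading frame.  It is *absent* when no locus
#' was found, or the best alignment covers less than `absent_threshold` of
#' the ancestral ORF (lost via large deletion).  Everything else is a
#' *pseudogene*.
#'
#' @param alignment An [align_orf()] result (may be `NULL` when `found` is
#'   `FALSE`).
#' @param ref_len Ancestral ORF length in bases.
#' @param found Logical; `FALSE` when no derived locus exists for the gene.
#' @param events Optional pre-computed [extract_mutations()] result; computed
#'   from `alignment` when omitted (nonsense detection needs the alignment).
#' @param absent_threshold Coverage floor separating vestigial fragments from
#'   absence.
#' @return `data.frame` row: `gene_id`, `status`, `coverage`, `reasons`
#'   (comma-separated rule codes).
#' @export
classify_ortholog <- function(alignment, ref_len, found = TRUE,
                              events = NULL, absent_threshold = 0.20) {
  gene_id <- if (!is.null(alignment)) alignment$gene_id else NA_character_
  if (!found || is.null(alignment) || alignment$ref_coverage < absent_threshold) {
    cov <- if (!is.null(alignment)) alignment$ref_coverage else 0
    return(data.frame(gene_id = gene_id, status = "absent", coverage = cov,
                      reasons = "not_found", stringsAsFactors = FALSE))
  }
  if (is.null(events)) events <- extract_mutations(alignment)
  cov_thresh <- if (ref_len < 300) 0.90 else 0.99
  reasons <- character(0)
  if (alignment$ref_coverage <= cov_thresh) reasons <- c(reasons, "coverage_short")
  fs <- events$category %in% c("internal_insertion", "internal_deletion") &
    events$frameshifting
  if (any(fs)) reasons <- c(reasons, "frameshift_indel")
  if (any(events$category == "nonsense")) reasons <- c(reasons, "premature_stop")
  # a mobile-element acquisition disrupts the gene whether or not its length
  # is a multiple of three
  if (any(events$category == "is_element")) reasons <- c(reasons, "is_insertion")
  if (length(reasons) == 0)
    data.frame(gene_id = gene_id, status = "intact",
               coverage = alignment$ref_coverage, reasons = "",
               stringsAsFactors = FALSE)
  else
    data.frame(gene_id = gene_id, status = "pseudogene",
               coverage = alignment$ref_coverage,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
}

# Does an inserted query substring match an IS-catalog entry
# (>= 80% identity over >= 80% of the catalog element length)?
match_is_catalog <- function(ins_seq, is_catalog, scoring = align_scoring()) {
  if (length(is_catalog) == 0 || nchar(ins_seq) < 0.5 * min(nchar(is_catalog)))
    return(NA_character_)
  for (nm in names(is_catalog)) {
    el <- is_catalog[[nm]]
    if (nchar(ins_seq) < 0.8 * nchar(el)) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(el), Biostrings::DNAString(ins_seq),
      type = "local", substitutionMatrix = .submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    cov <- (Biostrings::end(Biostrings::pattern(al)) -
            Biostrings::start(Biostrings::pattern(al)) + 1) / nchar(el)
    if (cov >= 0.8 && Biostrings::pid(al, type = "PID1") >= 80) return(nm)
  }
  NA_character_
}

#' Extract categorized disrupting mutations from an alignment
#'
#' Indels are read off the aligned segments: insertions whose sequence
#' matches an IS-catalog entry (at least 80% identity over at least 80% of
#' the element length) are `is_element`, other insertions are
#' `internal_insertion`; deletions that include the first (last) ancestral
#' codon, or abut an unaligned ancestral terminus, are 5' (3') deletions, and
#' unaligned ancestral termini themselves are reported as terminal deletions;
#' interior deletions are `internal_deletion`.  Nonsense mutations are point
#' substitutions that create a premature stop codon in the ancestral reading
#' frame, assessed independently of any frameshift: each ancestral codon
#' whose three positions align gap-free is translated from the aligned query
#' bases, and a stop at an interior codon (where the ancestral codon is not
#' itself a stop) is reported once, with size 0.
#'
#' @param alignment An [align_orf()] result.
#' @param qry_seq Derived locus sequence; required to test insertions against
#'   `is_catalog` (defaults to `NULL`, in which case all insertions are
#'   internal).
#' @param is_catalog Named character vector of IS sequences (optional).
#' @param min_terminal Minimum unaligned terminus length (bases) reported as
#'   a terminal deletion; shorter overhangs are alignment clipping noise.
#' @param scoring Scoring used for IS-catalog matching.
#' @return `data.frame`: `gene_id`, `category`, `ref_position`, `size`,
#'   `frameshifting`.
#' @export
extract_mutations <- function(alignment, qry_seq = NULL, is_catalog = NULL,
                              min_terminal = 6, scoring = align_scoring()) {
  empty <- data.frame(gene_id = character(0), category = character(0),
                      ref_position = integer(0), size = integer(0),
                      frameshifting = logical(0), stringsAsFactors = FALSE)
  if (length(alignment$segments) == 0) return(empty)
  gene_id <- alignment$gene_id
  ref_len <- alignment$ref_len
  segs <- alignment$segments
  ref_starts <- vapply(segs, `[[`, numeric(1), "ref_start")
  segs <- segs[order(ref_starts)]
  first <- segs[[1]]; last <- segs[[length(segs)]]

  rows <- list()
  add <- function(category, ref_position, size, frameshifting) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene_id = gene_id, category = category, ref_position = ref_position,
      size = size, frameshifting = frameshifting, stringsAsFactors = FALSE)
  }

  # unaligned ancestral termini
  lead <- first$ref_start - 1L
  if (lead >= min_terminal) add("five_prime_deletion", 1L, lead, lead %% 3 != 0)
  trail <- ref_len - last$ref_end
  if (trail >= min_terminal)
    add("three_prime_deletion", last$ref_end + 1L, trail, trail %% 3 != 0)

  # indels (within segments and between chained segments)
  ind <- alignment$indels
  if (nrow(ind)) for (k in seq_len(nrow(ind))) {
    p <- ind$ref_position[k]; sz <- ind$length[k]
    if (ind$kind[k] == "ins") {
      cat_k <- "internal_insertion"
      if (!is.null(qry_seq) && !is.null(is_catalog)) {
        qp <- alignment$qry_map[match(p, alignment$ref_map)]
        if (!is.na(qp)) {
          ins_seq <- substr(qry_seq, qp + 1L, qp + sz)
          if (!is.na(match_is_catalog(ins_seq, is_catalog, scoring)))
            cat_k <- "is_element"
        }
      }
      add(cat_k, p, sz, sz %% 3 != 0)
    } else {
      touches_start <- p <= 3L
      touches_end <- p + sz - 1L >= ref_len - 2L
      abuts_lead <- lead >= min_terminal && p <= first$ref_start
      abuts_trail <- trail >= min_terminal && p + sz - 1L >= last$ref_end
      cat_k <- if (touches_start || abuts_lead) "five_prime_deletion"
        else if (touches_end || abuts_trail) "three_prime_deletion"
        else "internal_deletion"
      add(cat_k, p, sz, sz %% 3 != 0)
    }
  }

  # nonsense: project aligned query bases onto gap-free ancestral codons
  n_codon <- ref_len %/% 3
  if (n_codon >= 2 && length(alignment$ref_map)) {
    idx <- match(seq_len(ref_len), alignment$ref_map)  # ref pos -> column
    p1 <- 3L * seq_len(n_codon - 1L) - 2L      # exclude the terminal codon
    c1 <- idx[p1]; c2 <- idx[p1 + 1L]; c3 <- idx[p1 + 2L]
    ok <- !is.na(c1) & !is.na(c2) & !is.na(c3)
    # consecutive query positions guarantee the codon aligns gap-free
    ok[ok] <- alignment$qry_map[c2[ok]] == alignment$qry_map[c1[ok]] + 1L &
              alignment$qry_map[c3[ok]] == alignment$qry_map[c2[ok]] + 1L
    if (any(ok)) {
      qcod <- paste0(alignment$qry_at[c1[ok]], alignment$qry_at[c2[ok]],
                     alignment$qry_at[c3[ok]])
      rcod <- substring(alignment$ref_seq, p1[ok], p1[ok] + 2L)
      hit <- qcod %in% STOP_CODONS & !(rcod %in% STOP_CODONS)
      for (p in p1[ok][hit]) add("nonsense", p, 0L, FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$ref_position), , drop = FALSE]
}

#' Compare a derived genome against its ancestral reference
#'
#' Pairs ORFs by shared `gene_id`, aligns each ancestral ORF to its derived
#' locus, classifies every compared gene and extracts its disrupting
#' mutations.
#'
#' @param ancestral,derived [genome_annotation()] objects.
#' @param is_catalog Optional named character vector of IS sequences.
#' @param scoring [align_scoring()] parameters.
#' @param absent_threshold Passed to [classify_ortholog()].
#' @return List with `classification` (one row per ancestral gene), `events`
#'   (pooled [extract_mutations()] rows for pseudogenes) and `alignments`
#'   (named list of `orf_alignment` objects for found genes).
#' @export
compare_genomes <- function(ancestral, derived, is_catalog = NULL,
                            scoring = align_scoring(), absent_threshold = 0.20) {
  anc <- ancestral$orfs
  der <- derived$orfs
  der_seq <- setNames(der$sequence, der$gene_id)
  cls <- vector("list", nrow(anc))
  evs <- vector("list", nrow(anc))
  alns <- list()

  found <- anc$gene_id %in% names(der_seq)
  differs <- found & anc$sequence != unname(der_seq[anc$gene_id])
  primaries <- vector("list", nrow(anc))
  if (any(differs)) {
    # batch the expensive primary local alignments in one call
    primaries[differs] <- batch_local(anc$sequence[differs],
                                      unname(der_seq[anc$gene_id[differs]]),
                                      scoring)
  }
  for (i in seq_len(nrow(anc))) {
    gid <- anc$gene_id[i]
    ref <- anc$sequence[i]
    if (!found[i]) {
      cls[[i]] <- classify_ortholog(NULL, nchar(ref), found = FALSE)
      cls[[i]]$gene_id <- gid
      next
    }
    prim <- if (!differs[i]) NULL
            else if (is.null(primaries[[i]])) NA else primaries[[i]]
    al <- align_orf(ref, der_seq[[gid]], scoring, gene_id = gid,
                    .primary = prim)
    ev <- extract_mutations(al, qry_seq = der_seq[[gid]], is_catalog = is_catalog,
                            scoring = scoring)
    cls[[i]] <- classify_ortholog(al, nchar(ref), found = TRUE, events = ev,
                                  absent_threshold = absent_threshold)
    alns[[gid]] <- al
    evs[[i]] <- ev
  }
  classification <- do.call(rbind, cls)
  status <- setNames(classification$status, classification$gene_id)
  empty_ev <- data.frame(gene_id = character(0), category = character(0),
                         ref_position = integer(0), size = integer(0),
                         frameshifting = logical(0), stringsAsFactors = FALSE)
  events <- do.call(rbind, c(evs[!vapply(evs, is.null, logical(1))],
                             list(empty_ev)))
  # mutation events are tabulated for visibly disrupted genes only
  events <- events[status[events$gene_id] == "pseudogene", , drop = FALSE]
  rownames(events) <- NULL
  list(classification = classification, events = events, alignments = alns)
}

#' Allelic spectrum of pseudogene mutations
#'
#' @param events [extract_mutations()]-style `data.frame` (pooled over the
#'   pseudogenes of one genome).
#' @param pseudogene_count Optional number of pseudogenes, carried into the
#'   table.
#' @return `data.frame` with one row per category: `count`, `proportion`, and
#'   `percent` (rounded to whole percent for reporting).  Attribute
#'   `total_mutations` holds the total count.
#' @export
spectrum <- function(events, pseudogene_count = NA_integer_) {
  counts <- table(factor(events$category, levels = MUTATION_CATEGORIES))
  total <- sum(counts)
  out <- data.frame(category = MUTATION_CATEGORIES,
                    count = as.integer(counts),
                    proportion = if (total > 0) as.numeric(counts) / total else 0,
                    stringsAsFactors = FALSE)
  out$percent <- round(100 * out$proportion)
  attr(out, "total_mutations") <- total
  attr(out, "pseudogene_count") <- pseudogene_count
  out
}

#' Per-pseudogene mutation density
#'
#' @param events Pooled events `data.frame`.
#' @param classification Classification `data.frame` from [compare_genomes()].
#' @param ancestral_lengths Named vector of ancestral ORF lengths (bases).
#' @param current_lengths Named vector of derived locus lengths; required for
#'   `mode = "current"`.
#' @param mode `"ancestral"` uses the ancestral ORF size, `"current"` the
#'   observed (possibly truncated) locus size.
#' @return `data.frame` per pseudogene: `gene_id`, `n_events`, `length_bp`,
#'   `density_per_kb` (`NA` when the current length is zero).
#' @export
mutation_density <- function(events, classification, ancestral_lengths,
                             current_lengths = NULL,
                             mode = c("ancestral", "current")) {
  mode <- match.arg(mode)
  pg <- classification$gene_id[classification$status == "pseudogene"]
  n_ev <- table(factor(events$gene_id, levels = pg))
  len <- if (mode == "ancestral") ancestral_lengths[pg] else current_lengths[pg]
  density <- ifelse(is.na(len) | len == 0, NA_real_,
                    as.integer(n_ev) / (len / 1000))
  data.frame(gene_id = pg, n_events = as.integer(n_ev),
             length_bp = as.numeric(len), density_per_kb = density,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Poisson dispersion diagnostic for per-pseudogene mutation counts
#'
#' Variance-to-mean ratio and the index-of-dispersion chi-square test of the
#' counts against a Poisson distribution with matched mean
#' (`sum((x - mean)^2) / mean ~ chi-square(n - 1)` under the null).
#'
#' @param counts Integer vector of disrupting-mutation counts, one per
#'   pseudogene (length >= 2, not all zero).
#' @return List: `vmr`, `chisq`, `df`, `p_value`.
#' @export
poisson_dispersion <- function(counts) {
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m == 0) stop("all counts are zero; pseudogenes must carry >= 1 event")
  vmr <- var(counts) / m
  chisq <- sum((counts - m)^2) / m
  df <- length(counts) - 1
  list(vmr = vmr, chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}
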
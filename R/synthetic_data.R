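#' Erosion-simulation configuration
#'
#' Bundles every parameter of the forward genome-erosion simulator.  Defaults
#' describe the study conditions the package is validated under: an ancestral
#' inventory of ~4,000 codon-structured ORFs with a right-skewed (gamma,
#' shape 2) length distribution of mean 950 bases, a neutral class of 1,500
#' genes, a budget of 3,000 disrupting mutations placed in proportion to gene
#' length, 10% of the neutral class lost by whole-gene deletion, a
#' disrupting-mutation category mix matching the allelic spectrum observed in
#' the weevil symbiont (19/34/7/11/19/10% across internal insertions,
#' internal deletions, 5' deletions, 3' deletions, nonsense substitutions and
#' IS-element insertions), and AT-biased background substitution concentrated
#' at fourfold-degenerate sites.
#'
#' @param seed Integer RNG seed (mandatory: the single stream drives both
#'   genome synthesis and erosion).
#' @param n_genes Number of ancestral ORFs.
#' @param length_mean,length_shape,length_min Gamma length model in bases;
#'   draws are rounded to codon multiples and floored at `length_min`.
#' @param gc1_target,gc2_target,gc4_target,gci_target Probability that a
#'   first-, second-, third-codon-position or intergenic base is G/C.
#' @param igs_mean Mean intergenic spacer length (bases, Poisson, min 20).
#' @param n_neutral Number of genes under relaxed selection; the default
#'   keeps the study proportion (1,500 of 4,000) at any genome size.
#' @param mutation_budget Total disrupting mutations to place (default twice
#'   the neutral-class size, i.e. 3,000 under the default conditions).
#' @param category_mix Named probabilities over the six disrupting-mutation
#'   categories (must sum to 1).
#' @param deletion_fraction Fraction of neutral genes removed entirely.
#' @param point_sub_rate_gc4 Background per-site substitution probability at
#'   fourfold-degenerate third positions (and intergenic sites).
#' @param point_sub_rate_gc2 Background per-site substitution probability at
#'   all other coding positions.
#' @param relaxed_gc2_extra Additional second-position substitution
#'   probability on neutral genes (relaxed selection on the protein).
#' @param at_bias Probability that a substitution at a fourfold-degenerate or
#'   intergenic site moves toward A/T.
#' @param is_catalog Named character vector of IS-element sequences.
#' @return List of class `erosion_config`.
#' @export
erosion_config <- function(seed,
                           n_genes = 4000,
                           length_mean = 950, length_shape = 2, length_min = 90,
                           gc1_target = 0.55, gc2_target = 0.40,
                           gc4_target = 0.55, gci_target = 0.50,
                           igs_mean = 130,
                           n_neutral = round(0.375 * n_genes),
                           mutation_budget = 2 * n_neutral,
                           category_mix = c(internal_insertion = 0.19,
                                            internal_deletion = 0.34,
                                            five_prime_deletion = 0.07,
                                            three_prime_deletion = 0.11,
                                            nonsense = 0.19,
                                            is_element = 0.10),
                           deletion_fraction = 0.10,
                           point_sub_rate_gc4 = 0.043,
                           point_sub_rate_gc2 = 0.008,
                           relaxed_gc2_extra = 0.008,
                           at_bias = 0.85,
                           is_catalog = default_is_catalog()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes >= 1, n_neutral <= n_genes, length_mean >= 6)
  if (!setequal(names(category_mix), MUTATION_CATEGORIES))
    stop("category_mix must be named by the six mutation categories")
  category_mix <- category_mix[MUTATION_CATEGORIES]
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1")
  rates <- c(deletion_fraction, point_sub_rate_gc4, point_sub_rate_gc2,
             relaxed_gc2_extra, gc1_target, gc2_target, gc4_target, gci_target)
  if (any(rates < 0 | rates > 1)) stop("rates and targets must lie in [0, 1]")
  if (category_mix[["is_element"]] > 0 && length(is_catalog) == 0)
    stop("category_mix requests IS insertions but is_catalog is empty")
  structure(as.list(environment()), class = "erosion_config")
}

#' Synthetic IS-element catalog
#'
#' Deterministically generated insertion-sequence stand-ins (the sequences are
#' random but fixed, independent of the simulation seed) with realistic
#' lengths.  Labelled synthetic: they share no homology with any real IS
#' family.
#'
#' @param lengths Element lengths in bases.
#' @return Named character vector of sequences.
#' @export
default_is_catalog <- function(lengths = c(ISsyn1 = 768, ISsyn2 = 1026, ISsyn3 = 1200)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(424243L)
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Sample n codon strings with per-position G/C probabilities, rejecting stop
# codons (resampled until none remain).
sample_codons <- function(n, gc1, gc2, gc4) {
  draw_base <- function(n, gc) {
    isgc <- runif(n) < gc
    b <- character(n)
    b[isgc] <- sample(c("G", "C"), sum(isgc), replace = TRUE)
    b[!isgc] <- sample(c("A", "T"), sum(!isgc), replace = TRUE)
    b
  }
  codons <- paste0(draw_base(n, gc1), draw_base(n, gc2), draw_base(n, gc4))
  repeat {
    bad <- codons %in% STOP_CODONS
    if (!any(bad)) break
    codons[bad] <- paste0(draw_base(sum(bad), gc1), draw_base(sum(bad), gc2),
                          draw_base(sum(bad), gc4))
  }
  codons
}

#' Generate a synthetic ancestral genome
#'
#' Emulates the gene inventory of a free-living-like reference: every ORF
#' begins with ATG, contains no internal stop, ends with a stop codon, and
#' has its length drawn from the configured gamma model rounded to codons.
#' ORFs are placed on random strands of a single contig, separated by
#' intergenic spacers with configurable G+C.
#'
#' @param config An [erosion_config()].
#' @return A [genome_annotation()] with `genome_id = "ancestral"`.
#' @export
generate_ancestral <- function(config) {
  stopifnot(inherits(config, "erosion_config"))
  set.seed(config$seed)
  n <- config$n_genes
  len <- pmax(round(rgamma(n, shape = config$length_shape,
                           scale = config$length_mean / config$length_shape) / 3) * 3,
              config$length_min)

  n_body <- len / 3 - 2
  body <- sample_codons(sum(n_body), config$gc1_target, config$gc2_target,
                        config$gc4_target)
  gene_of_codon <- rep(seq_len(n), n_body)
  stops <- sample(STOP_CODONS, n, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  genes <- vapply(split(body, gene_of_codon), paste, character(1), collapse = "")
  genes <- paste0("ATG", genes, stops)

  spacer_len <- pmax(rpois(n + 1, config$igs_mean), 20)
  spacers <- vapply(spacer_len, function(L) {
    isgc <- runif(L) < config$gci_target
    paste(ifelse(isgc, sample(c("G", "C"), L, replace = TRUE),
                 sample(c("A", "T"), L, replace = TRUE)), collapse = "")
  }, character(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  placed <- ifelse(strand == "+", genes,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAStringSet(genes))))
  pieces <- character(2 * n + 1)
  pieces[seq(1, 2 * n + 1, by = 2)] <- spacers
  pieces[seq(2, 2 * n, by = 2)] <- placed
  contig <- paste(pieces, collapse = "")

  width <- nchar(pieces)
  ends <- cumsum(width)
  gene_slots <- seq(2, 2 * n, by = 2)
  orfs <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    contig_id = "chr1",
    start = ends[gene_slots] - width[gene_slots] + 1,
    end = ends[gene_slots],
    strand = strand,
    cog = sample(c(LETTERS[1:20], NA), n, replace = TRUE),
    is_mobile = FALSE,
    sequence = genes,
    stringsAsFactors = FALSE)
  genome_annotation("ancestral", c(chr1 = contig), orfs)
}

# --- erosion -----------------------------------------------------------------

# Codons one substitution away from a stop, with the substitutions that get
# there.  Returns a data.frame of (pos_in_codon, new_base) options for `codon`.
stop_reachable <- function(codon) {
  opts <- list()
  b <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (nb in c("A", "C", "G", "T")) {
    if (nb == b[pos]) next
    cand <- b; cand[pos] <- nb
    if (paste(cand, collapse = "") %in% STOP_CODONS)
      opts[[length(opts) + 1]] <- data.frame(pos = pos, new = nb,
                                             stringsAsFactors = FALSE)
  }
  if (length(opts)) do.call(rbind, opts) else NULL
}

INDEL_SIZES <- c(1L, 2L, 4L, 5L, 7L, 8L, 10L)

#' Erode an ancestral genome into a derived symbiont genome
#'
#' Implements length-biased accumulation of disrupting mutations in a neutral
#' gene class.  First, `deletion_fraction * n_neutral` neutral genes are
#' removed wholly ("absent").  Then `mutation_budget` disrupting events are
#' placed one at a time: the target gene is drawn from the remaining neutral
#' genes with probability proportional to its current length, the category
#' from `category_mix`.  Event realizations: internal indels of 1-10 bases
#' with length not a multiple of three (frameshifting by construction);
#' nonsense events substitute one base of an interior codon to create an
#' in-frame stop; 5'/3' deletions remove a uniform 10-50% of the respective
#' ancestral gene end; IS insertions splice a catalog element into the gene
#' interior (20-80% of its span, where disruption is unambiguous).  Finally,
#' AT-biased background substitutions are applied to every surviving gene at
#' the configured per-site rates (fourfold-degenerate third positions vs all
#' other coding positions, with the extra relaxed-selection rate at second
#' positions of neutral genes), and to intergenic spacers at the
#' fourfold-site rate.  Background substitutions that would create an
#' in-frame stop are suppressed, mimicking purifying selection against
#' nonsense changes and keeping the logged event list the only source of
#' frame disruptions.
#'
#' @param ancestral A [genome_annotation()] from [generate_ancestral()] (or
#'   compatible: codon-complete ORFs).
#' @param config The [erosion_config()].
#' @return List with elements `derived` (a [genome_annotation()]) and `truth`
#'   (list: `genes` data.frame with `gene_id`, `is_neutral`, `fate`
#'   (`intact`/`pseudogene`/`absent`), `n_events`; `events` data.frame with
#'   `gene_id`, `category`, `position` (ancestral coordinate), `size`;
#'   `substitutions` data.frame logging background point substitutions).
#' @export
erode <- function(ancestral, config) {
  stopifnot(inherits(ancestral, "genome_annotation"),
            inherits(config, "erosion_config"))
  if (config$category_mix[["is_element"]] > 0 && length(config$is_catalog) == 0)
    stop("category_mix requests IS insertions but is_catalog is empty")
  set.seed(config$seed + 1L)

  orfs <- ancestral$orfs
  n <- nrow(orfs)
  ids <- orfs$gene_id
  L <- nchar(orfs$sequence)
  stopifnot(config$n_neutral <= n)

  neutral <- sort(sample.int(n, config$n_neutral))
  n_del <- round(config$deletion_fraction * config$n_neutral)
  absent <- if (n_del > 0) sort(sample(neutral, n_del)) else integer(0)
  targets <- setdiff(neutral, absent)

  # Per-gene erosion state, ancestral coordinates.
  prefix_cut <- integer(n); suffix_cut <- integer(n)
  cur_len <- as.numeric(L)
  events <- vector("list", config$mutation_budget)
  seqs <- strsplit(orfs$sequence, "")

  M <- config$mutation_budget
  if (M > 0 && length(targets) > 0) {
    cats <- sample(MUTATION_CATEGORIES, M, replace = TRUE,
                   prob = config$category_mix)
    for (m in seq_len(M)) {
      g <- targets[sample.int(length(targets), 1, prob = cur_len[targets])]
      cat_m <- cats[m]
      Lg <- L[g]
      lo <- prefix_cut[g] + 1L
      hi <- Lg - suffix_cut[g]
      span <- hi - lo + 1L
      ev <- NULL
      if (cat_m == "nonsense") {
        # interior codons only (not start, not terminal stop), inside the
        # surviving span, reachable from a stop by one substitution
        c_lo <- max(2L, ceiling(lo / 3) + 1L)
        c_hi <- min(Lg / 3 - 1L, floor(hi / 3) - 1L)
        if (c_hi >= c_lo) {
          for (try in 1:25) {
            ci <- sample1(c_lo:c_hi)
            cod <- paste(seqs[[g]][(3 * ci - 2):(3 * ci)], collapse = "")
            opt <- stop_reachable(cod)
            if (!is.null(opt)) {
              pick <- opt[sample.int(nrow(opt), 1), ]
              p <- 3 * ci - 3 + pick$pos
              seqs[[g]][p] <- pick$new
              ev <- list(gene_id = ids[g], category = "nonsense",
                         position = p, size = 0L)
              break
            }
          }
        }
      } else if (cat_m %in% c("internal_insertion", "internal_deletion")) {
        size <- sample(INDEL_SIZES, 1)
        flank <- min(30L, max(6L, span %/% 4))
        if (span - 2L * flank - size > 1L) {
          p <- sample1((lo + flank):(hi - flank - size))
          if (cat_m == "internal_deletion") cur_len[g] <- cur_len[g] - size
          else cur_len[g] <- cur_len[g] + size
          ev <- list(gene_id = ids[g], category = cat_m,
                     position = p, size = size)
        }
      } else if (cat_m == "five_prime_deletion") {
        # stacked terminal deletions never remove more than 75% of the gene,
        # so a truncated gene stays distinguishable from a deleted one
        cut <- min(ceiling(runif(1, 0.10, 0.50) * Lg),
                   floor(0.75 * Lg) - suffix_cut[g])
        if (cut > prefix_cut[g] && cut < hi - 30L) {
          cur_len[g] <- cur_len[g] - (cut - prefix_cut[g])
          prefix_cut[g] <- cut
          ev <- list(gene_id = ids[g], category = "five_prime_deletion",
                     position = 1L, size = cut)
        }
      } else if (cat_m == "three_prime_deletion") {
        cut <- min(ceiling(runif(1, 0.10, 0.50) * Lg),
                   floor(0.75 * Lg) - prefix_cut[g])
        if (cut > suffix_cut[g] && Lg - cut > lo + 30L) {
          cur_len[g] <- cur_len[g] - (cut - suffix_cut[g])
          suffix_cut[g] <- cut
          ev <- list(gene_id = ids[g], category = "three_prime_deletion",
                     position = Lg - cut + 1L, size = cut)
        }
      } else { # is_element
        el <- sample.int(length(config$is_catalog), 1)
        p <- lo + round(runif(1, 0.20, 0.80) * (span - 1L))
        cur_len[g] <- cur_len[g] + nchar(config$is_catalog[[el]])
        ev <- list(gene_id = ids[g], category = "is_element",
                   position = p, size = nchar(config$is_catalog[[el]]),
                   is_name = names(config$is_catalog)[el])
      }
      if (is.null(ev)) {
        # degenerate span: fall back to a guaranteed small frameshift
        p <- max(lo + 3L, min(hi - 4L, lo + span %/% 2))
        cur_len[g] <- cur_len[g] - 1
        ev <- list(gene_id = ids[g], category = "internal_deletion",
                   position = p, size = 1L)
      }
      ev$cycle <- m
      events[[m]] <- ev
    }
  }
  events <- if (M > 0 && length(targets) > 0) {
    do.call(rbind, lapply(events, function(e)
      data.frame(gene_id = e$gene_id, category = e$category,
                 position = e$position, size = e$size,
                 is_name = if (is.null(e$is_name)) NA_character_ else e$is_name,
                 cycle = e$cycle, stringsAsFactors = FALSE)))
  } else {
    data.frame(gene_id = character(0), category = character(0),
               position = integer(0), size = integer(0),
               is_name = character(0), cycle = integer(0))
  }

  # --- background substitutions ---------------------------------------------
  # Site classes from the ANCESTRAL codons (degeneracy is assigned against the
  # reference template, and injected nonsense stops must not perturb it).
  any_subs <- config$point_sub_rate_gc4 > 0 || config$point_sub_rate_gc2 > 0 ||
    config$relaxed_gc2_extra > 0
  site_cls <- if (any_subs) lapply(orfs$sequence, site_classes_seq) else NULL
  sub_log <- vector("list", n)
  survivors <- setdiff(seq_len(n), absent)
  if (any_subs) for (g in survivors) {
    cls <- site_cls[[g]]
    r <- numeric(L[g])
    r[cls == 4L] <- config$point_sub_rate_gc4
    r[cls != 4L] <- config$point_sub_rate_gc2
    if (g %in% neutral && config$relaxed_gc2_extra > 0)
      r[cls == 2L] <- r[cls == 2L] + config$relaxed_gc2_extra
    ns <- events$position[events$gene_id == ids[g] & events$category == "nonsense"]
    if (length(ns)) {
      prot <- as.vector(outer(((ns - 1L) %/% 3L) * 3L, 1:3, `+`))
      r[prot] <- 0  # injected stops stay: the event log is the ground truth
    }
    hit <- which(runif(L[g]) < r)
    if (!length(hit)) next
    old <- seqs[[g]][hit]
    new <- vapply(seq_along(hit), function(k) {
      site <- hit[k]
      at_ward <- cls[site] == 4L && runif(1) < config$at_bias
      pool <- if (at_ward) setdiff(c("A", "T"), old[k]) else setdiff(c("A", "C", "G", "T"), old[k])
      sample(pool, 1)
    }, character(1))
    # suppress substitutions that would create an in-frame stop
    ci <- (hit - 1L) %/% 3L
    keep <- logical(length(hit))
    for (k in seq_along(hit)) {
      cod <- seqs[[g]][(3 * ci[k] + 1):(3 * ci[k] + 3)]
      cod[(hit[k] - 1L) %% 3L + 1L] <- new[k]
      keep[k] <- !(paste(cod, collapse = "") %in% STOP_CODONS) ||
        ci[k] == L[g] / 3 - 1  # terminal stop codon may stay a stop
    }
    hit <- hit[keep]; old <- old[keep]; new <- new[keep]
    if (!length(hit)) next
    seqs[[g]][hit] <- new
    sub_log[[g]] <- data.frame(gene_id = ids[g], position = hit,
                               ref_base = old, new_base = new,
                               stringsAsFactors = FALSE)
  }
  sub_log <- if (any(!vapply(sub_log, is.null, logical(1))))
    do.call(rbind, sub_log[!vapply(sub_log, is.null, logical(1))])
  else data.frame(gene_id = character(0), position = integer(0),
                  ref_base = character(0), new_base = character(0))

  # --- realize derived gene sequences ---------------------------------------
  derived_seq <- character(n)
  for (g in survivors) {
    s <- seqs[[g]]
    keep <- rep(TRUE, L[g])
    ins_at <- vector("list", L[g] + 1L)  # insertion emitted after position p
    ge <- events[events$gene_id == ids[g], , drop = FALSE]
    if (nrow(ge)) for (k in seq_len(nrow(ge))) {
      cat_k <- ge$category[k]; p <- ge$position[k]; sz <- ge$size[k]
      if (cat_k == "internal_deletion") {
        keep[p:min(L[g], p + sz - 1L)] <- FALSE
      } else if (cat_k == "five_prime_deletion") {
        keep[1:sz] <- FALSE
      } else if (cat_k == "three_prime_deletion") {
        keep[(L[g] - sz + 1L):L[g]] <- FALSE
      } else if (cat_k == "internal_insertion") {
        ins_at[[p + 1L]] <- c(ins_at[[p + 1L]],
                              paste(sample(c("A", "C", "G", "T"), sz, replace = TRUE),
                                    collapse = ""))
      } else if (cat_k == "is_element") {
        ins_at[[p + 1L]] <- c(ins_at[[p + 1L]], config$is_catalog[[ge$is_name[k]]])
      }
    }
    has_ins <- !vapply(ins_at, is.null, logical(1))
    if (any(has_ins)) {
      out <- character(0)
      bounds <- c(0L, which(has_ins) - 1L, L[g])
      bounds <- sort(unique(bounds))
      for (b in seq_len(length(bounds) - 1L)) {
        seg <- (bounds[b] + 1L):bounds[b + 1L]
        out <- c(out, paste(s[seg][keep[seg]], collapse = ""))
        at <- bounds[b + 1L] + 1L
        if (at <= L[g] + 1L && !is.null(ins_at[[at]]))
          out <- c(out, ins_at[[at]])
      }
      derived_seq[g] <- paste(out, collapse = "")
    } else {
      derived_seq[g] <- paste(s[keep], collapse = "")
    }
  }

  # --- reassemble derived contig ---------------------------------------------
  anc_ig <- intergenic_ranges(ancestral)[["chr1"]]
  spacers <- as.character(Biostrings::DNAStringSet(ancestral$contigs[["chr1"]],
                                                   start = IRanges::start(anc_ig),
                                                   end = IRanges::end(anc_ig)))
  spacers <- vapply(spacers, mutate_neutral_seq,
                    rate = config$point_sub_rate_gc4, at_bias = config$at_bias,
                    FUN.VALUE = character(1), USE.NAMES = FALSE)

  ord <- order(orfs$start)
  pieces <- character(0); meta <- list()
  pos <- 0L
  stopifnot(length(spacers) == n + 1)  # generator layout: spacer between genes
  for (j in seq_len(n)) {
    pieces <- c(pieces, spacers[j]); pos <- pos + nchar(spacers[j])
    g <- ord[j]
    if (g %in% absent || nchar(derived_seq[g]) == 0) next
    placed <- if (orfs$strand[g] == "+") derived_seq[g] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(derived_seq[g])))
    pieces <- c(pieces, placed)
    meta[[length(meta) + 1]] <- data.frame(
      gene_id = ids[g], contig_id = "chr1",
      start = pos + 1L, end = pos + nchar(placed),
      strand = orfs$strand[g], cog = orfs$cog[g],
      is_mobile = orfs$is_mobile[g],
      sequence = derived_seq[g], stringsAsFactors = FALSE)
    pos <- pos + nchar(placed)
  }
  pieces <- c(pieces, spacers[n + 1])
  derived <- genome_annotation("derived", c(chr1 = paste(pieces, collapse = "")),
                               do.call(rbind, meta))

  n_ev <- table(factor(events$gene_id, levels = ids))
  fate <- ifelse(seq_len(n) %in% absent, "absent",
                 ifelse(as.integer(n_ev) > 0, "pseudogene", "intact"))
  truth <- list(
    genes = data.frame(gene_id = ids,
                       is_neutral = seq_len(n) %in% neutral,
                       fate = fate,
                       n_events = as.integer(n_ev),
                       ancestral_length = L,
                       stringsAsFactors = FALSE),
    events = events,
    substitutions = sub_log)
  list(derived = derived, truth = truth)
}

# Draw one element from a vector (safe for length-1 vectors, unlike sample()).
sample1 <- function(x) x[sample.int(length(x), 1)]

# Per-position site class of a codon-complete ORF: 1 = first, 2 = second,
# 3 = non-degenerate third, 4 = fourfold-degenerate third position.
# Degeneracy is read from the actual codon; stop codons never contribute.
site_classes_seq <- function(seq) {
  L <- nchar(seq)
  n_codon <- L %/% 3
  cls <- rep(c(1L, 2L, 3L), n_codon)
  starts <- seq_len(n_codon) * 3 - 2
  pre <- substring(seq, starts, starts + 1)
  four <- pre %in% FOURFOLD_PREFIXES
  codons <- substring(seq, starts, starts + 2)
  four[codons %in% STOP_CODONS] <- FALSE
  cls[seq_len(n_codon) * 3][four] <- 4L
  cls
}

# Apply AT-biased substitutions at a single neutral rate to a sequence.
mutate_neutral_seq <- function(seq, rate, at_bias) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  if (!length(hit)) return(seq)
  s[hit] <- vapply(s[hit], function(b) {
    pool <- if (runif(1) < at_bias) setdiff(c("A", "T"), b)
            else setdiff(c("A", "C", "G", "T"), b)
    sample(pool, 1)
  }, character(1))
  paste(s, collapse = "")
}
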
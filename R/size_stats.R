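#' Class-wise ancestral ORF size summary
#'
#' Mean ancestral ORF sizes of the intact, pseudogene and absent classes (the
#' sizes are always the *ancestral* ortholog sizes, whatever happened to the
#' derived locus), with standard errors of the mean, plus the size-difference
#' statistic `delta = mean(pseudogene) - mean(intact)`.  A positive delta
#' indicates length-biased disruption and implies cryptic pseudogenes among
#' the intact class.  A two-sided Welch test of the intact/pseudogene mean
#' difference is reported alongside.
#'
#' @param classification Classification `data.frame` (columns `gene_id`,
#'   `status`).
#' @param ancestral_lengths Named vector of ancestral ORF lengths in bases.
#' @return List: `summary` (`data.frame`, classes all/intact/pseudogene/
#'   absent with `n`, `mean_bp`, `sem_bp`), `delta_bp` (`NA` when either
#'   class is empty) and `welch_p`.
#' @export
size_summary <- function(classification, ancestral_lengths) {
  stopifnot(all(classification$gene_id %in% names(ancestral_lengths)))
  len <- ancestral_lengths[classification$gene_id]
  groups <- list(all = len,
                 intact = len[classification$status == "intact"],
                 pseudogene = len[classification$status == "pseudogene"],
                 absent = len[classification$status == "absent"])
  summary <- do.call(rbind, lapply(names(groups), function(cl) {
    x <- groups[[cl]]
    data.frame(class = cl, n = length(x),
               mean_bp = if (length(x)) mean(x) else NA_real_,
               sem_bp = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  delta <- if (length(groups$intact) && length(groups$pseudogene))
    mean(groups$pseudogene) - mean(groups$intact) else NA_real_
  welch_p <- if (length(groups$intact) > 1 && length(groups$pseudogene) > 1)
    tryCatch(t.test(groups$pseudogene, groups$intact)$p.value,
             error = function(e) NA_real_)   # degenerate (constant) samples
  else NA_real_
  list(summary = summary, delta_bp = delta, welch_p = welch_p)
}

#' Ortholog retention by functional category
#'
#' Cross-tabulates the fate of ancestral orthologs in two derived genomes per
#' COG functional category: retained intact in both, retained intact in
#' exactly one, or lost/disrupted in both.  Genes without a category label
#' are bucketed as `"unassigned"`.
#'
#' @param classification_a,classification_b Classification `data.frame`s for
#'   the two derived genomes (same ancestral gene set).
#' @param cog_labels Named character vector: gene_id -> COG category letter
#'   (`NA` allowed).
#' @return `data.frame` per category: `n_genes`, `retained_both`,
#'   `retained_one`, `lost_both`.
#' @export
retention_by_category <- function(classification_a, classification_b, cog_labels) {
  ids <- intersect(classification_a$gene_id, classification_b$gene_id)
  if (!length(ids)) stop("no shared genes between the two classifications")
  a <- setNames(classification_a$status, classification_a$gene_id)[ids]
  b <- setNames(classification_b$status, classification_b$gene_id)[ids]
  cog <- cog_labels[ids]
  cog[is.na(cog)] <- "unassigned"
  intact_a <- a == "intact"; intact_b <- b == "intact"
  tab <- data.frame(category = cog,
                    both = intact_a & intact_b,
                    one = xor(intact_a, intact_b),
                    neither = !intact_a & !intact_b)
  out <- do.call(rbind, lapply(split(tab, tab$category), function(d)
    data.frame(category = d$category[1], n_genes = nrow(d),
               retained_both = sum(d$both), retained_one = sum(d$one),
               lost_both = sum(d$neither), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$category), , drop = FALSE]
}
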
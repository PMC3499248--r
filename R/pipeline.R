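#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; drives the erosion simulator and the Monte Carlo
#'   estimator.
#' @param erosion An [erosion_config()]; defaults to the standard study
#'   conditions under the master seed.
#' @param scoring [align_scoring()] parameters.
#' @param mc Named list of [mc_config()] overrides (e.g. `replicates`,
#'   `n_cycles`).
#' @param ancestral_fasta,ancestral_annotation,derived_fasta,derived_annotation
#'   Optional paths to pre-existing genomes; when supplied, the simulate
#'   stage is skipped and the comparison runs on the loaded genomes.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       erosion = erosion_config(seed = seed),
                       scoring = align_scoring(), mc = list(),
                       ancestral_fasta = NULL, ancestral_annotation = NULL,
                       derived_fasta = NULL, derived_annotation = NULL) {
  paths <- c(ancestral_fasta, ancestral_annotation,
             derived_fasta, derived_annotation)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  ext <- !vapply(list(ancestral_fasta, ancestral_annotation,
                      derived_fasta, derived_annotation), is.null, logical(1))
  if (any(ext) && !all(ext))
    stop("external genomes need all four of ancestral/derived fasta and annotation paths")
  structure(list(out_dir = out_dir, seed = seed, erosion = erosion,
                 scoring = scoring, mc = mc,
                 ancestral_fasta = ancestral_fasta,
                 ancestral_annotation = ancestral_annotation,
                 derived_fasta = derived_fasta,
                 derived_annotation = derived_annotation),
            class = "run_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full erosion-analysis pipeline
#'
#' Synthesize (or load) an ancestral/derived genome pair, compare them,
#' and emit the full report bundle as TSV files: genome summaries, per-gene
#' classification, mutation events, allelic spectrum, composition and
#' divergence metrics, class size summary, the Monte Carlo estimate of genes
#' under relaxed selection, and a manifest recording seed and package
#' version.  All randomness derives from the config seed, so re-running with
#' the same config reproduces every output byte-identically.
#'
#' @param config A [run_config()].
#' @param stages Subset of stages to run (the comparison stage is implied by
#'   any downstream stage).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "compare", "spectrum",
                                    "composition", "sizes", "cryptic"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  res <- list()

  if (!is.null(config$ancestral_fasta)) {
    ancestral <- load_genome(config$ancestral_fasta, config$ancestral_annotation,
                             genome_id = "ancestral")
    derived <- load_genome(config$derived_fasta, config$derived_annotation,
                           genome_id = "derived")
    truth <- NULL
  } else {
    say("simulate: generating ancestral genome (%d genes)",
        config$erosion$n_genes)
    ancestral <- generate_ancestral(config$erosion)
    er <- erode(ancestral, config$erosion)
    derived <- er$derived
    truth <- er$truth
    if ("simulate" %in% stages) {
      write_genome(ancestral, file.path(config$out_dir, "ancestral.fa"),
                   file.path(config$out_dir, "ancestral.tsv"))
      write_genome(derived, file.path(config$out_dir, "derived.fa"),
                   file.path(config$out_dir, "derived.tsv"))
      write_tsv(truth$genes, file.path(config$out_dir, "truth_genes.tsv"))
      write_tsv(truth$events, file.path(config$out_dir, "truth_events.tsv"))
      yaml::write_yaml(config$erosion[setdiff(names(config$erosion), "is_catalog")],
                       file.path(config$out_dir, "erosion_config.yaml"))
    }
  }
  res$ancestral <- ancestral; res$derived <- derived; res$truth <- truth

  needs_compare <- any(c("compare", "spectrum", "composition", "sizes",
                         "cryptic") %in% stages)
  if (needs_compare) {
    say("compare: aligning %d orthologs", nrow(ancestral$orfs))
    cmp <- compare_genomes(ancestral, derived,
                           is_catalog = config$erosion$is_catalog,
                           scoring = config$scoring)
    res$comparison <- cmp
    write_tsv(cmp$classification, file.path(config$out_dir, "classification.tsv"))
    write_tsv(cmp$events, file.path(config$out_dir, "events.tsv"))
    write_tsv(rbind(genome_summary(ancestral),
                    genome_summary(derived, cmp$classification)),
              file.path(config$out_dir, "genome_summary.tsv"))
  }

  anc_len <- setNames(nchar(ancestral$orfs$sequence), ancestral$orfs$gene_id)

  if ("spectrum" %in% stages) {
    sp <- spectrum(cmp$events,
                   pseudogene_count = sum(cmp$classification$status == "pseudogene"))
    res$spectrum <- sp
    write_tsv(sp, file.path(config$out_dir, "spectrum.tsv"))
  }
  if ("composition" %in% stages) {
    say("composition: site classes and divergence")
    res$composition <- composition_metrics(ancestral, derived, cmp)
    write_tsv(res$composition, file.path(config$out_dir, "composition.tsv"))
    skew <- gc_skew(ancestral$contigs[[1]],
                    window = min(40000, Biostrings::width(ancestral$contigs)[1]))
    write_tsv(skew, file.path(config$out_dir, "gc_skew.tsv"))
  }
  if ("sizes" %in% stages) {
    sz <- size_summary(cmp$classification, anc_len)
    res$sizes <- sz
    write_tsv(sz$summary, file.path(config$out_dir, "sizes.tsv"))
  }
  if ("cryptic" %in% stages) {
    say("cryptic: Monte Carlo estimation of relaxed-selection class size")
    cls <- cmp$classification
    compared <- cls$gene_id[cls$status != "absent"]
    P <- sum(cls$status == "pseudogene")
    delta <- size_summary(cls[cls$status != "absent", ], anc_len)$delta_bp
    mc_args <- modifyList(list(lengths = unname(anc_len[compared]),
                               target_pseudo_count = P, target_delta = delta,
                               seed = config$seed), config$mc)
    mc <- estimate_neutral_count(do.call(mc_config, mc_args))
    res$mc <- mc
    write_tsv(data.frame(n_hat = mc$n_hat, matched_cycle = mc$matched_cycle,
                         matched_delta = mc$matched_delta,
                         matched_density_per_kb = mc$matched_density),
              file.path(config$out_dir, "mc_result.tsv"))
  }

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("erosim")),
                   stages = stages,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  say("done in %.1f s", manifest$elapsed_sec)
  invisible(res)
}
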
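test_that("ORF sequences are spliced and strand-corrected on load", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); tsv <- file.path(dir, "g.tsv")

  # forward gene on a single contig
  writeLines(c(">c1", "ATGAAATAG"), fa)
  write.table(data.frame(gene_id = "g1", contig_id = "c1", start = 1, end = 9,
                         strand = "+", cog = NA),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- load_genome(fa, tsv)
  expect_equal(ann$orfs$sequence, "ATGAAATAG")

  # the same gene annotated on the minus strand of the reverse complement
  writeLines(c(">c1", "CTATTTCAT"), fa)
  write.table(data.frame(gene_id = "g1", contig_id = "c1", start = 1, end = 9,
                         strand = "-", cog = NA),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_genome(fa, tsv)$orfs$sequence, "ATGAAATAG")
})

test_that("annotation referencing a missing contig fails naming the feature", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); tsv <- file.path(dir, "g.tsv")
  writeLines(c(">c1", "ATGAAATAG"), fa)
  write.table(data.frame(gene_id = "gX", contig_id = "nope", start = 1, end = 9,
                         strand = "+", cog = NA),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_genome(fa, tsv), "gX")

  write.table(data.frame(gene_id = "gY", contig_id = "c1", start = 4, end = 22,
                         strand = "+", cog = NA),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_genome(fa, tsv), "gY")
})

test_that("write/load round-trip reproduces ORF sequences byte-identically", {
  toy <- make_toy_genome()
  dir <- withr::local_tempdir()
  for (ext in c("tsv", "gff3")) {
    fa <- file.path(dir, paste0("t.", ext, ".fa"))
    annp <- file.path(dir, paste0("t.", ext))
    write_genome(toy, fa, annp)
    back <- load_genome(fa, annp)
    expect_identical(sort(back$orfs$gene_id), sort(toy$orfs$gene_id))
    expect_identical(back$orfs$sequence[match(toy$orfs$gene_id, back$orfs$gene_id)],
                     toy$orfs$sequence)
    expect_identical(back$orfs$is_mobile[match(toy$orfs$gene_id, back$orfs$gene_id)],
                     toy$orfs$is_mobile)
  }
})

test_that("translate_frame finds internal stops like a codon scan", {
  tf <- translate_frame("ATGAAATAG")
  expect_equal(tf$peptide, "MK*")
  expect_equal(tf$internal_stops, integer(0))

  tf <- translate_frame("ATGTAAAAATAG")
  expect_equal(tf$peptide, "M*K*")
  expect_equal(tf$internal_stops, 2L)   # the TAA codon; terminal TAG excluded

  # trailing partial codon ignored; GTG translated literally
  expect_equal(translate_frame("GTGAAAT")$peptide, "VK")

  set.seed(42)
  for (r in 1:5) {
    s <- random_dna(999)
    expect_equal(translate_frame(s)$internal_stops, stop_scan_oracle(s))
  }
})

test_that("annotation intactness follows the 90% size / no-frameshift rule", {
  expect_true(annotation_intact(900, 1000, FALSE))
  expect_false(annotation_intact(899, 1000, FALSE))
  expect_false(annotation_intact(1000, 1000, TRUE))
})

test_that("genome summary reports sizes, mobile DNA and G+C", {
  toy <- make_toy_genome()
  s <- genome_summary(toy)
  expect_equal(s$size_bp, sum(Biostrings::width(toy$contigs)))
  expect_equal(s$mobile_bp, 12)
  expect_equal(s$n_genes, 3)

  allg <- genome_annotation("g", c(c1 = "GGGGGG"),
                            data.frame(gene_id = "x", contig_id = "c1",
                                       start = 1, end = 6, strand = "+"))
  expect_equal(genome_summary(allg)$gc_percent, 100)

  set.seed(7)
  s <- random_dna(5000)
  counted <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_equal(gc_content(s),
               100 * (counted[["G"]] + counted[["C"]]) / sum(counted))
})

test_that("pooled G+C equals the length-weighted mean of per-contig G+C", {
  set.seed(11)
  contigs <- c(a = random_dna(1000), b = random_dna(2500), c = random_dna(400))
  per <- vapply(contigs, gc_content, numeric(1))
  w <- nchar(contigs)
  expect_equal(gc_content(contigs), sum(per * w) / sum(w), tolerance = 1e-12)
})

test_that("N bases are excluded from G+C denominators", {
  expect_equal(gc_content("GGNNNN"), 100)
  expect_equal(gc_content("GANN"), 50)
  expect_true(is.na(gc_content("NNNN")))
})
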
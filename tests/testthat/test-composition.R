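test_that("site classes match the genetic-code enumeration on small ORFs", {
  ann <- genome_annotation("t", c(c1 = paste0("TT", "ATGGCTTAA", "TT")),
                           data.frame(gene_id = "g1", contig_id = "c1",
                                      start = 3, end = 11, strand = "+"))
  sites <- classify_sites(ann)
  expect_equal(sites$gc2$g1, c(2, 5, 8))      # second positions of ATG GCT TAA
  expect_equal(sites$gc4$g1, 6)               # GCT third base only
  # Lys codons are two-fold: no GC4 sites
  ann2 <- genome_annotation("t", c(c1 = "ATGAAAAAATAA"),
                            data.frame(gene_id = "g1", contig_id = "c1",
                                       start = 1, end = 12, strand = "+"))
  expect_equal(length(classify_sites(ann2)$gc4$g1), 0)

  # random ORFs against the exhaustive codon-table oracle
  set.seed(111)
  for (r in 1:5) {
    n_codon <- 40
    cods <- replicate(n_codon, {
      repeat {
        cc <- random_dna(3)
        if (!cc %in% c("TAA", "TAG", "TGA")) return(cc)
      }
    })
    s <- paste(c(cods, "TAA"), collapse = "")
    ann3 <- genome_annotation("t", c(c1 = s),
                              data.frame(gene_id = "g", contig_id = "c1",
                                         start = 1, end = nchar(s), strand = "+"))
    got4 <- classify_sites(ann3)$gc4$g
    want4 <- unname(which(rep(vapply(c(cods, "TAA"), fourfold_oracle, logical(1)),
                              each = 3) & rep(c(FALSE, FALSE, TRUE), n_codon + 1)))
    expect_equal(got4, want4)
  }
})

test_that("site classes partition: GC2, GC4 and intergenic never overlap", {
  fx <- erode_fixture(seed = 19, n_genes = 40)
  sites <- classify_sites(fx$ancestral)
  for (g in names(sites$gc2))
    expect_length(intersect(sites$gc2[[g]], sites$gc4[[g]]), 0)
  ig <- sites$intergenic[["chr1"]]
  orf_rng <- IRanges::IRanges(fx$ancestral$orfs$start, fx$ancestral$orfs$end)
  expect_equal(sum(IRanges::width(IRanges::intersect(ig, IRanges::reduce(orf_rng)))), 0)
})

test_that("gc_percent recovers configured composition targets", {
  allg <- genome_annotation("g", c(c1 = paste0("ATG", "GGCGGC", "TAA")),
                            data.frame(gene_id = "x", contig_id = "c1",
                                       start = 1, end = 12, strand = "+"))
  sites <- classify_sites(allg)
  expect_equal(gc_percent(allg, sites, "gc4"), 100)   # GGC third bases all C

  cfg <- erosion_config(seed = 23, n_genes = 800, gc4_target = 0.40)
  anc <- generate_ancestral(cfg)
  s <- classify_sites(anc)
  expect_lt(abs(gc_percent(anc, s, "gc4") - 40), 2)
  expect_lt(abs(gc_percent(anc, s, "gci") - 50), 2)
})

test_that("site divergence is a p-distance with symmetric projection", {
  s <- paste0("ATG", paste(rep("GCT", 30), collapse = ""), "TAA")
  ann <- genome_annotation("t", c(c1 = s),
                           data.frame(gene_id = "g", contig_id = "c1",
                                      start = 1, end = nchar(s), strand = "+"))
  sites <- classify_sites(ann)
  al <- list(g = align_orf(s, s, gene_id = "g"))
  expect_equal(site_divergence(al, sites, "gc4")$divergence, 0)

  # one substitution at a GC4 site out of 30
  q <- paste0(substr(s, 1, 5), "A", substr(s, 7, nchar(s)))  # GCT -> GCA
  al2 <- list(g = align_orf(s, q, gene_id = "g"))
  d <- site_divergence(al2, sites, "gc4")
  expect_equal(d$n_sites, 30)
  expect_equal(d$divergence, 1 / 30)
})

test_that("gc skew takes its extreme and null values", {
  expect_equal(gc_skew(strrep("G", 5000), window = 1000)$skew[1], 1)
  expect_equal(gc_skew(strrep("C", 5000), window = 1000)$skew[1], -1)
  expect_equal(gc_skew(strrep("GCAT", 2000), window = 2000)$skew[1], 0)
  sk <- gc_skew(strrep("GCAT", 25000), window = 40000, step = 20000)
  expect_true(all(sk$end <= 100000))
})

test_that("divergence time conversion is dimensionally sound", {
  expect_equal(divergence_time(0, 2.2e-7), 0)
  expect_equal(divergence_time(4.4e-7 * 2 * 1, 4.4e-7), 1)
  # the printed silent-site divergence and clock rate give ~97,700 years at
  # unit generation scaling
  expect_equal(divergence_time(0.043, 2.2e-7), 97727.27, tolerance = 1e-6)
  # a generations-per-year scaling of ~3.5 brings the estimate to ~28,000
  expect_equal(divergence_time(0.043, 2.2e-7, generations_scaling = 3.49),
               28000, tolerance = 0.01)
})
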
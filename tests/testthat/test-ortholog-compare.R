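test_that("intactness thresholds follow the coverage and frame rules", {
  mk <- function(cov, ref_len) {
    # minimal alignment stub: clean alignment with the requested coverage
    n <- round(cov * ref_len)
    s <- random_dna(ref_len)
    structure(list(gene_id = "g", ref_len = ref_len, qry_len = n, ref_seq = s,
                   segments = list(list(ref_start = 1L, ref_end = n,
                                        qry_start = 1L, qry_end = n,
                                        aligned_ref = substr(s, 1, n),
                                        aligned_qry = substr(s, 1, n),
                                        score = n)),
                   aligned_ref = substr(s, 1, n), aligned_qry = substr(s, 1, n),
                   ref_start = 1L, ref_end = n, qry_start = 1L, qry_end = n,
                   ref_coverage = n / ref_len, score = n,
                   indels = data.frame(ref_position = integer(0),
                                       length = integer(0), kind = character(0)),
                   substitutions = data.frame(ref_position = integer(0),
                                              ref_base = character(0),
                                              qry_base = character(0)),
                   ref_map = seq_len(n), qry_at = strsplit(substr(s, 1, n), "")[[1]],
                   qry_map = seq_len(n)), class = "orf_alignment")
  }
  set.seed(71)
  expect_equal(classify_ortholog(mk(0.995, 1000), 1000)$status, "intact")
  expect_equal(classify_ortholog(mk(0.92, 250), 250)$status, "intact")
  expect_equal(classify_ortholog(mk(0.95, 1000), 1000)$status, "pseudogene")
  expect_equal(classify_ortholog(mk(0.05, 1000), 1000)$status, "absent")
  expect_equal(classify_ortholog(NULL, 1000, found = FALSE)$status, "absent")

  # full coverage but one frameshifting deletion
  s <- random_dna(999)
  q <- paste0(substr(s, 1, 500), substr(s, 502, 999))
  al <- align_orf(s, q, gene_id = "g")
  expect_equal(classify_ortholog(al, 999)$status, "pseudogene")
  expect_match(classify_ortholog(al, 999)$reasons, "frameshift_indel")
})

test_that("nonsense detection projects onto the ancestral frame through frameshifts", {
  # TGG -> TGA at an interior codon (CAT-repeat body keeps TGG unique)
  body <- paste(rep("CAT", 60), collapse = "")
  s <- paste0("ATG", substr(body, 1, 90), "TGG", substr(body, 91, 180), "TAA")
  q <- sub("TGG", "TGA", s)
  al <- align_orf(s, q, gene_id = "g")
  ev <- extract_mutations(al)
  expect_equal(ev$category, "nonsense")
  expect_equal(ev$ref_position, 94)   # codon 32, first base
  expect_equal(ev$size, 0)
  expect_equal(classify_ortholog(al, nchar(s))$status, "pseudogene")

  # the stop is still found when an upstream frameshift shifted the query,
  # and the terminal ancestral stop codon is never a nonsense event
  q2 <- paste0(substr(q, 1, 10), substr(q, 12, nchar(q)))  # 1-bp del upstream
  ev2 <- extract_mutations(align_orf(s, q2, gene_id = "g"))
  expect_true("nonsense" %in% ev2$category)
  expect_equal(ev2$ref_position[ev2$category == "nonsense"], 94)
})

test_that("unaligned termini and terminal-touching gaps become terminal deletions", {
  set.seed(81)
  s <- random_dna(1000)
  # first 120 bases missing from the locus
  ev <- extract_mutations(align_orf(s, substr(s, 121, 1000), gene_id = "g"))
  expect_equal(ev$category, "five_prime_deletion")
  expect_equal(ev$size, 120)
  # last 200 bases missing
  ev <- extract_mutations(align_orf(s, substr(s, 1, 800), gene_id = "g"))
  expect_equal(ev$category, "three_prime_deletion")
  expect_equal(ev$size, 200)
})

test_that("catalog-matching insertions are classified as IS elements", {
  set.seed(91)
  catalog <- default_is_catalog()
  s <- random_dna(900)
  q <- paste0(substr(s, 1, 450), catalog[["ISsyn3"]], substr(s, 451, 900))
  al <- align_orf(s, q, gene_id = "g")
  ev <- extract_mutations(al, qry_seq = q, is_catalog = catalog)
  expect_equal(ev$category, "is_element")
  expect_equal(ev$size, 1200)
  expect_equal(classify_ortholog(al, 900, events = ev)$status, "pseudogene")

  # without a catalog the same insertion is a plain internal insertion
  ev0 <- extract_mutations(al, qry_seq = q)
  expect_equal(ev0$category, "internal_insertion")
})

test_that("clean alignments yield no mutation events", {
  s <- random_dna(600)
  expect_equal(nrow(extract_mutations(align_orf(s, s, gene_id = "g"))), 0)
})

test_that("classification matches the simulator ground truth exactly (no background noise)", {
  fx <- erode_fixture(seed = 17)
  cmp <- compare_genomes(fx$ancestral, fx$derived, is_catalog = fx$cfg$is_catalog)
  expect_identical(cmp$classification$gene_id, fx$truth$genes$gene_id)
  expect_identical(cmp$classification$status, fx$truth$genes$fate)
  # one status per compared gene, statuses exhaustive
  expect_equal(nrow(cmp$classification), nrow(fx$ancestral$orfs))
  expect_true(all(cmp$classification$status %in% c("intact", "pseudogene", "absent")))
})

test_that("detected event categories match injected events on single-event genes", {
  fx <- erode_fixture(seed = 18)
  cmp <- compare_genomes(fx$ancestral, fx$derived, is_catalog = fx$cfg$is_catalog)
  single <- fx$truth$genes$gene_id[fx$truth$genes$n_events == 1 &
                                   fx$truth$genes$fate == "pseudogene"]
  truth1 <- fx$truth$events[fx$truth$events$gene_id %in% single, ]
  det1 <- cmp$events[cmp$events$gene_id %in% single, ]
  m <- merge(truth1[, c("gene_id", "category")],
             det1[, c("gene_id", "category")], by = "gene_id",
             suffixes = c("_truth", "_det"))
  expect_gte(nrow(m), 15)
  expect_true(all(m$category_truth == m$category_det))
})

test_that("the spectrum table tabulates counts and proportions", {
  expect_equal(sum(spectrum(data.frame(gene_id = character(0),
                                       category = character(0)))$count), 0)
  ev <- data.frame(gene_id = "g", category = rep("nonsense", 10))
  sp <- spectrum(ev)
  expect_equal(sp$proportion[sp$category == "nonsense"], 1)
  expect_equal(sp$percent[sp$category == "nonsense"], 100)
  expect_equal(sum(sp$proportion), 1)
})

test_that("mutation density uses the requested length denominator", {
  cls <- data.frame(gene_id = c("a", "b"), status = "pseudogene")
  ev <- data.frame(gene_id = c("a", "a", "b"), category = "nonsense")
  d_anc <- mutation_density(ev, cls, c(a = 1000, b = 500),
                            mode = "ancestral")
  expect_equal(d_anc$density_per_kb, c(2.0, 2.0))
  d_cur <- mutation_density(ev, cls, c(a = 1000, b = 500),
                            current_lengths = c(a = 500, b = 0),
                            mode = "current")
  expect_equal(d_cur$density_per_kb[1], 4.0)   # halved denominator
  expect_true(is.na(d_cur$density_per_kb[2]))  # zero current length
})

test_that("dispersion diagnostics distinguish Poisson from mixtures", {
  expect_equal(poisson_dispersion(rep(3, 50))$vmr, 0)
  set.seed(101)
  null_counts <- rpois(2000, 2)
  pd <- poisson_dispersion(null_counts)
  expect_gt(pd$vmr, 0.9); expect_lt(pd$vmr, 1.1)
  expect_gt(pd$p_value, 1e-4)
  mixed <- c(rpois(1000, 1), rpois(1000, 5))
  expect_gt(poisson_dispersion(mixed)$vmr, 1)
  expect_error(poisson_dispersion(rep(0, 10)), "zero")
})
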
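test_that("generated ORFs are codon-clean and length-calibrated", {
  cfg <- erosion_config(seed = 1, n_genes = 60, igs_mean = 40)
  anc <- generate_ancestral(cfg)
  expect_equal(nrow(anc$orfs), 60)
  expect_true(all(substr(anc$orfs$sequence, 1, 3) == "ATG"))
  last3 <- substring(anc$orfs$sequence, nchar(anc$orfs$sequence) - 2)
  expect_true(all(last3 %in% c("TAA", "TAG", "TGA")))
  expect_true(all(vapply(anc$orfs$sequence,
                         function(s) length(translate_frame(s)$internal_stops) == 0,
                         logical(1))))
  expect_true(all(nchar(anc$orfs$sequence) %% 3 == 0))

  # sequences really sit at the annotated coordinates
  rebuilt <- erosim:::orf_sequences(anc$contigs, anc$orfs)
  expect_identical(rebuilt, anc$orfs$sequence)
})

test_that("length distribution matches the configured gamma model", {
  cfg <- erosion_config(seed = 5, n_genes = 4000)
  anc <- generate_ancestral(cfg)
  len <- nchar(anc$orfs$sequence)
  se <- 950 / sqrt(2) / sqrt(4000)   # gamma(shape 2) sd = mean / sqrt(shape)
  expect_lt(abs(mean(len) - 950), 3 * se + 3)  # +3 bp for codon rounding/floor
})

test_that("same seed reproduces the genome byte-identically, different seeds differ", {
  cfg <- erosion_config(seed = 9, n_genes = 40)
  a1 <- generate_ancestral(cfg)
  a2 <- generate_ancestral(cfg)
  expect_identical(as.character(a1$contigs), as.character(a2$contigs))
  expect_identical(a1$orfs, a2$orfs)

  e1 <- erode(a1, cfg); e2 <- erode(a2, cfg)
  expect_identical(e1$truth$events, e2$truth$events)
  expect_identical(as.character(e1$derived$contigs),
                   as.character(e2$derived$contigs))

  cfg3 <- erosion_config(seed = 10, n_genes = 40)
  a3 <- generate_ancestral(cfg3)
  expect_false(identical(as.character(a1$contigs), as.character(a3$contigs)))
  e3 <- erode(a3, cfg3)
  expect_false(identical(e1$truth$events, e3$truth$events))
})

test_that("a zero-mutation erosion returns the ancestral genome unchanged", {
  cfg <- erosion_config(seed = 3, n_genes = 30, mutation_budget = 0,
                        deletion_fraction = 0, point_sub_rate_gc4 = 0,
                        point_sub_rate_gc2 = 0, relaxed_gc2_extra = 0)
  anc <- generate_ancestral(cfg)
  er <- erode(anc, cfg)
  expect_identical(as.character(er$derived$contigs), as.character(anc$contigs))
  expect_identical(er$derived$orfs$sequence, anc$orfs$sequence)
  expect_true(all(er$truth$genes$fate == "intact"))
})

test_that("saturating budgets disrupt every surviving neutral gene", {
  fx <- erode_fixture(seed = 4, n_genes = 50, n_neutral = 50,
                      mutation_budget = 50 * 50, deletion_fraction = 0)
  expect_true(all(fx$truth$genes$fate == "pseudogene"))
  expect_true(all(fx$truth$genes$n_events >= 1))
})

test_that("realized pseudogene count follows the length-binomial closed form", {
  fx <- erode_fixture(seed = 6, n_genes = 600, n_neutral = 600,
                      mutation_budget = 500, deletion_fraction = 0)
  L <- fx$truth$genes$ancestral_length
  p <- 1 - (1 - L / sum(L))^500
  expected <- sum(p)
  sd_count <- sqrt(sum(p * (1 - p)))
  observed <- sum(fx$truth$genes$fate == "pseudogene")
  expect_lt(abs(observed - expected), 3 * sd_count)
})

test_that("truth-table invariants hold", {
  fx <- erode_fixture(seed = 8)
  tg <- fx$truth$genes
  # disrupting events only on neutral genes; pseudogene <=> at least one event
  expect_true(all(tg$is_neutral[tg$fate != "intact"]))
  expect_true(all(tg$n_events[tg$fate == "pseudogene"] >= 1))
  expect_true(all(tg$n_events[tg$fate != "pseudogene"] == 0))
  # absent genes are really gone from the derived annotation
  expect_false(any(tg$gene_id[tg$fate == "absent"] %in% fx$derived$orfs$gene_id))
  expect_setequal(fx$derived$orfs$gene_id, tg$gene_id[tg$fate != "absent"])
})

test_that("event categories converge to the configured mix", {
  mix <- c(internal_insertion = 0.19, internal_deletion = 0.34,
           five_prime_deletion = 0.07, three_prime_deletion = 0.11,
           nonsense = 0.19, is_element = 0.10)
  fx <- erode_fixture(seed = 12, n_genes = 1200, n_neutral = 1200,
                      mutation_budget = 2400, deletion_fraction = 0)
  tab <- table(factor(fx$truth$events$category, levels = names(mix)))
  n <- sum(tab)
  p_hat <- as.numeric(tab) / n
  se <- sqrt(mix * (1 - mix) / n)
  expect_true(all(abs(p_hat - mix) < 3.5 * se))
})

test_that("disruption is length-biased exactly when lengths are heterogeneous", {
  # equal lengths: no expected size difference between disrupted and intact
  set.seed(99)
  diffs <- replicate(30, {
    cfg <- erosion_config(seed = sample.int(1e6, 1), n_genes = 80,
                          length_mean = 300, length_shape = 1e6,
                          n_neutral = 80, mutation_budget = 60,
                          deletion_fraction = 0, point_sub_rate_gc4 = 0,
                          point_sub_rate_gc2 = 0, relaxed_gc2_extra = 0)
    anc <- generate_ancestral(cfg)
    tg <- erode(anc, cfg)$truth$genes
    mean(tg$ancestral_length[tg$fate == "pseudogene"]) -
      mean(tg$ancestral_length[tg$fate == "intact"])
  })
  expect_lt(abs(mean(diffs)), 5)   # equal-length model: difference ~ 0

  # heterogeneous lengths: disrupted genes are larger on average
  fx <- erode_fixture(seed = 13, n_genes = 500, n_neutral = 500,
                      mutation_budget = 400, deletion_fraction = 0)
  tg <- fx$truth$genes
  expect_gt(mean(tg$ancestral_length[tg$fate == "pseudogene"]),
            mean(tg$ancestral_length[tg$fate == "intact"]))
})

test_that("IS insertions require a catalog", {
  expect_error(
    erosion_config(seed = 1, is_catalog = character(0)),
    "is_catalog")
})

test_that("degenerate site classes follow the genetic code", {
  # every third position of a fourfold family codon, nothing else
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  for (cod in sample(codons, 20)) {
    cls <- erosim:::site_classes_seq(cod)
    expect_identical(cls[3] == 4L, fourfold_oracle(cod), label = cod)
  }
})
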
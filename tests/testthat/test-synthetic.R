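test_that("ancestral sequences follow the i.i.d. law and are seed-deterministic", {
  expect_identical(generate_ancestral_sequence(500, 0.5, seed = 3),
                   generate_ancestral_sequence(500, 0.5, seed = 3))
  expect_false(generate_ancestral_sequence(500, 0.5, seed = 3) ==
                 generate_ancestral_sequence(500, 0.5, seed = 4))

  s <- generate_ancestral_sequence(1000, 0.5, seed = 11)
  gc <- count_dinucleotides(s)
  n_gc <- gc$mono[["C"]] + gc$mono[["G"]]
  expect_lt(abs(n_gc - 500), 4 * sqrt(1000 * 0.5 * 0.5))  # binomial 4 sd

  # i.i.d. letters have expected O/E of 1 for every dinucleotide
  oes <- vapply(1:60, function(i) {
    dinucleotide_oe(count_dinucleotides(
      generate_ancestral_sequence(1000, 0.5, seed = 100 + i)), "CG")$oe
  }, numeric(1))
  expect_gt(mean(oes), 0.9)
  expect_lt(mean(oes), 1.1)

  expect_error(generate_ancestral_sequence(0, 0.5), "positive")
  expect_error(generate_ancestral_sequence(10, 1.2), "between 0 and 1")
})

test_that("evolution is deterministic, length-preserving and leaves N alone", {
  anc <- paste0(generate_ancestral_sequence(300, 0.42, seed = 5), "NNNN")
  e1 <- evolve_sequence(anc, 0.05, 10, rounds = 5, seed = 9)
  e2 <- evolve_sequence(anc, 0.05, 10, rounds = 5, seed = 9)
  expect_identical(e1, e2)
  expect_equal(nchar(e1), nchar(anc))
  expect_identical(substr(e1, 301, 304), "NNNN")
  expect_false(e1 == anc)
  expect_identical(evolve_sequence(anc, 0.05, 10, rounds = 0, seed = 9), anc)

  expect_error(evolve_sequence(anc, 0.7, 1), "base_rate")
  expect_error(evolve_sequence(anc, 0.01, 0.5), "cpg_multiplier")
})

test_that("a unit CpG multiplier does not preferentially deplete CpG", {
  before <- after <- numeric(60)
  for (i in 1:60) {
    anc <- generate_ancestral_sequence(800, 0.42, seed = 500 + i)
    ev <- evolve_sequence(anc, 0.01, cpg_multiplier = 1, rounds = 10,
                          seed = 900 + i)
    before[i] <- dinucleotide_oe(count_dinucleotides(anc), "CG")$oe
    after[i] <- dinucleotide_oe(count_dinucleotides(ev), "CG")$oe
  }
  expect_gt(t.test(before, after, paired = TRUE)$p.value, 0.01)
})

test_that("CpG hypermutability depletes CpG, monotonically in the multiplier", {
  mean_oe <- vapply(c(1, 4, 12), function(mult) {
    mean(vapply(1:40, function(i) {
      anc <- generate_ancestral_sequence(600, 0.42, seed = 2000 + i)
      ev <- evolve_sequence(anc, 0.01, cpg_multiplier = mult, rounds = 10,
                            seed = 3000 + i)
      dinucleotide_oe(count_dinucleotides(ev), "CG")$oe
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_oe) < 0))
  expect_lt(mean_oe[3], 0.8)
})

test_that("unigene sets carry complete truth and a planted two-population signal", {
  gs <- generate_unigene_set(n_genes = 400, seed = 17)
  expect_identical(gs$truth$gene_id, names(gs$sequences))
  expect_equal(anyDuplicated(gs$truth$gene_id), 0L)
  expect_true(all(gs$truth$class %in% c("methylated", "unmethylated")))
  expect_true(all(nchar(gs$sequences) >= 101 & nchar(gs$sequences) <= 4278))
  expect_identical(gs$truth$length, unname(nchar(gs$sequences)))

  prof <- oe_profile(gs$sequences)
  fit <- fit_mixture(prof$oe[is.finite(prof$oe)], 2, seed = 1)
  expect_gte(diff(fit$means), 0.3)

  # class means straddle the mixture: truth drives the O/E separation
  class_means <- tapply(prof$oe, gs$truth$class, mean, na.rm = TRUE)
  expect_lt(class_means[["methylated"]], class_means[["unmethylated"]] - 0.3)
})

test_that("the CpG-specific signal leaves GpC unimodal", {
  gs <- generate_unigene_set(n_genes = 300, seed = 23)
  gpc <- oe_profile(gs$sequences, "GC")
  non_reject <- vapply(1:3, function(s) {
    !oe_unimodality_test(gpc, n_bootstrap = 99, seed = s)$reject_unimodal
  }, logical(1))
  expect_gte(sum(non_reject), 2)

  # and GpC shows no separated modes while CG does, on the same gene set
  cg <- oe_profile(gs$sequences)
  fit_gc <- fit_mixture(gpc$oe[is.finite(gpc$oe)], 2, seed = 1)
  fit_cg <- fit_mixture(cg$oe[is.finite(cg$oe)], 2, seed = 1)
  expect_lt(diff(fit_gc$means), 0.2)
  expect_gte(diff(fit_cg$means), 0.3)
})

test_that("planted annotations are deterministic and carry the enrichment", {
  truth <- data.frame(gene_id = sprintf("g%03d", 1:250),
                      class = rep(c("methylated", "unmethylated"), c(120, 130)),
                      stringsAsFactors = FALSE)
  a1 <- plant_annotations(truth, sprintf("GO:%02d", 1:10), "GO:01",
                          enrichment_factor = 8, baseline = 0.05, seed = 4)
  a2 <- plant_annotations(truth, sprintf("GO:%02d", 1:10), "GO:01",
                          enrichment_factor = 8, baseline = 0.05, seed = 4)
  expect_identical(a1, a2)
  expect_true(all(names(a1) %in% truth$gene_id))
  expect_true(all(lengths(a1) > 0))

  hits <- vapply(a1, function(t) "GO:01" %in% t, logical(1))
  rate_meth <- mean(hits[names(hits) %in% truth$gene_id[truth$class == "methylated"]])
  rate_unmeth <- mean(hits[names(hits) %in% truth$gene_id[truth$class == "unmethylated"]])
  expect_gt(rate_meth, rate_unmeth)

  expect_error(plant_annotations(truth, "GO:01", "GO:01", enrichment_factor = 0.5),
               "factor")
})

test_that("repeat genomes expose a digest-readable methylation signal", {
  gen <- generate_genome_with_repeats(n_repeats = 15, repeat_length = 60,
                                      spacer_length = 250,
                                      methylate_repeats = TRUE, seed = 6)
  chars <- strsplit(gen$sequence, "", fixed = TRUE)[[1]]
  expect_true(all(chars[gen$mask$forward + 1] == "C"))
  expect_true(all(chars[gen$mask$reverse + 1] == "G"))
  expect_equal(nrow(gen$repeat_intervals), 15)

  hmw <- 500
  sig <- compare_digests(digest(gen$sequence, "HpaII", gen$mask),
                         digest(gen$sequence, "MspI", gen$mask), hmw)
  expect_gt(sig, 0)

  unmeth <- generate_genome_with_repeats(n_repeats = 15, repeat_length = 60,
                                         spacer_length = 250,
                                         methylate_repeats = FALSE, seed = 6)
  expect_length(unmeth$mask$forward, 0)
  sig0 <- compare_digests(digest(unmeth$sequence, "HpaII", unmeth$mask),
                          digest(unmeth$sequence, "MspI", unmeth$mask), hmw)
  expect_equal(sig0, 0)

  # same seed, same genome regardless of masking flag
  expect_identical(gen$sequence, unmeth$sequence)
})
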
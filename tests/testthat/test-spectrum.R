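test_that("substitutions collapse to six strand-symmetric classes", {
  expect_identical(as.character(classify_substitution("G", "A")$class), "G:C>A:T")
  expect_identical(classify_substitution("G", "A")$kind, "transition")
  expect_identical(as.character(classify_substitution("T", "C")$class), "A:T>G:C")
  expect_identical(classify_substitution("T", "C")$kind, "transition")
  expect_identical(as.character(classify_substitution("G", "T")$class), "G:C>T:A")
  expect_identical(classify_substitution("G", "T")$kind, "transversion")
  # strand collapse holds for all 12 ordered pairs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) for (a in setdiff(names(comp), r)) {
    expect_identical(classify_substitution(r, a)$class,
                     classify_substitution(comp[[r]], comp[[a]])$class)
  }
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A, C, G, T")
})

test_that("ts/tv ratio counts transitions over transversions", {
  calls <- spectrum_calls(c("A:T>G:C" = 17, "G:C>A:T" = 40, "A:T>C:G" = 3,
                            "G:C>T:A" = 10, "A:T>T:A" = 9, "G:C>C:G" = 9))
  expect_equal(titv_ratio(calls), 57 / 31)
  expect_equal(round(titv_ratio(calls), 2), 1.84)
  expect_equal(titv_ratio(spectrum_calls(c("A:T>G:C" = 5, "G:C>T:A" = 5))), 1.0)
  expect_equal(titv_ratio(spectrum_calls(c("G:C>T:A" = 5))), 0 / 5 + 0)
  expect_warning(out <- titv_ratio(spectrum_calls(c("A:T>G:C" = 5))),
                 "transversions")
  expect_identical(out, Inf)
})

test_that("calls partition by CDS annotation with region-specific rates", {
  # 600 bp genome, one 300 bp CDS at 101-400
  set.seed(2)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  g <- toy_genome(seq, 101, 400)
  calls <- make_calls("L01", c(150, 250, 350, 50, 500),
                      substring(seq, c(150, 250, 350, 50, 500),
                                c(150, 250, 350, 50, 500)), "N")
  calls$alt <- vapply(calls$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  part <- partition_by_annotation(calls, g, denominator = 6e5)
  expect_equal(part$n_coding, 3)
  expect_equal(part$n_noncoding, 2)
  expect_equal(part$rate_coding$denominator, 0.5 * 6e5)
  expect_error(partition_by_annotation(make_calls("L01", 601, "A", "G"), g),
               "outside")
  # fully coding genome labels everything coding
  g2 <- toy_genome(strrep("ATGAAATAA", 10), 1, 90)
  expect_equal(partition_by_annotation(
    make_calls("L01", c(5, 50), "A", "G"), g2)$n_noncoding, 0)
  # identical proportions in a balanced toy table give Fisher p = 1
  gb <- toy_genome(paste(rep("ACGT", 500), collapse = ""), 1, 1000)
  pb <- partition_by_annotation(make_calls("L01", c(10, 20, 30, 40,
                                                    1010, 1020, 1030, 1040),
                                           "A", "G"), gb, denominator = 2000)
  expect_equal(pb$fisher_p, 1)
})

test_that("coding effects are classified strand-aware through the genetic code", {
  # plus strand: CDS ATGAAA; third-position wobble is synonymous
  g <- toy_genome(paste0("ATGAAA", strrep("T", 24)), 1, 6)
  expect_identical(classify_coding_effect(6, "A", "G", g), "synonymous")
  expect_identical(classify_coding_effect(4, "A", "G", g), "nonsynonymous")
  expect_error(classify_coding_effect(20, "T", "A", g), "not inside")
  expect_error(classify_coding_effect(6, "C", "G", g), "does not match")
  # minus strand: genome GGGTTTCAT is CDS ATGAAACCC read off the reverse
  # strand; forward G>A at genome pos 1 is codon-3 C>T, CCC>CCT (Pro>Pro)
  gm <- toy_genome(paste0("GGGTTTCAT", strrep("A", 21)), 1, 9, strand = "-")
  expect_identical(classify_coding_effect(1, "G", "A", gm), "synonymous")
  # and forward T>C at pos 5 hits codon AAA>AGA (Lys>Arg)
  expect_identical(classify_coding_effect(5, "T", "C", gm), "nonsynonymous")
})

test_that("expected NS:S enumeration matches closed-form toy cases", {
  # CDS of pure AAA codons: of the 9 changes per codon only AAA>AAG is
  # synonymous; with w_ti/w_tv = 2 the ratio is (2*2 + 6)/(2) = 5
  g <- toy_genome(strrep("AAA", 20), 1, 60)
  expect_equal(expected_ns_ratio(g, titv = 1), 5.0)
  # pure GGG codons, equal weights: 6 NS vs 3 S changes per codon
  g2 <- toy_genome(strrep("GGG", 20), 1, 60)
  expect_equal(expected_ns_ratio(g2, titv = 1, ti_weight_multiplier = 1), 2.0)
  expect_error(expected_ns_ratio(toy_genome("ACGTACGT"), 1), "no CDS")
})

test_that("expected NS:S matches an independent brute-force enumerator", {
  g <- generate_genome(genome_spec(length = 6000, seed = 17))
  for (titv in c(1, 1.84)) {
    expect_equal(expected_ns_ratio(g, titv),
                 oracle_expected_ns(g, titv), tolerance = 1e-10)
  }
  # multiplier exposed: equal-weight enumeration also agrees
  expect_equal(expected_ns_ratio(g, 1.84, ti_weight_multiplier = 1),
               oracle_expected_ns(g, 1.84, multiplier = 1), tolerance = 1e-10)
})

test_that("the NS:S goodness-of-fit test behaves at and away from expectation", {
  at <- ns_ratio_test(30, 10, 3.0)
  expect_equal(at$chi2, 0)
  expect_equal(at$p, 1)
  expect_equal(at$df, 1)
  # counts 38:25 against expected 2.76: frozen hand computation
  t1 <- ns_ratio_test(38, 25, 2.76)
  expect_equal(t1$chi2, 5.5268, tolerance = 1e-4)
  expect_equal(t1$observed_ratio, 38 / 25)
  expect_lt(t1$p, 0.05)
  expect_error(ns_ratio_test(0, 0, 2), "no coding")
})

test_that("spectrum summaries conserve counts across partitions", {
  g <- shared_genome()
  sim <- simulate_ma_experiment(g, experiment_config(
    n_lines = 10, callable_sites = 2e5, sub_rate = 5e-9, indel_rate = 0,
    seed = 12))
  subs <- sim$truth
  sp <- spectrum_summary(subs, g, denominator = 10 * 2e5 * 159 * 18.3)
  n <- nrow(subs)
  expect_equal(sum(sp$class_counts), n)
  expect_equal(sp$n_transitions + sp$n_transversions, n)
  expect_equal(sp$partition$n_coding + sp$partition$n_noncoding, n)
  expect_equal(sp$n_synonymous + sp$n_nonsynonymous, sp$partition$n_coding)
  # simulated classes agree with re-classification from alleles
  expect_identical(as.character(classify_substitution(subs$ref, subs$alt)$class),
                   subs$class)
})

test_that("simulated spectra converge to the configured weights", {
  g <- shared_genome()
  sim <- simulate_ma_experiment(g, experiment_config(
    n_lines = 20, callable_sites = 2e5, sub_rate = 2e-8, indel_rate = 0,
    seed = 77))
  counts <- table(factor(sim$truth$class, levels = substitution_classes()))
  w <- default_spectrum_weights()[substitution_classes()]
  expect_gt(sum(counts), 200)
  gof <- chisq.test(as.integer(counts), p = w / sum(w))
  expect_gt(gof$p.value, 0.01)
})
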
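test_that("fixtures round-trip through ingest, reproducing the truth exactly", {
  g <- shared_genome()
  sim <- simulate_ma_experiment(g, experiment_config(
    n_lines = 8, callable_sites = 2e5, sub_rate = 3e-9, indel_rate = 1.5e-9,
    seed = 5))
  d <- withr::local_tempdir()
  fx <- write_fixtures(g, sim$truth, sim$lines, d)
  expect_length(fx$vcfs, 8L)
  expect_true(file.exists(fx$fasta) && file.exists(fx$gff3) &&
                file.exists(fx$metadata))
  ing <- read_callsets(fx$vcfs, fx$metadata)
  got <- ing$calls[order(ing$calls$line_id, ing$calls$pos), ]
  want <- sim$truth[order(sim$truth$line_id, sim$truth$pos), ]
  expect_equal(nrow(got), nrow(want))
  for (col in c("line_id", "pos", "ref", "alt", "mclass"))
    expect_identical(unname(got[[col]]), unname(want[[col]]))
  # clean fixtures survive the full filter cascade untouched
  kept <- remove_shared_mutations(apply_consensus_filter(apply_site_filters(got)))
  expect_equal(nrow(kept), nrow(want))
  # and the annotation round-trips too
  g2 <- read_genome(fx$fasta, fx$gff3)
  expect_identical(as.character(g2$seq), as.character(g$seq))
  expect_equal(GenomicRanges::start(g2$cds), GenomicRanges::start(g$cds))
  expect_equal(as.character(GenomicRanges::strand(g2$cds)),
               as.character(GenomicRanges::strand(g$cds)))
})

test_that("generations are derived from CFU counts when absent from metadata", {
  d <- withr::local_tempdir()
  meta <- file.path(d, "lines.tsv")
  write.table(data.frame(line_id = "L01", transfers = 159, cfu = 323000,
                         callable_sites = 3.5e6),
              meta, sep = "\t", quote = FALSE, row.names = FALSE)
  vcf <- file.path(d, "L01.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL01",
               "chr\t10\t.\tACCT\tA\t500\tPASS\tMQ=60\tGT:AD\t1:0,100"), vcf)
  ing <- read_callsets(vcf, meta)
  # 159 transfers x log2(323000) generations per transfer
  expect_equal(ing$lines$generations, 159 * 18.30117464, tolerance = 1e-8)
  # allele-length rule: ref ACCT / alt A is a 3 bp deletion
  expect_identical(ing$calls$mclass, "deletion")
  expect_equal(ing$calls$allele_fraction, 1.0)
  # a VCF with no metadata row is a hard error naming the line
  vcf2 <- file.path(d, "L99.vcf")
  file.copy(vcf, vcf2)
  expect_error(read_callsets(vcf2, meta), "L99")
})

test_that("site and consensus filters use strict thresholds", {
  calls <- make_calls("L01", 1:4, "A", "G",
                      qual = c(100, 101, 500, 500),
                      mq = c(60, 60, 59, 60),
                      allele_fraction = c(1, 1, 1, 0.99))
  out <- apply_site_filters(calls)
  # qual = 100 fails (strict >), mq = 59 fails (strict >)
  expect_identical(out$pos, c(2L, 4L))
  out2 <- apply_consensus_filter(out)
  expect_identical(out2$pos, 2L)  # allele fraction 0.99 fails (strict >)
  expect_identical(nrow(apply_consensus_filter(
    make_calls("L01", 1, "A", "G", allele_fraction = 0.995))), 1L)
  # filters are idempotent and order-independent (per-call predicates)
  expect_identical(apply_site_filters(out), out)
  expect_identical(
    apply_consensus_filter(apply_site_filters(calls)),
    apply_site_filters(apply_consensus_filter(calls)))
  # empty input passes through
  expect_identical(nrow(apply_site_filters(calls[0, ])), 0L)
})

test_that("mutations shared between lines are removed as non-unique", {
  calls <- rbind(
    make_calls(c("L01", "L02", "L03"), 100, "G", "A"),  # shared SNV
    make_calls("L04", 200, "G", "A"),                   # unique
    make_calls("L05", 300, "G", "T"),                   # same pos,
    make_calls("L06", 300, "G", "C"))                   # different ALTs
  out <- remove_shared_mutations(calls)
  expect_identical(sort(out$line_id), c("L04", "L05", "L06"))
  # invariant: no remaining triple occurs in two lines
  key <- paste(out$pos, out$ref, out$alt)
  expect_false(any(duplicated(key)))
  expect_identical(nrow(remove_shared_mutations(calls[0, ])), 0L)
})

test_that("caller reconciliation reports concordance and honors the policy", {
  # caller A: 87 calls; caller B: 97 calls of which 82 match A
  a <- make_calls("L01", 1:87, "G", "A")
  b <- rbind(make_calls("L01", 1:82, "G", "A"),
             make_calls("L01", 1001:1015, "G", "A"))
  b$caller <- "B"
  rec <- reconcile_callers(a, b)
  expect_equal(rec$report$n_a, 87)
  expect_equal(rec$report$n_b, 97)
  expect_equal(rec$report$fraction_b_in_a, 82 / 97)
  expect_equal(round(rec$report$fraction_b_in_a, 3), 0.845)
  expect_identical(rec$calls$caller,
                   c(rep("both", 82), rep("A", 5)))
  expect_equal(nrow(reconcile_callers(a, b, policy = "intersection")$calls), 82)
  expect_equal(nrow(reconcile_callers(a, b, policy = "union")$calls), 102)
  # identical and disjoint sets
  expect_equal(reconcile_callers(a, a)$report$fraction_b_in_a, 1.0)
  expect_equal(reconcile_callers(a, make_calls("L01", 5001:5010, "G", "A")
                                 )$report$fraction_b_in_a, 0.0)
})

test_that("indel representations from different callers match after left-normalization", {
  # genome ...ACCCCG...: deleting one C is reported at any anchor in the run
  gchr <- paste0(strrep("T", 10), "ACCCCG", strrep("T", 10))
  a <- make_calls("L01", 11, "AC", "A")    # left-anchored
  b <- make_calls("L01", 14, "CC", "C")    # right-shifted representation
  rec <- reconcile_callers(a, b, genome = gchr)
  expect_equal(rec$report$n_shared, 1)
  # without the genome the representations cannot be proven equal
  expect_equal(reconcile_callers(a, b)$report$n_shared, 0)
  nv <- normalize_variant(14, "CC", "C", gchr)
  expect_equal(nv, list(pos = 11, ref = "AC", alt = "A"))
})
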
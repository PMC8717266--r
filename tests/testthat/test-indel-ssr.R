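test_that("the SSR finder reports maximal primitive tandem repeats", {
  # aperiodic flank; starts with C and ends with T so it cannot extend any
  # of the planted core repeats across the junction
  pad <- "CGTAGCTTGATCCATGGTACGAAT"
  # threshold boundary: 8xA qualifies, 7xA does not
  s8 <- find_ssrs(paste0(pad, "AAAAAAAA", pad))
  expect_equal(length(s8), 1L)
  expect_identical(s8$motif, "A")
  expect_equal(s8$copies, 8)
  expect_equal(GenomicRanges::start(s8), nchar(pad) + 1L)
  expect_equal(length(find_ssrs(paste0(pad, "AAAAAAA", pad))), 0L)
  # primitivity + maximality: 5xAC is one dinucleotide SSR, nothing else
  sac <- find_ssrs(paste0(pad, "ACACACACAC", pad))
  expect_equal(length(sac), 1L)
  expect_identical(sac$motif, "AC")
  expect_equal(sac$copies, 5)
  # partial final unit gives fractional copies
  sp <- find_ssrs(paste0(pad, "ACGACGACGACGAC", pad))  # 4 2/3 copies of ACG
  expect_equal(sp$copies, 14 / 3)
  expect_identical(sp$motif, "ACG")
})

test_that("the SSR finder matches a quadratic brute-force scanner", {
  set.seed(5)
  for (rep_i in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
    got <- find_ssrs(s)
    want <- oracle_find_ssrs(s)
    expect_equal(GenomicRanges::start(got), want$start)
    expect_equal(GenomicRanges::end(got), want$end)
    expect_identical(got$motif, want$motif)
    expect_equal(got$copies, want$copies)
  }
  # and on a GC-rich genome slice with planted SSRs
  g <- shared_genome()
  s <- substr(as.character(g$seq), 1, 30000)
  got <- find_ssrs(s)
  want <- oracle_find_ssrs(s)
  expect_equal(GenomicRanges::start(got), want$start)
  expect_equal(GenomicRanges::end(got), want$end)
})

test_that("every reported SSR is non-extendable", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  ssrs <- find_ssrs(s)
  expect_gte(length(ssrs), 1)
  for (i in seq_along(ssrs)) {
    st <- GenomicRanges::start(ssrs)[i]; en <- GenomicRanges::end(ssrs)[i]
    k <- nchar(ssrs$motif[i])
    if (st > k)
      expect_false(substring(s, st - 1, st - 1) == substring(s, st + k - 1, st + k - 1))
    if (en + 1 <= nchar(s))
      expect_false(substring(s, en + 1, en + 1) == substring(s, en - k + 1, en - k + 1))
  }
})

test_that("SSR genome coverage uses union semantics", {
  expect_equal(ssr_genome_fraction(GenomicRanges::GRanges(), 1e4), 0)
  one <- GenomicRanges::GRanges("g", IRanges::IRanges(101, 200))
  expect_equal(ssr_genome_fraction(one, 1e4), 0.01)
  two <- GenomicRanges::GRanges("g", IRanges::IRanges(c(101, 151), c(200, 250)))
  expect_equal(ssr_genome_fraction(two, 1e4), 0.015)
})

test_that("indel size balance totals insertions against deletions", {
  # 15 insertions totaling 90 bp, 16 deletions totaling 143 bp
  ins_sizes <- c(rep(6, 15))
  del_sizes <- c(rep(9, 15), 8)
  ins <- make_calls("L01", seq_along(ins_sizes) * 100, "A",
                    paste0("A", strrep("G", ins_sizes)))
  del <- make_calls("L02", seq_along(del_sizes) * 100,
                    vapply(del_sizes, function(d) paste0("A", strrep("G", d)),
                           character(1)), "A")
  bal <- indel_size_balance(rbind(ins, del))
  expect_equal(bal$n_insertions, 15)
  expect_equal(bal$n_deletions, 16)
  expect_equal(bal$bp_inserted, 90)
  expect_equal(bal$bp_deleted, 143)
  expect_equal(bal$net_bp, -53)
  # balance and degenerate cases
  pm <- rbind(make_calls("L01", 10, "A", "ACCC"),
              make_calls("L01", 50, "ACCC", "A"))
  expect_equal(indel_size_balance(pm)$net_bp, 0)
  empty <- indel_size_balance(pm[0, ])
  expect_equal(empty$net_bp, 0)
  expect_equal(empty$n_insertions + empty$n_deletions, 0)
  expect_error(indel_size_balance(make_calls("L01", 5, "A", "G")), "substitution")
})

test_that("indel region analysis reports coding depletion and SSR overlap", {
  g <- shared_genome()
  sim <- simulate_ma_experiment(g, experiment_config(
    n_lines = 10, callable_sites = 2e5, sub_rate = 0, indel_rate = 2e-9,
    seed = 14))
  ind <- sim$truth
  denom <- 10 * 2e5 * 159 * 18.3
  an <- indel_region_analysis(ind, g, denominator = denom)
  expect_equal(an$n_coding + an$n_noncoding, an$n_total)
  expect_equal(an$expected_coding, an$n_total * g$coding_fraction)
  expect_equal(an$expected_coding_rounded, round(an$expected_coding))
  expect_equal(an$n_insertions + an$n_deletions, an$n_total)
  expect_lte(an$n_in_ssr, an$n_total)
  expect_equal(an$rate_indel$m, an$n_total)
  # simulator truth agrees with interval-based SSR overlap
  expect_equal(an$n_in_ssr, sum(ind$in_ssr))
  # a 31-indel set with 12 SSR hits reports the familiar shares
  toy <- g; toy_ind <- ind[seq_len(min(31, nrow(ind))), ]
  an31 <- indel_region_analysis(toy_ind, toy)
  expect_equal(an31$ssr_fraction_of_indels,
               an31$n_in_ssr / nrow(toy_ind))
  # oversized events are rejected from the small-indel class
  big <- make_calls("L01", 1000, paste0("A", strrep("G", 60)), "A")
  expect_warning(an_big <- indel_region_analysis(big, g), "50")
  expect_equal(an_big$n_total, 0)
})

test_that("uniformly placed indels match the binomial coding expectation", {
  g <- shared_genome()
  # aggregate coding counts over replicate simulations with no hotspot
  tot <- 0L; n <- 0L
  for (r in 1:20) {
    sim <- simulate_ma_experiment(g, experiment_config(
      n_lines = 5, callable_sites = 2e5, sub_rate = 0, indel_rate = 4e-9,
      ssr_hotspot_multiplier = 1, seed = 500 + r))
    ind <- sim$truth
    if (!nrow(ind)) next
    an <- indel_region_analysis(ind, g)
    tot <- tot + an$n_coding; n <- n + an$n_total
  }
  band <- qbinom(c(0.005, 0.995), n, g$coding_fraction)
  expect_gte(tot, band[1])
  expect_lte(tot, band[2])
})
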
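#' The six strand-collapsed substitution classes
#'
#' @return Character vector of class labels in canonical order: the two
#'   transitions first, then the four transversions.
#' @export
substitution_classes <- function() {
  c("A:T>G:C", "G:C>A:T", "A:T>C:G", "G:C>T:A", "A:T>T:A", "G:C>C:G")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a base substitution into its strand-collapsed class
#'
#' A substitution and its reverse-complement are the same mutational event
#' (e.g. `A>G` on one strand is `T>C` on the other), so the 12 ordered base
#' changes collapse to 6 classes written on the base pair: `A:T>G:C` and
#' `G:C>A:T` are transitions, the remaining four are transversions.
#'
#' @param ref_base,alt_base Reference and alternate bases (vectorized;
#'   uppercase ACGT).
#' @return A data.frame with columns `class` (one of
#'   [substitution_classes()]) and `kind` (`"transition"`/`"transversion"`).
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  ok <- ref_base %in% names(COMPLEMENT) & alt_base %in% names(COMPLEMENT)
  if (!all(ok)) stop("bases must be one of A, C, G, T")
  if (any(ref_base == alt_base)) stop("ref and alt bases must differ")
  # orient each event so the reference is written as A (for A:T pairs) or
  # G (for G:C pairs)
  flip <- ref_base %in% c("T", "C")
  oriented_alt <- ifelse(flip, COMPLEMENT[alt_base], alt_base)
  ref_pair <- ifelse(ref_base %in% c("A", "T"), "A:T", "G:C")
  cls <- paste0(ref_pair, ">", oriented_alt, ":", COMPLEMENT[oriented_alt])
  purine <- c("A", "G")
  kind <- ifelse((ref_base %in% purine) == (alt_base %in% purine),
                 "transition", "transversion")
  data.frame(class = factor(cls, levels = substitution_classes()),
             kind = kind)
}

#' Transition/transversion ratio of a substitution call set
#'
#' @param calls A mutation-call data.frame (see [read_callsets()]); only
#'   rows with `mclass == "substitution"` are used.
#' @return `n_transitions / n_transversions`; `Inf` (with a warning) when
#'   there are no transversions.
#' @export
titv_ratio <- function(calls) {
  subs <- calls[calls$mclass == "substitution", , drop = FALSE]
  if (nrow(subs) == 0L) stop("no substitutions in input")
  kind <- classify_substitution(subs$ref, subs$alt)$kind
  ti <- sum(kind == "transition"); tv <- sum(kind == "transversion")
  if (tv == 0L) {
    warning("no transversions observed; ts/tv ratio is undefined (Inf)")
    return(Inf)
  }
  ti / tv
}

#' Partition mutation calls by coding annotation
#'
#' Labels each call coding when its position falls in a CDS interval, and
#' contrasts region-specific rates. Region denominators are the coding (or
#' noncoding) fraction of the genome times the pooled site-generation
#' denominator. Association between region and mutation occurrence is
#' tested with the exact two-sided test on the 2x2 table of (events,
#' non-event site-generations) by region ([fisher_exact_2x2()], with
#' site-generations rounded to integers).
#'
#' @param calls Mutation-call data.frame with columns `pos`, `ref`, `alt`.
#' @param genome An [annotated_genome()].
#' @param denominator Total site-generations; when `NULL` only counts are
#'   returned.
#' @param level Confidence level for region rate CIs.
#' @return A list with `coding` (logical per call), `n_coding`,
#'   `n_noncoding`, `coding_fraction`, and (when a denominator is given)
#'   `rate_coding`, `rate_noncoding` ([pooled_rate()]-style estimates) and
#'   `fisher_p`.
#' @export
partition_by_annotation <- function(calls, genome, denominator = NULL, level = 0.95) {
  if (any(calls$pos < 1 | calls$pos > genome$length))
    stop("call position outside the genome")
  pos_gr <- GenomicRanges::GRanges(genome$seqname,
                                   IRanges::IRanges(calls$pos, width = 1L))
  coding <- IRanges::overlapsAny(pos_gr, genome$cds, ignore.strand = TRUE)
  out <- list(coding = coding,
              n_coding = sum(coding),
              n_noncoding = sum(!coding),
              coding_fraction = genome$coding_fraction)
  if (!is.null(denominator)) {
    d_cod <- genome$coding_fraction * denominator
    d_non <- (1 - genome$coding_fraction) * denominator
    out$rate_coding <- rate_from_count(sum(coding), d_cod, level)
    out$rate_noncoding <- rate_from_count(sum(!coding), d_non, level)
    out$fisher_p <- fisher_exact_2x2(
      sum(coding), d_cod - sum(coding),
      sum(!coding), d_non - sum(!coding))
  }
  out
}

# rate_estimate from a bare count and denominator (no per-line breakdown)
rate_from_count <- function(m, denominator, level = 0.95) {
  if (denominator <= 0) stop("degenerate denominator")
  ci <- poisson_ci(m, denominator, level)
  structure(
    list(m = m, denominator = denominator, mu = m / denominator,
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         sem = NA_real_, level = level),
    class = "rate_estimate")
}

genetic_code_11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

# codon containing genome position p within one CDS (coding orientation);
# returns the codon string and the 1-based offset of p within it
codon_at <- function(genome_chr, cds_start, cds_end, cds_strand, p) {
  width <- cds_end - cds_start + 1L
  if (width %% 3L != 0L)
    stop("annotation error: CDS length not divisible by 3")
  offset <- if (cds_strand == "-") cds_end - p + 1L else p - cds_start + 1L
  codon_idx0 <- (offset - 1L) %/% 3L
  within <- (offset - 1L) %% 3L + 1L
  if (cds_strand == "-") {
    g_hi <- cds_end - codon_idx0 * 3L
    codon <- rev_comp(substring(genome_chr, g_hi - 2L, g_hi))
  } else {
    g_lo <- cds_start + codon_idx0 * 3L
    codon <- substring(genome_chr, g_lo, g_lo + 2L)
  }
  list(codon = codon, within = within)
}

rev_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Classify a coding substitution as synonymous or nonsynonymous
#'
#' Locates the codon containing the site (reverse-complementing for
#' minus-strand CDS), applies the substitution, and translates with the
#' bacterial genetic code (translation table 11). An unchanged amino acid
#' (including stop-to-stop) is synonymous; anything else, including a
#' gained stop, is nonsynonymous. At sites covered by several CDS the call
#' is nonsynonymous if it is nonsynonymous in any reading frame.
#'
#' @param pos Genome position (1-based) of the substitution.
#' @param ref,alt Reference and alternate bases.
#' @param genome An [annotated_genome()].
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_coding_effect <- function(pos, ref, alt, genome) {
  gchr <- as.character(genome$seq)
  hits <- which(GenomicRanges::start(genome$cds) <= pos &
                GenomicRanges::end(genome$cds) >= pos)
  if (!length(hits)) stop("position ", pos, " is not inside any CDS")
  if (substring(gchr, pos, pos) != toupper(ref))
    stop("reference allele does not match the genome at position ", pos)
  code <- genetic_code_11()
  effects <- vapply(hits, function(i) {
    st <- as.character(GenomicRanges::strand(genome$cds))[i]
    ca <- codon_at(gchr, GenomicRanges::start(genome$cds)[i],
                   GenomicRanges::end(genome$cds)[i], st, pos)
    base_new <- if (st == "-") COMPLEMENT[[toupper(alt)]] else toupper(alt)
    mutated <- ca$codon
    substring(mutated, ca$within, ca$within) <- base_new
    code[[ca$codon]] == code[[mutated]]
  }, logical(1))
  if (all(effects)) "synonymous" else "nonsynonymous"
}

#' Classify coding effects for a table of substitution calls
#'
#' Vectorized convenience over [classify_coding_effect()]; noncoding calls
#' get `NA`.
#'
#' @param calls Mutation-call data.frame (substitutions only are
#'   classified).
#' @param genome An [annotated_genome()].
#' @return Character vector aligned with `calls` rows
#'   (`"synonymous"`/`"nonsynonymous"`/`NA`).
#' @export
classify_coding_effects <- function(calls, genome) {
  out <- rep(NA_character_, nrow(calls))
  if (!nrow(calls)) return(out)
  is_sub <- calls$mclass == "substitution"
  pos_gr <- GenomicRanges::GRanges(genome$seqname,
                                   IRanges::IRanges(calls$pos, width = 1L))
  coding <- IRanges::overlapsAny(pos_gr, genome$cds, ignore.strand = TRUE)
  idx <- which(is_sub & coding)
  for (i in idx) {
    out[i] <- classify_coding_effect(calls$pos[i], calls$ref[i],
                                     calls$alt[i], genome)
  }
  out
}

#' Expected nonsynonymous:synonymous ratio under a ts/tv-weighted null
#'
#' Enumerates every possible single-base change at every CDS position
#' (3 changes per site; codon usage enters through the actual coding
#' sequence, including the annotated stop codons), weights each specific
#' transition `w_ti` and each specific transversion `w_tv = 1` with
#' `w_ti = ti_weight_multiplier * titv`, and returns the weighted
#' nonsynonymous:synonymous ratio. The default multiplier of 2 makes the
#' aggregate expected transition:transversion count ratio equal the
#' observed `titv`, because each site offers one transition and two
#' transversions.
#'
#' @param genome An [annotated_genome()] with at least one CDS.
#' @param titv Observed transition/transversion count ratio, `> 0`.
#' @param ti_weight_multiplier Ratio `w_ti / (w_tv * titv)`; default 2.
#' @return Expected NS:S ratio.
#' @export
expected_ns_ratio <- function(genome, titv, ti_weight_multiplier = 2) {
  if (length(genome$cds) == 0L) stop("genome has no CDS")
  stopifnot(titv > 0, ti_weight_multiplier > 0)
  gchr <- as.character(genome$seq)
  counts <- integer(0)
  all_codons <- character(0)
  for (i in seq_along(genome$cds)) {
    st <- GenomicRanges::start(genome$cds)[i]
    en <- GenomicRanges::end(genome$cds)[i]
    if ((en - st + 1L) %% 3L != 0L)
      stop("annotation error: CDS length not divisible by 3")
    s <- substring(gchr, st, en)
    if (as.character(GenomicRanges::strand(genome$cds))[i] == "-")
      s <- rev_comp(s)
    starts <- seq(1L, nchar(s), by = 3L)
    all_codons <- c(all_codons, substring(s, starts, starts + 2L))
  }
  usage <- table(all_codons)
  w_ti <- ti_weight_multiplier * titv
  tab <- codon_change_table()
  ns_w <- 0; s_w <- 0
  for (codon in names(usage)) {
    rows <- tab[tab$codon == codon, ]
    w <- ifelse(rows$transition, w_ti, 1)
    ns_w <- ns_w + as.numeric(usage[[codon]]) * sum(w[!rows$synonymous])
    s_w <- s_w + as.numeric(usage[[codon]]) * sum(w[rows$synonymous])
  }
  if (s_w == 0) stop("no synonymous changes possible in this annotation")
  ns_w / s_w
}

codon_change_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- genetic_code_11()
    bases <- c("A", "C", "G", "T")
    codons <- names(code)
    rows <- list()
    purine <- c("A", "G")
    for (codon in codons) {
      for (p in 1:3) {
        refb <- substring(codon, p, p)
        for (altb in setdiff(bases, refb)) {
          mutated <- codon
          substring(mutated, p, p) <- altb
          rows[[length(rows) + 1L]] <- data.frame(
            codon = codon, pos = p, alt = altb,
            synonymous = code[[codon]] == code[[mutated]],
            transition = (refb %in% purine) == (altb %in% purine))
        }
      }
    }
    tab <<- do.call(rbind, rows)
    tab
  }
})

#' Goodness-of-fit test of the observed NS:S split against an expected ratio
#'
#' One-degree-of-freedom chi-square of the observed (nonsynonymous,
#' synonymous) counts against expected proportions `(r/(1+r), 1/(1+r))`
#' for expected ratio `r`, without continuity correction.
#'
#' @param n_nonsyn,n_syn Observed counts.
#' @param expected_ratio Expected NS:S ratio, `> 0`.
#' @return List with `chi2`, `df` (1), `p`, and `observed_ratio`.
#' @export
ns_ratio_test <- function(n_nonsyn, n_syn, expected_ratio) {
  total <- n_nonsyn + n_syn
  if (total <= 0) stop("no coding substitutions to test")
  stopifnot(expected_ratio > 0)
  probs <- c(expected_ratio, 1) / (1 + expected_ratio)
  ht <- suppressWarnings(
    stats::chisq.test(c(n_nonsyn, n_syn), p = probs, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       observed_ratio = n_nonsyn / n_syn)
}

#' Summarize the substitution spectrum of a call set
#'
#' Aggregates class counts, ts/tv, coding/noncoding partition and
#' synonymous/nonsynonymous counts for a filtered mutation-call table.
#'
#' @param calls Mutation-call data.frame.
#' @param genome An [annotated_genome()].
#' @param denominator Optional site-generation denominator for per-class
#'   rates.
#' @param level Confidence level.
#' @return List with `class_counts` (named, canonical order),
#'   `n_transitions`, `n_transversions`, `titv`, `partition`
#'   (from [partition_by_annotation()]), `n_synonymous`,
#'   `n_nonsynonymous`, and `class_rates` when a denominator is given.
#' @export
spectrum_summary <- function(calls, genome, denominator = NULL, level = 0.95) {
  subs <- calls[calls$mclass == "substitution", , drop = FALSE]
  cls <- classify_substitution(subs$ref, subs$alt)
  class_counts <- table(cls$class)
  n_ti <- sum(cls$kind == "transition")
  n_tv <- sum(cls$kind == "transversion")
  part <- partition_by_annotation(subs, genome, denominator, level)
  eff <- classify_coding_effects(subs, genome)
  out <- list(
    class_counts = stats::setNames(as.integer(class_counts), names(class_counts)),
    n_transitions = n_ti, n_transversions = n_tv,
    titv = if (n_tv > 0) n_ti / n_tv else Inf,
    partition = part,
    n_synonymous = sum(eff == "synonymous", na.rm = TRUE),
    n_nonsynonymous = sum(eff == "nonsynonymous", na.rm = TRUE))
  if (!is.null(denominator)) {
    gcf <- genome$gc_content
    share <- ifelse(grepl("^G:C", names(class_counts)), gcf, 1 - gcf)
    out$class_rates <- lapply(seq_along(class_counts), function(i) {
      rate_from_count(as.integer(class_counts[i]), share[i] * denominator, level)
    })
    names(out$class_rates) <- names(class_counts)
  }
  out
}
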
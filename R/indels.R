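#' Insertion/deletion size balance
#'
#' Event sizes are `|len(alt) - len(ref)|` bp; totals per direction and
#' the signed net change (`bp_inserted - bp_deleted`) summarize whether
#' the genome is gaining or losing sequence through small indels.
#'
#' @param indels Mutation-call data.frame containing only insertions and
#'   deletions.
#' @return List with `n_insertions`, `n_deletions`, `bp_inserted`,
#'   `bp_deleted`, `net_bp`.
#' @export
indel_size_balance <- function(indels) {
  if (nrow(indels) && any(indels$mclass == "substitution"))
    stop("input contains substitutions; indels only")
  size <- abs(nchar(indels$alt) - nchar(indels$ref))
  ins <- indels$mclass == "insertion"
  del <- indels$mclass == "deletion"
  list(n_insertions = sum(ins), n_deletions = sum(del),
       bp_inserted = sum(size[ins]), bp_deleted = sum(size[del]),
       net_bp = sum(size[ins]) - sum(size[del]))
}

# affected genomic span of a left-anchored call: anchor..anchor+len(ref)-1
# for deletions, the anchor point for insertions/substitutions
affected_ranges <- function(calls, seqname) {
  if (!nrow(calls)) return(GenomicRanges::GRanges())
  width <- ifelse(calls$mclass == "deletion", nchar(calls$ref), 1L)
  GenomicRanges::GRanges(seqname, IRanges::IRanges(calls$pos, width = width))
}

#' Regional and SSR analysis of small indels
#'
#' Counts indels in coding vs noncoding regions and inside vs outside SSR
#' spans (an indel overlaps an SSR when its left-normalized affected span
#' intersects the SSR interval), contrasts the observed coding count with
#' the expectation under uniform placement (`total * coding_fraction`),
#' tests region and SSR enrichment with the exact two-sided 2x2 test, and
#' attaches pooled rate estimates. Events longer than `max_size` bp are
#' dropped with a warning as outside the small-indel class.
#'
#' @param indels Mutation-call data.frame of insertions/deletions.
#' @param genome An [annotated_genome()].
#' @param ssrs SSR `GRanges`; defaults to the genome's detected set.
#' @param denominator Total site-generations (`NULL` to skip rates and
#'   tests needing exposure).
#' @param level Confidence level.
#' @param max_size Small-indel size cap in bp.
#' @return List with counts (`n_insertions`, `n_deletions`, size balance
#'   fields), `n_coding`, `n_noncoding`, `expected_coding` (unrounded),
#'   `expected_coding_rounded`, `n_in_ssr`, `ssr_fraction_of_indels`,
#'   `fisher_p_region`, `fisher_p_ssr`, and rate estimates
#'   (`rate_indel`, `rate_insertion`, `rate_deletion`) when a denominator
#'   is supplied.
#' @export
indel_region_analysis <- function(indels, genome, ssrs = genome$ssrs,
                                  denominator = NULL, level = 0.95,
                                  max_size = 50) {
  if (nrow(indels) && any(indels$mclass == "substitution"))
    stop("input contains substitutions; indels only")
  size <- abs(nchar(indels$alt) - nchar(indels$ref))
  if (any(size > max_size)) {
    warning(sum(size > max_size), " event(s) longer than ", max_size,
            " bp dropped as outside the small-indel class")
    indels <- indels[size <= max_size, , drop = FALSE]
  }
  total <- nrow(indels)
  spans <- affected_ranges(indels, genome$seqname)
  coding <- IRanges::overlapsAny(spans, genome$cds, ignore.strand = TRUE)
  in_ssr <- if (length(ssrs)) IRanges::overlapsAny(spans, ssrs, ignore.strand = TRUE)
            else rep(FALSE, total)
  bal <- indel_size_balance(indels)
  ssr_frac_genome <- ssr_genome_fraction(ssrs, genome$length)
  out <- c(bal, list(
    n_total = total,
    n_coding = sum(coding), n_noncoding = sum(!coding),
    expected_coding = total * genome$coding_fraction,
    expected_coding_rounded = round(total * genome$coding_fraction),
    expected_noncoding = total * (1 - genome$coding_fraction),
    n_in_ssr = sum(in_ssr),
    ssr_fraction_of_indels = if (total) sum(in_ssr) / total else NA_real_,
    ssr_fraction_of_genome = ssr_frac_genome,
    coding = coding, in_ssr = in_ssr))
  if (!is.null(denominator)) {
    d_cod <- genome$coding_fraction * denominator
    d_non <- (1 - genome$coding_fraction) * denominator
    out$fisher_p_region <- fisher_exact_2x2(
      sum(coding), d_cod - sum(coding), sum(!coding), d_non - sum(!coding))
    d_ssr <- ssr_frac_genome * denominator
    d_out <- (1 - ssr_frac_genome) * denominator
    out$fisher_p_ssr <- fisher_exact_2x2(
      sum(in_ssr), d_ssr - sum(in_ssr), sum(!in_ssr), d_out - sum(!in_ssr))
    out$rate_indel <- rate_from_count(total, denominator, level)
    out$rate_insertion <- rate_from_count(bal$n_insertions, denominator, level)
    out$rate_deletion <- rate_from_count(bal$n_deletions, denominator, level)
    out$rate_in_ssr <- if (ssr_frac_genome > 0)
      rate_from_count(sum(in_ssr), d_ssr, level) else NULL
    out$rate_outside_ssr <- if (ssr_frac_genome < 1)
      rate_from_count(sum(!in_ssr), d_out, level) else NULL
  }
  out
}
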
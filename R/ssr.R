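#' Default SSR detection thresholds
#'
#' Minimum copy number per motif length (1-6 bp) for a perfect tandem repeat
#' to be called a simple sequence repeat. The defaults (mono >= 8 copies,
#' di >= 5, tri >= 4, tetra/penta/hexa >= 3) yield roughly 1% genome coverage
#' on a 60.5% GC bacterial-like genome, in line with typical prokaryotic SSR
#' content.
#'
#' @return Named numeric vector of length 6.
#' @export
default_ssr_thresholds <- function() {
  c(mono = 8, di = 5, tri = 4, tetra = 3, penta = 3, hexa = 3)
}

#' Find simple sequence repeats
#'
#' Scans a genome for all maximal perfect tandem repeats with a primitive
#' motif of 1-6 bp meeting per-motif-size copy-number thresholds. A repeat is
#' maximal when extending it one base left or right breaks the tandem
#' pattern; a partial final motif unit is allowed (fractional copy number).
#' Overlapping candidates are resolved greedily: longest span first, ties
#' broken by smaller motif, then leftmost start.
#'
#' The scan is vectorized on the period-k self-match vector
#' `s[i] == s[i+k]`: maximal runs of matches of length r correspond to
#' maximal period-k repeats of length r + k.
#'
#' @param genome An [annotated_genome()], `DNAString`, or character scalar.
#' @param thresholds Numeric vector of length 6: minimum copies for motif
#'   lengths 1..6.
#' @return A [GenomicRanges::GRanges] with metadata columns `motif` and
#'   `copies`, sorted by position.
#' @export
find_ssrs <- function(genome, thresholds = default_ssr_thresholds()) {
  stopifnot(length(thresholds) == 6L, all(thresholds >= 1))
  s <- genome_sequence_chr(genome)
  seqname <- if (inherits(genome, "annotated_genome")) genome$seqname else "genome"
  raw <- charToRaw(s)
  L <- length(raw)
  starts <- integer(0); lens <- integer(0); ks <- integer(0)
  for (k in 1:6) {
    if (L <= k) next
    eq <- raw[seq_len(L - k)] == raw[(k + 1L):L]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & (r$lengths + k) / k >= thresholds[k]
    if (!any(keep)) next
    st <- run_start[keep]
    ln <- r$lengths[keep] + k
    # primitive motifs only: a motif that is itself periodic is covered at
    # its smaller period
    motifs <- substring(s, st, st + k - 1L)
    prim <- rep(TRUE, length(st))
    for (d in seq_len(k - 1L)) {
      if (k %% d != 0L) next
      prim <- prim & motifs != strrep(substring(motifs, 1L, d), k %/% d)
    }
    starts <- c(starts, st[prim]); lens <- c(lens, ln[prim])
    ks <- c(ks, rep.int(k, sum(prim)))
  }
  if (!length(starts)) {
    return(GenomicRanges::GRanges(seqinfo = NULL))
  }
  ord <- order(-lens, ks, starts)
  starts <- starts[ord]; lens <- lens[ord]; ks <- ks[ord]
  covered <- logical(L)
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    span <- starts[i]:(starts[i] + lens[i] - 1L)
    if (!any(covered[span])) {
      keep[i] <- TRUE
      covered[span] <- TRUE
    }
  }
  starts <- starts[keep]; lens <- lens[keep]; ks <- ks[keep]
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = starts, width = lens))
  gr$motif <- substring(s, starts, starts + ks - 1L)
  gr$copies <- lens / ks
  GenomicRanges::sort(gr)
}

#' Fraction of a genome covered by SSRs
#'
#' @param ssrs SSR intervals as a `GRanges` (overlaps are union-counted).
#' @param genome_length Genome length in bp.
#' @return Covered fraction in `[0, 1]`.
#' @export
ssr_genome_fraction <- function(ssrs, genome_length) {
  stopifnot(genome_length > 0)
  if (length(ssrs) == 0L) return(0)
  sum(GenomicRanges::width(IRanges::reduce(GenomicRanges::ranges(ssrs)))) / genome_length
}

#' Write SSR intervals as BED
#'
#' Emits 0-based half-open BED with the motif in the name column and the
#' copy number as score.
#'
#' @param ssrs SSR `GRanges` from [find_ssrs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(ssrs, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ssrs)),
    start = GenomicRanges::start(ssrs) - 1L,
    end = GenomicRanges::end(ssrs),
    name = ssrs$motif,
    score = round(ssrs$copies, 2),
    strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
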
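#' Annotated genome container
#'
#' Bundles a single-contig reference sequence with its CDS annotation and
#' derived composition summaries (GC fraction, coding fraction) plus the set
#' of simple sequence repeats (SSRs) detected on it. All coordinates are
#' 1-based inclusive, following the Biostrings/GenomicRanges convention.
#'
#' @param seq A [Biostrings::DNAString], `DNAStringSet` of length 1, or a
#'   character scalar over the alphabet ACGT.
#' @param cds A [GenomicRanges::GRanges] of CDS intervals (strand `+`/`-`),
#'   or `NULL` for an unannotated genome. Intervals must lie within the
#'   sequence and must not overlap one another.
#' @param seqname Contig name used on export.
#' @param ssrs Optional precomputed SSR `GRanges` (as returned by
#'   [find_ssrs()]); when `NULL`, [find_ssrs()] is run with default
#'   thresholds.
#'
#' @return An object of class `annotated_genome`: a list with elements
#'   `seq` (DNAString), `cds` (GRanges), `seqname`, `length`, `gc_content`,
#'   `coding_fraction` and `ssrs`.
#' @export
annotated_genome <- function(seq, cds = NULL, seqname = "genome", ssrs = NULL) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("annotated_genome() expects a single-contig sequence")
    seqname <- names(seq)[1] %||% seqname
    seq <- seq[[1]]
  }
  L <- length(seq)
  if (L == 0L) stop("genome sequence is empty")
  if (is.null(cds)) {
    cds <- GenomicRanges::GRanges()
  }
  cds <- methods::as(cds, "GRanges")
  if (length(cds)) {
    if (max(GenomicRanges::end(cds)) > L || min(GenomicRanges::start(cds)) < 1L)
      stop("CDS intervals extend outside the genome")
    if (!all(GenomicRanges::width(IRanges::reduce(GenomicRanges::ranges(cds))) ==
             sum(GenomicRanges::width(cds))) &&
        sum(GenomicRanges::width(IRanges::reduce(GenomicRanges::ranges(cds)))) <
        sum(GenomicRanges::width(cds)))
      stop("CDS intervals overlap")
    cds <- GenomicRanges::sort(cds, ignore.strand = TRUE)
  }
  af <- Biostrings::alphabetFrequency(seq, baseOnly = TRUE)
  gc <- unname((af["C"] + af["G"]) / L)
  coding_bp <- if (length(cds)) sum(GenomicRanges::width(cds)) else 0L
  g <- structure(
    list(seq = seq, cds = cds, seqname = seqname, length = L,
         gc_content = gc, coding_fraction = coding_bp / L, ssrs = NULL),
    class = "annotated_genome")
  g$ssrs <- if (is.null(ssrs)) find_ssrs(g) else ssrs
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "annotated_genome '%s': %s bp, GC %.3f, %d CDS (coding fraction %.3f), %d SSRs (%.2f%% of genome)\n",
    x$seqname, format(x$length, big.mark = ","), x$gc_content,
    length(x$cds), x$coding_fraction, length(x$ssrs),
    100 * ssr_genome_fraction(x$ssrs, x$length)))
  invisible(x)
}

#' Read a reference genome with its CDS annotation
#'
#' Loads a FASTA reference (single contig) and a GFF3 annotation, keeping
#' features of type `CDS`, and assembles an [annotated_genome()].
#'
#' @param fasta Path to the genome FASTA.
#' @param gff3 Path to the GFF3 annotation, or `NULL` for none.
#' @param ssr_thresholds Per-motif-size minimum copy numbers forwarded to
#'   [find_ssrs()].
#' @return An `annotated_genome`.
#' @export
read_genome <- function(fasta, gff3 = NULL, ssr_thresholds = default_ssr_thresholds()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    stop("expected a single-contig FASTA, found ", length(seqs), " records in ", fasta)
  seqname <- sub("\\s.*$", "", names(seqs)[1])
  cds <- NULL
  if (!is.null(gff3)) {
    ann <- rtracklayer::import(gff3)
    cds <- ann[ann$type == "CDS"]
    S4Vectors::mcols(cds) <- NULL
  }
  seq <- seqs[[1]]
  g <- annotated_genome(seq, cds = cds, seqname = seqname,
                        ssrs = GenomicRanges::GRanges())
  g$ssrs <- find_ssrs(g, thresholds = ssr_thresholds)
  g
}

# character scalar of the genome sequence, accepting several input shapes
genome_sequence_chr <- function(genome) {
  if (inherits(genome, "annotated_genome")) return(as.character(genome$seq))
  if (methods::is(genome, "DNAString")) return(as.character(genome))
  if (is.character(genome) && length(genome) == 1L) return(genome)
  stop("cannot interpret 'genome' as a sequence")
}
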
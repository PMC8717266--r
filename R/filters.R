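#' Site-quality filter
#'
#' Retains calls with `qual > min_qual` and `mq > min_mq` — strict
#' inequalities, so boundary values are excluded. Calls with missing
#' quality values are removed.
#'
#' @param calls Mutation-call data.frame (see [read_callsets()]).
#' @param min_qual Phred-scaled site quality threshold (default 100).
#' @param min_mq RMS mapping-quality threshold (default 59).
#' @return Filtered data.frame.
#' @export
apply_site_filters <- function(calls, min_qual = 100, min_mq = 59) {
  stopifnot(min_qual >= 0, min_mq >= 0)
  keep <- which(calls$qual > min_qual & calls$mq > min_mq)
  calls[keep, , drop = FALSE]
}

#' Consensus-read filter
#'
#' Retains calls whose alternate-allele read fraction strictly exceeds
#' `min_fraction` (default 0.99): the line-specific consensus must be
#' supported by more than 99% of reads, the remaining 1% allowing for
#' aberrant reads from sequencing error or index impurity.
#'
#' @param calls Mutation-call data.frame.
#' @param min_fraction Minimum consensus read fraction in `[0, 1]`.
#' @return Filtered data.frame.
#' @export
apply_consensus_filter <- function(calls, min_fraction = 0.99) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  calls[which(calls$allele_fraction > min_fraction), , drop = FALSE]
}

#' Remove mutations shared between lines
#'
#' Any (position, ref, alt) triple observed in two or more lines is
#' removed from all lines: a variant recurring across independently
#' bottlenecked lineages is ancestral polymorphism or a systematic calling
#' artifact, not an independent spontaneous mutation.
#'
#' @param calls Mutation-call data.frame.
#' @return Data.frame containing only line-unique calls.
#' @export
remove_shared_mutations <- function(calls) {
  if (!nrow(calls)) return(calls)
  key <- paste(calls$pos, calls$ref, calls$alt, sep = "\r")
  n_lines <- vapply(split(calls$line_id, key),
                    function(x) length(unique(x)), integer(1))
  calls[key %in% names(n_lines)[n_lines == 1L], , drop = FALSE]
}

#' Left-normalize a variant against the reference
#'
#' Shifts an indel to its smallest coordinate representation: trims the
#' shared suffix (extending leftward with reference bases when an allele
#' would become empty), then trims the shared prefix. Callers report
#' indels in different conventions; normalization makes their calls
#' comparable.
#'
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Allele strings.
#' @param genome_chr Reference sequence as a character scalar (`NULL` to
#'   skip the leftward extension, i.e. trim-only normalization).
#' @return List with `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, genome_chr = NULL) {
  repeat {
    nr <- nchar(ref); na_ <- nchar(alt)
    if (nr > 0 && na_ > 0 &&
        substring(ref, nr, nr) == substring(alt, na_, na_)) {
      if ((nr == 1L || na_ == 1L)) {
        if (is.null(genome_chr) || pos <= 1L) break
        pad <- substring(genome_chr, pos - 1L, pos - 1L)
        ref <- paste0(pad, substring(ref, 1L, nr - 1L))
        alt <- paste0(pad, substring(alt, 1L, na_ - 1L))
        pos <- pos - 1L
      } else {
        ref <- substring(ref, 1L, nr - 1L)
        alt <- substring(alt, 1L, na_ - 1L)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

normalized_key <- function(calls, genome_chr = NULL) {
  vapply(seq_len(nrow(calls)), function(i) {
    if (calls$mclass[i] == "substitution") {
      paste(calls$line_id[i], calls$pos[i], calls$ref[i], calls$alt[i])
    } else {
      nv <- normalize_variant(calls$pos[i], calls$ref[i], calls$alt[i], genome_chr)
      paste(calls$line_id[i], nv$pos, nv$ref, nv$alt)
    }
  }, character(1))
}

#' Reconcile two independent callers
#'
#' Matches calls on (line, position, ref, alt) after indel
#' left-normalization and reports the concordance: set sizes, the
#' intersection, and the fraction of caller B's calls recovered by caller
#' A. The merged call set follows `policy`: `"primary"` keeps caller A's
#' calls (marking those also in B as `caller = "both"`), `"intersection"`
#' keeps only calls in both, `"union"` adds B's private calls to A's.
#'
#' @param calls_a,calls_b Mutation-call data.frames from the two callers,
#'   filtered identically.
#' @param genome Optional [annotated_genome()] (or character sequence) for
#'   full left-alignment of indels during matching.
#' @param policy Merge policy.
#' @return List with `report` (data.frame: `n_a`, `n_b`, `n_shared`,
#'   `fraction_b_in_a`) and `calls` (the merged set).
#' @export
reconcile_callers <- function(calls_a, calls_b, genome = NULL,
                              policy = c("primary", "intersection", "union")) {
  policy <- match.arg(policy)
  gchr <- if (is.null(genome)) NULL else genome_sequence_chr(genome)
  key_a <- normalized_key(calls_a, gchr)
  key_b <- normalized_key(calls_b, gchr)
  shared <- key_a %in% key_b
  n_shared <- length(intersect(key_a, key_b))
  report <- data.frame(
    n_a = nrow(calls_a), n_b = nrow(calls_b), n_shared = n_shared,
    fraction_b_in_a = if (nrow(calls_b)) n_shared / nrow(calls_b) else NA_real_)
  merged <- switch(policy,
    primary = {
      m <- calls_a
      if (nrow(m)) m$caller <- ifelse(shared, "both", m$caller)
      m
    },
    intersection = {
      m <- calls_a[shared, , drop = FALSE]
      if (nrow(m)) m$caller <- "both"
      m
    },
    union = {
      m <- calls_a
      if (nrow(m)) m$caller <- ifelse(shared, "both", m$caller)
      rbind(m, calls_b[!(key_b %in% key_a), , drop = FALSE])
    })
  list(report = report, calls = merged)
}
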
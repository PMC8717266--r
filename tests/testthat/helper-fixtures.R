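# shared small synthetic genome, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

shared_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    .fixture_cache$genome <- generate_genome(
      genome_spec(length = 2e5, seed = 42))
  }
  .fixture_cache$genome
}

# annotated genome from an explicit sequence and CDS table
toy_genome <- function(seq, cds_start = integer(0), cds_end = integer(0),
                       strand = "+") {
  cds <- if (length(cds_start)) {
    GenomicRanges::GRanges("toy", IRanges::IRanges(cds_start, cds_end),
                           strand = strand)
  } else NULL
  annotated_genome(seq, cds = cds, seqname = "toy")
}

# minimal mutation-call data.frame
make_calls <- function(line_id, pos, ref, alt,
                       allele_fraction = 1, qual = 500, mq = 60,
                       caller = "A") {
  nr <- nchar(ref); na_ <- nchar(alt)
  mclass <- ifelse(nr == 1 & na_ == 1, "substitution",
                   ifelse(na_ > nr, "insertion", "deletion"))
  data.frame(line_id = line_id, pos = pos, ref = ref, alt = alt,
             mclass = mclass, allele_fraction = allele_fraction,
             qual = qual, mq = mq, caller = caller)
}

# calls realizing a given ts/tv and directional class split
spectrum_calls <- function(n_per_class) {
  ref_alt <- list("A:T>G:C" = c("A", "G"), "G:C>A:T" = c("G", "A"),
                  "A:T>C:G" = c("A", "C"), "G:C>T:A" = c("G", "T"),
                  "A:T>T:A" = c("A", "T"), "G:C>C:G" = c("G", "C"))
  rows <- lapply(names(n_per_class), function(cl) {
    n <- n_per_class[[cl]]
    if (n == 0) return(NULL)
    make_calls(sprintf("L%03d", seq_len(n)), seq_len(n),
               ref_alt[[cl]][1], ref_alt[[cl]][2])
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
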
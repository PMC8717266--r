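#' Specification for a synthetic annotated genome
#'
#' Parameters of the synthetic single-contig genome generator. Defaults
#' emulate a 4.13 Mb, 60.5% GC bacterial chromosome with 88.3% of its
#' length in coding sequence and ~1% covered by simple sequence repeats.
#'
#' @param length Genome length in bp.
#' @param gc_content Target GC fraction in `[0, 1]`.
#' @param coding_fraction Target fraction of the genome in CDS, `[0, 1]`.
#' @param ssr_target_fraction Target fraction of the genome covered by
#'   planted SSR tracts.
#' @param seed Integer RNG seed; the full genome is a deterministic
#'   function of the spec.
#' @param mean_cds_length Mean CDS length in bp (drawn around this, always
#'   a multiple of 3).
#' @param coding_ssr_share Share of planted SSR bp hosted inside CDS;
#'   coding-hosted SSR motifs are G/C-only, which cannot create stop codons
#'   in any frame or strand.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = 4.13e6, gc_content = 0.605,
                        coding_fraction = 0.883, ssr_target_fraction = 0.0098,
                        seed = 1L, mean_cds_length = 900,
                        coding_ssr_share = 0.924) {
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0) stop("invalid spec: length must be positive")
  for (f in c(gc_content, coding_fraction, ssr_target_fraction, coding_ssr_share))
    if (!is.finite(f) || f < 0 || f > 1) stop("invalid spec: fractions must be in [0, 1]")
  if (coding_fraction > 0 && (gc_content < 0.02 || gc_content > 0.98))
    stop("invalid spec: GC content this extreme is incompatible with stop-free CDS sampling")
  structure(list(length = length, gc_content = gc_content,
                 coding_fraction = coding_fraction,
                 ssr_target_fraction = ssr_target_fraction,
                 seed = as.integer(seed), mean_cds_length = mean_cds_length,
                 coding_ssr_share = coding_ssr_share),
            class = "genome_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# GC probability for codon sampling such that the renormalized 61-codon
# pool has the target expected GC per base
codon_gc_prob <- function(target_gc) {
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::getGeneticCode("11"))
  keep <- !(codons %in% STOP_CODONS)
  gc_count <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("C", "G")),
                     numeric(1))
  expected_gc <- function(pg) {
    p <- c(A = (1 - pg) / 2, C = pg / 2, G = pg / 2, T = (1 - pg) / 2)
    cp <- vapply(strsplit(codons, ""), function(x) prod(p[x]), numeric(1))
    cp <- cp * keep
    sum(cp * gc_count) / sum(cp) / 3
  }
  stats::uniroot(function(pg) expected_gc(pg) - target_gc,
                 c(1e-4, 1 - 1e-4), tol = 1e-8)$root
}

count_gc <- function(s) {
  lengths(regmatches(s, gregexpr("[GC]", s)))
}

#' Generate a synthetic annotated genome
#'
#' Builds a random single-contig genome matching a [genome_spec()]:
#' non-overlapping CDS on both strands separated by noncoding spacers,
#' each CDS an ATG start, a run of stop-free codons sampled at the target
#' GC composition, and a stop codon; SSR tracts planted in CDS interiors
#' (G/C-only motifs, which can never form a stop codon) and in spacers;
#' remaining noncoding bases drawn i.i.d. with a GC probability solved so
#' the whole-genome GC matches the spec. Realized GC and coding fractions
#' land within 0.01 of their targets; planted SSRs are detectable by
#' [find_ssrs()] at default thresholds.
#'
#' @param spec A [genome_spec()].
#' @return An [annotated_genome()].
#' @export
generate_genome <- function(spec) {
  if (!inherits(spec, "genome_spec")) stop("spec must be a genome_spec")
  set.seed(spec$seed)
  L <- as.integer(round(spec$length))
  gv <- character(L)

  # ---- layout: alternating spacers and CDS ----
  cds_start <- integer(0); cds_len <- integer(0)
  if (spec$coding_fraction > 0) {
    target_codons <- round(L * spec$coding_fraction / 3)
    n_cds <- max(1L, round(target_codons * 3 / spec$mean_cds_length))
    mean_codons <- spec$mean_cds_length / 3
    codons <- pmax(12L, round(stats::rnorm(n_cds, mean_codons, mean_codons / 3)))
    codons <- pmax(12L, round(codons * target_codons / sum(codons)))
    resid <- target_codons - sum(codons)
    codons[which.max(codons)] <- max(12L, codons[which.max(codons)] + resid)
    noncoding_total <- L - 3L * sum(codons)
    if (noncoding_total < 2L * (n_cds + 1L))
      stop("invalid spec: coding_fraction leaves no room for spacers")
    w <- stats::rexp(n_cds + 1L) + 0.1
    spacer <- pmax(2L, floor(noncoding_total * w / sum(w)))
    spacer[n_cds + 1L] <- spacer[n_cds + 1L] + (noncoding_total - sum(spacer))
    while (spacer[n_cds + 1L] < 2L) {
      i <- which.max(spacer[seq_len(n_cds)])
      take <- min(spacer[i] - 2L, 2L - spacer[n_cds + 1L])
      spacer[i] <- spacer[i] - take
      spacer[n_cds + 1L] <- spacer[n_cds + 1L] + take
    }
    pos <- 1L
    cds_start <- integer(n_cds); cds_len <- 3L * codons
    for (i in seq_len(n_cds)) {
      pos <- pos + spacer[i]
      cds_start[i] <- pos
      pos <- pos + cds_len[i]
    }
  }
  n_cds <- length(cds_start)
  cds_end <- cds_start + cds_len - 1L
  strand <- if (n_cds) sample(c("+", "-"), n_cds, replace = TRUE) else character(0)

  # ---- CDS sequences ----
  gc_committed <- 0
  if (n_cds) {
    pg <- codon_gc_prob(spec$gc_content)
    p <- c(A = (1 - pg) / 2, C = pg / 2, G = pg / 2, T = (1 - pg) / 2)
    codon_pool <- setdiff(names(Biostrings::getGeneticCode("11")), STOP_CODONS)
    pool_prob <- vapply(strsplit(codon_pool, ""), function(x) prod(p[x]), numeric(1))
    internal <- cds_len / 3L - 2L
    total_internal <- sum(internal)
    drawn <- sample(codon_pool, total_internal, replace = TRUE, prob = pool_prob)
    offsets <- c(0L, cumsum(internal))
    stops <- sample(STOP_CODONS, n_cds, replace = TRUE)
    for (i in seq_len(n_cds)) {
      body <- drawn[(offsets[i] + 1L):offsets[i + 1L]]
      cseq <- paste0("ATG", paste(body, collapse = ""), stops[i])
      if (strand[i] == "-") cseq <- rev_comp(cseq)
      gv[cds_start[i]:cds_end[i]] <- strsplit(cseq, "")[[1]]
    }
    gc_committed <- sum(count_gc(paste(gv[unlist(mapply(seq.int, cds_start, cds_end,
                                                        SIMPLIFY = FALSE))],
                                       collapse = "")))
  }

  # ---- SSR planting ----
  ssr_target_bp <- round(spec$ssr_target_fraction * L)
  planted_bp <- 0L
  thr <- default_ssr_thresholds()
  coding_motifs <- c("G", "C", "GC", "CG", "GGC", "GCC", "CCG", "CGG")
  noncoding_motifs <- c("A", "T", "G", "C", "AT", "TA", "AG", "CT", "GA", "TC",
                        "GC", "CG", "AAT", "GGA", "TTC", "CCG")
  cds_free <- rep(TRUE, n_cds)
  spacer_rng <- if (n_cds) {
    sp_start <- c(1L, cds_end + 1L)
    sp_end <- c(cds_start - 1L, L)
    keep <- sp_end >= sp_start
    cbind(sp_start[keep], sp_end[keep])
  } else cbind(1L, L)
  spacer_free <- rep(TRUE, nrow(spacer_rng))
  while (planted_bp < ssr_target_bp) {
    in_coding <- n_cds > 0 && any(cds_free) &&
      stats::runif(1) < spec$coding_ssr_share
    motif <- if (in_coding) sample(coding_motifs, 1) else sample(noncoding_motifs, 1)
    k <- nchar(motif)
    copies <- max(ceiling(thr[k]), ceiling(sample(12:30, 1) / k))
    len <- as.integer(k * copies)
    tract <- strrep(motif, copies)
    placed <- FALSE
    if (in_coding) {
      ok <- which(cds_free & cds_len >= len + 12L)
      if (length(ok)) {
        i <- if (length(ok) == 1L) ok else sample(ok, 1)
        lo <- cds_start[i] + 3L
        hi <- cds_end[i] - 3L - len + 1L
        at <- if (hi > lo) sample(lo:hi, 1) else lo
        old <- paste(gv[at:(at + len - 1L)], collapse = "")
        gv[at:(at + len - 1L)] <- strsplit(tract, "")[[1]]
        gc_committed <- gc_committed - count_gc(old) + count_gc(tract)
        cds_free[i] <- FALSE
        placed <- TRUE
      }
    } else {
      ok <- which(spacer_free & (spacer_rng[, 2] - spacer_rng[, 1] + 1L) >= len + 2L)
      if (length(ok)) {
        i <- if (length(ok) == 1L) ok else sample(ok, 1)
        lo <- spacer_rng[i, 1] + 1L
        hi <- spacer_rng[i, 2] - len
        at <- if (hi > lo) sample(lo:hi, 1) else lo
        gv[at:(at + len - 1L)] <- strsplit(tract, "")[[1]]
        gc_committed <- gc_committed + count_gc(tract)
        spacer_free[i] <- FALSE
        placed <- TRUE
      }
    }
    if (placed) planted_bp <- planted_bp + len
    if (!placed && ((in_coding && !any(cds_free)) ||
                    (!in_coding && !any(spacer_free)))) break
    if (!placed && !any(cds_free) && !any(spacer_free)) break
  }

  # ---- fill remaining noncoding bases at the compensating GC probability ----
  open <- !nzchar(gv)
  n_open <- sum(open)
  if (n_open > 0L) {
    p_nc <- (spec$gc_content * L - gc_committed) / n_open
    p_nc <- min(0.98, max(0.02, p_nc))
    gv[open] <- sample(c("A", "C", "G", "T"), n_open, replace = TRUE,
                       prob = c((1 - p_nc) / 2, p_nc / 2, p_nc / 2, (1 - p_nc) / 2))
  }

  cds <- if (n_cds) {
    GenomicRanges::GRanges("synthetic1",
                           IRanges::IRanges(cds_start, cds_end),
                           strand = strand)
  } else NULL
  annotated_genome(paste(gv, collapse = ""), cds = cds, seqname = "synthetic1")
}
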
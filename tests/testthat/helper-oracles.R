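# Independent reference implementations used to cross-check the package.
# These share no helpers with the package code paths they validate.

# Poisson CI by numerical inversion of the Poisson CDF
oracle_poisson_ci <- function(count, denominator, level = 0.95) {
  alpha <- 1 - level
  hi_bracket <- max(10, 5 * count + 20)
  low <- if (count == 0) 0 else
    stats::uniroot(function(l) 1 - stats::ppois(count - 1, l) - alpha / 2,
                   c(1e-10, hi_bracket), tol = 1e-12)$root
  high <- stats::uniroot(function(l) stats::ppois(count, l) - alpha / 2,
                         c(1e-10, hi_bracket), tol = 1e-12)$root
  c(low, high) / denominator
}

# quadratic brute-force SSR scanner: explicit per-position extension loops
# plus an independently coded overlap-resolution pass
oracle_find_ssrs <- function(seq_chr, thresholds = c(8, 5, 4, 3, 3, 3)) {
  s <- strsplit(seq_chr, "")[[1]]
  L <- length(s)
  cand <- list()
  for (k in 1:6) {
    i <- 1L
    while (i + k <= L) {
      if (s[i + k] == s[i]) {
        j <- i
        while (j + k <= L && s[j + k] == s[j]) j <- j + 1L
        # j stops one past the last match: matches held for t = i..j-1,
        # so the tandem span is i .. (j-1)+k
        start <- i; end <- j + k - 1L
        len <- end - start + 1L
        motif <- paste(s[start:(start + k - 1L)], collapse = "")
        primitive <- TRUE
        for (d in seq_len(k - 1L)) {
          if (k %% d == 0L &&
              motif == paste(rep(substr(motif, 1, d), k / d), collapse = ""))
            primitive <- FALSE
        }
        if (primitive && len / k >= thresholds[k]) {
          cand[[length(cand) + 1L]] <- list(start = start, end = end,
                                            k = k, motif = motif,
                                            copies = len / k)
        }
        i <- j + 1L  # next period-k run cannot start before the break
      } else i <- i + 1L
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), copies = numeric(0)))
  }
  df <- do.call(rbind, lapply(cand, as.data.frame))
  df$len <- df$end - df$start + 1L
  df <- df[order(-df$len, df$k, df$start), ]
  chosen <- df[0, ]
  for (r in seq_len(nrow(df))) {
    row <- df[r, ]
    clash <- nrow(chosen) > 0 &&
      any(row$start <= chosen$end & row$end >= chosen$start)
    if (!clash) chosen <- rbind(chosen, row)
  }
  chosen <- chosen[order(chosen$start), ]
  data.frame(start = chosen$start, end = chosen$end,
             motif = chosen$motif, copies = chosen$copies)
}

# brute-force expected NS:S enumerator: walks every coding position of
# every CDS, mutates the containing codon, and compares translations
# codon by codon (independent of the package's codon-usage tabulation)
oracle_expected_ns <- function(genome, titv, multiplier = 2) {
  code <- Biostrings::getGeneticCode("11")
  w_ti <- multiplier * titv
  purine <- c("A", "G")
  ns_w <- 0; s_w <- 0
  for (i in seq_along(genome$cds)) {
    st <- GenomicRanges::start(genome$cds)[i]
    en <- GenomicRanges::end(genome$cds)[i]
    cseq <- substr(as.character(genome$seq), st, en)
    if (as.character(GenomicRanges::strand(genome$cds))[i] == "-")
      cseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cseq)))
    chars <- strsplit(cseq, "")[[1]]
    for (p in seq_along(chars)) {
      ci <- (p - 1) %/% 3
      codon <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
      w_in <- (p - 1) %% 3 + 1
      for (b in setdiff(c("A", "C", "G", "T"), chars[p])) {
        mcod <- codon
        substr(mcod, w_in, w_in) <- b
        w <- if ((chars[p] %in% purine) == (b %in% purine)) w_ti else 1
        if (code[[codon]] == code[[mcod]]) s_w <- s_w + w else ns_w <- ns_w + w
      }
    }
  }
  ns_w / s_w
}
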
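#' Configuration of a simulated mutation-accumulation experiment
#'
#' Defaults emulate the study conditions the package is designed around:
#' 69 lines bottlenecked through 159 single-colony transfers of ~18.3
#' generations each (~2900 generations/line), 3.5 Mb of callable sites per
#' line, a base-substitution rate of 1.22e-10 and an indel rate of
#' 4.35e-11 per site per generation, an AT-biased substitution spectrum,
#' and a 64-fold indel-rate enrichment inside SSR tracts (the fold-change
#' implied by ~39% of indels falling in ~1% of the genome).
#'
#' @param n_lines Number of MA lines.
#' @param transfers_per_line Single-colony transfers per line (scalar or
#'   per-line vector).
#' @param generations_per_transfer Generations elapsing between
#'   bottlenecks (log2 of the colony CFU).
#' @param callable_sites Callable sites N_i per line (scalar or vector).
#' @param sub_rate Base-substitution rate per site per generation.
#' @param indel_rate Indel rate per site per generation.
#' @param spectrum_weights Named nonnegative weights over the six
#'   strand-collapsed substitution classes ([substitution_classes()]).
#' @param indel_size_distribution Named probability vector over indel
#'   sizes in bp (names are sizes); default a geometric-like decay over
#'   1-50 bp.
#' @param ssr_hotspot_multiplier Fold-increase of the per-site indel rate
#'   inside SSR spans, `>= 1`.
#' @param seed Integer RNG seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_lines = 69, transfers_per_line = 159,
                              generations_per_transfer = 18.3,
                              callable_sites = 3.5e6,
                              sub_rate = 1.22e-10, indel_rate = 4.35e-11,
                              spectrum_weights = default_spectrum_weights(),
                              indel_size_distribution = default_indel_sizes(),
                              ssr_hotspot_multiplier = 64, seed = 1L) {
  if (n_lines < 1) stop("invalid config: n_lines must be >= 1")
  if (sub_rate < 0 || indel_rate < 0) stop("invalid config: rates must be >= 0")
  if (ssr_hotspot_multiplier < 1) stop("invalid config: hotspot multiplier must be >= 1")
  if (any(spectrum_weights < 0) || !any(spectrum_weights > 0))
    stop("invalid config: spectrum weights must be nonnegative with one positive")
  if (!all(substitution_classes() %in% names(spectrum_weights)))
    stop("spectrum_weights must be named by the six substitution classes")
  if (abs(sum(indel_size_distribution) - 1) > 1e-6)
    stop("indel_size_distribution must sum to 1")
  structure(list(
    n_lines = as.integer(n_lines),
    transfers_per_line = transfers_per_line,
    generations_per_transfer = generations_per_transfer,
    callable_sites = callable_sites,
    sub_rate = sub_rate, indel_rate = indel_rate,
    spectrum_weights = spectrum_weights[substitution_classes()],
    indel_size_distribution = indel_size_distribution,
    ssr_hotspot_multiplier = ssr_hotspot_multiplier,
    seed = as.integer(seed)), class = "experiment_config")
}

#' Default substitution-spectrum weights
#'
#' AT-biased spectrum: relative weights 17 (A:T>G:C), 40 (G:C>A:T),
#' 3 (A:T>C:G), 10 (G:C>T:A), 9 (A:T>T:A), 9 (G:C>C:G) — transitions
#' dominate (ts/tv 57:31) and G:C pairs mutate toward A:T far more often
#' than the reverse.
#'
#' @return Named numeric weights over [substitution_classes()].
#' @export
default_spectrum_weights <- function() {
  c("A:T>G:C" = 17, "G:C>A:T" = 40, "A:T>C:G" = 3,
    "G:C>T:A" = 10, "A:T>T:A" = 9, "G:C>C:G" = 9)
}

#' Default indel size distribution
#'
#' Geometric-like decay over 1-50 bp, `P(s) propto exp(-(s-1)/6)`, giving
#' mean events of roughly 6-7 bp as seen in small-indel call sets.
#'
#' @return Named probability vector (names are sizes in bp).
#' @export
default_indel_sizes <- function() {
  s <- 1:50
  p <- exp(-(s - 1) / 6)
  stats::setNames(p / sum(p), s)
}

# alternate base for a ref base under a strand-collapsed class
alt_for_class <- local({
  map <- NULL
  function(class, ref) {
    if (is.null(map)) {
      m <- list()
      for (r in c("A", "C", "G", "T")) for (a in setdiff(c("A", "C", "G", "T"), r)) {
        cl <- as.character(classify_substitution(r, a)$class)
        m[[paste(cl, r)]] <- a
      }
      map <<- m
    }
    unlist(map[paste(class, ref)], use.names = FALSE)
  }
})

#' Simulate a mutation-accumulation experiment
#'
#' Draws per-line substitution and indel counts as Poisson with mean
#' `rate * N_i * T_i`, places substitutions by sampling a spectrum class
#' and then a site of the required composition (a G:C class requires a
#' G/C site), and places indels with probability weight multiplied by
#' `ssr_hotspot_multiplier` inside SSR spans. Deletions remove the
#' following bases (left-anchored allele convention); insertions duplicate
#' the downstream tract, emulating replication slippage. At most one
#' mutation is placed per site per line.
#'
#' @param genome An [annotated_genome()].
#' @param config An [experiment_config()].
#' @return A list with `truth` (data.frame: `line_id`, `pos`, `ref`,
#'   `alt`, `mclass`, `class` (substitution class or `NA`), `in_ssr`) and
#'   `lines` (data.frame: `line_id`, `transfers`, `generations`,
#'   `callable_sites`, `cfu`).
#' @export
simulate_ma_experiment <- function(genome, config) {
  if (!inherits(config, "experiment_config")) stop("config must be an experiment_config")
  set.seed(config$seed)
  L <- genome$length
  n <- config$n_lines
  transfers <- rep_len(config$transfers_per_line, n)
  gpt <- rep_len(config$generations_per_transfer, n)
  Ni <- rep_len(config$callable_sites, n)
  Ti <- transfers * gpt
  if (all(Ni == 0)) stop("degenerate experiment: zero callable sites")
  line_id <- sprintf("L%02d", seq_len(n))
  lines <- data.frame(line_id = line_id, transfers = transfers,
                      generations = Ti, callable_sites = Ni,
                      cfu = round(2 ^ gpt))

  rawv <- charToRaw(as.character(genome$seq))
  is_gc <- rawv == charToRaw("G") | rawv == charToRaw("C")
  gc_sites <- which(is_gc)
  at_sites <- which(!is_gc)
  ssr_mask <- logical(L)
  if (length(genome$ssrs)) {
    red <- IRanges::reduce(GenomicRanges::ranges(genome$ssrs))
    for (i in seq_along(red))
      ssr_mask[IRanges::start(red)[i]:IRanges::end(red)[i]] <- TRUE
  }
  ssr_pos <- which(ssr_mask)
  S <- length(ssr_pos)
  k <- config$ssr_hotspot_multiplier
  p_in_ssr <- if (S > 0) k * S / (k * S + (L - S)) else 0
  gchr <- as.character(genome$seq)
  base_at <- function(p) substring(gchr, p, p)
  sizes <- as.integer(names(config$indel_size_distribution))

  weights <- config$spectrum_weights
  classes <- names(weights)
  gc_class <- grepl("^G:C", classes)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    used <- integer(0)
    n_sub <- stats::rpois(1, config$sub_rate * Ni[i] * Ti[i])
    n_ind <- stats::rpois(1, config$indel_rate * Ni[i] * Ti[i])
    recs <- list()
    if (n_sub > 0) {
      cl_idx <- sample(length(classes), n_sub, replace = TRUE, prob = weights)
      for (j in seq_len(n_sub)) {
        pool <- if (gc_class[cl_idx[j]]) gc_sites else at_sites
        repeat {
          p <- pool[sample.int(length(pool), 1)]
          if (!p %in% used) break
        }
        used <- c(used, p)
        refb <- base_at(p)
        recs[[length(recs) + 1L]] <- data.frame(
          pos = p, ref = refb, alt = alt_for_class(classes[cl_idx[j]], refb),
          mclass = "substitution", class = classes[cl_idx[j]],
          in_ssr = ssr_mask[p])
      }
    }
    if (n_ind > 0) {
      for (j in seq_len(n_ind)) {
        size <- sizes[sample.int(length(sizes), 1,
                                 prob = config$indel_size_distribution)]
        is_del <- stats::runif(1) < 0.5
        repeat {
          in_ssr_stratum <- stats::runif(1) < p_in_ssr
          p <- if (in_ssr_stratum) ssr_pos[sample.int(S, 1)]
               else sample.int(L, 1)
          if (!in_ssr_stratum && S > 0 && ssr_mask[p]) next
          if (p >= 1 && p + size <= L && !p %in% used) break
        }
        used <- c(used, p)
        anchor <- base_at(p)
        if (is_del) {
          ref <- substring(gchr, p, p + size)
          alt <- anchor
          span <- p:(p + size)
        } else {
          ref <- anchor
          alt <- paste0(anchor, substring(gchr, p + 1L, p + size))
          span <- p
        }
        recs[[length(recs) + 1L]] <- data.frame(
          pos = p, ref = ref, alt = alt,
          mclass = if (is_del) "deletion" else "insertion",
          class = NA_character_, in_ssr = any(ssr_mask[span]))
      }
    }
    if (length(recs)) {
      df <- do.call(rbind, recs)
      df <- cbind(line_id = line_id[i], df)
      rows[[i]] <- df[order(df$pos), ]
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  truth <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(line_id = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               mclass = character(0), class = character(0),
               in_ssr = logical(0))
  }
  list(truth = truth, lines = lines)
}
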
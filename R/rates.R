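#' Generations elapsed from a colony-forming-unit count
#'
#' A colony grown from a single founder cell reaches `CFU` cells after
#' `log2(CFU)` doublings, so the number of generations per transfer is
#' estimated as `log2(cfu)`.
#'
#' @param cfu Colony-forming-unit count(s), `>= 1`.
#' @return Generations per transfer (vectorized).
#' @export
generations_from_cfu <- function(cfu) {
  if (any(!is.finite(cfu)) || any(cfu < 1))
    stop("cfu must be >= 1")
  log2(cfu)
}

#' Exact Poisson confidence interval for a rate
#'
#' Garwood's exact interval from chi-square quantiles: for `m` observed
#' events the count interval is
#' `[qchisq(alpha/2, 2m)/2, qchisq(1 - alpha/2, 2m + 2)/2]`, with the lower
#' bound defined as 0 when `m = 0`; dividing by the exposure denominator
#' gives the rate interval.
#'
#' @param count Observed event count, `>= 0`.
#' @param denominator Exposure (site-generations), `> 0`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)` on the rate scale.
#' @export
poisson_ci <- function(count, denominator, level = 0.95) {
  stopifnot(count >= 0, denominator > 0)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- 1 - level
  low <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
  high <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  c(low = low / denominator, high = high / denominator)
}

#' Pooled mutation-rate estimate across MA lines
#'
#' The pooled rate is `mu = m / sum_i(N_i * T_i)` where `m` is the total
#' event count across lines, `N_i` the callable sites and `T_i` the
#' generations of line i. The exact Poisson CI comes from [poisson_ci()].
#' When per-line counts are supplied, the standard error of the mean
#' per-line rate is `sd(m_i / (N_i T_i)) / sqrt(n)` (sample SD, n-1
#' denominator).
#'
#' @param m Total event count (scalar), or a vector of per-line counts
#'   (length `nrow(lines)`, optionally named by `line_id`) from which the
#'   total and the SEM are derived.
#' @param lines Data frame of MA-line metadata with columns `generations`
#'   and `callable_sites` (see [read_callsets()]).
#' @param level Confidence level.
#' @return A `rate_estimate`: list with `m`, `denominator`, `mu`, `ci_low`,
#'   `ci_high`, `sem`, `level`.
#' @export
pooled_rate <- function(m, lines, level = 0.95) {
  nt <- as.numeric(lines$callable_sites) * as.numeric(lines$generations)
  denominator <- sum(nt)
  if (!is.finite(denominator) || denominator <= 0)
    stop("degenerate experiment: total site-generations is zero")
  sem <- NA_real_
  if (length(m) > 1L) {
    if (length(m) != nrow(lines))
      stop("per-line counts must match the number of lines")
    if (!is.null(names(m)) && !is.null(lines$line_id))
      m <- m[as.character(lines$line_id)]
    if (any(nt <= 0)) stop("degenerate experiment: a line has zero site-generations")
    per_line <- m / nt
    sem <- stats::sd(per_line) / sqrt(length(per_line))
    m <- sum(m)
  }
  stopifnot(m >= 0)
  ci <- poisson_ci(m, denominator, level)
  structure(
    list(m = m, denominator = denominator, mu = m / denominator,
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         sem = sem, level = level),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate: m = %d over %.4g site-generations\n", x$m, x$denominator))
  cat(sprintf("  mu = %.3g  [%g%% CI %.3g, %.3g]%s\n",
              x$mu, 100 * x$level, x$ci_low, x$ci_high,
              if (is.na(x$sem)) "" else sprintf("  SEM(per-line) = %.3g", x$sem)))
  invisible(x)
}

#' Per-genome mutation rate
#'
#' Events per genome per generation: `m / (n_lines * generations)`, i.e. the
#' average number of mutations a genome acquires in one cell division.
#'
#' @param m Total event count.
#' @param n_lines Number of MA lines.
#' @param generations Mean generations per line.
#' @return Rate per genome per generation.
#' @export
per_genome_rate <- function(m, n_lines, generations) {
  if (n_lines <= 0 || generations <= 0)
    stop("n_lines and generations must be positive")
  stopifnot(m >= 0)
  m / (n_lines * generations)
}

#' Conditional (directional) mutation rates at G:C and A:T sites
#'
#' Directional rates normalized by the number of available sites:
#' `mu_gc_to_at` divides the count of changes away from G:C pairs by the
#' G/C share of the site-generation denominator, and `mu_at_to_gc` divides
#' the changes away from A:T pairs by the A/T share.
#'
#' @param counts_to_at Events at G/C sites mutating toward A/T
#'   (G:C>A:T transitions plus G:C>T:A transversions).
#' @param counts_to_gc Events at A/T sites mutating toward G/C
#'   (A:T>G:C transitions plus A:T>C:G transversions).
#' @param gc_fraction Genome GC fraction in (0, 1).
#' @param denominator Total site-generations.
#' @param level Confidence level for the per-direction Poisson CIs.
#' @return A list with `mu_gc_to_at`, `mu_at_to_gc`, their CIs
#'   (`ci_gc_to_at`, `ci_at_to_gc`) and `gc_fraction`.
#' @export
conditional_rates <- function(counts_to_at, counts_to_gc, gc_fraction,
                              denominator, level = 0.95) {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly inside (0, 1)")
  stopifnot(counts_to_at >= 0, counts_to_gc >= 0, denominator > 0)
  d_gc <- gc_fraction * denominator
  d_at <- (1 - gc_fraction) * denominator
  list(
    mu_gc_to_at = counts_to_at / d_gc,
    mu_at_to_gc = counts_to_gc / d_at,
    ci_gc_to_at = poisson_ci(counts_to_at, d_gc, level),
    ci_at_to_gc = poisson_ci(counts_to_gc, d_at, level),
    gc_fraction = gc_fraction)
}

#' Expected GC content at mutational equilibrium
#'
#' Under mutation pressure alone, genome GC content converges to
#' `mu_at_to_gc / (mu_gc_to_at + mu_at_to_gc)`. The result is invariant to
#' common rescaling of the two rates, so composition-normalized counts can
#' be supplied directly.
#'
#' @param mu_at_to_gc Rate of change toward G/C at A:T sites.
#' @param mu_gc_to_at Rate of change toward A/T at G:C sites.
#' @return Expected equilibrium GC fraction.
#' @export
equilibrium_gc <- function(mu_at_to_gc, mu_gc_to_at) {
  stopifnot(mu_at_to_gc >= 0, mu_gc_to_at >= 0)
  if (mu_at_to_gc + mu_gc_to_at == 0)
    stop("equilibrium undefined: both directional rates are zero")
  mu_at_to_gc / (mu_gc_to_at + mu_at_to_gc)
}

#' Exact two-sided test of association for a 2x2 table with large margins
#'
#' Fisher's exact test conditioned on the table margins, computed directly
#' from the hypergeometric density. [stats::fisher.test()] rejects tables
#' whose entries exceed integer range, which site-generation denominators
#' (~1e11) do; here the support of the conditional distribution is bounded
#' by the smaller margin (the event count), so the two-sided p-value (sum of
#' outcomes no more probable than the observed one) is computed stably at
#' any denominator scale. Agrees with [stats::fisher.test()] on small
#' tables.
#'
#' @param a,b,c,d Table cells: rows are categories (e.g. coding/noncoding),
#'   columns are (events, non-event exposure units).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  a <- round(a); b <- round(b); c <- round(c); d <- round(d)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  k <- a + c
  dens <- stats::dhyper(0:k, a + b, c + d, k)
  min(1, sum(dens[dens <= dens[a + 1] * (1 + 1e-7)]))
}
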
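#' Build a pipeline configuration
#'
#' Accepts a YAML file path or a named list and fills defaults. Required
#' paths: `genome_fasta`, `metadata`, and `vcf_dir` (directory of per-line
#' `.vcf` files) or an explicit `vcf_paths` vector; `annotation_gff3` is
#' optional (without it, coding analyses are skipped).
#'
#' @param config Path to a YAML config or a named list.
#' @param ... Overrides applied on top of the file/list values.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(config, list(...))
  defaults <- list(
    genome_fasta = NULL, annotation_gff3 = NULL,
    vcf_dir = NULL, vcf_paths = NULL, vcf_dir_b = NULL,
    metadata = NULL, out_dir = NULL,
    min_qual = 100, min_mq = 59, min_consensus = 0.99,
    confidence = 0.95,
    ssr_thresholds = unname(default_ssr_thresholds()),
    ti_weight_multiplier = 2,
    merge_policy = "primary", seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  structure(cfg, class = "pipeline_config")
}

resolve_vcfs <- function(dir, paths) {
  if (!is.null(paths)) return(paths)
  if (is.null(dir)) stop("config must give vcf_dir or vcf_paths")
  if (!dir.exists(dir)) stop("VCF directory not found: ", dir)
  sort(list.files(dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE))
}

#' Run the full MA analysis pipeline
#'
#' Executes ingest (VCF + metadata), the site/consensus/uniqueness filter
#' cascade, optional dual-caller reconciliation, rate estimation with
#' exact Poisson CIs, spectrum and coding-effect analysis, and indel/SSR
#' analysis; writes TSV reports plus a call-level filter log to
#' `out_dir` when set.
#'
#' @param config A [pipeline_config()] (or path/list coercible to one).
#' @return A `ma_report` bundle (list of all stage results), invisibly
#'   when reports are written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$genome_fasta) || !file.exists(config$genome_fasta))
    stop("ingest: genome FASTA not found: ",
         config$genome_fasta %||% "<missing>")
  if (is.null(config$metadata) || !file.exists(config$metadata))
    stop("ingest: metadata file not found: ", config$metadata %||% "<missing>")
  genome <- read_genome(config$genome_fasta, config$annotation_gff3,
                        ssr_thresholds = config$ssr_thresholds)
  vcfs <- resolve_vcfs(config$vcf_dir, config$vcf_paths)
  ing <- read_callsets(vcfs, config$metadata, caller = "A")
  calls <- ing$calls; lines <- ing$lines

  log <- data.frame(stage = "ingest", n_in = nrow(calls), n_out = nrow(calls))
  add_log <- function(stage, n_in, n_out) {
    log <<- rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out))
  }
  n0 <- nrow(calls)
  calls <- apply_site_filters(calls, config$min_qual, config$min_mq)
  add_log("site_filters", n0, nrow(calls))
  n0 <- nrow(calls)
  calls <- apply_consensus_filter(calls, config$min_consensus)
  add_log("consensus_filter", n0, nrow(calls))
  n0 <- nrow(calls)
  calls <- remove_shared_mutations(calls)
  add_log("unique_filter", n0, nrow(calls))

  concordance <- NULL
  if (!is.null(config$vcf_dir_b)) {
    ing_b <- read_callsets(resolve_vcfs(config$vcf_dir_b, NULL),
                           config$metadata, caller = "B")
    calls_b <- remove_shared_mutations(apply_consensus_filter(
      apply_site_filters(ing_b$calls, config$min_qual, config$min_mq),
      config$min_consensus))
    rec <- reconcile_callers(calls, calls_b, genome = genome,
                             policy = config$merge_policy)
    concordance <- rec$report
    n0 <- nrow(calls)
    calls <- rec$calls
    add_log("reconcile_callers", n0, nrow(calls))
  }

  subs <- calls[calls$mclass == "substitution", , drop = FALSE]
  indels <- calls[calls$mclass != "substitution", , drop = FALSE]
  level <- config$confidence
  denominator <- sum(as.numeric(lines$callable_sites) * as.numeric(lines$generations))

  count_per_line <- function(df) {
    stats::setNames(vapply(lines$line_id,
                           function(l) sum(df$line_id == l), numeric(1)),
                    lines$line_id)
  }
  rate_sub <- pooled_rate(count_per_line(subs), lines, level)
  rate_indel <- pooled_rate(count_per_line(indels), lines, level)
  genome_rate <- per_genome_rate(nrow(subs), nrow(lines),
                                 mean(lines$generations))

  spec <- NULL; effects <- NULL; cond <- NULL; eq_gc <- NULL
  if (nrow(subs)) {
    spec <- spectrum_summary(subs, genome, denominator, level)
    cc <- spec$class_counts
    cond <- conditional_rates(
      counts_to_at = cc[["G:C>A:T"]] + cc[["G:C>T:A"]],
      counts_to_gc = cc[["A:T>G:C"]] + cc[["A:T>C:G"]],
      gc_fraction = genome$gc_content, denominator = denominator,
      level = level)
    eq_gc <- equilibrium_gc(cond$mu_at_to_gc, cond$mu_gc_to_at)
    if (length(genome$cds) && is.finite(spec$titv) && spec$titv > 0 &&
        spec$n_synonymous + spec$n_nonsynonymous > 0) {
      exp_ratio <- expected_ns_ratio(genome, spec$titv,
                                     config$ti_weight_multiplier)
      effects <- c(list(expected_ratio = exp_ratio),
                   ns_ratio_test(spec$n_nonsynonymous, spec$n_synonymous,
                                 exp_ratio))
    }
  }
  indel_an <- indel_region_analysis(indels, genome, genome$ssrs,
                                    denominator, level)

  bundle <- structure(list(
    genome = genome, lines = lines, calls = calls, log = log,
    concordance = concordance, denominator = denominator,
    rate_sub = rate_sub, rate_indel = rate_indel,
    genome_rate = genome_rate,
    spectrum = spec, conditional = cond, equilibrium_gc = eq_gc,
    effects = effects, indels = indel_an, level = level),
    class = "ma_report")

  if (!is.null(config$out_dir)) {
    write_reports(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

rate_row <- function(category, r) {
  data.frame(category = category, m = r$m, denominator = r$denominator,
             mu = r$mu, ci_low = r$ci_low, ci_high = r$ci_high,
             sem = r$sem)
}

write_reports <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  rates <- rbind(rate_row("substitution", bundle$rate_sub),
                 rate_row("indel", bundle$rate_indel))
  if (!is.null(bundle$indels$rate_insertion)) {
    rates <- rbind(rates,
                   rate_row("insertion", bundle$indels$rate_insertion),
                   rate_row("deletion", bundle$indels$rate_deletion))
  }
  sp <- bundle$spectrum
  if (!is.null(sp)) {
    if (!is.null(sp$partition$rate_coding)) {
      rates <- rbind(rates,
                     rate_row("substitution_coding", sp$partition$rate_coding),
                     rate_row("substitution_noncoding", sp$partition$rate_noncoding))
    }
    cr <- bundle$conditional
    rates <- rbind(rates, data.frame(
      category = c("mu_gc_to_at", "mu_at_to_gc"),
      m = NA, denominator = NA,
      mu = c(cr$mu_gc_to_at, cr$mu_at_to_gc),
      ci_low = c(cr$ci_gc_to_at[1], cr$ci_at_to_gc[1]),
      ci_high = c(cr$ci_gc_to_at[2], cr$ci_at_to_gc[2]), sem = NA))
    spectrum_df <- data.frame(class = names(sp$class_counts),
                              count = unname(sp$class_counts))
    if (!is.null(sp$class_rates)) {
      spectrum_df$rate <- vapply(sp$class_rates, `[[`, numeric(1), "mu")
      spectrum_df$ci_low <- vapply(sp$class_rates, `[[`, numeric(1), "ci_low")
      spectrum_df$ci_high <- vapply(sp$class_rates, `[[`, numeric(1), "ci_high")
    }
    wt(spectrum_df, "spectrum.tsv")
    if (!is.null(bundle$effects)) {
      wt(data.frame(synonymous = sp$n_synonymous,
                    nonsynonymous = sp$n_nonsynonymous,
                    observed_ratio = bundle$effects$observed_ratio,
                    expected_ratio = bundle$effects$expected_ratio,
                    chi2 = bundle$effects$chi2, p = bundle$effects$p),
         "effects.tsv")
    }
  }
  wt(rates, "rates.tsv")
  ind <- bundle$indels
  indel_calls <- bundle$calls[bundle$calls$mclass != "substitution", , drop = FALSE]
  if (nrow(indel_calls)) {
    wt(data.frame(line_id = indel_calls$line_id, pos = indel_calls$pos,
                  size = abs(nchar(indel_calls$alt) - nchar(indel_calls$ref)),
                  sign = ifelse(indel_calls$mclass == "insertion", "+", "-"),
                  region = ifelse(ind$coding, "coding", "noncoding"),
                  in_ssr = ind$in_ssr),
       "indels.tsv")
  }
  write_ssr_bed(bundle$genome$ssrs, file.path(out_dir, "ssrs.bed"))
  wt(bundle$log, "filter_log.tsv")
  if (!is.null(bundle$concordance)) wt(bundle$concordance, "concordance.tsv")
  writeLines(render_summary(bundle), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Render a human-readable analysis summary
#'
#' @param bundle An `ma_report` from [run_pipeline()].
#' @return Character vector of summary lines, invisibly printed-friendly.
#' @export
render_summary <- function(bundle) {
  f <- function(...) sprintf(...)
  r <- bundle$rate_sub; ri <- bundle$rate_indel
  out <- c(
    "== MA experiment summary ==",
    f("lines: %d   site-generations: %.4g", nrow(bundle$lines), bundle$denominator),
    f("base substitutions: m = %d, mu = %.3g [%.3g, %.3g] /site/gen",
      r$m, r$mu, r$ci_low, r$ci_high),
    f("per-genome substitution rate: %.3g /genome/gen", bundle$genome_rate),
    f("indels: m = %d, mu = %.3g [%.3g, %.3g] /site/gen",
      ri$m, ri$mu, ri$ci_low, ri$ci_high))
  sp <- bundle$spectrum
  if (!is.null(sp)) {
    out <- c(out,
      "-- spectrum --",
      paste(names(sp$class_counts),
            unname(sp$class_counts), sep = ": ", collapse = "  "),
      f("transitions: %d  transversions: %d  ts/tv = %.2f",
        sp$n_transitions, sp$n_transversions, sp$titv),
      f("coding: %d/%d (%.1f%%)  noncoding: %d",
        sp$partition$n_coding, sp$n_transitions + sp$n_transversions,
        100 * sp$partition$n_coding / max(1, sp$n_transitions + sp$n_transversions),
        sp$partition$n_noncoding),
      f("conditional rates: mu_GC->AT = %.3g  mu_AT->GC = %.3g",
        bundle$conditional$mu_gc_to_at, bundle$conditional$mu_at_to_gc),
      f("equilibrium GC content: %.0f%%", 100 * bundle$equilibrium_gc))
    if (!is.null(bundle$effects)) {
      out <- c(out,
        f("synonymous: %d  nonsynonymous: %d  observed NS:S = %.2f  expected = %.2f (chi2 = %.2f, df = %d, p = %.2g)",
          sp$n_synonymous, sp$n_nonsynonymous,
          bundle$effects$observed_ratio, bundle$effects$expected_ratio,
          bundle$effects$chi2, bundle$effects$df, bundle$effects$p))
    }
  }
  ind <- bundle$indels
  out <- c(out,
    "-- indels --",
    f("insertions: %d (%d bp)  deletions: %d (%d bp)  net: %+d bp",
      ind$n_insertions, ind$bp_inserted, ind$n_deletions, ind$bp_deleted,
      ind$net_bp),
    f("coding: %d (expected %.1f)  noncoding: %d",
      ind$n_coding, ind$expected_coding, ind$n_noncoding),
    f("in SSRs: %d/%d (%.1f%%; SSRs cover %.2f%% of genome)",
      ind$n_in_ssr, ind$n_total, 100 * (ind$ssr_fraction_of_indels %||% 0),
      100 * ind$ssr_fraction_of_genome))
  out
}

#' @export
print.ma_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
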
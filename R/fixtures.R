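#' Write a simulated experiment as standard-format fixture files
#'
#' Emits the genome as FASTA, the CDS annotation as GFF3, one VCF v4.2 per
#' line holding that line's ground-truth mutations (QUAL, INFO/MQ and
#' FORMAT/AD populated above the default filter thresholds, so a clean
#' round trip through [read_callsets()] and the filters reproduces the
#' truth exactly), and a TSV of line metadata. Indels are already in the
#' left-anchored padding-base convention; records are never multi-allelic.
#'
#' @param genome An [annotated_genome()].
#' @param truth Ground-truth mutation table from
#'   [simulate_ma_experiment()].
#' @param lines Line-metadata data.frame (same source).
#' @param out_dir Output directory (created if needed).
#' @param qual QUAL emitted per record.
#' @param mq INFO/MQ emitted per record.
#' @param depth Alt-allele read depth emitted per record (ref depth 0, so
#'   the allele fraction is 1).
#' @return Invisibly, a list of written paths: `fasta`, `gff3`, `vcfs`
#'   (named by line), `metadata`.
#' @export
write_fixtures <- function(genome, truth, lines, out_dir,
                           qual = 500, mq = 60, depth = 100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  fasta <- file.path(out_dir, "genome.fasta")
  seqs <- Biostrings::DNAStringSet(genome$seq)
  names(seqs) <- genome$seqname
  Biostrings::writeXStringSet(seqs, fasta)

  gff3 <- file.path(out_dir, "annotation.gff3")
  cds <- genome$cds
  if (length(cds)) {
    S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
      source = "mamut", type = "CDS",
      ID = sprintf("cds%05d", seq_along(cds)),
      phase = 0L)
  }
  rtracklayer::export(cds, gff3, format = "gff3")

  vcfs <- character(0)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$seqname, genome$length),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  for (i in seq_len(nrow(lines))) {
    lid <- lines$line_id[i]
    path <- file.path(out_dir, paste0(lid, ".vcf"))
    tr <- truth[truth$line_id == lid, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    recs <- if (nrow(tr)) {
      sprintf("%s\t%d\t.\t%s\t%s\t%g\tPASS\tMQ=%g\tGT:AD:DP\t1:0,%d:%d",
              genome$seqname, tr$pos, tr$ref, tr$alt, qual, mq, depth, depth)
    } else character(0)
    writeLines(c(header,
                 paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", lid),
                 recs), path)
    vcfs[lid] <- path
  }

  metadata <- file.path(out_dir, "lines.tsv")
  meta <- lines[, c("line_id", "transfers", "cfu", "callable_sites")]
  utils::write.table(meta, metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, gff3 = gff3, vcfs = vcfs, metadata = metadata))
}

#' Read per-line VCF call sets with their line metadata
#'
#' Parses one VCF per MA line (the file base name is the line id), splits
#' multi-allelic records into per-ALT calls, classifies each call as
#' substitution/insertion/deletion from the allele lengths, and joins the
#' line metadata. When the metadata lacks a `generations` column it is
#' computed as `transfers * log2(cfu)` ([generations_from_cfu()]).
#'
#' @param vcf_paths Character vector of per-line VCF paths.
#' @param metadata Path to the line-metadata TSV (columns `line_id`,
#'   `transfers`, `callable_sites`, and `cfu` and/or `generations`).
#' @param caller Caller label recorded on every call (`"A"` or `"B"`).
#' @return A list with `calls` (data.frame: `line_id`, `pos`, `ref`,
#'   `alt`, `mclass`, `allele_fraction`, `qual`, `mq`, `caller`) and
#'   `lines` (metadata with a `generations` column).
#' @export
read_callsets <- function(vcf_paths, metadata, caller = "A") {
  if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
  meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  req <- c("line_id", "transfers", "callable_sites")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns line_id, transfers, callable_sites")
  if (!"generations" %in% names(meta)) {
    if (!"cfu" %in% names(meta))
      stop("metadata needs either a generations or a cfu column")
    meta$generations <- meta$transfers * generations_from_cfu(meta$cfu)
  }
  calls <- list()
  for (path in vcf_paths) {
    lid <- sub("\\.vcf(\\.gz)?$", "", basename(path))
    if (!lid %in% meta$line_id)
      stop("missing metadata: no row for line '", lid, "' (", path, ")")
    calls[[lid]] <- parse_vcf_calls(path, lid, caller)
  }
  calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (is.null(calls)) calls <- empty_calls()
  list(calls = calls, lines = meta)
}

empty_calls <- function() {
  data.frame(line_id = character(0), pos = integer(0), ref = character(0),
             alt = character(0), mclass = character(0),
             allele_fraction = numeric(0), qual = numeric(0),
             mq = numeric(0), caller = character(0))
}

parse_vcf_calls <- function(path, line_id, caller) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(fix)) return(empty_calls())
  if (!is.matrix(fix)) # single-record VCFs come back as a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) return(empty_calls())
  mq <- suppressWarnings(vcfR::extract.info(v, "MQ", as.numeric = TRUE))
  if (is.null(mq)) mq <- rep(NA_real_, nrow(fix))
  ad <- tryCatch(suppressWarnings(vcfR::extract.gt(v, "AD")[, 1]),
                 error = function(e) rep(NA_character_, nrow(fix)))
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    depths <- suppressWarnings(as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    total <- sum(depths, na.rm = TRUE)
    for (a in seq_along(alts)) {
      ref <- fix[i, "REF"]; alt <- alts[a]
      if (is.na(alt) || alt %in% c(".", "*")) next
      nr <- nchar(ref); na_ <- nchar(alt)
      mclass <- if (nr == 1L && na_ == 1L) "substitution"
        else if (na_ > nr) "insertion"
        else if (nr > na_) "deletion"
        else NA_character_
      if (is.na(mclass)) {
        warning("skipping complex (equal-length, multi-base) record at ",
                fix[i, "CHROM"], ":", fix[i, "POS"], " in ", path)
        next
      }
      af <- if (total > 0 && length(depths) > a) depths[a + 1L] / total else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        line_id = line_id,
        pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, mclass = mclass,
        allele_fraction = af,
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        mq = mq[i], caller = caller)
    }
  }
  if (!length(out)) return(empty_calls())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
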
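#' End-to-end per-sample calling run
#'
#' Reads paired FASTQ, runs QC, anchored alignment, event calling and
#' window summarization ([call_sample()]), and writes
#' `<sample>_summary.tsv`, `<sample>_alleles.tsv`, `<sample>_calls.vcf`
#' and `<sample>_report.json` (the fully resolved configuration plus all
#' conservation tallies) under `out_dir`. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param fq1,fq2 FASTQ paths (gzip allowed); with `interleaved = TRUE`
#'   only `fq1` is read.
#' @param fasta,config reference FASTA and config paths (see
#'   [load_reference()]).
#' @param out_dir output directory (created if needed).
#' @param sample_id sample label (defaults to the `fq1` base name).
#' @param interleaved single interleaved FASTQ input.
#' @param qc,scoring,min_overlap pipeline parameters.
#' @return invisibly, the [call_sample()] result.
#' @export
run_call <- function(fq1, fq2 = NULL, fasta, config, out_dir,
                     sample_id = NULL, interleaved = FALSE,
                     qc = qc_params(), scoring = align_scoring(),
                     min_overlap = 20L) {
  reference <- load_reference(fasta, config)
  pairs <- read_fastq_pairs(fq1, fq2, interleaved = interleaved)
  if (is.null(sample_id)) {
    sample_id <- sub("(_R1)?\\.(fastq|fq)(\\.gz)?$", "", basename(fq1))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- call_sample(pairs, reference, sample_id = sample_id, qc = qc,
                     scoring = scoring,
                     window = window_of(reference, min_overlap))
  prefix <- file.path(out_dir, sample_id)
  write_summary_tsv(res$summary, prefix)
  write_vcf(res$summary, reference, paste0(prefix, "_calls.vcf"))
  report <- list(
    sample_id = sample_id,
    inputs = list(fq1 = fq1, fq2 = fq2, fasta = fasta, config = config),
    config = list(qc = unclass(qc), scoring = unclass(scoring),
                  min_overlap = min_overlap),
    tallies = as.list(res$summary$counts),
    nfs_fraction = res$summary$nfs_fraction)
  jsonlite::write_json(report, paste0(prefix, "_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Group comparison run
#'
#' Reads a two-column group file (`sample`, `group` with levels `A` and
#' `B`), loads each sample's `<sample>_summary.tsv` from `summary_dir`,
#' runs [pairwise_enrichment()] and writes `comparisons.tsv` plus a
#' one-line `verdict.txt` under `out_dir`.
#'
#' @param group_file TSV with columns `sample` and `group`.
#' @param summary_dir directory holding the per-sample summary TSVs.
#' @param out_dir output directory.
#' @param alpha significance level.
#' @param correct Yates continuity correction.
#' @return invisibly, the [pairwise_enrichment()] result.
#' @export
run_compare <- function(group_file, summary_dir, out_dir, alpha = 0.05,
                        correct = FALSE) {
  groups <- read.delim(group_file, colClasses = "character")
  if (!all(c("sample", "group") %in% names(groups))) {
    stop("group file must have columns 'sample' and 'group'")
  }
  paths <- file.path(summary_dir, paste0(groups$sample, "_summary.tsv"))
  missing <- groups$sample[!file.exists(paths)]
  if (length(missing)) {
    stop("no summary found for sample(s): ", paste(missing, collapse = ", "))
  }
  summaries <- lapply(paths, read_summary_tsv)
  ga <- summaries[groups$group == "A"]
  gb <- summaries[groups$group == "B"]
  enr <- pairwise_enrichment(ga, gb, alpha = alpha, correct = correct)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(enr$grid, file.path(out_dir, "comparisons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  verdict <- sprintf(
    "NFS enriched in group A in %d/%d comparisons (%.1f%%) at alpha %g",
    enr$n_significant, enr$n_comparisons, 100 * enr$fraction_significant,
    alpha)
  writeLines(verdict, file.path(out_dir, "verdict.txt"))
  message(verdict)
  invisible(enr)
}
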
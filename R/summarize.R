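#' Summarize pair calls for one sample
#'
#' Tallies window-qualified pairs into wild-type, mutant (split into
#' frameshift and non-frameshift) and discordant, and builds an allele
#' table keyed by the canonical (left-aligned) event set of each mutant
#' pair, with genomic coordinates attached.
#'
#' @param calls list of `pair_call` objects ([apply_window()]).
#' @param reference an [amplicon_reference()].
#' @param sample_id sample label.
#' @param upstream named integer vector of upstream tallies to carry into
#'   the summary (e.g. `n_pairs_input`, `n_pass_qc`, `n_unaligned`,
#'   `n_improper`); optional.
#' @return a `sample_summary` with fields `sample_id`, `counts` (named
#'   integer vector: `n_window`, `n_wt`, `n_mutant`, `n_fs`, `n_nfs`,
#'   `n_discordant`, `n_off_window`, plus any upstream tallies),
#'   `nfs_fraction` (NFS / mutant; `NA` if no mutant pairs) and
#'   `allele_table` (data.frame).
#' @export
summarize_sample <- function(calls, reference, sample_id = "sample",
                             upstream = integer(0)) {
  status <- vapply(calls, function(x) x$status, character(1))
  n_off <- sum(status == "off_window")
  n_wt <- sum(status == "wt")
  n_disc <- sum(status == "discordant")
  mutant <- calls[status == "mutant"]
  frames <- vapply(mutant, classify_frame, character(1))
  n_fs <- sum(frames == "FS")
  n_nfs <- sum(frames == "NFS")
  n_mut <- length(mutant)
  n_window <- n_wt + n_mut + n_disc
  stopifnot(n_fs + n_nfs == n_mut)

  allele_table <- data.frame(allele = character(0), n_pairs = integer(0),
                             net_indel = integer(0), frame = character(0),
                             contig = character(0), genomic = character(0))
  if (n_mut > 0L) {
    keys <- vapply(mutant, function(x) events_key(x$events), character(1))
    for (k in unique(keys)) {
      sel <- which(keys == k)
      x <- mutant[[sel[1]]]
      gdesc <- vapply(x$events, function(e) {
        g <- to_genomic(e, reference)
        paste0(g$kind, ":", g$contig, ":", g$genomic_pos, ":", g$length,
               if (g$kind == "ins") paste0(":", g$inserted_seq) else "")
      }, character(1))
      allele_table <- rbind(allele_table, data.frame(
        allele = k, n_pairs = length(sel), net_indel = x$net_indel,
        frame = classify_frame(x), contig = reference$genomic_contig,
        genomic = paste(sort(gdesc), collapse = ";")))
    }
    allele_table <- allele_table[order(-allele_table$n_pairs,
                                       allele_table$allele), , drop = FALSE]
    rownames(allele_table) <- NULL
  }

  counts <- c(upstream,
              n_window = n_window, n_wt = n_wt, n_mutant = n_mut,
              n_fs = n_fs, n_nfs = n_nfs, n_discordant = n_disc,
              n_off_window = n_off)
  structure(list(sample_id = sample_id,
                 counts = counts,
                 nfs_fraction = if (n_mut > 0L) n_nfs / n_mut else NA_real_,
                 allele_table = allele_table),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("sample_summary '", x$sample_id, "'\n", sep = "")
  print(x$counts)
  if (!is.na(x$nfs_fraction)) {
    cat(sprintf("NFS fraction among mutant pairs: %.4f\n", x$nfs_fraction))
  }
  if (nrow(x$allele_table)) {
    cat("top alleles:\n")
    print(head(x$allele_table, 5))
  }
  invisible(x)
}

#' Run the per-sample calling pipeline in memory
#'
#' Chains QC ([qc_pairs()]), pair alignment ([align_pair()]), event
#' extraction, mate reconciliation and window summarization for one
#' sample, asserting read-pair conservation across all stages:
#' input = QC-dropped + unaligned + improper + off-window + wt + mutant
#' + discordant.
#'
#' @param pairs a [read_pairs()] object.
#' @param reference an [amplicon_reference()].
#' @param sample_id sample label.
#' @param qc a [qc_params()].
#' @param scoring an [align_scoring()].
#' @param window a [window_of()] spec (default: from `reference`).
#' @param max_fragment_span maximum proper-pair reference span.
#' @return list with `summary` (a [summarize_sample()] result), `calls`
#'   (per-pair status data.frame) and `report` (named tallies).
#' @export
call_sample <- function(pairs, reference, sample_id = "sample",
                        qc = qc_params(), scoring = align_scoring(),
                        window = window_of(reference),
                        max_fragment_span = nchar(reference$sequence) + 50L) {
  stopifnot(inherits(pairs, "read_pairs"),
            inherits(reference, "amplicon_reference"))
  n_input <- length(pairs)
  qcres <- qc_pairs(pairs, qc)
  kept <- qcres$pairs
  index <- build_index(reference)

  n_unaligned <- 0L
  n_improper <- 0L
  calls <- list()
  call_status <- character(length(kept))
  for (i in seq_len(length(kept))) {
    ap <- align_pair(kept$seq1[i], kept$seq2[i], index, reference, scoring,
                     max_fragment_span)
    if (ap$status != "ok") {
      if (ap$reason == "mate_unaligned") n_unaligned <- n_unaligned + 1L
      else n_improper <- n_improper + 1L
      call_status[i] <- ap$reason
      next
    }
    e1 <- extract_events(ap$aln1, reference)
    e2 <- extract_events(ap$aln2, reference)
    recon <- reconcile_pair(ap$aln1, ap$aln2, e1, e2, reference)
    pc <- apply_window(recon, ap$aln1, ap$aln2, window)
    calls[[length(calls) + 1L]] <- pc
    call_status[i] <- pc$status
  }

  upstream <- c(n_pairs_input = n_input,
                n_qc_short = unname(qcres$report["n_short"]),
                n_qc_low_quality = unname(qcres$report["n_low_quality"]),
                n_pass_qc = unname(qcres$report["n_kept"]),
                n_unaligned = n_unaligned,
                n_improper = n_improper)
  summary <- summarize_sample(calls, reference, sample_id, upstream)

  cnt <- summary$counts
  stopifnot(cnt[["n_pairs_input"]] ==
              cnt[["n_qc_short"]] + cnt[["n_qc_low_quality"]] +
              cnt[["n_unaligned"]] + cnt[["n_improper"]] +
              cnt[["n_off_window"]] + cnt[["n_wt"]] + cnt[["n_mutant"]] +
              cnt[["n_discordant"]])

  list(summary = summary,
       calls = data.frame(id = kept$id, status = call_status),
       report = cnt)
}

#' Write a sample summary as TSV files
#'
#' Emits `<prefix>_summary.tsv` (one row per tally, plus the NFS
#' fraction) and `<prefix>_alleles.tsv` (the allele table).
#'
#' @param summary a `sample_summary`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_summary_tsv <- function(summary, prefix) {
  stopifnot(inherits(summary, "sample_summary"))
  f1 <- paste0(prefix, "_summary.tsv")
  df <- data.frame(field = c("sample_id", names(summary$counts),
                             "nfs_fraction"),
                   value = c(summary$sample_id,
                             as.character(summary$counts),
                             as.character(summary$nfs_fraction)))
  write.table(df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- paste0(prefix, "_alleles.tsv")
  write.table(summary$allele_table, f2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read back a summary TSV written by [write_summary_tsv()]
#'
#' Recovers the fields needed downstream (tallies and NFS/FS counts);
#' used by the group-comparison command.
#'
#' @param path a `*_summary.tsv` file.
#' @return a list with `sample_id` and `counts`.
#' @export
read_summary_tsv <- function(path) {
  df <- read.delim(path, colClasses = "character")
  vals <- setNames(df$value, df$field)
  counts <- suppressWarnings(vapply(vals[setdiff(names(vals),
                                                 c("sample_id",
                                                   "nfs_fraction"))],
                                    as.integer, integer(1)))
  list(sample_id = unname(vals[["sample_id"]]), counts = counts)
}

#' Write mutant alleles as a minimal VCF
#'
#' One record per distinct event across the allele table, VCF 4.2
#' conventions (insertions and deletions are anchored on the preceding
#' reference base), with `COUNT` (supporting pair count, summed over
#' alleles containing the event) and `FRAME` info tags.
#'
#' @param summary a `sample_summary`.
#' @param reference the [amplicon_reference()] used for calling.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(summary, reference, path) {
  stopifnot(inherits(summary, "sample_summary"))
  refseq <- reference$sequence
  off <- reference$genomic_offset
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", reference$genomic_contig, ">"),
             "##INFO=<ID=COUNT,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
             "##INFO=<ID=FRAME,Number=1,Type=String,Description=\"FS or NFS of the carrying allele\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  at <- summary$allele_table
  if (nrow(at)) {
    for (i in seq_len(nrow(at))) {
      for (ev in strsplit(at$genomic[i], ";", fixed = TRUE)[[1]]) {
        p <- strsplit(ev, ":", fixed = TRUE)[[1]]
        kind <- p[1]; contig <- p[2]
        gpos <- as.integer(p[3]); len <- as.integer(p[4])
        local <- gpos - off + 1L
        if (kind == "del") {
          pos <- local - 1L
          if (pos < 1L) next  # deletion at the amplicon edge: unanchorable
          ref <- substr(refseq, pos, pos + len)
          alt <- substr(refseq, pos, pos)
        } else {
          pos <- local
          if (pos < 1L) next
          ref <- substr(refseq, pos, pos)
          alt <- paste0(ref, p[5])
        }
        lines <- c(lines, paste(contig, off + pos - 1L, ".", ref, alt, ".",
                                "PASS",
                                paste0("COUNT=", at$n_pairs[i],
                                       ";FRAME=", at$frame[i]),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
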
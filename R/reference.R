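#' Amplicon reference locus
#'
#' Describes the PCR amplicon that reads are aligned against: the amplicon
#' sequence itself (target locus supplemented with short genomic flanks,
#' 10 bp by default), the sgRNA (guide) and PAM intervals on it, the guide
#' strand, and the genomic coordinate of the amplicon's first base so that
#' calls can be reported in genomic space.
#'
#' The guide and PAM are located on the amplicon by exact match at
#' construction time: for a `+` strand guide the PAM must sit immediately
#' 3' of the guide on the amplicon; for a `-` strand guide the reverse
#' complements of both are located, with the PAM immediately 5' of the
#' guide match in amplicon coordinates. All intervals are 1-based and
#' inclusive, following the R/Bioconductor convention.
#'
#' @param sequence character scalar, amplicon sequence over `{A,C,G,T,N}`.
#' @param guide_seq character scalar, sgRNA protospacer (typically 20 nt),
#'   written 5'->3' on its own strand.
#' @param pam_seq character scalar, PAM (e.g. `"AGG"`), 5'->3' on the guide
#'   strand.
#' @param guide_strand `"+"` or `"-"`: strand of the amplicon the guide
#'   matches.
#' @param locus_id character label for the locus.
#' @param genomic_contig contig/chromosome name for genomic reporting.
#' @param genomic_offset 1-based genomic coordinate of the first amplicon
#'   base.
#' @param flank_len length in bp of the genomic flanks included in
#'   `sequence` (bookkeeping only; default 10).
#' @param frame_offset codon phase (0, 1 or 2) of the first guide base;
#'   reporting only.
#' @return an object of class `amplicon_reference` with fields
#'   `sequence`, `guide_interval`, `pam_interval` (both `c(start, end)`,
#'   1-based inclusive), `guide_strand`, `locus_id`, `genomic_contig`,
#'   `genomic_offset`, `flank_len`, `frame_offset`.
#' @examples
#' ref <- amplicon_reference(
#'   sequence = paste0(strrep("A", 15), "GGCTGATCCAGTACGTCGAT", "TGG",
#'                     strrep("C", 15)),
#'   guide_seq = "GGCTGATCCAGTACGTCGAT", pam_seq = "TGG")
#' ref$guide_interval
#' @export
amplicon_reference <- function(sequence, guide_seq, pam_seq,
                               guide_strand = "+",
                               locus_id = "amplicon",
                               genomic_contig = ".",
                               genomic_offset = 1L,
                               flank_len = 10L,
                               frame_offset = 0L) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("amplicon sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("amplicon sequence contains characters outside {A,C,G,T,N}")
  }
  if (!guide_strand %in% c("+", "-")) stop("guide_strand must be '+' or '-'")
  guide_seq <- toupper(guide_seq)
  pam_seq <- toupper(pam_seq)
  if (nchar(sequence) <= 2L * flank_len) {
    stop("amplicon sequence must be longer than twice the flank length")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")

  gsearch <- if (guide_strand == "+") guide_seq else revcomp(guide_seq)
  gpos <- locate_naive(sequence, gsearch)
  if (length(gpos) == 0L) {
    stop("guide sequence not found on the amplicon (strand ", guide_strand, ")")
  }
  if (length(gpos) > 1L) {
    stop("guide sequence matches the amplicon more than once")
  }
  guide_interval <- c(gpos, gpos + nchar(gsearch) - 1L)

  if (guide_strand == "+") {
    pam_interval <- c(guide_interval[2] + 1L,
                      guide_interval[2] + nchar(pam_seq))
    pam_found <- substr(sequence, pam_interval[1], pam_interval[2])
    pam_expect <- pam_seq
  } else {
    pam_interval <- c(guide_interval[1] - nchar(pam_seq),
                      guide_interval[1] - 1L)
    pam_found <- substr(sequence, max(1L, pam_interval[1]), pam_interval[2])
    pam_expect <- revcomp(pam_seq)
  }
  if (pam_interval[1] < 1L || pam_interval[2] > nchar(sequence) ||
      pam_found != pam_expect) {
    stop("PAM '", pam_seq, "' is not adjacent to the guide on strand ",
         guide_strand, " (found '", pam_found, "')")
  }

  structure(list(
    locus_id = locus_id,
    sequence = sequence,
    flank_len = as.integer(flank_len),
    genomic_contig = genomic_contig,
    genomic_offset = as.integer(genomic_offset),
    guide_interval = as.integer(guide_interval),
    pam_interval = as.integer(pam_interval),
    guide_strand = guide_strand,
    frame_offset = as.integer(frame_offset)
  ), class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("amplicon_reference '", x$locus_id, "' (", nchar(x$sequence), " bp)\n",
      sep = "")
  cat("  contig ", x$genomic_contig, " offset ", x$genomic_offset, "\n",
      sep = "")
  cat("  guide [", x$guide_interval[1], ",", x$guide_interval[2], "] (",
      x$guide_strand, "), PAM [", x$pam_interval[1], ",", x$pam_interval[2],
      "]\n", sep = "")
  invisible(x)
}

#' Load an amplicon reference from FASTA plus a config file
#'
#' The FASTA must contain a single record. The config is a DCF
#' (`key: value`) file with keys `locus_id`, `genomic_contig`,
#' `genomic_offset`, `flank_len`, `guide_seq`, `pam_seq`, `guide_strand`
#' and `frame_offset`; missing optional keys fall back to the
#' [amplicon_reference()] defaults. The guide and PAM are located in the
#' sequence by exact match at load time.
#'
#' @param fasta path to a single-record FASTA file.
#' @param config path to the DCF config file.
#' @return an [amplicon_reference()] object.
#' @export
load_reference <- function(fasta, config) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(seqs))
  }
  cfg <- read.dcf(config)
  cfg <- setNames(as.list(cfg[1, ]), colnames(cfg))
  need <- c("guide_seq", "pam_seq")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("reference config is missing required keys: ",
         paste(missing, collapse = ", "))
  }
  amplicon_reference(
    sequence = as.character(seqs[[1]]),
    guide_seq = cfg$guide_seq,
    pam_seq = cfg$pam_seq,
    guide_strand = cfg$guide_strand %||% "+",
    locus_id = cfg$locus_id %||% names(seqs)[1],
    genomic_contig = cfg$genomic_contig %||% ".",
    genomic_offset = as.integer(cfg$genomic_offset %||% 1L),
    flank_len = as.integer(cfg$flank_len %||% 10L),
    frame_offset = as.integer(cfg$frame_offset %||% 0L)
  )
}

#' Write an amplicon reference as FASTA plus config
#'
#' Inverse of [load_reference()]; used by the simulator to emit
#' self-contained fixture bundles.
#'
#' @param reference an [amplicon_reference()].
#' @param fasta,config output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta, config) {
  stopifnot(inherits(reference, "amplicon_reference"))
  seqs <- Biostrings::DNAStringSet(reference$sequence)
  names(seqs) <- reference$locus_id
  Biostrings::writeXStringSet(seqs, fasta)
  gi <- reference$guide_interval
  guide_on_amp <- substr(reference$sequence, gi[1], gi[2])
  pi <- reference$pam_interval
  pam_on_amp <- substr(reference$sequence, pi[1], pi[2])
  if (reference$guide_strand == "-") {
    guide_on_amp <- revcomp(guide_on_amp)
    pam_on_amp <- revcomp(pam_on_amp)
  }
  m <- matrix(c(reference$locus_id, reference$genomic_contig,
                reference$genomic_offset, reference$flank_len,
                guide_on_amp, pam_on_amp, reference$guide_strand,
                reference$frame_offset), nrow = 1)
  colnames(m) <- c("locus_id", "genomic_contig", "genomic_offset",
                   "flank_len", "guide_seq", "pam_seq", "guide_strand",
                   "frame_offset")
  write.dcf(m, config)
  invisible(c(fasta, config))
}

#' Summarization window over the sgRNA and PAM
#'
#' The editing-outcome window is the union of the guide and PAM intervals;
#' a read pair contributes to the window summary only if at least one mate
#' overlaps this interval by at least `min_overlap` reference bases
#' (default 20).
#'
#' @param reference an [amplicon_reference()].
#' @param min_overlap minimum reference overlap in bp for a read alignment
#'   to qualify.
#' @return a `window_spec` list with fields `start`, `end` (1-based
#'   inclusive) and `min_overlap`.
#' @export
window_of <- function(reference, min_overlap = 20L) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  gi <- reference$guide_interval
  pi <- reference$pam_interval
  # adjacency was validated at construction; the union must be contiguous
  if (max(gi[1], pi[1]) != min(gi[2], pi[2]) + 1L) {
    stop("guide and PAM intervals are not adjacent")
  }
  structure(list(start = min(gi[1], pi[1]),
                 end = max(gi[2], pi[2]),
                 min_overlap = as.integer(min_overlap)),
            class = "window_spec")
}

#' Translate an amplicon-local indel event to genomic coordinates
#'
#' @param event an `indel_event` (see [extract_events()]).
#' @param reference an [amplicon_reference()].
#' @return the event with `contig` and 1-based `genomic_pos` fields added.
#'   For deletions `genomic_pos` is the first deleted base; for insertions
#'   it is the base after which the sequence is inserted.
#' @export
to_genomic <- function(event, reference) {
  stopifnot(inherits(reference, "amplicon_reference"))
  pos <- event$ref_pos
  n <- nchar(reference$sequence)
  if (event$kind == "del") {
    if (pos < 1L || pos + event$length - 1L > n) {
      stop("deletion event lies outside the reference")
    }
  } else {
    if (pos < 0L || pos > n) stop("insertion event lies outside the reference")
  }
  event$contig <- reference$genomic_contig
  event$genomic_pos <- reference$genomic_offset + pos - 1L
  event
}
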
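#' Quality-control parameters
#'
#' Defaults reproduce the published analysis settings for 150 bp
#' paired-end MiSeq amplicon reads: truncate to 120 bp to drop the noisy
#' 3' tail, clip Nextera adapter read-through, retain only pairs with both
#' mates strictly longer than 15 bp, and drop pairs where either mate has
#' 50% or more of its bases below Q30.
#'
#' @param trim_to 3' truncation length in bp.
#' @param adapters character vector of adapter sequences searched as
#'   read-suffix/adapter-prefix overlaps.
#' @param min_len_exclusive reads of this length or shorter fail the
#'   length filter (strict inequality: 16 bp is the minimum retained).
#' @param q_threshold Phred threshold; a base with quality strictly below
#'   this counts as low quality. `N` bases always count as low quality.
#' @param max_lowq_fraction a read whose low-quality fraction is greater
#'   than or equal to this is dropped.
#' @return a `qc_params` list.
#' @export
qc_params <- function(trim_to = 120L,
                      adapters = nextera_adapters(),
                      min_len_exclusive = 15L,
                      q_threshold = 30L,
                      max_lowq_fraction = 0.5) {
  if (trim_to <= min_len_exclusive) {
    stop("trim_to must exceed min_len_exclusive")
  }
  if (max_lowq_fraction < 0 || max_lowq_fraction > 1) {
    stop("max_lowq_fraction must lie in [0, 1]")
  }
  structure(list(trim_to = as.integer(trim_to),
                 adapters = toupper(adapters),
                 min_len_exclusive = as.integer(min_len_exclusive),
                 q_threshold = as.integer(q_threshold),
                 max_lowq_fraction = max_lowq_fraction),
            class = "qc_params")
}

#' Nextera read-through adapter sequences
#'
#' The Tn5 mosaic-end sequence observed at the 3' end of a read when the
#' insert is shorter than the read length.
#'
#' @return character vector of adapter sequences.
#' @export
nextera_adapters <- function() c("CTGTCTCTTATACACATCT")

#' Truncate reads at the 3' end
#'
#' Keeps the 5' end; reads already at or below `trim_to` are unchanged,
#' so the operation is idempotent and never lengthens a read.
#'
#' @param pairs a [read_pairs()] object.
#' @param trim_to target length in bp.
#' @return the truncated [read_pairs()].
#' @export
trim_3prime <- function(pairs, trim_to = 120L) {
  stopifnot(inherits(pairs, "read_pairs"), trim_to >= 1L)
  read_pairs(pairs$id,
             substr(pairs$seq1, 1L, trim_to), substr(pairs$qual1, 1L, trim_to),
             substr(pairs$seq2, 1L, trim_to), substr(pairs$qual2, 1L, trim_to))
}

# clip the longest read suffix that matches an adapter prefix with
# overlap >= 5 and at most one mismatch per 10 overlapping bases;
# returns the clip length (0 = no hit)
.adapter_clip_len <- function(seq, adapters) {
  len <- nchar(seq)
  if (len < 5L) return(0L)
  rv <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (ad in adapters) {
    av <- strsplit(ad, "", fixed = TRUE)[[1]]
    maxov <- min(len, length(av))
    if (maxov < 5L) next
    for (ov in seq(maxov, 5L)) {
      mism <- sum(rv[(len - ov + 1L):len] != av[seq_len(ov)])
      if (mism <= ov %/% 10L) return(ov)
    }
  }
  0L
}

#' Clip adapter read-through from the 3' end
#'
#' Removes the longest read suffix matching a prefix of any adapter, with
#' a minimum overlap of 5 bp and at most one mismatch allowed per 10
#' overlapping bases. 5' content is never touched.
#'
#' @param pairs a [read_pairs()] object.
#' @param adapters adapter sequences (default [nextera_adapters()]).
#' @return the clipped [read_pairs()].
#' @export
clip_adapters <- function(pairs, adapters = nextera_adapters()) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (length(adapters) == 0L) stop("adapters must be non-empty")
  adapters <- toupper(adapters)
  clip <- function(seqs, quals) {
    cl <- vapply(seqs, .adapter_clip_len, integer(1), adapters = adapters,
                 USE.NAMES = FALSE)
    keep <- nchar(seqs) - cl
    list(seq = substr(seqs, 1L, keep), qual = substr(quals, 1L, keep))
  }
  a <- clip(pairs$seq1, pairs$qual1)
  b <- clip(pairs$seq2, pairs$qual2)
  read_pairs(pairs$id, a$seq, a$qual, b$seq, b$qual)
}

# fraction of bases that are N or below the Phred threshold
.lowq_fraction <- function(seq, qual, q_threshold) {
  n <- nchar(seq)
  if (n == 0L) return(1)
  q <- phred_ints(qual)
  isn <- strsplit(seq, "", fixed = TRUE)[[1]] == "N"
  sum(q < q_threshold | isn) / n
}

#' Pair-level length and quality filter
#'
#' A pair is dropped as `"short"` if either mate's length is less than or
#' equal to `min_len_exclusive` (15 by default: a 15 bp read fails, a
#' 16 bp read passes), and as `"low_quality"` if either mate has at least
#' `max_lowq_fraction` of its bases below `q_threshold` (`N` bases always
#' count as low quality). Length is tested first, so a pair failing both
#' is tallied as `"short"`.
#'
#' @param pairs a [read_pairs()] object (post trim/clip).
#' @param params a [qc_params()] object.
#' @return list with `pairs` (the retained [read_pairs()]), `reason`
#'   (per-input-pair factor: `kept`, `short`, `low_quality`) and `report`
#'   (named counts, conserving the input total).
#' @export
filter_pairs <- function(pairs, params = qc_params()) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(params, "qc_params"))
  n <- length(pairs)
  reason <- rep("kept", n)
  short <- nchar(pairs$seq1) <= params$min_len_exclusive |
    nchar(pairs$seq2) <= params$min_len_exclusive
  reason[short] <- "short"
  todo <- which(!short)
  if (length(todo)) {
    f1 <- mapply(.lowq_fraction, pairs$seq1[todo], pairs$qual1[todo],
                 MoreArgs = list(q_threshold = params$q_threshold),
                 USE.NAMES = FALSE)
    f2 <- mapply(.lowq_fraction, pairs$seq2[todo], pairs$qual2[todo],
                 MoreArgs = list(q_threshold = params$q_threshold),
                 USE.NAMES = FALSE)
    lowq <- pmax(f1, f2) >= params$max_lowq_fraction
    reason[todo[lowq]] <- "low_quality"
  }
  report <- c(n_input = n,
              n_kept = sum(reason == "kept"),
              n_short = sum(reason == "short"),
              n_low_quality = sum(reason == "low_quality"))
  stopifnot(report[["n_kept"]] + report[["n_short"]] +
              report[["n_low_quality"]] == n)
  list(pairs = pairs[reason == "kept"], reason = reason, report = report)
}

#' Full QC chain: trim, clip, filter
#'
#' Applies [trim_3prime()], [clip_adapters()] and [filter_pairs()] in that
#' fixed order. Re-running the chain on its own output is a no-op.
#'
#' @inheritParams filter_pairs
#' @return as [filter_pairs()].
#' @export
qc_pairs <- function(pairs, params = qc_params()) {
  pairs <- trim_3prime(pairs, params$trim_to)
  pairs <- clip_adapters(pairs, params$adapters)
  filter_pairs(pairs, params)
}
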
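#' Alignment scoring and anchoring parameters
#'
#' Scoring is chosen for sensitive detection of both short and long
#' insertions and deletions: a cheap per-base gap extension keeps a
#' single long deletion (e.g. 95 bp) preferable to many mismatches, while
#' up to four mismatches are tolerated per accepted read. The mismatch
#' cap is enforced after the optimal alignment is computed, not inside
#' the dynamic program.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0); `N` against anything scores as a
#'   mismatch.
#' @param gap_open score of a gap's first base (< 0).
#' @param gap_extend score of each further gap base; a length-L gap
#'   contributes `gap_open + (L-1) * gap_extend`.
#' @param max_mismatches maximum mismatches in an accepted alignment.
#' @param anchor_k length of the exact terminal anchor k-mers.
#' @param max_softclip maximum bases soft-clipped at either read end
#'   while searching for an anchor.
#' @return an `align_scoring` list.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L,
                          gap_open = -6L, gap_extend = -1L,
                          max_mismatches = 4L,
                          anchor_k = 10L, max_softclip = 10L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= gap_extend, gap_extend < 0,
            max_mismatches >= 0, anchor_k >= 1, max_softclip >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_mismatches = as.integer(max_mismatches),
                 anchor_k = as.integer(anchor_k),
                 max_softclip = as.integer(max_softclip)),
            class = "align_scoring")
}

#' Terminal anchor candidates for one read
#'
#' For each soft-clip offset `s = 0, 1, ..., max_softclip` (unit-step
#' sliding window), the `anchor_k`-mer starting `s` bases in from the
#' read end is looked up in the suffix array; every exact hit becomes a
#' candidate. Candidates are returned in ascending soft-clip order.
#'
#' @param seq read sequence (already in the orientation being tested).
#' @param index a `suffix_array` over the reference.
#' @param scoring an [align_scoring()].
#' @param end `"left"` or `"right"` read end.
#' @return data.frame with columns `softclip`, `read_start` (1-based
#'   start of the anchored k-mer in the read) and `ref_pos` (1-based
#'   reference hit); zero rows if no anchor exists.
#' @export
find_terminal_anchors <- function(seq, index, scoring, end = c("left", "right")) {
  end <- match.arg(end)
  k <- scoring$anchor_k
  len <- nchar(seq)
  softclip <- read_start <- ref_pos <- integer(0)
  for (s in 0:scoring$max_softclip) {
    rs <- if (end == "left") s + 1L else len - s - k + 1L
    if (rs < 1L || rs + k - 1L > len) break
    hits <- locate_exact(index, substr(seq, rs, rs + k - 1L))
    if (length(hits)) {
      softclip <- c(softclip, rep.int(s, length(hits)))
      read_start <- c(read_start, rep.int(rs, length(hits)))
      ref_pos <- c(ref_pos, hits)
    }
  }
  data.frame(softclip = softclip, read_start = read_start, ref_pos = ref_pos)
}

#' Select the maximally distanced anchor pair
#'
#' Enumerates all consistent (left, right) candidate combinations — left
#' reference position not beyond the right one — and returns them ordered
#' by decreasing reference span (right anchor end minus left anchor
#' start), breaking ties by smaller total soft-clip, then leftmost left
#' anchor.
#'
#' @param left,right candidate data.frames from [find_terminal_anchors()].
#' @param anchor_k anchor k-mer length.
#' @return data.frame of consistent pairs (columns `l_softclip`,
#'   `l_read_start`, `l_ref`, `r_softclip`, `r_read_start`, `r_ref`,
#'   `span`), best first; zero rows if no consistent pair exists.
#' @export
select_anchor_pair <- function(left, right, anchor_k = 10L) {
  if (nrow(left) == 0L || nrow(right) == 0L) {
    return(data.frame())
  }
  nl <- nrow(left); nr <- nrow(right)
  li <- rep(seq_len(nl), times = nr)
  ri <- rep(seq_len(nr), each = nl)
  ok <- left$ref_pos[li] <= right$ref_pos[ri] &
    left$read_start[li] <= right$read_start[ri]
  li <- li[ok]; ri <- ri[ok]
  if (length(li) == 0L) return(data.frame())
  span <- right$ref_pos[ri] + anchor_k - left$ref_pos[li]
  o <- order(-span, left$softclip[li] + right$softclip[ri],
             left$ref_pos[li], right$ref_pos[ri])
  data.frame(l_softclip = left$softclip[li], l_read_start = left$read_start[li],
             l_ref = left$ref_pos[li],
             r_softclip = right$softclip[ri],
             r_read_start = right$read_start[ri],
             r_ref = right$ref_pos[ri], span = span)[o, , drop = FALSE]
}

#' Affine-gap alignment of a read core against a reference segment
#'
#' Optimal global (endpoint-pinned) Gotoh dynamic-programming alignment
#' of the inter-anchor read segment against the inter-anchor reference
#' segment. Ties prefer fewer gap openings; indel placement is further
#' left-normalised when events are extracted.
#'
#' @param read_core read sequence between (and including) the anchored
#'   termini.
#' @param ref_segment reference sequence spanning the anchors.
#' @param scoring an [align_scoring()].
#' @return list with `score`, `ops` (data.frame of CIGAR-style runs:
#'   `op` in `M`/`I`/`D`, `len`) and `n_mismatch`.
#' @export
smith_waterman_segment <- function(read_core, ref_segment,
                                   scoring = align_scoring()) {
  r <- .gotoh_align(read_core, ref_segment, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  list(score = r$score,
       ops = data.frame(op = as.character(r$op), len = as.integer(r$len)),
       n_mismatch = r$n_mismatch)
}

# attempt alignment of `seq` (already oriented) against the reference;
# returns an alignment record or list(reason = ...)
.align_one_strand <- function(seq, strand, index, refseq, scoring) {
  len <- nchar(seq)
  if (len < scoring$anchor_k) return(list(reason = "no_anchor"))
  left <- find_terminal_anchors(seq, index, scoring, "left")
  right <- find_terminal_anchors(seq, index, scoring, "right")
  if (nrow(left) == 0L || nrow(right) == 0L) {
    return(list(reason = "no_anchor"))
  }
  cand <- select_anchor_pair(left, right, scoring$anchor_k)
  if (nrow(cand) == 0L) return(list(reason = "anchor_conflict"))
  cand <- cand[cand$span == cand$span[1], , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(cand))) {
    sL <- cand$l_softclip[i]; sR <- cand$r_softclip[i]
    core <- substr(seq, sL + 1L, len - sR)
    ref_start <- cand$l_ref[i]
    ref_end <- cand$r_ref[i] + scoring$anchor_k - 1L
    seg <- substr(refseq, ref_start, ref_end)
    a <- smith_waterman_segment(core, seg, scoring)
    if (is.null(best) || a$score > best$score) {
      best <- list(strand = strand, ref_start = ref_start, ref_end = ref_end,
                   ops = a$ops, score = a$score, n_mismatch = a$n_mismatch,
                   softclip_left = sL, softclip_right = sR, seq = seq)
    }
  }
  # length bookkeeping must hold for every alignment we emit
  stopifnot(
    sum(best$ops$len[best$ops$op %in% c("M", "I")]) +
      best$softclip_left + best$softclip_right == len,
    sum(best$ops$len[best$ops$op %in% c("M", "D")]) ==
      best$ref_end - best$ref_start + 1L)
  best
}

#' Anchor and align a single read
#'
#' Both the read and its reverse complement are anchored against the
#' reference; for each strand the maximally distanced consistent anchor
#' pair is aligned by [smith_waterman_segment()] and the highest-scoring
#' alignment across strands is selected. Alignments with more than
#' `max_mismatches` mismatches are rejected.
#'
#' @param seq read sequence.
#' @param index `suffix_array` over the reference.
#' @param reference an [amplicon_reference()].
#' @param scoring an [align_scoring()].
#' @return list with `status = "aligned"` and `aln` (fields `strand`,
#'   `ref_start`, `ref_end` — 1-based inclusive —, `ops`, `score`,
#'   `n_mismatch`, `softclip_left`, `softclip_right`, `seq` in aligned
#'   orientation), or `status = "unaligned"` with `reason` one of
#'   `no_anchor`, `anchor_conflict`, `too_many_mismatches`.
#' @export
align_read <- function(seq, index, reference, scoring = align_scoring()) {
  seq <- toupper(seq)
  fw <- .align_one_strand(seq, "+", index, reference$sequence, scoring)
  rv <- .align_one_strand(revcomp(seq), "-", index, reference$sequence,
                          scoring)
  alns <- Filter(function(x) is.null(x$reason), list(fw, rv))
  if (length(alns) == 0L) {
    reasons <- c(fw$reason, rv$reason)
    reason <- if ("anchor_conflict" %in% reasons) "anchor_conflict" else
      "no_anchor"
    return(list(status = "unaligned", reason = reason))
  }
  best <- alns[[1]]
  if (length(alns) == 2L && alns[[2]]$score > best$score) best <- alns[[2]]
  if (best$n_mismatch > scoring$max_mismatches) {
    return(list(status = "unaligned", reason = "too_many_mismatches"))
  }
  list(status = "aligned", aln = best)
}

#' Align both mates of a pair and check orientation
#'
#' Both mates must align, on opposite strands, facing inward (the
#' plus-strand mate leftmost on the reference), with the implied fragment
#' span at most `max_fragment_span` (default: amplicon length + 50 bp).
#'
#' @param seq1,seq2 mate sequences.
#' @param index,reference,scoring as in [align_read()].
#' @param max_fragment_span maximum reference span of a proper pair.
#' @return list with `status = "ok"` plus `aln1`, `aln2`, or
#'   `status = "rejected"` with `reason` `mate_unaligned` or
#'   `improper_orientation`.
#' @export
align_pair <- function(seq1, seq2, index, reference,
                       scoring = align_scoring(),
                       max_fragment_span = nchar(reference$sequence) + 50L) {
  a1 <- align_read(seq1, index, reference, scoring)
  a2 <- align_read(seq2, index, reference, scoring)
  if (a1$status != "aligned" || a2$status != "aligned") {
    return(list(status = "rejected", reason = "mate_unaligned"))
  }
  x <- a1$aln; y <- a2$aln
  if (x$strand == y$strand) {
    return(list(status = "rejected", reason = "improper_orientation"))
  }
  p <- if (x$strand == "+") x else y
  m <- if (x$strand == "+") y else x
  span <- m$ref_end - p$ref_start + 1L
  if (p$ref_start > m$ref_start || span < 1L || span > max_fragment_span) {
    return(list(status = "rejected", reason = "improper_orientation"))
  }
  list(status = "ok", aln1 = x, aln2 = y)
}
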
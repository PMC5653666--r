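#' Indel event
#'
#' A single insertion or deletion in amplicon coordinates, stored in
#' left-aligned canonical form so identical alleles observed in different
#' reads compare equal.
#'
#' For a deletion, `ref_pos` is the 1-based position of the first deleted
#' base; for an insertion, `ref_pos` is the 1-based position of the base
#' *after which* the sequence is inserted (0 = before the first base).
#'
#' @param kind `"ins"` or `"del"`.
#' @param ref_pos 1-based position (see above).
#' @param length event length in bp (>= 1).
#' @param inserted_seq inserted sequence (insertions only).
#' @return an `indel_event` list.
#' @export
indel_event <- function(kind, ref_pos, length, inserted_seq = NULL) {
  kind <- match.arg(kind, c("ins", "del"))
  stopifnot(length >= 1L)
  if (kind == "ins") {
    stopifnot(!is.null(inserted_seq), nchar(inserted_seq) == length)
  } else {
    inserted_seq <- NULL
  }
  structure(list(kind = kind, ref_pos = as.integer(ref_pos),
                 length = as.integer(length), inserted_seq = inserted_seq),
            class = "indel_event")
}

# canonical string key of an event (and of an event set)
event_key <- function(e) {
  if (e$kind == "del") paste0("del@", e$ref_pos, "-", e$length)
  else paste0("ins@", e$ref_pos, "+", e$length, ":", e$inserted_seq)
}

events_key <- function(events) {
  if (length(events) == 0L) return("WT")
  paste(sort(vapply(events, event_key, character(1))), collapse = ";")
}

# left-normalise an event against the reference sequence
left_align_event <- function(event, refseq) {
  ch <- function(i) substr(refseq, i, i)
  if (event$kind == "del") {
    p <- event$ref_pos; L <- event$length
    while (p > 1L && ch(p - 1L) == ch(p + L - 1L)) p <- p - 1L
    event$ref_pos <- p
  } else {
    q <- event$ref_pos; S <- event$inserted_seq; L <- event$length
    while (q >= 1L && ch(q) == substr(S, L, L)) {
      S <- paste0(substr(S, L, L), substr(S, 1L, L - 1L))
      q <- q - 1L
    }
    event$ref_pos <- q
    event$inserted_seq <- S
  }
  event
}

#' Extract left-aligned indel events from an accepted alignment
#'
#' One event per insertion/deletion run in the alignment; mismatches are
#' never events. Each event is left-normalised against the full
#' reference, so the same allele yields the same event regardless of
#' where the dynamic program placed the gap.
#'
#' @param aln an accepted alignment from [align_read()].
#' @param reference an [amplicon_reference()].
#' @return list of [indel_event()]s (possibly empty).
#' @export
extract_events <- function(aln, reference) {
  refseq <- reference$sequence
  events <- list()
  ref_cur <- aln$ref_start
  read_cur <- aln$softclip_left + 1L
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "M") {
      ref_cur <- ref_cur + len
      read_cur <- read_cur + len
    } else if (op == "D") {
      events[[length(events) + 1L]] <-
        left_align_event(indel_event("del", ref_cur, len), refseq)
      ref_cur <- ref_cur + len
    } else {
      ins <- substr(aln$seq, read_cur, read_cur + len - 1L)
      events[[length(events) + 1L]] <-
        left_align_event(indel_event("ins", ref_cur - 1L, len, ins), refseq)
      read_cur <- read_cur + len
    }
  }
  events
}

# right-normalise an event (rightmost equivalent placement)
right_align_event <- function(event, refseq) {
  n <- nchar(refseq)
  ch <- function(i) substr(refseq, i, i)
  if (event$kind == "del") {
    p <- event$ref_pos; L <- event$length
    while (p + L - 1L < n && ch(p) == ch(p + L)) p <- p + 1L
    event$ref_pos <- p
  } else {
    q <- event$ref_pos; S <- event$inserted_seq; L <- event$length
    while (q + 1L <= n && ch(q + 1L) == substr(S, 1L, 1L)) {
      S <- paste0(substr(S, 2L, L), substr(S, 1L, 1L))
      q <- q + 1L
    }
    event$ref_pos <- q
    event$inserted_seq <- S
  }
  event
}

# is the event observable within the mate's aligned reference span?
# An indel inside a repeat tract is only observable by a read that spans
# the whole tract of equivalent placements plus one flanking base on each
# side; a read ending inside the tract aligns cleanly without the event.
.event_covered <- function(e, aln, refseq) {
  r <- right_align_event(e, refseq)
  if (e$kind == "del") {
    aln$ref_start <= e$ref_pos - 1L &&
      aln$ref_end >= r$ref_pos + r$length
  } else {
    # insertion sits between ref_pos and ref_pos + 1
    aln$ref_start <= e$ref_pos && aln$ref_end >= r$ref_pos + 1L
  }
}

#' Reconcile the two mates of a proper pair
#'
#' An event observable in both mates' reference spans must be reported
#' identically by both mates, otherwise the pair is `discordant`. Events
#' observable in only one mate are accepted from that mate. The accepted
#' events are the de-duplicated union.
#'
#' @param aln1,aln2 accepted mate alignments.
#' @param events1,events2 event lists from [extract_events()].
#' @param reference the [amplicon_reference()] (for repeat-tract
#'   observability).
#' @return list with `status` (`"wt"`, `"mutant"` or `"discordant"`) and
#'   `events` (accepted events; empty unless mutant).
#' @export
reconcile_pair <- function(aln1, aln2, events1, events2, reference) {
  refseq <- reference$sequence
  k1 <- vapply(events1, event_key, character(1))
  k2 <- vapply(events2, event_key, character(1))
  all_events <- c(events1, events2)
  all_keys <- c(k1, k2)
  for (i in seq_along(all_events)) {
    e <- all_events[[i]]
    if (.event_covered(e, aln1, refseq) && .event_covered(e, aln2, refseq)) {
      if (!(all_keys[i] %in% k1) || !(all_keys[i] %in% k2)) {
        return(list(status = "discordant", events = list()))
      }
    }
  }
  keep <- !duplicated(all_keys)
  events <- all_events[keep]
  list(status = if (length(events)) "mutant" else "wt", events = events)
}

#' Apply the sgRNA+PAM summarization window to a reconciled pair
#'
#' A pair qualifies for the window summary only if at least one mate's
#' aligned reference span (deleted reference counts as covered) overlaps
#' the window by at least `window$min_overlap` bases; otherwise the pair
#' is `off_window` and excluded from the tallies. Among qualifying pairs,
#' only events overlapping the window interval count: a qualifying pair
#' whose events all lie outside the window is wild type for the window
#' summary.
#'
#' @param recon result of [reconcile_pair()].
#' @param aln1,aln2 the mate alignments.
#' @param window a [window_of()] spec.
#' @return a `pair_call` list: `status` in `wt`/`mutant`/`discordant`/
#'   `off_window`, `events` (window-overlapping accepted events) and
#'   `net_indel` (insertions minus deletions over those events, bp).
#' @export
apply_window <- function(recon, aln1, aln2, window) {
  ov <- function(aln) {
    max(0L, min(aln$ref_end, window$end) - max(aln$ref_start, window$start) + 1L)
  }
  if (max(ov(aln1), ov(aln2)) < window$min_overlap) {
    return(structure(list(status = "off_window", events = list(),
                          net_indel = 0L), class = "pair_call"))
  }
  if (recon$status == "discordant") {
    return(structure(list(status = "discordant", events = list(),
                          net_indel = 0L), class = "pair_call"))
  }
  in_window <- function(e) {
    if (e$kind == "del") {
      e$ref_pos <= window$end && e$ref_pos + e$length - 1L >= window$start
    } else {
      e$ref_pos >= window$start - 1L && e$ref_pos <= window$end
    }
  }
  wevents <- Filter(in_window, recon$events)
  net <- 0L
  for (e in wevents) {
    net <- net + if (e$kind == "ins") e$length else -e$length
  }
  structure(list(status = if (length(wevents)) "mutant" else "wt",
                 events = wevents, net_indel = as.integer(net)),
            class = "pair_call")
}

#' Frameshift / non-frameshift classification
#'
#' A mutant pair is frameshift (`FS`) when its net indel length over
#' window-overlapping events is not a multiple of 3, non-frameshift
#' (`NFS`) otherwise. A 95 bp deletion (95 mod 3 = 2) is FS; a 3 bp
#' deletion is NFS.
#'
#' @param call a `pair_call` with `status == "mutant"`.
#' @return `"FS"` or `"NFS"`.
#' @export
classify_frame <- function(call) {
  if (call$status != "mutant") {
    stop("classify_frame is defined for mutant pairs only")
  }
  if (call$net_indel %% 3L != 0L) "FS" else "NFS"
}
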
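ref <- test_reference()
refseq <- ref$sequence
win <- window_of(ref)

test_that("events are read off alignments and left-normalised", {
  # single D(1) at reference position 65 (no repeat context by check below)
  aln <- fake_aln(31L, 120L,
                  ops = data.frame(op = c("M", "D", "M"),
                                   len = c(34L, 1L, 55L)),
                  seq = paste0(substr(refseq, 31, 64), substr(refseq, 66, 120)))
  ev <- extract_events(aln, ref)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "del")
  expect_equal(ev[[1]]$length, 1L)
  # left-aligned: the event equals its own left normalisation
  expect_equal(ev[[1]],
               amplicall:::left_align_event(ev[[1]], refseq))

  # deletion inside a homopolymer reports the leftmost shift: all
  # equivalent placements (enumerated naively) collapse to one position
  txt <- paste0("GTC", strrep("A", 6), "CGT")
  r2 <- amplicon_reference(paste0("TTGACCGGTT", txt, "ACGGATCCAA"),
                           guide_seq = "GTCAAAAAAC", pam_seq = "GTA")
  del2 <- indel_event("del", 16L, 2L)  # inside the A-run (positions 14-19)
  canon <- amplicall:::left_align_event(del2, r2$sequence)
  expect_equal(canon$ref_pos, 14L)  # first A of the run
  for (p in 14:18) {  # every in-run placement normalises identically
    expect_equal(amplicall:::left_align_event(indel_event("del", p, 2L),
                                              r2$sequence)$ref_pos, 14L)
  }

  # insertions rotate to their leftmost placement
  insev <- indel_event("ins", 16L, 2L, "AA")  # inside the A-run
  expect_equal(amplicall:::left_align_event(insev, r2$sequence)$ref_pos, 13L)

  # no gap ops -> no events
  expect_length(extract_events(fake_aln(31L, 120L), ref), 0)
})

test_that("mates must agree on events both could observe", {
  # both mates span the event region
  d7 <- indel_event("del", 60L, 7L)
  a1 <- fake_aln(21L, 140L); a2 <- fake_aln(41L, 160L)
  both <- reconcile_pair(a1, a2, list(d7), list(d7), ref)
  expect_equal(both$status, "mutant")
  expect_length(both$events, 1)  # counted once

  # only one mate reports an event both overlap -> discordant
  disc <- reconcile_pair(a1, a2, list(d7), list(), ref)
  expect_equal(disc$status, "discordant")

  # event outside the other mate's span is accepted from one mate
  far <- indel_event("del", 200L, 4L)
  a3 <- fake_aln(150L, 240L)
  one <- reconcile_pair(a1, a3, list(), list(far), ref)
  expect_equal(one$status, "mutant")
  expect_length(one$events, 1)

  # an indel inside a repeat tract is only "observable" by a mate whose
  # span clears the whole tract: mate ending inside the CCC run at the
  # guide 3' end cannot contradict the other mate
  delC <- amplicall:::left_align_event(indel_event("del", 148L, 1L), refseq)
  short <- fake_aln(31L, 149L)   # ends inside the tract
  long <- fake_aln(109L, 229L)
  res <- reconcile_pair(short, long, list(), list(delC), ref)
  expect_equal(res$status, "mutant")
})

test_that("the 20 bp window overlap rule is a strict boundary", {
  # window is [131, 153]; spans overlapping by 19 vs 20 bp
  recon <- list(status = "wt", events = list())
  a19 <- fake_aln(31L, 149L)  # overlap 149-131+1 = 19
  a20 <- fake_aln(31L, 150L)  # overlap 20
  expect_equal(apply_window(recon, a19, a19, win)$status, "off_window")
  expect_equal(apply_window(recon, a20, a20, win)$status, "wt")
  # one qualifying mate suffices
  expect_equal(apply_window(recon, a19, a20, win)$status, "wt")
})

test_that("events outside the window do not make a pair mutant", {
  a <- fake_aln(100L, 240L)
  far <- indel_event("del", 190L, 2L)  # well 3' of the window
  recon <- list(status = "mutant", events = list(far))
  pc <- apply_window(recon, a, a, win)
  expect_equal(pc$status, "wt")
  expect_equal(pc$net_indel, 0L)
  # the same event at the cut site counts
  near <- cut_deletion(ref, 2L)
  pc2 <- apply_window(list(status = "mutant", events = list(near)), a, a, win)
  expect_equal(pc2$status, "mutant")
  expect_equal(pc2$net_indel, -2L)
})

test_that("frame classification is net length mod 3", {
  mk <- function(events) {
    net <- sum(vapply(events, function(e)
      if (e$kind == "ins") e$length else -e$length, integer(1)))
    structure(list(status = "mutant", events = events,
                   net_indel = as.integer(net)), class = "pair_call")
  }
  expect_equal(classify_frame(mk(list(indel_event("del", 140L, 3L)))), "NFS")
  expect_equal(classify_frame(mk(list(indel_event("del", 100L, 95L)))), "FS")
  # complex allele: ins 4 + del 1 -> net +3 -> NFS
  expect_equal(classify_frame(mk(list(indel_event("ins", 140L, 4L, "ACGT"),
                                      indel_event("del", 150L, 1L)))), "NFS")
  # property: classification depends only on net mod 3
  withr::local_seed(77)
  for (i in 1:50) {
    evs <- replicate(sample(1:3, 1), {
      if (runif(1) < 0.5) indel_event("del", sample(50:200, 1),
                                      sample(1:20, 1))
      else {
        L <- sample(1:6, 1)
        indel_event("ins", sample(50:200, 1), L, random_dna(L))
      }
    }, simplify = FALSE)
    call <- mk(evs)
    expect_equal(classify_frame(call),
                 if (call$net_indel %% 3L != 0L) "FS" else "NFS")
  }
  expect_error(classify_frame(structure(list(status = "wt"),
                                        class = "pair_call")),
               "mutant")
})

test_that("sample summaries tally and conserve", {
  mkcall <- function(status, net = 0L, events = list()) {
    structure(list(status = status, events = events,
                   net_indel = as.integer(net)), class = "pair_call")
  }
  fs <- mkcall("mutant", -1L, list(cut_deletion(ref, 1L)))
  nfs <- mkcall("mutant", -3L, list(cut_deletion(ref, 3L)))
  calls <- c(replicate(100, mkcall("wt"), simplify = FALSE),
             replicate(50, fs, simplify = FALSE),
             replicate(25, nfs, simplify = FALSE))
  s <- summarize_sample(calls, ref, "toy")
  expect_equal(unname(s$counts[c("n_window", "n_wt", "n_mutant", "n_fs",
                                 "n_nfs")]),
               c(175L, 100L, 75L, 50L, 25L))
  expect_equal(s$nfs_fraction, 1 / 3)
  expect_equal(sum(s$allele_table$n_pairs), 75L)
  expect_equal(s$allele_table$frame[s$allele_table$n_pairs == 50], "FS")

  # empty input -> all-zero summary
  s0 <- summarize_sample(list(), ref, "empty")
  expect_true(all(s0$counts == 0L))
  expect_true(is.na(s0$nfs_fraction))

  # all discordant
  sd <- summarize_sample(replicate(10, mkcall("discordant"),
                                   simplify = FALSE), ref, "disc")
  expect_equal(unname(sd$counts[c("n_window", "n_wt", "n_mutant",
                                  "n_discordant")]), c(10L, 0L, 0L, 10L))
})
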
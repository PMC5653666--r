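ref <- test_reference()
idx <- build_index(ref)
sc <- align_scoring()

test_that("terminal anchors slide with the soft-clip window", {
  withr::local_seed(61)
  # perfect copy of reference[21,140]: both ends anchor at softclip 0
  rd <- substr(ref$sequence, 21, 140)
  left <- find_terminal_anchors(rd, idx, sc, "left")
  right <- find_terminal_anchors(rd, idx, sc, "right")
  expect_equal(left$ref_pos[left$softclip == 0], 21L)
  expect_equal(right$ref_pos[right$softclip == 0], 131L)

  # 4 nt of foreign sequence at 5': first anchor appears at softclip 4
  rd2 <- paste0("NNNN", substr(ref$sequence, 21, 120))
  left2 <- find_terminal_anchors(rd2, idx, sc, "left")
  expect_equal(min(left2$softclip), 4L)
  expect_equal(left2$ref_pos[left2$softclip == 4][1], 21L)
  # oracle: at each softclip s, hits equal a naive scan of that 10-mer
  for (s in unique(left2$softclip)) {
    kmer <- substr(rd2, s + 1, s + 10)
    expect_equal(sort(left2$ref_pos[left2$softclip == s]),
                 naive_locate(ref$sequence, kmer))
  }

  # repeated terminal 10-mer yields two candidate positions
  reptext <- paste0("ACGTACGTAC", random_dna(30), "ACGTACGTAC")
  repidx <- build_index(reptext)
  a <- find_terminal_anchors("ACGTACGTACGT", repidx, sc, "left")
  expect_equal(sort(a$ref_pos[a$softclip == 0]), c(1L, 41L))
})

test_that("anchor pairs maximise reference span with softclip tie-breaks", {
  left <- data.frame(softclip = c(0L, 0L), read_start = c(1L, 1L),
                     ref_pos = c(20L, 60L))
  right <- data.frame(softclip = 0L, read_start = 101L, ref_pos = 130L)
  best <- select_anchor_pair(left, right, anchor_k = 10L)[1, ]
  expect_equal(c(best$l_ref, best$r_ref), c(20L, 130L))
  expect_equal(best$span, 120L)

  # equal spans: smaller total softclip wins
  left2 <- data.frame(softclip = 0L, read_start = 1L, ref_pos = 20L)
  right2 <- data.frame(softclip = c(2L, 0L), read_start = c(99L, 101L),
                       ref_pos = c(130L, 130L))
  cand <- select_anchor_pair(left2, right2, anchor_k = 10L)
  expect_equal(cand$span[1], cand$span[2])
  expect_equal(cand$r_softclip[1], 0L)

  # no consistent pair
  bad <- select_anchor_pair(
    data.frame(softclip = 0L, read_start = 1L, ref_pos = 150L),
    data.frame(softclip = 0L, read_start = 101L, ref_pos = 20L), 10L)
  expect_equal(nrow(bad), 0L)
})

test_that("segment alignment matches hand-computed and oracle scores", {
  # 1 bp deletion: 9 matches (+18) and one opened gap (-6)
  a <- smith_waterman_segment("ACGTCGTAC", "ACGTACGTAC")
  expect_equal(a$score, 12L)
  expect_equal(a$ops$op, c("M", "D", "M"))
  expect_equal(sum(a$ops$len[a$ops$op == "D"]), 1L)
  expect_equal(a$n_mismatch, 0L)

  # identity
  s50 <- random_dna(50)
  b <- smith_waterman_segment(s50, s50)
  expect_equal(b$score, 100L)
  expect_equal(b$ops, data.frame(op = "M", len = 50L))

  # planted 6 bp insertion is recovered verbatim
  withr::local_seed(21)
  refseg <- random_dna(80)
  ins <- "TTAGCA"
  read <- paste0(substr(refseg, 1, 40), ins, substr(refseg, 41, 80))
  cc <- smith_waterman_segment(read, refseg)
  expect_equal(cc$ops$op, c("M", "I", "M"))
  expect_equal(cc$ops$len, c(40L, 6L, 40L))
  expect_equal(cc$score, 80L * 2L - 6L - 5L)

  # oracle equality on random perturbed instances
  for (i in 1:60) {
    seg <- random_dna(sample(60:120, 1))
    rd <- seg
    if (runif(1) < 0.7) {  # plant an indel
      L <- sample(1:8, 1); p <- sample(15:40, 1)
      rd <- if (runif(1) < 0.5) {
        paste0(substr(rd, 1, p), substr(rd, p + L + 1, nchar(rd)))
      } else {
        paste0(substr(rd, 1, p), random_dna(L), substr(rd, p + 1, nchar(rd)))
      }
    }
    rd <- plant_subs(rd, sample(5:(nchar(rd) - 5), sample(0:4, 1)))
    expect_equal(smith_waterman_segment(rd, seg)$score,
                 oracle_align_score(rd, seg))
  }
})

test_that("align_read handles perfect, mismatched and long-deletion reads", {
  rd <- substr(ref$sequence, 21, 140)
  a <- align_read(rd, idx, ref)
  expect_equal(a$status, "aligned")
  expect_equal(a$aln$ops, data.frame(op = "M", len = 120L))
  expect_equal(c(a$aln$ref_start, a$aln$ref_end), c(21L, 140L))
  expect_equal(a$aln$n_mismatch, 0L)

  # 4 scattered substitutions accepted, 5 rejected
  withr::local_seed(33)
  pos <- c(25, 45, 65, 85, 105)
  a4 <- align_read(plant_subs(rd, pos[1:4]), idx, ref)
  expect_equal(a4$status, "aligned")
  expect_equal(a4$aln$n_mismatch, 4L)
  a5 <- align_read(plant_subs(rd, pos), idx, ref)
  expect_equal(a5$status, "unaligned")
  expect_equal(a5$reason, "too_many_mismatches")
  # raising the cap monotonically recovers the read
  a5b <- align_read(plant_subs(rd, pos), idx, ref,
                    align_scoring(max_mismatches = 5L))
  expect_equal(a5b$status, "aligned")

  # read spanning a 95 bp deletion allele: one D op of length 95
  hap <- make_haplotype(ref, list(cut_deletion(ref, 95L, offset = -30L)))
  rd95 <- substr(hap, 40, 159)
  a95 <- align_read(rd95, idx, ref)
  expect_equal(a95$status, "aligned")
  expect_equal(a95$aln$ops$op, c("M", "D", "M"))
  expect_equal(a95$aln$ops$len[2], 95L)

  # unalignable foreign read
  expect_equal(align_read(strrep("AGGC", 30), idx, ref)$reason, "no_anchor")
})

test_that("strand symmetry: the reverse complement aligns identically", {
  withr::local_seed(55)
  for (i in 1:20) {
    st <- sample(1:60, 1)
    rd <- substr(ref$sequence, st, st + sample(80:160, 1))
    rd <- plant_subs(rd, sample(15:60, sample(0:2, 1)))
    fw <- align_read(rd, idx, ref)
    rv <- align_read(revcomp(rd), idx, ref)
    expect_equal(fw$status, "aligned")
    expect_equal(rv$status, "aligned")
    expect_equal(rv$aln$score, fw$aln$score)
    expect_equal(rv$aln$strand, "-")
    expect_equal(c(rv$aln$ref_start, rv$aln$ref_end),
                 c(fw$aln$ref_start, fw$aln$ref_end))
  }
})

test_that("pair alignment enforces proper FR orientation", {
  seg <- substr(ref$sequence, 31, 200)
  # FR by construction
  ok <- align_pair(substr(seg, 1, 120), revcomp(substr(seg, 51, 170)),
                   idx, ref)
  expect_equal(ok$status, "ok")
  # both mates forward -> improper
  ff <- align_pair(substr(seg, 1, 120), substr(seg, 51, 170), idx, ref)
  expect_equal(ff$status, "rejected")
  expect_equal(ff$reason, "improper_orientation")
  # RF (facing outward) -> improper
  rf <- align_pair(revcomp(substr(seg, 1, 120)), substr(seg, 51, 170),
                   idx, ref)
  expect_equal(rf$reason, "improper_orientation")
  # unalignable mate propagates
  bad <- align_pair(substr(seg, 1, 120), strrep("AGGC", 30), idx, ref)
  expect_equal(bad$reason, "mate_unaligned")
})
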
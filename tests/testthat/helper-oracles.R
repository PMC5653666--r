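# Independent oracles and fixture builders shared across the suite.

# naive O(n*m) exact-match scan, independent of the suffix array
naive_locate <- function(text, query) {
  n <- nchar(text); m <- nchar(query)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(text, starts, starts + m - 1L) == query]
}

# all k-mer positions of a text by one naive pass (no suffix array)
naive_kmer_table <- function(text, k) {
  starts <- seq_len(nchar(text) - k + 1L)
  split(starts, substring(text, starts, starts + k - 1L))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# full-DP affine-gap global alignment score oracle (Biostrings).
# amplicall charges gap_open for a gap's first base and gap_extend for
# each further base; Biostrings charges gapOpening + L * gapExtension
# for a length-L gap, hence the -(open - ext) translation.
oracle_align_score <- function(read, ref, match = 2, mismatch = -3,
                               gap_open = -6, gap_extend = -1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ref),
    substitutionMatrix = mat,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend,
    type = "global")
  Biostrings::score(pa)
}

test_reference <- function() example_reference()

# a perfect-quality read_pairs object from explicit sequences
perfect_pairs <- function(seq1, seq2, id = sprintf("p%03d", seq_along(seq1))) {
  q <- function(s) vapply(nchar(s), function(l) strrep("I", l), character(1))
  read_pairs(id, seq1, q(seq1), seq2, q(seq2))
}

# a proper FR pair reading out a reference (or haplotype) segment
segment_pair <- function(hap, start, end) {
  seg <- substr(hap, start, end)
  perfect_pairs(seg, revcomp(seg), id = "seg_pair")
}

# plant substitutions at given 1-based positions of a string
plant_subs <- function(seq, positions) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

# minimal alignment record for event/window unit tests
fake_aln <- function(ref_start, ref_end, ops = NULL, seq = NULL,
                     strand = "+", softclip_left = 0L, softclip_right = 0L) {
  if (is.null(ops)) {
    ops <- data.frame(op = "M", len = ref_end - ref_start + 1L)
  }
  list(strand = strand, ref_start = ref_start, ref_end = ref_end,
       ops = ops, score = 0L, n_mismatch = 0L,
       softclip_left = softclip_left, softclip_right = softclip_right,
       seq = seq)
}
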
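test_that("3' trimming keeps the 5' end, never lengthens, is idempotent", {
  p <- perfect_pairs(random_dna(150), random_dna(100))
  t1 <- trim_3prime(p, 120L)
  expect_equal(nchar(t1$seq1), 120L)
  expect_equal(substr(p$seq1, 1, 120), t1$seq1)
  expect_equal(t1$seq2, p$seq2)            # shorter than target: unchanged
  expect_equal(nchar(t1$qual1), 120L)      # qualities follow the sequence
  expect_identical(trim_3prime(t1, 120L), t1)
})

test_that("adapter clipping removes suffix-prefix overlaps only", {
  withr::local_seed(11)
  ad <- nextera_adapters()[1]
  body <- random_dna(80)
  # full adapter appended
  p <- perfect_pairs(paste0(body, ad), body)
  c1 <- clip_adapters(p)
  expect_equal(c1$seq1, body)
  expect_equal(c1$seq2, body)  # no adapter content: unchanged
  # minimal 5 nt overlap
  p5 <- perfect_pairs(paste0(body, substr(ad, 1, 5)), body)
  expect_equal(clip_adapters(p5)$seq1, body)
  # 4 nt overlap is below the minimum: untouched
  p4 <- perfect_pairs(paste0(body, substr(ad, 1, 4)), body)
  expect_equal(clip_adapters(p4)$seq1, paste0(body, substr(ad, 1, 4)))
  # one mismatch in a >= 10 base overlap is tolerated
  p10 <- perfect_pairs(paste0(body, plant_subs(substr(ad, 1, 12), 6)), body)
  expect_equal(clip_adapters(p10)$seq1, body)
})

test_that("pair filters implement the strict boundary rules", {
  mk <- function(len, q = 40L) {
    list(seq = random_dna(len),
         qual = strrep(intToUtf8(q + 33L), len))
  }
  good <- mk(120)
  # length 15 dropped, 16 retained (strictly greater than 15)
  for (len in c(15L, 16L)) {
    r <- mk(len)
    p <- read_pairs("x", r$seq, r$qual, good$seq, good$qual)
    res <- filter_pairs(p)
    expect_equal(unname(res$reason),
                 if (len == 15L) "short" else "kept")
  }
  # exactly 50% of bases below Q30 -> dropped; just under -> kept
  q29 <- intToUtf8(29L + 33L); q40 <- intToUtf8(40L + 33L)
  half_low <- paste0(strrep(q29, 60), strrep(q40, 60))
  just_ok <- paste0(strrep(q29, 59), strrep(q40, 61))
  p <- read_pairs(c("a", "b"),
                  c(random_dna(120), random_dna(120)), c(half_low, just_ok),
                  rep(good$seq, 2), rep(good$qual, 2))
  res <- filter_pairs(p)
  expect_equal(unname(res$reason), c("low_quality", "kept"))
  # N counts as low quality regardless of its score
  nseq <- paste0(strrep("N", 60), random_dna(60))
  pn <- read_pairs("n", nseq, strrep(q40, 120), good$seq, good$qual)
  expect_equal(unname(filter_pairs(pn)$reason), "low_quality")
  # zero-length read is "short", not an exception
  p0 <- read_pairs("z", "", "", good$seq, good$qual)
  expect_equal(unname(filter_pairs(p0)$reason), "short")
})

test_that("filter tallies conserve the input count", {
  withr::local_seed(42)
  n <- 60
  lens <- sample(c(10L, 15L, 16L, 80L, 120L), n, replace = TRUE)
  qlow <- runif(n) < 0.3
  seqs <- vapply(lens, random_dna, character(1))
  quals <- mapply(function(l, low) {
    q <- if (low) c(rep(20L, ceiling(l / 2)), rep(40L, floor(l / 2)))
         else rep(40L, l)
    intToUtf8(q + 33L)
  }, lens, qlow)
  p <- read_pairs(sprintf("r%02d", 1:n), seqs, quals,
                  vapply(rep(120L, n), random_dna, character(1)),
                  rep(strrep("I", 120), n))
  rep_ <- filter_pairs(p)$report
  expect_equal(rep_[["n_kept"]] + rep_[["n_short"]] +
                 rep_[["n_low_quality"]], n)
})

test_that("the QC chain is order-stable and idempotent", {
  withr::local_seed(9)
  ref <- test_reference()
  sim <- simulate_pairs(ref, list(allele_spec("WT", fraction = 1)),
                        sim_params(n_pairs = 40, fragment_mean = 130,
                                   fragment_sd = 25, seed = 5))
  once <- qc_pairs(sim$pairs)
  twice <- qc_pairs(once$pairs)
  expect_identical(twice$pairs, once$pairs)
  expect_equal(unname(twice$report[["n_kept"]]), length(once$pairs))
})

test_that("FASTQ io round-trips pairs, plain and gzipped", {
  withr::local_seed(3)
  p <- perfect_pairs(c(random_dna(50), random_dna(60)),
                     c(random_dna(50), random_dna(55)),
                     id = c("read_one", "read_two"))
  for (ext in c(".fastq", ".fastq.gz")) {
    f1 <- tempfile(fileext = ext); f2 <- tempfile(fileext = ext)
    write_fastq_pairs(p, f1, f2)
    back <- read_fastq_pairs(f1, f2)
    expect_identical(back, p)
    unlink(c(f1, f2))
  }
  # mismatched ids fail loudly
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq_pairs(p, f1, f2)
  p2 <- p; p2$id <- c("read_one", "other")
  write_fastq_pairs(p2, f2, f2)
  expect_error(read_fastq_pairs(f1, f2), "ids disagree")
  unlink(c(f1, f2))
})
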
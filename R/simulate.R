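#' Allele specification for the read simulator
#'
#' @param label allele name (e.g. `"WT"`, `"del1"`).
#' @param events list of [indel_event()]s defining the allele; empty for
#'   wild type.
#' @param fraction expected proportion of fragments drawn from this
#'   allele.
#' @return an `allele_spec` list.
#' @export
allele_spec <- function(label, events = list(), fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(label = label, events = events, fraction = fraction),
            class = "allele_spec")
}

#' Simulation parameters
#'
#' The defaults emulate the study design the pipeline targets: 150 bp
#' paired-end MiSeq reads from a short PCR amplicon, with a high quality
#' plateau (Q37) decaying linearly to Q20 over the last 30 cycles plus
#' small per-base jitter, a low uniform substitution error rate, and
#' Nextera adapter read-through when the fragment is shorter than the
#' read. Sequencer indel errors are not simulated by default so that any
#' called event traces back to a planted allele.
#'
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp.
#' @param fragment_mean,fragment_sd normal fragment-length model
#'   (truncated to `[30, haplotype length]`).
#' @param sub_rate per-base substitution error probability.
#' @param adapter_readthrough append adapter sequence when the fragment
#'   is shorter than the read.
#' @param q_plateau,q_floor,decay_cycles,q_jitter_sd quality model: Q
#'   stays at `q_plateau` until the last `decay_cycles` cycles, then
#'   decays linearly to `q_floor`; Gaussian jitter with this sd is added
#'   and clamped to `[2, 40]`.
#' @param seed integer seed; all randomness in the simulator derives from
#'   it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_pairs = 1000L, read_len = 150L,
                       fragment_mean = 180, fragment_sd = 20,
                       sub_rate = 0.002, adapter_readthrough = TRUE,
                       q_plateau = 37L, q_floor = 20L, decay_cycles = 30L,
                       q_jitter_sd = 2, seed = 1L) {
  stopifnot(n_pairs >= 1, read_len >= 20, sub_rate >= 0, sub_rate <= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_len = as.integer(read_len),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 sub_rate = sub_rate,
                 adapter_readthrough = isTRUE(adapter_readthrough),
                 q_plateau = as.integer(q_plateau),
                 q_floor = as.integer(q_floor),
                 decay_cycles = as.integer(decay_cycles),
                 q_jitter_sd = q_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Apply an allele's events to the reference sequence
#'
#' Events are applied right to left so earlier positions stay valid; the
#' wild-type allele returns the reference verbatim. Overlapping events
#' are rejected.
#'
#' @param reference an [amplicon_reference()].
#' @param events list of [indel_event()]s.
#' @return character scalar haplotype sequence.
#' @export
make_haplotype <- function(reference, events = list()) {
  seqs <- reference$sequence
  if (length(events) == 0L) return(seqs)
  pos <- vapply(events, function(e) e$ref_pos, integer(1))
  ord <- order(pos, decreasing = TRUE)
  # overlap check on deletion footprints / insertion points
  iv <- t(vapply(events, function(e) {
    if (e$kind == "del") c(e$ref_pos, e$ref_pos + e$length - 1L)
    else c(e$ref_pos, e$ref_pos)
  }, integer(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    stop("allele events overlap on the reference")
  }
  for (e in events[ord]) {
    if (e$kind == "del") {
      stopifnot(e$ref_pos >= 1L, e$ref_pos + e$length - 1L <= nchar(seqs))
      seqs <- paste0(substr(seqs, 1L, e$ref_pos - 1L),
                     substr(seqs, e$ref_pos + e$length, nchar(seqs)))
    } else {
      stopifnot(e$ref_pos >= 0L, e$ref_pos <= nchar(seqs))
      seqs <- paste0(substr(seqs, 1L, e$ref_pos),
                     e$inserted_seq,
                     substr(seqs, e$ref_pos + 1L, nchar(seqs)))
    }
  }
  seqs
}

# per-cycle quality profile of length `len` under the decay model
.quality_profile <- function(len, params) {
  q <- rep(params$q_plateau, len)
  dk <- params$decay_cycles
  if (len > 0L && dk > 0L) {
    tail_len <- min(dk, len)
    idx <- (len - tail_len + 1L):len
    frac <- seq_len(tail_len) / dk
    q[idx] <- round(params$q_plateau -
                      frac * (params$q_plateau - params$q_floor))
  }
  q
}

.mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

#' Simulate paired-end amplicon reads from an allele spectrum
#'
#' Each pair draws an allele by its fraction, samples a fragment within
#' the allele haplotype, and reads both ends inward for `read_len` bases
#' (truncated at the fragment ends, with adapter fill-in on read-through
#' if enabled). Substitution errors and qualities follow
#' [sim_params()]. Fully deterministic for a fixed seed.
#'
#' @param reference an [amplicon_reference()].
#' @param spectrum list of [allele_spec()]s; fractions must sum to 1.
#' @param params a [sim_params()].
#' @param id_prefix prefix for read ids.
#' @return list with `pairs` (a [read_pairs()]) and `truth` (data.frame:
#'   `id`, `allele`, `frag_start`, `frag_len`).
#' @export
simulate_pairs <- function(reference, spectrum, params = sim_params(),
                           id_prefix = "sim") {
  fr <- vapply(spectrum, function(a) a$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop("allele fractions must sum to 1")
  haps <- vapply(spectrum, function(a) make_haplotype(reference, a$events),
                 character(1))
  labels <- vapply(spectrum, function(a) a$label, character(1))
  if (any(nchar(haps) < 30L)) {
    stop("an allele haplotype is shorter than the minimum fragment (30 bp)")
  }
  set.seed(params$seed)
  n <- params$n_pairs
  which_allele <- sample.int(length(spectrum), n, replace = TRUE, prob = fr)
  hlen <- nchar(haps)[which_allele]
  frag <- pmin(pmax(as.integer(round(rnorm(n, params$fragment_mean,
                                           params$fragment_sd))), 30L), hlen)
  start <- as.integer(floor(runif(n) * (hlen - frag + 1))) + 1L

  adapter <- nextera_adapters()[1]
  rl <- params$read_len
  seq1 <- character(n); seq2 <- character(n)
  qual1 <- character(n); qual2 <- character(n)
  for (i in seq_len(n)) {
    hap <- haps[which_allele[i]]
    rd_len <- min(rl, frag[i])
    r1 <- substr(hap, start[i], start[i] + rd_len - 1L)
    r2 <- revcomp(substr(hap, start[i] + frag[i] - rd_len,
                         start[i] + frag[i] - 1L))
    if (params$adapter_readthrough && frag[i] < rl) {
      fill <- min(rl - frag[i], nchar(adapter))
      r1 <- paste0(r1, substr(adapter, 1L, fill))
      r2 <- paste0(r2, substr(adapter, 1L, fill))
    }
    r1 <- .mutate_bases(r1, params$sub_rate)
    r2 <- .mutate_bases(r2, params$sub_rate)
    q1 <- .quality_profile(nchar(r1), params) +
      as.integer(round(rnorm(nchar(r1), 0, params$q_jitter_sd)))
    q2 <- .quality_profile(nchar(r2), params) +
      as.integer(round(rnorm(nchar(r2), 0, params$q_jitter_sd)))
    seq1[i] <- r1; seq2[i] <- r2
    qual1[i] <- phred_string(pmin(pmax(q1, 2L), 40L))
    qual2[i] <- phred_string(pmin(pmax(q2, 2L), 40L))
  }
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
  list(pairs = read_pairs(ids, seq1, qual1, seq2, qual2),
       truth = data.frame(id = ids, allele = labels[which_allele],
                          frag_start = start, frag_len = frag))
}

#' Canonical indel alleles around the cut site
#'
#' Convenience constructors for the allele spectra used throughout the
#' documentation and tests. The Cas9 blunt cut falls 3 bp upstream of the
#' PAM; deletions start at the first base 3' of the cut.
#'
#' @param reference an [amplicon_reference()].
#' @return 1-based amplicon position of the first base after the cut.
#' @export
cut_site <- function(reference) {
  gi <- reference$guide_interval
  if (reference$guide_strand == "+") gi[2] - 2L else gi[1] + 3L
}

#' @rdname cut_site
#' @param length deletion length in bp.
#' @param offset shift of the deletion start relative to the cut site.
#' @export
cut_deletion <- function(reference, length, offset = 0L) {
  indel_event("del", cut_site(reference) + offset, length)
}

#' @rdname cut_site
#' @param seq inserted sequence.
#' @export
cut_insertion <- function(reference, seq) {
  indel_event("ins", cut_site(reference) - 1L, nchar(seq), seq)
}

#' Write the canonical fixture bundle
#'
#' Emits a self-contained test bundle under `out_dir`: the bundled
#' synthetic amplicon reference (FASTA + config), a clean wild-type run
#' (zero error rate), a mixed-spectrum run (WT 0.6, 1 bp deletion 0.3,
#' 3 bp deletion 0.1), and two 6-sample groups whose NFS fractions among
#' mutant reads differ (0.5 vs 0.1) for enrichment power testing —
#' 14 FASTQ pairs in total, each with a truth table. A `groups_power.tsv`
#' file compares the two groups; `groups_null.tsv` compares the
#' high-NFS group against itself for null calibration. All seeds derive
#' from `seed` and are recorded in `manifest.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base integer seed.
#' @param n_pairs read pairs per simulated sample.
#' @return invisibly, the manifest as a list.
#' @export
write_fixture_set <- function(out_dir, seed = 1L, n_pairs = 400L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- example_reference()
  write_reference(reference, file.path(out_dir, "reference.fa"),
                  file.path(out_dir, "reference.cfg"))

  spectra <- list(
    wt_clean = list(spec = list(allele_spec("WT", fraction = 1)),
                    sub_rate = 0),
    mixed = list(spec = list(
      allele_spec("WT", fraction = 0.6),
      allele_spec("del1", list(cut_deletion(reference, 1L)), 0.3),
      allele_spec("del3", list(cut_deletion(reference, 3L)), 0.1)),
      sub_rate = 0.002))
  # group samples: NFS fraction among mutants 0.5 (hi) vs 0.1 (lo)
  hi <- list(spec = list(
    allele_spec("WT", fraction = 0.3),
    allele_spec("del1", list(cut_deletion(reference, 1L)), 0.35),
    allele_spec("del3", list(cut_deletion(reference, 3L)), 0.35)),
    sub_rate = 0.002)
  lo <- list(spec = list(
    allele_spec("WT", fraction = 0.3),
    allele_spec("del1", list(cut_deletion(reference, 1L)), 0.63),
    allele_spec("del3", list(cut_deletion(reference, 3L)), 0.07)),
    sub_rate = 0.002)
  for (i in 1:6) {
    spectra[[sprintf("hi_%d", i)]] <- hi
    spectra[[sprintf("lo_%d", i)]] <- lo
  }

  manifest <- list(seed = seed, n_pairs = n_pairs, samples = list())
  for (k in seq_along(spectra)) {
    name <- names(spectra)[k]
    s <- spectra[[k]]
    sseed <- (seed * 1000L + k) %% .Machine$integer.max
    sim <- simulate_pairs(reference, s$spec,
                          sim_params(n_pairs = n_pairs, sub_rate = s$sub_rate,
                                     seed = sseed),
                          id_prefix = name)
    fq1 <- file.path(out_dir, paste0(name, "_R1.fastq.gz"))
    fq2 <- file.path(out_dir, paste0(name, "_R2.fastq.gz"))
    write_fastq_pairs(sim$pairs, fq1, fq2)
    write.table(sim$truth, file.path(out_dir, paste0(name, "_truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$samples[[name]] <- list(seed = sseed, fq1 = basename(fq1),
                                     fq2 = basename(fq2))
  }
  write.table(data.frame(sample = c(sprintf("hi_%d", 1:6),
                                    sprintf("lo_%d", 1:6)),
                         group = rep(c("A", "B"), each = 6)),
              file.path(out_dir, "groups_power.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = rep(sprintf("hi_%d", 1:6), 2),
                         group = rep(c("A", "B"), each = 6)),
              file.path(out_dir, "groups_null.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Bundled synthetic example reference
#'
#' Loads the synthetic amplicon reference shipped with the package
#' (`inst/extdata/synthetic_amplicon.fa` + `.cfg`): a 280 bp invented
#' sequence standing in for a Kras exon-3 style PCR amplicon, with a
#' 20 nt guide and AGG PAM near the center and 10 bp nominal genomic
#' flanks. It is synthetic — no genomic sequence was copied.
#'
#' @return an [amplicon_reference()].
#' @export
example_reference <- function() {
  load_reference(
    system.file("extdata", "synthetic_amplicon.fa", package = "amplicall"),
    system.file("extdata", "synthetic_amplicon.cfg", package = "amplicall"))
}
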
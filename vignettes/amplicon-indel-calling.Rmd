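---
title: "Calling CRISPR editing outcomes from amplicon sequencing with amplicall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling CRISPR editing outcomes from amplicon sequencing with amplicall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicall)
```

## Scope and model

`amplicall` genotypes a single CRISPR-targeted locus from paired-end
amplicon deep sequencing. The unit of evidence is the *read pair*; the
unit of biology is the *allele*, a set of indel events on the amplicon.
The pipeline assumes:

* one amplicon per run, short enough that a fragment spans a useful part
  of it (hundreds of bp, not genome-scale);
* editing outcomes are insertions and deletions near the guide;
  substitutions are treated as sequencing/PCR noise and never produce a
  mutant call (they are tolerated up to the mismatch cap and otherwise
  cause the read to be discarded, not miscalled);
* Phred+33 qualities (Sanger scale).

A read pair ends in exactly one of the mutually exclusive states
`qc_dropped` (short / low quality), `mate_unaligned`,
`improper_orientation`, `off_window`, `wt`, `mutant`, or `discordant`,
and the pipeline asserts this conservation identity on every run — a
violated identity is a hard failure, not a warning.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `trim_to` | 120 | bp | drop the noisy 3′ tail of 150 bp MiSeq reads |
| `min_len_exclusive` | 15 | bp | *strictly greater than* 15 bp retained |
| `q_threshold` / `max_lowq_fraction` | Q30 / 0.5 | — | drop a pair if either mate has ≥ 50% bases below Q30; `N` always counts as low quality (it carries no call) |
| `anchor_k` | 10 | bp | exact terminal k-mer for suffix-array anchoring |
| `max_softclip` | 10 | bp | unit-step sliding window for anchor search |
| `match`/`mismatch` | +2 / −3 | score | standard short-read ratios |
| `gap_open`/`gap_extend` | −6 / −1 | score | first gap base / each further base; cheap extension keeps one long deletion (e.g. 95 bp, cost −100) far above 95 scattered mismatches, which is what long-indel sensitivity requires |
| `max_mismatches` | 4 | count | accepted-alignment cap, applied *after* the optimal alignment is found |
| `min_overlap` | 20 | bp | window qualification: a mate must overlap the sgRNA+PAM interval by at least this |
| `alpha` | 0.05 | — | significance level of the χ² comparisons |
| `max_fragment_span` | amplicon + 50 | bp | proper-pair limit; amplicons are short, so anything larger indicates a mis-anchored mate |

All defaults are overridable in code and from the CLI, and every run
report records the fully resolved configuration.

## Numerical and algorithmic choices

**Coordinates.** All intervals are 1-based inclusive, the R/Bioconductor
convention, both internally and in reports; genomic positions are
`genomic_offset + local − 1`.

**Suffix array.** The index stores the lexicographic suffix order and
answers exact lookups by binary search; byte-order sorting coincides with
alphabetical order on the DNA alphabet. A k-mer table (default k = 10,
the anchor size) is attached as a constant-time accelerator in the spirit
of an enhanced suffix array's auxiliary tables; it is checked in the
tests to return exactly the binary-search (and naive-scan) result set.
`N` never matches an anchor query: anchors must be unambiguous.

**Alignment.** The inter-anchor segment is aligned by global affine-gap
(Gotoh) dynamic programming — "global" because the anchor
correspondences pin both endpoints; the anchors themselves were exact
matches, so this equals an unconstrained optimal alignment of the
segment (asserted against an independent full-DP oracle on 500 random
instances). Among anchor pairs the maximal reference span wins, then
smaller total soft-clip, then the leftmost anchor; among equally scoring
DP paths the traceback prefers diagonal moves and gap extension over gap
opening (fewer gap openings). Ties in indel *placement* do not matter
downstream because events are left-normalised (below). The mismatch cap
is deliberately a post-filter so the DP stays optimal.

**Event canonicalisation.** Every I/D run is shifted to its leftmost
equivalent placement against the reference (deletion: slide while the
base before equals the last deleted base; insertion: rotate the inserted
sequence). Identical alleles observed by different reads therefore
produce identical event keys.

**Mate reconciliation and repeat tracts.** Both mates must report an
event that both *could have observed*. Observability is evaluated over
the event's full ambiguity tract — from its leftmost to its rightmost
equivalent placement plus one flanking base on each side — because a
read that ends *inside* a homopolymer containing the indel aligns
cleanly without it and carries no evidence either way. With the naive
rule ("event position inside both spans") a 1 bp deletion in the `CCC`
run adjacent to the bundled reference's PAM produced ~2.5% spurious
discordant pairs; with the tract rule, error-free simulations produce
zero. Discordant pairs are excluded from both WT and mutant tallies and
reported separately.

**Window summarisation.** Deleted reference bases count as covered when
computing window overlap (a read spanning a deletion across the window
still genotypes it). A qualifying pair whose events all fall outside the
window is wild type *for the window summary*. 19 bp of overlap is
excluded; 20 bp is included (strict boundary, tested).

**Frame classification.** FS iff the net indel length (insertions minus
deletions over window-overlapping events) is not divisible by 3. The
codon phase of the guide (`frame_offset`) is carried for reporting only:
mod-3 of the net length decides frame status regardless of phase. The
NFS fraction denominator is mutant pairs only (`n_nfs / (n_fs + n_nfs)`),
matching the contrast of NFS versus FS mutant reads; a flag on the
enrichment input can include WT in sensitivity analyses by construction
of the counts passed in.

**χ² of proportions.** The closed-form Pearson statistic on the 2×2
(NFS, FS) table, 1 df, *without* Yates continuity correction by default
— amplicon read counts are in the hundreds to thousands, where the
correction is immaterial; `correct = TRUE` applies it. Tables with an
empty margin are marked untestable and logged rather than raising.
"Significant" means `p < alpha` *and* the NFS fraction is higher in
group A: the question is enrichment, not mere difference. No
multiple-testing correction is applied across the pairwise grid, by
design. The directional rejection rate under the null is therefore
≈ alpha/2 per comparison, which the calibration test asserts (two-sided
rate in [0.03, 0.07], directional in [0.015, 0.035] at alpha = 0.05 over
500 replicate 6-vs-6 grids).

## The simulator: what it emulates and what it does not

`simulate_pairs()` draws each pair from a stated allele spectrum,
samples a fragment (normal length model, default mean 180 bp, sd 20 bp,
truncated to the haplotype), reads 150 bp inward from both ends,
appends Nextera adapter on read-through, applies uniform substitution
errors (default 0.002/base) and a quality profile with a Q37 plateau
decaying linearly to Q20 over the last 30 cycles plus Gaussian jitter
(sd 2). Everything derives from one integer seed; the same seed
reproduces the FASTQ bytes.

It deliberately does **not** model sequencer indel errors (off by
default so every called event traces to a planted allele), PCR chimeras
or jackpots, position-dependent substitution spectra, or real MiSeq
error profiles. A green recovery test therefore establishes that the
*caller* is correct on reads whose noise is substitution-only — not that
the pipeline is robust to artefacts the simulator does not produce.
Fragments that genuinely do not reach 20 bp of window overlap, and the
rare fragment that ends inside the repeat tract of its own indel, are
counted as `off_window`/`wt` respectively; this is the expected, small
(< 0.5%) reason recovery is not exactly 100% even at zero error rate.

The bundled reference (`example_reference()`) is a **synthetic** 280 bp
amplicon — an invented sequence standing in for a mouse *Kras* exon-3
style amplicon, with a 20 nt guide, `AGG` PAM, unique 10-mers (so every
anchor is unambiguous) and a nominal 10 bp genomic flank annotation. No
genomic sequence was copied. The canonical long-deletion fixture is a
95 bp deletion overlapping the guide window (95 mod 3 = 2 ⇒ FS).

The default fixture bundle simulates 400 pairs per sample (runtime
budget); statistical power and null-calibration checks that the design
states at 1000 mutant reads per sample are run at full size directly on
binomial counts, which is the scale at which those checks are defined.

## Degenerate inputs

Empty FASTQ yields an all-zero summary; a zero-length read is dropped as
`short`, not an exception; a truncated FASTQ record fails parsing with a
stage-attributed error; an empty χ² margin is untestable, not an error;
an empty group in a comparison is a configuration error; overlapping
events in an allele specification are a specification error.

## Known limitations

* Single amplicon per index/run; multiplexing is handled by running per
  amplicon (batching via the CLI), not by a joint index.
* One inter-anchor segment per read: chimeric/split alignments beyond a
  single gap structure are out of scope.
* Quality scores do not inform the alignment score, only the QC filter.
* Substitution alleles (point edits) are invisible by design.
* Alleles are keyed by their event set within a pair's observed span;
  phasing across pairs is not attempted.
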
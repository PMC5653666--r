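#' Paired-end read container
#'
#' Column-oriented container for read pairs: parallel character vectors of
#' ids, mate sequences and Phred+33 quality strings. This layout keeps the
#' QC steps vectorised; per-read records are materialised only inside the
#' aligner.
#'
#' @param id character vector of read ids (shared by both mates).
#' @param seq1,seq2 character vectors of mate-1/mate-2 sequences.
#' @param qual1,qual2 Phred+33 quality strings, same lengths as the
#'   sequences.
#' @return a `read_pairs` object.
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  n <- length(id)
  stopifnot(length(seq1) == n, length(qual1) == n,
            length(seq2) == n, length(qual2) == n)
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2))) {
    stop("sequence and quality lengths differ within a read")
  }
  structure(list(id = as.character(id),
                 seq1 = toupper(seq1), qual1 = as.character(qual1),
                 seq2 = toupper(seq2), qual2 = as.character(qual2)),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
`[.read_pairs` <- function(x, i) {
  read_pairs(x$id[i], x$seq1[i], x$qual1[i], x$seq2[i], x$qual2[i])
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs with", length(x), "pairs\n")
  invisible(x)
}

.read_one_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = sub("\\s.*$", "", names(x)),
       seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Read paired FASTQ files
#'
#' Reads two parallel FASTQ files (plain or gzip, Phred+33) and pairs the
#' mates by record order; record counts must agree and, when both files
#' carry ids, the ids must agree record by record (a `/1`, `/2` or space
#' suffix is stripped).
#'
#' @param fq1,fq2 paths to the mate-1 and mate-2 FASTQ files.
#' @param interleaved if `TRUE`, `fq1` is a single interleaved file
#'   (records alternating mate 1, mate 2) and `fq2` must be missing.
#' @return a [read_pairs()] object.
#' @export
read_fastq_pairs <- function(fq1, fq2 = NULL, interleaved = FALSE) {
  if (interleaved) {
    if (!is.null(fq2)) stop("interleaved input takes a single file")
    x <- .read_one_fastq(fq1)
    n <- length(x$id)
    if (n %% 2L != 0L) {
      stop("interleaved FASTQ '", fq1, "' has an odd number of records (",
           n, ")")
    }
    o1 <- seq(1L, n, by = 2L); o2 <- seq(2L, n, by = 2L)
    r1 <- list(id = x$id[o1], seq = x$seq[o1], qual = x$qual[o1])
    r2 <- list(id = x$id[o2], seq = x$seq[o2], qual = x$qual[o2])
  } else {
    r1 <- .read_one_fastq(fq1)
    r2 <- .read_one_fastq(fq2)
    if (length(r1$id) != length(r2$id)) {
      stop("mate files have different record counts: ", length(r1$id),
           " vs ", length(r2$id))
    }
  }
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop("mate ids disagree at record ", bad[1], ": '", id1[bad[1]],
         "' vs '", id2[bad[1]], "'")
  }
  read_pairs(id1, r1$seq, r1$qual, r2$seq, r2$qual)
}

#' Write paired FASTQ files
#'
#' @param pairs a [read_pairs()] object.
#' @param fq1,fq2 output paths; a `.gz` suffix selects gzip compression.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, fq1, fq2) {
  .write_one <- function(id, seq, qual, path) {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- id
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(qual),
      compress = grepl("\\.gz$", path))
  }
  .write_one(pairs$id, pairs$seq1, pairs$qual1, fq1)
  .write_one(pairs$id, pairs$seq2, pairs$qual2, fq2)
  invisible(c(fq1, fq2))
}

# decode a Phred+33 quality string to integer scores
phred_ints <- function(qual) utf8ToInt(qual) - 33L

# encode integer Phred scores to a +33 string
phred_string <- function(q) intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
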
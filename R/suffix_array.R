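#' Suffix-array index of a reference sequence
#'
#' Builds the lexicographic suffix order of the amplicon sequence. The
#' index supports exact-substring lookup ([locate_exact()]) by binary
#' search, which is all the anchoring step requires; no LCP/child tables
#' are kept. Sorting uses byte (C-locale) order, which coincides with
#' alphabetical order on the upper-case DNA alphabet.
#'
#' @param x an [amplicon_reference()] or a character scalar sequence.
#' @param cache_k optional k-mer length for a constant-time lookup table
#'   over the suffix order (an accelerator in the spirit of the enhanced
#'   suffix array's auxiliary tables; it changes nothing about the result
#'   set). Defaults to the anchoring k-mer size.
#' @return a `suffix_array` object with fields `text` and `order`
#'   (1-based suffix start positions in lexicographic order).
#' @examples
#' sa <- build_index("AGAGA")
#' sa$order  # suffixes A, AGA, AGAGA, GA, GAGA -> 5 3 1 4 2
#' @export
build_index <- function(x, cache_k = 10L) {
  text <- if (inherits(x, "amplicon_reference")) x$sequence else
    toupper(as.character(x))
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("cannot index an empty sequence")
  }
  n <- nchar(text)
  ord <- order(substring(text, seq_len(n), n), method = "radix")
  cache <- NULL
  if (!is.null(cache_k) && cache_k >= 1L && n >= cache_k) {
    starts <- seq_len(n - cache_k + 1L)
    cache <- list2env(split(starts,
                            substring(text, starts, starts + cache_k - 1L)),
                      hash = TRUE)
  }
  structure(list(text = text, order = as.integer(ord),
                 cache_k = if (is.null(cache)) NA_integer_ else
                   as.integer(cache_k),
                 cache = cache),
            class = "suffix_array")
}

#' @export
print.suffix_array <- function(x, ...) {
  cat("suffix_array over", nchar(x$text), "bp\n")
  invisible(x)
}

# compare query against the length-m prefix of the suffix starting at pos:
# -1 if prefix < query, 0 if equal, +1 if prefix > query
.sa_cmp <- function(text, pos, query, m) {
  pref <- substr(text, pos, pos + m - 1L)
  if (pref < query) -1L else if (pref > query) 1L else 0L
}

#' Exact-match positions of a query in an indexed sequence
#'
#' Binary search over the suffix order for all start positions where
#' `query` occurs verbatim. `N` never matches: a query containing `N`
#' returns no hits (anchors must be unambiguous), and an `N` in the text
#' only ever equals a literal `N` in the query, which is excluded.
#'
#' @param index a `suffix_array` from [build_index()].
#' @param query character scalar, length >= 1.
#' @return sorted integer vector of 1-based start positions (possibly
#'   empty).
#' @examples
#' locate_exact(build_index("ACGTACGT"), "ACGT")  # 1 5
#' @export
locate_exact <- function(index, query) {
  stopifnot(inherits(index, "suffix_array"))
  query <- toupper(as.character(query))
  m <- nchar(query)
  if (m < 1L) stop("query must have length >= 1")
  if (grepl("N", query, fixed = TRUE)) return(integer(0))
  if (!is.na(index$cache_k) && m == index$cache_k) {
    hits <- index$cache[[query]]
    return(if (is.null(hits)) integer(0) else hits)
  }
  text <- index$text
  ord <- index$order
  n <- length(ord)

  # lower bound: first suffix whose m-prefix is >= query
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.sa_cmp(text, ord[mid], query, m) < 0L) lo <- mid + 1L else hi <- mid
  }
  hits <- integer(0)
  i <- lo
  while (i <= n && .sa_cmp(text, ord[i], query, m) == 0L) {
    hits <- c(hits, ord[i])
    i <- i + 1L
  }
  sort(hits)
}

# naive O(n*m) scan; the anchoring code uses locate_exact, this is shared
# by reference loading (guide/PAM placement) where clarity beats speed
locate_naive <- function(text, query) {
  n <- nchar(text); m <- nchar(query)
  if (m < 1L || m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(text, starts, starts + m - 1L) == query]
}
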
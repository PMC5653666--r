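#' Chi-square test of proportions on a 2x2 table
#'
#' Pearson chi-square comparing the NFS (non-frameshift) read fraction
#' between two samples, computed from the closed form
#' \deqn{\chi^2 = \frac{N (ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},
#'   \quad N = a+b+c+d,}
#' with 1 degree of freedom and no continuity correction by default
#' (amplicon read counts are large enough that the correction is
#' immaterial; it is available behind `correct = TRUE`, which applies the
#' Yates adjustment). The test is two-sided; `significant` additionally
#' requires the NFS fraction to be *higher* in sample A (enrichment, not
#' mere difference).
#'
#' @param a,b NFS and FS pair counts of sample A.
#' @param c_,d NFS and FS pair counts of sample B.
#' @param alpha significance level (default 0.05).
#' @param correct apply the Yates continuity correction.
#' @return an `enrichment_result` list: `chi2`, `df` (1), `p`,
#'   `direction` (sign of the NFS-fraction difference A - B),
#'   `significant`, `testable`. Tables with an empty margin are marked
#'   `testable = FALSE` (`chi2` and `p` are `NA`).
#' @examples
#' chi2_proportions(30, 70, 10, 90)  # chi2 = 12.5
#' @export
chi2_proportions <- function(a, b, c_, d, alpha = 0.05, correct = FALSE) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    return(structure(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                          direction = NA_real_, significant = FALSE,
                          testable = FALSE, alpha = alpha),
                     class = "enrichment_result"))
  }
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / prod(margins)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- sign(a / (a + b) - c_ / (c_ + d))
  structure(list(chi2 = chi2, df = 1L, p = p, direction = direction,
                 significant = (p < alpha) && (direction > 0),
                 testable = TRUE, alpha = alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (!x$testable) {
    cat("enrichment_result: untestable (empty margin)\n")
  } else {
    cat(sprintf("chi2 = %.4f (df 1), p = %.4g, direction %+d, %s\n",
                x$chi2, x$p, x$direction,
                if (x$significant) "NFS enriched in A" else "not significant"))
  }
  invisible(x)
}

# coerce sample summaries / count rows to an (nfs, fs) pair
.nfs_fs <- function(x) {
  if (inherits(x, "sample_summary")) {
    c(nfs = unname(x$counts[["n_nfs"]]), fs = unname(x$counts[["n_fs"]]))
  } else if (!is.null(x$counts)) {
    c(nfs = unname(x$counts[["n_nfs"]]), fs = unname(x$counts[["n_fs"]]))
  } else {
    c(nfs = as.integer(x[["n_nfs"]]), fs = as.integer(x[["n_fs"]]))
  }
}

.sample_label <- function(x, i) {
  if (!is.null(x$sample_id)) x$sample_id else paste0("sample", i)
}

#' All pairwise NFS-enrichment comparisons between two groups
#'
#' Tests every sample of group A against every sample of group B with
#' [chi2_proportions()] (NFS vs FS counts among mutant pairs), mirroring
#' the pairwise tumor-versus-tumor design: 6 vs 6 samples yields 36
#' comparisons. A comparison counts as significant when the NFS fraction
#' is significantly higher in the group-A sample.
#'
#' @param groupA,groupB lists of [summarize_sample()] results (or any
#'   objects carrying `n_nfs`/`n_fs` counts).
#' @param alpha significance level.
#' @param correct passed to [chi2_proportions()].
#' @return a `pairwise_enrichment` list: `grid` (one row per comparison:
#'   sample labels, the 2x2 counts, `chi2`, `p`, `direction`,
#'   `significant`, `testable`), `n_comparisons`, `n_significant`,
#'   `n_untestable`, `fraction_significant`.
#' @export
pairwise_enrichment <- function(groupA, groupB, alpha = 0.05,
                                correct = FALSE) {
  if (length(groupA) == 0L || length(groupB) == 0L) {
    stop("both groups must contain at least one sample")
  }
  rows <- list()
  for (i in seq_along(groupA)) {
    ca <- .nfs_fs(groupA[[i]])
    for (j in seq_along(groupB)) {
      cb <- .nfs_fs(groupB[[j]])
      r <- chi2_proportions(ca[["nfs"]], ca[["fs"]], cb[["nfs"]], cb[["fs"]],
                            alpha = alpha, correct = correct)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_a = .sample_label(groupA[[i]], i),
        sample_b = .sample_label(groupB[[j]], j),
        a = ca[["nfs"]], b = ca[["fs"]], c = cb[["nfs"]], d = cb[["fs"]],
        chi2 = r$chi2, p = r$p, direction = r$direction,
        significant = r$significant, testable = r$testable)
    }
  }
  grid <- do.call(rbind, rows)
  n_comparisons <- nrow(grid)
  n_significant <- sum(grid$significant)
  structure(list(grid = grid,
                 n_comparisons = n_comparisons,
                 n_significant = n_significant,
                 n_untestable = sum(!grid$testable),
                 fraction_significant = n_significant / n_comparisons,
                 alpha = alpha),
            class = "pairwise_enrichment")
}

#' @export
print.pairwise_enrichment <- function(x, ...) {
  cat(sprintf(
    "pairwise_enrichment: NFS enriched in A in %d/%d comparisons (%.1f%%) at alpha %.3g\n",
    x$n_significant, x$n_comparisons, 100 * x$fraction_significant, x$alpha))
  if (x$n_untestable) cat(" ", x$n_untestable, "untestable comparison(s)\n")
  invisible(x)
}
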
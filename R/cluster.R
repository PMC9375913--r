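# Binomial test for clustering of variants in the overlap of two coding
# regions.  With n variants falling in the union of the two regions and
# success probability p = |intersection| / |union| (a variant is assumed
# equally likely to hit any nucleotide, independently), the count in the
# intersection is X ~ B(n, p); the observed count k is scored as
# z = (k - np) / sqrt(np(1-p)), significant above 2.58 (one-sided, p < 0.01).

as_iranges <- function(x) {
  if (methods::is(x, "IRanges")) return(x)
  x <- as.data.frame(x)
  IRanges::IRanges(start = x$start, end = x$end)
}

#' Overlap probability of two interval sets
#'
#' `p = length(seq1 intersect seq2) / length(seq1 union seq2)`, with lengths
#' in nucleotides (intervals are 1-based inclusive).
#'
#' @param seq1,seq2 Data frames with `start`, `end` columns (or `IRanges`),
#'   in a common coordinate space.
#' @return Overlap probability in `[0, 1]` (0 for disjoint inputs, where
#'   the downstream z-score is undefined).
#' @export
#' @examples
#' overlap_probability(data.frame(start = 1, end = 100),
#'                     data.frame(start = 51, end = 150))
overlap_probability <- function(seq1, seq2) {
  r1 <- IRanges::reduce(as_iranges(seq1))
  r2 <- IRanges::reduce(as_iranges(seq2))
  stopifnot(length(r1) > 0, length(r2) > 0)
  inter <- sum(IRanges::width(IRanges::intersect(r1, r2)))
  uni <- sum(IRanges::width(IRanges::union(r1, r2)))
  inter / uni
}

#' Count variants in the union and intersection of two ORF regions
#'
#' @param variants Variant tibble (or any data frame with a `pos` column).
#' @param orf_a,orf_b Interval sets as in [overlap_probability()], same
#'   coordinate space as `pos`.
#' @return List with `n` (variants in the union) and `k` (variants in the
#'   intersection).
#' @export
count_overlap_variants <- function(variants, orf_a, orf_b) {
  ra <- IRanges::reduce(as_iranges(orf_a))
  rb <- IRanges::reduce(as_iranges(orf_b))
  pos <- IRanges::IRanges(start = variants$pos, width = 1L)
  in_a <- IRanges::overlapsAny(pos, ra)
  in_b <- IRanges::overlapsAny(pos, rb)
  list(n = sum(in_a | in_b), k = sum(in_a & in_b))
}

#' Binomial cluster-enrichment test
#'
#' @param n Number of variants in the union of the two coding regions.
#' @param k Number of variants in their intersection.
#' @param p Overlap probability, either computed with
#'   [overlap_probability()] or supplied directly (e.g. a published value).
#' @param z_threshold Significance threshold on the z-score (default 2.58,
#'   i.e. one-sided p < 0.01).
#' @return An `overlap_test` object with fields `n`, `k`, `p`, `mean`
#'   (`np`), `sd` (`sqrt(np(1-p))`), `z` and `significant`; supports
#'   [generics::tidy()], [generics::glance()] and `print()`.
#' @export
#' @examples
#' binomial_cluster_test(26, 19, 0.387)
binomial_cluster_test <- function(n, k, p, z_threshold = 2.58) {
  stopifnot(n >= 1, k >= 0, k <= n)
  if (p <= 0 || p >= 1) {
    abort("p must be strictly between 0 and 1 (sd = 0 leaves z undefined)")
  }
  m <- n * p
  s <- sqrt(n * p * (1 - p))
  z <- (k - m) / s
  structure(
    list(n = as.integer(n), k = as.integer(k), p = p, mean = m, sd = s,
         z = z, z_threshold = z_threshold, significant = z > z_threshold),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Binomial cluster-enrichment test\n")
  cat(sprintf("  n = %d variants in union, k = %d in intersection (%.1f%%)\n",
              x$n, x$k, 100 * x$k / x$n))
  cat(sprintf("  overlap probability p = %.4g\n", x$p))
  cat(sprintf("  expected %.2f +/- %.2f, observed %d\n", x$mean, x$sd, x$k))
  cat(sprintf("  z = %.2f (%ssignificant at z > %.2f)\n", x$z,
              if (x$significant) "" else "not ", x$z_threshold))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname binomial_cluster_test
#' @param x An `overlap_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.overlap_test <- function(x, ...) {
  tibble(n = x$n, k = x$k, p = x$p, mean = x$mean, sd = x$sd, z = x$z,
         significant = x$significant)
}

#' @rdname binomial_cluster_test
#' @exportS3Method generics::glance
glance.overlap_test <- function(x, ...) {
  tibble(z = x$z, z_threshold = x$z_threshold, significant = x$significant,
         observed_fraction = x$k / x$n, expected_fraction = x$p)
}
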
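#' Top-s sample set induced by a gene
#'
#' Reduces a gene's expression vector to the partition it induces on the
#' samples: the s samples where it is most highly expressed against the
#' remaining n - s. Ties at the boundary are broken deterministically by
#' ascending sample index, so the result is reproducible across runs.
#' Sample indices are 1-based.
#'
#' @param values complete (post-imputation) numeric vector of length n.
#' @param s partition size, 1 <= s <= n.
#' @param probe_id optional identifier carried along.
#' @return An object of class `top_sample_set`: list with `probe_id`, `s`,
#'   `samples` (sorted integer vector of size s) and `rank_order` (the same
#'   indices ordered by descending expression).
#' @export
induce_partition <- function(values, s, probe_id = "") {
  n <- length(values)
  s <- as.integer(s)
  if (s < 1L || s > n) stop("'s' out of range: s = ", s, ", n = ", n)
  if (anyNA(values)) stop("'values' must be complete (impute first)")
  ord <- order(-values, seq_len(n))[seq_len(s)]
  structure(list(probe_id = probe_id, s = s,
                 samples = sort.int(ord), rank_order = ord),
            class = "top_sample_set")
}

#' @export
print.top_sample_set <- function(x, ...) {
  cat(sprintf("top_sample_set '%s': s = %d, samples {%s}\n",
              x$probe_id, x$s, paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Overlap deficit between two top-s sample sets
#'
#' For equal-size sets A, B the deficit s - |A intersect B| equals |A \ B| =
#' |B \ A| (half the symmetric difference); it is 0 iff the sets are
#' identical and at most s.
#'
#' @param a,b `top_sample_set` objects with equal `s`.
#' @return Integer mismatch count.
#' @export
mismatch <- function(a, b) {
  if (a$s != b$s) stop("partition sizes differ: ", a$s, " vs ", b$s)
  a$s - length(intersect(a$samples, b$samples))
}

#' Tolerance-t matching rule
#'
#' Two genes induce the "same" partition at tolerance t when their top-s
#' sample sets differ in at most t elements. Monotone in t: a match at t is a
#' match at every larger t.
#'
#' @inheritParams mismatch
#' @param t tolerance, integer >= 0.
#' @return Logical.
#' @export
is_match <- function(a, b, t) {
  if (t < 0) stop("'t' must be >= 0")
  mismatch(a, b) <= t
}

#' Tail probability of the overlap of two random size-s subsets
#'
#' Probability that two independent uniform-random size-s subsets of n
#' samples share at least k elements:
#' sum_{i >= k} C(s, i) C(n - s, s - i) / C(n, s) — the upper tail of the
#' hypergeometric distribution. This counting rule bounds how surprising an
#' observed top-s overlap is under independence, and motivates the grid
#' bounds on (s, t).
#'
#' @param n number of samples.
#' @param s subset size.
#' @param k minimum overlap, 0 <= k <= s <= n.
#' @return Probability in \[0, 1\].
#' @export
overlap_tail_pvalue <- function(n, s, k) {
  if (k < 0 || s < k || n < s) stop("require 0 <= k <= s <= n")
  if (k == 0) return(1)
  stats::phyper(k - 1, s, n - s, s, lower.tail = FALSE)
}
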
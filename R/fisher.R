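#' Two-sided Fisher's exact test for lesion presence counts
#'
#' For a voxel where `a` of `n1` group-A patients and `b` of `n2` group-B
#' patients carry a lesion, the 2x2 table is `[[a, n1-a], [b, n2-b]]`. The
#' two-sided p-value follows the point-probability rule: with both margins
#' fixed the first cell is hypergeometric, and p is the sum of the point
#' probabilities of all tables in the support whose probability does not
#' exceed that of the observed table (relative tolerance 1e-7 on the
#' comparison, guarding against floating-point ties).
#'
#' @param a,b lesion counts in groups A and B.
#' @param n1,n2 group sizes.
#' @return p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, n1, n2) {
  if (a < 0 || a > n1 || b < 0 || b > n2) {
    stop("counts out of range: need 0 <= a <= n1 and 0 <= b <= n2")
  }
  m <- a + b
  k <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(k, n1, n2, m)
  keep <- probs <= probs[match(a, k)] * (1 + 1e-7)
  if (all(keep)) 1 else min(1, sum(probs[keep]))
}

#' Precompute all Fisher p-values for fixed group sizes
#'
#' At fixed (n1, n2) only (n1 + 1) x (n2 + 1) distinct count pairs exist, so
#' the voxel-wise test reduces to one lookup per voxel.
#'
#' @param n1,n2 group sizes.
#' @return (n1+1) x (n2+1) matrix; entry `[a + 1, b + 1]` is
#'   `fisher_two_sided(a, b, n1, n2)`.
#' @export
fisher_p_table <- function(n1, n2) {
  out <- matrix(NA_real_, n1 + 1L, n2 + 1L)
  for (m in 0:(n1 + n2)) {
    k <- max(0, m - n2):min(n1, m)
    probs <- stats::dhyper(k, n1, n2, m)
    for (i in seq_along(k)) {
      keep <- probs <= probs[i] * (1 + 1e-7)
      out[k[i] + 1L, m - k[i] + 1L] <-
        if (all(keep)) 1 else min(1, sum(probs[keep]))
    }
  }
  out
}
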
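#' Two-sample two-dimensional Kolmogorov-Smirnov (Fasano-Franceschini) test
#'
#' Generalizes the two-sample KS test to 2D point clouds. Every data point
#' serves as a quadrant origin: the plane is split into four blocks, the
#' empirical block probabilities of the two samples are compared, and the
#' statistic conditioned on one sample is the maximum discrepancy over that
#' sample's origins; `D` is the mean of the two conditioned maxima. At each
#' origin both the boundary-inclusive (`<=`) and the strict (`<`) quadrant
#' partitions are evaluated and the larger discrepancy kept, the 2D
#' analogue of taking the supremum of `|F_A - F_B|` from both sides of a
#' jump in 1D. When one coordinate is constant the statistic reduces
#' exactly to the one-dimensional two-sample KS statistic. The p-value is
#' obtained by permutation of the pooled sample labels.
#'
#' @param a,b two-column matrices or data.frames of (x, y) points; each
#'   sample needs at least 3 points.
#' @param nPerm number of label permutations (0 skips the p-value).
#' @param seed integer seed for the permutations.
#' @return list with `D` (in `[0, 1]`), `p`, `n_a`, `n_b`, `nPerm`.
#' @examples
#' a <- cbind(rnorm(20), rnorm(20))
#' fasano_franceschini(a, a + 2, nPerm = 200, seed = 1)$D
#' @export
fasano_franceschini <- function(a, b, nPerm = 2000, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 2 || ncol(b) != 2) stop("samples must be two-column")
  if (nrow(a) < 3 || nrow(b) < 3) stop("each sample needs >= 3 points")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite coordinates")
  x <- c(a[, 1], b[, 1]); y <- c(a[, 2], b[, 2])
  lab <- c(rep(0L, nrow(a)), rep(1L, nrow(b)))
  degenerate <- length(unique(x)) == 1 && length(unique(y)) == 1
  if (degenerate) warning("all points identical; D = 0 and p = 1")
  res <- with_seed(seed, .ff_test_cpp(x, y, lab, as.integer(nPerm)))
  list(D = res$D, p = if (degenerate && nPerm > 0) 1 else res$p,
       n_a = nrow(a), n_b = nrow(b), nPerm = nPerm)
}
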
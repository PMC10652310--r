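#' Rank genes for preranked enrichment
#'
#' Orders tested genes by a signed score, descending, with deterministic
#' lexicographic tie-breaking on gene id. No fold-change filtering is
#' applied: every tested gene enters the ranking.
#'
#' @param de a `de_result` data.frame (from [nb_wald_test()] or
#'   [nb_quasi_test()]).
#' @param metric ranking score: the test statistic (default) or the log2
#'   fold change.
#' @return Named numeric vector of scores, sorted descending.
#' @export
rank_genes <- function(de, metric = c("stat", "log2FC")) {
  metric <- match.arg(metric)
  sc <- de[[metric]]
  keep <- !is.na(sc) & is.finite(sc)
  if (!any(keep)) stop("no finite scores to rank")
  sc <- sc[keep]
  names(sc) <- de$gene[keep]
  sc[order(-sc, names(sc), method = "radix")]
}

# ES of a weighted KS running sum given sorted hit positions.
# after[i]  = value just after hit i; before[i] = value just before hit i.
# The walk is piecewise linear decreasing between hits and ends at 0, so the
# signed extremum is attained at one of these 2k points.
.es_from_hits <- function(pos, wts, N) {
  k <- length(pos)
  if (k == 0) stop("empty hit set")
  if (k >= N) stop("set spans the whole universe; ES is degenerate")
  Wk <- sum(wts)
  if (Wk <= 0) wts <- rep(1, k)
  W <- cumsum(wts) / sum(wts)
  miss <- (pos - seq_len(k)) / (N - k)
  after <- W - miss
  before <- c(0, W[-k]) - miss
  i_max <- which.max(after)
  i_min <- which.min(before)
  max_dev <- unname(after[i_max])
  min_dev <- min(unname(before[i_min]), 0)
  if (max_dev >= -min_dev) list(es = max_dev, at = i_max, sign = 1L)
  else list(es = min_dev, at = i_min, sign = -1L)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: each set member ("hit") increments the running sum
#' by its `|score|^w` normalized by the in-set total; each miss decrements by
#' `1/(N - k)`. The enrichment score is the signed extremum of the walk.
#'
#' @param ranked named numeric vector from [rank_genes()].
#' @param set character vector of member genes.
#' @param w hit weight exponent (0 gives the classic unweighted KS walk).
#' @return list with `es`, `argmax` (rank position of the extremum),
#'   `hits` (rank positions of members), `leading_edge` (member genes up to,
#'   or from, the extremum depending on sign).
#' @export
enrichment_score <- function(ranked, set, w = 1) {
  pos <- which(names(ranked) %in% set)
  if (!length(pos)) stop("set does not intersect the ranked universe")
  wts <- abs(ranked[pos])^w
  r <- .es_from_hits(pos, wts, length(ranked))
  le <- if (r$sign > 0) names(ranked)[pos[seq_len(r$at)]]
        else names(ranked)[pos[r$at:length(pos)]]
  list(es = r$es, argmax = pos[r$at], hits = pos, leading_edge = le)
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For each eligible set, computes the weighted-KS enrichment score, then
#' builds a null by redrawing the set's rank positions at random (membership
#' permutation, the preranked convention), preserving set size. The
#' permutation p-value and the normalized enrichment score are
#' sign-stratified: a set's ES is compared against permuted ES of matching
#' sign, and NES is the ES divided by the mean absolute permuted ES of that
#' sign. Benjamini-Hochberg adjustment is applied across reported sets.
#'
#' @param de a `de_result` or a pre-ranked named numeric vector of scores.
#' @param gmt named list of gene sets (e.g. from [read_gmt()]).
#' @param nPerm number of membership permutations (p >= 1/(nPerm+1)).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe; sets outside the bounds are excluded.
#' @param w hit weight exponent.
#' @param metric ranking metric when `de` is a `de_result`.
#' @param seed integer seed for the permutation draws.
#' @return data.frame (`enrichment_result`): `set`, `size`, `ES`, `NES`,
#'   `p`, `q`, `direction`, `leading_edge` (comma-separated). Parameters are
#'   recorded in attributes `nPerm`, `min_size`, `max_size`, `w`.
#' @export
gsea <- function(de, gmt, nPerm = 15000, min_size = 10, max_size = 600,
                 w = 1, metric = "stat", seed = 1L) {
  ranked <- if (is.numeric(de)) {
    if (is.null(names(de))) stop("pre-ranked scores must be named")
    de[order(-de, names(de), method = "radix")]
  } else rank_genes(de, metric)
  N <- length(ranked)
  absw <- abs(ranked)^w
  universe <- names(ranked)

  sizes <- vapply(gmt, function(s) sum(universe %in% s), integer(1))
  eligible <- sizes >= min_size & sizes <= max_size
  if (!any(eligible)) {
    warning("no gene set within the size bounds")
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0), leading_edge = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- with_seed(seed, {
      rows <- lapply(names(gmt)[eligible], function(nm) {
        obs <- enrichment_score(ranked, gmt[[nm]], w)
        k <- length(obs$hits)
        perm <- vapply(seq_len(nPerm), function(i) {
          pos <- sort.int(sample.int(N, k))
          .es_from_hits(pos, absw[pos], N)$es
        }, numeric(1))
        same <- if (obs$es >= 0) perm[perm >= 0] else perm[perm < 0]
        p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
        nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
        data.frame(set = nm, size = k, ES = obs$es, NES = nes, p = p,
                   direction = if (obs$es >= 0) "up" else "down",
                   leading_edge = paste(obs$leading_edge, collapse = ","),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, c(rows, make.row.names = FALSE))
    })
    out$q <- bh_adjust(out$p)
    out <- out[, c("set", "size", "ES", "NES", "p", "q", "direction",
                   "leading_edge")]
  }
  attr(out, "nPerm") <- nPerm
  attr(out, "min_size") <- min_size
  attr(out, "max_size") <- max_size
  attr(out, "w") <- w
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Pairwise overlap of significant gene sets
#'
#' Plain set-overlap bookkeeping for enriched categories: shared-gene counts
#' and Jaccard indices between every pair of selected sets.
#'
#' @param results an `enrichment_result` data.frame, or a character vector
#'   of set names.
#' @param gmt named list of gene sets.
#' @param q_max when `results` is an `enrichment_result`, keep sets with
#'   `q < q_max`; use `Inf` to keep all.
#' @return data.frame with one row per unordered pair: `set_a`, `set_b`,
#'   `shared`, `jaccard`.
#' @export
set_overlap_table <- function(results, gmt, q_max = 0.05) {
  nms <- if (is.character(results)) results
         else results$set[!is.na(results$q) & results$q < q_max]
  nms <- intersect(nms, names(gmt))
  if (length(nms) < 2)
    return(data.frame(set_a = character(0), set_b = character(0),
                      shared = integer(0), jaccard = numeric(0)))
  prs <- utils::combn(nms, 2)
  rows <- apply(prs, 2, function(p) {
    a <- unique(gmt[[p[1]]]); b <- unique(gmt[[p[2]]])
    sh <- length(intersect(a, b))
    data.frame(set_a = p[1], set_b = p[2], shared = sh,
               jaccard = sh / length(union(a, b)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
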
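#' Principal-component association with Smurfness and age
#'
#' PCA on the `n_top` highest-variance genes of the log-normalized
#' expression matrix, followed by association of the first two components
#' with the binary Smurf state (one-way ANOVA R-squared and p) and with
#' chronological age (Pearson correlation and p). In a biphasic cohort the
#' expected structure is a first component separating Smurfs from
#' non-Smurfs and a second tracking age.
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata with `smurf` and `age_days` columns.
#' @param n_top number of top-variance genes entering the PCA (capped at the
#'   gene count, with a warning).
#' @param sf optional size factors.
#' @return list with `var_explained` (fraction per PC), `assoc`
#'   (data.frame: `pc`, `factor`, `statistic` -- ANOVA R2 or Pearson r --
#'   and `p`), and `scores` (samples x PCs).
#' @export
pca_factor_association <- function(counts, metadata, n_top = 1000,
                                   sf = NULL) {
  if (ncol(counts) < 3) stop("need >= 3 samples")
  X <- log_norm(counts, sf)
  if (n_top > nrow(X)) {
    warning("n_top exceeds gene count; using all genes")
    n_top <- nrow(X)
  }
  v <- apply(X, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  pc <- stats::prcomp(t(X[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)

  assoc_one <- function(score, pc_name) {
    fit <- stats::aov(score ~ factor(metadata$smurf))
    ss <- summary(fit)[[1]]
    r2 <- ss[["Sum Sq"]][1] / sum(ss[["Sum Sq"]])
    p_an <- ss[["Pr(>F)"]][1]
    ct <- stats::cor.test(score, metadata$age_days)
    rbind(
      data.frame(pc = pc_name, factor = "smurf", statistic = r2, p = p_an),
      data.frame(pc = pc_name, factor = "age", statistic = unname(ct$estimate),
                 p = ct$p.value))
  }
  assoc <- rbind(assoc_one(pc$x[, 1], "PC1"), assoc_one(pc$x[, 2], "PC2"))
  list(var_explained = ve, assoc = assoc, scores = pc$x)
}

# Vectorized OLS of every gene on a fixed design matrix.
# Returns coefficients, per-coefficient t p-values, R2 and overall F p.
.lm_scan <- function(Y, X) {
  n <- ncol(Y); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("collinear design: rank ", qx$rank, " < ", p)
  B <- qr.coef(qx, t(Y))                       # p x G
  res <- t(Y) - X %*% B                        # n x G
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  xtxi <- chol2inv(qr.R(qx))
  se <- sqrt(outer(diag(xtxi), sigma2))        # p x G
  tstat <- B / pmax(se, 1e-300)
  pt2 <- 2 * stats::pt(abs(tstat), df = n - p, lower.tail = FALSE)
  pt2 <- pmax(pt2, 1e-300)
  ybar <- colMeans(t(Y))
  tss <- colSums((t(Y) - rep(ybar, each = n))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  fstat <- ((tss - rss) / (p - 1)) / pmax(sigma2, 1e-300)
  fp <- pmax(stats::pf(fstat, p - 1, n - p, lower.tail = FALSE), 1e-300)
  list(coef = B, p = pt2, r2 = r2, f_p = fp)
}

#' Per-gene Smurfness x age interaction scan
#'
#' Fits, for every gene, an ordinary least-squares model of log-normalized
#' expression on Smurf status, chronological age (per decade, centred at
#' 20 days) and their interaction, and tests each coefficient. The
#' interaction coefficient captures expression changes specific to old
#' Smurfs. Benjamini-Hochberg adjustment is applied within each coefficient
#' family separately.
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata with `smurf` (0/1) and `age_days`.
#' @param q_max FDR threshold for the exported significant-gene lists.
#' @param sf optional size factors.
#' @return list with `table` (per gene: coefficients, p/q per coefficient,
#'   `r2`, overall `f_p`) and `significant` (gene lists for `smurf`, `age`,
#'   `interaction`).
#' @export
interaction_scan <- function(counts, metadata, q_max = 0.05, sf = NULL) {
  if (length(unique(metadata$smurf)) < 2 ||
      length(unique(metadata$age_days)) < 2)
    stop("need both Smurf states and >= 2 ages")
  Y <- log_norm(counts, sf)
  aged <- (metadata$age_days - 20) / 10
  X <- cbind(intercept = 1, smurf = metadata$smurf, age = aged,
             interaction = metadata$smurf * aged)
  fit <- .lm_scan(Y, X)
  gene <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))
  tab <- data.frame(
    gene = gene,
    b_intercept = fit$coef[1, ], b_smurf = fit$coef[2, ],
    b_age = fit$coef[3, ], b_interaction = fit$coef[4, ],
    p_smurf = fit$p[2, ], p_age = fit$p[3, ], p_interaction = fit$p[4, ],
    r2 = fit$r2, f_p = fit$f_p, stringsAsFactors = FALSE)
  tab$q_smurf <- bh_adjust(tab$p_smurf)
  tab$q_age <- bh_adjust(tab$p_age)
  tab$q_interaction <- bh_adjust(tab$p_interaction)
  sig <- function(q) tab$gene[!is.na(q) & q < q_max]
  list(table = tab,
       significant = list(smurf = sig(tab$q_smurf), age = sig(tab$q_age),
                          interaction = sig(tab$q_interaction)))
}

#' Age regression in non-Smurfs with significance and fit filters
#'
#' Regresses each gene's log-normalized expression on chronological age
#' using non-Smurf samples only, and retains genes passing both an F-test
#' (`p < p_max`) and a goodness-of-fit filter (`R2 > r2_min`). The retained
#' genes are partitioned by slope sign; overlap with a supplied Smurf DEG
#' list is reported, quantifying how much of the apparent chronological
#' signal is shared with the Smurf signature.
#'
#' @param counts genes x samples count matrix (all samples; Smurfs are
#'   dropped internally).
#' @param metadata sample metadata with `smurf` and `age_days`.
#' @param p_max F-test threshold.
#' @param r2_min R-squared threshold.
#' @param smurf_degs optional character vector of Smurf DEG ids.
#' @param sf optional size factors (estimated on the full matrix).
#' @return list with `table` (gene, slope per day, `r2`, `p`, `passes`),
#'   `passing`, `n_up`, `n_down`, and `overlap` (count and fraction of
#'   passing genes present in `smurf_degs`, when supplied).
#' @export
age_regression_nonsmurf <- function(counts, metadata, p_max = 0.05,
                                    r2_min = 0.5, smurf_degs = NULL,
                                    sf = NULL) {
  sf <- sf %||% size_factors(counts)
  ns <- metadata$smurf == 0
  if (length(unique(metadata$age_days[ns])) < 3)
    stop("need >= 3 distinct ages among non-Smurf samples")
  Y <- log_norm(counts, sf)[, ns, drop = FALSE]
  x <- metadata$age_days[ns]
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(Y %*% xc) / sxx
  fitted_ss <- slope^2 * sxx
  tss <- rowSums((Y - rowMeans(Y))^2)
  r2 <- ifelse(tss > 0, fitted_ss / tss, NA_real_)
  r2 <- pmin(r2, 1)
  fstat <- r2 / pmax(1 - r2, 1e-300) * (n - 2)
  p <- pmax(stats::pf(fstat, 1, n - 2, lower.tail = FALSE), 1e-300)
  gene <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))
  passes <- !is.na(r2) & p < p_max & r2 > r2_min
  tab <- data.frame(gene = gene, slope = slope, r2 = r2, p = p,
                    passes = passes, stringsAsFactors = FALSE)
  passing <- tab$gene[passes]
  out <- list(table = tab, passing = passing,
              n_up = sum(passes & slope > 0),
              n_down = sum(passes & slope < 0))
  if (!is.null(smurf_degs)) {
    shared <- intersect(passing, smurf_degs)
    out$overlap <- list(n = length(shared),
                        fraction = if (length(passing))
                          length(shared) / length(passing) else NA_real_)
  }
  out
}

#' Transcriptional-noise (relative standard deviation) analysis
#'
#' Computes, within every (Smurf state, age) group with at least 3 samples,
#' the per-gene relative standard deviation (sd/mean of normalized
#' expression; genes with zero mean excluded), locates the peak of each
#' group's RSD distribution by Gaussian-kernel density (Silverman bandwidth,
#' 512-point grid over the uncapped values), and compares age groups within
#' each state by two-sample KS tests. The 40-vs-20-day peak ratio per state
#' is the headline noise readout; `rsd_cap` only truncates plots, never the
#' statistics.
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata with `smurf` and `age_days`.
#' @param rsd_cap display cap stored alongside the results.
#' @param sf optional size factors.
#' @return A `noise_summary` list: `rsd` (long data.frame gene, smurf,
#'   age_days, rsd), `peaks` (density modes per group), `ks` (pairwise KS D
#'   and p between ages within state), `peak_ratios` (oldest/youngest peak
#'   per state).
#' @export
rsd_analysis <- function(counts, metadata, rsd_cap = 0.6, sf = NULL) {
  N <- normalized_counts(counts, sf)
  gene <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))
  groups <- unique(metadata[, c("smurf", "age_days")])
  groups <- groups[order(groups$smurf, groups$age_days), ]
  rsd_long <- list(); peaks <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- metadata$smurf == groups$smurf[i] &
      metadata$age_days == groups$age_days[i]
    if (sum(sel) < 3) {
      warning(sprintf("group (smurf=%d, age=%g) has <3 samples; skipped",
                      groups$smurf[i], groups$age_days[i]))
      next
    }
    M <- N[, sel, drop = FALSE]
    mu <- rowMeans(M)
    ok <- mu > 0
    if (!any(ok)) {
      warning(sprintf("group (smurf=%d, age=%g) has no expressed genes; skipped",
                      groups$smurf[i], groups$age_days[i]))
      next
    }
    rsd <- apply(M[ok, , drop = FALSE], 1, stats::sd) / mu[ok]
    # the kernel density needs >= 2 points; with a single expressed gene the
    # modal RSD is that gene's RSD
    peak_rsd <- if (length(rsd) >= 2) {
      d <- stats::density(rsd, bw = "nrd0", n = 512, from = 0, to = max(rsd))
      d$x[which.max(d$y)]
    } else unname(rsd)
    key <- sprintf("s%d_a%g", groups$smurf[i], groups$age_days[i])
    rsd_long[[key]] <- data.frame(gene = gene[ok], smurf = groups$smurf[i],
                                  age_days = groups$age_days[i], rsd = rsd,
                                  stringsAsFactors = FALSE)
    peaks[[key]] <- data.frame(smurf = groups$smurf[i],
                               age_days = groups$age_days[i],
                               peak = peak_rsd,
                               n_genes = sum(ok))
  }
  rsd_long <- do.call(rbind, c(rsd_long, make.row.names = FALSE))
  peaks <- do.call(rbind, c(peaks, make.row.names = FALSE))

  ks <- list()
  for (s in unique(peaks$smurf)) {
    ages <- sort(peaks$age_days[peaks$smurf == s])
    if (length(ages) < 2) next
    for (pair in utils::combn(ages, 2, simplify = FALSE)) {
      a <- rsd_long$rsd[rsd_long$smurf == s & rsd_long$age_days == pair[1]]
      b <- rsd_long$rsd[rsd_long$smurf == s & rsd_long$age_days == pair[2]]
      kt <- suppressWarnings(stats::ks.test(a, b))
      ks[[length(ks) + 1L]] <- data.frame(
        smurf = s, age_a = pair[1], age_b = pair[2],
        D = unname(kt$statistic), p = kt$p.value)
    }
  }
  ks <- if (length(ks)) do.call(rbind, ks) else
    data.frame(smurf = integer(0), age_a = numeric(0), age_b = numeric(0),
               D = numeric(0), p = numeric(0))

  ratios <- do.call(rbind, lapply(unique(peaks$smurf), function(s) {
    ps <- peaks[peaks$smurf == s, ]
    data.frame(smurf = s,
               age_young = min(ps$age_days), age_old = max(ps$age_days),
               ratio = ps$peak[which.max(ps$age_days)] /
                 ps$peak[which.min(ps$age_days)])
  }))
  structure(list(rsd = rsd_long, peaks = peaks, ks = ks,
                 peak_ratios = ratios, rsd_cap = rsd_cap),
            class = "noise_summary")
}

#' Per-gene correlation map and gene-set tests in (r_smurf, r_age) space
#'
#' For every gene, computes the point-biserial correlation of
#' log-normalized expression with Smurf status and the Pearson correlation
#' with chronological age. Each gene set with at least `min_genes` detected
#' members is then compared against the remaining genes in this 2D
#' correlation space with the permutation Fasano-Franceschini test,
#' locating pathways along the Smurfness and chronological-age axes.
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata with `smurf` and `age_days`.
#' @param gmt named list of gene sets.
#' @param min_genes minimum detected members per set.
#' @param nPerm label permutations for each set's test.
#' @param sf optional size factors.
#' @param seed integer seed.
#' @return A `correlation_map` list: `genes` (gene, r_smurf, r_age) and
#'   `sets` (set, n_genes, mean_r_smurf, mean_r_age, D, p, BH q).
#' @export
correlation_map <- function(counts, metadata, gmt, min_genes = 10,
                            nPerm = 2000, sf = NULL, seed = 1L) {
  X <- log_norm(counts, sf)
  gene <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))
  s <- as.numeric(metadata$smurf)
  a <- as.numeric(metadata$age_days)
  r_s <- suppressWarnings(as.numeric(stats::cor(t(X), s)))
  r_a <- suppressWarnings(as.numeric(stats::cor(t(X), a)))
  ok <- is.finite(r_s) & is.finite(r_a)
  genes <- data.frame(gene = gene[ok], r_smurf = r_s[ok], r_age = r_a[ok],
                      stringsAsFactors = FALSE)

  rows <- list()
  for (nm in names(gmt)) {
    memb <- genes$gene %in% gmt[[nm]]
    if (sum(memb) < min_genes) next
    ff <- fasano_franceschini(
      genes[memb, c("r_smurf", "r_age")],
      genes[!memb, c("r_smurf", "r_age")],
      nPerm = nPerm, seed = derive_seed(seed, paste0("ff_", nm)))
    rows[[nm]] <- data.frame(
      set = nm, n_genes = sum(memb),
      mean_r_smurf = mean(genes$r_smurf[memb]),
      mean_r_age = mean(genes$r_age[memb]),
      D = ff$D, p = ff$p, stringsAsFactors = FALSE)
  }
  sets <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
          else data.frame(set = character(0), n_genes = integer(0),
                          mean_r_smurf = numeric(0), mean_r_age = numeric(0),
                          D = numeric(0), p = numeric(0))
  sets$q <- bh_adjust(sets$p)
  structure(list(genes = genes, sets = sets), class = "correlation_map")
}

#' Attribute ageing transcriptional hallmarks to Smurfness or age
#'
#' Combines per-contrast enrichment results with the noise summary to
#' assign each hallmark (ATH1-ATH6) to the axis that drives it. A hallmark
#' counts as responsive in a contrast when any of its mapped sets reaches
#' `q < q_max` there. Precedence: responsive in the non-Smurf age contrast
#' -> `chronological`; otherwise responsive in the old- vs young-Smurf
#' contrast -> `old_smurf`; otherwise responsive in the Smurf vs non-Smurf
#' contrast -> `smurf_specific`; otherwise `none`. The noise facet of ATH6
#' is attributed separately: `chronological` when the old/young RSD peak
#' ratio exceeds `noise_ratio_min` in both Smurf states.
#'
#' @param enrichments named list of `enrichment_result` tables for contrasts
#'   `smurf` (Smurf vs non-Smurf), `old_smurf` (old vs young Smurfs) and
#'   `nonsmurf_age` (old vs young non-Smurfs).
#' @param noise a [rsd_analysis()] `noise_summary`.
#' @param hallmark_map data.frame with columns `set`, `hallmark`.
#' @param q_max enrichment FDR threshold.
#' @param noise_ratio_min peak-ratio threshold for the noise facet.
#' @return data.frame: `hallmark`, `facet`, the per-contrast significance
#'   flags and the final `attribution`.
#' @export
hallmark_attribution <- function(enrichments, noise, hallmark_map,
                                 q_max = 0.05, noise_ratio_min = 1.5) {
  need <- c("smurf", "old_smurf", "nonsmurf_age")
  if (!all(need %in% names(enrichments)))
    stop("enrichments must contain: ", paste(need, collapse = ", "))
  hallmarks <- union(paste0("ATH", 1:6), unique(hallmark_map$hallmark))
  sig_in <- function(res, sets) {
    hit <- res$set %in% sets & !is.na(res$q) & res$q < q_max
    any(hit)
  }
  rows <- lapply(hallmarks, function(h) {
    sets <- hallmark_map$set[hallmark_map$hallmark == h]
    present <- any(unlist(lapply(enrichments[need],
                                 function(r) sets %in% r$set)))
    if (!length(sets) || !present) {
      warning("hallmark ", h, " has no mapped set in the enrichment results")
      return(data.frame(hallmark = h, facet = "expression",
                        sig_smurf = FALSE, sig_old_smurf = FALSE,
                        sig_age = FALSE, attribution = "none",
                        stringsAsFactors = FALSE))
    }
    s1 <- sig_in(enrichments$smurf, sets)
    s2 <- sig_in(enrichments$old_smurf, sets)
    s3 <- sig_in(enrichments$nonsmurf_age, sets)
    attr_ <- if (s3) "chronological" else if (s2) "old_smurf"
             else if (s1) "smurf_specific" else "none"
    data.frame(hallmark = h, facet = "expression", sig_smurf = s1,
               sig_old_smurf = s2, sig_age = s3, attribution = attr_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  noisy <- nrow(noise$peak_ratios) > 0 &&
    all(noise$peak_ratios$ratio > noise_ratio_min)
  tab <- rbind(tab, data.frame(
    hallmark = "ATH6", facet = "noise", sig_smurf = FALSE,
    sig_old_smurf = FALSE, sig_age = noisy,
    attribution = if (noisy) "chronological" else "none",
    stringsAsFactors = FALSE))
  tab
}

#' Expected bulk expression of an unlabeled Smurf/non-Smurf mixture
#'
#' At prevalence `p`, the population-mean expression of a gene is
#' `(1 - p) * mu_nonsmurf + p * mu_smurf`. As prevalence rises with age, a
#' purely Smurf-associated gene acquires a spurious chronological-age slope
#' in unlabeled samples -- the core confounding that motivates stratifying
#' expression analyses by Smurf state.
#'
#' @param mu_nonsmurf,mu_smurf per-gene mean expression in each state.
#' @param p prevalence, scalar or vector in `[0, 1]`.
#' @return If `p` is scalar, a vector of mixture means; otherwise a
#'   genes x length(p) matrix.
#' @export
mixture_projection <- function(mu_nonsmurf, mu_smurf, p) {
  if (any(p < 0 | p > 1)) stop("prevalence must lie in [0, 1]")
  if (length(mu_nonsmurf) != length(mu_smurf))
    stop("state mean vectors differ in length")
  if (length(p) == 1) (1 - p) * mu_nonsmurf + p * mu_smurf
  else outer(mu_nonsmurf, 1 - p) + outer(mu_smurf, p)
}
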
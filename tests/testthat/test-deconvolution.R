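test_that("PCA attributes a dominant binary shift to the first component", {
  set.seed(11)
  n_g <- 300; n_s <- 12
  smurf <- rep(c(0L, 1L), each = 6)
  mu <- matrix(rep(rlnorm(n_g, 5, 1), n_s), ncol = n_s)
  mu[1:150, smurf == 1] <- mu[1:150, smurf == 1] * 4
  counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = 50), ncol = n_s,
                   dimnames = list(sprintf("g%03d", 1:n_g),
                                   sprintf("s%02d", 1:n_s)))
  meta <- data.frame(sample = colnames(counts), smurf = smurf,
                     age_days = rep(c(20L, 30L, 40L), 4))
  expect_warning(res <- pca_factor_association(counts, meta, n_top = 1000),
                 "using all genes")
  r2 <- res$assoc$statistic[res$assoc$pc == "PC1" &
                              res$assoc$factor == "smurf"]
  expect_gt(r2, 0.9)
  expect_equal(sum(res$var_explained), 1, tolerance = 1e-12)
})

test_that("PCA tracks age when age is the only signal", {
  tr <- generate_gene_truth(
    n_genes = 1200,
    class_fractions = c(smurf_up = 0, smurf_down = 0, age_linear = 0.3,
                        old_smurf_interaction = 0),
    effect_mean_age = 1, seed = 12)
  ex <- simulate_counts(tr, seed = 13)
  res <- pca_factor_association(ex$counts, ex$samples)
  pc1 <- res$assoc[res$assoc$pc == "PC1", ]
  expect_lt(pc1$p[pc1$factor == "age"], 0.01)
  expect_gt(abs(pc1$statistic[pc1$factor == "age"]), 0.7)
  expect_gt(pc1$p[pc1$factor == "smurf"], 0.05)
})

test_that("the study bundle separates Smurfness (PC1) from age (PC2)", {
  ex <- mid_expt()
  res <- pca_factor_association(ex$counts, ex$samples, sf = mid_sf())
  a <- res$assoc
  expect_lt(a$p[a$pc == "PC1" & a$factor == "smurf"], 0.01)
  expect_lt(a$p[a$pc == "PC2" & a$factor == "age"], 0.01)
  expect_error(pca_factor_association(ex$counts[, 1:2],
                                      ex$samples[1:2, ]), ">= 3 samples")
})

test_that("the interaction scan is exact on noise-free constructions", {
  meta <- default_design()
  n <- nrow(meta)
  aged <- (meta$age_days - 20) / 10
  # expression y = 3 + 0.5 * smurf exactly (counts = 2^y - 1, unit factors)
  y <- 3 + 0.5 * meta$smurf
  counts <- matrix(2^y - 1, nrow = 1,
                   dimnames = list("g1", meta$sample))
  res <- interaction_scan(rbind(counts, counts), meta, sf = rep(1, n))
  expect_equal(res$table$b_smurf[1], 0.5, tolerance = 1e-10)
  expect_equal(res$table$b_age[1], 0, tolerance = 1e-10)
  expect_equal(res$table$b_interaction[1], 0, tolerance = 1e-10)
  expect_equal(res$table$r2[1], 1, tolerance = 1e-10)
})

test_that("a pure interaction signal hits only the interaction term", {
  meta <- default_design()
  aged <- (meta$age_days - 20) / 10
  set.seed(14)
  # 60 replicate genes with the same pure-interaction signal and
  # independent noise: every interaction p-value is tiny, while the
  # main-effect p-values behave as nulls (median near 0.5)
  G <- 60
  counts <- t(vapply(seq_len(G), function(g) {
    y <- 5 + 0.5 * meta$smurf * aged + rnorm(nrow(meta), sd = 0.02)
    2^y - 1
  }, numeric(nrow(meta))))
  rownames(counts) <- sprintf("g%02d", seq_len(G))
  colnames(counts) <- meta$sample
  res <- interaction_scan(counts, meta, sf = rep(1, nrow(meta)))
  expect_true(all(res$table$p_interaction < 1e-6))
  expect_gt(median(res$table$p_smurf), 0.2)
  expect_gt(median(res$table$p_age), 0.2)
  expect_true("g01" %in% res$significant$interaction)
})

test_that("interaction-scan type-I error is near nominal on null genes", {
  tr <- null_truth(2000, seed = 15, dispersion_age_gamma = 0)
  ex <- simulate_counts(tr, seed = 16)
  res <- interaction_scan(ex$counts, ex$samples)
  for (p in list(res$table$p_smurf, res$table$p_age,
                 res$table$p_interaction)) {
    expect_gt(mean(p < 0.05), 0.02)
    expect_lt(mean(p < 0.05), 0.09)
  }
})

test_that("collinear designs are rejected with a clear message", {
  meta <- data.frame(sample = paste0("s", 1:8),
                     smurf = rep(c(0L, 1L), each = 4),
                     age_days = rep(c(20L, 40L), each = 4))
  counts <- matrix(rpois(8 * 5, 50), nrow = 5,
                   dimnames = list(paste0("g", 1:5), meta$sample))
  # smurf == old indicator -> interaction column duplicates factors
  expect_error(interaction_scan(counts, meta, sf = rep(1, 8)), "collinear")
})

test_that("non-Smurf age regression is exact on a noise-free gene", {
  meta <- default_design()
  ns <- meta$smurf == 0
  y <- numeric(nrow(meta))
  y[ns] <- meta$age_days[ns] / 10
  y[!ns] <- 5
  counts <- rbind(g1 = 2^y - 1, g2 = 2^pmax(y, 0.5) - 1)
  colnames(counts) <- meta$sample
  res <- age_regression_nonsmurf(counts, meta, sf = rep(1, nrow(meta)))
  expect_equal(res$table$slope[1], 0.1, tolerance = 1e-10)
  expect_equal(res$table$r2[1], 1, tolerance = 1e-10)
  expect_true(res$table$passes[1])
  expect_equal(res$n_up, 2)
})

test_that("age regression needs three ages and filters noise genes", {
  meta <- default_design()
  sub <- meta$age_days %in% c(20, 40)
  counts <- matrix(rpois(sum(sub) * 4, 100), nrow = 4,
                   dimnames = list(paste0("g", 1:4), meta$sample[sub]))
  expect_error(age_regression_nonsmurf(counts, meta[sub, ]),
               ">= 3 distinct ages")

  tr <- null_truth(500, seed = 17)
  ex <- simulate_counts(tr, seed = 18)
  res <- age_regression_nonsmurf(ex$counts, ex$samples)
  expect_lt(mean(res$table$passes), 0.01)
})

test_that("generator age-class genes pass the regression filters", {
  tr <- mid_truth()
  ex <- mid_expt()
  smurf_degs <- mid_wald()
  degs <- smurf_degs$gene[!is.na(smurf_degs$q) & smurf_degs$q < 0.05]
  res <- age_regression_nonsmurf(ex$counts, ex$samples, smurf_degs = degs,
                                 sf = mid_sf())
  strong_age <- tr$gene[tr$class == "age_linear" & abs(tr$beta_age) >= 0.5]
  expect_gt(mean(strong_age %in% res$passing), 0.8)
  expect_true(all(c("n", "fraction") %in% names(res$overlap)))
  # slope signs match the generator
  idx <- match(intersect(strong_age, res$passing), res$table$gene)
  tru <- tr$beta_age[match(res$table$gene[idx], tr$gene)]
  expect_true(all(sign(res$table$slope[idx]) == sign(tru)))
})

test_that("RSD values, KS tests and peak ratios behave as constructed", {
  # gene (2, 4, 6): sd = 2, mean = 4 -> RSD = 0.5 exactly
  counts <- rbind(g1 = c(2, 4, 6), g2 = c(10, 10, 10))
  meta <- data.frame(sample = paste0("s", 1:3), smurf = 0L, age_days = 20L)
  colnames(counts) <- meta$sample
  ns <- rsd_analysis(counts, meta, sf = rep(1, 3))
  expect_equal(ns$rsd$rsd[ns$rsd$gene == "g1"], 0.5, tolerance = 1e-12)
  expect_equal(ns$rsd$rsd[ns$rsd$gene == "g2"], 0, tolerance = 1e-12)

  # identical age-group matrices -> KS D = 0
  counts2 <- cbind(counts, counts)
  meta2 <- data.frame(sample = paste0("s", 1:6), smurf = 0L,
                      age_days = rep(c(20L, 40L), each = 3))
  colnames(counts2) <- meta2$sample
  ns2 <- rsd_analysis(counts2, meta2, sf = rep(1, 6))
  expect_equal(ns2$ks$D, 0)
  expect_equal(ns2$peak_ratios$ratio, 1, tolerance = 1e-12)

  # undersized groups are skipped with warnings (one per skipped group)
  meta3 <- meta2; meta3$age_days[6] <- 30L
  w <- capture_warnings(rsd_analysis(counts2, meta3, sf = rep(1, 6)))
  expect_true(all(grepl("skipped", w)) && length(w) > 0)
})

test_that("zero-mean genes are excluded from RSD", {
  counts <- rbind(g1 = c(5, 6, 7), g2 = c(0, 0, 0))
  meta <- data.frame(sample = paste0("s", 1:3), smurf = 1L, age_days = 20L)
  colnames(counts) <- meta$sample
  ns <- rsd_analysis(counts, meta, sf = rep(1, 3))
  expect_false("g2" %in% ns$rsd$gene)
  expect_equal(ns$peaks$n_genes, 1)
})

test_that("correlation map is exact for an indicator gene", {
  meta <- default_design()
  ind <- as.numeric(meta$smurf)
  counts <- rbind(g1 = 2^(5 + ind) - 1,
                  g2 = 2^(5 + 0.01 * seq_len(nrow(meta))) - 1)
  colnames(counts) <- meta$sample
  cm <- correlation_map(counts, meta, gmt = list(), sf = rep(1, nrow(meta)))
  expect_equal(cm$genes$r_smurf[cm$genes$gene == "g1"], 1, tolerance = 1e-12)
  # ages are balanced across states, so the indicator is age-orthogonal
  expect_equal(cm$genes$r_age[cm$genes$gene == "g1"], 0, tolerance = 1e-12)
})

test_that("truth-built sets separate in correlation space; decoys need size", {
  ex <- mid_expt()
  gs <- mid_sets()
  gmt <- list(up = gs$sets$class_smurf_up,
              tiny = gs$sets$DECOY_01[1:5])
  cm <- correlation_map(ex$counts, ex$samples, gmt, nPerm = 400,
                        sf = mid_sf(), seed = 19)
  expect_false("tiny" %in% cm$sets$set)          # below min_genes
  up <- cm$sets[cm$sets$set == "up", ]
  expect_gt(up$mean_r_smurf, 0.2)
  expect_lt(up$q, 0.05)
  # determinism under the seed
  cm2 <- correlation_map(ex$counts, ex$samples, gmt, nPerm = 400,
                         sf = mid_sf(), seed = 19)
  expect_identical(cm$sets, cm2$sets)
})

test_that("hallmark attribution applies the contrast precedence rule", {
  mk <- function(sets, qs) data.frame(set = sets, q = qs,
                                      stringsAsFactors = FALSE)
  map <- data.frame(set = c("s1", "s2", "s5", "s6"),
                    hallmark = c("ATH1", "ATH2", "ATH5", "ATH6"))
  noise <- list(peak_ratios = data.frame(smurf = c(0, 1),
                                         ratio = c(1.9, 1.8)))
  enr <- list(
    smurf = mk(c("s1", "s2", "s5", "s6"), c(0.001, 0.2, 0.01, 0.01)),
    old_smurf = mk(c("s1", "s2", "s5", "s6"), c(0.5, 0.5, 0.001, 0.04)),
    nonsmurf_age = mk(c("s1", "s2", "s5", "s6"), c(0.9, 0.9, 0.9, 0.01)))
  w <- capture_warnings(tab <- hallmark_attribution(enr, noise, map))
  expect_true(any(grepl("no mapped set", w)))
  att <- function(h) tab$attribution[tab$hallmark == h &
                                       tab$facet == "expression"]
  expect_equal(att("ATH1"), "smurf_specific")
  expect_equal(att("ATH2"), "none")          # nowhere significant
  expect_equal(att("ATH5"), "old_smurf")     # old-Smurf beats Smurf
  expect_equal(att("ATH6"), "chronological") # age contrast takes precedence
  expect_equal(att("ATH3"), "none")          # unmapped -> warned, none
  noise_row <- tab[tab$hallmark == "ATH6" & tab$facet == "noise", ]
  expect_equal(noise_row$attribution, "chronological")

  # noise facet requires the ratio in both states
  noise2 <- list(peak_ratios = data.frame(smurf = c(0, 1),
                                          ratio = c(1.9, 1.2)))
  suppressWarnings(tab2 <- hallmark_attribution(enr, noise2, map))
  expect_equal(tab2$attribution[tab2$facet == "noise"], "none")
  expect_error(hallmark_attribution(enr[1:2], noise, map), "must contain")
})

test_that("mixture projection reproduces its algebra and bounds", {
  expect_equal(mixture_projection(c(10, 5), c(20, 9), 0), c(10, 5))
  expect_equal(mixture_projection(10, 20, 0.5), 15)
  expect_equal(mixture_projection(c(10, 0), c(20, 8), 1), c(20, 8))
  m <- mixture_projection(c(10, 0), c(20, 8), c(0, 0.5, 1))
  expect_equal(dim(m), c(2, 3))
  expect_equal(m[1, ], c(10, 15, 20))
  expect_error(mixture_projection(1, 2, 1.5), "\\[0, 1\\]")
  expect_error(mixture_projection(1:2, 1:3, 0.5), "differ in length")
})
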
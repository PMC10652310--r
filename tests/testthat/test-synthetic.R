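test_that("gene truth respects class fractions and determinism", {
  tr0 <- null_truth(500, seed = 1)
  expect_true(all(tr0$class == "null"))
  expect_true(all(tr0$beta_smurf == 0 & tr0$beta_age == 0 & tr0$beta_int == 0))

  expect_error(generate_gene_truth(100, class_fractions = c(smurf_up = 0.9,
                                                            smurf_down = 0.2)),
               "sum to at most 1")
  expect_error(generate_gene_truth(100, class_fractions = c(smurf_up = -0.1)),
               "class fractions")

  t1 <- generate_gene_truth(n_genes = 800, seed = 5)
  t2 <- generate_gene_truth(n_genes = 800, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- generate_gene_truth(n_genes = 800, seed = 6)
  expect_false(identical(t1$mu, t3$mu))
})

test_that("default truth has the study's dimensions and class balance", {
  tr <- full_truth()
  expect_equal(nrow(tr), 15364)
  # Smurf-class count ~ Binomial(15364, 0.196): allow 4 standard deviations
  n_smurf_class <- sum(tr$class %in% c("smurf_up", "smurf_down"))
  expect_lt(abs(n_smurf_class - 15364 * 0.196),
            4 * sqrt(15364 * 0.196 * 0.804))
  # sign consistency of classes
  expect_true(all(tr$beta_smurf[tr$class == "smurf_up"] > 0))
  expect_true(all(tr$beta_smurf[tr$class == "smurf_down"] < 0))
  expect_true(all(tr$beta_smurf[tr$class == "null"] == 0))
  # hallmark tags drawn from the intended classes
  expect_true(all(tr$class[tr$hallmark %in% paste0("ATH", 1:4)]
                  %in% c("smurf_up", "smurf_down")))
  expect_true(all(tr$class[tr$hallmark %in% c("ATH5", "ATH6")]
                  == "old_smurf_interaction"))
  expect_true(all(tr$mu > 0) && all(tr$alpha0 > 0))
})

test_that("default design is 16 + 16 samples allocated 5/6/5 by age", {
  d <- default_design()
  expect_equal(nrow(d), 32)
  expect_equal(sum(d$smurf == 1), 16)
  expect_equal(sum(d$smurf == 0), 16)
  expect_equal(as.integer(table(d$age_days[d$smurf == 1])), c(5L, 6L, 5L))
  expect_equal(as.integer(table(d$age_days[d$smurf == 0])), c(5L, 6L, 5L))
  expect_false(anyDuplicated(d$sample) > 0)
})

test_that("dispersion grows linearly with age, x4 from 20 to 40 days", {
  expect_equal(dispersion_at_age(0.01, 20), 0.01)
  expect_equal(dispersion_at_age(0.01, 40), 0.04)
  expect_equal(dispersion_at_age(0.01, 30), 0.025)
  expect_equal(dispersion_at_age(c(0.01, 0.1), 40, gamma = 1),
               c(0.02, 0.2))
})

test_that("simulated counts honour the mean construction", {
  # one gene, beta_smurf = 1: expected Smurf mean exactly twice non-Smurf
  tr <- null_truth(1, seed = 1)
  tr$mu <- 100; tr$beta_smurf <- 1; tr$alpha0 <- 0.001
  n_rep <- 4000
  des <- data.frame(sample = sprintf("x%04d", 1:(2 * n_rep)),
                    age_days = 20L, smurf = rep(c(0L, 1L), each = n_rep),
                    hours_since_transition = "none")
  ex <- simulate_counts(tr, des, size_factors = rep(1, 2 * n_rep), seed = 3)
  m_ns <- mean(ex$counts[1, des$smurf == 0])
  m_s <- mean(ex$counts[1, des$smurf == 1])
  expect_equal(m_ns, 100, tolerance = 0.02)
  expect_equal(m_s, 200, tolerance = 0.02)
  expect_error(simulate_counts(tr, des, size_factors = c(0, rep(1, 2 * n_rep - 1))),
               "positive")
})

test_that("count moments match negative-binomial mean and variance", {
  tr <- null_truth(1000, seed = 7, dispersion_age_gamma = 0)
  des <- data.frame(sample = sprintf("x%03d", 1:40), age_days = 20L,
                    smurf = 0L, hours_since_transition = "none")
  ex <- simulate_counts(tr, des, size_factors = rep(1, 40), seed = 8)
  m <- rowMeans(ex$counts)
  v <- apply(ex$counts, 1, var)
  expect_equal(median(m / tr$mu), 1, tolerance = 0.05)
  # var = mu + alpha mu^2; compare in aggregate (per-gene variance is noisy)
  expect_equal(median(v / (tr$mu + tr$alpha0 * tr$mu^2)), 1, tolerance = 0.25)
})

test_that("age-linked dispersion doubles the modal RSD from 20 to 40 days", {
  tr <- null_truth(2000, seed = 9)
  des <- data.frame(sample = sprintf("x%02d", 1:12),
                    age_days = rep(c(20L, 40L), each = 6),
                    smurf = 0L, hours_since_transition = "none")
  ex <- simulate_counts(tr, des, seed = 10)
  ns <- rsd_analysis(ex$counts, ex$samples)
  ratio <- ns$peak_ratios$ratio[1]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.3)
})

test_that("recovered size factors track the generator's", {
  ex <- mid_expt()
  expect_gt(cor(mid_sf(), ex$samples$size_factor), 0.99)
})

test_that("gene sets are class-faithful and size-bounded", {
  gs <- mid_sets()
  tr <- mid_truth()
  expect_true(all(paste0("ATH", 1:6, "_a") %in% names(gs$sets)))
  for (h in paste0("ATH", 1:6)) {
    tagged <- tr$gene[tr$hallmark == h]
    expect_setequal(c(gs$sets[[paste0(h, "_a")]], gs$sets[[paste0(h, "_b")]]),
                    tagged)
  }
  nulls <- tr$gene[tr$class == "null" & tr$hallmark == "none"]
  decoys <- grep("^DECOY_", names(gs$sets), value = TRUE)
  expect_length(decoys, 4)
  for (d in decoys) expect_true(all(gs$sets[[d]] %in% nulls))
  expect_true(all(lengths(gs$sets) >= 10 & lengths(gs$sets) <= 600))
  expect_true(all(gs$hallmarks$set %in% names(gs$sets)))
})

test_that("fixture bundles are complete and byte-stable under a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  tr <- generate_gene_truth(n_genes = 400, hallmark_set_size = 6, seed = 21)
  p1 <- write_fixture_bundle(d1, seed = 77, truth = tr, cohort_n = 60)
  p2 <- write_fixture_bundle(d2, seed = 77, truth = tr, cohort_n = 60)
  expect_true(all(file.exists(p1)))
  expect_setequal(names(p1), c("counts", "metadata", "genesets", "hallmarks",
                               "truth", "longevity", "prevalence"))
  for (nm in names(p1))
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
                     label = nm)
  cts <- read.delim(p1[["counts"]], check.names = FALSE)
  expect_equal(names(cts)[1], "gene_id")
  expect_equal(ncol(cts), 33)          # gene_id + 32 samples
  expect_equal(nrow(cts), 400)
  expect_equal(nrow(validate_inputs(as.list(p1))), 0)
})

test_that("longevity tables obey the prevalence scoring rule", {
  lt <- simulate_longevity_tables(two_phase_params(c = 0.002),
                                  two_phase_params(c = 0.001),
                                  n = 100, horizon = 100, seed = 3)
  expect_true(all(lt$prevalence$n_alive >= 20))
  expect_true(all(lt$prevalence$n_smurf <= lt$prevalence$n_alive))
  expect_true(all(diff(lt$prevalence$day[
    lt$prevalence$condition == "control"]) > 0))
  agg <- tapply(lt$longevity$deaths, lt$longevity$condition, sum)
  expect_true(all(agg <= 100))
})
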
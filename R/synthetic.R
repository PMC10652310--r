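#' Generate per-gene ground truth for the count simulator
#'
#' Draws a gene table with baseline means, effect sizes and dispersions that
#' emulate the structure of a whole-body biphasic ageing RNA-seq study:
#' a large Smurf-specific differential-expression class (~20% of genes, the
#' scale of the 3009/15,364 DEGs observed), a small class varying linearly
#' with chronological age in both states (~2%), a class responding only in
#' old Smurfs (interaction, ~15%), and a null remainder. Effect sizes are in
#' log2 units; age effects are per decade of life (ages are sampled at
#' 20/30/40 days). A heavy 5% tail of Smurf effects at |log2FC| >= 2 mimics
#' strongly induced immune genes.
#'
#' Dispersion grows linearly with age,
#' `alpha(age) = alpha0 * (1 + gamma * (age - 20) / 20)`, so that with the
#' default `gamma = 3` the dispersion at 40 days is four times that at
#' 20 days and the modal relative standard deviation roughly doubles -- the
#' transcriptional-noise signature of chronological age.
#'
#' @param n_genes number of genes (default 15364).
#' @param class_fractions named fractions for classes `smurf_up`,
#'   `smurf_down`, `age_linear`, `old_smurf_interaction`; must lie in
#'   `[0, 1]` and sum to at most 1 (remainder is null).
#' @param effect_mean_smurf,effect_mean_age,effect_mean_interaction mean
#'   absolute effect sizes (log2 units; age/interaction per decade).
#' @param heavy_tail_prob fraction of Smurf-class genes drawn from the
#'   strong-effect tail (|log2FC| = 2 + Exp).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   means (expected normalized counts).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   baseline NB dispersion `alpha0`.
#' @param dispersion_age_gamma slope of the dispersion-age link.
#' @param hallmark_set_size genes tagged per ageing transcriptional hallmark
#'   (ATH1-ATH6).
#' @param smurf_attenuation optional per-decade attenuation of Smurf-class
#'   effects with age (`beta_int = -smurf_attenuation * beta_smurf` for
#'   Smurf-class genes). Emulates cohorts where old Smurfs and old
#'   non-Smurfs converge, so the number of age-matched Smurf DEGs declines
#'   with chronological age. Default 0 (a stable Smurf signature).
#' @param seed integer seed.
#' @return data.frame (`gene_truth`) with columns `gene`, `class`, `mu`,
#'   `beta_smurf`, `beta_age`, `beta_int`, `alpha0`, `hallmark`; the
#'   dispersion-age slope is kept in `attr(, "dispersion_age_gamma")`.
#' @export
generate_gene_truth <- function(n_genes = 15364,
                                class_fractions = c(smurf_up = 0.105,
                                                    smurf_down = 0.091,
                                                    age_linear = 0.0196,
                                                    old_smurf_interaction = 0.151),
                                effect_mean_smurf = 0.8,
                                effect_mean_age = 0.5,
                                effect_mean_interaction = 0.8,
                                heavy_tail_prob = 0.05,
                                baseline_meanlog = 7, baseline_sdlog = 1,
                                dispersion_meanlog = log(0.0025),
                                dispersion_sdlog = 0.4,
                                dispersion_age_gamma = 3,
                                hallmark_set_size = 60,
                                smurf_attenuation = 0,
                                seed = 1L) {
  need <- c("smurf_up", "smurf_down", "age_linear", "old_smurf_interaction")
  cf <- stats::setNames(rep(0, 4), need)
  cf[names(class_fractions)] <- class_fractions
  if (any(cf < 0) || any(cf > 1) || sum(cf) > 1)
    stop("class fractions must lie in [0, 1] and sum to at most 1")
  if (n_genes < 1) stop("`n_genes` must be >= 1")
  with_seed(seed, {
    gene <- sprintf("g%05d", seq_len(n_genes))
    # class labels: multinomial draw so realized counts have binomial spread
    cls <- sample(c(need, "null"), n_genes, replace = TRUE,
                  prob = c(cf, 1 - sum(cf)))
    mu <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    alpha0 <- stats::rlnorm(n_genes, dispersion_meanlog, dispersion_sdlog)
    beta_smurf <- beta_age <- beta_int <- numeric(n_genes)

    is_s <- cls %in% c("smurf_up", "smurf_down")
    n_s <- sum(is_s)
    if (n_s) {
      mag <- stats::rgamma(n_s, shape = 4, rate = 4 / effect_mean_smurf)
      tail <- stats::runif(n_s) < heavy_tail_prob
      mag[tail] <- 2 + stats::rexp(sum(tail), rate = 3)
      beta_smurf[is_s] <- ifelse(cls[is_s] == "smurf_up", mag, -mag)
    }
    is_a <- cls == "age_linear"
    if (any(is_a)) {
      mag <- stats::rgamma(sum(is_a), shape = 4, rate = 4 / effect_mean_age)
      beta_age[is_a] <- mag * sample(c(-1, 1), sum(is_a), replace = TRUE)
    }
    is_i <- cls == "old_smurf_interaction"
    if (any(is_i)) {
      mag <- stats::rgamma(sum(is_i), shape = 4, rate = 4 / effect_mean_interaction)
      beta_int[is_i] <- mag * sample(c(-1, 1), sum(is_i), replace = TRUE)
    }
    if (smurf_attenuation != 0)
      beta_int[is_s] <- beta_int[is_s] - smurf_attenuation * beta_smurf[is_s]

    hallmark <- rep("none", n_genes)
    tag <- function(pool, label, sign_col, want_sign) {
      idx <- which(pool & hallmark == "none" &
                     (if (is.null(want_sign)) TRUE
                      else sign(sign_col) == want_sign))
      take <- utils::head(sample(idx), hallmark_set_size)
      hallmark[take] <<- label
    }
    # ATH1 inflammation (up), ATH2 stress response (up), ATH3 metabolic
    # decline (down), ATH4 protein-synthesis reduction (down) are
    # Smurf-specific; ATH5 cell-cycle reduction and ATH6 transcriptional
    # dysregulation respond only in old Smurfs.
    tag(is_s, "ATH1", beta_smurf, 1)
    tag(is_s, "ATH2", beta_smurf, 1)
    tag(is_s, "ATH3", beta_smurf, -1)
    tag(is_s, "ATH4", beta_smurf, -1)
    tag(is_i, "ATH5", beta_int, -1)
    tag(is_i, "ATH6", beta_int, 1)

    out <- data.frame(gene = gene, class = cls, mu = mu,
                      beta_smurf = beta_smurf, beta_age = beta_age,
                      beta_int = beta_int, alpha0 = alpha0,
                      hallmark = hallmark, stringsAsFactors = FALSE)
    attr(out, "dispersion_age_gamma") <- dispersion_age_gamma
    class(out) <- c("gene_truth", "data.frame")
    out
  })
}

#' Default sample design of a biphasic whole-body RNA-seq study
#'
#' 16 Smurf and 16 non-Smurf samples over three ages (20, 30, 40 days),
#' allocated 5/6/5 per age within each state. Smurf samples carry a
#' time-since-transition annotation (5 h, 1 day, or mixed) that is metadata
#' only -- the pooled design treats all Smurfs alike.
#'
#' @return data.frame with columns `sample`, `age_days`, `smurf`,
#'   `hours_since_transition`.
#' @export
default_design <- function() {
  ages <- rep(c(20L, 30L, 40L), times = c(5L, 6L, 5L))
  hst <- rep(c("5h", "1d", "M"), length.out = 16L)
  rbind(
    data.frame(sample = sprintf("S%02d_%dd", 1:16, ages),
               age_days = ages, smurf = 1L, hours_since_transition = hst,
               stringsAsFactors = FALSE),
    data.frame(sample = sprintf("N%02d_%dd", 1:16, ages),
               age_days = ages, smurf = 0L, hours_since_transition = "none",
               stringsAsFactors = FALSE)
  )
}

#' Age-dependent negative-binomial dispersion
#' @param alpha0 baseline dispersion at 20 days.
#' @param age_days sample age.
#' @param gamma dispersion-age slope.
#' @return dispersion values `alpha0 * (1 + gamma * (age - 20)/20)`.
#' @export
dispersion_at_age <- function(alpha0, age_days, gamma = 3) {
  alpha0 * (1 + gamma * pmax(age_days - 20, 0) / 20)
}

#' Simulate a count matrix from gene truth and a sample design
#'
#' Counts are drawn from a negative binomial with mean
#' `s_j * mu_g * 2^(bS*S_j + bA*(age_j-20)/10 + bI*S_j*(age_j-20)/10)` and
#' dispersion `alpha_g(age_j)` (see [dispersion_at_age()]). Size factors
#' `s_j` default to log-normal(0, 0.1) draws so that normalization is
#' non-trivial downstream.
#'
#' @param truth a [generate_gene_truth()] table.
#' @param design sample metadata as from [default_design()].
#' @param size_factors optional positive per-sample scales; drawn if `NULL`.
#' @param seed integer seed.
#' @return A `counts_experiment`: list with integer matrix `counts`
#'   (genes x samples), `samples` (design plus `size_factor`), and `truth`.
#' @export
simulate_counts <- function(truth, design = default_design(),
                            size_factors = NULL, seed = 1L) {
  stopifnot(is.data.frame(truth), is.data.frame(design))
  if (!is.null(size_factors) && any(size_factors <= 0))
    stop("size factors must be positive")
  gamma <- attr(truth, "dispersion_age_gamma") %||% 3
  with_seed(seed, {
    n_g <- nrow(truth); n_s <- nrow(design)
    s <- size_factors %||% stats::rlnorm(n_s, 0, 0.1)
    aged <- (design$age_days - 20) / 10
    lfc <- outer(truth$beta_smurf, design$smurf) +
      outer(truth$beta_age, aged) +
      outer(truth$beta_int, design$smurf * aged)
    mu <- truth$mu * 2^lfc * rep(s, each = n_g)
    alpha <- outer(truth$alpha0, design$age_days,
                   function(a0, ag) dispersion_at_age(a0, ag, gamma))
    counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu,
                                    size = 1 / pmax(alpha, 1e-8)),
                     nrow = n_g,
                     dimnames = list(truth$gene, design$sample))
    samples <- design
    samples$size_factor <- s
    structure(list(counts = counts, samples = samples, truth = truth),
              class = "counts_experiment")
  })
}

#' @export
print.counts_experiment <- function(x, ...) {
  cat(sprintf("counts_experiment: %d genes x %d samples (%d Smurf, %d non-Smurf)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$smurf == 1), sum(x$samples$smurf == 0)))
  invisible(x)
}

#' Build gene-set collections matched to the generator's truth
#'
#' Emits two gene sets per ageing transcriptional hallmark (ATH1-ATH6,
#' splitting the tagged genes in half), one set per generator class, and
#' decoy sets drawn purely from null genes. Decoys calibrate the permutation
#' null of the enrichment machinery.
#'
#' @param truth a [generate_gene_truth()] table.
#' @param n_decoys number of decoy sets.
#' @param decoy_size_range inclusive size range of decoy sets.
#' @param seed integer seed.
#' @return list with `sets` (named list of character vectors) and
#'   `hallmarks` (data.frame set, hallmark).
#' @export
make_gene_sets <- function(truth, n_decoys = 20,
                           decoy_size_range = c(15, 120), seed = 1L) {
  with_seed(seed, {
    sets <- list()
    hm <- data.frame(set = character(0), hallmark = character(0),
                     stringsAsFactors = FALSE)
    for (h in paste0("ATH", 1:6)) {
      g <- truth$gene[truth$hallmark == h]
      if (length(g) >= 4) {
        half <- ceiling(length(g) / 2)
        sets[[paste0(h, "_a")]] <- g[seq_len(half)]
        sets[[paste0(h, "_b")]] <- g[(half + 1):length(g)]
        hm <- rbind(hm, data.frame(set = paste0(h, c("_a", "_b")),
                                   hallmark = h, stringsAsFactors = FALSE))
      }
    }
    for (cl in c("smurf_up", "smurf_down", "age_linear",
                 "old_smurf_interaction")) {
      g <- truth$gene[truth$class == cl]
      if (length(g) >= 10)
        sets[[paste0("class_", cl)]] <- utils::head(sample(g), 200)
    }
    nulls <- truth$gene[truth$class == "null" & truth$hallmark == "none"]
    for (i in seq_len(n_decoys)) {
      k <- sample(decoy_size_range[1]:decoy_size_range[2], 1)
      sets[[sprintf("DECOY_%02d", i)]] <- sample(nulls, min(k, length(nulls)))
    }
    list(sets = sets, hallmarks = hm)
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Produces everything the downstream pipeline consumes: `counts.tsv` (raw
#' integer counts, gene id + one column per sample), `metadata.csv`,
#' `genesets.gmt`, `hallmarks.tsv` (set to hallmark map), `gene_truth.tsv`,
#' and two-phase longevity tables `longevity.csv`
#' (condition, day, deaths, n_at_risk) and `prevalence.csv`
#' (condition, day, n_alive, n_smurf) simulated for a control and a
#' Smurf-transition-delayed condition. Byte-identical under the same seed.
#'
#' @param outdir output directory (created if missing).
#' @param seed master seed; stage seeds are derived with [derive_seed()].
#' @param n_genes number of genes.
#' @param truth optional pre-built truth table (overrides `n_genes`).
#' @param design sample design.
#' @param cohort_n flies per longevity condition.
#' @param control_params,treated_params [two_phase_params()] for the two
#'   longevity conditions; the default treated condition halves the
#'   transition coefficient (delayed Smurf entry).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture_bundle <- function(outdir, seed = 1L, n_genes = 15364,
                                 truth = NULL, design = default_design(),
                                 cohort_n = 150,
                                 control_params = two_phase_params(c = 0.002),
                                 treated_params = two_phase_params(c = 0.001)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- truth %||%
    generate_gene_truth(n_genes = n_genes, seed = derive_seed(seed, "truth"))
  expt <- simulate_counts(truth, design, seed = derive_seed(seed, "counts"))
  gs <- make_gene_sets(truth, seed = derive_seed(seed, "genesets"))

  paths <- c(counts = file.path(outdir, "counts.tsv"),
             metadata = file.path(outdir, "metadata.csv"),
             genesets = file.path(outdir, "genesets.gmt"),
             hallmarks = file.path(outdir, "hallmarks.tsv"),
             truth = file.path(outdir, "gene_truth.tsv"),
             longevity = file.path(outdir, "longevity.csv"),
             prevalence = file.path(outdir, "prevalence.csv"))

  cdf <- data.frame(gene_id = rownames(expt$counts), expt$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cdf, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  write.table(expt$samples[, c("sample", "age_days", "smurf",
                               "hours_since_transition")],
              paths["metadata"], sep = ",", quote = FALSE,
              row.names = FALSE, eol = "\n")
  write_gmt(gs$sets, paths["genesets"])
  write_tsv_header(gs$hallmarks, paths["hallmarks"])
  write_tsv_header(as.data.frame(truth), paths["truth"])

  lt <- simulate_longevity_tables(control_params, treated_params,
                                  n = cohort_n,
                                  seed = derive_seed(seed, "longevity"))
  write.table(format_df_for_tsv(lt$longevity), paths["longevity"], sep = ",",
              quote = FALSE, row.names = FALSE, eol = "\n")
  write.table(format_df_for_tsv(lt$prevalence), paths["prevalence"], sep = ",",
              quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(paths)
}

#' Simulate longevity and Smurf-prevalence observation tables
#'
#' Runs the individual-based two-phase simulation for a control and a
#' treated condition, scores deaths on a thrice-weekly schedule and Smurf
#' prevalence weekly, mirroring how longevity screens record these data.
#' Prevalence is only scored while at least `min_alive_prevalence` flies
#' remain: proportions over a handful of survivors are too unstable to
#' record.
#'
#' @param control_params,treated_params [two_phase_params()] objects.
#' @param n flies per condition.
#' @param horizon final observation day.
#' @param prevalence_days days on which Smurf prevalence is scored.
#' @param min_alive_prevalence minimum live flies for a prevalence record.
#' @param seed integer seed.
#' @return list of data.frames `longevity` (condition, day, deaths,
#'   n_at_risk) and `prevalence` (condition, day, n_alive, n_smurf).
#' @export
simulate_longevity_tables <- function(control_params, treated_params,
                                      n = 150, horizon = 120,
                                      prevalence_days = seq(7, horizon, by = 7),
                                      min_alive_prevalence = 20, seed = 1L) {
  conds <- list(control = control_params, treated = treated_params)
  score_days <- sort(unique(c(seq(2, horizon, by = 2), seq(3, horizon, by = 7))))
  prev_days <- prevalence_days
  lon <- prev <- list()
  for (i in seq_along(conds)) {
    cn <- names(conds)[i]
    co <- simulate_cohort(conds[[i]], n = n, horizon = horizon,
                          seed = derive_seed(seed, paste0("cohort_", cn)))
    death <- co$individuals$death_age
    death <- death[!is.na(death)]
    cuts <- c(0, score_days)
    deaths <- as.integer(table(cut(death, cuts, right = TRUE)))
    at_risk <- n - c(0, utils::head(cumsum(deaths), -1))
    keep <- deaths > 0 | score_days <= max(death, 0)
    lon[[cn]] <- data.frame(condition = cn, day = score_days,
                            deaths = deaths, n_at_risk = at_risk,
                            stringsAsFactors = FALSE)[keep, ]
    d <- co$daily[co$daily$day %in% prev_days &
                    co$daily$n_alive >= min_alive_prevalence, ]
    prev[[cn]] <- data.frame(condition = cn, day = d$day,
                             n_alive = d$n_alive, n_smurf = d$n_smurf,
                             stringsAsFactors = FALSE)
  }
  list(longevity = do.call(rbind, c(lon, make.row.names = FALSE)),
       prevalence = do.call(rbind, c(prev, make.row.names = FALSE)))
}
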
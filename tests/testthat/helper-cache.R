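# Shared, lazily built fixtures. Expensive objects (count bundles, DE runs)
# are computed once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# mid-size bundle for unit tests (same structure as the default study
# design, fewer genes for speed)
mid_truth <- function() memo("mid_truth",
  generate_gene_truth(n_genes = 4000, seed = 42))
mid_expt <- function() memo("mid_expt",
  simulate_counts(mid_truth(), seed = 43))
mid_sf <- function() memo("mid_sf", size_factors(mid_expt()$counts))
mid_wald <- function() memo("mid_wald",
  nb_wald_test(mid_expt()$counts, mid_expt()$samples, sf = mid_sf()))
mid_quasi <- function() memo("mid_quasi",
  nb_quasi_test(mid_expt()$counts, mid_expt()$samples, sf = mid_sf()))
mid_sets <- function() memo("mid_sets",
  make_gene_sets(mid_truth(), n_decoys = 4, seed = 44))

# full-size bundle at the default study dimensions (15,364 genes, 16 + 16
# samples); used by the acceptance suite
full_truth <- function() memo("full_truth", generate_gene_truth(seed = 101))
full_expt <- function() memo("full_expt",
  simulate_counts(full_truth(), seed = 102))
full_sets <- function() memo("full_sets",
  make_gene_sets(full_truth(), seed = 103))
full_sf <- function() memo("full_sf", size_factors(full_expt()$counts))
full_wald <- function() memo("full_wald",
  nb_wald_test(full_expt()$counts, full_expt()$samples, sf = full_sf()))
full_quasi <- function() memo("full_quasi",
  nb_quasi_test(full_expt()$counts, full_expt()$samples, sf = full_sf()))

# an all-null gene truth (no differential classes)
null_truth <- function(n_genes, seed, ...) {
  generate_gene_truth(
    n_genes = n_genes,
    class_fractions = c(smurf_up = 0, smurf_down = 0, age_linear = 0,
                        old_smurf_interaction = 0),
    seed = seed, ...)
}

# balanced per-age design (5 Smurf + 5 non-Smurf at each of 20/30/40 days)
balanced_design <- function() {
  ages <- rep(c(20L, 30L, 40L), each = 5L)
  rbind(
    data.frame(sample = sprintf("S%02d", seq_along(ages)), age_days = ages,
               smurf = 1L, hours_since_transition = "M",
               stringsAsFactors = FALSE),
    data.frame(sample = sprintf("N%02d", seq_along(ages)), age_days = ages,
               smurf = 0L, hours_since_transition = "none",
               stringsAsFactors = FALSE))
}

# Exhaustive running-sum oracle for the enrichment score: walks every rank
# position explicitly and returns the signed extremum of the running sum.
walk_es_oracle <- function(scores, member, w = 1) {
  N <- length(scores)
  hitw <- abs(scores)^w
  if (sum(hitw[member]) <= 0) hitw[member] <- 1
  Wk <- sum(hitw[member])
  miss_dec <- 1 / (N - sum(member))
  run <- 0
  mx <- 0
  mn <- 0
  for (i in seq_len(N)) {
    run <- run + if (member[i]) hitw[i] / Wk else -miss_dec
    if (run > mx) mx <- run
    if (run < mn) mn <- run
  }
  # return both extrema: when |mx| == |mn| exactly, the signed choice is
  # convention- and rounding-dependent, so callers check that the ES equals
  # one of the extrema and has the maximal magnitude
  list(mx = unname(mx), mn = unname(mn))
}

# assert that an enrichment score matches the exhaustive walk
expect_es_matches_walk <- function(es, scores, member, w) {
  o <- walk_es_oracle(scores, member, w)
  expect_equal(abs(es), max(o$mx, -o$mn), tolerance = 1e-12)
  expect_lt(min(abs(es - o$mx), abs(es - o$mn)), 1e-12)
}

# Brute-force Fasano-Franceschini statistic: O(n^2) quadrant counting with
# both boundary-inclusive and strict partitions at every data-point origin.
ff_oracle <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  pts <- rbind(a, b)
  lab <- c(rep(0L, na), rep(1L, nb))
  quad_d <- function(ox, oy, closed) {
    cmp <- if (closed) `<=` else `<`
    qa <- c(0, 0, 0, 0); qb <- c(0, 0, 0, 0)
    for (i in seq_len(nrow(pts))) {
      lx <- cmp(pts[i, 1], ox); ly <- cmp(pts[i, 2], oy)
      k <- 1 + lx + 2 * ly
      if (lab[i]) qb[k] <- qb[k] + 1 else qa[k] <- qa[k] + 1
    }
    max(abs(qa / na - qb / nb))
  }
  dA <- dB <- 0
  for (i in seq_len(nrow(pts))) {
    d <- max(quad_d(pts[i, 1], pts[i, 2], TRUE),
             quad_d(pts[i, 1], pts[i, 2], FALSE))
    if (lab[i]) dB <- max(dB, d) else dA <- max(dA, d)
  }
  (dA + dB) / 2
}
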
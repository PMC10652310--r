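#' Build a pipeline run configuration
#'
#' Collects every analysis threshold with its default in one declarative
#' object: FDR 0.05, GSEA with 15,000 membership permutations and set sizes
#' 10-600, PCA on the 1000 top-variance genes, age-regression filters
#' p < 0.05 and R2 > 0.5, 10-gene minimum for correlation-map sets, RSD
#' display cap 0.6. The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param counts,metadata,genesets,hallmarks,longevity,prevalence input
#'   paths (any may be `NULL` when the corresponding stage is off).
#' @param outdir output directory.
#' @param seed master seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param fdr FDR threshold used for DEG calls and enrichment significance.
#' @param gsea_nperm,gsea_min_size,gsea_max_size GSEA parameters.
#' @param n_top top-variance genes for PCA.
#' @param age_p_max,age_r2_min age-regression filters.
#' @param min_genes minimum detected members for correlation-map sets.
#' @param ff_nperm permutations for the 2D KS set tests.
#' @param rsd_cap display cap for RSD distributions.
#' @param stages character vector of stages to run, a subset of
#'   `c("de", "gsea", "deconvolve", "longevity")`.
#' @return A `run_config` list.
#' @export
run_config <- function(counts = NULL, metadata = NULL, genesets = NULL,
                       hallmarks = NULL, longevity = NULL, prevalence = NULL,
                       outdir = "smurfdeconv_out", seed = 1L, fdr = 0.05,
                       gsea_nperm = 15000, gsea_min_size = 10,
                       gsea_max_size = 600, n_top = 1000,
                       age_p_max = 0.05, age_r2_min = 0.5, min_genes = 10,
                       ff_nperm = 2000, rsd_cap = 0.6,
                       stages = c("de", "gsea", "deconvolve", "longevity")) {
  bad <- setdiff(stages, c("de", "gsea", "deconvolve", "longevity"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(counts = counts, metadata = metadata, genesets = genesets,
                 hallmarks = hallmarks, longevity = longevity,
                 prevalence = prevalence, outdir = outdir,
                 seed = as.integer(seed), fdr = fdr,
                 gsea_nperm = gsea_nperm, gsea_min_size = gsea_min_size,
                 gsea_max_size = gsea_max_size, n_top = n_top,
                 age_p_max = age_p_max, age_r2_min = age_r2_min,
                 min_genes = min_genes, ff_nperm = ff_nperm,
                 rsd_cap = rsd_cap, stages = as.character(stages)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Validate pipeline input files
#'
#' Checks counts/metadata concordance, value sanity (non-negative integer
#' counts, 0/1 Smurf state), GMT well-formedness and monotone day columns
#' in the longevity tables. Problems are returned as diagnostics, never
#' thrown.
#'
#' @param paths named list or vector with any of `counts`, `metadata`,
#'   `genesets`, `longevity`, `prevalence`.
#' @return data.frame of diagnostics (`input`, `problem`); zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  diags <- list()
  note <- function(input, problem)
    diags[[length(diags) + 1L]] <<- data.frame(
      input = input, problem = problem, stringsAsFactors = FALSE)

  counts <- meta <- NULL
  if (!is.null(paths$counts)) {
    if (!file.exists(paths$counts)) note("counts", "file not found")
    else {
      counts <- utils::read.delim(paths$counts, check.names = FALSE)
      if (names(counts)[1] != "gene_id") note("counts", "first column must be gene_id")
      m <- as.matrix(counts[, -1, drop = FALSE])
      if (any(is.na(m))) note("counts", "missing values")
      else {
        if (any(m < 0)) note("counts", "invalid count: negative value")
        if (any(m != floor(m))) note("counts", "invalid count: non-integer")
      }
      if (anyDuplicated(counts$gene_id)) note("counts", "duplicated gene ids")
    }
  }
  if (!is.null(paths$metadata)) {
    if (!file.exists(paths$metadata)) note("metadata", "file not found")
    else {
      meta <- utils::read.csv(paths$metadata, stringsAsFactors = FALSE)
      need <- c("sample", "age_days", "smurf")
      miss <- setdiff(need, names(meta))
      if (length(miss)) note("metadata", paste("missing column(s):",
                                               paste(miss, collapse = ", ")))
      else if (!all(meta$smurf %in% c(0, 1)))
        note("metadata", "smurf must be 0/1")
    }
  }
  if (!is.null(counts) && !is.null(meta) && "sample" %in% names(meta)) {
    cs <- names(counts)[-1]
    if (length(setdiff(cs, meta$sample)) || length(setdiff(meta$sample, cs)))
      note("counts/metadata", "unmatched sample")
  }
  if (!is.null(paths$genesets)) {
    if (!file.exists(paths$genesets)) note("genesets", "file not found")
    else tryCatch(invisible(read_gmt(paths$genesets)),
                  error = function(e) note("genesets", conditionMessage(e)))
  }
  for (nm in c("longevity", "prevalence")) {
    if (is.null(paths[[nm]])) next
    if (!file.exists(paths[[nm]])) { note(nm, "file not found"); next }
    tab <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE)
    if (!"day" %in% names(tab)) { note(nm, "missing day column"); next }
    by_cond <- split(tab$day, tab$condition %||% "all")
    if (any(vapply(by_cond, is.unsorted, logical(1))))
      note(nm, "day column not monotone within condition")
  }
  if (length(diags)) do.call(rbind, c(diags, make.row.names = FALSE))
  else data.frame(input = character(0), problem = character(0))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: differential
#' expression (both estimators, plus age-matched DEG counts), preranked
#' enrichment, the deconvolution battery (PCA association, interaction
#' scan, non-Smurf age regression, RSD noise, correlation map, hallmark
#' attribution), and longevity statistics. Every output table carries the
#' configuration hash and master seed in a `#` header, and a rerun with the
#' same configuration is byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- c(config_hash = hash, seed = config$seed)
  logf <- file.path(config$outdir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage_on <- function(s) s %in% config$stages
  out <- list(config = config, paths = character(0))
  fail <- function(stage, e)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)

  say("configuration hash %s, master seed %d", hash, config$seed)
  diags <- validate_inputs(config[c("counts", "metadata", "genesets",
                                    "longevity", "prevalence")])
  out$diagnostics <- diags
  if (nrow(diags)) {
    say("validation raised %d diagnostic(s)", nrow(diags))
    stop("invalid inputs: ",
         paste(diags$input, diags$problem, sep = ": ", collapse = "; "))
  }

  need_expr <- any(c("de", "gsea", "deconvolve") %in% config$stages)
  if (need_expr) {
    cts <- utils::read.delim(config$counts, check.names = FALSE)
    counts <- as.matrix(cts[, -1, drop = FALSE])
    rownames(counts) <- cts$gene_id
    meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
    counts <- counts[, meta$sample, drop = FALSE]
    sf <- size_factors(counts)
  }

  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    write_tsv_header(df, p, hdr)
    out$paths[name] <<- p
  }

  de_a <- NULL
  if (stage_on("de")) tryCatch({
    say("stage de: %d genes x %d samples", nrow(counts), ncol(counts))
    de_a <- nb_wald_test(counts, meta, contrast = "smurf", sf = sf)
    de_b <- nb_quasi_test(counts, meta, contrast = "smurf", sf = sf)
    emit(as.data.frame(de_a), "de.tsv")
    emit(as.data.frame(de_b), "de_variantB.tsv")
    byage <- deg_count_by_age(counts, meta, q_max = config$fdr)
    emit(byage$summary, "deg_count_by_age.tsv")
    out$de <- list(wald = de_a, quasi = de_b, by_age = byage$summary)
  }, error = function(e) fail("de", e))

  gmt <- NULL; enr <- NULL
  if (stage_on("gsea")) tryCatch({
    if (is.null(de_a)) stop("gsea requires the de stage")
    gmt <- read_gmt(config$genesets)
    say("stage gsea: %d sets, nPerm = %d", length(gmt), config$gsea_nperm)
    enr <- gsea(de_a, gmt, nPerm = config$gsea_nperm,
                min_size = config$gsea_min_size,
                max_size = config$gsea_max_size,
                seed = derive_seed(config$seed, "gsea_smurf"))
    emit(as.data.frame(enr), "gsea.tsv")
    ov <- set_overlap_table(enr, gmt, q_max = config$fdr)
    emit(ov, "set_overlap.tsv")
    out$gsea <- enr
  }, error = function(e) fail("gsea", e))

  if (stage_on("deconvolve")) tryCatch({
    say("stage deconvolve")
    if (is.null(de_a) || is.null(enr))
      stop("deconvolve requires the de and gsea stages")
    pca <- pca_factor_association(counts, meta, n_top = config$n_top, sf = sf)
    emit(pca$assoc, "pca_association.tsv")
    scan <- interaction_scan(counts, meta, q_max = config$fdr, sf = sf)
    emit(scan$table, "gene_lm.tsv")
    smurf_degs <- de_a$gene[!is.na(de_a$q) & de_a$q < config$fdr]
    agereg <- age_regression_nonsmurf(counts, meta,
                                      p_max = config$age_p_max,
                                      r2_min = config$age_r2_min,
                                      smurf_degs = smurf_degs, sf = sf)
    emit(agereg$table, "age_regression.tsv")
    noise <- rsd_analysis(counts, meta, rsd_cap = config$rsd_cap, sf = sf)
    emit(noise$peaks, "noise_peaks.tsv")
    emit(noise$ks, "noise_ks.tsv")
    cmap <- correlation_map(counts, meta, gmt,
                            min_genes = config$min_genes,
                            nPerm = config$ff_nperm, sf = sf,
                            seed = derive_seed(config$seed, "corr_map"))
    emit(cmap$sets, "corr_map.tsv")

    contrast_enrich <- function(state_keep, label) {
      sub <- meta$smurf == state_keep & meta$age_days %in%
        range(meta$age_days)
      m2 <- meta[sub, , drop = FALSE]
      m2$old <- as.integer(m2$age_days == max(m2$age_days))
      de2 <- nb_wald_test(counts[, sub, drop = FALSE], m2, contrast = "old")
      gsea(de2, gmt, nPerm = config$gsea_nperm,
           min_size = config$gsea_min_size, max_size = config$gsea_max_size,
           seed = derive_seed(config$seed, paste0("gsea_", label)))
    }
    enr_olds <- contrast_enrich(1L, "old_smurf")
    enr_agens <- contrast_enrich(0L, "nonsmurf_age")
    hm_map <- read_tsv_header(config$hallmarks)
    hma <- hallmark_attribution(
      list(smurf = enr, old_smurf = enr_olds, nonsmurf_age = enr_agens),
      noise, hm_map, q_max = config$fdr)
    emit(hma, "hallmark_attribution.tsv")
    out$deconvolution <- list(pca = pca, interaction = scan,
                              age_regression = agereg, noise = noise,
                              correlation_map = cmap, hallmarks = hma)
  }, error = function(e) fail("deconvolve", e))

  if (stage_on("longevity")) tryCatch({
    say("stage longevity")
    ev <- utils::read.csv(config$longevity, stringsAsFactors = FALSE)
    pv <- utils::read.csv(config$prevalence, stringsAsFactors = FALSE)
    ctrl <- if ("control" %in% ev$condition) "control" else
      unique(ev$condition)[1]
    ls <- mean_lifespan(ev, control = ctrl)
    emit(as.data.frame(ls), "lifespan.tsv")
    pf <- fit_prevalence(pv, control = ctrl)
    emit(pf$per_condition, "prevalence_fit.tsv")
    if (!is.null(pf$interaction))
      emit(pf$interaction, "prevalence_interaction.tsv")
    out$longevity <- list(lifespan = ls, prevalence = pf)
  }, error = function(e) fail("longevity", e))

  report <- if (length(config$stages) == 0) {
    data.frame(section = character(0), item = character(0),
               value = character(0))
  } else {
    rp <- list()
    add <- function(section, item, value)
      rp[[length(rp) + 1L]] <<- data.frame(
        section = section, item = item, value = as.character(value),
        stringsAsFactors = FALSE)
    if (!is.null(out$de))
      add("de", "n_deg_smurf",
          sum(out$de$wald$q < config$fdr, na.rm = TRUE))
    if (!is.null(out$gsea))
      add("gsea", "n_enriched_sets",
          sum(out$gsea$q < config$fdr, na.rm = TRUE))
    if (!is.null(out$deconvolution)) {
      hm <- out$deconvolution$hallmarks
      for (i in seq_len(nrow(hm)))
        add("hallmarks", paste0(hm$hallmark[i], "_", hm$facet[i]),
            hm$attribution[i])
      for (i in seq_len(nrow(out$deconvolution$noise$peak_ratios)))
        add("noise", sprintf("peak_ratio_smurf%d",
                             out$deconvolution$noise$peak_ratios$smurf[i]),
            sprintf("%.3f", out$deconvolution$noise$peak_ratios$ratio[i]))
    }
    if (!is.null(out$longevity)) {
      for (i in seq_len(nrow(out$longevity$lifespan)))
        add("longevity", paste0("ML_", out$longevity$lifespan$condition[i]),
            sprintf("%.2f", out$longevity$lifespan$mean_lifespan[i]))
    }
    if (length(rp)) do.call(rbind, rp) else
      data.frame(section = character(0), item = character(0),
                 value = character(0))
  }
  emit(report, "report.tsv")
  out$report <- report
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  writeLines(log_lines, logf)
  invisible(out)
}
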
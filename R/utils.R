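#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from one master seed so that a full run is reproducible end to end. The
#' derivation is `(master * 1000003 + hash(stage)) mod (2^31 - 1)` where
#' `hash` sums the UTF-8 code points of the stage name scaled by position.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"simulate_counts"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp)) %% 2147483647
  s <- ((abs(master) %% 2147483647) * 1000003 + h) %% 2147483647
  as.integer(max(1, s))
}

#' Run code with a locally set RNG seed
#'
#' Saves and restores `.Random.seed` so library functions that seed
#' internally do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Write a table as TSV with a provenance comment header
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param header named character vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(x, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header)) {
    writeLines(sprintf("# %s=%s", names(header), as.character(header)), con)
  }
  write.table(format_df_for_tsv(x), con,
              sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

# Locale/precision-stable formatting so identical inputs give identical bytes.
format_df_for_tsv <- function(x) {
  as.data.frame(lapply(x, function(col) {
    if (is.double(col)) formatC(col, digits = 15, format = "g") else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a TSV written by [write_tsv_header()]
#'
#' @param path file path; `#`-prefixed header lines are skipped.
#' @return data.frame.
#' @export
read_tsv_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Benjamini-Hochberg adjustment restricted to non-NA entries
#' @param p numeric p-values, possibly with NA for untested entries.
#' @return adjusted q-values with NA preserved.
#' @keywords internal
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
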
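#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. A missing description field (lines
#' with a single tab before the first member) is tolerated.
#'
#' @param path file path.
#' @return Named list of character vectors of member genes; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), description = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  nm <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  # tolerate files that omit the description: treat field 2 as a member if
  # it looks like one and the line has no other members
  empty <- lengths(sets) == 0 & nzchar(desc)
  sets[empty] <- as.list(desc[empty])
  desc[empty] <- ""
  names(sets) <- nm
  structure(sets, description = stats::setNames(desc, nm))
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description strings (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
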
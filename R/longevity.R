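#' Mean-lifespan summary from death-event tables
#'
#' Computes, per condition, the mean lifespan `ML = sum(day * deaths) /
#' sum(deaths)` and the median lifespan from a complete (uncensored) death
#' table, plus the percent change versus a designated control,
#' `(ML_t - ML_c) / ML_c * 100` (reported to one decimal).
#'
#' @param events data.frame with columns `condition`, `day`, `deaths`.
#' @param control optional condition name used as reference for percent
#'   change.
#' @return data.frame (`lifespan_summary`): `condition`, `n`,
#'   `mean_lifespan`, `median_lifespan`, `pct_change`.
#' @examples
#' ev <- data.frame(condition = "c", day = c(10, 20), deaths = c(2, 2))
#' mean_lifespan(ev)$mean_lifespan  # 15
#' @export
mean_lifespan <- function(events, control = NULL) {
  stopifnot(all(c("condition", "day", "deaths") %in% names(events)))
  rows <- lapply(split(events, events$condition), function(e) {
    n <- sum(e$deaths)
    if (n <= 0) stop("condition ", e$condition[1], " has zero deaths")
    e <- e[order(e$day), ]
    ml <- sum(e$day * e$deaths) / n
    med <- e$day[which(cumsum(e$deaths) >= n / 2)[1]]
    data.frame(condition = e$condition[1], n = n, mean_lifespan = ml,
               median_lifespan = med, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$pct_change <- NA_real_
  if (!is.null(control)) {
    if (!control %in% out$condition) stop("unknown control condition")
    mlc <- out$mean_lifespan[out$condition == control]
    out$pct_change <- round((out$mean_lifespan - mlc) / mlc * 100, 1)
  }
  class(out) <- c("lifespan_summary", "data.frame")
  out
}

#' Percent change in mean lifespan
#' @param ml_control,ml_treated mean lifespans in days.
#' @return `(ml_treated - ml_control) / ml_control * 100`, one decimal.
#' @export
pct_change <- function(ml_control, ml_treated) {
  round((ml_treated - ml_control) / ml_control * 100, 1)
}

#' Stepwise survival curve from a death-event table
#'
#' @param events data.frame with `day` and `deaths` for one condition (or
#'   with a `condition` column restricted to one level).
#' @param n initial population size; defaults to the total death count
#'   (complete follow-up).
#' @return data.frame `day`, `survival` with `S(day) = 1 - cumdeaths/n`,
#'   right-continuous.
#' @export
survival_curve <- function(events, n = NULL) {
  if ("condition" %in% names(events) &&
      length(unique(events$condition)) > 1)
    stop("one condition at a time")
  e <- events[order(events$day), ]
  if (any(e$deaths < 0)) stop("negative death counts")
  cum <- cumsum(e$deaths)
  n <- n %||% sum(e$deaths)
  if (any(cum > n)) stop("cumulative deaths exceed population size")
  data.frame(day = e$day, survival = 1 - cum / n)
}

#' Smurf-prevalence regression with a condition interaction
#'
#' Fits, per condition, an ordinary least-squares line of the Smurf
#' proportion (`n_smurf / n_alive`) on chronological age, with the F-test
#' for a non-zero slope; then fits a joint model with a condition factor
#' and an age-by-condition interaction. A significant negative interaction
#' for a treated condition indicates a slower increase of the Smurf
#' proportion with age -- delayed entry into the terminal phase.
#'
#' @param obs data.frame with columns `condition`, `day`, `n_alive`,
#'   `n_smurf` (or a precomputed `proportion`).
#' @param control condition treated as the reference level; defaults to the
#'   first condition.
#' @param weighted if `TRUE`, observations are weighted by `n_alive`.
#' @return A `prevalence_fit` list: `per_condition` (condition, slope per
#'   day, intercept, `r2`, F-test `p`, n) and `interaction` (data.frame of
#'   age x condition interaction coefficients and p-values versus the
#'   control).
#' @export
fit_prevalence <- function(obs, control = NULL, weighted = FALSE) {
  stopifnot(all(c("condition", "day") %in% names(obs)))
  if (!"proportion" %in% names(obs)) {
    stopifnot(all(c("n_alive", "n_smurf") %in% names(obs)))
    obs$proportion <- ifelse(obs$n_alive > 0, obs$n_smurf / obs$n_alive,
                             NA_real_)
  }
  obs <- obs[is.finite(obs$proportion), ]
  conds <- unique(obs$condition)
  control <- control %||% conds[1]
  if (!control %in% conds) stop("unknown control condition")
  wts <- if (weighted) obs$n_alive else NULL

  per <- lapply(conds, function(cn) {
    e <- obs[obs$condition == cn, ]
    if (length(unique(e$day)) < 3)
      stop("condition ", cn, " needs >= 3 observation days")
    fit <- stats::lm(proportion ~ day, data = e,
                     weights = if (weighted) e$n_alive else NULL)
    sm <- summary(fit)
    fp <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                    lower.tail = FALSE)
    data.frame(condition = cn, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = sm$r.squared, p = unname(fp), n = nrow(e),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, make.row.names = FALSE))

  inter <- NULL
  if (length(conds) > 1) {
    obs$condition <- stats::relevel(factor(obs$condition), ref = control)
    joint <- stats::lm(proportion ~ day * condition, data = obs,
                       weights = wts)
    cf <- summary(joint)$coefficients
    ix <- grep("^day:condition", rownames(cf))
    inter <- data.frame(
      condition = sub("^day:condition", "", rownames(cf)[ix]),
      interaction = cf[ix, "Estimate"], p = cf[ix, "Pr(>|t|)"],
      stringsAsFactors = FALSE)
  }
  structure(list(per_condition = per, interaction = inter,
                 control = control, weighted = weighted),
            class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat("Smurf-prevalence regression (control:", x$control, ")\n")
  print(x$per_condition, row.names = FALSE)
  if (!is.null(x$interaction)) {
    cat("age x condition interaction vs control:\n")
    print(x$interaction, row.names = FALSE)
  }
  invisible(x)
}
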
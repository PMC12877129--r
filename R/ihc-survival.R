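#' Classify a sample by its nuclear-TET2 fraction
#'
#' Four localization categories from the fraction of tumor cells showing
#' nuclear TET2: >= 90% nucleus_only, 50-90% nucleus_major, 10-50%
#' cytoplasm_major, < 10% cytoplasm_only. Lower bounds are inclusive (0.9
#' is nucleus_only, 0.5 nucleus_major, 0.1 cytoplasm_major); the cut points
#' are configurable.
#'
#' @param f nuclear fraction(s) in \[0, 1\].
#' @param thresholds increasing cut points `c(lo, mid, hi)` (default
#'   `c(0.1, 0.5, 0.9)`).
#' @return Factor with levels nucleus_only, nucleus_major, cytoplasm_major,
#'   cytoplasm_only.
#' @export
classify_sample <- function(f, thresholds = c(0.1, 0.5, 0.9)) {
  if (any(!is.finite(f) | f < 0 | f > 1)) {
    stop_("nuclear fraction must lie in [0, 1]")
  }
  if (length(thresholds) != 3L || is.unsorted(thresholds, strictly = TRUE)) {
    stop_("'thresholds' must be three strictly increasing cut points")
  }
  lev <- c("nucleus_only", "nucleus_major", "cytoplasm_major", "cytoplasm_only")
  cat_ <- ifelse(f >= thresholds[3], lev[1],
          ifelse(f >= thresholds[2], lev[2],
          ifelse(f >= thresholds[1], lev[3], lev[4])))
  factor(cat_, levels = lev)
}

#' Cross-tabulate localization category against tumor stage
#'
#' Counts with margins plus a chi-square test of independence (no
#' continuity correction, so the statistic equals the textbook
#' sum((O - E)^2 / E)). Records missing the requested stage are skipped
#' with a warning and counted; degenerate tables (a single category or
#' stage) are flagged rather than tested.
#'
#' @param records cohort data frame with a `category` column (see
#'   [read_cohort_csv()] / [simulate_ihc_cohort()]).
#' @param stage_col stage column name (default `"stage_dukes"`).
#' @return List with `table` (category x stage counts), `margins`,
#'   `statistic`, `df`, `p_value`, `n_skipped`, `degenerate`.
#' @export
crosstab_stage <- function(records, stage_col = "stage_dukes") {
  if (!stage_col %in% names(records)) {
    stop_(sprintf("records lack stage column '%s'", stage_col))
  }
  stage <- records[[stage_col]]
  keep <- !is.na(stage) & nzchar(as.character(stage))
  n_skipped <- sum(!keep)
  if (n_skipped) {
    warning(sprintf("%d record(s) missing '%s' skipped", n_skipped, stage_col),
            call. = FALSE)
  }
  tab <- table(category = droplevels(factor(records$category[keep])),
               stage = droplevels(factor(stage[keep])))
  degenerate <- any(dim(tab) < 2L)
  if (degenerate) {
    return(list(table = tab, margins = stats::addmargins(tab),
                statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_skipped = n_skipped, degenerate = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("chi-square approximation may be poor: expected counts < 5",
            call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, margins = stats::addmargins(tab),
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, n_skipped = n_skipped, degenerate = FALSE)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the ordered distinct event times, with the
#' standard convention that subjects censored at an event time remain at
#' risk for that time's events. With no censoring the estimate equals one
#' minus the empirical distribution of event times.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return A `SurvivalCurve`: data frame with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, plus attributes `median` (KM median, `NA` if
#'   the curve never reaches 0.5) and `n`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop_("empty survival input")
  if (length(times) != length(events)) {
    stop_("times and events must have equal length")
  }
  if (any(!is.finite(times) | times < 0)) stop_("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop_("events must be 0 or 1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, n_censor = sf$n.censor,
                      survival = sf$surv)
  med <- unname(summary(sf)$table["median"])
  structure(curve, class = c("SurvivalCurve", "data.frame"),
            median = med, n = length(times))
}

#' Survival probability at given times from a fitted curve
#'
#' @param curve a `SurvivalCurve`.
#' @param at times at which to evaluate the step function.
#' @return Survival probabilities (right-continuous step interpolation).
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(tt) {
    idx <- which(curve$time <= tt)
    if (!length(idx)) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Restricted mean survival time from a fitted curve
#'
#' Area under the Kaplan-Meier step function up to the horizon `tau`; a
#' whole-curve summary of survival that remains stable in small strata
#' where the KM median is noisy or undefined.
#'
#' @param curve a `SurvivalCurve` from [km_estimate()].
#' @param tau horizon (default: last observed time in the curve).
#' @return Restricted mean survival time.
#' @export
km_rmst <- function(curve, tau = max(curve$time)) {
  ev <- curve$time[curve$time <= tau]
  ts <- c(0, ev, tau)
  sv <- c(1, km_survival_at(curve, ev))
  sum(diff(ts) * sv)
}

#' Log-rank test across survival groups
#'
#' Standard (unweighted) log-rank: at each distinct event time the observed
#' event counts per group are compared with their expectation under the
#' common-hazard null, and the statistic is the usual quadratic form with
#' hypergeometric variance, referred to a chi-square with k - 1 degrees of
#' freedom.
#'
#' @param groups either a named list of data frames with `time` and `event`
#'   columns (one per group, k >= 2), or a data frame with `time`, `event`
#'   and `group` columns.
#' @return List with `statistic`, `df`, `p_value`, `n_per_group`,
#'   `observed`, `expected`.
#' @export
logrank_test <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("time", "event", "group") %in% names(groups)))
    df <- groups
  } else {
    if (length(groups) < 2L) stop_("need >= 2 groups")
    nm <- names(groups) %||% paste0("g", seq_along(groups))
    df <- do.call(rbind, Map(function(g, n) {
      if (!nrow(g)) stop_(sprintf("group '%s' is empty", n))
      data.frame(time = g$time, event = g$event, group = n)
    }, groups, nm))
  }
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2L) stop_("need >= 2 groups")
  if (sum(df$event) == 0) stop_("no events in any group; log-rank undefined")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  df_chi <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = df_chi,
       p_value = stats::pchisq(sd_$chisq, df_chi, lower.tail = FALSE),
       n_per_group = as.vector(sd_$n), observed = as.vector(sd_$obs),
       expected = as.vector(sd_$exp))
}
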
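#' Split cells into TET2-high and TET2-low strata
#'
#' Default rule is a median split with ties assigned to the low stratum;
#' a numeric cutoff can be supplied instead.
#'
#' @param scores per-cell TET2(-target) scores (>= 20 cells).
#' @param cutoff_rule `"median"` or a numeric cutoff; cells strictly above
#'   the cutoff are labelled high.
#' @return Factor with levels `low`, `high`, one per cell.
#' @export
stratify_by_tet2 <- function(scores, cutoff_rule = "median") {
  if (length(scores) < 20L) {
    stop_(sprintf("need >= 20 cells to stratify (got %d)", length(scores)))
  }
  if (length(unique(scores)) == 1L) {
    stop_("all scores identical; no high/low split possible")
  }
  cutoff <- if (identical(cutoff_rule, "median")) stats::median(scores)
            else check_scalar_number(cutoff_rule, "cutoff_rule")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

# closed-form OLS slope of y on x
ols_slope <- function(x, y) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) stop_("degenerate (zero-variance) predictor")
  stats::cov(x, y) / vx
}

#' Windowed negative-feedback slope test
#'
#' Within a pseudotime-bin window (default the type-III window, bins
#' 36..75), the response module score (EMT by default) is regressed on the
#' TET2-target score separately in two groups of cells (e.g. FLAG vs
#' TET2CD, or TET2-low vs TET2-high). A negative feedback loop shows up as
#' an attenuated slope in the high-TET2 / TET2CD group; the slope
#' difference is tested by permuting group labels within the window.
#'
#' @param cell_scores per-cell score data frame from [score_modules()]
#'   (`$cell_scores`): must contain `bin` plus the predictor and response
#'   columns.
#' @param groups two-level factor (or vector) aligned with `cell_scores`
#'   rows; the first level is group A.
#' @param window inclusive bin window `c(lo, hi)` (default `c(36, 75)`).
#' @param predictor,response module column names (defaults
#'   `"TET2_TARGETS"` and `"EMT_MARKERS"`).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"greater"` tests slope_A > slope_B (the feedback
#'   direction when A is the uncoupled group), `"two.sided"` tests any
#'   difference.
#' @return A `FeedbackResult`: list with `window`, `slope_A`, `slope_B`,
#'   `delta_slope`, `p_perm`, `group_means` (per-group mean TET2/EMT/WNT
#'   scores where present), `n_A`, `n_B`.
#' @export
windowed_feedback_test <- function(cell_scores, groups, window = c(36, 75),
                                   predictor = "TET2_TARGETS",
                                   response = "EMT_MARKERS",
                                   n_perm = 1000, seed = 1,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop_("'groups' must have exactly two levels")
  if (length(groups) != nrow(cell_scores)) {
    stop_("'groups' must align with the rows of cell_scores")
  }
  for (col in c("bin", predictor, response)) {
    if (!col %in% names(cell_scores)) {
      stop_(sprintf("cell_scores lacks required column '%s'", col))
    }
  }
  inw <- cell_scores$bin >= window[1] & cell_scores$bin <= window[2]
  g <- groups[inw]
  x <- cell_scores[[predictor]][inw]
  y <- cell_scores[[response]][inw]
  n_ab <- table(g)
  if (any(n_ab < 10L)) {
    stop_(sprintf("need >= 10 cells per group inside bins %d..%d (got %s)",
                  window[1], window[2], paste(n_ab, collapse = "/")))
  }
  lv <- levels(g)
  delta <- function(lab) {
    ols_slope(x[lab == lv[1]], y[lab == lv[1]]) -
      ols_slope(x[lab == lv[2]], y[lab == lv[2]])
  }
  d_obs <- delta(g)
  exceed <- with_seed_(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      d_p <- delta(sample(g))
      if (alternative == "greater") d_p >= d_obs else abs(d_p) >= abs(d_obs)
    }, logical(1)))
  })
  score_cols <- intersect(c("TET2_TARGETS", "EMT_MARKERS", "WNT_TARGETS"),
                          names(cell_scores))
  gm <- lapply(lv, function(l) {
    colMeans(cell_scores[inw & groups == l, score_cols, drop = FALSE])
  })
  names(gm) <- lv
  structure(list(window = window,
                 slope_A = ols_slope(x[g == lv[1]], y[g == lv[1]]),
                 slope_B = ols_slope(x[g == lv[2]], y[g == lv[2]]),
                 delta_slope = d_obs,
                 p_perm = (1 + exceed) / (n_perm + 1),
                 group_means = gm,
                 n_A = unname(n_ab[1]), n_B = unname(n_ab[2])),
            class = "FeedbackResult")
}

#' @method print FeedbackResult
#' @export
print.FeedbackResult <- function(x, ...) {
  cat(sprintf("FeedbackResult (bins %d..%d): slope_A %.4f, slope_B %.4f, delta %.4f, p_perm %.4g\n",
              x$window[1], x$window[2], x$slope_A, x$slope_B,
              x$delta_slope, x$p_perm))
  invisible(x)
}

#' Ordered group means of module scores
#'
#' Per-group mean module scores, returned in the supplied group order (the
#' "arrows" of a PT -> MT-high -> MT-low progression display).
#'
#' @param cell_scores per-cell score data frame (see
#'   [windowed_feedback_test()]).
#' @param groups factor/vector aligned with `cell_scores` rows; its level
#'   order fixes the output order.
#' @param score_cols module columns to average (default TET2/EMT/WNT where
#'   present).
#' @return Matrix groups x modules of mean scores.
#' @export
group_trajectory_summary <- function(cell_scores, groups,
                                     score_cols = intersect(
                                       c("TET2_TARGETS", "EMT_MARKERS", "WNT_TARGETS"),
                                       names(cell_scores))) {
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (length(groups) != nrow(cell_scores)) {
    stop_("'groups' must align with the rows of cell_scores")
  }
  empty <- setdiff(levels(groups), unique(as.character(groups)))
  if (length(empty)) {
    stop_(sprintf("empty group(s): %s", paste(empty, collapse = ", ")))
  }
  out <- t(vapply(levels(groups), function(l) {
    colMeans(cell_scores[groups == l, score_cols, drop = FALSE])
  }, numeric(length(score_cols))))
  colnames(out) <- score_cols
  out
}
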
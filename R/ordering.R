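#' Fit a four-parameter logistic to a module's binned score curve
#'
#' Least-squares fit of `f(t) = base + amp / (1 + exp(-k * (t - t50)))` with
#' k constrained to (0, 10\] and t50 to \[0, 100\]. Starting values come from
#' the data: base from the early bins, amp from the late-minus-early
#' difference, t50 from the steepest change of a 5-bin moving average, and
#' k = 0.1. The fit is flagged non-converged when the optimizer fails or the
#' goodness of fit falls below `r2_min` (flat or noisy modules are thereby
#' excluded from event ordering rather than given spurious times).
#'
#' @param bin_scores per-bin module scores (finite; at least 8 bins).
#' @param bin_positions pseudotime positions of the bins (default bin index).
#' @param module_name optional label carried into the result.
#' @param r2_min convergence gate on r-squared (default 0.3).
#' @return A `LogisticFit`: list with `module_name`, `base`, `amp`, `k`,
#'   `t50`, `r2`, `converged`.
#' @export
fit_logistic <- function(bin_scores, bin_positions = seq_along(bin_scores),
                         module_name = NA_character_, r2_min = 0.3) {
  if (length(bin_scores) != length(bin_positions)) {
    stop_("bin_scores and bin_positions must have equal length")
  }
  if (any(!is.finite(bin_scores))) stop_("bin_scores contain non-finite values")
  if (length(bin_scores) < 8L) {
    stop_(sprintf("need >= 8 bins to fit a logistic (got %d)", length(bin_scores)))
  }
  failed <- function(r2 = -Inf) {
    structure(list(module_name = module_name, base = NA_real_, amp = NA_real_,
                   k = NA_real_, t50 = NA_real_, r2 = r2, converged = FALSE),
              class = "LogisticFit")
  }
  y <- as.numeric(bin_scores)
  t <- as.numeric(bin_positions)
  ord <- order(t)
  y <- y[ord]; t <- t[ord]
  if (stats::sd(y) == 0) return(failed())
  n <- length(y)
  head_n <- max(3L, n %/% 10L)
  base0 <- mean(y[seq_len(head_n)])
  amp0 <- mean(y[seq(n - head_n + 1L, n)]) - base0
  if (amp0 == 0) amp0 <- 1e-3 * sign(stats::cor(t, y) + 1e-12)
  sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  d <- abs(diff(sm))
  t50_0 <- if (all(is.na(d))) mean(range(t)) else t[which.max(d)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ base + amp / (1 + exp(-k * (t - t50))),
      start = list(base = base0, amp = amp0, k = 0.1, t50 = t50_0),
      lower = c(base = -Inf, amp = -Inf, k = 1e-4, t50 = 0),
      upper = c(base = Inf, amp = Inf, k = 10, t50 = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  structure(list(module_name = module_name,
                 base = unname(cf["base"]), amp = unname(cf["amp"]),
                 k = unname(cf["k"]), t50 = unname(cf["t50"]),
                 r2 = r2,
                 converged = is.finite(r2) && r2 >= r2_min &&
                   cf["k"] > 0 && cf["amp"] != 0),
            class = "LogisticFit")
}

#' @method print LogisticFit
#' @export
print.LogisticFit <- function(x, ...) {
  cat(sprintf("LogisticFit%s: base %.3g amp %.3g k %.3g t50 %.4g (r2 %.3f, %s)\n",
              if (is.na(x$module_name)) "" else paste0(" '", x$module_name, "'"),
              x$base, x$amp, x$k, x$t50, x$r2,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit logistic curves for every module of a bin profile
#'
#' @param profile a `BinProfile` from [score_modules()].
#' @param r2_min convergence gate passed to [fit_logistic()].
#' @return Named list of `LogisticFit` objects, one per module.
#' @export
fit_module_curves <- function(profile, r2_min = 0.3) {
  mods <- colnames(profile$module_scores)
  fits <- lapply(mods, function(m) {
    fit_logistic(profile$module_scores[, m], profile$bins,
                 module_name = m, r2_min = r2_min)
  })
  names(fits) <- mods
  fits
}

#' Evaluate a fitted curve on a "change completed" scale
#'
#' The fitted logistic is evaluated on `grid` and min-max normalized to
#' \[0, 1\]; deactivating modules (amp < 0) are reflected so every module's
#' normalized curve rises from 0 toward 1, making activation and
#' deactivation events comparable. The normalized curve crosses 0.5 at t50.
#'
#' @param fit a converged `LogisticFit`.
#' @param grid evaluation grid (default 0..100 in steps of 0.5).
#' @return Data frame with columns `t` and `value`.
#' @export
normalize_curve <- function(fit, grid = seq(0, 100, by = 0.5)) {
  if (!isTRUE(fit$converged)) {
    stop_("cannot normalize a non-converged fit")
  }
  vals <- fit$base + fit$amp / (1 + exp(-fit$k * (grid - fit$t50)))
  nv <- minmax01(vals)
  if (fit$amp < 0) nv <- 1 - nv
  data.frame(t = grid, value = nv)
}

#' Event time of a fitted module curve
#'
#' The pseudotime at which the normalized curve crosses 0.5; analytically
#' equal to the fit's t50 and independent of the steepness k.
#'
#' @param fit a converged `LogisticFit`.
#' @return Event time in pseudotime units.
#' @export
event_time <- function(fit) {
  if (!isTRUE(fit$converged)) stop_("event time undefined for a non-converged fit")
  fit$t50
}

#' Order module activation events along the trajectory
#'
#' Converged fits are sorted by event time; pairs closer than `tie_eps`
#' pseudotime units are additionally reported as unordered ties.
#'
#' @param fits list of `LogisticFit` objects (>= 2 converged).
#' @param tie_eps tie width in pseudotime units (default 1.0).
#' @return An `EventOrder`: list with `modules` (ascending event time),
#'   `event_times` (named), `ties` (data frame of unordered pairs) and
#'   `bootstrap_support` (`NULL` until [bootstrap_order()]).
#' @export
order_events <- function(fits, tie_eps = 1.0) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) < 2L) {
    stop_(sprintf("need >= 2 converged fits to order events (got %d)", length(conv)))
  }
  et <- vapply(conv, event_time, numeric(1))
  names(et) <- vapply(conv, `[[`, character(1), "module_name")
  et <- sort(et)
  pairs <- utils::combn(names(et), 2)
  tied <- abs(et[pairs[1, ]] - et[pairs[2, ]]) < tie_eps
  ties <- data.frame(module_a = pairs[1, tied], module_b = pairs[2, tied],
                     stringsAsFactors = FALSE)
  structure(list(modules = names(et), event_times = et, ties = ties,
                 bootstrap_support = NULL),
            class = "EventOrder")
}

#' @method print EventOrder
#' @export
print.EventOrder <- function(x, ...) {
  cat("EventOrder:", paste(x$modules, collapse = " -> "), "\n")
  cat("  event times:",
      paste(sprintf("%s=%.1f", names(x$event_times), x$event_times),
            collapse = ", "), "\n")
  if (nrow(x$ties)) {
    cat("  ties:", paste(sprintf("%s~%s", x$ties$module_a, x$ties$module_b),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bootstrap support for the recovered event order
#'
#' Cells are resampled with replacement B times; binning, module scoring,
#' logistic fitting and ordering are rerun on each resample (pseudotime
#' values are inherited from the full data, so the support reflects
#' scoring/fitting variability). For every ordered pair in the full-data
#' order, the support is the fraction of retained resamples preserving that
#' pairwise order. Resamples with fewer than two converged fits are dropped
#' and counted; more than 50% drops is an error.
#'
#' @param em normalized [expression_matrix()].
#' @param modules list of [gene_module()] objects.
#' @param pt binned `PseudotimeAssignment` for the same cells.
#' @param B number of bootstrap resamples (>= 20).
#' @param seed RNG seed (results are deterministic given the seed).
#' @param r2_min,tie_eps passed to the fitting/ordering steps.
#' @return An `EventOrder` with `bootstrap_support` (named vector,
#'   `"A<B"` -> support) and attributes `n_dropped`, `B`.
#' @export
bootstrap_order <- function(em, modules, pt, B = 50, seed = 1,
                            r2_min = 0.3, tie_eps = 1.0) {
  B <- check_count(B, "B", lower = 20L)
  profile <- score_modules(em, modules, pt)
  full <- order_events(fit_module_curves(profile, r2_min), tie_eps)
  n <- length(pt$cell)
  pairs <- utils::combn(full$modules, 2)
  wins <- integer(ncol(pairs)); kept <- 0L; dropped <- 0L
  with_seed_(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      cells_b <- sprintf("bs%06d", seq_len(n))
      em_b <- expression_matrix(em$values[idx, , drop = FALSE],
                                row_ids = cells_b, gene_ids = em$gene_ids,
                                kind = em$kind)
      pt_b <- bin_pseudotime(subset_pseudotime(pt, idx, cells = cells_b),
                             pt$n_bins)
      ord_b <- tryCatch(
        order_events(fit_module_curves(score_modules(em_b, modules, pt_b),
                                       r2_min), tie_eps),
        error = function(e) NULL
      )
      if (is.null(ord_b)) { dropped <- dropped + 1L; next }
      kept <- kept + 1L
      et_b <- ord_b$event_times
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; z <- pairs[2, j]
        if (a %in% names(et_b) && z %in% names(et_b) && et_b[a] < et_b[z]) {
          wins[j] <- wins[j] + 1L
        }
      }
    }
  })
  if (dropped > B / 2) {
    stop_(sprintf("%d of %d bootstrap resamples failed to yield >= 2 converged fits",
                  dropped, B))
  }
  support <- wins / kept
  names(support) <- paste(pairs[1, ], pairs[2, ], sep = "<")
  full$bootstrap_support <- support
  attr(full, "n_dropped") <- dropped
  attr(full, "B") <- B
  full
}
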
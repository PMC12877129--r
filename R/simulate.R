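#' Expected log-expression of a module at a progression coordinate
#'
#' Evaluates `baseline + amplitude / (1 + exp(-steepness * (t - midpoint)))`.
#'
#' @param t progression coordinate(s) on \[0, 100\].
#' @param p a [module_activation_params()] object.
#' @return Expected log-expression, same length as `t`.
#' @export
module_mean <- function(t, p) {
  if (any(t < 0 | t > 100)) stop_("t must lie in [0, 100]")
  p$baseline + p$amplitude / (1 + exp(-p$steepness * (t - p$midpoint)))
}

# Normalized TET2-target activity on [0, 1]: the logistic factor alone.
tet2_activity <- function(t, p_tet2) {
  1 / (1 + exp(-p_tet2$steepness * (t - p_tet2$midpoint)))
}

# Per-gene log-rate matrix (cells x genes) for one vector of latent t under
# one condition. Feedback: under the TET2CD condition the per-cell
# TET2-target activity is act(t) times a mean-one lognormal cell factor;
# TET2-target genes are driven by that activity, and EMT/WNT amplitudes are
# scaled by (1 - gamma * activity). The cell factor gives cells at matched t
# genuine TET2 variation, so a TET2-high/low stratification carries the
# feedback signature (high TET2 -> attenuated EMT), not just the t trend.
simulate_log_rates <- function(t, cfg, condition, gene_meta) {
  n <- length(t)
  logr <- matrix(0, nrow = n, ncol = nrow(gene_meta))
  tet2_p <- cfg$module_params[["TET2_TARGETS"]]
  apply_fb <- cfg$feedback_gamma > 0 && condition == "TET2CD" &&
    !is.null(tet2_p)
  activity <- if (is.null(tet2_p)) rep(0, n) else tet2_activity(t, tet2_p)
  if (apply_fb && cfg$activity_sd > 0) {
    cell_factor <- exp(stats::rnorm(n, -cfg$activity_sd^2 / 2, cfg$activity_sd))
    activity <- pmin(1, activity * cell_factor)
  }
  fb_mult <- if (apply_fb) 1 - cfg$feedback_gamma * activity else rep(1, n)
  for (j in seq_len(nrow(gene_meta))) {
    mod <- gene_meta$module[j]
    if (mod == "background") {
      logr[, j] <- gene_meta$base_lograte[j]
    } else {
      p <- cfg$module_params[[mod]]
      if (apply_fb && mod == "TET2_TARGETS") {
        logr[, j] <- p$baseline + gene_meta$base_lograte[j] +
          p$amplitude * activity
      } else {
        amp <- p$amplitude
        if (mod %in% c("EMT_MARKERS", "WNT_TARGETS")) {
          amp <- amp * fb_mult        # per-cell effective amplitude
        }
        logr[, j] <- p$baseline + gene_meta$base_lograte[j] +
          amp / (1 + exp(-p$steepness * (t - p$midpoint)))
      }
    }
  }
  logr
}

# Fixed per-gene metadata (names, module membership, baseline jitter).
make_gene_meta <- function(cfg) {
  mods <- names(cfg$module_params)
  module_genes <- unlist(lapply(mods, function(m) {
    sprintf("%s_%02d", m, seq_len(cfg$genes_per_module))
  }))
  bg_genes <- sprintf("BG_%04d", seq_len(cfg$n_genes_background))
  data.frame(
    gene = c(module_genes, bg_genes),
    module = c(rep(mods, each = cfg$genes_per_module),
               rep("background", cfg$n_genes_background)),
    base_lograte = c(stats::rnorm(length(module_genes), 0, 0.1),
                     stats::rnorm(length(bg_genes), 1, 0.5)),
    stringsAsFactors = FALSE
  )
}

nb_counts <- function(log_rates, lib_sizes, dispersion) {
  rates <- exp(log_rates)
  mu <- rates / rowSums(rates) * lib_sizes
  cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
                nrow = nrow(mu))
  cnt
}

#' Simulate a single-cell experiment with known ground truth
#'
#' Emulates the structure of a long-term-culture scRNA-seq experiment: each
#' cell carries a latent progression coordinate t on \[0, 100\] drawn from a
#' timepoint-specific Beta distribution; five gene modules follow staggered
#' sigmoid activation/deactivation programs in t; counts are negative
#' binomial around the per-cell expected rates scaled to a lognormal library
#' size. Two conditions are generated (default FLAG and TET2CD); with
#' `feedback_gamma > 0` the TET2CD condition attenuates the EMT/WNT
#' amplitudes in proportion to the TET2-target activity at t, implementing
#' the negative feedback loop. Identical configurations (including seed)
#' give identical output.
#'
#' @param cfg configuration from [default_config()], fields overridable.
#' @return List with components `matrix` (counts [expression_matrix()]),
#'   `annotations` (data frame: cell, condition, timepoint, type),
#'   `truth` (list: `cells` data frame with `t_true` and type,
#'   `module_midpoints`, `event_order`), and `modules` (list of
#'   [gene_module()] objects naming the simulated module genes).
#' @export
simulate_cells <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  with_seed_(cfg$seed, {
    gene_meta <- make_gene_meta(cfg)
    tps <- names(cfg$timepoint_mixture)
    all_counts <- list(); ann <- list(); truth_cells <- list()
    for (cond in cfg$conditions) {
      n <- cfg$n_cells
      timepoint <- sample(rep(tps, length.out = n))
      ab <- do.call(rbind, cfg$timepoint_mixture)[timepoint, , drop = FALSE]
      t_true <- 100 * stats::rbeta(n, ab[, 1], ab[, 2])
      lib <- stats::rlnorm(n, meanlog = log(cfg$library_size_mean) - 0.3^2 / 2,
                           sdlog = 0.3)
      logr <- simulate_log_rates(t_true, cfg, cond, gene_meta)
      cnt <- nb_counts(logr, lib, cfg$dispersion)
      cells <- sprintf("%s_c%05d", cond, seq_len(n))
      rownames(cnt) <- cells
      all_counts[[cond]] <- cnt
      ann[[cond]] <- data.frame(cell = cells, condition = cond,
                                timepoint = timepoint,
                                type = type_from_t(t_true),
                                stringsAsFactors = FALSE)
      truth_cells[[cond]] <- data.frame(cell = cells, t_true = t_true,
                                        type = type_from_t(t_true),
                                        stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, all_counts)
    colnames(counts) <- gene_meta$gene
    midpoints <- vapply(cfg$module_params, `[[`, numeric(1), "midpoint")
    modules <- lapply(names(cfg$module_params), function(m) {
      gene_module(m, gene_meta$gene[gene_meta$module == m],
                  provenance = "synthetic")
    })
    names(modules) <- names(cfg$module_params)
    list(
      matrix = expression_matrix(
        methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
        kind = "counts"),
      annotations = do.call(rbind, c(ann, list(make.row.names = FALSE))),
      truth = list(
        cells = do.call(rbind, c(truth_cells, list(make.row.names = FALSE))),
        module_midpoints = midpoints,
        event_order = names(sort(midpoints))
      ),
      modules = modules
    )
  })
}

#' Simulate a bulk cohort as stage-linked cell averages
#'
#' Each bulk sample gets a latent coordinate t ~ Uniform(0, 100); its
#' profile is the mean log-CPM of `cells_per_sample` simulated cells whose
#' latent coordinates jitter around the sample's t. Tumor stage I-IV is
#' assigned by monotone thresholds on t.
#'
#' @param cfg configuration (module/noise parameters are reused).
#' @param n_samples number of bulk samples (>= 2).
#' @param cells_per_sample cells averaged per sample.
#' @param stage_rule three strictly increasing thresholds on \[0, 100\]
#'   separating stages I|II|III|IV.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return List with `matrix` (normalized [expression_matrix()]), `stages`
#'   (factor I-IV) and `truth` (data frame sample, t_true, stage).
#' @export
simulate_bulk_cohort <- function(cfg = default_config(), n_samples = 100,
                                 cells_per_sample = 20,
                                 stage_rule = c(25, 50, 75),
                                 seed = cfg$seed) {
  cfg <- validate_config(cfg)
  n_samples <- check_count(n_samples, "n_samples", lower = 2L)
  cells_per_sample <- check_count(cells_per_sample, "cells_per_sample")
  if (length(stage_rule) != 3L || is.unsorted(stage_rule, strictly = TRUE) ||
      any(stage_rule <= 0) || any(stage_rule >= 100)) {
    stop_("'stage_rule' must be three strictly increasing thresholds inside (0, 100)")
  }
  with_seed_(seed, {
    gene_meta <- make_gene_meta(cfg)
    t_s <- stats::runif(n_samples, 0, 100)
    profiles <- matrix(0, nrow = n_samples, ncol = nrow(gene_meta))
    for (i in seq_len(n_samples)) {
      tc <- pmin(100, pmax(0, t_s[i] + stats::rnorm(cells_per_sample, 0, 3)))
      lib <- stats::rlnorm(cells_per_sample,
                           meanlog = log(cfg$library_size_mean) - 0.3^2 / 2,
                           sdlog = 0.3)
      logr <- simulate_log_rates(tc, cfg, cfg$conditions[1], gene_meta)
      cnt <- nb_counts(logr, lib, cfg$dispersion)
      lcpm <- log1p(cnt / rowSums(cnt) * 1e4)
      profiles[i, ] <- colMeans(lcpm)
    }
    rownames(profiles) <- sprintf("bulk_s%04d", seq_len(n_samples))
    colnames(profiles) <- gene_meta$gene
    stages <- cut(t_s, breaks = c(0, stage_rule, 100),
                  labels = c("I", "II", "III", "IV"),
                  right = FALSE, include.lowest = TRUE)
    list(
      matrix = expression_matrix(profiles, kind = "normalized"),
      stages = stages,
      truth = data.frame(sample = rownames(profiles), t_true = t_s,
                         stage = stages, stringsAsFactors = FALSE)
    )
  })
}

#' Simulate an IHC-scored clinical cohort with survival outcomes
#'
#' Each patient gets a nuclear-TET2 fraction f ~ Uniform(0, 1); event times
#' are exponential with rate `lambda0 * exp(-hazard_beta * f)`, so a larger
#' `hazard_beta` makes high nuclear TET2 more protective (hazard_beta = 0 is
#' the null of no association). Censoring times are uniform on
#' `[0, 1 / (lambda0 * censor_rate)]` (no censoring when `censor_rate = 0`).
#' Stage is drawn from a latent severity correlated with 1 - f.
#'
#' @param n_samples cohort size (>= 10).
#' @param hazard_beta protective log-hazard coefficient for f (>= 0).
#' @param censor_rate censoring intensity in \[0, 1).
#' @param seed RNG seed.
#' @param lambda0 baseline exponential event rate (> 0).
#' @return Data frame of cohort records: sample_id, nuclear_fraction,
#'   category, stage_dukes, stage_tnm, time, event.
#' @export
simulate_ihc_cohort <- function(n_samples = 263, hazard_beta = 1.5,
                                censor_rate = 0.2, seed = 1,
                                lambda0 = 0.05) {
  n_samples <- check_count(n_samples, "n_samples", lower = 10L)
  check_scalar_number(hazard_beta, "hazard_beta", lower = 0)
  check_scalar_number(censor_rate, "censor_rate", lower = 0)
  if (censor_rate >= 1) stop_("'censor_rate' must be in [0, 1)")
  check_scalar_number(lambda0, "lambda0", lower = 0, strict_lower = TRUE)
  with_seed_(seed, {
    f <- stats::runif(n_samples)
    rate <- lambda0 * exp(-hazard_beta * f)
    t_event <- stats::rexp(n_samples, rate = rate)
    if (censor_rate > 0) {
      t_cens <- stats::runif(n_samples, 0, 1 / (lambda0 * censor_rate))
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    severity <- (1 - f) + stats::rnorm(n_samples, 0, 0.25)
    dukes <- cut(severity, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
                 labels = c("A", "B", "C", "D"))
    tnm_map <- c(A = "T1N0M0", B = "T3N0M0", C = "T3N1M0", D = "T4N1M1")
    data.frame(
      sample_id = sprintf("pt%04d", seq_len(n_samples)),
      nuclear_fraction = f,
      category = classify_sample(f),
      stage_dukes = dukes,
      stage_tnm = unname(tnm_map[as.character(dukes)]),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE
    )
  })
}
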
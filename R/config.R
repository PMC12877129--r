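#' Sigmoid activation parameters for one gene module
#'
#' Each module's expected log-expression along the latent progression
#' coordinate t in \[0, 100\] follows a four-parameter logistic:
#' `baseline + amplitude / (1 + exp(-steepness * (t - midpoint)))`.
#' A negative amplitude describes a deactivating module (e.g. OXPHOS
#' shutting down during metabolic reprogramming).
#'
#' @param module_name module identifier.
#' @param baseline expression level at the early end (log scale).
#' @param amplitude signed total change (log scale); must be non-zero.
#' @param steepness rate per pseudotime unit; must be > 0.
#' @param midpoint half-activation point on \[0, 100\].
#' @return A `ModuleActivationParams` object.
#' @export
module_activation_params <- function(module_name, baseline, amplitude,
                                     steepness, midpoint) {
  if (!is.character(module_name) || length(module_name) != 1L) {
    stop_("'module_name' must be a single string")
  }
  check_scalar_number(baseline, "baseline")
  check_scalar_number(amplitude, "amplitude")
  if (amplitude == 0) stop_("'amplitude' must be non-zero for an event module")
  check_scalar_number(steepness, "steepness", lower = 0, strict_lower = TRUE)
  check_scalar_number(midpoint, "midpoint", lower = 0, upper = 100)
  structure(list(module_name = module_name, baseline = baseline,
                 amplitude = amplitude, steepness = steepness,
                 midpoint = midpoint),
            class = "ModuleActivationParams")
}

#' Default module activation parameters
#'
#' Five modules with staggered midpoints encode the progression program:
#' metabolic switching first (OXPHOS down, glycolysis up, midpoint 30),
#' then WNT-target activation (45), then EMT induction (50), and TET2-target
#' activation last (65). The source study reports this order, not numeric
#' midpoints; the values here are the generator's documented defaults,
#' spaced widely enough to be recoverable yet close enough (WNT vs EMT) to
#' exercise the tie handling.
#'
#' @return Named list of [module_activation_params()] objects.
#' @export
default_module_params <- function() {
  mk <- module_activation_params
  list(
    OXPHOS       = mk("OXPHOS",       baseline = 1.5, amplitude = -1.5, steepness = 0.2, midpoint = 30),
    GLYCOLYSIS   = mk("GLYCOLYSIS",   baseline = 0.5, amplitude =  1.5, steepness = 0.2, midpoint = 30),
    WNT_TARGETS  = mk("WNT_TARGETS",  baseline = 0.5, amplitude =  1.5, steepness = 0.2, midpoint = 45),
    EMT_MARKERS  = mk("EMT_MARKERS",  baseline = 0.5, amplitude =  1.5, steepness = 0.2, midpoint = 50),
    TET2_TARGETS = mk("TET2_TARGETS", baseline = 0.5, amplitude =  1.5, steepness = 0.2, midpoint = 65)
  )
}

#' Default pipeline configuration
#'
#' One flat list drives both the synthetic-data generator and the analysis
#' defaults. The timepoint mixture maps the four harvest days to Beta
#' parameter pairs for the latent progression coordinate; the defaults
#' Beta(1,4)/(2,3)/(3,2)/(4,1) shift mass later for later days while their
#' equal-weight mixture is exactly Uniform(0,1), so the marginal latent t is
#' uniform on \[0, 100\].
#'
#' @return Named configuration list. Keys:
#' \describe{
#'   \item{n_cells}{cells per condition (default 2000).}
#'   \item{n_genes_background}{progression-independent genes (200).}
#'   \item{genes_per_module}{genes per module (20).}
#'   \item{module_params}{list of [module_activation_params()].}
#'   \item{timepoint_mixture}{named list day -> c(alpha, beta).}
#'   \item{dispersion}{negative-binomial dispersion theta, variance
#'     mu + mu^2/theta (10).}
#'   \item{library_size_mean}{expected counts per cell (5000).}
#'   \item{feedback_gamma}{TET2 -> EMT/WNT negative-feedback coupling in
#'     \[0, 1) (0 = off).}
#'   \item{activity_sd}{lognormal sd of the per-cell TET2-activity factor
#'     used when feedback is on (0.3); gives cells at matched t genuine
#'     TET2 variation so TET2-high/low stratification is informative.}
#'   \item{conditions}{condition labels (FLAG, TET2CD).}
#'   \item{seed}{integer RNG seed.}
#'   \item{n_bins}{pseudotime groups (100).}
#'   \item{min_genes_per_cell, min_cells_per_gene}{QC thresholds (200, 3).}
#'   \item{window}{type-III pseudotime window for the feedback test
#'     (bins 36..75).}
#'   \item{r2_min}{convergence gate for logistic fits (0.3).}
#'   \item{tie_eps}{event-time tie width in pseudotime units (1.0).}
#' }
#' @export
default_config <- function() {
  list(
    n_cells = 2000L,
    n_genes_background = 200L,
    genes_per_module = 20L,
    module_params = default_module_params(),
    timepoint_mixture = list(day6 = c(1, 4), day9 = c(2, 3),
                             day12 = c(3, 2), day15 = c(4, 1)),
    dispersion = 10,
    library_size_mean = 5000,
    feedback_gamma = 0,
    activity_sd = 0.3,
    conditions = c("FLAG", "TET2CD"),
    seed = 1L,
    n_bins = 100L,
    min_genes_per_cell = 200L,
    min_cells_per_gene = 3L,
    window = c(36L, 75L),
    r2_min = 0.3,
    tie_eps = 1.0
  )
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list as returned by [default_config()] /
#'   [load_config()], possibly with fields overridden.
#' @return The validated configuration, invisibly usable downstream.
#' @export
validate_config <- function(cfg) {
  cfg$n_cells <- check_count(cfg$n_cells, "n_cells")
  cfg$n_genes_background <- check_count(cfg$n_genes_background, "n_genes_background")
  cfg$genes_per_module <- check_count(cfg$genes_per_module, "genes_per_module")
  check_scalar_number(cfg$dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$library_size_mean, "library_size_mean",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(cfg$feedback_gamma, "feedback_gamma", lower = 0)
  if (cfg$feedback_gamma >= 1) stop_("'feedback_gamma' must be in [0, 1)")
  check_scalar_number(cfg$activity_sd %||% 0.3, "activity_sd", lower = 0)
  cfg$activity_sd <- cfg$activity_sd %||% 0.3
  if (length(cfg$conditions) < 1L || anyDuplicated(cfg$conditions)) {
    stop_("'conditions' must be distinct labels")
  }
  cfg$seed <- check_count(cfg$seed, "seed", lower = 0L)
  cfg$n_bins <- check_count(cfg$n_bins, "n_bins", lower = 2L)
  cfg$min_genes_per_cell <- check_count(cfg$min_genes_per_cell,
                                        "min_genes_per_cell", lower = 0L)
  cfg$min_cells_per_gene <- check_count(cfg$min_cells_per_gene,
                                        "min_cells_per_gene", lower = 0L)
  if (length(cfg$window) != 2L || cfg$window[1] > cfg$window[2] ||
      cfg$window[1] < 1 || cfg$window[2] > cfg$n_bins) {
    stop_("'window' must be c(lo, hi) with 1 <= lo <= hi <= n_bins")
  }
  check_scalar_number(cfg$r2_min, "r2_min", upper = 1)
  check_scalar_number(cfg$tie_eps, "tie_eps", lower = 0)
  if (!is.list(cfg$timepoint_mixture) || is.null(names(cfg$timepoint_mixture))) {
    stop_("'timepoint_mixture' must be a named list of c(alpha, beta) pairs")
  }
  for (tp in names(cfg$timepoint_mixture)) {
    ab <- cfg$timepoint_mixture[[tp]]
    if (length(ab) != 2L || any(!is.finite(ab)) || any(ab <= 0)) {
      stop_(sprintf("'timepoint_mixture' entry '%s' must be two positive numbers", tp))
    }
  }
  mp <- cfg$module_params
  if (!is.list(mp) || !length(mp)) stop_("'module_params' must be a non-empty list")
  for (i in seq_along(mp)) {
    p <- mp[[i]]
    if (!inherits(p, "ModuleActivationParams")) {
      # re-validate plain lists (e.g. parsed from JSON)
      mp[[i]] <- module_activation_params(p$module_name, p$baseline,
                                          p$amplitude, p$steepness, p$midpoint)
    }
  }
  names(mp) <- vapply(mp, `[[`, character(1), "module_name")
  cfg$module_params <- mp
  cfg
}

#' Type labels from the latent progression coordinate
#'
#' Fixed thresholds partition \[0, 100\] into the five cell types: I
#' \[0, 20), II \[20, 40), III \[40, 60), IV \[60, 80), V \[80, 100\].
#' The type-III band brackets the bin window 36..75 used by the feedback
#' analysis up to trajectory noise.
#'
#' @param t_true latent coordinates on \[0, 100\].
#' @return Factor with levels I..V.
#' @export
type_from_t <- function(t_true) {
  if (any(t_true < 0 | t_true > 100)) stop_("t_true must lie in [0, 100]")
  cut(t_true, breaks = c(0, 20, 40, 60, 80, 100),
      labels = c("I", "II", "III", "IV", "V"),
      right = FALSE, include.lowest = TRUE)
}
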
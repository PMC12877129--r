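# Shared test fixtures, built in code.

# Scaled-down generator configuration for unit tests (the defaults of
# default_config() are the full study conditions used in the acceptance
# suite).
small_config <- function(n_cells = 400, seed = 1, ...) {
  cfg <- default_config()
  cfg$n_cells <- n_cells
  cfg$n_genes_background <- 60L
  cfg$genes_per_module <- 10L
  cfg$seed <- seed
  extra <- list(...)
  cfg[names(extra)] <- extra
  cfg
}

# One small simulated experiment, cached per test file run.
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cells(small_config(seed = 42))
    cache
  }
})

# Counts matrix fixture with exact entries for IO round trips.
tiny_counts <- function() {
  m <- matrix(c(0, 1, 2,
                3, 0, 4), nrow = 3, ncol = 2,
              dimnames = list(c("cellA", "cellB", "cellC"), c("g1", "g2")))
  expression_matrix(m, kind = "counts")
}

# Noiseless samples of the four-parameter logistic.
logistic_samples <- function(base, amp, k, t50, t = 1:100) {
  base + amp / (1 + exp(-k * (t - t50)))
}
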
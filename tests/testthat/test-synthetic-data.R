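test_that("module_mean evaluates the sigmoid exactly", {
  p <- module_activation_params("M", baseline = 1, amplitude = 2,
                                steepness = 0.2, midpoint = 50)
  # midpoint identity
  expect_equal(module_mean(50, p), 1 + 2 / 2)
  # direct evaluation at t = 60: 1 + 2 / (1 + exp(-2))
  expect_equal(module_mean(60, p), 1 + 2 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(module_mean(60, p), 2.76159415595576, tolerance = 1e-10)
  # saturation for steep curves below the midpoint
  steep <- module_activation_params("M", 1, 2, steepness = 5, midpoint = 50)
  expect_equal(module_mean(30, steep), 1, tolerance = 1e-6)
  expect_error(module_mean(101, p), "\\[0, 100\\]")
})

test_that("module parameter validation names the offending field", {
  expect_error(module_activation_params("M", 1, 0, 0.2, 50), "amplitude")
  expect_error(module_activation_params("M", 1, 2, -1, 50), "steepness")
  expect_error(module_activation_params("M", 1, 2, 0.2, 150), "midpoint")
  cfg <- small_config()
  cfg$dispersion <- -1
  expect_error(simulate_cells(cfg), "dispersion")
  cfg <- small_config()
  cfg$feedback_gamma <- 1
  expect_error(simulate_cells(cfg), "feedback_gamma")
})

test_that("identical configurations give byte-identical simulations", {
  a <- simulate_cells(small_config(n_cells = 150, seed = 7))
  b <- simulate_cells(small_config(n_cells = 150, seed = 7))
  expect_identical(as.matrix(a$matrix$values), as.matrix(b$matrix$values))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  c <- simulate_cells(small_config(n_cells = 150, seed = 8))
  expect_false(identical(as.matrix(a$matrix$values), as.matrix(c$matrix$values)))
})

test_that("simulated counts honor library size, integrality and type labels", {
  cfg <- small_config(n_cells = 2000, seed = 11)
  sim <- simulate_cells(cfg)
  v <- sim$matrix$values
  expect_true(all(v@x >= 0))
  expect_true(all(v@x == round(v@x)))
  # realized library size tracks the configured mean (law of large numbers)
  libs <- Matrix::rowSums(v)
  expect_lt(abs(mean(libs) - cfg$library_size_mean) / cfg$library_size_mean, 0.1)
  # type labels follow the fixed thresholds on t_true
  tc <- sim$truth$cells
  expect_true(all(tc$type[tc$t_true < 20] == "I"))
  expect_true(all(tc$type[tc$t_true >= 80] == "V"))
  # no module gene is all-zero at this depth
  mod_genes <- unlist(lapply(sim$modules, `[[`, "genes"))
  expect_true(all(Matrix::colSums(v[, mod_genes]) > 0))
  # true event order is the midpoint-sorted module list
  expect_identical(sim$truth$event_order[1:2], c("OXPHOS", "GLYCOLYSIS"))
  expect_identical(sim$truth$event_order[5], "TET2_TARGETS")
})

test_that("type label fractions match threshold widths for uniform t", {
  sim <- simulate_cells(small_config(n_cells = 3000, seed = 3))
  frac <- table(sim$truth$cells$type) / nrow(sim$truth$cells)
  # each band spans 20% of [0, 100]; binomial error at n = 6000
  expect_true(all(abs(frac - 0.2) < 3 * sqrt(0.2 * 0.8 / nrow(sim$truth$cells))))
})

test_that("without feedback the two conditions are exchangeable", {
  nonrej <- vapply(1:10, function(s) {
    sim <- simulate_cells(small_config(n_cells = 300, seed = s,
                                       feedback_gamma = 0))
    norm <- normalize_log_cpm(sim$matrix)
    emt <- intersect(sim$modules$EMT_MARKERS$genes, norm$gene_ids)
    score <- Matrix::rowMeans(norm$values[, emt])
    cond <- sim$annotations$condition
    stats::t.test(score[cond == "FLAG"], score[cond == "TET2CD"])$p.value > 0.01
  }, logical(1))
  expect_gte(sum(nonrej), 9L)
})

test_that("feedback attenuates the noiseless EMT curve only late in the trajectory", {
  cfg <- small_config(feedback_gamma = 0.5)
  p_emt <- cfg$module_params$EMT_MARKERS
  p_tet2 <- cfg$module_params$TET2_TARGETS
  t <- seq(0, 100, by = 1)
  plain <- module_mean(t, p_emt)
  act <- 1 / (1 + exp(-p_tet2$steepness * (t - p_tet2$midpoint)))
  coupled <- p_emt$baseline +
    p_emt$amplitude * (1 - cfg$feedback_gamma * act) /
      (1 + exp(-p_emt$steepness * (t - p_emt$midpoint)))
  upper <- t > 50
  expect_true(all(coupled[upper] < plain[upper]))
})

test_that("bulk cohort samples are stage-monotone cell averages", {
  cfg <- small_config(n_cells = 50)
  bulk <- simulate_bulk_cohort(cfg, n_samples = 30, cells_per_sample = 5,
                               seed = 5)
  expect_identical(bulk$matrix$kind, "normalized")
  expect_equal(dim(bulk$matrix)[1], 30)
  # stage labels non-decreasing in sample t
  ord <- order(bulk$truth$t_true)
  expect_false(is.unsorted(as.integer(bulk$truth$stage[ord])))
  # module-score direction matches amplitude sign between trajectory ends
  ends <- simulate_bulk_cohort(cfg, n_samples = 2, cells_per_sample = 40,
                               seed = 9)
  # construct extremes directly: compare profiles of earliest vs latest sample
  lo <- which.min(ends$truth$t_true); hi <- which.max(ends$truth$t_true)
  if (abs(ends$truth$t_true[hi] - ends$truth$t_true[lo]) > 50) {
    sim <- simulate_cells(cfg)
    for (m in c("GLYCOLYSIS", "TET2_TARGETS")) {
      genes <- sim$modules[[m]]$genes
      d <- mean(ends$matrix$values[hi, genes]) - mean(ends$matrix$values[lo, genes])
      expect_gt(d, 0)
    }
    genes <- sim$modules$OXPHOS$genes
    expect_lt(mean(ends$matrix$values[hi, genes]) -
                mean(ends$matrix$values[lo, genes]), 0)
  }
  expect_error(simulate_bulk_cohort(cfg, n_samples = 10,
                                    stage_rule = c(50, 25, 75)),
               "stage_rule")
})

test_that("a singleton bulk sample equals its cell's normalized profile", {
  cfg <- small_config(n_cells = 50)
  bulk <- simulate_bulk_cohort(cfg, n_samples = 2, cells_per_sample = 1,
                               seed = 2)
  # profile must be a valid log-CPM vector: undo the transform and check
  # the implied counts are integers summing to the implied library
  prof <- bulk$matrix$values[1, ]
  counts <- expm1(prof)                  # counts * 1e4 / lib
  lib_scaled <- sum(counts)              # = 1e4 for a single cell
  expect_equal(lib_scaled, 1e4, tolerance = 1e-6)
})

test_that("IHC cohort generator encodes the protective nuclear-TET2 hazard", {
  rec <- simulate_ihc_cohort(n_samples = 200, hazard_beta = 1.5,
                             censor_rate = 0, seed = 1)
  expect_true(all(rec$event == 1L))
  expect_true(all(rec$time >= 0))
  expect_true(all(levels(rec$category) %in%
                    c("nucleus_only", "nucleus_major",
                      "cytoplasm_major", "cytoplasm_only")))
  # null model: survival independent of f
  nonsig <- vapply(1:10, function(s) {
    r <- simulate_ihc_cohort(n_samples = 200, hazard_beta = 0,
                             censor_rate = 0.2, seed = s)
    logrank_test(data.frame(time = r$time, event = r$event,
                            group = r$category))$p_value > 0.05
  }, logical(1))
  expect_gte(sum(nonsig), 8L)
  expect_error(simulate_ihc_cohort(n_samples = 5), "n_samples")
  expect_error(simulate_ihc_cohort(hazard_beta = -1), "hazard_beta")
})
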
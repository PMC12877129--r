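test_that("qc_filter removes cells then genes in order", {
  m <- matrix(c(5, 0, 0,
                4, 3, 0,
                2, 2, 2,
                0, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  em <- expression_matrix(m, kind = "counts")
  expect_identical(as.matrix(suppressMessages(qc_filter(em, 0, 0))$values), m)

  # brute-force expectation for thresholds (2, 2): apply the rule literally
  keep_cells <- rowSums(m > 0) >= 2          # c2, c3
  m2 <- m[keep_cells, , drop = FALSE]
  keep_genes <- colSums(m2 > 0) >= 2         # g1, g2
  expected <- m2[, keep_genes, drop = FALSE]
  got <- suppressMessages(qc_filter(em, 2, 2))
  expect_identical(as.matrix(got$values), expected)

  # all-zero cell removed at threshold 1
  got1 <- suppressMessages(qc_filter(em, 1, 0))
  expect_false("c4" %in% got1$row_ids)

  expect_error(suppressMessages(qc_filter(em, 10, 0)), "all 4 cells")
})

test_that("log-CPM normalization matches the closed form and is scale-invariant", {
  em <- expression_matrix(matrix(c(10000, 0, 3, 1), 2, byrow = TRUE,
                                 dimnames = list(c("a", "b"), c("g1", "g2"))),
                          kind = "counts")
  norm <- normalize_log_cpm(em)
  expect_equal(norm$values["a", "g1"], log(1 + 1e4))
  expect_equal(norm$values["b", "g1"], log(1 + 3 / 4 * 1e4))
  expect_equal(norm$values["b", "g2"], log(1 + 1 / 4 * 1e4))

  em3 <- expression_matrix(3 * as.matrix(em$values), kind = "counts")
  expect_equal(as.matrix(normalize_log_cpm(em3)$values),
               as.matrix(norm$values))

  zero <- expression_matrix(matrix(c(1, 0, 0, 0), 2,
                                   dimnames = list(c("a", "b"), c("g1", "g2"))),
                            kind = "counts")
  expect_error(normalize_log_cpm(zero), "zero total")
  expect_error(normalize_log_cpm(norm), "kind 'counts'")
})

test_that("pseudotime recovers a one-dimensional sigmoid program", {
  set.seed(101)
  n <- 1000
  t_true <- runif(n, 0, 100)
  genes <- c(outer(1:20, c(30, 50, 70), function(i, m) {
    paste0("g", i, "_m", m)
  }))
  x <- sapply(seq_along(genes), function(j) {
    mid <- c(30, 50, 70)[(j - 1) %/% 20 + 1]
    1 / (1 + exp(-0.2 * (t_true - mid))) + rnorm(n, 0, 0.05)
  })
  x <- x - min(x)
  em <- expression_matrix(x, row_ids = sprintf("c%04d", 1:n),
                          gene_ids = genes, kind = "normalized")
  root_cells <- em$row_ids[t_true < 5]
  pt <- infer_pseudotime(em, genes, root_cells)
  expect_gte(cor(pt$t, t_true, method = "spearman"), 0.9)
  expect_true(all(pt$t >= 0 & pt$t <= 100))

  # reversing the root flips t to 100 - t (no ties here)
  late_cells <- em$row_ids[t_true > 95]
  pt_rev <- infer_pseudotime(em, genes, late_cells)
  expect_equal(pt_rev$t, 100 - pt$t, tolerance = 1e-8)
})

test_that("duplicated cells get equal pseudotime and order permutation is safe", {
  sim <- cached_sim()
  norm <- normalize_log_cpm(sim$matrix)
  genes <- unlist(lapply(sim$modules, `[[`, "genes"))
  pt <- infer_pseudotime(norm, genes, sim$modules$OXPHOS)

  # permuting the cells permutes t identically
  idx <- sample(length(pt$cell))
  em_p <- expression_matrix(norm$values[idx, ], kind = "normalized")
  pt_p <- infer_pseudotime(em_p, genes, sim$modules$OXPHOS)
  expect_equal(pt_p$t[match(pt$cell, pt_p$cell)], pt$t, tolerance = 1e-6)

  # duplicated rows tie
  v2 <- rbind(norm$values[1:50, ], norm$values[1:50, ])
  rownames(v2) <- c(paste0("a", 1:50), paste0("b", 1:50))
  v2 <- rbind(v2, norm$values[51:200, ])
  em_d <- expression_matrix(v2, kind = "normalized")
  pt_d <- infer_pseudotime(em_d, genes, sim$modules$OXPHOS)
  expect_equal(unname(pt_d$t[1:50]), unname(pt_d$t[51:100]), tolerance = 1e-8)

  expect_error(infer_pseudotime(norm, genes[1:5], sim$modules$OXPHOS), ">= 10")
})

test_that("pseudotime is invariant to a global count scaling", {
  sim <- cached_sim()
  genes <- unlist(lapply(sim$modules, `[[`, "genes"))
  pt1 <- infer_pseudotime(normalize_log_cpm(sim$matrix), genes,
                          sim$modules$OXPHOS)
  scaled <- expression_matrix(sim$matrix$values * 5, kind = "counts")
  pt2 <- infer_pseudotime(normalize_log_cpm(scaled), genes,
                          sim$modules$OXPHOS)
  expect_equal(pt1$t, pt2$t, tolerance = 1e-6)
})

test_that("equal-count binning balances bin sizes to within one cell", {
  mk_pt <- function(n) {
    structure(list(cell = sprintf("c%04d", 1:n), t = seq(0, 100, length.out = n),
                   bin = rep(NA_integer_, n), n_bins = NA_integer_,
                   orientation_evidence = 1),
              class = "PseudotimeAssignment")
  }
  b200 <- bin_pseudotime(mk_pt(200), 100)
  expect_true(all(table(b200$bin) == 2))
  b201 <- bin_pseudotime(mk_pt(201), 100)
  sizes <- table(b201$bin)
  expect_identical(sum(sizes == 2), 99L)
  expect_identical(sum(sizes == 3), 1L)
  # bin index increases with t
  expect_false(is.unsorted(b201$bin[order(b201$t)]))
  expect_error(bin_pseudotime(mk_pt(200), 1), "n_bins")
  expect_error(bin_pseudotime(mk_pt(50), 100), "50 cells")
})

test_that("module scores are centered z-score means with sensible bin curves", {
  sim <- cached_sim()
  res <- run_event_ordering(sim$matrix, sim$modules, n_bins = 50)
  prof <- res$profile
  # per-cell module scores have mean ~ 0 across all cells
  for (m in names(sim$modules)) {
    expect_lt(abs(mean(prof$cell_scores[[m]])), 1e-8)
  }
  # single-gene module score equals that gene's z-score
  g1 <- sim$modules$TET2_TARGETS$genes[1]
  single <- gene_module("SINGLE", g1)
  prof1 <- score_modules(res$normalized, list(single), res$pt)
  z <- scale(as.matrix(res$normalized$values[, g1]))
  expect_equal(unname(prof1$cell_scores$SINGLE), as.numeric(z), tolerance = 1e-8)
  # TET2-target bin curve rises along pseudotime
  rho <- cor(prof$bins, prof$module_scores[, "TET2_TARGETS"],
             method = "spearman")
  expect_gt(rho, 0.8)
  # unknown module errors by name
  expect_error(score_modules(res$normalized,
                             list(gene_module("GHOST", "NOT_A_GENE")), res$pt),
               "GHOST")
})

test_that("noiseless bin curves reproduce the generative sigmoids affinely", {
  cfg <- small_config(n_cells = 2000, seed = 13,
                      dispersion = 1e6, library_size_mean = 2e5)
  sim <- simulate_cells(cfg)
  res <- run_event_ordering(sim$matrix, sim$modules, n_bins = 100)
  tt <- sim$truth$cells$t_true[match(res$pt$cell, sim$truth$cells$cell)]
  bin_t <- tapply(tt, res$pt$bin, mean)
  for (m in names(sim$modules)) {
    p <- cfg$module_params[[m]]
    expected <- module_mean(bin_t, p)
    expect_gt(abs(cor(expected, res$profile$module_scores[, m])), 0.99)
  }
})
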
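test_that("the eigengene summarizes the core profile with a fixed orientation", {
  ## rank-1 case: every core gene an affine copy of one profile, so the
  ## standardized submatrix has identical rows and the eigengene is the
  ## standardized profile itself
  withr::with_seed(3, v <- rnorm(12))
  lg <- outer(c(2, 3, 0.5, 1.5), v) + c(1, 0, 4, -2)
  rownames(lg) <- paste0("g", 1:4); colnames(lg) <- paste0("s", 1:12)
  e <- expr_matrix(lg, "log")
  eig <- compute_eigengene(e, paste0("g", 1:4))
  expect_gt(abs(cor(eig, v)), 1 - 1e-10)
  expect_gt(cor(eig, v), 0)       # positive orientation

  ## common signal plus small noise: eigengene tracks the signal
  for (s in 1:5) {
    withr::with_seed(s, {
      f <- rnorm(60)
      m <- matrix(rep(f, each = 20), 20) + matrix(rnorm(1200, sd = 0.3), 20)
    })
    rownames(m) <- paste0("g", 1:20); colnames(m) <- paste0("s", 1:60)
    eig <- compute_eigengene(expr_matrix(m, "log"), paste0("g", 1:20))
    expect_gt(cor(eig, f), 0.99)
  }

  ## flipping the sign of the data leaves the oriented eigengene aligned
  m2 <- -m
  eig2 <- compute_eigengene(expr_matrix(m2, "log"), paste0("g", 1:20))
  expect_gt(cor(eig2, colMeans(m2)), 0)

  expect_error(compute_eigengene(e, "g1"), "at least 2")
  flat <- expr_matrix(matrix(5, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5))),
                      "linear")
  expect_error(compute_eigengene(flat, c("a", "b")), "rank 0")
})

test_that("single-factor data normalizes to constants (exact cancellation)", {
  withr::with_seed(14, f <- runif(10, 1, 4))
  cgene <- c(2, 3, 5, 1, 8)
  v <- outer(cgene, f)
  rownames(v) <- paste0("g", 1:5); colnames(v) <- paste0("s", 1:10)
  nr <- immfocus_normalize(expr_matrix(v, "linear"), c("g1", "g2"))
  expect_lt(max(apply(nr$normalized_expr$values, 1, sd)), 1e-6)
  expect_true(all(nr$f_ings > 0))
  expect_true(all(nr$ings_final %in% nr$ings_initial))
})

test_that("normalization thresholds and spaces are validated", {
  ds <- generate_synthetic(scenario("nested", seed = 0))
  core <- ds$truth_core[[1]]
  ## impossible correlation threshold -> empty INGS
  expect_error(immfocus_normalize(ds$expr, core, rho_threshold = 1),
               "lower `rho_threshold`")
  ## log-space input is refused
  expect_error(immfocus_normalize(nestwgcna:::as_log_expr(ds$expr), core),
               "linear")
  expect_error(immfocus_normalize(ds$expr, character(0)), "non-empty")
})

test_that("core normalization removes the shared-factor correlation", {
  ds <- generate_synthetic(scenario("nested", seed = 0))
  cgm <- ds$truth_cgm$gene_ids
  core <- ds$truth_core[[1]]
  noncore <- setdiff(cgm, core)
  eig <- compute_eigengene(ds$expr, core)
  pre <- mean(abs(apply(log2(ds$expr$values[noncore, ] + 1), 1,
                        cor, eig, method = "spearman")))
  nr <- immfocus_normalize(ds$expr, core)
  post <- mean(abs(apply(log2(nr$normalized_expr$values[noncore, ] + 1), 1,
                         cor, eig, method = "spearman")))
  expect_gt(pre, 0.7)
  expect_lt(post, 0.3)
  ## containment chain and positive factors
  expect_true(all(nr$ings_final %in% nr$ings_initial))
  expect_true(all(nr$ings_initial %in% cgm))
  expect_true(all(nr$f_ings > 0))
  expect_true(all(is.finite(nr$cv_ratio)))
})

test_that("normalization is scale-free in the expression units", {
  ds <- generate_synthetic(scenario("nested", seed = 1))
  core <- ds$truth_core[[1]]
  n1 <- immfocus_normalize(ds$expr, core)
  scaled <- expr_matrix(ds$expr$values * 7, "linear")
  n2 <- immfocus_normalize(scaled, core)
  expect_equal(n2$normalized_expr$values, n1$normalized_expr$values,
               tolerance = 1e-6)
})

test_that("fine-grained modules recover planted sub-structure after normalization", {
  ds <- generate_synthetic(scenario("nested", seed = 0))
  cgm <- ds$truth_cgm$gene_ids
  fg <- infer_fgms(ds$expr, cgm, ds$truth_core[[1]],
                   fgm_min_cluster_size = 15, seed = 0)
  tr <- ds$truth_fgm[[1]]
  sub_genes <- tr$gene_ids[tr$labels >= 0]
  expect_gte(ari_on_genes(fg$assignment, tr, sub_genes), 0.8)
  expect_gte(length(fg$fgm_gene_sets), 3L)
  ## FGM genes live inside the parent CGM and are pairwise disjoint
  all_fgm <- unlist(fg$fgm_gene_sets, use.names = FALSE)
  expect_true(all(all_fgm %in% cgm))
  expect_identical(anyDuplicated(all_fgm), 0L)
  expect_identical(fg$assignment$level, "FGM")
})

test_that("a module without sub-structure yields at most one FGM", {
  ds <- generate_synthetic(scenario("null_cgm", seed = 0))
  fg <- suppressWarnings(   # an all-noise FGM round warns, by contract
    infer_fgms(ds$expr, ds$truth_cgm$gene_ids, ds$truth_core[[1]],
               fgm_min_cluster_size = 15, seed = 0))
  expect_lte(length(fg$fgm_gene_sets), 1L)
})

test_that("a module too small for the FGM floor returns an empty set with a warning", {
  ds <- generate_synthetic(scenario("nested", seed = 2))
  small <- ds$truth_cgm$gene_ids[1:25]
  expect_warning(
    fg <- infer_fgms(ds$expr, small, small[1:5], fgm_min_cluster_size = 15,
                     seed = 2),
    "too small")
  expect_length(fg$fgm_gene_sets, 0)
  expect_true(all(fg$assignment$labels == -1L))
  expect_error(infer_fgms(ds$expr, small, c(small[1], "not_a_gene"), 15),
               "subset")
})
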
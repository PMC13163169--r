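test_that("generation is deterministic and structurally consistent", {
  sp <- scenario("default", seed = 5)
  d1 <- generate_synthetic(sp)
  d2 <- generate_synthetic(sp)
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$truth_cgm$labels, d2$truth_cgm$labels)

  ## strictly positive linear expression, labels consistent with the spec
  expect_true(all(d1$expr$values > 0))
  expect_identical(d1$expr$space, "linear")
  expect_identical(sum(d1$truth_cgm$labels >= 0), 4L * 300L)
  expect_identical(sum(d1$truth_cgm$labels == -1L), 50L + 500L)
  expect_length(d1$truth_core, 4L)
  expect_true(all(vapply(d1$truth_core, length, 1L) == 120L))
  for (k in names(d1$truth_fgm)) {
    tf <- d1$truth_fgm[[k]]
    expect_identical(sum(tf$labels >= 0), 120L)             # 3 x 40 sub genes
    expect_true(all(tf$gene_ids %in%
                      module_genes(d1$truth_cgm, sub("CGM_", "", k))))
    ## sub-blocks sit on periphery genes, never on the core
    expect_length(intersect(tf$gene_ids[tf$labels >= 0], d1$truth_core[[k]]), 0)
  }
})

test_that("pairwise correlations match the closed form lambda^2/(lambda^2+sigma^2)", {
  sp <- synthetic_spec(n_samples = 500L, seed = 9)
  ds <- generate_synthetic(sp)
  lv <- log2(ds$expr$values)
  ## core genes of one module share only the module factor at loading 0.9
  core <- ds$truth_core[["CGM_0"]]
  cc <- cor(t(lv[core, ]))
  emp_core <- mean(cc[upper.tri(cc)])
  expect_equal(emp_core, 0.9^2 / (0.9^2 + 1), tolerance = 0.05)
  ## plain periphery genes (loading 0.6, no sub-factor)
  tf <- ds$truth_fgm[["CGM_0"]]
  plain <- setdiff(tf$gene_ids[tf$labels == -1L], core)
  pp <- cor(t(lv[plain, ]))
  expect_equal(mean(pp[upper.tri(pp)]), 0.6^2 / (0.6^2 + 1), tolerance = 0.05)
  ## genes in different modules are uncorrelated
  other <- ds$truth_core[["CGM_1"]]
  expect_equal(mean(cor(t(lv[core, ]), t(lv[other, ]))), 0, tolerance = 0.05)
})

test_that("within-module r^2 exceeds between-module r^2 by the model margin", {
  ## analytic within-CGM mean r^2 for the default loadings (flat noise sd 1):
  ## pair-type mixture of core-core, core-periphery, periphery pairs with and
  ## without a shared sub-factor
  r2 <- function(cov, v1, v2) (cov / sqrt(v1 * v2))^2
  vc <- 0.9^2 + 1; vp <- 0.6^2 + 1; vs <- 0.6^2 + 0.6^2 + 1
  n_core <- 120; n_sub <- 120; n_plain <- 60; gpc <- 300
  pairs_total <- choose(gpc, 2)
  w_cc <- choose(n_core, 2)
  w_ss_same <- 3 * choose(40, 2)
  w_ss_diff <- choose(n_sub, 2) - w_ss_same
  w_pp <- choose(n_plain, 2)
  w_cs <- n_core * n_sub; w_cp <- n_core * n_plain; w_sp <- n_sub * n_plain
  analytic_within <- (w_cc * r2(0.81, vc, vc) +
                      w_ss_same * r2(0.36 + 0.36, vs, vs) +
                      w_ss_diff * r2(0.36, vs, vs) +
                      w_pp * r2(0.36, vp, vp) +
                      w_cs * r2(0.54, vc, vs) +
                      w_cp * r2(0.54, vc, vp) +
                      w_sp * r2(0.36, vs, vp)) / pairs_total

  margins <- vapply(0:4, function(s) {
    ds <- generate_synthetic(scenario("default", seed = s))
    lv <- log2(ds$expr$values)
    g0 <- module_genes(ds$truth_cgm, 0)
    g1 <- module_genes(ds$truth_cgm, 1)
    within <- cor(t(lv[g0, ]))^2
    between <- cor(t(lv[g0, ]), t(lv[g1, ]))^2
    ## empirical within matches the analytic mixture (absolute scale)
    expect_lt(abs(mean(within[upper.tri(within)]) - analytic_within), 0.02)
    mean(within[upper.tri(within)]) - mean(between)
  }, numeric(1))
  expect_true(all(margins > 0.08))
})

test_that("noise-free single-factor data approaches perfect correlation", {
  sp <- synthetic_spec(n_samples = 50L, n_cgms = 1L, genes_per_cgm = 30L,
                       core_fraction = 1, n_subfactors_per_cgm = 0L,
                       genes_per_subfactor = 0L, core_loading = 0.9,
                       n_housekeeping = 0L, n_noise_genes = 0L,
                       noise_sd = 1e-4, seed = 4)
  ds <- generate_synthetic(sp)
  r2 <- cor(t(log2(ds$expr$values)))^2
  expect_gt(min(r2), 0.999)
})

test_that("housekeeping genes track every module factor but stay out of cores", {
  ds <- generate_synthetic(scenario("default", seed = 1))
  hk <- grep("^HK_", ds$truth_cgm$gene_ids, value = TRUE)
  lv <- log2(ds$expr$values)
  for (c_i in 1:4) {
    rr <- apply(lv[hk, ], 1, cor, ds$factors$F[c_i, ])
    expect_gt(mean(rr), 0.1)   # weak positive coupling to every factor
  }
  ## the broadly connected housekeeping genes are not absorbed into a
  ## module's dense core
  g0 <- module_genes(ds$truth_cgm, 0)
  adj <- compute_adjacency(nestwgcna:::as_log_expr(
    expr_matrix(ds$expr$values[c(g0, hk), ], "linear")))
  core <- extract_core(c(g0, hk), adj)
  expect_length(intersect(core, hk), 0)
})

test_that("scenario presets and validation behave as documented", {
  no <- scenario("noise_only")
  expect_identical(no$n_cgms, 0L)
  expect_identical(no$n_noise_genes, 1000L)
  ne <- scenario("nested", seed = 3)
  expect_identical(ne$n_cgms, 1L)
  expect_identical(ne$n_subfactors_per_cgm, 3L)
  expect_identical(ne$seed, 3L)
  expect_identical(scenario("default")$n_noise_genes, 500L)
  expect_error(scenario("bogus"))

  expect_error(synthetic_spec(n_samples = 2), "n_samples")
  expect_error(synthetic_spec(core_loading = 1.4), "core_loading")
  expect_error(synthetic_spec(n_cgms = 1L, genes_per_cgm = 50L,
                              core_fraction = 0.5,
                              n_subfactors_per_cgm = 3L,
                              genes_per_subfactor = 20L),
               "do not fit")
  expect_error(synthetic_spec(n_cgms = 0L, n_noise_genes = 0L,
                              n_housekeeping = 0L), "no genes")
})
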
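test_that("agreement metrics match scikit-learn on frozen label fixtures", {
  p1 <- metric_fixture_labels()
  m1 <- metrics_for_labels(p1$a, p1$b)
  expect_equal(unname(m1["ari"]), unname(sklearn_pair1["ari"]), tolerance = 1e-12)
  expect_equal(unname(m1["ami"]), unname(sklearn_pair1["ami"]), tolerance = 1e-12)
  expect_equal(unname(m1["v_measure"]), unname(sklearn_pair1["v"]), tolerance = 1e-12)

  p2 <- metric_fixture_labels2()
  m2 <- metrics_for_labels(p2$a, p2$b)
  expect_equal(unname(m2["ari"]), unname(sklearn_pair2["ari"]), tolerance = 1e-12)
  expect_equal(unname(m2["ami"]), unname(sklearn_pair2["ami"]), tolerance = 1e-12)
  expect_equal(unname(m2["v_measure"]), unname(sklearn_pair2["v"]), tolerance = 1e-12)

  ## and the ARI agrees with the independent mclust implementation
  expect_equal(unname(m2["ari"]), mclust::adjustedRandIndex(p2$a, p2$b),
               tolerance = 1e-12)
})

test_that("metric identities: self-agreement, permutation invariance, symmetry", {
  withr::with_seed(9, lab <- sample(c(-1L, 0L, 1L, 2L), 80, replace = TRUE))
  m <- metrics_for_labels(lab, lab)
  expect_equal(unname(m), c(1, 1, 1))
  ## permuting label names changes nothing
  perm <- c(`-1` = 2L, `0` = -1L, `1` = 0L, `2` = 1L)
  m2 <- metrics_for_labels(lab, perm[as.character(lab)])
  expect_equal(unname(m2), c(1, 1, 1))
  ## symmetry in the arguments
  withr::with_seed(10, lab2 <- sample(0:3, 80, replace = TRUE))
  expect_equal(metrics_for_labels(lab, lab2), metrics_for_labels(lab2, lab))
  ## a trivial one-cluster partition scores ARI (and AMI) of 0
  balanced <- rep(0:9, each = 100)
  m3 <- metrics_for_labels(rep(0L, 1000), balanced)
  expect_equal(unname(m3["ari"]), 0)
  expect_equal(unname(m3["ami"]), 0, tolerance = 1e-12)
  ## genes present in only one assignment are dropped before comparison
  a <- module_assignment(sprintf("g%d", 1:10), rep(0L, 10))
  b <- module_assignment(sprintf("g%d", 6:15), rep(0L, 10))
  expect_message(mm <- compare_clusterings(a, b), "shared genes")
  expect_equal(unname(mm["ari"]), 1)
  expect_error(compare_clusterings(a, module_assignment("x", 0L)), "share no genes")
})

test_that("bootstrap coverage converges to 1 - 1/e and B = 2 gives one pair", {
  frac <- bootstrap_unique_fraction(1000, reps = 50, seed = 1)
  expect_equal(frac, 1 - exp(-1), tolerance = 0.01)

  ds <- generate_synthetic(strong_signal_spec(seed = 12))
  r2 <- bootstrap_stability(ds$expr, min_cluster_size = 30, B = 2, seed = 12)
  expect_identical(r2$n_pairs, 1L)
  expect_error(bootstrap_stability(ds$expr, B = 1), "B >= 2")
})

test_that("module detection is stable under bootstrap resampling of strong signal", {
  ds <- generate_synthetic(strong_signal_spec(seed = 11))
  r <- bootstrap_stability(ds$expr, min_cluster_size = 30, B = 3, seed = 11)
  expect_gte(unname(r$mean["ari"]), 0.8)
  expect_identical(r$n_pairs, 3L)
  expect_equal(mean(r$unique_fraction), 1 - exp(-1), tolerance = 0.05)
  expect_true(all(r$pair_metrics$ari >= -1 & r$pair_metrics$ari <= 1))
  expect_true(all(r$pair_metrics$v_measure >= 0 & r$pair_metrics$v_measure <= 1))
})

test_that("knowledge score reproduces hand-enumerated counts and exact p-values", {
  ## constructed fixture with all four pair categories populated
  genes <- sprintf("g%02d", 1:12)
  modules <- module_assignment(genes, c(rep(0L, 5), rep(1L, 4), -1L, -1L, -1L))
  tf <- list(TFa = genes[c(1:3, 6:7, 10)], TFb = genes[c(4, 8, 11:12)])
  ks <- knowledge_score(modules, tf)

  ## independent oracle: enumerate the pairs directly from the definitions;
  ## the universe is the module-assigned genes that carry TF annotation
  assigned <- genes[1:9]
  keep <- assigned[assigned %in% unlist(tf)]
  share <- outer(seq_along(keep), seq_along(keep), Vectorize(function(i, j)
    any(vapply(tf, function(t) keep[i] %in% t && keep[j] %in% t, logical(1)))))
  labs <- modules$labels[match(keep, genes)]
  same <- outer(labs, labs, "==")
  up <- upper.tri(share)
  expected <- c(cp_kp = sum(same[up] & share[up]),
                notcp_kp = sum(!same[up] & share[up]),
                cp_notkp = sum(same[up] & !share[up]),
                notcp_notkp = sum(!same[up] & !share[up]))
  expect_equal(ks$counts, expected)
  expect_equal(sum(ks$counts), choose(length(keep), 2))
  expect_equal(ks$score,
               unname((expected[1] * expected[4]) / (expected[2] * expected[3])))
  ft <- stats::fisher.test(matrix(expected, 2), alternative = "greater")
  expect_equal(ks$p_value, ft$p.value, tolerance = 1e-9)
  expect_identical(ks$n_tf_annotated_genes, 7L)   # g05/g09 lack TF annotation

  ## degenerate table: zero denominator is flagged and reported as +Inf
  m2 <- module_assignment(paste0("h", 1:8), c(rep(0L, 4), rep(1L, 4)))
  tf2 <- list(T1 = paste0("h", 1:4), T2 = paste0("h", 5:8))
  ks2 <- knowledge_score(m2, tf2)
  expect_true(ks2$undefined)
  expect_identical(ks2$score, Inf)
  expect_error(knowledge_score(m2, list(T1 = "absent_gene")), "TF-annotated")
})

test_that("the exact tail p agrees with fisher.test across table margins", {
  withr::with_seed(77, {
    for (i in 1:300) {
      M <- sample(4:30, 1)
      K <- sample(1:(M - 1), 1)
      C <- sample(1:(M - 1), 1)
      a <- sample(max(0, K + C - M):min(K, C), 1)
      tab <- c(a, K - a, C - a, M - K - C + a)
      p_mine <- nestwgcna:::hypergeom_tail_p(tab[1], tab[2], tab[3], tab[4])
      p_ref <- stats::fisher.test(matrix(tab, 2), alternative = "greater")$p.value
      expect_equal(p_mine, p_ref, tolerance = 1e-9)
    }
  })
})

test_that("random labelings concentrate the knowledge score at 1", {
  withr::with_seed(88, {
    genes <- sprintf("g%02d", 1:50)
    scores <- vapply(1:200, function(i) {
      modules <- module_assignment(genes, sample(0:4, 50, replace = TRUE))
      tf <- lapply(1:6, function(k) sample(genes, 15))
      names(tf) <- paste0("TF", 1:6)
      ks <- knowledge_score(modules, tf)
      if (ks$undefined) NA_real_ else ks$score
    }, numeric(1))
  })
  expect_gt(mean(scores, na.rm = TRUE), 0.8)
  expect_lt(mean(scores, na.rm = TRUE), 1.25)
})

test_that("module scores are z-score means with core-referenced normalization", {
  e <- random_expr(12, 20, seed = 5)
  g <- gene_ids(e)
  ## module identical to its core: normalized score is exactly zero
  sc0 <- score_module(e, g[1:4], core_genes = g[1:4])
  expect_equal(sc0$normalized, rep(0, 20))
  ## single-gene module: raw score equals that gene's z-scored log profile
  sc1 <- score_module(e, g[1])
  z <- scale(log2(e$values[g[1], ] + 1))[, 1]
  expect_equal(sc1$raw, unname(z))
  ## gene-wise affine rescaling of the log values leaves raw scores unchanged
  lv <- log2(e$values + 1)
  lv2 <- lv * seq(0.5, 3, length.out = 12) + seq_len(12)
  e2 <- expr_matrix(lv2, "log")
  sc2a <- score_module(expr_matrix(lv, "log"), g[2:6])
  sc2b <- score_module(e2, g[2:6])
  expect_equal(sc2a$raw, sc2b$raw, tolerance = 1e-12)
  ## ratio mode
  scr <- score_module(e, g[1:3], core_genes = g[4:6], mode = "ratio")
  expect_equal(scr$normalized,
               unname(colMeans(e$values[g[1:3], ]) /
                        (colMeans(e$values[g[4:6], ]) + 1e-9)))
  expect_error(score_module(e, character(0)), "empty")
  expect_error(score_module(e, "nope"), "absent")
})

test_that("a sample with boosted sub-factor activity scores higher after normalization", {
  for (s in 1:5) {
    withr::with_seed(s, {
      n <- 40
      f <- rnorm(n)                    # core process activity
      sub <- rnorm(n)
      sub[1] <- sub[1] + 3             # sample 1: boosted subprocess at same core
      core_mat <- matrix(rep(f, each = 10), 10) + matrix(rnorm(10 * n, sd = .3), 10)
      mod_mat <- matrix(rep(f + 0.8 * sub, each = 8), 8) +
        matrix(rnorm(8 * n, sd = .3), 8)
      lin <- 2^(rbind(core_mat, mod_mat) + 6)
      rownames(lin) <- c(sprintf("c%d", 1:10), sprintf("m%d", 1:8))
      colnames(lin) <- sprintf("s%d", 1:n)
    })
    e <- expr_matrix(lin, "linear")
    sc <- score_module(e, sprintf("m%d", 1:8), core_genes = sprintf("c%d", 1:10))
    expect_gt(sc$normalized[1], max(quantile(sc$normalized[-1], 0.9)))
  }
})

test_that("median dichotomization sends ties to the low group", {
  expect_identical(sum(dichotomize_scores(1:10) == "high"), 5L)
  expect_true(all(dichotomize_scores(rep(2, 6)) == "low"))
  x <- c(1, 2, 3, 4, 100)   # split at the median, not the mean
  expect_identical(dichotomize_scores(x), c("low", "low", "low", "high", "high"))
  e <- random_expr(6, 10, seed = 2)
  sc <- score_module(e, gene_ids(e)[1:3], core_genes = gene_ids(e)[4:6])
  expect_identical(sum(dichotomize_scores(sc) == "high") +
                     sum(dichotomize_scores(sc) == "low"), 10L)
  expect_error(dichotomize_scores(1), "2 samples")
})
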
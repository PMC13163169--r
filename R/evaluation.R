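## Clustering agreement metrics, stability analyses, transcription-factor
## co-regulation scoring, and module signature scores.

## contingency table of two integer label vectors (noise -1 already mapped)
label_contingency <- function(a, b) {
  table(factor(a), factor(b))
}

ari_from_table <- function(ct) {
  n <- sum(ct)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(ct))
  sa <- sum_comb(rowSums(ct))
  sb <- sum_comb(colSums(ct))
  expected <- sa * sb / choose(n, 2)
  mx <- (sa + sb) / 2
  if (mx == expected) return(1)   # both partitions trivial
  (sij - expected) / (mx - expected)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

mi_from_table <- function(ct) {
  n <- sum(ct)
  p <- ct / n
  pa <- rowSums(p); pb <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log(p[idx] / (pa[idx[, 1L]] * pb[idx[, 2L]])))
}

## Expected mutual information under the permutation (hypergeometric) model.
emi_from_table <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1L, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lchoose(b[j], nij) + lchoose(n - b[j], a[i] - nij) - lchoose(n, a[i])
        emi <- emi + exp(lp) * (nij / n) * log((n * nij) / (a[i] * b[j]))
      }
    }
  }
  emi
}

ami_from_table <- function(ct) {
  n <- sum(ct)
  mi <- mi_from_table(ct)
  ha <- entropy_nats(rowSums(ct) / n)
  hb <- entropy_nats(colSums(ct) / n)
  denom_mean <- (ha + hb) / 2          # arithmetic averaging
  if (denom_mean == 0) return(1)       # both partitions trivial
  emi <- emi_from_table(ct)
  if (abs(denom_mean - emi) < 1e-15) return(0)
  (mi - emi) / (denom_mean - emi)
}

vmeasure_from_table <- function(ct) {
  n <- sum(ct)
  ha <- entropy_nats(rowSums(ct) / n)
  hb <- entropy_nats(colSums(ct) / n)
  if (ha == 0 && hb == 0) return(1)
  mi <- mi_from_table(ct)
  h <- if (ha == 0) 1 else mi / ha     # homogeneity / completeness
  c <- if (hb == 0) 1 else mi / hb
  if (h + c == 0) return(0)
  2 * h * c / (h + c)
}

#' Compare two module assignments
#'
#' Adjusted Rand Index, Adjusted Mutual Information (arithmetic-mean
#' normalization, hypergeometric expected MI) and V-measure between two
#' partitions of the same gene universe. Genes present in only one
#' assignment are dropped (with a message); the noise label -1 is treated
#' as a cluster of its own.
#'
#' @param a,b [module_assignment()] objects.
#' @return named numeric vector `c(ari, ami, v_measure)`.
#' @export
compare_clusterings <- function(a, b) {
  stopifnot(inherits(a, "module_assignment"), inherits(b, "module_assignment"))
  common <- intersect(a$gene_ids, b$gene_ids)
  if (length(common) == 0L) stop("assignments share no genes")
  if (length(common) < length(a$gene_ids) || length(common) < length(b$gene_ids))
    message("comparing on the ", length(common), " shared genes")
  la <- a$labels[match(common, a$gene_ids)]
  lb <- b$labels[match(common, b$gene_ids)]
  ct <- label_contingency(la, lb)
  c(ari = unname(ari_from_table(ct)), ami = unname(ami_from_table(ct)),
    v_measure = unname(vmeasure_from_table(ct)))
}

#' Expected unique fraction of a bootstrap pseudosample
#'
#' Draws `reps` bootstrap resamples of size n from n items and returns the
#' mean fraction of distinct items, which converges to 1 - 1/e (~0.632).
#'
#' @param n sample size.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return mean unique fraction across replicates.
#' @export
bootstrap_unique_fraction <- function(n, reps = 200L, seed = 0L) {
  withr::with_seed(as.integer(seed), {
    mean(vapply(seq_len(reps),
                function(i) length(unique(sample.int(n, n, replace = TRUE))) / n,
                numeric(1)))
  })
}

#' Bootstrap stability of module detection
#'
#' Draws `B` bootstrap pseudosamples of the samples (columns, n draws of n
#' with replacement, ~63.2% unique), reruns CGM detection on each, and
#' summarizes all pairwise ARI / AMI / V-measure values.
#'
#' @param expr an [expr_matrix()] (already gene-filtered; all replicates use
#'   this shared gene set).
#' @param min_cluster_size passed to [detect_cgms()].
#' @param B number of pseudosamples (>= 2).
#' @param seed integer seed controlling both the resampling and the
#'   per-replicate pipeline seeds.
#' @return object of class `stability_report`: per-pair metric table,
#'   means, standard deviations, coefficients of variation, unique-sample
#'   fractions, failed replicate indices.
#' @export
bootstrap_stability <- function(expr, min_cluster_size = 50L, B = 10L, seed = 0L) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (B < 2L) stop("need B >= 2 pseudosamples")
  n <- n_samples(expr)
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  })
  unique_fraction <- vapply(draws, function(d) length(unique(d)) / n, numeric(1))
  assignments <- vector("list", B)
  failed <- integer(0)
  for (b in seq_len(B)) {
    cols <- draws[[b]]
    vals <- expr$values[, cols, drop = FALSE]
    colnames(vals) <- sprintf("bs%d_%d", b, seq_along(cols))
    res <- tryCatch(
      detect_cgms(expr_matrix(vals, expr$space),
                  min_cluster_size = min_cluster_size,
                  seed = as.integer(seed) + b),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", b, " failed and was excluded: ",
              conditionMessage(res))
      failed <- c(failed, b)
    } else assignments[[b]] <- res
  }
  ok <- setdiff(seq_len(B), failed)
  if (length(ok) < 2L) stop("fewer than 2 successful replicates")
  pairs <- utils::combn(ok, 2L)
  metrics <- t(apply(pairs, 2L, function(p)
    compare_clusterings(assignments[[p[1L]]], assignments[[p[2L]]])))
  summarize_stability(metrics, pairs, unique_fraction, failed,
                      mode = "bootstrap")
}

summarize_stability <- function(metrics, pairs, unique_fraction, failed, mode) {
  means <- colMeans(metrics)
  sds <- apply(metrics, 2L, sd)
  structure(list(
    pair_metrics = data.frame(a = pairs[1L, ], b = pairs[2L, ], metrics),
    mean = means, sd = sds,
    cv = ifelse(means != 0, sds / abs(means), NA_real_),
    n_pairs = ncol(pairs),
    unique_fraction = unique_fraction,
    failed_replicates = failed,
    mode = mode
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability_report [%s]: %d pairs; mean ARI %.3f, AMI %.3f, V %.3f\n",
    x$mode, x$n_pairs, x$mean["ari"], x$mean["ami"], x$mean["v_measure"]))
  invisible(x)
}

#' Cross-dataset stability
#'
#' Runs CGM detection on two datasets restricted to their shared gene set
#' and compares the assignments.
#'
#' @param expr_a,expr_b [expr_matrix()] objects sharing gene IDs.
#' @param min_cluster_size,seed passed to [detect_cgms()].
#' @return list with the two assignments and the metric vector.
#' @export
cross_dataset_stability <- function(expr_a, expr_b, min_cluster_size = 50L,
                                    seed = 0L) {
  shared <- intersect(gene_ids(expr_a), gene_ids(expr_b))
  if (length(shared) == 0L) stop("datasets share no genes")
  sub <- function(e) expr_matrix(e$values[shared, , drop = FALSE], e$space)
  a <- detect_cgms(sub(expr_a), min_cluster_size, seed)
  b <- detect_cgms(sub(expr_b), min_cluster_size, seed + 1L)
  list(assignment_a = a, assignment_b = b,
       metrics = compare_clusterings(a, b), mode = "cross_dataset")
}

## one-sided (greater) exact p for a 2x2 table by hypergeometric tail sum
hypergeom_tail_p <- function(a, b, c, d) {
  K <- a + b          # knowledge pairs
  C <- a + c          # co-expressed pairs
  M <- a + b + c + d
  hi <- min(K, C)
  if (a > hi) return(0)
  sum(dhyper(a:hi, K, M - K, C))
}

#' Transcription-factor knowledge score
#'
#' Odds ratio relating "gene pair shares a module" (co-expressed pair, CP)
#' to "gene pair shares at least one transcription-factor regulator"
#' (knowledge pair, KP), over all unordered pairs of TF-annotated genes.
#' Genes without TF annotation, and noise-labeled genes, are excluded. The
#' score is (CP&KP * !CP&!KP) / (!CP&KP * CP&!KP); significance comes from
#' the exact hypergeometric tail (one-sided Fisher test in the enrichment
#' direction by default).
#'
#' @param modules a [module_assignment()].
#' @param tf_targets named list: TF -> character vector of target genes
#'   (e.g. read from a GMT file with [read_gmt()]).
#' @param alternative `"greater"` (default) or `"two.sided"` (delegated to
#'   [stats::fisher.test()]).
#' @return object of class `knowledge_score`: `counts` (named a/b/c/d),
#'   `score`, `p_value`, `n_tf_annotated_genes`, `undefined` flag set when
#'   the denominator vanishes (score reported as +Inf).
#' @export
knowledge_score <- function(modules, tf_targets, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(modules, "module_assignment"), is.list(tf_targets))
  annotated <- unique(unlist(tf_targets, use.names = FALSE))
  keep <- modules$labels != -1L & modules$gene_ids %in% annotated
  genes <- modules$gene_ids[keep]
  labels <- modules$labels[keep]
  ng <- length(genes)
  if (ng < 2L) stop("fewer than 2 TF-annotated genes in assigned modules")

  ## gene x TF incidence; pairs sharing >= 1 TF have a positive inner product
  inc <- vapply(tf_targets, function(t) genes %in% t, logical(ng))
  inc <- matrix(as.numeric(inc), nrow = ng)
  share <- tcrossprod(inc) > 0

  same_module <- outer(labels, labels, "==")
  up <- upper.tri(share)
  kp <- share[up]
  cp <- same_module[up]
  counts <- c(cp_kp = sum(cp & kp), notcp_kp = sum(!cp & kp),
              cp_notkp = sum(cp & !kp), notcp_notkp = sum(!cp & !kp))
  denom <- counts["notcp_kp"] * counts["cp_notkp"]
  undefined <- denom == 0
  score <- if (undefined) Inf else
    unname((counts["cp_kp"] * counts["notcp_notkp"]) / denom)
  p <- if (alternative == "greater") {
    hypergeom_tail_p(counts["cp_kp"], counts["notcp_kp"],
                     counts["cp_notkp"], counts["notcp_notkp"])
  } else {
    stats::fisher.test(matrix(counts[c("cp_kp", "notcp_kp",
                                       "cp_notkp", "notcp_notkp")], 2L),
                       alternative = "two.sided")$p.value
  }
  structure(list(counts = counts, score = score, p_value = p,
                 n_tf_annotated_genes = ng, undefined = undefined,
                 alternative = alternative),
            class = "knowledge_score")
}

#' @export
print.knowledge_score <- function(x, ...) {
  cat(sprintf("knowledge_score: %.4f (p = %.3g, %d annotated genes)\n",
              x$score, x$p_value, x$n_tf_annotated_genes))
  invisible(x)
}

#' Module signature score
#'
#' Raw score: per-sample mean of gene-wise z-scored log2(x+1) expression
#' over the module genes. When a core gene set is supplied the normalized
#' score is the raw module score minus the raw core score ("proportion of a
#' subprocess within its process"); a ratio of linear-space means is
#' available as `mode = "ratio"`.
#'
#' @param expr an [expr_matrix()].
#' @param genes module gene IDs (non-empty, present in `expr`).
#' @param core_genes optional core gene IDs for normalization.
#' @param mode `"difference"` (default) or `"ratio"` for the normalized
#'   score.
#' @return object of class `module_score`: data.frame with `sample_id`,
#'   `raw` and (when core given) `normalized` columns, plus attributes.
#' @export
score_module <- function(expr, genes, core_genes = NULL,
                         mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty module gene set")
  if (!all(genes %in% gene_ids(expr)))
    stop("module genes absent from expression matrix")
  zmean <- function(gs) {
    x <- as_log_expr(expr)$values[gs, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    z <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
    colMeans(z)
  }
  raw <- zmean(genes)
  out <- data.frame(sample_id = sample_ids(expr), raw = unname(raw),
                    stringsAsFactors = FALSE)
  if (!is.null(core_genes)) {
    core_genes <- as.character(core_genes)
    if (!all(core_genes %in% gene_ids(expr)))
      stop("core genes absent from expression matrix")
    if (mode == "difference") {
      out$normalized <- out$raw - unname(zmean(core_genes))
    } else {
      lin <- expr$values
      num <- colMeans(lin[genes, , drop = FALSE])
      den <- colMeans(lin[core_genes, , drop = FALSE])
      out$normalized <- num / (den + 1e-9)
    }
  }
  structure(out, class = c("module_score", "data.frame"),
            mode = if (is.null(core_genes)) "raw" else mode)
}

#' Median split of module scores
#'
#' Samples strictly above the median are "high"; ties go to "low".
#'
#' @param scores a `module_score` (the `normalized` column is used when
#'   present, else `raw`) or a plain numeric vector.
#' @return character vector of "high"/"low" labels.
#' @export
dichotomize_scores <- function(scores) {
  x <- if (inherits(scores, "module_score")) {
    if (!is.null(scores$normalized)) scores$normalized else scores$raw
  } else as.numeric(scores)
  if (length(x) < 2L) stop("need at least 2 samples")
  ifelse(x > median(x), "high", "low")
}
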
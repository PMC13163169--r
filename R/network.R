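#' Coefficient-of-determination adjacency
#'
#' Adjacency a_ij = corr(gene_i, gene_j)^2, i.e. the pairwise correlation
#' raised to a fixed soft-threshold power beta = 2. Squaring yields the
#' coefficient of determination: a_ij is the fraction of variance of one
#' gene explained by the other, an intuitively scaled weight in [0, 1] that
#' needs no scale-free tuning. Note that correlated and anti-correlated
#' pairs receive the same adjacency.
#'
#' Correlations are computed on the matrix as stored; pass log-space data
#' (the pipeline uses log2(TPM+1)) for variance-stabilized estimates.
#'
#' @param expr an [expr_matrix()] with >= 3 samples and no zero-variance
#'   genes (guaranteed after [filter_genes()]).
#' @param corr_method `"pearson"` (default) or `"spearman"`.
#' @return object of class `adjacency_matrix`: list with `values` (symmetric
#'   matrix, unit diagonal), `beta = 2`, `corr_method`.
#' @export
compute_adjacency <- function(expr, corr_method = c("pearson", "spearman")) {
  corr_method <- match.arg(corr_method)
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  if (ncol(v) < 3L) stop("need at least 3 samples to estimate correlations")
  vars <- apply(v, 1L, var)
  if (any(vars == 0))
    stop("zero-variance gene(s) present: ",
         paste(head(rownames(v)[vars == 0], 5L), collapse = ", "))
  a <- cor(t(v), method = corr_method)^2
  a[a > 1] <- 1
  a[a < 0] <- 0
  diag(a) <- 1
  a <- (a + t(a)) / 2
  structure(list(values = a, gene_ids = rownames(v), beta = 2L,
                 corr_method = corr_method),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("adjacency_matrix: %d genes, beta = %d, %s correlation\n",
              length(x$gene_ids), x$beta, x$corr_method))
  invisible(x)
}

#' Dissimilarity d = 1 - a
#'
#' Entrywise complement of the adjacency. Combined with the coefficient of
#' determination this gives zero self-distance exactly (a duplicated gene is
#' at distance 0 from its copy), symmetry and non-negativity; these are the
#' only metric-like properties the pipeline relies on.
#'
#' @param adj an `adjacency_matrix` from [compute_adjacency()].
#' @return object of class `dissimilarity_matrix` with `values` in [0, 1]
#'   and zero diagonal.
#' @export
compute_dissimilarity <- function(adj) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  d <- 1 - adj$values
  diag(d) <- 0
  structure(list(values = d, gene_ids = adj$gene_ids),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix: %d genes\n", length(x$gene_ids)))
  invisible(x)
}

#' Export a network matrix as TSV
#'
#' @param x an `adjacency_matrix` or `dissimilarity_matrix`.
#' @param path output TSV (first column `gene_id`).
#' @export
write_network_tsv <- function(x, path) {
  dt <- data.table::data.table(gene_id = x$gene_ids)
  m <- x$values
  for (j in seq_along(x$gene_ids)) dt[[x$gene_ids[j]]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
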
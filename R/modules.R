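#' Derive embedding and clustering parameters
#'
#' Heuristics tying the clustering knobs to a single intuitive choice, the
#' minimum cluster size: the embedding dimensionality follows the sample
#' count as `round(log2(N) + 1)` (intrinsic dimensionality grows with
#' dataset size; floor 2), `n_neighbors = 2 * min_cluster_size` keeps
#' clusters well connected, and `min_samples = floor(min_cluster_size / 2)`
#' (floor 1) fixes the density estimate.
#'
#' @param n_samples number of RNA-Seq samples N (>= 4).
#' @param min_cluster_size minimum module size (>= 2).
#' @param seed integer seed recorded alongside the parameters.
#' @return object of class `clustering_params`.
#' @export
derive_params <- function(n_samples, min_cluster_size, seed = 0L) {
  if (n_samples < 4L) stop("need at least 4 samples")
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  structure(list(
    min_cluster_size = as.integer(min_cluster_size),
    n_components = max(2L, as.integer(round(log2(n_samples) + 1))),
    n_neighbors = 2L * as.integer(min_cluster_size),
    min_samples = max(1L, as.integer(min_cluster_size) %/% 2L),
    random_seed = as.integer(seed)
  ), class = "clustering_params")
}

#' @export
print.clustering_params <- function(x, ...) {
  cat(sprintf(
    "clustering_params: min_cluster_size %d, n_components %d, n_neighbors %d, min_samples %d, seed %d\n",
    x$min_cluster_size, x$n_components, x$n_neighbors, x$min_samples, x$random_seed))
  invisible(x)
}

#' Embed a dissimilarity matrix
#'
#' UMAP embedding of the genes, treating the dissimilarity entries as
#' precomputed pairwise distances.
#'
#' @param dissim a `dissimilarity_matrix` from [compute_dissimilarity()].
#' @param params a `clustering_params` from [derive_params()].
#' @return genes x n_components matrix with gene IDs as rownames.
#' @export
embed_dissimilarity <- function(dissim, params) {
  stopifnot(inherits(dissim, "dissimilarity_matrix"),
            inherits(params, "clustering_params"))
  D <- dissim$values
  rownames(D) <- colnames(D) <- dissim$gene_ids
  umap_embed(D, n_components = params$n_components,
             n_neighbors = params$n_neighbors, seed = params$random_seed)
}

#' Module assignment container
#'
#' @param gene_ids_vec character vector of gene IDs.
#' @param labels integer labels per gene; -1 marks unassigned (noise) genes,
#'   assigned modules are numbered 0..K-1.
#' @param level `"CGM"` or `"FGM"`.
#' @param parent_module for FGM assignments, the parent CGM identifier.
#' @param params optional `clustering_params` used to produce the labels.
#' @return object of class `module_assignment`.
#' @export
module_assignment <- function(gene_ids_vec, labels, level = c("CGM", "FGM"),
                              parent_module = NULL, params = NULL) {
  level <- match.arg(level)
  stopifnot(length(gene_ids_vec) == length(labels))
  structure(list(gene_ids = as.character(gene_ids_vec),
                 labels = as.integer(labels),
                 level = level, parent_module = parent_module,
                 params = params),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  k <- length(unique(x$labels[x$labels >= 0L]))
  cat(sprintf("module_assignment [%s]: %d genes, %d modules, %d unassigned\n",
              x$level, length(x$gene_ids), k, sum(x$labels == -1L)))
  invisible(x)
}

#' Genes of one module
#'
#' @param assignment a `module_assignment`.
#' @param label module label.
#' @return character vector of gene IDs.
#' @export
module_genes <- function(assignment, label) {
  assignment$gene_ids[assignment$labels == as.integer(label)]
}

#' Module labels present in an assignment
#' @param assignment a `module_assignment`.
#' @export
module_labels <- function(assignment) {
  sort(unique(assignment$labels[assignment$labels >= 0L]))
}

#' Cluster an embedding into modules
#'
#' HDBSCAN with Euclidean distances on the embedding, using the minimum
#' cluster size and `min_samples` from `params`. If no cluster is found a
#' warning is raised and every gene is labeled noise.
#'
#' @param embedding genes x dims matrix from [embed_dissimilarity()].
#' @param params a `clustering_params`.
#' @param level assignment level recorded in the output.
#' @return a [module_assignment()].
#' @export
cluster_embedding <- function(embedding, params, level = "CGM") {
  stopifnot(inherits(params, "clustering_params"))
  labels <- hdbscan_cluster(embedding, min_cluster_size = params$min_cluster_size,
                            min_samples = params$min_samples)
  module_assignment(rownames(embedding), labels, level = level, params = params)
}

#' Detect coarse-grained modules
#'
#' First-round network inference: squared-correlation adjacency on
#' log2(x+1)-transformed expression, 1 - a dissimilarity, UMAP embedding,
#' HDBSCAN clustering. Deterministic for a fixed seed.
#'
#' @param expr an [expr_matrix()]; linear-space data are log2(x+1)
#'   transformed before correlation.
#' @param min_cluster_size minimum module size (default 50).
#' @param seed integer seed.
#' @param corr_method correlation estimator, see [compute_adjacency()].
#' @return a [module_assignment()] at CGM level.
#' @export
detect_cgms <- function(expr, min_cluster_size = 50L, seed = 0L,
                        corr_method = "pearson") {
  expr <- as_log_expr(expr)
  params <- derive_params(n_samples(expr), min_cluster_size, seed)
  adj <- compute_adjacency(expr, corr_method = corr_method)
  dis <- compute_dissimilarity(adj)
  emb <- embed_dissimilarity(dis, params)
  cluster_embedding(emb, params, level = "CGM")
}
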
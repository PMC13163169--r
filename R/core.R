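#' Weighted k-core decomposition
#'
#' Generalized core decomposition of a weighted undirected graph. The k-core
#' of a weighted graph is the maximal induced subgraph in which every node's
#' sum of incident edge weights (its weighted degree) is at least k; the
#' core number c(u) is the largest k whose k-core contains u, and the graph
#' degeneracy is the largest core number. Computed by iteratively removing
#' the node with minimum current weighted degree and recording the running
#' maximum of that minimum (the standard generalized-cores peeling).
#'
#' Ties in the minimum weighted degree are broken by lexicographic node ID
#' so the removal order, and therefore the output, is deterministic.
#'
#' @param weights symmetric non-negative numeric matrix of edge weights with
#'   node IDs as dimnames; the diagonal is ignored (no self-loops). A zero
#'   weight means no edge.
#' @return object of class `core_decomposition`: list with `core_number`
#'   (named numeric), `degeneracy`, `max_core_nodes` (IDs whose core number
#'   reaches the degeneracy within tolerance 1e-9) and `removal_order`.
#' @export
weighted_core_numbers <- function(weights) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix")
  n <- nrow(weights)
  if (n == 0L) stop("graph must have at least one node")
  if (ncol(weights) != n) stop("`weights` must be square")
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <- sprintf("n%03d", seq_len(n))
  }
  ids <- rownames(weights)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("edge weights must be finite")
  if (any(weights < 0)) stop("negative edge weights are not allowed")
  if (max(abs(weights - t(weights))) > 1e-12) stop("`weights` must be symmetric")
  w <- weights
  diag(w) <- 0

  ## order nodes lexicographically once; peeling then resolves ties by index
  ord0 <- order(ids)
  w <- w[ord0, ord0, drop = FALSE]
  ids_sorted <- ids[ord0]

  alive <- rep(TRUE, n)
  deg <- rowSums(w)
  core <- numeric(n)
  removal <- character(0)
  running_max <- 0
  for (step in seq_len(n)) {
    cand <- which(alive)
    u <- cand[which.min(deg[cand])]   # which.min takes first = lexicographic tie-break
    running_max <- max(running_max, deg[u])
    core[u] <- running_max
    alive[u] <- FALSE
    removal <- c(removal, ids_sorted[u])
    if (any(alive)) deg[alive] <- deg[alive] - w[alive, u]
  }
  core_number <- setNames(core, ids_sorted)[ids]
  degeneracy <- max(core_number)
  structure(list(
    core_number = core_number,
    degeneracy = degeneracy,
    max_core_nodes = names(core_number)[core_number >= degeneracy - 1e-9],
    removal_order = removal
  ), class = "core_decomposition")
}

#' @export
print.core_decomposition <- function(x, ...) {
  cat(sprintf("core_decomposition: %d nodes, degeneracy %.4f, max core %d nodes\n",
              length(x$core_number), x$degeneracy, length(x$max_core_nodes)))
  invisible(x)
}

#' Extract the core of a module
#'
#' Builds the complete weighted graph on a module's genes with the adjacency
#' values a_ij as edge weights and returns the maximum weighted k-core: the
#' densest, most mutually correlated gene subset, taken as the module core.
#'
#' @param module_genes character vector of gene IDs (>= 2), a subset of the
#'   adjacency's genes.
#' @param adj an `adjacency_matrix` from [compute_adjacency()].
#' @return character vector of core gene IDs.
#' @export
extract_core <- function(module_genes, adj) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  module_genes <- as.character(module_genes)
  missing <- setdiff(module_genes, adj$gene_ids)
  if (length(missing) > 0)
    stop("module genes absent from adjacency: ",
         paste(head(missing, 5L), collapse = ", "))
  if (length(module_genes) < 2L)
    stop("a module must have at least 2 genes to extract a core")
  idx <- match(module_genes, adj$gene_ids)
  w <- adj$values[idx, idx, drop = FALSE]
  dimnames(w) <- list(module_genes, module_genes)
  diag(w) <- 0
  weighted_core_numbers(w)$max_core_nodes
}
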
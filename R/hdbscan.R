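## HDBSCAN (hierarchical density-based clustering) on a Euclidean embedding.
##
## Implemented from the standard algorithm: per-point core distances, the
## mutual-reachability graph, its minimum spanning tree (Prim), the single-
## linkage merge tree over sorted MST edges, condensation of the hierarchy
## at `min_cluster_size`, and excess-of-mass cluster selection on the
## condensed-tree stabilities. Points outside every selected cluster get the
## noise label -1. The computation is exact and deterministic.

## kth nearest neighbour distance, counting the point itself as neighbour 0.
core_distances <- function(D, min_samples) {
  n <- nrow(D)
  k <- max(1L, as.integer(min_samples))
  if (k == 1L) return(numeric(n))
  apply(D, 1L, function(d) sort(d, partial = k)[k])
}

## Prim's MST on the dense mutual-reachability matrix. O(n^2).
mst_prim <- function(M) {
  n <- nrow(M)
  in_tree <- rep(FALSE, n)
  best_w <- rep(Inf, n)
  best_from <- rep(NA_integer_, n)
  edges <- matrix(0, n - 1L, 3L)   # from, to, weight
  cur <- 1L
  in_tree[1L] <- TRUE
  for (t in seq_len(n - 1L)) {
    w <- M[cur, ]
    upd <- !in_tree & w < best_w
    best_w[upd] <- w[upd]
    best_from[upd] <- cur
    cand <- which(!in_tree)
    nxt <- cand[which.min(best_w[cand])]
    edges[t, ] <- c(best_from[nxt], nxt, best_w[nxt])
    in_tree[nxt] <- TRUE
    cur <- nxt
  }
  edges[order(edges[, 3L], edges[, 1L], edges[, 2L]), , drop = FALSE]
}

## Single-linkage merge tree from MST edges sorted by weight.
## Node ids: points 1..n, internal nodes n+1..2n-1.
## Returns per-merge left/right child ids, merge distance, subtree size.
single_linkage_tree <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nm <- n - 1L
  left <- integer(nm); right <- integer(nm); dist <- numeric(nm); size <- integer(nm)
  sizes <- c(rep(1L, n), integer(nm))
  for (t in seq_len(nm)) {
    ra <- find(edges[t, 1L]); rb <- find(edges[t, 2L])
    node <- n + t
    left[t] <- ra; right[t] <- rb
    dist[t] <- edges[t, 3L]
    size[t] <- sizes[ra] + sizes[rb]
    sizes[node] <- size[t]
    parent[ra] <- node; parent[rb] <- node
  }
  list(left = left, right = right, dist = dist, size = size, n = n)
}

## leaves under a node of the single-linkage tree
sl_leaves <- function(tree, node) {
  n <- tree$n
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x <= n) out <- c(out, x)
    else {
      t <- x - n
      stack <- c(stack, tree$left[t], tree$right[t])
    }
  }
  out
}

## Condense the single-linkage tree at min_cluster_size.
## Rows: parent condensed cluster, child (condensed cluster id or -point),
## lambda = 1/distance at which the child separates, child size.
condense_tree <- function(tree, min_cluster_size) {
  n <- tree$n
  root <- 2L * n - 1L
  node_size <- function(x) if (x <= n) 1L else tree$size[x - n]
  lambda_of <- function(d) if (d > 0) 1 / d else Inf

  res_parent <- integer(0); res_child <- integer(0)
  res_lambda <- numeric(0); res_size <- integer(0)
  add_row <- function(p, ch, lam, sz) {
    res_parent[length(res_parent) + 1L] <<- p
    res_child[length(res_child) + 1L] <<- ch
    res_lambda[length(res_lambda) + 1L] <<- lam
    res_size[length(res_size) + 1L] <<- sz
  }

  relabel <- integer(root)
  next_label <- 1L
  relabel[root] <- next_label
  ignore <- logical(root)

  ## process internal nodes from root downward (decreasing id = BFS-compatible
  ## order since children always have smaller ids than parents)
  for (node in rev(seq.int(n + 1L, root))) {
    if (ignore[node]) next
    t <- node - n
    l <- tree$left[t]; r <- tree$right[t]
    lam <- lambda_of(tree$dist[t])
    sl <- node_size(l); sr <- node_size(r)
    l_big <- sl >= min_cluster_size
    r_big <- sr >= min_cluster_size
    drop_points <- function(sub) {
      for (p in sl_leaves(tree, sub)) add_row(relabel[node], -p, lam, 1L)
      if (sub > n) {
        for (x in sl_leaves_internal(tree, sub)) ignore[x] <<- TRUE
      }
      ignore[sub] <<- TRUE
    }
    if (l_big && r_big) {
      next_label <- next_label + 1L; relabel[l] <- next_label
      add_row(relabel[node], relabel[l], lam, sl)
      next_label <- next_label + 1L; relabel[r] <- next_label
      add_row(relabel[node], relabel[r], lam, sr)
    } else if (!l_big && !r_big) {
      drop_points(l)
      drop_points(r)
    } else if (l_big) {
      relabel[l] <- relabel[node]
      drop_points(r)
    } else {
      relabel[r] <- relabel[node]
      drop_points(l)
    }
  }
  list(parent = res_parent, child = res_child, lambda = res_lambda,
       size = res_size, n_clusters = next_label)
}

## internal nodes under a node (for the ignore bookkeeping)
sl_leaves_internal <- function(tree, node) {
  n <- tree$n
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x > n) {
      out <- c(out, x)
      t <- x - n
      stack <- c(stack, tree$left[t], tree$right[t])
    }
  }
  out
}

## Stability of each condensed cluster: sum over child rows of
## (lambda_child - lambda_birth) * size, birth = lambda at which the cluster
## itself appeared as a child (0 for the root).
condensed_stability <- function(ct) {
  births <- numeric(ct$n_clusters)
  is_cl <- ct$child > 0
  births[ct$child[is_cl]] <- ct$lambda[is_cl]
  lam <- pmin(ct$lambda, 1e12)   # cap infinite lambdas from zero distances
  stab <- numeric(ct$n_clusters)
  contrib <- (lam - births[ct$parent]) * ct$size
  for (i in seq_along(ct$parent))
    stab[ct$parent[i]] <- stab[ct$parent[i]] + contrib[i]
  stab
}

## Excess-of-mass selection over the condensed tree.
eom_select <- function(ct, allow_single_cluster = FALSE) {
  k <- ct$n_clusters
  stab <- condensed_stability(ct)
  children <- vector("list", k)
  parent_of <- integer(k)
  for (i in seq_along(ct$parent)) {
    if (ct$child[i] > 0) {
      children[[ct$parent[i]]] <- c(children[[ct$parent[i]]], ct$child[i])
      parent_of[ct$child[i]] <- ct$parent[i]
    }
  }
  selected <- logical(k)
  start <- if (allow_single_cluster) 1L else 2L
  for (c_id in rev(seq_len(k))) {
    if (c_id < start) break
    ch <- children[[c_id]]
    sub <- if (length(ch) > 0) sum(stab[ch]) else 0
    if (length(ch) > 0 && sub > stab[c_id]) {
      stab[c_id] <- sub
      selected[c_id] <- FALSE
    } else {
      selected[c_id] <- TRUE
    }
  }
  ## a selected ancestor absorbs its descendants
  for (c_id in seq_len(k)) {
    if (!selected[c_id]) next
    p <- parent_of[c_id]
    while (p >= 1L && p != 0L) {
      if (selected[p]) { selected[c_id] <- FALSE; break }
      p <- parent_of[p]
    }
  }
  list(selected = which(selected), stability = stab, parent_of = parent_of)
}

#' HDBSCAN clustering of points in Euclidean space
#'
#' @param X numeric matrix (points x dimensions).
#' @param min_cluster_size smallest group of points accepted as a cluster.
#' @param min_samples neighbourhood size for the core-distance density
#'   estimate (the point itself counts); defaults to `min_cluster_size %/% 2`
#'   with a floor of 1.
#' @param allow_single_cluster permit the hierarchy root to be returned as a
#'   single cluster (off by default, as in the reference implementation).
#' @return integer vector of cluster labels per point, 0-based and ordered
#'   by decreasing cluster size; noise points get -1. If no cluster meets
#'   the selection criteria a warning is raised and all points are noise.
#' @export
hdbscan_cluster <- function(X, min_cluster_size, min_samples = NULL,
                            allow_single_cluster = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(min_samples)) min_samples <- max(1L, min_cluster_size %/% 2L)
  if (n < 2L * min_cluster_size)
    stop("need at least 2 * min_cluster_size = ", 2L * min_cluster_size,
         " points, got ", n)
  D <- as.matrix(stats::dist(X))
  core <- core_distances(D, min_samples)
  M <- pmax(D, outer(core, core, pmax))
  diag(M) <- 0
  edges <- mst_prim(M)
  tree <- single_linkage_tree(edges, n)
  ct <- condense_tree(tree, min_cluster_size)
  labels <- rep(-1L, n)
  if (ct$n_clusters >= 1L) {
    sel <- eom_select(ct, allow_single_cluster)
    if (length(sel$selected) > 0) {
      ## a point belongs to a selected cluster iff it fell out of that
      ## cluster or one of its condensed descendants; points lost above the
      ## selected level are noise
      for (c_id in sel$selected) {
        members <- condensed_members(ct, c_id)
        labels[members] <- c_id
      }
      labels <- relabel_by_size(labels)
    }
  }
  if (all(labels == -1L))
    warning("no cluster satisfied the density criteria; all points labeled noise")
  labels
}

## all points (leaves) recorded under a condensed cluster, descendants included
condensed_members <- function(ct, cluster) {
  out <- integer(0)
  stack <- cluster
  while (length(stack) > 0) {
    c_id <- stack[length(stack)]
    stack <- stack[-length(stack)]
    rows <- which(ct$parent == c_id)
    pts <- -ct$child[rows][ct$child[rows] < 0]
    out <- c(out, pts)
    stack <- c(stack, ct$child[rows][ct$child[rows] > 0])
  }
  out
}

## map arbitrary positive labels to 0..K-1 by decreasing size (ties: first
## occurrence); -1 stays -1
relabel_by_size <- function(labels) {
  pos <- labels[labels != -1L]
  if (length(pos) == 0L) return(labels)
  tab <- sort(table(pos), decreasing = TRUE)
  map <- setNames(seq_along(tab) - 1L, names(tab))
  out <- labels
  out[labels != -1L] <- map[as.character(pos)]
  as.integer(out)
}
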
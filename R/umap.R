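## UMAP on a precomputed distance matrix.
##
## A self-contained implementation of the reference UMAP algorithm restricted
## to what the pipeline needs: dense precomputed pairwise distances in, a
## deterministic low-dimensional Euclidean embedding out. The stages are the
## standard ones: exact k-nearest neighbours, per-point smooth-kNN bandwidth
## calibration (binary search for sigma_i so the local weights sum to
## log2(k), with rho_i the distance to the nearest neighbour), fuzzy-union
## symmetrization, classical-MDS initialization, and stochastic gradient
## optimization of the cross-entropy layout (compiled kernel, own RNG).

#' Fitted output-space curve parameters
#'
#' Least-squares fit of 1 / (1 + a * x^(2b)) to the piecewise target curve
#' defined by `min_dist` and `spread`, as in the reference implementation.
#' @keywords internal
find_ab_params <- function(spread = 1, min_dist = 0.1) {
  xv <- seq(0, spread * 3, length.out = 300)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  obj <- function(p) {
    f <- 1 / (1 + p[1] * xv^(2 * p[2]))
    sum((f - yv)^2)
  }
  fit <- optim(c(1.6, 0.9), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  list(a = fit$par[1], b = fit$par[2])
}

## k nearest neighbours (excluding self) from a dense distance matrix.
knn_from_dist <- function(D, k) {
  n <- nrow(D)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    o <- order(d)[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[o]
  }
  list(idx = idx, dist = dst)
}

## Per-point bandwidths: rho = nearest nonzero neighbour distance, sigma by
## 64-step binary search so sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k).
smooth_knn <- function(knn_dist, n_iter = 64L, tol = 1e-5) {
  n <- nrow(knn_dist)
  k <- ncol(knn_dist)
  target <- log2(k)
  rho <- numeric(n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- knn_dist[i, ]
    nz <- di[di > 0]
    rho[i] <- if (length(nz) > 0) min(nz) else 0
    lo <- 0; hi <- Inf; mid <- 1
    for (iter in seq_len(n_iter)) {
      ps <- sum(exp(-pmax(di - rho[i], 0) / mid))
      if (abs(ps - target) < tol) break
      if (ps > target) {
        hi <- mid; mid <- (lo + hi) / 2
      } else {
        lo <- mid
        mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
      }
    }
    mean_d <- mean(di)
    sigma[i] <- max(mid, if (rho[i] > 0) 1e-3 * mean_d else 1e-3 * max(mean_d, 1e-12))
  }
  list(rho = rho, sigma = sigma)
}

## Directed membership strengths -> fuzzy set union (w1 + w2 - w1*w2).
fuzzy_graph <- function(knn, bw) {
  n <- nrow(knn$idx)
  k <- ncol(knn$idx)
  i_ind <- rep(seq_len(n), each = k)
  j_ind <- as.integer(t(knn$idx))
  d <- as.numeric(t(knn$dist))
  w <- exp(-pmax(d - bw$rho[i_ind], 0) / bw$sigma[i_ind])
  key_ij <- (i_ind - 1) * n + (j_ind - 1)
  key_ji <- (j_ind - 1) * n + (i_ind - 1)
  rev_pos <- match(key_ij, key_ji)          # position of the transposed entry
  w_rev <- ifelse(is.na(rev_pos), 0, w[rev_pos])
  w_union <- w + w_rev - w * w_rev
  keep_first <- is.na(rev_pos) | key_ij <= key_ji  # one record per unordered pair
  list(i = i_ind[keep_first], j = j_ind[keep_first], w = w_union[keep_first])
}

#' UMAP embedding of a precomputed distance matrix
#'
#' @param D symmetric matrix of pairwise distances (dissimilarities).
#' @param n_components output dimensionality.
#' @param n_neighbors local neighbourhood size; must be < nrow(D).
#' @param seed integer seed; the embedding is fully deterministic given the
#'   seed (single-threaded optimizer with its own RNG).
#' @param n_epochs optimization epochs.
#' @param min_dist,spread output-space packing parameters (reference defaults).
#' @param init `"mds"` (classical MDS of D, deterministic) or `"random"`.
#' @return numeric matrix (points x n_components), rownames taken from `D`.
#' @export
umap_embed <- function(D, n_components, n_neighbors, seed = 0L,
                       n_epochs = 300L, min_dist = 0.1, spread = 1,
                       init = c("mds", "random")) {
  init <- match.arg(init)
  if (!is.matrix(D)) stop("`D` must be a matrix")
  n <- nrow(D)
  if (n_neighbors >= n)
    stop("number of points (", n, ") must exceed n_neighbors (", n_neighbors,
         "); use a smaller min_cluster_size")
  if (n_components < 1L) stop("n_components must be >= 1")

  knn <- knn_from_dist(D, n_neighbors)
  bw <- smooth_knn(knn$dist)
  g <- fuzzy_graph(knn, bw)

  ## edge sampling schedule: stronger edges are updated more often
  keep <- g$w >= max(g$w) / n_epochs
  head_i <- g$i[keep] - 1L
  tail_i <- g$j[keep] - 1L
  eps <- max(g$w) / g$w[keep]

  emb0 <- withr::with_seed(as.integer(seed) + 1L, {
    if (init == "mds") {
      cm <- suppressWarnings(stats::cmdscale(D, k = n_components))
      if (ncol(cm) < n_components)
        cm <- cbind(cm, matrix(rnorm(n * (n_components - ncol(cm)), sd = 1e-4),
                               n, n_components - ncol(cm)))
      scale_f <- max(abs(cm))
      if (scale_f == 0) scale_f <- 1
      cm <- cm / scale_f * 10
      cm + matrix(rnorm(n * n_components, sd = 1e-4), n, n_components)
    } else {
      matrix(runif(n * n_components, -10, 10), n, n_components)
    }
  })

  ab <- if (abs(min_dist - 0.1) < 1e-12 && abs(spread - 1) < 1e-12) {
    list(a = 1.57694346088252, b = 0.895060878123132)
  } else find_ab_params(spread, min_dist)

  emb <- umap_optimize_layout(emb0, head_i, tail_i, eps, ab$a, ab$b,
                              as.integer(n_epochs), 1.0, 5L,
                              as.double(abs(as.integer(seed)) %% 2^31))
  rownames(emb) <- rownames(D)
  emb
}
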
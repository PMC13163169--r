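#' Synthetic expression specification
#'
#' Parameters of the planted-structure generator. Each coarse module (CGM)
#' is driven by its own standard-normal latent factor F_c; a subset of its
#' genes ("core") loads strongly on F_c, the remaining ("periphery") genes
#' load more weakly, and disjoint blocks of periphery genes additionally
#' load on nested sub-factors S_cj that are independent of F_c. Housekeeping
#' genes load weakly on every F_c; noise genes carry noise only. Per-gene
#' loadings can be jittered uniformly around the stated values to emulate
#' the core-periphery loading continuum of real modules.
#'
#' Gene g of CGM c has log2-expression
#' `lambda_g * F_c + lambda_sub * S_cj + eps`, `eps ~ N(0, noise_sd^2)`,
#' plus a per-gene baseline; linear expression is 2^(log-expression), so
#' two genes sharing only F_c have log-domain correlation
#' `lambda^2 / (lambda^2 + noise_sd^2)` at equal loadings — the closed form
#' used to calibrate the generator.
#'
#' @param n_samples,n_cgms,genes_per_cgm,core_fraction,n_subfactors_per_cgm,genes_per_subfactor
#'   structure counts; sub-factor blocks are placed on periphery genes, so
#'   `n_subfactors_per_cgm * genes_per_subfactor` must not exceed the
#'   periphery size.
#' @param core_loading,periphery_loading,subfactor_loading factor loadings
#'   in (0, 1].
#' @param core_loading_jitter,periphery_loading_jitter half-width of the
#'   uniform jitter applied per gene around the respective loading.
#' @param n_housekeeping,hk_loading broadly connected genes loading
#'   `hk_loading` on every CGM factor.
#' @param n_noise_genes,noise_sd unstructured genes and the shared noise SD
#'   (log2 units).
#' @param subfactor_core_corr correlation between each sub-factor and its
#'   CGM factor (0 = independent; available for robustness experiments).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 150L, n_cgms = 4L, genes_per_cgm = 300L,
                           core_fraction = 0.4, n_subfactors_per_cgm = 3L,
                           genes_per_subfactor = 40L, core_loading = 0.9,
                           periphery_loading = 0.6, subfactor_loading = 0.6,
                           core_loading_jitter = 0, periphery_loading_jitter = 0,
                           n_housekeeping = 50L, hk_loading = 0.3,
                           n_noise_genes = 500L, noise_sd = 1,
                           subfactor_core_corr = 0, seed = 0L) {
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  for (nm in c("n_samples", "n_cgms", "genes_per_cgm", "n_subfactors_per_cgm",
               "genes_per_subfactor", "n_housekeeping", "n_noise_genes", "seed"))
    spec[[nm]] <- as.integer(spec[[nm]])
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_samples < 4L) stop("n_samples must be >= 4")
    if (n_cgms < 0L || n_noise_genes < 0L || n_housekeeping < 0L)
      stop("counts must be non-negative")
    if (n_cgms == 0L && n_noise_genes == 0L && n_housekeeping == 0L)
      stop("the dataset would contain no genes")
    if (n_cgms > 0L && genes_per_cgm < 1L) stop("genes_per_cgm must be positive")
    for (nm in c("core_loading", "periphery_loading", "subfactor_loading",
                 "hk_loading")) {
      v <- get(nm)
      if (v < 0 || v > 1) stop(nm, " must be in [0, 1]")
    }
    if (core_loading + core_loading_jitter > 1 + 1e-12 ||
        periphery_loading + periphery_loading_jitter > 1 + 1e-12)
      stop("loading + jitter must stay within (0, 1]")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (abs(subfactor_core_corr) > 1) stop("subfactor_core_corr must be in [-1, 1]")
    if (n_cgms > 0L) {
      n_core <- round(core_fraction * genes_per_cgm)
      if (n_subfactors_per_cgm * genes_per_subfactor > genes_per_cgm - n_core)
        stop("sub-factor blocks (", n_subfactors_per_cgm * genes_per_subfactor,
             " genes) do not fit into the periphery (",
             genes_per_cgm - n_core, " genes)")
    }
  })
  invisible(spec)
}

#' Named scenario presets
#'
#' Fixed parameterizations used throughout the test and acceptance suites:
#'
#' * `default` — 4 CGMs x 300 genes (150 samples), core loading 0.9,
#'   periphery 0.6, three 40-gene sub-factor blocks per CGM (loading 0.6),
#'   50 housekeeping and 500 noise genes, noise SD 1.
#' * `nested` — a single 300-gene CGM carrying three 40-gene sub-factor
#'   blocks under a dominant shared factor, with a heterogeneous
#'   core-periphery loading continuum (core 0.85-1.0, periphery 0.7-0.95,
#'   sub-factor loading 0.4, noise SD 0.35). The shared factor dominates
#'   every gene's correlation with the module eigengene before
#'   normalization; after core normalization the sub-factor blocks are the
#'   only coherent structure left.
#' * `core_periphery` — a single 200-gene module, half at loading 0.9 and
#'   half at 0.5, for core-extraction checks.
#' * `noise_only` — 1000 unstructured genes.
#' * `null_cgm` — the `nested` module without its sub-factors.
#'
#' @param name preset name.
#' @param seed seed stored in the returned spec.
#' @return a [synthetic_spec()].
#' @export
scenario <- function(name = c("default", "nested", "core_periphery",
                              "noise_only", "null_cgm"), seed = 0L) {
  name <- match.arg(name)
  switch(name,
    default = synthetic_spec(seed = seed),
    nested = synthetic_spec(
      n_samples = 150L, n_cgms = 1L, genes_per_cgm = 300L, core_fraction = 0.4,
      n_subfactors_per_cgm = 3L, genes_per_subfactor = 40L,
      core_loading = 0.925, core_loading_jitter = 0.075,
      periphery_loading = 0.825, periphery_loading_jitter = 0.125,
      subfactor_loading = 0.4, n_housekeeping = 0L, n_noise_genes = 0L,
      noise_sd = 0.35, seed = seed),
    core_periphery = synthetic_spec(
      n_samples = 150L, n_cgms = 1L, genes_per_cgm = 200L, core_fraction = 0.5,
      n_subfactors_per_cgm = 0L, genes_per_subfactor = 0L,
      core_loading = 0.9, periphery_loading = 0.5,
      n_housekeeping = 0L, n_noise_genes = 0L, noise_sd = 1, seed = seed),
    noise_only = synthetic_spec(
      n_samples = 150L, n_cgms = 0L, genes_per_cgm = 0L,
      n_subfactors_per_cgm = 0L, genes_per_subfactor = 0L,
      n_housekeeping = 0L, n_noise_genes = 1000L, noise_sd = 1, seed = seed),
    null_cgm = synthetic_spec(
      n_samples = 150L, n_cgms = 1L, genes_per_cgm = 300L, core_fraction = 0.4,
      n_subfactors_per_cgm = 0L, genes_per_subfactor = 0L,
      core_loading = 0.925, core_loading_jitter = 0.075,
      periphery_loading = 0.825, periphery_loading_jitter = 0.125,
      n_housekeeping = 0L, n_noise_genes = 0L, noise_sd = 0.35, seed = seed))
}

#' Generate a synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_dataset`: `expr` (linear-space
#'   [expr_matrix()]), `truth_cgm` (a [module_assignment()]; housekeeping
#'   and noise genes are -1), `truth_fgm` (per-CGM [module_assignment()]
#'   of the planted sub-blocks; core and plain periphery genes are -1),
#'   `truth_core` (per-CGM core gene sets), `factors` (latent F and S
#'   values), `loadings` (per-gene CGM-factor loading), `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  withr::with_seed(as.integer(spec$seed), generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  ns <- spec$n_samples
  K <- spec$n_cgms
  sample_names <- sprintf("S%03d", seq_len(ns))

  Fm <- if (K > 0) matrix(rnorm(K * ns), K, ns) else matrix(0, 0, ns)
  S_list <- vector("list", max(K, 0L))

  gene_names <- character(0)
  log_expr <- NULL
  cgm_label <- integer(0)
  loadings <- numeric(0)
  truth_fgm <- list()
  truth_core <- list()

  jit <- function(center, half, n) {
    if (half == 0) rep(center, n) else runif(n, center - half, center + half)
  }

  for (c_i in seq_len(K)) {
    gpc <- spec$genes_per_cgm
    n_core <- round(spec$core_fraction * gpc)
    n_sub_total <- spec$n_subfactors_per_cgm * spec$genes_per_subfactor
    g_names <- sprintf("CGM%d_G%03d", c_i, seq_len(gpc))
    lam <- c(jit(spec$core_loading, spec$core_loading_jitter, n_core),
             jit(spec$periphery_loading, spec$periphery_loading_jitter,
                 gpc - n_core))
    L <- lam %o% Fm[c_i, ]

    sub_label <- rep(-1L, gpc)
    if (spec$n_subfactors_per_cgm > 0L) {
      S <- matrix(rnorm(spec$n_subfactors_per_cgm * ns),
                  spec$n_subfactors_per_cgm, ns)
      if (spec$subfactor_core_corr != 0) {
        rho <- spec$subfactor_core_corr
        S <- rho * matrix(Fm[c_i, ], spec$n_subfactors_per_cgm, ns,
                          byrow = TRUE) + sqrt(1 - rho^2) * S
      }
      S_list[[c_i]] <- S
      for (j in seq_len(spec$n_subfactors_per_cgm)) {
        rows <- n_core + (j - 1L) * spec$genes_per_subfactor +
          seq_len(spec$genes_per_subfactor)
        L[rows, ] <- L[rows, ] + spec$subfactor_loading *
          matrix(S[j, ], length(rows), ns, byrow = TRUE)
        sub_label[rows] <- j - 1L
      }
    }
    L <- L + matrix(rnorm(gpc * ns, sd = spec$noise_sd), gpc, ns)

    gene_names <- c(gene_names, g_names)
    log_expr <- rbind(log_expr, L)
    cgm_label <- c(cgm_label, rep(c_i - 1L, gpc))
    loadings <- c(loadings, lam)
    truth_core[[sprintf("CGM_%d", c_i - 1L)]] <- g_names[seq_len(n_core)]
    truth_fgm[[sprintf("CGM_%d", c_i - 1L)]] <-
      module_assignment(g_names, sub_label, level = "FGM",
                        parent_module = sprintf("CGM_%d", c_i - 1L))
  }

  if (spec$n_housekeeping > 0L) {
    hk_names <- sprintf("HK_G%03d", seq_len(spec$n_housekeeping))
    base <- if (K > 0) spec$hk_loading * matrix(colSums(Fm),
                                                spec$n_housekeeping, ns,
                                                byrow = TRUE) else 0
    L <- base + matrix(rnorm(spec$n_housekeeping * ns, sd = spec$noise_sd),
                       spec$n_housekeeping, ns)
    gene_names <- c(gene_names, hk_names)
    log_expr <- rbind(log_expr, L)
    cgm_label <- c(cgm_label, rep(-1L, spec$n_housekeeping))
    loadings <- c(loadings, rep(spec$hk_loading, spec$n_housekeeping))
  }

  if (spec$n_noise_genes > 0L) {
    nz_names <- sprintf("NOISE_G%04d", seq_len(spec$n_noise_genes))
    L <- matrix(rnorm(spec$n_noise_genes * ns, sd = max(spec$noise_sd, 1e-6)),
                spec$n_noise_genes, ns)
    gene_names <- c(gene_names, nz_names)
    log_expr <- rbind(log_expr, L)
    cgm_label <- c(cgm_label, rep(-1L, spec$n_noise_genes))
    loadings <- c(loadings, rep(0, spec$n_noise_genes))
  }

  baselines <- runif(length(gene_names), 2, 8)
  vals <- 2^(log_expr + baselines)
  dimnames(vals) <- list(gene_names, sample_names)

  structure(list(
    expr = expr_matrix(vals, space = "linear"),
    truth_cgm = module_assignment(gene_names, cgm_label, level = "CGM"),
    truth_fgm = truth_fgm,
    truth_core = truth_core,
    factors = list(F = Fm, S = S_list),
    loadings = setNames(loadings, gene_names),
    spec = spec
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d samples, %d planted CGMs\n",
              length(x$truth_cgm$gene_ids), n_samples(x$expr), x$spec$n_cgms))
  invisible(x)
}
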
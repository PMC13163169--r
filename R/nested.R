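#' Module eigengene
#'
#' First principal component of the standardized core-gene submatrix,
#' returned as one score per sample. Computed on log2(x+1) values when the
#' input is linear. The sign is oriented so the eigengene correlates
#' positively with mean core expression.
#'
#' @param expr an [expr_matrix()].
#' @param core_genes character vector (>= 2 genes) present in `expr`.
#' @return numeric vector, one value per sample, named by sample ID.
#' @export
compute_eigengene <- function(expr, core_genes) {
  stopifnot(inherits(expr, "expr_matrix"))
  core_genes <- as.character(core_genes)
  missing <- setdiff(core_genes, gene_ids(expr))
  if (length(missing) > 0)
    stop("core genes absent from expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  if (length(core_genes) < 2L) stop("need at least 2 core genes")
  x <- as_log_expr(expr)$values[core_genes, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (all(sds == 0)) stop("core submatrix has rank 0 (all genes constant)")
  xs <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  sv <- svd(xs, nu = 0L, nv = 1L)
  eig <- sv$v[, 1L]
  ref <- colMeans(xs)
  if (sd(ref) > 0 && cor(eig, ref) < 0) eig <- -eig
  setNames(eig, sample_ids(expr))
}

#' Core-anchored two-pass normalization
#'
#' Removes a module's dominant core signal from all genes so that secondary
#' co-expression structure becomes visible. The procedure:
#'
#' 1. compute the core eigengene;
#' 2. select the initial normalization gene set (INGS): genes whose Spearman
#'    correlation with the eigengene exceeds `rho_threshold`;
#' 3. first normalization: each sample's factor is the mean linear
#'    expression of the INGS genes and every gene is divided by it, except
#'    that each INGS gene is divided by the mean of the *remaining* INGS
#'    genes (no self-normalization);
#' 4. keep the INGS genes whose coefficient of variation shrank to less
#'    than `cv_ratio_threshold` times its pre-normalization value
#'    (the final INGS);
#' 5. second normalization of the original matrix with factors from the
#'    final INGS, same self-exclusion rule.
#'
#' @param expr an [expr_matrix()] in linear space (factors are expression
#'   averages).
#' @param core_genes gene IDs seeding the eigengene (typically from
#'   [extract_core()]).
#' @param rho_threshold Spearman cutoff for INGS membership (default 0.9).
#' @param cv_ratio_threshold CV-shrinkage cutoff for the final INGS
#'   (default 0.8).
#' @return object of class `normalization_result`: `eigengene`,
#'   `ings_initial`, `ings_final`, `f_ings` (per-sample factors of the
#'   second pass), `cv_ratio` (per initial-INGS gene), `normalized_expr`
#'   (linear-space [expr_matrix()]).
#' @export
immfocus_normalize <- function(expr, core_genes, rho_threshold = 0.9,
                               cv_ratio_threshold = 0.8) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$space != "linear")
    stop("normalization runs in linear space; supply untransformed values")
  if (length(core_genes) == 0L) stop("`core_genes` must be non-empty")
  v <- expr$values
  eig <- compute_eigengene(expr, core_genes)

  rho <- apply(v, 1L, function(g) suppressWarnings(cor(g, eig, method = "spearman")))
  rho[is.na(rho)] <- 0
  ings_initial <- rownames(v)[rho > rho_threshold]
  if (length(ings_initial) == 0L)
    stop("no gene has Spearman correlation > ", rho_threshold,
         " with the core eigengene; lower `rho_threshold`")

  norm_pass <- function(mat, ings) {
    f <- colMeans(mat[ings, , drop = FALSE])
    if (any(f <= 0))
      stop("non-positive normalization factor; input must be linear-space expression")
    out <- sweep(mat, 2L, f + 1e-9, "/")
    if (length(ings) > 1L) {
      tot <- colSums(mat[ings, , drop = FALSE])
      for (g in ings) {
        f_g <- (tot - mat[g, ]) / (length(ings) - 1L)   # mean of remaining INGS
        out[g, ] <- mat[g, ] / (f_g + 1e-9)
      }
    } else {
      warning("single INGS gene; self-exclusion impossible, using the shared factor")
    }
    list(values = out, f = f)
  }

  pass1 <- norm_pass(v, ings_initial)
  cv <- function(x) sd(x) / (mean(x) + 1e-9)
  cv_before <- apply(v[ings_initial, , drop = FALSE], 1L, cv)
  cv_after <- apply(pass1$values[ings_initial, , drop = FALSE], 1L, cv)
  cv_ratio <- setNames(cv_after / (cv_before + 1e-9), ings_initial)
  ings_final <- ings_initial[cv_ratio < cv_ratio_threshold]
  if (length(ings_final) == 0L) {
    warning("no INGS gene passed the CV-ratio filter (< ", cv_ratio_threshold,
            "); keeping the initial INGS")
    ings_final <- ings_initial
  }
  pass2 <- norm_pass(v, ings_final)

  structure(list(
    eigengene = eig,
    ings_initial = ings_initial,
    ings_final = ings_final,
    f_ings = pass2$f,
    cv_ratio = cv_ratio,
    normalized_expr = expr_matrix(pass2$values, space = "linear")
  ), class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf(
    "normalization_result: %d initial INGS, %d final INGS, %d samples\n",
    length(x$ings_initial), length(x$ings_final), length(x$f_ings)))
  invisible(x)
}

#' Infer fine-grained modules within a CGM
#'
#' Second-round network inference: the expression matrix is restricted to
#' the CGM genes, normalized on the core gene set (see
#' [immfocus_normalize()]), log2(x+1)-transformed, and clustered again with
#' the same network pipeline at a smaller minimum cluster size. Genes left
#' unassigned at FGM level carry label -1.
#'
#' @param expr linear-space [expr_matrix()] covering the CGM genes.
#' @param cgm_genes genes of the parent CGM.
#' @param core_genes the CGM core (subset of `cgm_genes`).
#' @param fgm_min_cluster_size minimum FGM size (default 15).
#' @param seed integer seed.
#' @param parent_module identifier of the parent CGM stored in the output.
#' @param normalize set `FALSE` to skip the core normalization (ablation
#'   mode; the shared module factor then typically masks the sub-structure).
#' @param rho_threshold,cv_ratio_threshold passed to [immfocus_normalize()].
#' @return object of class `fgm_set`: `assignment` (a [module_assignment()]
#'   at FGM level), `fgm_gene_sets` (list of gene vectors named
#'   `FGM_<j>`), `normalization` (the `normalization_result`, or NULL in
#'   ablation mode), `parent_cgm`.
#' @export
infer_fgms <- function(expr, cgm_genes, core_genes, fgm_min_cluster_size = 15L,
                       seed = 0L, parent_module = "CGM_0", normalize = TRUE,
                       rho_threshold = 0.9, cv_ratio_threshold = 0.8) {
  stopifnot(inherits(expr, "expr_matrix"))
  cgm_genes <- as.character(cgm_genes)
  core_genes <- as.character(core_genes)
  if (!all(core_genes %in% cgm_genes))
    stop("`core_genes` must be a subset of `cgm_genes`")
  if (!all(cgm_genes %in% gene_ids(expr)))
    stop("some `cgm_genes` are absent from `expr`")
  if (length(cgm_genes) <= 2L * fgm_min_cluster_size) {
    warning("CGM too small (", length(cgm_genes),
            " genes) for fgm_min_cluster_size = ", fgm_min_cluster_size,
            "; returning an empty FGM set")
    empty <- module_assignment(cgm_genes, rep(-1L, length(cgm_genes)),
                               level = "FGM", parent_module = parent_module)
    return(structure(list(assignment = empty, fgm_gene_sets = list(),
                          normalization = NULL, parent_cgm = parent_module),
                     class = "fgm_set"))
  }
  sub <- expr_matrix(expr$values[cgm_genes, , drop = FALSE], expr$space)
  norm <- NULL
  if (normalize) {
    norm <- immfocus_normalize(sub, core_genes, rho_threshold = rho_threshold,
                               cv_ratio_threshold = cv_ratio_threshold)
    sub <- norm$normalized_expr
  }
  assignment <- detect_cgms(sub, min_cluster_size = fgm_min_cluster_size,
                            seed = seed)
  assignment <- module_assignment(assignment$gene_ids, assignment$labels,
                                  level = "FGM", parent_module = parent_module,
                                  params = assignment$params)
  sets <- lapply(module_labels(assignment), function(l) module_genes(assignment, l))
  names(sets) <- sprintf("FGM_%d", module_labels(assignment))
  structure(list(assignment = assignment, fgm_gene_sets = sets,
                 normalization = norm, parent_cgm = parent_module),
            class = "fgm_set")
}

#' @export
print.fgm_set <- function(x, ...) {
  cat(sprintf("fgm_set [%s]: %d FGMs over %d genes\n", x$parent_cgm,
              length(x$fgm_gene_sets), length(x$assignment$gene_ids)))
  invisible(x)
}
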
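#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. Thresholds are validated
#' against their documented ranges; the seed is recorded in all outputs.
#'
#' @param input path of the expression matrix (TSV/CSV/MTX), or `NULL` when
#'   an [expr_matrix()] is passed to [run_full()] directly.
#' @param annotation optional path of a two-column gene annotation TSV.
#' @param out_dir output directory (created if absent).
#' @param transform `"none"` or `"log2p1"` applied at load time; the
#'   pipeline keeps a linear copy for normalization either way, so the
#'   default `"none"` expects linear (TPM-like) input.
#' @param corr_method correlation estimator.
#' @param min_cluster_size CGM-level minimum module size.
#' @param fgm_min_cluster_size FGM-level minimum module size.
#' @param rho_threshold,cv_ratio_threshold normalization thresholds, see
#'   [immfocus_normalize()].
#' @param me_threshold gene filter threshold, see [filter_genes()].
#' @param seed integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, annotation = NULL, out_dir = "nestwgcna_out",
                       transform = "none", corr_method = "pearson",
                       min_cluster_size = 50L, fgm_min_cluster_size = 15L,
                       rho_threshold = 0.9, cv_ratio_threshold = 0.8,
                       me_threshold = exp(-1), seed = 0L) {
  if (!corr_method %in% c("pearson", "spearman")) stop("invalid corr_method")
  if (!transform %in% c("none", "log2p1")) stop("invalid transform")
  if (min_cluster_size < 2L || fgm_min_cluster_size < 2L)
    stop("cluster sizes must be >= 2")
  if (rho_threshold < 0 || rho_threshold > 1) stop("rho_threshold must be in [0,1]")
  if (cv_ratio_threshold <= 0) stop("cv_ratio_threshold must be positive")
  if (me_threshold < 0 || me_threshold > 1) stop("me_threshold must be in [0,1]")
  structure(list(input = input, annotation = annotation, out_dir = out_dir,
                 transform = transform, corr_method = corr_method,
                 min_cluster_size = as.integer(min_cluster_size),
                 fgm_min_cluster_size = as.integer(fgm_min_cluster_size),
                 rho_threshold = rho_threshold,
                 cv_ratio_threshold = cv_ratio_threshold,
                 me_threshold = me_threshold, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full nested pipeline
#'
#' Gene filtering, CGM detection, per-CGM core extraction, core-anchored
#' normalization and FGM detection, with GMT/TSV/JSON outputs written to
#' `config$out_dir`. Two runs with identical configuration produce
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param expr optional [expr_matrix()]; when `NULL` the matrix is loaded
#'   from `config$input`.
#' @return (invisibly) list with the filtered matrix, CGM assignment, per-
#'   CGM cores and FGM sets, and the output file paths.
#' @export
run_full <- function(config, expr = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(expr)) {
    if (is.null(config$input)) stop("no input: set `config$input` or pass `expr`")
    expr <- load_expression(config$input, transform = config$transform)
  }
  if (expr$space != "linear")
    stop("run_full() needs linear-space input (normalization divides expression averages)")
  annotation <- if (!is.null(config$annotation)) read_annotation(config$annotation)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  message("[1/4] gene filtering")
  filt <- if (is.null(annotation)) {
    suppressWarnings(filter_genes(expr, NULL, config$me_threshold))
  } else filter_genes(expr, annotation, config$me_threshold)
  expr_f <- filt$expr

  message("[2/4] CGM detection (", length(gene_ids(expr_f)), " genes)")
  cgms <- detect_cgms(expr_f, min_cluster_size = config$min_cluster_size,
                      seed = config$seed, corr_method = config$corr_method)

  message("[3/4] core extraction + nested FGM inference")
  adj <- compute_adjacency(as_log_expr(expr_f), corr_method = config$corr_method)
  labels <- module_labels(cgms)
  cores <- list(); fgm_sets <- list(); gmt <- list()
  for (l in labels) {
    cgm_name <- sprintf("CGM_%d", l)
    genes_l <- module_genes(cgms, l)
    gmt[[cgm_name]] <- genes_l
    core_l <- extract_core(genes_l, adj)
    cores[[cgm_name]] <- core_l
    gmt[[paste0(cgm_name, "_core")]] <- core_l
    fgm <- tryCatch(
      withCallingHandlers(
        infer_fgms(expr_f, genes_l, core_l,
                   fgm_min_cluster_size = config$fgm_min_cluster_size,
                   seed = config$seed + l + 1L, parent_module = cgm_name,
                   rho_threshold = config$rho_threshold,
                   cv_ratio_threshold = config$cv_ratio_threshold),
        warning = function(w) {
          message("  ", cgm_name, ": ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        ## a module whose genes never reach the INGS correlation threshold
        ## cannot be core-normalized; record it and keep the CGM/core output
        message("  ", cgm_name, ": FGM inference skipped (",
                conditionMessage(e), ")")
        empty <- module_assignment(genes_l, rep(-1L, length(genes_l)),
                                   level = "FGM", parent_module = cgm_name)
        structure(list(assignment = empty, fgm_gene_sets = list(),
                       normalization = NULL, parent_cgm = cgm_name),
                  class = "fgm_set")
      })
    fgm_sets[[cgm_name]] <- fgm
    for (nm in names(fgm$fgm_gene_sets))
      gmt[[paste0(cgm_name, "_", nm)]] <- fgm$fgm_gene_sets[[nm]]
  }

  message("[4/4] writing outputs to ", config$out_dir)
  paths <- list(
    gmt = file.path(config$out_dir, "modules.gmt"),
    assignment = file.path(config$out_dir, "cgm_assignment.tsv"),
    metadata = file.path(config$out_dir, "run_metadata.json"))
  write_gmt(gmt, paths$gmt)
  write_assignment_tsv(cgms, paths$assignment)
  params <- derive_params(n_samples(expr_f), config$min_cluster_size, config$seed)
  meta <- list(config = unclass(config), config_hash = config_hash(config),
               derived = unclass(params)[c("n_components", "n_neighbors",
                                           "min_samples")],
               n_genes_input = length(gene_ids(expr)),
               n_genes_retained = length(gene_ids(expr_f)),
               n_samples = n_samples(expr_f),
               n_cgms = length(labels))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             paths$metadata)
  invisible(list(expr = expr_f, filter_report = filt$report, cgms = cgms,
                 cores = cores, fgm_sets = fgm_sets, paths = paths))
}

#' Run an evaluation
#'
#' Dispatches the stability or knowledge-score computations and writes a
#' JSON report.
#'
#' @param mode `"stability"` (bootstrap), `"compare"` (two stored
#'   assignments) or `"kscore"`.
#' @param out_path JSON report path.
#' @param expr [expr_matrix()] for `"stability"`.
#' @param assignment,assignment_b stored assignments (paths or
#'   [module_assignment()] objects) for `"compare"` / `"kscore"`.
#' @param tf_gmt TF -> target GMT path (or named list) for `"kscore"`.
#' @param B,min_cluster_size,seed bootstrap parameters.
#' @return the report list, invisibly; the JSON file is written to
#'   `out_path`.
#' @export
run_eval <- function(mode = c("stability", "compare", "kscore"), out_path,
                     expr = NULL, assignment = NULL, assignment_b = NULL,
                     tf_gmt = NULL, B = 10L, min_cluster_size = 50L, seed = 0L) {
  mode <- match.arg(mode)
  as_assign <- function(x) if (is.character(x)) read_assignment(x) else x
  report <- switch(mode,
    stability = {
      r <- bootstrap_stability(expr, min_cluster_size = min_cluster_size,
                               B = B, seed = seed)
      list(mode = "stability", n_pairs = r$n_pairs,
           mean = as.list(r$mean), sd = as.list(r$sd), cv = as.list(r$cv),
           unique_fraction = r$unique_fraction,
           failed_replicates = r$failed_replicates, seed = seed)
    },
    compare = {
      m <- compare_clusterings(as_assign(assignment), as_assign(assignment_b))
      list(mode = "compare", metrics = as.list(m))
    },
    kscore = {
      tf <- if (is.character(tf_gmt)) read_gmt(tf_gmt) else tf_gmt
      ks <- knowledge_score(as_assign(assignment), tf)
      list(mode = "kscore", counts = as.list(ks$counts), score = ks$score,
           p_value = ks$p_value, n_tf_annotated_genes = ks$n_tf_annotated_genes)
    })
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, na = "null"), out_path)
  invisible(report)
}
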
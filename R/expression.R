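#' Expression matrix container
#'
#' Lightweight container for a genes x samples expression matrix. Values are
#' non-negative in `"linear"` space (TPM-like) or unrestricted reals in
#' `"log"` space (after a log2(x+1) transform). Gene and sample identifiers
#' live in the dimnames and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete and unique dimnames.
#' @param space `"linear"` or `"log"`.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `space`.
#' @export
expr_matrix <- function(values, space = c("linear", "log")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (ncol(values) < 3L)
    stop("at least 3 samples are required, got ", ncol(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (space == "linear" && any(values < 0))
    stop("negative values are not allowed in linear space")
  structure(list(values = values, space = space), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s space]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr_matrix
#' @export
n_samples <- function(x) ncol(x$values)

## Coerce to log2(x+1) space if needed; no-op for matrices already in log space.
as_log_expr <- function(expr) {
  if (expr$space == "log") return(expr)
  expr_matrix(log2(expr$values + 1), space = "log")
}

#' Load an expression matrix from disk
#'
#' Reads TSV/CSV (genes as rows, first column gene IDs, header = sample IDs)
#' or MatrixMarket (`.mtx` with `.rows`/`.cols` sidecar files holding one
#' identifier per line).
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`. Guessed from the extension by
#'   default.
#' @param transform `"none"` keeps the values as stored (linear space);
#'   `"log2p1"` applies log2(x+1) and marks the matrix as log space.
#' @return an [expr_matrix()].
#' @export
load_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            transform = c("none", "log2p1")) {
  format <- match.arg(format)
  transform <- match.arg(transform)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format from extension of ", path,
                          "; pass `format` explicitly"))
  }
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    dt <- tryCatch(
      data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
      error = function(e) stop("malformed ", format, " file ", path, ": ",
                               conditionMessage(e)))
    if (ncol(dt) < 2L) stop("malformed ", format, " file ", path,
                            ": need a gene ID column plus >=1 sample column")
    ids <- as.character(dt[[1L]])
    vals <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(dt[-1L], is.numeric, logical(1)))[1L]
      stop("malformed ", format, " file ", path, ": non-numeric sample column '",
           colnames(dt)[-1L][bad], "'")
    }
    if (anyNA(vals)) {
      line <- which(rowSums(is.na(vals)) > 0)[1L]
      stop("malformed ", format, " file ", path, ": missing value at data line ",
           line, " (gene ", ids[line], ")")
    }
    rownames(vals) <- ids
  } else {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed mtx file ", path, ": ",
                                           conditionMessage(e)))
    sidecar <- function(ext) {
      p <- sub("\\.mtx$", ext, path, ignore.case = TRUE)
      if (identical(p, path)) p <- paste0(path, ext)
      if (!file.exists(p)) stop("sidecar file not found: ", p)
      readLines(p)
    }
    ids <- sidecar(".rows")
    cols <- sidecar(".cols")
    if (length(ids) != nrow(m) || length(cols) != ncol(m))
      stop("mtx dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecar row/col files")
    vals <- as.matrix(m)
    dimnames(vals) <- list(ids, cols)
  }
  if (transform == "log2p1") {
    if (any(vals < 0)) stop("log2p1 transform requires non-negative input")
    expr_matrix(log2(vals + 1), space = "log")
  } else {
    expr_matrix(vals, space = "linear")
  }
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression()] for the TSV format: first column `gene_id`,
#' remaining columns one per sample.
#'
#' @param expr an [expr_matrix()].
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene_id = gene_ids(expr))
  for (s in sample_ids(expr)) dt[[s]] <- expr$values[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Per-gene misclassification error
#'
#' One minus the relative frequency of the most common value across samples.
#' A constant gene has error 0; a gene whose modal value occurs in half of
#' the samples has error 0.5. Near-constant genes carry little information
#' and break down under bootstrap resampling, which retains ~63.2% unique
#' samples per pseudosample.
#'
#' @param expr an [expr_matrix()]; values are used as stored (the statistic
#'   is invariant under any bijective transform).
#' @return named numeric vector in `[0, 1 - 1/N]`.
#' @export
misclassification_error <- function(expr) {
  v <- expr$values
  n <- ncol(v)
  me <- apply(v, 1L, function(x) 1 - max(tabulate(match(x, unique(x)))) / n)
  setNames(me, gene_ids(expr))
}

#' Filter genes by biotype and misclassification error
#'
#' Applies the two gene filters used before network construction: an optional
#' protein-coding filter driven by a gene -> biotype annotation, and the
#' misclassification-error filter that drops genes whose error falls below
#' `me_threshold` (default 1/e).
#'
#' @param expr an [expr_matrix()].
#' @param annotation optional two-column data.frame (`gene_id`, `biotype`) or
#'   named character vector mapping gene IDs to biotypes. Genes without an
#'   entry are kept (and counted in the report). When `NULL` the coding
#'   filter is skipped with a warning.
#' @param me_threshold drop genes with misclassification error strictly below
#'   this value. Default `exp(-1)`.
#' @return list with elements `expr` (the filtered [expr_matrix()]) and
#'   `report` (class `gene_filter_report`: per-gene errors, dropped sets,
#'   threshold, number of unannotated genes kept).
#' @export
filter_genes <- function(expr, annotation = NULL, me_threshold = exp(-1)) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- gene_ids(expr)
  n_unannotated <- 0L
  dropped_noncoding <- character(0)
  if (is.null(annotation)) {
    warning("no gene annotation supplied; skipping the protein-coding filter")
  } else {
    map <- annotation_map(annotation)
    covered <- genes[genes %in% names(map)]
    n_unannotated <- length(genes) - length(covered)
    dropped_noncoding <- covered[tolower(map[covered]) != "protein_coding"]
  }
  keep1 <- setdiff(genes, dropped_noncoding)
  me <- misclassification_error(expr)[keep1]
  dropped_low <- names(me)[me < me_threshold]
  retained <- setdiff(keep1, dropped_low)
  if (length(retained) == 0L)
    stop("all genes removed by filtering; consider lowering `me_threshold` (",
         signif(me_threshold, 4), ")")
  report <- structure(list(
    misclassification_error = me,
    dropped_noncoding = dropped_noncoding,
    dropped_low_information = dropped_low,
    threshold = me_threshold,
    n_unannotated_kept = n_unannotated
  ), class = "gene_filter_report")
  list(expr = expr_matrix(expr$values[retained, , drop = FALSE], expr$space),
       report = report)
}

#' @export
print.gene_filter_report <- function(x, ...) {
  cat(sprintf(
    "gene_filter_report: %d noncoding dropped, %d low-information dropped (ME < %.4f)\n",
    length(x$dropped_noncoding), length(x$dropped_low_information), x$threshold))
  invisible(x)
}

annotation_map <- function(annotation) {
  if (is.character(annotation) && !is.null(names(annotation))) return(annotation)
  if (is.data.frame(annotation) && ncol(annotation) >= 2L)
    return(setNames(as.character(annotation[[2L]]), as.character(annotation[[1L]])))
  stop("`annotation` must be a named character vector or a two-column data.frame")
}

#' Read a two-column gene annotation TSV
#'
#' @param path TSV with columns `gene_id` and `biotype` (header optional).
#' @return named character vector gene_id -> biotype.
#' @export
read_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto", data.table = FALSE)
  if (ncol(dt) < 2L) stop("annotation file must have two columns: ", path)
  setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
}

#' Joint gene filter across datasets
#'
#' Restricts to genes present in every dataset and removes genes whose
#' misclassification error falls below `me_threshold` in at least one of
#' them, mirroring the "dropped if failing in any dataset" rule used when
#' several cohorts are analysed jointly.
#'
#' @param exprs list of [expr_matrix()] objects sharing a gene ID namespace.
#' @param me_threshold see [filter_genes()].
#' @return character vector of retained gene IDs.
#' @export
multi_dataset_filter <- function(exprs, me_threshold = exp(-1)) {
  stopifnot(is.list(exprs), length(exprs) >= 2L)
  common <- Reduce(intersect, lapply(exprs, gene_ids))
  if (length(common) == 0L)
    stop("datasets share no gene IDs; cannot apply a joint filter")
  fails <- lapply(exprs, function(e) {
    me <- misclassification_error(e)[common]
    names(me)[me < me_threshold]
  })
  retained <- setdiff(common, unique(unlist(fails)))
  if (length(retained) == 0L)
    stop("all shared genes fail the misclassification-error filter in some dataset")
  retained
}
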
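#' Read a GMT gene-set file
#'
#' Thin wrapper around [fgsea::gmtPathways()]; returns a named list of
#' character vectors (set name -> member genes). For TF target maps the set
#' name is the transcription factor.
#'
#' @param path GMT file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' One line per set: name, description, then the member genes,
#' tab-separated. Output is deterministic (sets written in list order).
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "nestwgcna") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a module assignment as TSV
#'
#' Two columns: `gene_id`, `label` (-1 = unassigned).
#'
#' @param assignment a [module_assignment()].
#' @param path output file.
#' @export
write_assignment_tsv <- function(assignment, path) {
  data.table::fwrite(
    data.table::data.table(gene_id = assignment$gene_ids,
                           label = assignment$labels),
    path, sep = "\t")
  invisible(path)
}

#' Read a module assignment from TSV or GMT
#'
#' TSV input must carry `gene_id` and `label` columns; GMT input assigns
#' label k-1 to the genes of the k-th set.
#'
#' @param path input file.
#' @param level assignment level to record.
#' @export
read_assignment <- function(path, level = "CGM") {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    genes <- unique(unlist(sets, use.names = FALSE))
    labels <- rep(-1L, length(genes))
    for (k in seq_along(sets)) labels[genes %in% sets[[k]]] <- k - 1L
    return(module_assignment(genes, labels, level = level))
  }
  dt <- data.table::fread(path, data.table = FALSE)
  if (!all(c("gene_id", "label") %in% colnames(dt)))
    stop("assignment TSV needs `gene_id` and `label` columns: ", path)
  module_assignment(as.character(dt$gene_id), as.integer(dt$label),
                    level = level)
}

#' Write per-sample values as TSV
#' @param x named numeric vector (names = sample IDs).
#' @param path output file.
#' @param value_name column name for the values.
#' @export
write_sample_tsv <- function(x, path, value_name = "value") {
  dt <- data.table::data.table(sample_id = names(x))
  dt[[value_name]] <- unname(x)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
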
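#' Two-group expression time-course dataset
#'
#' A light container pairing a genes x samples matrix of
#' log10(1 + normalized count) values with its sample annotation. The
#' annotation rows match the matrix columns one-to-one (by \code{sample_id});
#' groups must be \code{young}/\code{old} and gene identifiers must be unique.
#'
#' @param values Numeric matrix, rows = genes (rownames = gene ids),
#'   columns = samples.
#' @param samples data.frame with columns \code{sample_id}, \code{group},
#'   \code{donor}, \code{timepoint_hr}; rows in any order (reconciled by
#'   \code{sample_id}).
#' @return A list of class \code{expression_dataset} with elements
#'   \code{values} and \code{samples} (reordered to match the matrix columns).
#' @export
expression_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  need <- c("sample_id", "group", "donor", "timepoint_hr")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(colnames(values)))
    stop("`values` must have sample ids as column names")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have gene ids as row names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  extra <- setdiff(colnames(values), samples$sample_id)
  if (length(extra))
    stop("samples present in matrix but not annotation: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(samples$sample_id, colnames(values))
  if (length(absent))
    stop("samples present in annotation but not matrix: ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in annotation")
  samples <- samples[match(colnames(values), samples$sample_id), need]
  rownames(samples) <- NULL
  bad_group <- setdiff(unique(samples$group), c("young", "old"))
  if (length(bad_group))
    stop("unknown group labels: ", paste(bad_group, collapse = ", "))
  if (!is.numeric(samples$timepoint_hr))
    stop("`timepoint_hr` must be numeric")
  structure(list(values = values, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%d young, %d old; timepoints %s h)\n",
    nrow(x$values), ncol(x$values), sum(x$samples$group == "young"),
    sum(x$samples$group == "old"),
    paste(range(x$samples$timepoint_hr), collapse = "-")))
  invisible(x)
}

#' Read / write an expression dataset as TSV
#'
#' The matrix TSV has a \code{gene_id} column followed by one column per
#' sample; the annotation TSV has columns \code{sample_id}, \code{group},
#' \code{donor}, \code{timepoint_hr}. Column order in the matrix may differ
#' from annotation row order; they are reconciled by \code{sample_id}, with
#' typed errors naming any offending samples, genes or non-numeric cells.
#'
#' @param matrix_path,annotation_path TSV file paths.
#' @return For \code{load_expression}, an [expression_dataset()].
#' @export
load_expression <- function(matrix_path, annotation_path) {
  mat_df <- read_tsv_plain(matrix_path)
  ann <- read_tsv_plain(annotation_path)
  if (!"gene_id" %in% names(mat_df))
    stop("matrix TSV must have a 'gene_id' first column")
  gene_ids <- as.character(mat_df$gene_id)
  val_df <- mat_df[setdiff(names(mat_df), "gene_id")]
  non_num <- names(val_df)[!vapply(val_df, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric expression values in sample columns: ",
         paste(non_num, collapse = ", "))
  values <- as.matrix(val_df)
  rownames(values) <- gene_ids
  expression_dataset(values, ann)
}

#' @rdname load_expression
#' @param dataset An [expression_dataset()].
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mat_df <- data.frame(gene_id = rownames(dataset$values),
                       dataset$values, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write_tsv_atomic(mat_df, matrix_path)
  write_tsv_atomic(dataset$samples, annotation_path)
  invisible(c(matrix_path, annotation_path))
}
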
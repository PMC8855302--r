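#' Expression matrix with sample metadata and spike-in flags
#'
#' Container for a gene x sample abundance table on the FPKM scale, the raw
#' input of the pipeline. Rows whose identifier starts with the spike-in
#' prefix (default `"ERCC-"`) are flagged as exogenous spike-in species and
#' are exempt from gene-level filtering, classification and totals.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). All values must be
#'   non-negative and finite.
#' @param samples data.frame of per-sample metadata with columns
#'   `sample_id`, `stage` (e.g. `"zygote"`, `"2cell"`, `"8cell"`),
#'   `condition` (e.g. `"WT"`, `"KD"`) and `replicate` (integer index).
#'   Rows are matched to `colnames(values)` by `sample_id`.
#' @param spikein_prefix identifier prefix marking spike-in rows.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples` and logical vector `spikein` (one flag per row of `values`).
#' @seealso [read_expression_matrix()], [normalize_spikeins()],
#'   [floor_and_filter()]
#' @export
expression_matrix <- function(values, samples, spikein_prefix = "ERCC-") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative")
  }
  samples <- as.data.frame(samples)
  required <- c("sample_id", "stage", "condition", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("`samples` lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!setequal(samples$sample_id, colnames(values)) ||
      nrow(samples) != ncol(values)) {
    stop("`samples$sample_id` must match colnames(values) one-to-one")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(
      values = values,
      samples = samples,
      spikein = startsWith(rownames(values), spikein_prefix)
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<%s> %d genes (+%d spike-ins) x %d samples\n",
    class(x)[1], sum(!x$spikein), sum(x$spikein), ncol(x$values)
  ))
  groups <- table(paste(x$samples$stage, x$samples$condition, sep = "/"))
  cat("groups:", paste(sprintf("%s(n=%d)", names(groups), groups),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# non-spike-in submatrix
gene_values <- function(x) x$values[!x$spikein, , drop = FALSE]

# column indices for one stage x condition group
group_columns <- function(x, stage, condition) {
  which(x$samples$stage == stage & x$samples$condition == condition)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' @param matrix_file tab-delimited table; first column gene identifiers,
#'   remaining columns one per sample with sample identifiers in the header.
#' @param metadata_file tab-delimited sample table with columns
#'   `sample_id`, `stage`, `condition`, `replicate`.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()] object.
#' @export
read_expression_matrix <- function(matrix_file, metadata_file,
                                   spikein_prefix = "ERCC-") {
  tab <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  samples <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
  expression_matrix(values, samples, spikein_prefix = spikein_prefix)
}

#' Write an expression matrix and its sample metadata to TSV
#'
#' @param x an `expr_matrix`.
#' @param matrix_file,metadata_file output paths.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, matrix_file, metadata_file = NULL) {
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_file)) {
    utils::write.table(x$samples, metadata_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read a gene list (one identifier per line)
#'
#' @param file path to a plain-text file, one gene identifier per line; blank
#'   lines and leading/trailing whitespace are dropped.
#' @return character vector of identifiers.
#' @export
read_gene_list <- function(file) {
  ids <- trimws(readLines(file, warn = FALSE))
  ids[nzchar(ids)]
}

#' Write a gene list (one identifier per line)
#'
#' @param ids character vector of gene identifiers (or a [gene_set()]).
#' @param file output path.
#' @export
write_gene_list <- function(ids, file) {
  if (inherits(ids, "gene_set")) ids <- ids$members
  writeLines(as.character(ids), file)
  invisible(file)
}
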
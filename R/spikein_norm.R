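#' Per-sample spike-in scale factors (median-of-ratios)
#'
#' Computes one multiplicative factor per sample that equalizes spike-in
#' levels across samples, anchoring absolute (copy-number scale)
#' comparisons. For each spike-in species g a reference level `ref_g` is the
#' geometric mean of its values across samples; the factor for sample j is
#'
#'   s_j = median over g of ( ref_g / value[g, j] )
#'
#' The median over species makes the factor robust to dropout of individual
#' spike-ins. Zero spike-in values are treated as missing for the median
#' (never as infinite ratios); a sample with more than half of its spike-ins
#' missing triggers a warning, and a sample with no usable spike-in is an
#' error because normalization is then impossible.
#'
#' @param x an [expression_matrix()] (or normalized matrix) containing at
#'   least one spike-in row.
#' @return named numeric vector of scale factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, 2,
#'             dimnames = list(c("ERCC-1", "g1"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), stage = "zygote",
#'                  condition = "WT", replicate = 1:2)
#' compute_spikein_factors(expression_matrix(m, md))
#' @export
compute_spikein_factors <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  sp <- x$values[x$spikein, , drop = FALSE]
  if (nrow(sp) == 0L) stop("no spike-in rows; normalization impossible")
  sp[sp == 0] <- NA_real_
  n_missing <- colSums(is.na(sp))
  if (any(n_missing == nrow(sp))) {
    stop("sample(s) with all-zero spike-ins: ",
         paste(colnames(sp)[n_missing == nrow(sp)], collapse = ", "),
         "; normalization impossible")
  }
  if (any(n_missing > nrow(sp) / 2)) {
    warning("sample(s) with > 50% missing spike-ins: ",
            paste(colnames(sp)[n_missing > nrow(sp) / 2], collapse = ", "))
  }
  ref <- apply(sp, 1L, geomean)
  factors <- apply(ref / sp, 2L, stats::median, na.rm = TRUE)
  names(factors) <- colnames(x$values)
  attr(factors, "reference") <- ref
  factors
}

#' Apply spike-in normalization to an expression matrix
#'
#' Multiplies every sample column (genes and spike-ins alike) by its
#' [compute_spikein_factors()] factor, so that the median ratio of the fixed
#' spike-in reference to every sample's spike-ins equals 1 exactly. The
#' result stays on the "normalized FPKM" scale on which all downstream
#' totals, classifications and fold changes operate. Because the reference
#' is the geometric mean across the samples at hand, rescaling one input
#' column rescales all normalized values by a single common constant
#' (c^(1/n)); every between-sample and between-gene ratio — and hence every
#' downstream result — is invariant.
#'
#' @inheritParams compute_spikein_factors
#' @return a `norm_expr` object: an `expr_matrix` carrying, additionally,
#'   `scale_factors`, the per-spike-in `spikein_reference`, a `floored`
#'   flag (FALSE here) and an empty `excluded_gene_ids` list.
#' @seealso [floor_and_filter()], [normalize_expression()]
#' @export
normalize_spikeins <- function(x) {
  factors <- compute_spikein_factors(x)
  x$spikein_reference <- attr(factors, "reference")
  attr(factors, "reference") <- NULL
  x$values <- sweep(x$values, 2L, factors, `*`)
  x$scale_factors <- factors
  x$floored <- FALSE
  x$excluded_gene_ids <- character(0)
  class(x) <- c("norm_expr", "expr_matrix")
  x
}

#' Exclusion and flooring of low-abundance genes
#'
#' Applies the two FPKM-threshold rules used before all downstream analyses:
#' genes (never spike-ins) with a value below 1 in every sample are removed
#' and listed in `excluded_gene_ids`; for the remaining genes, any value
#' below 1 is set to 1. Flooring guarantees finite ratios without
#' pseudocounts. The operation is idempotent.
#'
#' @param x an [expression_matrix()] or the result of
#'   [normalize_spikeins()].
#' @return a `norm_expr` object with `floored = TRUE` and the removed
#'   identifiers in `excluded_gene_ids`.
#' @examples
#' m <- matrix(c(0.5, 0.8, 0.5, 3, 1, 1), 3, 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB", "ERCC-1"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), stage = "zygote",
#'                  condition = "WT", replicate = 1:2)
#' ff <- floor_and_filter(expression_matrix(m, md))
#' ff$excluded_gene_ids  # "gA"
#' @export
floor_and_filter <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) == 0L || nrow(x$values) == 0L) stop("empty matrix")
  genes <- !x$spikein
  below <- x$values < 1 & genes  # spike-ins exempt from both rules
  drop <- genes & rowSums(x$values >= 1) == 0L
  excluded <- rownames(x$values)[drop]
  x$values[below] <- 1
  x$values <- x$values[!drop, , drop = FALSE]
  x$spikein <- x$spikein[!drop]
  x$floored <- TRUE
  x$excluded_gene_ids <- unique(c(x$excluded_gene_ids %||% character(0),
                                  excluded))
  if (!inherits(x, "norm_expr")) {
    x$scale_factors <- NULL
    class(x) <- c("norm_expr", "expr_matrix")
  }
  x
}

#' Full normalization pipeline: spike-in scaling then flooring
#'
#' Convenience wrapper running [normalize_spikeins()] followed (by default)
#' by [floor_and_filter()]. Scaling comes first: the floor of 1 is a
#' convention on the final normalized-FPKM scale.
#'
#' @inheritParams compute_spikein_factors
#' @param floor apply the exclusion/flooring rules after scaling?
#' @return a `norm_expr` object.
#' @export
normalize_expression <- function(x, floor = TRUE) {
  out <- normalize_spikeins(x)
  if (floor) out <- floor_and_filter(out)
  out
}

#' Relative total mRNA copy-number change
#'
#' Sums normalized non-spike-in values per sample, averages replicates
#' within each stage x condition group, and divides by the baseline group's
#' average so the baseline (e.g. WT zygote) is exactly 1.0. With constant
#' spike-ins the ratio tracks relative total mRNA copy number per embryo.
#'
#' @param norm a `norm_expr` object (see [normalize_expression()]).
#' @param baseline_stage,baseline_condition the group set to 1.0.
#' @return data.frame with one row per stage x condition group: `stage`,
#'   `condition`, `n_replicates`, `relative_total`.
#' @export
total_copy_change <- function(norm, baseline_stage = "zygote",
                              baseline_condition = "WT") {
  stopifnot(inherits(norm, "expr_matrix"))
  totals <- colSums(gene_values(norm))
  groups <- unique(norm$samples[, c("stage", "condition")])
  rownames(groups) <- NULL
  groups$n_replicates <- NA_integer_
  groups$relative_total <- NA_real_
  means <- numeric(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    cols <- group_columns(norm, groups$stage[i], groups$condition[i])
    groups$n_replicates[i] <- length(cols)
    means[i] <- mean(totals[cols])
  }
  base <- which(groups$stage == baseline_stage &
                  groups$condition == baseline_condition)
  if (length(base) != 1L) {
    stop("baseline group ", baseline_stage, "/", baseline_condition,
         " not present")
  }
  groups$relative_total <- means / means[base]
  groups
}

#' Replicate-correlation quality control
#'
#' Computes Spearman's rank correlation (average ranks for ties) for every
#' pair of replicates within each stage x condition group, over non-spike-in
#' gene values. Groups with fewer than two replicates are omitted with a
#' message.
#'
#' @param norm a `norm_expr` (or raw `expr_matrix`).
#' @return data.frame of class `qc_report` with columns `stage`,
#'   `condition`, `sample_a`, `sample_b`, `spearman_r`.
#' @export
qc_replicate_correlation <- function(norm) {
  stopifnot(inherits(norm, "expr_matrix"))
  vals <- gene_values(norm)
  groups <- unique(norm$samples[, c("stage", "condition")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    cols <- group_columns(norm, groups$stage[i], groups$condition[i])
    if (length(cols) < 2L) {
      message("group ", groups$stage[i], "/", groups$condition[i],
              " has < 2 replicates; omitted from QC")
      next
    }
    pairs <- utils::combn(cols, 2L)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      out[[length(out) + 1L]] <- data.frame(
        stage = groups$stage[i], condition = groups$condition[i],
        sample_a = colnames(vals)[a], sample_b = colnames(vals)[b],
        spearman_r = stats::cor(vals[, a], vals[, b], method = "spearman")
      )
    }
  }
  if (!length(out)) stop("no group with >= 2 replicates")
  res <- do.call(rbind, out)
  class(res) <- c("qc_report", "data.frame")
  res
}
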
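CLASS_LABELS <- c("maternal_decay", "zygotic_activated", "stable")

#' Three-group transcript classification across two stages
#'
#' Classifies every retained (non-spike-in) gene by its expression change in
#' one condition between two stages, mirroring the canonical
#' maternal-to-zygotic-transition grouping: a gene whose stage-A/stage-B
#' ratio exceeds `fold` is a decaying maternal transcript
#' (`maternal_decay`), one whose stage-B/stage-A ratio exceeds `fold` is a
#' zygotically activated transcript (`zygotic_activated`), and everything
#' else is `stable`. Replicates are aggregated by arithmetic mean before
#' ratios. Inequalities are strict; a ratio exactly at the threshold falls
#' into `stable`, so the three groups always partition the gene universe.
#'
#' Values should be floored (see [floor_and_filter()]) so ratios are finite.
#'
#' @param norm a `norm_expr` object.
#' @param stage_a earlier stage (numerator of the decay ratio).
#' @param stage_b later stage (denominator).
#' @param condition condition in which the dynamics are read (default WT).
#' @param fold strict ratio threshold (> 1); default 2.
#' @return data.frame of class `gene_classification` with columns `gene_id`,
#'   `ratio` (mean stage-A / mean stage-B) and `class` (factor with levels
#'   `maternal_decay`, `zygotic_activated`, `stable`).
#' @export
classify_genes <- function(norm, stage_a = "zygote", stage_b = "2cell",
                           condition = "WT", fold = 2) {
  stopifnot(inherits(norm, "expr_matrix"), fold > 1)
  cols_a <- group_columns(norm, stage_a, condition)
  cols_b <- group_columns(norm, stage_b, condition)
  if (!length(cols_a) || !length(cols_b)) {
    stop("stage/condition group missing: need ", stage_a, " and ", stage_b,
         " in ", condition)
  }
  vals <- gene_values(norm)
  mean_a <- rowMeans(vals[, cols_a, drop = FALSE])
  mean_b <- rowMeans(vals[, cols_b, drop = FALSE])
  ratio <- mean_a / mean_b
  cls <- ifelse(ratio > fold, "maternal_decay",
                ifelse(1 / ratio > fold, "zygotic_activated", "stable"))
  res <- data.frame(
    gene_id = rownames(vals),
    ratio = unname(ratio),
    class = factor(cls, levels = CLASS_LABELS)
  )
  attr(res, "fold") <- fold
  attr(res, "stages") <- c(stage_a, stage_b)
  attr(res, "condition") <- condition
  class(res) <- c("gene_classification", "data.frame")
  res
}

#' Per-group median expression trajectory
#'
#' For each classification group and each stage of one condition, the median
#' over member genes of the replicate-averaged expression value — the
#' summary line drawn through each group's expression profiles.
#'
#' @param norm a `norm_expr` covering the same gene universe as
#'   `classification`.
#' @param classification a [classify_genes()] result.
#' @param condition condition whose samples to summarize.
#' @return data.frame with columns `class`, `stage`, `n_genes`,
#'   `median_expr`; empty groups are flagged with a message and excluded.
#' @export
median_trajectory <- function(norm, classification, condition = "WT") {
  stopifnot(inherits(norm, "expr_matrix"),
            inherits(classification, "gene_classification"))
  vals <- gene_values(norm)
  idx <- match(classification$gene_id, rownames(vals))
  if (anyNA(idx)) stop("classification contains genes absent from matrix")
  stages <- unique(norm$samples$stage[norm$samples$condition == condition])
  if (!length(stages)) stop("condition ", condition, " not present")
  out <- list()
  for (cl in CLASS_LABELS) {
    members <- idx[classification$class == cl]
    if (!length(members)) {
      message("group ", cl, " is empty; excluded from trajectory")
      next
    }
    for (st in stages) {
      cols <- group_columns(norm, st, condition)
      avg <- rowMeans(vals[members, cols, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        class = cl, stage = st, n_genes = length(members),
        median_expr = stats::median(avg)
      )
    }
  }
  do.call(rbind, out)
}

#' Knockdown-to-control median fold change for one group at one stage
#'
#' Ratio of a group's median expression in a test (knockdown) trajectory to
#' the matched control trajectory. Folds above 1 read as "increased by
#' f-fold"; folds below 1 are additionally reported as "decreased by
#' (1/f)-fold", matching how suppression is conventionally quoted.
#'
#' @param trajectory_test,trajectory_ref [median_trajectory()] outputs for
#'   the test (e.g. knockdown) and reference (e.g. WT) conditions.
#' @param group classification group label.
#' @param stage stage label.
#' @return one-row data.frame: `class`, `stage`, `fold_change`
#'   (test/reference), `direction` (`"increased"`/`"decreased"`) and
#'   `reported_fold` (always >= 1, on the quoted scale).
#' @export
median_fold_change <- function(trajectory_test, trajectory_ref,
                               group, stage) {
  pick <- function(tr, what) {
    row <- tr[tr$class == group & tr$stage == stage, "median_expr"]
    if (length(row) != 1L) {
      stop(what, " trajectory lacks group ", group, " at stage ", stage)
    }
    row
  }
  m_test <- pick(trajectory_test, "test")
  m_ref <- pick(trajectory_ref, "reference")
  if (m_ref == 0 || m_test == 0) stop("zero group median; values unfloored?")
  fold <- m_test / m_ref
  data.frame(
    class = group, stage = stage, fold_change = fold,
    direction = if (fold >= 1) "increased" else "decreased",
    reported_fold = if (fold >= 1) fold else 1 / fold
  )
}

#' Fold-threshold differential gene sets between two conditions
#'
#' At one stage, genes whose replicate-mean expression in the test condition
#' exceeds the reference by more than `fold` form the `up` set; genes lower
#' by more than `fold` form the `down` set. Inequalities are strict, so the
#' two sets are disjoint. No dispersion model or FDR is involved — these are
#' the pure fold-change sets used for overlap analyses.
#'
#' @param norm a `norm_expr` with floored values.
#' @param stage stage at which to compare.
#' @param test_condition,ref_condition condition labels.
#' @param fold strict ratio threshold (> 1); default 2.
#' @return object of class `differential_sets`: list with character vectors
#'   `up` and `down`, plus `fold`, `stage`, `conditions` and the `universe`
#'   of gene ids tested.
#' @export
differential_sets <- function(norm, stage, test_condition, ref_condition,
                              fold = 2) {
  stopifnot(inherits(norm, "expr_matrix"), fold > 1)
  cols_t <- group_columns(norm, stage, test_condition)
  cols_r <- group_columns(norm, stage, ref_condition)
  if (!length(cols_t) || !length(cols_r)) {
    stop("condition missing at stage ", stage)
  }
  vals <- gene_values(norm)
  mean_t <- rowMeans(vals[, cols_t, drop = FALSE])
  mean_r <- rowMeans(vals[, cols_r, drop = FALSE])
  ratio <- mean_t / mean_r
  structure(
    list(
      up = rownames(vals)[ratio > fold],
      down = rownames(vals)[1 / ratio > fold],
      fold = fold, stage = stage,
      conditions = c(test = test_condition, reference = ref_condition),
      universe = rownames(vals)
    ),
    class = "differential_sets"
  )
}

#' @export
print.differential_sets <- function(x, ...) {
  cat(sprintf(
    "<differential_sets> %s vs %s at %s (fold > %g): %d up, %d down of %d\n",
    x$conditions[["test"]], x$conditions[["reference"]], x$stage, x$fold,
    length(x$up), length(x$down), length(x$universe)
  ))
  invisible(x)
}
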
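#' Relative qPCR quantification by the delta-delta-CT method
#'
#' For every gene, per-replicate relative expression is
#' `dCT = CT(gene) - CT(reference)`; the condition contrast is
#' `ddCT = mean dCT(test) - mean dCT(reference condition)` and the fold
#' change is `2^-ddCT`. The standard error is computed on the fold scale:
#' each test replicate i yields `fold_i = 2^-(dCT_i - mean dCT(ref))`, and
#' SEM is their standard error (the per-dCT-scale SEM is also returned). A
#' Welch two-sided t-test compares replicate dCT values between conditions.
#' With a single replicate in either condition the fold is still reported
#' but SEM and p are omitted with a notice.
#'
#' @param table data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct_gene`, `ct_reference` (one row per gene x condition x replicate;
#'   `ct_reference` is the same-sample CT of the reference gene, e.g.
#'   Gapdh).
#' @param test_condition,ref_condition condition labels; the fold change is
#'   test relative to reference.
#' @return data.frame with one row per gene: `gene`, `n_test`, `n_ref`,
#'   `ddct`, `fold_change`, `sem_fold`, `sem_ddct`, `p_value`.
#' @examples
#' tab <- generate_qpcr(c("Btg4"), true_fold = 4, ct_noise_sd = 0, seed = 1)
#' ddct_fold_change(tab, "KD", "WT")$fold_change  # exactly 4
#' @export
ddct_fold_change <- function(table, test_condition, ref_condition) {
  required <- c("gene", "condition", "replicate", "ct_gene", "ct_reference")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("qPCR table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(table$ct_gene)) || any(!is.finite(table$ct_reference))) {
    stop("CT values must be finite")
  }
  for (cond in c(test_condition, ref_condition)) {
    if (!any(table$condition == cond)) stop("condition absent: ", cond)
  }
  table$dct <- table$ct_gene - table$ct_reference
  out <- lapply(unique(table$gene), function(g) {
    dct_t <- table$dct[table$gene == g & table$condition == test_condition]
    dct_r <- table$dct[table$gene == g & table$condition == ref_condition]
    if (!length(dct_t) || !length(dct_r)) {
      stop("gene ", g, " missing replicates in one condition")
    }
    ddct <- mean(dct_t) - mean(dct_r)
    fold_i <- 2^-(dct_t - mean(dct_r))
    res <- data.frame(
      gene = g, n_test = length(dct_t), n_ref = length(dct_r),
      ddct = ddct, fold_change = 2^-ddct,
      sem_fold = NA_real_, sem_ddct = NA_real_, p_value = NA_real_
    )
    if (length(dct_t) >= 2L && length(dct_r) >= 2L) {
      res$sem_fold <- stats::sd(fold_i) / sqrt(length(fold_i))
      res$sem_ddct <- stats::sd(dct_t) / sqrt(length(dct_t))
      if (stats::sd(dct_t) > 0 || stats::sd(dct_r) > 0) {
        res$p_value <- stats::t.test(dct_t, dct_r)$p.value
      }
    } else {
      message("gene ", g, ": single replicate; SEM and p-value omitted")
    }
    res
  })
  do.call(rbind, out)
}

#' Background-corrected immunofluorescence antibody signal
#'
#' Quantifies an antibody signal relative to the DNA (DAPI) channel from
#' image measurements, correcting both channels for background and
#' normalizing by the measured areas:
#'
#'   S = A_d (S_a - S_ba) / ( A_a (S_d - S_bd) )
#'
#' where S_a/S_ba are antibody and antibody-background fluorescence,
#' S_d/S_bd DNA and DNA-background fluorescence, and A_a/A_d the measured
#' antibody-signal and DNA areas. S is dimensionless and invariant to joint
#' rescaling of both channels' background-subtracted intensities.
#'
#' @param s_a,s_ba antibody fluorescence and its background (arbitrary
#'   units).
#' @param s_d,s_bd DNA fluorescence and its background.
#' @param a_a,a_d antibody-signal area and DNA area (must be > 0).
#' @return numeric vector of signals S (vectorized over measurements).
#' @export
if_signal <- function(s_a, s_ba, s_d, s_bd, a_a, a_d) {
  if (any(a_a <= 0) || any(a_d <= 0)) stop("areas must be positive")
  if (any(s_d - s_bd <= 0)) {
    stop("DNA fluorescence must exceed its background (S_d > S_bd)")
  }
  a_d * (s_a - s_ba) / (a_a * (s_d - s_bd))
}

#' Compartment proportions of a quantified signal
#'
#' Fraction of a signal residing in the cytoplasm versus the nuclei, from
#' the two compartments' quantified signals (e.g. [if_signal()] values).
#'
#' @param cyto_signal,nuc_signal non-negative quantified signals, not both
#'   zero (vectorized).
#' @return data.frame with columns `cyto_fraction` and `nuc_fraction`
#'   summing to 1 row-wise.
#' @export
compartment_proportion <- function(cyto_signal, nuc_signal) {
  if (any(cyto_signal < 0) || any(nuc_signal < 0)) {
    stop("signals must be non-negative")
  }
  total <- cyto_signal + nuc_signal
  if (any(total == 0)) stop("both compartment signals are zero")
  data.frame(cyto_fraction = cyto_signal / total,
             nuc_fraction = nuc_signal / total)
}
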
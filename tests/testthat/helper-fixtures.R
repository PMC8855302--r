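# Small in-code fixtures and independent brute-force oracles.

# expression matrix from a plain numeric matrix; metadata derived from
# sample ids of the form "<condition>_<stage>_r<i>"
make_expr <- function(values) {
  ids <- colnames(values)
  parts <- strsplit(ids, "_")
  samples <- data.frame(
    sample_id = ids,
    stage = vapply(parts, `[`, "", 2),
    condition = vapply(parts, `[`, "", 1),
    replicate = as.integer(sub("^r", "", vapply(parts, `[`, "", 3)))
  )
  expression_matrix(values, samples)
}

# 2-gene + 1-spike-in convenience matrix
tiny_expr <- function(g1 = c(2, 2, 4, 4), g2 = c(3, 3, 3, 3),
                      spike = c(5, 5, 5, 5)) {
  vals <- rbind(gA = g1, gB = g2, `ERCC-1` = spike)
  colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                      "WT_2cell_r1", "WT_2cell_r2")
  make_expr(vals)
}

# oracle: median-of-ratios spike-in factors, written out naively
oracle_spikein_factors <- function(spike_mat) {
  ref <- apply(spike_mat, 1, function(v) exp(mean(log(v))))
  out <- numeric(ncol(spike_mat))
  for (j in seq_len(ncol(spike_mat))) {
    ratios <- c()
    for (g in seq_len(nrow(spike_mat))) {
      ratios <- c(ratios, ref[g] / spike_mat[g, j])
    }
    out[j] <- median(ratios)
  }
  out
}

# oracle: Spearman correlation as Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# oracle: upper-tail hypergeometric P(X >= k) by direct summation of the
# mass function written with binomial coefficients
oracle_hyper_upper <- function(k, n_a, n_b, n_univ) {
  i <- k:min(n_a, n_b)
  sum(choose(n_a, i) * choose(n_univ - n_a, n_b - i)) / choose(n_univ, n_b)
}

# oracle: upper-tail hypergeometric by exhaustive enumeration of all draws
# of size n_b from the universe (universe small enough for combn)
oracle_hyper_enum <- function(k, n_a, n_b, n_univ) {
  draws <- combn(n_univ, n_b)
  hits <- colSums(draws <= n_a)  # elements 1..n_a form set A
  mean(hits >= k)
}

# oracle: Venn regions by per-element membership tabulation
oracle_venn3 <- function(a, b, c_) {
  ids <- unique(c(a, b, c_))
  counts <- c(a_only = 0, b_only = 0, c_only = 0, ab = 0, ac = 0, bc = 0,
              abc = 0)
  for (id in ids) {
    key <- paste0(if (id %in% a) "a" else "", if (id %in% b) "b" else "",
                  if (id %in% c_) "c" else "")
    key <- switch(key, a = "a_only", b = "b_only", c = "c_only", key)
    counts[key] <- counts[key] + 1
  }
  counts
}
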
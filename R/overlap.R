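#' Named gene set
#'
#' @param members character vector of gene identifiers; duplicates dropped.
#' @param name display name.
#' @param note free-text provenance (threshold rule or file source).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(members, name = "set", note = "") {
  members <- unique(as.character(members))
  structure(list(name = name, members = members, note = note),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members%s\n", x$name, length(x$members),
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

as_gene_set <- function(x, name = "set") {
  if (inherits(x, "gene_set")) x
  else if (inherits(x, "differential_sets")) {
    stop("pass `x$up` or `x$down`, not the differential_sets object")
  } else gene_set(x, name = name)
}

#' Pairwise gene-set overlap with printed-style percentages
#'
#' Intersection count and the overlap expressed as a percentage of each set,
#' rounded to one decimal with the half-up rule (the style in which overlap
#' ratios are quoted, e.g. "3014 out of 3515 (85.7%)"). If a universe size
#' is supplied, the upper-tail hypergeometric enrichment p-value is attached
#' via [hypergeometric_enrichment()].
#'
#' @param set_a,set_b [gene_set()] objects (bare character vectors are
#'   coerced).
#' @param universe_size optional integer universe size for enrichment.
#' @return object of class `overlap_result`: list with `names`, `size_a`,
#'   `size_b`, `intersection`, `fraction_of_a`, `fraction_of_b` (percent,
#'   1 decimal), and when `universe_size` is given `universe_size`,
#'   `p_value`, `log10_p`.
#' @examples
#' a <- gene_set(sprintf("g%d", 1:3515), "up_in_KD")
#' b <- gene_set(sprintf("g%d", 1:3014), "z_decay")
#' overlap_fraction(a, b)$fraction_of_a  # 85.7
#' @export
overlap_fraction <- function(set_a, set_b, universe_size = NULL) {
  set_a <- as_gene_set(set_a, "A"); set_b <- as_gene_set(set_b, "B")
  if (!length(set_a$members) || !length(set_b$members)) {
    stop("overlap fraction undefined for an empty set")
  }
  k <- length(intersect(set_a$members, set_b$members))
  res <- list(
    names = c(set_a$name, set_b$name),
    size_a = length(set_a$members),
    size_b = length(set_b$members),
    intersection = k,
    fraction_of_a = round_half_up(100 * k / length(set_a$members), 1),
    fraction_of_b = round_half_up(100 * k / length(set_b$members), 1)
  )
  if (!is.null(universe_size)) {
    enr <- hypergeometric_enrichment(set_a, set_b, universe_size)
    res$universe_size <- universe_size
    res$p_value <- enr$p_value
    res$log10_p <- enr$log10_p
  }
  structure(res, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %s (n=%d) vs %s (n=%d): %d shared (%.1f%% of %s, %.1f%% of %s)\n",
    x$names[1], x$size_a, x$names[2], x$size_b, x$intersection,
    x$fraction_of_a, x$names[1], x$fraction_of_b, x$names[2]
  ))
  if (!is.null(x$p_value)) {
    cat(sprintf("  enrichment: P = %.3g (log10 P = %.1f), universe N = %d\n",
                x$p_value, x$log10_p, x$universe_size))
  }
  invisible(x)
}

#' Hypergeometric gene-set overlap enrichment
#'
#' Upper-tail probability of observing at least the realized intersection k
#' between two sets drawn without replacement from a universe of size N:
#' P(X >= k) for X ~ Hypergeometric(N, |A|, |B|). Computed in log space so
#' that astronomically significant overlaps (log10 P far below the double
#' underflow limit) remain representable through `log10_p` even when the
#' natural-scale `p_value` underflows to 0.
#'
#' @inheritParams overlap_fraction
#' @param universe_size integer N; must be at least |A union B|.
#' @return list with `intersection` k, `size_a`, `size_b`, `universe_size`,
#'   `p_value` (natural scale) and `log10_p`.
#' @export
hypergeometric_enrichment <- function(set_a, set_b, universe_size) {
  set_a <- as_gene_set(set_a, "A"); set_b <- as_gene_set(set_b, "B")
  n_a <- length(set_a$members); n_b <- length(set_b$members)
  n_union <- length(union(set_a$members, set_b$members))
  if (universe_size < n_union) {
    stop("universe_size (", universe_size, ") smaller than |A union B| (",
         n_union, ")")
  }
  k <- length(intersect(set_a$members, set_b$members))
  # P(X >= k) = upper tail at k-1; log scale via phyper
  log_p <- stats::phyper(k - 1L, n_a, universe_size - n_a, n_b,
                         lower.tail = FALSE, log.p = TRUE)
  list(
    intersection = k, size_a = n_a, size_b = n_b,
    universe_size = universe_size,
    p_value = exp(log_p),
    log10_p = log_p / log(10)
  )
}

#' Three-way Venn region counts
#'
#' Exact counts for the seven regions of a three-set Venn diagram. Regions
#' are exclusive (e.g. `a_only` excludes members of B and C; `ab` excludes
#' C) and sum to |A union B union C|.
#'
#' @param set_a,set_b,set_c [gene_set()] objects or character vectors.
#' @return named integer vector with elements `a_only`, `b_only`, `c_only`,
#'   `ab`, `ac`, `bc`, `abc`.
#' @export
three_way_overlap <- function(set_a, set_b, set_c) {
  a <- as_gene_set(set_a, "A")$members
  b <- as_gene_set(set_b, "B")$members
  c_ <- as_gene_set(set_c, "C")$members
  all_ids <- union(union(a, b), c_)
  in_a <- all_ids %in% a; in_b <- all_ids %in% b; in_c <- all_ids %in% c_
  c(
    a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab = sum(in_a & in_b & !in_c),
    ac = sum(in_a & !in_b & in_c),
    bc = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c)
  )
}
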
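#' Parse one 3'-ligation RACE read into poly(A) / oligo(U) tail calls
#'
#' A 3'-ligation RACE read (sense strand, DNA space) carries a gene-specific
#' anchor, then the mRNA 3' tail, then the ligated linker. The tail grammar
#' is an adenosine run optionally followed by a terminal uridine run (U
#' sequenced as T in cDNA):
#'
#'   ... anchor  A^a  T^u  linker ...
#'
#' The anchor is located as its rightmost match in the read and the linker
#' as its leftmost match after the anchor; the tail is the substring
#' strictly between them. `oligoU_len` is the maximal terminal run of T at
#' the tail's 3' end and `polyA_len` the maximal run of A immediately 5' of
#' it. Any residual bases 5' of the A-run (interleaved or non-A/T tails) set
#' the `parse_ok` flag to FALSE rather than being guessed at.
#'
#' @param read nucleotide string over A/C/G/T/N (one read).
#' @param anchor_seq,linker_seq gene-specific anchor and ligated linker
#'   sequences (A/C/G/T). Defaults are the package's documented synthetic
#'   anchor and the universal miRNA cloning linker.
#' @param max_mismatch allowed mismatches when locating anchor and linker;
#'   default 0 (exact matching, appropriate for Sanger reads of clones).
#' @param read_id identifier carried into the record.
#' @return one-row data.frame (a tail record): `read_id`, `polyA_len`,
#'   `oligoU_len`, `anchor_found`, `linker_found`, `parse_ok`,
#'   `classification` in `A-only`, `A+U`, `U-only`, `no-tail` (NA when the
#'   read could not be parsed).
#' @examples
#' parse_tail(paste0(race_default_anchor(), strrep("A", 15), strrep("T", 4),
#'                   race_default_linker()))
#' @export
parse_tail <- function(read, anchor_seq = race_default_anchor(),
                       linker_seq = race_default_linker(),
                       max_mismatch = 0, read_id = "read") {
  read <- toupper(as.character(read))
  check_dna(anchor_seq, "anchor_seq"); check_dna(linker_seq, "linker_seq")
  if (grepl("[^ACGTN]", read)) stop("read contains non-A/C/G/T/N characters")
  rec <- data.frame(
    read_id = read_id, polyA_len = NA_integer_, oligoU_len = NA_integer_,
    anchor_found = FALSE, linker_found = FALSE, parse_ok = FALSE,
    classification = NA_character_
  )
  anchor_starts <- find_matches(read, anchor_seq, max_mismatch)
  if (!length(anchor_starts)) return(rec)
  rec$anchor_found <- TRUE
  anchor_end <- max(anchor_starts) + nchar(anchor_seq) - 1L
  linker_starts <- find_matches(read, linker_seq, max_mismatch)
  linker_starts <- linker_starts[linker_starts > anchor_end]
  if (!length(linker_starts)) return(rec)
  rec$linker_found <- TRUE
  tail_seq <- substr(read, anchor_end + 1L, min(linker_starts) - 1L)
  u_len <- run_length_at_end(tail_seq, "T")
  a_len <- run_length_at_end(substr(tail_seq, 1L, nchar(tail_seq) - u_len), "A")
  if (a_len + u_len < nchar(tail_seq)) return(rec)  # interior residue
  rec$polyA_len <- a_len
  rec$oligoU_len <- u_len
  rec$parse_ok <- TRUE
  rec$classification <-
    if (a_len > 0 && u_len > 0) "A+U"
    else if (a_len > 0) "A-only"
    else if (u_len > 0) "U-only"
    else "no-tail"
  rec
}

#' Parse a batch of RACE reads (FASTA file or DNAStringSet)
#'
#' @param reads path to a FASTA file or a [Biostrings::DNAStringSet].
#' @inheritParams parse_tail
#' @return data.frame of tail records, one row per read (see
#'   [parse_tail()]).
#' @export
parse_tails <- function(reads, anchor_seq = race_default_anchor(),
                        linker_seq = race_default_linker(),
                        max_mismatch = 0) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads)
  }
  if (inherits(reads, "DNAStringSet")) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    reads <- as.character(reads)
  } else {
    ids <- names(reads) %||% as.character(seq_along(reads))
  }
  recs <- mapply(parse_tail, read = reads, read_id = ids,
                 MoreArgs = list(anchor_seq = anchor_seq,
                                 linker_seq = linker_seq,
                                 max_mismatch = max_mismatch),
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Uridylation frequency by poly(A)-tail-length bin
#'
#' Splits successfully parsed tail records into a short-tail bin
#' (`polyA_len < short_cut`, strict) and a long-tail bin, and reports the
#' fraction of reads in each bin carrying a terminal oligo(U) of at least
#' `min_u` nucleotides. An enrichment of uridylation in the short bin is
#' the signature of stalled decay of deadenylated, uridylated transcripts.
#'
#' @param records data.frame of tail records from [parse_tails()].
#' @param short_cut poly(A)-length cutoff in nucleotides (default 20 nt;
#'   short means strictly below it).
#' @param min_u minimum terminal U-run length (nt) to call a read
#'   uridylated (default 1).
#' @return data.frame with rows `short` and `long`: `bin`, `polyA_range`,
#'   `n_reads`, `n_uridylated`, `uridylation_frequency` (NA for an empty
#'   bin).
#' @export
uridylation_by_tail_bin <- function(records, short_cut = 20, min_u = 1) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("no tail records supplied")
  }
  ok <- records$anchor_found & records$linker_found & records$parse_ok
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0L) stop("no successfully parsed tail records")
  is_short <- records$polyA_len < short_cut
  urid <- records$oligoU_len >= min_u
  summarize_bin <- function(sel) {
    n <- sum(sel)
    data.frame(n_reads = n, n_uridylated = sum(urid & sel),
               uridylation_frequency = if (n) sum(urid & sel) / n else NA_real_)
  }
  out <- cbind(
    data.frame(bin = c("short", "long"),
               polyA_range = c(sprintf("<%g nt", short_cut),
                               sprintf(">=%g nt", short_cut))),
    rbind(summarize_bin(is_short), summarize_bin(!is_short))
  )
  attr(out, "min_u") <- min_u
  out
}

# internal: match start positions, exact via fixed regex, else Biostrings
find_matches <- function(read, pattern, max_mismatch = 0) {
  if (max_mismatch == 0) {
    hits <- gregexpr(pattern, read, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  } else {
    Biostrings::start(Biostrings::matchPattern(
      pattern, Biostrings::DNAString(read), max.mismatch = max_mismatch
    ))
  }
}

run_length_at_end <- function(s, base) {
  n <- nchar(s)
  k <- 0L
  while (k < n && substr(s, n - k, n - k) == base) k <- k + 1L
  k
}

check_dna <- function(s, what) {
  s <- toupper(as.character(s))
  if (!nzchar(s) || grepl("[^ACGT]", s)) {
    stop(what, " must be a non-empty string over A/C/G/T")
  }
  invisible(s)
}

#' Default RACE anchor and linker sequences
#'
#' The default linker is the universal miRNA cloning linker sequence ligated
#' to mRNA 3' ends; the default anchor is a fixed synthetic gene-specific
#' primer-site stand-in used by the read generator. Both are configurable
#' in every function that takes them.
#'
#' @return a nucleotide string.
#' @export
race_default_anchor <- function() "GCTGATTACGCGTTGC"

#' @rdname race_default_anchor
#' @export
race_default_linker <- function() "CTGTAGGCACCATCAAT"
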
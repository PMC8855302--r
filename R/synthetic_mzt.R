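# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an integer `seed` is required (reproducibility is mandatory)")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Parameters of the synthetic maternal-to-zygotic-transition experiment
#'
#' Bundles and validates the knobs of [generate_mzt_experiment()]. Defaults
#' encode a duplicate-sample zygote / late-2-cell design with three
#' transcript classes in roughly the proportions seen in early mouse
#' embryos, a knockdown that stabilizes decaying maternal transcripts
#' 2.32-fold and suppresses zygotic activation 4.37-fold, and moderate
#' log-normal measurement noise.
#'
#' @param n_decay,n_zga,n_stable gene counts per dynamic class
#'   (maternal-decay, zygotic-activated, stable).
#' @param decay_fold true zygote/2-cell abundance ratio of every decay gene
#'   (> 2 so labels are recoverable at zero noise).
#' @param zga_fold true 2-cell/zygote ratio of every activated gene (> 2).
#' @param kd_stabilization multiplicative factor (> 1) applied to decay-gene
#'   2-cell levels in the knockdown condition (stabilized maternal mRNA).
#' @param kd_zga_suppression multiplicative factor in (0, 1) applied to
#'   activated-gene 2-cell levels in the knockdown (failed activation).
#' @param noise_sd standard deviation of log-scale multiplicative noise
#'   applied to every measurement (0 = noise-free).
#' @param n_replicates replicates per stage x condition (>= 1).
#' @param n_spikeins spike-in species count (constant true abundance).
#' @param seed integer random seed; required, no default.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_decay = 300, n_zga = 70, n_stable = 240,
                              decay_fold = 4, zga_fold = 4,
                              kd_stabilization = 2.32,
                              kd_zga_suppression = 1 / 4.37,
                              noise_sd = 0.1, n_replicates = 2,
                              n_spikeins = 20, seed) {
  if (missing(seed)) stop("`seed` is required (reproducibility is mandatory)")
  p <- list(n_decay = n_decay, n_zga = n_zga, n_stable = n_stable,
            decay_fold = decay_fold, zga_fold = zga_fold,
            kd_stabilization = kd_stabilization,
            kd_zga_suppression = kd_zga_suppression,
            noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
            n_spikeins = n_spikeins, seed = seed)
  stopifnot(
    n_decay >= 0, n_zga >= 0, n_stable >= 0, n_spikeins >= 0,
    decay_fold > 2, zga_fold > 2,
    kd_stabilization > 1,
    kd_zga_suppression > 0, kd_zga_suppression < 1,
    noise_sd >= 0
  )
  if (p$n_replicates < 1L) stop("n_replicates must be positive")
  structure(p, class = "simulation_params")
}

#' Generate a synthetic zygote-to-2-cell knockdown experiment
#'
#' Produces an FPKM-scale expression matrix with known ground truth. The
#' design is two stages (`zygote`, `2cell`) x two conditions (`WT`, `KD`)
#' x `n_replicates`. True (pre-noise) abundances per class, with b the
#' gene's baseline drawn log-normally:
#'
#' * maternal decay: zygote = b x decay_fold, WT 2-cell = b, KD 2-cell =
#'   b x kd_stabilization (decay blocked by the knockdown);
#' * zygotic activated: zygote = b, WT 2-cell = b x zga_fold, KD 2-cell =
#'   b x zga_fold x kd_zga_suppression (activation fails);
#' * stable and spike-ins: identical in every sample.
#'
#' Zygote-stage samples are identical in expectation across conditions: the
#' knockdown is delivered at the zygote stage and its effect appears only
#' later. Measured values are true abundance times `exp(N(0, noise_sd))`.
#' Identical parameters (including seed) give bit-identical output.
#'
#' @param params a [simulation_params()] object.
#' @return list of class `mzt_simulation` with elements `matrix` (an
#'   [expression_matrix()]) and `truth` (data.frame: `gene_id`, `class`,
#'   and expected abundance columns `expected_<stage>_<condition>`).
#' @export
generate_mzt_experiment <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  n_genes <- p$n_decay + p$n_zga + p$n_stable
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  classes <- rep(CLASS_LABELS, c(p$n_decay, p$n_zga, p$n_stable))
  spike_ids <- if (p$n_spikeins > 0) {
    sprintf("ERCC-%04d", seq_len(p$n_spikeins))
  } else character(0)

  samples <- expand.grid(
    replicate = seq_len(p$n_replicates),
    stage = c("zygote", "2cell"), condition = c("WT", "KD"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("stage", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$condition,
                               samples$stage, samples$replicate)

  with_seed(p$seed, {
    base <- stats::rlnorm(n_genes, meanlog = log(30), sdlog = 0.8)
    spike_base <- if (p$n_spikeins > 0) {
      stats::rlnorm(p$n_spikeins, meanlog = log(100), sdlog = 1)
    } else numeric(0)

    expected_one <- function(stage, condition) {
      out <- base
      decay <- classes == "maternal_decay"
      zga <- classes == "zygotic_activated"
      if (stage == "zygote") {
        out[decay] <- base[decay] * p$decay_fold
      } else {
        out[zga] <- base[zga] * p$zga_fold
        if (condition == "KD") {
          out[decay] <- base[decay] * p$kd_stabilization
          out[zga] <- out[zga] * p$kd_zga_suppression
        }
      }
      c(out, spike_base)
    }

    expected <- vapply(seq_len(nrow(samples)),
                       function(j) expected_one(samples$stage[j],
                                                samples$condition[j]),
                       numeric(n_genes + p$n_spikeins))
    noise <- if (p$noise_sd > 0) {
      matrix(exp(stats::rnorm(length(expected), 0, p$noise_sd)),
             nrow = nrow(expected))
    } else 1
    values <- expected * noise
    dimnames(values) <- list(c(gene_ids, spike_ids), samples$sample_id)

    truth <- data.frame(gene_id = gene_ids, class = classes)
    for (st in c("zygote", "2cell")) {
      for (cond in c("WT", "KD")) {
        truth[[sprintf("expected_%s_%s", st, cond)]] <-
          expected_one(st, cond)[seq_len(n_genes)]
      }
    }

    structure(
      list(matrix = expression_matrix(values, samples), truth = truth,
           params = p),
      class = "mzt_simulation"
    )
  })
}

#' @export
print.mzt_simulation <- function(x, ...) {
  cat("<mzt_simulation>\n")
  print(x$matrix)
  cat("truth classes:", paste(sprintf("%s=%d", names(table(x$truth$class)),
                                      table(x$truth$class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tail-length sampling scheme for synthetic RACE reads
#'
#' Describes how per-read (poly(A), oligo(U)) lengths are drawn: poly(A)
#' lengths uniform over `polyA_range`; a read is uridylated with probability
#' `urid_prob_short` when its poly(A) is shorter than `short_cut` nt and
#' `urid_prob_long` otherwise (the short-tail enrichment pattern of
#' uridylation-primed decay intermediates); U-run lengths of uridylated
#' reads are uniform over `u_range`.
#'
#' @param polyA_range integer range (min, max) of poly(A) lengths, nt.
#' @param short_cut short-tail cutoff, nt.
#' @param urid_prob_short,urid_prob_long uridylation probabilities per bin.
#' @param u_range integer range of oligo(U) lengths for uridylated reads.
#' @return list of class `race_tail_spec`.
#' @export
race_tail_spec <- function(polyA_range = c(0, 60), short_cut = 20,
                           urid_prob_short = 0.8, urid_prob_long = 0.1,
                           u_range = c(1, 6)) {
  stopifnot(length(polyA_range) == 2L, polyA_range[1] >= 0,
            polyA_range[1] <= polyA_range[2],
            urid_prob_short >= 0, urid_prob_short <= 1,
            urid_prob_long >= 0, urid_prob_long <= 1,
            length(u_range) == 2L, u_range[1] >= 1,
            u_range[1] <= u_range[2])
  structure(list(polyA_range = polyA_range, short_cut = short_cut,
                 urid_prob_short = urid_prob_short,
                 urid_prob_long = urid_prob_long, u_range = u_range),
            class = "race_tail_spec")
}

#' Generate synthetic 3'-ligation RACE reads with known tails
#'
#' Builds DNA-space reads `anchor + A^a + T^u + linker` (U sequenced as T in
#' cDNA) from either an explicit list of (a, u) tail lengths or a
#' [race_tail_spec()] sampling scheme, together with the per-read truth.
#'
#' @param tail_spec either a data.frame with integer columns `polyA_len`
#'   and `oligoU_len` (one row per read) or a [race_tail_spec()].
#' @param n_reads number of reads to draw (required with a
#'   `race_tail_spec`; ignored for an explicit table).
#' @param anchor_seq,linker_seq sequences flanking the tail (A/C/G/T only).
#' @param seed integer seed (required when sampling from a
#'   `race_tail_spec`).
#' @return list with `reads` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame `read_id`, `polyA_len`, `oligoU_len`).
#' @export
generate_race_reads <- function(tail_spec, n_reads = NULL,
                                anchor_seq = race_default_anchor(),
                                linker_seq = race_default_linker(),
                                seed = NULL) {
  check_dna(anchor_seq, "anchor_seq"); check_dna(linker_seq, "linker_seq")
  if (is.data.frame(tail_spec)) {
    stopifnot(all(c("polyA_len", "oligoU_len") %in% names(tail_spec)))
    tails <- tail_spec[, c("polyA_len", "oligoU_len")]
  } else if (inherits(tail_spec, "race_tail_spec")) {
    if (is.null(n_reads) || n_reads < 1L) {
      stop("`n_reads` required when sampling from a race_tail_spec")
    }
    tails <- with_seed(seed, {
      a <- sample(tail_spec$polyA_range[1]:tail_spec$polyA_range[2],
                  n_reads, replace = TRUE)
      p_urid <- ifelse(a < tail_spec$short_cut, tail_spec$urid_prob_short,
                       tail_spec$urid_prob_long)
      urid <- stats::runif(n_reads) < p_urid
      u <- ifelse(urid,
                  sample(tail_spec$u_range[1]:tail_spec$u_range[2],
                         n_reads, replace = TRUE),
                  0L)
      data.frame(polyA_len = a, oligoU_len = u)
    })
  } else {
    stop("`tail_spec` must be a data.frame of tails or a race_tail_spec")
  }
  if (any(tails$polyA_len < 0) || any(tails$oligoU_len < 0)) {
    stop("tail lengths must be >= 0")
  }
  ids <- sprintf("read_%04d", seq_len(nrow(tails)))
  seqs <- paste0(anchor_seq,
                 strrep("A", tails$polyA_len),
                 strrep("T", tails$oligoU_len),
                 linker_seq)
  reads <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  list(reads = reads,
       truth = data.frame(read_id = ids, polyA_len = tails$polyA_len,
                          oligoU_len = tails$oligoU_len))
}

#' Generate a synthetic qPCR CT table with a known fold change
#'
#' Emits per-replicate CT values for each gene in two conditions (`WT`,
#' `KD`) plus the matched reference-gene CTs, such that the expected
#' delta-delta-CT equals `-log2(true_fold)` — i.e. [ddct_fold_change()]
#' recovers `true_fold` exactly at zero noise. Gaussian noise of standard
#' deviation `ct_noise_sd` (cycles) is added independently to every gene
#' and reference CT.
#'
#' @param genes character vector of gene names.
#' @param true_fold true KD/WT fold change (> 0); scalar or one per gene.
#' @param ct_noise_sd CT measurement noise, cycles.
#' @param n_replicates biological replicates per condition (default 3).
#' @param seed integer seed; required.
#' @return data.frame in [ddct_fold_change()] input format, with an extra
#'   `true_fold` column.
#' @export
generate_qpcr <- function(genes, true_fold, ct_noise_sd = 0,
                          n_replicates = 3, seed) {
  if (any(true_fold <= 0)) stop("true_fold must be positive")
  stopifnot(length(genes) >= 1L, n_replicates >= 1L)
  true_fold <- rep_len(true_fold, length(genes))
  with_seed(seed, {
    base_dct <- stats::runif(length(genes), 2, 8)  # WT abundance spread
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        condition = c("WT", "KD"),
                        gene = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- match(grid$gene, genes)
    dct_true <- base_dct[gi] -
      ifelse(grid$condition == "KD", log2(true_fold[gi]), 0)
    ct_reference <- 18 + stats::rnorm(nrow(grid), 0, ct_noise_sd)
    ct_gene <- 18 + dct_true + stats::rnorm(nrow(grid), 0, ct_noise_sd)
    data.frame(gene = grid$gene, condition = grid$condition,
               replicate = grid$replicate,
               ct_gene = ct_gene, ct_reference = ct_reference,
               true_fold = true_fold[gi])
  })
}

#' Generate synthetic immunofluorescence measurements with a known signal
#'
#' Emits raw-measurement rows (fluorescence, background and area per
#' channel) constructed so that [if_signal()] returns `true_signal` times a
#' log-normal noise factor (exactly `true_signal` at zero noise).
#'
#' @param n number of measurements (e.g. embryos).
#' @param true_signal true antibody signal S (> 0); scalar or length n.
#' @param noise_sd log-scale noise on the realized signal.
#' @param seed integer seed; required.
#' @return data.frame with columns `s_a`, `s_ba`, `s_d`, `s_bd`, `a_a`,
#'   `a_d`, `true_signal`.
#' @export
generate_if_measurements <- function(n, true_signal, noise_sd = 0, seed) {
  stopifnot(n >= 1L, all(true_signal > 0), noise_sd >= 0)
  true_signal <- rep_len(true_signal, n)
  with_seed(seed, {
    a_a <- stats::rlnorm(n, log(50), 0.3)
    a_d <- stats::rlnorm(n, log(40), 0.3)
    s_bd <- stats::runif(n, 5, 15)
    s_d <- s_bd + stats::runif(n, 80, 120)
    s_ba <- stats::runif(n, 5, 15)
    realized <- true_signal * exp(stats::rnorm(n, 0, noise_sd))
    s_a <- s_ba + realized * a_a * (s_d - s_bd) / a_d
    data.frame(s_a = s_a, s_ba = s_ba, s_d = s_d, s_bd = s_bd,
               a_a = a_a, a_d = a_d, true_signal = true_signal)
  })
}
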
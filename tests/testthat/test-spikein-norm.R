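test_that("flooring removes all-low genes, floors the rest, spares spike-ins", {
  vals <- rbind(
    low_everywhere = c(0.5, 0.8, 0.2, 0.4),
    partly_low = c(0.5, 3.0, 2.0, 1.5),
    fine = c(2, 3, 4, 5),
    `ERCC-1` = c(0.2, 0.2, 0.2, 0.2)  # spike-ins exempt
  )
  colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                      "WT_2cell_r1", "WT_2cell_r2")
  ff <- floor_and_filter(make_expr(vals))

  expect_false("low_everywhere" %in% rownames(ff$values))
  expect_identical(ff$excluded_gene_ids, "low_everywhere")
  expect_equal(unname(ff$values["partly_low", ]), c(1, 3, 2, 1.5))
  expect_equal(unname(ff$values["ERCC-1", ]), rep(0.2, 4))
  expect_true(ff$floored)

  # idempotence
  ff2 <- floor_and_filter(ff)
  expect_equal(ff2$values, ff$values)
  expect_identical(ff2$excluded_gene_ids, ff$excluded_gene_ids)

  # matrix already >= 1 is untouched
  ok <- floor_and_filter(tiny_expr())
  expect_equal(ok$values, tiny_expr()$values)
  expect_length(ok$excluded_gene_ids, 0)
})

test_that("spike-in factors: identity, scale equivariance, oracle match", {
  # identical spike-in columns -> all factors 1
  expect_equal(as.numeric(compute_spikein_factors(tiny_expr())), rep(1, 4))

  # doubling one sample's spike-ins: its factor compensates by the inverse,
  # scaled by the shared geometric-mean shift 2^(1/4)
  m <- tiny_expr(spike = c(10, 5, 5, 5))
  f <- compute_spikein_factors(m)
  expect_equal(unname(f[1] / f[2]), 0.5)

  # randomized 5-spike-in x 4-sample table vs naive oracle
  set.seed(101)
  for (rep in 1:5) {
    sp <- matrix(runif(20, 0.5, 50), 5, 4)
    vals <- rbind(matrix(runif(12, 1, 100), 3, 4), sp)
    rownames(vals) <- c("g1", "g2", "g3", paste0("ERCC-", 1:5))
    colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                        "WT_2cell_r1", "WT_2cell_r2")
    x <- make_expr(vals)
    expect_equal(as.numeric(compute_spikein_factors(x)),
                 oracle_spikein_factors(sp))
  }
})

test_that("normalization equalizes spike-ins and is scale invariant", {
  set.seed(7)
  vals <- rbind(matrix(runif(20, 1, 100), 5, 4),
                matrix(runif(12, 5, 50), 3, 4))
  rownames(vals) <- c(paste0("g", 1:5), paste0("ERCC-", 1:3))
  colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                      "WT_2cell_r1", "WT_2cell_r2")
  x <- make_expr(vals)
  norm <- normalize_spikeins(x)

  # after scaling, every sample's median spike-in ratio to the stored
  # normalization reference is exactly 1
  sp <- norm$values[norm$spikein, ]
  for (j in 1:4) {
    expect_equal(median(norm$spikein_reference / sp[, j]), 1,
                 tolerance = 1e-12)
  }

  # multiplying one sample column by c > 0 rescales all normalized values
  # by one common constant only: every ratio, and hence every downstream
  # result, is unchanged
  vals2 <- vals
  vals2[, 2] <- vals2[, 2] * 7.3
  norm2 <- normalize_spikeins(make_expr(vals2))
  rel <- norm2$values / norm$values
  expect_equal(max(rel) / min(rel), 1, tolerance = 1e-12)
  expect_equal(total_copy_change(norm2, "zygote", "WT"),
               total_copy_change(norm, "zygote", "WT"))
})

test_that("spike-in edge cases: zeros as missing, all-zero sample fatal", {
  m <- tiny_expr(spike = c(5, 5, 5, 5))
  m$values <- rbind(m$values, `ERCC-2` = c(0, 8, 8, 8))
  m$spikein <- c(m$spikein, TRUE)
  f <- compute_spikein_factors(m)  # zero ignored, not ratio Inf
  expect_true(all(is.finite(f)))

  bad <- tiny_expr(spike = c(0, 5, 5, 5))
  expect_error(compute_spikein_factors(bad), "all-zero spike-ins")
  nosp <- tiny_expr()
  nosp$values <- nosp$values[1:2, ]
  nosp$spikein <- c(FALSE, FALSE)
  expect_error(compute_spikein_factors(nosp), "no spike-in")
})

test_that("total copy change anchors at baseline and tracks global scaling", {
  x <- tiny_expr()
  norm <- normalize_expression(x)
  tc <- total_copy_change(norm, "zygote", "WT")
  expect_equal(tc$relative_total[tc$stage == "zygote"], 1.0)

  # every 2-cell gene value double the zygote value, spike-ins constant
  vals <- rbind(g1 = c(10, 10, 20, 20), g2 = c(4, 4, 8, 8),
                `ERCC-1` = c(6, 6, 6, 6))
  colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                      "WT_2cell_r1", "WT_2cell_r2")
  tc2 <- total_copy_change(normalize_spikeins(make_expr(vals)), "zygote", "WT")
  expect_equal(tc2$relative_total[tc2$stage == "2cell"], 2.0)

  expect_error(total_copy_change(norm, "8cell", "WT"), "not present")

  # row-permutation invariance
  perm <- x
  ord <- c(2, 3, 1)
  perm$values <- perm$values[ord, ]
  perm$spikein <- perm$spikein[ord]
  expect_equal(total_copy_change(normalize_spikeins(perm), "zygote", "WT"),
               tc)
})

test_that("knockdown stabilization raises the KD 2-cell total over WT", {
  sim <- generate_mzt_experiment(simulation_params(noise_sd = 0, seed = 11))
  norm <- normalize_expression(sim$matrix, floor = FALSE)
  tc <- total_copy_change(norm, "zygote", "WT")

  # oracle: direct sum of the truth table's expected abundances
  truth_total <- function(col) sum(sim$truth[[col]])
  expect_equal(
    tc$relative_total[tc$stage == "2cell" & tc$condition == "KD"],
    truth_total("expected_2cell_KD") / truth_total("expected_zygote_WT")
  )
  expect_gt(tc$relative_total[tc$stage == "2cell" & tc$condition == "KD"],
            tc$relative_total[tc$stage == "2cell" & tc$condition == "WT"])
})

test_that("replicate Spearman QC matches the rank-formula oracle", {
  x <- tiny_expr()
  qc <- qc_replicate_correlation(x)
  expect_true(all(qc$spearman_r >= -1 & qc$spearman_r <= 1))

  # duplicate columns -> rs = 1
  dup <- tiny_expr(g1 = c(5, 5, 9, 9), g2 = c(2, 2, 7, 7))
  expect_equal(qc_replicate_correlation(dup)$spearman_r, rep(1, 2))

  # rank reversal -> rs = -1
  vals <- rbind(g1 = c(1, 9), g2 = c(5, 5), g3 = c(9, 1))
  vals <- cbind(vals, vals[, 1:2])  # pad to reuse metadata shape
  colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                      "WT_2cell_r1", "WT_2cell_r2")
  qc_rev <- qc_replicate_correlation(make_expr(vals))
  expect_equal(qc_rev$spearman_r[qc_rev$stage == "zygote"], -1)

  # random 10-gene pairs vs oracle, with ties
  set.seed(21)
  for (rep in 1:5) {
    vals <- matrix(sample(1:8, 40, replace = TRUE), 10, 4)
    rownames(vals) <- paste0("g", 1:10)
    colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                        "WT_2cell_r1", "WT_2cell_r2")
    qc <- qc_replicate_correlation(make_expr(vals))
    z <- qc[qc$stage == "zygote", ]
    expect_equal(z$spearman_r, oracle_spearman(vals[, 1], vals[, 2]))
  }

  # groups with a single replicate are dropped with a message
  single <- tiny_expr()
  single$values <- single$values[, c(1, 3, 4)]
  single$samples <- single$samples[c(1, 3, 4), ]
  expect_message(qc1 <- qc_replicate_correlation(single), "omitted")
  expect_true(all(qc1$stage == "2cell"))
})
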
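test_that("classification thresholds, boundary convention and partition", {
  vals <- rbind(
    decay = c(6, 6, 2, 2),       # ratio 3 -> maternal_decay
    zga = c(2, 2, 5, 5),         # 1/r = 2.5 -> zygotic_activated
    boundary_up = c(4, 4, 2, 2), # ratio exactly 2 -> stable
    boundary_dn = c(2, 2, 4, 4), # 1/r exactly 2 -> stable
    flat = c(3, 3, 3, 3),
    `ERCC-1` = c(5, 5, 5, 5)
  )
  colnames(vals) <- c("WT_zygote_r1", "WT_zygote_r2",
                      "WT_2cell_r1", "WT_2cell_r2")
  cl <- classify_genes(floor_and_filter(make_expr(vals)))
  got <- setNames(as.character(cl$class), cl$gene_id)
  expect_identical(got[["decay"]], "maternal_decay")
  expect_identical(got[["zga"]], "zygotic_activated")
  expect_identical(got[["boundary_up"]], "stable")
  expect_identical(got[["boundary_dn"]], "stable")
  expect_identical(got[["flat"]], "stable")
  expect_false("ERCC-1" %in% cl$gene_id)

  # partition property: group sizes always sum to the retained universe
  expect_equal(sum(table(cl$class)), 5)
})

test_that("swapping the two stages swaps decay and activated exactly", {
  sim <- generate_mzt_experiment(simulation_params(seed = 5))
  norm <- normalize_expression(sim$matrix)
  fwd <- classify_genes(norm, "zygote", "2cell")
  rev <- classify_genes(norm, "2cell", "zygote")
  expect_setequal(fwd$gene_id[fwd$class == "maternal_decay"],
                  rev$gene_id[rev$class == "zygotic_activated"])
  expect_setequal(fwd$gene_id[fwd$class == "zygotic_activated"],
                  rev$gene_id[rev$class == "maternal_decay"])
  expect_setequal(fwd$gene_id[fwd$class == "stable"],
                  rev$gene_id[rev$class == "stable"])
})

test_that("zero-noise synthetic labels are recovered perfectly", {
  sim <- generate_mzt_experiment(simulation_params(noise_sd = 0, seed = 2))
  norm <- normalize_expression(sim$matrix)
  cl <- classify_genes(norm)
  expect_identical(as.character(cl$class[match(sim$truth$gene_id,
                                               cl$gene_id)]),
                   sim$truth$class)
})

test_that("median trajectories match a sort-and-pick oracle", {
  sim <- generate_mzt_experiment(simulation_params(
    n_decay = 20, n_zga = 10, n_stable = 15, seed = 9))
  norm <- normalize_expression(sim$matrix)
  cl <- classify_genes(norm)
  tr <- median_trajectory(norm, cl, "WT")

  vals <- norm$values[!norm$spikein, ]
  for (i in seq_len(nrow(tr))) {
    members <- cl$gene_id[cl$class == tr$class[i]]
    cols <- grep(paste0("^WT_", tr$stage[i]), colnames(vals))
    avg <- sort(rowMeans(vals[members, cols, drop = FALSE]))
    n <- length(avg)
    med <- if (n %% 2) avg[(n + 1) / 2] else (avg[n / 2] + avg[n / 2 + 1]) / 2
    expect_equal(tr$median_expr[i], unname(med))
  }

  # singleton and small-group medians
  vals2 <- rbind(one = c(8, 8, 2, 2), a = c(1, 1, 5, 5), b = c(1, 1, 25, 25),
                 c = c(1, 1, 500, 500), `ERCC-1` = c(5, 5, 5, 5))
  colnames(vals2) <- c("WT_zygote_r1", "WT_zygote_r2",
                       "WT_2cell_r1", "WT_2cell_r2")
  x2 <- floor_and_filter(make_expr(vals2))
  cl2 <- classify_genes(x2)
  # the stable group is empty here: flagged and excluded, others computed
  expect_message(tr2 <- median_trajectory(x2, cl2, "WT"), "empty")
  expect_false("stable" %in% tr2$class)
  expect_equal(tr2$median_expr[tr2$class == "maternal_decay" &
                                 tr2$stage == "zygote"], 8)
  expect_equal(tr2$median_expr[tr2$class == "zygotic_activated" &
                                 tr2$stage == "2cell"], 25)
})

test_that("median fold change: identity, scaling, parameter recovery", {
  sim <- generate_mzt_experiment(simulation_params(seed = 3))
  norm <- normalize_expression(sim$matrix)
  cl <- classify_genes(norm)
  tr_wt <- median_trajectory(norm, cl, "WT")
  expect_equal(
    median_fold_change(tr_wt, tr_wt, "maternal_decay", "2cell")$fold_change,
    1.0
  )

  tr3 <- tr_wt
  tr3$median_expr <- tr3$median_expr * 3
  fc <- median_fold_change(tr3, tr_wt, "stable", "zygote")
  expect_equal(fc$fold_change, 3.0)
  expect_identical(fc$direction, "increased")

  # suppression is reported on the "decreased by f-fold" scale
  fc_dn <- median_fold_change(tr_wt, tr3, "stable", "zygote")
  expect_equal(fc_dn$fold_change, 1 / 3)
  expect_equal(fc_dn$reported_fold, 3.0)
  expect_identical(fc_dn$direction, "decreased")

  # low-noise knockdown recovers the stabilization factor within 10%
  sim_kd <- generate_mzt_experiment(simulation_params(
    kd_stabilization = 2.3, noise_sd = 0.05, seed = 17))
  norm_kd <- normalize_expression(sim_kd$matrix)
  cl_kd <- classify_genes(norm_kd)
  fold <- median_fold_change(
    median_trajectory(norm_kd, cl_kd, "KD"),
    median_trajectory(norm_kd, cl_kd, "WT"),
    "maternal_decay", "2cell"
  )$fold_change
  expect_lt(abs(fold - 2.3) / 2.3, 0.10)
})

test_that("differential sets: thresholds, disjointness, truth recovery", {
  # identical conditions -> both sets empty
  vals <- rbind(g1 = c(2, 2, 2, 2), g2 = c(7, 7, 7, 7),
                `ERCC-1` = c(5, 5, 5, 5))
  colnames(vals) <- c("WT_2cell_r1", "WT_2cell_r2",
                      "KD_2cell_r1", "KD_2cell_r2")
  ds0 <- differential_sets(make_expr(vals), "2cell", "KD", "WT")
  expect_length(ds0$up, 0)
  expect_length(ds0$down, 0)

  # 4.2 vs 2.0 -> ratio 2.1 > 2 -> up; boundary ratio 2 stays out
  vals2 <- rbind(up = c(2, 2, 4.2, 4.2), edge = c(2, 2, 4, 4),
                 `ERCC-1` = c(5, 5, 5, 5))
  colnames(vals2) <- colnames(vals)
  ds1 <- differential_sets(make_expr(vals2), "2cell", "KD", "WT")
  expect_identical(ds1$up, "up")
  expect_length(ds1$down, 0)

  # zero-noise knockdown: up = decay truth set, down = activated truth set
  sim <- generate_mzt_experiment(simulation_params(noise_sd = 0, seed = 4))
  norm <- normalize_expression(sim$matrix)
  ds <- differential_sets(norm, "2cell", "KD", "WT")
  expect_setequal(ds$up,
                  sim$truth$gene_id[sim$truth$class == "maternal_decay"])
  expect_setequal(ds$down,
                  sim$truth$gene_id[sim$truth$class == "zygotic_activated"])
  expect_length(intersect(ds$up, ds$down), 0)

  # up-set shrinks monotonically in the fold threshold
  sizes <- vapply(c(1.5, 2, 2.5, 3, 4),
                  function(f) length(differential_sets(norm, "2cell", "KD",
                                                       "WT", fold = f)$up),
                  1L)
  expect_true(all(diff(sizes) <= 0))
})
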
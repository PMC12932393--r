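test_that("pseudobulk aggregation sums cells and conserves totals", {
  counts <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
                   dimnames = list(c("gA", "gB"), paste0("cell", 1:3)))
  pb <- pseudobulk_aggregate(counts, rep("MG1", 3), rep("s1", 3))
  expect_equal(unname(pb$MG1$expr[, "s1"]), c(9, 12))
  expect_equal(unname(pb$MG1$cell_counts["s1"]), 3L)

  # splitting cells into batches and re-aggregating gives the same totals
  set.seed(90)
  big <- matrix(rpois(5 * 30, 4), 5, 30,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:30)))
  states <- sample(c("MG1", "MG2"), 30, TRUE)
  samples <- sample(c("s1", "s2"), 30, TRUE)
  pb1 <- pseudobulk_aggregate(big, states, samples)
  ord <- sample(30)
  pb2 <- pseudobulk_aggregate(big[, ord], states[ord], samples[ord])
  expect_equal(pb1, pb2)
  # aggregation conserves total cell counts
  expect_equal(sum(vapply(pb1, function(x) sum(x$cell_counts), numeric(1))), 30)
  # empty state/sample combination yields zeros with count 0
  pb3 <- pseudobulk_aggregate(big[, 1:2, drop = FALSE], c("MG1", "MG1"),
                              c("s1", "s1"))
  expect_equal(unname(pb3$MG1$cell_counts), 2L)
})

test_that("state proportions normalize, exclude rare states, and test shifts", {
  set.seed(91)
  groups <- rep(c("Control", "LOAD-S1", "LOAD-S2"), each = 30)
  n <- length(groups)
  base <- rbind(MG1 = 400, MG2 = 300, MG3 = 200, MG4 = 3)
  cc <- matrix(rpois(4 * n, base), 4, n, dimnames = list(rownames(base), NULL))
  cc["MG2", groups == "LOAD-S1"] <- rpois(30, 450)   # planted +proportion shift
  colnames(cc) <- paste0("s", 1:n)
  sp <- state_proportions(cc, groups)
  expect_equal(unname(colSums(sp$proportions)), rep(1, n))
  expect_true("MG4" %in% sp$excluded)    # < 100 cells in at least one group
  expect_false("MG4" %in% names(sp$tests))
  tk <- sp$tests$MG2$tukey
  expect_lt(min(tk$p_adj[grepl("LOAD-S1", tk$comparison)]), 0.05)

  # a state with exactly 99 cells in one group is excluded
  cc2 <- cc
  cc2["MG3", ] <- 5
  cc2["MG3", groups == "Control"] <- c(9, rep(3, 29))  # 96 cells in controls
  expect_true("MG3" %in% state_proportions(cc2, groups)$excluded)
})

test_that("control-anchored PCA removes outliers and uses control statistics only", {
  study <- small_study()
  mg <- study$microglia
  st <- names(mg$pseudobulk)[1]
  proj <- control_pca_projection(mg$pseudobulk[[st]], mg$samples$group)
  expect_s3_class(proj, "pca_projection")
  expect_equal(nrow(proj$scores), nrow(mg$samples))

  # a control with large per-gene distortions (not a depth change, which
  # normalization removes) is flagged and removed
  pb <- mg$pseudobulk[[st]]
  spike <- pb
  ctrl_ids <- mg$samples$sample_id[mg$samples$group == "Control"]
  set.seed(93)
  spike[, ctrl_ids[1]] <- round(spike[, ctrl_ids[1]] *
                                  2^rnorm(nrow(spike), 0, 4))
  proj2 <- control_pca_projection(spike, mg$samples$group)
  expect_true(ctrl_ids[1] %in% proj2$outliers)

  # multiplying the subtype samples never changes control-derived loadings
  mod <- pb
  s1_ids <- mg$samples$sample_id[mg$samples$group == "LOAD-S1"]
  mod[, s1_ids] <- mod[, s1_ids] * 5
  proj3 <- control_pca_projection(mod, mg$samples$group)
  expect_equal(proj3$rotation, proj$rotation, tolerance = 1e-6)
  expect_equal(proj3$scores[ctrl_ids, ], proj$scores[ctrl_ids, ],
               tolerance = 1e-6)
})

test_that("the permutation separation test hits its floor and is deterministic", {
  set.seed(92)
  scores <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 10), 10, 2))
  groups <- rep(c("a", "b"), each = 10)
  res <- permutation_separation_test(scores, groups, n_perm = 500, seed = 3)
  expect_equal(res$p, 1 / 501)
  expect_true(res$observed > res$null_hi)
  res2 <- permutation_separation_test(scores, groups, n_perm = 500, seed = 3)
  expect_identical(res$p, res2$p)
  expect_error(permutation_separation_test(scores, groups, n_perm = 50), "100")
  # centroid statistic is available and agrees qualitatively
  resc <- permutation_separation_test(scores, groups, n_perm = 500, seed = 3,
                                      stat = "centroid")
  expect_equal(resc$p, 1 / 501)
})

test_that("activation scores standardize on controls and detect marker shifts", {
  study <- small_study()
  mg <- study$microglia
  st <- names(mg$truth$state_shift)[1]       # the shifted state
  act <- activation_scores(mg$pseudobulk[[st]], mg$markers[[st]],
                           mg$samples$group)
  ctrl <- mg$samples$group == "Control"
  expect_equal(mean(act$z[ctrl]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(act$z[ctrl]), 1, tolerance = 1e-10)
  # a sample made uniformly highest on every marker gets the top score
  boost <- mg$pseudobulk[[st]]
  mk_rows <- mg$markers[[st]]
  boost[mk_rows, 7] <- apply(boost[mk_rows, , drop = FALSE], 1, max) * 4
  act_b <- activation_scores(boost, mk_rows, mg$samples$group)
  expect_equal(unname(which.max(act_b$score)), 7L)
  # orientation contract: score correlates positively with marker mean
  lc <- tmm_logcpm(mg$pseudobulk[[st]])$logcpm
  expect_gt(stats::cor(act$score, colMeans(lc[mk_rows, ])), 0)
  # planted +1 shift in LOAD-S1: S1 vs S2 t-test significant
  expect_lt(act$t_test$p.value, 0.01)
  expect_gt(mean(act$z[mg$samples$group == "LOAD-S1"]),
            mean(act$z[mg$samples$group == "LOAD-S2"]))
})

test_that("pseudobulk DEA applies the dual-significance rule per state", {
  study <- small_study()
  mg <- study$microglia
  pb <- lapply(mg$pseudobulk, function(m) list(expr = m))
  groups <- stats::setNames(mg$samples$group, mg$samples$sample_id)
  dea <- pseudobulk_dea(pb, groups)
  st <- names(mg$truth$state_shift)[1]
  tab <- dea[[st]]
  # the rule: flagged iff significant subtype-vs-subtype AND vs control
  manual <- tab$p_s1_s2 < 0.05 &
    ((!is.na(tab$p_s1_ctrl) & tab$p_s1_ctrl < 0.05) |
       (!is.na(tab$p_s2_ctrl) & tab$p_s2_ctrl < 0.05))
  expect_equal(tab$flagged, manual)
  # shifted-state markers are enriched among flagged genes
  mk <- intersect(mg$markers[[st]], tab$gene)
  expect_gt(mean(tab$flagged[tab$gene %in% mk]),
            mean(tab$flagged[!tab$gene %in% mk]))
})

test_that("morphology comparisons match closed-form Welch and Cohen values", {
  tab <- data.frame(donor = paste0("d", 1:6), region = "IT",
                    group = rep(c("g1", "g2"), each = 3),
                    pam = c(1, 2, 3, 4, 5, 6) / 10,
                    stage3 = c(1, 2, 3, 4, 5, 6))
  res <- morphology_compare(tab)
  row <- res[res$measure == "stage3", ]
  expect_equal(row$cohens_d, -3)                  # groups {1,2,3} vs {4,5,6}
  expect_equal(abs(row$t), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(row$df, 4, tolerance = 1e-10)
  # identical groups: d = 0, p = 1
  tab2 <- tab; tab2$pam <- rep(c(1, 2, 3) / 10, 2); tab2$stage3 <- rep(1:3, 2)
  res2 <- morphology_compare(tab2)
  expect_equal(res2$cohens_d, c(0, 0))
  expect_equal(res2$p, c(1, 1))
  # BH family is per measure across regions and pairs
  study <- small_study()
  mo <- morphology_compare(study$morphology)
  for (ms in unique(mo$measure)) {
    idx <- mo$measure == ms
    expect_equal(mo$p_adj[idx], stats::p.adjust(mo$p[idx], "BH"))
  }
  # single-donor groups are skipped
  tab3 <- rbind(tab, data.frame(donor = "d7", region = "IT", group = "g3",
                                pam = 0.5, stage3 = 5))
  res3 <- morphology_compare(tab3)
  expect_false(any(res3$group2 == "g3" | res3$group1 == "g3"))
})
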
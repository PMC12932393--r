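# Independent dense PLS-DA oracle: power iteration on X'Y Y'X with explicit
# deflation, no sparsity.
dense_pls_oracle <- function(X, y, ncomp) {
  Xc <- scale(X)
  Y <- stats::model.matrix(~ factor(y) - 1)
  Yc <- scale(Y, scale = FALSE)
  scores <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc) %*% crossprod(Yc, Xc)
    w <- rnorm(ncol(Xc))
    for (it in 1:2000) w <- { v <- M %*% w; v / sqrt(sum(v^2)) }
    tt <- Xc %*% w
    scores[, h] <- tt
    pl <- crossprod(Xc, tt) / sum(tt^2)
    Xc <- Xc - tt %*% t(pl)
    Yc <- Yc - tt %*% t(crossprod(Yc, tt) / sum(tt^2))
  }
  scores
}

test_that("keep = 1 selects the brute-force best single-feature discriminant", {
  set.seed(20)
  y <- rep(c("a", "b"), each = 10)
  X <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[, 4] <- X[, 4] + ifelse(y == "a", 2, -2)
  best <- names(which.max(abs(apply(scale(X), 2, function(col)
    stats::cor(col, as.numeric(factor(y)))))))
  fit <- fit_splsda(X, y, n_components = 1, keep_per_component = 1)
  expect_identical(selected_features(fit)$per_component[[1]], best)
  expect_identical(best, "f4")
})

test_that("the dense limit matches a power-iteration oracle on small matrices", {
  set.seed(21)
  X <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("a", "b"), each = 5)
  fit <- fit_splsda(X, y, n_components = 3, keep_per_component = 8)
  oracle <- dense_pls_oracle(X, y, 3)
  for (h in 1:3) {
    s <- sign(sum(fit$scores[, h] * oracle[, h]))
    expect_lt(max(abs(fit$scores[, h] - s * oracle[, h])), 1e-8)
  }
})

test_that("the dense fit agrees with the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  set.seed(22)
  X <- matrix(rnorm(12 * 9), 12, 9, dimnames = list(NULL, paste0("f", 1:9)))
  y <- rep(c("a", "b", "c"), each = 4)
  fit <- fit_splsda(X, y, n_components = 2, keep_per_component = 9)
  mo <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(9, 9))
  for (h in 1:2)
    expect_gt(abs(stats::cor(fit$scores[, h], mo$variates$X[, h])), 1 - 1e-8)
  # sparse: selected supports agree component-wise
  fit_s <- fit_splsda(X, y, n_components = 2, keep_per_component = 3)
  mo_s <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(3, 3))
  for (h in 1:2)
    expect_setequal(selected_features(fit_s)$per_component[[h]],
                    rownames(mo_s$loadings$X)[mo_s$loadings$X[, h] != 0])
})

test_that("selection counting and set algebra behave as expected", {
  set.seed(23)
  X <- matrix(rnorm(30 * 50), 30, 50, dimnames = list(NULL, paste0("f", 1:50)))
  y <- rep(c("a", "b"), each = 15)
  fit <- fit_splsda(X, y, n_components = 4, keep_per_component = 5)
  sel <- selected_features(fit)
  expect_true(all(lengths(sel$per_component) == 5))
  expect_lte(length(sel$union), 4 * 5)
  fit1 <- fit_splsda(X, y, n_components = 1, keep_per_component = 5)
  expect_identical(selected_features(fit1)$union,
                   selected_features(fit1)$per_component[[1]])
})

test_that("component scores are pairwise uncorrelated and weights unit-norm", {
  set.seed(24)
  X <- matrix(rnorm(40 * 100), 40, 100, dimnames = list(NULL, paste0("f", 1:100)))
  y <- rep(c("a", "b"), each = 20)
  fit <- fit_splsda(X, y, n_components = 4, keep_per_component = 20)
  cc <- stats::cor(fit$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 4))
})

test_that("projection is exact on training data and stable to duplication", {
  set.seed(25)
  X <- matrix(rnorm(20 * 30), 20, 30, dimnames = list(paste0("s", 1:20),
                                                      paste0("f", 1:30)))
  y <- rep(c("a", "b"), each = 10)
  fit <- fit_splsda(X, y, n_components = 2, keep_per_component = 10)
  expect_lt(max(abs(project_splsda(fit, X) - fit$scores)), 1e-10)
  Xd <- X[c(1, 1, 5), ]
  pr <- project_splsda(fit, Xd)
  expect_equal(pr[1, ], pr[2, ])
  # too few shared selected features is an error
  sel <- selected_features(fit)$union
  Xm <- X[, setdiff(colnames(X), sel[-(1:2)]), drop = FALSE]
  expect_error(project_splsda(fit, Xm), "shared")
})

test_that("feature scaling by a positive constant leaves selection unchanged", {
  set.seed(26)
  X <- matrix(rnorm(24 * 40), 24, 40, dimnames = list(NULL, paste0("f", 1:40)))
  y <- rep(c("a", "b"), each = 12)
  fit1 <- fit_splsda(X, y, n_components = 2, keep_per_component = 6)
  X2 <- X
  X2[, 7] <- X2[, 7] * 50
  X2[, 13] <- X2[, 13] * 0.01
  fit2 <- fit_splsda(X2, y, n_components = 2, keep_per_component = 6)
  expect_identical(selected_features(fit1)$per_component,
                   selected_features(fit2)$per_component)
})

test_that("the 450K-masked cohort keeps planted clusters separated after projection", {
  run <- full_pipeline_run()
  study <- run$study
  ann1 <- study$samples[[1]]
  ann3 <- study$samples[[3]]
  shared <- intersect(rownames(study$beta[[1]]), rownames(study$beta[[3]]))
  r1 <- residualize(study$beta[[1]], ann1[, c("age", "sex", "prop_neuron", "batch")])
  r3 <- residualize(study$beta[[3]], ann3[, c("age", "sex", "prop_neuron", "batch")])
  load1 <- ann1$sample_id[ann1$truth %in% c("LOAD-S1", "LOAD-S2")]
  load3 <- ann3$sample_id[ann3$truth %in% c("LOAD-S1", "LOAD-S2")]
  fit <- fit_splsda(t(r1[shared, load1]), ann1$truth[match(load1, ann1$sample_id)],
                    n_components = 2, keep_per_component = 500)
  sc <- project_splsda(fit, t(r3[shared, load3]))
  expect_gt(mean_silhouette(sc, ann3$truth[match(load3, ann3$sample_id)]), 0.2)
})

test_that("label randomization erodes feature-selection overlap monotonically", {
  set.seed(27)
  n <- 60; p <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 1:30] <- X[, 1:30] + ifelse(y == "a", 1.5, -1.5)
  rc <- randomization_robustness(X, y, n_components = 2,
                                 keep_per_component = 30,
                                 proportions = c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                                 n_repeats = 10, seed = 5)
  expect_equal(unname(rc$mean_overlap[1]), 1)       # no randomization
  expect_lt(rc$mean_overlap["p1"], rc$mean_overlap["p0.05"])
  trend <- stats::cor.test(rc$proportions, rc$mean_overlap, method = "spearman")
  expect_lt(trend$estimate, 0)
  expect_lt(trend$p.value, 0.05)
  # seeded reproducibility
  rc2 <- randomization_robustness(X, y, n_components = 2,
                                  keep_per_component = 30,
                                  proportions = c(0, 0.5, 1), n_repeats = 3,
                                  seed = 5)
  expect_identical(rc2$overlap[, "p1"],
                   randomization_robustness(X, y, 2, 30, c(0, 0.5, 1), 3, 5)$overlap[, "p1"])
})
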
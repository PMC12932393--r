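test_that("low-expression filter applies the strict-fraction rule", {
  counts <- rbind(
    removed = c(rep(9, 9), 100),       # low in 9/10 > 0.8
    kept = c(rep(9, 8), 100, 100),     # low in exactly 8/10, boundary kept
    high = rep(50, 10))
  out <- filter_low_expression(counts)
  expect_identical(rownames(out), c("kept", "high"))
  allzero <- matrix(0, 3, 4)
  expect_equal(nrow(filter_low_expression(allzero)), 0)
})

test_that("TMM factors match a hand computation and logCPM is depth-invariant", {
  set.seed(70)
  counts <- matrix(rnbinom(6 * 4, mu = 200, size = 5) + 1, 6, 4,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  res <- tmm_logcpm(counts)
  expect_equal(prod(res$factors), 1, tolerance = 1e-10)  # geometric mean 1

  # hand-computed trimmed weighted mean for sample 1 against the reference
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75) / sum(x))
  ref <- which.min(abs(uq - mean(uq)))
  s <- setdiff(1:4, ref)[1]
  pr <- counts[, s] / lib[s]; pq <- counts[, ref] / lib[ref]
  keep <- pr > 0 & pq > 0
  M <- log2(pr / pq)[keep]; A <- (log2(pr) + log2(pq))[keep] / 2
  w <- ((lib[s] - counts[keep, s]) / (lib[s] * counts[keep, s]) +
          (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref]))^-1
  loM <- stats::quantile(M, 0.3, type = 1); hiM <- stats::quantile(M, 0.7, type = 1)
  loA <- stats::quantile(A, 0.05, type = 1); hiA <- stats::quantile(A, 0.95, type = 1)
  trim <- M >= loM & M <= hiM & A >= loA & A <= hiA
  hand <- 2^(sum(w[trim] * M[trim]) / sum(w[trim]))
  ratio <- res$factors[s] / res$factors[ref]
  expect_equal(ratio, hand, tolerance = 0.01)

  # a pure depth change leaves factors equal and logCPM identical
  c2 <- cbind(a = counts[, 1], b = 2 * counts[, 1])
  r2 <- tmm_logcpm(c2)
  expect_equal(r2$factors[1], r2$factors[2], tolerance = 1e-12)
  expect_equal(r2$logcpm[, "a"], r2$logcpm[, "b"], tolerance = 1e-12)
  expect_error(tmm_logcpm(cbind(counts, zero = rep(0, 6))), "positive")
})

test_that("moderated t reduces to the classical t in known regimes", {
  set.seed(71)
  expr <- matrix(rnorm(50 * 12, 8, 1), 50, 12,
                 dimnames = list(paste0("g", 1:50), NULL))
  grp <- rep(c("a", "b"), each = 6)
  res <- moderated_t_dea(expr, grp)
  prior <- attr(res, "prior")
  # equal-variance genes: d0 is infinite and all posterior variances shrink
  # to the common value; with real spread the moderated and ordinary t agree
  # in direction and rank
  tt <- apply(expr, 1, function(x) stats::t.test(x[grp == "b"], x[grp == "a"],
                                                 var.equal = TRUE)$statistic)
  expect_gt(stats::cor(res$t, tt), 0.98)
  expect_equal(sign(res$t), unname(sign(tt)))
  # identical residual variances: shrinkage is a no-op on the variances
  expr2 <- matrix(rep(c(rnorm(12)), each = 20), 20, 12) +
    outer(rnorm(20), rep(0, 12))
  grp2 <- rep(c("a", "b"), 6)
  res2 <- moderated_t_dea(expr2 + matrix(0, 20, 12), grp2)
  expect_true(is.infinite(attr(res2, "prior")["d0"]) ||
                attr(res2, "prior")["d0"] > 50)
})

test_that("moderated t agrees with the limma reference on fold changes", {
  skip_if_not_installed("limma")
  set.seed(72)
  expr <- matrix(rnorm(200 * 16, 8, 1), 200, 16,
                 dimnames = list(paste0("g", 1:200), NULL))
  grp <- factor(rep(c("a", "b"), each = 8))
  expr[1:20, grp == "b"] <- expr[1:20, grp == "b"] + 1.5
  res <- moderated_t_dea(expr, grp)
  fit <- limma::eBayes(limma::lmFit(expr, stats::model.matrix(~ grp)))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(stats::cor(res$t, fit$t[, 2]), 0.999)
})

test_that("planted DEGs are detected at high sensitivity", {
  study <- small_study()
  sens <- vapply(1:2, function(co) {
    ann <- study$samples[[co]]
    keep <- ann$truth %in% c("Control", "LOAD-S1")
    cts <- filter_low_expression(study$expression[[co]][, ann$sample_id[keep]])
    lc <- tmm_logcpm(cts)$logcpm
    res <- moderated_t_dea(lc, factor(ann$truth[keep],
                                      levels = c("Control", "LOAD-S1")))
    planted <- intersect(study$truth$degs[["LOAD-S1"]], res$gene)
    mean(res$fdr[match(planted, res$gene)] < 0.05)
  }, numeric(1))
  expect_gte(mean(sens), 0.8)
})

test_that("the consensus DEG filter applies each rule exactly", {
  mk <- function(lfc, p, fdr) data.frame(gene = paste0("g", seq_along(lfc)),
                                         log2fc = lfc, p = p, fdr = fdr)
  # FCs (1.6, 1.2, 1.3) same sign, p pass all, FDR pass in one -> retained
  r <- list(mk(log2(c(1.6, 1.4)), c(0.01, 0.2), c(0.04, 0.5)),
            mk(log2(c(1.2, 1.45)), c(0.04, 0.01), c(0.2, 0.04)),
            mk(log2(c(1.3, 1.3)), c(0.03, 0.01), c(0.3, 0.04)))
  expect_identical(cross_cohort_deg_filter(r), "g1")
  # sign flip in one cohort excludes
  r2 <- r; r2[[2]]$log2fc[1] <- -r2[[2]]$log2fc[1]
  expect_false("g1" %in% cross_cohort_deg_filter(r2))
  # no cohort exceeding FC 1.5 excludes (gene 2: 1.4/1.45/1.3)
  expect_false("g2" %in% cross_cohort_deg_filter(r))
  # relaxing thresholds never removes genes (monotonicity)
  kept <- cross_cohort_deg_filter(r)
  relaxed <- cross_cohort_deg_filter(r, fc = 1.2, p_all = 0.1, fdr_one = 0.1)
  expect_true(all(kept %in% relaxed))
})

test_that("promoter-window pairing is inclusive at the boundary", {
  cpgs <- data.frame(probe_id = c("c1", "c2", "c3"), chr = "chr1",
                     pos = c(5000, 15000, 25001))
  genes <- data.frame(gene_id = c("gA", "gB"), chr = "chr1",
                      tss = c(5000, 15000))
  pairs <- cpg_gene_pairs(cpgs, genes, window = 10000)
  expect_true(any(pairs$cpg == "c1" & pairs$gene == "gA"))   # distance 0
  expect_true(any(pairs$cpg == "c1" & pairs$gene == "gB"))   # exactly 10,000
  expect_false(any(pairs$cpg == "c3" & pairs$gene == "gB"))  # 10,001
  # chromosome mismatch never pairs
  genes2 <- data.frame(gene_id = "gC", chr = "chr2", tss = 5000)
  expect_equal(nrow(cpg_gene_pairs(cpgs, genes2)), 0)
})

test_that("CpG-expression correlations use midranks and replicate across cohorts", {
  # tie handling: beta (0.1, 0.1, 0.2) vs expr (1, 2, 3) -> rho = sqrt(3)/2
  beta1 <- matrix(c(0.1, 0.1, 0.2, 0.15, 0.18, 0.12), 2, 3, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), paste0("s", 1:3)))
  expr1 <- matrix(c(1, 2, 3, 5, 4, 6), 2, 3, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  labs <- stats::setNames(rep("LOAD-S1", 3), paste0("s", 1:3))
  pairs <- data.frame(cpg = c("c1", "c2"), gene = c("g1", "g2"))
  out <- correlate_cpg_expression(list(beta1), list(expr1), pairs, list(labs),
                                  subtypes = "LOAD-S1", min_samples = 3)
  expect_equal(out$correlations$rho[out$correlations$cpg == "c1"],
               sqrt(3) / 2, tolerance = 1e-10)

  # a monotone pair planted in two cohorts is flagged replicated
  set.seed(73)
  mk_cohort <- function() {
    b <- matrix(runif(40 * 12, 0.2, 0.8), 40, 12,
                dimnames = list(paste0("c", 1:40), paste0("s", 1:12)))
    e <- matrix(rnorm(40 * 12, 8), 40, 12,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
    e["g1", ] <- 5 + 10 * b["c1", ]
    list(b = b, e = e)
  }
  c1 <- mk_cohort(); c2 <- mk_cohort()
  labs2 <- stats::setNames(rep("LOAD-S2", 12), paste0("s", 1:12))
  pairs2 <- data.frame(cpg = paste0("c", 1:40), gene = paste0("g", 1:40))
  out2 <- correlate_cpg_expression(list(c1$b, c2$b), list(c1$e, c2$e), pairs2,
                                   list(labs2, labs2), subtypes = "LOAD-S2")
  rep1 <- out2$replicated[out2$replicated$cpg == "c1", ]
  expect_true(rep1$replicated)
  # strata below the sample floor are skipped
  expect_error(correlate_cpg_expression(list(c1$b), list(c1$e), pairs2,
                                        list(labs2[1:3])),
               "minimum sample size")
})
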
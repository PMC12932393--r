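test_that("cluster median profiles are per-probe medians of members", {
  b <- matrix(c(0.2, 0.4, 0.9,
                0.1, 0.5, 0.3), 2, 3, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  prof <- cluster_median_profiles(b, c(s1 = "A", s2 = "A", s3 = "A"))
  expect_equal(unname(prof[, "A"]), c(0.4, 0.3))
  # single-member cluster equals that sample
  prof2 <- cluster_median_profiles(b, c(s1 = "A", s2 = "B", s3 = "B"))
  expect_equal(unname(prof2[, "A"]), b[, "s1"], ignore_attr = TRUE)
  # duplicating the median sample leaves the profile unchanged
  b2 <- cbind(b, s4 = c(0.4, 0.3))
  prof3 <- cluster_median_profiles(b2, c(s1 = "A", s2 = "A", s3 = "A", s4 = "A"))
  expect_equal(prof3[, "A"], prof[, "A"])
})

test_that("profile correlations match the hand-evaluated Pearson formula", {
  x <- c(0.1, 0.2, 0.3, 0.4); y <- c(0.1, 0.25, 0.28, 0.41)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  profs <- list(a = matrix(x, 4, 1, dimnames = list(paste0("p", 1:4), "A")),
                b = matrix(y, 4, 1, dimnames = list(paste0("p", 1:4), "A")))
  cc <- correlate_profiles(profs, min_shared = 4)
  expect_equal(unname(cc[["a|b"]]$r[1, 1]), hand)
  # identical and anti-monotone profiles
  profs2 <- list(a = matrix(cbind(x, rev(x)), 4, 2,
                            dimnames = list(paste0("p", 1:4), c("A", "B"))),
                 b = matrix(x, 4, 1, dimnames = list(paste0("p", 1:4), "A")))
  cc2 <- correlate_profiles(profs2, min_shared = 4)
  expect_equal(unname(cc2[["a|b"]]$r["A", "A"]), 1)
  expect_equal(unname(cc2[["a|b"]]$r["B", "A"]), -1)
  expect_error(correlate_profiles(profs, min_shared = 100), "shares only")
})

test_that("mutual-best-match blocks recover planted correspondence", {
  set.seed(30)
  base <- matrix(rnorm(200 * 3), 200, 3,
                 dimnames = list(paste0("p", 1:200), c("A", "B", "C")))
  noisy <- function(perm) {
    m <- base[, perm] + matrix(rnorm(600, sd = 0.1), 200)
    colnames(m) <- c("A", "B", "C")
    m
  }
  profs <- list(c1 = noisy(c(1, 2, 3)), c2 = noisy(c(2, 3, 1)),
                c3 = noisy(c(3, 1, 2)))
  blocks <- match_blocks(correlate_profiles(profs, min_shared = 100))
  expect_equal(nrow(blocks), 3)
  # c1 cluster A carries base profile 1, found in c2 under "C", c3 under "B"
  row <- blocks[blocks$c1 == "A", ]
  expect_equal(row$c2, "C")
  expect_equal(row$c3, "B")

  # a cohort-specific cluster with a unique signature stays unmatched
  profs$c1 <- cbind(profs$c1, D = rnorm(200))
  blocks2 <- match_blocks(correlate_profiles(profs, min_shared = 100))
  expect_false("D" %in% blocks2$c1)

  expect_error(match_blocks(correlate_profiles(profs[1:2], min_shared = 100)),
               "exactly 3")
})

test_that("hypergeometric hull p-values match an exhaustive tail-sum oracle", {
  tail_sum <- function(obs, N, K, n) {
    xs <- obs:min(K, n)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
  }
  # closed-form check: N=100, K=30, n=40, observed=25
  expect_equal(stats::phyper(24, 30, 70, 40, lower.tail = FALSE),
               tail_sum(25, 100, 30, 40))
  # sweep of small tables
  set.seed(31)
  for (i in 1:25) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    obs <- sample(max(0, n - (N - K)):min(K, n), 1)
    expect_equal(stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE),
                 tail_sum(obs, N, K, n), tolerance = 1e-12)
  }
})

test_that("points on polygon boundaries count as inside, degenerate hulls work", {
  pip <- methsubtypes:::points_in_polygon
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(pip(rbind(c(0.5, 0.5), c(1, 0), c(0, 0), c(1, 1), c(2, 2)), tri),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  seg <- rbind(c(0, 0), c(2, 2))   # zero-width polygon
  expect_equal(pip(rbind(c(1, 1), c(1, 0)), seg), c(TRUE, FALSE))
  expect_equal(pip(rbind(c(3, 3)), rbind(c(3, 3))), TRUE)
})

test_that("a replication cohort identical to discovery lands in its own hulls", {
  set.seed(32)
  n <- 30; p <- 60
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n),
                                                  paste0("f", 1:p)))
  X[, 1:10] <- X[, 1:10] + ifelse(y == "A", 2, -2)
  hr <- hull_replication(X, y, X, y, n_components = 2, keep_per_component = 20)
  tt <- hr$tests
  matched <- tt[tt$replication_cluster == tt$discovery_hull, ]
  expect_true(all(matched$p < 1e-6))
  # all own-cluster samples are inside their own hull
  expect_true(all(matched$outside == 0))
  # observed = 0 has p = 1 (upper tail includes the whole support)
  off <- tt[tt$replication_cluster != tt$discovery_hull, ]
  expect_true(all(off$p[off$inside == 0] == 1))
})

test_that("confirmation requires every rotation under both methods", {
  run <- full_pipeline_run()
  res <- run$res
  expect_equal(nrow(res$confirmed), 2)
  expect_true(all(res$blocks$confirmed %in% c(TRUE, FALSE)))
  # tampering with one rotation must break confirmation
  hr <- res$hull_results
  one <- hr$kmeans[[1]]
  one$tests$p_adj <- 1
  hr$kmeans[[1]] <- one
  reblocked <- confirm_subtypes(res$blocks[, 1:3], hr)
  expect_true(all(!reblocked$confirmed))
  broken <- hr
  broken$hierarchical[[1]] <- NULL
  expect_error(confirm_subtypes(res$blocks[, 1:3], broken), "missing")
})

test_that("pipeline calls are invariant to sample order within cohorts", {
  study <- generate_methylation_cohorts(
    sim_config(seed = 61L, n_cpgs = 600,
               samples_per_group = c(Control = 12L, `LOAD-S1` = 18L,
                                     `LOAD-S2` = 18L),
               cohort_specific_n = 0L,
               signature_sizes = c(S1 = 60L, S2 = 60L, sharedLOAD = 30L,
                                   cohortSpecific = 20L, NFT = 30L)))
  run_perm <- function(perm_seed) {
    beta <- study$beta; samples <- study$samples
    if (!is.null(perm_seed)) {
      set.seed(perm_seed)
      for (co in seq_along(beta)) {
        perm <- sample(ncol(beta[[co]]))
        beta[[co]] <- beta[[co]][, perm]
        samples[[co]] <- samples[[co]][perm, ]
      }
    }
    res <- subtype_pipeline(beta, samples, k_range = 2:4, n_components = 3,
                            keep_per_component = 60, min_shared = 50, seed = 9)
    res$calls[order(res$calls$sample_id), ]
  }
  r1 <- run_perm(NULL)
  r2 <- run_perm(123)
  expect_equal(adjusted_rand_index(r1$call, r2$call), 1)
})
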
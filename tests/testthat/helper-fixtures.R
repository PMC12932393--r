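# Shared fixtures, built lazily and cached for the duration of the test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small planted three-cohort study used by several module tests.
small_cfg <- function(seed = 101L) {
  sim_config(
    seed = seed, n_cpgs = 800,
    samples_per_group = c(Control = 15L, `LOAD-S1` = 15L, `LOAD-S2` = 15L),
    cohort_specific_n = 8L,
    signature_sizes = c(S1 = 40L, S2 = 40L, sharedLOAD = 25L,
                        cohortSpecific = 25L, NFT = 30L))
}

small_study <- function() cached("small_study", function() {
  simulate_study(small_cfg())
})

# The full-size planted study of the discovery -> replication analysis,
# shared between the subtype-recovery and hull-significance checks.
full_pipeline_run <- function() cached("full_pipeline_run", function() {
  study <- generate_methylation_cohorts(sim_config(seed = 42L))
  res <- subtype_pipeline(study$beta, study$samples, seed = 42L)
  list(study = study, res = res)
})

# Euclidean silhouette width for a labeled score matrix.
mean_silhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  sil <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Vectorized per-row two-group Welch t-test p-values (independent oracle for
# calibration checks on simulated matrices).
row_t_pvalues <- function(mat, grp1, grp2) {
  m1 <- rowMeans(mat[, grp1, drop = FALSE])
  m2 <- rowMeans(mat[, grp2, drop = FALSE])
  v1 <- apply(mat[, grp1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, grp2, drop = FALSE], 1, stats::var)
  n1 <- length(grp1); n2 <- length(grp2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tstat), df)
}
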
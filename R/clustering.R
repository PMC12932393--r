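#' Ward-D2 hierarchical clustering
#'
#' Agglomerative clustering with the Ward-D2 criterion on Euclidean distances
#' (distances are not pre-squared; the Lance-Williams recurrence operates on
#' squared distances internally, the standard `ward.D2` convention), cut at
#' `k` clusters.
#'
#' @param X Samples x features numeric matrix.
#' @param k Number of clusters (2 <= k <= nrow(X)).
#' @return Integer labels in 1..k, named by rownames of `X`.
#' @export
hierarchical_cluster <- function(X, k) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be at least 1")
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Seeded k-means clustering
#'
#' Lloyd/Hartigan-Wong k-means with multiple seeded restarts; the solution
#' with the lowest total within-cluster sum of squares is kept.
#'
#' @inheritParams hierarchical_cluster
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts (default 25).
#' @return Integer labels in 1..k, named by rownames of `X`.
#' @export
kmeans_cluster <- function(X, k, seed = 1L, nstart = 25L) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of samples")
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = nstart,
                                      iter.max = 50))
  stats::setNames(km$cluster, rownames(X))
}

wcss_of <- function(X, labels) {
  sum(vapply(split(seq_len(nrow(X)), labels), function(idx) {
    xs <- X[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

#' Elbow-based selection of the number of clusters
#'
#' Computes the within-cluster sum of squares over `k_range` for the chosen
#' clustering method and takes the elbow as the k maximizing the second
#' forward difference of the log-WCSS curve (a scale-free knee criterion, one
#' of several heuristics; see the vignette). A flat curve, where the maximal
#' second difference is below `tol`, is flagged low-confidence.
#'
#' @param X Samples x features matrix.
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param k_range Integer vector of at least 3 candidate k values.
#' @param seed Seed for k-means restarts.
#' @param tol Relative flatness tolerance for the low-confidence flag.
#' @return List of class `k_selection`: `k_range`, `wcss`, `chosen_k`,
#'   `second_diff`, `low_confidence`.
#' @export
elbow_select <- function(X, method = c("hierarchical", "kmeans"), k_range,
                         seed = 1L, tol = 0.01) {
  method <- match.arg(method)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) stop("k_range must span at least 3 values")
  wcss <- vapply(k_range, function(k) {
    lab <- if (method == "hierarchical") hierarchical_cluster(X, k)
           else kmeans_cluster(X, k, seed = seed)
    wcss_of(X, lab)
  }, numeric(1))
  if (method == "kmeans" && any(diff(wcss) > 1e-8)) {
    # restarts occasionally miss; rerun harder before giving up
    wcss <- vapply(k_range, function(k)
      wcss_of(X, kmeans_cluster(X, k, seed = seed, nstart = 100L)), numeric(1))
    if (any(diff(wcss) > 1e-8))
      warning("k-means WCSS curve non-monotone even with 100 restarts")
  }
  interior <- seq(2, length(k_range) - 1)
  lw <- log(wcss)
  d2 <- lw[interior - 1] - 2 * lw[interior] + lw[interior + 1]
  chosen <- k_range[interior][which.max(d2)]
  structure(list(k_range = k_range, wcss = wcss, chosen_k = chosen,
                 second_diff = stats::setNames(d2, k_range[interior]),
                 low_confidence = max(d2) < tol),
            class = "k_selection")
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by `max`, `sqrt` (geometric mean) or `mean`
#' of the two label entropies. Returns 0 when either labeling is constant.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @param variant Normalization: `"max"` (default), `"sqrt"` or `"mean"`.
#' @return NMI in [0, 1].
#' @export
nmi <- function(labels_a, labels_b, variant = c("max", "sqrt", "mean")) {
  variant <- match.arg(variant)
  if (length(labels_a) == 0 || length(labels_b) == 0)
    stop("empty label vectors")
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj_[col(pij)[nz]])))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pi_); hb <- h(pj_)
  denom <- switch(variant, max = max(ha, hb), sqrt = sqrt(ha * hb),
                  mean = (ha + hb) / 2)
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}

#' Select k by hierarchical / k-means agreement
#'
#' For each candidate k, clusters with both methods and scores their agreement
#' by NMI; the k with maximal NMI is chosen. Ties are broken by elbow
#' strength on the hierarchical WCSS curve and only then by the smallest k,
#' because cleanly separated data tie at NMI = 1 for every k up to the true
#' cluster count. When the maximal NMI falls below `min_nmi` the selection is
#' flagged.
#'
#' @inheritParams elbow_select
#' @param variant NMI normalization variant.
#' @param min_nmi Agreement floor below which the choice is flagged.
#' @return List of class `k_selection_nmi`: `k_range`, `nmi_per_k`,
#'   `chosen_k`, `flagged`.
#' @export
select_k_by_nmi <- function(X, k_range, seed = 1L, variant = "max",
                            min_nmi = 0.3) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 1) {
    return(structure(list(k_range = k_range, nmi_per_k = NA_real_,
                          chosen_k = k_range, flagged = FALSE),
                     class = "k_selection_nmi"))
  }
  X <- as.matrix(X)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  hl <- stats::cutree(hc, k = k_range)
  if (is.null(dim(hl))) hl <- matrix(hl, ncol = 1)
  vals <- vapply(seq_along(k_range), function(i)
    nmi(hl[, i], kmeans_cluster(X, k_range[i], seed = seed),
        variant = variant), numeric(1))
  # cleanly separated data tie at NMI = 1 for every k up to the true cluster
  # count; break ties by elbow strength (second forward difference of the
  # hierarchical log-WCSS curve), then by the smallest k
  wcss <- vapply(seq_along(k_range), function(i) wcss_of(X, hl[, i]), numeric(1))
  below <- if (min(k_range) <= 2L) wcss_of(X, rep(1L, nrow(X))) else
    wcss_of(X, stats::cutree(hc, k = min(k_range) - 1L))
  above <- wcss_of(X, stats::cutree(hc, k = min(nrow(X), max(k_range) + 1L)))
  lw <- log(pmax(c(below, wcss, above), .Machine$double.eps))
  d2 <- lw[seq_along(k_range)] - 2 * lw[seq_along(k_range) + 1L] +
    lw[seq_along(k_range) + 2L]
  tied <- which(vals > max(vals) - 1e-10)
  chosen <- k_range[tied[which.max(d2[tied])]]
  structure(list(k_range = k_range, nmi_per_k = stats::setNames(vals, k_range),
                 elbow_strength = stats::setNames(d2, k_range),
                 chosen_k = chosen, flagged = max(vals) < min_nmi),
            class = "k_selection_nmi")
}

#' Consensus labels from two clusterings
#'
#' Matches k-means clusters to hierarchical clusters by optimal one-to-one
#' assignment on the contingency table (maximum total overlap, exhaustive over
#' permutations, deterministic) and assigns a consensus label only to samples
#' whose matched labels agree.
#'
#' @param hier,kmeans Equal-length label vectors with the same number of
#'   clusters.
#' @return Data frame of class `cluster_assignment` with `sample_id`,
#'   `hierarchical_label`, `kmeans_label` (relabeled to the matched
#'   hierarchical cluster) and `consensus_label` (LETTERS or NA).
#' @export
consensus_labels <- function(hier, kmeans) {
  if (length(hier) != length(kmeans)) stop("label vectors differ in length")
  kh <- length(unique(hier)); kk <- length(unique(kmeans))
  if (kh != kk) stop("the two clusterings have different numbers of clusters")
  hl <- as.integer(factor(hier)); kl <- as.integer(factor(kmeans))
  tab <- table(factor(hl, levels = 1:kh), factor(kl, levels = 1:kh))
  match_cols <- best_assignment(unclass(tab))
  # relabel kmeans so matched cluster shares the hierarchical index
  remap <- integer(kh)
  remap[match_cols] <- seq_len(kh)
  kl2 <- remap[kl]
  agree <- hl == kl2
  ids <- names(hier)
  if (is.null(ids)) ids <- as.character(seq_along(hier))
  out <- data.frame(sample_id = ids, hierarchical_label = hl,
                    kmeans_label = kl2,
                    consensus_label = ifelse(agree, LETTERS[hl], NA_character_),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Association of cluster labels with batch / technical variables
#'
#' Continuous variables are tested by Spearman correlation against the integer
#' cluster codes; discrete variables by NMI with a seeded permutation p-value.
#'
#' @param labels Cluster label vector.
#' @param batch_table Data frame of technical variables (one row per sample).
#' @param n_perm Permutations for the NMI null (default 1000).
#' @param seed Permutation seed.
#' @return Data frame: variable, type, statistic (rho or NMI), p.
#' @export
batch_association <- function(labels, batch_table, n_perm = 1000L, seed = 1L) {
  stopifnot(nrow(batch_table) == length(labels))
  codes <- as.integer(factor(labels))
  rows <- lapply(names(batch_table), function(v) {
    x <- batch_table[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("variable '", v, "' is constant; reported as NA")
      return(data.frame(variable = v, type = NA_character_,
                        statistic = NA_real_, p = NA_real_))
    }
    if (is.numeric(x)) {
      ct <- suppressWarnings(stats::cor.test(codes, x, method = "spearman"))
      data.frame(variable = v, type = "continuous",
                 statistic = unname(ct$estimate), p = ct$p.value)
    } else {
      obs <- nmi(labels, x)
      null <- with_seed(stream_seed(seed, match(v, names(batch_table))),
                        replicate(n_perm, nmi(sample(labels), x)))
      data.frame(variable = v, type = "discrete", statistic = obs,
                 p = (1 + sum(null >= obs)) / (1 + n_perm))
    }
  })
  do.call(rbind, rows)
}
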
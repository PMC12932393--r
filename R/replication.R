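#' Per-cluster median methylation profiles
#'
#' @param beta Probes x samples matrix (beta or residualized values).
#' @param labels Cluster label per sample (NA samples are ignored); names must
#'   match columns of `beta` when present.
#' @return Probes x clusters matrix of per-probe medians; empty clusters are
#'   skipped with a warning.
#' @export
cluster_median_profiles <- function(beta, labels) {
  beta <- as.matrix(beta)
  if (!is.null(names(labels))) {
    if (!all(names(labels) %in% colnames(beta)))
      stop("labeled samples missing from beta")
    beta <- beta[, names(labels), drop = FALSE]
  } else if (length(labels) != ncol(beta)) {
    stop("labels must match the samples of beta")
  }
  keep <- !is.na(labels)
  all_lev <- if (is.factor(labels)) levels(labels) else
    sort(unique(as.character(labels[keep])))
  labels <- as.character(labels[keep]); beta <- beta[, keep, drop = FALSE]
  lev <- sort(unique(labels))
  empty <- setdiff(all_lev, lev)
  if (length(empty)) warning("clusters with no members skipped: ",
                             paste(empty, collapse = ", "))
  prof <- vapply(lev, function(cl) {
    apply(beta[, labels == cl, drop = FALSE], 1, stats::median)
  }, numeric(nrow(beta)))
  rownames(prof) <- rownames(beta)
  prof
}

#' Cross-cohort Pearson correlations of cluster median profiles
#'
#' @param profiles Named list (one per cohort) of probes x clusters median
#'   matrices with probe rownames.
#' @param min_shared Minimum shared probes per cohort pair (default 100).
#' @return List keyed `"i|j"` over cohort pairs (i < j), each with matrices
#'   `r` and `p` (clusters of i x clusters of j) and `n_shared`.
#' @export
correlate_profiles <- function(profiles, min_shared = 100L) {
  nc <- length(profiles)
  if (is.null(names(profiles))) names(profiles) <- seq_len(nc)
  out <- list()
  for (i in seq_len(nc - 1)) for (j in seq(i + 1, nc)) {
    shared <- intersect(rownames(profiles[[i]]), rownames(profiles[[j]]))
    if (length(shared) < min_shared)
      stop("cohort pair ", names(profiles)[i], "/", names(profiles)[j],
           " shares only ", length(shared), " probes")
    a <- profiles[[i]][shared, , drop = FALSE]
    b <- profiles[[j]][shared, , drop = FALSE]
    r <- stats::cor(a, b)
    p <- matrix(NA_real_, ncol(a), ncol(b), dimnames = dimnames(r))
    for (u in seq_len(ncol(a))) for (v in seq_len(ncol(b)))
      p[u, v] <- stats::cor.test(a[, u], b[, v])$p.value
    out[[paste(names(profiles)[i], names(profiles)[j], sep = "|")]] <-
      list(r = r, p = p, n_shared = length(shared))
  }
  out
}

#' Match clusters across three cohorts into correlation blocks
#'
#' A block is a triple (one cluster per cohort) in which every pair is a
#' mutual best match (row and column maximum) in its cross-cohort correlation
#' matrix. Clusters in no block remain unmatched.
#'
#' @param correlations Output of [correlate_profiles()] for exactly 3 cohorts.
#' @return Data frame with one row per block and one column per cohort (the
#'   matched cluster label); zero rows when no block exists.
#' @export
match_blocks <- function(correlations) {
  pairs <- strsplit(names(correlations), "|", fixed = TRUE)
  cohorts <- unique(unlist(pairs))
  if (length(cohorts) != 3)
    stop("block matching requires correlation matrices for exactly 3 cohorts")
  mutual <- function(r) {
    hits <- which(r == apply(r, 1, max) &
                  r == matrix(apply(r, 2, max), nrow(r), ncol(r), byrow = TRUE),
                  arr.ind = TRUE)
    data.frame(a = rownames(r)[hits[, 1]], b = colnames(r)[hits[, 2]],
               stringsAsFactors = FALSE)
  }
  mm <- lapply(correlations, function(x) mutual(x$r))
  key <- function(i, j) {
    k <- paste(cohorts[i], cohorts[j], sep = "|")
    if (k %in% names(mm)) return(mm[[k]])
    rev_k <- paste(cohorts[j], cohorts[i], sep = "|")
    data.frame(a = mm[[rev_k]]$b, b = mm[[rev_k]]$a, stringsAsFactors = FALSE)
  }
  m12 <- key(1, 2); m13 <- key(1, 3); m23 <- key(2, 3)
  blocks <- list()
  for (r in seq_len(nrow(m12))) {
    a <- m12$a[r]; b <- m12$b[r]
    cand <- m13$b[m13$a == a]
    for (cc in cand) {
      if (any(m23$a == b & m23$b == cc))
        blocks[[length(blocks) + 1]] <- c(a, b, cc)
    }
  }
  out <- as.data.frame(do.call(rbind, blocks), stringsAsFactors = FALSE)
  if (nrow(out)) names(out) <- cohorts else
    out <- stats::setNames(data.frame(character(), character(), character(),
                                      stringsAsFactors = FALSE), cohorts)
  out
}

#' Convex-hull latent-space replication test
#'
#' Fits sPLS-DA on the discovery cohort, builds a 2-D convex hull (components
#' 1-2) around each discovery cluster, projects the replication cohort into
#' the same space and, for each (replication cluster, discovery hull) pair,
#' performs a one-sided hypergeometric test of over-representation of the
#' cluster's samples inside the hull. Boundary points count as inside;
#' degenerate (collinear) clusters fall back to a zero-width polygon.
#'
#' @param X_disc,labels_disc Discovery samples x features matrix and cluster
#'   labels.
#' @param X_repl,labels_repl Replication matrix and cluster labels.
#' @param n_components,keep_per_component sPLS-DA parameters (>= 2
#'   components).
#' @param min_shared Passed to [project_splsda()].
#' @return Object of class `hull_replication`: data frame `tests` with
#'   replication cluster, discovery hull, inside/outside counts, `p`
#'   (hypergeometric upper tail) and `p_adj` (BH within this rotation), plus
#'   the hull vertex list and the projected scores.
#' @export
hull_replication <- function(X_disc, labels_disc, X_repl, labels_repl,
                             n_components = 6L, keep_per_component = 2000L,
                             min_shared = 0.5) {
  fit <- fit_splsda(X_disc, labels_disc,
                    n_components = max(2L, n_components),
                    keep_per_component = keep_per_component)
  sc_d <- fit$scores[, 1:2, drop = FALSE]
  hulls <- lapply(split(seq_along(labels_disc), labels_disc), function(idx) {
    pts <- sc_d[idx, , drop = FALSE]
    pts[grDevices::chull(pts), , drop = FALSE]
  })
  sc_r <- project_splsda(fit, X_repl, min_shared = min_shared)[, 1:2, drop = FALSE]
  N <- length(labels_repl)
  inside <- sapply(hulls, function(h) points_in_polygon(sc_r, h))
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = N)
  colnames(inside) <- names(hulls)
  rows <- list()
  for (cl in sort(unique(as.character(labels_repl)))) {
    in_cl <- labels_repl == cl
    for (h in names(hulls)) {
      K <- sum(inside[, h])          # replication samples inside hull h
      n_cl <- sum(in_cl)             # size of replication cluster cl
      obs <- sum(inside[in_cl, h])   # cluster members inside the hull
      p <- stats::phyper(obs - 1, K, N - K, n_cl, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        replication_cluster = cl, discovery_hull = h,
        inside = obs, outside = n_cl - obs, hull_total = K, n_total = N,
        p = p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  structure(list(tests = tests, hulls = hulls, scores_replication = sc_r,
                 scores_discovery = sc_d, fit = fit),
            class = "hull_replication")
}

#' Confirm subtypes from correlation blocks and hull replication
#'
#' A correlation block becomes a confirmed subtype only when, under both
#' clustering methods and for every ordered discovery/replication cohort pair
#' within the triple, the block's replication cluster is significantly
#' over-represented inside the block's discovery hull (BH-adjusted
#' hypergeometric p below `alpha` within each rotation).
#'
#' @param blocks Data frame from [match_blocks()] (consensus-label blocks).
#' @param hull_results Nested list: `hull_results[[method]][["d|r"]]` a
#'   [hull_replication()] object for each ordered cohort pair `d|r` and each
#'   clustering method.
#' @param alpha Significance level on BH-adjusted p (default 0.05).
#' @return Data frame `blocks` augmented with a `confirmed` flag and, per
#'   rotation/method, the minimum adjusted p among the block's pairs.
#' @export
confirm_subtypes <- function(blocks, hull_results, alpha = 0.05) {
  cohorts <- names(blocks)
  methods <- names(hull_results)
  if (nrow(blocks) == 0) {
    blocks$confirmed <- logical(0)
    return(blocks)
  }
  rotations <- unlist(lapply(cohorts, function(d)
    lapply(setdiff(cohorts, d), function(r) c(d, r))), recursive = FALSE)
  confirmed <- logical(nrow(blocks))
  worst <- numeric(nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    ok <- TRUE; wp <- 0
    for (m in methods) for (rot in rotations) {
      key <- paste(rot[1], rot[2], sep = "|")
      hr <- hull_results[[m]][[key]]
      if (is.null(hr)) stop("missing hull rotation ", key, " for method ", m)
      tt <- hr$tests
      row <- tt[tt$replication_cluster == blocks[b, rot[2]] &
                tt$discovery_hull == blocks[b, rot[1]], ]
      if (nrow(row) != 1 || row$p_adj >= alpha) ok <- FALSE
      if (nrow(row) == 1) wp <- max(wp, row$p_adj)
    }
    confirmed[b] <- ok
    worst[b] <- wp
  }
  blocks$confirmed <- confirmed
  blocks$max_p_adj <- worst
  blocks
}
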
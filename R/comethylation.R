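#' Detect co-methylation modules (simplified signed network)
#'
#' A deliberately lightweight module detector: signed adjacency
#' `((1 + cor)/2)^soft_power` between probes, dissimilarity `1 - adjacency`,
#' average-linkage hierarchical clustering cut at `cut_height`, with clusters
#' below `min_size` set to module 0 (unassigned). It captures blocks of
#' mutually correlated probes; it does not compute topological overlap or
#' block-wise networks.
#'
#' @param X Probes x samples matrix (>= 3 probes).
#' @param soft_power Soft-thresholding power (default 6).
#' @param cut_height Tree cut height on the dissimilarity (default 0.35).
#' @param min_size Minimum module size (default 10).
#' @return Object of class `module_set`: integer module id per probe (0 =
#'   unassigned; modules numbered by decreasing size) and the parameters.
#' @export
detect_modules <- function(X, soft_power = 6, cut_height = 0.35, min_size = 10L) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 probes")
  sds <- apply(X, 1, stats::sd)
  if (any(sds < 1e-12)) {
    warning(sum(sds < 1e-12), " constant probe(s) dropped")
    X <- X[sds >= 1e-12, , drop = FALSE]
  }
  r <- stats::cor(t(X))
  adj <- ((1 + r) / 2)^soft_power
  diss <- stats::as.dist(1 - adj)
  hc <- stats::hclust(diss, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  module <- integer(nrow(X))
  ord <- keep[order(-sizes[keep])]
  for (i in seq_along(ord)) module[raw == as.integer(ord[i])] <- i
  names(module) <- rownames(X)
  structure(list(module = module,
                 params = list(soft_power = soft_power,
                               cut_height = cut_height, min_size = min_size)),
            class = "module_set")
}

#' Module eigenprobe
#'
#' First principal component of the probe-standardized module matrix with
#' samples as observations, sign-oriented so that it correlates positively
#' with the module's mean standardized profile.
#'
#' @param X_module Probes x samples matrix of one module (>= 2 probes).
#' @return Object of class `eigenprobe`: per-sample `score` (unit norm),
#'   `explained_variance`, `flipped` orientation flag.
#' @export
eigenprobe <- function(X_module) {
  X_module <- as.matrix(X_module)
  if (nrow(X_module) < 2) stop("module needs at least 2 probes")
  Z <- t(scale(t(X_module)))
  Z[is.nan(Z)] <- 0
  sv <- svd(Z, nu = 0, nv = 1)
  score <- sv$v[, 1]
  ev <- sv$d[1]^2 / sum(sv$d^2)
  mean_prof <- colMeans(Z)
  flipped <- FALSE
  ori <- sum(score * mean_prof)
  if (ori < 0) { score <- -score; flipped <- TRUE }
  names(score) <- colnames(X_module)
  structure(list(score = score, explained_variance = ev, flipped = flipped),
            class = "eigenprobe")
}

#' Association of a module eigenprobe with cluster labels
#'
#' One-way ANOVA of eigenprobe scores across cluster labels, followed by
#' Tukey HSD pairwise comparisons.
#'
#' @param eig An [eigenprobe()] or a numeric score vector.
#' @param cluster_labels Group label per sample (>= 2 groups with >= 2
#'   samples each).
#' @return List: `F`, `p`, `tukey` (pairwise frame: comparison, diff, p_adj).
#' @export
module_cluster_association <- function(eig, cluster_labels) {
  score <- if (inherits(eig, "eigenprobe")) eig$score else eig
  g <- factor(cluster_labels)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  fit <- stats::aov(score ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Cross-platform module preservation check
#'
#' Recomputes each module's eigenprobe from the probes available on the
#' reduced platform and calls the module preserved when (a) the eigenprobe
#' differs across cluster labels (ANOVA p < `alpha`) on both platforms and
#' (b) for every cluster, a paired t-test between full- and subset-platform
#' eigenprobe scores is non-significant (p > `alpha`). Identical score
#' vectors (zero differences) count as non-significant. Modules losing all
#' but one probe are reported non-evaluable.
#'
#' @param X_full Probes x samples matrix (full platform).
#' @param X_subset Row subset of `X_full` (reduced platform probes).
#' @param modules A [detect_modules()] result (defined on the full set).
#' @param cluster_labels Group labels per sample.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: module, n_probes_full, n_probes_subset, anova_p_full,
#'   anova_p_subset, min_paired_p, preserved, evaluable.
#' @export
preservation_check <- function(X_full, X_subset, modules, cluster_labels,
                               alpha = 0.05) {
  if (!all(rownames(X_subset) %in% rownames(X_full)))
    stop("subset probes must be a subset of the full probe set")
  g <- factor(cluster_labels)
  ids <- sort(setdiff(unique(modules$module), 0L))
  rows <- lapply(ids, function(m) {
    probes <- names(modules$module)[modules$module == m]
    sub_probes <- intersect(probes, rownames(X_subset))
    if (length(sub_probes) < 2) {
      return(data.frame(module = m, n_probes_full = length(probes),
                        n_probes_subset = length(sub_probes),
                        anova_p_full = NA_real_, anova_p_subset = NA_real_,
                        min_paired_p = NA_real_, preserved = NA,
                        evaluable = FALSE))
    }
    e_full <- eigenprobe(X_full[probes, , drop = FALSE])
    Xs <- X_subset
    cn_full <- colnames(X_full); cn_sub <- colnames(Xs)
    if (!is.null(cn_full) && !is.null(cn_sub) && !identical(cn_full, cn_sub)) {
      if (anyDuplicated(cn_full) || !all(cn_full %in% cn_sub))
        stop("subset samples cannot be aligned to the full matrix")
      Xs <- Xs[, cn_full, drop = FALSE]
    } else if (ncol(Xs) != ncol(X_full)) {
      stop("full and subset matrices must cover the same samples")
    }
    e_sub <- eigenprobe(Xs[sub_probes, , drop = FALSE])
    # align subset orientation to the full eigenprobe
    if (stats::cor(e_full$score, e_sub$score) < 0)
      e_sub$score <- -e_sub$score
    a_full <- module_cluster_association(e_full, g)$p
    a_sub <- module_cluster_association(e_sub, g)$p
    paired_p <- vapply(levels(g), function(lev) {
      d <- e_full$score[g == lev] - e_sub$score[g == lev]
      if (all(abs(d) < 1e-12) || stats::sd(d) < 1e-12) return(1)
      stats::t.test(d)$p.value
    }, numeric(1))
    data.frame(module = m, n_probes_full = length(probes),
               n_probes_subset = length(sub_probes),
               anova_p_full = a_full, anova_p_subset = a_sub,
               min_paired_p = min(paired_p),
               preserved = a_full < alpha && a_sub < alpha &&
                 all(paired_p > alpha),
               evaluable = TRUE)
  })
  do.call(rbind, rows)
}
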
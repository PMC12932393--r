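#' Pseudobulk aggregation of single-cell counts
#'
#' Sums gene counts over all cells belonging to each (state, sample) pair and
#' records the per-sample cell counts.
#'
#' @param counts Genes x cells count matrix.
#' @param cell_state State label per cell.
#' @param cell_sample Sample label per cell.
#' @return Named list per state: `expr` (genes x samples sums over every
#'   sample observed anywhere) and `cell_counts` (cells per sample; 0 where a
#'   state has no cells in a sample).
#' @export
pseudobulk_aggregate <- function(counts, cell_state, cell_sample) {
  counts <- as.matrix(counts)
  if (length(cell_state) != ncol(counts) || length(cell_sample) != ncol(counts))
    stop("labels must cover all cells")
  samples <- sort(unique(as.character(cell_sample)))
  states <- sort(unique(as.character(cell_state)))
  out <- lapply(states, function(st) {
    expr <- vapply(samples, function(sm) {
      idx <- cell_state == st & cell_sample == sm
      if (!any(idx)) numeric(nrow(counts)) else
        rowSums(counts[, idx, drop = FALSE])
    }, numeric(nrow(counts)))
    rownames(expr) <- rownames(counts)
    n_cells <- vapply(samples, function(sm)
      sum(cell_state == st & cell_sample == sm), integer(1))
    list(expr = expr, cell_counts = n_cells)
  })
  names(out) <- states
  out
}

#' Microglial-state proportional abundance
#'
#' Converts per-sample state cell counts into proportions of total microglia,
#' excludes any state with fewer than `min_cells` cells summed within any
#' group, and tests group differences per retained state by one-way ANOVA
#' with Tukey HSD post hoc comparisons.
#'
#' @param cell_counts States x samples count matrix.
#' @param groups Group label per sample.
#' @param min_cells Exclusion threshold (default 100).
#' @return List: `proportions` (states x samples), `excluded` state ids,
#'   `tests` (per state: F, p, Tukey frame).
#' @export
state_proportions <- function(cell_counts, groups, min_cells = 100L) {
  cell_counts <- as.matrix(cell_counts)
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("every group needs at least one sample")
  totals <- colSums(cell_counts)
  if (any(totals <= 0)) stop("every sample needs a positive total cell count")
  props <- sweep(cell_counts, 2, totals, `/`)
  group_tot <- t(apply(cell_counts, 1, function(x) tapply(x, groups, sum)))
  excluded <- rownames(cell_counts)[apply(group_tot < min_cells, 1, any)]
  retained <- setdiff(rownames(cell_counts), excluded)
  tests <- lapply(retained, function(st) {
    res <- module_cluster_association(props[st, ], groups)
    c(list(state = st), res)
  })
  names(tests) <- retained
  list(proportions = props, excluded = excluded, tests = tests)
}

#' Control-anchored PCA projection of state pseudobulk profiles
#'
#' Normalizes pseudobulk counts (TMM + logCPM), screens control samples for
#' outliers in an initial control PCA (distance from the median score vector
#' over the components explaining at least `var_explained` of the variance;
#' samples beyond median + `mad_k` x MAD are dropped), refits the PCA on the
#' cleaned controls after gene-wise centering/scaling by control statistics,
#' and projects every sample with the control rotation. Only control-derived
#' statistics enter the projection.
#'
#' @param pseudobulk Genes x samples count matrix for one state.
#' @param groups Group label per sample; controls are `control_level`.
#' @param control_level Label identifying controls (default "Control").
#' @param mad_k Outlier multiplier (default 3.5; MAD uses the 1.4826
#'   consistency constant).
#' @param var_explained Variance fraction defining the outlier-screening
#'   subspace (default 0.8).
#' @param min_controls Minimum controls after cleaning (default 5).
#' @return Object of class `pca_projection`: `scores` (samples x PC1-2),
#'   `groups`, `explained_variance`, `outliers`, `rotation`, control
#'   `center`/`scale`.
#' @export
control_pca_projection <- function(pseudobulk, groups,
                                   control_level = "Control", mad_k = 3.5,
                                   var_explained = 0.8, min_controls = 5L) {
  pseudobulk <- as.matrix(pseudobulk)
  groups <- as.character(groups)
  ctrl <- which(groups == control_level)
  if (length(ctrl) < min_controls) stop("too few control samples")
  # strictly control-anchored normalization: the TMM reference is chosen
  # among controls and the prior count is fixed, so control logCPM values
  # never depend on the disease samples
  lib <- colSums(pseudobulk)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  f75 <- apply(pseudobulk[, ctrl, drop = FALSE], 2, function(x)
    stats::quantile(x, 0.75) / sum(x))
  ref <- ctrl[which.min(abs(f75 - mean(f75)))]
  fac <- edgeR::calcNormFactors(pseudobulk, refColumn = ref, method = "TMM")
  eff <- lib * fac
  E <- t(log2((pseudobulk + 0.5) / (eff[col(pseudobulk)] + 1) * 1e6))
  Ec <- E[ctrl, , drop = FALSE]
  keep_gene <- apply(Ec, 2, stats::sd) > 1e-10
  if (!all(keep_gene))
    message(sum(!keep_gene), " zero-variance gene(s) in controls dropped")
  E <- E[, keep_gene, drop = FALSE]; Ec <- Ec[, keep_gene, drop = FALSE]
  # initial PCA for outlier screening
  pc0 <- stats::prcomp(Ec, center = TRUE, scale. = TRUE)
  evar <- pc0$sdev^2 / sum(pc0$sdev^2)
  k0 <- which(cumsum(evar) >= var_explained)[1]
  sc0 <- pc0$x[, seq_len(k0), drop = FALSE]
  med <- apply(sc0, 2, stats::median)
  dist0 <- sqrt(rowSums(sweep(sc0, 2, med)^2))
  thr <- stats::median(dist0) + mad_k * stats::mad(dist0)
  out_ids <- rownames(Ec)[dist0 > thr]
  clean <- Ec[dist0 <= thr, , drop = FALSE]
  if (nrow(clean) < min_controls) stop("too few controls after outlier removal")
  mu <- colMeans(clean)
  sdv <- apply(clean, 2, stats::sd)
  keep2 <- sdv > 1e-10
  clean <- clean[, keep2, drop = FALSE]
  pc <- stats::prcomp(scale(clean, center = mu[keep2], scale = sdv[keep2]),
                      center = FALSE, scale. = FALSE)
  all_scaled <- scale(E[, keep2, drop = FALSE], center = mu[keep2],
                      scale = sdv[keep2])
  scores <- all_scaled %*% pc$rotation[, 1:2, drop = FALSE]
  structure(list(scores = scores, groups = groups,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
                 outliers = out_ids,
                 rotation = pc$rotation[, 1:2, drop = FALSE],
                 center = mu[keep2], scale = sdv[keep2]),
            class = "pca_projection")
}

#' Permutation test for group separation in PC space
#'
#' The separation statistic is the median Euclidean distance over all
#' cross-group sample pairs in PC1-2 (`stat = "centroid"` uses the distance
#' between group centroids instead). The null permutes group labels
#' (preserving group sizes); the empirical p is
#' `(1 + #{null >= observed}) / (1 + n_perm)` and the reported interval is
#' the 2.5/97.5 percentile band of the null. P-values are BH-adjusted across
#' the tested group pairs.
#'
#' @param scores Samples x 2 score matrix (or a `pca_projection`).
#' @param groups Group label per sample (ignored when `scores` is a
#'   `pca_projection`).
#' @param n_perm Number of permutations (default 10,000; minimum 100).
#' @param seed Integer seed.
#' @param stat `"median_pair"` (default) or `"centroid"`.
#' @return Data frame: group1, group2, observed, p, p_adj, null_lo, null_hi.
#' @export
permutation_separation_test <- function(scores, groups = NULL,
                                        n_perm = 10000L, seed = 1L,
                                        stat = c("median_pair", "centroid")) {
  stat <- match.arg(stat)
  if (inherits(scores, "pca_projection")) {
    groups <- scores$groups
    scores <- scores$scores
  }
  if (n_perm < 100) stop("need at least 100 permutations")
  groups <- factor(groups)
  if (any(table(groups) < 3)) stop("every group needs at least 3 samples")
  D <- as.matrix(stats::dist(scores[, 1:2, drop = FALSE]))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  stat_fun <- function(g) {
    vapply(seq_len(ncol(pairs)), function(k) {
      i <- which(g == pairs[1, k]); j <- which(g == pairs[2, k])
      if (stat == "median_pair") stats::median(D[i, j])
      else sqrt(sum((colMeans(scores[i, 1:2, drop = FALSE]) -
                     colMeans(scores[j, 1:2, drop = FALSE]))^2))
    }, numeric(1))
  }
  obs <- stat_fun(groups)
  null <- with_seed(stream_seed(seed, 11L), {
    vapply(seq_len(n_perm), function(b) stat_fun(sample(groups)), numeric(ncol(pairs)))
  })
  null <- matrix(null, nrow = ncol(pairs))
  p <- vapply(seq_len(ncol(pairs)), function(k)
    (1 + sum(null[k, ] >= obs[k])) / (1 + n_perm), numeric(1))
  ci <- apply(null, 1, stats::quantile, probs = c(0.025, 0.975))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], observed = obs,
             p = p, p_adj = stats::p.adjust(p, method = "BH"),
             null_lo = ci[1, ], null_hi = ci[2, ],
             stringsAsFactors = FALSE)
}

#' Marker-based microglial activation scores
#'
#' PC1 of the marker-gene logCPM matrix across all samples of a state,
#' sign-oriented to correlate positively with mean marker expression, then
#' standardized into Z-scores against the control mean and sd. Group shifts
#' between LOAD-S1 and LOAD-S2 are tested by a two-sided Welch t-test on the
#' Z-scores.
#'
#' @param pseudobulk Genes x samples count matrix for one state.
#' @param markers Marker gene ids (>= 2 present in the matrix).
#' @param groups Group label per sample.
#' @param control_level Label identifying controls.
#' @param compare Two group labels to contrast (default LOAD-S1 vs LOAD-S2).
#' @return List of class `activation_scores`: `score`, `z`, `groups`,
#'   `t_test` (htest or NULL when a contrast group is absent).
#' @export
activation_scores <- function(pseudobulk, markers, groups,
                              control_level = "Control",
                              compare = c("LOAD-S1", "LOAD-S2")) {
  norm <- tmm_logcpm(pseudobulk)
  markers <- intersect(markers, rownames(norm$logcpm))
  if (length(markers) < 2) stop("need at least 2 marker genes present")
  M <- t(norm$logcpm[markers, , drop = FALSE])   # samples x markers
  Z <- scale(M)
  Z[is.nan(Z)] <- 0
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (stats::cor(score, rowMeans(M)) < 0) score <- -score
  ctrl <- groups == control_level
  mu <- mean(score[ctrl]); sdv <- stats::sd(score[ctrl])
  if (!is.finite(sdv) || sdv < 1e-12) stop("control scores have zero sd")
  z <- (score - mu) / sdv
  tt <- NULL
  if (all(compare %in% groups))
    tt <- stats::t.test(z[groups == compare[1]], z[groups == compare[2]])
  structure(list(score = score, z = z, groups = groups, t_test = tt),
            class = "activation_scores")
}

#' Pseudobulk differential expression with the dual-significance rule
#'
#' Runs moderated-t DEA per state for the subtype-to-subtype contrast and
#' each subtype-versus-control contrast, and flags a gene when it is
#' nominally significant (p < `alpha`) between subtypes and versus controls
#' in at least one subtype.
#'
#' @param pseudobulk Named list per state: `expr` genes x samples counts (or
#'   a matrix for a single state).
#' @param groups Named group vector per sample (or a list parallel to
#'   `pseudobulk`).
#' @param subtype_levels The two subtype labels.
#' @param control_level Control label.
#' @param alpha Lenient significance threshold (default 0.05).
#' @param min_n Minimum samples per side of a contrast (default 3).
#' @return Named list per state (skipped states are dropped with a message):
#'   data frame gene, p_s1_s2, p_s1_ctrl, p_s2_ctrl, flagged.
#' @export
pseudobulk_dea <- function(pseudobulk, groups,
                           subtype_levels = c("LOAD-S1", "LOAD-S2"),
                           control_level = "Control", alpha = 0.05,
                           min_n = 3L) {
  if (is.matrix(pseudobulk)) pseudobulk <- list(state = list(expr = pseudobulk))
  out <- list()
  for (st in names(pseudobulk)) {
    expr <- pseudobulk[[st]]$expr
    g <- if (is.list(groups) && !is.data.frame(groups)) groups[[st]] else groups
    g <- g[colnames(expr)]
    run <- function(a, b) {
      ia <- which(g == a); ib <- which(g == b)
      # zero-library pseudobulk samples (states with no usable cells in a
      # sample) cannot be normalized and are dropped from the contrast
      ia <- ia[colSums(expr[, ia, drop = FALSE]) > 0]
      ib <- ib[colSums(expr[, ib, drop = FALSE]) > 0]
      if (length(ia) < min_n || length(ib) < min_n) return(NULL)
      sub <- cbind(expr[, ia, drop = FALSE], expr[, ib, drop = FALSE])
      lc <- tmm_logcpm(sub)$logcpm
      moderated_t_dea(lc, factor(rep(c(a, b), c(length(ia), length(ib))),
                                 levels = c(b, a)))
    }
    d12 <- run(subtype_levels[1], subtype_levels[2])
    d1c <- run(subtype_levels[1], control_level)
    d2c <- run(subtype_levels[2], control_level)
    if (is.null(d12) || (is.null(d1c) && is.null(d2c))) {
      message("state ", st, " skipped: insufficient samples")
      next
    }
    genes <- d12$gene
    p1c <- if (is.null(d1c)) rep(NA_real_, length(genes)) else d1c$p[match(genes, d1c$gene)]
    p2c <- if (is.null(d2c)) rep(NA_real_, length(genes)) else d2c$p[match(genes, d2c$gene)]
    ctrl_sig <- (!is.na(p1c) & p1c < alpha) | (!is.na(p2c) & p2c < alpha)
    out[[st]] <- data.frame(gene = genes, p_s1_s2 = d12$p, p_s1_ctrl = p1c,
                            p_s2_ctrl = p2c,
                            flagged = d12$p < alpha & ctrl_sig,
                            stringsAsFactors = FALSE)
  }
  out
}

#' Morphology group comparisons
#'
#' For each region and measure, all pairwise group comparisons by Welch's
#' t-test (Satterthwaite degrees of freedom) with Cohen's d on the pooled
#' standard deviation; BH correction across all comparisons within each
#' measure. Pairs with a single-donor group are skipped.
#'
#' @param table Data frame with `donor`, `region`, `group` and measure
#'   columns.
#' @param measures Measure column names (default `pam`, `stage3`).
#' @return Data frame: measure, region, group1, group2, n1, n2, t, df,
#'   cohens_d, p, p_adj.
#' @export
morphology_compare <- function(table, measures = c("pam", "stage3")) {
  rows <- list()
  for (ms in measures) {
    for (rg in unique(table$region)) {
      sub <- table[table$region == rg, , drop = FALSE]
      grs <- sort(unique(sub$group))
      if (length(grs) < 2) next
      cmb <- utils::combn(grs, 2)
      for (k in seq_len(ncol(cmb))) {
        x <- sub[[ms]][sub$group == cmb[1, k]]
        y <- sub[[ms]][sub$group == cmb[2, k]]
        if (length(x) < 2 || length(y) < 2) next
        tt <- stats::t.test(x, y)
        sp <- sqrt(((length(x) - 1) * stats::var(x) +
                      (length(y) - 1) * stats::var(y)) /
                     (length(x) + length(y) - 2))
        rows[[length(rows) + 1]] <- data.frame(
          measure = ms, region = rg, group1 = cmb[1, k], group2 = cmb[2, k],
          n1 = length(x), n2 = length(y),
          t = unname(tt$statistic), df = unname(tt$parameter),
          cohens_d = (mean(x) - mean(y)) / sp,
          p = tt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparable group pair found")
  out$p_adj <- NA_real_
  for (ms in unique(out$measure)) {
    idx <- out$measure == ms
    out$p_adj[idx] <- stats::p.adjust(out$p[idx], method = "BH")
  }
  rownames(out) <- NULL
  out
}
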
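#' Filter lowly expressed genes
#'
#' Removes a gene when its count falls below `count_threshold` in more than
#' `sample_fraction` of the samples (strictly more; a gene low in exactly the
#' boundary fraction is kept).
#'
#' @param counts Genes x samples non-negative integer matrix.
#' @param count_threshold Count considered "low" (default 10).
#' @param sample_fraction Fraction of samples allowed to be low (default 0.8).
#' @return The retained rows of `counts`.
#' @export
filter_low_expression <- function(counts, count_threshold = 10,
                                  sample_fraction = 0.8) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) stop("need at least one sample")
  low_frac <- rowMeans(counts < count_threshold)
  counts[low_frac <= sample_fraction, , drop = FALSE]
}

#' TMM normalization factors and logCPM
#'
#' Between-sample scaling factors by the trimmed mean of M-values (30%
#' log-ratio trim, 5% absolute-expression trim, precision-weighted mean,
#' reference sample chosen as the library whose upper quartile is closest to
#' the mean upper quartile), normalized to geometric mean 1, followed by
#' log2 counts per million on the effective (factor-adjusted) library sizes
#' with a library-size-proportional prior count of 0.5 — so a pure
#' sequencing-depth change leaves logCPM exactly invariant.
#'
#' @param counts Genes x samples matrix with positive library sizes.
#' @return List: `factors` (TMM normalization factors), `logcpm` (genes x
#'   samples), `lib_size`.
#' @export
tmm_logcpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  logcpm <- edgeR::cpm(dge, log = TRUE, prior.count = 0.5)
  list(factors = dge$samples$norm.factors, logcpm = logcpm, lib_size = lib)
}

# inverse of trigamma by Newton iteration (for the prior df estimate)
trigamma_inv <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Moderated-t differential expression
#'
#' Per-gene ordinary least squares on the group contrast plus covariates,
#' with residual variances shrunk towards a common prior by empirical Bayes:
#' the prior degrees of freedom d0 and scale s0^2 are estimated by method of
#' moments on the log residual variances, posterior variances are the
#' d0/d-weighted average, and the moderated t has d + d0 degrees of freedom.
#'
#' @param expr Genes x samples expression matrix (logCPM scale; coefficients
#'   are then log2 fold changes).
#' @param groups Two-level factor (or coercible) per sample; the coefficient
#'   is level2 minus level1.
#' @param covariates Optional data frame of adjustment covariates.
#' @param bacon Apply [bacon_correct()] to the resulting z-statistics
#'   (default FALSE; needs many genes).
#' @param cohort Cohort label stored with the result.
#' @return Data frame of class `deg_result`: gene, log2fc, t, df_total, p,
#'   fdr.
#' @export
moderated_t_dea <- function(expr, groups, covariates = NULL, bacon = FALSE,
                            cohort = NA_character_) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  X <- cbind(1, as.numeric(groups) - 1)
  colnames(X) <- c("(Intercept)", "group")
  if (!is.null(covariates))
    X <- cbind(X, stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design")
  d <- nrow(X) - ncol(X)
  if (d < 1) stop("no residual degrees of freedom")
  coefs <- qr.coef(qx, t(expr))["group", ]
  resid <- qr.resid(qx, t(expr))
  s2 <- colSums(resid^2) / d
  v_grp <- chol2inv(qr.R(qx))[2, 2]
  # empirical Bayes on log variances
  ok <- s2 > 1e-12
  ls2 <- log(s2[ok])
  e_moment <- mean(ls2)
  v_moment <- stats::var(ls2)
  excess <- v_moment - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s02 <- exp(e_moment - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inv(excess)
    s02 <- exp(e_moment - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  tmod <- coefs / sqrt(s2_post * v_grp)
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  if (bacon) {
    bc <- bacon_correct(tmod)
    tmod <- bc$z
    p <- 2 * stats::pnorm(-abs(tmod))
  }
  out <- data.frame(gene = rownames(expr), log2fc = coefs, t = tmod,
                    df_total = df_total, p = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cohort") <- cohort
  attr(out, "prior") <- c(d0 = d0, s02 = s02, d = d)
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Cross-cohort consensus DEG filter
#'
#' A gene is retained when its log2 fold change has the same sign in all
#' cohorts, its |fold change| exceeds `fc` (linear scale) in at least one
#' cohort, it is nominally significant (p < `p_all`) in all cohorts and
#' FDR-significant (< `fdr_one`) in at least one. Genes missing from any
#' cohort are excluded.
#'
#' @param results List of `deg_result` frames, one per cohort.
#' @param fc Linear fold-change threshold (default 1.5).
#' @param p_all Nominal p threshold required in every cohort.
#' @param fdr_one FDR threshold required in at least one cohort.
#' @return Character vector of consensus DEG gene ids.
#' @export
cross_cohort_deg_filter <- function(results, fc = 1.5, p_all = 0.05,
                                    fdr_one = 0.05) {
  genes <- Reduce(intersect, lapply(results, `[[`, "gene"))
  lfc <- sapply(results, function(r) r$log2fc[match(genes, r$gene)])
  pv <- sapply(results, function(r) r$p[match(genes, r$gene)])
  fdr <- sapply(results, function(r) r$fdr[match(genes, r$gene)])
  same_sign <- apply(sign(lfc), 1, function(s) all(s == s[1]) && all(s != 0))
  big_fc <- apply(abs(lfc), 1, max) > log2(fc)
  p_ok <- apply(pv, 1, max) < p_all
  fdr_ok <- apply(fdr, 1, min) < fdr_one
  genes[same_sign & big_fc & p_ok & fdr_ok]
}

#' Candidate CpG-gene pairs within a promoter window
#'
#' Pairs a CpG with a gene when the CpG position lies within `window` bases
#' of the gene's TSS (inclusive boundary), on the same chromosome.
#'
#' @param cpg_coords Data frame: `probe_id`, `chr`, `pos`.
#' @param gene_tss Data frame: `gene_id`, `chr`, `tss`.
#' @param window Window half-width in bases (default 10,000).
#' @return Data frame: cpg, gene, distance (signed, pos - tss).
#' @export
cpg_gene_pairs <- function(cpg_coords, gene_tss, window = 10000L) {
  out <- list()
  for (ch in intersect(unique(cpg_coords$chr), unique(gene_tss$chr))) {
    cp <- cpg_coords[cpg_coords$chr == ch, , drop = FALSE]
    gn <- gene_tss[gene_tss$chr == ch, , drop = FALSE]
    gn <- gn[order(gn$tss), , drop = FALSE]
    lo <- findInterval(cp$pos - window - 0.5, gn$tss) + 1L
    hi <- findInterval(cp$pos + window + 0.5, gn$tss)
    keep <- hi >= lo
    if (!any(keep)) next
    idx <- which(keep)
    out[[ch]] <- do.call(rbind, lapply(idx, function(i) {
      js <- lo[i]:hi[i]
      data.frame(cpg = cp$probe_id[i], gene = gn$gene_id[js],
                 distance = cp$pos[i] - gn$tss[js],
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(cpg = character(), gene = character(),
                                      distance = integer())
  rownames(res) <- NULL
  res
}

#' CpG-expression Spearman correlations with cross-cohort replication
#'
#' For each subtype stratum within each cohort, computes Spearman's rho
#' (midranks for ties) between each pair's CpG beta values and gene
#' expression, adjusts p-values by BH within the (cohort, subtype) family,
#' and flags a pair replicated for a subtype when its FDR falls below
#' `fdr` in at least `min_cohorts` cohorts. Strata with fewer than
#' `min_samples` samples are skipped.
#'
#' @param beta_list,expr_list Per-cohort probes x samples beta and genes x
#'   samples expression matrices (aligned samples).
#' @param pairs Data frame from [cpg_gene_pairs()] (columns cpg, gene).
#' @param labels_list Per-cohort named subtype label vectors.
#' @param subtypes Strata to analyze (default LOAD-S1/LOAD-S2).
#' @param fdr,min_cohorts Replication rule (defaults 0.1 and 2).
#' @param min_samples Minimum stratum size (default 5).
#' @return List: `correlations` (long frame: cohort, subtype, cpg, gene, rho,
#'   p, fdr), `replicated` (pair x subtype flags).
#' @export
correlate_cpg_expression <- function(beta_list, expr_list, pairs, labels_list,
                                     subtypes = c("LOAD-S1", "LOAD-S2"),
                                     fdr = 0.1, min_cohorts = 2L,
                                     min_samples = 5L) {
  rows <- list()
  for (co in seq_along(beta_list)) {
    labs <- labels_list[[co]]
    for (st in subtypes) {
      ids <- names(labs)[!is.na(labs) & labs == st]
      ids <- intersect(intersect(ids, colnames(beta_list[[co]])),
                       colnames(expr_list[[co]]))
      if (length(ids) < min_samples) next
      ok <- pairs$cpg %in% rownames(beta_list[[co]]) &
        pairs$gene %in% rownames(expr_list[[co]])
      pp <- pairs[ok, , drop = FALSE]
      if (nrow(pp) == 0) next
      stat <- t(vapply(seq_len(nrow(pp)), function(i) {
        ct <- suppressWarnings(stats::cor.test(
          beta_list[[co]][pp$cpg[i], ids], expr_list[[co]][pp$gene[i], ids],
          method = "spearman"))
        c(unname(ct$estimate), ct$p.value)
      }, numeric(2)))
      rows[[length(rows) + 1]] <- data.frame(
        cohort = co, subtype = st, cpg = pp$cpg, gene = pp$gene,
        rho = stat[, 1], p = stat[, 2],
        fdr = stats::p.adjust(stat[, 2], method = "BH"),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) stop("no stratum reached the minimum sample size")
  key <- paste(long$cpg, long$gene, long$subtype, sep = "\r")
  n_rep <- tapply(long$fdr < fdr, key, sum)
  uk <- strsplit(names(n_rep), "\r", fixed = TRUE)
  replicated <- data.frame(cpg = vapply(uk, `[`, "", 1),
                           gene = vapply(uk, `[`, "", 2),
                           subtype = vapply(uk, `[`, "", 3),
                           n_significant = as.integer(n_rep),
                           replicated = as.integer(n_rep) >= min_cohorts,
                           stringsAsFactors = FALSE)
  rownames(replicated) <- NULL
  list(correlations = long, replicated = replicated)
}
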
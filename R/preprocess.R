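#' Residualize a methylation matrix against sample covariates
#'
#' Fits an ordinary least squares model per probe (row) on the supplied
#' covariates, always including an intercept, and returns the residuals. This
#' is the pre-clustering adjustment that removes age, sex, cell-composition
#' and technical batch structure from the beta matrix.
#'
#' @param beta Probes x samples numeric matrix (beta values in (0,1), or any
#'   real matrix such as M-values).
#' @param covariates Data frame with one row per sample, in column order of
#'   `beta`. Factors/characters are expanded to dummy columns via
#'   [stats::model.matrix()].
#' @param as_mvalues If `TRUE`, logit-transform `beta` before residualizing.
#' @return Probes x samples residual matrix with attribute
#'   `design_columns` naming the regressed covariate columns.
#' @export
residualize <- function(beta, covariates, as_mvalues = FALSE) {
  beta <- as.matrix(beta)
  if (nrow(covariates) != ncol(beta))
    stop("covariates must have one row per sample (column of beta)")
  if (anyNA(covariates))
    stop("missing covariate values: ",
         paste(names(covariates)[colSums(is.na(covariates)) > 0], collapse = ", "))
  covariates <- as.data.frame(covariates)
  X <- if (ncol(covariates) == 0) matrix(1, nrow(covariates), 1,
                                         dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  Y <- if (as_mvalues) logit(beta) else beta
  res <- t(qr.resid(qx, t(Y)))
  dimnames(res) <- dimnames(beta)
  attr(res, "design_columns") <- colnames(X)
  res
}

#' Filter probes by a robust spread statistic
#'
#' The per-probe spread is the 90th percentile of absolute deviations from the
#' probe median across samples (linear interpolation between order
#' statistics). Probes whose spread exceeds the `spread_quantile` quantile of
#' the spread distribution are retained; with `spread_quantile = 0` every
#' probe with strictly positive spread is retained.
#'
#' @param residuals Probes x samples numeric matrix.
#' @param spread_quantile Retention cutoff as a quantile of the spread
#'   statistic across probes, in [0, 1).
#' @param deviation_percentile Percentile of absolute deviations used as the
#'   spread statistic (default 0.9).
#' @return The retained rows of `residuals`; attributes `spread` (named
#'   statistic for all input probes) and `n_retained`.
#' @export
filter_most_variable <- function(residuals, spread_quantile = 0.5,
                                 deviation_percentile = 0.9) {
  if (spread_quantile < 0 || spread_quantile >= 1)
    stop("spread_quantile must lie in [0, 1)")
  residuals <- as.matrix(residuals)
  if (ncol(residuals) < 2) stop("need at least 2 samples")
  med <- apply(residuals, 1, stats::median)
  spread <- apply(abs(residuals - med), 1, stats::quantile,
                  probs = deviation_percentile, names = FALSE)
  cutoff <- if (spread_quantile == 0) 0 else
    stats::quantile(spread, spread_quantile, names = FALSE)
  keep <- spread > cutoff
  out <- residuals[keep, , drop = FALSE]
  attr(out, "spread") <- stats::setNames(spread, rownames(residuals))
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Restrict a probe matrix to a platform probe list
#'
#' Row subset preserving the original probe order, e.g. to intersect an
#' EPIC-derived matrix with the probes available on a 450K-like platform.
#'
#' @param residuals Probes x samples matrix with probe ids as rownames.
#' @param probe_list Character vector of probe ids to keep.
#' @return The intersected matrix, rows in original order.
#' @export
intersect_platform <- function(residuals, probe_list) {
  if (length(probe_list) == 0) stop("probe_list is empty")
  keep <- rownames(residuals) %in% probe_list
  if (!any(keep)) stop("no overlap between matrix probes and probe_list")
  residuals[keep, , drop = FALSE]
}
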
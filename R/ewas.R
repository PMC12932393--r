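#' Estimate surrogate variables by permutation parallel analysis
#'
#' Removes the outcome and known covariates from the data, then compares the
#' singular-value spectrum of the residual matrix with spectra of matrices
#' whose rows are independently permuted across samples. The number of
#' surrogates is the number of leading eigenvalues exceeding the permutation
#' 95th percentile (counted consecutively from the first); the surrogates are
#' the corresponding right singular vectors.
#'
#' @param dat Probes x samples matrix.
#' @param outcome Numeric or factor outcome per sample.
#' @param covariates Data frame of known covariates (may be NULL).
#' @param n_perm Number of permutations (default 20).
#' @param seed Integer seed.
#' @param max_sv Upper bound on the number of surrogates returned.
#' @return Samples x n_sv matrix (possibly 0 columns) with attribute
#'   `eigenvalues`.
#' @export
estimate_svs <- function(dat, outcome, covariates = NULL, n_perm = 20L,
                         seed = 1L, max_sv = 10L) {
  dat <- as.matrix(dat)
  n <- ncol(dat)
  cov_df <- data.frame(.outcome = outcome)
  if (!is.null(covariates)) cov_df <- cbind(cov_df, covariates)
  if (n < ncol(cov_df) + 3) stop("too few samples for surrogate estimation")
  res <- residualize(dat, cov_df)
  res <- res - rowMeans(res)
  k <- min(max_sv, n - 1, nrow(res))
  sv <- svd(res, nu = 0, nv = k)
  # eigenvalues as fractions of the trace, so the comparison with the
  # permutation null is insensitive to total-variance differences
  ev <- sv$d[seq_len(k)]^2 / sum(res^2)
  null_ev <- with_seed(stream_seed(seed, 7L), {
    replicate(n_perm, {
      # permute each probe independently, then re-residualize by the same
      # design so observed and null spectra live in spaces of equal rank
      perm <- residualize(t(apply(res, 1, sample)), cov_df)
      perm <- perm - rowMeans(perm)
      svd(perm, nu = 0, nv = 0)$d[seq_len(k)]^2 / sum(perm^2)
    })
  })
  thresh <- apply(null_ev, 1, stats::quantile, probs = 0.95)
  sig <- ev > thresh
  n_sv <- if (!sig[1]) 0L else which(c(!sig, TRUE))[1] - 1L
  out <- sv$v[, seq_len(n_sv), drop = FALSE]
  if (n_sv > 0) colnames(out) <- paste0("SV", seq_len(n_sv))
  rownames(out) <- colnames(dat)
  attr(out, "eigenvalues") <- ev
  attr(out, "null_95") <- thresh
  out
}

#' Per-CpG regression EWAS
#'
#' Ordinary least squares of each probe on the outcome plus covariates and
#' surrogate variables; reports the outcome coefficient, its standard error,
#' z (= estimate/se) and the two-sided p-value from the t reference
#' distribution.
#'
#' @param beta Probes x samples matrix.
#' @param outcome Numeric (or 2-level factor, coded 0/1) outcome per sample.
#' @param covariates Optional data frame of covariates.
#' @param surrogates Optional samples x k matrix of surrogate variables.
#' @param cohort Cohort id stored with the result.
#' @return Data frame of class `ewas_result`: cpg, estimate, se, z, p.
#' @export
run_ewas <- function(beta, outcome, covariates = NULL, surrogates = NULL,
                     cohort = NA_character_) {
  beta <- as.matrix(beta)
  if (is.factor(outcome) || is.character(outcome)) {
    f <- factor(outcome)
    if (nlevels(f) != 2) stop("categorical outcome must have exactly 2 levels")
    outcome <- as.numeric(f) - 1
  }
  X <- cbind(`(Intercept)` = 1, outcome = outcome)
  if (!is.null(covariates))
    X <- cbind(X, stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE])
  if (!is.null(surrogates)) X <- cbind(X, as.matrix(surrogates))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design; offending columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  n <- nrow(X); pcol <- ncol(X); df <- n - pcol
  if (df < 1) stop("no residual degrees of freedom")
  coefs <- qr.coef(qx, t(beta))
  resid <- qr.resid(qx, t(beta))
  sigma2 <- colSums(resid^2) / df
  xtxinv <- chol2inv(qr.R(qx))
  v_out <- xtxinv[2, 2]
  est <- coefs["outcome", ]
  se <- sqrt(sigma2 * v_out)
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  # exact normal-quantile z of the t-based p, with the standard error
  # rescaled so estimate/se = z; downstream normal-theory pooling then stays
  # calibrated even at modest sample sizes
  z <- sign(tstat) * stats::qnorm(p / 2, lower.tail = FALSE)
  ratio <- ifelse(abs(tstat) > 1e-12, tstat / z, 1)
  out <- data.frame(cpg = rownames(beta), estimate = est, se = se * ratio,
                    z = z, p = p, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cohort") <- cohort
  attr(out, "df") <- df
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Empirical-Bayes bias and inflation correction of test statistics
#'
#' Fits a three-component normal mixture to the z-scores by a constrained EM:
#' the central component carries the largest weight and models the null
#' (bias = its mean, inflation = its standard deviation); the side components
#' absorb true signals and are constrained to lie left/right of the central
#' mean with at least its spread. Corrected statistics are
#' z' = (z - bias)/inflation, with estimates rescaled consistently
#' (est' = (est - bias * se)/inflation) at unchanged standard errors.
#'
#' @param estimates,ses Effect estimates and standard errors (or pass z-scores
#'   as `estimates` with `ses = 1`).
#' @param seed Accepted for interface stability; the EM is deterministic
#'   (moment-based initialization).
#' @param max_iter,tol EM stopping rule.
#' @param only_if_inflated When `TRUE`, statistics are corrected only for
#'   inflation actually present (the applied inflation divisor is floored at
#'   1), mirroring the assess-then-correct-if-needed workflow; the estimated
#'   `inflation` is reported either way.
#' @return Object of class `bacon_fit`: `bias`, `inflation` (estimated),
#'   `inflation_applied`, mixture parameters, and corrected `z`, `estimates`,
#'   `ses`.
#' @export
bacon_correct <- function(estimates, ses = rep(1, length(estimates)),
                          seed = 1L, max_iter = 500L, tol = 1e-8,
                          only_if_inflated = FALSE) {
  z <- estimates / ses
  if (any(!is.finite(z))) stop("non-finite z-scores")
  n <- length(z)
  if (n < 1000) warning("bacon-style correction is unreliable below ~1,000 tests")
  m0 <- stats::median(z); s0 <- stats::mad(z)
  pi_ <- c(0.9, 0.05, 0.05)
  mu <- c(m0, m0 - 3 * s0, m0 + 3 * s0)
  sd_ <- c(s0, 2 * s0, 2 * s0)
  loglik_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) pi_[k] * stats::dnorm(z, mu[k], sd_[k]),
                   numeric(n))
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    pi_ <- nk / n
    mu_new <- colSums(resp * z) / nk
    sd_new <- sqrt(colSums(resp * (z - rep(mu_new, each = n))^2) / nk)
    # constraints: side (signal) components stay well separated from the
    # central (null) component and at least as spread; without the
    # separation floor the sides absorb null tails and the inflation
    # estimate is biased low on moderate test counts
    sd_new <- pmax(sd_new, c(1e-3, sd_new[1], sd_new[1]))
    mu_new[2] <- min(mu_new[2], mu_new[1] - 4 * sd_new[1])
    mu_new[3] <- max(mu_new[3], mu_new[1] + 4 * sd_new[1])
    mu <- mu_new; sd_ <- sd_new
    if (is.finite(loglik_old) && abs(ll - loglik_old) < tol * (1 + abs(ll))) break
    loglik_old <- ll
  }
  if (it == max_iter && abs(ll - loglik_old) >= tol * (1 + abs(ll)))
    stop("EM did not converge after ", max_iter,
         " iterations (loglik ", signif(ll, 8), ")")
  central <- which.max(pi_)
  bias <- mu[central]; inflation <- sd_[central]
  applied <- if (only_if_inflated) max(1, inflation) else inflation
  z_c <- (z - bias) / applied
  structure(list(bias = bias, inflation = inflation,
                 inflation_applied = applied,
                 weights = pi_, means = mu, sds = sd_,
                 n_iter = it,
                 z = z_c,
                 estimates = (estimates - bias * ses) / applied,
                 ses = ses),
            class = "bacon_fit")
}

#' @export
print.bacon_fit <- function(x, ...) {
  cat(sprintf("bacon-style correction: bias %.4f, inflation %.4f (%d EM iterations)\n",
              x$bias, x$inflation, x$n_iter))
  invisible(x)
}

#' Inverse-variance meta-analysis of per-cohort EWAS results
#'
#' Fixed-effect pooling with weights 1/se^2; optionally DerSimonian-Laird
#' random effects (tau^2 from Cochran's Q). CpGs present in a single cohort
#' are reported unpooled and flagged. The Bonferroni family is the set of
#' CpGs entering the meta-analysis (>= 2 cohorts); the DMP flag requires a
#' Bonferroni-adjusted p below `alpha`.
#'
#' @param results List of `ewas_result` data frames (columns cpg, estimate,
#'   se), one per cohort.
#' @param method `"fixed"` (default) or `"dl"` (DerSimonian-Laird random
#'   effects).
#' @param alpha DMP threshold on the Bonferroni-adjusted p.
#' @return Data frame of class `meta_ewas`: cpg, n_cohorts, estimate, se, z,
#'   p, p_bonferroni, dmp, Q, tau2, single_cohort.
#' @export
meta_analyze <- function(results, method = c("fixed", "dl"), alpha = 0.05) {
  method <- match.arg(method)
  if (length(results) < 2) stop("need results from at least 2 cohorts")
  cpgs <- unique(unlist(lapply(results, `[[`, "cpg")))
  K <- length(results)
  est <- se <- matrix(NA_real_, length(cpgs), K)
  for (k in seq_len(K)) {
    idx <- match(results[[k]]$cpg, cpgs)
    est[idx, k] <- results[[k]]$estimate
    se[idx, k] <- results[[k]]$se
  }
  w <- 1 / se^2
  n_coh <- rowSums(!is.na(est))
  sw <- rowSums(w, na.rm = TRUE)
  fixed_est <- rowSums(w * est, na.rm = TRUE) / sw
  Q <- rowSums(w * (est - fixed_est)^2, na.rm = TRUE)
  tau2 <- rep(0, length(cpgs))
  if (method == "dl") {
    c_ <- sw - rowSums(w^2, na.rm = TRUE) / sw
    tau2 <- pmax(0, (Q - (n_coh - 1)) / c_)
    w2 <- 1 / (se^2 + tau2)
    sw2 <- rowSums(w2, na.rm = TRUE)
    pooled <- rowSums(w2 * est, na.rm = TRUE) / sw2
    pooled_se <- sqrt(1 / sw2)
  } else {
    pooled <- fixed_est
    pooled_se <- sqrt(1 / sw)
  }
  single <- n_coh < 2
  if (any(single)) {
    k1 <- apply(est[single, , drop = FALSE], 1, function(x) which(!is.na(x))[1])
    pooled[single] <- est[cbind(which(single), k1)]
    pooled_se[single] <- se[cbind(which(single), k1)]
  }
  zv <- pooled / pooled_se
  p <- 2 * stats::pnorm(-abs(zv))
  p_bonf <- rep(NA_real_, length(cpgs))
  p_bonf[!single] <- stats::p.adjust(p[!single], method = "bonferroni")
  out <- data.frame(cpg = cpgs, n_cohorts = n_coh, estimate = pooled,
                    se = pooled_se, z = zv, p = p, p_bonferroni = p_bonf,
                    dmp = !is.na(p_bonf) & p_bonf < alpha,
                    Q = Q, tau2 = tau2, single_cohort = single,
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_ewas", "data.frame")
  out
}
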
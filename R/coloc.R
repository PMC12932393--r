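#' Wakefield log approximate Bayes factor
#'
#' Single-SNP log ABF for an association summary statistic under a normal
#' prior on the effect with standard deviation `W`:
#' \deqn{\log ABF = \tfrac12 \log\frac{se^2}{se^2+W^2} +
#'       \tfrac12 z^2 \frac{W^2}{se^2+W^2}, \quad z = \beta/se.}
#'
#' @param beta,se Effect estimates and standard errors (se > 0), vectorized.
#' @param W Prior standard deviation of the true effect (default 0.15, the
#'   conventional quantitative-trait value).
#' @return Log approximate Bayes factors.
#' @export
wakefield_labf <- function(beta, se, W = 0.15) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W))
    stop("non-finite inputs")
  if (any(se <= 0)) stop("se must be positive")
  if (W < 0) stop("W must be non-negative")
  r <- W^2 / (se^2 + W^2)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

#' Build association statistics for colocalization
#'
#' Accepts either effect/se columns directly or p-value + MAF + sample-size
#' columns, from which the standard error of a standardized quantitative
#' trait effect is reconstructed as `1/sqrt(2 maf (1-maf) n)` and the effect
#' as `|z| * se` (sign unknown; the ABF depends on z^2 only).
#'
#' @param snp SNP identifiers (unique).
#' @param beta,se Effect estimates and standard errors, or `NULL`.
#' @param p,maf,n P-values, minor-allele frequencies and sample sizes, used
#'   when `beta`/`se` are absent.
#' @param trait Trait label.
#' @param mqtl_p_threshold Optional pre-selection threshold: rows with
#'   `p > threshold` are flagged (`suggestive = FALSE`) for upstream
#'   cis-mQTL filtering.
#' @return Data frame of class `assoc_stats`: snp, beta, se, trait,
#'   suggestive.
#' @export
assoc_stats <- function(snp, beta = NULL, se = NULL, p = NULL, maf = NULL,
                        n = NULL, trait = "trait",
                        mqtl_p_threshold = NULL) {
  if (anyDuplicated(snp)) stop("SNP ids must be unique per trait")
  if (is.null(beta) || is.null(se)) {
    if (is.null(p) || is.null(maf) || is.null(n))
      stop("provide either beta+se or p+maf+n")
    se <- 1 / sqrt(2 * maf * (1 - maf) * n)
    beta <- abs(stats::qnorm(p / 2)) * se
  }
  if (any(se <= 0)) stop("se must be positive")
  pv <- if (!is.null(p)) p else 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(snp = as.character(snp), beta = beta, se = se,
                    trait = trait,
                    suggestive = if (is.null(mqtl_p_threshold)) TRUE
                                 else pv <= mqtl_p_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_stats", "data.frame")
  out
}

#' Bayesian colocalization over five hypotheses
#'
#' Computes per-SNP Wakefield log ABFs for each trait and sums over the SNP
#' configurations of the five standard hypotheses in log space (H0 no
#' association; H1/H2 one trait only; H3 two distinct causal variants,
#' obtained as the cross-product sum minus the shared-SNP diagonal; H4 one
#' shared causal variant). Priors are applied per configuration and the
#' posteriors normalized.
#'
#' @param stats1,stats2 `assoc_stats` (or data frames with snp/beta/se) for
#'   the two traits; at least 2 shared SNPs required.
#' @param p1,p2,p12 Prior probabilities that a SNP is causal for trait 1
#'   only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param W Wakefield prior sd for both traits.
#' @return Object of class `coloc_posteriors`: `pp` (PP0-PP4, summing to 1),
#'   `n_snps`, `priors`, per-SNP labf sums.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W = 0.15) {
  shared <- intersect(stats1$snp, stats2$snp)
  if (length(shared) < 2) stop("need at least 2 shared SNPs")
  i1 <- match(shared, stats1$snp); i2 <- match(shared, stats2$snp)
  l1 <- wakefield_labf(stats1$beta[i1], stats1$se[i1], W)
  l2 <- wakefield_labf(stats2$beta[i2], stats2$se[i2], W)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over i != j of exp(l1_i + l2_j) = (sum_i)(sum_j) - diagonal
  s3 <- logdiffexp(s1 + s2, s12)
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s3,
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12, W = W),
                 labf_sums = c(s1 = s1, s2 = s2, s12 = s12, s3 = s3)),
            class = "coloc_posteriors")
}

#' @export
print.coloc_posteriors <- function(x, ...) {
  cat("Colocalization posteriors over", x$n_snps, "shared SNPs\n")
  print(round(x$pp, 4))
  cat("colocalized (PP3+PP4 > 0.90):", colocalized(x), "\n")
  invisible(x)
}

#' Colocalization decision rule
#'
#' The combined posterior of a shared genomic signal (distinct or shared
#' causal variant) must exceed the threshold: PP3 + PP4 > 0.90 by default.
#' `rule = "h4"` applies the common H4-only convention instead.
#'
#' @param posteriors A [coloc_abf()] result.
#' @param rule `"h3h4"` (default) or `"h4"`.
#' @param threshold Posterior threshold (default 0.90).
#' @return Logical.
#' @export
colocalized <- function(posteriors, rule = c("h3h4", "h4"), threshold = 0.90) {
  rule <- match.arg(rule)
  pp <- posteriors$pp
  if (rule == "h3h4") unname(pp["PP3"] + pp["PP4"] > threshold)
  else unname(pp["PP4"] > threshold)
}
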
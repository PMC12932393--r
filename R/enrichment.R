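# Conditional MLE of the noncentral hypergeometric odds ratio for the 2x2
# table with x = |A n B|, margins K = |A|, n = |B|, universe N. This is the
# odds ratio classically reported alongside Fisher's exact test: the score
# equation E_psi[X] = x is solved on the same bounded parametrization and at
# the same root tolerance as the classical implementation, so printed values
# are reproduced digit for digit.
conditional_mle_or <- function(x, K, n, N) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  if (x < lo || x > hi) stop("overlap outside the feasible support")
  if (x == hi && x == lo) return(NA_real_)   # degenerate support
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  support <- lo:hi
  base_lp <- lchoose(K, support) + lchoose(N - K, n - support)
  cond_mean <- function(psi) {
    if (psi == 0) return(lo)
    if (is.infinite(psi)) return(hi)
    lp <- base_lp + support * log(psi)
    lp <- lp - max(lp)
    w <- exp(lp)
    sum(support * w) / sum(w)
  }
  mu1 <- cond_mean(1)
  if (mu1 == x) return(1)
  if (mu1 > x)
    stats::uniroot(function(t) cond_mean(t) - x, c(0, 1))$root
  else
    1 / stats::uniroot(function(t) cond_mean(1 / t) - x,
                       c(.Machine$double.eps, 1))$root
}

#' Set-overlap enrichment with a conditional-MLE odds ratio
#'
#' Builds the 2x2 overlap table of two sets within a universe, computes the
#' one-sided (enrichment) hypergeometric p-value, and estimates the odds
#' ratio as the conditional maximum-likelihood estimate of the noncentral
#' hypergeometric model, the value classically reported by Fisher's exact
#' test.
#'
#' @param setA,setB Character vectors, subsets of `universe`.
#' @param universe Character vector defining the background.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return List of class `overlap_result`: `table` (named counts), `odds_ratio`,
#'   `p`, `overlap`, sizes.
#' @export
fisher_overlap <- function(setA, setB, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  N <- length(universe); K <- length(setA); n <- length(setB)
  x <- length(intersect(setA, setB))
  tab <- c(in_both = x, A_only = K - x, B_only = n - x,
           neither = N - K - n + x)
  if (K == 0 || n == 0) {
    return(structure(list(table = tab, odds_ratio = NA_real_, p = 1,
                          overlap = x, universe_size = N),
                     class = "overlap_result"))
  }
  p_greater <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  p <- if (alternative == "greater") p_greater else
    stats::fisher.test(matrix(tab, 2, 2))$p.value
  structure(list(table = tab, odds_ratio = conditional_mle_or(x, K, n, N),
                 p = p, overlap = x, universe_size = N),
            class = "overlap_result")
}

#' Set-overlap enrichment from printed counts
#'
#' Same statistic as [fisher_overlap()] but starting from the four counts of
#' a published overlap (overlap size, two set sizes, universe size) rather
#' than explicit id vectors.
#'
#' @param overlap,size_a,size_b,universe_size Non-negative integers with
#'   `overlap <= min(size_a, size_b)` and sets within the universe.
#' @inheritParams fisher_overlap
#' @return An `overlap_result` (see [fisher_overlap()]).
#' @export
fisher_overlap_counts <- function(overlap, size_a, size_b, universe_size,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(overlap >= 0, overlap <= min(size_a, size_b),
            size_a <= universe_size, size_b <= universe_size)
  tab <- c(in_both = overlap, A_only = size_a - overlap,
           B_only = size_b - overlap,
           neither = universe_size - size_a - size_b + overlap)
  if (any(tab < 0)) stop("counts are inconsistent with the universe size")
  p_greater <- stats::phyper(overlap - 1, size_a, universe_size - size_a,
                             size_b, lower.tail = FALSE)
  p <- if (alternative == "greater") p_greater else
    stats::fisher.test(matrix(tab, 2, 2))$p.value
  structure(list(table = tab,
                 odds_ratio = conditional_mle_or(overlap, size_a, size_b,
                                                 universe_size),
                 p = p, overlap = overlap, universe_size = universe_size),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of A=%d, B=%d in universe %d; OR %.2f, p %.3g\n",
              x$overlap, x$table[1] + x$table[2], x$table[1] + x$table[3],
              x$universe_size, x$odds_ratio, x$p))
  invisible(x)
}

#' Regulatory-feature enrichment of CpG sets
#'
#' Assigns each universe CpG to regulatory intervals (0-based half-open BED
#' convention) and tests each feature for enrichment of each CpG set against
#' the background by [fisher_overlap()], with BH correction across features
#' within each set.
#'
#' @param cpg_sets Named list of CpG id vectors (e.g. per subtype).
#' @param peaks Data frame with `chr`, `start`, `end` (0-based half-open) and
#'   `feature`.
#' @param universe Data frame with `probe_id`, `chr`, `pos` (0-based) for the
#'   background CpGs.
#' @return Data frame: set, feature, overlap, odds_ratio, p, p_adj.
#' @export
regulatory_enrichment <- function(cpg_sets, peaks, universe) {
  if (any(peaks$start >= peaks$end))
    stop("malformed intervals: start must be < end (0-based half-open)")
  cpg_gr <- GenomicRanges::GRanges(universe$chr,
                                   IRanges::IRanges(universe$pos + 1, width = 1))
  rows <- list()
  for (set_name in names(cpg_sets)) {
    feats <- unique(peaks$feature)
    res <- lapply(feats, function(f) {
      pk <- peaks[peaks$feature == f, , drop = FALSE]
      pk_gr <- GenomicRanges::GRanges(pk$chr, IRanges::IRanges(pk$start + 1, pk$end))
      hit <- IRanges::overlapsAny(cpg_gr, pk_gr)
      fo <- fisher_overlap(cpg_sets[[set_name]], universe$probe_id[hit],
                           universe$probe_id)
      data.frame(set = set_name, feature = f, overlap = fo$overlap,
                 odds_ratio = fo$odds_ratio, p = fo$p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    rows[[set_name]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type CpG-panel enrichment
#'
#' Tests DMP sets against cell-type reference CpG panels stratified by
#' specificity level, with BH correction within the panel family.
#'
#' @param dmps Character vector of DMP CpG ids.
#' @param panels Data frame with `cpg_id`, `cell_type`, `level`.
#' @param universe Character vector of background CpG ids.
#' @return Data frame: cell_type, level, overlap, odds_ratio, p, p_adj.
#' @export
celltype_enrichment <- function(dmps, panels, universe) {
  if (!all(panels$cpg_id %in% universe))
    stop("panels must be subsets of the universe")
  combos <- unique(panels[, c("cell_type", "level")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- panels$cell_type == combos$cell_type[i] & panels$level == combos$level[i]
    fo <- fisher_overlap(dmps, panels$cpg_id[sel], universe)
    data.frame(cell_type = combos$cell_type[i], level = combos$level[i],
               overlap = fo$overlap, odds_ratio = fo$odds_ratio, p = fo$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
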
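#' Discovery and cross-cohort replication of methylation subtypes
#'
#' Runs the full per-cohort discovery and cross-cohort replication pipeline:
#' covariate residualization, variability filtering, dual clustering
#' (Ward-D2 hierarchical and k-means) of the LOAD samples with k chosen by
#' hierarchical/k-means NMI agreement (elbow curves reported alongside),
#' consensus labeling, median-profile correlation block matching across
#' cohorts, convex-hull sPLS-DA replication for every ordered cohort pair
#' under both clustering methods, and the final confirmation rule. A subtype
#' is confirmed only when its block is a mutual-best-match correlation triple
#' and every hull test within the triple is significant under both methods;
#' samples outside confirmed blocks are called Unassigned.
#'
#' @param beta List of probes x samples beta matrices, one per cohort.
#' @param samples List of per-cohort sample annotation frames with at least
#'   `sample_id` and `diagnosis` ("Control"/"LOAD") plus the covariate
#'   columns.
#' @param covariate_cols Covariates residualized out before clustering.
#' @param k_range Candidate numbers of clusters.
#' @param spread_quantile Variability-filter cutoff (see
#'   [filter_most_variable()]).
#' @param n_components,keep_per_component sPLS-DA parameters for the hull
#'   stage. `keep_per_component = NULL` (default) selects
#'   `min(2000, max(50, round(0.015 * n_shared_probes)))`: at full array
#'   scale this reproduces the conventional 2000 features per component,
#'   while at reduced scale it keeps the selection comparably sparse so
#'   projections are not dominated by noise features.
#' @param alpha Significance level for the BH-adjusted hull tests.
#' @param min_shared Minimum shared probes across cohorts.
#' @param seed Integer seed (k-means restarts).
#' @return Object of class `subtype_result`: `calls` (per-sample subtype
#'   call), `assignments`, `k_selection`, `elbow`, `blocks` (with confirmation
#'   flags), `correlations`, `hull_results` and the probe sets used.
#' @export
subtype_pipeline <- function(beta, samples,
                             covariate_cols = c("age", "sex", "prop_neuron", "batch"),
                             k_range = 2:5,
                             spread_quantile = 0.5,
                             n_components = 6L, keep_per_component = NULL,
                             alpha = 0.05, min_shared = 100L, seed = 1L) {
  n_coh <- length(beta)
  if (n_coh != length(samples)) stop("beta and samples must align per cohort")
  if (is.null(names(beta))) names(beta) <- paste0("cohort", seq_len(n_coh))
  k_range <- sort(unique(as.integer(k_range)))

  resid <- filtered <- vector("list", n_coh)
  assignments <- ksel <- elbow <- vector("list", n_coh)
  names(resid) <- names(filtered) <- names(assignments) <-
    names(ksel) <- names(elbow) <- names(beta)

  for (co in seq_len(n_coh)) {
    ann <- samples[[co]]
    stopifnot(all(c("sample_id", "diagnosis") %in% names(ann)))
    b <- beta[[co]][, ann$sample_id, drop = FALSE]
    resid[[co]] <- residualize(b, ann[, covariate_cols, drop = FALSE])
    filtered[[co]] <- filter_most_variable(resid[[co]], spread_quantile)

    load_ids <- ann$sample_id[ann$diagnosis == "LOAD"]
    X <- t(filtered[[co]][, load_ids, drop = FALSE])
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    hl_all <- stats::cutree(hc, k = k_range)
    km_all <- lapply(k_range, function(k) kmeans_cluster(X, k, seed = stream_seed(seed, co)))
    nmi_k <- vapply(seq_along(k_range), function(i)
      nmi(hl_all[, i], km_all[[i]]), numeric(1))
    wcss_h <- vapply(seq_along(k_range), function(i) wcss_of(X, hl_all[, i]), numeric(1))
    wcss_k <- vapply(km_all, function(l) wcss_of(X, l), numeric(1))
    # elbow strength per k: second forward difference of the WCSS curve,
    # extended to k = 1 (total centered SS) so the smallest candidate has an
    # interior difference; used to arbitrate NMI ties
    wcss_below <- if (min(k_range) <= 2L) wcss_of(X, rep(1L, nrow(X))) else
      wcss_of(X, stats::cutree(hc, k = min(k_range) - 1L))
    wcss_above <- wcss_of(X, stats::cutree(hc, k = max(k_range) + 1L))
    wcss_ext <- c(wcss_below, wcss_h, wcss_above)
    lw <- log(wcss_ext)
    d2 <- lw[seq_along(k_range)] - 2 * lw[seq_along(k_range) + 1L] +
      lw[seq_along(k_range) + 2L]
    tied <- which(nmi_k > max(nmi_k) - 1e-10)
    chosen_i <- tied[which.max(d2[tied])]
    ksel[[co]] <- structure(
      list(k_range = k_range,
           nmi_per_k = stats::setNames(nmi_k, k_range),
           elbow_strength = stats::setNames(d2, k_range),
           chosen_k = k_range[chosen_i], flagged = max(nmi_k) < 0.3),
      class = "k_selection_nmi")
    elbow[[co]] <- list(k_range = k_range, wcss_hierarchical = wcss_h,
                        wcss_kmeans = wcss_k, second_diff = d2)
    hl <- stats::setNames(hl_all[, chosen_i], load_ids)
    kl <- stats::setNames(km_all[[chosen_i]], load_ids)
    assignments[[co]] <- consensus_labels(hl, kl)
  }

  shared <- Reduce(intersect, lapply(filtered, rownames))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " probes shared across cohorts after filtering")

  # anchor every cohort's residuals to its own controls before any
  # cross-cohort comparison: per-cohort OLS centers each probe on the full
  # cohort mean, which depends on the cohort's cluster composition, whereas
  # the control population is comparable across cohorts
  anchored <- lapply(seq_len(n_coh), function(co) {
    ctrl <- samples[[co]]$sample_id[samples[[co]]$diagnosis == "Control"]
    if (length(ctrl) == 0) return(resid[[co]])
    resid[[co]] - rowMeans(resid[[co]][, ctrl, drop = FALSE])
  })

  profiles <- lapply(seq_len(n_coh), function(co) {
    a <- assignments[[co]]
    labs <- stats::setNames(a$consensus_label, a$sample_id)
    cluster_median_profiles(anchored[[co]][shared, , drop = FALSE], labs[!is.na(labs)])
  })
  names(profiles) <- names(beta)
  correlations <- correlate_profiles(profiles, min_shared = min_shared)
  blocks <- match_blocks(correlations)

  keepx <- if (is.null(keep_per_component))
    min(2000L, max(50L, round(0.015 * length(shared))))
  else min(keep_per_component, length(shared))
  hull_results <- list(hierarchical = list(), kmeans = list())
  label_sets <- list(
    hierarchical = lapply(assignments, function(a)
      stats::setNames(LETTERS[a$hierarchical_label], a$sample_id)),
    kmeans = lapply(assignments, function(a)
      stats::setNames(LETTERS[a$kmeans_label], a$sample_id)))
  empty_hull <- structure(
    list(tests = data.frame(replication_cluster = character(),
                            discovery_hull = character(), inside = integer(),
                            outside = integer(), hull_total = integer(),
                            n_total = integer(), p = numeric(),
                            p_adj = numeric(), stringsAsFactors = FALSE)),
    class = "hull_replication")
  for (m in names(label_sets)) {
    for (d in seq_len(n_coh)) for (r in seq_len(n_coh)) {
      if (d == r) next
      labs_d <- label_sets[[m]][[d]]
      # clusters below 3 samples cannot support a hull; drop them from the
      # discovery side (their blocks then simply fail confirmation)
      ok_cl <- names(table(labs_d))[table(labs_d) >= 3]
      labs_d <- labs_d[labs_d %in% ok_cl]
      key <- paste(names(beta)[d], names(beta)[r], sep = "|")
      if (length(unique(labs_d)) < 2) {
        hull_results[[m]][[key]] <- empty_hull
        next
      }
      Xd <- t(anchored[[d]][shared, names(labs_d), drop = FALSE])
      Xr <- t(anchored[[r]][shared, names(label_sets[[m]][[r]]), drop = FALSE])
      hull_results[[m]][[key]] <- tryCatch(
        hull_replication(Xd, labs_d, Xr, label_sets[[m]][[r]],
                         n_components = n_components,
                         keep_per_component = keepx),
        error = function(e) {
          warning("hull rotation ", key, " (", m, ") failed: ",
                  conditionMessage(e))
          empty_hull
        })
    }
  }

  blocks <- confirm_subtypes(blocks, hull_results, alpha = alpha)
  confirmed <- blocks[blocks$confirmed, , drop = FALSE]
  if (nrow(confirmed)) {
    confirmed <- confirmed[order(confirmed[[1]]), , drop = FALSE]
    confirmed$subtype <- paste0("LOAD-S", seq_len(nrow(confirmed)))
  }

  calls <- do.call(rbind, lapply(seq_len(n_coh), function(co) {
    ann <- samples[[co]]
    a <- assignments[[co]]
    lab <- stats::setNames(a$consensus_label, a$sample_id)
    call <- ifelse(ann$diagnosis == "Control", "Control", "Unassigned")
    if (nrow(confirmed)) {
      for (b in seq_len(nrow(confirmed))) {
        hit <- !is.na(lab[ann$sample_id]) &
          lab[ann$sample_id] == confirmed[b, names(beta)[co]] &
          ann$diagnosis == "LOAD"
        call[hit] <- confirmed$subtype[b]
      }
    }
    data.frame(sample_id = ann$sample_id, cohort = names(beta)[co],
               call = call, stringsAsFactors = FALSE)
  }))

  structure(list(calls = calls, assignments = assignments,
                 k_selection = ksel, elbow = elbow, blocks = blocks,
                 confirmed = if (nrow(confirmed)) confirmed else blocks[0, ],
                 correlations = correlations, hull_results = hull_results,
                 shared_probes = shared,
                 params = list(k_range = k_range, alpha = alpha,
                               n_components = n_components,
                               keep_per_component = keepx, seed = seed)),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("Cross-cohort methylation subtype result\n")
  cat("  cohorts:", length(x$assignments),
      "| shared probes:", length(x$shared_probes), "\n")
  cat("  chosen k:", paste(vapply(x$k_selection, `[[`, 1L, "chosen_k"),
                           collapse = ", "), "\n")
  cat("  confirmed subtypes:", nrow(x$confirmed), "\n")
  print(table(x$calls$call))
  invisible(x)
}

#' @export
summary.subtype_result <- function(object, ...) {
  print(object)
  cat("\nBlocks:\n")
  print(object$blocks)
  invisible(object)
}
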
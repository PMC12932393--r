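#' Fit a sparse PLS discriminant analysis model
#'
#' Labels are dummy-coded and features centered/scaled; per component the
#' dominant direction of \eqn{X'Y Y'X} is computed (first left singular vector
#' of \eqn{X'Y}), sparsified by soft-thresholding so that exactly
#' `keep_per_component` largest-magnitude entries remain, and renormalized to
#' unit norm. Scores are `X w`; X and Y are deflated by regression on the
#' scores. A regression-form rotation matrix (weights corrected for loadings)
#' is stored so projecting the training data reproduces the training scores
#' exactly.
#'
#' @param X Samples x features numeric matrix with feature names.
#' @param labels Class labels, one per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param n_components Number of latent components (default 6).
#' @param keep_per_component Number of features retained per component
#'   (default 2000, capped at the number of usable features).
#' @return Object of class `splsda_fit` with weights, loadings, rotation,
#'   training scores, means/sds and class levels.
#' @export
fit_splsda <- function(X, labels, n_components = 6L, keep_per_component = 2000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) {
    warning(sum(sds < 1e-12), " constant feature(s) dropped")
    X <- X[, sds >= 1e-12, drop = FALSE]
    sds <- sds[sds >= 1e-12]
  }
  keep_per_component <- min(keep_per_component, ncol(X))
  mus <- colMeans(X)
  Xc <- scale(X, center = mus, scale = sds)
  Y <- stats::model.matrix(~ labels - 1)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  p <- ncol(Xc); g <- ncol(Yc)
  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(X), paste0("comp", seq_len(n_components))))
  Xd <- Xc; Yd <- Yc
  for (h in seq_len(n_components)) {
    M <- crossprod(Xd, Yd)
    w <- svd(M, nu = 1, nv = 0)$u[, 1]
    if (keep_per_component < p) {
      thr <- sort(abs(w), decreasing = TRUE)[keep_per_component + 1]
      w <- sign(w) * pmax(abs(w) - thr, 0)
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate component ", h, ": all weights thresholded away")
    w <- w / nw
    tt <- Xd %*% w
    ss <- sum(tt^2)
    pl <- crossprod(Xd, tt) / ss
    dl <- crossprod(Yd, tt) / ss
    Xd <- Xd - tt %*% t(pl)
    Yd <- Yd - tt %*% t(dl)
    W[, h] <- w; P[, h] <- pl
  }
  R <- W %*% solve(crossprod(P, W))
  dimnames(R) <- dimnames(W)
  scores <- Xc %*% R
  rownames(scores) <- rownames(X)
  structure(list(weights = W, x_loadings = P, rotation = R, scores = scores,
                 feature_means = mus, feature_sds = sds,
                 n_components = n_components,
                 keep_per_component = keep_per_component,
                 class_levels = levels(labels), labels = labels),
            class = "splsda_fit")
}

#' @export
print.splsda_fit <- function(x, ...) {
  cat("sPLS-DA fit:", x$n_components, "components, keepX",
      x$keep_per_component, "per component\n")
  cat("  classes:", paste(x$class_levels, collapse = ", "), "\n")
  cat("  selected features (union):", length(selected_features(x)$union), "\n")
  invisible(x)
}

#' Selected features of a sPLS-DA model
#'
#' @param model A fitted [fit_splsda()] object.
#' @return List with `per_component` (nonzero-support feature names per
#'   component) and their `union`.
#' @export
selected_features <- function(model) {
  per <- lapply(seq_len(model$n_components), function(h)
    names(which(model$weights[, h] != 0)))
  names(per) <- colnames(model$weights)
  list(per_component = per, union = unique(unlist(per)))
}

#' Project new samples into a fitted sPLS-DA latent space
#'
#' New data are restricted to the features shared with the model, scaled with
#' the training means/sds, and multiplied by the rotation restricted to the
#' shared features; each component column is renormalized by the ratio of
#' full-to-restricted rotation norms so that a complete feature set reproduces
#' training scores exactly. Fails when fewer than `min_shared` of the model's
#' selected features are available.
#'
#' @param model A [fit_splsda()] object.
#' @param X_new Samples x features matrix (named columns).
#' @param min_shared Minimum fraction of selected features that must be
#'   present (default 0.5).
#' @return Samples x components score matrix.
#' @export
project_splsda <- function(model, X_new, min_shared = 0.5) {
  X_new <- as.matrix(X_new)
  shared <- intersect(names(model$feature_means), colnames(X_new))
  sel <- selected_features(model)$union
  cover <- length(intersect(sel, shared)) / length(sel)
  if (cover < min_shared)
    stop(sprintf("only %.0f%% of selected features shared; projection unreliable",
                 100 * cover))
  Xs <- scale(X_new[, shared, drop = FALSE],
              center = model$feature_means[shared],
              scale = model$feature_sds[shared])
  Rs <- model$rotation[shared, , drop = FALSE]
  full_norm <- sqrt(colSums(model$rotation^2))
  sub_norm <- sqrt(colSums(Rs^2))
  fac <- ifelse(sub_norm > 1e-12, full_norm / sub_norm, 0)
  scores <- Xs %*% Rs
  sweep(scores, 2, fac, `*`)
}

#' @export
predict.splsda_fit <- function(object, newdata, ...) {
  project_splsda(object, newdata, ...)
}

#' Label-randomization robustness of sPLS-DA feature selection
#'
#' Refits the model after permuting the labels of a random fraction of
#' samples, over a grid of fractions and repeats, and records the overlap of
#' the selected-feature union with the reference model's union. Permutations
#' that would leave a class with fewer than two samples are resampled.
#'
#' @inheritParams fit_splsda
#' @param proportions Fractions of samples whose labels are permuted
#'   (default 1.00 down to 0.01).
#' @param n_repeats Repeats per proportion (default 10).
#' @param seed Integer seed.
#' @return Object of class `robustness_curve`: `overlap` (repeats x
#'   proportions matrix), `proportions`, `mean_overlap`.
#' @export
randomization_robustness <- function(X, labels, n_components = 6L,
                                     keep_per_component = 2000L,
                                     proportions = c(1, 0.75, 0.5, 0.25, 0.1, 0.05, 0.01),
                                     n_repeats = 10L, seed = 1L) {
  labels <- factor(labels)
  ref <- fit_splsda(X, labels, n_components, keep_per_component)
  ref_sel <- selected_features(ref)$union
  n <- length(labels)
  overlap <- matrix(NA_real_, n_repeats, length(proportions),
                    dimnames = list(NULL, paste0("p", proportions)))
  for (j in seq_along(proportions)) {
    pj <- proportions[j]
    for (r in seq_len(n_repeats)) {
      labs <- with_seed(stream_seed(seed, j * 1000L + r), {
        for (try in 1:50) {
          l2 <- labels
          idx <- sample.int(n, round(pj * n))
          l2[idx] <- sample(l2[idx])
          if (all(table(l2) >= 2)) break
        }
        if (any(table(l2) < 2)) stop("could not draw a valid label permutation")
        l2
      })
      fit <- fit_splsda(X, labs, n_components, keep_per_component)
      sel <- selected_features(fit)$union
      overlap[r, j] <- length(intersect(sel, ref_sel)) / length(ref_sel)
    }
  }
  structure(list(overlap = overlap, proportions = proportions,
                 mean_overlap = colMeans(overlap)),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("sPLS-DA label-randomization robustness\n")
  print(round(rbind(proportion = x$proportions, mean_overlap = x$mean_overlap), 3))
  invisible(x)
}
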